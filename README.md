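# mixbn

Bayesian-network analysis of mixed discrete/continuous cohort data
with missing values: BIC-scored structure learning, bootstrap average
networks with per-edge strength and direction, an analytic
significance threshold, network-guided nearest-neighbour imputation,
Markov-blanket queries, and genetics-based variable filtering with
weighted allele scores as causal anchors.

## Who this is for

Multi-omics cohort studies (clinical traits, metabolites, proteins,
gene expression, genotypes measured on the same individuals) routinely
face two problems when inferring variable-to-variable relationships:
no individual has complete data, and observational data alone cannot
orient most edges.  `mixbn` implements a workflow for exactly that
setting, validated end-to-end on a synthetic generator that emulates a
large multi-centre type-2-diabetes cohort (3029 individuals, 260 mixed
variables, block-missing clinical data, allele-score anchors).

## The model

Networks are scored under the conditional linear-Gaussian model:
continuous nodes are Gaussian linear regressions on their continuous
parents within each configuration of their discrete parents; discrete
nodes are multinomial; discrete nodes may not have continuous parents
(a binary trait may be *declared* continuous to lift that
restriction).  The network score is the decomposable

    BIC(G) = sum_v [ -2 loglik_v + k_v log(n) ]        (lower is better)

optimised by constrained steepest-descent hill climbing over
add/delete/reverse moves.  Uncertainty is quantified by bootstrap
model averaging: individuals are resampled with replacement, the best
network refitted per replicate, and each pair of variables tallied
into a **strength** (proportion of replicates connecting them) and a
**direction** (proportion of a given orientation when connected).  A
significance threshold on strengths is estimated analytically as the
quantile at the CDF level minimising the L1 distance between the
empirical strength CDF and the ideal noise/signal step CDF.

Missing data are handled by a two-stage scheme: random fill from each
variable's observed values, an initial best-fit network on the filled
data, then per-cell donor imputation where the donor is the nearest
neighbour over the variables adjacent to the missing one in that
initial network.  Genetic allele scores (weighted sums of risk-allele
dosages over LD-clumped significant SNPs) enter the network as
parent-only anchors, which resolves the orientation of downstream
edges.

## Worked example

The `analysis/` directory is a numbered workflow over a synthetic
cohort (600 individuals, 24 variables, 5% missing cells, not one
complete row).  Running

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_impute_missing.R
Rscript analysis/03_average_network.R
Rscript analysis/04_network_queries.R
Rscript analysis/05_genetics_allele_scores.R
```

prints, among other things:

```
cohort: 600 individuals (158 cases), 24 variables
missing cells: 5.0%; complete rows: 0
ground-truth network: 15 edges

imputed 723 cells: 245 from nearest-neighbour donors, 478 random fallback

analytic strength threshold: 0.5678 (CDF level 0.853)
average network: 102 candidate pairs; 15 edges above threshold

mean edges per parent variable: 1.15
mean edges per child variable:  1.36
true edges recovered at the analytic threshold: 100% (15 of 15)
structural Hamming distance to truth: 1
```

Read: although not a single row was complete, imputation followed by
200-replicate bootstrap averaging recovered every generating edge at
the analytically chosen threshold, with one orientation error
(SHD 1).  Stage 5 demonstrates the genetics side: a GWAS-style scan,
Bonferroni retention (≥ 20 significant SNPs), LD clumping of 33
significant SNPs to 6 independent index SNPs, and an allele score
explaining 75% of the simulated trait.

The same steps are available as one call:

```r
library(mixbn)
dl <- direct_like(seed = 1, n = 600, n_cases = 158, scale = 0.08)
res <- run_pipeline(pipeline_config(dl$data, constraints = dl$constraints,
                                    output_dir = "out", n_replicates = 200,
                                    seed = 1, blanket_nodes = dl$t2d_var))
res$strength_threshold
markov_blanket(res$edges, dl$t2d_var)
```

Every artefact is written with a JSON provenance sidecar (seeds,
parameters, config hash, package version), and rerunning a
configuration reproduces byte-identical edge tables.

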