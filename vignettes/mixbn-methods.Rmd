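---
title: "Methods: mixed-data Bayesian networks with bootstrap averaging and network-guided imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-data Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixbn)
```

# The problem

Multi-omics cohort studies measure hundreds of mixed
discrete/continuous variables — clinical traits, metabolites, proteins,
gene expression — on thousands of individuals, and ask which variables
drive which.  Bayesian networks address this by searching for a
directed acyclic graph (DAG) whose conditional independence structure
best fits the data.  Two practical obstacles dominate: such cohorts
rarely contain a single individual with complete data, and most edges
in an observational network cannot be oriented from the joint
distribution alone.  This package implements a complete workflow for
that setting: conditional linear-Gaussian network scoring and search,
bootstrap model averaging with per-edge confidence values,
network-guided nearest-neighbour imputation, genetic allele scores as
causal anchors, and a synthetic cohort generator so that the whole
pipeline can be validated without restricted data.

# The model and its score

Variables are typed by declaration, not inference: `dtype` in the
metadata decides whether a variable is modelled as Gaussian or
multinomial.  This matters for binary traits: a disease indicator can
be *declared* continuous so that continuous variables are allowed as
its parents (the conditional Gaussian model forbids continuous parents
of discrete children).  The package honours the declaration even when
a variable takes only two values.

Under the conditional linear-Gaussian (CLG) model, each continuous
node is a linear regression on its continuous parents, fitted
separately within every configuration of its discrete parents; each
discrete node is multinomial within every configuration of its
(necessarily discrete) parents.  The network score is the
decomposable BIC on the natural-log scale,

$$\mathrm{BIC}(G) = \sum_{v} \big(-2\,\ell_v + k_v \log n\big),$$

a penalised negative log-likelihood — lower is better.  Other BIC
conventions (halved, sign-flipped) rescale every family identically
and cannot change which graph wins; this one is fixed so that scores
are reproducible across runs and tests.

Two numerical choices keep scores finite on degenerate input:

* **Residual-variance floor.** A perfectly fitted family (zero
  residual variance) has unbounded likelihood.  The variance estimate
  is floored at `max(1e-12 * var(child), 1e-300)`, so exact linear
  dependencies — which synthetic data can easily produce — score very
  well but finitely.
* **Observed-configuration counting.** Parameters are counted only
  for discrete-parent configurations that actually occur: unobserved
  cells contribute neither likelihood nor parameters.  With several
  multi-level discrete parents, counting empty cells would otherwise
  inflate the penalty without bound.  A family whose MLE is undefined
  (an observed configuration with fewer rows than regression
  coefficients) is flagged invalid and scores `+Inf`, which simply
  makes the corresponding move unavailable to the search.

Family scores are cached keyed by (node, sorted parent set); the cache
is private to one dataset and rebuilt per bootstrap replicate, and by
contract a cached value always equals a fresh evaluation (a property
the test suite checks).

# Structure search

`best_fit_network()` is steepest-descent hill climbing over single-edge
moves (add, delete, reverse), starting from the empty graph plus any
required edges.  Every candidate move is screened for acyclicity, for
the declared edge constraints, and for the typing rule; the move with
the best score improvement is applied; search stops when no move
improves the score by more than `eps = 1e-9` (an absolute guard
against floating-point noise).  Ties are broken lexicographically by
(child, parent, move kind), so a climb is fully deterministic.

Greedy search has a well-known failure mode around collider
structures (`A -> C <- B` with `A` independent of `B`): the score of
the first edge addition is identical in both orientations, the tie
rule may commit to the wrong one, and no later single move can repair
it.  `random_restarts > 0` runs extra climbs from random
constraint-respecting graphs (a random node order with forward-edge
probability 0.5 — deliberately dense, because sparse random starts
tend to fall back into the same basin) and keeps the best final
score.  The default remains 0 restarts: a single deterministic climb
is the right default for bootstrap averaging, where orientation noise
is averaged out, and restart behaviour stays an explicit opt-in.

## Constraints

Constraint sets carry required and forbidden directed edges plus two
role rules: `parent_only` nodes admit no incoming edges, `no_parents`
nodes admit none at all.  The discrete-child/continuous-parent
prohibition is enforced automatically at search time rather than
stored per edge.  `allele_score_constraints()` encodes the anchoring
convention for genetic scores: the only edge an allele score may take
part in is the one towards the variable it was built for — edges into
a score, and from a score to anything else (including other scores),
are forbidden.  Whether the anchor edge is merely permitted (default)
or required is a flag, since both readings of "constrained as a
parent" are defensible; with informative scores the search keeps the
edge either way.

# Bootstrap averaging

`bootstrap_average()` resamples individuals with replacement, refits
the best network per replicate, and tallies, for each unordered pair,
the *strength* (proportion of replicates with an edge between the two
nodes, in either direction) and the *direction* (proportion of those
replicates with a given orientation).  These behave like, and are
colloquially called, posterior probabilities of edge existence and
orientation, but they are bootstrap proportions — the documentation
uses strength/direction as the primary terms.

One master seed spawns an independent seed per replicate, so results
are bit-identical however replicates are scheduled, and a replicate
can be reproduced alone.  Exact 0.5 direction ties are oriented
towards the lexicographically larger node name and flagged
`direction_unresolved` — determinism without a causal claim.

## The analytic strength threshold

An ideal average network would show strengths of exactly 0 and 1; its
empirical CDF would be flat at some level $c$ (the noise fraction) on
$[0, 1)$.  `estimate_strength_threshold()` finds the level $c$
minimising the $L_1$ distance $\int_0^1 |\hat F(x) - c|\,dx$ between
that ideal CDF and the observed one — a length-weighted median of the
step heights of $\hat F$ — and returns the corresponding $c$-quantile
of the strengths.  Edges strictly above the threshold are significant;
the strict inequality matches the convention of keeping edges whose
support *exceeds* the cut.  Two boundary cases are fixed by the same
logic: when every strength is 1 the level is 0 and the threshold is 0
(nothing is noise, everything passes), and a two-point \{0, 1\}
strength set splits exactly.  `threshold_network()` applies the
strength cut, orients each kept pair by majority, and optionally
applies an *inclusive* direction threshold (a pair exactly at the
direction cut is retained — direction values sit on a coarse grid of
multiples of $1/R$, and the display convention keeps boundary edges).

# Network-guided nearest-neighbour imputation

`impute()` implements a two-stage scheme designed around a specific
goal: not minimal per-cell error, but a completed dataset from which
the *network* can be learned accurately.

1. **Random fill.** Every missing cell is replaced by a random draw
   (with replacement) from the variable's observed values, and a
   best-fit network is learned on this provisional dataset.
2. **Donor copying.** For each individual with missing data and each
   missing variable in turn, the variables adjacent to it in the
   initial network (orientation ignored) and observed for that
   individual define a distance; the closest individual observed for
   those variables *and* the missing one donates its observed value.
   Each missing variable gets its own donor.

The distance is a mixed Gower-style metric: squared differences of
z-scored continuous values (mean/SD from observed data) plus a
squared `discrete_mismatch_cost` (default 1, i.e. one standard
deviation) per unequal discrete value, square-rooted.  The metric
lives in one function (`nearest_neighbour()`) precisely so it can be
substituted.  Donor ties go to the smallest row index.

When no donor qualifies, the nearby variable with the most
missingness is dropped and the search retried; if the nearby set
empties (or was empty — an isolated variable in the initial network),
the cell falls back to a random draw from the observed values, which
matches the stage-1 fill distribution and guarantees termination.
Under heavy block missingness a substantial share of cells can take
this fallback (co-missing neighbours disqualify donors); that is the
intended degradation, since random fills are exactly what the initial
network was learned from.  The pass is run once by default; an
iterate-to-convergence flag exists but is off, as a single pass is
the described procedure and iteration has no obvious stopping theory.

Observed cells are never modified — imputed output is bit-identical
to the input wherever the input was observed — and imputed values
always lie in the variable's observed support, both tested
invariants.

# Genetics: filtering, clumping, allele scores

The genetic module reduces a large variable panel to those with
robust genetic signal and builds the anchor variables:

* `association_scan()`: per-SNP linear regression of a trait on
  dosage plus covariates (genetic principal components are supplied
  precomputed as a covariate matrix; computing PCA is standard
  procedure outside this package's scope).  Missing dosages are
  mean-imputed per SNP; monomorphic SNPs report an undefined effect
  with p = 1; p-values are Wald tests on the t distribution.
* `bonferroni_retain()`: the threshold is the nominal level divided
  by the *total* number of tests in the scan at hand
  (variables × SNPs).  The correction scope is configurable via the
  `alpha` override since per-variable correction is also defensible.
  Metabolites and proteins need at least 20 significant SNPs;
  expression variables more than one; clinical scans use a 0.05
  level.
* `clump()`: greedy p-ascending selection of index SNPs, discarding
  unclaimed SNPs within the window whose dosage r² with the index
  exceeds the cut.  Defaults r² = 0.1 within 250 kb — conventional
  clumping settings, both exposed as arguments.
* `allele_score()`: per-individual weighted sum of risk-allele
  dosages, missing dosages contributing the SNP's mean.
* `inverse_normal_transform()`: rank-based mapping to standard-normal
  quantiles with rankit offset 0.5 (Blom's 0.375 by argument); ties
  share averaged ranks, missing values stay missing.

# The synthetic cohort generator

`simulate_model()` draws a ground-truth CLG network with variables in
the five cohort classes, class-assortative edges (same-class pairs get
80% of the connection probability mass, mirroring the strong diagonal
dominance of class-to-class edge tables in such cohorts), a parent cap,
coefficients of controlled magnitude with random sign, and allele
scores as roots with exactly one child.  Two generator details exist so
that *declared effect sizes mean what they say*: per-configuration
intercepts of continuous nodes sit on an equally spaced grid scaled by
a drawn effect (two configurations cannot collapse onto nearly equal
means), and discrete CPTs are rotations of a common base distribution
across parent configurations (columns cannot be accidentally
near-identical).  Without these, a "strong" discrete edge could be
statistically invisible, and recovery checks would measure luck rather
than the method.  `simulate_dataset()` samples ancestrally in
topological order; SNP dosages are Binomial(2, MAF) with optional
first-order LD (each SNP copies its predecessor with probability
√r²); allele-score columns are standardised by their theoretical
moments so anchor effects are on the coefficient scale.

`inject_missingness()` applies block missingness — whole
(group × variable) blocks absent, partial MCAR fractions, and an
option forcing every row to be incomplete.  The `direct_like()` preset
assembles the full emulation at its reference size: 3029 individuals
(795 cases), 260 variables in class counts 65/34/27/33/101
(clinical/metabolite/protein/expression/allele score), a binary
disease indicator thresholded to the case rate but declared
continuous, clinical variables block-missing by case/control group so
that no individual is complete, and 14 individuals missing every
protein.  A `scale` argument shrinks the class counts proportionally
for desk-scale runs.

What the generator does *not* emulate: realistic molecular network
topology beyond class assortativity, non-Gaussian continuous margins,
missingness that depends on the unobserved values (MNAR), measurement
error, or linkage between different scores' SNP sets.  Tests passing
on this generator therefore demonstrate that the machinery is correct
and well-calibrated under the model's own assumptions — they do not
certify performance on real cohort data, where faithfulness and CLG
assumptions are approximations.

# Validation design and problem sizes

The test suite pairs every operation with an independent oracle:
closed-form multinomial likelihoods, `lm()`-based Gaussian family
scores, exhaustive enumeration of all 25 three-node DAGs against the
hill climber, brute-force Markov blankets on random DAGs, hand-counted
bootstrap tallies, a grid-search minimiser for the threshold level,
and a brute-force greedy re-implementation for clumping.

Simulation studies run at sizes chosen to give stable pass/fail
behaviour while keeping the default suite fast: 20-node anchored
networks with n = 2000 and 100 bootstrap replicates for structure
recovery (effects of magnitude at least 0.5); 15-node networks with
n = 1500, five variables 25% missing with complete rows held under
5%, and 30 replicates for the imputation-value comparison (effects
0.3–0.6, deliberately in the regime where a sixty-row complete-case
subset loses power but the full sample does not); a three-node
anchored chain with the score explaining about 20% of its target's
variance for direction resolution.  The analysis scripts under
`analysis/` use a 600 × 24 scaled cohort with 200 replicates.

# Known limitations

* Hill climbing explores DAG space, not equivalence classes; without
  anchors, reversible edges carry direction values near 0.5 and only
  the anchored portions of the graph orient reliably.  This is the
  method's design: direction should be read off the bootstrap
  direction value, not off a single best fit.
* The CLG family forbids continuous parents of discrete children, so
  any real discrete-by-continuous feedback is representable only in
  the reverse orientation (the usual workaround — declaring binary
  traits continuous — is supported and used for the disease
  indicator).
* The imputation is single-donor and single-pass; it propagates no
  uncertainty, so downstream strengths do not account for imputation
  variability (consistent with its stated goal of network recovery,
  not inference on imputed values).
* Scores assume i.i.d. rows; family or cryptic relatedness structure
  is not modelled (genetic PCs absorb coarse stratification in the
  association scans only).
* The genetics module operates at desk scale (hundreds of SNPs); it
  is a faithful implementation of the filtering logic, not a
  genome-scale GWAS engine.
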