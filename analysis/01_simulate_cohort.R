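#!/usr/bin/env Rscript

# Stage 1: generate the synthetic cohort used by the rest of the
# workflow.
#
# The generator emulates the structure of a large multi-centre
# type-2-diabetes study scaled to desk size: mixed clinical / omics
# variables with class-assortative dependencies, allele scores anchoring
# molecular variables, a binary disease indicator declared continuous,
# block-missing clinical data such that no individual is complete, and a
# handful of individuals missing every protein.

library(mixbn)

dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)

dl <- direct_like(seed = 1, n = 600, n_cases = 158, scale = 0.08,
                  n_protein_missing = 4, edge_density = 0.12)

write_data(dl$data, "results/cohort/data.tsv")
write_meta(dl$data$meta, "results/cohort/metadata.tsv")
write_constraints(dl$constraints, "results/cohort/constraints.tsv")
write_edge_table(
  data.frame(edges(dl$model$dag), strength = 1, direction = 1),
  "results/cohort/truth_edges.csv")
writeLines(dl$t2d_var, "results/cohort/disease_variable.txt")

cat(sprintf("cohort: %d individuals (%d cases), %d variables\n",
            n_samples(dl$data), length(dl$case_rows),
            n_variables(dl$data)))
print(table(dl$data$meta$vclass))
cat(sprintf("missing cells: %.1f%%; complete rows: %d\n",
            100 * mean(dl$data$missing),
            sum(rowSums(dl$data$missing) == 0)))
cat(sprintf("ground-truth network: %d edges\n", n_edges(dl$model$dag)))
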