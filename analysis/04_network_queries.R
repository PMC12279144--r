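#!/usr/bin/env Rscript

# Stage 4: interrogate the thresholded average network.
#
# Degree summaries, class-to-class edge percentages (the assortativity
# table), the Markov blanket of the disease indicator, the sub-network
# of disease-adjacent variables, and recovery against the ground truth
# that stage 1 wrote down.

library(mixbn)

meta <- read_meta("results/cohort/metadata.tsv")
net <- read_edge_table("results/cohort/thresholded_edges.csv")
truth <- read_edge_table("results/cohort/truth_edges.csv")
disease <- readLines("results/cohort/disease_variable.txt")

deg <- degree_summary(net)
cat(sprintf("mean edges per parent variable: %.2f\n", deg$mean_out_per_parent))
cat(sprintf("mean edges per child variable:  %.2f\n", deg$mean_in_per_child))

cem <- class_edge_matrix(net, meta)
utils::write.csv(as.data.frame(cem), "results/cohort/class_edge_matrix.csv")
cat("class-to-class edge percentages (rows sum to 100):\n")
print(round(matrix(cem, nrow = nrow(cem), dimnames = dimnames(cem)), 2))
cat(sprintf("allele-score anchor edges kept: %d\n",
            nrow(attr(cem, "allele_score_edges"))))

bl <- markov_blanket(net, disease)
cat(sprintf("Markov blanket of %s (%d variables): %s\n", disease,
            length(bl), paste(bl, collapse = ", ")))
sub <- subnetwork(net, c(disease, bl))
write_edge_table(sub, sprintf("results/cohort/blanket_%s.csv", disease))

# recovery against the generating network
nodes <- meta$name
learned <- dag(nodes, net[, c("from", "to")])
true_dag <- dag(nodes, truth[, c("from", "to")])
key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
recovered <- mean(key(truth) %in% key(net))
cat(sprintf("true edges recovered at the analytic threshold: %.0f%% (%d of %d)\n",
            100 * recovered, sum(key(truth) %in% key(net)), nrow(truth)))
cat(sprintf("structural Hamming distance to truth: %d\n",
            shd(true_dag, learned)))
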