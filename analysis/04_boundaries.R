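#!/usr/bin/env Rscript
# Splice-boundary analyses on simulated data with known ground truth:
# microhomology distribution with and without a planted junction repeat,
# and the penultimate-base relaxation contrast.

library(intronevo)

dir.create("results", showWarnings = FALSE)

# planted 3-bp microhomology at every junction
td <- simulate_dataset(sim_config(n_leaves = 12, loss_prob = 0,
                                  micro_k = 3, mut_rate = 0), seed = 4001)
sv <- microhomology_survey(td$structures)
write.table(sv$per_slot, "results/microhomology_planted.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# no planted homology: the background distribution of k
td0 <- simulate_dataset(sim_config(n_leaves = 12, loss_prob = 0,
                                   micro_k = 0, mut_rate = 0), seed = 4002)
sv0 <- microhomology_survey(td0$structures)
write.table(sv0$per_slot, "results/microhomology_null.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("planted modal k:", sv$per_slot$modal_k, "\n")
cat("null modal k:   ", sv0$per_slot$modal_k, "\n")

# penultimate-base contrast across relaxation strengths
rows <- lapply(c(0, 0.5, 1), function(strength) {
  ps <- vapply(1:200, function(r) {
    g <- simulate_penultimate(12, 12, strength = strength, seed = 6000 + r)
    penultimate_test(g$bases_present, g$bases_absent, phase = 1)$p_value
  }, numeric(1))
  data.frame(strength = strength, median_p = median(ps),
             frac_below_0.05 = mean(ps < 0.05))
})
pen <- do.call(rbind, rows)
write.table(pen, "results/penultimate_power.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(pen)

# intron size statistics per slot on the planted data set
write.table(size_stats(td$structures), "results/intron_sizes.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
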