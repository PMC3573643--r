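#!/usr/bin/env Rscript
# Stage 5: model and partition-scheme selection on a fixed topology. Picks
# the best substitution model per partition by AICc, then compares the
# unpartitioned against the partitioned scheme by AICc, BIC and the
# decision-theoretic branch-length risk.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
  value = TRUE))), "00_config.R"))

# a smaller tree keeps the fixed-topology optimizations quick
tree <- sim_tree(8, depth = 0.6, seed = SEED + 2L)
aln <- sim_nucleotide(tree, list(
  list(name = "a", length = 350, model = model_slow, multiplier = 0.4),
  list(name = "b", length = 350, model = model_fast, multiplier = 3)),
  seed = SEED + 2L)

sel <- select_substitution_model(aln, partition = "a", tree = tree,
                                 constraints = c("JC", "HKY", "GTR"),
                                 heterogeneity = c("", "G"))
write.table(sel$table, file.path(RESULTS, "model_selection.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("best model for partition 'a' by AICc:", sel$table$model[1], "\n")

one <- seq_alignment(aln$seqs, taxa = aln$taxa)
f1 <- fit_tree(tree, one, substitution_model("HKY", n_cat = 0),
               tol = 1e-4, max_passes = 4)
f2 <- fit_tree(f1$tree, aln, substitution_model("HKY", n_cat = 0),
               tol = 1e-4, max_passes = 4)
cmp <- compare_partition_schemes(list(unpartitioned = f1, two_class = f2))
write.table(cmp$table, file.path(RESULTS, "partition_schemes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(cmp$table)
cat("winners:", paste(names(cmp$winner), cmp$winner, sep = "=",
                      collapse = "  "), "\n")
cat(sprintf("rate multipliers (two_class): %s\n",
            paste(round(f2$multipliers, 3), collapse = " ")))
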