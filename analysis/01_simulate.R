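#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study system — reference tree, bounded-pool
# morphology, partitioned nucleotide supermatrix, and a codon gene with a
# clade-specific selection shift — and write everything in standard formats.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
  value = TRUE))), "00_config.R"))

tree <- sim_tree(N_TAXA, depth = 1.5, seed = SEED)
write_tree(tree, file.path(DATA_DIR, "reference_tree.nwk"))

cm <- sim_morphology(tree, n_char = N_CHAR, rate = 1.2, seed = SEED)
write_character_matrix(cm, file.path(DATA_DIR, "morphology.nex"))
info <- cm$info[, c("index", "ordered", "weight", "class")]
write.table(info, file.path(DATA_DIR, "morphology_info.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

drift_tips <- extract.clade(tree, Ntip(tree) + 3)$tip.label
aln <- sim_nucleotide(tree, list(
  list(name = "slow", length = LEN_SLOW, model = model_slow,
       multiplier = 0.4),
  list(name = "fast", length = LEN_FAST, model = model_fast, multiplier = 8,
       drift = list(tips = drift_tips, pi = c(.12, .38, .38, .12)))),
  seed = SEED)
write_alignment(aln, "fasta", file.path(DATA_DIR, "supermatrix.fasta"))
writeLines(c(sprintf("slow = 1-%d", LEN_SLOW),
             sprintf("fast = %d-%d", LEN_SLOW + 1, LEN_SLOW + LEN_FAST)),
           file.path(DATA_DIR, "partitions.txt"))

tr_c <- sim_tree(8, depth = 0.9, seed = SEED + 3L)
fg <- tryCatch(pick_clade(tr_c, min_tips = 3, max_tips = 3),
               error = function(e) pick_clade(tr_c, min_tips = 2,
                                              max_tips = 4))
sim_c <- sim_codon(tr_c, N_CODONS, kappa = 2,
                   classes = data.frame(prop = c(0.55, 0.1, 0.35),
                                        omega = c(0.05, 1, 0.05),
                                        omega_fg = c(0.05, 1, 2.5)),
                   foreground = fg, seed = SEED + 3L)
write_alignment(sim_c$aln, "fasta", file.path(DATA_DIR, "codon_gene.fasta"))
write_tree(tr_c, file.path(DATA_DIR, "codon_tree.nwk"))
writeLines(fg, file.path(DATA_DIR, "foreground_clade.txt"))
write.table(sim_c$truth, file.path(DATA_DIR, "codon_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("simulated study system written to", DATA_DIR, "\n")
cat(sprintf("  morphology: %d taxa x %d characters, %.1f%% missing\n",
            N_TAXA, N_CHAR, 100 * summary(cm)$missing_frac))
cat(sprintf("  supermatrix: %d sites in 2 partitions\n",
            LEN_SLOW + LEN_FAST))
cat(sprintf("  codon gene: %d codons, foreground clade {%s}\n",
            N_CODONS, paste(fg, collapse = ", ")))
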