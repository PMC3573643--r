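#!/usr/bin/env Rscript
# Stage 3: molecular saturation. Transition/transversion slopes against
# model-corrected distances per partition, base-composition homogeneity, and
# the resulting exclusion/down-weighting scheme.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
  value = TRUE))), "00_config.R"))

aln <- read_alignment(file.path(DATA_DIR, "supermatrix.fasta"), "fasta",
                      partitions = file.path(DATA_DIR, "partitions.txt"))

profiles <- list(distance_profile(aln, "slow", model_slow),
                 distance_profile(aln, "fast", model_fast))
tab <- weighting_scheme(profiles)
write.table(tab, file.path(RESULTS, "saturation_profile.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

for (i in seq_along(profiles)) {
  p <- profiles[[i]]
  cat(sprintf("%-6s slope_tv %.2f  slope_ti %.2f  chi2 p %.2g  -> weight %.2f\n",
              tab$partition[i], p$slope_tv, p$slope_ti, p$p_chisq,
              tab$weight[i]))
}
cat("rationale:\n")
for (i in seq_len(nrow(tab))) cat("  -", tab$rationale[i], "\n")
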