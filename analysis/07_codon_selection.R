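#!/usr/bin/env Rscript
# Stage 7: adaptive convergence in the codon gene. Nearly-neutral vs clade
# model C with a likelihood-ratio test and empirical-Bayes site flags, then
# the per-site amino-acid support profile under mtMAM against a simulated
# null, and the association between flagged codons and support extremes.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
  value = TRUE))), "00_config.R"))

aln <- read_alignment(file.path(DATA_DIR, "codon_gene.fasta"), "fasta",
                      type = "codon")
tree <- read_tree(paste(readLines(file.path(DATA_DIR, "codon_tree.nwk")),
                        collapse = ""))
fg <- readLines(file.path(DATA_DIR, "foreground_clade.txt"))
truth <- read.delim(file.path(DATA_DIR, "codon_truth.tsv"))

nf <- fit_codon_model(aln, tree, "M1a", omega_starts = c(0.1, 1))
af <- fit_codon_model(aln, tree, "cladeC", foreground = fg,
                      omega_starts = c(0.1, 1))
shift <- selection_shift_test(nf, af, eb_threshold = 0.9)
cat(sprintf("nearly neutral: lnL = %.2f (omega0 = %.3f, p0 = %.2f)\n",
            nf$logLik, nf$params["omega0"], nf$params["p0"]))
cat(sprintf("clade model C : lnL = %.2f (omega2 bg = %.3f, fg = %.3f)\n",
            af$logLik, af$params["omega2_bg"], af$params["omega2_fg"]))
cat(sprintf("LRT = %.2f (df %d), p = %.3g; %d codons flagged at 0.90\n",
            shift$lrt, shift$df, shift$p, length(shift$flagged)))
truly <- which(truth$class == 3)
cat(sprintf("flag recall on the generator's divergent class: %.2f\n",
            length(intersect(shift$flagged, truly)) / length(truly)))

tru <- unroot(tree)
focal <- which(tru$edge[, 2] == getMRCA(tru, fg))
if (!length(focal) || tru$edge[focal, 1] <= Ntip(tru))
  focal <- which(tru$edge[, 1] > Ntip(tru) & tru$edge[, 2] > Ntip(tru))[1]
alt <- alternative_topologies(tru, focal)$nni1
aa <- translate_codons(aln)
prof <- site_support_profile(aa, tru, alt)
cat(sprintf("protein profile: lnL(with) - lnL(without) = %.2f over %d sites\n",
            prof$logLik_with - prof$logLik_without, length(prof$delta)))

nulls <- lapply(1:4, function(k) {
  ns <- sim_codon(tree, ncol(aa), kappa = unname(nf$params["kappa"]),
                  classes = data.frame(prop = unname(nf$params[c("p0", "p1")]),
                                       omega = c(unname(nf$params["omega0"]),
                                                 1)),
                  seed = SEED + 100L + k)
  site_support_profile(translate_codons(ns$aln), tru, alt)$delta
})
ca <- convergence_association(prof$delta, shift$flagged, nulls,
                              regions = rep(c("trans-membrane", "loop",
                                              "carboxy-terminus"),
                                            length.out = ncol(aa)))
write.table(data.frame(codon = seq_along(prof$delta), delta = prof$delta,
                       category = ca$category,
                       flagged = seq_along(prof$delta) %in% shift$flagged),
            file.path(RESULTS, "per_site_profile.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("null envelope [%.2f, %.2f]; %d support / %d rejection extremes\n",
            ca$envelope[1], ca$envelope[2],
            sum(ca$category == "support-extreme"),
            sum(ca$category == "rejection-extreme")))
cat(sprintf("flagged x extremes: G_%d = %.3f, p = %.3g\n",
            ca$extremes_test$df, ca$extremes_test$G, ca$extremes_test$p))
cat(sprintf("flagged x regions : G_%d = %.3f, p = %.3g\n",
            ca$regions_test$df, ca$regions_test$G, ca$regions_test$p))
jsonlite::write_json(list(
  lnL_null = nf$logLik, lnL_cladeC = af$logLik, lrt = shift$lrt,
  lrt_p = shift$p, n_flagged = length(shift$flagged),
  omega2_bg = unname(af$params["omega2_bg"]),
  omega2_fg = unname(af$params["omega2_fg"]),
  extremes_G = ca$extremes_test$G, extremes_p = ca$extremes_test$p,
  regions_G = ca$regions_test$G, regions_p = ca$regions_test$p),
  file.path(RESULTS, "codon_selection.json"), auto_unbox = TRUE, digits = NA)
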