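#!/usr/bin/env Rscript
# Stage 2: character-state exhaustion. Builds the state:step curve on the
# reference tree, locates the breakpoint, tests whether new states arrive
# early, and compares the finite-pool and power-law accumulation models.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
  value = TRUE))), "00_config.R"))

tree <- read_tree(paste(readLines(file.path(DATA_DIR, "reference_tree.nwk")),
                        collapse = ""))
cm <- read_character_matrix(file.path(DATA_DIR, "morphology.nex"),
                            info = file.path(DATA_DIR, "morphology_info.tsv"))

curve <- state_step_curve(cm, tree)
write.table(curve, file.path(RESULTS, "exhaustion_curve.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

bp <- fit_breakpoint(curve)
mw <- state_addition_test(curve, cutoff = bp$breakpoint)
fits <- fit_exhaustion_models(curve, min_t = bp$breakpoint)

report <- list(
  breakpoint = bp$breakpoint, slope_before = bp$slope1,
  slope_after = bp$slope2,
  mann_whitney_W = mw$W, mann_whitney_p = mw$p,
  finite_smax = unname(fits$finite$parameters["Smax"]),
  finite_smax_se = unname(fits$finite$se[1]),
  power_b = unname(fits$power$parameters["b"]),
  power_c = unname(fits$power$parameters["c"]),
  delta_aic = fits$delta_aic, preferred_model = fits$best,
  support_for_other = fits$support)
jsonlite::write_json(report, file.path(RESULTS, "exhaustion_fits.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("breakpoint at step %.0f of %d; slopes %.3f -> %.3f\n",
            bp$breakpoint, max(curve$t), bp$slope1, bp$slope2))
cat(sprintf("new states arrive early beyond it (Mann-Whitney W = %.0f, p = %.3g)\n",
            mw$W, mw$p))
cat(sprintf("accumulation: %s model preferred (delta AIC = %.1f); Smax = %.1f, power exponent = %.3f\n",
            fits$best, fits$delta_aic,
            unname(fits$finite$parameters["Smax"]),
            unname(fits$power$parameters["c"])))
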