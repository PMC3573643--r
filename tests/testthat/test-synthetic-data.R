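test_that("Yule trees have the right shape, depth and determinism", {
  tr <- sim_tree(4, depth = 1, seed = 1)
  expect_equal(ape::Ntip(tr), 4)
  expect_equal(tr$Nnode, 3)              # rooted binary
  expect_true(ape::is.rooted(tr))
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_error(sim_tree(3), "at least 4")

  depths <- vapply(1:200, function(k)
    max(ape::node.depth.edgelength(sim_tree(6, depth = 2, seed = k))),
    numeric(1))
  expect_equal(mean(depths), 2, tolerance = 1e-9)  # depth is rescaled exactly

  expect_identical(write_tree(sim_tree(10, seed = 42)),
                   write_tree(sim_tree(10, seed = 42)))
})

test_that("nucleotide simulation matches its stationary model", {
  tr <- sim_tree(8, depth = 0.5, seed = 2)
  m <- substitution_model("HKY", rates = c(1, 3, 1, 1, 3, 1),
                          pi = c(.4, .1, .3, .2))
  # zero rate multiplier: all sequences identical
  a0 <- sim_nucleotide(tr, list(list(name = "g", length = 100, model = m,
                                     multiplier = 0)), seed = 2)
  expect_true(all(apply(a0$seqs, 2, function(x) length(unique(x)) == 1)))

  # empirical composition near the stationary frequencies at 10 kb
  a1 <- sim_nucleotide(tr, list(list(name = "g", length = 10000, model = m,
                                     multiplier = 1)), seed = 3)
  emp <- table(factor(a1$seqs, c("A", "C", "G", "T"))) / length(a1$seqs)
  expect_equal(as.numeric(emp), c(.4, .1, .3, .2), tolerance = 0.02)

  # deterministic under the seed
  a2 <- sim_nucleotide(tr, list(list(name = "g", length = 50, model = m)),
                       seed = 9)
  a3 <- sim_nucleotide(tr, list(list(name = "g", length = 50, model = m)),
                       seed = 9)
  expect_identical(a2$seqs, a3$seqs)
})

test_that("fast partitions on deep trees show the saturation signature", {
  hky <- substitution_model("HKY", rates = c(1, 5, 1, 1, 5, 1),
                            pi = c(.3, .2, .2, .3))
  hits <- 0; n_rep <- 10
  for (k in seq_len(n_rep)) {
    tr <- sim_tree(14, depth = 1.5, seed = 400 + k)
    aln <- sim_nucleotide(tr, list(list(name = "fast", length = 300,
                                        model = hky, multiplier = 8)),
                          seed = 400 + k)
    pr <- distance_profile(aln, "fast", hky)
    if (!is.na(pr$slope_ti) && pr$slope_ti < 0.2) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("codon simulation respects omega and emits a faithful truth table", {
  tr <- sim_tree(6, depth = 0.6, seed = 5)
  # omega 0 everywhere: translation is identical across taxa
  s0 <- sim_codon(tr, 100, classes = data.frame(prop = 1, omega = 0),
                  seed = 5)
  aa <- translate_codons(s0$aln)
  expect_true(all(apply(aa, 2, function(x) length(unique(x)) == 1)))

  # a simple counting proxy for dN/dS rises monotonically with omega
  t2 <- read_tree("(x:0.4,y:0.4);")
  prop_nonsyn <- vapply(c(0.05, 0.2, 0.5, 1, 2), function(w) {
    s <- sim_codon(t2, 800, classes = data.frame(prop = 1, omega = w),
                   seed = round(w * 100))
    aa <- translate_codons(s$aln)
    nt_diff <- vapply(seq_len(800), function(k)
      any(s$aln$seqs[1, (3 * k - 2):(3 * k)] !=
          s$aln$seqs[2, (3 * k - 2):(3 * k)]), logical(1))
    sum(aa[1, ] != aa[2, ]) / max(sum(nt_diff), 1)
  }, numeric(1))
  expect_equal(cor(prop_nonsyn, seq_along(prop_nonsyn), method = "spearman"),
               1)

  # truth-table class proportions match the spec within sampling error
  s1 <- sim_codon(tr, 2000, classes = data.frame(prop = c(0.7, 0.3),
                                                 omega = c(0.1, 1)), seed = 6)
  expect_equal(mean(s1$truth$class == 1), 0.7, tolerance = 0.04)
})

test_that("morphology simulation respects pools, censuses and io round-trips", {
  tr <- sim_tree(30, depth = 1.2, seed = 7)
  cm <- sim_morphology(tr, n_char = 120,
                       pool_probs = c("2" = 1), missing_fraction = 0.2,
                       polymorphic_fraction = 0.02, seed = 7)
  # pool bound 2: no character shows more than 2 states
  nstates <- vapply(seq_len(120), function(j) {
    obs <- unlist(cm$states[, j])
    length(unique(obs[!is.na(obs)]))
  }, numeric(1))
  expect_true(all(nstates <= 2))
  s <- summary(cm)
  expect_equal(s$missing_frac, 0.2, tolerance = 0.02)

  cm80 <- sim_morphology(sim_tree(80, depth = 1.5, seed = 8), n_char = 220,
                         seed = 8)
  expect_equal(summary(cm80)$missing_frac, 0.286, tolerance = 0.02)

  # identical under the same seed, parseable through the NEXUS writer
  cmA <- sim_morphology(tr, n_char = 30, seed = 11)
  cmB <- sim_morphology(tr, n_char = 30, seed = 11)
  expect_identical(cmA$states, cmB$states)
  rt <- read_character_matrix(write_character_matrix(cmA))
  expect_identical(rt$states, cmA$states)
})

test_that("bounded state pools produce curved, early-saturating exhaustion", {
  wins <- 0; n_rep <- 8
  for (k in seq_len(n_rep)) {
    tr <- sim_tree(25, depth = 1.5, seed = 500 + k)
    cm <- sim_morphology(tr, n_char = 80, missing_fraction = 0.1,
                         rate = 1.5, seed = 500 + k)
    cu <- state_step_curve(cm, tr)
    pts <- phyloconflict:::curve_points(cu)
    # straight-line AIC (2 params + error) vs best accumulation model
    lin <- stats::lm(S ~ t, data = pts)
    n <- nrow(pts)
    aic_lin <- n * log(sum(stats::resid(lin)^2) / n) + 2 * 3
    f <- fit_exhaustion_models(cu)
    best_aic <- min(f$finite$aic, f$power$aic)
    if (best_aic < aic_lin) wins <- wins + 1
  }
  expect_gte(wins, 7)
})
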