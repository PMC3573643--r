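# A fixed small study system reused across the codon tests: 8 taxa with a
# genuine 3-tip foreground clade.
codon_tree <- sim_tree(8, depth = 0.9, seed = 41)
fg_clade <- pick_clade(codon_tree, min_tips = 3, max_tips = 3)

test_that("codon machinery is structurally sound", {
  st <- phyloconflict:::get_codon_structure("vertebrate_mt")
  expect_equal(st$s, 60)                       # 4 stops in the mt code
  stu <- phyloconflict:::get_codon_structure("universal")
  expect_equal(stu$s, 61)
  Q <- phyloconflict:::codon_Q(2, 0.1, rep(1 / 60, 60), st)
  expect_equal(rowSums(Q), rep(0, 60), tolerance = 1e-12)
  expect_equal(-sum(diag(Q)) / 60, 1, tolerance = 1e-12)  # unit expected rate
  # multi-nucleotide jumps are forbidden
  expect_true(all(Q[!st$single & !diag(60)] == 0))
})

test_that("identical sequences leave omega unidentifiable, with a warning", {
  S <- matrix(rep(strsplit("ATGGCCATA", "")[[1]], 4), 4, byrow = TRUE,
              dimnames = list(paste0("t", 1:4), NULL))
  aln <- seq_alignment(S, type = "codon")
  tr <- read_tree("((t1:0.1,t2:0.1):0.1,(t3:0.1,t4:0.1):0.1);")
  expect_warning(fit_codon_model(aln, tr, "M1a", omega_starts = 0.1),
                 "unidentifiable|no substitutions")
})

test_that("nearly-neutral fits recover generating omega0 and p0", {
  ok <- 0; n_rep <- 6
  for (k in seq_len(n_rep)) {
    sim <- sim_codon(codon_tree, 300, kappa = 2,
                     classes = data.frame(prop = c(0.85, 0.15),
                                          omega = c(0.1, 1)),
                     seed = 700 + k)
    fit <- fit_codon_model(sim$aln, codon_tree, "M1a",
                           omega_starts = c(0.1, 1))
    if (abs(fit$params["omega0"] - 0.1) <= 0.05 &&
        abs(fit$params["p0"] - 0.85) <= 0.1) ok <- ok + 1
  }
  expect_gte(ok, 5)
})

test_that("clade model C recovers the foreground/background omega ordering", {
  ok <- 0; n_rep <- 5
  for (k in seq_len(n_rep)) {
    sim <- sim_codon(codon_tree, 300, kappa = 2,
                     classes = data.frame(prop = c(0.65, 0.1, 0.25),
                                          omega = c(0.08, 1, 0.12),
                                          omega_fg = c(0.08, 1, 1.6)),
                     foreground = fg_clade, seed = 800 + k)
    fit <- fit_codon_model(sim$aln, codon_tree, "cladeC",
                           foreground = fg_clade, omega_starts = c(0.1, 1))
    if (fit$params["omega2_fg"] > fit$params["omega2_bg"]) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("the selection-shift LRT is calibrated and flags shifted codons", {
  # identical fits: LRT 0, p = 1 (synthesize via a null-vs-null comparison)
  simn <- sim_codon(codon_tree, 150, kappa = 2,
                    classes = data.frame(prop = c(0.9, 0.1),
                                         omega = c(0.1, 1)), seed = 900)
  nf <- fit_codon_model(simn$aln, codon_tree, "M1a", omega_starts = c(0.1))
  fake_alt <- nf; fake_alt$model <- "cladeC"
  fake_alt$posterior <- cbind(nf$posterior, 0)
  r0 <- selection_shift_test(nf, fake_alt)
  expect_equal(r0$lrt, 0)
  expect_equal(r0$p, 1)
  expect_length(r0$flagged, 0)

  # type-I: data without any clade shift rarely rejects
  rej <- 0; n_rep <- 6
  for (k in seq_len(n_rep)) {
    sim <- sim_codon(codon_tree, 150, kappa = 2,
                     classes = data.frame(prop = c(0.9, 0.1),
                                          omega = c(0.15, 1)),
                     seed = 910 + k)
    nf <- fit_codon_model(sim$aln, codon_tree, "M1a", omega_starts = c(0.1, 1))
    af <- fit_codon_model(sim$aln, codon_tree, "cladeC",
                          foreground = fg_clade, omega_starts = c(0.1, 1))
    r <- selection_shift_test(nf, af)
    if (r$p < 0.05) rej <- rej + 1
  }
  expect_lte(rej, 2)

  # positive control: strong foreground shift is detected and the flagged
  # codons are mostly truly shifted ones
  sim <- sim_codon(codon_tree, 400, kappa = 2,
                   classes = data.frame(prop = c(0.55, 0.1, 0.35),
                                        omega = c(0.05, 1, 0.05),
                                        omega_fg = c(0.05, 1, 2.5)),
                   foreground = fg_clade, seed = 930)
  nf <- fit_codon_model(sim$aln, codon_tree, "M1a", omega_starts = c(0.1, 1))
  af <- fit_codon_model(sim$aln, codon_tree, "cladeC",
                        foreground = fg_clade, omega_starts = c(0.1, 1))
  r <- selection_shift_test(nf, af, eb_threshold = 0.95)
  expect_lt(r$p, 0.001)
  truly <- which(sim$truth$class == 3)
  expect_gte(length(r$flagged), 1)
  false_flags <- setdiff(r$flagged, truly)
  expect_lte(length(false_flags), max(1, 0.05 * length(r$flagged)))

  # invariance to taxon order
  set.seed(7)
  perm <- sample(nrow(sim$aln$seqs))
  aln2 <- seq_alignment(sim$aln$seqs[perm, ], type = "codon",
                        code = sim$aln$code)
  nf2 <- fit_codon_model(aln2, codon_tree, "M1a", omega_starts = c(0.1))
  nf1 <- fit_codon_model(sim$aln, codon_tree, "M1a", omega_starts = c(0.1))
  expect_equal(nf2$logLik, nf1$logLik, tolerance = 1e-4)
})

test_that("per-site protein support profiles are exact and additive", {
  # identical topologies give an all-zero profile
  tr <- sim_tree(6, depth = 0.6, seed = 55)
  sim <- sim_codon(tr, 80, seed = 55)
  aa <- translate_codons(sim$aln)
  pr0 <- site_support_profile(aa, tr, tr)
  expect_equal(pr0$delta, rep(0, 80), tolerance = 1e-5)

  # brute-force oracle on a 4-taxon fixture (fixed branch lengths)
  t4 <- read_tree("((a:0.2,b:0.3):0.15,(c:0.25,d:0.1):0.2);")
  set.seed(66)
  A <- matrix(sample(phyloconflict:::AA, 4 * 12, TRUE), 4, 12,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  mod <- mtmam_model()
  pat <- phyloconflict:::aa_patterns(A)
  mine <- phyloconflict:::aa_site_loglik(t4, pat, mod,
                                         t4$edge.length)[pat$map]
  expect_equal(mine, brute_aa_site_loglik(t4, A, mod), tolerance = 1e-8)

  # additivity of the profile
  t6 <- sim_tree(6, depth = 0.6, seed = 56)
  ie <- which(t6$edge[, 1] > 6 & t6$edge[, 2] > 6)
  alt <- alternative_topologies(ape::unroot(t6), ie[1])$nni1
  pr <- site_support_profile(aa, t6, alt)
  expect_equal(sum(pr$delta), pr$logLik_with - pr$logLik_without,
               tolerance = 1e-8)
})

test_that("convergence association classifies extremes and matches the G formula", {
  # contrived 3x2 table equals the hand-summed G
  tab <- matrix(c(12, 3, 40, 2, 8, 5), 3, 2, byrow = TRUE)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  gh <- 2 * sum(ifelse(tab > 0, tab * log(tab / e), 0))
  g <- g_test_independence(tab)
  expect_equal(g$G, gh)
  expect_equal(g$df, 2)

  set.seed(20)
  null_profiles <- replicate(30, rnorm(200, 0, 0.5), simplify = FALSE)
  profile <- rnorm(200, 0, 0.5)
  profile[1:12] <- 3      # constructed support extremes
  profile[13:20] <- -3    # constructed rejection extremes
  flags <- c(1:10, 13:16, 50:52)
  ca <- convergence_association(profile, flags, null_profiles,
                                regions = rep(c("tm", "ct", "loop"),
                                              length.out = 200))
  expect_equal(sum(ca$category == "support-extreme"), 12, tolerance = 3)
  expect_lt(ca$extremes_test$p, 0.001)
  expect_equal(ca$regions_test$df, 2)
  expect_true(all(table(ca$category) >= 0))

  # no flags: association reported as undefined
  ca0 <- convergence_association(profile, integer(0), null_profiles)
  expect_match(ca0$note, "undefined")

  # permuted flags give a calibrated (non-anticonservative) G test
  pvals <- replicate(60, {
    fl <- sample(200, 17)
    convergence_association(profile, fl, null_profiles)$extremes_test$p
  })
  expect_lte(mean(pvals < 0.05), 0.15)
  expect_gt(mean(pvals), 0.3)

  # envelope stabilizes as the null pool grows
  set.seed(21)
  big <- replicate(200, rnorm(200, 0, 0.5), simplify = FALSE)
  e100 <- stats::quantile(unlist(big[1:100]), c(0.025, 0.975))
  e200 <- stats::quantile(unlist(big), c(0.025, 0.975))
  expect_lt(max(abs(e100 - e200)), 0.05)
})
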