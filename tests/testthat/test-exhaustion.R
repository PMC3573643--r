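make_curve <- function(steps, new_states) {
  out <- data.frame(branch = seq_along(steps), rank = seq_along(steps),
                    steps = steps, new_states = new_states)
  out$t <- cumsum(out$steps); out$S <- cumsum(out$new_states)
  class(out) <- c("exhaustion_curve", "data.frame")
  out
}

test_that("state:step curves account for every ACCTRAN step and new state", {
  # single character changing once -> one curve record with (1, 1)
  t4 <- read_tree("((A:1,B:1):1,(C:1,D:1):1);")
  cm <- char_matrix(cells_matrix(list(0, 0, 1, 1), taxa = c("A", "B", "C", "D")))
  cu <- state_step_curve(cm, t4)
  expect_equal(max(cu$t), 1)
  expect_equal(max(cu$S), 1)

  # total per-branch steps equal summed ACCTRAN tree lengths
  set.seed(31)
  for (k in 1:8) {
    tr <- sim_tree(12, depth = 1, seed = 30 + k)
    cmr <- sim_morphology(tr, n_char = 25, missing_fraction = 0.1, seed = k)
    cu <- state_step_curve(cmr, tr)
    tot <- sum(vapply(seq_len(25), function(j)
      acctran_changes(tr, stats::setNames(cmr$states[, j], cmr$taxa))$steps,
      numeric(1)))
    expect_equal(max(cu$t), tot)
    expect_true(all(diff(cu$S) >= 0))
  }
  # taxon mismatch errors
  cm_bad <- char_matrix(cells_matrix(list(0, 1), taxa = c("X", "Y")))
  expect_error(state_step_curve(cm_bad, t4), "absent")
})

test_that("breakpoint regression recovers noiseless breaks and beats the grid", {
  cu <- make_curve(rep(5, 20), rep(0, 20))
  cu$S <- ifelse(cu$t <= 50, cu$t, 50 + 0.3 * (cu$t - 50))
  bp <- fit_breakpoint(cu)
  expect_equal(bp$breakpoint, 50, tolerance = 1e-6)
  expect_equal(bp$slope1, 1, tolerance = 1e-8)
  expect_equal(bp$slope2, 0.3, tolerance = 1e-8)

  # refined breakpoint never does worse than the exhaustive grid oracle
  set.seed(61)
  for (k in 1:10) {
    steps <- sample(2:8, 15, replace = TRUE)
    cuk <- make_curve(steps, rbinom(15, steps, 0.4))
    bpk <- fit_breakpoint(cuk)
    pts <- phyloconflict:::curve_points(cuk)
    grid_rss <- vapply(pts$t[pts$t > min(pts$t) & pts$t < max(pts$t)],
      function(b) {
        X <- cbind(1, pts$t, pmax(pts$t - b, 0))
        sum(stats::lm.fit(X, pts$S)$residuals^2)
      }, numeric(1))
    expect_lte(bpk$rss, min(grid_rss) + 1e-9)
  }
  # collinear curve flags the single-segment fallback
  lin <- make_curve(rep(3, 10), rep(0, 10)); lin$S <- lin$t
  expect_true(fit_breakpoint(lin)$degenerate)
  expect_error(fit_breakpoint(make_curve(c(1, 2), c(1, 0))), "8 curve points")
})

test_that("the rank test matches exact enumeration and handles no-contrast", {
  # one group at steps 1:3, other at 4:6 -> U = 0, exact two-sided p = 0.1
  cu <- make_curve(rep(1, 6), c(1, 1, 1, 0, 0, 0))
  r <- state_addition_test(cu, cutoff = 0)
  expect_equal(unname(r$U), 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$p, exact_mw_p(1:3, 4:6))

  # perfectly interleaved labels carry no early/late signal
  cu2 <- make_curve(rep(1, 40), rep(c(1, 0), 20))
  r2 <- state_addition_test(cu2, cutoff = 0)
  expect_gt(r2$p, 0.5)

  # enumeration oracle on random labelings
  set.seed(17)
  for (k in 1:10) {
    lab <- sample(c(rep(1, 4), rep(0, 5)))
    cuk <- make_curve(rep(1, 9), lab)
    rk <- state_addition_test(cuk, cutoff = 0)
    expect_equal(rk$p, exact_mw_p(which(lab == 1), which(lab == 0)),
                 tolerance = 1e-9)
  }
  cu3 <- make_curve(rep(1, 5), rep(1, 5))
  expect_error(state_addition_test(cu3, 0), "no contrast")
})

test_that("rank test keeps its nominal size on exchangeable curves", {
  # under consistent state addition, the new-state label is independent of
  # the step index; the rejection rate at alpha = 0.05 stays near nominal
  set.seed(97)
  n_rep <- 120; alpha <- 0.05
  rej <- 0
  for (k in seq_len(n_rep)) {
    steps <- rpois(40, 4) + 1
    new <- rbinom(40, steps, 0.3)
    cu <- make_curve(steps, pmin(new, steps))
    p <- tryCatch(state_addition_test(cu, cutoff = 0)$p, error = function(e) 1)
    if (p < alpha) rej <- rej + 1
  }
  # binomial(120, 0.05) 99.5th percentile is 12
  expect_lte(rej, 12)
})

test_that("accumulation models recover their generating parameters", {
  t <- seq(5, 400, by = 5)
  cu_fin <- make_curve(c(t[1], diff(t)), rep(0, length(t)))
  cu_fin$S <- 100 * (1 - (1 - 1 / 100)^cu_fin$t)
  f <- fit_exhaustion_models(cu_fin)
  expect_equal(unname(f$finite$parameters["Smax"]), 100, tolerance = 1e-4)
  expect_equal(f$best, "finite")

  cu_pow <- cu_fin
  cu_pow$S <- 11.124 * cu_pow$t^0.488
  g <- fit_exhaustion_models(cu_pow)
  expect_equal(unname(g$power$parameters["b"]), 11.124, tolerance = 1e-4)
  expect_equal(unname(g$power$parameters["c"]), 0.488, tolerance = 1e-4)
  expect_equal(g$best, "power")
  expect_gte(g$delta_aic, 0)
})

test_that("AIC follows the n*log(RSS/n) + 2k convention on a small fixture", {
  t <- seq(2, 20, by = 2)
  cu <- make_curve(c(t[1], diff(t)), rep(0, 10))
  cu$S <- 4 * cu$t^0.5 + c(0.2, -0.1, 0.15, -0.2, 0.1, -0.05, 0.12, -0.08,
                           0.03, -0.11)
  f <- fit_exhaustion_models(cu)
  n <- f$power$n
  expect_equal(f$power$aic, n * log(f$power$rss / n) + 2 * 3)
  expect_equal(f$finite$aic, n * log(f$finite$rss / n) + 2 * 2)
})

test_that("curves and model choice are invariant to state relabeling", {
  tr <- sim_tree(15, depth = 1.2, seed = 44)
  cm <- sim_morphology(tr, n_char = 40, missing_fraction = 0.1, seed = 44)
  cu1 <- state_step_curve(cm, tr)
  # affine relabeling of every character's states (x -> x + 3)
  cm2 <- cm
  for (j in seq_len(nrow(cm$info))) for (i in seq_along(cm$taxa)) {
    s <- cm$states[[i, j]]
    if (!(length(s) == 1 && is.na(s))) cm2$states[[i, j]] <- s + 3L
  }
  cu2 <- state_step_curve(cm2, tr)
  expect_equal(cu1$t, cu2$t)
  expect_equal(cu1$S, cu2$S)
})
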