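#' Character-state exhaustion curve
#'
#' Optimizes every character (treated as unordered) on the rooted tree by
#' accelerated transformation, orders branches from oldest to youngest (node
#' ages when branch lengths carry time, breadth-first depth rank otherwise;
#' see [branch_order()]), and accumulates per-branch parsimony steps and
#' first appearances of character states. A state is "new" on the first
#' branch, in traversal order, where a change into it is inferred and it was
#' not part of the root reconstruction nor seen earlier in the traversal.
#'
#' @param cm A [char_matrix()]; ordered flags are ignored (all characters
#'   unordered, matching how exhaustion is scored).
#' @param tree rooted `phylo` whose tips cover the matrix taxa.
#' @param use_ages order branches by node age (default when branch lengths
#'   are present).
#' @return data frame of class `exhaustion_curve`: branch (edge row), rank,
#'   steps, new_states, t (cumulative steps), S (cumulative new states).
#' @export
state_step_curve <- function(cm, tree, use_ages = !is.null(tree$edge.length)) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  missing_taxa <- setdiff(cm$taxa, tree$tip.label)
  if (length(missing_taxa))
    stop("matrix taxa absent from tree: ", paste(missing_taxa, collapse = ", "))
  nchr <- nrow(cm$info)
  ne <- nrow(tree$edge)
  steps_by_edge <- numeric(ne)
  # per-edge list of (character, state) arrivals
  arrivals <- vector("list", ne)
  seen <- vector("list", nchr)   # states already credited, per character
  for (j in seq_len(nchr)) {
    cells <- stats::setNames(cm$states[, j], cm$taxa)
    ac <- acctran_changes(tree, cells, ordered = FALSE)
    seen[[j]] <- ac$root_states
    if (nrow(ac$changes)) {
      for (r in seq_len(nrow(ac$changes))) {
        e <- ac$changes$edge[r]
        steps_by_edge[e] <- steps_by_edge[e] + ac$changes$steps[r]
        arrivals[[e]] <- rbind(arrivals[[e]],
                               c(j, ac$changes$to[r]))
      }
    }
  }
  ord <- branch_order(tree, use_ages = use_ages)
  out <- data.frame(branch = ord, rank = seq_along(ord),
                    steps = steps_by_edge[ord], new_states = 0L)
  for (k in seq_along(ord)) {
    arr <- arrivals[[ord[k]]]
    if (is.null(arr)) next
    nn <- 0L
    for (r in seq_len(nrow(arr))) {
      j <- arr[r, 1]; s <- arr[r, 2]
      if (!s %in% seen[[j]]) { nn <- nn + 1L; seen[[j]] <- c(seen[[j]], s) }
    }
    out$new_states[k] <- nn
  }
  out$t <- cumsum(out$steps)
  out$S <- cumsum(out$new_states)
  class(out) <- c("exhaustion_curve", "data.frame")
  out
}

curve_points <- function(curve) {
  pts <- curve[curve$steps > 0, c("t", "S")]
  rbind(data.frame(t = 0, S = 0), pts)
}

#' Breakpoint of the state:step curve
#'
#' Least-squares continuous two-segment ("hinge") regression of cumulative
#' states on cumulative steps. The breakpoint is found by an exhaustive grid
#' over the observed step counts followed by local continuous refinement
#' with [stats::optimize()]. The earlier (linear) segment is what the
#' exhaustion analysis subsequently discards.
#'
#' @param curve an `exhaustion_curve`.
#' @return list with `breakpoint`, `slope1`, `slope2`, `intercept`, `rss`,
#'   and `degenerate` (single-segment fallback when the hinge adds nothing).
#' @export
fit_breakpoint <- function(curve) {
  pts <- curve_points(curve)
  if (nrow(pts) < 8) stop("need at least 8 curve points")
  t <- pts$t; S <- pts$S
  rss_at <- function(bp) {
    X <- cbind(1, t, pmax(t - bp, 0))
    fit <- stats::lm.fit(X, S)
    sum(fit$residuals^2)
  }
  cand <- t[t > min(t) & t < max(t)]
  cand <- sort(unique(cand))
  if (length(cand) < 2) cand <- seq(min(t), max(t), length.out = 25)[-c(1, 25)]
  grid_rss <- vapply(cand, rss_at, numeric(1))
  k <- which.min(grid_rss)
  lo <- if (k > 1) cand[k - 1] else min(t)
  hi <- if (k < length(cand)) cand[k + 1] else max(t)
  opt <- stats::optimize(rss_at, c(lo, hi))
  bp <- if (opt$objective < grid_rss[k]) opt$minimum else cand[k]
  X <- cbind(1, t, pmax(t - bp, 0))
  fit <- stats::lm.fit(X, S)
  cf <- fit$coefficients
  lin <- stats::lm.fit(cbind(1, t), S)
  degenerate <- (sum(lin$residuals^2) - sum(fit$residuals^2)) <=
    1e-10 * max(1, sum(lin$residuals^2))
  list(breakpoint = bp, slope1 = unname(cf[2]),
       slope2 = unname(cf[2] + cf[3]), intercept = unname(cf[1]),
       rss = sum(fit$residuals^2), degenerate = degenerate)
}

#' Rank test for late addition of new states
#'
#' Beyond the breakpoint, individual steps are labeled by whether they added
#' a new character state; under the null of consistent state addition the
#' two label groups are exchangeable along the step index. Two-sided
#' Mann-Whitney test on the step indices: exact enumeration for small
#' tie-free samples (n1*n2 < 2500), normal approximation with tie and
#' continuity correction otherwise (the [stats::wilcox.test()] conventions).
#' Within a branch contributing several steps, the earliest of them are
#' labeled as the state-adding steps.
#'
#' @param curve an `exhaustion_curve`.
#' @param cutoff breakpoint step count; only steps with index > cutoff enter.
#' @return list with `W` (Mann-Whitney statistic of the state-adding group,
#'   the R convention: rank sum minus its minimum, identical to U), `U`,
#'   `rank_sum`, and two-sided `p`.
#' @export
state_addition_test <- function(curve, cutoff) {
  idx_new <- numeric(0); idx_old <- numeric(0)
  t_prev <- 0
  for (k in seq_len(nrow(curve))) {
    st <- curve$steps[k]
    if (st <= 0) next
    pos <- t_prev + seq_len(st)
    t_prev <- t_prev + st
    nn <- min(curve$new_states[k], st)
    if (nn > 0) idx_new <- c(idx_new, pos[seq_len(nn)])
    if (st > nn) idx_old <- c(idx_old, pos[(nn + 1):st])
  }
  idx_new <- idx_new[idx_new > cutoff]
  idx_old <- idx_old[idx_old > cutoff]
  if (!length(idx_new) || !length(idx_old))
    stop("no contrast: one step category is empty beyond the cutoff")
  wt <- suppressWarnings(stats::wilcox.test(idx_new, idx_old,
                                            alternative = "two.sided"))
  n1 <- length(idx_new)
  rk <- rank(c(idx_new, idx_old))
  list(W = unname(wt$statistic), U = unname(wt$statistic),
       rank_sum = sum(rk[seq_len(n1)]), p = wt$p.value,
       n_new = n1, n_old = length(idx_old))
}

#' Competing models of character-state accumulation
#'
#' Fits, by nonlinear least squares with multiple starting values, two
#' models to the post-breakpoint state:step points: a finite-pool
#' (rarefaction) model `S(t) = S_max * (1 - (1 - 1/S_max)^t)`, expected when
#' the number of attainable states has a ceiling, and a power law
#' `S(t) = b * t^c`, expected when new states keep arriving at a decaying
#' rate. Models are compared by `AIC = n*log(RSS/n) + 2k` with the Gaussian
#' error variance counted in `k`, so the difference in AIC is well defined
#' across the two fits.
#'
#' @param curve_tail an `exhaustion_curve` (or its post-breakpoint subset).
#' @param min_t drop points with cumulative steps at or below this value
#'   (the breakpoint), 0 to use everything.
#' @return list with elements `finite` and `power` (each: parameters, se,
#'   rss, aic, converged), `delta_aic` (vs the better model, named), and
#'   `support` (verbal category for the worse model).
#' @export
fit_exhaustion_models <- function(curve_tail, min_t = 0) {
  pts <- curve_points(curve_tail)
  pts <- pts[pts$t > min_t & pts$t > 0, ]
  if (nrow(pts) < 4) stop("too few points to fit accumulation models")
  t <- pts$t; S <- pts$S
  n <- length(t)

  fit_one <- function(formula, starts, lower) {
    best <- NULL
    for (st in starts) {
      f <- tryCatch(minpack.lm::nlsLM(formula, data = data.frame(t = t, S = S),
                                      start = st, lower = lower,
                                      control = minpack.lm::nls.lm.control(maxiter = 200)),
                    error = function(e) NULL)
      if (is.null(f)) next
      rss <- sum(stats::resid(f)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
    }
    best
  }

  smax0 <- max(S)
  fin <- fit_one(S ~ Smax * (1 - (1 - 1 / Smax)^t),
                 list(list(Smax = smax0 * 1.05), list(Smax = smax0 * 2),
                      list(Smax = smax0 * 10)),
                 lower = c(Smax = max(S) + 1e-6))
  pow <- fit_one(S ~ b * t^c,
                 list(list(b = 1, c = 0.5), list(b = max(S) / max(t), c = 1),
                      list(b = 10, c = 0.3)),
                 lower = c(b = 1e-12, c = 1e-12))

  pack <- function(res, k_par) {
    if (is.null(res)) return(list(converged = FALSE))
    cf <- stats::coef(res$fit)
    se <- tryCatch(sqrt(diag(stats::vcov(res$fit))), error = function(e)
      rep(NA_real_, length(cf)))
    k <- k_par + 1  # + error variance
    list(converged = TRUE, parameters = cf, se = se, rss = res$rss,
         aic = n * log(res$rss / n) + 2 * k, n = n, k = k)
  }
  finite <- pack(fin, 1); power <- pack(pow, 2)
  out <- list(finite = finite, power = power)
  if (finite$converged && power$converged) {
    d <- finite$aic - power$aic
    out$delta_aic <- abs(d)
    out$best <- if (d <= 0) "finite" else "power"
    out$support <- if (out$delta_aic < 2) "substantial"
      else if (out$delta_aic <= 7) "considerably less"
      else "essentially none"
  }
  out
}
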