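#' Conflict-annotation thresholds
#'
#' An alternative resolution counts as conflicting when supported at or
#' above 50% bootstrap or 0.97 posterior probability; reports use these
#' constants.
#'
#' @name conflict_thresholds
#' @export
CONFLICT_BOOTSTRAP <- 0.50

#' @rdname conflict_thresholds
#' @export
CONFLICT_POSTERIOR <- 0.97

#' Alternative resolutions around a focal internal branch
#'
#' The two nearest-neighbor-interchange rearrangements of the focal branch
#' of an unrooted binary tree, plus the original topology; optionally the
#' collapsed (polytomy) topology, represented as the original with the focal
#' branch flagged for constraint to zero length during re-optimization.
#'
#' @param tree unrooted binary `phylo`.
#' @param focal_branch row index into `tree$edge` of an internal branch.
#' @param include_collapsed also return the collapsed representation.
#' @return list with `original`, `nni1`, `nni2` (`phylo`, no branch
#'   lengths), and optionally `collapsed` (list of tree + `fixed_edge`).
#' @export
alternative_topologies <- function(tree, focal_branch,
                                   include_collapsed = FALSE) {
  tree <- ape::unroot(tree)
  ntip <- ape::Ntip(tree)
  a <- tree$edge[focal_branch, 1]; b <- tree$edge[focal_branch, 2]
  if (a <= ntip || b <= ntip)
    stop("focal branch is terminal; alternatives need an internal branch")
  tr <- phylo_to_adj(tree)
  # adjacency node ids: tips got ids 1..ntip in tip order, internals follow
  # in the order ape numbered them
  amap <- c(seq_len(ntip), ntip + seq_len(tree$Nnode))
  aa <- amap[a]; bb <- amap[b]
  xs <- setdiff(tr$adj[[aa]], bb)
  ys <- setdiff(tr$adj[[bb]], aa)
  swap <- function(x, y) {
    t2 <- adj_disconnect(tr, aa, x)
    t2 <- adj_disconnect(t2, bb, y)
    t2 <- adj_connect(t2, aa, y)
    adj_connect(t2, bb, x)
  }
  out <- list(original = tree,
              nni1 = adj_to_phylo(swap(xs[2], ys[1]), tree$tip.label),
              nni2 = adj_to_phylo(swap(xs[2], ys[2]), tree$tip.label))
  if (include_collapsed)
    out$collapsed <- list(tree = tree, fixed_edge = focal_branch)
  out
}

#' Partitioned likelihood support
#'
#' Per-partition sum of per-site log-likelihood differences between the best
#' topology and each alternative: positive values mean the partition's sites
#' support the best tree over that alternative. Columns sum exactly to the
#' total log-likelihood difference.
#'
#' @param slm a [site_likelihood_matrix()].
#' @param best column name of the best topology (default: highest total).
#' @return object of class `pls_table`: data frame partitions x
#'   alternatives, plus a `total` row.
#' @export
partitioned_support <- function(slm, best = NULL) {
  L <- slm$logl
  totals <- colSums(L)
  if (is.null(best)) best <- colnames(L)[which.max(totals)]
  if (!best %in% colnames(L)) stop("unknown topology: ", best)
  alts <- setdiff(colnames(L), best)
  parts <- unique(slm$partition)
  if (any(!parts %in% slm$partition)) stop("partition with no sites")
  tab <- matrix(0, length(parts), length(alts),
                dimnames = list(parts, alts))
  for (p in parts) {
    rows <- slm$partition == p
    for (a in alts)
      tab[p, a] <- sum(L[rows, best] - L[rows, a])
  }
  structure(list(pls = tab, best = best,
                 total = colSums(L[, best, drop = FALSE]) [1] - totals[alts]),
            class = "pls_table")
}

#' @export
print.pls_table <- function(x, ...) {
  cat("partitioned likelihood support (best =", x$best, ")\n")
  print(round(x$pls, 3))
  invisible(x)
}

#' RELL-based weighted Shimodaira-Hasegawa and approximately unbiased tests
#'
#' Both tests resample per-site log-likelihood vectors without
#' re-optimization (RELL). The weighted SH test standardizes each pairwise
#' log-likelihood difference by its bootstrap standard deviation, takes the
#' maximum over rivals as the statistic, and compares it against the
#' centered bootstrap null; it controls familywise error over the candidate
#' set and is conservative. The AU test runs a multiscale bootstrap over
#' `scales`, fits `z(r) = d*sqrt(r) + c/sqrt(r)` to the probit-transformed
#' per-scale bootstrap probabilities by weighted least squares, and reports
#' `p_AU = 1 - pnorm(d - c)`, correcting the selection bias of picking the
#' best tree.
#'
#' @param slm a [site_likelihood_matrix()] (2+ topologies).
#' @param n_boot bootstrap replicates per scale.
#' @param scales relative bootstrap sample sizes for the AU multiscale fit.
#' @param seed integer seed (results are deterministic given it).
#' @return data frame of class `topology_test_result`: topology, logLik,
#'   delta (to best), p_WSH, p_AU, au_d, au_c; attribute `settings`.
#' @export
topology_tests <- function(slm, n_boot = 10000,
                           scales = seq(0.5, 1.4, by = 0.1), seed = 1) {
  L <- slm$logl
  n <- nrow(L); m <- ncol(L)
  if (m < 2) stop("need at least two topologies")
  if (n < 100) warning("fewer than 100 sites; topology tests will be crude")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  totals <- colSums(L)
  degenerate <- all(apply(L, 1, function(r) max(r) - min(r)) < 1e-12)
  if (degenerate) {
    out <- data.frame(topology = colnames(L), logLik = totals, delta = 0,
                      p_WSH = 1, p_AU = 1, au_d = NA_real_, au_c = NA_real_)
    attr(out, "degenerate") <- TRUE
    class(out) <- c("topology_test_result", "data.frame")
    return(out)
  }

  # --- WSH at scale 1
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  Lb <- matrix(0, n_boot, m)
  for (j in seq_len(m)) {
    lj <- L[, j]
    Lb[, j] <- colSums(matrix(lj[idx], nrow = n))
  }
  Lc <- sweep(Lb, 2, colMeans(Lb))       # centered RELL totals
  sd_pair <- matrix(1e-12, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    s <- stats::sd(Lc[, j] - Lc[, i])
    sd_pair[i, j] <- sd_pair[j, i] <- max(s, 1e-12)
  }
  p_wsh <- numeric(m)
  for (i in seq_len(m)) {
    rivals <- setdiff(seq_len(m), i)
    t_obs <- max((totals[rivals] - totals[i]) / sd_pair[i, rivals])
    t_null <- do.call(pmax, lapply(rivals, function(j)
      (Lc[, j] - Lc[, i]) / sd_pair[i, j]))
    p_wsh[i] <- mean(t_null >= t_obs)
  }

  # --- AU multiscale
  bp <- matrix(0, length(scales), m)
  for (si in seq_along(scales)) {
    nr <- max(2L, round(n * scales[si]))
    idx <- matrix(sample.int(n, nr * n_boot, replace = TRUE), nrow = nr)
    Lb <- matrix(0, n_boot, m)
    for (j in seq_len(m)) {
      lj <- L[, j]
      Lb[, j] <- colSums(matrix(lj[idx], nrow = nr))
    }
    win <- max.col(Lb, ties.method = "random")
    bp[si, ] <- tabulate(win, m) / n_boot
  }
  au <- vapply(seq_len(m), function(i) {
    # a topology that never (always) wins at any scale has p 0 (1): the
    # probit fit is unidentified on flat clipped probabilities
    if (all(bp[, i] <= 1 / n_boot))
      return(c(d = NA_real_, c = NA_real_, p = 0))
    if (all(bp[, i] >= 1 - 1 / n_boot))
      return(c(d = NA_real_, c = NA_real_, p = 1))
    p <- pmin(pmax(bp[, i], 0.5 / n_boot), 1 - 0.5 / n_boot)
    z <- stats::qnorm(1 - p)
    w <- n_boot * stats::dnorm(z)^2 / (p * (1 - p))
    X <- cbind(sqrt(scales), 1 / sqrt(scales))
    cf <- stats::lm.wfit(X, z, w)$coefficients
    c(d = cf[1], c = cf[2],
      p = 1 - stats::pnorm(cf[1] - cf[2]))
  }, numeric(3))

  out <- data.frame(topology = colnames(L), logLik = totals,
                    delta = max(totals) - totals,
                    p_WSH = p_wsh, p_AU = pmin(pmax(au[3, ], 0), 1),
                    au_d = au[1, ], au_c = au[2, ])
  attr(out, "settings") <- list(n_boot = n_boot, scales = scales, seed = seed)
  class(out) <- c("topology_test_result", "data.frame")
  out
}

#' Append a random topology to a candidate set
#'
#' Likelihood-based tree comparisons are more interpretable when the range
#' of log-likelihood differences is anchored by a topology known to be poor;
#' this draws a random unrooted topology over the same taxa.
#'
#' @param taxa tip labels.
#' @param seed integer seed.
#' @return unrooted `phylo` without branch lengths.
#' @export
random_topology <- function(taxa, seed = 1) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  ape::rtopology(length(taxa), rooted = FALSE, tip.label = taxa)
}
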