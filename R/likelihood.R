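# --- generic pruning core --------------------------------------------------

# IUPAC tip likelihoods for nucleotides
iupac_partial <- function(ch) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = NT, "?" = NT, "-" = NT, "X" = NT)
  s <- sets[[ch]]
  if (is.null(s)) s <- NT
  as.numeric(NT %in% s)
}

# Compress an alignment chunk (taxa x sites of single characters) into
# patterns. Returns tip partial-likelihood matrices per taxon (s x npat),
# pattern weights and the site -> pattern map.
nt_patterns <- function(S) {
  key <- apply(S, 2, paste, collapse = "\r")
  u <- !duplicated(key)
  pat_idx <- match(key, key[u])
  P <- S[, u, drop = FALSE]
  tipL <- lapply(seq_len(nrow(P)), function(i)
    vapply(P[i, ], iupac_partial, numeric(4)))
  list(tipL = tipL, w = as.vector(table(factor(pat_idx, seq_len(sum(u))))),
       map = pat_idx, npat = sum(u))
}

# Felsenstein pruning over patterns. `Pfun(edge_row)` returns the transition
# matrix for that edge. Numerical underflow is handled by per-pattern
# rescaling (skipped on small trees, where 4-20 state partials cannot
# underflow); returns per-pattern log-likelihood given root frequencies.
prune_loglik <- function(tree, tipL, Pfun, root_freq,
                         rescale = ape::Ntip(tree) > 50) {
  ntip <- ape::Ntip(tree)
  nnode <- max(tree$edge)
  npat <- ncol(tipL[[1]])
  s <- length(root_freq)
  partial <- vector("list", nnode)
  for (i in seq_len(ntip)) partial[[i]] <- tipL[[i]]
  logscale <- numeric(npat)
  po <- reorder_rows(tree, "postorder")
  for (i in po) {
    p <- tree$edge[i, 1]; v <- tree$edge[i, 2]
    contrib <- Pfun(i) %*% partial[[v]]
    cur <- if (is.null(partial[[p]])) contrib else partial[[p]] * contrib
    if (rescale) {
      mx <- do.call(pmax, lapply(seq_len(s), function(r) cur[r, ]))
      low <- which(mx < 1e-280 & mx > 0)
      if (length(low)) {
        cur[, low] <- cur[, low] / rep(mx[low], each = s)
        logscale[low] <- logscale[low] + log(mx[low])
      }
    }
    partial[[p]] <- cur
  }
  root <- ntip + 1L
  lik <- as.vector(root_freq %*% partial[[root]])
  log(pmax(lik, 1e-320)) + logscale
}

# Per-pattern log-likelihood of a nucleotide model on a fixed tree with
# given edge lengths (optionally scaled by a partition rate multiplier).
# Gamma categories are stacked into one block-diagonal pruning pass.
nt_site_loglik <- function(tree, pat, model, edge_len, multiplier = 1) {
  Q <- gtr_Q(model$rates, model$pi)
  eig <- rev_eigen(Q, model$pi)
  rates <- if (model$n_cat > 0) discrete_gamma_rates(model$alpha, model$n_cat) else 1
  pinv <- model$p_inv
  nr <- length(rates)
  if (is.null(pat$tipL_stack) || pat$stack_nr != nr) {
    pat$tipL_stack <- lapply(pat$tipL, function(x)
      do.call(rbind, rep(list(x), nr)))
    pat$stack_nr <- nr
  }
  Ps <- lapply(seq_len(nrow(tree$edge)), function(i) {
    P <- matrix(0, 4 * nr, 4 * nr)
    for (k in seq_len(nr)) {
      ix <- (k - 1) * 4 + 1:4
      P[ix, ix] <- pmat(eig, edge_len[i] * multiplier * rates[k] / (1 - pinv))
    }
    P
  })
  ll <- prune_loglik(tree, pat$tipL_stack, function(i) Ps[[i]],
                     rep(model$pi, nr) / nr, rescale = ape::Ntip(tree) > 50)
  lik <- exp(ll) * (1 - pinv)
  if (pinv > 0) {
    # invariant-site mass: sites whose tips all admit a common state
    inv <- vapply(seq_len(pat$npat), function(k) {
      common <- rep(1, 4)
      for (tl in pat$tipL) common <- common * tl[, k]
      sum(model$pi * (common > 0))
    }, numeric(1))
    lik <- lik + pinv * inv
  }
  log(pmax(lik, 1e-320))
}

# --- parameter packing ------------------------------------------------------

pack_model <- function(model) {
  th <- numeric(0)
  if (model$constraint %in% c("SYM", "GTR")) th <- c(th, log(model$rates[1:5]))
  if (model$constraint == "HKY") th <- c(th, log(model$rates[2]))
  if (model$constraint %in% c("HKY", "GTR"))
    th <- c(th, log(model$pi[1:3] / model$pi[4]))
  if (model$p_inv > 0) th <- c(th, stats::qlogis(min(model$p_inv, 0.95)))
  if (model$n_cat > 0) th <- c(th, log(model$alpha))
  th
}

unpack_model <- function(th, template) {
  m <- template; k <- 0L
  if (m$constraint %in% c("SYM", "GTR")) {
    m$rates <- c(exp(th[k + 1:5]), 1); k <- k + 5L
  }
  if (m$constraint == "HKY") {
    kappa <- exp(th[k + 1]); k <- k + 1L
    m$rates <- c(1, kappa, 1, 1, kappa, 1)
  }
  if (m$constraint %in% c("HKY", "GTR")) {
    e <- exp(c(th[k + 1:3], 0)); m$pi <- e / sum(e); k <- k + 3L
  }
  if (m$p_inv > 0) { m$p_inv <- stats::plogis(th[k + 1]) * 0.99; k <- k + 1L }
  if (m$n_cat > 0) { m$alpha <- min(max(exp(th[k + 1]), 0.02), 100); k <- k + 1L }
  m
}

# --- partitioned fixed-topology fit ----------------------------------------

#' Fit a partitioned model on a fixed topology
#'
#' Joint optimization of shared branch lengths, per-partition substitution
#' parameters, and per-partition rate multipliers (site-weighted mean
#' constrained to 1) by alternating rounds of Brent search per edge and
#' bounded quasi-Newton on the model parameters, until the total
#' log-likelihood changes by less than `tol` between passes. Per-site
#' log-likelihoods are retained for downstream topology tests.
#'
#' @param tree fixed topology (`phylo`); starting branch lengths are used
#'   when present, otherwise 0.1.
#' @param aln a [seq_alignment()].
#' @param models a single [substitution_model()] (recycled) or a list, one
#'   per partition, giving the model structure for each partition.
#' @param optimize_model optimize substitution parameters (otherwise fixed
#'   as given).
#' @param multipliers estimate per-partition rate multipliers (forced to 1
#'   when `FALSE`, which enforces strictly identical branch lengths across
#'   partitions).
#' @param tol convergence tolerance on the total log-likelihood.
#' @param max_passes cap on alternating optimization passes.
#' @return object of class `partition_fit`: `tree` (with optimized branch
#'   lengths), `models`, `multipliers`, `logLik`, `site_loglik` (per site,
#'   original order), `partition_loglik`, `K` (free parameter count), `n`
#'   (sites), `AICc`, `BIC`.
#' @export
fit_tree <- function(tree, aln, models = substitution_model("GTR", n_cat = 4),
                     optimize_model = TRUE, multipliers = TRUE,
                     tol = 1e-6, max_passes = 60, fixed_edges = NULL,
                     fixed_edge_length = 1e-8) {
  np <- length(aln$partition_names)
  if (inherits(models, "substitution_model"))
    models <- rep(list(models), np)
  stopifnot(length(models) == np)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  tree$edge.length[tree$edge.length < 1e-8] <- 1e-8
  if (!all(aln$taxa %in% tree$tip.label) || !all(tree$tip.label %in% aln$taxa))
    stop("tree tips and alignment taxa must match")
  S <- aln$seqs[match(tree$tip.label, aln$taxa), , drop = FALSE]

  pats <- lapply(seq_len(np), function(k) {
    sites <- which(aln$partition == k)
    if (!length(sites)) stop("partition with no sites: ",
                             aln$partition_names[k])
    p <- c(nt_patterns(S[, sites, drop = FALSE]), list(sites = sites))
    nr <- max(1L, models[[k]]$n_cat)
    p$tipL_stack <- lapply(p$tipL, function(x) do.call(rbind, rep(list(x), nr)))
    p$stack_nr <- nr
    p
  })
  w_sites <- vapply(pats, function(p) length(p$sites), numeric(1))
  mult <- rep(1, np)

  # joint parameter vector: log edge lengths | model params per partition |
  # log multipliers for partitions 2..np (first is the reference; the set is
  # renormalized to site-weighted mean 1)
  ne <- nrow(tree$edge)
  mpar <- if (optimize_model) lapply(models, pack_model)
          else rep(list(numeric(0)), np)
  mlen <- lengths(mpar)
  nmul <- if (multipliers && np > 1) np - 1L else 0L
  unpack_all <- function(th) {
    el <- exp(th[seq_len(ne)])
    mods <- models
    off <- ne
    if (optimize_model) for (k in seq_len(np)) {
      if (mlen[k]) mods[[k]] <- unpack_model(th[off + seq_len(mlen[k])], models[[k]])
      off <- off + mlen[k]
    }
    mu <- rep(1, np)
    if (nmul) {
      mu[2:np] <- exp(th[off + seq_len(nmul)])
      mu <- mu / stats::weighted.mean(mu, w_sites)
    }
    list(el = el, models = mods, mult = mu)
  }
  obj <- function(th) {
    s <- unpack_all(th)
    -sum(vapply(seq_len(np), function(k)
      sum(pats[[k]]$w * nt_site_loglik(tree, pats[[k]], s$models[[k]],
                                       s$el, s$mult[k])), numeric(1)))
  }
  th <- c(log(tree$edge.length), unlist(mpar), rep(0, nmul))
  lower <- c(rep(log(1e-8), ne), rep(-8, sum(mlen)), rep(log(0.02), nmul))
  upper <- c(rep(log(10), ne), rep(8, sum(mlen)), rep(log(50), nmul))
  if (length(fixed_edges)) {
    # pin selected branches (e.g. a collapsed focal node) at a fixed length
    th[fixed_edges] <- log(fixed_edge_length)
    lower[fixed_edges] <- upper[fixed_edges] <- log(fixed_edge_length)
  }
  cur <- -obj(th)
  for (pass in seq_len(max_passes)) {
    o <- stats::optim(th, obj, method = "L-BFGS-B", lower = lower,
                      upper = upper, control = list(maxit = 200))
    if (-o$value > cur + 1e-12) th <- o$par
    improved <- -o$value - cur
    cur <- max(cur, -o$value)
    if (improved < tol) break
  }
  s <- unpack_all(th)
  tree$edge.length <- s$el
  models <- s$models
  mult <- s$mult

  site_ll <- numeric(ncol(S))
  part_totals <- numeric(np)
  for (k in seq_len(np)) {
    ll <- nt_site_loglik(tree, pats[[k]], models[[k]], tree$edge.length,
                         mult[k])
    site_ll[pats[[k]]$sites] <- ll[pats[[k]]$map]
    part_totals[k] <- sum(pats[[k]]$w * ll)
  }
  K <- sum(vapply(models, n_free_params, integer(1))) +
       (if (multipliers && np > 1) np - 1L else 0L) +
       nrow(tree$edge)
  n <- ncol(S)
  ll_tot <- sum(part_totals)
  structure(list(tree = tree, models = models, multipliers = mult,
                 logLik = ll_tot, site_loglik = site_ll,
                 partition_loglik = stats::setNames(part_totals,
                                                    aln$partition_names),
                 K = K, n = n,
                 AICc = -2 * ll_tot + 2 * K + 2 * K * (K + 1) / max(n - K - 1, 1),
                 BIC = -2 * ll_tot + K * log(n)),
            class = "partition_fit")
}

#' @export
print.partition_fit <- function(x, ...) {
  cat(sprintf("partition_fit: lnL = %.4f, K = %d, n = %d sites\n",
              x$logLik, x$K, x$n))
  cat(sprintf("  AICc = %.2f  BIC = %.2f\n", x$AICc, x$BIC))
  invisible(x)
}

#' Best-fit substitution model for a partition by AICc
#'
#' Fits every candidate (constraint x rate-heterogeneity combination) on a
#' fixed topology (a Jukes-Cantor neighbor-joining tree when none is given),
#' optimizing branch lengths and model parameters, and ranks by
#' `AICc = -2 lnL + 2K + 2K(K+1)/(n-K-1)` where `K` counts substitution
#' parameters plus branch lengths and `n` is the site count.
#'
#' @param aln a [seq_alignment()].
#' @param partition partition name/id (default: all sites).
#' @param tree optional fixed topology.
#' @param constraints model families to try.
#' @param heterogeneity rate-variation add-ons: subsets of
#'   `c("", "G", "I", "IG")`.
#' @return list with `best` (`substitution_model`), `best_fit`
#'   (`partition_fit`), and `table` (model, K, lnL, AICc, sorted).
#' @export
select_substitution_model <- function(aln, partition = NULL, tree = NULL,
                                      constraints = c("JC", "HKY", "SYM", "GTR"),
                                      heterogeneity = c("", "G", "I", "IG")) {
  sites <- if (is.null(partition)) seq_len(ncol(aln$seqs))
           else partition_sites(aln, partition)
  sub <- seq_alignment(aln$seqs[, sites, drop = FALSE], taxa = aln$taxa)
  if (is.null(tree)) {
    d <- ape::dist.dna(ape::as.DNAbin(tolower(sub$seqs)), model = "JC69",
                       pairwise.deletion = TRUE)
    d[!is.finite(d)] <- max(d[is.finite(d)], 1) * 2
    tree <- ape::nj(d)
    tree$edge.length[tree$edge.length < 0] <- 1e-8
  }
  emp_pi <- base_freqs(sub$seqs)
  rows <- NULL; fits <- list()
  for (cs in constraints) for (h in heterogeneity) {
    m <- substitution_model(cs,
                            pi = if (cs %in% c("HKY", "GTR")) emp_pi else rep(0.25, 4),
                            p_inv = if (grepl("I", h)) 0.2 else 0,
                            alpha = 1,
                            n_cat = if (grepl("G", h)) 4L else 0L)
    nm <- paste0(cs, switch(h, G = "+G", I = "+I", IG = "+I+G", ""))
    K <- n_free_params(m) + nrow(tree$edge)
    if (ncol(sub$seqs) <= K + 1) {
      warning("skipping ", nm, ": fewer sites than parameters + 1")
      next
    }
    fit <- fit_tree(tree, sub, m, tol = 1e-4, max_passes = 12)
    fits[[nm]] <- fit
    rows <- rbind(rows, data.frame(model = nm, K = fit$K, logLik = fit$logLik,
                                   AICc = fit$AICc))
  }
  rows <- rows[order(rows$AICc), ]
  best_nm <- rows$model[1]
  list(best = fits[[best_nm]]$models[[1]], best_fit = fits[[best_nm]],
       table = rows)
}

base_freqs <- function(S) {
  cnt <- table(factor(S[ambig_ok(S)], NT))
  p <- as.numeric(cnt) + 1e-6
  p / sum(p)
}

#' Compare partitioning schemes on a fixed topology
#'
#' AICc and BIC from each scheme's fit, plus the decision-theoretic risk
#' `risk_i = sum_j w_j * d(i, j)` where `d` is the Euclidean distance
#' between optimized branch-length vectors and `w_j` are BIC weights
#' (`w_j` proportional to `exp(-BIC_j / 2)`). The scheme minimizing each
#' criterion is reported.
#'
#' @param fits named list of `partition_fit` objects on the same topology
#'   and site set.
#' @return list with `table` (scheme, K, lnL, AICc, BIC, DT risk) and
#'   `winner` (named vector per criterion).
#' @export
compare_partition_schemes <- function(fits) {
  if (is.null(names(fits))) names(fits) <- paste0("scheme", seq_along(fits))
  keys <- vapply(fits, function(f) topology_key(f$tree), character(1))
  if (length(unique(keys)) != 1) stop("fits are on different topologies")
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1) stop("fits are on different site sets")
  bl <- lapply(fits, function(f) sort_edge_lengths(f$tree))
  bic <- vapply(fits, function(f) f$BIC, numeric(1))
  w <- exp(-(bic - min(bic)) / 2); w <- w / sum(w)
  risk <- vapply(seq_along(fits), function(i)
    sum(w * vapply(seq_along(fits), function(j)
      sqrt(sum((bl[[i]] - bl[[j]])^2)), numeric(1))), numeric(1))
  tab <- data.frame(scheme = names(fits),
                    K = vapply(fits, function(f) f$K, numeric(1)),
                    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
                    AICc = vapply(fits, function(f) f$AICc, numeric(1)),
                    BIC = bic, DT_risk = risk)
  list(table = tab,
       winner = c(AICc = tab$scheme[which.min(tab$AICc)],
                  BIC = tab$scheme[which.min(tab$BIC)],
                  DT = tab$scheme[which.min(tab$DT_risk)]))
}

# branch lengths keyed by the tip-set split, so vectors align across fits
sort_edge_lengths <- function(tree) {
  ntip <- ape::Ntip(tree)
  below <- vector("list", max(tree$edge))
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  key <- character(nrow(tree$edge))
  for (i in reorder_rows(tree, "postorder")) {
    p <- tree$edge[i, 1]; v <- tree$edge[i, 2]
    below[[p]] <- c(below[[p]], below[[v]])
    key[i] <- paste(sort(below[[v]]), collapse = "|")
  }
  stats::setNames(tree$edge.length, key)[order(key)]
}

# --- site-likelihood interchange -------------------------------------------

#' Write/read the site-likelihood matrix
#'
#' Tab-separated interchange between the likelihood engine and the topology
#' tests: columns `site`, `partition`, then one log-likelihood column per
#' candidate topology.
#'
#' @param slm matrix/data.frame: rows sites, columns topologies; or the list
#'   produced by [site_likelihood_matrix()].
#' @param path file path.
#' @name site_likelihood_io
#' @export
write_site_likelihoods <- function(slm, path) {
  df <- data.frame(site = seq_len(nrow(slm$logl)),
                   partition = slm$partition, slm$logl,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname site_likelihood_io
#' @export
read_site_likelihoods <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  site_likelihood_matrix(as.matrix(df[, -(1:2), drop = FALSE]),
                         partition = df$partition)
}

#' Bundle per-site log-likelihoods for several candidate topologies
#'
#' @param logl numeric matrix: rows sites, one column per topology (named).
#' @param partition per-site partition labels (single label recycled).
#' @return object of class `site_likelihood_matrix`.
#' @export
site_likelihood_matrix <- function(logl, partition = "all") {
  logl <- as.matrix(logl)
  if (any(!is.finite(logl))) stop("non-finite site log-likelihoods")
  if (is.null(colnames(logl)))
    colnames(logl) <- paste0("tree", seq_len(ncol(logl)))
  partition <- rep_len(as.character(partition), nrow(logl))
  structure(list(logl = logl, partition = partition),
            class = "site_likelihood_matrix")
}
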