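# --- codon model machinery --------------------------------------------------

# Precompute the single-nucleotide-change structure of the sense-codon space.
codon_structure <- function(code = "vertebrate_mt") {
  gc <- genetic_code(code)
  codons <- gc$codons
  s <- length(codons)
  aa <- unlist(gc$table[codons])
  cm <- do.call(rbind, strsplit(codons, ""))
  diffpos <- matrix(0L, s, s)
  ti <- matrix(FALSE, s, s)
  for (i in seq_len(s)) for (j in seq_len(s)) {
    if (i == j) next
    d <- which(cm[i, ] != cm[j, ])
    if (length(d) == 1L) {
      diffpos[i, j] <- d
      ti[i, j] <- is_transition(cm[i, d], cm[j, d])
    }
  }
  list(codons = codons, aa = aa, s = s, single = diffpos > 0, ti = ti,
       nonsyn = outer(aa, aa, "!="), cm = cm, code = code)
}

codon_struct_cache <- new.env(parent = emptyenv())
get_codon_structure <- function(code) {
  if (is.null(codon_struct_cache[[code]]))
    codon_struct_cache[[code]] <- codon_structure(code)
  codon_struct_cache[[code]]
}

# F3x4 codon frequencies from position-specific base frequencies.
f3x4_freqs <- function(aln, struct) {
  nc <- ncol(aln$seqs) / 3L
  pos_pi <- lapply(1:3, function(p) {
    cols <- seq(p, ncol(aln$seqs), by = 3)
    base_freqs(aln$seqs[, cols, drop = FALSE])
  })
  pi <- vapply(seq_len(struct$s), function(i) {
    prod(vapply(1:3, function(p)
      pos_pi[[p]][match(struct$cm[i, p], NT)], numeric(1)))
  }, numeric(1))
  pi / sum(pi)
}

# Goldman-Yang style codon rate matrix, scaled to one expected substitution
# per codon at stationarity.
codon_Q <- function(kappa, omega, pi, struct) {
  R <- matrix(0, struct$s, struct$s)
  R[struct$single] <- 1
  R[struct$single & struct$ti] <- kappa
  R[struct$single & struct$nonsyn] <-
    R[struct$single & struct$nonsyn] * omega
  Q <- R * rep(pi, each = struct$s)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

codon_patterns <- function(aln, struct) {
  nc <- ncol(aln$seqs) / 3L
  X <- matrix(0L, nrow(aln$seqs), nc, dimnames = list(aln$taxa, NULL))
  for (i in seq_len(nrow(X))) for (k in seq_len(nc)) {
    cod <- paste(aln$seqs[i, (3 * k - 2):(3 * k)], collapse = "")
    X[i, k] <- match(cod, struct$codons, nomatch = 0L)  # 0 = ambiguous/gap
  }
  key <- apply(X, 2, paste, collapse = ",")
  u <- !duplicated(key)
  map <- match(key, key[u])
  P <- X[, u, drop = FALSE]
  tipL <- lapply(seq_len(nrow(P)), function(i) {
    M <- matrix(0, struct$s, ncol(P))
    for (k in seq_len(ncol(P))) {
      if (P[i, k] > 0) M[P[i, k], k] <- 1 else M[, k] <- 1
    }
    M
  })
  list(tipL = tipL, w = as.vector(table(factor(map, seq_len(sum(u))))),
       map = map, npat = sum(u), n_codons = nc)
}

# Edges belonging to a foreground clade: the stem edge of the MRCA of
# `tips` plus all edges among its descendants.
#' Foreground branch set of a clade
#' @param tree `phylo`.
#' @param tips tip labels defining the clade (MRCA stem + descendants).
#' @return integer vector of `tree$edge` row indices.
#' @export
foreground_edges <- function(tree, tips) {
  stopifnot(all(tips %in% tree$tip.label))
  if (length(tips) == 1L) return(which(tree$edge[, 2] ==
                                         match(tips, tree$tip.label)))
  mrca <- ape::getMRCA(tree, tips)
  desc <- c(mrca, phangorn::Descendants(tree, mrca, type = "all"))
  which(tree$edge[, 2] %in% desc)
}

# per-class, per-edge site likelihood for a codon class
codon_class_lik <- function(tree, pat, eig_bg, eig_fg, fg_edges, edge_len) {
  Ps <- lapply(seq_len(nrow(tree$edge)), function(i) {
    e <- if (i %in% fg_edges) eig_fg else eig_bg
    pmat(e$eig, edge_len[i])
  })
  pi <- eig_bg$pi
  exp(prune_loglik(tree, pat$tipL, function(i) Ps[[i]], pi,
                   rescale = ape::Ntip(tree) > 25))
}

#' Fit a codon site-class model (nearly neutral or clade model C)
#'
#' The nearly-neutral (M1a) model mixes two site classes, purifying
#' (`0 < omega0 < 1`, proportion `p0`) and neutral (`omega = 1`); clade
#' model C adds a third, divergent class whose omega differs between a
#' designated foreground clade (`omega2_fg`) and the background
#' (`omega2_bg`). Codon frequencies are F3x4 from the observed
#' position-specific base frequencies (F61 by flag); rate matrices are
#' Goldman-Yang with transition/transversion ratio `kappa`, each class
#' scaled to one expected substitution per codon. The likelihood is a
#' pruning-algorithm mixture; optimization is bounded quasi-Newton
#' multi-started over a grid of omega starting values. Posterior site-class
#' probabilities at the MLEs (naive empirical Bayes) are retained.
#'
#' @param aln codon [seq_alignment()].
#' @param tree `phylo` with branch lengths in expected substitutions per
#'   codon.
#' @param model `"M1a"` or `"cladeC"`.
#' @param foreground tip labels of the foreground clade (cladeC only).
#' @param optimize_branch_lengths jointly optimize branch lengths (slower);
#'   otherwise they are fixed as given.
#' @param omega_starts starting values for the omega parameters; the
#'   default multi-start grid follows common practice for these models.
#' @param freq `"F3x4"` or `"F61"` codon frequencies.
#' @return object of class `codon_model_fit`: `logLik`, `params` (kappa,
#'   p0, p1, omega0, omega2_bg, omega2_fg as applicable), `posterior`
#'   (sites x classes), `site_loglik`, `start_log`, `df` (free parameter
#'   count), `model`, `foreground`.
#' @export
fit_codon_model <- function(aln, tree, model = c("M1a", "cladeC"),
                            foreground = NULL,
                            optimize_branch_lengths = FALSE,
                            omega_starts = c(0.001, 0.01, 0.1, 1, 10),
                            freq = c("F3x4", "F61")) {
  model <- match.arg(model); freq <- match.arg(freq)
  stopifnot(aln$type == "codon")
  struct <- get_codon_structure(aln$code)
  tree <- ape::reorder.phylo(tree, "postorder")
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  if (!setequal(aln$taxa, tree$tip.label))
    stop("alignment taxa and tree tips must match")
  ord <- match(tree$tip.label, aln$taxa)
  aln$seqs <- aln$seqs[ord, , drop = FALSE]
  aln$taxa <- aln$taxa[ord]
  pat <- codon_patterns(aln, struct)
  if (all(vapply(seq_len(pat$npat), function(k)
    length(unique(vapply(pat$tipL, function(M) which.max(M[, k]), 1L))) == 1L,
    logical(1))))
    warning("no substitutions observed: omega is unidentifiable")
  pi <- if (freq == "F3x4") f3x4_freqs(aln, struct) else {
    cnt <- tabulate(unlist(lapply(pat$tipL, function(M)
      apply(M, 2, function(col) if (sum(col) == 1) which.max(col) else NA))),
      struct$s)
    (cnt + 1) / sum(cnt + 1)
  }
  fg_edges <- integer(0)
  if (model == "cladeC") {
    if (is.null(foreground) || !length(foreground))
      stop("cladeC needs a non-empty foreground clade")
    fg_edges <- foreground_edges(tree, foreground)
  }
  ne <- nrow(tree$edge)
  optbl <- isTRUE(optimize_branch_lengths)

  # parameter vector: [log kappa | class mix | log omegas | (log edges)]
  n_mix <- if (model == "M1a") 1L else 2L
  n_om <- if (model == "M1a") 1L else 3L
  build <- function(th) {
    kappa <- exp(th[1])
    mix_raw <- th[1 + seq_len(n_mix)]
    p <- exp(c(mix_raw, 0)); p <- p / sum(p)
    om <- exp(th[1 + n_mix + seq_len(n_om)])
    el <- if (optbl) exp(th[1 + n_mix + n_om + seq_len(ne)])
          else tree$edge.length
    list(kappa = kappa, p = p, om = om, el = el)
  }
  site_lik <- function(pp) {
    w0 <- min(pp$om[1], 0.999)
    eig_w0 <- list(eig = rev_eigen(codon_Q(pp$kappa, w0, pi, struct), pi), pi = pi)
    eig_w1 <- list(eig = rev_eigen(codon_Q(pp$kappa, 1, pi, struct), pi), pi = pi)
    cls <- list(codon_class_lik(tree, pat, eig_w0, eig_w0, fg_edges, pp$el),
                codon_class_lik(tree, pat, eig_w1, eig_w1, fg_edges, pp$el))
    if (model == "cladeC") {
      eig_bg <- list(eig = rev_eigen(codon_Q(pp$kappa, pp$om[2], pi, struct), pi), pi = pi)
      eig_fg <- list(eig = rev_eigen(codon_Q(pp$kappa, pp$om[3], pi, struct), pi), pi = pi)
      cls[[3]] <- codon_class_lik(tree, pat, eig_bg, eig_fg, fg_edges, pp$el)
    }
    cls
  }
  negll <- function(th) {
    pp <- build(th)
    cls <- site_lik(pp)
    lik <- Reduce(`+`, Map(function(L, w) L * w, cls, pp$p))
    -sum(pat$w * log(pmax(lik, 1e-320)))
  }

  starts <- lapply(omega_starts, function(w) {
    om0 <- min(w, 0.9)
    th <- c(log(2), rep(log(4), n_mix),
            log(c(om0, if (model == "cladeC") c(max(w, 1e-3), max(w, 1e-3)))))
    if (optbl) th <- c(th, log(pmax(tree$edge.length, 1e-6)))
    th
  })
  lower <- c(log(0.05), rep(-12, n_mix), rep(log(1e-6), n_om),
             if (optbl) rep(log(1e-8), ne))
  upper <- c(log(50), rep(12, n_mix),
             c(log(0.999), if (model == "cladeC") rep(log(50), 2)),
             if (optbl) rep(log(10), ne))
  best <- NULL; slog <- NULL
  for (si in seq_along(starts)) {
    o <- try(stats::optim(starts[[si]], negll, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = 300)), silent = TRUE)
    if (inherits(o, "try-error")) next
    slog <- rbind(slog, data.frame(start_omega = omega_starts[si],
                                   logLik = -o$value,
                                   converged = o$convergence == 0))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("all codon-model starts failed")
  pp <- build(best$par)
  cls <- site_lik(pp)
  mat <- do.call(cbind, Map(function(L, w) L * w, cls, pp$p))
  lik <- rowSums(mat)
  post <- mat / lik
  site_ll <- log(lik)[pat$map]
  params <- c(kappa = pp$kappa, p0 = pp$p[1], p1 = pp$p[2], omega0 = pp$om[1])
  df <- 1L + n_mix + n_om   # kappa + mixture proportions + free omegas
  if (model == "cladeC")
    params <- c(params, p2 = pp$p[3], omega2_bg = pp$om[2],
                omega2_fg = pp$om[3])
  structure(list(logLik = -best$value, params = params,
                 posterior = post[pat$map, , drop = FALSE],
                 site_loglik = site_ll, start_log = slog,
                 df = df + if (optbl) ne else 0L,
                 model = model, foreground = foreground,
                 pi = pi, tree = tree),
            class = "codon_model_fit")
}

#' @export
print.codon_model_fit <- function(x, ...) {
  cat(sprintf("codon_model_fit (%s): lnL = %.4f\n", x$model, x$logLik))
  print(round(x$params, 5))
  invisible(x)
}

#' Likelihood-ratio test for a clade-specific selection shift
#'
#' Compares the nearly-neutral fit against clade model C on the same data:
#' `2 * (lnL_alt - lnL_null)` against chi-square with `df` equal to the
#' difference in free parameters (3: the divergent-class proportion and its
#' two omegas). Codons assigned to the divergent class with posterior
#' probability at or above `eb_threshold` are flagged.
#'
#' @param null_fit `codon_model_fit` with `model == "M1a"`.
#' @param alt_fit `codon_model_fit` with `model == "cladeC"`.
#' @param eb_threshold posterior threshold for flagging codons.
#' @return list with `lrt`, `df`, `p`, `flagged` (codon indices),
#'   `posterior_divergent`.
#' @export
selection_shift_test <- function(null_fit, alt_fit, eb_threshold = 0.95) {
  stopifnot(null_fit$model == "M1a", alt_fit$model == "cladeC")
  lrt <- 2 * (alt_fit$logLik - null_fit$logLik)
  if (lrt < -1e-4)
    stop("alternative fit worse than null beyond tolerance: ",
         "rerun with more starting values")
  lrt <- max(lrt, 0)
  df <- 3L
  post2 <- alt_fit$posterior[, 3]
  list(lrt = lrt, df = df,
       p = stats::pchisq(lrt, df, lower.tail = FALSE),
       flagged = which(post2 >= eb_threshold),
       posterior_divergent = post2)
}
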