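AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
        "F", "P", "S", "T", "W", "Y", "V")

#' The mtMAM amino-acid replacement model
#'
#' Exchangeabilities and stationary frequencies of the empirical replacement
#' model estimated from mammalian mitochondrial proteins, taken from the
#' model library shipped with \pkg{phangorn}. Alternative empirical models
#' can be supplied wherever a `list(Q, pi)` in this layout is accepted.
#'
#' @return list with `Q` (20x20 scaled rate matrix, rows/cols in
#'   `ARNDCQEGHILKMFPSTWYV` order) and `pi` (frequencies).
#' @export
mtmam_model <- function() {
  env <- environment()
  Q <- NULL; bf <- NULL
  getAA <- get("getModelAA", envir = asNamespace("phangorn"))
  getAA("mtmam", bf = TRUE, Q = TRUE)   # assigns Q (lower triangle) and bf here
  s <- length(bf)
  M <- matrix(0, s, s, dimnames = list(toupper(AA), toupper(AA)))
  M[lower.tri(M)] <- Q
  M <- M + t(M)
  M <- M * rep(bf, each = s)
  diag(M) <- -rowSums(M)
  mu <- -sum(bf * diag(M))
  list(Q = M / mu, pi = bf)
}

aa_patterns <- function(aa_mat) {
  bad <- !(aa_mat %in% AA)
  if (any(bad)) {
    warning(sum(bad), " non-standard residue(s) treated as missing")
  }
  key <- apply(aa_mat, 2, paste, collapse = "\r")
  u <- !duplicated(key)
  map <- match(key, key[u])
  P <- aa_mat[, u, drop = FALSE]
  tipL <- lapply(seq_len(nrow(P)), function(i) {
    M <- matrix(0, 20, ncol(P))
    for (k in seq_len(ncol(P))) {
      j <- match(P[i, k], AA)
      if (is.na(j)) M[, k] <- 1 else M[j, k] <- 1
    }
    M
  })
  list(tipL = tipL, w = as.vector(table(factor(map, seq_len(sum(u))))),
       map = map, npat = sum(u))
}

aa_site_loglik <- function(tree, pat, model, edge_len) {
  eig <- rev_eigen(model$Q, model$pi)
  Ps <- lapply(edge_len, function(t) pmat(eig, t))
  prune_loglik(tree, pat$tipL, function(i) Ps[[i]], model$pi,
               rescale = ape::Ntip(tree) > 25)
}

# optimize branch lengths of `tree` under the protein model
fit_protein_tree <- function(tree, pat, model, max_iter = 200) {
  tree <- ape::reorder.phylo(tree, "postorder")
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  tree$edge.length[tree$edge.length < 1e-8] <- 1e-8
  ne <- nrow(tree$edge)
  obj <- function(th)
    -sum(pat$w * aa_site_loglik(tree, pat, model, exp(th)))
  o <- stats::optim(log(tree$edge.length), obj, method = "L-BFGS-B",
                    lower = rep(log(1e-8), ne), upper = rep(log(10), ne),
                    control = list(maxit = max_iter))
  tree$edge.length <- exp(o$par)
  list(tree = tree, logLik = -o$value)
}

#' Per-site amino-acid support profile between two topologies
#'
#' Optimizes branch lengths of each topology under an empirical replacement
#' model (mtMAM by default) and returns the per-site log-likelihood
#' difference `lnL(with) - lnL(without)`. Positive sites support the
#' `tree_with` resolution (synapomorphies of the focal clade), negative
#' sites reject it. The per-site differences sum to the total difference
#' exactly.
#'
#' @param aa_aln amino-acid matrix (taxa x sites, one-letter codes), e.g.
#'   from [translate_codons()].
#' @param tree_with,tree_without the two topologies to compare.
#' @param matrix replacement model, a `list(Q, pi)`; default [mtmam_model()].
#' @return list with `delta` (per-site differences), `logLik_with`,
#'   `logLik_without`, `site_with`, `site_without`.
#' @export
site_support_profile <- function(aa_aln, tree_with, tree_without,
                                 matrix = mtmam_model()) {
  stopifnot(all(rownames(aa_aln) %in% tree_with$tip.label),
            setequal(tree_with$tip.label, tree_without$tip.label))
  run <- function(tree) {
    A <- aa_aln[match(tree$tip.label, rownames(aa_aln)), , drop = FALSE]
    pat <- aa_patterns(A)
    ft <- fit_protein_tree(tree, pat, matrix)
    ll <- aa_site_loglik(ft$tree, pat, matrix, ft$tree$edge.length)
    list(site = ll[pat$map], total = sum(pat$w * ll))
  }
  w <- run(tree_with); wo <- run(tree_without)
  list(delta = w$site - wo$site,
       logLik_with = w$total, logLik_without = wo$total,
       site_with = w$site, site_without = wo$site)
}

#' Association between selection-shifted codons and topology-support extremes
#'
#' Classifies each site of an observed per-site support profile as a
#' support extreme, middle, or rejection extreme relative to the percentile
#' envelope of pooled null profiles (simulated under the null codon model on
#' the without-clade topology and profiled identically), then tests whether
#' flagged (selection-shifted) codons are over-represented among the
#' extremes (G-test of independence on the 3x2 table, df 2) and whether they
#' associate with annotated protein regions (regions x flagged G-test).
#'
#' @param profile numeric per-site log-likelihood differences (observed).
#' @param flags integer indices of selection-flagged codons.
#' @param null_profiles list of numeric vectors (or a matrix, sites in
#'   columns) of null per-site differences.
#' @param regions optional character vector: region label per site (must
#'   cover every site).
#' @param probs envelope percentiles.
#' @return list with `category` (per site), `envelope`, `extremes_test`
#'   (G, df, p), `table`, and when regions are given `regions_test`,
#'   `regions_table`.
#' @export
convergence_association <- function(profile, flags, null_profiles,
                                    regions = NULL,
                                    probs = c(0.025, 0.975)) {
  pooled <- unlist(null_profiles)
  env <- stats::quantile(pooled, probs = probs, names = FALSE)
  category <- ifelse(profile > env[2], "support-extreme",
                     ifelse(profile < env[1], "rejection-extreme", "middle"))
  n <- length(profile)
  if (!length(flags)) {
    return(list(category = category, envelope = env,
                extremes_test = NULL, note = "no flagged codons: association undefined"))
  }
  flagged <- seq_len(n) %in% flags
  tab <- table(factor(category, c("support-extreme", "middle",
                                  "rejection-extreme")),
               factor(flagged, c(FALSE, TRUE)))
  ex <- g_test_independence(tab)
  out <- list(category = category, envelope = env, table = tab,
              extremes_test = ex)
  if (!is.null(regions)) {
    if (length(regions) != n) stop("region annotation must cover every site")
    rt <- table(factor(regions), factor(flagged, c(FALSE, TRUE)))
    out$regions_table <- rt
    out$regions_test <- g_test_independence(rt)
  }
  out
}
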