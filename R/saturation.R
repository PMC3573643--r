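ambig_ok <- function(x) x %in% NT

#' Pairwise maximum-likelihood distance under a GTR-family model
#'
#' Branch length (expected substitutions/site) maximizing the pairwise
#' likelihood, with the model's exchangeabilities, frequencies, invariant
#' proportion and gamma shape held fixed (alignment-wide estimates);
#' optimized by Brent search to tolerance 1e-8. Under Jukes-Cantor with no
#' rate heterogeneity this equals the closed form `-3/4 log(1 - 4p/3)`.
#'
#' @param x,y aligned character vectors over `A,C,G,T` (other symbols are
#'   excluded pairwise).
#' @param model a [substitution_model()].
#' @return distance (Inf when saturated beyond the search bound).
#' @export
ml_pair_distance <- function(x, y, model = substitution_model("JC")) {
  keep <- ambig_ok(x) & ambig_ok(y)
  x <- x[keep]; y <- y[keep]
  if (!length(x)) return(NA_real_)
  tab <- table(factor(x, NT), factor(y, NT))
  if (sum(tab) == sum(diag(tab))) return(0)
  Q <- gtr_Q(model$rates, model$pi)
  eig <- rev_eigen(Q, model$pi)
  rates <- if (model$n_cat > 0) discrete_gamma_rates(model$alpha, model$n_cat) else 1
  pinv <- model$p_inv
  negll <- function(t) {
    F <- matrix(0, 4, 4)
    for (r in rates) F <- F + pmat(eig, t * r) / length(rates)
    F <- model$pi * F * (1 - pinv)
    if (pinv > 0) diag(F) <- diag(F) + pinv * model$pi
    F[F < 1e-300] <- 1e-300
    -sum(tab * log(F))
  }
  opt <- stats::optimize(negll, c(1e-9, 20), tol = 1e-8)
  if (opt$minimum > 19) return(Inf)
  opt$minimum
}

#' Saturation profile of one partition
#'
#' For every sequence pair with sufficient overlap, uncorrected p-distances
#' split into transition-type and transversion-type mismatches, and the
#' model-corrected maximum-likelihood distance. The saturation signal is the
#' ordinary least-squares slope (with intercept by default) of each
#' uncorrected distance on the corrected distance: slopes near 0 mean
#' observed differences no longer track evolutionary change.
#'
#' @param aln a [seq_alignment()].
#' @param partition partition name or id (default: all sites).
#' @param model a [substitution_model()] with alignment-wide parameters.
#' @param min_overlap minimum shared unambiguous sites for a pair to count.
#' @param intercept fit the slope with an intercept (set `FALSE` to force
#'   the line through the origin).
#' @return object of class `saturation_profile`: matrices `d_ti`, `d_tv`,
#'   `d_corr`; `slope_ti`, `slope_tv` (NA when undefined); `n_pairs_used`,
#'   `skipped_pairs`; and the base-homogeneity test (`chisq`, `df`,
#'   `p_chisq`).
#' @export
distance_profile <- function(aln, partition = NULL,
                             model = substitution_model("JC"),
                             min_overlap = 50, intercept = TRUE) {
  sites <- if (is.null(partition)) seq_len(ncol(aln$seqs))
           else partition_sites(aln, partition)
  S <- aln$seqs[, sites, drop = FALSE]
  n <- nrow(S)
  if (n < 3) stop("need at least 3 sequences")
  d_ti <- d_tv <- d_corr <- matrix(0, n, n,
                                   dimnames = list(aln$taxa, aln$taxa))
  skipped <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    keep <- ambig_ok(S[i, ]) & ambig_ok(S[j, ])
    if (sum(keep) < min_overlap) {
      skipped <- rbind(skipped, data.frame(i = aln$taxa[i], j = aln$taxa[j],
                                           shared = sum(keep)))
      d_ti[i, j] <- d_ti[j, i] <- NA
      d_tv[i, j] <- d_tv[j, i] <- NA
      d_corr[i, j] <- d_corr[j, i] <- NA
      next
    }
    x <- S[i, keep]; y <- S[j, keep]
    diff <- x != y
    ti <- diff & is_transition(x, y)
    d_ti[i, j] <- d_ti[j, i] <- sum(ti) / sum(keep)
    d_tv[i, j] <- d_tv[j, i] <- sum(diff & !ti) / sum(keep)
    d_corr[i, j] <- d_corr[j, i] <- ml_pair_distance(x, y, model)
  }
  ut <- upper.tri(d_corr)
  ok <- ut & is.finite(d_corr) & !is.na(d_corr)
  slope <- function(yv) {
    xs <- d_corr[ok]; ys <- yv[ok]
    if (length(xs) < 2 || stats::var(xs) == 0) return(NA_real_)
    if (intercept) unname(stats::coef(stats::lm(ys ~ xs))[2])
    else sum(xs * ys) / sum(xs^2)
  }
  hom <- base_homogeneity_test(aln, partition)
  structure(list(partition = if (is.null(partition)) "all" else partition,
                 d_ti = d_ti, d_tv = d_tv, d_corr = d_corr,
                 slope_ti = slope(d_ti), slope_tv = slope(d_tv),
                 n_pairs_used = sum(ok), skipped_pairs = skipped,
                 chisq = hom$chisq, df = hom$df, p_chisq = hom$p),
            class = "saturation_profile")
}

#' Chi-square test of base-composition homogeneity across taxa
#'
#' Taxa x base contingency table (gaps and ambiguity codes excluded) tested
#' against pooled frequencies. Bases absent from every taxon are dropped
#' with a warning and the degrees of freedom adjusted; taxa with no
#' countable sites are dropped likewise.
#'
#' @param aln a [seq_alignment()].
#' @param partition partition name or id (default all sites).
#' @return list with `chisq`, `df`, `p`, and the count `table`.
#' @export
base_homogeneity_test <- function(aln, partition = NULL) {
  sites <- if (is.null(partition)) seq_len(ncol(aln$seqs))
           else partition_sites(aln, partition)
  S <- aln$seqs[, sites, drop = FALSE]
  if (nrow(S) < 2) stop("need at least 2 sequences")
  tab <- t(apply(S, 1, function(r) table(factor(r[ambig_ok(r)], NT))))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  drop <- colSums(tab) == 0
  if (any(drop)) {
    warning("base(s) absent from all taxa dropped: ",
            paste(colnames(tab)[drop], collapse = ", "))
    tab <- tab[, !drop, drop = FALSE]
  }
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chisq <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE), table = tab)
}

#' Exclusion/down-weighting scheme from saturation slopes
#'
#' Operationalizes the treatment of saturated partitions: a transition slope
#' at or below `exclude_below` marks observed change as fully independent of
#' evolutionary change (weight 0, excluded); larger slopes below
#' `downweight_below` mark partial saturation (default weight 0.25);
#' everything else keeps weight 1. The exclusion default is deliberately
#' close to zero: only classes whose observed transitions carry essentially
#' no signal at all are dropped, while merely saturated classes (slopes of a
#' few percent) are retained at reduced weight. Undefined slopes keep weight
#' 1 with a warning.
#'
#' @param profiles list of `saturation_profile` objects.
#' @param exclude_below,downweight_below,downweight slope thresholds and the
#'   reduced weight.
#' @return data frame: partition, slope_ti, slope_tv, chisq, p_chisq,
#'   weight, rationale.
#' @export
weighting_scheme <- function(profiles, exclude_below = 0.005,
                             downweight_below = 0.2, downweight = 0.25) {
  if (inherits(profiles, "saturation_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    s <- p$slope_ti
    if (is.na(s)) {
      warning("undefined slope for partition ", p$partition,
              "; keeping weight 1")
      w <- 1; why <- "slope undefined; retained at full weight"
    } else if (s <= exclude_below) {
      w <- 0
      why <- sprintf("transition slope %.3f <= %.3f: observed change independent of evolutionary change; excluded", s, exclude_below)
    } else if (s < downweight_below) {
      w <- downweight
      why <- sprintf("transition slope %.3f < %.2f: saturated; down-weighted to %.2f", s, downweight_below, downweight)
    } else {
      w <- 1; why <- sprintf("transition slope %.3f: unsaturated", s)
    }
    data.frame(partition = as.character(p$partition), slope_ti = p$slope_ti,
               slope_tv = p$slope_tv, chisq = p$chisq, p_chisq = p$p_chisq,
               weight = w, rationale = why, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
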