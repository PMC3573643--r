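#' G-test of goodness of fit
#'
#' Log-likelihood ratio test `G = 2 * sum(o * ln(o/e))` (no Williams
#' correction), df = classes - 1, p from the chi-square distribution.
#' Classes with zero expected count are pooled into the following class with
#' a warning; zero observed counts contribute 0 to G.
#'
#' @param observed observed counts.
#' @param expected expected counts (same total; rescaled if not).
#' @return list with `G`, `df`, `p`.
#' @export
g_test <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("observed and expected must have equal length")
  if (length(observed) < 2) stop("need at least two classes")
  expected <- expected * sum(observed) / sum(expected)
  while (any(expected == 0)) {
    k <- which(expected == 0)[1]
    j <- if (k < length(expected)) k + 1L else k - 1L
    warning("pooling class with zero expected count")
    expected[j] <- expected[j] + expected[k]
    observed[j] <- observed[j] + observed[k]
    expected <- expected[-k]; observed <- observed[-k]
    if (length(observed) < 2) stop("pooling left fewer than two classes")
  }
  term <- ifelse(observed > 0, observed * log(observed / expected), 0)
  G <- 2 * sum(term)
  df <- length(observed) - 1L
  list(G = G, df = df, p = stats::pchisq(G, df, lower.tail = FALSE))
}

#' G-test of independence for a two-way table
#'
#' `G = 2 * sum(o * ln(o/e))` with expectations from the product of margins;
#' df = (rows-1)(cols-1). Rows or columns with zero margin are dropped.
#'
#' @param tab matrix of counts.
#' @return list with `G`, `df`, `p`.
#' @export
g_test_independence <- function(tab) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("table degenerate after dropping empty margins")
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  term <- ifelse(tab > 0, tab * log(tab / e), 0)
  G <- 2 * sum(term)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(G = G, df = df, p = stats::pchisq(G, df, lower.tail = FALSE))
}

#' Compare retention-index distributions between data partitions
#'
#' Two-sample Kolmogorov-Smirnov test on per-character RI values, plus a
#' G-test of goodness of fit comparing observed counts of perfectly retained
#' characters (RI = 1) across classes against the counts expected if classes
#' were represented proportionally to their size.
#'
#' @param ri_a,ri_b numeric vectors of defined per-character RI values.
#' @param class_counts optional data frame with columns `class`,
#'   `n_ri1` (observed RI = 1 characters), `n_total` (class size); the
#'   G-test expectation is proportional to `n_total`.
#' @return list with `D`, `p_ks`, and (when `class_counts` given) `G`, `df`,
#'   `p_g`.
#' @export
ri_distribution_tests <- function(ri_a, ri_b, class_counts = NULL) {
  if (!length(ri_a) || !length(ri_b)) stop("empty RI vector")
  ks <- suppressWarnings(stats::ks.test(ri_a, ri_b))
  out <- list(D = unname(ks$statistic), p_ks = ks$p.value)
  if (!is.null(class_counts)) {
    stopifnot(all(c("class", "n_ri1", "n_total") %in% names(class_counts)))
    g <- g_test(class_counts$n_ri1,
                class_counts$n_total / sum(class_counts$n_total) *
                  sum(class_counts$n_ri1))
    out$G <- g$G; out$df <- g$df; out$p_g <- g$p
  }
  out
}
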