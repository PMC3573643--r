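NT <- c("A", "C", "G", "T")

# Transition pairs (A<->G, C<->T); everything else is a transversion.
is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
  (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Nucleotide substitution model specification
#'
#' GTR-family models. `rates` are the six exchangeabilities in the order
#' AC, AG, AT, CG, CT, GT with GT fixed to 1; `pi` are stationary base
#' frequencies (A,C,G,T). The constraint tag fixes the free-parameter
#' structure: `JC` (all rates 1, equal frequencies), `HKY` (transition rate
#' free, frequencies free), `SYM` (all rates free, equal frequencies), `GTR`
#' (everything free). Rate variation across sites uses `n_cat` discrete
#' gamma categories with shape `alpha` (0 categories = no gamma) plus a
#' proportion of invariant sites `p_inv`.
#'
#' @param constraint one of `"JC"`, `"HKY"`, `"SYM"`, `"GTR"`.
#' @param rates six exchangeabilities (GT last, fixed to 1).
#' @param pi base frequencies summing to 1.
#' @param p_inv proportion of invariant sites in `[0,1)`.
#' @param alpha gamma shape (> 0); ignored when `n_cat == 0`.
#' @param n_cat number of discrete gamma categories (0 disables gamma).
#' @return An object of class `substitution_model`.
#' @export
substitution_model <- function(constraint = c("GTR", "JC", "HKY", "SYM"),
                               rates = rep(1, 6), pi = rep(0.25, 4),
                               p_inv = 0, alpha = 1, n_cat = 0L) {
  constraint <- match.arg(constraint)
  stopifnot(length(rates) == 6, length(pi) == 4)
  if (abs(sum(pi) - 1) > 1e-12) stop("frequencies must sum to 1")
  if (any(pi <= 0)) stop("frequencies must be positive")
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must be in [0,1)")
  if (n_cat > 0 && alpha <= 0) stop("gamma shape must be positive")
  rates <- rates / rates[6]
  if (constraint == "JC") { rates <- rep(1, 6); pi <- rep(0.25, 4) }
  if (constraint == "SYM") pi <- rep(0.25, 4)
  if (constraint == "HKY") {
    kappa <- rates[2]
    rates <- c(1, kappa, 1, 1, kappa, 1)
  }
  structure(list(constraint = constraint, rates = rates, pi = pi,
                 p_inv = p_inv, alpha = alpha, n_cat = as.integer(n_cat)),
            class = "substitution_model")
}

#' Number of free parameters of a substitution model
#' @param model A `substitution_model`.
#' @return Integer count (exchangeabilities + frequencies + p_inv + alpha).
#' @export
n_free_params <- function(model) {
  k <- switch(model$constraint, JC = 0L, HKY = 1L + 3L, SYM = 5L, GTR = 5L + 3L)
  k + (model$p_inv > 0) + (model$n_cat > 0)
}

# Scaled reversible rate matrix from exchangeabilities and frequencies.
# Rows/cols in NT order; expected rate 1 substitution/site at stationarity.
gtr_Q <- function(rates, pi) {
  Q <- matrix(0, 4, 4, dimnames = list(NT, NT))
  Q["A", "C"] <- rates[1]; Q["A", "G"] <- rates[2]; Q["A", "T"] <- rates[3]
  Q["C", "G"] <- rates[4]; Q["C", "T"] <- rates[5]; Q["G", "T"] <- rates[6]
  Q <- Q + t(Q)
  Q <- Q * rep(pi, each = 4)      # q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# Eigen-decomposition of a reversible Q via symmetrization; valid for any
# state space (nucleotide, amino acid, codon).
rev_eigen <- function(Q, pi) {
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(vals = e$values,
       right = e$vectors / sp,         # diag(1/sp) %*% U
       left = t(e$vectors * sp))       # t(U) %*% diag(sp)
}

# Transition probability matrix P(t) from rev_eigen output.
pmat <- function(eig, t) {
  P <- eig$right %*% (exp(eig$vals * t) * eig$left)
  P[P < 0] <- 0
  P
}

#' Discrete gamma category rates (mean of each quantile class)
#'
#' Standard discretization: the gamma(shape, rate = shape) distribution is
#' cut into `n_cat` equal-probability classes and each class is represented
#' by its conditional mean, so the category rates average 1.
#'
#' @param alpha gamma shape.
#' @param n_cat number of categories.
#' @return Numeric vector of `n_cat` relative rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, n_cat) {
  if (n_cat <= 1) return(1)
  q <- stats::qgamma(seq_len(n_cat - 1) / n_cat, shape = alpha, rate = alpha)
  bounds <- c(0, q, Inf)
  # conditional means via the incomplete-gamma identity
  upper <- stats::pgamma(bounds[-1], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(bounds[-length(bounds)], shape = alpha + 1, rate = alpha)
  r <- (upper - lower) * n_cat
  r / mean(r)
}

#' Genetic code tables
#'
#' @param code `"vertebrate_mt"` or `"universal"`.
#' @return list with `table` (named list codon -> one-letter amino acid,
#'   stops excluded), `stops`, and `codons` (sense codons in fixed order).
#' @export
genetic_code <- function(code = c("vertebrate_mt", "universal")) {
  code <- match.arg(code)
  b <- c("T", "C", "A", "G")
  # standard code laid out in TCAG order
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",   # TTT..TGG
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- as.vector(t(outer(b, b, paste0)))
  codons <- as.vector(vapply(b, function(x) paste0(codons, ""), character(16)))
  # build explicitly: first base slowest
  codons <- character(64); k <- 0L
  for (b1 in b) for (b2 in b) for (b3 in b) { k <- k + 1L; codons[k] <- paste0(b1, b2, b3) }
  names(aa) <- codons
  if (code == "vertebrate_mt") {
    aa["AGA"] <- "*"; aa["AGG"] <- "*"   # arginine codons become stops
    aa["ATA"] <- "M"; aa["TGA"] <- "W"
  }
  stops <- names(aa)[aa == "*"]
  sense <- names(aa)[aa != "*"]
  list(table = as.list(aa[sense]), stops = stops, codons = sense)
}
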