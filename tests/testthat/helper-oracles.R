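# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own algorithms: parsimony scores come from exhaustive
# enumeration of internal-state assignments, likelihoods from explicit
# summation over ancestral states.

# list-matrix builder for char_matrix fixtures
cells_matrix <- function(..., taxa = NULL) {
  cols <- list(...)
  ntax <- length(cols[[1]])
  st <- matrix(list(), ntax, length(cols))
  for (j in seq_along(cols)) for (i in seq_len(ntax))
    st[[i, j]] <- if (length(cols[[j]][[i]]) == 1 && is.na(cols[[j]][[i]]))
      NA_integer_ else as.integer(cols[[j]][[i]])
  rownames(st) <- if (is.null(taxa)) paste0("t", seq_len(ntax)) else taxa
  st
}

# Exhaustive minimum steps over all internal-state assignments.
brute_steps <- function(tree, cells, ordered = FALSE) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  cells <- cells[tree$tip.label]
  scored <- !vapply(cells, function(s) length(s) == 1 && is.na(s), logical(1))
  obs <- sort(unique(unlist(cells[scored])))
  if (length(obs) < 2) return(0)
  states <- if (ordered) seq(min(obs), max(obs)) else obs
  cost <- function(a, b) if (ordered) abs(a - b) else as.numeric(a != b)
  n_int <- max(tree$edge) - ntip
  grid <- expand.grid(rep(list(states), n_int))
  tip_choices <- lapply(seq_len(ntip), function(i) {
    s <- cells[[i]]
    if (length(s) == 1 && is.na(s)) return(states)      # unconstrained
    if (ordered) states[states >= min(s) & states <= max(s)] else s
  })
  best <- Inf
  tip_grid <- expand.grid(tip_choices)
  for (g in seq_len(nrow(grid))) {
    internal <- as.numeric(grid[g, ])
    for (tg in seq_len(nrow(tip_grid))) {
      asg <- c(as.numeric(tip_grid[tg, ]), internal)
      tot <- 0
      for (e in seq_len(nrow(tree$edge)))
        tot <- tot + cost(asg[tree$edge[e, 1]], asg[tree$edge[e, 2]])
      if (tot < best) best <- tot
    }
  }
  best
}

# Explicit-summation likelihood for small nucleotide trees.
brute_nt_loglik <- function(tree, S, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  Q <- phyloconflict:::gtr_Q(model$rates, model$pi)
  eig <- phyloconflict:::rev_eigen(Q, model$pi)
  rates <- if (model$n_cat > 0)
    discrete_gamma_rates(model$alpha, model$n_cat) else 1
  ntip <- ape::Ntip(tree); root <- ntip + 1L
  n_int <- max(tree$edge) - ntip
  idx <- match(tree$tip.label, rownames(S))
  tot <- 0
  for (site in seq_len(ncol(S))) {
    obs <- match(S[idx, site], c("A", "C", "G", "T"))
    lik_var <- 0
    for (r in rates) {
      P <- lapply(tree$edge.length, function(t)
        phyloconflict:::pmat(eig, t * r / (1 - model$p_inv)))
      grid <- expand.grid(rep(list(1:4), n_int))
      for (g in seq_len(nrow(grid))) {
        asg <- c(obs, as.integer(grid[g, ]))
        pr <- model$pi[asg[root]]
        for (e in seq_len(nrow(tree$edge)))
          pr <- pr * P[[e]][asg[tree$edge[e, 1]], asg[tree$edge[e, 2]]]
        lik_var <- lik_var + pr / length(rates)
      }
    }
    lik <- lik_var * (1 - model$p_inv)
    if (model$p_inv > 0 && all(obs == obs[1]))
      lik <- lik + model$p_inv * model$pi[obs[1]]
    tot <- tot + log(lik)
  }
  tot
}

# Explicit-summation per-site amino-acid log-likelihoods (4 taxa).
brute_aa_site_loglik <- function(tree, A, mod) {
  tree <- ape::reorder.phylo(tree, "postorder")
  eig <- phyloconflict:::rev_eigen(mod$Q, mod$pi)
  P <- lapply(tree$edge.length, function(t) phyloconflict:::pmat(eig, t))
  ntip <- ape::Ntip(tree); root <- ntip + 1L
  n_int <- max(tree$edge) - ntip
  aa_levels <- phyloconflict:::AA
  idx <- match(tree$tip.label, rownames(A))
  grid <- expand.grid(rep(list(1:20), n_int))
  vapply(seq_len(ncol(A)), function(site) {
    obs <- match(A[idx, site], aa_levels)
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      asg <- c(obs, as.integer(grid[g, ]))
      pr <- mod$pi[asg[root]]
      for (e in seq_len(nrow(tree$edge)))
        pr <- pr * P[[e]][asg[tree$edge[e, 1]], asg[tree$edge[e, 2]]]
      lik <- lik + pr
    }
    log(lik)
  }, numeric(1))
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
exact_mw_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pooled <- c(x, y)
  u_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  us <- apply(combos, 2, function(ix)
    sum(rank(pooled)[ix]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# random character matrix over small state pools
random_char_matrix <- function(ntax, nchar, max_state = 2, seed = 1,
                               taxa = paste0("t", seq_len(ntax))) {
  set.seed(seed)
  st <- matrix(list(), ntax, nchar)
  for (j in seq_len(nchar)) for (i in seq_len(ntax))
    st[[i, j]] <- sample(0:max_state, 1)
  rownames(st) <- taxa
  char_matrix(st)
}
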