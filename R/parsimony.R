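# Internal: per-taxon tip cost matrix for one character.
# Returns matrix (n_states x n_taxa) of 0/Inf admissible-state costs, plus
# the state values the rows refer to. Polymorphic cells cost 0 to any member
# state; for ordered characters a polymorphic set is its interval hull.
# Missing/inapplicable cells cost 0 everywhere (no constraint).
tip_costs <- function(cells, ordered) {
  obs <- sort(unique(unlist(cells[!vapply(cells, function(s)
    length(s) == 1L && is.na(s), logical(1))])))
  if (!length(obs)) return(NULL)
  states <- if (ordered) seq.int(min(obs), max(obs)) else obs
  ns <- length(states)
  C <- matrix(0, ns, length(cells))
  for (i in seq_along(cells)) {
    s <- cells[[i]]
    if (length(s) == 1L && is.na(s)) next
    ok <- if (ordered) states >= min(s) & states <= max(s) else states %in% s
    C[!ok, i] <- Inf
  }
  list(C = C, states = states)
}

state_cost <- function(states, ordered) {
  if (ordered) abs(outer(states, states, "-"))
  else 1 - diag(length(states))
}

# Sankoff downpass over a rooted tree. Returns node cost matrices
# (n_states x n_nodes) where entry [s, v] is the minimal cost of the subtree
# rooted at v given state s at v.
sankoff_down <- function(tree, C_tips, cost) {
  nnode <- max(tree$edge)
  ntip <- ape::Ntip(tree)
  ns <- nrow(C_tips)
  cv <- matrix(0, ns, nnode)
  cv[, seq_len(ntip)] <- C_tips
  po <- reorder_rows(tree, "postorder")
  for (i in po) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    # min over child state of (cost(s_parent, s_child) + c_child)
    add <- apply(cost + rep(cv[, ch], each = ns), 1, min)
    cv[, p] <- cv[, p] + add
  }
  cv
}

#' Minimal parsimony steps of a character on a tree
#'
#' Fitch counting for unordered characters (polymorphic cells are state
#' sets), Sankoff with linear cost `|i - j|` for ordered characters.
#' Missing and inapplicable cells contribute no cost. The count does not
#' depend on root placement (costs are symmetric).
#'
#' @param tree `phylo` with at least the scored taxa as tips.
#' @param cells list of integer state vectors named by taxon (`NA` missing).
#' @param ordered logical; additive coding.
#' @return list with `steps` and `uninformative` flag (all-missing or
#'   constant character).
#' @export
count_steps <- function(tree, cells, ordered = FALSE) {
  cells <- align_cells(tree, cells)
  tc <- tip_costs(cells, ordered)
  if (is.null(tc) || length(tc$states) == 1L)
    return(list(steps = 0, uninformative = TRUE))
  cost <- state_cost(tc$states, ordered)
  cv <- sankoff_down(tree, tc$C, cost)
  root <- ape::Ntip(tree) + 1L
  list(steps = min(cv[, root]), uninformative = FALSE)
}

align_cells <- function(tree, cells) {
  if (is.null(names(cells)))
    stop("cells must be named by taxon")
  miss <- setdiff(tree$tip.label, names(cells))
  out <- cells[tree$tip.label[tree$tip.label %in% names(cells)]]
  if (length(miss)) {
    fill <- rep(list(NA_integer_), length(miss)); names(fill) <- miss
    out <- c(out, fill)
  }
  out[tree$tip.label]
}

#' Minimum and maximum conceivable steps of a character
#'
#' `m` is the minimum number of steps over all possible trees; `g` is the
#' cost on a star tree minimized over a single ancestral state (the maximum
#' steps any tree can force). These bound the observed steps and define the
#' consistency and retention indices. Polymorphic cells are satisfiable by
#' any member state (interval hull when ordered).
#'
#' @param cells list of state vectors (one per scored taxon, `NA` missing).
#' @param ordered logical.
#' @return list with `m`, `g`, and `defined` (`g > m`; RI exists).
#' @export
step_bounds <- function(cells, ordered = FALSE) {
  keep <- !vapply(cells, function(s) length(s) == 1L && is.na(s), logical(1))
  cells <- cells[keep]
  if (!length(cells)) return(list(m = 0, g = 0, defined = FALSE))
  obs <- sort(unique(unlist(cells)))
  if (length(obs) == 1L) return(list(m = 0, g = 0, defined = FALSE))
  if (ordered) {
    lo <- vapply(cells, min, numeric(1)); hi <- vapply(cells, max, numeric(1))
    m <- max(0, max(lo) - min(hi))
    g <- min(vapply(seq.int(min(obs), max(obs)), function(a)
      sum(pmax(lo - a, 0) + pmax(a - hi, 0)), numeric(1)))
  } else {
    # m: minimal number of states hitting every cell, minus 1 (exact over
    # subsets of the observed pool, which is small for discrete morphology)
    m <- min_hitting_states(cells, obs) - 1
    g <- min(vapply(obs, function(a)
      sum(vapply(cells, function(s) as.numeric(!a %in% s), numeric(1))),
      numeric(1)))
  }
  list(m = m, g = g, defined = g > m)
}

min_hitting_states <- function(cells, pool) {
  if (all(lengths(cells) == 1L)) return(length(pool))
  np <- length(pool)
  for (k in seq_len(np)) {
    combos <- utils::combn(pool, k, simplify = FALSE)
    for (sel in combos)
      if (all(vapply(cells, function(s) any(s %in% sel), logical(1))))
        return(k)
  }
  np
}

#' Per-character homoplasy indices and ensemble CI/RI
#'
#' For every character, observed steps `s` on the tree, bounds `m` and `g`,
#' consistency index `CI = m/s` and retention index `RI = (g-s)/(g-m)`
#' (undefined when `g == m`). Ensemble indices are computed over all
#' variable characters by default (`CI = sum(m)/sum(s)`,
#' `RI = (sum(g)-sum(s))/(sum(g)-sum(m))`, the latter restricted to
#' characters with defined RI); `informative_only = TRUE` restricts both to
#' parsimony-informative characters.
#'
#' @param cm A [char_matrix()].
#' @param tree `phylo`; matrix taxa absent from the tree are dropped with a
#'   warning, and matrix taxa must be a subset of the tree tips.
#' @param informative_only restrict ensemble indices to informative
#'   characters.
#' @return list with `per_character` (data frame: index, class, ordered,
#'   weight, m, s, g, CI, RI, informative) and `ensemble_CI`, `ensemble_RI`.
#' @export
homoplasy_indices <- function(cm, tree, informative_only = FALSE) {
  extra <- setdiff(cm$taxa, tree$tip.label)
  if (length(extra)) {
    warning("dropping matrix taxa absent from tree: ",
            paste(extra, collapse = ", "))
    keep <- !cm$taxa %in% extra
    cm$states <- cm$states[keep, , drop = FALSE]
    cm$cell_class <- cm$cell_class[keep, , drop = FALSE]
    cm$taxa <- cm$taxa[keep]
  }
  nchr <- nrow(cm$info)
  rec <- data.frame(index = seq_len(nchr), class = cm$info$class,
                    ordered = cm$info$ordered, weight = cm$info$weight,
                    m = NA_real_, s = NA_real_, g = NA_real_,
                    CI = NA_real_, RI = NA_real_, informative = FALSE)
  for (j in seq_len(nchr)) {
    cells <- stats::setNames(cm$states[, j], cm$taxa)
    st <- count_steps(tree, cells, cm$info$ordered[j])
    b <- step_bounds(cells, cm$info$ordered[j])
    rec$m[j] <- b$m; rec$g[j] <- b$g; rec$s[j] <- st$steps
    rec$CI[j] <- if (st$steps > 0) b$m / st$steps else NA_real_
    rec$RI[j] <- if (b$defined) (b$g - st$steps) / (b$g - b$m) else NA_real_
    rec$informative[j] <- is_informative(cells)
  }
  variable <- rec$s > 0
  if (!any(variable)) stop("no variable characters: ensemble indices undefined")
  sel <- if (informative_only) variable & rec$informative else variable
  ens_ci <- sum(rec$m[sel]) / sum(rec$s[sel])
  ri_ok <- sel & !is.na(rec$RI)
  ens_ri <- (sum(rec$g[ri_ok]) - sum(rec$s[ri_ok])) /
            (sum(rec$g[ri_ok]) - sum(rec$m[ri_ok]))
  list(per_character = rec, ensemble_CI = ens_ci, ensemble_RI = ens_ri)
}

is_informative <- function(cells) {
  keep <- !vapply(cells, function(s) length(s) == 1L && is.na(s), logical(1))
  cells <- cells[keep]
  if (length(cells) < 2) return(FALSE)
  pool <- sort(unique(unlist(cells)))
  cnt <- vapply(pool, function(a)
    sum(vapply(cells, function(s) a %in% s, logical(1))), numeric(1))
  sum(cnt >= 2) >= 2
}

#' ACCTRAN change map of a character on a rooted tree
#'
#' Assigns ancestral states by accelerated transformation: changes are
#' placed as close to the root as a minimum-length reconstruction permits.
#' Implemented as a Sankoff downpass followed by a preorder assignment that,
#' at each branch, picks the child state minimizing subtree-plus-branch cost
#' and, among ties, the state farthest from the parent state (forcing the
#' change onto the current, more rootward, branch); remaining ties go to the
#' lower state.
#'
#' @param tree rooted `phylo`.
#' @param cells named list of state vectors (`NA` missing).
#' @param ordered logical.
#' @return list with `changes` (data frame: edge, from, to, steps),
#'   `node_state` (assigned state per node), `root_states` (states present
#'   at the root reconstruction), and `steps` (total, equals
#'   [count_steps()]).
#' @export
acctran_changes <- function(tree, cells, ordered = FALSE) {
  if (!ape::is.rooted(tree))
    stop("tree must be rooted; root it on the outgroup edge first")
  cells <- align_cells(tree, cells)
  tc <- tip_costs(cells, ordered)
  nnode <- max(tree$edge); root <- ape::Ntip(tree) + 1L
  if (is.null(tc) || length(tc$states) == 1L) {
    st <- if (is.null(tc)) NA_integer_ else tc$states
    return(list(changes = data.frame(edge = integer(0), from = integer(0),
                                     to = integer(0), steps = numeric(0)),
                node_state = rep(st[1], nnode), root_states = st,
                steps = 0))
  }
  cost <- state_cost(tc$states, ordered)
  cv <- sankoff_down(tree, tc$C, cost)
  assign <- integer(nnode)
  rvals <- cv[, root]
  assign[root] <- which(rvals == min(rvals))[1]
  pre <- reorder_rows(tree, "preorder")
  changes <- data.frame(edge = integer(0), from = integer(0), to = integer(0),
                        steps = numeric(0))
  for (i in pre) {
    p <- tree$edge[i, 1]; v <- tree$edge[i, 2]
    a <- assign[p]
    tot <- cost[a, ] + cv[, v]
    cand <- which(tot == min(tot))
    # accelerated: among optima take the state farthest from the parent
    s <- cand[order(-cost[a, cand], tc$states[cand])][1]
    assign[v] <- s
    if (s != a) {
      d <- cost[a, s]
      changes <- rbind(changes, data.frame(
        edge = i, from = tc$states[a], to = tc$states[s], steps = d))
    }
  }
  list(changes = changes,
       node_state = tc$states[assign],
       root_states = tc$states[assign[root]],
       steps = sum(changes$steps))
}

#' Weighted tree length and informative-character census
#'
#' @param cm A [char_matrix()].
#' @param tree `phylo`.
#' @param weights optional per-character weights overriding `cm$info$weight`;
#'   zero-weight characters are excluded from both length and census.
#' @return list with `length` (sum of weight x steps) and
#'   `n_informative` (included characters that are parsimony-informative).
#' @export
matrix_score <- function(cm, tree, weights = NULL) {
  if (is.null(weights)) weights <- cm$info$weight
  if (any(weights < 0)) stop("weights must be non-negative")
  nchr <- nrow(cm$info)
  len <- 0; ninf <- 0L
  for (j in seq_len(nchr)) {
    if (weights[j] == 0) next
    cells <- stats::setNames(cm$states[, j], cm$taxa)
    st <- count_steps(tree, cells, cm$info$ordered[j])
    len <- len + weights[j] * st$steps
    if (is_informative(cells)) ninf <- ninf + 1L
  }
  list(length = len, n_informative = ninf)
}
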