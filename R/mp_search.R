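# --- internal unrooted tree representation -------------------------------
# Adjacency list over node ids; tips are 1..n (carrying taxon indices),
# internal nodes any larger ids. Unrooted binary: internal degree 3.

adj_new <- function() list(adj = list(), tip_of = integer(0), next_id = 1L)

adj_add_node <- function(tr, tip = NA_integer_) {
  id <- tr$next_id
  tr$adj[[id]] <- integer(0)
  tr$tip_of[id] <- tip
  tr$next_id <- id + 1L
  list(tr = tr, id = id)
}

adj_connect <- function(tr, a, b) {
  tr$adj[[a]] <- c(tr$adj[[a]], b)
  tr$adj[[b]] <- c(tr$adj[[b]], a)
  tr
}

adj_disconnect <- function(tr, a, b) {
  tr$adj[[a]] <- setdiff(tr$adj[[a]], b)
  tr$adj[[b]] <- setdiff(tr$adj[[b]], a)
  tr
}

# all edges as a 2-column matrix (a < b)
adj_edges <- function(tr) {
  out <- NULL
  for (a in seq_along(tr$adj)) {
    nb <- tr$adj[[a]]
    nb <- nb[nb > a]
    if (length(nb)) out <- rbind(out, cbind(a, nb))
  }
  out
}

# remove a degree-2 node, fusing its two incident edges
adj_suppress <- function(tr, v) {
  nb <- tr$adj[[v]]
  if (length(nb) != 2) return(tr)
  tr <- adj_disconnect(tr, v, nb[1])
  tr <- adj_disconnect(tr, v, nb[2])
  adj_connect(tr, nb[1], nb[2])
}

# nodes reachable from `start` (after an edge removal)
adj_component <- function(tr, start) {
  seen <- integer(0); stack <- start
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v %in% seen) next
    seen <- c(seen, v)
    stack <- c(stack, setdiff(tr$adj[[v]], seen))
  }
  seen
}

# convert to rooted ape::phylo (rooted at an arbitrary tip's neighbor)
adj_to_phylo <- function(tr, tip_labels) {
  connected <- lengths(tr$adj) > 0
  tips <- which(!is.na(tr$tip_of) & connected[seq_along(tr$tip_of)])
  n <- length(tips)
  # relabel: tips 1..n, internals n+1..; root at neighbor of first tip
  start <- tr$adj[[tips[1]]][1]
  new_id <- integer(tr$next_id - 1L)
  new_id[tips] <- rank(tr$tip_of[tips])
  nxt <- n + 1L
  edge <- matrix(0L, 0, 2)
  # DFS from start (v already has its id assigned by the caller)
  visit <- function(v, parent) {
    for (u in tr$adj[[v]]) {
      if (!is.na(parent) && u == parent) next
      if (!is.na(tr$tip_of[u])) {
        edge <<- rbind(edge, c(new_id[v], new_id[u]))
      } else {
        new_id[u] <<- nxt; nxt <<- nxt + 1L
        edge <<- rbind(edge, c(new_id[v], new_id[u]))
        visit(u, v)
      }
    }
  }
  new_id[start] <- nxt; nxt <- nxt + 1L
  visit(start, NA)
  storage.mode(edge) <- "integer"
  structure(list(edge = edge, tip.label = tip_labels[sort(tr$tip_of[tips])],
                 Nnode = nxt - 1L - n),
            class = "phylo")
}

phylo_to_adj <- function(phy) {
  phy <- ape::unroot(phy)
  ntip <- ape::Ntip(phy)
  tr <- adj_new()
  nmap <- integer(max(phy$edge))
  for (i in seq_len(ntip)) {
    r <- adj_add_node(tr, tip = i); tr <- r$tr; nmap[i] <- r$id
  }
  for (v in sort(unique(as.vector(phy$edge)))) {
    if (v > ntip) { r <- adj_add_node(tr); tr <- r$tr; nmap[v] <- r$id }
  }
  for (i in seq_len(nrow(phy$edge)))
    tr <- adj_connect(tr, nmap[phy$edge[i, 1]], nmap[phy$edge[i, 2]])
  tr
}

# canonical key of the unrooted topology: sorted split strings
topology_key <- function(phy) {
  phy <- ape::unroot(phy)
  ntip <- ape::Ntip(phy)
  labs <- sort(phy$tip.label)
  splits <- character(0)
  po <- reorder_rows(phy, "postorder")
  below <- vector("list", max(phy$edge))
  for (i in seq_len(ntip)) below[[i]] <- phy$tip.label[i]
  for (i in po) {
    p <- phy$edge[i, 1]; ch <- phy$edge[i, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
    s <- sort(below[[ch]])
    if (length(s) > 1 && length(s) < ntip - 1) {
      if (!(labs[1] %in% s)) splits <- c(splits, paste(s, collapse = "|"))
      else splits <- c(splits, paste(sort(setdiff(labs, s)), collapse = "|"))
    }
  }
  paste(sort(unique(splits)), collapse = ";")
}

# --- fast whole-matrix scoring -------------------------------------------

prepare_chars <- function(cm, weights = NULL) {
  if (is.null(weights)) weights <- cm$info$weight
  out <- list()
  for (j in seq_len(nrow(cm$info))) {
    if (weights[j] == 0) next
    cells <- stats::setNames(cm$states[, j], cm$taxa)
    tc <- tip_costs(cells, cm$info$ordered[j])
    if (is.null(tc) || length(tc$states) == 1L) next
    out[[length(out) + 1L]] <- list(
      C = tc$C, cost = state_cost(tc$states, cm$info$ordered[j]),
      w = weights[j], taxa = names(cells))
  }
  out
}

score_phylo <- function(phy, prep) {
  po <- reorder_rows(phy, "postorder")
  ntip <- ape::Ntip(phy); root <- ntip + 1L
  tipidx <- match(phy$tip.label, prep[[1]]$taxa)
  total <- 0
  for (ch in prep) {
    ns <- nrow(ch$C)
    cv <- matrix(0, ns, max(phy$edge))
    cv[, seq_len(ntip)] <- ch$C[, tipidx]
    for (i in po) {
      p <- phy$edge[i, 1]; v <- phy$edge[i, 2]
      add <- apply(ch$cost + rep(cv[, v], each = ns), 1, min)
      cv[, p] <- cv[, p] + add
    }
    total <- total + ch$w * min(cv[, root])
  }
  total
}

score_adj <- function(tr, prep, tip_labels) {
  score_phylo(adj_to_phylo(tr, tip_labels), prep)
}

# --- search ---------------------------------------------------------------

# Insert taxon (tip id) onto edge (a,b); returns new tree
adj_insert_tip <- function(tr, tipnode, a, b) {
  tr <- adj_disconnect(tr, a, b)
  r <- adj_add_node(tr); tr <- r$tr; x <- r$id
  tr <- adj_connect(tr, a, x)
  tr <- adj_connect(tr, x, b)
  adj_connect(tr, x, tipnode)
}

random_addition_tree <- function(prep, taxa, order_idx) {
  n <- length(taxa)
  tr <- adj_new()
  tipnode <- integer(n)
  for (i in seq_len(n)) { r <- adj_add_node(tr, tip = i); tr <- r$tr; tipnode[i] <- r$id }
  a <- order_idx[1]; b <- order_idx[2]; c3 <- order_idx[3]
  r <- adj_add_node(tr); tr <- r$tr; hub <- r$id
  for (t in c(a, b, c3)) tr <- adj_connect(tr, hub, tipnode[t])
  for (k in 4:length(order_idx)) {
    t <- order_idx[k]
    edges <- adj_edges(tr)
    best <- Inf; best_tr <- NULL
    for (e in seq_len(nrow(edges))) {
      cand <- adj_insert_tip(tr, tipnode[t], edges[e, 1], edges[e, 2])
      sc <- score_adj(cand, prep, taxa)
      if (sc < best) { best <- sc; best_tr <- cand }
    }
    tr <- best_tr
  }
  tr
}

# Full TBR neighborhood sweep: returns improved tree or NULL
tbr_improve <- function(tr, prep, taxa, cur_score) {
  edges <- adj_edges(tr)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    cut <- adj_disconnect(tr, a, b)
    comp_a <- adj_component(cut, a)
    comp_b <- adj_component(cut, b)
    # suppress the degree-2 stubs left at the cut ends
    cut2 <- adj_suppress(adj_suppress(cut, a), b)
    ends_a <- if (length(comp_a) == 1L) matrix(c(a, a), 1) else {
      ea <- adj_edges_subset(cut2, comp_a); ea }
    ends_b <- if (length(comp_b) == 1L) matrix(c(b, b), 1) else {
      adj_edges_subset(cut2, comp_b) }
    for (i in seq_len(nrow(ends_a))) for (j in seq_len(nrow(ends_b))) {
      cand <- reconnect(cut2, ends_a[i, ], ends_b[j, ])
      sc <- score_adj(cand, prep, taxa)
      if (sc < cur_score - 1e-9) return(list(tr = cand, score = sc))
    }
  }
  NULL
}

adj_edges_subset <- function(tr, nodes) {
  out <- NULL
  for (a in nodes) {
    nb <- tr$adj[[a]]
    nb <- nb[nb > a & nb %in% nodes]
    if (length(nb)) out <- rbind(out, cbind(a, nb))
  }
  out
}

# Reconnect two components: ea/eb are either a degenerate (tip tip) pair for
# single-node components, or an edge to subdivide.
reconnect <- function(tr, ea, eb) {
  if (ea[1] == ea[2]) x <- ea[1]
  else {
    tr <- adj_disconnect(tr, ea[1], ea[2])
    r <- adj_add_node(tr); tr <- r$tr; x <- r$id
    tr <- adj_connect(tr, ea[1], x); tr <- adj_connect(tr, x, ea[2])
  }
  if (eb[1] == eb[2]) y <- eb[1]
  else {
    tr <- adj_disconnect(tr, eb[1], eb[2])
    r <- adj_add_node(tr); tr <- r$tr; y <- r$id
    tr <- adj_connect(tr, eb[1], y); tr <- adj_connect(tr, y, eb[2])
  }
  adj_connect(tr, x, y)
}

#' Maximum parsimony heuristic search
#'
#' Random-addition-sequence stepwise assembly followed by
#' tree-bisection-reconnection (TBR) branch swapping to a local optimum,
#' repeated `n_reps` times. All distinct topologies attaining the best
#' length found are returned. Deterministic given `seed`.
#'
#' @param cm A [char_matrix()].
#' @param weights optional per-character weights (zero = excluded).
#' @param n_reps number of random-addition replicates.
#' @param seed integer seed.
#' @return list with `trees` (list of unrooted `phylo`), `length` (best
#'   weighted length), and `replicate_lengths`.
#' @export
mp_search <- function(cm, weights = NULL, n_reps = 10, seed = 1) {
  n <- length(cm$taxa)
  if (n < 4) stop("need at least 4 taxa for a tree search")
  prep <- prepare_chars(cm, weights)
  if (!length(prep)) stop("no variable characters to analyse")
  set.seed(seed)
  best_score <- Inf; best <- list(); rep_len <- numeric(n_reps)
  for (rep in seq_len(n_reps)) {
    ord <- sample.int(n)
    tr <- random_addition_tree(prep, cm$taxa, ord)
    sc <- score_adj(tr, prep, cm$taxa)
    repeat {
      imp <- tbr_improve(tr, prep, cm$taxa, sc)
      if (is.null(imp)) break
      tr <- imp$tr; sc <- imp$score
    }
    rep_len[rep] <- sc
    if (sc < best_score - 1e-9) {
      best_score <- sc
      best <- list(adj_to_phylo(tr, cm$taxa))
    } else if (abs(sc - best_score) <= 1e-9) {
      phy <- adj_to_phylo(tr, cm$taxa)
      keys <- vapply(best, topology_key, character(1))
      if (!topology_key(phy) %in% keys) best <- c(best, list(phy))
    }
  }
  list(trees = best, length = best_score, replicate_lengths = rep_len)
}
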