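# Stable per-component seed derivation: one RNG stream per generator, so
# adding a generator never shifts the draws of another.
derive_seed <- function(master, component) {
  h <- 0
  for (code in utf8ToInt(component)) h <- (h * 31 + code) %% 2147483647
  as.integer((as.numeric(master) * 1000003 + h) %% 2147483647)
}

#' Simulate a Yule tree with node ages
#'
#' Pure-birth topology conditioned on the number of tips (via
#' [ape::rphylo()]), rescaled to the target root-to-tip depth. Node ages are
#' implied by the ultrametric branch lengths.
#'
#' @param n_taxa number of tips (>= 4).
#' @param birth speciation rate.
#' @param depth target root-to-tip depth (expected substitutions/site or
#'   time, depending on downstream use).
#' @param seed integer seed.
#' @return `phylo` with branch lengths; tips labeled `t1..tn`.
#' @export
sim_tree <- function(n_taxa, birth = 1, depth = 1, seed = 1) {
  if (n_taxa < 4) stop("need at least 4 taxa")
  set.seed(derive_seed(seed, "tree"))
  tr <- ape::rphylo(n_taxa, birth = birth, death = 0)
  cur <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * depth / cur
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  tr
}

# draw child states for each site given parent states and a P matrix
draw_states <- function(parent, P) {
  s <- ncol(P)
  cum <- t(apply(P, 1, cumsum))
  u <- stats::runif(length(parent))
  vapply(seq_along(parent), function(i)
    findInterval(u[i], cum[parent[i], ], left.open = TRUE) + 1L,
    integer(1))
}

sim_states_down <- function(tree, n_sites, root_freq, Pfun) {
  # Pfun(edge_index, rate) -> P; here rate baked in by caller
  nnode <- max(tree$edge)
  states <- matrix(0L, nnode, n_sites)
  root <- ape::Ntip(tree) + 1L
  states[root, ] <- sample.int(length(root_freq), n_sites, replace = TRUE,
                               prob = root_freq)
  for (i in reorder_rows(tree, "preorder")) {
    p <- tree$edge[i, 1]; v <- tree$edge[i, 2]
    states[v, ] <- draw_states(states[p, ], Pfun(i))
  }
  states[seq_len(ape::Ntip(tree)), , drop = FALSE]
}

#' Pick a clade of a given size from a tree
#'
#' Convenience for designating foreground clades: returns the tip labels of
#' the first internal node (in node order) whose descendant count lies in
#' `[min_tips, max_tips]`, preferring the largest admissible clade size.
#'
#' @param tree `phylo`.
#' @param min_tips,max_tips admissible clade sizes.
#' @return character vector of tip labels.
#' @export
pick_clade <- function(tree, min_tips = 2, max_tips = 4) {
  ntip <- ape::Ntip(tree)
  nodes <- (ntip + 1):max(tree$edge)
  sizes <- vapply(nodes, function(v)
    length(phangorn::Descendants(tree, v, "tips")[[1]]), numeric(1))
  ok <- nodes[sizes >= min_tips & sizes <= max_tips]
  if (!length(ok)) stop("no clade of the requested size exists")
  best <- ok[which.max(sizes[match(ok, nodes)])]
  tree$tip.label[phangorn::Descendants(tree, best, "tips")[[1]]]
}

#' Simulate a partitioned nucleotide alignment
#'
#' Site-wise simulation down the tree, one GTR-family model and rate
#' multiplier per partition, with optional base-composition drift (a shifted
#' stationary composition applied on the edges of designated subtrees, the
#' way compositional bias overprints saturated fast classes in real data).
#'
#' @param tree `phylo` with branch lengths.
#' @param partitions list of per-partition specs: `name`, `length`,
#'   `model` ([substitution_model()]), `multiplier` (relative rate), and
#'   optional `drift = list(tips =, pi =)` applying composition `pi` on the
#'   clade spanned by `tips`.
#' @param seed integer seed.
#' @return [seq_alignment()] with the partition map attached.
#' @export
sim_nucleotide <- function(tree, partitions, seed = 1) {
  set.seed(derive_seed(seed, "nucleotide"))
  ntip <- ape::Ntip(tree)
  chunks <- list(); map <- integer(0)
  for (k in seq_along(partitions)) {
    sp <- partitions[[k]]
    m <- sp$model
    mult <- if (is.null(sp$multiplier)) 1 else sp$multiplier
    eig <- rev_eigen(gtr_Q(m$rates, m$pi), m$pi)
    drift_edges <- integer(0); eig_d <- NULL
    if (!is.null(sp$drift)) {
      drift_edges <- foreground_edges(tree, sp$drift$tips)
      eig_d <- rev_eigen(gtr_Q(m$rates, sp$drift$pi), sp$drift$pi)
    }
    rates <- if (m$n_cat > 0) discrete_gamma_rates(m$alpha, m$n_cat) else 1
    site_rate <- sample(rates, sp$length, replace = TRUE)
    if (m$p_inv > 0)
      site_rate[stats::runif(sp$length) < m$p_inv] <- 0
    # group sites by rate for vectorized edge draws
    S <- matrix("A", ntip, sp$length)
    for (r in unique(site_rate)) {
      cols <- which(site_rate == r)
      if (!length(cols)) next
      if (mult * r == 0) {
        root <- sample.int(4, 1, prob = m$pi)
        S[, cols] <- NT[root]
        next
      }
      Pcache <- lapply(seq_len(nrow(tree$edge)), function(i) {
        e <- if (i %in% drift_edges) eig_d else eig
        pmat(e, tree$edge.length[i] * mult * r)
      })
      st <- sim_states_down(tree, length(cols), m$pi,
                            function(i) Pcache[[i]])
      S[, cols] <- NT[st]
    }
    chunks[[k]] <- S
    map <- c(map, rep.int(k, sp$length))
  }
  seqs <- do.call(cbind, chunks)
  rownames(seqs) <- tree$tip.label
  seq_alignment(seqs, taxa = tree$tip.label, partition = map,
                partition_names = vapply(partitions, function(x)
                  x$name, character(1)))
}

#' Simulate a codon alignment with site classes and a clade omega shift
#'
#' Goldman-Yang codon simulation with a fixed transition/transversion ratio
#' and per-class omega; sites are assigned to classes with the given
#' proportions, and an optional foreground clade uses a different omega in
#' the divergent class. The per-site class assignment is returned as truth
#' for recovery tests. Stop codons cannot arise (the generator acts on the
#' sense-codon space).
#'
#' @param tree `phylo` with branch lengths in expected substitutions/codon.
#' @param n_codons number of codon sites.
#' @param kappa transition/transversion ratio.
#' @param classes data frame with columns `prop`, `omega` (background), and
#'   optionally `omega_fg` (defaults to `omega`).
#' @param foreground tip labels of the foreground clade (NULL = none).
#' @param pi codon frequencies (default uniform over sense codons).
#' @param code genetic code.
#' @param seed integer seed.
#' @return list with `aln` (codon [seq_alignment()]) and `truth` (data
#'   frame: codon, class).
#' @export
sim_codon <- function(tree, n_codons, kappa = 2,
                      classes = data.frame(prop = c(0.9, 0.1),
                                           omega = c(0.1, 1)),
                      foreground = NULL, pi = NULL,
                      code = "vertebrate_mt", seed = 1) {
  set.seed(derive_seed(seed, "codon"))
  struct <- get_codon_structure(code)
  if (is.null(pi)) pi <- rep(1 / struct$s, struct$s)
  if (is.null(classes$omega_fg)) classes$omega_fg <- classes$omega
  fg_edges <- if (is.null(foreground)) integer(0)
              else foreground_edges(tree, foreground)
  cls <- sample.int(nrow(classes), n_codons, replace = TRUE,
                    prob = classes$prop)
  ntip <- ape::Ntip(tree)
  X <- matrix(0L, ntip, n_codons)
  for (k in seq_len(nrow(classes))) {
    cols <- which(cls == k)
    if (!length(cols)) next
    eb <- rev_eigen(codon_Q(kappa, classes$omega[k], pi, struct), pi)
    ef <- rev_eigen(codon_Q(kappa, classes$omega_fg[k], pi, struct), pi)
    Pcache <- lapply(seq_len(nrow(tree$edge)), function(i)
      pmat(if (i %in% fg_edges) ef else eb, tree$edge.length[i]))
    X[, cols] <- sim_states_down(tree, length(cols), pi,
                                 function(i) Pcache[[i]])
  }
  seqs <- matrix("", ntip, 3 * n_codons)
  for (k in seq_len(n_codons))
    seqs[, (3 * k - 2):(3 * k)] <-
      do.call(rbind, strsplit(struct$codons[X[, k]], ""))
  rownames(seqs) <- tree$tip.label
  aln <- seq_alignment(seqs, taxa = tree$tip.label, type = "codon",
                       code = code)
  list(aln = aln, truth = data.frame(codon = seq_len(n_codons), class = cls))
}

#' Simulate a bounded-state-pool morphological matrix
#'
#' Each character evolves on the tree under a k-state Markov model whose
#' state pool is bounded (most characters binary, the rest multistate, as in
#' typical morphological matrices); ordered characters take +/-1 steps on a
#' reflecting chain. Missing cells and polymorphic cells are injected at the
#' specified fractions after simulation. The bounded pools make repeated
#' steps revisit old states, which is exactly the exhaustion structure the
#' state:step analysis is designed to detect.
#'
#' @param tree `phylo` with branch lengths.
#' @param n_char number of characters.
#' @param pool_probs named numeric: probability of each pool size k (names
#'   are the sizes); default 69% binary, remainder spread over 3-6 states.
#' @param ordered_fraction fraction of multistate characters coded ordered.
#' @param missing_fraction fraction of cells set to missing.
#' @param polymorphic_fraction fraction of cells made polymorphic.
#' @param rate mean per-character rate multiplier (characters vary
#'   lognormally around it).
#' @param seed integer seed.
#' @return A [char_matrix()] with class labels `"simulated"`.
#' @export
sim_morphology <- function(tree, n_char = 220,
                           pool_probs = c("2" = 0.69, "3" = 0.13, "4" = 0.08,
                                          "5" = 0.06, "6" = 0.04),
                           ordered_fraction = 0.2,
                           missing_fraction = 0.286,
                           polymorphic_fraction = 0.02,
                           rate = 1, seed = 1) {
  set.seed(derive_seed(seed, "morphology"))
  ntip <- ape::Ntip(tree)
  pools <- as.integer(sample(names(pool_probs), n_char, replace = TRUE,
                             prob = pool_probs))
  ordered <- pools > 2 & stats::runif(n_char) < ordered_fraction
  char_rate <- rate * stats::rlnorm(n_char, meanlog = 0, sdlog = 0.7)
  states <- matrix(list(), ntip, n_char, dimnames = list(tree$tip.label, NULL))
  for (j in seq_len(n_char)) {
    k <- pools[j]
    if (ordered[j]) {
      Q <- matrix(0, k, k)
      for (i in seq_len(k - 1)) { Q[i, i + 1] <- 1; Q[i + 1, i] <- 1 }
    } else {
      Q <- matrix(1 / (k - 1), k, k)
    }
    diag(Q) <- 0; diag(Q) <- -rowSums(Q)
    piu <- rep(1 / k, k)
    mu <- -sum(piu * diag(Q))
    eig <- rev_eigen(Q / mu, piu)
    Pcache <- lapply(tree$edge.length, function(t)
      pmat(eig, t * char_rate[j]))
    st <- sim_states_down(tree, 1, piu, function(i) Pcache[[i]])
    for (i in seq_len(ntip)) states[[i, j]] <- st[i, 1] - 1L
  }
  # polymorphism: add an adjacent (ordered) or random other (unordered) state
  n_cells <- ntip * n_char
  poly <- sample.int(n_cells, round(polymorphic_fraction * n_cells))
  for (c0 in poly) {
    i <- (c0 - 1) %% ntip + 1L; j <- (c0 - 1) %/% ntip + 1L
    s <- states[[i, j]]; k <- pools[j]
    extra <- if (ordered[j]) {
      if (s + 1L < k) s + 1L else s - 1L
    } else sample(setdiff(seq_len(k) - 1L, s), 1)
    states[[i, j]] <- sort(c(s, extra))
  }
  miss <- sample(setdiff(seq_len(n_cells), poly),
                 round(missing_fraction * n_cells))
  for (c0 in miss) {
    i <- (c0 - 1) %% ntip + 1L; j <- (c0 - 1) %/% ntip + 1L
    states[[i, j]] <- NA_integer_
  }
  char_matrix(states, taxa = tree$tip.label, ordered = ordered,
              weight = 1, class = "simulated")
}
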