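#' Read a Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned object is
#' an `ape` `phylo`, the package-wide tree container. Beyond parsing, this
#' checks the invariants the downstream analyses rely on: unique leaf labels,
#' non-negative branch lengths, and a single root.
#'
#' @param text Newick string (single tree, terminated by `;`).
#' @return A `phylo` object.
#' @export
read_tree <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("`text` must be a single Newick string")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop(sprintf("unbalanced parentheses: %d '(' vs %d ')'", n_open, n_close))
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: could not read tree")
  validate_tree(tr)
  tr
}

#' Write a tree as Newick
#'
#' Branch lengths are emitted with 6 significant digits; internal node labels
#' (e.g. support values) are preserved.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
write_tree <- function(tree, file = NULL) {
  validate_tree(tree)
  txt <- ape::write.tree(tree, digits = 6)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate leaf labels: ", paste(unique(dup), collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  tab <- tabulate(tree$edge[, 2], nbins = max(tree$edge))
  if (any(tab[tree$edge[, 2]] > 1))
    stop("node with more than one parent: tree is not a tree")
  invisible(tree)
}

#' Node ages of an ultrametric-ish tree
#'
#' Ages are measured backwards from the most distant tip (age 0 at that tip).
#' For non-ultrametric trees the age of a node is depth(max) - depth(node),
#' which is non-increasing from root to tips along every path.
#'
#' @param tree A `phylo` with branch lengths.
#' @return Numeric vector of ages indexed by node number (tips first).
#' @export
node_ages <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  depths <- ape::node.depth.edgelength(tree)
  max(depths) - depths
}

#' Order branches from oldest to youngest
#'
#' Used by the exhaustion analysis, which accumulates parsimony changes along
#' branches beginning with the oldest. When the tree carries branch lengths
#' interpretable as time, branches are ordered by the age of their parent
#' node (older first). Otherwise a breadth-first depth rank is used, with
#' ties broken by descendant clade size (larger first) and then by the label
#' of the first tip in the clade, so the order is deterministic.
#'
#' @param tree Rooted `phylo`.
#' @param use_ages Use node ages from branch lengths when available.
#' @return Integer vector of row indices into `tree$edge`, oldest first.
#' @export
branch_order <- function(tree, use_ages = !is.null(tree$edge.length)) {
  ne <- nrow(tree$edge)
  if (use_ages && !is.null(tree$edge.length)) {
    ages <- node_ages(tree)
    key1 <- -ages[tree$edge[, 1]]   # older parent first
    key2 <- -ages[tree$edge[, 2]]
  } else {
    depth <- node_depths(tree)
    key1 <- depth[tree$edge[, 1]]
    key2 <- depth[tree$edge[, 2]]
  }
  csize <- clade_sizes(tree)
  ftip <- first_tip_label(tree)
  ord <- order(key1, key2, -csize[tree$edge[, 2]], ftip[tree$edge[, 2]])
  ord
}

node_depths <- function(tree) {
  root <- ape::Ntip(tree) + 1L
  depth <- rep.int(NA_integer_, max(tree$edge))
  depth[root] <- 0L
  for (i in reorder_rows(tree, "preorder"))
    depth[tree$edge[i, 2]] <- depth[tree$edge[i, 1]] + 1L
  depth
}

clade_sizes <- function(tree) {
  n <- max(tree$edge)
  sz <- integer(n)
  sz[seq_len(ape::Ntip(tree))] <- 1L
  for (i in reorder_rows(tree, "postorder"))
    sz[tree$edge[i, 1]] <- sz[tree$edge[i, 1]] + sz[tree$edge[i, 2]]
  sz
}

first_tip_label <- function(tree) {
  n <- max(tree$edge)
  lab <- character(n)
  lab[seq_len(ape::Ntip(tree))] <- tree$tip.label
  for (i in reorder_rows(tree, "postorder")) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    if (lab[p] == "" || lab[ch] < lab[p]) lab[p] <- min(lab[p][lab[p] != ""], lab[ch])
  }
  lab
}

# Row indices of tree$edge in pre/postorder without mutating the tree.
reorder_rows <- function(tree, order = c("postorder", "preorder")) {
  order <- match.arg(order)
  tr <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  if (order == "postorder") tr else rev(tr)
}
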