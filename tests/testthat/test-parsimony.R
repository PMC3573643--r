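t4 <- read_tree("((A,B),(C,D));")

test_that("step counts match hand examples and the exhaustive oracle", {
  expect_equal(count_steps(t4, list(A = 0L, B = 0L, C = 1L, D = 1L))$steps, 1)
  t2 <- read_tree("(A,B);")
  expect_equal(count_steps(t2, list(A = 0L, B = 2L), ordered = TRUE)$steps, 2)
  expect_true(count_steps(t4, list(A = NA_integer_, B = NA_integer_,
                                   C = NA_integer_, D = NA_integer_))$uninformative)

  set.seed(101)
  for (k in 1:25) {
    tr <- ape::rtree(sample(5:7, 1))
    ordered <- k %% 2 == 0
    cells <- as.list(sample(0:2, ape::Ntip(tr), replace = TRUE))
    names(cells) <- tr$tip.label
    if (k %% 5 == 0) cells[[1]] <- NA_integer_          # missing cell
    if (k %% 7 == 0) cells[[2]] <- c(0L, 1L)            # polymorphic cell
    expect_equal(count_steps(tr, cells, ordered)$steps,
                 brute_steps(tr, cells, ordered),
                 info = paste("case", k))
  }
})

test_that("step counts are invariant to re-rooting", {
  set.seed(7)
  tr <- ape::rtree(8)
  cells <- as.list(sample(0:2, 8, replace = TRUE))
  names(cells) <- tr$tip.label
  ref <- count_steps(tr, cells)$steps
  refo <- count_steps(tr, cells, ordered = TRUE)$steps
  for (k in 1:20) {
    node <- sample(c(seq_len(8), 10:14), 1)
    tr2 <- tryCatch(ape::root(tr, node = max(node, 10), resolve.root = TRUE),
                    error = function(e) NULL)
    if (is.null(tr2)) next
    expect_equal(count_steps(tr2, cells)$steps, ref)
    expect_equal(count_steps(tr2, cells, ordered = TRUE)$steps, refo)
  }
})

test_that("step bounds bracket observed steps, with the worked examples", {
  b <- step_bounds(list(a = 0L, b = 0L, c = 0L, d = 1L, e = 1L, f = 2L))
  expect_equal(c(b$m, b$g), c(2, 3))
  b <- step_bounds(list(a = 0L, b = 0L, c = 2L, d = 2L), ordered = TRUE)
  expect_equal(c(b$m, b$g), c(2, 4))
  b <- step_bounds(list(a = 1L, b = 1L, c = 1L))
  expect_false(b$defined)

  # g equals brute-force single-ancestral-state star minimization; m <= s <= g
  set.seed(33)
  for (k in 1:20) {
    tr <- ape::rtree(6)
    cells <- as.list(sample(0:2, 6, replace = TRUE))
    names(cells) <- tr$tip.label
    ordered <- k %% 2 == 0
    b <- step_bounds(cells, ordered)
    s <- count_steps(tr, cells, ordered)$steps
    expect_lte(b$m, s); expect_lte(s, b$g)
    obs <- sort(unique(unlist(cells)))
    star_g <- min(vapply(if (ordered) seq(min(obs), max(obs)) else obs,
      function(a) sum(vapply(cells, function(x)
        if (ordered) min(abs(a - x)) else as.numeric(!a %in% x),
        numeric(1))), numeric(1)))
    expect_equal(b$g, star_g)
  }
})

test_that("homoplasy indices give CI/RI hand values and valid ensembles", {
  cm <- char_matrix(cells_matrix(list(0, 1, 0, 1), taxa = c("A", "B", "C", "D")))
  h <- homoplasy_indices(cm, t4)
  expect_equal(h$per_character$CI, 0.5)
  expect_equal(h$per_character$RI, 0)

  cm2 <- char_matrix(cells_matrix(list(0, 0, 2, 2), taxa = c("A", "B", "C", "D")),
                     ordered = TRUE)
  h2 <- homoplasy_indices(cm2, t4)
  expect_equal(h2$per_character$RI, 1)

  set.seed(9)
  cm3 <- random_char_matrix(6, 15, seed = 9, taxa = NULL)
  tr <- ape::rtree(6, tip.label = cm3$taxa)
  h3 <- homoplasy_indices(cm3, tr)
  expect_true(all(h3$per_character$m <= h3$per_character$s))
  expect_true(all(h3$per_character$s <= h3$per_character$g))
  ri <- h3$per_character$RI
  expect_true(all(ri[!is.na(ri)] >= 0 & ri[!is.na(ri)] <= 1))
  expect_gt(h3$ensemble_CI, 0); expect_lte(h3$ensemble_CI, 1)
})

test_that("ACCTRAN maps place changes rootward and conserve step totals", {
  t5 <- read_tree("(((A,B),C),D);")
  ac <- acctran_changes(t5, list(A = 0L, B = 0L, C = 1L, D = 1L))
  expect_equal(nrow(ac$changes), 1)
  expect_setequal(c(ac$changes$from, ac$changes$to), c(0, 1))
  expect_error(acctran_changes(ape::unroot(ape::rtree(5)),
                               stats::setNames(as.list(0:4), paste0("t", 1:5))),
               "root")
  set.seed(55)
  for (k in 1:60) {
    tr <- ape::rtree(sample(5:9, 1))
    cells <- as.list(sample(0:3, ape::Ntip(tr), replace = TRUE))
    names(cells) <- tr$tip.label
    ac <- acctran_changes(tr, cells)
    expect_equal(ac$steps, count_steps(tr, cells)$steps)
  }
})

test_that("weighted length and informative census follow the weighting rules", {
  # chars with steps 1 and 2 at weights 1 and 0.25 give length 1.5
  st <- cells_matrix(list(0, 0, 1, 1), list(0, 1, 2, 2),
                     taxa = c("A", "B", "C", "D"))
  cm <- char_matrix(st, weight = c(1, 0.25))
  ms <- matrix_score(cm, t4)
  expect_equal(ms$length, 1.5)
  # autapomorphy is not parsimony informative
  cm2 <- char_matrix(cells_matrix(list(0, 0, 0, 1), taxa = c("A", "B", "C", "D")))
  expect_equal(matrix_score(cm2, t4)$n_informative, 0)
  # zero weight excludes from both length and census
  cm3 <- char_matrix(st, weight = c(0, 1))
  expect_equal(matrix_score(cm3, t4)$length, 2)
})

test_that("TBR search finds the exhaustive optimum on 6 taxa", {
  # homoplasy-free matrix recovers its generating tree at the minimum length
  set.seed(21)
  tt <- ape::rtree(6)
  ntip <- 6; po <- phyloconflict:::reorder_rows(tt, "postorder")
  below <- vector("list", max(tt$edge))
  for (i in 1:ntip) below[[i]] <- i
  cols <- list()
  for (i in po) {
    p <- tt$edge[i, 1]; v <- tt$edge[i, 2]
    below[[p]] <- c(below[[p]], below[[v]])
    if (v > ntip) {
      x <- rep(0L, ntip); x[below[[v]]] <- 1L
      cols[[length(cols) + 1]] <- as.list(x)
    }
  }
  st <- do.call(cells_matrix, c(cols, list(taxa = tt$tip.label)))
  cm <- char_matrix(st)
  res <- mp_search(cm, n_reps = 3, seed = 4)
  expect_equal(res$length, length(cols))
  expect_equal(phangorn::RF.dist(res$trees[[1]], ape::unroot(tt)), 0)

  # random matrices: search optimum equals exhaustive search over 105 trees
  for (k in 1:3) {
    cmr <- random_char_matrix(6, 10, seed = 100 + k)
    res <- mp_search(cmr, n_reps = 5, seed = k)
    allt <- phangorn::allTrees(6, rooted = FALSE, tip.label = cmr$taxa)
    best <- min(vapply(allt, function(tr)
      matrix_score(cmr, tr)$length, numeric(1)))
    expect_equal(res$length, best)
  }
  expect_error(mp_search(random_char_matrix(3, 5), n_reps = 1), "4 taxa")
})

test_that("RI distribution comparisons match hand-computed statistics", {
  r <- ri_distribution_tests(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_equal(r$D, 0)
  expect_equal(r$p_ks, 1)
  cc <- data.frame(class = c("a", "b"), n_ri1 = c(30, 10), n_total = c(50, 50))
  r2 <- ri_distribution_tests(runif(10), runif(10), cc)
  expect_equal(r2$G, 2 * (30 * log(30 / 20) + 10 * log(10 / 20)))
  expect_equal(r2$df, 1)
  # observed == expected gives G = 0
  g0 <- g_test(c(20, 20), c(20, 20))
  expect_equal(g0$G, 0)
  expect_equal(g0$p, 1)
  expect_error(ri_distribution_tests(numeric(0), c(1)), "empty")
})

test_that("unit-cost Sankoff agrees with an independent Fitch implementation", {
  set.seed(71)
  for (k in 1:20) {
    tr <- ape::rtree(7)
    x <- sample(0:2, 7, replace = TRUE)
    cells <- stats::setNames(as.list(x), tr$tip.label)
    pd <- phangorn::phyDat(matrix(as.character(x), ncol = 1,
                                  dimnames = list(tr$tip.label, NULL)),
                           type = "USER", levels = c("0", "1", "2"))
    expect_equal(count_steps(tr, cells)$steps,
                 phangorn::parsimony(tr, pd))
  }
})
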