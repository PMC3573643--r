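random_aln <- function(ntax, n, seed, taxa = paste0("t", seq_len(ntax))) {
  set.seed(seed)
  seq_alignment(matrix(sample(c("A", "C", "G", "T"), ntax * n, TRUE),
                       ntax, n, dimnames = list(taxa, NULL)))
}

test_that("pruning likelihood equals explicit summation on 4-taxon trees", {
  set.seed(19)
  tr <- read_tree("((A:0.12,B:0.23):0.1,(C:0.31,D:0.08):0.15);")
  for (k in 1:5) {
    aln <- random_aln(4, 30, 500 + k, taxa = c("A", "B", "C", "D"))
    m <- substitution_model("GTR",
                            rates = c(runif(5, 0.3, 4), 1),
                            pi = as.vector(stats::rgamma(4, 5) ->
                                             g0) / sum(g0),
                            p_inv = if (k %% 2) 0.2 else 0,
                            alpha = 0.7, n_cat = if (k %% 2) 4L else 0L)
    pat <- phyloconflict:::nt_patterns(aln$seqs[tr$tip.label, ])
    mine <- sum(pat$w * phyloconflict:::nt_site_loglik(tr, pat, m,
                                                       tr$edge.length))
    expect_equal(mine, brute_nt_loglik(tr, aln$seqs, m), tolerance = 1e-8)
  }
})

test_that("identical sequences at zero branch length give the base-frequency likelihood", {
  set.seed(3)
  x <- sample(c("A", "C", "G", "T"), 40, TRUE)
  S <- rbind(A = x, B = x)
  tr <- read_tree("(A:0.00000001,B:0.00000001);")
  m <- substitution_model("HKY", rates = c(1, 3, 1, 1, 3, 1),
                          pi = c(.4, .1, .2, .3))
  pat <- phyloconflict:::nt_patterns(S)
  ll <- sum(pat$w * phyloconflict:::nt_site_loglik(tr, pat, m, tr$edge.length))
  expect_equal(ll, sum(log(m$pi[match(x, c("A", "C", "G", "T"))])),
               tolerance = 1e-4)
})

test_that("a two-taxon JC fit recovers the closed-form distance", {
  set.seed(13)
  x <- sample(c("A", "C", "G", "T"), 600, TRUE)
  y <- x; flip <- runif(600) < 0.25
  y[flip] <- sample(c("A", "C", "G", "T"), sum(flip), TRUE)
  p <- mean(x != y)
  aln <- seq_alignment(rbind(A = x, B = y))
  tr <- read_tree("(A:0.1,B:0.1);")
  fit <- fit_tree(tr, aln, substitution_model("JC"), tol = 1e-8)
  expect_equal(sum(fit$tree$edge.length), -0.75 * log(1 - 4 * p / 3),
               tolerance = 1e-5)
})

test_that("likelihood is invariant to re-rooting and nesting never hurts", {
  tr <- sim_tree(6, depth = 0.5, seed = 77)
  aln <- sim_nucleotide(tr, list(list(name = "g", length = 300,
    model = substitution_model("HKY", rates = c(1, 3, 1, 1, 3, 1),
                               pi = c(.3, .2, .3, .2)))), seed = 77)
  m <- substitution_model("GTR", rates = c(1.5, 3, 0.7, 1.2, 4, 1),
                          pi = c(.28, .22, .27, .23), p_inv = 0.1,
                          alpha = 0.9, n_cat = 4)
  base_ll <- function(tree) {
    pat <- phyloconflict:::nt_patterns(aln$seqs[tree$tip.label, ])
    sum(pat$w * phyloconflict:::nt_site_loglik(tree, pat, m, tree$edge.length))
  }
  ref <- base_ll(tr)
  set.seed(5)
  for (k in 1:10) {
    tr2 <- ape::root(ape::unroot(tr), outgroup = sample(tr$tip.label, 1),
                     resolve.root = TRUE)
    expect_equal(base_ll(tr2), ref, tolerance = 1e-6)
  }
  # nesting: the JC likelihood can never exceed an optimized GTR+I+G
  fit_jc <- fit_tree(tr, aln, substitution_model("JC"), tol = 1e-4,
                     max_passes = 4)
  fit_gtr <- fit_tree(tr, aln,
                      substitution_model("GTR", pi = rep(0.25, 4),
                                         p_inv = 0.1, alpha = 1, n_cat = 4),
                      tol = 1e-4, max_passes = 4)
  expect_gte(fit_gtr$logLik, fit_jc$logLik - 1e-6)
})

test_that("partitioned fits are additive over partitions and sites", {
  tr <- sim_tree(6, depth = 0.4, seed = 88)
  parts <- list(
    list(name = "slow", length = 200, model = substitution_model("JC"),
         multiplier = 0.5),
    list(name = "fast", length = 200, model = substitution_model("JC"),
         multiplier = 3))
  aln <- sim_nucleotide(tr, parts, seed = 88)
  fit <- fit_tree(tr, aln, substitution_model("HKY", n_cat = 0),
                  tol = 1e-4, max_passes = 4)
  expect_equal(sum(fit$site_loglik), fit$logLik, tolerance = 1e-8)
  expect_equal(sum(fit$partition_loglik), fit$logLik, tolerance = 1e-8)
  expect_equal(length(fit$multipliers), 2)
  expect_equal(stats::weighted.mean(fit$multipliers, c(200, 200)), 1,
               tolerance = 1e-6)
  # the faster partition earns the larger multiplier
  expect_gt(fit$multipliers[2], fit$multipliers[1])
})

test_that("one gamma category is exactly the no-gamma model", {
  tr <- sim_tree(5, depth = 0.4, seed = 91)
  aln <- random_aln(5, 100, 91, taxa = tr$tip.label)
  m1 <- substitution_model("HKY", rates = c(1, 2, 1, 1, 2, 1),
                           pi = c(.3, .2, .25, .25), alpha = 0.5, n_cat = 1L)
  m0 <- substitution_model("HKY", rates = c(1, 2, 1, 1, 2, 1),
                           pi = c(.3, .2, .25, .25), n_cat = 0L)
  pat <- phyloconflict:::nt_patterns(aln$seqs[tr$tip.label, ])
  expect_equal(
    phyloconflict:::nt_site_loglik(tr, pat, m1, tr$edge.length),
    phyloconflict:::nt_site_loglik(tr, pat, m0, tr$edge.length))
})

test_that("AICc, BIC and the DT risk follow their formulas", {
  tr <- sim_tree(5, depth = 0.4, seed = 92)
  aln <- sim_nucleotide(tr, list(list(name = "g", length = 250,
    model = substitution_model("JC"))), seed = 92)
  fit <- fit_tree(tr, aln, substitution_model("JC"), tol = 1e-4,
                  max_passes = 3)
  K <- fit$K; n <- fit$n; ll <- fit$logLik
  expect_equal(fit$AICc, -2 * ll + 2 * K + 2 * K * (K + 1) / (n - K - 1))
  expect_equal(fit$BIC, -2 * ll + K * log(n))

  fit2 <- fit_tree(tr, aln, substitution_model("HKY", n_cat = 0),
                   tol = 1e-4, max_passes = 3)
  cmp <- compare_partition_schemes(list(jc = fit, hky = fit2))
  bic <- cmp$table$BIC
  w <- exp(-(bic - min(bic)) / 2); w <- w / sum(w)
  d12 <- sqrt(sum((phyloconflict:::sort_edge_lengths(fit$tree) -
                   phyloconflict:::sort_edge_lengths(fit2$tree))^2))
  expect_equal(cmp$table$DT_risk, c(w[2] * d12, w[1] * d12), tolerance = 1e-12)
  expect_true(all(c("AICc", "BIC", "DT") %in% names(cmp$winner)))
})

test_that("richer partitioning is preferred when rates truly differ", {
  tr <- sim_tree(6, depth = 0.5, seed = 93)
  parts <- list(
    list(name = "a", length = 350, model = substitution_model("HKY",
      rates = c(1, 6, 1, 1, 6, 1), pi = c(.35, .15, .2, .3)), multiplier = 0.3),
    list(name = "b", length = 350, model = substitution_model("HKY",
      rates = c(1, 1.5, 1, 1, 1.5, 1), pi = c(.2, .3, .3, .2)), multiplier = 3))
  aln <- sim_nucleotide(tr, parts, seed = 93)
  one <- seq_alignment(aln$seqs, taxa = aln$taxa)   # single partition
  f1 <- fit_tree(tr, one, substitution_model("HKY", n_cat = 0),
                 tol = 1e-4, max_passes = 4)
  f2 <- fit_tree(f1$tree, aln, substitution_model("HKY", n_cat = 0),
                 tol = 1e-4, max_passes = 4)
  expect_gte(f2$logLik, f1$logLik)       # nesting
  cmp <- compare_partition_schemes(list(one_part = f1, two_part = f2))
  expect_equal(unname(cmp$winner["AICc"]), "two_part")
  expect_equal(unname(cmp$winner["BIC"]), "two_part")
})

test_that("model selection by AICc identifies simple generating models", {
  hits <- 0
  for (k in 1:4) {
    tr <- sim_tree(5, depth = 0.6, seed = 600 + k)
    aln <- sim_nucleotide(tr, list(list(name = "g", length = 1500,
      model = substitution_model("JC"))), seed = 600 + k)
    sel <- select_substitution_model(aln, tree = tr,
                                     constraints = c("JC", "GTR"),
                                     heterogeneity = c("", "IG"))
    if (startsWith(sel$table$model[1], "JC")) hits <- hits + 1
  }
  expect_gte(hits, 3)
})

test_that("site-likelihood matrices survive the TSV interchange", {
  set.seed(2)
  L <- matrix(rnorm(60), 20, 3,
              dimnames = list(NULL, c("best", "alt", "rand")))
  slm <- site_likelihood_matrix(L, partition = rep(c("p1", "p2"), each = 10))
  path <- tempfile(fileext = ".tsv")
  write_site_likelihoods(slm, path)
  slm2 <- read_site_likelihoods(path)
  expect_equal(slm2$logl, slm$logl, tolerance = 1e-12)
  expect_equal(slm2$partition, slm$partition)
  expect_error(site_likelihood_matrix(matrix(c(1, Inf), 1)), "finite")
})
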