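test_that("tree covariance equals shared root-to-MRCA path lengths", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  C <- phylo_vcv(tree)
  expect_equal(C["a", "a"], 2)
  expect_equal(C["b", "b"], 2)
  expect_equal(C["c", "c"], 2)
  expect_equal(C["a", "b"], 1)
  expect_equal(C["a", "c"], 0)

  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  Cs <- phylo_vcv(star)
  expect_equal(unname(Cs), diag(4))

  set.seed(23)
  rt <- ape::rtree(12)
  expect_equal(phylo_vcv(rt)[rt$tip.label, rt$tip.label],
               brute_vcv(rt), tolerance = 1e-12)
})

test_that("lambda optimiser agrees with an independent dense grid search", {
  set.seed(71)
  for (i in 1:3) {
    tree <- ape::rtree(40)
    x <- ape::rTraitCont(tree, model = "BM", sigma = 1)
    fit <- pagels_lambda(tree, x)
    expect_lt(abs(fit$lambda - oracle_lambda_grid(tree, x)), 0.01)
    expect_gte(fit$loglik, fit$loglik0)
    expect_true(fit$p_value >= 0 && fit$p_value <= 1)
  }
})

test_that("lambda matches the reference phylogenetics implementation", {
  skip_if_not_installed("phytools")
  set.seed(72)
  tree <- ape::rtree(60)
  x <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  fit <- pagels_lambda(tree, x)
  ref <- phytools::phylosig(tree, x, method = "lambda", test = TRUE)
  C <- phylo_vcv(tree)
  xx <- x[tree$tip.label]
  # identical likelihood surface: our profile likelihood reproduces the
  # reference value at the reference's own optimum, and our optimum is at
  # least as good (the reference caps its search interval differently)
  expect_equal(cellphylo:::lambda_loglik(ref$lambda, xx, C), ref$logL,
               tolerance = 1e-4)
  expect_gte(fit$loglik, ref$logL - 1e-6)
  expect_equal(fit$loglik0, ref$logL0, tolerance = 1e-4)
})

test_that("profile likelihood reduces to closed forms on a 3-tip tree", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  x <- c(a = 0.3, b = 0.7, c = 2.1)
  C <- phylo_vcv(tree)[names(x), names(x)]
  for (lam in c(0, 0.5, 1)) {
    Cl <- lam * C
    diag(Cl) <- diag(C)
    Ci <- solve(Cl)
    mu <- sum(Ci %*% x) / sum(Ci)
    s2 <- as.numeric(t(x - mu) %*% Ci %*% (x - mu)) / 3
    manual <- -3 / 2 * log(2 * pi * s2) -
      as.numeric(determinant(Cl)$modulus) / 2 - 3 / 2
    expect_equal(cellphylo:::lambda_loglik(lam, x, C), manual,
                 tolerance = 1e-10)
  }
})

test_that("permutation destroys lambda signal; constant traits error", {
  set.seed(73)
  tree <- ape::rtree(80)
  x <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  lams <- replicate(10, {
    xp <- setNames(sample(x), names(x))
    pagels_lambda(tree, xp)$lambda
  })
  expect_lt(median(lams), 0.1)
  expect_error(pagels_lambda(tree, setNames(rep(1, 80), tree$tip.label)),
               "constant")
})

test_that("Blomberg's K matches the reference implementation and the star limit", {
  set.seed(74)
  tree <- ape::rtree(40)
  x <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  expect_equal(blomberg_k(tree, x),
               as.numeric(picante::Kcalc(x[tree$tip.label], tree)),
               tolerance = 1e-8)
  # permutation pushes K far below 1
  xp <- setNames(sample(x), names(x))
  ks <- replicate(10, blomberg_k(tree, setNames(sample(x), names(x))))
  expect_lt(mean(ks), 0.7)
  # equal-length star tree: K is exactly 1 for any trait
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1);")
  y <- setNames(rnorm(5), star$tip.label)
  expect_equal(blomberg_k(star, y), 1, tolerance = 1e-10)
})

test_that("SES MPD flags clade-restricted groups as clustered", {
  sim <- simulate_dataset(sim_config(n_cells = 40, n_sites = 10, seed = 5))
  tree <- sim$truth$tree
  groups <- sim$truth$clades
  res <- ses_mpd(tree, groups, n_perm = 199, seed = 9)
  expect_equal(nrow(res), 2)
  expect_true(all(res$z < 0))           # each clade is phylogenetically tight
  expect_true(all(res$p_value < 0.05))
  # deterministic under the seed
  res2 <- ses_mpd(tree, groups, n_perm = 199, seed = 9)
  expect_equal(res, res2)
})

test_that("SES MPD guards degenerate groups", {
  set.seed(75)
  tree <- ape::rtree(12)
  all_one <- setNames(rep("g", 12), tree$tip.label)
  res <- ses_mpd(tree, all_one, n_perm = 99, seed = 2)
  expect_equal(res$z, 0)
  singleton <- setNames(c("a", rep("b", 11)), tree$tip.label)
  expect_error(ses_mpd(tree, singleton, n_perm = 99), "singleton")
  expect_error(ses_mpd(tree, all_one, n_perm = 10), "at least 99")
})

test_that("adjusted Rand index matches brute-force pair enumeration", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  set.seed(76)
  for (i in 1:5) {
    a <- sample(3, 30, replace = TRUE)
    b <- sample(4, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), brute_ari(a, b),
                 tolerance = 1e-12)
    expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
  }
  # invariant to label renaming; aligns named vectors by cell
  a <- setNames(c(1, 1, 2, 2), c("w", "x", "y", "z"))
  b <- setNames(c("q", "q", "p", "p"), c("y", "z", "w", "x"))
  expect_equal(adjusted_rand_index(a, b), 1)
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("BH correction is appended per trait", {
  res <- tibble::tibble(trait = c("t1", "t2"), p_value = c(0.01, 0.04))
  out <- adjust_fdr(res)
  expect_equal(out$fdr, p.adjust(res$p_value, "BH"))
})
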