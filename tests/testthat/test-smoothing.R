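test_that("profile sampling honours degenerate distributions and the seed", {
  arr <- array(0, dim = c(2, 2, 3))
  arr[1, , 1] <- 1                      # site 1: surely R
  arr[2, , 3] <- 1                      # site 2: surely A
  pr <- make_probs(arr)
  draws <- sample_profiles(pr, n_samplings = 20, seed = 4)
  expect_true(all(draws[, 1, ] == 1L))
  expect_true(all(draws[, 2, ] == 3L))
  expect_identical(draws, sample_profiles(pr, n_samplings = 20, seed = 4))

  arr2 <- array(1 / 3, dim = c(3, 3, 3))
  pr2 <- make_probs(arr2)
  d1 <- sample_profiles(pr2, n_samplings = 20, seed = 4)
  expect_identical(d1, sample_profiles(pr2, n_samplings = 20, seed = 4))
  expect_false(identical(d1, sample_profiles(pr2, n_samplings = 20,
                                             seed = 5)))
})

test_that("sampled frequencies converge to the generating distribution", {
  arr <- array(rep(c(0.3, 0.4, 0.3), each = 1), dim = c(1, 1, 3))
  pr <- make_probs(arr)
  draws <- sample_profiles(pr, n_samplings = 10000, seed = 11)
  freq <- tabulate(draws, nbins = 3) / 10000
  expect_lt(max(abs(freq - c(0.3, 0.4, 0.3))), 0.02)
})

test_that("pairwise similarity spans identity, disagreement and chance", {
  # identical degenerate profiles -> similarity 1
  arr <- array(0, dim = c(4, 2, 3))
  arr[, , 1] <- 1
  expect_equal(pairwise_similarity(make_probs(arr), 50, seed = 1)[1, 2], 1)

  # degenerate but opposite at every site -> 0
  arr2 <- array(0, dim = c(4, 2, 3))
  arr2[, 1, 1] <- 1
  arr2[, 2, 3] <- 1
  expect_equal(pairwise_similarity(make_probs(arr2), 50, seed = 1)[1, 2], 0)

  # uniform over genotypes -> expected agreement 1/3
  arr3 <- array(1 / 3, dim = c(60, 2, 3))
  s <- pairwise_similarity(make_probs(arr3), 200, seed = 2)[1, 2]
  expect_lt(abs(s - 1 / 3), 0.03)
})

test_that("similarity matrices are symmetric, unit-diagonal, site-order invariant", {
  set.seed(8)
  arr <- array(stats::runif(5 * 4 * 3), dim = c(5, 4, 3))
  arr <- arr / rep(apply(arr, 1:2, sum), times = 3)
  s <- pairwise_similarity(make_probs(arr), 100, seed = 3)
  expect_equal(s, t(s))
  expect_equal(unname(diag(s)), rep(1, 4))
  expect_true(all(s >= 0 & s <= 1))
  perm <- c(3, 1, 5, 2, 4)
  s_perm <- pairwise_similarity(make_probs(arr[perm, , ]), 100, seed = 3)
  # same seed, same per-element draws up to site relabeling
  expect_equal(unname(colMeans(s)), unname(colMeans(s_perm)), tolerance = 0.1)
})

test_that("kNN selection matches a brute-force sort oracle", {
  set.seed(12)
  n <- 9
  s <- matrix(runif(n * n), n, n)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  colnames(s) <- rownames(s) <- paste0("c", 1:n)
  nb <- build_knn(s, 3)
  for (j in 1:n) {
    v <- s[, j]
    v[j] <- -Inf
    ord <- order(-v, seq_len(n))
    expect_equal(unname(nb$idx[, j]), ord[1:3])
    expect_false(j %in% nb$idx[, j])
    expect_true(all(diff(nb$score[, j]) <= 0))
  }
})

test_that("kNN ties resolve to the lowest-indexed cells", {
  s <- matrix(0.5, 4, 4)
  diag(s) <- 1
  colnames(s) <- rownames(s) <- paste0("c", 1:4)
  nb <- build_knn(s, 2)
  expect_equal(unname(nb$idx[, 1]), c(2L, 3L))
  expect_equal(unname(nb$idx[, 4]), c(1L, 2L))
  expect_error(build_knn(s, 4), "k must")
})

test_that("smoothing follows the convex-combination equation exactly", {
  # one site, three cells; c1's only neighbours are c2 and c3
  arr <- array(c(0.6, 0.2, 0.2,
                 0.3, 0.5, 0.5,
                 0.1, 0.3, 0.3), dim = c(1, 3, 3))
  pr <- make_probs(arr)
  nb <- structure(list(idx = matrix(c(2L, 3L, 1L, 3L, 1L, 2L), 2, 3),
                       score = matrix(1, 2, 3),
                       cells = c("c1", "c2", "c3")),
                  class = "neighbor_map")
  out <- smooth_probabilities(pr, nb, delta = 0.5)
  expect_equal(unname(out[1, 1, ]), c(0.4, 0.4, 0.2), tolerance = 1e-12)

  # delta = 0 is the identity
  out0 <- smooth_probabilities(pr, nb, delta = 0)
  expect_equal(unclass(out0), unclass(pr), ignore_attr = TRUE)

  expect_error(smooth_probabilities(pr, nb, delta = 1.2), "delta")
})

test_that("shared distributions are a fixed point for any delta", {
  arr <- array(rep(c(0.2, 0.5, 0.3), each = 6), dim = c(2, 3, 3))
  pr <- make_probs(arr)
  nb <- build_knn(pairwise_similarity(pr, 20, seed = 2), 2)
  for (delta in c(0, 0.3, 10 / 11, 1)) {
    out <- smooth_probabilities(pr, nb, delta)
    expect_equal(unclass(out), unclass(pr), ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("delta = K/(K+1) reduces smoothing to the plain (K+1)-cell average", {
  set.seed(31)
  arr <- array(stats::runif(6 * 5 * 3), dim = c(6, 5, 3))
  arr <- arr / rep(apply(arr, 1:2, sum), times = 3)
  pr <- make_probs(arr)
  k <- 3
  nb <- build_knn(pairwise_similarity(pr, 50, seed = 5), k)
  out <- smooth_probabilities(pr, nb, k / (k + 1))
  for (j in 1:5) {
    members <- c(j, nb$idx[, j])
    avg <- apply(unclass(pr)[, members, , drop = FALSE], c(1, 3), mean)
    expect_equal(unname(unclass(out)[, j, ]), unname(avg), tolerance = 1e-12)
  }
  # simplex preserved
  expect_lt(max(abs(apply(unclass(out), 1:2, sum) - 1)), 1e-9)
  # convexity: each value between own value and neighbour mean
  for (j in 1:5) {
    nbr_mean <- apply(unclass(pr)[, nb$idx[, j], , drop = FALSE],
                      c(1, 3), mean)
    own <- unclass(pr)[, j, ]
    lo <- pmin(own, nbr_mean) - 1e-12
    hi <- pmax(own, nbr_mean) + 1e-12
    expect_true(all(unclass(out)[, j, ] >= lo & unclass(out)[, j, ] <= hi))
  }
})

test_that("end-to-end smoothing is deterministic and dropout-free", {
  sim <- simulate_dataset(sim_config(n_cells = 40, n_sites = 60, seed = 9))
  sm1 <- smooth_genotypes(sim$counts, k = 5, n_samplings = 30, seed = 17)
  sm2 <- smooth_genotypes(sim$counts, k = 5, n_samplings = 30, seed = 17)
  expect_identical(sm1$calls, sm2$calls)
  expect_identical(unclass(sm1$probs), unclass(sm2$probs))
  expect_false(any(sm1$calls == "MISSING"))

  one_cell <- subset_counts(sim$counts, cells = 1)
  expect_error(smooth_genotypes(one_cell), "at least 2 cells")
})

test_that("smoothing improves clade recovery on two-clade data", {
  res <- smoothing_ari_experiment(sim_config(n_cells = 150, n_sites = 250,
                                             seed = 41), seed = 6)
  expect_gt(res$ari_after, res$ari_before)
})
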