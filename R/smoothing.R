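#' Sample discrete genotype profiles from genotype probabilities
#'
#' Each site-cell element is drawn independently from its (R, H, A)
#' distribution, once per sampling iteration. Dropout elements participate
#' through their prior, so every site contributes to every draw.
#'
#' @param probs A `genotype_probs` object.
#' @param n_samplings Number of profile draws (default 100).
#' @param seed Integer RNG seed; the draws are reproducible given the seed.
#' @return An integer array `n_samplings` x sites x cells with values 1 (R),
#'   2 (H), 3 (A).
#' @export
sample_profiles <- function(probs, n_samplings = 100, seed = 1L) {
  stopifnot(n_samplings >= 1)
  pr <- unclass(probs)
  pR <- prob_slice(pr, "R")
  pRH <- pR + prob_slice(pr, "H")
  out <- array(NA_integer_,
               dim = c(n_samplings, dim(pr)[1], dim(pr)[2]),
               dimnames = c(list(NULL), dimnames(pr)[1:2]))
  n <- length(pR)
  withr::with_seed(seed, {
    for (t in seq_len(n_samplings)) {
      u <- stats::runif(n)
      out[t, , ] <- 1L + (u > pR) + (u > pRH)
    }
  })
  out
}

# draw one sites x cells genotype matrix (values 1/2/3) from cumulative probs
draw_profile <- function(pR, pRH) {
  u <- stats::runif(length(pR))
  m <- 1L + (u > pR) + (u > pRH)
  dim(m) <- dim(pR)
  m
}

#' Sampled-profile similarity between all pairs of cells
#'
#' The genotype similarity of two cells is the fraction of sites at which
#' their sampled genotype profiles agree, averaged over `n_samplings`
#' independent draws (a simple matching coefficient over sites). One profile
#' is drawn per cell per iteration and reused for every pair, which matches
#' the per-pair description in expectation while keeping the computation a
#' handful of matrix cross-products.
#'
#' @param probs A `genotype_probs` object with at least 1 site and 2 cells.
#' @param n_samplings Number of profile draws (default 100).
#' @param seed Integer RNG seed.
#' @return A symmetric cells x cells matrix with unit diagonal, values in
#'   \[0, 1\].
#' @export
pairwise_similarity <- function(probs, n_samplings = 100, seed = 1L) {
  pr <- unclass(probs)
  n_sites <- dim(pr)[1]
  n_cells <- dim(pr)[2]
  if (n_sites < 1) stop("similarity needs at least one site")
  if (n_cells < 2) stop("similarity needs at least two cells")
  pR <- prob_slice(pr, "R")
  pRH <- pR + prob_slice(pr, "H")
  agree <- matrix(0, n_cells, n_cells)
  withr::with_seed(seed, {
    for (t in seq_len(n_samplings)) {
      g <- draw_profile(pR, pRH)
      for (k in 1:3) {
        ind <- g == k
        storage.mode(ind) <- "double"
        agree <- agree + crossprod(ind)
      }
    }
  })
  s <- agree / (n_samplings * n_sites)
  # exact symmetry and unit diagonal by construction; enforce against fp noise
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- list(dimnames(pr)[[2]], dimnames(pr)[[2]])
  s
}

#' K nearest neighbours from a similarity matrix
#'
#' For each cell, the `k` other cells with the highest similarity; ties are
#' broken by ascending cell index so the neighbour map is deterministic.
#'
#' @param similarity Square symmetric similarity matrix (unit diagonal).
#' @param k Number of neighbours, `1 <= k <= ncol - 1`.
#' @return A `neighbor_map` object: list with integer matrix `idx` (k x
#'   cells), numeric matrix `score`, and `cells`. Scores are non-increasing
#'   down each column.
#' @export
build_knn <- function(similarity, k) {
  n <- ncol(similarity)
  if (nrow(similarity) != n) stop("similarity matrix must be square")
  if (k < 1 || k >= n)
    stop("k must satisfy 1 <= k <= n_cells - 1 (n_cells = ", n, ")")
  cells <- colnames(similarity)
  if (is.null(cells)) cells <- as.character(seq_len(n))
  idx <- matrix(0L, k, n)
  score <- matrix(0, k, n)
  for (j in seq_len(n)) {
    s <- similarity[, j]
    s[j] <- -Inf                       # never self
    ord <- order(s, seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")
    idx[, j] <- ord[seq_len(k)]
    score[, j] <- s[ord[seq_len(k)]]
  }
  colnames(idx) <- colnames(score) <- cells
  structure(list(idx = idx, score = score, cells = cells),
            class = "neighbor_map")
}

#' @export
print.neighbor_map <- function(x, ...) {
  cat("<neighbor_map> K = ", nrow(x$idx), " over ", length(x$cells),
      " cells\n", sep = "")
  invisible(x)
}

#' Long-format view of a neighbour map
#'
#' @param x A `neighbor_map`.
#' @param ... Unused.
#' @return Tibble with columns cell, rank, neighbor, score.
#' @export
tidy.neighbor_map <- function(x, ...) {
  k <- nrow(x$idx)
  tibble::tibble(
    cell = rep(x$cells, each = k),
    rank = rep(seq_len(k), times = length(x$cells)),
    neighbor = x$cells[as.vector(x$idx)],
    score = as.vector(x$score)
  )
}

#' Smooth genotype probabilities toward the K nearest neighbours
#'
#' Each cell's per-site genotype distribution is replaced by the convex
#' combination
#' \deqn{\hat p_{i,j,g} = (1-\delta)\, p_{i,j,g} +
#'       \delta\, \frac{1}{K}\sum_{k \in N(i)} p_{k,j,g},}
#' where N(i) are the cell's neighbours. With the default
#' `delta = K/(K+1)` this is exactly the plain average of the cell with its
#' K neighbours.
#'
#' @param probs A `genotype_probs` object.
#' @param neighbors A `neighbor_map` built on the same cells.
#' @param delta Neighbour mass fraction in \[0, 1\].
#' @return A `genotype_probs` object of the same shape; triples remain on the
#'   probability simplex.
#' @export
smooth_probabilities <- function(probs, neighbors, delta) {
  if (!is.numeric(delta) || length(delta) != 1 || is.na(delta) ||
      delta < 0 || delta > 1)
    stop("delta must lie in [0, 1]")
  pr <- unclass(probs)
  n_cells <- dim(pr)[2]
  if (length(neighbors$cells) != n_cells)
    stop("neighbor map does not match the cells of `probs`")
  k <- nrow(neighbors$idx)
  # cells x cells averaging operator: column j holds 1/K at j's neighbours
  A <- matrix(0, n_cells, n_cells)
  A[cbind(as.vector(neighbors$idx), rep(seq_len(n_cells), each = k))] <- 1 / k
  out <- pr
  for (g in GENOTYPES) {
    m <- prob_slice(pr, g)
    out[, , g] <- (1 - delta) * m + delta * (m %*% A)
  }
  structure(out, class = "genotype_probs", theta = attr(probs, "theta"),
            sites = attr(probs, "sites"))
}

#' Full genotype calling with kNN smoothing
#'
#' End-to-end composition: beta-binomial genotype probabilities, sampled-
#' profile pairwise similarity, K-nearest-neighbour selection, probability
#' smoothing, and a final argmax call. The smoothed calls contain no
#' missing values: dropout elements borrow their genotype from the
#' neighbourhood.
#'
#' @param counts A [cell_counts] with at least 2 cells.
#' @param theta Noise threshold for the beta model (default 0.3).
#' @param k Number of neighbours (default 10, capped at `n_cells - 1`).
#' @param delta Neighbour mass fraction; default `k/(k+1)`.
#' @param n_samplings Profile draws for the similarity score (default 100).
#' @param seed Integer RNG seed.
#' @return A list with elements `probs` (smoothed `genotype_probs`), `calls`
#'   (character matrix), `neighbors` (`neighbor_map`), `raw_probs`
#'   (pre-smoothing probabilities), and the parameters used.
#' @export
smooth_genotypes <- function(counts, theta = 0.3, k = 10,
                             delta = k / (k + 1), n_samplings = 100,
                             seed = 1L) {
  stopifnot(inherits(counts, "cell_counts"))
  n_cells <- length(counts$cells)
  if (n_cells < 2)
    stop("smoothing needs at least 2 cells (no neighbours exist)")
  if (k >= n_cells) k <- n_cells - 1L
  raw <- genotype_probabilities(counts, theta)
  sim <- pairwise_similarity(raw, n_samplings = n_samplings, seed = seed)
  nb <- build_knn(sim, k)
  sm <- smooth_probabilities(raw, nb, delta)
  list(probs = sm, calls = call_genotypes(sm), neighbors = nb,
       raw_probs = raw, similarity = sim,
       params = list(theta = theta, k = k, delta = delta,
                     n_samplings = n_samplings, seed = seed))
}
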