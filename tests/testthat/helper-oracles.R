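# Independent oracles used to freeze expected values. Each deliberately
# avoids the code path it checks.

# genotype probabilities by numeric quadrature of the Beta density over the
# three theta-delimited regions of allele frequency
quad_probs <- function(r, a, theta) {
  f <- function(p) stats::dbeta(p, a + 1, r + 1)
  pR <- stats::integrate(f, 0, theta, rel.tol = 1e-12)$value
  pA <- stats::integrate(f, 1 - theta, 1, rel.tol = 1e-12)$value
  c(R = pR, H = 1 - pR - pA, A = pA)
}

# Brownian-motion covariance by explicit root-to-tip path walks on the edge
# table (no vcv.phylo)
brute_vcv <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(node) {
    nodes <- integer(0)
    while (node != root) {
      nodes <- c(nodes, node)
      node <- parent[node]
    }
    nodes
  }
  paths <- lapply(seq_len(ntip), path_to_root)
  C <- matrix(0, ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) {
    for (j in i:ntip) {
      shared <- intersect(paths[[i]], paths[[j]])
      C[i, j] <- C[j, i] <- sum(elen[shared])
    }
  }
  C
}

# adjusted Rand index by explicit enumeration of all element pairs
brute_ari <- function(a, b) {
  n <- length(a)
  s_both <- s_a <- s_b <- 0
  npair <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      s_both <- s_both + (same_a && same_b)
      s_a <- s_a + same_a
      s_b <- s_b + same_b
      npair <- npair + 1
    }
  }
  expected <- s_a * s_b / npair
  maxidx <- (s_a + s_b) / 2
  if (maxidx == expected) return(0)
  (s_both - expected) / (maxidx - expected)
}

# profile log-likelihood of lambda, written independently (solve/determinant
# instead of cholesky), for the grid-search oracle
oracle_lambda_loglik <- function(lam, x, C) {
  Cl <- lam * C
  diag(Cl) <- diag(C)
  n <- length(x)
  # the MVN likelihood is only defined on positive-definite covariances
  ev <- eigen(Cl, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(-Inf)
  Ci <- tryCatch(solve(Cl), error = function(e) NULL)
  if (is.null(Ci)) return(-Inf)
  mu <- sum(Ci %*% x) / sum(Ci)
  s2 <- as.numeric(t(x - mu) %*% Ci %*% (x - mu)) / n
  if (s2 <= 0) return(-Inf)
  ld <- as.numeric(determinant(Cl, logarithm = TRUE)$modulus)
  -n / 2 * log(2 * pi * s2) - ld / 2 - n / 2
}

oracle_lambda_grid <- function(tree, x, step = 0.001) {
  C <- brute_vcv(tree)
  x <- x[tree$tip.label]
  off <- C
  diag(off) <- 0
  lam_max <- max(diag(C)) / max(off)
  grid <- seq(0, lam_max, by = step)
  ll <- vapply(grid, oracle_lambda_loglik, numeric(1), x = x, C = C)
  grid[which.max(ll)]
}

# random additive 4-taxon instance: a sister-pair topology with positive
# branch lengths and its exact leaf-to-leaf distances
random_additive_instance <- function() {
  labs <- sample(letters[1:4])
  p <- stats::runif(4, 0.1, 2)   # pendant branches
  m <- stats::runif(1, 0.1, 2)   # internal branch
  d <- matrix(0, 4, 4, dimnames = list(labs, labs))
  d[1, 2] <- p[1] + p[2]
  d[3, 4] <- p[3] + p[4]
  for (i in 1:2) for (j in 3:4) d[i, j] <- p[i] + m + p[j]
  d <- d + t(d)
  list(d = d, sisters = list(labs[1:2], labs[3:4]))
}

# exhaustive four-point scoring: the generating split minimizes the sum of
# within-pair distances over the three possible pairings
four_point_argmin <- function(d) {
  labs <- rownames(d)
  pairings <- list(list(labs[c(1, 2)], labs[c(3, 4)]),
                   list(labs[c(1, 3)], labs[c(2, 4)]),
                   list(labs[c(1, 4)], labs[c(2, 3)]))
  score <- vapply(pairings, function(pp)
    d[pp[[1]][1], pp[[1]][2]] + d[pp[[2]][1], pp[[2]][2]], numeric(1))
  pairings[[which.min(score)]]
}
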