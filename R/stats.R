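#' Brownian-motion covariance of a rooted tree
#'
#' Under Brownian motion along the tree, the covariance of the trait values
#' at two tips equals the shared root-to-MRCA path length. `phylo_vcv()`
#' returns that tips x tips matrix (diagonal: root-to-tip distances).
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return Symmetric positive semidefinite matrix with tip labels as
#'   dimnames.
#' @export
phylo_vcv <- function(tree) {
  check_tree(tree)
  # the basal node is taken as the root; this admits star-like trees and
  # multi-clade basal polytomies, whose ape representation is "unrooted"
  ape::vcv.phylo(tree)
}

#' Pagel's lambda phylogenetic signal for a continuous trait
#'
#' Lambda rescales the off-diagonal entries of the Brownian-motion covariance
#' C while leaving the diagonal intact; the trait is modelled as multivariate
#' normal with mean mu and covariance sigma^2 C(lambda). The ML estimate of
#' lambda is found on \[0, lambda_max\], where
#' `lambda_max = max(diag(C)) / max(offdiag(C))` is the largest value keeping
#' C(lambda) a valid covariance — this deliberately allows estimates above 1.
#' Significance is a likelihood-ratio test against lambda = 0 (trait
#' independent of the tree) on one degree of freedom.
#'
#' Binary group labels can be passed as factors/characters with exactly two
#' levels; they are coded 0/1 and treated as continuous, which follows the
#' common practice of applying the continuous-trait statistic to lineage
#' membership but is a documented approximation, not a threshold model.
#'
#' @param tree Rooted `phylo`; tips must cover the trait names.
#' @param trait Named numeric vector (or two-level factor/character), one
#'   value per tip.
#' @return An object of class `phylo_signal`: list with `lambda`, `loglik`,
#'   `loglik0`, `p_value`, `lambda_max`, `n`.
#' @export
pagels_lambda <- function(tree, trait) {
  xt <- align_trait(tree, trait)
  x <- xt$x
  C <- phylo_vcv(xt$tree)
  if (stats::var(x) == 0)
    stop("trait is constant: phylogenetic signal undefined")
  off <- C
  diag(off) <- 0
  lam_max <- max(diag(C)) / max(off)
  nll <- function(lam) -lambda_loglik(lam, x, C)
  opt <- stats::optimize(nll, c(0, lam_max), tol = 1e-8)
  ll0 <- lambda_loglik(0, x, C)
  ll1 <- -opt$objective
  # the optimum can sit at the boundary; never report a worse fit than lambda=0
  if (ll0 > ll1) {
    opt$minimum <- 0
    ll1 <- ll0
  }
  lrt <- 2 * (ll1 - ll0)
  structure(list(lambda = opt$minimum, loglik = ll1, loglik0 = ll0,
                 p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
                 lambda_max = lam_max, n = length(x)),
            class = "phylo_signal")
}

# profile log-likelihood of lambda: mu and sigma^2 at their conditional MLEs
lambda_loglik <- function(lam, x, C) {
  Cl <- lam * C
  diag(Cl) <- diag(C)
  n <- length(x)
  ch <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(ch)) return(-1e10)   # finite penalty keeps optimize() quiet
  logdet <- 2 * sum(log(diag(ch)))
  Ci1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  Cix <- backsolve(ch, forwardsolve(t(ch), x))
  mu <- sum(Cix) / sum(Ci1)
  r <- x - mu
  Cir <- backsolve(ch, forwardsolve(t(ch), r))
  s2 <- sum(r * Cir) / n
  if (s2 <= 0) return(-1e10)
  -n / 2 * log(2 * pi * s2) - logdet / 2 - n / 2
}

align_trait <- function(tree, trait) {
  check_tree(tree)
  if (is.data.frame(trait)) stop("trait must be a named vector")
  if (is.factor(trait) || is.character(trait)) {
    lev <- unique(as.character(trait))
    if (length(lev) != 2)
      stop("categorical traits must have exactly 2 levels for 0/1 coding")
    nm <- names(trait)
    trait <- as.numeric(as.character(trait) == lev[2])
    names(trait) <- nm
  }
  if (is.null(names(trait)))
    stop("trait must be named by tip label")
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(miss))
    stop("trait missing for tip(s): ", paste(utils::head(miss, 3),
                                             collapse = ", "))
  list(tree = tree, x = trait[tree$tip.label])
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat(sprintf("Pagel's lambda = %.4f (logL = %.3f, logL[lambda=0] = %.3f, p = %.3g)\n",
              x$lambda, x$loglik, x$loglik0, x$p_value))
  invisible(x)
}

#' @export
tidy.phylo_signal <- function(x, ...) {
  tibble::tibble(estimate = x$lambda, loglik = x$loglik,
                 loglik0 = x$loglik0, statistic = 2 * (x$loglik - x$loglik0),
                 p.value = x$p_value)
}

#' @export
glance.phylo_signal <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, lambda_max = x$lambda_max,
                 p.value = x$p_value, n = x$n)
}

#' Blomberg's K phylogenetic signal
#'
#' The ratio of the observed mean squared error of the trait about its
#' phylogenetically corrected mean to the mean squared error under the
#' Brownian-motion expectation, scaled so K = 1 is the Brownian expectation;
#' K well below 1 indicates less signal than Brownian motion.
#'
#' @inheritParams pagels_lambda
#' @return A single positive number.
#' @export
blomberg_k <- function(tree, trait) {
  xt <- align_trait(tree, trait)
  x <- xt$x
  C <- phylo_vcv(xt$tree)
  if (stats::var(x) == 0)
    stop("trait is constant: phylogenetic signal undefined")
  n <- length(x)
  # trees with clamped zero-length branches can make C exactly singular
  # (identical tips); a tiny ridge keeps the statistic defined there
  Ci <- tryCatch(solve(C), error = function(e)
    solve(C + diag(1e-8 * mean(diag(C)), n)))
  one <- rep(1, n)
  a <- as.numeric(one %*% Ci %*% x) / as.numeric(one %*% Ci %*% one)
  mse0 <- sum((x - a)^2) / (n - 1)
  mse <- as.numeric(t(x - a) %*% Ci %*% (x - a)) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(Ci)) / (n - 1)
  (mse0 / mse) / expected
}

#' Standardized effect size of mean pairwise distance per group
#'
#' For every group of tips, the observed mean pairwise cophenetic distance
#' (MPD) is compared against a null built by permuting tip labels across the
#' whole tree while holding group sizes fixed. z = (obs - null mean) / null
#' sd; negative z means the group's cells cluster phylogenetically, positive
#' z that they are spread evenly across the tree. `p_value` is the lower-tail
#' permutation rank of the observed MPD, so small values indicate clustering.
#'
#' @param tree Rooted `phylo`.
#' @param groups Named character/factor vector of group labels, one per tip.
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Integer RNG seed.
#' @return A tibble, one row per group: `group`, `n_tips`, `mpd_obs`,
#'   `null_mean`, `null_sd`, `z`, `p_value`.
#' @export
ses_mpd <- function(tree, groups, n_perm = 999, seed = 1L) {
  check_tree(tree)
  if (n_perm < 99) stop("n_perm must be at least 99")
  if (is.null(names(groups))) stop("groups must be named by tip label")
  groups <- groups[tree$tip.label]
  if (anyNA(groups)) stop("groups missing for some tips")
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("singleton group(s): ", paste(names(sizes)[sizes < 2],
                                       collapse = ", "))
  dis <- stats::cophenetic(tree)
  if (length(sizes) == 1) {
    # one group covering every tip: label permutations cannot change MPD
    mpd_all <- mean(dis[upper.tri(dis)])
    return(tibble::tibble(group = names(sizes),
                          n_tips = as.integer(sizes),
                          mpd_obs = mpd_all, null_mean = mpd_all,
                          null_sd = 0, z = 0, p_value = 1))
  }
  comm <- t(vapply(names(sizes),
                   function(g) as.numeric(groups == g),
                   numeric(length(groups))))
  colnames(comm) <- tree$tip.label
  rownames(comm) <- names(sizes)
  res <- withr::with_seed(seed,
    picante::ses.mpd(comm, dis, null.model = "taxa.labels",
                     runs = n_perm, abundance.weighted = FALSE))
  z <- ifelse(is.finite(res$mpd.rand.sd) & res$mpd.rand.sd > 0,
              (res$mpd.obs - res$mpd.rand.mean) / res$mpd.rand.sd, 0)
  tibble::tibble(
    group = rownames(res),
    n_tips = as.integer(res$ntaxa),
    mpd_obs = res$mpd.obs,
    null_mean = res$mpd.rand.mean,
    null_sd = res$mpd.rand.sd,
    z = z,
    p_value = res$mpd.obs.p
  )
}

#' Adjusted Rand index between two labelings
#'
#' Pair-counting agreement between two partitions of the same cells,
#' corrected for chance agreement; 1 for identical partitions, about 0 for
#' independent ones.
#'
#' @param labels_a,labels_b Vectors of equal length (paired by position, or
#'   by name when both are named).
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b)))
      stop("labelings cover different cells")
    labels_b <- labels_b[names(labels_a)]
  }
  if (length(labels_a) != length(labels_b))
    stop("labelings differ in length")
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' Benjamini-Hochberg correction across many signal tests
#'
#' Convenience wrapper for screening many traits: adds an `fdr` column to a
#' results table holding a `p_value` column.
#'
#' @param results A data frame with a `p_value` column.
#' @return The same table with an `fdr` column appended.
#' @export
adjust_fdr <- function(results) {
  stopifnot("p_value" %in% names(results))
  results$fdr <- stats::p.adjust(results$p_value, method = "BH")
  results
}
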