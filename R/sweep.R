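#' Clade-recovery metrics for a genotype call matrix
#'
#' Clusters cells from their calls (Ward hierarchical clustering on N-masked
#' Hamming distances of the encoded alignment, cut at the true number of
#' clades) and scores the agreement with the true clade labels by the
#' adjusted Rand index. Cell pairs with no comparable columns get the
#' maximal distance before clustering.
#'
#' @param calls Genotype call matrix (R/H/A, MISSING allowed).
#' @param sites Site table aligned with `calls`.
#' @param truth_clades Named clade labels per cell.
#' @return ARI between the call-based clustering and the true clades.
#' @export
genotype_clustering_ari <- function(calls, sites, truth_clades) {
  aln <- encode_alignment(calls, sites)
  d <- suppressWarnings(hamming_distance_matrix(aln))
  d[is.na(d)] <- 1
  k <- length(unique(truth_clades[colnames(calls)]))
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  adjusted_rand_index(cl, truth_clades[names(cl)])
}

#' Does smoothing sharpen the clade structure of the genotype matrix?
#'
#' Runs the canonical before/after comparison on one simulated data set:
#' coarse-filter the sites on unsmoothed calls (the published stage order —
#' smoothing operates on the post-coarse-filter site set), then score the
#' clade recovery of the unsmoothed and the smoothed call matrices with
#' [genotype_clustering_ari()].
#'
#' @param config A [sim_config()].
#' @param params [filter_params()] for the coarse filter.
#' @param seed Integer RNG seed for the smoothing stage.
#' @return A tibble row with `ari_before`, `ari_after`, `n_sites_kept`.
#' @export
smoothing_ari_experiment <- function(config = sim_config(),
                                     params = filter_params(
                                       "lenient", min_cell_reads = 0),
                                     seed = 1L) {
  sim <- simulate_dataset(config)
  x <- coarse_filter_sites(sim$counts, call_unsmoothed(sim$counts), params)
  before <- call_unsmoothed(x)
  sm <- smooth_genotypes(x, seed = seed)
  tibble::tibble(
    ari_before = genotype_clustering_ari(before, x$sites, sim$truth$clades),
    ari_after = genotype_clustering_ari(sm$calls, x$sites, sim$truth$clades),
    n_sites_kept = nrow(x$sites))
}

#' Two-group partition of a rooted tree at its root split
#'
#' @param tree Rooted `phylo`.
#' @return Named vector assigning each tip to `"g1"` or `"g2"` by the root's
#'   first-child subtree.
#' @export
tree_bipartition <- function(tree) {
  check_tree(tree)
  root <- ape::Ntip(tree) + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  first <- kids[1]
  in_first <- if (first <= ape::Ntip(tree)) {
    tree$tip.label[first]
  } else {
    ape::extract.clade(tree, first)$tip.label
  }
  out <- stats::setNames(rep("g2", ape::Ntip(tree)), tree$tip.label)
  out[in_first] <- "g1"
  out
}

#' Evaluate clade recovery of a simulated data set end-to-end
#'
#' Runs the analysis pipeline on simulated counts — smoothing, coarse
#' filtering, top-N selection, sequence encoding, neighbour-joining fallback
#' tree — and scores the result against the simulation truth with the
#' phylogenetic signal of the 0/1 clade label on the tree and the ARI
#' between the tree's root bipartition and the true clades.
#'
#' The fallback tree is a point estimate, not a Bayesian posterior summary,
#' so signal magnitudes are comparable only across runs of this harness,
#' not with values computed on externally inferred trees.
#'
#' @param counts Simulated [cell_counts].
#' @param truth Truth list from [simulate_dataset()].
#' @param params [filter_params()] used for coarse filtering / site cap.
#' @param theta,k,delta,n_samplings,seed Smoothing parameters.
#' @param flip_fraction Optional fraction of elements corrupted at the
#'   probability level before smoothing ([flip_probabilities()]; default 0).
#' @return A tibble row: `lambda`, `lambda_p`, `ari_tree`, `ari_calls`,
#'   `n_sites_used`, `n_cells`.
#' @export
evaluate_recovery <- function(counts, truth,
                              params = filter_params("lenient",
                                                     min_cell_reads = 0),
                              theta = 0.3, k = 10, delta = k / (k + 1),
                              n_samplings = 100, seed = 1L,
                              flip_fraction = 0) {
  x <- coarse_filter_sites(counts, call_unsmoothed(counts, theta), params)
  if (k >= length(x$cells)) k <- length(x$cells) - 1L
  pr <- genotype_probabilities(x, theta)
  if (flip_fraction > 0)
    pr <- flip_probabilities(pr, flip_fraction, seed = seed + 1L)
  sim <- pairwise_similarity(pr, n_samplings = n_samplings, seed = seed)
  nb <- build_knn(sim, k)
  smp <- smooth_probabilities(pr, nb, delta)
  top <- select_top_sites(x, params$max_sites)
  sel <- match(site_ids(top), site_ids(x))
  calls <- call_genotypes(smp)[sel, , drop = FALSE]
  aln <- encode_alignment(calls, top$sites)
  d <- suppressWarnings(hamming_distance_matrix(aln))
  d[is.na(d)] <- 1
  tree <- nj_tree(d)
  labels <- truth$clades[tree$tip.label]
  lam <- pagels_lambda(tree, factor(labels))
  bip <- tree_bipartition(tree)
  tibble::tibble(
    lambda = lam$lambda,
    lambda_p = lam$p_value,
    ari_tree = adjusted_rand_index(bip[names(labels)], labels),
    ari_calls = genotype_clustering_ari(calls, top$sites, truth$clades),
    n_sites_used = nrow(top$sites),
    n_cells = length(x$cells)
  )
}

#' Robustness sweeps over data-quality and algorithm parameters
#'
#' Reruns the simulate-smooth-filter-tree-score pipeline across a grid of a
#' single factor and tabulates the recovery metrics, mirroring the standard
#' robustness experiments: number of neighbours K, number of sites,
#' sparsity, fraction of corrupted genotypes, and subclone frequency.
#'
#' @param what One of `"k"`, `"n_sites"`, `"sparsity"`, `"flip"`,
#'   `"subclone"`.
#' @param grid Numeric vector of parameter values (defaults per sweep).
#' @param config Base [sim_config()]; one data set is simulated per
#'   configuration and shared across the grid where the sweep degrades data
#'   (sparsity, flip, subclone), or reused with different analysis settings
#'   (k, n_sites).
#' @param params [filter_params()] used in evaluation.
#' @param seed Integer RNG seed for the analysis stages.
#' @return A tibble: `sweep`, `value`, plus the [evaluate_recovery()]
#'   columns.
#' @export
run_robustness_sweep <- function(what = c("k", "n_sites", "sparsity", "flip",
                                          "subclone"),
                                 grid = NULL, config = sim_config(),
                                 params = filter_params("lenient",
                                                        min_cell_reads = 0),
                                 seed = 1L) {
  what <- match.arg(what)
  if (is.null(grid))
    grid <- switch(what,
                   k = c(2, 5, 10, 20),
                   n_sites = c(10, 50, 100, 250, 500),
                   sparsity = c(0.65, 0.75, 0.85, 0.90),
                   flip = c(0, 0.1, 0.2, 0.35, 0.5),
                   subclone = c(0.05, 0.1, 0.2, 0.35, 0.5))
  sim <- simulate_dataset(config)
  rows <- purrr::map(grid, function(v) {
    res <- switch(
      what,
      k = evaluate_recovery(sim$counts, sim$truth, params, k = v,
                            seed = seed),
      n_sites = {
        p <- params
        p$max_sites <- v
        evaluate_recovery(sim$counts, sim$truth, p, seed = seed)
      },
      sparsity = {
        cc <- if (v > sparsity(sim$counts))
          degrade_sparsity(sim$counts, v, seed = seed) else sim$counts
        evaluate_recovery(cc, sim$truth, params, seed = seed)
      },
      flip = evaluate_recovery(sim$counts, sim$truth, params,
                               flip_fraction = v, seed = seed),
      subclone = {
        pools <- split(names(sim$truth$clades), sim$truth$clades)
        major <- subset_counts(sim$counts, cells = pools[[1]])
        minor <- subset_counts(sim$counts, cells = pools[[2]])
        # constant mixture size feasible across the whole frequency grid
        total <- floor(length(pools[[1]]) / max(1 - grid))
        mix <- spike_subclone(major, minor, v, total, seed = seed)
        truth <- list(clades = mix$labels,
                      genotypes = sim$truth$genotypes[, mix$counts$cells],
                      tree = NULL)
        p <- params
        p$monomorphic_frac <- 0.95   # subclone setting: keep near-fixed sites
        evaluate_recovery(mix$counts, truth, p, seed = seed)
      })
    dplyr::bind_cols(tibble::tibble(sweep = what, value = v), res)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cellphylo_sweep", class(out))
  out
}
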