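# Small programmatic fixtures shared across test files.

make_sites <- function(n, chrom = "1", spacing = 100, start = 1000) {
  pos <- seq(start, by = spacing, length.out = n)
  tibble::tibble(chrom = chrom, pos = pos,
                 ref_allele = rep(c("A", "C", "G", "T"), length.out = n),
                 alt_allele = rep(c("G", "T", "A", "C"), length.out = n))
}

make_counts <- function(ref, alt, chrom = "1") {
  ref <- as.matrix(ref)
  alt <- as.matrix(alt)
  cells <- sprintf("c%02d", seq_len(ncol(ref)))
  cell_counts(make_sites(nrow(ref), chrom = chrom), cells, ref, alt)
}

# a probability object built directly from a sites x cells x 3 array
make_probs <- function(arr, theta = 0.3) {
  dimnames(arr) <- list(paste0("s", seq_len(dim(arr)[1])),
                        paste0("c", seq_len(dim(arr)[2])),
                        c("R", "H", "A"))
  structure(arr, class = "genotype_probs", theta = theta,
            sites = make_sites(dim(arr)[1]))
}

write_test_vcf <- function(path, rows) {
  header <- c("##fileformat=VCFv4.2",
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", sep = "\t"))
  writeLines(c(header, rows), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, id = ".") {
  paste(chrom, pos, id, ref, alt, ".", "PASS", ".", sep = "\t")
}
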