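# Shared small fixtures, built in code at test time.

# small single-chromosome cohort for fast unit tests
small_cohort <- function(n_pairs = 30, n_variants = 600, length_cM = 100,
                         error_rate = 0, seed = 1, keep_haplotypes = FALSE,
                         ...) {
  simulate_sib_pairs(
    n_pairs, uniform_map("1", 1e8, length_cM),
    mating_config(n_variants = n_variants, error_rate = error_rate,
                  seed = seed, ...),
    keep_haplotypes = keep_haplotypes)
}

# true type-1/type-2 boundaries of a cohort, as a truth table for matching
truth_12_boundaries <- function(cohort) {
  cx <- classify_crossovers(cohort)
  tr <- cx[cx$transition == "1-2", ]
  tr$mid_bp <- tr$pos
  tr
}

# drop truth boundaries within N variants of either chromosome end
interior_truth <- function(truth, cohort, N) {
  keep <- rep(TRUE, nrow(truth))
  for (ch in unique(truth$chrom)) {
    pv <- sort(cohort$variants$pos[cohort$variants$chrom == ch])
    lo <- pv[min(N + 1L, length(pv))]
    hi <- pv[max(length(pv) - N, 1L)]
    sel <- truth$chrom == ch
    keep[sel] <- truth$mid_bp[sel] >= lo & truth$mid_bp[sel] <= hi
  }
  truth[keep, , drop = FALSE]
}

# fraction of truth boundaries recovered by a catalog within tol_bp
boundary_recall <- function(catalog, truth, tol_bp) {
  if (!nrow(truth)) return(NA_real_)
  key_c <- paste(catalog$pair, catalog$chrom)
  key_t <- paste(truth$pair, truth$chrom)
  mean(vapply(seq_len(nrow(truth)), function(i) {
    j <- which(key_c == key_t[i])
    length(j) > 0 && any(abs(catalog$mid_bp[j] - truth$mid_bp[i]) <= tol_bp)
  }, TRUE))
}

# hand-written toy VCF (3 samples x 3 biallelic + 1 multi-allelic record)
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "v1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "v2", "C", "T", ".", "PASS", ".", "GT",
          "0/1", "./.", "0/0", sep = "\t"),
    paste("1", "300", "v3", "G", "A,C", ".", "PASS", ".", "GT",
          "0/1", "0/2", "0/0", sep = "\t"),
    paste("2", "150", "v4", "T", "C", ".", "PASS", ".", "GT",
          "1|1", "0|1", "0|0", sep = "\t")), path)
  path
}
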