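#' Break catalog
#'
#' A catalog of detected recombination breaks across a set of sibling pairs.
#' The sibling-pair detector sees the type-1/type-2 region boundaries, which
#' are half of all crossovers generated by the four meioses behind a pair, so
#' per-pair call counts convert to sex-averaged per-meiosis map lengths by a
#' factor of 2 (see [estimate_map_length()]).
#'
#' @param calls data.frame with at least `chrom` and `mid_bp` columns
#'   (`pair`, `Z`, `start`, `end` kept when present).
#' @param n_pairs Number of sibling pairs the catalog was built from (>= 1).
#' @return The calls data.frame with class `break_catalog` and attribute
#'   `n_pairs`.
#' @export
break_catalog <- function(calls, n_pairs) {
  stopifnot(is.data.frame(calls), n_pairs >= 1,
            all(c("chrom", "mid_bp") %in% names(calls)))
  structure(calls, n_pairs = as.integer(n_pairs),
            class = c("break_catalog", "data.frame"))
}

#' Per-chromosome genetic length from a break catalog
#'
#' With `B_c` detected boundaries on chromosome `c` over `n` pairs, the
#' sex-averaged per-meiosis length is estimated as
#' `cM = 100 * B_c / (2 n)`: each pair contributes 4 meioses of which the
#' detector sees half the breaks, so the divisor per pair is 2. The standard
#' error assumes a Poisson model for the counts:
#' `SE = 100 * sqrt(B_c) / (2 n)`.
#'
#' @param catalog A [break_catalog()].
#' @return data.frame: `chrom`, `n_breaks`, `cM`, `se`.
#' @export
estimate_map_length <- function(catalog) {
  stopifnot(inherits(catalog, "break_catalog"))
  n_pairs <- attr(catalog, "n_pairs")
  if (is.null(n_pairs) || n_pairs < 1) stop("catalog has no pairs")
  B <- table(catalog$chrom)
  data.frame(chrom = names(B),
             n_breaks = as.integer(B),
             cM = 100 * as.integer(B) / (2 * n_pairs),
             se = 100 * sqrt(as.integer(B)) / (2 * n_pairs),
             stringsAsFactors = FALSE)
}

#' Mean detected breaks per individual
#'
#' `B / (2 n_pairs)`: the per-individual rate used for whole-genome
#' comparisons between cohorts. With a complete catalog this converges to
#' the genome length in Morgans.
#'
#' @param catalog A [break_catalog()].
#' @return Single number (breaks per individual).
#' @export
breaks_per_individual <- function(catalog) {
  stopifnot(inherits(catalog, "break_catalog"))
  nrow(catalog) / (2 * attr(catalog, "n_pairs"))
}

#' Expected catalog size from cohort size and per-individual break rate
#'
#' @param n_pairs Number of sibling pairs.
#' @param per_individual Mean detected breaks per individual.
#' @return Expected total number of catalogued events
#'   (`n_pairs * 2 * per_individual`).
#' @export
catalog_size <- function(n_pairs, per_individual) {
  stopifnot(n_pairs >= 0, per_individual >= 0)
  n_pairs * 2 * per_individual
}

.make_bins <- function(len, bin_bp) {
  if (bin_bp <= 0) stop("bin size must be positive")
  edges <- seq(0, len, by = bin_bp)
  if (edges[length(edges)] < len) edges <- c(edges, len)
  edges
}

#' Binned break density histogram
#'
#' Raw break counts per physical bin, per chromosome.
#'
#' @param catalog A [break_catalog()].
#' @param bin_bp Bin size in bp (> 0).
#' @param chrom_lengths Named vector of chromosome bp lengths; required to
#'   produce (all-zero) rows for chromosomes without calls, otherwise
#'   inferred from the largest break position.
#' @return data.frame: `chrom`, `bin_start`, `bin_end` (0-based half-open),
#'   `count`.
#' @export
density_histogram <- function(catalog, bin_bp, chrom_lengths = NULL) {
  stopifnot(inherits(catalog, "break_catalog"))
  if (bin_bp <= 0) stop("bin size must be positive")
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths) else
    unique(catalog$chrom)
  out <- lapply(chroms, function(ch) {
    x <- catalog$mid_bp[catalog$chrom == ch]
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else
      if (length(x)) max(x) else bin_bp
    edges <- .make_bins(len, bin_bp)
    cnt <- if (length(x))
      tabulate(findInterval(x, edges, rightmost.closed = TRUE),
               nbins = length(edges) - 1L) else
      integer(length(edges) - 1L)
    data.frame(chrom = ch, bin_start = edges[-length(edges)],
               bin_end = edges[-1], count = cnt, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cumulative genetic map from a break catalog
#'
#' Running sum of binned break counts, scaled so that the curve ends at the
#' [estimate_map_length()] value for the chromosome (i.e. expressed in
#' sex-averaged per-meiosis cM).
#'
#' @inheritParams density_histogram
#' @return data.frame: `chrom`, `bp` (bin right edge, plus a leading 0 row),
#'   `cum_cM`.
#' @export
cumulative_map <- function(catalog, bin_bp, chrom_lengths = NULL) {
  h <- density_histogram(catalog, bin_bp, chrom_lengths)
  est <- estimate_map_length(catalog)
  out <- lapply(unique(h$chrom), function(ch) {
    hh <- h[h$chrom == ch, ]
    tot <- sum(hh$count)
    cM_end <- est$cM[match(ch, est$chrom)]
    if (is.na(cM_end)) cM_end <- 0
    scale <- if (tot > 0) cM_end / tot else 0
    data.frame(chrom = ch, bp = c(0, hh$bin_end),
               cum_cM = c(0, cumsum(hh$count) * scale),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare an estimated map against a reference map
#'
#' Per-chromosome length differences and ratios, plus (optionally) binned
#' cumulative-curve residuals after linear interpolation of both curves onto
#' a common bp grid.
#'
#' @param est Output of [estimate_map_length()].
#' @param ref Named list of reference [genetic_map()]s, or a named numeric
#'   vector of reference cM lengths.
#' @param cumulative Optional output of [cumulative_map()]; when supplied
#'   (and `ref` holds maps), residual curves are computed.
#' @return List with `lengths` (data.frame: chrom, est_cM, ref_cM, delta_cM,
#'   ratio) and `residuals` (data.frame: chrom, bp, est_cM, ref_cM, residual;
#'   NULL when `cumulative` is not given).
#' @export
compare_maps <- function(est, ref, cumulative = NULL) {
  ref_len <- if (is.numeric(ref)) ref else
    vapply(ref, map_length_cM, 0)
  shared <- intersect(est$chrom, names(ref_len))
  if (!length(shared)) stop("no shared chromosomes between estimate and reference")
  lengths_df <- data.frame(
    chrom = shared,
    est_cM = est$cM[match(shared, est$chrom)],
    ref_cM = unname(ref_len[shared]),
    stringsAsFactors = FALSE)
  lengths_df$delta_cM <- lengths_df$est_cM - lengths_df$ref_cM
  lengths_df$ratio <- lengths_df$est_cM / lengths_df$ref_cM
  resid <- NULL
  if (!is.null(cumulative) && !is.numeric(ref)) {
    resid <- do.call(rbind, lapply(intersect(shared, unique(cumulative$chrom)),
      function(ch) {
        cc <- cumulative[cumulative$chrom == ch, ]
        rf <- bp_to_cM(ref[[ch]], cc$bp)
        data.frame(chrom = ch, bp = cc$bp, est_cM = cc$cum_cM, ref_cM = rf,
                   residual = cc$cum_cM - rf, stringsAsFactors = FALSE)
      }))
  }
  list(lengths = lengths_df, residuals = resid)
}

#' z-statistic for an ancestry-group deviation in mean break count
#'
#' Tests a group's mean deviation from a null (reference-population) break
#' count distribution: `z = mean_deviation / (null_sd / sqrt(n))`.
#'
#' @param mean_deviation Observed deviation of the group mean from the null
#'   mean (breaks per individual).
#' @param null_sd Null per-individual standard deviation (> 0).
#' @param n Group size (>= 1).
#' @return z value.
#' @examples
#' ancestry_ztest(2.65, 4.8, 292)  # 9.43
#' @export
ancestry_ztest <- function(mean_deviation, null_sd, n) {
  stopifnot(null_sd > 0)
  if (n < 1) stop("n must be at least 1")
  mean_deviation / (null_sd / sqrt(n))
}
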