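#' Construct a genetic map
#'
#' A genetic map relates physical position (bp, 1-based) to cumulative genetic
#' distance (centiMorgans) along one chromosome. The cumulative curve must
#' start at 0 and be non-decreasing; between the tabulated points the map is
#' linearly interpolated in both directions.
#'
#' @param chrom Chromosome label (length-1 character).
#' @param pos Integer-ish vector of strictly increasing 1-based bp positions.
#' @param cum_cM Numeric vector of cumulative centiMorgans at `pos`;
#'   `cum_cM[1]` must be 0 and the vector non-decreasing.
#' @return An object of class `genetic_map`: a list with elements `chrom`,
#'   `pos`, `cum_cM`.
#' @examples
#' gm <- genetic_map("1", c(1, 5e6, 1e7), c(0, 10, 25))
#' map_length_cM(gm)
#' @export
genetic_map <- function(chrom, pos, cum_cM) {
  stopifnot(length(chrom) == 1L, length(pos) == length(cum_cM), length(pos) >= 2L)
  pos <- as.numeric(pos)
  cum_cM <- as.numeric(cum_cM)
  if (any(diff(pos) <= 0)) stop("map positions must be strictly increasing")
  if (any(diff(cum_cM) < 0)) stop("cumulative cM must be non-decreasing")
  if (cum_cM[1] != 0) stop("cumulative cM must start at 0")
  structure(list(chrom = as.character(chrom), pos = pos, cum_cM = cum_cM),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("<genetic_map> chr %s: %d anchor points, %.0f-%.0f bp, %.2f cM\n",
              x$chrom, length(x$pos), x$pos[1], x$pos[length(x$pos)],
              map_length_cM(x)))
  invisible(x)
}

#' Total genetic length of a map in centiMorgans
#' @param map A `genetic_map`.
#' @return Total length in cM (last cumulative value).
#' @export
map_length_cM <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  map$cum_cM[length(map$cum_cM)]
}

#' Interpolate genetic position (cM) at physical positions
#' @param map A `genetic_map`.
#' @param bp Physical positions (bp); clamped to the map's range.
#' @return Cumulative cM at each `bp`.
#' @export
bp_to_cM <- function(map, bp) {
  stopifnot(inherits(map, "genetic_map"))
  stats::approx(map$pos, map$cum_cM, xout = pmin(pmax(bp, map$pos[1]),
                map$pos[length(map$pos)]), ties = "ordered")$y
}

#' Interpolate physical position at genetic positions (inverse map)
#'
#' Inverse interpolation of the cumulative curve. Over zero-rate intervals
#' (flat cM) the inverse is not unique; the rightmost bp of the flat stretch
#' is returned, so values just above it interpolate from the correct edge.
#'
#' @param map A `genetic_map`.
#' @param cM Cumulative cM values in `[0, map_length_cM(map)]`.
#' @return bp positions.
#' @export
cM_to_bp <- function(map, cM) {
  stopifnot(inherits(map, "genetic_map"))
  if (any(cM < 0 | cM > map_length_cM(map) + 1e-9))
    stop("cM outside map range")
  u <- map$cum_cM
  p <- map$pos
  n <- length(u)
  idx <- findInterval(cM, u)           # rightmost anchor with u[idx] <= cM
  hi <- pmin(idx + 1L, n)
  du <- u[hi] - u[idx]
  frac <- ifelse(du > 0, (cM - u[idx]) / du, 0)
  p[idx] + frac * (p[hi] - p[idx])
}

#' Uniform-rate genetic map
#'
#' Convenience constructor for a constant-rate chromosome.
#'
#' @param chrom Chromosome label.
#' @param length_bp Physical length in bp.
#' @param length_cM Genetic length in cM.
#' @return A `genetic_map` with two anchor points.
#' @export
uniform_map <- function(chrom, length_bp, length_cM) {
  genetic_map(chrom, c(1, length_bp), c(0, length_cM))
}

#' Genetic map with a single rate hotspot
#'
#' Constant background rate with one interval at `fold` times that rate.
#' The total genetic length is fixed at `length_cM`; the background rate is
#' scaled so that background plus hotspot mass sum to the total.
#'
#' @param chrom Chromosome label.
#' @param length_bp Physical length in bp.
#' @param length_cM Total genetic length in cM.
#' @param hotspot_start,hotspot_end Hotspot bp interval (1-based, inclusive
#'   bounds used as map anchors).
#' @param fold Rate multiplier inside the hotspot (> 0).
#' @return A `genetic_map`.
#' @export
hotspot_map <- function(chrom, length_bp, length_cM, hotspot_start,
                        hotspot_end, fold = 10) {
  stopifnot(fold > 0, hotspot_start > 1, hotspot_end < length_bp,
            hotspot_start < hotspot_end)
  w <- hotspot_end - hotspot_start
  # background rate r solves r * (length_bp - w) + fold * r * w = length_cM
  r <- length_cM / ((length_bp - w) + fold * w)
  pos <- c(1, hotspot_start, hotspot_end, length_bp)
  cum <- c(0,
           r * (hotspot_start - 1),
           r * (hotspot_start - 1) + fold * r * w,
           length_cM)
  genetic_map(chrom, pos, cum)
}

#' Default autosomal genetic lengths (cM)
#'
#' Sex-averaged per-meiosis genetic lengths for the 22 human autosomes, as
#' estimated from a large sibling-pair biobank cohort; the genome total is
#' 3,338 cM. Used as the default whole-genome configuration of the simulator.
#'
#' @return Named numeric vector (names "1".."22"), in cM.
#' @export
default_autosome_cM <- function() {
  stats::setNames(
    c(261.4, 266.4, 212.4, 202.1, 194.5, 186.8, 174.9, 162.1, 157.4, 162.6,
      155.0, 159.7, 122.7, 114.1, 121.5, 121.3, 119.6, 109.9, 98.3, 98.7,
      75.4, 65.2),
    as.character(1:22))
}

#' Build a whole-genome list of uniform maps
#'
#' @param lengths_cM Named vector of per-chromosome genetic lengths (cM);
#'   defaults to [default_autosome_cM()].
#' @param bp_per_cM Physical bp per cM (uniform rate); default 1e6.
#' @return Named list of `genetic_map` objects.
#' @export
genome_maps <- function(lengths_cM = default_autosome_cM(), bp_per_cM = 1e6) {
  stopifnot(!is.null(names(lengths_cM)))
  out <- lapply(names(lengths_cM), function(ch) {
    uniform_map(ch, round(lengths_cM[[ch]] * bp_per_cM), lengths_cM[[ch]])
  })
  names(out) <- names(lengths_cM)
  out
}
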