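#' Sibling-pair break detector parameters
#'
#' The detector scans a chromosome comparing the genotype similarity of two
#' siblings in two flanking windows of `N` variants and calls a break where
#' the indicator
#' \deqn{Z = (N_+ - N_-) / (a + N - \max(N_+, N_-))}
#' peaks in magnitude. `Z > 0` means the right window is the more similar one
#' (entering an identical-by-descent region left to right). Defaults were
#' chosen by calibration on simulated cohorts against the parent-informed
#' oracle.
#'
#' @param N Flanking window size in variants (>= 10).
#' @param a Positive denominator offset, much smaller than `N`; keeps the
#'   denominator away from zero in fully identical windows.
#' @param theta Calling threshold on `|Z|`.
#' @param min_sep Minimum separation (in variants) between calls on one
#'   pair-chromosome; must be `>= N`.
#' @param min_overlap Minimum fraction of co-observed (non-missing in both
#'   sibs) loci per window; windows below this are skipped.
#' @param maf_min Variants with minor-allele frequency below this are
#'   excluded before scanning (clusters of rare variants mimic IBD).
#' @param tau Mismatch tolerance: windows with at most `tau` mismatches are
#'   treated as near-maximal similarity in diagnostics.
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(N = 50, a = 2, theta = 5, min_sep = N,
                            min_overlap = 0.8, maf_min = 0.05, tau = 2) {
  stopifnot(N >= 10, a > 0, a < N, theta > 0, min_sep >= N,
            min_overlap > 0, min_overlap <= 1, tau >= 0)
  structure(list(N = as.integer(N), a = a, theta = theta,
                 min_sep = as.integer(min_sep), min_overlap = min_overlap,
                 maf_min = maf_min, tau = tau),
            class = "detector_params")
}

#' Flanking-window genotype similarity at one position
#'
#' Counts the loci with identical dosage in the two siblings in the left
#' window `[i-N, i-1]` and the right window `[i, i+N-1]` (1-based variant
#' indices). Pairs with a missing dosage in either sibling are excluded from
#' the count, and the number of co-observed loci per window is reported.
#'
#' @param s1,s2 Dosage vectors (0/1/2, NA = missing) of the two siblings.
#' @param i Variant index; the candidate boundary lies between variants
#'   `i-1` and `i`. Must satisfy `N < i <= length(s1) - N + 1`.
#' @param N Window size.
#' @return List with `n_minus`, `n_plus` (identical-in-state counts) and
#'   `n_eff_minus`, `n_eff_plus` (co-observed loci per window).
#' @export
window_similarity <- function(s1, s2, i, N) {
  len <- length(s1)
  stopifnot(length(s2) == len)
  if (i - N < 1 || i + N - 1 > len)
    stop("window extends past chromosome end")
  left <- (i - N):(i - 1); right <- i:(i + N - 1)
  eq <- s1 == s2
  list(n_minus = sum(eq[left], na.rm = TRUE),
       n_plus = sum(eq[right], na.rm = TRUE),
       n_eff_minus = sum(!is.na(eq[left])),
       n_eff_plus = sum(!is.na(eq[right])))
}

#' Break indicator Z from window similarities
#'
#' \eqn{Z = (N_+ - N_-) / (a + N - \max(N_+, N_-))}. The numerator is large
#' when the two flanking windows differ strongly in similarity; the
#' denominator is small when at least one window is close to fully identical
#' (as in IBD-on-both-sides regions), sharpening peaks at their boundaries.
#' Antisymmetric under swapping the windows.
#'
#' @param n_minus,n_plus Identical-in-state counts for the left and right
#'   windows (vectorized).
#' @param N Window size.
#' @param a Positive denominator offset.
#' @return Z values.
#' @export
z_indicator <- function(n_minus, n_plus, N, a) {
  stopifnot(a > 0)
  (n_plus - n_minus) / (a + (N - pmax(n_plus, n_minus)))
}

#' Call recombination breaks on one sibling pair chromosome
#'
#' Scans all valid positions, computes `Z`, and calls local maxima of `|Z|`
#' at or above `theta`, applying greedy non-maximum suppression so calls are
#' separated by at least `min_sep` variants (ties broken toward the smaller
#' index). Windows with fewer than `min_overlap * N` co-observed loci are
#' skipped; counts in partially observed windows are rescaled to the full
#' window size. No calls are possible within `N` variants of either
#' chromosome end, so breaks there are undercounted by construction.
#'
#' @param s1,s2 Sibling dosage vectors (0/1/2, NA = missing).
#' @param positions 1-based bp positions of the variants.
#' @param params A [detector_params()].
#' @return data.frame of calls: `idx` (boundary between variants `idx-1` and
#'   `idx`), `start`/`end` (0-based half-open bp bracket of the marker gap),
#'   `mid_bp`, `Z`, `direction` (`"gain_identity"` if the right window is
#'   more similar, else `"loss_identity"`). Empty (with a warning) when the
#'   chromosome has fewer than `2N + 1` variants.
#' @export
call_breaks <- function(s1, s2, positions, params = detector_params()) {
  stopifnot(inherits(params, "detector_params"),
            length(s1) == length(s2), length(positions) == length(s1))
  N <- params$N
  len <- length(s1)
  empty <- data.frame(idx = integer(0), start = numeric(0), end = numeric(0),
                      mid_bp = numeric(0), Z = numeric(0),
                      direction = character(0))
  if (len < 2L * N + 1L) {
    warning("too few variants for window size N; no calls made")
    return(empty)
  }
  eq <- as.integer(s1 == s2)
  obs <- !is.na(eq)
  eq0 <- ifelse(obs, eq, 0L)
  cs_eq <- c(0L, cumsum(eq0))
  cs_obs <- c(0L, cumsum(as.integer(obs)))
  idx <- (N + 1L):(len - N + 1L)
  nm <- cs_eq[idx] - cs_eq[idx - N]
  np <- cs_eq[idx + N] - cs_eq[idx]
  em <- cs_obs[idx] - cs_obs[idx - N]
  ep <- cs_obs[idx + N] - cs_obs[idx]
  ok <- em >= params$min_overlap * N & ep >= params$min_overlap * N &
        em > 0 & ep > 0
  z <- rep(NA_real_, length(idx))
  z[ok] <- z_indicator(nm[ok] * N / em[ok], np[ok] * N / ep[ok], N, params$a)
  az <- abs(z)
  az[is.na(az)] <- -Inf
  k <- length(az)
  is_peak <- az >= params$theta &
    az >= c(-Inf, az[-k]) & az > c(az[-1], -Inf)
  # ">=" left / ">" right keeps the first index of a plateau
  cand <- which(is_peak)
  if (!length(cand)) return(empty)
  cand <- cand[order(-az[cand], cand)]
  kept <- integer(0)
  for (cc in cand) {
    if (!length(kept) || all(abs(kept - cc) >= params$min_sep))
      kept <- c(kept, cc)
  }
  kept <- sort(kept)
  bi <- idx[kept]
  data.frame(idx = bi,
             start = positions[bi - 1L], end = positions[bi] - 1L,
             mid_bp = (positions[bi - 1L] + positions[bi]) / 2,
             Z = z[kept],
             direction = ifelse(z[kept] > 0, "gain_identity",
                                "loss_identity"),
             stringsAsFactors = FALSE)
}

#' Run the break detector over a simulated cohort
#'
#' Applies the minor-allele-frequency filter, then calls breaks for every
#' pair on every chromosome.
#'
#' @param cohort A `sib_cohort`.
#' @param params A [detector_params()].
#' @param pairs Optional subset of pair indices.
#' @return A [break_catalog()]: data.frame of calls with `pair` and `chrom`
#'   columns plus the [call_breaks()] columns, and attribute `n_pairs`.
#' @export
detect_cohort <- function(cohort, params = detector_params(), pairs = NULL) {
  stopifnot(inherits(cohort, "sib_cohort"))
  if (is.null(pairs)) pairs <- cohort$pairs$pair
  freq <- colMeans(cohort$geno, na.rm = TRUE) / 2
  keep <- pmin(freq, 1 - freq) >= params$maf_min
  out <- vector("list", length(pairs) * length(cohort$maps))
  k <- 0L
  for (ch in names(cohort$maps)) {
    sel <- which(cohort$variants$chrom == ch & keep)
    pv <- cohort$variants$pos[sel]
    for (p in pairs) {
      calls <- call_breaks(cohort$geno[2L * p - 1L, sel],
                           cohort$geno[2L * p, sel], pv, params)
      if (nrow(calls)) {
        calls$pair <- p
        calls$chrom <- ch
        k <- k + 1L
        out[[k]] <- calls
      }
    }
  }
  calls <- if (k) do.call(rbind, out[seq_len(k)]) else
    data.frame(idx = integer(0), start = numeric(0), end = numeric(0),
               mid_bp = numeric(0), Z = numeric(0), direction = character(0),
               pair = integer(0), chrom = character(0))
  break_catalog(calls, n_pairs = length(pairs))
}

# match calls to true boundaries within tol_bp; returns recall/precision/F1
.match_stats <- function(calls, truth, tol_bp) {
  if (nrow(truth) == 0)
    return(c(recall = NA, precision = NA, f1 = NA))
  truth_key <- paste(truth$pair, truth$chrom)
  call_key <- paste(calls$pair, calls$chrom)
  hit_truth <- vapply(seq_len(nrow(truth)), function(i) {
    j <- which(call_key == truth_key[i])
    length(j) && any(abs(calls$mid_bp[j] - truth$mid_bp[i]) <= tol_bp)
  }, TRUE)
  hit_call <- if (nrow(calls)) vapply(seq_len(nrow(calls)), function(i) {
    j <- which(truth_key == call_key[i])
    length(j) && any(abs(truth$mid_bp[j] - calls$mid_bp[i]) <= tol_bp)
  }, TRUE) else logical(0)
  recall <- mean(hit_truth)
  precision <- if (length(hit_call)) mean(hit_call) else 0
  f1 <- if (recall + precision > 0)
    2 * recall * precision / (recall + precision) else 0
  c(recall = recall, precision = precision, f1 = f1)
}

#' Calibrate detector parameters against a break oracle
#'
#' Grid search over `(N, a, theta)` maximizing F1 for recovery of known
#' type-1/type-2 boundaries (e.g. from the parent-informed oracle of
#' [trio_informative_breaks()], or simulation truth). A call matches a truth
#' boundary when both lie on the same pair-chromosome within `tol_bp`.
#' Boundaries within `N` variants of a chromosome end are excluded from the
#' recall denominator (undetectable by construction).
#'
#' @param cohort A `sib_cohort` calibration cohort.
#' @param truth data.frame of true boundaries: `pair`, `chrom`, `mid_bp`.
#' @param grid data.frame with columns `N`, `a`, `theta` (one row per
#'   candidate).
#' @param tol_bp Matching tolerance in bp (default: `N` times the median
#'   marker spacing, per grid row).
#' @return List with `params` (best [detector_params()]), `table` (the grid
#'   with recall/precision/f1 columns).
#' @export
calibrate_detector <- function(cohort, truth, grid, tol_bp = NULL) {
  stopifnot(inherits(cohort, "sib_cohort"), nrow(grid) >= 1,
            all(c("N", "a", "theta") %in% names(grid)))
  spacing <- stats::median(diff(sort(cohort$variants$pos)))
  res <- matrix(NA_real_, nrow(grid), 3,
                dimnames = list(NULL, c("recall", "precision", "f1")))
  for (r in seq_len(nrow(grid))) {
    p <- detector_params(N = grid$N[r], a = grid$a[r], theta = grid$theta[r])
    cat_r <- detect_cohort(cohort, p)
    tol <- if (is.null(tol_bp)) grid$N[r] * spacing else tol_bp
    # drop truth boundaries within N variants of an end
    tr <- truth
    for (ch in unique(tr$chrom)) {
      pv <- sort(cohort$variants$pos[cohort$variants$chrom == ch])
      lo <- pv[min(grid$N[r] + 1L, length(pv))]
      hi <- pv[max(length(pv) - grid$N[r], 1L)]
      drop <- tr$chrom == ch & (tr$mid_bp < lo | tr$mid_bp > hi)
      tr <- tr[!drop, , drop = FALSE]
    }
    res[r, ] <- .match_stats(cat_r, tr, tol)
  }
  tab <- cbind(grid, res)
  best <- which.max(res[, "f1"])
  list(params = detector_params(N = grid$N[best], a = grid$a[best],
                                theta = grid$theta[best]),
       table = tab)
}
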