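#' Classify the joint inheritance state of a sibling pair
#'
#' At any point of the genome each sibling carries one paternal chromatid
#' (`"a"` or `"b"`) and one maternal chromatid. The joint state of a pair
#' falls into one of three region types: type 1 (identical by descent on both
#' parental sides), type 2 (IBD on exactly one side), type 3 (IBD on
#' neither).
#'
#' @param sib1,sib2 Length-2 character vectors `c(paternal, maternal)` with
#'   values `"a"`/`"b"`.
#' @return Integer region type 1, 2 or 3.
#' @examples
#' classify_pair_state(c("a", "a"), c("a", "a"))  # 1
#' classify_pair_state(c("a", "a"), c("a", "b"))  # 2
#' @export
classify_pair_state <- function(sib1, sib2) {
  stopifnot(length(sib1) == 2L, length(sib2) == 2L,
            all(c(sib1, sib2) %in% c("a", "b")))
  3L - sum(sib1 == sib2)
}

#' Enumerate all 16 joint inheritance patterns
#'
#' @return data.frame with columns `s1_pat`, `s1_mat`, `s2_pat`, `s2_mat`,
#'   `type`; one row per ordered pattern (16 rows: 4 of type 1, 8 of type 2,
#'   4 of type 3).
#' @export
enumerate_pair_states <- function() {
  g <- expand.grid(s1_pat = c("a", "b"), s1_mat = c("a", "b"),
                   s2_pat = c("a", "b"), s2_mat = c("a", "b"),
                   stringsAsFactors = FALSE)
  g$type <- vapply(seq_len(nrow(g)), function(i)
    classify_pair_state(c(g$s1_pat[i], g$s1_mat[i]),
                        c(g$s2_pat[i], g$s2_mat[i])), 0L)
  g
}

# vectorized region type from four chromatid-label vectors
.region_type_vec <- function(inh) {
  3L - ((inh$s1_pat == inh$s2_pat) + (inh$s1_mat == inh$s2_mat))
}

#' Segment a chromosome into ground-truth region types
#'
#' Given the four per-variant chromatid-label vectors of a sibling pair
#' (e.g. from [inheritance_vectors()]), tiles the chromosome into maximal
#' runs of constant region type and reports every type change as a boundary.
#' Boundary bp positions are reported as the midpoint of the bracketing
#' marker interval, with the full interval retained (0-based half-open).
#'
#' @param inh List with equal-length vectors `s1_pat`, `s1_mat`, `s2_pat`,
#'   `s2_mat` (values `"a"`/`"b"`).
#' @param positions 1-based bp positions of the variants.
#' @return List with `segments` (data.frame: start_idx/end_idx 0-based
#'   half-open variant range, start_bp/end_bp, type) and `boundaries`
#'   (data.frame: idx of first variant right of the boundary (1-based),
#'   start/end 0-based half-open bp bracket, mid_bp, from_type, to_type,
#'   transition label such as `"1-2"`, and `cause` naming the gamete(s)
#'   whose chromatid toggled). Type jumps with `|to - from| == 2` are
#'   flagged with `jump2 = TRUE` (they require coincident crossovers in two
#'   meioses within one marker interval).
#' @export
segment_truth <- function(inh, positions) {
  ln <- lengths(inh)
  if (length(unique(c(ln, length(positions)))) != 1L)
    stop("inheritance vectors and positions must have equal length")
  ty <- .region_type_vec(inh)
  r <- rle(ty)
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  segments <- data.frame(
    start_idx = starts - 1L, end_idx = ends,          # 0-based half-open
    start_bp = positions[starts] - 1L, end_bp = positions[ends],
    type = r$values)
  bidx <- ends[-length(ends)] + 1L                    # first variant of next run
  if (length(bidx)) {
    from <- ty[bidx - 1L]; to <- ty[bidx]
    cause <- vapply(bidx, function(i) {
      tog <- vapply(inh, function(v) v[i - 1L] != v[i], TRUE)
      paste(names(inh)[tog], collapse = ",")
    }, "")
    boundaries <- data.frame(
      idx = bidx,
      start = positions[bidx - 1L], end = positions[bidx] - 1L,
      mid_bp = (positions[bidx - 1L] + positions[bidx]) / 2,
      from_type = from, to_type = to,
      transition = paste(pmin(from, to), pmax(from, to), sep = "-"),
      jump2 = abs(to - from) == 2L,
      cause = cause, stringsAsFactors = FALSE)
  } else {
    boundaries <- data.frame(idx = integer(0), start = numeric(0),
                             end = numeric(0), mid_bp = numeric(0),
                             from_type = integer(0), to_type = integer(0),
                             transition = character(0), jump2 = logical(0),
                             cause = character(0))
  }
  list(segments = segments, boundaries = boundaries)
}

#' Continuous ground-truth region segments for one pair
#'
#' Computes the exact region-type tiling of a chromosome in continuous bp
#' space directly from the recorded crossover sets (no marker
#' discretisation).
#'
#' @param cohort A `sib_cohort`.
#' @param pair Pair index.
#' @param chrom Chromosome label.
#' @return data.frame: `start`, `end` (0-based half-open bp over the full
#'   chromosome), `type`.
#' @export
true_region_segments <- function(cohort, pair,
                                 chrom = names(cohort$maps)[1]) {
  stopifnot(inherits(cohort, "sib_cohort"))
  x <- cohort$xo[[chrom]]
  len <- cohort$maps[[chrom]]$pos[length(cohort$maps[[chrom]]$pos)]
  g0 <- (pair - 1L) * 4L
  brks <- lapply(1:4, function(m) .gamete_breaks(cohort, chrom, g0 + m))
  cuts <- sort(unique(unlist(brks)))
  edges <- c(0, cuts, len)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  lab <- function(m) (findInterval(mids, brks[[m]]) + x$start[g0 + m]) %% 2L
  ty <- 3L - ((lab(1) == lab(3)) + (lab(2) == lab(4)))
  r <- rle(ty)
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  data.frame(start = edges[starts], end = edges[ends + 1L], type = r$values)
}

#' Classify every true crossover by the region transition it causes
#'
#' For each recorded crossover, evaluates the pair region type immediately
#' left and right of the break in continuous bp space. Every crossover
#' toggles exactly one side's IBD state, so each is a boundary with a type
#' change of 1; the transition is `"1-2"`, `"2-3"` or (never, in continuous
#' space) `"1-3"`.
#'
#' @param cohort A `sib_cohort`.
#' @return [true_crossovers()] output with added `from_type`, `to_type`,
#'   `transition` columns.
#' @export
classify_crossovers <- function(cohort) {
  stopifnot(inherits(cohort, "sib_cohort"))
  xs <- true_crossovers(cohort)
  if (nrow(xs) == 0) {
    xs$from_type <- xs$to_type <- integer(0); xs$transition <- character(0)
    return(xs)
  }
  from <- to <- integer(nrow(xs))
  for (ch in unique(xs$chrom)) {
    x <- cohort$xo[[ch]]
    sel <- which(xs$chrom == ch)
    for (i in sel) {
      g0 <- (xs$pair[i] - 1L) * 4L
      p <- xs$pos[i]
      lab <- function(m, at) {
        brk <- .gamete_breaks(cohort, ch, g0 + m)
        (sum(brk < at) + x$start[g0 + m]) %% 2L
      }
      eps <- 1e-6
      tfun <- function(at)
        3L - ((lab(1, at) == lab(3, at)) + (lab(2, at) == lab(4, at)))
      from[i] <- tfun(p - eps)
      to[i] <- tfun(p + eps)
    }
  }
  xs$from_type <- from
  xs$to_type <- to
  xs$transition <- paste(pmin(from, to), pmax(from, to), sep = "-")
  xs
}

#' Per-pair genome fractions of the three region types
#'
#' @param cohort A `sib_cohort`.
#' @return data.frame: pair, frac1, frac2, frac3 (bp fractions over the
#'   whole simulated genome; they sum to 1).
#' @export
region_fractions <- function(cohort) {
  stopifnot(inherits(cohort, "sib_cohort"))
  n_pairs <- nrow(cohort$pairs)
  tot <- sum(vapply(cohort$maps, function(m) m$pos[length(m$pos)], 0))
  out <- matrix(0, n_pairs, 3)
  for (ch in names(cohort$maps)) {
    for (p in seq_len(n_pairs)) {
      seg <- true_region_segments(cohort, p, ch)
      w <- tapply(seg$end - seg$start, factor(seg$type, levels = 1:3), sum)
      w[is.na(w)] <- 0
      out[p, ] <- out[p, ] + w
    }
  }
  data.frame(pair = seq_len(n_pairs), frac1 = out[, 1] / tot,
             frac2 = out[, 2] / tot, frac3 = out[, 3] / tot)
}

#' Parent-informed (quartet) recombination break oracle
#'
#' At sites where the father is heterozygous and the mother homozygous, the
#' paternal allele transmitted to each child is directly observable
#' (`sib dosage - mother's homozygous allele`), and agreement between the two
#' siblings' transmitted alleles indicates whether they inherited the same
#' paternal chromatid. The agreement indicator is piecewise constant along
#' the chromosome and toggles exactly at the union of the two siblings'
#' paternal crossovers; toggle locations are reported as break intervals
#' (symmetrically for mother-informative sites). Under genotyping error the
#' agreement sequence is smoothed by a running majority vote.
#'
#' @param father,mother,sib1,sib2 Dosage vectors (0/1/2, NA allowed) on one
#'   chromosome.
#' @param positions 1-based bp positions.
#' @param smooth_window Odd majority-vote window size (default 5); 1 means
#'   no smoothing.
#' @return List with `father` and `mother` break-interval data.frames
#'   (`start`, `end` 0-based half-open bp between flanking informative sites,
#'   `mid_bp`, `support` = run lengths on both sides), `n_informative`
#'   (per parent), and `n_skipped` (Mendelian-inconsistent sites).
#' @export
trio_informative_breaks <- function(father, mother, sib1, sib2, positions,
                                    smooth_window = 5) {
  n <- length(positions)
  stopifnot(length(father) == n, length(mother) == n,
            length(sib1) == n, length(sib2) == n,
            smooth_window >= 1, smooth_window %% 2 == 1)
  n_skipped <- 0L

  one_side <- function(het, hom, lab) {
    info <- which(!is.na(het) & !is.na(hom) & het == 1L & hom %in% c(0L, 2L))
    res <- list(breaks = data.frame(start = numeric(0), end = numeric(0),
                                    mid_bp = numeric(0), support = integer(0)),
                n_informative = length(info))
    if (length(info) < 2L) return(res)
    t1 <- sib1[info] - hom[info] / 2L
    t2 <- sib2[info] - hom[info] / 2L
    ok <- !is.na(t1) & !is.na(t2) & t1 %in% c(0, 1) & t2 %in% c(0, 1)
    n_skipped <<- n_skipped + sum(!ok)
    info <- info[ok]
    if (length(info) < 2L) return(res)
    agree <- as.integer(t1[ok] == t2[ok])
    if (smooth_window > 1 && length(agree) >= smooth_window) {
      k <- smooth_window
      sm <- as.integer(stats::filter(agree, rep(1, k), sides = 2) > k / 2)
      half <- (k - 1L) / 2L
      sm[seq_len(half)] <- sm[half + 1L]
      sm[(length(sm) - half + 1L):length(sm)] <- sm[length(sm) - half]
      agree <- sm
    }
    r <- rle(agree)
    if (length(r$values) < 2L) return(res)
    ends <- cumsum(r$lengths)
    left <- info[ends[-length(ends)]]
    right <- info[ends[-length(ends)] + 1L]
    res$breaks <- data.frame(
      start = positions[left], end = positions[right] - 1L,
      mid_bp = (positions[left] + positions[right]) / 2,
      support = pmin(r$lengths[-length(r$lengths)], r$lengths[-1]))
    res$n_informative <- length(info)
    res
  }

  fa <- one_side(father, mother, "father")
  mo <- one_side(mother, father, "mother")
  list(father = fa$breaks, mother = mo$breaks,
       n_informative = c(father = fa$n_informative,
                         mother = mo$n_informative),
       n_skipped = n_skipped)
}
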