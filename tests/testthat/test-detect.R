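test_that("window similarity counts identical-in-state loci", {
  s <- rep(c(0L, 1L, 2L), length.out = 40)
  ws <- window_similarity(s, s, 11, 10)
  expect_equal(ws$n_minus, 10)
  expect_equal(ws$n_plus, 10)

  # complement (0 <-> 2) in the right window only
  s2 <- s
  s2[11:20] <- 2L - s2[11:20]
  s2[s2 == 1L & seq_along(s2) %in% 11:20] <- 0L  # break het matches too
  s2[11:20] <- ifelse(s[11:20] == 1L, 0L, 2L - s[11:20])
  ws2 <- window_similarity(s, s2, 11, 10)
  expect_equal(ws2$n_minus, 10)
  expect_equal(ws2$n_plus, 0)
  expect_error(window_similarity(s, s, 5, 10), "past chromosome end")

  # missing dosages shrink the effective window
  s3 <- s
  s3[c(2, 4)] <- NA
  ws3 <- window_similarity(s3, s, 11, 10)
  expect_equal(ws3$n_eff_minus, 8)
  expect_equal(ws3$n_minus, 8)
})

test_that("random-genotype window similarity matches the closed form", {
  # independent HWE genotypes, MAF 0.3: match probability = sum_g P(g)^2
  p <- 0.3
  pg <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  match_prob <- sum(pg^2)
  set.seed(31)
  N <- 50
  frac <- replicate(1000, {
    a <- sample(0:2, N, replace = TRUE, prob = pg)
    b <- sample(0:2, N, replace = TRUE, prob = pg)
    mean(a == b)
  })
  expect_lt(abs(mean(frac) - match_prob), 0.02)
  # and window_similarity agrees with direct counting on one draw
  a <- sample(0:2, 2 * N, replace = TRUE, prob = pg)
  b <- sample(0:2, 2 * N, replace = TRUE, prob = pg)
  ws <- window_similarity(a, b, N + 1, N)
  expect_equal(ws$n_minus, sum(a[1:N] == b[1:N]))
  expect_equal(ws$n_plus, sum(a[(N + 1):(2 * N)] == b[(N + 1):(2 * N)]))
})

test_that("Z indicator evaluates its closed form and is antisymmetric", {
  expect_equal(z_indicator(30, 30, 50, 2), 0)
  expect_equal(z_indicator(30, 50, 50, 2), 10)
  expect_equal(z_indicator(50, 30, 50, 2), -10)
  # antisymmetry under window swap, over a grid
  for (nm in c(0, 10, 35, 50)) for (np in c(0, 20, 50))
    expect_equal(z_indicator(nm, np, 50, 2), -z_indicator(np, nm, 50, 2))
  # denominator bounded below by a
  expect_equal(z_indicator(0, 50, 50, 0.5), 100)
})

test_that("identical siblings yield no break calls", {
  set.seed(41)
  s <- sample(0:2, 500, replace = TRUE, prob = c(0.49, 0.42, 0.09))
  pos <- sort(sample(1e8, 500))
  calls <- call_breaks(s, s, pos, detector_params())
  expect_equal(nrow(calls), 0)
  expect_warning(call_breaks(s[1:60], s[1:60], pos[1:60], detector_params()),
                 "too few variants")
})

test_that("a single true boundary is called and bracketed", {
  for (seed in 1:20) {
    co <- small_cohort(n_pairs = 1, n_variants = 3000, seed = seed,
                       length_cM = 100)
    tr <- truth_12_boundaries(co)
    tr <- interior_truth(tr, co, 50)
    catg <- detect_cohort(co, detector_params())
    pv <- co$variants$pos
    tol <- 50 * median(diff(pv))
    for (i in seq_len(nrow(tr))) {
      near <- abs(catg$mid_bp - tr$mid_bp[i]) <= tol
      # each interior truth boundary with no close companion must be matched
      # (isolation radius is generous: suppression acts in variant index,
      # where skewed marker gaps make bp distance an imperfect proxy)
      others <- classify_crossovers(co)
      if (sum(abs(others$pos - tr$mid_bp[i]) <= 3 * tol) == 1)
        expect_true(any(near),
                    info = sprintf("seed %d boundary at %.0f", seed,
                                   tr$mid_bp[i]))
    }
    # calls that exist must contain their boundary in the marker bracket
    expect_true(all(catg$start < catg$end + 2))
  }
})

test_that("call rate is half the crossover rate with high interior recall", {
  co <- small_cohort(n_pairs = 500, n_variants = 10000, seed = 3,
                     error_rate = 0.001)
  cx <- classify_crossovers(co)
  catg <- detect_cohort(co, detector_params())
  expect_lt(abs(nrow(catg) / nrow(cx) - 0.5), 0.03)
  tr <- interior_truth(truth_12_boundaries(co), co, 50)
  tol <- 50 * median(diff(sort(co$variants$pos)))
  expect_gte(boundary_recall(catg, tr, tol), 0.95)
})

test_that("the detector stays quiet inside long uniform-type regions", {
  # siblings sharing both parental sides everywhere: type-1 interior
  co <- small_cohort(n_pairs = 20, n_variants = 5000, seed = 8,
                     length_cM = 250, error_rate = 0.001)
  catg <- detect_cohort(co, detector_params())
  tr <- truth_12_boundaries(co)
  tol <- 50 * median(diff(sort(co$variants$pos)))
  key_t <- paste(tr$pair, tr$chrom)
  false_pos <- vapply(seq_len(nrow(catg)), function(i) {
    j <- which(key_t == paste(catg$pair[i], catg$chrom[i]))
    !length(j) || all(abs(tr$mid_bp[j] - catg$mid_bp[i]) > tol)
  }, TRUE)
  # fewer than 0.1 false calls per pair-chromosome
  expect_lt(sum(false_pos) / 20, 0.1)
})

test_that("direction encodes which side is the identical one", {
  co <- small_cohort(n_pairs = 50, n_variants = 4000, seed = 9)
  catg <- detect_cohort(co, detector_params())
  cx <- classify_crossovers(co)
  tol <- 50 * median(diff(sort(co$variants$pos)))
  checked <- 0L
  for (i in seq_len(nrow(catg))) {
    j <- which(cx$pair == catg$pair[i] &
                 abs(cx$pos - catg$mid_bp[i]) <= tol &
                 cx$transition == "1-2")
    if (length(j) == 1) {
      # entering type 1 left-to-right means the right window is more similar
      expected <- if (cx$to_type[j] == 1) "gain_identity" else "loss_identity"
      expect_equal(catg$direction[i], expected)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 50)
})

test_that("calls respect the minimum separation", {
  co <- small_cohort(n_pairs = 100, n_variants = 2000, seed = 10,
                     length_cM = 250)
  catg <- detect_cohort(co, detector_params())
  for (p in unique(catg$pair)) {
    idx <- sort(catg$idx[catg$pair == p])
    if (length(idx) > 1) expect_true(all(diff(idx) >= 50))
  }
})

test_that("calibration selects well-performing parameters", {
  co <- small_cohort(n_pairs = 200, n_variants = 2500, seed = 15,
                     error_rate = 0.001)
  tr <- truth_12_boundaries(co)
  grid <- expand.grid(N = c(25, 50, 100), a = c(1, 2, 5), theta = c(2, 5, 10))
  cal <- calibrate_detector(co, tr, grid)
  expect_equal(nrow(cal$table), 27)
  expect_gte(max(cal$table$f1, na.rm = TRUE), 0.95)
  best <- cal$table[which.max(cal$table$f1), ]
  expect_equal(cal$params$N, as.integer(best$N))

  # degenerate one-point grid returns that point
  one <- calibrate_detector(co, tr, data.frame(N = 50, a = 2, theta = 5))
  expect_equal(one$params$N, 50L)
  expect_equal(one$params$a, 2)
})

test_that("larger windows buy robustness to genotyping error", {
  # at a high error rate, a wide window retains more F1 than a minimal one
  f1_of <- function(N, co, tr) {
    cal <- calibrate_detector(co, tr, data.frame(N = N, a = 2, theta = 5))
    cal$table$f1
  }
  diffs <- vapply(1:3, function(seed) {
    co <- small_cohort(n_pairs = 60, n_variants = 2500, seed = seed,
                       error_rate = 0.02)
    tr <- truth_12_boundaries(co)
    f1_of(100, co, tr) - f1_of(12, co, tr)
  }, 0)
  expect_true(all(diffs > 0))
})

test_that("brute-force changepoint search agrees on small chromosomes", {
  # exhaustive |Z| evaluation (direct window counting at every index)
  # versus the cumulative-sum scan
  for (seed in 1:5) {
    co <- small_cohort(n_pairs = 1, n_variants = 400, seed = seed + 50,
                       length_cM = 60)
    s1 <- co$geno[1, ]; s2 <- co$geno[2, ]
    pv <- co$variants$pos
    params <- detector_params(N = 30, min_sep = 30)
    calls <- call_breaks(s1, s2, pv, params)
    z_bf <- vapply(31:371, function(i) {
      ws <- window_similarity(s1, s2, i, 30)
      z_indicator(ws$n_minus, ws$n_plus, 30, 2)
    }, 0)
    # every call must be a local max of the brute-force |Z| above theta
    for (k in seq_len(nrow(calls))) {
      j <- calls$idx[k] - 30
      expect_gte(abs(z_bf[j]), params$theta)
      expect_equal(abs(z_bf[j]), max(abs(z_bf[max(1, j - 5):min(341, j + 5)])))
    }
    # and every sufficiently isolated brute-force peak must be called
    above <- which(abs(z_bf) >= params$theta)
    if (length(above) && nrow(calls))
      expect_true(all(vapply(above, function(j)
        min(abs(calls$idx - (j + 30))) <= 30, TRUE)))
  }
})
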