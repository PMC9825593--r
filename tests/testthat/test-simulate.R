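test_that("zero-length maps never produce crossovers", {
  gm <- genetic_map("1", c(1, 1e6), c(0, 0))
  set.seed(1)
  for (i in 1:20) expect_length(sample_crossovers(gm)$pos, 0)
})

test_that("poisson crossover counts match the Poisson(L) law", {
  gm <- uniform_map("1", 1e8, 100)  # 1 Morgan
  set.seed(42)
  counts <- replicate(10000, length(sample_crossovers(gm)$pos))
  expect_equal(mean(counts), 1.00, tolerance = 0.03)
  # Poisson limit: variance approximately equals the mean
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.06)
})

test_that("crossovers land in proportion to cM mass (hotspot)", {
  # hotspot covering 1% of bp but ~50% of cM
  len_bp <- 1e8
  hs <- c(4e7, 4e7 + 0.01 * len_bp)
  # fold = 99 puts 99*0.01/(0.99 + 99*0.01) = 50% of the cM mass in 1% of bp
  hm <- hotspot_map("1", len_bp, 100, hs[1], hs[2], fold = 99)
  mass <- (bp_to_cM(hm, hs[2]) - bp_to_cM(hm, hs[1])) / 100
  expect_equal(mass, 0.5, tolerance = 0.01)
  set.seed(7)
  pos <- unlist(replicate(10000, sample_crossovers(hm)$pos))
  in_hot <- mean(pos >= hs[1] & pos <= hs[2])
  expect_gte(in_hot, 0.45)
})

test_that("gamma renewal with nu = 1 matches poisson statistics", {
  gm <- uniform_map("1", 1e8, 200)
  set.seed(5)
  k_g <- replicate(3000, length(
    sample_crossovers(gm, interference_params("gamma_renewal", nu = 1))$pos))
  expect_equal(mean(k_g), 2, tolerance = 0.1)
  expect_equal(var(k_g) / mean(k_g), 1, tolerance = 0.1)
})

test_that("interference (nu > 1) suppresses close double crossovers", {
  gm <- uniform_map("1", 1e8, 300)
  set.seed(9)
  gap_frac <- function(nu) {
    gaps <- unlist(replicate(4000, {
      p <- sample_crossovers(gm, interference_params("gamma_renewal", nu))$pos
      if (length(p) >= 2) diff(p) / 1e6  # cM units (1 Mb = 1 cM here)
    }))
    mean(gaps < 20)  # fraction of gaps closer than 20 cM
  }
  expect_lt(gap_frac(8), gap_frac(1))
  expect_error(interference_params("gamma_renewal", nu = 0.5), "nu")
})

test_that("make_gamete follows the transmitted chromatid", {
  pos <- seq(1e6, 1e8, length.out = 50)
  hap_a <- rep(0L, 50); hap_b <- rep(1L, 50)
  no_xo <- structure(list(pos = numeric(0), start_chromatid = "a", chrom = "1"),
                     class = "crossover_set")
  g <- make_gamete(hap_a, hap_b, pos, no_xo)
  expect_equal(g$alleles, hap_a)
  expect_true(all(g$chromatid == "a"))

  mid <- structure(list(pos = 5e7, start_chromatid = "a", chrom = "1"),
                   class = "crossover_set")
  g1 <- make_gamete(hap_a, hap_b, pos, mid)
  expect_equal(g1$alleles, as.integer(pos > 5e7))

  # two breaks: a | b | a, checked against independent per-variant lookup
  two <- structure(list(pos = c(3e7, 7e7), start_chromatid = "a", chrom = "1"),
                   class = "crossover_set")
  set.seed(2)
  ha <- rbinom(50, 1, 0.5); hb <- rbinom(50, 1, 0.5)
  g2 <- make_gamete(ha, hb, pos, two)
  oracle <- vapply(seq_along(pos), function(i) {
    n_before <- sum(two$pos < pos[i])  # brute-force re-evaluation
    if (n_before %% 2 == 0) ha[i] else hb[i]
  }, 0)
  expect_equal(g2$alleles, oracle)
  expect_equal(g2$chromatid,
               ifelse(vapply(pos, function(p) sum(two$pos < p), 0) %% 2 == 0,
                      "a", "b"))
})

test_that("cohorts are reproducible given config and seed", {
  co1 <- small_cohort(n_pairs = 10, n_variants = 200, seed = 33,
                      error_rate = 0.01)
  co2 <- small_cohort(n_pairs = 10, n_variants = 200, seed = 33,
                      error_rate = 0.01)
  expect_identical(co1$geno, co2$geno)
  expect_identical(co1$xo, co2$xo)
  expect_identical(co1$phenotypes, co2$phenotypes)
})

test_that("every offspring allele traces to a parental chromatid at eps = 0", {
  co <- small_cohort(n_pairs = 8, n_variants = 300, seed = 4,
                     keep_haplotypes = TRUE)
  H <- co$haplotypes
  pv <- co$variants$pos
  for (p in seq_len(8)) {
    iv <- inheritance_vectors(co, p)
    pick <- function(hap1, hap2, lab) ifelse(lab == "a", hap1, hap2)
    s1 <- pick(H$F1[[1]][p, ], H$F2[[1]][p, ], iv$s1_pat) +
          pick(H$M1[[1]][p, ], H$M2[[1]][p, ], iv$s1_mat)
    s2 <- pick(H$F1[[1]][p, ], H$F2[[1]][p, ], iv$s2_pat) +
          pick(H$M1[[1]][p, ], H$M2[[1]][p, ], iv$s2_mat)
    expect_equal(unname(co$geno[2 * p - 1, ]), s1)
    expect_equal(unname(co$geno[2 * p, ]), s2)
  }
})

test_that("identical crossovers and parents force identical siblings", {
  # force sib2's gametes to equal sib1's by overwriting the truth record,
  # then rebuild sib2's genotypes from the shared inheritance
  co <- small_cohort(n_pairs = 4, n_variants = 200, seed = 6,
                     keep_haplotypes = TRUE)
  x <- co$xo[[1]]
  for (p in 1:4) {
    g0 <- (p - 1) * 4
    for (m in 1:2) {
      src <- g0 + m; dst <- g0 + m + 2
      x$start[dst] <- x$start[src]
      # equalize break sets by emptying both (no crossovers at all)
      x$counts[c(src, dst)] <- 0L
    }
  }
  x$offsets <- c(0L, cumsum(x$counts))
  x$pos <- numeric(0)
  co$xo[[1]] <- x
  H <- co$haplotypes
  for (p in 1:4) {
    iv <- inheritance_vectors(co, p)
    expect_identical(iv$s1_pat, iv$s2_pat)
    expect_identical(iv$s1_mat, iv$s2_mat)
    pick <- function(h1, h2, lab) ifelse(lab == "a", h1, h2)
    s1 <- pick(H$F1[[1]][p, ], H$F2[[1]][p, ], iv$s1_pat) +
          pick(H$M1[[1]][p, ], H$M2[[1]][p, ], iv$s1_mat)
    s2 <- pick(H$F1[[1]][p, ], H$F2[[1]][p, ], iv$s2_pat) +
          pick(H$M1[[1]][p, ], H$M2[[1]][p, ], iv$s2_mat)
    expect_identical(s1, s2)
  }
})

test_that("random mating leaves parental scores uncorrelated", {
  co <- small_cohort(n_pairs = 5000, n_variants = 100, seed = 12,
                     assort_m = 0)
  expect_equal(co$assort_achieved, 0, tolerance = 0.03)
})

test_that("assortative pairing calibrates to the target m", {
  co <- small_cohort(n_pairs = 5000, n_variants = 100, seed = 13,
                     assort_m = 0.3)
  expect_lt(abs(co$assort_achieved - 0.3), 0.01)
  co_neg <- small_cohort(n_pairs = 5000, n_variants = 100, seed = 14,
                         assort_m = -0.2)
  expect_lt(abs(co_neg$assort_achieved + 0.2), 0.01)
})

test_that("genotyping error flips roughly the configured fraction", {
  co0 <- small_cohort(n_pairs = 40, n_variants = 500, seed = 21)
  co1 <- small_cohort(n_pairs = 40, n_variants = 500, seed = 21,
                      error_rate = 0.02)
  # same seed: identical meioses, so differences are exactly the error sites
  flipped <- mean(co0$geno != co1$geno)
  expect_lt(abs(flipped - 0.02), 0.004)
  expect_true(all(co1$geno %in% 0:2))
})

test_that("phenotype output requires positive heritability", {
  gm <- uniform_map("1", 1e7, 10)
  cfg <- mating_config(n_variants = 50, h2 = 0, seed = 1)
  expect_error(simulate_sib_pairs(5, gm, cfg), "h2")
  co <- simulate_sib_pairs(5, gm, cfg, phenotypes = FALSE)
  expect_null(co$phenotypes)
})
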