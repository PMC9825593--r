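#' Crossover interference model parameters
#'
#' Crossovers along a chromosome are modelled as a point process on the
#' genetic-distance (cM) scale. The default is a Poisson process of unit rate
#' per Morgan (no interference). Optionally a stationary gamma-renewal process
#' with shape `nu >= 1` and unit mean rate per Morgan can be used; larger `nu`
#' makes nearby double crossovers rarer (positive interference). `nu = 1`
#' reduces exactly to the Poisson model.
#'
#' @param model `"poisson"` or `"gamma_renewal"`.
#' @param nu Gamma shape parameter, `>= 1`. Ignored for `"poisson"`.
#' @return An object of class `interference_params`.
#' @export
interference_params <- function(model = c("poisson", "gamma_renewal"), nu = 1) {
  model <- match.arg(model)
  if (!is.numeric(nu) || length(nu) != 1L || nu < 1)
    stop("interference shape nu must be a single number >= 1")
  structure(list(model = model, nu = nu), class = "interference_params")
}

#' Sample crossover positions for one meiosis
#'
#' Draws the number and bp positions of crossovers for a single gamete.
#' Under the Poisson model the break count is Poisson with mean equal to the
#' map length in Morgans and positions are uniform on the cumulative-cM scale,
#' mapped back to bp by inverse interpolation of the genetic map (so breaks
#' concentrate in high-rate regions). Under the gamma-renewal model,
#' inter-crossover gaps on the Morgan scale follow a stationary gamma renewal
#' process with shape `nu` and unit mean rate (simulated with a burn-in to
#' reach stationarity).
#'
#' @param map A [genetic_map()].
#' @param interference An [interference_params()].
#' @param start_chromatid `"a"` or `"b"`; which chromatid the gamete starts
#'   on at the left end of the chromosome. Sampled uniformly if `NULL`.
#' @return An object of class `crossover_set`: list with `pos` (sorted bp
#'   positions), `start_chromatid`, and `chrom`.
#' @export
sample_crossovers <- function(map, interference = interference_params(),
                              start_chromatid = NULL) {
  if (!inherits(map, "genetic_map")) stop("`map` must be a genetic_map")
  if (!inherits(interference, "interference_params"))
    stop("`interference` must be interference_params()")
  L <- map_length_cM(map) / 100  # Morgans
  cM_breaks <-
    if (interference$model == "poisson" || L == 0) {
      sort(stats::runif(stats::rpois(1, L), 0, L * 100))
    } else {
      .gamma_renewal_points(L, interference$nu) * 100
    }
  if (is.null(start_chromatid))
    start_chromatid <- sample(c("a", "b"), 1L)
  stopifnot(start_chromatid %in% c("a", "b"))
  structure(list(pos = if (length(cM_breaks)) cM_to_bp(map, cM_breaks)
                 else numeric(0),
                 start_chromatid = start_chromatid,
                 chrom = map$chrom),
            class = "crossover_set")
}

# Stationary gamma renewal on [0, L] Morgans, shape nu, unit mean rate.
# Started 25 Morgans before the origin so the process is stationary at 0.
.gamma_renewal_points <- function(L, nu) {
  burn <- 25
  pts <- numeric(0)
  t <- -burn
  repeat {
    n_chunk <- max(16L, ceiling((L + burn) * 2))
    gaps <- stats::rgamma(n_chunk, shape = nu, rate = nu)
    arr <- t + cumsum(gaps)
    pts <- c(pts, arr)
    t <- arr[length(arr)]
    if (t > L) break
  }
  pts[pts >= 0 & pts <= L]
}

#' Build a gamete from a parental haplotype pair and a crossover set
#'
#' The transmitted chromatid starts at `xo$start_chromatid` and toggles
#' between `a` and `b` at each crossover; the gamete allele at each variant is
#' taken from the currently transmitted chromatid.
#'
#' @param hap_a,hap_b Parental chromatid allele vectors (0/1), equal length.
#' @param positions 1-based bp positions of the variants (increasing).
#' @param xo A `crossover_set` from [sample_crossovers()].
#' @return List with `alleles` (0/1 vector) and `chromatid` (per-variant
#'   `"a"`/`"b"` label — the inheritance truth).
#' @export
make_gamete <- function(hap_a, hap_b, positions, xo) {
  stopifnot(length(hap_a) == length(hap_b),
            length(positions) == length(hap_a),
            inherits(xo, "crossover_set"))
  parity <- (findInterval(positions, xo$pos) +
             (xo$start_chromatid == "b")) %% 2L
  # parity 0 -> chromatid a, 1 -> chromatid b
  list(alleles = ifelse(parity == 0L, hap_a, hap_b),
       chromatid = c("a", "b")[parity + 1L])
}

#' Simulator configuration
#'
#' @param n_variants Total number of variants (allocated to chromosomes
#'   proportionally to physical length when a genome map list is used).
#' @param maf_min,maf_max Per-variant minor-allele frequencies are drawn
#'   uniformly from this range. The detector assumes common variants, so the
#'   default floor is 0.05.
#' @param error_rate Per-genotype error rate `epsilon` in `[0, 0.05]`: each
#'   offspring dosage is independently replaced by a uniformly chosen
#'   *different* dosage with this probability.
#' @param assort_m Target assortativity: correlation between father and
#'   mother polygenic scores, realized by noisy rank matching calibrated
#'   toward the target.
#' @param h2 Target narrow-sense heritability of the simulated phenotype in
#'   `(0, 1]`; phenotype = true score + Gaussian noise with variance
#'   `V (1 - h2) / h2` so that `Var(score)/Var(phenotype) = h2`.
#' @param beta_sd SD of the per-variant effect sizes (drawn `N(0, beta_sd^2)`).
#' @param seed Integer RNG seed; the full cohort is reproducible given the
#'   configuration and seed.
#' @return An object of class `mating_config`.
#' @export
mating_config <- function(n_variants = 1000, maf_min = 0.05, maf_max = 0.5,
                          error_rate = 0, assort_m = 0, h2 = 0.5,
                          beta_sd = 1, seed = NULL) {
  stopifnot(n_variants >= 2,
            maf_min > 0, maf_max <= 0.5, maf_min <= maf_max,
            error_rate >= 0, error_rate <= 0.05,
            assort_m > -1, assort_m < 1,
            h2 >= 0, h2 <= 1)
  structure(list(n_variants = as.integer(n_variants), maf_min = maf_min,
                 maf_max = maf_max, error_rate = error_rate,
                 assort_m = assort_m, h2 = h2, beta_sd = beta_sd,
                 seed = seed),
            class = "mating_config")
}

# Noisy rank matching of mothers to fathers, calibrated so that
# cor(father score, mother score) approaches the target m.
.assort_permutation <- function(sf, sm, m, tol = 0.005, max_iter = 30L) {
  n <- length(sf)
  if (m == 0) return(sample.int(n))
  zf <- as.numeric(scale(sf))
  lam <- max(min(m, 0.999), -0.999)
  best <- NULL
  best_err <- Inf
  for (it in seq_len(max_iter)) {
    v <- lam * zf + sqrt(1 - lam^2) * stats::rnorm(n)
    perm <- order(sm)[rank(v, ties.method = "first")]
    achieved <- stats::cor(sf, sm[perm])
    err <- abs(achieved - m)
    if (err < best_err) { best <- perm; best_err <- err }
    if (err < tol) break
    lam <- max(min(lam + 0.9 * (m - achieved), 0.999), -0.999)
  }
  best
}

#' Simulate a cohort of sibling pairs
#'
#' Generates, for each pair: two phased parents (haplotypes drawn per variant
#' from the configured allele-frequency distribution, linkage equilibrium),
#' four independent meioses (sperm and egg per sibling) with crossovers drawn
#' from the genetic map, offspring genotypes as gamete sums with optional
#' genotyping error, true polygenic scores, and phenotypes. Parents are paired
#' so that the correlation of their polygenic scores approaches
#' `cfg$assort_m`. The full inheritance truth (crossover positions and start
#' chromatids for every gamete) is retained.
#'
#' @param n_pairs Number of sibling pairs.
#' @param map A single [genetic_map()] or a named list of them (a genome),
#'   e.g. from [genome_maps()].
#' @param cfg A [mating_config()].
#' @param interference An [interference_params()].
#' @param keep_haplotypes Keep the phased parental haplotype matrices
#'   (memory-heavy; needed only for allele-level conservation checks).
#' @param phenotypes Compute phenotypes (requires `cfg$h2 > 0`).
#' @return An object of class `sib_cohort`. Main components: `variants`
#'   (data.frame: id, chrom, pos, maf, beta), `geno` (integer matrix,
#'   individuals x variants, row names `P<i>_s1`/`P<i>_s2`), `parent_geno`
#'   (fathers then mothers, couple-aligned), `scores` (data.frame with true
#'   scores), `phenotypes`, `parent_scores`, `pairs`, `xo` (per-chromosome
#'   crossover truth), `maps`, `cfg`, `assort_achieved`.
#' @export
simulate_sib_pairs <- function(n_pairs, map, cfg = mating_config(),
                               interference = interference_params(),
                               keep_haplotypes = FALSE, phenotypes = TRUE) {
  stopifnot(n_pairs >= 1, inherits(cfg, "mating_config"))
  if (inherits(map, "genetic_map")) {
    maps <- stats::setNames(list(map), map$chrom)
  } else {
    stopifnot(is.list(map), all(vapply(map, inherits, TRUE, "genetic_map")))
    maps <- stats::setNames(map, vapply(map, function(m) m$chrom, ""))
  }
  if (phenotypes && cfg$h2 <= 0)
    stop("phenotype output requested but cfg$h2 is 0")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  n_chr <- length(maps)
  chr_bp <- vapply(maps, function(m) m$pos[length(m$pos)], 0)
  # allocate variants proportionally to physical length, at least 2 per chrom
  nv_chr <- if (n_chr == 1L) cfg$n_variants else
    pmax(2L, round(cfg$n_variants * chr_bp / sum(chr_bp)))

  variants <- do.call(rbind, lapply(seq_len(n_chr), function(ci) {
    nv <- nv_chr[ci]
    pos <- sort(sample(seq(2, chr_bp[ci] - 1), nv))
    data.frame(id = sprintf("%s_v%d", names(maps)[ci], seq_len(nv)),
               chrom = names(maps)[ci], pos = pos,
               maf = stats::runif(nv, cfg$maf_min, cfg$maf_max),
               beta = stats::rnorm(nv, 0, cfg$beta_sd),
               stringsAsFactors = FALSE)
  }))
  rownames(variants) <- NULL
  nv_tot <- nrow(variants)
  chr_of <- variants$chrom

  # phased parents: per chromosome, haplotype matrices n_pairs x nv (0/1)
  draw_haps <- function(maf) {
    nv <- length(maf)
    matrix(stats::rbinom(n_pairs * nv, 1L, rep(maf, each = n_pairs)),
           n_pairs, nv)
  }
  F1 <- F2 <- M1 <- M2 <- vector("list", n_chr)
  for (ci in seq_len(n_chr)) {
    maf <- variants$maf[chr_of == names(maps)[ci]]
    F1[[ci]] <- draw_haps(maf); F2[[ci]] <- draw_haps(maf)
    M1[[ci]] <- draw_haps(maf); M2[[ci]] <- draw_haps(maf)
  }
  beta_chr <- split(variants$beta, factor(chr_of, levels = names(maps)))
  score_parents <- function(H1, H2) {
    s <- numeric(n_pairs)
    for (ci in seq_len(n_chr))
      s <- s + drop((H1[[ci]] + H2[[ci]]) %*% beta_chr[[ci]])
    s
  }
  sf <- score_parents(F1, F2)
  sm <- score_parents(M1, M2)
  perm <- .assort_permutation(sf, sm, cfg$assort_m)
  if (n_pairs >= 2) {
    for (ci in seq_len(n_chr)) {
      M1[[ci]] <- M1[[ci]][perm, , drop = FALSE]
      M2[[ci]] <- M2[[ci]][perm, , drop = FALSE]
    }
    sm <- sm[perm]
  }
  assort_achieved <- if (n_pairs >= 3) stats::cor(sf, sm) else NA_real_

  # crossover truth, drawn vectorized per chromosome: gamete index
  # g = (pair-1)*4 + m, with m = 1 sib1-paternal, 2 sib1-maternal,
  # 3 sib2-paternal, 4 sib2-maternal
  n_g <- 4L * n_pairs
  xo <- vector("list", n_chr)
  names(xo) <- names(maps)
  for (ci in seq_len(n_chr)) {
    L <- map_length_cM(maps[[ci]]) / 100
    if (interference$model == "poisson") {
      counts <- stats::rpois(n_g, L)
      tot <- sum(counts)
      cMs <- stats::runif(tot, 0, L * 100)
      g_idx <- rep.int(seq_len(n_g), counts)
      o <- order(g_idx, cMs)
      pos <- if (tot) cM_to_bp(maps[[ci]], cMs[o]) else numeric(0)
    } else {
      lst <- lapply(seq_len(n_g), function(g)
        .gamma_renewal_points(L, interference$nu) * 100)
      counts <- lengths(lst)
      cMs <- unlist(lst, use.names = FALSE)
      pos <- if (length(cMs)) cM_to_bp(maps[[ci]], cMs) else numeric(0)
    }
    xo[[ci]] <- list(counts = as.integer(counts),
                     offsets = c(0L, cumsum(as.integer(counts))),
                     pos = pos,
                     start = sample(0:1, n_g, replace = TRUE))
  }

  # offspring genotypes
  geno <- matrix(0L, 2L * n_pairs, nv_tot)
  ids <- as.vector(rbind(sprintf("P%d_s1", seq_len(n_pairs)),
                         sprintf("P%d_s2", seq_len(n_pairs))))
  rownames(geno) <- ids
  colnames(geno) <- variants$id
  col0 <- c(0L, cumsum(nv_chr))
  for (ci in seq_len(n_chr)) {
    pv <- variants$pos[chr_of == names(maps)[ci]]
    x <- xo[[ci]]
    cols <- (col0[ci] + 1L):col0[ci + 1L]
    for (i in seq_len(n_pairs)) {
      fa <- F1[[ci]][i, ]; fb <- F2[[ci]][i, ]
      ma <- M1[[ci]][i, ]; mb <- M2[[ci]][i, ]
      gam <- vector("list", 4L)
      for (m in 1:4) {
        g <- (i - 1L) * 4L + m
        brk <- if (x$counts[g]) x$pos[(x$offsets[g] + 1L):x$offsets[g + 1L]]
               else numeric(0)
        par_b <- (findInterval(pv, brk) + x$start[g]) %% 2L
        gam[[m]] <- if (m %% 2L == 1L) {  # paternal
          fa * (1L - par_b) + fb * par_b
        } else {
          ma * (1L - par_b) + mb * par_b
        }
      }
      geno[2L * i - 1L, cols] <- gam[[1]] + gam[[2]]
      geno[2L * i, cols] <- gam[[3]] + gam[[4]]
    }
  }

  score_true <- drop(geno %*% variants$beta)
  names(score_true) <- ids

  # genotyping error: replace with a uniformly random different dosage
  if (cfg$error_rate > 0) {
    n_cells <- length(geno)
    err_idx <- which(stats::runif(n_cells) < cfg$error_rate)
    if (length(err_idx)) {
      shift <- sample(1:2, length(err_idx), replace = TRUE)
      geno[err_idx] <- (geno[err_idx] + shift) %% 3L
    }
  }

  parent_geno <- matrix(0L, 2L * n_pairs, nv_tot)
  rownames(parent_geno) <- c(sprintf("P%d_f", seq_len(n_pairs)),
                             sprintf("P%d_m", seq_len(n_pairs)))
  colnames(parent_geno) <- variants$id
  for (ci in seq_len(n_chr)) {
    cols <- (col0[ci] + 1L):col0[ci + 1L]
    parent_geno[seq_len(n_pairs), cols] <- F1[[ci]] + F2[[ci]]
    parent_geno[n_pairs + seq_len(n_pairs), cols] <- M1[[ci]] + M2[[ci]]
  }

  pheno <- NULL
  if (phenotypes) {
    V <- stats::var(score_true)
    noise_sd <- if (V > 0) sqrt(V * (1 - cfg$h2) / cfg$h2) else 0
    pheno <- score_true + stats::rnorm(length(score_true), 0, noise_sd)
  }

  structure(list(
    variants = variants,
    geno = geno,
    parent_geno = parent_geno,
    haplotypes = if (keep_haplotypes)
      list(F1 = F1, F2 = F2, M1 = M1, M2 = M2) else NULL,
    scores = data.frame(id = ids,
                        pair = rep(seq_len(n_pairs), each = 2L),
                        sib = rep(1:2, n_pairs),
                        score_true = unname(score_true),
                        stringsAsFactors = FALSE),
    phenotypes = pheno,
    parent_scores = data.frame(pair = seq_len(n_pairs),
                               father = sf, mother = sm),
    pairs = data.frame(pair = seq_len(n_pairs),
                       sib1 = sprintf("P%d_s1", seq_len(n_pairs)),
                       sib2 = sprintf("P%d_s2", seq_len(n_pairs)),
                       stringsAsFactors = FALSE),
    xo = xo,
    maps = maps,
    cfg = cfg,
    interference = interference,
    assort_achieved = assort_achieved),
    class = "sib_cohort")
}

#' @export
print.sib_cohort <- function(x, ...) {
  cat(sprintf(paste0("<sib_cohort> %d pairs, %d variants on %d chromosome(s)",
                     " (%.1f cM total), error rate %.4g\n"),
              nrow(x$pairs), nrow(x$variants), length(x$maps),
              sum(vapply(x$maps, map_length_cM, 0)), x$cfg$error_rate))
  invisible(x)
}

#' All true crossovers of a cohort
#'
#' @param cohort A `sib_cohort`.
#' @return data.frame: pair, sib (1/2), parent ("father"/"mother"), chrom,
#'   pos (bp), in gamete order.
#' @export
true_crossovers <- function(cohort) {
  stopifnot(inherits(cohort, "sib_cohort"))
  out <- lapply(names(cohort$xo), function(ch) {
    x <- cohort$xo[[ch]]
    if (sum(x$counts) == 0)
      return(NULL)
    g <- rep.int(seq_along(x$counts), x$counts)
    m <- (g - 1L) %% 4L + 1L
    data.frame(pair = (g - 1L) %/% 4L + 1L,
               sib = c(1L, 1L, 2L, 2L)[m],
               parent = c("father", "mother", "father", "mother")[m],
               chrom = ch, pos = x$pos, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(pair = integer(0), sib = integer(0),
                      parent = character(0), chrom = character(0),
                      pos = numeric(0))
  rownames(out) <- NULL
  out
}

# breaks of gamete g on chromosome ch (internal)
.gamete_breaks <- function(cohort, ch, g) {
  x <- cohort$xo[[ch]]
  if (x$counts[g] == 0) numeric(0)
  else x$pos[(x$offsets[g] + 1L):x$offsets[g + 1L]]
}

#' Per-variant inheritance truth for one pair
#'
#' Reconstructs, from the recorded crossover sets, which parental chromatid
#' (`"a"` or `"b"`) each sibling carries at every variant on a chromosome.
#'
#' @param cohort A `sib_cohort`.
#' @param pair Pair index.
#' @param chrom Chromosome label (default: first).
#' @return List of four character vectors: `s1_pat`, `s1_mat`, `s2_pat`,
#'   `s2_mat`.
#' @export
inheritance_vectors <- function(cohort, pair, chrom = names(cohort$maps)[1]) {
  stopifnot(inherits(cohort, "sib_cohort"), chrom %in% names(cohort$maps))
  pv <- cohort$variants$pos[cohort$variants$chrom == chrom]
  x <- cohort$xo[[chrom]]
  out <- lapply(1:4, function(m) {
    g <- (pair - 1L) * 4L + m
    parity <- (findInterval(pv, .gamete_breaks(cohort, chrom, g)) +
               x$start[g]) %% 2L
    c("a", "b")[parity + 1L]
  })
  names(out) <- c("s1_pat", "s1_mat", "s2_pat", "s2_mat")
  out
}
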