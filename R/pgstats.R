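#' Polygenic score model (weight table)
#'
#' A PGS is a linear function of allele dosages: `S_i = sum_j G_ij beta_j`.
#'
#' @param variant_id Unique variant identifiers.
#' @param beta Per-allele effect sizes (finite).
#' @param effect_allele Optional effect-allele labels; when the genotype
#'   table carries ref/alt alleles, dosages of variants whose effect allele
#'   is the reference are flipped (`2 - dosage`) before scoring.
#' @return An object of class `pgs_model` (data.frame).
#' @export
pgs_model <- function(variant_id, beta, effect_allele = NULL) {
  stopifnot(length(variant_id) == length(beta), all(is.finite(beta)))
  if (anyDuplicated(variant_id)) stop("variant ids must be unique")
  df <- data.frame(variant_id = as.character(variant_id), beta = beta,
                   stringsAsFactors = FALSE)
  df$effect_allele <- if (is.null(effect_allele)) NA_character_ else
    as.character(effect_allele)
  structure(df, class = c("pgs_model", "data.frame"))
}

#' Score individuals with a PGS model
#'
#' Dot product of dosages and weights over the model variants present in the
#' genotype matrix. Model variants absent from the matrix are dropped (count
#' reported); missing dosages are replaced by the variant's mean dosage
#' (count reported).
#'
#' @param geno Dosage matrix, individuals x variants, with variant ids as
#'   column names.
#' @param model A [pgs_model()].
#' @param alt Optional named vector of alternate-allele labels per variant
#'   (names = variant ids); used together with `model$effect_allele` to
#'   orient dosages.
#' @return Named numeric vector of scores, with attributes
#'   `n_missing_variants` and `n_imputed_dosages`.
#' @export
pgs_score <- function(geno, model, alt = NULL) {
  stopifnot(inherits(model, "pgs_model"), is.matrix(geno))
  hit <- match(model$variant_id, colnames(geno))
  present <- !is.na(hit)
  if (!any(present)) stop("no model variants present in the genotype matrix")
  G <- geno[, hit[present], drop = FALSE]
  beta <- model$beta[present]
  if (!is.null(alt) && !all(is.na(model$effect_allele))) {
    ea <- model$effect_allele[present]
    av <- alt[model$variant_id[present]]
    flip <- !is.na(ea) & !is.na(av) & ea != av
    if (any(flip)) G[, flip] <- 2 - G[, flip]
  }
  n_imp <- sum(is.na(G))
  if (n_imp) {
    mu <- colMeans(G, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    na_idx <- which(is.na(G), arr.ind = TRUE)
    G[na_idx] <- mu[na_idx[, 2]]
  }
  s <- drop(G %*% beta)
  names(s) <- rownames(geno)
  attr(s, "n_missing_variants") <- sum(!present)
  attr(s, "n_imputed_dosages") <- n_imp
  s
}

#' Random pairing of individuals, avoiding known siblings
#'
#' Builds a seeded random partition of the ids into pairs such that no pair
#' is a known sibling pair (and no one is paired with themselves). An odd
#' leftover individual is dropped and reported.
#'
#' @param ids Character vector of individual ids (>= 2 distinct).
#' @param seed Integer seed; the pairing is deterministic given `ids` and
#'   `seed`.
#' @param sib_pairs Optional data.frame/matrix with two id columns listing
#'   forbidden (sibling) pairs.
#' @return data.frame `id1`, `id2`, with attribute `dropped` (id of the odd
#'   leftover, or NULL).
#' @export
random_pairing <- function(ids, seed, sib_pairs = NULL) {
  ids <- unique(as.character(ids))
  if (length(ids) < 2) stop("need at least 2 distinct ids")
  forbidden <- character(0)
  if (!is.null(sib_pairs) && nrow(sib_pairs)) {
    a <- as.character(sib_pairs[[1]]); b <- as.character(sib_pairs[[2]])
    forbidden <- c(paste(pmin(a, b), pmax(a, b)))
  }
  set.seed(seed)
  ord <- sample(ids)
  dropped <- NULL
  if (length(ord) %% 2 == 1) {
    dropped <- ord[length(ord)]
    ord <- ord[-length(ord)]
  }
  id1 <- ord[c(TRUE, FALSE)]
  id2 <- ord[c(FALSE, TRUE)]
  bad_key <- function(x, y) paste(pmin(x, y), pmax(x, y))
  viol <- which(bad_key(id1, id2) %in% forbidden)
  tries <- 0L
  while (length(viol) && tries < 1000L) {
    tries <- tries + 1L
    i <- viol[1]
    j <- sample(seq_along(id1), 1)
    # swap partners of pairs i and j if both results are allowed
    if (j != i) {
      k1 <- bad_key(id1[i], id2[j]); k2 <- bad_key(id1[j], id2[i])
      if (!(k1 %in% forbidden) && !(k2 %in% forbidden)) {
        tmp <- id2[i]; id2[i] <- id2[j]; id2[j] <- tmp
      }
    }
    viol <- which(bad_key(id1, id2) %in% forbidden)
  }
  if (length(viol))
    stop("could not build a sibling-free random pairing (constraints too tight)")
  structure(data.frame(id1 = id1, id2 = id2, stringsAsFactors = FALSE),
            dropped = dropped)
}

#' Sibling vs random-pair score difference statistics
#'
#' Computes the standard deviations of signed score differences for sibling
#' pairs (`Delta S`) and random unrelated pairs (`Delta U`), the variance
#' ratio `V(Delta S)/V(Delta U)` (theory: 1/2 for additive scores under
#' random mating), and the ratio `sqrt(2) * sd(Delta S)/sd(Delta U)`
#' (theory: 1) with a seeded bootstrap standard error.
#'
#' @param scores Named numeric vector of scores.
#' @param sib_pairs data.frame `id1`, `id2` of sibling pairs.
#' @param random_pairs data.frame `id1`, `id2` of random pairs (e.g. from
#'   [random_pairing()]).
#' @param n_boot Bootstrap resamples for the ratio SE.
#' @param seed Seed for the bootstrap.
#' @return List of class `diff_stats`: `sd_s`, `sd_u`, `var_ratio`,
#'   `sqrt2_ratio`, `sqrt2_ratio_se`, `n_sib`, `n_random`.
#' @export
pair_differences <- function(scores, sib_pairs, random_pairs,
                             n_boot = 1000, seed = 1) {
  get_diff <- function(pairs, what) {
    a <- as.character(pairs[[1]]); b <- as.character(pairs[[2]])
    if (any(a == b))
      stop("self-pair found in ", what, " pairs")
    s1 <- scores[a]; s2 <- scores[b]
    if (anyNA(s1) || anyNA(s2)) stop("pair ids missing from scores")
    unname(s1 - s2)
  }
  ds <- get_diff(sib_pairs, "sibling")
  du <- get_diff(random_pairs, "random")
  if (length(ds) < 30 || length(du) < 30)
    stop("need at least 30 pairs of each kind")
  sd_s <- stats::sd(ds); sd_u <- stats::sd(du)
  ratio <- sqrt(2) * sd_s / sd_u
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    sqrt(2) * stats::sd(ds[sample.int(length(ds), replace = TRUE)]) /
      stats::sd(du[sample.int(length(du), replace = TRUE)])
  }, 0)
  structure(list(sd_s = sd_s, sd_u = sd_u,
                 var_ratio = stats::var(ds) / stats::var(du),
                 sqrt2_ratio = ratio,
                 sqrt2_ratio_se = stats::sd(boot),
                 n_sib = length(ds), n_random = length(du)),
            class = "diff_stats")
}

#' @export
print.diff_stats <- function(x, ...) {
  cat(sprintf(paste0("<diff_stats> sd(dS) = %.4g, sd(dU) = %.4g, ",
                     "V(dS)/V(dU) = %.3f, sqrt2*sd(dS)/sd(dU) = %.3f (%.3f)\n"),
              x$sd_s, x$sd_u, x$var_ratio, x$sqrt2_ratio, x$sqrt2_ratio_se))
  invisible(x)
}

#' Assortativity from sibling score covariance
#'
#' Inverts the sibling-covariance identity `cov(S1, S2) = (V/2)(1 + m)`:
#' `m = 2 cov(S1, S2) / V - 1`, where `V` is the score variance of the
#' general (mating) population. The covariance is computed symmetrically in
#' the two pair members (pair order is arbitrary) and the standard error by
#' leave-one-pair-out jackknife.
#'
#' @param s1,s2 Scores of the two members of each sibling pair.
#' @param V Population score variance (> 0).
#' @return List of class `assortativity_estimate`: `m`, `se`, `cov`, `V`,
#'   `n_pairs`.
#' @export
assortativity <- function(s1, s2, V) {
  stopifnot(length(s1) == length(s2))
  if (!is.numeric(V) || V <= 0) stop("population variance V must be > 0")
  n <- length(s1)
  mu <- mean(c(s1, s2))
  cv <- mean((s1 - mu) * (s2 - mu))
  m <- 2 * cv / V - 1
  se <- NA_real_
  if (n >= 10) {
    # leave-one-pair-out jackknife in closed form
    S <- sum(s1) + sum(s2)
    P <- sum(s1 * s2)
    mu_i <- (S - s1 - s2) / (2 * (n - 1))
    cov_i <- (P - s1 * s2 - mu_i * (S - s1 - s2) + (n - 1) * mu_i^2) / (n - 1)
    mj <- 2 * cov_i / V - 1
    se <- sqrt((n - 1) / n * sum((mj - mean(mj))^2))
  }
  structure(list(m = m, se = se, cov = cv, V = V, n_pairs = n),
            class = "assortativity_estimate")
}

#' @export
print.assortativity_estimate <- function(x, ...) {
  cat(sprintf("<assortativity> m = %.3f (se %.3f), cov = %.4g, V = %.4g, %d pairs\n",
              x$m, x$se, x$cov, x$V, x$n_pairs))
  invisible(x)
}

#' Narrow-sense heritability captured by a score
#'
#' Two estimators and their average: (1) the variance ratio
#' `Var(score)/Var(phenotype)` and (2) the squared correlation
#' `corr(score, phenotype)^2`.
#'
#' @param scores,phenotypes Paired finite numeric vectors.
#' @return List of class `heritability_estimate`: `h2_ratio`, `h2_corr`,
#'   `h2_avg`, `n`.
#' @export
heritability <- function(scores, phenotypes) {
  stopifnot(length(scores) == length(phenotypes),
            all(is.finite(scores)), all(is.finite(phenotypes)))
  vy <- stats::var(phenotypes)
  if (vy == 0) stop("phenotype variance is zero")
  h2_ratio <- stats::var(scores) / vy
  h2_corr <- stats::cor(scores, phenotypes)^2
  structure(list(h2_ratio = h2_ratio, h2_corr = h2_corr,
                 h2_avg = (h2_ratio + h2_corr) / 2, n = length(scores)),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("<heritability> ratio = %.3f, corr^2 = %.3f, average = %.3f (n = %d)\n",
              x$h2_ratio, x$h2_corr, x$h2_avg, x$n))
  invisible(x)
}

#' Close sibling edges into families
#'
#' Treats sibling pairs as edges of a graph and returns its connected
#' components as families (if A-B and B-C are sibling pairs, A-B-C is one
#' family). Edges that also appear in the parent-child list are excluded
#' first.
#'
#' @param sib_edges data.frame/matrix with two id columns of sibling pairs.
#' @param parent_child Optional two-column structure of parent-child pairs
#'   to filter out of the sibling edges.
#' @return List of class `family_graph`: `families` (data.frame `id`,
#'   `family`), `n_families`, `n_excluded_edges`.
#' @export
family_closure <- function(sib_edges, parent_child = NULL) {
  a <- as.character(sib_edges[[1]]); b <- as.character(sib_edges[[2]])
  key <- paste(pmin(a, b), pmax(a, b))
  n_excl <- 0L
  if (!is.null(parent_child) && NROW(parent_child)) {
    pa <- as.character(parent_child[[1]]); pb <- as.character(parent_child[[2]])
    pkey <- paste(pmin(pa, pb), pmax(pa, pb))
    drop <- key %in% pkey
    n_excl <- sum(drop)
    a <- a[!drop]; b <- b[!drop]
  }
  if (!length(a)) {
    return(structure(list(families = data.frame(id = character(0),
                                                family = integer(0)),
                          n_families = 0L, n_excluded_edges = n_excl),
                     class = "family_graph"))
  }
  g <- igraph::graph_from_data_frame(data.frame(a, b), directed = FALSE)
  comp <- igraph::components(g)
  structure(list(families = data.frame(id = names(comp$membership),
                                       family = as.integer(comp$membership),
                                       stringsAsFactors = FALSE),
                 n_families = comp$no, n_excluded_edges = n_excl),
            class = "family_graph")
}

#' @export
print.family_graph <- function(x, ...) {
  cat(sprintf("<family_graph> %d families over %d individuals (%d parent-child edges excluded)\n",
              x$n_families, nrow(x$families), x$n_excluded_edges))
  invisible(x)
}

#' Center scores within families
#'
#' Either around the family's sibling mean (`"sib_mean"`; the only option
#' when parents are unavailable) or around the midparent score
#' (`"midparent"`: mean of the two parental scores). Sib-mean centering
#' removes slightly more variance than midparent centering because the
#' sibling mean only approaches the midparent for large sibships.
#'
#' @param scores Named numeric vector of individual scores.
#' @param families data.frame `id`, `family` (e.g. from
#'   [family_closure()]`$families`).
#' @param mode `"sib_mean"` or `"midparent"`.
#' @param parents For `"midparent"`: data.frame `family`, `father`, `mother`
#'   with parental scores. Families with a missing parent score are skipped
#'   (centered value NA) and reported via attribute `skipped_families`.
#' @return Named vector of centered scores (same order as `scores`;
#'   individuals without a family are NA).
#' @export
center_scores <- function(scores, families, mode = c("sib_mean", "midparent"),
                          parents = NULL) {
  mode <- match.arg(mode)
  fam <- families$family[match(names(scores), families$id)]
  out <- rep(NA_real_, length(scores))
  names(out) <- names(scores)
  skipped <- integer(0)
  if (mode == "sib_mean") {
    ok <- !is.na(fam)
    ctr <- stats::ave(scores[ok], fam[ok], FUN = mean)
    out[ok] <- scores[ok] - ctr
  } else {
    if (is.null(parents)) stop("midparent centering requires `parents`")
    mid <- (parents$father + parents$mother) / 2
    names(mid) <- as.character(parents$family)
    mp <- mid[as.character(fam)]
    skipped <- unique(fam[!is.na(fam) & is.na(mp)])
    ok <- !is.na(fam) & !is.na(mp)
    out[ok] <- scores[ok] - mp[ok]
  }
  attr(out, "skipped_families") <- skipped
  out
}
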