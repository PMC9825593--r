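#' Mixture-model risk parameters for one disease
#'
#' The polygenic score distribution of a population is modelled as a
#' two-component normal mixture: controls `N(mu0, sigma)` with weight
#' `1 - pi` and cases `N(mu1, sigma)` with weight `pi`, where `pi` is the
#' lifetime risk. The case and control SDs are assumed equal, with `sigma`
#' taken from the controls (the larger class, hence better statistics).
#'
#' @param pi Lifetime risk, strictly inside (0, 1).
#' @param mu0,mu1 Mean score of controls and cases.
#' @param sigma Control score SD (> 0).
#' @return An object of class `risk_model_params`.
#' @export
risk_model_params <- function(pi, mu0, mu1, sigma) {
  stopifnot(is.numeric(pi), pi > 0, pi < 1, is.finite(mu0), is.finite(mu1))
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  structure(list(pi = pi, mu0 = mu0, mu1 = mu1, sigma = sigma),
            class = "risk_model_params")
}

#' Absolute risk from the mixture model
#'
#' Posterior probability of being a case given the score `x`:
#' \deqn{r(x) = [1 + ((1-\pi)/\pi) N(x; \mu_0, \sigma)/N(x; \mu_1, \sigma)]^{-1}}
#' Computed in log space for numerical stability. Strictly increasing in `x`
#' when `mu1 > mu0`, always inside (0, 1), and equal to `pi` at the midpoint
#' `(mu0 + mu1)/2` (or everywhere when `mu0 == mu1`).
#'
#' @param x Score value(s).
#' @param params A [risk_model_params()].
#' @return Risk values in (0, 1), vectorized over `x`.
#' @examples
#' p <- risk_model_params(pi = 0.1, mu0 = 0, mu1 = 1, sigma = 1)
#' mixture_risk(0.5, p)  # = 0.1
#' @export
mixture_risk <- function(x, params) {
  stopifnot(inherits(params, "risk_model_params"))
  log_ratio <- stats::dnorm(x, params$mu0, params$sigma, log = TRUE) -
    stats::dnorm(x, params$mu1, params$sigma, log = TRUE)
  stats::plogis(log(params$pi / (1 - params$pi)) - log_ratio)
}

#' Fit mixture parameters from labeled scores
#'
#' Class means from the labels and the control-group SD; the lifetime risk
#' `pi` is an external input (cohort prevalence is not lifetime risk and is
#' never used).
#'
#' @param scores Numeric score vector.
#' @param case Logical (or 0/1) case labels, same length.
#' @param pi Externally supplied lifetime risk in (0, 1).
#' @return A [risk_model_params()].
#' @export
fit_mixture <- function(scores, case, pi) {
  case <- as.logical(case)
  stopifnot(length(scores) == length(case), !anyNA(case))
  if (sum(case) < 2 || sum(!case) < 2)
    stop("need at least 2 cases and 2 controls")
  risk_model_params(pi = pi,
                    mu0 = mean(scores[!case]),
                    mu1 = mean(scores[case]),
                    sigma = stats::sd(scores[!case]))
}

#' Health index configuration
#'
#' Per-disease inputs for the composite index: label, average lifespan
#' reduction `l` (years), average lifetime risk `rho`, and the mixture
#' [risk_model_params()] used to turn a score into an absolute risk.
#'
#' @param diseases data.frame with columns `label`, `l`, `rho`, `pi`, `mu0`,
#'   `mu1`, `sigma`.
#' @return An object of class `health_index_config`.
#' @export
health_index_config <- function(diseases) {
  need <- c("label", "l", "rho", "pi", "mu0", "mu1", "sigma")
  stopifnot(is.data.frame(diseases), all(need %in% names(diseases)))
  if (anyDuplicated(diseases$label)) stop("disease labels must be unique")
  stopifnot(all(diseases$l >= 0), all(diseases$rho > 0 & diseases$rho < 1))
  models <- lapply(seq_len(nrow(diseases)), function(i)
    risk_model_params(diseases$pi[i], diseases$mu0[i], diseases$mu1[i],
                      diseases$sigma[i]))
  names(models) <- diseases$label
  structure(list(diseases = diseases, models = models),
            class = "health_index_config")
}

#' Composite health index in life-years
#'
#' `I = sum_d l_d (rho_d - r_d(x_d))`: expected life-years relative to the
#' population average, summed over the configured diseases. Positive when
#' the individual's absolute risks are below the population lifetime risks.
#' Linear in the per-disease terms, but nonlinear in the underlying scores
#' (through `r`), so family index distributions are not simple rescalings of
#' the score distributions.
#'
#' @param x Named numeric vector of per-disease scores (names = disease
#'   labels), or a matrix (individuals x diseases with disease column
#'   names).
#' @param config A [health_index_config()].
#' @return Index value(s) in life-years; vector for matrix input.
#' @export
health_index <- function(x, config) {
  stopifnot(inherits(config, "health_index_config"))
  labels <- config$diseases$label
  if (is.matrix(x)) {
    missing <- setdiff(labels, colnames(x))
    if (length(missing))
      stop("missing disease scores: ", paste(missing, collapse = ", "))
    risks <- vapply(labels, function(d)
      mixture_risk(x[, d], config$models[[d]]), numeric(nrow(x)))
    if (nrow(x) == 1L) risks <- matrix(risks, nrow = 1L)
    drop(risks %*% (-config$diseases$l) +
           sum(config$diseases$l * config$diseases$rho))
  } else {
    missing <- setdiff(labels, names(x))
    if (length(missing))
      stop("missing disease scores: ", paste(missing, collapse = ", "))
    sum(vapply(seq_along(labels), function(i) {
      d <- labels[i]
      config$diseases$l[i] *
        (config$diseases$rho[i] - mixture_risk(x[[d]], config$models[[d]]))
    }, 0))
  }
}

#' Illustrative health index configuration
#'
#' A small synthetic multi-disease configuration useful for demonstrations
#' and tests. The lifespan reductions, lifetime risks and mixture parameters
#' are illustrative placeholders, not published disease parameterizations.
#'
#' @param n_diseases Number of diseases (default 5).
#' @param seed Seed for the synthetic parameter draw.
#' @return A [health_index_config()].
#' @export
example_health_index_config <- function(n_diseases = 5, seed = 7) {
  set.seed(seed)
  lifetime <- stats::runif(n_diseases, 0.02, 0.3)
  health_index_config(data.frame(
    label = sprintf("disease_%d", seq_len(n_diseases)),
    l = stats::runif(n_diseases, 2, 12),
    rho = lifetime,
    pi = lifetime,
    mu0 = 0,
    mu1 = stats::runif(n_diseases, 0.5, 1.5),
    sigma = 1,
    stringsAsFactors = FALSE))
}
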