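#' Prior configuration for the Bayesian CNMA models
#'
#' Collects every hyperparameter of the model family in one object. Defaults
#' follow common practice for (component) network meta-analysis of log odds
#' ratios / mean differences:
#' \itemize{
#'   \item main component effects \eqn{d_q \sim N(0, 10^2)};
#'   \item study baselines \eqn{\sim N(0, 10^2)} (i.e. variance 100);
#'   \item heterogeneity \eqn{\tau^2 \sim LN(-1.67, 1.472^2)} — an
#'     empirically based informative prior for log-odds-ratio outcomes —
#'     with half-normal and uniform alternatives on \eqn{\tau};
#'   \item SSVS: spike SD \eqn{\eta} with prior \eqn{N(0, 10^{-2})}
#'     truncated to \eqn{\eta > 0} (or a fixed value), slab multiplier
#'     \eqn{g = 100}, prior inclusion probability 0.5 per pair;
#'   \item Bayesian LASSO: \eqn{\lambda^{-1} \sim U(0, 5)}, with a
#'     half-normal alternative \eqn{\lambda^{-1} \sim N(0,100)I(0,)} or a
#'     fixed \eqn{\lambda};
#'   \item IPD: prognostic coefficients \eqn{\beta \sim N(0,10^2)},
#'     effect-modification coefficients \eqn{\gamma} either unshrunk
#'     \eqn{N(0,10^2)}, SSVS-shrunk, or given a conditional Laplace prior
#'     (which requires a common residual SD \eqn{\sigma} across IPD
#'     studies); \eqn{\sigma \sim U(0, 10)}; baselines \eqn{\alpha_i \sim
#'     N(0, 10^2)}.
#' }
#'
#' @param d_sd prior SD of main component effects.
#' @param baseline_sd prior SD of study baselines (arm-level models) and of
#'   IPD study intercepts.
#' @param tau_prior one of \code{"lognormal"} (on \eqn{\tau^2}),
#'   \code{"half-normal"} or \code{"uniform"} (on \eqn{\tau}).
#' @param tau_lnorm_mean,tau_lnorm_sd lognormal parameters for \eqn{\tau^2}.
#' @param tau_hn_sd half-normal SD for \eqn{\tau}.
#' @param tau_unif_max upper bound of the uniform prior on \eqn{\tau}.
#' @param eta_prior_sd SD of the truncated-normal prior on the spike scale
#'   \eqn{\eta}; ignored when \code{eta_fixed} is given.
#' @param eta_fixed optional fixed spike SD (the original SSVS formulation).
#' @param g slab-to-spike SD ratio (slab SD \eqn{= g\eta}); must exceed 1.
#' @param inclusion_prior default prior inclusion probability for admitted
#'   interaction pairs.
#' @param lambda_prior \code{"inverse-uniform"} (\eqn{\lambda^{-1} \sim
#'   U(0, \code{lambda_inv_max})}), \code{"inverse-half-normal"}
#'   (\eqn{\lambda^{-1} \sim N(0, \code{lambda_inv_hn_sd}^2)I(0,)}) or
#'   \code{"fixed"}.
#' @param lambda_inv_max,lambda_inv_hn_sd,lambda_fixed LASSO hyperprior
#'   settings.
#' @param beta_sd,gamma_sd prior SDs for \eqn{\beta} and unshrunk
#'   \eqn{\gamma}.
#' @param sigma_unif_max upper bound of the uniform prior on \eqn{\sigma}.
#' @param laplace_convention exponent convention of the conditional Laplace
#'   prior on \eqn{\gamma}: \code{"sigma2"} uses rate \eqn{\lambda/\sigma^2};
#'   \code{"park-casella"} uses rate \eqn{\lambda/\sigma} (the normalized
#'   form). See \code{\link{conditional_laplace_logdensity}}.
#' @return object of class \code{prior_config} (a list of the above).
#' @export
prior_config <- function(d_sd = 10, baseline_sd = 10,
                         tau_prior = c("lognormal", "half-normal", "uniform"),
                         tau_lnorm_mean = -1.67, tau_lnorm_sd = 1.472,
                         tau_hn_sd = 10, tau_unif_max = 5,
                         eta_prior_sd = 0.1, eta_fixed = NULL, g = 100,
                         inclusion_prior = 0.5,
                         lambda_prior = c("inverse-uniform",
                                          "inverse-half-normal", "fixed"),
                         lambda_inv_max = 5, lambda_inv_hn_sd = 10,
                         lambda_fixed = NULL,
                         beta_sd = 10, gamma_sd = 10, sigma_unif_max = 10,
                         laplace_convention = c("sigma2", "park-casella")) {
  tau_prior <- match.arg(tau_prior)
  lambda_prior <- match.arg(lambda_prior)
  laplace_convention <- match.arg(laplace_convention)
  stopifnot(d_sd > 0, baseline_sd > 0, tau_lnorm_sd > 0, tau_hn_sd > 0,
            tau_unif_max > 0, eta_prior_sd > 0, g > 1,
            inclusion_prior > 0, inclusion_prior < 1,
            lambda_inv_max > 0, lambda_inv_hn_sd > 0,
            beta_sd > 0, gamma_sd > 0, sigma_unif_max > 0)
  if (!is.null(eta_fixed) && eta_fixed <= 0) stop("eta_fixed must be > 0")
  if (lambda_prior == "fixed" &&
      (is.null(lambda_fixed) || lambda_fixed <= 0))
    stop("lambda_prior = 'fixed' requires lambda_fixed > 0")
  structure(list(d_sd = d_sd, baseline_sd = baseline_sd,
                 tau_prior = tau_prior, tau_lnorm_mean = tau_lnorm_mean,
                 tau_lnorm_sd = tau_lnorm_sd, tau_hn_sd = tau_hn_sd,
                 tau_unif_max = tau_unif_max,
                 eta_prior_sd = eta_prior_sd, eta_fixed = eta_fixed, g = g,
                 inclusion_prior = inclusion_prior,
                 lambda_prior = lambda_prior, lambda_inv_max = lambda_inv_max,
                 lambda_inv_hn_sd = lambda_inv_hn_sd,
                 lambda_fixed = lambda_fixed,
                 beta_sd = beta_sd, gamma_sd = gamma_sd,
                 sigma_unif_max = sigma_unif_max,
                 laplace_convention = laplace_convention),
            class = "prior_config")
}

#' Read a prior configuration from YAML
#'
#' The YAML keys are exactly the arguments of \code{\link{prior_config}};
#' unknown keys are rejected.
#'
#' @param path path to a YAML file.
#' @return a \code{prior_config}.
#' @export
read_prior_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(formals(prior_config)))
  if (length(unknown))
    stop("unknown prior key(s) in ", path, ": ", paste(unknown, collapse = ", "))
  do.call(prior_config, cfg)
}

#' Spike-and-slab log density
#'
#' The SSVS prior for an interaction coefficient is a mixture of two
#' zero-mean normals: a narrow spike with SD \eqn{\eta} (indicator
#' \eqn{I = 0}; the term is effectively absent from the model) and a wide
#' slab with SD \eqn{g\eta} (\eqn{I = 1}; the term is included). This
#' function returns the log density of the component selected by
#' \code{indicator}.
#'
#' @param d coefficient value(s).
#' @param indicator 0 (spike) or 1 (slab).
#' @param eta spike SD, \eqn{> 0}.
#' @param g slab multiplier, \eqn{> 1}.
#' @return log density, vectorized over \code{d}.
#' @export
spike_slab_logdensity <- function(d, indicator, eta, g = 100) {
  if (!is.finite(eta) || eta <= 0) stop("eta must be > 0")
  if (g <= 1) stop("g must be > 1")
  if (!all(indicator %in% c(0, 1))) stop("indicator must be 0 or 1")
  sd <- ifelse(indicator == 1, g * eta, eta)
  stats::dnorm(d, 0, sd, log = TRUE)
}

#' Marginal spike-and-slab log density
#'
#' Log density of the two-component mixture with inclusion probability
#' \code{p}: \eqn{(1-p)\,N(0,\eta^2) + p\,N(0, g^2\eta^2)}.
#'
#' @inheritParams spike_slab_logdensity
#' @param p prior inclusion probability in (0, 1).
#' @export
spike_slab_marginal_logdensity <- function(d, eta, g = 100, p = 0.5) {
  if (!is.finite(eta) || eta <= 0) stop("eta must be > 0")
  stopifnot(p > 0, p < 1)
  log((1 - p) * stats::dnorm(d, 0, eta) + p * stats::dnorm(d, 0, g * eta))
}

#' Full conditional inclusion probability of an SSVS indicator
#'
#' The Gibbs update for the inclusion indicator given the current
#' coefficient value:
#' \deqn{P(I=1 \mid d) = \frac{p\,\phi(d; 0, g^2\eta^2)}
#'   {p\,\phi(d; 0, g^2\eta^2) + (1-p)\,\phi(d; 0, \eta^2)}.}
#' It is increasing in \eqn{|d|} (large coefficients favour the slab) and in
#' the prior probability \code{prior_p}.
#'
#' @param d current coefficient value(s).
#' @param eta spike SD.
#' @param g slab multiplier.
#' @param prior_p prior inclusion probability.
#' @return probability in [0, 1], vectorized over \code{d}.
#' @export
indicator_full_conditional <- function(d, eta, g = 100, prior_p = 0.5) {
  if (!is.finite(eta) || eta <= 0) stop("eta must be > 0")
  stopifnot(prior_p > 0, prior_p < 1)
  # work on log scale for numerical stability at large |d|
  ls <- log(prior_p) + stats::dnorm(d, 0, g * eta, log = TRUE)
  ln <- log1p(-prior_p) + stats::dnorm(d, 0, eta, log = TRUE)
  1 / (1 + exp(ln - ls))
}

#' Laplace (double-exponential) log density
#'
#' The Bayesian-LASSO prior for interaction coefficients:
#' \eqn{\pi(d) = (\lambda/2) e^{-\lambda |d|}}, log density
#' \eqn{\log(\lambda/2) - \lambda |d|}. Larger \eqn{\lambda} shrinks
#' coefficients harder towards zero.
#'
#' @param d coefficient value(s).
#' @param lambda rate \eqn{> 0}.
#' @return log density, vectorized over \code{d}.
#' @export
laplace_logdensity <- function(d, lambda) {
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0")
  log(lambda / 2) - lambda * abs(d)
}

#' Conditional Laplace log density for effect-modification coefficients
#'
#' A Laplace prior on the component-covariate interaction coefficients
#' \eqn{\gamma} conditioned on the residual variance, which yields unimodal
#' posteriors; it requires a common residual SD \eqn{\sigma} across IPD
#' studies. Two exponent conventions are supported:
#' \describe{
#'   \item{\code{"sigma2"} (default)}{\eqn{\sum_k [\log(\lambda/(2\sigma)) -
#'     \lambda |\gamma_k| / \sigma^2]}. Note this form does not integrate
#'     to 1 (its integral over one coordinate is \eqn{\sigma}); it is usable
#'     as an unnormalized prior since \eqn{\sigma}-dependence only rescales.}
#'   \item{\code{"park-casella"}}{\eqn{\sum_k [\log(\lambda/(2\sigma)) -
#'     \lambda |\gamma_k| / \sigma]}, the properly normalized
#'     double-exponential with rate \eqn{\lambda/\sigma}.}
#' }
#'
#' @param gamma numeric vector of coefficients.
#' @param lambda rate \eqn{> 0}.
#' @param sigma common residual SD \eqn{> 0}.
#' @param convention \code{"sigma2"} or \code{"park-casella"}.
#' @param common_sigma must be TRUE; passing FALSE signals that the model is
#'   running per-study variances, under which this prior is not defined.
#' @return total log density over the vector.
#' @export
conditional_laplace_logdensity <- function(gamma, lambda, sigma,
                                           convention = c("sigma2", "park-casella"),
                                           common_sigma = TRUE) {
  convention <- match.arg(convention)
  if (!isTRUE(common_sigma))
    stop("conditional Laplace prior requires a common sigma across IPD studies")
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  denom <- if (convention == "sigma2") sigma^2 else sigma
  sum(log(lambda / (2 * sigma)) - lambda * abs(gamma) / denom)
}

#' Read an interaction-pair specification from CSV
#'
#' Columns \code{comp1, comp2}, optional \code{prior_inclusion}. Rows with
#' \code{prior_inclusion = 0} are dropped (pair excluded from the model
#' up front).
#'
#' @param path CSV path.
#' @param catalog a \code{\link{component_catalog}}.
#' @param default_inclusion prior probability for rows without their own.
#' @return an \code{\link{interaction_set}}.
#' @export
read_interaction_set <- function(path, catalog, default_inclusion = 0.5) {
  df <- read_csv_checked(path, required = c("comp1", "comp2"))
  if ("prior_inclusion" %in% names(df)) {
    df <- df[is.na(df$prior_inclusion) | df$prior_inclusion > 0, , drop = FALSE]
  }
  interaction_set(df, catalog, prior_inclusion = default_inclusion)
}
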