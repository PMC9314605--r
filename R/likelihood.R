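#' Random-effects covariance of a multi-arm study
#'
#' The exchangeable covariance of the \eqn{k-1} random relative effects of a
#' \eqn{k}-arm study vs its reference arm: variance \eqn{\tau^2} on the
#' diagonal and \eqn{\tau^2/2} off the diagonal. This is the standard NMA
#' structure guaranteeing that every pairwise comparison within the study
#' has random-effect variance \eqn{\tau^2} (consistency of heterogeneity).
#'
#' @param tau2 heterogeneity variance \eqn{\ge 0}.
#' @param k_arms number of arms, \eqn{\ge 2}.
#' @return a \code{(k-1) x (k-1)} covariance matrix.
#' @export
multiarm_re_covariance <- function(tau2, k_arms) {
  if (k_arms < 2L) stop("k_arms must be >= 2")
  if (tau2 < 0) stop("tau2 must be >= 0")
  m <- k_arms - 1L
  matrix(tau2 / 2, m, m) + diag(tau2 / 2, m)
}

#' Log-likelihood contribution of one aggregate study
#'
#' Reference (non-MCMC) implementation of the aggregate-data likelihoods,
#' evaluated at given parameter values.
#' \itemize{
#'   \item contrast-level: \eqn{\sum_j \log N(y_j; \delta_j, s_j^2)};
#'     \code{params$delta} holds one relative effect per non-reference arm.
#'   \item arm-binomial: \eqn{\sum_k \log Bin(r_k; n_k,
#'     logit^{-1}(\mu + \theta_k))}; \code{params$baseline} is the study
#'     baseline log-odds \eqn{\mu} and \code{params$theta} the per-arm
#'     contrast vs arm 1 (\code{theta[1] = 0}).
#'   \item arm-normal: identity link on per-arm means with sampling SD
#'     \code{sd/sqrt(n)}.
#' }
#'
#' @param study an \code{ad_contrast_study} or \code{ad_arm_study}.
#' @param params list with \code{delta}, or \code{baseline} and
#'   \code{theta}, as above.
#' @return scalar log likelihood.
#' @export
loglik_ad <- function(study, params) {
  if (inherits(study, "ad_contrast_study")) {
    if (length(params$delta) != length(study$y))
      stop("params$delta must have one entry per non-reference arm")
    return(sum(stats::dnorm(study$y, params$delta, study$se, log = TRUE)))
  }
  if (!inherits(study, "ad_arm_study")) stop("unsupported study type")
  k <- length(study$combos)
  theta <- params$theta
  if (length(theta) != k || theta[1L] != 0)
    stop("params$theta must have length = arms with theta[1] = 0")
  if (study$outcome == "binary") {
    p <- stats::plogis(params$baseline + theta)
    sum(stats::dbinom(study$r, study$n, p, log = TRUE))
  } else {
    sum(stats::dnorm(study$mean, params$baseline + theta,
                     study$sd / sqrt(study$n), log = TRUE))
  }
}

#' Log-likelihood contribution of one IPD patient record
#'
#' Reference implementation of the one-stage IPD likelihood. For a patient
#' with centered covariates \eqn{x} randomized to combination \eqn{t} in a
#' study whose reference combination is \eqn{t_0}, the mean is
#' \deqn{\alpha_i + \beta' x + \left(\sum_{q \in t} \gamma_q -
#'   \sum_{q \in t_0} \gamma_q\right)' x + \delta,}
#' where \eqn{\delta} is the study's random relative effect for that arm
#' (zero on the reference arm). At \eqn{x = 0} the \eqn{\gamma} terms drop
#' out entirely, so \eqn{d}-based contrasts are conditional effects at the
#' covariate means.
#'
#' @param y observed outcome.
#' @param x numeric covariate vector (centered).
#' @param combo,ref_combo the patient's and the study-reference
#'   combinations (labels or parsed).
#' @param alpha study intercept.
#' @param beta prognostic coefficient vector.
#' @param gamma effect-modification matrix, components x covariates
#'   (rownames = catalog codes).
#' @param delta the arm's random relative effect (0 for the reference arm).
#' @param sigma residual SD (continuous outcome).
#' @param catalog a \code{\link{component_catalog}}.
#' @param outcome \code{"continuous"} or \code{"binary"} (Bernoulli-logit;
#'   \code{sigma} ignored).
#' @return scalar log likelihood.
#' @export
loglik_ipd_patient <- function(y, x, combo, ref_combo, alpha, beta, gamma,
                               delta, sigma, catalog,
                               outcome = c("continuous", "binary")) {
  outcome <- match.arg(outcome)
  combo <- as_combination(combo, catalog)
  ref_combo <- as_combination(ref_combo, catalog)
  if (length(x) != length(beta) || length(x) != ncol(gamma))
    stop("covariate length mismatch between x, beta and gamma")
  drow <- as.numeric(unclass(catalog) %in% unclass(combo)) -
    as.numeric(unclass(catalog) %in% unclass(ref_combo))
  gmod <- as.numeric(drow %*% gamma)
  m <- alpha + sum(beta * x) + sum(gmod * x) + delta
  if (outcome == "continuous") {
    stats::dnorm(y, m, sigma, log = TRUE)
  } else {
    stats::dbinom(y, 1L, stats::plogis(m), log = TRUE)
  }
}

#' Covariate-adjusted mean of an aggregate study
#'
#' Aggregate-data meta-regression over study-mean covariates: the observed
#' relative effect is modelled as \eqn{N(\delta_i + \beta' \bar{x}_i,
#' s_i^2)} instead of \eqn{N(\delta_i, s_i^2)}, aligning the marginal AD
#' estimates with the conditional IPD estimates when study means are
#' centered by the same global constants.
#'
#' @param delta_i the study's random relative effect.
#' @param beta prognostic coefficient vector.
#' @param xbar_i centered study-mean covariate vector (may be NULL when
#'   \code{adjust = FALSE}).
#' @param adjust logical switch; when FALSE the mean is \code{delta_i}
#'   regardless of \code{xbar_i}.
#' @return adjusted mean.
#' @export
ad_metaregression_mean <- function(delta_i, beta, xbar_i, adjust = TRUE) {
  if (!adjust) return(delta_i)
  if (is.null(xbar_i)) stop("study-mean covariates required when adjust = TRUE")
  if (length(beta) != length(xbar_i)) stop("beta/xbar length mismatch")
  delta_i + sum(beta * xbar_i)
}
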