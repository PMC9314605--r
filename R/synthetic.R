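#' Generating truth for synthetic component networks
#'
#' Defines a complete generative scenario — catalog, true component effects,
#' true pair interactions, heterogeneity, study plan, and (for IPD) patient
#' model — so that every model in the package can be checked by parameter
#' recovery without external data.
#'
#' The default scenario is a 6-component network of 40 two-arm and 5
#' three-arm studies with heterogeneity \eqn{\tau = 0.3}, true main effects
#' \code{(0.8, -0.5, 0.3, 0, 0.6, -0.2)} and a single true synergy of 1.0
#' between \code{c1} and \code{c2}; contrast standard errors are drawn
#' uniformly from [0.15, 0.35] — sizes typical of a moderate evidence base
#' on a standardized-effect scale, small enough that selection fits run in
#' seconds. The combination pool contains singletons and mixed combinations
#' so that all main effects and the true interaction are estimable. IPD
#' defaults: 8 two-arm studies of 60 patients per arm, residual SD
#' \eqn{\sigma = 1}, a standard-normal and a Bernoulli(0.5) covariate
#' (mimicking a severity score and a binary demographic), prognostic
#' effects \eqn{\beta = (0.5, -0.3)} and one non-zero effect modification
#' (component \code{c1} by the continuous covariate, 0.4).
#'
#' @param catalog a \code{\link{component_catalog}}.
#' @param d named numeric vector of true component effects (names = codes).
#' @param pair_effects named numeric vector of true interaction effects,
#'   names in canonical \code{"p:q"} form (may be empty).
#' @param tau true heterogeneity SD.
#' @param pool character vector of combination labels studies draw arms from.
#' @param n_two_arm,n_three_arm numbers of two- and three-arm AD studies.
#' @param se_range range of contrast standard errors (contrast-level AD).
#' @param arm_n patients per arm (arm-level binomial AD).
#' @param baseline_sd SD of study baselines (arm-level AD and IPD
#'   intercepts).
#' @param n_ipd number of IPD studies.
#' @param patients_per_arm IPD patients per arm.
#' @param beta true prognostic coefficients (one per covariate).
#' @param gamma true effect-modification matrix, components x covariates
#'   (rownames = codes, colnames = covariate names); default all zero
#'   except \code{gamma["c1", 1] = 0.4} under the default catalog.
#' @param sigma true IPD residual SD.
#' @return object of class \code{synthetic_truth}.
#' @export
synthetic_truth <- function(catalog = component_catalog(paste0("c", 1:6)),
                            d = stats::setNames(c(0.8, -0.5, 0.3, 0, 0.6, -0.2),
                                                unclass(catalog)),
                            pair_effects = c("c1:c2" = 1.0),
                            tau = 0.3,
                            pool = c("c1", "c2", "c1 + c2", "c3", "c4",
                                     "c1 + c3", "c2 + c4", "c5", "c6",
                                     "c3 + c5 + c6"),
                            n_two_arm = 40, n_three_arm = 5,
                            se_range = c(0.15, 0.35),
                            arm_n = 150, baseline_sd = 0.5,
                            n_ipd = 8, patients_per_arm = 60,
                            beta = c(x1 = 0.5, x2 = -0.3),
                            gamma = NULL, sigma = 1) {
  stopifnot(inherits(catalog, "component_catalog"),
            length(d) == length(catalog), tau >= 0, sigma >= 0)
  if (is.null(names(d))) names(d) <- unclass(catalog)
  if (length(pool) < 2L) stop("combination pool must have >= 2 entries")
  lapply(pool, parse_combination, catalog = catalog)  # validates
  if (is.null(gamma)) {
    gamma <- matrix(0, length(catalog), length(beta),
                    dimnames = list(unclass(catalog), names(beta)))
    if ("c1" %in% unclass(catalog) && length(beta) >= 1L)
      gamma["c1", 1L] <- 0.4
  }
  structure(list(catalog = catalog, d = d, pair_effects = pair_effects,
                 tau = tau, pool = pool, n_two_arm = n_two_arm,
                 n_three_arm = n_three_arm, se_range = se_range,
                 arm_n = arm_n, baseline_sd = baseline_sd, n_ipd = n_ipd,
                 patients_per_arm = patients_per_arm, beta = beta,
                 gamma = gamma, sigma = sigma),
            class = "synthetic_truth")
}

# Internal: theta of a combination under the truth (main + interactions).
truth_theta <- function(truth, combo) {
  cb <- unclass(as_combination(combo, truth$catalog))
  th <- sum(truth$d[cb])
  if (length(truth$pair_effects)) {
    for (pr in names(truth$pair_effects)) {
      pq <- strsplit(pr, ":", fixed = TRUE)[[1L]]
      if (all(pq %in% cb)) th <- th + truth$pair_effects[[pr]]
    }
  }
  th
}

# Internal: random relative effects of a study's non-reference arms under
# the exchangeable tau^2 / tau^2/2 structure (shared-term construction).
draw_study_deltas <- function(truth, combos) {
  means <- vapply(combos[-1L], function(cb)
    truth_theta(truth, cb) - truth_theta(truth, combos[[1L]]), 0)
  u <- stats::rnorm(1L, 0, truth$tau / sqrt(2))
  means + u + stats::rnorm(length(means), 0, truth$tau / sqrt(2))
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate an aggregate-data component network
#'
#' Draws a network of studies whose arms are combinations from the truth's
#' pool. Contrast-level: \eqn{y \sim N(\delta, s^2)} with \eqn{\delta \sim
#' N(\theta_Y - \theta_X, \tau^2)} (exchangeable multi-arm structure) and
#' \eqn{s} uniform in \code{se_range}. Arm-level binomial: \eqn{r \sim
#' Bin(n, logit^{-1}(\mu_i + \delta_{arm}))} with study baselines
#' \eqn{\mu_i \sim N(0, \code{baseline_sd}^2)}.
#'
#' @param truth a \code{\link{synthetic_truth}}.
#' @param seed integer seed; identical seeds give identical datasets.
#' @param likelihood \code{"contrast-normal"} or \code{"arm-binomial"}.
#' @return a \code{\link{network_dataset}} with the truth attached as
#'   attribute \code{"truth"}.
#' @export
simulate_ad <- function(truth, seed, likelihood = c("contrast-normal",
                                                    "arm-binomial")) {
  stopifnot(inherits(truth, "synthetic_truth"))
  likelihood <- match.arg(likelihood)
  if (missing(seed)) stop("seed is required")
  ns <- truth$n_two_arm + truth$n_three_arm
  ds <- with_seed(seed, {
    studies <- vector("list", ns)
    for (i in seq_len(ns)) {
      k <- if (i <= truth$n_two_arm) 2L else 3L
      arms <- sample(truth$pool, k)
      combos <- lapply(arms, parse_combination, catalog = truth$catalog)
      deltas <- draw_study_deltas(truth, combos)
      if (likelihood == "contrast-normal") {
        se <- stats::runif(k - 1L, truth$se_range[1L], truth$se_range[2L])
        studies[[i]] <- ad_contrast_study(
          sprintf("sim%03d", i), combos,
          y = stats::rnorm(k - 1L, deltas, se), se = se,
          scale = "MD", catalog = truth$catalog)
      } else {
        mu <- stats::rnorm(1L, 0, truth$baseline_sd)
        p <- stats::plogis(mu + c(0, deltas))
        studies[[i]] <- ad_arm_study(
          sprintf("sim%03d", i), combos, outcome = "binary",
          r = stats::rbinom(k, truth$arm_n, p),
          n = rep(truth$arm_n, k), catalog = truth$catalog)
      }
    }
    if (likelihood == "contrast-normal")
      network_dataset(truth$catalog, ad_contrast = studies)
    else network_dataset(truth$catalog, ad_arm = studies)
  })
  attr(ds, "truth") <- truth
  ds
}

#' Simulate an IPD component network
#'
#' Draws \code{n_ipd} two-arm studies of \code{patients_per_arm} patients
#' per arm. Patient outcomes follow the one-stage IPD model: study
#' intercept, prognostic effects \eqn{\beta' x}, effect modification
#' \eqn{(\Gamma' \Delta)' x} for the component difference \eqn{\Delta} of
#' the arm vs the study reference, plus the study's random relative effect
#' and residual noise \eqn{N(0, \sigma^2)}. Covariates: first a standard
#' normal, second (if present) Bernoulli(0.5); centering happens on
#' assembly.
#'
#' @inheritParams simulate_ad
#' @return a \code{\link{network_dataset}} of IPD studies with the truth
#'   attached as attribute \code{"truth"}.
#' @export
simulate_ipd <- function(truth, seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (missing(seed)) stop("seed is required")
  ncov <- length(truth$beta)
  cov_names <- names(truth$beta) %||% paste0("x", seq_len(ncov))
  ds <- with_seed(seed, {
    studies <- vector("list", truth$n_ipd)
    for (i in seq_len(truth$n_ipd)) {
      arms <- sample(truth$pool, 2L)
      combos <- lapply(arms, parse_combination, catalog = truth$catalog)
      combos <- combos[order_combinations(combos, truth$catalog)]
      deltas <- c(0, draw_study_deltas(truth, combos))
      alpha <- stats::rnorm(1L, 0, truth$baseline_sd)
      npat <- 2L * truth$patients_per_arm
      x <- matrix(0, npat, ncov, dimnames = list(NULL, cov_names))
      if (ncov >= 1L) x[, 1L] <- stats::rnorm(npat)
      if (ncov >= 2L) for (c in 2L:ncov) x[, c] <- stats::rbinom(npat, 1L, 0.5)
      armk <- rep(1:2, each = truth$patients_per_arm)
      drow <- t(vapply(combos, function(cb)
        as.numeric(unclass(truth$catalog) %in% unclass(cb)),
        numeric(length(truth$catalog))))
      gmod <- (drow[2L, ] - drow[1L, ]) %*% truth$gamma  # 1 x ncov
      m <- alpha + as.numeric(x %*% truth$beta) +
        ifelse(armk == 2L, as.numeric(x %*% t(gmod)), 0) + deltas[armk]
      y <- stats::rnorm(npat, m, truth$sigma)
      pat <- data.frame(patient_id = sprintf("p%04d", seq_len(npat)),
                        arm_label = vapply(combos, combination_label, "")[armk],
                        y = y)
      pat[cov_names] <- x
      studies[[i]] <- ipd_study(sprintf("ipd%03d", i), pat, cov_names,
                                truth$catalog)
    }
    network_dataset(truth$catalog, ipd = studies)
  })
  attr(ds, "truth") <- truth
  ds
}

#' Operating characteristics of interaction selection
#'
#' Over replicate fits that share a generating truth, flags each admitted
#' pair (SSVS: posterior inclusion frequency above \code{threshold}; other
#' modes: 95\% credible interval of the coefficient excluding zero) and
#' tabulates the flags against the truly non-zero interactions.
#'
#' @param fits list of \code{bcnma_fit} objects (replicates).
#' @param truth the shared \code{\link{synthetic_truth}}.
#' @param threshold inclusion-frequency threshold for SSVS fits.
#' @return list with the confusion counts (\code{tp}, \code{fp}, \code{tn},
#'   \code{fn}), \code{sensitivity} (NA when no true interaction exists),
#'   \code{specificity} (NA when all pairs are truly active), and the
#'   per-replicate flag matrix.
#' @export
selection_operating_characteristics <- function(fits, truth, threshold = 0.5) {
  stopifnot(length(fits) >= 1L, inherits(truth, "synthetic_truth"))
  pairs <- fits[[1L]]$spec$interactions$pair
  flags <- vapply(fits, function(f) {
    if (identical(f$spec$interaction_mode, "ssvs")) {
      s <- ssvs_inclusion_summary(f)
      s$inclusion_freq[match(pairs, s$pair)] > threshold
    } else {
      mat <- as.matrix(f$draws)[, paste0("dpair[", pairs, "]"), drop = FALSE]
      qs <- apply(mat, 2L, stats::quantile, probs = c(0.025, 0.975))
      qs[1L, ] > 0 | qs[2L, ] < 0
    }
  }, logical(length(pairs)))
  flags <- matrix(flags, nrow = length(pairs),
                  dimnames = list(pairs, NULL))
  active <- pairs %in% names(truth$pair_effects)[
    abs(unlist(truth$pair_effects)) > 0]
  tp <- sum(flags[active, , drop = FALSE])
  fn <- sum(!flags[active, , drop = FALSE])
  fp <- sum(flags[!active, , drop = FALSE])
  tn <- sum(!flags[!active, , drop = FALSE])
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_,
       flags = flags)
}
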