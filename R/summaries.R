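#' Posterior parameter summary
#'
#' One row per scalar parameter: posterior mean, SD, median, equal-tailed
#' 95\% credible interval, split-Rhat and effective sample size.
#'
#' @param fit a \code{bcnma_fit} (or a \code{coda::mcmc.list}).
#' @param params optional character vector restricting the parameters.
#' @return data.frame with columns \code{parameter}, \code{mean}, \code{sd},
#'   \code{median}, \code{lower}, \code{upper}, \code{rhat}, \code{ess}.
#' @export
summarize_fit <- function(fit, params = NULL) {
  draws <- if (inherits(fit, "bcnma_fit")) fit$draws else coda::as.mcmc.list(fit)
  mat <- as.matrix(draws)
  if (!is.null(params)) mat <- mat[, params, drop = FALSE]
  qs <- t(apply(mat, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975)))
  out <- data.frame(parameter = colnames(mat),
                    mean = colMeans(mat),
                    sd = apply(mat, 2L, stats::sd),
                    median = qs[, 1L], lower = qs[, 2L], upper = qs[, 3L],
                    row.names = NULL)
  diag <- if (inherits(fit, "bcnma_fit")) fit$diagnostics else convergence_diag(draws)
  idx <- match(out$parameter, diag$parameter)
  out$rhat <- diag$rhat[idx]
  out$ess <- diag$ess[idx]
  out
}

# Internal: does the fit parameterise at the component level?
fit_is_component <- function(fit) {
  if (!is.null(fit$spec$level)) fit$spec$level == "component"
  else isTRUE(fit$spec$component_level)
}

# Internal: per-draw relative effect of combination a vs b on the linear
# scale, including interaction terms and (optionally) effect modification
# at a centered covariate profile.
relative_effect_draws <- function(fit, a, b, profile = NULL) {
  catalog <- fit$catalog
  a <- as_combination(a, catalog); b <- as_combination(b, catalog)
  mat <- as.matrix(fit$draws)
  if (fit_is_component(fit)) {
    interactions <- fit$spec$interactions
    if (is.null(interactions)) interactions <- interaction_set(NULL, catalog)
    row <- contrast_design_row(b, a, catalog, interactions)
    main_cols <- paste0("d[", unclass(catalog), "]")
    pair_cols <- if (nrow(interactions)) paste0("dpair[", interactions$pair, "]")
    have_pairs <- !is.null(pair_cols) && all(pair_cols %in% colnames(mat))
    w <- row[seq_along(catalog)]
    eff <- as.numeric(mat[, main_cols, drop = FALSE] %*% w)
    if (nrow(interactions) && have_pairs) {
      wp <- row[interactions$pair]
      eff <- eff + as.numeric(mat[, pair_cols, drop = FALSE] %*% wp)
    }
    main_names <- unclass(catalog)
    grow <- contrast_design_row(b, a, catalog)
  } else {
    labs <- fit$main_params
    need <- setdiff(c(combination_label(a), combination_label(b)), labs)
    if (length(need))
      stop("combination(s) not in the fitted network: ",
           paste(need, collapse = "; "))
    row <- stats::setNames(numeric(length(labs)), labs)
    row[combination_label(a)] <- row[combination_label(a)] + 1
    row[combination_label(b)] <- row[combination_label(b)] - 1
    eff <- as.numeric(mat[, paste0("d[", labs, "]"), drop = FALSE] %*% row)
    main_names <- labs
    grow <- row
  }
  if (!is.null(profile)) {
    if (!length(fit$covariate_names))
      stop("fit has no covariates; cannot apply a patient profile")
    x <- as.numeric(profile[fit$covariate_names])
    if (any(is.na(x)))
      stop("profile must name every covariate: ",
           paste(fit$covariate_names, collapse = ", "))
    x <- x - as.numeric(fit$covariate_means[fit$covariate_names])
    gcols <- as.vector(outer(main_names, fit$covariate_names,
                             function(q, c) paste0("gamma[", q, ",", c, "]")))
    if (all(gcols %in% colnames(mat))) {
      G <- mat[, gcols, drop = FALSE]
      wg <- as.vector(outer(grow[main_names], x))
      eff <- eff + as.numeric(G %*% wg)
    } else if (any(abs(x) > 0)) {
      stop("fit has no effect-modification (gamma) draws; profile must equal ",
           "the covariate means")
    }
  }
  eff
}

#' Relative treatment effect between two combinations
#'
#' Summarizes, draw by draw, \eqn{\theta_A - \theta_B} (components +
#' admitted interactions, plus effect modification
#' \eqn{(\sum_{q \in A}\gamma_q - \sum_{q \in B}\gamma_q)'x} when a patient
#' profile is given), optionally exponentiated to an odds-ratio scale.
#' Positive values (OR > 1) favour combination \code{a} on the outcome's
#' natural direction — whether that is desirable depends on whether the
#' outcome is a benefit (e.g. remission) or a harm (e.g. a symptom score).
#'
#' @param fit a \code{bcnma_fit}.
#' @param a,b combination labels (or parsed combinations).
#' @param profile optional named vector of raw (uncentered) covariate
#'   values; it is centered by the constants stored in the fit.
#' @param scale \code{"auto"} (linear, i.e. the modelling scale),
#'   \code{"MD"}/\code{"logOR"} (linear) or \code{"OR"} (exponentiated).
#' @return object of class \code{relative_effect_estimate}: list with
#'   \code{comparison}, \code{scale}, \code{mean}, \code{median},
#'   \code{lower}, \code{upper}, \code{estimable}, \code{profile} and the
#'   underlying \code{draws}.
#' @export
relative_effect <- function(fit, a, b, profile = NULL,
                            scale = c("auto", "MD", "logOR", "OR")) {
  stopifnot(inherits(fit, "bcnma_fit"))
  scale <- match.arg(scale)
  eff <- relative_effect_draws(fit, a, b, profile)
  a <- as_combination(a, fit$catalog); b <- as_combination(b, fit$catalog)

  estimable <- TRUE
  ns <- fit$estimability$null_space
  if (ncol(ns)) {
    if (fit_is_component(fit)) {
      row <- contrast_design_row(b, a, fit$catalog, fit$spec$interactions)
    } else {
      row <- stats::setNames(numeric(length(fit$main_params)), fit$main_params)
      row[combination_label(a)] <- row[combination_label(a)] + 1
      row[combination_label(b)] <- row[combination_label(b)] - 1
    }
    common <- intersect(names(row), rownames(ns))
    estimable <- all(abs(crossprod(ns[common, , drop = FALSE],
                                   row[common])) < 1e-6)
  }
  if (scale == "OR") eff <- exp(eff)
  qs <- stats::quantile(eff, c(0.5, 0.025, 0.975))
  out <- structure(list(comparison = paste0("(", combination_label(a),
                                            ") vs (", combination_label(b), ")"),
                        scale = scale, mean = mean(eff), median = qs[[1L]],
                        lower = qs[[2L]], upper = qs[[3L]],
                        estimable = estimable, profile = profile,
                        draws = eff),
                   class = "relative_effect_estimate")
  if (!estimable)
    warning("contrast not estimable from the network design: ",
            "the posterior is prior-driven")
  out
}

#' @export
print.relative_effect_estimate <- function(x, digits = 2, ...) {
  cat(x$comparison, if (!is.null(x$profile)) " (at given profile)", "\n",
      sep = "")
  cat(sprintf("  %s: median %.*f (mean %.*f), 95%% CrI [%.*f; %.*f]%s\n",
              if (x$scale == "OR") "OR" else "effect",
              digits, x$median, digits, x$mean, digits, x$lower,
              digits, x$upper,
              if (!x$estimable) "  [INESTIMABLE: prior-driven]" else ""))
  invisible(x)
}

#' Batch patient-specific predictions
#'
#' Cross-product of patient profiles and combination comparisons, one
#' summarized relative effect per cell — the backend of a patient-facing
#' effect calculator.
#'
#' @param fit a \code{bcnma_fit}.
#' @param profiles data.frame of raw covariate profiles (one row each), or
#'   NULL for a single covariate-mean row.
#' @param comparisons list of length-2 vectors/lists \code{c(a, b)}.
#' @param scale as in \code{\link{relative_effect}}.
#' @return data.frame with one row per profile x comparison.
#' @export
prediction_table <- function(fit, profiles = NULL, comparisons,
                             scale = c("auto", "MD", "logOR", "OR")) {
  scale <- match.arg(scale)
  if (length(comparisons) == 0L)
    return(data.frame(profile = integer(0), comparison = character(0),
                      median = numeric(0), mean = numeric(0),
                      lower = numeric(0), upper = numeric(0),
                      estimable = logical(0)))
  if (is.null(profiles)) {
    profiles <- as.data.frame(as.list(fit$covariate_means))
    if (!ncol(profiles)) profiles <- data.frame(row.names = 1L)
  }
  out <- list()
  for (pi in seq_len(nrow(profiles))) {
    prof <- if (ncol(profiles)) unlist(profiles[pi, , drop = FALSE]) else NULL
    for (cmp in comparisons) {
      re <- suppressWarnings(
        relative_effect(fit, cmp[[1L]], cmp[[2L]], profile = prof,
                        scale = scale))
      out[[length(out) + 1L]] <- data.frame(
        profile = pi, comparison = re$comparison, median = re$median,
        mean = re$mean, lower = re$lower, upper = re$upper,
        estimable = re$estimable)
    }
  }
  do.call(rbind, out)
}
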