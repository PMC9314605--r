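#' Specify an aggregate-data (C)NMA model
#'
#' @param level \code{"component"} (treatment effects are sums of component
#'   effects, the CNMA assumption) or \code{"treatment"} (classic NMA: one
#'   parameter per distinct combination, the first in canonical order being
#'   the network reference).
#' @param interaction_mode how two-way component interactions enter:
#'   \code{"none"} (additive model), \code{"full"} (vague normal priors),
#'   \code{"ssvs"} (spike-and-slab with inclusion indicators) or
#'   \code{"lasso"} (Bayesian LASSO / double-exponential shrinkage).
#'   Requires \code{level = "component"}.
#' @param likelihood \code{"auto"} (inferred from the evidence type),
#'   \code{"contrast-normal"}, \code{"arm-binomial"} (logit link) or
#'   \code{"arm-normal"}.
#' @param priors a \code{\link{prior_config}}.
#' @param interactions an \code{\link{interaction_set}} of admitted pairs;
#'   when NULL and interactions are requested, every two-way pair is
#'   admitted with the default prior inclusion probability.
#' @return object of class \code{ad_model_spec}.
#' @export
ad_model_spec <- function(level = c("component", "treatment"),
                          interaction_mode = c("none", "full", "ssvs", "lasso"),
                          likelihood = c("auto", "contrast-normal",
                                         "arm-binomial", "arm-normal"),
                          priors = prior_config(), interactions = NULL) {
  level <- match.arg(level)
  interaction_mode <- match.arg(interaction_mode)
  likelihood <- match.arg(likelihood)
  stopifnot(inherits(priors, "prior_config"))
  if (interaction_mode != "none" && level != "component")
    stop("interaction modes require level = 'component'")
  structure(list(level = level, interaction_mode = interaction_mode,
                 likelihood = likelihood, priors = priors,
                 interactions = interactions),
            class = "ad_model_spec")
}

#' Fit a Bayesian (component) network meta-analysis to aggregate data
#'
#' Fits the random-effects network meta-analysis family to the aggregate
#' studies of a dataset: treatment-level NMA, additive CNMA, CNMA with full
#' two-way interactions, with spike-and-slab (SSVS) interaction selection,
#' or with Bayesian-LASSO interaction shrinkage. Likelihoods: normal on
#' contrast-level relative effects, or binomial-logit / normal on arm-level
#' summaries. Multi-arm studies use the consistency-preserving exchangeable
#' random-effects structure (variance \eqn{\tau^2}, covariance
#' \eqn{\tau^2/2}) via its sequential-conditional decomposition.
#'
#' For contrast-level multi-arm studies the contrasts share the reference
#' arm; if a \code{ref_se} is recorded the induced covariance
#' \code{ref_se^2} enters a multivariate normal likelihood, otherwise the
#' contrasts are treated as independent and a note is recorded in the fit
#' metadata.
#'
#' @param dataset a \code{\link{network_dataset}} with aggregate studies of
#'   a single evidence type (contrast-level or arm-level).
#' @param spec an \code{\link{ad_model_spec}}.
#' @param mcmc an \code{\link{mcmc_control}}.
#' @param seed integer seed driving all chains (mandatory, for
#'   reproducibility).
#' @return object of class \code{bcnma_fit}: \code{draws} (a
#'   \code{coda::mcmc.list} with labelled parameters \code{d[..]},
#'   \code{dpair[p:q]}, \code{I[p:q]}, \code{tau}, \code{mu[study]},
#'   \code{eta}, \code{lambda} as applicable), the estimability report,
#'   convergence diagnostics and run metadata.
#' @export
fit_ad <- function(dataset, spec = ad_model_spec(), mcmc = mcmc_control(),
                   seed) {
  stopifnot(inherits(dataset, "network_dataset"),
            inherits(spec, "ad_model_spec"), inherits(mcmc, "mcmc_control"))
  if (missing(seed)) stop("seed is required")
  seed <- as.integer(seed)

  has_contrast <- length(dataset$ad_contrast) > 0L
  has_arm <- length(dataset$ad_arm) > 0L
  if (!has_contrast && !has_arm) stop("dataset has no aggregate-data studies")
  if (has_contrast && has_arm)
    stop("mixed contrast-level and arm-level aggregate data: fit separately")
  lik <- spec$likelihood
  if (lik == "auto") {
    lik <- if (has_contrast) "contrast-normal"
           else if (dataset$ad_arm[[1L]]$outcome == "binary") "arm-binomial"
           else "arm-normal"
  }
  if (lik == "contrast-normal" && !has_contrast)
    stop("contrast-normal likelihood requires contrast-level studies")
  if (lik != "contrast-normal" && !has_arm)
    stop("arm-level likelihood requires arm-level studies")
  if (lik == "arm-binomial" && dataset$ad_arm[[1L]]$outcome != "binary")
    stop("arm-binomial likelihood requires binary arm data")
  if (lik == "arm-normal" && dataset$ad_arm[[1L]]$outcome != "continuous")
    stop("arm-normal likelihood requires continuous arm data")

  studies <- if (has_contrast) dataset$ad_contrast else dataset$ad_arm
  catalog <- dataset$catalog

  interactions <- spec$interactions
  if (spec$interaction_mode == "none") {
    interactions <- interaction_set(NULL, catalog)
  } else if (is.null(interactions)) {
    interactions <- all_pairs(catalog, spec$priors$inclusion_prior)
  }
  np <- nrow(interactions)

  # parameterisation: components (+pairs) or one parameter per combination
  sub <- dataset
  sub$ipd <- list()
  if (has_contrast) sub$ad_arm <- list() else sub$ad_contrast <- list()
  if (spec$level == "component") {
    design <- build_design(sub, interactions)
    param_names <- c(unclass(catalog), interactions$pair)
    row_fun <- function(ref, cb)
      contrast_design_row(ref, cb, catalog, interactions)
    fix_first <- FALSE
    n_main <- length(catalog)
  } else {
    design <- build_design(sub, interaction_set(NULL, catalog))
    labs <- sort(rownames(design$combination_matrix))
    param_names <- labs
    row_fun <- function(ref, cb) {
      v <- stats::setNames(numeric(length(labs)), labs)
      v[combination_label(cb)] <- v[combination_label(cb)] + 1
      v[combination_label(ref)] <- v[combination_label(ref)] - 1
      v
    }
    fix_first <- TRUE
    n_main <- length(labs)
  }
  est <- estimability(design)

  # ragged (study x arm) arrays
  ns <- length(studies)
  na <- vapply(studies, function(s) length(s$combos), 0L)
  maxk <- max(na)
  p_all <- n_main + if (spec$level == "component") np else 0L
  X <- array(0, dim = c(ns, maxk, p_all))
  for (i in seq_len(ns)) {
    cbs <- studies[[i]]$combos
    for (k in seq_along(cbs)[-1L])
      X[i, k, ] <- row_fun(cbs[[1L]], cbs[[k]])
  }

  data <- list(Ns = ns, na = na, Nc = n_main, X = X)
  notes <- design$warnings
  if (lik == "contrast-normal") {
    scales <- unique(vapply(studies, function(s) s$scale, ""))
    if (length(scales) > 1L)
      warning("mixed effect scales among contrast studies: ",
              paste(scales, collapse = ", "))
    y <- prec <- matrix(NA_real_, ns, maxk)
    ref_se <- vapply(studies, function(s) s$ref_se %||% 0, 0)
    for (i in seq_len(ns)) {
      y[i, 2:na[i]] <- studies[[i]]$y
      prec[i, 2:na[i]] <- 1 / studies[[i]]$se^2
    }
    use_mvn <- any(ref_se > 0)
    if (use_mvn) {
      Omega <- array(0, dim = c(ns, maxk - 1L, maxk - 1L))
      for (i in seq_len(ns)) {
        m <- na[i] - 1L
        V <- diag(studies[[i]]$se^2, m) + ref_se[i]^2
        Omega[i, 1:m, 1:m] <- solve(V)
      }
      data$Omega <- Omega
      data$y <- y
      lik_str <- paste0(
        "  for (i in 1:Ns) {\n",
        "    y[i, 2:na[i]] ~ dmnorm(delta[i, 2:na[i]],",
        " Omega[i, 1:(na[i]-1), 1:(na[i]-1)])\n",
        "  }\n")
    } else {
      if (any(na > 2L))
        notes <- c(notes, paste(
          "multi-arm contrast-level study without ref_se:",
          "contrasts treated as independent (approximation)"))
      data$y <- y
      data$precy <- prec
      lik_str <- paste0(
        "  for (i in 1:Ns) {\n",
        "    for (k in 2:na[i]) { y[i, k] ~ dnorm(delta[i, k], precy[i, k]) }\n",
        "  }\n")
    }
    baseline_str <- ""
    monitors <- character(0)
  } else {
    prec_base <- 1 / spec$priors$baseline_sd^2
    if (lik == "arm-binomial") {
      r <- nn <- matrix(NA_real_, ns, maxk)
      for (i in seq_len(ns)) {
        r[i, 1:na[i]] <- studies[[i]]$r
        nn[i, 1:na[i]] <- studies[[i]]$n
      }
      data$r <- r
      data$nn <- nn
      lik_str <- paste0(
        "  for (i in 1:Ns) {\n",
        "    for (k in 1:na[i]) {\n",
        "      r[i, k] ~ dbin(pr[i, k], nn[i, k])\n",
        "      logit(pr[i, k]) <- mu[i] + delta[i, k]\n",
        "    }\n",
        "  }\n")
    } else {
      ybar <- precbar <- matrix(NA_real_, ns, maxk)
      for (i in seq_len(ns)) {
        ybar[i, 1:na[i]] <- studies[[i]]$mean
        precbar[i, 1:na[i]] <- studies[[i]]$n / studies[[i]]$sd^2
      }
      data$ybar <- ybar
      data$precbar <- precbar
      lik_str <- paste0(
        "  for (i in 1:Ns) {\n",
        "    for (k in 1:na[i]) {\n",
        "      ybar[i, k] ~ dnorm(mu[i] + delta[i, k], precbar[i, k])\n",
        "    }\n",
        "  }\n")
    }
    baseline_str <- sprintf(
      "  for (i in 1:Ns) { mu[i] ~ dnorm(0, %.10g) }\n", prec_base)
    monitors <- "mu"
  }

  pair_active <- spec$level == "component" && np > 0L
  if (pair_active) {
    data$Np <- np
    if (spec$interaction_mode == "ssvs") data$p_incl <- interactions$prior_inclusion
  }
  model_string <- paste0(
    "model {\n",
    jags_re_contrast_block("delta", "X", "Ns", "na"),
    lik_str, baseline_str,
    jags_tau_block(spec$priors),
    jags_d_block(spec$priors, fix_first = fix_first),
    if (pair_active) jags_pair_block(spec$interaction_mode, spec$priors) else "",
    jags_dall_block(if (pair_active) np else 0L),
    "}\n")

  monitors <- c("d", "tau", monitors)
  if (pair_active) {
    monitors <- c(monitors, "dpair")
    if (spec$interaction_mode == "ssvs") {
      monitors <- c(monitors, "Ipair")
      if (is.null(spec$priors$eta_fixed)) monitors <- c(monitors, "eta")
    }
    if (spec$interaction_mode == "lasso" &&
        spec$priors$lambda_prior != "fixed") monitors <- c(monitors, "lambda")
  }

  rename <- c(
    stats::setNames(paste0("d[", param_names[seq_len(n_main)], "]"),
                    paste0("d[", seq_len(n_main), "]")),
    if (n_main == 1L) stats::setNames(paste0("d[", param_names[1L], "]"), "d"))
  if (pair_active) {
    rename <- c(rename,
      stats::setNames(paste0("dpair[", interactions$pair, "]"),
                      paste0("dpair[", seq_len(np), "]")),
      stats::setNames(paste0("I[", interactions$pair, "]"),
                      paste0("Ipair[", seq_len(np), "]")),
      if (np == 1L) stats::setNames(c(paste0("dpair[", interactions$pair, "]"),
                                      paste0("I[", interactions$pair, "]")),
                                    c("dpair", "Ipair")))
  }
  if (lik != "contrast-normal") {
    sids <- vapply(studies, function(s) s$study_id, "")
    rename <- c(rename, stats::setNames(paste0("mu[", sids, "]"),
                                        paste0("mu[", seq_len(ns), "]")))
  }

  spec$interactions <- interactions
  draws <- run_jags(model_string, data, monitors, mcmc, seed, rename)
  model_name <- paste0("AD ", if (spec$level == "treatment") "NMA" else
    paste0("CNMA/", spec$interaction_mode), ", ", lik)
  fit <- new_bcnma_fit(draws, model_name, dataset, design, est, spec, mcmc,
                       seed, extra_meta = list(likelihood = lik, notes = notes))
  fit$main_params <- param_names[seq_len(n_main)]
  fit
}

#' Posterior inclusion summary of an SSVS fit
#'
#' For each admitted interaction pair, the posterior inclusion frequency
#' (mean of the indicator draws — how often the interaction was in the
#' model) and the posterior mean coefficient. Plotting coefficient against
#' frequency gives the characteristic V-shaped selection scatter.
#'
#' @param fit a \code{bcnma_fit} from an SSVS model.
#' @return data.frame with columns \code{pair}, \code{inclusion_freq},
#'   \code{coef_mean}, \code{prior_inclusion}.
#' @export
ssvs_inclusion_summary <- function(fit) {
  stopifnot(inherits(fit, "bcnma_fit"))
  if (!identical(fit$spec$interaction_mode, "ssvs"))
    stop("ssvs_inclusion_summary requires a fit with interaction_mode = 'ssvs'")
  pairs <- fit$spec$interactions$pair
  mat <- as.matrix(fit$draws)
  data.frame(
    pair = pairs,
    inclusion_freq = colMeans(mat[, paste0("I[", pairs, "]"), drop = FALSE]),
    coef_mean = colMeans(mat[, paste0("dpair[", pairs, "]"), drop = FALSE]),
    prior_inclusion = fit$spec$interactions$prior_inclusion,
    row.names = NULL)
}
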