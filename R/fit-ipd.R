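#' Specify a one-stage joint AD + IPD (C)NMA model
#'
#' @param component_level TRUE for the component model (treatment effects
#'   are sums of component effects and, optionally, pair interactions);
#'   FALSE for the treatment-level model (one \eqn{d} and one
#'   effect-modification vector per distinct combination, the first in
#'   canonical order being the reference with both fixed at zero).
#' @param interaction_mode prior on component-pair interaction terms:
#'   \code{"none"}, \code{"ssvs"} or \code{"lasso"}; requires
#'   \code{component_level = TRUE}.
#' @param gamma_shrinkage prior on the component-covariate
#'   effect-modification coefficients \eqn{\gamma}: \code{"none"} (vague
#'   normal), \code{"ssvs"}, or \code{"conditional-laplace"} (requires
#'   \code{sigma_mode = "common"} and a continuous IPD outcome).
#' @param sigma_mode residual SD of the IPD likelihood: \code{"per-study"}
#'   (\eqn{\sigma_i}) or \code{"common"} (single \eqn{\sigma}).
#' @param ad_metaregression adjust the aggregate part by regressing on
#'   centered study-mean covariates: \eqn{y_i \sim N(\delta_i +
#'   \beta'\bar{x}_i, s_i^2)}.
#' @param priors a \code{\link{prior_config}}.
#' @param interactions an \code{\link{interaction_set}}; NULL with an
#'   interaction mode admits every pair.
#' @return object of class \code{ipd_model_spec}.
#' @export
ipd_model_spec <- function(component_level = TRUE,
                           interaction_mode = c("none", "ssvs", "lasso"),
                           gamma_shrinkage = c("none", "ssvs",
                                               "conditional-laplace"),
                           sigma_mode = c("per-study", "common"),
                           ad_metaregression = FALSE,
                           priors = prior_config(), interactions = NULL) {
  interaction_mode <- match.arg(interaction_mode)
  gamma_shrinkage <- match.arg(gamma_shrinkage)
  sigma_mode <- match.arg(sigma_mode)
  stopifnot(inherits(priors, "prior_config"))
  if (interaction_mode != "none" && !component_level)
    stop("component interactions require component_level = TRUE")
  if (gamma_shrinkage == "conditional-laplace" && sigma_mode != "common")
    stop("the conditional Laplace prior on gamma requires a common sigma ",
         "across IPD studies (sigma_mode = 'common')")
  structure(list(component_level = component_level,
                 interaction_mode = interaction_mode,
                 gamma_shrinkage = gamma_shrinkage, sigma_mode = sigma_mode,
                 ad_metaregression = ad_metaregression, priors = priors,
                 interactions = interactions),
            class = "ipd_model_spec")
}

#' Fit a one-stage joint aggregate-data + IPD (component) NMA
#'
#' Combines contrast-level aggregate studies and individual-participant
#' studies in one likelihood. Aggregate studies contribute
#' \eqn{y_i \sim N(\delta_i (+ \beta'\bar{x}_i), s_i^2)}; each IPD patient
#' contributes \eqn{y_{ik} \sim N(\alpha_i + \beta'x_{ik} + (\Gamma'
#' \Delta_{arm})'x_{ik} + \delta_{i,arm}, \sigma_i^2)} (Bernoulli-logit for
#' binary outcomes), where \eqn{\Delta_{arm}} is the component difference
#' between the arm and the study's reference arm. Both evidence types share
#' the second-level random effects \eqn{\delta \sim N(\theta_Y - \theta_X,
#' \tau^2)} — the marginal AD and conditional IPD estimates are pooled as
#' exchangeable. Covariates must be centered (done by
#' \code{\link{network_dataset}}), so \eqn{d}-based contrasts are effects at
#' the covariate means.
#'
#' Given an \code{imputed_network_list} (stacked pre-imputed IPD copies),
#' the model is fitted to each imputed dataset and the posterior draws are
#' mixed via \code{\link{mix_imputation_draws}}.
#'
#' @param dataset a \code{\link{network_dataset}} (or
#'   \code{imputed_network_list}); arm-level aggregate studies are not
#'   supported in joint fits — collapse them to contrasts first.
#' @param spec an \code{\link{ipd_model_spec}}.
#' @param mcmc an \code{\link{mcmc_control}}.
#' @param seed integer seed (per-imputation fits use \code{seed + imputation}).
#' @return a \code{bcnma_fit}; parameter blocks \code{d[..]},
#'   \code{dpair[p:q]}, \code{I[p:q]}, \code{tau}, \code{alpha[study]},
#'   \code{beta[cov]}, \code{gamma[comp,cov]}, \code{sigma} (or
#'   \code{sigma[study]}), \code{lambda_gamma}, \code{eta} as applicable.
#' @export
fit_joint <- function(dataset, spec = ipd_model_spec(), mcmc = mcmc_control(),
                      seed) {
  if (missing(seed)) stop("seed is required")
  seed <- as.integer(seed)
  if (inherits(dataset, "imputed_network_list")) {
    fits <- lapply(seq_along(dataset), function(m)
      fit_joint(dataset[[m]], spec, mcmc, seed = seed + m))
    return(mix_imputation_draws(fits))
  }
  stopifnot(inherits(dataset, "network_dataset"),
            inherits(spec, "ipd_model_spec"), inherits(mcmc, "mcmc_control"))
  if (length(dataset$ad_arm))
    stop("joint fits support contrast-level aggregate studies only; ",
         "collapse arm-level studies to contrasts first")
  if (!length(dataset$ipd) && !length(dataset$ad_contrast))
    stop("dataset has no usable studies")
  catalog <- dataset$catalog
  cov_names <- dataset$covariate_names
  ncov <- length(cov_names)

  ipd_outcomes <- unique(vapply(dataset$ipd, function(s) s$outcome, ""))
  if (length(ipd_outcomes) > 1L) stop("IPD studies mix outcome types")
  binary_ipd <- length(ipd_outcomes) && ipd_outcomes == "binary"
  if (binary_ipd && spec$gamma_shrinkage == "conditional-laplace")
    stop("conditional Laplace gamma shrinkage requires a continuous IPD outcome")

  interactions <- spec$interactions
  if (spec$interaction_mode == "none") {
    interactions <- interaction_set(NULL, catalog)
  } else if (is.null(interactions)) {
    interactions <- all_pairs(catalog, spec$priors$inclusion_prior)
  }
  np <- nrow(interactions)

  # parameterisation (shared with fit_ad): component level or one parameter
  # per distinct combination, reference combination fixed at zero
  if (spec$component_level) {
    design <- build_design(dataset, interactions)
    main_names <- unclass(catalog)
    full_row <- function(ref, cb) contrast_design_row(ref, cb, catalog, interactions)
    main_row <- function(ref, cb) contrast_design_row(ref, cb, catalog)
    fix_first <- FALSE
  } else {
    design <- build_design(dataset, interaction_set(NULL, catalog))
    labs <- sort(rownames(design$combination_matrix))
    main_names <- labs
    trow <- function(ref, cb) {
      v <- stats::setNames(numeric(length(labs)), labs)
      v[combination_label(cb)] <- v[combination_label(cb)] + 1
      v[combination_label(ref)] <- v[combination_label(ref)] - 1
      v
    }
    full_row <- main_row <- trow
    fix_first <- TRUE
  }
  est <- estimability(design)
  n_main <- length(main_names)
  pair_active <- spec$component_level && np > 0L
  p_all <- n_main + if (pair_active) np else 0L

  data <- list(Nc = n_main)
  model_parts <- character(0)
  monitors <- c("d", "tau")
  rename <- c(
    stats::setNames(paste0("d[", main_names, "]"), paste0("d[", seq_len(n_main), "]")),
    if (n_main == 1L) stats::setNames(paste0("d[", main_names[1L], "]"), "d"))

  # ---- aggregate part -------------------------------------------------
  nsA <- length(dataset$ad_contrast)
  if (nsA) {
    adc <- dataset$ad_contrast
    naA <- vapply(adc, function(s) length(s$combos), 0L)
    maxkA <- max(naA)
    XA <- array(0, dim = c(nsA, maxkA, p_all))
    yA <- precA <- matrix(NA_real_, nsA, maxkA)
    for (i in seq_len(nsA)) {
      for (k in seq_len(naA[i])[-1L])
        XA[i, k, ] <- full_row(adc[[i]]$combos[[1L]], adc[[i]]$combos[[k]])
      yA[i, 2:naA[i]] <- adc[[i]]$y
      precA[i, 2:naA[i]] <- 1 / adc[[i]]$se^2
    }
    data <- c(data, list(NsA = nsA, naA = naA, XA = XA, yA = yA, precA = precA))
    adreg <- "0"
    if (spec$ad_metaregression) {
      if (!ncov) stop("ad_metaregression requires covariates")
      xbar <- t(vapply(adc, function(s) {
        if (is.null(s$covariate_means))
          stop("study ", s$study_id, ": ad_metaregression needs study-mean ",
               "covariates for every aggregate study")
        as.numeric(s$covariate_means[cov_names])
      }, numeric(ncov)))
      data$xbarA <- xbar
      adreg <- "inprod(beta[], xbarA[i, ])"
    }
    model_parts <- c(model_parts,
      jags_re_contrast_block("deltaA", "XA", "NsA", "naA"),
      paste0("  for (i in 1:NsA) {\n",
             "    for (k in 2:naA[i]) {\n",
             "      yA[i, k] ~ dnorm(deltaA[i, k] + ", adreg, ", precA[i, k])\n",
             "    }\n  }\n"))
  }

  # ---- IPD part -------------------------------------------------------
  nsI <- length(dataset$ipd)
  if (nsI) {
    ipd <- dataset$ipd
    combos_by_study <- lapply(ipd, function(s) {
      cbs <- lapply(unique(s$patients$arm_label), parse_combination,
                    catalog = catalog)
      cbs[order_combinations(cbs, catalog)]
    })
    naI <- vapply(combos_by_study, length, 0L)
    maxkI <- max(naI)
    XI <- array(0, dim = c(nsI, maxkI, p_all))
    XM <- array(0, dim = c(nsI, maxkI, n_main))
    for (i in seq_len(nsI)) {
      cbs <- combos_by_study[[i]]
      for (k in seq_along(cbs)[-1L]) {
        XI[i, k, ] <- full_row(cbs[[1L]], cbs[[k]])
        XM[i, k, ] <- main_row(cbs[[1L]], cbs[[k]])
      }
    }
    pts <- do.call(rbind, lapply(seq_len(nsI), function(i) {
      s <- ipd[[i]]
      labs <- vapply(combos_by_study[[i]], combination_label, "")
      data.frame(stu = i, armk = match(s$patients$arm_label, labs),
                 y = s$patients$y,
                 s$patients[, s$covariate_names, drop = FALSE])
    }))
    data <- c(data, list(NsI = nsI, naI = naI, XI = XI, Npat = nrow(pts),
                         stu = pts$stu, armk = pts$armk, ypat = pts$y))
    if (ncov) {
      data$XM <- XM
      data$x <- as.matrix(pts[, cov_names, drop = FALSE])
      data$Ncov <- ncov
    }

    mean_terms <- c("alpha[stu[p]]",
                    if (ncov) "inprod(beta[], x[p, ])",
                    if (ncov) "inprod(gmod[stu[p], armk[p], ], x[p, ])",
                    "deltaI[stu[p], armk[p]]")
    mean_expr <- paste(mean_terms, collapse = " + ")
    lik_line <- if (binary_ipd) {
      paste0("    ypat[p] ~ dbern(ppat[p])\n",
             "    logit(ppat[p]) <- ", mean_expr, "\n")
    } else if (spec$sigma_mode == "common") {
      paste0("    ypat[p] ~ dnorm(", mean_expr, ", prec_pat)\n")
    } else {
      paste0("    ypat[p] ~ dnorm(", mean_expr, ", prec_pat[stu[p]])\n")
    }
    sigma_block <- if (binary_ipd) "" else if (spec$sigma_mode == "common") {
      sprintf("  sigma ~ dunif(0, %.10g)\n  prec_pat <- pow(sigma, -2)\n",
              spec$priors$sigma_unif_max)
    } else {
      sprintf(paste0("  for (i in 1:NsI) {\n",
                     "    sigma[i] ~ dunif(0, %.10g)\n",
                     "    prec_pat[i] <- pow(sigma[i], -2)\n  }\n"),
              spec$priors$sigma_unif_max)
    }
    gmod_block <- if (ncov) paste0(
      "  for (i in 1:NsI) {\n",
      "    for (k in 1:naI[i]) {\n",
      "      for (c in 1:Ncov) { gmod[i, k, c] <- inprod(XM[i, k, ], gam[, c]) }\n",
      "    }\n  }\n") else ""
    model_parts <- c(model_parts,
      jags_re_contrast_block("deltaI", "XI", "NsI", "naI"),
      sprintf("  for (i in 1:NsI) { alpha[i] ~ dnorm(0, %.10g) }\n",
              1 / spec$priors$baseline_sd^2),
      gmod_block,
      paste0("  for (p in 1:Npat) {\n", lik_line, "  }\n"),
      sigma_block,
      if (ncov) jags_gamma_block(spec, fix_first) else "")

    monitors <- c(monitors, "alpha",
                  if (!binary_ipd) "sigma",
                  if (ncov) "beta", if (ncov) "gam",
                  if (ncov && spec$gamma_shrinkage == "ssvs") "Igam",
                  if (ncov && spec$gamma_shrinkage == "ssvs" &&
                      is.null(spec$priors$eta_fixed)) "eta_g",
                  if (ncov && spec$gamma_shrinkage == "conditional-laplace" &&
                      spec$priors$lambda_prior != "fixed") "lambda_gamma")
    sids <- vapply(ipd, function(s) s$study_id, "")
    rename <- c(rename,
      stats::setNames(paste0("alpha[", sids, "]"), paste0("alpha[", seq_len(nsI), "]")),
      if (nsI == 1L) stats::setNames(paste0("alpha[", sids, "]"), "alpha"),
      if (!binary_ipd && spec$sigma_mode == "per-study")
        stats::setNames(paste0("sigma[", sids, "]"), paste0("sigma[", seq_len(nsI), "]")),
      if (!binary_ipd && spec$sigma_mode == "per-study" && nsI == 1L)
        stats::setNames(paste0("sigma[", sids, "]"), "sigma"))
    if (ncov) {
      rename <- c(rename,
        stats::setNames(paste0("beta[", cov_names, "]"),
                        paste0("beta[", seq_len(ncov), "]")),
        if (ncov == 1L) stats::setNames(paste0("beta[", cov_names, "]"), "beta"))
      gm <- expand.grid(q = seq_len(n_main), c = seq_len(ncov))
      rename <- c(rename,
        stats::setNames(paste0("gamma[", main_names[gm$q], ",", cov_names[gm$c], "]"),
                        paste0("gam[", gm$q, ",", gm$c, "]")),
        stats::setNames(paste0("Igamma[", main_names[gm$q], ",", cov_names[gm$c], "]"),
                        paste0("Igam[", gm$q, ",", gm$c, "]")))
    }
  } else if (spec$ad_metaregression && ncov) {
    # beta enters through the AD regression alone
    model_parts <- c(model_parts, "")
    monitors <- c(monitors, "beta")
    data$Ncov <- ncov
    rename <- c(rename, stats::setNames(paste0("beta[", cov_names, "]"),
                                        paste0("beta[", seq_len(ncov), "]")),
                if (ncov == 1L) stats::setNames(paste0("beta[", cov_names, "]"), "beta"))
  }
  if (ncov && (nsI || spec$ad_metaregression)) {
    model_parts <- c(model_parts,
      sprintf("  for (c in 1:Ncov) { beta[c] ~ dnorm(0, %.10g) }\n",
              1 / spec$priors$beta_sd^2))
  }

  if (pair_active) {
    data$Np <- np
    if (spec$interaction_mode == "ssvs") data$p_incl <- interactions$prior_inclusion
    monitors <- c(monitors, "dpair",
                  if (spec$interaction_mode == "ssvs") "Ipair",
                  if (spec$interaction_mode == "ssvs" &&
                      is.null(spec$priors$eta_fixed)) "eta",
                  if (spec$interaction_mode == "lasso" &&
                      spec$priors$lambda_prior != "fixed") "lambda")
    rename <- c(rename,
      stats::setNames(paste0("dpair[", interactions$pair, "]"),
                      paste0("dpair[", seq_len(np), "]")),
      stats::setNames(paste0("I[", interactions$pair, "]"),
                      paste0("Ipair[", seq_len(np), "]")),
      if (np == 1L) stats::setNames(c(paste0("dpair[", interactions$pair, "]"),
                                      paste0("I[", interactions$pair, "]")),
                                    c("dpair", "Ipair")))
  }

  model_string <- paste0(
    "model {\n", paste(model_parts, collapse = ""),
    jags_tau_block(spec$priors),
    jags_d_block(spec$priors, fix_first = fix_first),
    if (pair_active) jags_pair_block(spec$interaction_mode, spec$priors) else "",
    jags_dall_block(if (pair_active) np else 0L),
    "}\n")

  spec$interactions <- interactions
  draws <- run_jags(model_string, data, unique(monitors), mcmc, seed, rename)
  model_name <- paste0(
    if (nsA && nsI) "AD&IPD " else if (nsI) "IPD " else "AD ",
    if (spec$component_level) "CNMA" else "NMA",
    if (spec$interaction_mode != "none") paste0("/", spec$interaction_mode) else "",
    if (spec$gamma_shrinkage != "none") paste0(", gamma:", spec$gamma_shrinkage) else "")
  fit <- new_bcnma_fit(draws, model_name, dataset, design, est, spec, mcmc,
                       seed, extra_meta = list(binary_ipd = binary_ipd))
  fit$main_params <- main_names
  fit
}

# gamma prior block: vague normal, SSVS, or conditional Laplace (common
# sigma; rate lambda_gamma/sigma^2 by default, lambda_gamma/sigma under the
# "park-casella" convention). For the treatment-level model the reference
# combination's gamma row is fixed at zero, like its d.
jags_gamma_block <- function(spec, fix_first) {
  priors <- spec$priors
  qstart <- if (fix_first) 2L else 1L
  fix_line <- if (fix_first) "  for (c in 1:Ncov) { gam[1, c] <- 0 }\n" else ""
  if (spec$gamma_shrinkage == "none") {
    return(paste0(fix_line, sprintf(
      "  for (q in %d:Nc) { for (c in 1:Ncov) { gam[q, c] ~ dnorm(0, %.10g) } }\n",
      qstart, 1 / priors$gamma_sd^2)))
  }
  if (spec$gamma_shrinkage == "ssvs") {
    eta_line <- if (!is.null(priors$eta_fixed)) {
      sprintf("  eta_g <- %.10g\n", priors$eta_fixed)
    } else {
      sprintf("  eta_g ~ dnorm(0, %.10g) T(0,)\n", 1 / priors$eta_prior_sd^2)
    }
    return(paste0(fix_line, eta_line,
      "  prec_gspike <- pow(eta_g, -2)\n",
      sprintf("  prec_gslab <- prec_gspike / %.10g\n", priors$g^2),
      sprintf("  for (q in %d:Nc) { for (c in 1:Ncov) {\n", qstart),
      sprintf("    Igam[q, c] ~ dbern(%.10g)\n", priors$inclusion_prior),
      "    gam[q, c] ~ dnorm(0, (1 - Igam[q, c]) * prec_gspike + Igam[q, c] * prec_gslab)\n",
      "  } }\n"))
  }
  # conditional Laplace
  denom <- if (priors$laplace_convention == "sigma2") "pow(sigma, 2)" else "sigma"
  paste0(fix_line,
         jags_lambda_block(priors, "lambda_gamma"),
         "  rate_gamma <- lambda_gamma / ", denom, "\n",
         sprintf("  for (q in %d:Nc) { for (c in 1:Ncov) { gam[q, c] ~ ddexp(0, rate_gamma) } }\n",
                 qstart))
}

#' Mix posterior draws across multiply imputed datasets
#'
#' Pools the fits obtained on each pre-imputed copy of an IPD dataset by
#' concatenating their posterior draws: with m fits of n kept draws each,
#' the mixed posterior has m x n draws, and the mixed mean of any parameter
#' is the average of the per-fit means. All fits must share the same
#' parameter blocks (identical model specification).
#'
#' @param fits list of \code{bcnma_fit} objects, one per imputed dataset.
#' @return a \code{bcnma_fit} whose \code{draws} hold all chains of all
#'   fits; \code{meta$m_imputations} and \code{meta$imputation_seeds} record
#'   the mixing.
#' @export
mix_imputation_draws <- function(fits) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "bcnma_fit")))
  if (length(fits) == 1L) return(fits[[1L]])
  vn <- lapply(fits, function(f) coda::varnames(f$draws))
  if (length(unique(vapply(vn, paste, "", collapse = "|"))) != 1L)
    stop("fits have different parameter blocks; cannot mix")
  models <- unique(vapply(fits, function(f) f$model, ""))
  if (length(models) != 1L)
    stop("fits come from different model specifications; cannot mix")
  chains <- do.call(c, lapply(fits, function(f) unclass(f$draws)))
  mixed <- fits[[1L]]
  mixed$draws <- coda::as.mcmc.list(chains)
  mixed$diagnostics <- convergence_diag(mixed$draws)
  mixed$meta$m_imputations <- length(fits)
  mixed$meta$imputation_seeds <- vapply(fits, function(f) f$meta$seed, 0L)
  mixed
}
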