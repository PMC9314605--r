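#' MCMC run settings
#'
#' Defaults follow the standard heavy-duty setting for CNMA analyses of
#' real networks: 4 independent chains of 30000 kept iterations after
#' 10000 burn-in. For small synthetic networks far fewer iterations
#' suffice; examples and tests in this package use reduced settings.
#'
#' @param iterations kept iterations per chain.
#' @param burnin burn-in iterations per chain (discarded).
#' @param chains number of independent chains.
#' @param thin thinning interval.
#' @param adapt JAGS adaptation steps.
#' @return object of class \code{mcmc_control}.
#' @export
mcmc_control <- function(iterations = 30000, burnin = 10000, chains = 4,
                         thin = 1, adapt = 500) {
  stopifnot(iterations > 0, burnin >= 0, chains >= 1, thin >= 1, adapt >= 0)
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), chains = as.integer(chains),
                 thin = as.integer(thin), adapt = as.integer(adapt)),
            class = "mcmc_control")
}

# Internal: compile and run a JAGS model; returns a renamed mcmc.list.
# `rename` maps JAGS variable names (e.g. "d[2]") to user-facing labels.
run_jags <- function(model_string, data, monitors, mcmc, seed, rename = NULL) {
  con <- textConnection(model_string)
  on.exit(close(con), add = TRUE)
  model <- rjags::jags.model(con, data = data,
                             inits = jags_inits(seed, mcmc$chains),
                             n.chains = mcmc$chains, n.adapt = mcmc$adapt,
                             quiet = TRUE)
  if (mcmc$burnin > 0) stats::update(model, mcmc$burnin, progress.bar = "none")
  draws <- rjags::coda.samples(model, monitors, n.iter = mcmc$iterations,
                               thin = mcmc$thin, progress.bar = "none")
  if (!is.null(rename)) {
    draws <- coda::as.mcmc.list(lapply(draws, function(ch) {
      vn <- coda::varnames(ch)
      hit <- vn %in% names(rename)
      vn[hit] <- rename[vn[hit]]
      colnames(ch) <- vn
      ch
    }))
  }
  draws
}

# Internal: split-Rhat of one parameter. Each chain is split in half, and
# the classic potential-scale-reduction factor is computed over the halves;
# constant series give 1 by convention.
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- floor(length(x) / 2)
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  n <- length(halves[[1L]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B_over_n <- stats::var(means)
  if (!is.finite(W) || W <= 0) {
    return(if (max(means) - min(means) < 1e-12) 1 else NA_real_)
  }
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

# Internal: convergence diagnostics. Returns a data.frame
# parameter/rhat/ess; rhat is NA when fewer than two half-chains exist.
convergence_diag <- function(draws) {
  vn <- coda::varnames(draws)
  ess <- tryCatch(coda::effectiveSize(draws),
                  error = function(e) rep(NA_real_, length(vn)))
  rhat <- vapply(vn, function(v) {
    split_rhat(lapply(draws, function(ch) as.numeric(ch[, v])))
  }, 0)
  data.frame(parameter = vn, rhat = unname(rhat), ess = as.numeric(ess[vn]))
}

# Internal: construct the fit container shared by fit_ad and fit_joint.
new_bcnma_fit <- function(draws, model, dataset, design, est_report, spec,
                          mcmc, seed, extra_meta = list()) {
  diag <- convergence_diag(draws)
  worst <- suppressWarnings(max(diag$rhat, na.rm = TRUE))
  if (is.finite(worst) && worst > 1.01)
    warning(sprintf("possible non-convergence: max split-Rhat = %.3f", worst))
  structure(list(draws = draws, model = model, spec = spec,
                 catalog = design$catalog,
                 interactions = design$interactions,
                 estimability = est_report,
                 covariate_names = dataset$covariate_names,
                 covariate_means = dataset$covariate_means,
                 diagnostics = diag,
                 meta = c(list(seed = seed, chains = mcmc$chains,
                               iterations = mcmc$iterations,
                               burnin = mcmc$burnin, thin = mcmc$thin),
                          extra_meta)),
            class = "bcnma_fit")
}

#' @export
print.bcnma_fit <- function(x, ...) {
  cat("Bayesian CNMA fit (", x$model, ")\n", sep = "")
  cat("  chains x kept iterations: ", x$meta$chains, " x ",
      x$meta$iterations, " (seed ", x$meta$seed, ")\n", sep = "")
  worst <- suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE))
  if (is.finite(worst)) cat("  max split-Rhat: ", round(worst, 3), "\n", sep = "")
  if (length(x$estimability$inestimable))
    cat("  WARNING: inestimable direction(s) involve ",
        paste(x$estimability$inestimable, collapse = ", "),
        "; their posteriors reproduce the priors\n", sep = "")
  cat("  parameters: ", paste(utils::head(coda::varnames(x$draws), 8L),
                              collapse = ", "),
      if (coda::nvar(x$draws) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}
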