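# Shared builders for small in-code fixtures.

cat6 <- component_catalog(paste0("c", 1:6))
cat2 <- component_catalog(c("c1", "c2"))

# quick two-arm contrast study
cstudy <- function(id, ref, other, y, se, catalog = cat6, ...) {
  ad_contrast_study(id, list(ref, other), y = y, se = se, scale = "MD",
                    catalog = catalog, ...)
}

# a small connected contrast-level network over 4 components
small_contrast_network <- function() {
  cat4 <- component_catalog(paste0("c", 1:4))
  studies <- list(
    cstudy("s1", "c1", "c2", 0.4, 0.2, cat4),
    cstudy("s2", "c1", "c1 + c2", 0.6, 0.25, cat4),
    cstudy("s3", "c2", "c3", -0.2, 0.2, cat4),
    cstudy("s4", "c3", "c4", 0.1, 0.3, cat4),
    ad_contrast_study("s5", list("c1", "c2", "c3"), y = c(0.3, 0.2),
                      se = c(0.2, 0.25), scale = "MD", catalog = cat4))
  network_dataset(cat4, ad_contrast = studies)
}

# IPD study with two arms and two covariates
small_ipd_study <- function(id = "i1", n = 30, catalog = cat2, seed = 99,
                            arms = c("c1", "c2")) {
  set.seed(seed)
  pat <- data.frame(
    patient_id = sprintf("%s_p%02d", id, seq_len(2 * n)),
    arm_label = rep(arms, each = n),
    y = rnorm(2 * n),
    x1 = rnorm(2 * n), x2 = rbinom(2 * n, 1, 0.5))
  ipd_study(id, pat, c("x1", "x2"), catalog)
}

# fast MCMC settings for tests
fast_mcmc <- function(iterations = 1500, burnin = 500, chains = 2) {
  mcmc_control(iterations, burnin, chains, adapt = 300)
}

# Monte-Carlo standard error of a posterior mean from an mcmc.list column
mcse_of <- function(fit, param) {
  ess <- fit$diagnostics$ess[fit$diagnostics$parameter == param]
  sdv <- stats::sd(as.matrix(fit$draws)[, param])
  sdv / sqrt(max(ess, 1))
}
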