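# Internal JAGS model-string builders shared by the AD and joint samplers.
# Each returns a character fragment; fit functions assemble them into a
# complete model block. Hyperparameters are inlined as constants so the
# data list stays small and model strings are self-describing.

jags_tau_block <- function(priors) {
  switch(priors$tau_prior,
    "lognormal" = sprintf(
      "  tau2 ~ dlnorm(%.10g, %.10g)\n  tau <- sqrt(tau2)\n  prec_tau <- 1/tau2\n",
      priors$tau_lnorm_mean, 1 / priors$tau_lnorm_sd^2),
    "half-normal" = sprintf(
      "  tau ~ dnorm(0, %.10g) T(0,)\n  prec_tau <- pow(tau, -2)\n",
      1 / priors$tau_hn_sd^2),
    "uniform" = sprintf(
      "  tau ~ dunif(0, %.10g)\n  prec_tau <- pow(tau, -2)\n",
      priors$tau_unif_max))
}

# Main-effect block. fix_first zeroes the first parameter (treatment-level
# reference); at the component level all d get the vague prior.
jags_d_block <- function(priors, fix_first = FALSE) {
  prec <- 1 / priors$d_sd^2
  if (fix_first) {
    sprintf("  d[1] <- 0\n  for (q in 2:Nc) { d[q] ~ dnorm(0, %.10g) }\n", prec)
  } else {
    sprintf("  for (q in 1:Nc) { d[q] ~ dnorm(0, %.10g) }\n", prec)
  }
}

# Interaction-coefficient block: full (vague normal), SSVS spike-and-slab
# with Bernoulli inclusion indicators, or Bayesian-LASSO double exponential.
# Expects data: Np (>0), and for SSVS a vector p_incl[1:Np].
jags_pair_block <- function(mode, priors) {
  if (mode == "full") {
    return(sprintf("  for (j in 1:Np) { dpair[j] ~ dnorm(0, %.10g) }\n",
                   1 / priors$d_sd^2))
  }
  if (mode == "ssvs") {
    eta_line <- if (!is.null(priors$eta_fixed)) {
      sprintf("  eta <- %.10g\n", priors$eta_fixed)
    } else {
      sprintf("  eta ~ dnorm(0, %.10g) T(0,)\n", 1 / priors$eta_prior_sd^2)
    }
    return(paste0(
      eta_line,
      "  prec_spike <- pow(eta, -2)\n",
      sprintf("  prec_slab <- prec_spike / %.10g\n", priors$g^2),
      "  for (j in 1:Np) {\n",
      "    Ipair[j] ~ dbern(p_incl[j])\n",
      "    prec_pair[j] <- (1 - Ipair[j]) * prec_spike + Ipair[j] * prec_slab\n",
      "    dpair[j] ~ dnorm(0, prec_pair[j])\n",
      "  }\n"))
  }
  if (mode == "lasso") {
    return(paste0(
      jags_lambda_block(priors, "lambda"),
      "  for (j in 1:Np) { dpair[j] ~ ddexp(0, lambda) }\n"))
  }
  stop("unknown interaction mode: ", mode)
}

jags_lambda_block <- function(priors, name = "lambda") {
  switch(priors$lambda_prior,
    "inverse-uniform" = sprintf(
      "  inv%s ~ dunif(0, %.10g)\n  %s <- 1/inv%s\n",
      name, priors$lambda_inv_max, name, name),
    "inverse-half-normal" = sprintf(
      "  inv%s ~ dnorm(0, %.10g) T(0,)\n  %s <- 1/inv%s\n",
      name, 1 / priors$lambda_inv_hn_sd^2, name, name),
    "fixed" = sprintf("  %s <- %.10g\n", name, priors$lambda_fixed))
}

jags_dall_block <- function(n_pairs) {
  s <- "  for (q in 1:Nc) { dall[q] <- d[q] }\n"
  if (n_pairs > 0L)
    s <- paste0(s, "  for (j in 1:Np) { dall[Nc + j] <- dpair[j] }\n")
  s
}

# Random-effects contrast block for one evidence group, using the standard
# sequential-conditional decomposition of the exchangeable multivariate
# normal (variance tau^2, covariance tau^2/2) so multi-arm studies preserve
# consistency. `dname` is the per-(study,arm) random-effect node; `Xname`
# the 3D design array; indices i over 1:<Ns var>, arms 2:<na var>[i].
jags_re_contrast_block <- function(dname, Xname, ns_var, na_var) {
  sprintf(paste0(
    "  for (i in 1:%s) {\n",
    "    %s_w[i, 1] <- 0\n",
    "    %s[i, 1] <- 0\n",
    "    for (k in 2:%s[i]) {\n",
    "      %s_fix[i, k] <- inprod(%s[i, k, ], dall[])\n",
    "      %s[i, k] ~ dnorm(%s_fix[i, k] + %s_sw[i, k], %s_taud[i, k])\n",
    "      %s_taud[i, k] <- prec_tau * 2 * (k - 1) / k\n",
    "      %s_w[i, k] <- %s[i, k] - %s_fix[i, k]\n",
    "      %s_sw[i, k] <- sum(%s_w[i, 1:(k - 1)]) / (k - 1)\n",
    "    }\n",
    "  }\n"),
    ns_var, dname, dname, na_var, dname, Xname, dname, dname, dname, dname,
    dname, dname, dname, dname, dname, dname)
}

# Derive reproducible per-chain JAGS RNG initialisations from one seed.
jags_inits <- function(seed, chains) {
  lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed * 11L + ch) %% 2147483646L + 1L)
  })
}
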