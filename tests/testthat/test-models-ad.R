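test_that("aggregate likelihood contributions match closed forms", {
  s <- cstudy("s", "c1", "c2", y = 0.4, se = 0.2)
  # at y = delta the normal log density is maximal: -log(se * sqrt(2*pi))
  expect_equal(loglik_ad(s, list(delta = 0.4)), -log(0.2 * sqrt(2 * pi)),
               tolerance = 1e-12)
  b <- ad_arm_study("b", list("c1", "c2"), "binary", r = c(10, 12),
                    n = c(20, 30), catalog = cat6)
  # p = 0.5 in arm 1: log C(20,10) + 20 log(0.5) for that arm
  ll <- loglik_ad(b, list(baseline = 0, theta = c(0, qlogis(0.3) - 0)))
  expect_equal(ll, dbinom(10, 20, 0.5, log = TRUE) +
                 dbinom(12, 30, 0.3, log = TRUE), tolerance = 1e-12)
  # link algebra: two-arm log OR between arms equals theta difference
  mu <- 0.3; dd <- 0.9
  p <- plogis(mu + c(0, dd))
  expect_equal(qlogis(p[2]) - qlogis(p[1]), dd, tolerance = 1e-12)
  expect_error(loglik_ad(b, list(baseline = 0, theta = c(0.1, 0))), "theta")
})

test_that("multi-arm random-effects covariance is exchangeable and PD", {
  expect_equal(multiarm_re_covariance(0.25, 2), matrix(0.25, 1, 1))
  expect_equal(multiarm_re_covariance(0.36, 3),
               matrix(c(0.36, 0.18, 0.18, 0.36), 2, 2))
  for (k in 2:6) {
    ev <- eigen(multiarm_re_covariance(0.5, k), symmetric = TRUE,
                only.values = TRUE)$values
    expect_true(all(ev > 0))
  }
  expect_error(multiarm_re_covariance(0.1, 1), "k_arms")
  expect_error(multiarm_re_covariance(-0.1, 2), "tau2")
})

test_that("additive fit equals the interaction fit with every pair excluded", {
  ds <- small_contrast_network()
  ctrl <- fast_mcmc(500, 200)
  f_add <- suppressWarnings(
    fit_ad(ds, ad_model_spec("component", "none"), ctrl, seed = 3))
  empty <- interaction_set(NULL, ds$catalog)
  f_exc <- suppressWarnings(
    fit_ad(ds, ad_model_spec("component", "full", interactions = empty),
           ctrl, seed = 3))
  expect_equal(as.matrix(f_add$draws), as.matrix(f_exc$draws))
})

test_that("fits are reproducible under the same seed and settings", {
  ds <- small_contrast_network()
  ctrl <- fast_mcmc(400, 100)
  f1 <- suppressWarnings(fit_ad(ds, ad_model_spec(), ctrl, seed = 11))
  f2 <- suppressWarnings(fit_ad(ds, ad_model_spec(), ctrl, seed = 11))
  expect_equal(as.matrix(f1$draws), as.matrix(f2$draws))
  f3 <- suppressWarnings(fit_ad(ds, ad_model_spec(), ctrl, seed = 12))
  expect_false(isTRUE(all.equal(as.matrix(f1$draws), as.matrix(f3$draws))))
})

test_that("spec/likelihood mismatches are rejected", {
  ds <- small_contrast_network()
  expect_error(ad_model_spec("treatment", "ssvs"), "component")
  expect_error(fit_ad(ds, ad_model_spec(likelihood = "arm-binomial"),
                      fast_mcmc(), seed = 1), "arm-level")
  expect_error(fit_ad(ds, ad_model_spec(), fast_mcmc()), "seed")
  b <- ad_arm_study("b", list("c1", "c2"), "continuous", mean = c(0, 1),
                    sd = c(1, 1), n = c(10, 10), catalog = cat6)
  dsb <- network_dataset(cat6, ad_arm = list(b))
  expect_error(fit_ad(dsb, ad_model_spec(likelihood = "arm-binomial"),
                      fast_mcmc(), seed = 1), "binary")
})

test_that("ssvs summary requires an ssvs fit and reports frequencies in [0,1]", {
  ds <- small_contrast_network()
  ints <- interaction_set(data.frame(comp1 = "c1", comp2 = "c2"), ds$catalog)
  ctrl <- fast_mcmc(600, 200)
  f_add <- suppressWarnings(fit_ad(ds, ad_model_spec(), ctrl, seed = 2))
  expect_error(ssvs_inclusion_summary(f_add), "ssvs")
  f <- suppressWarnings(
    fit_ad(ds, ad_model_spec("component", "ssvs", interactions = ints),
           ctrl, seed = 2))
  s <- ssvs_inclusion_summary(f)
  expect_equal(s$pair, "c1:c2")
  expect_true(all(s$inclusion_freq >= 0 & s$inclusion_freq <= 1))
})

test_that("arm-binomial and contrast-normal fits of the same data agree", {
  # two-arm binary studies, moderate event counts; contrasts = empirical
  # logOR with its large-sample SE
  set.seed(7)
  arm_studies <- list(); con_studies <- list()
  pool <- c("c1", "c2", "c1 + c2")
  for (i in 1:14) {
    arms <- sample(pool, 2)
    p <- plogis(rnorm(2, 0, 0.7))
    n <- c(200, 200)
    r <- pmin(pmax(rbinom(2, n, p), 5), n - 5)
    arm_studies[[i]] <- ad_arm_study(paste0("s", i), as.list(arms), "binary",
                                     r = r, n = n, catalog = cat2)
    lor <- qlogis(r[2] / n[2]) - qlogis(r[1] / n[1])
    se <- sqrt(sum(1 / r + 1 / (n - r)))
    con_studies[[i]] <- cstudy(paste0("s", i), arms[1], arms[2], lor, se, cat2)
  }
  ctrl <- fast_mcmc(2500, 500)
  fa <- suppressWarnings(fit_ad(network_dataset(cat2, ad_arm = arm_studies),
               ad_model_spec(), ctrl, seed = 5))
  fc <- suppressWarnings(fit_ad(network_dataset(cat2, ad_contrast = con_studies),
               ad_model_spec(), ctrl, seed = 5))
  ra <- relative_effect(fa, "c1 + c2", "c1")
  rc <- relative_effect(fc, "c1 + c2", "c1")
  expect_lt(abs(ra$mean - rc$mean), 0.15)
})

test_that("inestimable directions reproduce their priors", {
  # c1 and c2 always co-administered: the difference d1 - d2 is flat;
  # its posterior must match the prior N(0, 2 * d_sd^2)
  set.seed(21)
  ds <- network_dataset(component_catalog(c("c1", "c2", "c3")),
    ad_contrast = lapply(1:6, function(i)
      cstudy(paste0("s", i), "c3", "c1 + c2", rnorm(1, 0.5, 0.1), 0.2,
             component_catalog(c("c1", "c2", "c3")))))
  pr <- prior_config(d_sd = 2)
  # thinned long run: the flat direction is a slow-mixing random walk under
  # Gibbs, so decorrelate before comparing its draws with the prior
  f <- suppressWarnings(
    fit_ad(ds, ad_model_spec(priors = pr),
           mcmc_control(20000, 2000, 2, thin = 10, adapt = 500), seed = 8))
  m <- as.matrix(f$draws)
  flat <- m[, "d[c1]"] - m[, "d[c2]"]
  # prior of the flat direction: N(0, 2 * 2^2); KS distance to the prior cdf
  ks <- suppressWarnings(ks.test(flat, "pnorm", 0, sqrt(2 * 2^2)))
  expect_lt(unname(ks$statistic), 0.05)
  # while the estimable sum is data-driven (far tighter than its prior)
  expect_lt(sd(m[, "d[c1]"] + m[, "d[c2]"] - m[, "d[c3]"]), 0.5)
})
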