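test_that("spike and slab log densities match the closed-form normal", {
  # spike at the mode: sd 0.1
  expect_equal(spike_slab_logdensity(0, 0, eta = 0.1),
               log(1 / (0.1 * sqrt(2 * pi))), tolerance = 1e-10)
  # slab at the mode: sd = g * eta = 10
  expect_equal(spike_slab_logdensity(0, 1, eta = 0.1, g = 100),
               log(1 / (10 * sqrt(2 * pi))), tolerance = 1e-10)
  # general point, independent closed form
  expect_equal(spike_slab_logdensity(0.7, 1, eta = 0.2, g = 50),
               dnorm(0.7, 0, 10, log = TRUE), tolerance = 1e-12)
  expect_error(spike_slab_logdensity(0, 0, eta = -1), "eta")
  # marginal mixture arithmetic
  expect_equal(spike_slab_marginal_logdensity(0, eta = 0.1, g = 100, p = 0.5),
               log(0.5 * dnorm(0, 0, 0.1) + 0.5 * dnorm(0, 0, 10)),
               tolerance = 1e-12)
})

test_that("spike and slab components each integrate to one", {
  for (sd_pair in list(c(0.1, 100), c(0.05, 20))) {
    spike <- integrate(function(d) exp(spike_slab_logdensity(d, 0, sd_pair[1],
                                                             sd_pair[2])),
                       -Inf, Inf, rel.tol = 1e-12)
    slab <- integrate(function(d) exp(spike_slab_logdensity(d, 1, sd_pair[1],
                                                            sd_pair[2])),
                      -Inf, Inf, rel.tol = 1e-12)
    expect_equal(spike$value, 1, tolerance = 1e-8)
    expect_equal(slab$value, 1, tolerance = 1e-8)
  }
})

test_that("indicator full conditional equals the density-ratio formula", {
  # frozen value from the closed-form ratio at d = 0, eta 0.1, g 100, p 0.5:
  # phi(0;0,10^2) / (phi(0;0,10^2) + phi(0;0,0.1^2)) = 0.039894/(0.039894+3.989423)
  expect_equal(indicator_full_conditional(0, 0.1, 100, 0.5),
               0.0099009901, tolerance = 1e-8)
  # direct ratio formula at arbitrary points
  for (d in c(-0.4, 0.05, 1.3)) {
    p <- 0.37; eta <- 0.12; g <- 40
    direct <- p * dnorm(d, 0, g * eta) /
      (p * dnorm(d, 0, g * eta) + (1 - p) * dnorm(d, 0, eta))
    expect_equal(indicator_full_conditional(d, eta, g, p), direct,
                 tolerance = 1e-12)
  }
  # limit: slab dominates for large |d| (and stays finite/stable)
  expect_equal(indicator_full_conditional(50, 0.1, 100, 0.5), 1,
               tolerance = 1e-12)
  # monotone in |d| and in the prior probability
  ds <- seq(0, 2, by = 0.1)
  ps <- indicator_full_conditional(ds, 0.1, 100, 0.5)
  expect_true(all(diff(ps) >= 0))        # saturates at 1 for large |d|
  expect_true(all(diff(ps[ds <= 0.6]) > 0))
  expect_true(all(ps >= 0 & ps <= 1))
  expect_gt(indicator_full_conditional(0, 0.1, 100, 0.8),
            indicator_full_conditional(0, 0.1, 100, 0.5))
})

test_that("laplace log density matches its closed form and normalizes", {
  expect_equal(laplace_logdensity(0, 2), log(1), tolerance = 1e-12)
  expect_equal(laplace_logdensity(1, 2), log(1) - 2, tolerance = 1e-12)
  expect_error(laplace_logdensity(0, 0), "lambda")
  # quadrature oracle at lambda = 0.7
  q <- integrate(function(d) exp(laplace_logdensity(d, 0.7)), -Inf, Inf,
                 rel.tol = 1e-12)
  expect_equal(q$value, 1, tolerance = 1e-8)
})

test_that("conditional laplace follows the chosen exponent convention", {
  # zero coefficients: only the normalizing constants remain
  expect_equal(conditional_laplace_logdensity(c(0, 0), lambda = 1.3, sigma = 2),
               2 * log(1.3 / 4), tolerance = 1e-12)
  # per-coordinate scaling of the default (sigma^2 exponent) form
  g1 <- conditional_laplace_logdensity(0.5, 2, 1.5)
  g2 <- conditional_laplace_logdensity(1.0, 2, 1.5)
  expect_equal(g2 - g1, -2 * 0.5 / 1.5^2, tolerance = 1e-12)
  # normalization: the park-casella convention integrates to 1 ...
  pc <- integrate(function(g) vapply(g, function(gi) exp(
    conditional_laplace_logdensity(gi, 1.7, 2.2, "park-casella")), 0),
    -Inf, Inf, rel.tol = 1e-12)
  expect_equal(pc$value, 1, tolerance = 1e-8)
  # ... while the printed sigma^2 form integrates to sigma, not 1
  s2 <- integrate(function(g) vapply(g, function(gi) exp(
    conditional_laplace_logdensity(gi, 1.7, 2.2, "sigma2")), 0),
    -Inf, Inf, rel.tol = 1e-12)
  expect_equal(s2$value, 2.2, tolerance = 1e-6)
  # requires the common-sigma model
  expect_error(conditional_laplace_logdensity(0, 1, 1, common_sigma = FALSE),
               "common sigma")
})

test_that("prior configuration validates and loads from YAML", {
  expect_error(prior_config(g = 0.5))
  expect_error(prior_config(inclusion_prior = 1))
  expect_error(prior_config(lambda_prior = "fixed"), "lambda_fixed")
  cfg <- prior_config()
  expect_equal(cfg$tau_lnorm_mean, -1.67)
  expect_equal(cfg$tau_lnorm_sd, 1.472)
  expect_equal(cfg$lambda_inv_max, 5)
  expect_equal(cfg$g, 100)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("d_sd: 3", "g: 25", "tau_prior: uniform"), path)
  got <- read_prior_config(path)
  expect_equal(got$d_sd, 3)
  expect_equal(got$g, 25)
  expect_equal(got$tau_prior, "uniform")
  writeLines("not_a_key: 1", path)
  expect_error(read_prior_config(path), "unknown prior key")
})

test_that("pair specification files support exclusion and elevated priors", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(comp1 = c("c1", "c1", "c2"),
                       comp2 = c("c2", "c3", "c3"),
                       prior_inclusion = c(0.8, 0, NA)),
            path, row.names = FALSE)
  s <- read_interaction_set(path, cat6)
  expect_equal(nrow(s), 2L)  # the 0-prior pair is excluded up front
  expect_equal(s$prior_inclusion[s$pair == "c1:c2"], 0.8)
  expect_equal(s$prior_inclusion[s$pair == "c2:c3"], 0.5)
})
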