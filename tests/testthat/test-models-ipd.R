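test_that("IPD patient likelihood reduces correctly in special cases", {
  G <- matrix(c(0.4, 0, -0.2, 0.1), 2, 2,
              dimnames = list(c("c1", "c2"), c("x1", "x2")))
  # x = 0: gamma and beta drop out entirely; mean = alpha (+ delta off-ref)
  ll <- loglik_ipd_patient(1.2, c(0, 0), "c2", "c1", alpha = 1.2,
                           beta = c(9, 9), gamma = G, delta = 0, sigma = 1,
                           catalog = cat2)
  expect_equal(ll, dnorm(0, log = TRUE), tolerance = 1e-12)
  # gamma == 0: identical to the no-effect-modification likelihood
  G0 <- G * 0
  x <- c(0.7, 1)
  ll0 <- loglik_ipd_patient(0.5, x, "c2", "c1", 0.1, c(0.5, -0.3), G0,
                            delta = 0.4, sigma = 1.5, catalog = cat2)
  expect_equal(ll0, dnorm(0.5, 0.1 + sum(c(0.5, -0.3) * x) + 0.4, 1.5,
                          log = TRUE), tolerance = 1e-12)
  # same combination in both roles: gamma terms cancel, only delta remains
  llsame <- loglik_ipd_patient(0, x, "c1", "c1", 0, c(0, 0), G, delta = 0.3,
                               sigma = 1, catalog = cat2)
  expect_equal(llsame, dnorm(0, 0.3, 1, log = TRUE), tolerance = 1e-12)
  expect_error(loglik_ipd_patient(0, c(1, 2, 3), "c1", "c2", 0, c(0, 0), G,
                                  0, 1, cat2), "length mismatch")
})

test_that("aggregate meta-regression adjustment follows the switch", {
  expect_equal(ad_metaregression_mean(0.5, c(1, -1), c(0, 0)), 0.5)
  expect_equal(ad_metaregression_mean(0.5, c(1, -1), c(0.5, 0.5)), 0.5)
  expect_equal(ad_metaregression_mean(0.5, c(2, 1), c(0.3, -0.1)),
               0.5 + 0.5, tolerance = 1e-12)
  expect_equal(ad_metaregression_mean(0.7, c(2, 1), c(9, 9), adjust = FALSE),
               0.7)
  expect_error(ad_metaregression_mean(0, 1, NULL), "required")
})

test_that("spec invariants of the joint model are enforced", {
  expect_error(ipd_model_spec(gamma_shrinkage = "conditional-laplace",
                              sigma_mode = "per-study"), "common sigma")
  expect_error(ipd_model_spec(component_level = FALSE,
                              interaction_mode = "ssvs"), "component_level")
  ok <- ipd_model_spec(gamma_shrinkage = "conditional-laplace",
                       sigma_mode = "common")
  expect_s3_class(ok, "ipd_model_spec")
})

test_that("imputation draws mix by concatenation", {
  tr <- synthetic_truth(n_ipd = 2, patients_per_arm = 15)
  ds <- simulate_ipd(tr, seed = 31)
  ctrl <- fast_mcmc(400, 150, chains = 1)
  fits <- lapply(1:3, function(m)
    suppressWarnings(fit_joint(ds, ipd_model_spec(), ctrl, seed = 100 + m)))
  mixed <- mix_imputation_draws(fits)
  expect_equal(coda::niter(mixed$draws) * coda::nchain(mixed$draws),
               3 * 400)
  expect_equal(mixed$meta$m_imputations, 3L)
  # mixed mean = average of per-fit means (equal draw counts)
  p <- "d[c1]"
  permeans <- vapply(fits, function(f) mean(as.matrix(f$draws)[, p]), 0)
  expect_equal(mean(as.matrix(mixed$draws)[, p]), mean(permeans),
               tolerance = 1e-10)
  # identity for m = 1
  expect_identical(mix_imputation_draws(fits[1]), fits[[1]])
  # block mismatch rejected
  f_other <- suppressWarnings(
    fit_joint(ds, ipd_model_spec(sigma_mode = "common"), ctrl, seed = 200))
  expect_error(mix_imputation_draws(list(fits[[1]], f_other)), "cannot mix")
})

test_that("joint fit recovers IPD generating parameters", {
  tr <- synthetic_truth(n_ipd = 8, patients_per_arm = 50)
  ds <- simulate_ipd(tr, seed = 17)
  f <- suppressWarnings(fit_joint(ds, ipd_model_spec(interaction_mode = "ssvs",
                                    interactions = interaction_set(
                                      data.frame(comp1 = "c1", comp2 = "c2"),
                                      tr$catalog)),
                 fast_mcmc(1500, 500), seed = 17))
  s <- summarize_fit(f)
  check <- c("beta[x1]" = unname(tr$beta["x1"]),
             "beta[x2]" = unname(tr$beta["x2"]),
             "gamma[c1,x1]" = tr$gamma["c1", "x1"])
  for (p in names(check)) {
    row <- s[s$parameter == p, ]
    expect_lt(abs(row$mean - check[[p]]), 3 * row$sd)
  }
  # residual SDs close to truth
  sig <- s[grepl("^sigma", s$parameter), ]
  expect_true(all(abs(sig$mean - tr$sigma) < 4 * sig$sd + 0.1))
})

test_that("gamma shrinkage pulls null effect modification towards zero", {
  tr <- synthetic_truth(n_ipd = 6, patients_per_arm = 40)
  tr$gamma[] <- 0  # all true gamma null
  ds <- simulate_ipd(tr, seed = 23)
  ctrl <- fast_mcmc(1200, 400)
  f_un <- suppressWarnings(
    fit_joint(ds, ipd_model_spec(gamma_shrinkage = "none",
                                 sigma_mode = "common"), ctrl, seed = 4))
  f_sh <- suppressWarnings(
    fit_joint(ds, ipd_model_spec(gamma_shrinkage = "conditional-laplace",
                                 sigma_mode = "common"), ctrl, seed = 4))
  gcols <- grep("^gamma\\[", coda::varnames(f_un$draws), value = TRUE)
  sum_un <- mean(rowSums(abs(as.matrix(f_un$draws)[, gcols])))
  sum_sh <- mean(rowSums(abs(as.matrix(f_sh$draws)[, gcols])))
  expect_lt(sum_sh, sum_un)
})

test_that("joint AD+IPD evidence is more precise than either part alone", {
  tr <- synthetic_truth(n_ipd = 5, patients_per_arm = 40,
                        n_two_arm = 15, n_three_arm = 0)
  ad <- simulate_ad(tr, seed = 41)
  ipd <- simulate_ipd(tr, seed = 42)
  both <- ipd
  both$ad_contrast <- ad$ad_contrast
  ctrl <- fast_mcmc(1200, 400)
  spec <- ipd_model_spec()
  f_ad <- suppressWarnings(fit_joint(ad, spec, ctrl, seed = 6))
  f_ipd <- suppressWarnings(fit_joint(ipd, spec, ctrl, seed = 6))
  f_both <- suppressWarnings(fit_joint(both, spec, ctrl, seed = 6))
  sd_of <- function(f, p) sd(as.matrix(f$draws)[, p])
  # pooled evidence tightens the posterior of an estimable main effect
  expect_lt(sd_of(f_both, "d[c1]"), sd_of(f_ad, "d[c1]") + 1e-9)
  expect_lt(sd_of(f_both, "d[c1]"), sd_of(f_ipd, "d[c1]") + 1e-9)
})

test_that("conditional estimates at the covariate means equal d-based contrasts", {
  tr <- synthetic_truth(n_ipd = 4, patients_per_arm = 25)
  ds <- simulate_ipd(tr, seed = 55)
  f <- suppressWarnings(
    fit_joint(ds, ipd_model_spec(), fast_mcmc(500, 200), seed = 9))
  plain <- suppressWarnings(relative_effect(f, "c1 + c2", "c3"))
  at_means <- suppressWarnings(
    relative_effect(f, "c1 + c2", "c3", profile = f$covariate_means))
  expect_equal(plain$draws, at_means$draws, tolerance = 1e-10)
})
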