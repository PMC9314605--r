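# Build a deterministic fake fit with known draws for arithmetic checks.
fake_fit <- function(dmat, catalog = cat2, pairs = NULL, cov_names = character(0),
                     cov_means = setNames(numeric(0), character(0))) {
  ints <- if (is.null(pairs)) interaction_set(NULL, catalog) else pairs
  draws <- coda::as.mcmc.list(list(coda::mcmc(dmat)))
  structure(list(draws = draws, model = "fake",
                 spec = list(level = "component", interactions = ints),
                 catalog = catalog, interactions = ints,
                 estimability = list(null_space =
                   matrix(0, length(catalog) + nrow(ints), 0,
                          dimnames = list(c(unclass(catalog), ints$pair), NULL)),
                   inestimable = character(0)),
                 covariate_names = cov_names, covariate_means = cov_means,
                 diagnostics = data.frame(parameter = colnames(dmat),
                                          rhat = NA_real_, ess = nrow(dmat)),
                 meta = list(seed = 0), main_params = unclass(catalog)),
            class = "bcnma_fit")
}

test_that("summaries report exact quantities for degenerate draws", {
  m <- matrix(3.5, nrow = 50, ncol = 1, dimnames = list(NULL, "d[c1]"))
  m <- cbind(m, "d[c2]" = 0)
  f <- fake_fit(m)
  s <- summarize_fit(f)
  r <- s[s$parameter == "d[c1]", ]
  expect_equal(r$mean, 3.5)
  expect_equal(r$median, 3.5)
  expect_equal(c(r$lower, r$upper), c(3.5, 3.5))
})

test_that("credible intervals match the quantile oracle for normal draws", {
  set.seed(123)
  m <- matrix(rnorm(2e5), ncol = 1, dimnames = list(NULL, "d[c1]"))
  f <- fake_fit(cbind(m, "d[c2]" = 0))
  s <- summarize_fit(f, params = "d[c1]")
  expect_equal(s$lower, -1.96, tolerance = 0.02)
  expect_equal(s$upper, 1.96, tolerance = 0.02)
})

test_that("identical chains give split-Rhat of one", {
  ch <- coda::mcmc(matrix(rnorm(500), ncol = 1,
                          dimnames = list(NULL, "x")))
  d <- coda::as.mcmc.list(list(ch, ch))
  diag <- bcnma:::convergence_diag(d)
  expect_equal(diag$rhat, 1, tolerance = 0.02)
})

test_that("relative effects do fixed-draw arithmetic exactly", {
  m <- matrix(c(1, 2), nrow = 1, dimnames = list(NULL, c("d[c1]", "d[c2]")))
  f <- fake_fit(m)
  re <- relative_effect(f, "c1 + c2", "c1")
  expect_equal(re$median, 2)
  expect_equal(re$mean, 2)
  # self-comparison: zero effect, OR 1, zero-width interval
  same <- relative_effect(f, "c1", "c1", scale = "OR")
  expect_equal(same$median, 1)
  expect_equal(c(same$lower, same$upper), c(1, 1))
})

test_that("relative effects are antisymmetric, transitive and padding-invariant", {
  tr <- synthetic_truth(n_two_arm = 12, n_three_arm = 0)
  ds <- simulate_ad(tr, seed = 19)
  f <- suppressWarnings(
    fit_ad(ds, ad_model_spec("component", "ssvs",
                             interactions = interaction_set(
                               data.frame(comp1 = "c1", comp2 = "c2"),
                               tr$catalog)),
           fast_mcmc(400, 150), seed = 19))
  ab <- relative_effect(f, "c1 + c2", "c3")
  ba <- relative_effect(f, "c3", "c1 + c2")
  expect_equal(ab$draws, -ba$draws, tolerance = 1e-12)
  # OR scale is the reciprocal
  ab_or <- relative_effect(f, "c1 + c2", "c3", scale = "OR")
  expect_equal(ab_or$median, exp(ab$median), tolerance = 1e-5)
  # transitivity draw by draw
  ac <- relative_effect(f, "c1 + c2", "c4")
  cb <- relative_effect(f, "c4", "c3")
  expect_equal(ab$draws, ac$draws + cb$draws, tolerance = 1e-12)
  # adding a shared component changes nothing
  ab2 <- relative_effect(f, "c1 + c2 + c5", "c3 + c5")
  expect_equal(ab$draws, ab2$draws, tolerance = 1e-12)
})

test_that("patient profiles shift effects through gamma", {
  m <- matrix(c(1, 0.5, 0.4, -0.2), nrow = 1,
              dimnames = list(NULL, c("d[c1]", "d[c2]",
                                      "gamma[c1,x1]", "gamma[c2,x1]")))
  f <- fake_fit(m, cov_names = "x1", cov_means = c(x1 = 10))
  # raw profile x1 = 12 -> centered 2; effect = (d1 - d2) + 2*(g1 - g2)
  re <- relative_effect(f, "c1", "c2", profile = c(x1 = 12))
  expect_equal(re$median, (1 - 0.5) + 2 * (0.4 - (-0.2)), tolerance = 1e-12)
  # at the covariate mean the gamma term vanishes
  re0 <- relative_effect(f, "c1", "c2", profile = c(x1 = 10))
  expect_equal(re0$median, 0.5, tolerance = 1e-12)
  expect_error(relative_effect(f, "c1", "c2", profile = c(zz = 1)),
               "every covariate")
})

test_that("prediction tables cross profiles with comparisons", {
  m <- matrix(c(1, 0.5, 0.4, -0.2), nrow = 1,
              dimnames = list(NULL, c("d[c1]", "d[c2]",
                                      "gamma[c1,x1]", "gamma[c2,x1]")))
  f <- fake_fit(m, cov_names = "x1", cov_means = c(x1 = 0))
  tab <- prediction_table(f, data.frame(x1 = c(0, 1)),
                          list(c("c1", "c2"), c("c2", "c1"), c("c1", "c1")))
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$median[tab$profile == 1][1], 0.5)
  # empty comparison list -> empty table
  expect_equal(nrow(prediction_table(f, NULL, list())), 0L)
})
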