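test_that("contrast design rows follow the signed-membership rule", {
  cat4 <- component_catalog(paste0("c", 1:4))
  # disjoint combinations: -1 on X's components, +1 on Y's
  r <- contrast_design_row("c1 + c2", "c3 + c4", cat4)
  expect_equal(unname(r), c(-1, -1, 1, 1))
  # self-comparison: zero vector
  expect_equal(unname(contrast_design_row("c1 + c2", "c1 + c2", cat4)),
               rep(0, 4))
  # shared component cancels; pair appears only on the side having both
  ints <- interaction_set(data.frame(comp1 = "c1", comp2 = "c2"), cat4)
  r2 <- contrast_design_row("c1", "c1 + c2", cat4, ints)
  expect_equal(unname(r2), c(0, 1, 0, 0, 1))
})

test_that("design rows are antisymmetric and transitive", {
  set.seed(42)
  ints <- all_pairs(cat6)
  combos <- replicate(12, {
    k <- sample(1:4, 1)
    combination_label(parse_combination(
      paste(sample(unclass(cat6), k), collapse = "+"), cat6))
  })
  for (i in 1:10) {
    abc <- sample(combos, 3)
    rxy <- contrast_design_row(abc[1], abc[2], cat6, ints)
    ryx <- contrast_design_row(abc[2], abc[1], cat6, ints)
    expect_equal(rxy, -ryx)
    rxz <- contrast_design_row(abc[1], abc[3], cat6, ints)
    ryz <- contrast_design_row(abc[2], abc[3], cat6, ints)
    expect_equal(rxz, rxy + ryz)
  }
})

test_that("build_design stacks one row per non-reference arm", {
  ds <- small_contrast_network()
  d <- build_design(ds)
  # 4 two-arm studies + 1 three-arm study -> 6 contrast rows
  expect_equal(nrow(d$contrast_rows), 6L)
  expect_equal(ncol(d$contrast_rows), 4L)
  # with admitted pairs the interaction columns are appended
  ints <- interaction_set(data.frame(comp1 = "c1", comp2 = "c2"), ds$catalog)
  d2 <- build_design(ds, ints)
  expect_equal(colnames(d2$contrast_rows),
               c(paste0("c", 1:4), "c1:c2"))
  # a pair never co-occurring in an arm is warned about
  ints3 <- interaction_set(data.frame(comp1 = "c3", comp2 = "c4"), ds$catalog)
  d3 <- build_design(ds, ints3)
  expect_match(d3$warnings, "never co-occur")
})

test_that("interaction sets validate and canonicalize pairs", {
  expect_error(interaction_set(data.frame(comp1 = "c1", comp2 = "zz"), cat6),
               "unknown")
  expect_error(interaction_set(data.frame(comp1 = "c1", comp2 = "c1"), cat6),
               "identical")
  s <- interaction_set(data.frame(comp1 = "c3", comp2 = "c1"), cat6)
  expect_identical(s$pair, "c1:c3")
  expect_equal(nrow(all_pairs(cat6)), choose(6, 2))
})

test_that("estimability matches a brute-force rank oracle on toy designs", {
  # saturated toy network: all 4 subsets of {c1, c2} pairwise compared
  ints <- interaction_set(data.frame(comp1 = "c1", comp2 = "c2"), cat2)
  subsets <- list(character(0), "c1", "c2", c("c1", "c2"))
  memb <- function(s) c(as.numeric(c("c1", "c2") %in% s),
                        as.numeric(all(c("c1", "c2") %in% s)))
  # independent oracle: enumerate all pairwise difference rows, qr() rank
  oracle_rows <- do.call(rbind, apply(utils::combn(4, 2), 2, function(ij)
    memb(subsets[[ij[2]]]) - memb(subsets[[ij[1]]]), simplify = FALSE))
  expect_equal(qr(oracle_rows)$rank, 3L)

  # the non-empty subsets alone span only rank 2 of the 3 parameters
  # (d1 + d2 + d12 is confounded without a no-treatment arm), and the
  # package's numerical rank must agree with the qr() oracle on its rows
  labels <- c("c1", "c2", "c1 + c2")
  studies <- list()
  k <- 0
  for (i in 1:3) for (j in seq_len(3)[-seq_len(i)]) {
    k <- k + 1
    studies[[k]] <- cstudy(paste0("t", k), labels[i], labels[j], 0.1, 0.2, cat2)
  }
  ds <- network_dataset(cat2, ad_contrast = studies)
  est <- estimability(build_design(ds, ints),
                      queries = list(c("c1 + c2", "c1"), c("c2", "c1")))
  own_rows <- do.call(rbind, apply(utils::combn(3, 2), 2, function(ij)
    memb(strsplit(labels[ij[2]], " \\+ ")[[1]]) -
      memb(strsplit(labels[ij[1]], " \\+ ")[[1]]), simplify = FALSE))
  expect_equal(est$rank, qr(own_rows)$rank)
  # every comparison actually made stays estimable despite the deficiency
  expect_true(all(est$queries$estimable))

  # without the interaction column the same network is full rank
  est2 <- estimability(build_design(ds))
  expect_equal(est2$rank, 2L)
  expect_length(est2$inestimable, 0L)
})

test_that("always-co-administered components are individually inestimable", {
  ds <- network_dataset(cat6, ad_contrast = list(
    cstudy("s1", "c3", "c1 + c2", 0.5, 0.2),
    cstudy("s2", "c1 + c2", "c4", -0.1, 0.2),
    cstudy("s3", "c3", "c4", 0.2, 0.2)))
  est <- estimability(build_design(ds),
                      queries = list(c("c1", "c2"), c("c1 + c2", "c3")))
  expect_true(all(c("c1", "c2") %in% est$inestimable))
  # d1 - d2 inestimable, but the sum (via the compared combination) is fine
  expect_false(est$queries$estimable[1])
  expect_true(est$queries$estimable[2])
})

test_that("a component constant within every study has an all-zero column", {
  ds <- network_dataset(cat6, ad_contrast = list(
    cstudy("s1", "c5 + c1", "c5 + c2", 0.1, 0.2),
    cstudy("s2", "c5 + c2", "c5 + c3", 0.0, 0.2)))
  d <- build_design(ds)
  expect_equal(unname(d$contrast_rows[, "c5"]), c(0, 0))
  est <- estimability(d)
  expect_true("c5" %in% est$inestimable)
})

test_that("comparisons made within a study are always estimable", {
  ds <- small_contrast_network()
  d <- build_design(ds)
  queries <- list(c("c1", "c2"), c("c1", "c1 + c2"), c("c2", "c3"),
                  c("c3", "c4"))
  est <- estimability(d, queries = queries)
  expect_true(all(est$queries$estimable))
})
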