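test_that("delta notation conversion follows its definition", {
  expect_equal(delta_from_ratios(0.0111802, 0.0111802), 0)
  expect_equal(delta_from_ratios(1.01 * 0.0111802, 0.0111802), 10,
               tolerance = 1e-12)
  # hand arithmetic: (0.0108/0.0111802 - 1) * 1000
  expect_equal(delta_from_ratios(0.0108, 0.0111802), -34.0083,
               tolerance = 1e-4)
  expect_error(delta_from_ratios(-0.01), "positive")
  expect_error(delta_from_ratios(0.01, 0), "positive")
})

test_that("abundance-weighted side means are correct and bounded", {
  expect_equal(weighted_side_delta(5, -30), -30)
  expect_equal(weighted_side_delta(c(1, 3), c(-30, -34)), -33)
  expect_equal(weighted_side_delta(c(2, 3, 5), c(-31, -33, -35)), -33.6)
  # invariant to uniform rescaling; bounded by the delta extremes
  set.seed(42)
  for (i in 1:20) {
    ab <- runif(5, 0.1, 10)
    dl <- runif(5, -40, -25)
    w <- weighted_side_delta(ab, dl)
    expect_equal(weighted_side_delta(ab * 7.3, dl), w, tolerance = 1e-12)
    expect_gte(w, min(dl))
    expect_lte(w, max(dl))
  }
  expect_error(weighted_side_delta(numeric(0), numeric(0)), "one compound")
  expect_error(weighted_side_delta(c(0, 0), c(-30, -31)), "positive")
  expect_error(weighted_side_delta(c(-1, 2), c(-30, -31)), "non-negative")
})

test_that("leaf polarity is the difference of weighted side means", {
  same <- side_df(c(2, 3), c(-31, -33))
  expect_equal(leaf_polarity(same, same)$polarity, 0)
  expect_equal(
    leaf_polarity(side_df(1, -31), side_df(1, -30))$polarity, 1)
  res <- leaf_polarity(side_df(c(2, 3), c(-32, -34)),
                       side_df(c(2, 3), c(-31, -33)))
  expect_equal(res$polarity, 1.0, tolerance = 1e-12)
  expect_equal(res$delta_ad_weighted, -33.2)
  expect_equal(res$delta_ab_weighted, -32.2)
})

test_that("shared-compound pairing restricts both sides or errors", {
  ad <- side_df(c(1, 1), c(-32, -40), c("C29", "C31"))
  ab <- side_df(c(1, 1), c(-31, -10), c("C29", "C33"))
  res <- leaf_polarity(ad, ab, shared_only = TRUE)
  expect_equal(res$polarity, 1)  # only C29 used
  expect_equal(unname(res$n_compounds_used), c(1L, 1L))
  disjoint <- side_df(1, -30, "C27")
  expect_error(leaf_polarity(ad, disjoint, shared_only = TRUE),
               "No shared compounds.*C27")
})

test_that("post-stomatal boundary composition is linear in ci/ca", {
  expect_equal(boundary_delta(-8.5, 4.4, 0.75), -9.6)
  expect_equal(boundary_delta(-8.5, 4.4, 1), -8.5)
  expect_equal(boundary_delta(-8.0, 4.4, 0.5), -10.2)
  # slope +frac_a per unit of ci/ca
  r <- seq(0, 1, 0.25)
  expect_equal(diff(boundary_delta(-8.5, 4.4, r)) / diff(r),
               rep(4.4, 4))
  expect_error(boundary_delta(-8.5, 4.4, 1.2), "\\[0, 1\\]")
})

test_that("drawdown inversion reproduces hand-computed values", {
  expect_equal(co2_drawdown(-30, 0), 0)
  expect_equal(co2_drawdown(-30, 1), 1 / 15, tolerance = 1e-12)
  expect_equal(co2_drawdown(-30, -1), -1 / 17, tolerance = 1e-12)
  expect_equal(polarity_from_drawdown(0, -30), 0)
  expect_equal(polarity_from_drawdown(1 / 15, -30), 1, tolerance = 1e-12)
  expect_equal(polarity_from_drawdown(-1 / 17, -30), -1,
               tolerance = 1e-12)
})

test_that("forward and inverse drawdown round-trip to 1e-10", {
  set.seed(7)
  for (i in 1:200) {
    dl <- runif(1, -41, -26)
    p <- runif(1, -2, 2)
    if (p == 0) next
    N <- dl - (-9.6) + 4.4
    if (abs(N / p) <= 1 + 1e-6) next
    D <- co2_drawdown(dl, p)
    expect_equal(polarity_from_drawdown(D, dl), p, tolerance = 1e-10)
    # sign law in the physical leaf regime (N < 0)
    if (N < 0) expect_equal(sign(D), sign(p))
  }
})

test_that("non-physical polarity is rejected with diagnostics", {
  # delta_leaf = -14 gives N = -14 + 9.6 + 4.4 = 0 -> |N/p| = 0
  err <- tryCatch(co2_drawdown(-14, 1), error = identity)
  expect_s3_class(err, "amphistomy_nonphysical")
  expect_equal(err$polarity, 1)
  expect_equal(err$N, 0)
  # |polarity| slightly above |N| is also rejected
  expect_error(co2_drawdown(-30, 16.5), class = "amphistomy_nonphysical")
})

test_that("inferred CO2 ratio is insensitive to the boundary value", {
  expect_equal(boundary_sensitivity(-30, 1, perturbation = 0), 0)
  # hand computation at delta_l = -28, polarity = 1.5, delta_b = -9.6:
  # D = 0.12; shifting delta_b to -8.6 gives D = 1/9 (0.79 % ratio
  # change) and to -10.6 gives D = 1.5/11.5 (0.93 %); both signs are
  # scanned so the larger one is returned
  expect_equal(boundary_sensitivity(-28, 1.5, perturbation = 1),
               (1.5 / 11.5 - 0.12) / 1.12, tolerance = 1e-10)
  grid_max <- boundary_sensitivity(
    seq(-41, -28, 0.5), c(-seq(0.1, 1.5, 0.1), seq(0.1, 1.5, 0.1)))
  expect_lt(grid_max, 0.01)
})

test_that("intercellular CO2 back-calculation hits its limits", {
  p <- disc_params()
  # delta_leaf at which bulk discrimination equals frac_a (c_i = 0)
  dl0 <- (p$delta_air - p$frac_a) / (1 + p$frac_a / 1000)
  expect_equal(ci_from_bulk_delta(dl0), 0, tolerance = 1e-9)
  dl1 <- (p$delta_air - p$frac_b) / (1 + p$frac_b / 1000)
  expect_equal(ci_from_bulk_delta(dl1), p$c_a, tolerance = 1e-9)
  expect_equal(ci_from_bulk_delta(-28.26), 258.3, tolerance = 0.001)
  # strictly decreasing in delta_leaf over the unclamped band:
  # more negative leaf delta -> larger c_i
  dl <- seq(-37, -16, 0.5)
  expect_true(all(diff(ci_from_bulk_delta(dl)) < 0))
  expect_warning(ci_from_bulk_delta(-5), "clamped")
})

test_that("polarity_table aggregates per leaf and joins bulk delta", {
  compounds <- data.frame(
    leaf_id = rep(c("L1", "L2"), each = 4),
    side = rep(c("adaxial", "adaxial", "abaxial", "abaxial"), 2),
    compound = rep(c("C29", "C31"), 4),
    abundance = rep(c(2, 3), 4),
    delta_permil = c(-32, -34, -31, -33, -33, -35, -33, -35))
  leaves <- data.frame(leaf_id = c("L1", "L2"),
                       delta_leaf = c(-30, -30))
  out <- polarity_table(compounds, leaves)
  expect_equal(out$leaf_id, c("L1", "L2"))
  expect_equal(out$polarity, c(1, 0))
  expect_equal(out$drawdown, c(1 / 15, 0), tolerance = 1e-12)
  expect_equal(out$ratio, 1 + out$drawdown)
  expect_error(polarity_table(compounds, leaves[1, ]), "lacks leaf_id")
})

test_that("enrichment counting flags adaxially enriched instances", {
  tbl <- data.frame(delta_ad_permil = c(-30, -33, -31.5),
                    delta_ab_permil = c(-31, -32, -31.6))
  res <- enrichment_sign_count(tbl)
  expect_equal(res$n_total, 3L)
  expect_equal(res$n_adaxial_enriched, 2L)
  expect_equal(res$adaxial_enriched, c(TRUE, FALSE, TRUE))
})
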