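test_that("amphistomy level matches its definition and limits", {
  expect_equal(asl(0, 200), 0)
  expect_equal(asl(150, 150), 0.5)
  expect_equal(asl(50, 150), 0.25)
  expect_equal(asl(200, 0), 1)
  expect_error(asl(0, 0), "undefined")
  expect_error(asl(-1, 10), "non-negative")
})

test_that("amphiwaxy level matches its definition", {
  expect_equal(awl(3, 3), 0.5)
  expect_equal(awl(2, 1), 2 / 3)
  expect_equal(awl(0.9, 8.1), 0.1)
  expect_error(awl(0, 1), "positive")
  expect_error(awl(1, -2), "positive")
})

test_that("side patterning fractions are exchange-antisymmetric", {
  set.seed(11)
  x <- runif(25, 1, 400)
  y <- runif(25, 1, 400)
  expect_equal(asl(x, y) + asl(y, x), rep(1, 25), tolerance = 1e-12)
  expect_equal(awl(x, y) + awl(y, x), rep(1, 25), tolerance = 1e-12)
})

test_that("coupling regression matches hand-computed fits", {
  f <- fit_coupling(c(1, 2, 3), c(2, 4, 6))
  expect_equal(f$slope_k, 2, tolerance = 1e-12)
  expect_equal(f$intercept_a, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  f <- fit_coupling(c(1, 2, 3), c(1, 3, 4))
  expect_equal(f$slope_k, 1.5, tolerance = 1e-12)
  expect_equal(f$intercept_a, -1 / 3, tolerance = 1e-12)
  expect_equal(f$r_squared, 27 / 28, tolerance = 1e-12)
  f <- fit_coupling(c(1, 2, 3), c(5, 5, 5))
  expect_equal(f$slope_k, 0, tolerance = 1e-12)
  expect_equal(f$intercept_a, 5, tolerance = 1e-12)
  expect_equal(f$r_squared, 0)
})

test_that("coupling regression equals the normal-equations oracle", {
  set.seed(23)
  for (i in 1:30) {
    n <- sample(3:20, 1)
    x <- runif(n, 1, 300)
    y <- 0.5 * x + rnorm(n, 0, 20)
    f <- fit_coupling(x, y)
    o <- ols_oracle(x, y)
    expect_equal(f$slope_k, o$slope, tolerance = 1e-10)
    expect_equal(f$intercept_a, o$intercept, tolerance = 1e-10)
    expect_equal(f$r_squared, o$r_squared, tolerance = 1e-10)
    # log10 transform: same oracle on the transformed axes
    xp <- runif(n, 0.2, 30)
    yp <- 10^(1.1 * log10(xp) + rnorm(n, 0, 0.1))
    fl <- fit_coupling(xp, yp, "log10")
    ol <- ols_oracle(log10(xp), log10(yp))
    expect_equal(fl$slope_k, ol$slope, tolerance = 1e-10)
    expect_equal(fl$intercept_a, ol$intercept, tolerance = 1e-10)
  }
})

test_that("coupling regression rejects degenerate inputs", {
  expect_error(fit_coupling(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_error(fit_coupling(c(1, 2), c(1, 2)), "At least 3")
  expect_error(
    fit_coupling(c(1, -2, 3), c(1, 2, 3), "log10",
                 leaf_id = c("a", "b", "c")),
    "positive values.*b")
})

test_that("ASL curve agrees with direct ASL on exact linear data", {
  # a = 0: constant at the asymptote
  f0 <- exact_identity_fit(0.5, 0)
  expect_equal(asl_curve(f0, c(10, 100, 1000)), rep(1 / 3, 3),
               tolerance = 1e-12)
  # worked point: k = 0.5, a = 10, sd_ad = 60 pairs with sd_ab = 100
  f <- exact_identity_fit(0.5, 10)
  expect_equal(asl_curve(f, 60), 0.375, tolerance = 1e-12)
  expect_equal(asl_curve(f, 60), asl(60, 100), tolerance = 1e-12)
  # identity property on random exact lines
  set.seed(5)
  for (i in 1:20) {
    k <- runif(1, 0.1, 2)
    a <- runif(1, -30, 30)
    sd_ab <- runif(5, 80, 400)
    sd_ad <- k * sd_ab + a
    if (any(sd_ad <= 0)) next
    fit <- fit_coupling(sd_ab, sd_ad)
    expect_equal(asl_curve(fit, sd_ad), asl(sd_ad, sd_ab),
                 tolerance = 1e-12)
  }
})

test_that("ASL curve tends monotonically to its asymptote", {
  f_pos <- exact_identity_fit(0.5, 10)
  f_neg <- exact_identity_fit(0.5, -10)
  sd_grid <- c(50, 100, 500, 5000, 5e5)
  v_pos <- asl_curve(f_pos, sd_grid)
  v_neg <- asl_curve(f_neg, sd_grid)
  expect_true(all(diff(v_pos) < 0))  # from above when a > 0
  expect_true(all(diff(v_neg) > 0))  # from below when a < 0
  expect_equal(v_pos[5], asl_pot(0.5), tolerance = 1e-4)
  expect_equal(v_neg[5], asl_pot(0.5), tolerance = 1e-4)
  expect_error(asl_curve(f_pos, 1), "must be positive")  # denominator < 0
})

test_that("potential ASL is k/(k+1)", {
  expect_equal(asl_pot(1), 0.5)
  expect_equal(asl_pot(0), 0)
  expect_equal(asl_pot(0.37), 0.37 / 1.37)
  expect_equal(round(asl_pot(0.37), 2), 0.27)
  expect_error(asl_pot(-0.1), "negative slope")
})

test_that("AWL curve inverts the log-linear wax coupling", {
  f1 <- exact_log10_fit(1, 0)
  expect_equal(awl_curve(f1, c(0.5, 5, 50)), rep(0.5, 3),
               tolerance = 1e-12)
  f2 <- exact_log10_fit(1, log10(2))
  expect_equal(awl_curve(f2, c(1, 10)), rep(2 / 3, 2), tolerance = 1e-12)
  f3 <- exact_log10_fit(2, 0)
  expect_equal(awl_curve(f3, 100), 100 / 110, tolerance = 1e-12)
  # monotone in w_ad: increasing for k > 1, decreasing for k < 1
  w <- c(0.5, 1, 2, 5, 10, 20)
  expect_true(all(diff(awl_curve(exact_log10_fit(1.4, 0.1), w)) > 0))
  expect_true(all(diff(awl_curve(exact_log10_fit(0.7, 0.1), w)) < 0))
})

test_that("potential AWL reports the reference value and limit class", {
  expect_equal(awl_pot(exact_log10_fit(1, 0))$awl_pot, 0.5)
  p <- awl_pot(exact_log10_fit(1, log10(2)))
  expect_equal(p$awl_pot, 2 / 3, tolerance = 1e-12)
  expect_equal(p$limit, 2 / 3, tolerance = 1e-12)
  p2 <- awl_pot(exact_log10_fit(2, 0))
  expect_equal(p2$awl_pot, 10 / (10 + sqrt(10)), tolerance = 1e-12)
  expect_equal(p2$limit, 1)
  expect_equal(awl_pot(exact_log10_fit(0.7, 0.1))$limit, 0)
})

test_that("ASL-on-polarity regression recovers known lines", {
  flat <- data.frame(asl = rep(0.3, 10), polarity = seq(-1, 1, len = 10))
  r <- regress_asl_on_polarity(flat)
  expect_equal(r$slope, 0, tolerance = 1e-12)
  expect_equal(r$intercept, 0.3, tolerance = 1e-12)
  p <- seq(-1.5, 1.5, length.out = 54)
  exact <- data.frame(asl = 0.3 - 0.05 * p, polarity = p)
  r <- regress_asl_on_polarity(exact)
  expect_equal(r$slope, -0.05, tolerance = 1e-12)
  expect_equal(r$intercept, 0.3, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
})

test_that("zero-polarity intercept CI has near-nominal coverage", {
  set.seed(314)
  p <- seq(-1.5, 1.5, length.out = 54)
  hits <- 0L
  for (i in 1:500) {
    d <- data.frame(asl = 0.3 - 0.05 * p + rnorm(54, 0, 0.02),
                    polarity = p)
    r <- regress_asl_on_polarity(d)
    hits <- hits + (r$ci_low <= 0.3 && 0.3 <= r$ci_high)
  }
  expect_gte(hits / 500, 0.93)
})

test_that("small groups are skipped with a warning", {
  d <- data.frame(asl = c(runif(10), 0.2, 0.3),
                  polarity = c(rnorm(10), 0, 1),
                  species = c(rep("a", 10), "b", "b"))
  expect_warning(r <- regress_asl_on_polarity(d, group = "species"),
                 "skipped")
  expect_equal(nrow(r), 1L)
  expect_equal(r$species, "a")
})

test_that("per-leaf patterning summary appends ASL and AWL", {
  lv <- data.frame(leaf_id = c("a", "b"), sd_ad = c(50, 0),
                   sd_ab = c(150, 100), w_ad = c(2, 1), w_ab = c(1, 4))
  out <- patterning_summary(lv)
  expect_equal(out$asl, c(0.25, 0))
  expect_equal(out$awl, c(2 / 3, 0.2))
})
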