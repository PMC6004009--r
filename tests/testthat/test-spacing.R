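# Independent oracle: locate the largest crossing of the compound curve
# with the criterion level by dense-grid bracketing plus uniroot.
cs_bisect <- function(params, criterion = 0.025, tol = 1e-10) {
  level <- params$A - criterion
  lo <- params$mu - 10 * params$sigma
  hi <- params$mu + 10 * params$sigma
  grid <- seq(lo, hi, length.out = 20000)
  below <- psi(grid, params) < level
  if (!any(below)) return(NA_real_)
  i <- max(which(below))
  if (i == length(grid)) return(NA_real_)
  uniroot(function(x) psi(x, params) - level, c(grid[i], grid[i + 1]),
          tol = tol)$root
}

test_that("closed-form critical spacing matches its defining equation", {
  # criterion placing the level at the sigmoid midpoint gives x* = mu
  p <- crowding_params(A = 0.95, mu = 0.4, sigma = 0.3, m = 0, b = 0)
  crit_mid <- (p$A - p$gamma) / 2
  cs <- critical_spacing(p, criterion = crit_mid)
  expect_true(cs$defined)
  expect_equal(cs$value, p$mu, tolerance = 1e-12)
  # worked closed form
  p2 <- crowding_params(A = 0.95, mu = 0, sigma = 0.5, m = 0, b = 0)
  cs2 <- critical_spacing(p2, criterion = 0.025)
  expect_equal(cs2$value, 0.5 * qnorm(0.675 / 0.70), tolerance = 1e-12)
  expect_equal(cs2$value, cs_bisect(p2), tolerance = 1e-8)
  # asymptote too close to chance: undefined
  p3 <- crowding_params(A = 0.27, mu = 0.4, sigma = 0.3, m = 0, b = 0)
  cs3 <- critical_spacing(p3, criterion = 0.025)
  expect_false(cs3$defined)
  expect_true(is.na(cs3$value))
})

test_that("the recovery branch can mask the crossing entirely", {
  # recovery line above A - criterion at the sigmoid crossing
  p <- crowding_params(A = 0.9, mu = 0.3, sigma = 0.15, m = -0.01, b = 0.95)
  cs <- critical_spacing(p, criterion = 0.025)
  expect_false(cs$defined)
  # the oracle agrees: the compound curve never drops below the level
  expect_true(is.na(cs_bisect(p)))
})

test_that("closed form agrees with bisection over random parameter sets", {
  set.seed(77)
  n_checked <- 0
  while (n_checked < 1000) {
    p <- crowding_params(A = runif(1, 0.4, 0.999), mu = runif(1, -0.8, 0.9),
                         sigma = runif(1, 0.05, 1.5), m = -runif(1),
                         b = runif(1))
    cs <- critical_spacing(p, criterion = 0.025)
    if (!cs$defined) next
    expect_equal(cs$value, cs_bisect(p), tolerance = 1e-8)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 1000)
})

test_that("critical spacing is monotone in sigma, mu, and criterion", {
  base <- list(A = 0.95, mu = 0.4, sigma = 0.3, m = 0, b = 0)
  val <- function(mu = base$mu, sigma = base$sigma, criterion = 0.025) {
    critical_spacing(crowding_params(A = base$A, mu = mu, sigma = sigma,
                                     m = base$m, b = base$b),
                     criterion = criterion)$value
  }
  sig_grid <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(sapply(sig_grid, function(s) val(sigma = s))) > 0))
  mu_grid <- seq(-0.5, 0.8, by = 0.1)
  expect_true(all(diff(sapply(mu_grid, function(m) val(mu = m))) > 0))
  crit_grid <- seq(0.01, 0.2, by = 0.01)
  expect_true(all(diff(sapply(crit_grid,
                              function(cr) val(criterion = cr))) < 0))
})

test_that("Monte Carlo intervals are order statistics of the spacing draws", {
  p <- ref_params()
  # point-mass posterior: zero-width interval at the closed-form value
  point <- make_fit_stub(constant_draws(p, 200))
  ci0 <- cs_interval(point, n_mc = 500, seed = 1)
  expect_equal(ci0$ci_low, ci0$ci_high)
  expect_equal(ci0$value, critical_spacing(p)$value, tolerance = 1e-12)
  expect_equal(ci0$frac_undefined, 0)
  # dispersed posterior: endpoints are quantiles of the defined draws
  set.seed(2)
  d <- cbind(A = runif(300, 0.85, 0.99), b = runif(300, 0.5, 0.8),
             sigma = runif(300, 0.1, 0.5), mu = runif(300, 0.2, 0.7),
             m = -runif(300, 0.1, 0.9))
  fit <- make_fit_stub(d)
  ci <- cs_interval(fit, n_mc = 1000, seed = 3)
  ok <- ci$draws[!is.na(ci$draws)]
  expect_equal(ci$ci_low, quantile(ok, 0.025, names = FALSE))
  expect_equal(ci$ci_high, quantile(ok, 0.975, names = FALSE))
  expect_equal(ci$value, median(ok))
  expect_true(ci$ci_low <= ci$value && ci$value <= ci$ci_high)
  # seeded repeat is identical
  ci2 <- cs_interval(fit, n_mc = 1000, seed = 3)
  expect_identical(ci[c("value", "ci_low", "ci_high")],
                   ci2[c("value", "ci_low", "ci_high")])
  # mostly-undefined posteriors are flagged unreliable
  low <- d; low[, "A"] <- runif(300, 0.25, 0.28)
  ciu <- cs_interval(make_fit_stub(low), n_mc = 400, seed = 4)
  expect_true(ciu$unreliable)
})

test_that("spacing conversions follow the stated center-to-center formulas", {
  expect_equal(center_to_center(0.75, 2.25, "letters"), 3.0)
  expect_equal(center_to_center(1.0, 2.5, "bars"), 2.5)
  expect_equal(center_to_center(0, 2.0, "bars"), 1.2)
  expect_equal(center_to_center(0, 2.0, "letters"), 2.0)
  # strictly increasing in both arguments; letters >= bars
  ee <- seq(0, 2, by = 0.25)
  expect_true(all(diff(center_to_center(ee, 2)) > 0))
  sz <- seq(0.5, 4, by = 0.5)
  expect_true(all(diff(center_to_center(1, sz)) > 0))
  expect_true(all(center_to_center(ee, 2, "letters") >=
                  center_to_center(ee, 2, "bars")))
})

test_that("the size-limited reference line is proportional with slope 1.4", {
  expect_equal(size_limited_line(1.0), 1.4)
  expect_equal(size_limited_line(2.0), 2.8)
  expect_equal(size_limited_line(0), 0)
})

test_that("the spacing report flags 80-95% asymptotes and counts cells", {
  p_star <- crowding_params(A = 0.90, mu = 0.5, sigma = 0.2, m = -0.4,
                            b = 0.7)
  p_high <- crowding_params(A = 0.97, mu = 0.5, sigma = 0.2, m = -0.4,
                            b = 0.77)
  fits <- list(
    make_fit_stub(constant_draws(p_star, 100), stroke = 0.4),
    make_fit_stub(constant_draws(p_high, 100), stroke = 0.6))
  tab <- spacing_summary(fits, n_mc = 200, seed = 5)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$star, c(TRUE, FALSE))
  expect_equal(tab$letter_size, c(2.0, 3.0))
  expect_equal(tab$size_limited_cc, 1.4 * c(2.0, 3.0))
  # letter-flanker conversion of the edge-to-edge estimate
  expect_equal(tab$cs_cc, tab$cs_ee + tab$letter_size)
})
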