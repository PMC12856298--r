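test_that("CSA and tension normalization follow their formulas", {
  expect_equal(myocyte_csa(20, 20), pi * 100, tolerance = 1e-12)   # 314.16
  expect_equal(myocyte_csa(25, 15), pi * 25 * 15 / 4, tolerance = 1e-12)
  expect_error(myocyte_csa(0, 15), "> 0")
  expect_equal(tension_from_force(3, 300), 10)
  expect_equal(tension_from_force(0, 300), 0)
  expect_error(tension_from_force(3, 0), "CSA")
  expect_equal(slack_passive_tension(5, 2, 300), 10)
  expect_equal(slack_passive_tension(2, 2, 300), 0)
  expect_warning(pt <- slack_passive_tension(2, 5, 300), "negative")
  expect_equal(pt, -10)
  expect_equal(active_tension(30, 10), 20)
  expect_equal(active_tension(10, 10), 0)
})

test_that("noise-free simulated tensions sit exactly on the Hill curve", {
  m <- simulate_myocytes(n_animals = c(sham = 1), n_myocytes = 5,
                         ATmax = c(sham = 20), pCa50 = c(sham = 5.6),
                         nH = c(sham = 3), a = c(sham = 0.012),
                         b = c(sham = 2.5),
                         sd_animal = 0, sd_myocyte = 0, sd_resid = 0,
                         seed = 1)
  at <- m[m$kind == "at" & m$myocyte == m$myocyte[1], ]
  expect_equal(at$value[at$x == 5.6], 10)            # half-max by definition
  expect_equal(at$value[at$x == 5.0],
               20 / (1 + 10^(3 * (5.0 - 5.6))), tolerance = 1e-12)
  expect_equal(at$value[at$x == 5.0], 19.69, tolerance = 1e-3)
  m2 <- simulate_myocytes(n_animals = c(sham = 1), n_myocytes = 5, seed = 1)
  m3 <- simulate_myocytes(n_animals = c(sham = 1), n_myocytes = 5, seed = 1)
  expect_identical(m2, m3)
  expect_error(simulate_myocytes(n_myocytes = 3), "5")
  expect_error(simulate_myocytes(sd_resid = -1), ">= 0")
})

test_that("Hill parameters are recovered from noise-free curves", {
  pca <- c(5.0, 5.2, 5.4, 5.6, 5.8, 6.0)
  at <- 20 / (1 + 10^(3 * (pca - 5.6)))
  f <- fit_hill(pca, at)
  expect_equal(f$ATmax, 20, tolerance = 0.01)
  expect_equal(f$pCa50, 5.6, tolerance = 0.01)
  expect_equal(f$nH, 3, tolerance = 0.01)
  expect_equal(f$EC50, 10^-5.6, tolerance = 1e-4)
  # AT at the fitted pCa50 is half of the fitted maximum, by definition
  expect_equal(f$ATmax / (1 + 10^(f$nH * 0)), f$ATmax / 2)
  expect_error(fit_hill(pca[1:3], at[1:3]), ">= 4")
  expect_error(fit_hill(pca, rep(7, 6)), "degenerate")
})

test_that("SL-PT exponential fit recovers and scales correctly", {
  sl <- seq(1.8, 2.3, by = 0.1)
  pt <- 0.012 * exp(2.5 * sl)
  f <- fit_sl_pt(sl, pt)
  expect_equal(f$a, 0.012, tolerance = 0.01)
  expect_equal(f$b, 2.5, tolerance = 0.01)
  expect_equal(f$pt_2.2, 0.012 * exp(2.5 * 2.2), tolerance = 1e-4)
  # equivariance: scaling PT by k scales a by k, leaves b unchanged
  f2 <- fit_sl_pt(sl, 2 * pt)
  expect_equal(f2$a, 2 * f$a, tolerance = 1e-6)
  expect_equal(f2$b, f$b, tolerance = 1e-6)
  expect_equal(f2$pt_2.2, 2 * f$pt_2.2, tolerance = 1e-6)
  # constant tension flattens the exponent and is flagged
  fc <- fit_sl_pt(sl, rep(3, 6))
  expect_lt(abs(fc$b), 1e-6)
  expect_true(length(fc$flags) > 0)
  expect_error(fit_sl_pt(sl, -pt), "positive")
})

test_that("noisy recovery runs at the efficiency bound of the design", {
  # At residual SD = 5% of ATmax with the 6-point pCa ladder and a free Hill
  # coefficient, the Cramer-Rao bound puts the best attainable median |error|
  # of ATmax at 3.7%; the fit should sit essentially on that bound, and
  # pCa50 / the SL-PT exponent are recovered an order of magnitude tighter.
  m <- simulate_myocytes(n_animals = c(g = 40), n_myocytes = 5,
                         ATmax = c(g = 20), pCa50 = c(g = 5.55),
                         nH = c(g = 3), a = c(g = 0.012), b = c(g = 2.5),
                         sd_animal = 1, sd_myocyte = 0.5,
                         sd_resid = 1,           # 5% of ATmax
                         seed = 99)
  truth <- attr(m, "truth")
  ids <- truth$myocyte
  expect_equal(length(ids), 200)
  err <- t(vapply(ids, function(id) {
    d_at <- m[m$myocyte == id & m$kind == "at", ]
    d_pt <- m[m$myocyte == id & m$kind == "pt", ]
    tr <- truth[truth$myocyte == id, ]
    fh <- fit_hill(d_at$x, d_at$value)
    fs <- fit_sl_pt(d_pt$x, d_pt$value)
    c(abs(fh$ATmax - tr$ATmax) / tr$ATmax,
      abs(fh$pCa50 - tr$pCa50) / tr$pCa50,
      abs(fs$b - tr$b) / tr$b)
  }, numeric(3)))
  expect_lt(median(err[, 1]), 0.045)  # ATmax: CRLB-efficient
  expect_lt(median(err[, 2]), 0.01)   # pCa50
  expect_lt(median(err[, 3]), 0.03)   # SL-PT exponent
})

test_that("cluster bootstrap is seeded, covers the truth, and collapses", {
  m <- simulate_myocytes(n_animals = c(g = 6), n_myocytes = 5,
                         ATmax = c(g = 20), pCa50 = c(g = 5.55),
                         nH = c(g = 3), a = c(g = 0.012), b = c(g = 2.5),
                         sd_animal = 0.5, sd_myocyte = 0.5, sd_resid = 0.5,
                         seed = 21)
  d <- m[m$kind == "at", c("myocyte", "x", "value")]
  names(d) <- c("myocyte", "x", "y")
  band1 <- bootstrap_fit_band(d, "hill", B = 200, seed = 7)
  band2 <- bootstrap_fit_band(d, "hill", B = 200, seed = 7)
  expect_identical(band1, band2)
  truth <- hill_curve <- 20 / (1 + 10^(3 * (band1$x - 5.55)))
  expect_gte(mean(band1$lo <= truth & truth <= band1$hi), 0.9)
  # noise -> 0 collapses the band onto the fit
  d0 <- d
  d0$y <- 20 / (1 + 10^(3 * (d0$x - 5.55)))
  band0 <- bootstrap_fit_band(d0, "hill", B = 100, seed = 7)
  expect_lt(max(band0$hi - band0$lo), 1e-6)
  expect_error(bootstrap_fit_band(d[d$myocyte %in% unique(d$myocyte)[1:2], ],
                                  "hill", B = 100), ">= 3")
  expect_error(bootstrap_fit_band(d, "hill", B = 10), "B must")
})
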