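occ_run <- function(preset = cteph, n = 12, edv_end = 90, noise = 0,
                    seed = NULL) {
  sim <- simulate_occlusion(preset, n, edv_end = edv_end, noise_sd = noise,
                            seed = seed)
  select_occlusion_beats(segment_beats(sim$recording))
}

test_that("clean occlusion runs are accepted in full", {
  run <- occ_run()
  expect_equal(nrow(run$beats), 12)
  expect_equal(nrow(run$excluded), 0)
})

test_that("ectopic beats are excluded by the RR rule", {
  sim <- simulate_occlusion(cteph, 12, edv_end = 90)
  b <- segment_beats(sim$recording)
  b$RR[6] <- b$RR[6] * 0.65                  # injected ectopic, RR -35%
  run <- select_occlusion_beats(b)
  expect_equal(nrow(run$beats), 11)
  expect_equal(nrow(run$excluded), 1)
  expect_match(run$excluded$reason, "ectopic")
})

test_that("steady recordings contain no occlusion descent", {
  b <- segment_beats(simulate_steady(cteph, 8)$recording)
  expect_error(select_occlusion_beats(b), "no occlusion descent")
})

test_that("ESPVR on collinear synthetic points is exact", {
  es <- fit_espvr(occ_run())
  expect_equal(es$Ees, 2.0, tolerance = 1e-9)
  expect_equal(es$V0, 55, tolerance = 1e-7)
  expect_gt(es$r2, 0.999)
  expect_lt(es$quadratic_check$curvature_contribution, 1e-3)
  # constructed line
  b <- data.frame(ESV = seq(40, 90, by = 10), ESP = 0.2 * (seq(40, 90, 10) - 10))
  es2 <- fit_espvr(b)
  expect_equal(es2$Ees, 0.2, tolerance = 1e-12)
  expect_equal(es2$V0, 10, tolerance = 1e-9)
  # no volume spread
  flat <- data.frame(ESV = rep(80, 6), ESP = rep(50, 6))
  expect_error(fit_espvr(flat), "spread")
})

test_that("EDPVR recovery matches the generator for both phenotypes", {
  ed_c <- fit_edpvr(occ_run(cteph, edv_end = 90))
  expect_equal(ed_c$beta, 0.038, tolerance = 0.02)
  expect_equal(ed_c$A, 0.10382, tolerance = 0.02)
  expect_equal(ed_c$P_inf, 0, tolerance = 0.05)
  ed_s <- fit_edpvr(occ_run(sham, edv_end = 75))
  expect_equal(ed_s$beta, 0.015, tolerance = 0.02)
  flat <- data.frame(EDV = seq(90, 125, length.out = 8), EDP = rep(6, 8))
  expect_error(fit_edpvr(flat), "no curvature")
})

test_that("fitted beta tracks the generator stiffness monotonically", {
  betas <- c(0.02, 0.038, 0.06)
  fitted <- vapply(betas, function(bt) {
    # rescale A so EDP at EDV stays at 12 mmHg (physiological rendering)
    p <- make_preset("cteph", edpvr_beta = bt, edpvr_A = 12 / exp(bt * 125))
    fit_edpvr(occ_run(p))$beta
  }, numeric(1))
  expect_equal(fitted, betas, tolerance = 0.02)
  expect_true(all(diff(fitted) > 0))
})

test_that("PRSW slope matches a constructed line and the loop-area oracle", {
  edv <- seq(80, 130, by = 10)
  b <- data.frame(EDV = edv, SW = 20 * (edv - 60))
  pf <- fit_prsw(b)
  expect_equal(pf$Mw, 20, tolerance = 1e-12)
  expect_equal(pf$Vw, 60, tolerance = 1e-9)
  expect_error(fit_prsw(b[1, , drop = FALSE]), "multiple beats")
  # simulated occlusion against an independent per-beat polygon-area oracle
  sim <- simulate_occlusion(cteph, 12, edv_end = 90)
  beats <- segment_beats(sim$recording)
  sw_oracle <- vapply(seq_len(nrow(beats)), function(k) {
    w <- beats$start[k]:beats$end[k]
    oracle_polygon_area(sim$recording$data$P[w], sim$recording$data$V[w])
  }, numeric(1))
  oracle_fit <- stats::lm(sw_oracle ~ beats$EDV)
  pkg_fit <- fit_prsw(select_occlusion_beats(beats))
  expect_equal(pkg_fit$Mw, unname(coef(oracle_fit)[2]), tolerance = 0.05)
})

test_that("derived indices follow their defining ratios", {
  b <- segment_beats(simulate_steady(cteph, 5)$recording)
  expect_equal(arterial_elastance(b), 1.2, tolerance = 1e-9)
  bs <- segment_beats(simulate_steady(sham, 5)$recording)
  expect_equal(arterial_elastance(bs), 0.5, tolerance = 1e-9)
  b0 <- b; b0$SV <- 0
  expect_error(arterial_elastance(b0), "positive")
  expect_equal(coupling_ratio(2.0, 1.2), 1.667, tolerance = 1e-3)
  expect_equal(coupling_ratio(1, 1), 1)
  expect_error(coupling_ratio(2, 0), "Ea")
  expect_equal(compute_pvr(51, 9, 4.2), 10.0)
  expect_equal(compute_pvr(20, 20, 5), 0)
  expect_error(compute_pvr(51, 9, 0), "CO")
  expect_warning(compute_pvr(10, 20, 5), "negative")
})

test_that("the ventricular summary reproduces the preset end to end", {
  st <- simulate_steady(cteph, 5)
  oc <- simulate_occlusion(cteph, 12, edv_end = 90)
  s <- analyze_session(st$recording, oc$recording,
                       thermo_co = simulate_thermodilution(cteph, 0))
  expect_equal(s$EF, 0.35, tolerance = 1e-6)
  expect_equal(s$Ees, 2.0, tolerance = 1e-6)
  expect_equal(s$Ea, 1.2, tolerance = 1e-6)
  expect_equal(s$tau, 20, tolerance = 0.2)
  expect_equal(s$beta, 0.038, tolerance = 1e-3)
  expect_equal(s$EDP, 12, tolerance = 0.05)
  expect_equal(s$CO, 4.2)
  expect_equal(s$PVR, 10.0)
  sh <- analyze_session(simulate_steady(sham, 5)$recording,
                        simulate_occlusion(sham, 12, edv_end = 75)$recording)
  expect_equal(sh$EF, 0.51, tolerance = 0.005)
  expect_equal(sh$tau, 13, tolerance = 0.15)
  expect_equal(sh$beta, 0.015, tolerance = 5e-4)
  # missing relaxation fits are a hard error
  b <- segment_beats(st$recording)
  expect_error(ventricular_summary(b, tau_fits = NULL), "tau")
})

test_that("Ees stays accurate under 1 mmHg pressure noise", {
  errs <- vapply(1:100, function(s) {
    run <- occ_run(noise = 1, seed = s)
    abs(suppressWarnings(fit_espvr(run))$Ees - 2) / 2
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})
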