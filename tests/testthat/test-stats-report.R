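test_that("the test dispatcher follows the normality decision path", {
  set.seed(10)
  x <- rnorm(12, 10, 1); y <- rnorm(12, 11, 1)
  cmp <- two_group_compare(x, y)
  expect_equal(cmp$test, "student")
  expect_equal(cmp$style, "mean_sem")
  expect_gte(cmp$trace$shapiro_x, 0.05)
  # heteroscedastic but normal -> Welch
  set.seed(11)
  yw <- rnorm(40, 10, 6)
  cw <- two_group_compare(rnorm(40, 10, 1), yw)
  expect_equal(cw$test, "welch")
  expect_lt(cw$trace$var_test, 0.05)
  # clearly non-normal group -> Mann-Whitney, median(range) descriptives
  set.seed(12)
  ce <- two_group_compare(rnorm(30), rexp(30))
  expect_equal(ce$test, "mannwhitney")
  expect_equal(ce$style, "median_range")
  expect_error(two_group_compare(1:2, 1:5), "n >= 3")
})

test_that("identical groups give p near 1 and the path is deterministic", {
  set.seed(13)
  x <- rnorm(10)
  cmp <- two_group_compare(x, x)
  expect_gt(cmp$p, 0.99)
  cmp2 <- two_group_compare(x, x)
  expect_identical(cmp$p, cmp2$p)
  expect_identical(cmp$test, cmp2$test)
})

test_that("ANCOVA on fit parameters detects a strong group gap", {
  sim_ees <- function(gap, seed) {
    set.seed(seed)
    n <- 6
    v0 <- rnorm(2 * n, 40, 8)
    ees <- c(rnorm(n, 1.0, 0.1), rnorm(n, 1.0 + gap, 0.1)) + 0.005 * v0
    data.frame(group = rep(c("sham", "cteph"), each = n), Ees = ees, V0 = v0)
  }
  hits <- vapply(1:100, function(s)
    ancova_fit_param(sim_ees(1.0, s), "Ees", "V0")$p_group < 0.01,
    logical(1))
  expect_gte(mean(hits), 0.95)
  # null: group estimate centred on zero
  est <- vapply(1:50, function(s)
    ancova_fit_param(sim_ees(0, s + 500), "Ees", "V0")$estimate, numeric(1))
  expect_lt(abs(mean(est)), 0.05)
  one <- data.frame(group = c("a", "b"), Ees = c(1, 2), V0 = c(40, 41))
  expect_error(ancova_fit_param(one, "Ees", "V0"), ">= 3")
})

test_that("log transform engages on skewed positive responses", {
  set.seed(30)
  d <- data.frame(group = rep(c("a", "b"), each = 12),
                  beta = exp(rnorm(24, sd = 1.5)))
  res <- ancova_fit_param(d, "beta")
  expect_equal(res$transformation, "log")
})

test_that("the nested mixed model recovers its variance components", {
  sds <- t(vapply(1:100, function(s) {
    d <- simulate_nested_response(sd_animal = 2, sd_myocyte = 1,
                                  sd_resid = 0.5, seed = s)
    r <- mixed_model_myocytes(d)
    c(r$sd_animal, r$sd_myocyte, r$sd_resid)
  }, numeric(3)))
  expect_equal(median(sds[, 1]), 2, tolerance = 0.25)
  expect_equal(median(sds[, 2]), 1, tolerance = 0.25)
  expect_equal(median(sds[, 3]), 0.5, tolerance = 0.1)
})

test_that("the mixed-model group test has power at a 3x-animal-SD effect", {
  hits <- vapply(1:60, function(s) {
    d <- simulate_nested_response(group_effect = 6, sd_animal = 2,
                                  sd_myocyte = 1, sd_resid = 0.5,
                                  seed = 1000 + s)
    mixed_model_myocytes(d)$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)
  single <- simulate_nested_response(n_animals = c(1, 1), seed = 1)
  expect_error(mixed_model_myocytes(single), "3 animals")
})

test_that("the rendered report round-trips at printed precision", {
  set.seed(40)
  d <- data.frame(
    group = rep(c("sham", "cteph"), c(6, 7)),
    Pmax = c(rnorm(6, 34, 2), rnorm(7, 63, 4)),
    Ees = c(rnorm(6, 0.5, 0.1), rnorm(7, 2.0, 0.3)),
    beta = c(rnorm(6, 0.015, 0.004), rnorm(7, 0.038, 0.006)))
  rep_ <- summary_table(d, c("Pmax", "Ees", "beta"))
  expect_equal(rep_$variable, c("Pmax", "Ees", "beta"))
  expect_true(all(rep_$signif == "*"))
  # decimal rules: integer pressures, one-decimal elastances, 3-decimal beta
  expect_match(rep_$sham[rep_$variable == "Pmax"], "^\\d+ ± \\d+$")
  expect_match(rep_$sham[rep_$variable == "beta"], "0\\.\\d{3}")
  path <- file.path(tempdir(), "report.tsv")
  write_report(rep_, path)
  back <- read_report(path)
  expect_identical(back$sham, rep_$sham)
  expect_identical(back$p, rep_$p)
  unlink(path)
  expect_error(summary_table(d[, "group", drop = FALSE]), "no variables")
})

test_that("descriptive style matches the per-variable normality decision", {
  set.seed(41)
  d <- data.frame(group = rep(c("a", "b"), each = 15),
                  gauss = rnorm(30, 50, 5),
                  skewed = exp(rnorm(30, 0, 1.5)))
  rep_ <- summary_table(d, c("gauss", "skewed"))
  expect_match(rep_$a[1], "±")
  expect_match(rep_$a[2], "\\(")
})
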