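test_that("amplification efficiency follows the dilution-slope formula", {
  lg <- 0:-4
  expect_equal(check_efficiency(lg, 20 - 3.3219 * lg)$efficiency, 1,
               tolerance = 1e-4)
  expect_equal(check_efficiency(lg, 20 - 3.6 * lg)$efficiency, 0.8956,
               tolerance = 5e-4)
  expect_error(check_efficiency(0:-1, c(20, 23)), ">= 4")
  expect_error(check_efficiency(lg, 20 + 3.3 * lg), "positive")
})

test_that("dCt uses the dual-housekeeper geometric mean", {
  ct <- data.frame(
    sample = "s1", group = "sham",
    gene = c("MYH7", "GAPDH", "RPL4"), replicate = 1,
    Ct = c(25, 20, 22))
  ct <- rbind(ct, transform(ct, sample = "s2", Ct = c(24, 20, 22)))
  ct <- rbind(ct, transform(ct[1:3, ], sample = "c1", group = "cteph",
                            Ct = c(23, 20, 22)))
  re <- relative_expression(ct, reference_group = "sham")
  expect_equal(re$dCt[re$sample == "s1"], 25 - 21)
  # sample dCt 3 against a reference mean dCt of 4 -> fold 2
  # (s1 dCt 4, s2 dCt 3, sham mean 3.5; c1 dCt 2 -> fold 2^1.5)
  expect_equal(re$fold[re$sample == "c1"], 2^(3.5 - 2))
})

test_that("null tables give fold 1 and the reference geometric mean is 1", {
  q <- simulate_qpcr(noise_sd = 0, log2fc = c(), seed = 1)
  re <- relative_expression(q)
  expect_equal(re$fold, rep(1, nrow(re)))
  qn <- simulate_qpcr(noise_sd = 0.3, seed = 2)
  ren <- relative_expression(qn)
  gm <- tapply(log2(ren$fold[ren$group == "sham"]),
               ren$gene[ren$group == "sham"], mean)
  expect_equal(as.numeric(gm), rep(0, length(gm)), tolerance = 1e-12)
})

test_that("a known log2 fold change round-trips through the pipeline", {
  q <- simulate_qpcr(noise_sd = 0, log2fc = c(MYH7 = 2), seed = 1)
  re <- relative_expression(q)
  expect_equal(unique(re$fold[re$gene == "MYH7" & re$group == "cteph"]), 4)
  expect_equal(unique(re$fold[re$gene == "MYH6" & re$group == "cteph"]), 1)
  q1 <- simulate_qpcr(seed = 3)
  q2 <- simulate_qpcr(seed = 3)
  expect_identical(q1, q2)
})

test_that("folds are invariant to a constant shift of both housekeepers", {
  q <- simulate_qpcr(noise_sd = 0.3, seed = 4)
  re0 <- relative_expression(q)
  q2 <- q
  hk <- q2$gene %in% c("GAPDH", "RPL4")
  q2$Ct[hk] <- q2$Ct[hk] + 1.7
  re1 <- relative_expression(q2)
  expect_equal(re1$fold, re0$fold, tolerance = 1e-12)
})

test_that("missing housekeepers are a hard error", {
  q <- simulate_qpcr(noise_sd = 0, seed = 1)
  expect_error(relative_expression(q[q$gene != "RPL4", ]), "RPL4")
})

test_that("densitometry ratios are duplicate-averaged then sham-scaled", {
  d <- data.frame(sample = c("s1", "s2", "c1"),
                  group = c("sham", "sham", "cteph"),
                  target1 = c(1.8, 2.2, 4.0), target2 = c(2.2, 1.8, 4.0),
                  normalizer1 = c(0.9, 1.1, 1.0),
                  normalizer2 = c(1.1, 0.9, 1.0))
  out <- densitometry_normalize(d, reference_group = "sham")
  expect_equal(out$ratio, c(2, 2, 4))
  expect_equal(out$level, c(1, 1, 2))
  d0 <- d; d0$normalizer1 <- 0; d0$normalizer2 <- 0
  expect_error(densitometry_normalize(d0), "normalizer")
  # all-identical samples normalize to exactly 1
  di <- data.frame(sample = c("a", "b"), group = c("sham", "cteph"),
                   target1 = 3, normalizer1 = 1.5)
  expect_equal(densitometry_normalize(di)$level, c(1, 1))
})

test_that("percent wall thickness is a scale-free diameter ratio", {
  expect_equal(percent_wall_thickness(80, 60), 25)
  expect_equal(percent_wall_thickness(80, 0), 100)
  expect_error(percent_wall_thickness(60, 80), "smaller")
  expect_equal(percent_wall_thickness(80 * 3.7, 60 * 3.7),
               percent_wall_thickness(80, 60))
})

test_that("morphometry aggregates with the animal as the unit", {
  rec <- rbind(
    data.frame(animal = "a1", group = "cteph", structure = "arteriole",
               value = rep(40, 12)),
    data.frame(animal = "a2", group = "cteph", structure = "arteriole",
               value = rep(46, 11)))
  agg <- aggregate_morphometry(rec)
  expect_equal(agg$per_group$mean, 43)
  expect_equal(agg$per_group$n_animals, 2)
  # synthetic per-animal means recover exactly whatever was injected
  set.seed(8)
  vals <- lapply(1:3, function(i) 20 + i + rnorm(15))
  rec2 <- do.call(rbind, lapply(1:3, function(i)
    data.frame(animal = paste0("b", i), group = "sham",
               structure = "arteriole", value = vals[[i]])))
  agg2 <- aggregate_morphometry(rec2)
  expect_equal(sort(agg2$per_animal$value),
               sort(vapply(vals, mean, numeric(1))))
  # below-minimum counts warn but do not error
  low <- data.frame(animal = "a3", group = "sham", structure = "arteriole",
                    value = rep(30, 9))
  expect_warning(aggregate_morphometry(rbind(rec, low)), "below minimum")
  expect_error(aggregate_morphometry(rec[0, ]), "empty")
})
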