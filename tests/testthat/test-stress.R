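test_that("relative change matches its definition and edge cases", {
  expect_equal(relative_change(5, 5), 0)
  expect_equal(relative_change(0, 5), -1)
  # a root system growing from 476.97 cm to 2206.98 cm under drought
  expect_equal(round(relative_change(2206.98, 476.97), 4), 3.6271)
  expect_true(is.na(relative_change(3, 0)))
  expect_error(relative_change(-1, 2), "negative")
  # invariance under common rescaling
  expect_equal(relative_change(2206.98 * 7, 476.97 * 7),
               relative_change(2206.98, 476.97))
})

test_that("PAE is the stress/control P percentage", {
  expect_equal(pae(1.2, 1.2), 100)
  expect_equal(pae(0, 1.2), 0)
  expect_equal(pae(0.3, 1.2), 25)
  expect_true(is.na(pae(0.3, 0)))
  expect_equal(pae(0.3 * 2, 1.2 * 2), 25)
})

test_that("the seven indices match hand evaluation of their formulas", {
  idx <- stress_indices(0.4, 0.2, dwbar_c = 0.4, dwbar_s = 0.2)
  expect_equal(idx$ssi, 1)
  expect_equal(idx$ti, 0.2)
  expect_equal(idx$si, 0.5)
  expect_equal(idx$hmi, 2 * 0.4 * 0.2 / 0.6, tolerance = 1e-12)
  expect_equal(idx$mpi, 0.3)
  expect_equal(idx$gmpi, sqrt(0.08), tolerance = 1e-12)
  expect_equal(idx$sti, 0.5)
  expect_equal(round(idx$sts, 4), 3.0495)
  expect_equal(idx$sts, idx$ssi + idx$ti + idx$si + idx$hmi +
                 idx$mpi + idx$gmpi + idx$sti, tolerance = 1e-12)
})

test_that("no-stress identities and degenerate populations behave as defined", {
  idx <- stress_indices(0.4, 0.4, dwbar_c = 0.5, dwbar_s = 0.4)
  expect_equal(idx$ti, 0)
  expect_equal(idx$si, 1)
  expect_equal(idx$hmi, 0.4)
  expect_equal(idx$mpi, 0.4)
  expect_equal(idx$gmpi, 0.4)
  expect_error(stress_indices(0.4, 0.2, dwbar_c = 0.3, dwbar_s = 0.3),
               "population-degenerate")
  expect_error(stress_indices(c(0, 0.4), c(0.1, 0.2),
                              dwbar_c = 0.3, dwbar_s = 0.2),
               "must be > 0")
})

test_that("productivity means obey the HM <= GM <= AM chain with equality iff equal", {
  set.seed(31)
  dw_c <- stats::runif(500, 0.01, 2)
  dw_s <- stats::runif(500, 0.01, 2)
  idx <- stress_indices(dw_c, dw_s, dwbar_c = mean(dw_c), dwbar_s = mean(dw_s))
  expect_true(all(idx$hmi <= idx$gmpi + 1e-12))
  expect_true(all(idx$gmpi <= idx$mpi + 1e-12))
  eq <- abs(dw_c - dw_s) < 1e-14
  expect_true(all(abs(idx$hmi - idx$mpi)[!eq] > 0))
  # STI relates to GMPI through the control population mean
  expect_equal(idx$sti * mean(dw_c)^2, idx$gmpi^2, tolerance = 1e-9)
})

test_that("STS_SUM adds the three per-stress scores and propagates missingness", {
  sts <- data.frame(genotype = rep(1:2, each = 3),
                    stress = rep(c("LP", "D", "DLP"), 2),
                    sts = c(3.0495, 2, 1, 1, NA, 1))
  out <- sts_sum(sts)
  expect_equal(out$sts_sum[out$genotype == 1], 6.0495)
  expect_true(is.na(out$sts_sum[out$genotype == 2]))
  one <- sts_sum(data.frame(genotype = 1, stress = "D", sts = 1))
  expect_true(is.na(one$sts_sum))
  all1 <- sts_sum(data.frame(genotype = 1, stress = c("LP", "D", "DLP"),
                             sts = 1))
  expect_equal(all1$sts_sum, 3)
})

test_that("profile normalization divides by the group total", {
  expect_equal(normalize_profile(c(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(normalize_profile(c(2, 6)), c(0.25, 0.75))
  expect_equal(normalize_profile(5), 1)
  expect_error(normalize_profile(c(1, -1)), "zero")
})

test_that("index tables reproduce the expected correlation sign structure", {
  # genotypes whose roots elongate more under stress retain more P and score
  # lower on tolerance indices built from dry weight; the sign pattern of
  # PAE vs dRL (positive) and STS vs PAE (negative) must emerge
  set.seed(77)
  n <- 60
  adapt <- stats::rnorm(n)                     # latent root plasticity
  rl_c <- exp(stats::rnorm(n, log(1200), 0.2))
  rl_s <- rl_c * exp(0.4 * adapt + stats::rnorm(n, 0, 0.1))
  tp_c <- exp(stats::rnorm(n, log(2), 0.1))
  tp_s <- tp_c * exp(0.5 * adapt + stats::rnorm(n, 0, 0.1))
  tdm_c <- exp(stats::rnorm(n, log(0.6), 0.1))
  tdm_s <- tdm_c * exp(-0.4 * adapt + stats::rnorm(n, 0, 0.1)) * 0.5

  d_rl <- relative_change(rl_s, rl_c)
  p_eff <- pae(tp_s, tp_c)
  sts <- stress_indices(tdm_c, tdm_s)$sts
  expect_gt(cor(p_eff, d_rl), 0)
  expect_lt(cor(sts, p_eff), 0)
})
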