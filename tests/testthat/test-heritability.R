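test_that("one-factor ANOVA matches hand-computed sums of squares", {
  tt <- make_trait_table(genotype = 1, treatment = rep(c("C", "D"), each = 2),
                         block = rep(1:2, 2),
                         vals = list(RL = c(1, 2, 3, 4)))
  tab <- factorial_anova(tt, "RL", include_block = FALSE)
  w <- tab[tab$term == "W", ]
  res <- tab[tab$term == "Residuals", ]
  expect_equal(w$ss, 4)
  expect_equal(res$ss, 1)
  expect_equal(w$f, 8)
  expect_equal(w$df, 1)
  expect_equal(res$df, 2)
})

test_that("constant observations give zero F and p near 1", {
  tt <- make_trait_table(genotype = 1, treatment = rep(c("C", "D"), each = 2),
                         block = rep(1:2, 2),
                         vals = list(RL = rep(5, 4)))
  tab <- factorial_anova(tt, "RL", include_block = FALSE)
  f <- tab$f[tab$term == "W"]
  p <- tab$p[tab$term == "W"]
  expect_true(is.na(f) || f == 0)            # 0/0 mean squares are flagged
  expect_true(is.na(p) || p > 0.99)
})

test_that("ANOVA sums of squares decompose the total on balanced data", {
  p <- simulate_plants(sim_config(n_genotypes = 8, seed = 4))
  tt <- derive_traits(p)
  tab <- factorial_anova(tt, "RL")
  d <- tt[tt$trait == "RL", ]
  total_ss <- sum((d$value - mean(d$value))^2)
  expect_equal(sum(tab$ss), total_ss, tolerance = 1e-6)
})

test_that("genotype signal is detected and absent treatment effects stay ns", {
  # strong genotype variance, no treatment effect: the G term should be
  # significant and P/W not, in nearly all replicate simulations
  hits_g <- 0; hits_pw <- 0
  n_sim <- 20
  for (i in seq_len(n_sim)) {
    cfg <- sim_config(n_genotypes = 12, seed = 100 + i,
                      sig2_g = 0.5, sig2_gt = 0, sig2_block = 0,
                      sig2_e = 0.05)
    tt <- derive_traits(simulate_plants(cfg))
    tab <- factorial_anova(tt, "RDW", transform = log)
    p_g <- tab$p[tab$term == "G"]
    p_p <- tab$p[tab$term == "P"]
    p_w <- tab$p[tab$term == "W"]
    hits_g <- hits_g + (p_g <= 0.05)
    hits_pw <- hits_pw + (p_p > 0.05 && p_w > 0.05)
  }
  expect_gte(hits_g / n_sim, 0.9)
  expect_gte(hits_pw / n_sim, 0.7)
})

test_that("empty design cells are reported by name", {
  tt <- make_trait_table(genotype = rep(1:2, each = 4),
                         treatment = rep(c("C", "LP", "D", "DLP"), 2),
                         block = 1,
                         vals = list(RL = 1:8))
  tt <- tt[!(tt$genotype == 1 & tt$treatment == "DLP"), ]
  expect_error(factorial_anova(tt, "RL"), "empty design cells")
})

test_that("Tukey letters separate distant groups and share letters for close ones", {
  set.seed(8)
  same <- data.frame(v = c(rnorm(10, 5), rnorm(10, 5)),
                     g = rep(c("A", "B"), each = 10))
  lt <- tukey_hsd(same$v, same$g)
  expect_equal(unname(lt["A"]), unname(lt["B"]))

  far <- data.frame(v = c(rnorm(10, 0, 0.1), rnorm(10, 50, 0.1)),
                    g = rep(c("A", "B"), each = 10))
  lt2 <- tukey_hsd(far$v, far$g)
  expect_false(lt2[["A"]] == lt2[["B"]])
  expect_equal(unname(lt2[names(lt2)[1]]), "a")  # largest mean lettered first
  expect_equal(names(lt2)[1], "B")

  expect_error(tukey_hsd(rep(1, 8), rep(c("A", "B"), each = 4)),
               "zero within-group variance")
})

test_that("one treatment clearly above the rest is lettered alone", {
  # four treatments, one (D) far above the others, large replication
  set.seed(12)
  means <- c(C = 1290, LP = 1390, D = 1847, DLP = 1242)
  v <- unlist(lapply(means, function(m) rnorm(40, m, 60)))
  g <- rep(names(means), each = 40)
  lt <- tukey_hsd(v, g)
  expect_equal(unname(lt["D"]), "a")
  expect_false("a" %in% lt[c("C", "LP", "DLP")])
})

test_that("variance components and heritability follow the EMS algebra", {
  vc <- variance_components(ms_g = 10, ms_e = 2, r = 4)
  expect_equal(vc$vg, 2)
  expect_equal(vc$ve, 2)
  expect_equal(vc$h, 0.8)
  expect_false(vc$truncated)

  flat <- variance_components(ms_g = 2, ms_e = 2, r = 4)
  expect_equal(flat$vg, 0)
  expect_equal(flat$h, 0)

  neg <- variance_components(ms_g = 1, ms_e = 2, r = 4)
  expect_equal(neg$vg, 0)
  expect_true(neg$truncated)

  expect_equal(heritability_combined(1, 1, 1, r = 4, e = 4),
               1 / (1 + 0.25 + 0.0625), tolerance = 1e-12)
  expect_error(variance_components(10, 2, r = 1), "2 replicates")
})

test_that("combined heritability responds to its components in the right direction", {
  # monotone in each variance component
  expect_gt(heritability_combined(2, 1, 1, 4, 4),
            heritability_combined(1, 1, 1, 4, 4))
  expect_lt(heritability_combined(1, 2, 1, 4, 4),
            heritability_combined(1, 1, 1, 4, 4))
  expect_lt(heritability_combined(1, 1, 2, 4, 4),
            heritability_combined(1, 1, 1, 4, 4))
  set.seed(5)
  for (i in 1:50) {
    vg <- runif(1, 0, 3); vge <- runif(1, 0, 3); ve <- runif(1, 0.01, 3)
    h <- heritability_combined(vg, vge, ve, r = 4, e = 4)
    expect_true(h >= 0 && h <= 1)
  }
  # within one treatment the genotypic variance is confounded with the G x T
  # component; once that component is appreciable, the combined estimate must
  # fall below the single-treatment one (the converse is not true in general)
  vg <- 1; vge <- 1.5; ve <- 1
  h_single <- heritability_broad(vg + vge, ve, r = 4)
  h_com <- heritability_combined(vg, vge, ve, r = 4, e = 4)
  expect_lt(h_com, h_single)
})

test_that("heritability estimates from simulated trials stay in [0, 1]", {
  cfg <- sim_config(n_genotypes = 20, seed = 6, sig2_g = 0.2, sig2_gt = 0.1,
                    sig2_e = 0.2)
  tt <- derive_traits(simulate_plants(cfg))
  h <- heritability(tt, c("RL", "MRD", "RDW", "SDW"), transform = log)
  expect_true(all(h$h >= 0 & h$h <= 1))
  h1 <- heritability(tt, "RL", treatment = "C", transform = log)
  expect_true(h1$h >= 0 && h1$h <= 1)
  expect_equal(h1$scope, "C")
})
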