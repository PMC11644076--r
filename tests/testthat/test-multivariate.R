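test_that("CV filter is inclusive at the threshold and honours the drop list", {
  cv <- c(a = 0.29, b = 0.30, c = 0.31)
  expect_equal(filter_by_cv(cv, drop = character()), c("b", "c"))
  expect_equal(filter_by_cv(cv, threshold = 0), c("a", "b", "c"))
  cv2 <- c(RL = 0.6, RGR = 0.5, RLD = 0.4, RTD = 1.1)
  expect_equal(filter_by_cv(cv2), c("RL", "RTD"))

  # the twelve high-variability global traits of a control treatment
  screen_cv <- c(MRD = 0.31, RL = 0.61, RD = 0.50, RA = 0.57, RV = 0.79,
                 SRL = 0.73, RLI = 0.65, RTD = 1.12, RDW = 0.51,
                 SDW = 0.48, TDM = 0.45, RSR = 0.54)
  expect_equal(length(filter_by_cv(screen_cv)), 12)
})

test_that("Pearson matrix matches brute-force small-vector arithmetic", {
  x <- cbind(a = c(1, 2, 3, 5), b = c(2, 1, 4, 6), c = c(9, 7, 3, 1))
  cm <- pearson_with_p(x)
  brute <- function(u, v) {
    du <- u - mean(u); dv <- v - mean(v)
    sum(du * dv) / sqrt(sum(du^2) * sum(dv^2))
  }
  expect_equal(cm$r["a", "b"], brute(x[, 1], x[, 2]), tolerance = 1e-12)
  expect_equal(cm$r["a", "c"], brute(x[, 1], x[, 3]), tolerance = 1e-12)
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  # p-value from the t transform, checked against cor.test
  ct <- stats::cor.test(x[, 1], x[, 2])
  expect_equal(cm$p["a", "b"], ct$p.value, tolerance = 1e-10)
})

test_that("identical, orthogonal and degenerate trait pairs are handled", {
  v <- c(1, 4, 2, 8, 5)
  cm <- pearson_with_p(cbind(a = v, b = v))
  expect_equal(cm$r["a", "b"], 1)
  expect_equal(cm$p["a", "b"], 0)

  # exactly uncorrelated pair at n = 3: t = 0 gives p = 1
  cm0 <- pearson_with_p(cbind(a = c(-1, 0, 1), b = c(1, -2, 1)))
  expect_equal(cm0$r["a", "b"], 0, tolerance = 1e-12)
  expect_equal(cm0$p["a", "b"], 1, tolerance = 1e-12)

  cmc <- pearson_with_p(cbind(a = v, b = rep(2, 5)))
  expect_true(is.na(cmc$r["a", "b"]))

  two <- pearson_with_p(cbind(a = c(1, 2), b = c(2, 1)))
  expect_true(is.na(two$r["a", "b"]))          # fewer than 3 complete pairs
})

test_that("PCA on the correlation matrix obeys its spectral identities", {
  set.seed(3)
  x <- matrix(rnorm(200), 40, 5,
              dimnames = list(NULL, paste0("t", 1:5)))
  pca <- pca_standardized(x)
  expect_equal(sum(pca$eigenvalues), 5, tolerance = 1e-9)
  expect_equal(sum(pca$explained), 100, tolerance = 1e-9)
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))

  # rank-1 toy: two perfectly correlated traits
  y <- cbind(a = 1:10, b = 2 * (1:10) + 3)
  p1 <- pca_standardized(y)
  expect_equal(p1$eigenvalues, c(2, 0), tolerance = 1e-9)
  expect_equal(p1$explained[1], 100, tolerance = 1e-9)
  expect_equal(p1$retained, 1)

  # 3-trait toy: eigenvalues are the roots of the characteristic polynomial
  z <- cbind(a = c(1, 2, 4, 3, 6), b = c(2, 1, 5, 2, 7), c = c(5, 4, 1, 3, 0))
  R <- cor(z)
  # det(R - l I) for a 3x3 correlation matrix, coefficients by cofactor expansion
  c2 <- -sum(diag(R))
  c1 <- (R[1, 1] * R[2, 2] - R[1, 2]^2) + (R[1, 1] * R[3, 3] - R[1, 3]^2) +
        (R[2, 2] * R[3, 3] - R[2, 3]^2)
  c0 <- -det(R)
  roots <- sort(Re(polyroot(c(c0, c1, c2, 1))), decreasing = TRUE)
  p3 <- pca_standardized(z)
  expect_equal(p3$eigenvalues, roots, tolerance = 1e-8)
})

test_that("PCA drops constant traits and imputes missing values by trait means", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(2, NA, 4, 8), c = rep(1, 4))
  expect_message(expect_warning(p <- pca_standardized(x), "constant traits"),
                 "imputed")
  expect_equal(nrow(p$rotation), 2)
})

test_that("average-linkage clustering matches the linkage definition on a toy", {
  x <- rbind(c(0, 0), c(0, 1), c(10, 10))
  cl <- ahc_cluster(x, k = 2, scale. = FALSE)
  expect_equal(unname(cl$labels[1]), unname(cl$labels[2]))
  expect_false(cl$labels[3] == cl$labels[1])

  # k = n gives singletons; duplicated rows merge first at height 0
  cl3 <- ahc_cluster(x, k = 3, scale. = FALSE)
  expect_equal(length(unique(cl3$labels)), 3)
  dup <- ahc_cluster(rbind(c(1, 1), c(1, 1), c(5, 5)), k = 2, scale. = FALSE)
  expect_equal(min(dup$hclust$height), 0)
  expect_error(ahc_cluster(x, k = 4), "exceeds")
})

test_that("cluster group profiles sum to one across groups per trait", {
  set.seed(10)
  x <- matrix(rexp(60, 1 / 5), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  cl <- ahc_cluster(x, k = 4)
  expect_equal(unname(colSums(cl$profile)), rep(1, 3), tolerance = 1e-12)
  cl1 <- ahc_cluster(x, k = 1)
  expect_equal(unname(cl1$profile[1, ]), rep(1, 3))
})

test_that("clustering is invariant under genotype permutation", {
  set.seed(19)
  x <- matrix(rnorm(80), 20, 4, dimnames = list(paste0("g", 1:20), NULL))
  perm <- sample(20)
  a <- ahc_cluster(x, k = 3)$labels
  b <- ahc_cluster(x[perm, ], k = 3)$labels[rownames(x)]
  expect_equal(mclust::adjustedRandIndex(a, b), 1)
})

test_that("STS grouping clusters the score line and ranks groups by tolerance", {
  v <- c(g1 = 10, g2 = 9.5, g3 = 1, g4 = 1.1, g5 = 5)
  gr <- sts_grouping(v, k = 3)
  expect_equal(unname(gr$labels[c("g1", "g2")]), c(1, 1))
  expect_equal(unname(gr$labels["g5"]), 2)
  expect_equal(unname(gr$labels[c("g3", "g4")]), c(3, 3))
  expect_equal(unname(gr$roman["g1"]), "I")

  expect_equal(unname(sts_grouping(v, k = 1)$labels), rep(1, 5))
  expect_error(sts_grouping(rep(2, 5), k = 3), "unreachable")
  expect_error(sts_grouping(c(a = 1, b = NA), k = 1), "every genotype")
})
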