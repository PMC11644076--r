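#' Select screening traits by coefficient of variation
#'
#' Keeps traits whose CV (computed across genotype means within one
#' treatment) reaches the threshold, then removes any traits on the drop
#' list -- by default RGR and RLD, which are deterministic rescalings of
#' MRD and RL and would enter the multivariate analyses twice.
#'
#' @param cv Named numeric vector of per-trait CVs.
#' @param threshold Inclusive CV threshold (default 0.3).
#' @param drop Traits excluded regardless of CV.
#' @return Character vector of selected trait names.
#' @export
filter_by_cv <- function(cv, threshold = 0.3, drop = c("RGR", "RLD")) {
  sel <- names(cv)[!is.na(cv) & cv >= threshold]
  setdiff(sel, drop)
}

#' Pearson correlation matrix with p-values and significance stars
#'
#' Pairwise-complete Pearson correlations over the columns of a genotype x
#' trait matrix, with two-sided p-values from the t transform
#' `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom. Pairs with
#' fewer than 3 complete observations, and pairs involving a constant
#' trait, are flagged `NA`.
#'
#' @param x Numeric matrix (genotypes x traits).
#' @return List of class `correlation_matrix`: `r`, `p`, `n` (complete
#'   pairs) and `stars` matrices.
#' @export
pearson_with_p <- function(x) {
  x <- as.matrix(x)
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  ok <- !is.na(x)
  n <- crossprod(ok)                        # complete pairs per trait pair
  r[n < 3] <- NA
  df <- n - 2
  tstat <- r * sqrt(df / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[is.na(r)] <- NA
  p[!is.finite(tstat)] <- 0                 # |r| = 1 exactly
  diag(p) <- NA
  stars <- matrix(p_stars(p), nrow(p), dimnames = dimnames(p))
  structure(list(r = r, p = p, n = n, stars = stars),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("Pearson correlation matrix over %d traits\n", ncol(x$r)))
  print(round(x$r, digits))
  invisible(x)
}

#' Standardized principal component analysis
#'
#' Z-scores each trait, eigendecomposes the correlation matrix, and retains
#' components with eigenvalue > 1 (Kaiser rule). Constant traits are
#' dropped with a warning; missing values are imputed by the trait mean
#' (reported via a message). Loadings are the standardized form
#' (eigenvector x sqrt(eigenvalue)), i.e. trait-component correlations.
#'
#' @param x Numeric genotype x trait matrix with >= 3 rows and >= 2
#'   non-constant columns.
#' @return List of class `pca_result`: `eigenvalues`, `explained`
#'   (percentages summing to 100), `retained` (count with eigenvalue > 1),
#'   `loadings`, `rotation` (unit eigenvectors), `scores`.
#' @export
pca_standardized <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3 || ncol(x) < 2)
    stop("need at least 3 genotypes and 2 traits")
  n_imputed <- sum(is.na(x))
  if (n_imputed > 0) {
    message(n_imputed, " missing values imputed by trait means")
    for (j in seq_len(ncol(x))) {
      nas <- is.na(x[, j])
      x[nas, j] <- mean(x[, j], na.rm = TRUE)
    }
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant traits dropped from PCA: ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  z <- scale(x)
  R <- stats::cor(z)
  eig <- eigen(R, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)             # clamp numerical negatives
  vec <- eig$vectors
  # deterministic sign: largest-magnitude loading positive per component
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  dimnames(vec) <- list(colnames(x), paste0("PC", seq_along(lambda)))
  structure(list(
    eigenvalues = lambda,
    explained = 100 * lambda / sum(lambda),
    retained = sum(lambda > 1),
    loadings = vec %*% diag(sqrt(lambda), length(lambda)),
    rotation = vec,
    scores = z %*% vec,
    n_imputed = n_imputed
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(length(x$eigenvalues), 5)
  cat("Standardized PCA:", length(x$eigenvalues), "traits;",
      x$retained, "components with eigenvalue > 1\n")
  tab <- rbind(eigenvalue = x$eigenvalues[1:k],
               `explained %` = x$explained[1:k])
  colnames(tab) <- paste0("PC", 1:k)
  print(round(tab, 2))
  invisible(x)
}

#' Agglomerative hierarchical clustering of genotypes
#'
#' Average-linkage agglomeration on Euclidean distances between genotypes.
#' Traits are z-standardized first (without this, large-magnitude traits
#' such as specific root length would dominate the distances). The tree is
#' cut into `k` groups and each group's mean trait profile is normalized to
#' unit sum across groups per trait ([normalize_profile()]).
#'
#' @param x Numeric genotype x trait matrix.
#' @param k Number of groups (1 <= k <= number of genotypes).
#' @param scale. Z-standardize traits before the distance (default TRUE).
#' @return List of class `ahc_result`: `labels` (named group index per
#'   genotype), `profile` (k x trait matrix, columns summing to 1),
#'   `hclust` (the merge tree), `k`.
#' @export
ahc_cluster <- function(x, k = 5, scale. = TRUE) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k exceeds the number of genotypes")
  if (anyNA(x)) {
    message(sum(is.na(x)), " missing values imputed by trait means")
    for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
  }
  z <- if (scale.) {
    sds <- apply(x, 2, stats::sd)
    scale(x[, sds > 0, drop = FALSE])
  } else x
  hc <- stats::hclust(stats::dist(z, method = "euclidean"), method = "average")
  labels <- stats::cutree(hc, k = k)
  grp_means <- apply(x, 2, function(col) tapply(col, labels, mean))
  if (k == 1) grp_means <- matrix(grp_means, 1, dimnames = list("1", colnames(x)))
  profile <- apply(grp_means, 2, normalize_profile)
  if (k == 1) profile <- matrix(profile, 1, dimnames = dimnames(grp_means))
  structure(list(labels = labels, profile = profile, hclust = hc, k = k),
            class = "ahc_result")
}

#' @export
print.ahc_result <- function(x, ...) {
  cat(sprintf("Average-linkage AHC: %d genotypes in %d groups (sizes: %s)\n",
              length(x$labels), x$k,
              paste(table(x$labels), collapse = ", ")))
  invisible(x)
}

#' Group genotypes by their summed stress-tolerance score
#'
#' One-dimensional average-linkage clustering (Euclidean distance) of the
#' per-genotype STS_SUM values, cut into `k` groups, which are then ranked
#' by descending group mean: group 1 ("I") holds the highest-scoring
#' (most stress-tolerant) genotypes, group `k` the lowest.
#'
#' @param sts_sum Named numeric vector of STS_SUM values (no missing).
#' @param k Number of tolerance groups (default 5).
#' @return List of class `sts_grouping`: `labels` (integer 1..k per
#'   genotype, 1 = most tolerant), `roman` (the same as I..k labels),
#'   `group_means` (descending).
#' @export
sts_grouping <- function(sts_sum, k = 5) {
  if (anyNA(sts_sum)) stop("STS_SUM must be available for every genotype")
  if (length(unique(sts_sum)) < k)
    stop("fewer distinct STS_SUM values than groups; k unreachable")
  hc <- stats::hclust(stats::dist(sts_sum), method = "average")
  raw <- stats::cutree(hc, k = k)
  gm <- tapply(sts_sum, raw, mean)
  sorted <- sort(gm, decreasing = TRUE)
  new_for_raw <- stats::setNames(seq_along(sorted), names(sorted))
  labels <- unname(new_for_raw[as.character(raw)])  # 1 = highest mean STS
  names(labels) <- names(sts_sum)
  structure(list(labels = labels,
                 roman = stats::setNames(roman_group(labels), names(labels)),
                 group_means = sort(gm, decreasing = TRUE)),
            class = "sts_grouping")
}

#' @export
print.sts_grouping <- function(x, ...) {
  k <- length(x$group_means)
  cat(sprintf("STS-based grouping into %d groups (I = most tolerant)\n", k))
  print(table(factor(x$roman, levels = roman_group(seq_len(k)))))
  invisible(x)
}
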