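#' Log response ratio
#'
#' `LnR = ln(V_s / V_c)`, the natural-log ratio of the stress-group mean to
#' the control-group mean -- the standard effect size for ratio-scale
#' traits.
#'
#' @param v_s,v_c Strictly positive group means (vectorised).
#' @return LnR (unitless).
#' @export
log_response_ratio <- function(v_s, v_c) {
  if (any(!is.na(v_s) & v_s <= 0) || any(!is.na(v_c) & v_c <= 0))
    stop("group means must be strictly positive for a log response ratio")
  log(v_s / v_c)
}

#' Percent-change transform of a log response ratio
#'
#' `100 * (exp(LnR) - 1)`; strictly increasing in LnR and bounded below by
#' -100.
#'
#' @param lnr Log response ratio (vectorised).
#' @return Percent change.
#' @export
percent_change <- function(lnr) 100 * (exp(lnr) - 1)

#' Sampling variance of a log response ratio
#'
#' Delta-method variance `v = S_s^2/(n_s V_s^2) + S_c^2/(n_c V_c^2)` from
#' the group standard deviations, sizes and means.
#'
#' @param s_s,s_c Group standard deviations (>= 0).
#' @param n_s,n_c Group sizes (>= 1).
#' @param v_s,v_c Group means (> 0).
#' @return Sampling variance `v` (>= 0).
#' @export
lnr_variance <- function(s_s, n_s, v_s, s_c, n_c, v_c) {
  if (any(c(n_s, n_c) < 1)) stop("group sizes must be >= 1")
  if (any(!is.na(v_s) & v_s <= 0) || any(!is.na(v_c) & v_c <= 0))
    stop("group means must be strictly positive")
  stop_if_negative(s_s, "stress SD"); stop_if_negative(s_c, "control SD")
  s_s^2 / (n_s * v_s^2) + s_c^2 / (n_c * v_c^2)
}

#' Effect-size table of every trait under every stress
#'
#' For each trait and stress treatment, blocks are averaged within genotype,
#' group summaries (mean, SD, n over genotypes) are taken for the stress and
#' control groups, and the log response ratio, its sampling variance,
#' percent change and normal-approximation 95% confidence interval
#' (`LnR +/- 1.96 sqrt(v)`) are computed. The effect is called significant
#' when the interval excludes zero. Traits with a non-positive group mean
#' are returned with `NA` effect columns (with a warning).
#'
#' @param traits Long trait table from [derive_traits()].
#' @param trait Traits to include (default: all).
#' @param stresses Stress codes contrasted against `"C"`.
#' @return data.frame: `trait`, `stress`, `v_s`, `v_c`, `s_s`, `s_c`,
#'   `n_s`, `n_c`, `lnr`, `v`, `pct`, `ci_low`, `ci_high`, `significant`.
#' @export
effect_table <- function(traits, trait = unique(traits$trait),
                         stresses = intersect(c("LP", "D", "DLP"),
                                              unique(traits$treatment))) {
  ctrl <- genotype_means(traits, "C", select = trait)
  rows <- list()
  bad <- character()
  for (s in stresses) {
    str <- genotype_means(traits, s, select = trait)
    for (tr in trait) {
      xc <- ctrl[, tr]; xs <- str[, tr]
      xc <- xc[!is.na(xc)]; xs <- xs[!is.na(xs)]
      rec <- data.frame(trait = tr, stress = s,
                        v_s = mean(xs), v_c = mean(xc),
                        s_s = stats::sd(xs), s_c = stats::sd(xc),
                        n_s = length(xs), n_c = length(xc),
                        stringsAsFactors = FALSE)
      if (is.finite(rec$v_s) && is.finite(rec$v_c) &&
          rec$v_s > 0 && rec$v_c > 0) {
        rec$lnr <- log_response_ratio(rec$v_s, rec$v_c)
        rec$v <- lnr_variance(rec$s_s, rec$n_s, rec$v_s,
                              rec$s_c, rec$n_c, rec$v_c)
        rec$pct <- percent_change(rec$lnr)
        rec$ci_low <- rec$lnr - 1.96 * sqrt(rec$v)
        rec$ci_high <- rec$lnr + 1.96 * sqrt(rec$v)
        rec$significant <- rec$ci_low > 0 | rec$ci_high < 0
      } else {
        bad <- c(bad, paste0(tr, "/", s))
        rec[c("lnr", "v", "pct", "ci_low", "ci_high")] <- NA_real_
        rec$significant <- NA
      }
      rows[[paste(s, tr)]] <- rec
    }
  }
  if (length(bad))
    warning("non-positive group means; effects flagged NA for: ",
            paste(bad, collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pool effect sizes by fixed-effect inverse-variance weighting
#'
#' Combines a set of log-response-ratio records into an overall effect:
#' weights `w = 1/v`, pooled `LnR = sum(w LnR)/sum(w)`, 95% CI
#' `+/- 1.96 sqrt(1/sum(w))`, and the percent-change transform of the
#' pooled effect. Records with zero sampling variance are excluded from the
#' weighting with a warning; records with `NA` effect are dropped.
#'
#' @param records data.frame with columns `lnr` and `v` (e.g. rows of
#'   [effect_table()]).
#' @return One-row data.frame: `k` (records pooled), `lnr`, `v`, `ci_low`,
#'   `ci_high`, `pct`, `significant`.
#' @export
pool_effects <- function(records) {
  r <- records[!is.na(records$lnr) & !is.na(records$v), , drop = FALSE]
  if (nrow(r) == 0) stop("no effect records to pool")
  if (any(r$v == 0)) {
    warning("records with zero sampling variance excluded from pooling")
    r <- r[r$v > 0, , drop = FALSE]
    if (nrow(r) == 0) stop("no records with positive sampling variance")
  }
  w <- 1 / r$v
  est <- sum(w * r$lnr) / sum(w)
  v <- 1 / sum(w)
  ci <- est + c(-1, 1) * 1.96 * sqrt(v)
  data.frame(k = nrow(r), lnr = est, v = v,
             ci_low = ci[1], ci_high = ci[2],
             pct = percent_change(est),
             significant = ci[1] > 0 | ci[2] < 0)
}
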