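#' Factorial ANOVA of a trait over genotype, phosphorus and water factors
#'
#' Decomposes the four treatment codes into a 2 x 2 factorial -- phosphorus
#' supply P (sufficient for C and D, low for LP and DLP) and water status W
#' (watered for C and LP, osmotic stress for D and DLP) -- and fits the
#' fixed-effects model `value ~ block + G * P * W` by sequential
#' (Type I) sums of squares, the classical analysis for a balanced
#' randomized block trial. Factors with fewer than two observed levels are
#' dropped from the model. F statistics test each term against the residual
#' mean square.
#'
#' @param traits Long trait table from [derive_traits()].
#' @param trait Trait to analyse.
#' @param include_block Include the additive block term (default TRUE).
#' @param transform Optional function applied to the values before fitting
#'   (e.g. `log` for the multiplicative scale).
#' @return data.frame with columns `term`, `df`, `ss`, `ms`, `f`, `p`,
#'   `stars` (significance class at 0.05 / 0.01 / 0.001), residual row last.
#' @export
factorial_anova <- function(traits, trait, include_block = TRUE,
                            transform = NULL) {
  d <- traits[traits$trait == trait & !is.na(traits$value), ]
  if (nrow(d) == 0) stop("no data for trait ", trait)
  v <- if (is.null(transform)) d$value else transform(d$value)

  low_p <- c("LP", "DLP")
  dry_w <- c("D", "DLP")
  dd <- data.frame(
    value = v,
    G = factor(d$genotype),
    P = factor(ifelse(d$treatment %in% low_p, "low", "sufficient")),
    W = factor(ifelse(d$treatment %in% dry_w, "stress", "watered")),
    block = factor(d$block)
  )

  # missing design cells are not tolerated: every observed G x P x W
  # combination must be filled
  cell <- table(dd$G, dd$P, dd$W)
  if (nlevels(dd$G) > 1 && nlevels(dd$P) > 1 && nlevels(dd$W) > 1 &&
      any(cell == 0)) {
    empty <- which(cell == 0, arr.ind = TRUE)
    lab <- apply(empty, 1, function(i)
      paste(dimnames(cell)[[1]][i[1]], dimnames(cell)[[2]][i[2]],
            dimnames(cell)[[3]][i[3]], sep = ":"))
    stop("empty design cells: ", paste(utils::head(lab, 5), collapse = ", "))
  }
  counts <- table(interaction(dd$G, dd$P, dd$W, drop = TRUE))
  if (length(unique(counts)) > 1)
    warning("unbalanced design: sequential (Type I) sums of squares depend on term order")

  fac <- c("G", "P", "W")[c(nlevels(dd$G), nlevels(dd$P), nlevels(dd$W)) > 1]
  if (length(fac) == 0) stop("no factor varies; ANOVA undefined")
  rhs <- paste(fac, collapse = " * ")
  if (include_block && nlevels(dd$block) > 1) rhs <- paste("block +", rhs)
  fit <- stats::aov(stats::as.formula(paste("value ~", rhs)), data = dd)
  tab <- summary(fit)[[1]]
  if (!"Residuals" %in% trimws(rownames(tab)) || tab[nrow(tab), "Df"] == 0)
    stop("zero residual degrees of freedom; replicate observations are required")
  out <- data.frame(
    term = gsub(":", " x ", trimws(rownames(tab))),
    df = tab$Df, ss = tab$`Sum Sq`, ms = tab$`Mean Sq`,
    f = tab$`F value`, p = tab$`Pr(>F)`,
    stars = p_stars(tab$`Pr(>F)`),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out
}

#' Tukey HSD compact letter display over treatments
#'
#' Fits a one-way ANOVA of genotype-level values on the grouping factor and
#' summarises all pairwise Tukey honest-significant-difference comparisons
#' (family-wise alpha) as a compact letter display: groups sharing a letter
#' do not differ significantly, and letters are assigned in descending order
#' of the group means so the largest mean carries "a".
#'
#' @param values Numeric response (e.g. genotype means of a trait).
#' @param groups Grouping factor (e.g. treatment), >= 2 levels with >= 2
#'   values each.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Named character vector of letters, one per group level, ordered
#'   by descending group mean.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  d <- data.frame(value = values, grp = factor(groups))
  d <- d[stats::complete.cases(d), ]
  if (nlevels(droplevels(d$grp)) < 2) stop("need at least two groups")
  if (any(table(d$grp) < 2)) stop("need at least two values per group")
  fit <- stats::aov(value ~ grp, data = d)
  wvar <- tapply(d$value, d$grp, stats::var)
  if (all(wvar <= 1e-20 * (1 + mean(d$value)^2)))
    stop("zero within-group variance everywhere; Tukey HSD undefined")
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(grp = "Tukey"))
  cld <- multcomp::cld(glht, level = alpha)
  raw <- cld$mcletters$Letters
  means <- tapply(d$value, d$grp, mean)
  raw <- raw[order(-means)]
  # relabel so "a" is carried by the largest mean: map letter symbols by
  # first appearance while scanning groups in descending mean order
  map <- character()
  for (s in raw) for (ch in strsplit(s, "")[[1]])
    if (!ch %in% names(map)) map[ch] <- letters[length(map) + 1]
  vapply(raw, function(s) {
    paste(sort(unname(map[strsplit(s, "")[[1]]])), collapse = "")
  }, character(1))
}

#' Variance components and broad-sense heritability from mean squares
#'
#' Expected-mean-squares decomposition of the genotype (random) x treatment
#' layout. Single-treatment mode (`ms_ge = NULL`):
#' `V_G = (MS_G - MS_E)/r`, `V_e = MS_E`, and
#' `H = V_G / (V_G + V_e/r)`. Combined mode over `e` treatments:
#' `V_GE = (MS_GE - MS_E)/r`, `V_G = (MS_G - MS_GE)/(r e)`, and
#' `H_com = V_G / (V_G + V_GE/e + V_e/(r e))`. Negative component
#' estimates are truncated at zero (flagged in the result), so heritability
#' always lies in [0, 1].
#'
#' @param ms_g Genotype mean square.
#' @param ms_e Residual (error) mean square.
#' @param r Number of replicates (>= 2).
#' @param ms_ge Genotype x treatment mean square (combined mode only).
#' @param e Number of treatments (combined mode only).
#' @return List of class `variance_decomposition` with elements `vg`,
#'   `vge`, `ve`, `r`, `e`, `h`, `truncated`.
#' @export
variance_components <- function(ms_g, ms_e, r, ms_ge = NULL, e = NULL) {
  if (r < 2) stop("at least 2 replicates are required")
  if (any(c(ms_g, ms_e, ms_ge) < 0)) stop("mean squares must be >= 0")
  truncated <- FALSE
  trunc0 <- function(x) {
    if (x < 0) truncated <<- TRUE
    max(x, 0)
  }
  if (is.null(ms_ge)) {
    vg <- trunc0((ms_g - ms_e) / r)
    ve <- ms_e
    h <- heritability_broad(vg, ve, r)
    vge <- NA_real_
  } else {
    if (is.null(e) || e < 1) stop("combined mode needs the number of treatments `e`")
    vge <- trunc0((ms_ge - ms_e) / r)
    vg <- trunc0((ms_g - ms_ge) / (r * e))
    ve <- ms_e
    h <- heritability_combined(vg, vge, ve, r, e)
  }
  structure(list(vg = vg, vge = vge, ve = ve, r = r, e = e %||% NA_integer_,
                 h = h, truncated = truncated),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  mode <- if (is.na(x$vge)) "single-treatment" else "combined"
  cat(sprintf("Variance decomposition (%s): V_G = %.4g", mode, x$vg))
  if (!is.na(x$vge)) cat(sprintf(", V_GE = %.4g", x$vge))
  cat(sprintf(", V_e = %.4g; H = %.3f", x$ve, x$h))
  if (x$truncated) cat("  [negative component truncated to 0]")
  cat("\n")
  invisible(x)
}

#' Broad-sense heritability within one treatment
#'
#' `H = V_G / (V_G + V_e / r)`, the proportion of variance among genotype
#' means attributable to genotypic variance.
#'
#' @param vg Genotypic variance (>= 0).
#' @param ve Error variance (>= 0).
#' @param r Replicates.
#' @return H in [0, 1]; `NA` when both components are zero.
#' @export
heritability_broad <- function(vg, ve, r) {
  den <- vg + ve / r
  ifelse(den > 0, vg / den, NA_real_)
}

#' Broad-sense heritability across treatments
#'
#' `H_com = V_G / (V_G + V_GE/e + V_e/(r e))`, discounting genotype x
#' treatment variance over `e` treatments.
#'
#' @param vg,vge,ve Genotypic, genotype x treatment and error variances.
#' @param r Replicates; `e` number of treatments.
#' @param e Number of treatments.
#' @return H_com in [0, 1]; `NA` when all components are zero.
#' @export
heritability_combined <- function(vg, vge, ve, r, e) {
  den <- vg + vge / e + ve / (r * e)
  ifelse(den > 0, vg / den, NA_real_)
}

#' Heritability of traits from a trait table
#'
#' For each requested trait, estimates broad-sense heritability within one
#' treatment (two-way genotype + block ANOVA, Eq.-5-style) or across all
#' treatments (genotype x treatment ANOVA with additive block,
#' Eq.-6-style), via [variance_components()].
#'
#' @param traits Long trait table from [derive_traits()].
#' @param trait Character vector of traits (default: all present).
#' @param treatment One treatment code for single-treatment H, or `NULL`
#'   (default) for the combined estimate over all treatments.
#' @param transform Optional value transform (e.g. `log`) applied before the
#'   ANOVA; the generative model of [simulate_plants()] is additive on the
#'   log scale.
#' @return data.frame with columns `trait`, `scope`, `vg`, `vge`, `ve`,
#'   `r`, `e`, `h`.
#' @export
heritability <- function(traits, trait = unique(traits$trait),
                         treatment = NULL, transform = NULL) {
  rows <- lapply(trait, function(tr) {
    d <- traits[traits$trait == tr & !is.na(traits$value), ]
    if (!is.null(treatment)) d <- d[d$treatment == treatment, ]
    if (nrow(d) == 0)
      return(data.frame(trait = tr, scope = treatment %||% "combined",
                        vg = NA, vge = NA, ve = NA, r = NA, e = NA, h = NA))
    v <- if (is.null(transform)) d$value else transform(d$value)
    dd <- data.frame(value = v, G = factor(d$genotype),
                     trt = factor(d$treatment), block = factor(d$block))
    r <- round(nrow(dd) / (nlevels(dd$G) * nlevels(dd$trt)))
    blk <- if (nlevels(dd$block) > 1) "block + " else ""
    if (is.null(treatment)) {
      fit <- stats::aov(stats::as.formula(paste("value ~", blk, "G * trt")),
                        data = dd)
      tab <- summary(fit)[[1]]
      ms <- stats::setNames(tab$`Mean Sq`, trimws(rownames(tab)))
      vc <- variance_components(ms[["G"]], ms[["Residuals"]], r = r,
                                ms_ge = ms[["G:trt"]], e = nlevels(dd$trt))
    } else {
      fit <- stats::aov(stats::as.formula(paste("value ~", blk, "G")),
                        data = dd)
      tab <- summary(fit)[[1]]
      ms <- stats::setNames(tab$`Mean Sq`, trimws(rownames(tab)))
      vc <- variance_components(ms[["G"]], ms[["Residuals"]], r = r)
    }
    data.frame(trait = tr, scope = treatment %||% "combined",
               vg = vc$vg, vge = vc$vge, ve = vc$ve, r = vc$r, e = vc$e,
               h = vc$h, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
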