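#' Relative change of a trait under stress
#'
#' `(stress - control)/control`, the unitless relative increase (or
#' decrease) of a trait under a stress treatment, e.g. the relative root
#' length response ΔRL. Undefined where the control value is zero
#' (returned as `NA`).
#'
#' @param stress,control Non-negative trait values in matching units
#'   (vectorised).
#' @return Numeric vector of relative changes.
#' @export
relative_change <- function(stress, control) {
  stop_if_negative(stress, "stress values")
  stop_if_negative(control, "control values")
  ifelse(!is.na(control) & control > 0, (stress - control) / control, NA_real_)
}

#' Phosphorus acquisition efficiency
#'
#' Stress-plant phosphorus content as a percentage of control phosphorus
#' content: `PAE = 100 * P_S / P_C`. `NA` where the control content is zero.
#'
#' @param p_s,p_c Phosphorus content under stress and control (mg,
#'   vectorised).
#' @return PAE in percent.
#' @export
pae <- function(p_s, p_c) {
  stop_if_negative(p_s, "stress P content")
  stop_if_negative(p_c, "control P content")
  ifelse(!is.na(p_c) & p_c > 0, 100 * p_s / p_c, NA_real_)
}

#' Stress-tolerance indices from control and stressed dry weights
#'
#' Computes the seven classical tolerance/productivity indices for each
#' genotype from its (total) dry weight under control (`dw_c`) and under one
#' stress (`dw_s`), and the population mean dry weights of all genotypes
#' (`dwbar_c`, `dwbar_s`):
#' \describe{
#'   \item{SSI}{stress sensitivity index `(1 - dw_s/dw_c) / (1 - dwbar_s/dwbar_c)`}
#'   \item{TI}{tolerance index `dw_c - dw_s` (g)}
#'   \item{SI}{stress index `dw_s/dw_c`}
#'   \item{HMI}{harmonic mean index `2 dw_c dw_s / (dw_c + dw_s)` (g)}
#'   \item{MPI}{mean productivity index `(dw_c + dw_s)/2` (g)}
#'   \item{GMPI}{geometric mean productivity `sqrt(dw_c dw_s)` (g)}
#'   \item{STI}{stress tolerance index `dw_c dw_s / dwbar_c^2`}
#' }
#' The stress-tolerance score STS is their unweighted sum; with
#' `standardize = TRUE` each index is z-scored across genotypes before
#' summation (an optional variant -- the plain sum is the reference
#' definition).
#'
#' @param dw_c,dw_s Per-genotype control and stress dry weights (g).
#' @param dwbar_c,dwbar_s Population mean dry weights; default the means of
#'   `dw_c` and `dw_s` over genotypes with both values present.
#' @param standardize Use z-scored indices in the STS sum (default FALSE).
#' @return data.frame with columns `ssi`, `ti`, `si`, `hmi`, `mpi`, `gmpi`,
#'   `sti`, `sts`.
#' @export
stress_indices <- function(dw_c, dw_s,
                           dwbar_c = NULL, dwbar_s = NULL,
                           standardize = FALSE) {
  stop_if_negative(dw_c, "control dry weight")
  stop_if_negative(dw_s, "stress dry weight")
  complete <- !is.na(dw_c) & !is.na(dw_s)
  dwbar_c <- dwbar_c %||% mean(dw_c[complete])
  dwbar_s <- dwbar_s %||% mean(dw_s[complete])
  if (!is.finite(dwbar_c) || dwbar_c <= 0)
    stop("population mean control dry weight must be > 0")
  if (dwbar_s == dwbar_c)
    stop("population mean dry weights are equal: SSI denominator is zero (population-degenerate)")
  if (any(complete & dw_c <= 0))
    stop("genotype control dry weight must be > 0 for index computation")

  ssi  <- (1 - dw_s / dw_c) / (1 - dwbar_s / dwbar_c)
  ti   <- dw_c - dw_s
  si   <- dw_s / dw_c
  hmi  <- 2 * dw_c * dw_s / (dw_c + dw_s)
  mpi  <- (dw_c + dw_s) / 2
  gmpi <- sqrt(dw_c * dw_s)
  sti  <- dw_c * dw_s / dwbar_c^2

  idx <- cbind(ssi = ssi, ti = ti, si = si, hmi = hmi,
               mpi = mpi, gmpi = gmpi, sti = sti)
  sts <- if (standardize) rowSums(scale(idx)) else rowSums(idx)
  data.frame(idx, sts = sts)
}

#' Sum stress-tolerance scores over the three stresses
#'
#' `STS_SUM = STS_D + STS_DLP + STS_LP` per genotype; `NA` when any of the
#' three per-stress scores is missing.
#'
#' @param sts data.frame with columns `genotype`, `stress`, `sts`.
#' @param stresses Stress codes that must all be present (default LP, D,
#'   DLP).
#' @return data.frame with columns `genotype`, `sts_sum`.
#' @export
sts_sum <- function(sts, stresses = c("LP", "D", "DLP")) {
  gens <- unique(sts$genotype)
  out <- vapply(gens, function(g) {
    v <- sts$sts[sts$genotype == g][match(stresses, sts$stress[sts$genotype == g])]
    if (length(v) != length(stresses) || any(is.na(v))) NA_real_ else sum(v)
  }, numeric(1))
  data.frame(genotype = gens, sts_sum = out, row.names = NULL)
}

#' Normalize a profile of group means to unit sum
#'
#' Divides each value by the total, so the normalized values of all groups
#' sum to 1 for the trait: `x'_i = x_i / sum(x)`.
#'
#' @param x Numeric vector of group trait means with non-zero sum.
#' @return Vector of the same length summing to 1.
#' @export
normalize_profile <- function(x) {
  s <- sum(x)
  if (is.na(s) || s == 0) stop("profile sum is zero; normalization undefined")
  x / s
}

#' Per-genotype stress-index table from a trait table
#'
#' Block-averages the dry-weight trait per genotype and treatment, then
#' computes the seven indices, STS per stress, and STS_SUM across the three
#' stresses. Population mean dry weights are taken over genotypes with
#' complete control and stress values.
#'
#' @param traits Long trait table from [derive_traits()].
#' @param trait Dry-weight basis for the indices (default `"TDM"`, total
#'   dry mass).
#' @param stresses Stress codes to contrast against `"C"`.
#' @param standardize Passed to [stress_indices()].
#' @return List with `indices` (genotype, stress, the seven indices, sts)
#'   and `sts_sum` (genotype, sts_sum).
#' @export
stress_index_table <- function(traits, trait = "TDM",
                               stresses = intersect(c("LP", "D", "DLP"),
                                                    unique(traits$treatment)),
                               standardize = FALSE) {
  wide <- sapply(c("C", stresses), function(trt)
    genotype_means(traits, trt, select = trait)[, 1])
  gens <- rownames(wide) %||% seq_len(nrow(wide))
  rows <- list()
  for (s in stresses) {
    idx <- stress_indices(wide[, "C"], wide[, s], standardize = standardize)
    rows[[s]] <- data.frame(genotype = gens, stress = s, idx,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  indices <- do.call(rbind, rows)
  rownames(indices) <- NULL
  list(indices = indices, sts_sum = sts_sum(indices, stresses = stresses))
}

#' Δ-trait and PAE table for the stress treatments
#'
#' Relative changes of the root length and diameter traits (global, s1 and
#' sub) and phosphorus acquisition efficiency per genotype under each
#' stress, from block-averaged genotype means.
#'
#' @param traits Long trait table from [derive_traits()].
#' @param delta_traits Traits for which Δ = (stress - control)/control is
#'   reported.
#' @param p_trait Phosphorus-content trait used for PAE (default total P).
#' @param stresses Stress treatment codes.
#' @return Long data.frame: `genotype`, `stress`, `measure`
#'   (`"d<trait>"` or `"PAE"`), `value`.
#' @export
delta_pae_table <- function(traits,
                            delta_traits = c("RL", "RL_s1", "RL_sub",
                                             "RD", "RD_s1", "RD_sub"),
                            p_trait = "TP",
                            stresses = intersect(c("LP", "D", "DLP"),
                                                 unique(traits$treatment))) {
  out <- list()
  ctrl <- genotype_means(traits, "C", select = c(delta_traits, p_trait))
  for (s in stresses) {
    str <- genotype_means(traits, s, select = c(delta_traits, p_trait))
    for (tr in delta_traits) {
      out[[paste(s, tr)]] <- data.frame(
        genotype = rownames(ctrl), stress = s, measure = paste0("d", tr),
        value = relative_change(str[, tr], ctrl[, tr]),
        stringsAsFactors = FALSE)
    }
    out[[paste(s, "pae")]] <- data.frame(
      genotype = rownames(ctrl), stress = s, measure = "PAE",
      value = pae(str[, p_trait], ctrl[, p_trait]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
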