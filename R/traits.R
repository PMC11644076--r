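#' @title Trait derivation from plant records
#' @description Turn per-plant raw measurements into the full set of global
#'   and depth-local root and shoot traits used by the screening analyses.
#' @name trait_engine
NULL

# layer geometry of the growth panel: 20 cm layers on a 13 cm wide sheet,
# reference area 1430 cm^2 over 0-110 cm depth
PANEL_AREA_CM2 <- 1430
LAYER_WIDTH_CM <- 20
PANEL_WIDTH_CM <- 13

layer_cols <- function(plants, prefix) {
  cols <- grep(sprintf("^%s_s[0-9]+_", prefix), names(plants), value = TRUE)
  cols[order(as.integer(sub(sprintf("^%s_s([0-9]+)_.*$", prefix), "\\1", cols)))]
}

#' Derive global and depth-local traits from plant records
#'
#' Computes, for every plant, the whole-plant ("global") traits --
#' root length RL (cm), length-weighted mean diameter RD (mm), surface
#' area RA (cm^2) and volume RV (cm^3) from cylinder geometry, root length
#' density RLD = RL/1430 (cm cm^-2), specific root length SRL = RL/RDW
#' (cm g^-1), root length intensity RLI = RL/MRD (cm cm^-1), root tissue
#' density RTD = RDW/RV (g cm^-3), root and shoot growth rates
#' RGR = MRD/DAT and SGR = SH/DAT (cm d^-1), root:shoot ratio RSR,
#' total dry mass TDM, phosphorus contents RP = RPC*RDW, SP = SPC*SDW and
#' TP (mg) -- together with the depth-local traits of the top 20 cm root
#' layer (s1) and of everything below it to the root tip (sub): RL, RD, RA,
#' RV and RLD per segment plus the top/sub length ratio RLR_s1_sub.
#'
#' Undefined ratios (zero denominators) are flagged as `NA`, never returned
#' as zeros. If the input carries measured per-layer areas/volumes
#' (`ra_s*_cm2`, `rv_s*_cm3`), these override the geometric formulas.
#'
#' @param plants Plant-record data.frame (see [simulate_plants()] for the
#'   schema). Negative measurement values are an error.
#' @return Long-format data.frame with columns `genotype`, `treatment`,
#'   `block`, `trait`, `value`.
#' @export
derive_traits <- function(plants) {
  rl_cols <- layer_cols(plants, "rl")
  rd_cols <- layer_cols(plants, "rd")
  if (length(rl_cols) == 0 || length(rl_cols) != length(rd_cols))
    stop("plant table must carry matching rl_s*_cm and rd_s*_mm layer columns")
  L <- length(rl_cols)

  num_cols <- c("mrd_cm", "rn", rl_cols, rd_cols, "rdw_g", "sdw_g",
                "sh_cm", "ln", "tn", "rpc_mg_g", "spc_mg_g", "dat")
  for (cc in num_cols) stop_if_negative(plants[[cc]], cc)

  rl <- as.matrix(plants[, rl_cols])
  rd <- as.matrix(plants[, rd_cols])

  ra_cols <- layer_cols(plants, "ra")
  rv_cols <- layer_cols(plants, "rv")
  if (length(ra_cols) == L) {
    ra_lay <- as.matrix(plants[, ra_cols])
  } else {
    ra_lay <- pi * (rd / 10) * rl          # mm -> cm diameter
  }
  if (length(rv_cols) == L) {
    rv_lay <- as.matrix(plants[, rv_cols])
  } else {
    rv_lay <- (pi / 4) * (rd / 10)^2 * rl
  }

  safe_div <- function(num, den) ifelse(!is.na(den) & den > 0, num / den, NA_real_)

  RL <- rowSums(rl)
  RA <- rowSums(ra_lay)
  RV <- rowSums(rv_lay)
  RD <- safe_div(rowSums(rd * rl), RL)     # length-weighted mean diameter

  RL_s1  <- rl[, 1]
  RL_sub <- rowSums(rl[, -1, drop = FALSE])
  RA_s1  <- ra_lay[, 1]
  RA_sub <- rowSums(ra_lay[, -1, drop = FALSE])
  RV_s1  <- rv_lay[, 1]
  RV_sub <- rowSums(rv_lay[, -1, drop = FALSE])
  RD_s1  <- ifelse(RL_s1 > 0, rd[, 1], NA_real_)
  RD_sub <- safe_div(rowSums((rd * rl)[, -1, drop = FALSE]), RL_sub)

  s1_area  <- LAYER_WIDTH_CM * PANEL_WIDTH_CM
  sub_area <- PANEL_AREA_CM2 - s1_area

  MRD <- plants$mrd_cm
  RDW <- plants$rdw_g
  SDW <- plants$sdw_g
  DAT <- plants$dat

  vals <- list(
    MRD = MRD,
    RN  = plants$rn,
    RL  = RL,
    RD  = RD,
    RA  = RA,
    RV  = RV,
    RLD = RL / PANEL_AREA_CM2,
    SRL = safe_div(RL, RDW),
    RLI = safe_div(RL, MRD),
    RTD = safe_div(RDW, RV),
    RGR = safe_div(MRD, DAT),
    RDW = RDW,
    RPC = plants$rpc_mg_g,
    RP  = plants$rpc_mg_g * RDW,
    SDW = SDW,
    RSR = safe_div(RDW, SDW),
    TDM = RDW + SDW,
    SH  = plants$sh_cm,
    LN  = plants$ln,
    TN  = plants$tn,
    SGR = safe_div(plants$sh_cm, DAT),
    SPC = plants$spc_mg_g,
    SP  = plants$spc_mg_g * SDW,
    TP  = plants$rpc_mg_g * RDW + plants$spc_mg_g * SDW,
    RL_s1  = RL_s1,  RD_s1  = RD_s1,  RA_s1  = RA_s1,
    RV_s1  = RV_s1,  RLD_s1 = RL_s1 / s1_area,
    RL_sub = RL_sub, RD_sub = RD_sub, RA_sub = RA_sub,
    RV_sub = RV_sub, RLD_sub = RL_sub / sub_area,
    RLR_s1_sub = safe_div(RL_s1, RL_sub)
  )

  n <- nrow(plants)
  data.frame(
    genotype  = rep(plants$genotype, times = length(vals)),
    treatment = rep(plants$treatment, times = length(vals)),
    block     = rep(plants$block, times = length(vals)),
    trait     = rep(names(vals), each = n),
    value     = unlist(vals, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Global (whole-plant) traits in wide form
#'
#' @param plants Plant-record data.frame.
#' @return Wide data.frame: one row per plant, one column per global trait.
#' @export
derive_global_traits <- function(plants) {
  long <- derive_traits(plants)
  keep <- !grepl("_s1|_sub", long$trait)
  trait_pivot(long[keep, ])
}

#' Depth-local traits (s1 and sub segments) in wide form
#'
#' @param plants Plant-record data.frame.
#' @return Wide data.frame of the per-segment traits.
#' @export
derive_layer_traits <- function(plants) {
  long <- derive_traits(plants)
  keep <- grepl("_s1|_sub", long$trait)
  trait_pivot(long[keep, ])
}

#' Pivot a long trait table to one row per plant
#'
#' @param long Long trait table (`genotype`, `treatment`, `block`, `trait`,
#'   `value`).
#' @return Wide data.frame keyed by genotype x treatment x block.
#' @export
trait_pivot <- function(long) {
  key <- interaction(long$genotype, long$treatment, long$block, drop = TRUE)
  traits <- unique(long$trait)
  first <- !duplicated(key)
  out <- long[first, c("genotype", "treatment", "block")]
  for (tr in traits) {
    sub <- long[long$trait == tr, ]
    out[[tr]] <- sub$value[match(key[first], interaction(sub$genotype, sub$treatment, sub$block, drop = TRUE))]
  }
  rownames(out) <- NULL
  out
}

#' Genotype-mean trait matrix for one treatment
#'
#' Averages blocks within genotype and returns the genotype x trait matrix
#' for a single treatment -- the unit of analysis for correlations, PCA and
#' clustering.
#'
#' @param traits Long trait table from [derive_traits()].
#' @param treatment Treatment code to extract.
#' @param select Optional character vector of traits to keep.
#' @return Numeric matrix, rownames = genotype ids.
#' @export
genotype_means <- function(traits, treatment, select = NULL) {
  d <- traits[traits$treatment == treatment, ]
  if (nrow(d) == 0) stop("no rows for treatment ", treatment)
  if (!is.null(select)) d <- d[d$trait %in% select, ]
  agg <- stats::aggregate(value ~ genotype + trait, data = d,
                          FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
  gen <- sort(unique(agg$genotype))
  trs <- if (is.null(select)) unique(agg$trait) else select[select %in% agg$trait]
  m <- matrix(NA_real_, length(gen), length(trs), dimnames = list(gen, trs))
  m[cbind(match(agg$genotype, gen), match(agg$trait, trs))] <- agg$value
  m
}

#' Per-treatment descriptive statistics across genotypes
#'
#' Blocks are first averaged within genotype; the mean, sample SD and
#' coefficient of variation (CV = SD/mean) are then taken across genotype
#' means, per treatment and trait. A zero mean leaves the CV `NA`.
#'
#' @param traits Long trait table from [derive_traits()].
#' @return data.frame with columns `treatment`, `trait`, `n_genotypes`,
#'   `mean`, `sd`, `cv`.
#' @export
summarize_by_treatment <- function(traits) {
  out <- list()
  for (trt in unique(traits$treatment)) {
    m <- genotype_means(traits, trt)
    if (nrow(m) < 2)
      stop("at least 2 genotypes per treatment are required for dispersion statistics")
    mu <- colMeans(m, na.rm = TRUE)
    sd_ <- apply(m, 2, stats::sd, na.rm = TRUE)
    cv <- ifelse(!is.na(mu) & mu != 0, sd_ / mu, NA_real_)
    out[[trt]] <- data.frame(treatment = trt, trait = colnames(m),
                             n_genotypes = colSums(!is.na(m)),
                             mean = mu, sd = sd_, cv = cv,
                             stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}
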