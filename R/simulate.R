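#' Measured primitives carried by a simulated plant record
#'
#' The simulator draws these eleven whole-plant primitives directly; every
#' other trait (areas, volumes, densities, ratios, growth rates, P contents)
#' is derived from them by [derive_traits()].
#'
#' @format Character vector of trait codes: maximum root depth (MRD, cm),
#'   root number (RN), total root length (RL, cm), mean root diameter
#'   (RD, mm), root and shoot dry weight (RDW, SDW, g), shoot height (SH,
#'   cm), leaf and tiller number (LN, TN), root and shoot phosphorus
#'   concentration (RPC, SPC, mg g^-1).
#' @export
SIM_TRAITS <- c("MRD", "RN", "RL", "RD", "RDW", "SDW",
                "SH", "LN", "TN", "RPC", "SPC")

#' Configure a genotype x treatment trial simulation
#'
#' Builds and validates the parameter set for the log-normal trial
#' generator. Each primitive trait `t` of genotype `i` in treatment `j`,
#' block `k` is generated as
#' \deqn{y = \mu_t \, m_{tj} \, \exp(g_i + (gt)_{ij} + b_k + \epsilon)}
#' with `g`, `gt`, `b`, `eps` independent zero-mean Gaussians on the log
#' scale. Multipliers for the control treatment must equal 1.
#'
#' @param n_genotypes Number of genotypes.
#' @param treatments Treatment codes; the first code (or `"C"` when present)
#'   is the control. Default `c("C","LP","D","DLP")`: control, low
#'   phosphorus, PEG-induced drought, combined stress.
#' @param n_blocks Replicate blocks (sowing batches); at least 2 for
#'   heritability estimation.
#' @param n_layers Number of 20 cm depth layers on the growth panel
#'   (default 6, i.e. 0--120 cm).
#' @param dat Days after transplanting at harvest.
#' @param means Named positive vector of baseline (control) means over
#'   [SIM_TRAITS], in trait units.
#' @param multipliers Trait x treatment matrix of unitless treatment
#'   multipliers (rownames = traits, colnames = treatments). Defaults to 1.
#' @param sig2_g,sig2_gt,sig2_block,sig2_e Log-scale variance components
#'   (genotype, genotype x treatment, block, residual); scalars or named
#'   per-trait vectors, all >= 0.
#' @param seed Integer RNG seed stored with the configuration.
#' @return An object of class `sim_config`.
#' @seealso [wheat_preset()], [simulate_plants()]
#' @export
sim_config <- function(n_genotypes,
                       treatments = c("C", "LP", "D", "DLP"),
                       n_blocks = 4,
                       n_layers = 6,
                       dat = 65,
                       means = default_means(),
                       multipliers = NULL,
                       sig2_g = 0.15,
                       sig2_gt = 0.02,
                       sig2_block = 0.005,
                       sig2_e = 0.08,
                       seed = 1L) {
  traits <- SIM_TRAITS
  if (!all(traits %in% names(means)))
    stop("`means` must be named over all of: ", paste(traits, collapse = ", "))
  means <- means[traits]
  if (any(!is.finite(means)) || any(means <= 0))
    stop("all baseline means must be strictly positive")
  if (n_genotypes < 1 || n_blocks < 1 || n_layers < 1)
    stop("design dimensions must be positive")
  if (anyDuplicated(treatments)) stop("duplicated treatment codes")

  if (is.null(multipliers)) {
    multipliers <- matrix(1, length(traits), length(treatments),
                          dimnames = list(traits, treatments))
  }
  if (!all(traits %in% rownames(multipliers)) ||
      !all(treatments %in% colnames(multipliers)))
    stop("`multipliers` must cover every trait (rows) and treatment (columns)")
  multipliers <- multipliers[traits, treatments, drop = FALSE]
  if (any(!is.finite(multipliers)) || any(multipliers <= 0))
    stop("treatment multipliers must be positive")
  control <- if ("C" %in% treatments) "C" else treatments[1]
  if (any(abs(multipliers[, control] - 1) > 1e-12))
    stop("multipliers for the control treatment must all equal 1")

  expand_var <- function(v, nm) {
    if (length(v) == 1) v <- stats::setNames(rep(v, length(traits)), traits)
    if (!all(traits %in% names(v)))
      stop("per-trait `", nm, "` must be named over all simulated traits")
    v <- v[traits]
    if (any(!is.finite(v)) || any(v < 0))
      stop("variance components must be finite and >= 0")
    v
  }

  cfg <- structure(list(
    n_genotypes = as.integer(n_genotypes),
    treatments  = treatments,
    control     = control,
    n_blocks    = as.integer(n_blocks),
    n_layers    = as.integer(n_layers),
    dat         = dat,
    means       = means,
    multipliers = multipliers,
    sig2_g      = expand_var(sig2_g, "sig2_g"),
    sig2_gt     = expand_var(sig2_gt, "sig2_gt"),
    sig2_block  = expand_var(sig2_block, "sig2_block"),
    sig2_e      = expand_var(sig2_e, "sig2_e"),
    seed        = as.integer(seed)
  ), class = "sim_config")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Trial simulation configuration\n")
  cat(sprintf("  %d genotypes x %d treatments (%s) x %d blocks; %d x 20 cm layers; harvest %g DAT\n",
              x$n_genotypes, length(x$treatments),
              paste(x$treatments, collapse = ", "), x$n_blocks,
              x$n_layers, x$dat))
  cat(sprintf("  seed %d; control = %s\n", x$seed, x$control))
  invisible(x)
}

# Baseline control means for a winter-wheat screen in a semi-hydroponic
# panel system (trait units as in SIM_TRAITS).
default_means <- function() {
  c(MRD = 55.10, RN = 8.64, RL = 1290.21, RD = 0.18,
    RDW = 0.12, SDW = 0.52, SH = 45, LN = 8, TN = 3,
    RPC = 1.6, SPC = 2.4)
}

#' Preset configuration for a 100-genotype wheat screening trial
#'
#' Returns a [sim_config()] emulating a 100-genotype x 4-treatment
#' (C, LP, D, DLP) x 4-block winter-wheat screen harvested at 65 days
#' after transplanting. Treatment multipliers follow the characteristic
#' stress responses of such trials: drought (D) lengthens and deepens the
#' root system, low phosphorus (LP) and especially the combined stress
#' (DLP) depress biomass, shoot growth and phosphorus status, and all
#' three stresses thicken mean root diameter.
#'
#' @param seed RNG seed for the configuration.
#' @return A `sim_config` object.
#' @export
wheat_preset <- function(seed = 1L) {
  traits <- SIM_TRAITS
  trt <- c("C", "LP", "D", "DLP")
  m <- matrix(1, length(traits), 4, dimnames = list(traits, trt))
  m["MRD", ] <- c(1, 1.4495, 1.3301, 1.3577)
  m["RL",  ] <- c(1, 1.0777, 1.4313, 0.9628)
  m["RD",  ] <- c(1, 1.3333, 1.3333, 1.2778)
  m["RDW", ] <- c(1, 0.7500, 1.1667, 0.5833)
  m["SDW", ] <- c(1, 0.2308, 0.3077, 0.2115)
  m["RN",  ] <- c(1, 0.7164, 0.5683, 0.6493)
  m["SH",  ] <- c(1, 0.75, 0.80, 0.65)
  m["LN",  ] <- c(1, 0.80, 0.85, 0.60)
  m["TN",  ] <- c(1, 0.70, 0.75, 0.60)
  m["RPC", ] <- c(1, 0.60, 0.85, 0.50)
  m["SPC", ] <- c(1, 0.55, 0.80, 0.45)
  sim_config(n_genotypes = 100, treatments = trt, n_blocks = 4,
             n_layers = 6, dat = 65, multipliers = m, seed = seed)
}

#' Simulate replicated values of a single trait
#'
#' Low-level generator behind [simulate_plants()]: draws one positive trait
#' for every genotype x treatment x block cell from the multiplicative
#' log-normal model with additive genotype, genotype-by-treatment, block and
#' residual components on the log scale.
#'
#' @param n_genotypes,treatments,n_blocks Design dimensions.
#' @param mu Baseline (control) mean, > 0.
#' @param multipliers Named vector of treatment multipliers (default all 1).
#' @param sig2_g,sig2_gt,sig2_block,sig2_e Log-scale variances, >= 0.
#' @return A data.frame with columns `genotype`, `treatment`, `block`,
#'   `value`, one row per cell.
#' @export
simulate_trait_values <- function(n_genotypes, treatments = "C", n_blocks = 4,
                                  mu = 1, multipliers = NULL,
                                  sig2_g = 0, sig2_gt = 0,
                                  sig2_block = 0, sig2_e = 0) {
  if (mu <= 0) stop("baseline mean must be strictly positive")
  if (any(c(sig2_g, sig2_gt, sig2_block, sig2_e) < 0))
    stop("variance components must be >= 0")
  if (is.null(multipliers))
    multipliers <- stats::setNames(rep(1, length(treatments)), treatments)
  multipliers <- multipliers[treatments]

  nT <- length(treatments)
  g  <- stats::rnorm(n_genotypes, 0, sqrt(sig2_g))
  gt <- matrix(stats::rnorm(n_genotypes * nT, 0, sqrt(sig2_gt)), n_genotypes, nT)
  b  <- stats::rnorm(n_blocks, 0, sqrt(sig2_block))

  d <- expand.grid(block = seq_len(n_blocks),
                   treatment = treatments,
                   genotype = seq_len(n_genotypes),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("genotype", "treatment", "block")]
  it <- match(d$treatment, treatments)
  eps <- stats::rnorm(nrow(d), 0, sqrt(sig2_e))
  d$value <- mu * multipliers[it] *
    exp(g[d$genotype] + gt[cbind(d$genotype, it)] + b[d$block] + eps)
  rownames(d) <- NULL
  d
}

# Depth-layer allocation of total root length. Occupied layers are those the
# root system reaches (20*(k-1) < MRD). Shallow-rooting treatments (C, LP)
# weight the split toward the top layer, drought treatments (D, DLP) toward
# depth; with noise the weights perturb a Dirichlet draw, otherwise the
# expected weights are used so that a noise-free configuration is fully
# deterministic.
allocate_layers <- function(mrd, rl, deep, n_layers, noisy, conc = 8) {
  n_occ <- max(1L, min(ceiling(mrd / 20), n_layers))
  k <- seq_len(n_occ)
  rate <- if (deep) 0.25 else 0.9
  w <- exp(-rate * (k - 1))
  w <- w / sum(w)
  p <- if (noisy && n_occ > 1) {
    gam <- stats::rgamma(n_occ, shape = w * conc)
    if (sum(gam) <= 0) w else gam / sum(gam)
  } else w
  out <- numeric(n_layers)
  out[k] <- rl * p
  out
}

#' Generate a plant-level measurement table
#'
#' Draws one plant record per genotype x treatment x block cell of the
#' configured design. Whole-plant primitives come from the log-normal model
#' of [simulate_trait_values()]; counts (RN, LN, TN) are rounded to
#' non-negative integers; maximum root depth is clamped to the panel window;
#' total root length is split across the occupied 20 cm depth layers and
#' layer diameters are rescaled so their length-weighted mean equals the
#' simulated whole-plant diameter exactly. Identical configurations and
#' seeds give bit-identical tables.
#'
#' @param config A [sim_config()] object.
#' @param seed Optional override of `config$seed`.
#' @return A data.frame in the plant-record schema: `genotype`, `treatment`,
#'   `block`, `mrd_cm`, `rn`, `rl_s1_cm` ... `rl_sL_cm`,
#'   `rd_s1_mm` ... `rd_sL_mm`, `rdw_g`, `sdw_g`, `sh_cm`, `ln`, `tn`,
#'   `rpc_mg_g`, `spc_mg_g`, `dat`.
#' @export
simulate_plants <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed %||% config$seed)

  L <- config$n_layers
  noisy <- any(config$sig2_g > 0 | config$sig2_gt > 0 |
               config$sig2_block > 0 | config$sig2_e > 0)

  sims <- lapply(SIM_TRAITS, function(tr) {
    simulate_trait_values(config$n_genotypes, config$treatments,
                          config$n_blocks,
                          mu = config$means[[tr]],
                          multipliers = config$multipliers[tr, ],
                          sig2_g = config$sig2_g[[tr]],
                          sig2_gt = config$sig2_gt[[tr]],
                          sig2_block = config$sig2_block[[tr]],
                          sig2_e = config$sig2_e[[tr]])
  })
  names(sims) <- SIM_TRAITS

  d <- sims[[1]][, c("genotype", "treatment", "block")]
  val <- lapply(sims, `[[`, "value")

  mrd <- pmin(val$MRD, 20 * L)            # root tip within the panel window
  rl  <- val$RL
  rd  <- val$RD
  deep <- d$treatment %in% c("D", "DLP")

  rl_layers <- matrix(0, nrow(d), L)
  rd_layers <- matrix(0, nrow(d), L)
  for (i in seq_len(nrow(d))) {
    rli <- allocate_layers(mrd[i], rl[i], deep[i], L, noisy)
    occ <- rli > 0
    # mild thickening toward the surface plus record-level noise, rescaled so
    # the length-weighted mean diameter reproduces the simulated RD exactly
    raw <- 0.95^(seq_len(L) - 1)
    if (noisy) raw <- raw * exp(stats::rnorm(L, 0, 0.1))
    raw[!occ] <- 0
    wm <- sum(raw * rli) / rl[i]
    rd_layers[i, ] <- raw * (rd[i] / wm)
    rl_layers[i, ] <- rli
  }

  out <- data.frame(
    genotype = d$genotype,
    treatment = d$treatment,
    block = d$block,
    mrd_cm = mrd,
    rn = pmax(0, round(val$RN)),
    stringsAsFactors = FALSE
  )
  colnames(rl_layers) <- sprintf("rl_s%d_cm", seq_len(L))
  colnames(rd_layers) <- sprintf("rd_s%d_mm", seq_len(L))
  out <- cbind(out, rl_layers, rd_layers)
  out$rdw_g <- val$RDW
  out$sdw_g <- val$SDW
  out$sh_cm <- val$SH
  out$ln <- pmax(0, round(val$LN))
  out$tn <- pmax(0, round(val$TN))
  out$rpc_mg_g <- val$RPC
  out$spc_mg_g <- val$SPC
  out$dat <- config$dat
  out
}
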