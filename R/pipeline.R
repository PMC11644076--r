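#' Validate a plant-record table against the screening schema
#'
#' Checks column presence and types, non-negativity of every measurement,
#' treatment codes, duplicate design keys, and the depth-consistency rule
#' that a layer can carry root length only if the maximum root depth
#' reaches it (`rl_sk > 0` requires `20 (k-1) < mrd_cm`). All violations
#' are collected and reported together.
#'
#' @param plants data.frame to validate.
#' @param n_layers Expected number of 20 cm layers; inferred from the
#'   columns when `NULL`.
#' @return Invisibly `TRUE`; stops with an aggregated report otherwise.
#' @export
validate_plants <- function(plants, n_layers = NULL) {
  errs <- character()
  base_cols <- c("genotype", "treatment", "block", "mrd_cm", "rn",
                 "rdw_g", "sdw_g", "sh_cm", "ln", "tn",
                 "rpc_mg_g", "spc_mg_g", "dat")
  missing <- setdiff(base_cols, names(plants))
  if (length(missing))
    errs <- c(errs, paste("missing required columns:",
                          paste(missing, collapse = ", ")))
  rl_cols <- layer_cols(plants, "rl")
  rd_cols <- layer_cols(plants, "rd")
  L <- n_layers %||% length(rl_cols)
  if (length(rl_cols) == 0)
    errs <- c(errs, "no rl_s*_cm layer columns found")
  if (length(rl_cols) != length(rd_cols))
    errs <- c(errs, "rl_s*_cm and rd_s*_mm layer columns do not match")
  if (length(rl_cols) != L)
    errs <- c(errs, sprintf("expected %d layers, found %d", L, length(rl_cols)))
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)

  bad_trt <- setdiff(unique(plants$treatment), c("C", "LP", "D", "DLP"))
  if (length(bad_trt))
    errs <- c(errs, paste("unknown treatment codes:",
                          paste(bad_trt, collapse = ", ")))

  num_cols <- c("mrd_cm", "rn", rl_cols, rd_cols, "rdw_g", "sdw_g",
                "sh_cm", "ln", "tn", "rpc_mg_g", "spc_mg_g", "dat")
  for (cc in num_cols) {
    v <- plants[[cc]]
    if (!is.numeric(v)) {
      errs <- c(errs, paste0("column ", cc, " is not numeric"))
      next
    }
    bad <- which(!is.na(v) & v < 0)
    if (length(bad))
      errs <- c(errs, sprintf("negative values in %s (rows %s)", cc,
                              paste(utils::head(bad, 5), collapse = ", ")))
  }

  key <- interaction(plants$genotype, plants$treatment, plants$block, drop = TRUE)
  if (anyDuplicated(key))
    errs <- c(errs, sprintf("duplicated genotype x treatment x block keys (e.g. row %d)",
                            which(duplicated(key))[1]))

  for (k in seq_along(rl_cols)) {
    v <- plants[[rl_cols[k]]]
    bad <- which(!is.na(v) & v > 0 & plants$mrd_cm <= 20 * (k - 1))
    if (length(bad))
      errs <- c(errs, sprintf(
        "%s > 0 although mrd_cm does not reach layer %d (rows %s)",
        rl_cols[k], k, paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)
  invisible(TRUE)
}

#' Read a plant-record CSV and validate it
#'
#' @param path Path to a CSV in the plant-record schema.
#' @param n_layers Passed to [validate_plants()].
#' @return Validated data.frame.
#' @export
read_plants <- function(path, n_layers = NULL) {
  plants <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_plants(plants, n_layers = n_layers)
  plants
}

#' Run the full genotype-screening pipeline
#'
#' Executes every stage of the screening analysis on measured or simulated
#' plant records: trait derivation, per-treatment descriptive statistics,
#' stress-tolerance indices and scores, factorial ANOVA and broad-sense
#' heritability per trait, log-response-ratio effect sizes with pooled
#' per-stress and overall effects, and the multivariate block (CV-based
#' trait selection, Pearson correlations, standardized PCA, average-linkage
#' clustering per treatment, STS-based tolerance grouping). With `out_dir`
#' set, every stage also writes its CSV; identical inputs and seeds give
#' bit-identical output trees.
#'
#' @param config [sim_config()] used to simulate plants when `plants` is
#'   `NULL` (default [wheat_preset()]).
#' @param plants Optional measured plant-record table (validated first).
#' @param cv_threshold CV threshold for multivariate trait selection.
#' @param k Number of cluster/tolerance groups.
#' @param seed Overrides the configuration seed.
#' @param out_dir Optional output directory for the CSV bundle.
#' @param anova_traits Traits to run the factorial ANOVA on (default: all
#'   derived traits).
#' @return Object of class `root_screen` bundling all stage results.
#' @export
run_screen <- function(config = wheat_preset(), plants = NULL,
                       cv_threshold = 0.3, k = 5, seed = NULL,
                       out_dir = NULL, anova_traits = NULL) {
  seed <- as.integer(seed %||% config$seed)
  if (is.null(plants)) plants <- simulate_plants(config, seed = seed)
  validate_plants(plants)

  traits <- derive_traits(plants)
  summary_tab <- summarize_by_treatment(traits)

  idx <- stress_index_table(traits)
  dpae <- delta_pae_table(traits)

  all_traits <- unique(traits$trait)
  anova_traits <- anova_traits %||% all_traits
  anova_tab <- do.call(rbind, lapply(anova_traits, function(tr) {
    tab <- tryCatch(factorial_anova(traits, tr), error = function(e) NULL)
    if (is.null(tab)) return(NULL)
    cbind(trait = tr, tab)
  }))

  herit <- rbind(
    heritability(traits, all_traits),
    do.call(rbind, lapply(unique(traits$treatment), function(trt)
      heritability(traits, all_traits, treatment = trt)))
  )

  effects <- suppressWarnings(effect_table(traits))
  pooled <- do.call(rbind, lapply(split(effects, effects$stress), function(d)
    cbind(stress = d$stress[1], pool_effects(d))))
  overall <- cbind(stress = "all", pool_effects(effects))
  pooled <- rbind(pooled, overall)
  rownames(pooled) <- NULL

  # multivariate block: trait selection on control-treatment CVs
  cv_c <- with(summary_tab[summary_tab$treatment == "C", ],
               stats::setNames(cv, trait))
  globals <- all_traits[!grepl("_s1|_sub", all_traits)]
  selected <- filter_by_cv(cv_c[globals], threshold = cv_threshold)

  corr <- pearson_with_p(genotype_means(traits, "C", select = selected))
  pca <- pca_standardized(genotype_means(traits, "C", select = selected))
  clusters <- lapply(stats::setNames(nm = unique(traits$treatment)), function(trt)
    ahc_cluster(genotype_means(traits, trt, select = selected), k = k))
  groups <- sts_grouping(stats::setNames(idx$sts_sum$sts_sum,
                                         idx$sts_sum$genotype), k = k)

  res <- structure(list(
    plants = plants, traits = traits, summary = summary_tab,
    indices = idx$indices, sts_sum = idx$sts_sum, delta_pae = dpae,
    anova = anova_tab, heritability = herit,
    effects = effects, pooled_effects = pooled,
    selected_traits = selected, correlation = corr, pca = pca,
    clusters = clusters, sts_groups = groups,
    cv_threshold = cv_threshold, k = k, seed = seed
  ), class = "root_screen")

  if (!is.null(out_dir)) write_screen(res, out_dir)
  res
}

# CSV bundle for a finished run; plain write.csv so reruns are bit-identical
write_screen <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(d, name)
    utils::write.csv(d, file.path(out_dir, name), row.names = FALSE)
  wr(res$plants, "plants.csv")
  wr(res$traits, "traits_long.csv")
  wr(res$summary, "treatment_summary.csv")
  wr(res$indices, "stress_indices.csv")
  wr(res$sts_sum, "sts_sum.csv")
  wr(res$delta_pae, "delta_pae.csv")
  if (!is.null(res$anova)) wr(res$anova, "anova.csv")
  wr(res$heritability, "heritability.csv")
  wr(res$effects, "effects.csv")
  wr(res$pooled_effects, "effects_pooled.csv")

  r <- res$correlation$r
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  wr(data.frame(trait_i = rownames(r)[pairs[, 1]],
                trait_j = colnames(r)[pairs[, 2]],
                r = r[pairs], p = res$correlation$p[pairs],
                stars = res$correlation$stars[pairs]),
     "correlation.csv")
  wr(data.frame(component = paste0("PC", seq_along(res$pca$eigenvalues)),
                eigenvalue = res$pca$eigenvalues,
                explained_pct = res$pca$explained),
     "pca_eigenvalues.csv")
  wr(data.frame(trait = rownames(res$pca$rotation), res$pca$loadings),
     "pca_loadings.csv")
  assign_rows <- do.call(rbind, lapply(names(res$clusters), function(trt)
    data.frame(genotype = names(res$clusters[[trt]]$labels),
               treatment = trt,
               group = unname(res$clusters[[trt]]$labels))))
  wr(assign_rows, "clusters.csv")
  prof <- do.call(rbind, lapply(names(res$clusters), function(trt) {
    p <- res$clusters[[trt]]$profile
    data.frame(treatment = trt, group = rownames(p) %||% seq_len(nrow(p)), p)
  }))
  wr(prof, "cluster_profiles.csv")
  wr(data.frame(genotype = names(res$sts_groups$labels),
                group = unname(res$sts_groups$labels),
                roman = unname(res$sts_groups$roman)),
     "sts_groups.csv")
  log <- c(sprintf("seed: %d", res$seed),
           sprintf("plants: %d rows", nrow(res$plants)),
           sprintf("traits: %d rows (%d traits)", nrow(res$traits),
                   length(unique(res$traits$trait))),
           sprintf("selected traits (CV >= %g): %s", res$cv_threshold,
                   paste(res$selected_traits, collapse = ", ")),
           sprintf("cluster groups k = %d", res$k))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.root_screen <- function(x, ...) {
  nt <- length(unique(x$traits$trait))
  cat("Root-trait genotype screen\n")
  cat(sprintf("  %d plants (%d genotypes x %s x %d blocks), %d derived traits\n",
              nrow(x$plants), length(unique(x$plants$genotype)),
              paste(unique(x$plants$treatment), collapse = "/"),
              length(unique(x$plants$block)), nt))
  cat(sprintf("  %d traits selected at CV >= %g: %s\n",
              length(x$selected_traits), x$cv_threshold,
              paste(x$selected_traits, collapse = ", ")))
  cat(sprintf("  PCA: %d components with eigenvalue > 1 (%.1f%% variance)\n",
              x$pca$retained, sum(x$pca$explained[seq_len(x$pca$retained)])))
  cat(sprintf("  STS grouping: %s genotypes in group I (most tolerant)\n",
              sum(x$sts_groups$labels == 1)))
  invisible(x)
}

#' @export
summary.root_screen <- function(object, ...) {
  print(object)
  cat("\nPooled effect sizes (log response ratio):\n")
  print(object$pooled_effects[, c("stress", "k", "lnr", "ci_low", "ci_high", "pct")],
        digits = 3, row.names = FALSE)
  h <- object$heritability
  h <- h[h$scope == "combined" & !is.na(h$h), ]
  cat(sprintf("\nCombined heritability: median %.2f over %d traits; %d traits with H > 0.5\n",
              stats::median(h$h), nrow(h), sum(h$h > 0.5)))
  invisible(object)
}
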