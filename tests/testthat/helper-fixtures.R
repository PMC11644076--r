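# fixtures built in code: single plant records and tiny trial designs

# one plant record with overridable fields; defaults give a well-formed,
# 3-layer root system reaching 50 cm
make_plant <- function(...,
                       genotype = 1, treatment = "C", block = 1,
                       mrd_cm = 50, rn = 6,
                       rl = c(100, 50, 25), rd = c(0.3, 0.2, 0.2),
                       rdw_g = 0.1, sdw_g = 0.5, sh_cm = 40,
                       ln = 8, tn = 3, rpc_mg_g = 1.5, spc_mg_g = 2.5,
                       dat = 65) {
  p <- data.frame(genotype = genotype, treatment = treatment, block = block,
                  mrd_cm = mrd_cm, rn = rn, stringsAsFactors = FALSE)
  for (k in seq_along(rl)) p[[sprintf("rl_s%d_cm", k)]] <- rl[k]
  for (k in seq_along(rd)) p[[sprintf("rd_s%d_mm", k)]] <- rd[k]
  p$rdw_g <- rdw_g; p$sdw_g <- sdw_g; p$sh_cm <- sh_cm
  p$ln <- ln; p$tn <- tn
  p$rpc_mg_g <- rpc_mg_g; p$spc_mg_g <- spc_mg_g; p$dat <- dat
  extra <- list(...)
  for (nm in names(extra)) p[[nm]] <- extra[[nm]]
  p
}

# long trait table built directly from explicit values:
# vals is a named list trait -> vector over the design rows
make_trait_table <- function(genotype, treatment, block, vals) {
  do.call(rbind, lapply(names(vals), function(tr)
    data.frame(genotype = genotype, treatment = treatment, block = block,
               trait = tr, value = vals[[tr]], stringsAsFactors = FALSE)))
}

# small noise-free configuration (every replicate identical)
noise_free_config <- function(n_genotypes = 3, treatments = c("C", "D"),
                              n_blocks = 2, seed = 1) {
  sim_config(n_genotypes = n_genotypes, treatments = treatments,
             n_blocks = n_blocks, n_layers = 6,
             sig2_g = 0, sig2_gt = 0, sig2_block = 0, sig2_e = 0,
             seed = seed)
}
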