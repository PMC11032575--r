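# Shared fixtures, built in code at test time.

small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_genes = 30L, n_chromosomes = 2L,
         chrom_length_bp = 60000L, n_blocks_per_chrom = 5L,
         n_offspring = 20L, n_reads = 2000L),
    list(...))
  do.call(sim_config, args)
}

# founders + mosaic + diploid for one small strain
small_reference <- function(seed = 1) {
  cfg <- small_config(seed)
  founders <- gen_founders(cfg)
  mosaic <- gen_mosaic(cfg, "CC006")
  strain <- build_strain_transcriptome(mosaic, founders)
  diploid <- build_f1_diploid(strain, founders = founders)
  list(config = cfg, founders = founders, mosaic = mosaic,
       strain = strain, diploid = diploid)
}

# expression with planted modules for network tests
planted_expression <- function(seed, n_genes = 600L, n_modules = 5L,
                               module_size = 120L, noise_sd = 0.3,
                               n_samples = 50L, strain = "CCx", ...) {
  cfg <- sim_config(
    seed = seed, n_genes = n_genes, n_offspring = n_samples,
    noise_sd = noise_sd,
    module_spec = replicate(n_modules,
                            list(module_size = module_size,
                                 factor_effect_sd = 1), simplify = FALSE),
    ...)
  gen_expression(cfg, simulate_cross(cfg, gen_mosaic(cfg, strain)))
}

# adjusted Rand index (independent of mclust for portability of unit tests,
# but acceptance uses mclust::adjustedRandIndex as the oracle)
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_ <- si * sj / n
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
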