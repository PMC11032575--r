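#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' emulate the study design the pipeline targets: eight founder strains with
#' strain-specific SNPs, recombinant-inbred haplotype mosaics, F1 crosses of
#' hemizygous transgene carriers to wildtype Collaborative Cross males (50
#' percent carriers among offspring), 43 bp reads drawn from a diploid
#' transcriptome, and expression matrices with planted co-expression modules
#' and covariate effects.
#'
#' @param seed integer; mandatory master seed. Every generator is a pure
#'   function of `(config, seed)` - there is no implicit entropy.
#' @param n_genes number of genes (one intron-free transcript per gene).
#' @param n_chromosomes number of autosomes.
#' @param chrom_length_bp autosome length in bp.
#' @param snp_rate per-bp probability that a position segregates among the
#'   founders (default 0.005, of the order of the panel's variant density).
#' @param n_blocks_per_chrom haplotype blocks per autosome in a mosaic.
#' @param n_offspring F1 offspring per simulated cross.
#' @param transgene_carrier_prob probability an offspring carries the
#'   transgene (0.5 for a hemizygous x wildtype cross).
#' @param read_length read length in bp (43, single-end in the simulator).
#' @param n_reads number of reads to simulate.
#' @param sequencing_error_rate per-base substitution probability.
#' @param module_spec list of planted co-expression modules, each a list
#'   with elements `module_size` and `factor_effect_sd` (the scale of gene
#'   loadings on the module's latent sample factor).
#' @param covariate_effects named list, one element per metadata covariate
#'   (`genotype`, `sex`, `age`), each a list with `prop` (fraction of genes
#'   affected), `mean` and `sd` of the per-gene effect on the log2 scale.
#' @param noise_sd residual Gaussian noise SD of simulated log2 expression.
#' @param include_mt simulate a maternal-only mitochondrial chromosome.
#' @param n_mt_genes genes placed on chrMT (taken out of `n_genes`).
#' @param mt_length_bp chrMT length in bp.
#' @param transcript_length_range min/max transcript length in bp.
#' @param n_qc_metrics number of correlated sequencing-QC metrics per sample
#'   (carrying a planted batch direction) from which sequencing PCs are
#'   computed.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 50, n_chromosomes = 2)
sim_config <- function(seed,
                       n_genes = 200L,
                       n_chromosomes = 3L,
                       chrom_length_bp = 100000L,
                       snp_rate = 0.005,
                       n_blocks_per_chrom = 10L,
                       n_offspring = 24L,
                       transgene_carrier_prob = 0.5,
                       read_length = 43L,
                       n_reads = 10000L,
                       sequencing_error_rate = 0,
                       module_spec = list(),
                       covariate_effects = list(),
                       noise_sd = 1,
                       include_mt = TRUE,
                       n_mt_genes = 2L,
                       mt_length_bp = 16000L,
                       transcript_length_range = c(500L, 1500L),
                       n_qc_metrics = 8L) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' is mandatory and must be a single integer", call. = FALSE)
  stopifnot_positive(n_genes, "n_genes")
  stopifnot_positive(n_chromosomes, "n_chromosomes")
  stopifnot_positive(chrom_length_bp, "chrom_length_bp")
  stopifnot_scalar_prob(snp_rate, "snp_rate")
  stopifnot_positive(n_blocks_per_chrom, "n_blocks_per_chrom")
  stopifnot_positive(n_offspring, "n_offspring")
  stopifnot_scalar_prob(transgene_carrier_prob, "transgene_carrier_prob")
  stopifnot_positive(read_length, "read_length")
  stopifnot_positive(n_reads, "n_reads")
  stopifnot_scalar_prob(sequencing_error_rate, "sequencing_error_rate")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (length(transcript_length_range) != 2L ||
      transcript_length_range[1] > transcript_length_range[2])
    stop("'transcript_length_range' must be c(min, max)", call. = FALSE)
  if (length(module_spec)) {
    sizes <- vapply(module_spec, function(m) as.numeric(m$module_size), 0)
    if (any(sizes <= 0)) stop("module sizes must be positive", call. = FALSE)
    if (sum(sizes) > n_genes)
      stop("module_spec sizes must sum to <= n_genes", call. = FALSE)
  }
  if (include_mt && n_mt_genes >= n_genes)
    stop("n_mt_genes must be smaller than n_genes", call. = FALSE)

  structure(list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.integer(chrom_length_bp),
    snp_rate = snp_rate,
    n_blocks_per_chrom = as.integer(n_blocks_per_chrom),
    n_offspring = as.integer(n_offspring),
    transgene_carrier_prob = transgene_carrier_prob,
    read_length = as.integer(read_length),
    n_reads = as.integer(n_reads),
    sequencing_error_rate = sequencing_error_rate,
    module_spec = module_spec,
    covariate_effects = covariate_effects,
    noise_sd = noise_sd,
    include_mt = isTRUE(include_mt),
    n_mt_genes = as.integer(n_mt_genes),
    mt_length_bp = as.integer(mt_length_bp),
    transcript_length_range = as.integer(transcript_length_range),
    n_qc_metrics = as.integer(n_qc_metrics)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$n_genes, "genes on",
      x$n_chromosomes, "autosomes",
      if (x$include_mt) "+ chrMT" else "", "\n")
  invisible(x)
}
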