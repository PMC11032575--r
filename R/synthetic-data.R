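# Synthetic-data generator: founder transcriptomes, haplotype mosaics,
# F1 crosses, reads, and expression matrices with planted structure.
# Every generator records its ground truth so downstream stages can be
# scored exactly.

#' Generate the eight founder strain transcriptomes
#'
#' Builds a shared transcript skeleton (intron-free transcripts laid out
#' non-overlapping along each chromosome), plants segregating SNP positions
#' at rate `snp_rate` per transcribed bp, and derives the eight founder
#' sequences. Founder B (C57BL/6J) is the reference: at each SNP the B
#' allele is the reference base and each other founder carries the
#' alternate base independently with probability 1/2. The SNP table is the
#' ground truth against which reference construction and allele-aware
#' quantification can be scored.
#'
#' @param config a [sim_config()].
#' @return object of class `founder_set`: list with `founders` (named list
#'   A..H of data.frames `transcript_id, gene_id, chromosome, start, end,
#'   sequence`), `skeleton` (the shared coordinate table), `snps` (ground
#'   truth: chromosome, genomic position, transcript, position in
#'   transcript, ref/alt base, and one logical column per founder telling
#'   whether it carries the alternate allele), and `chrom_lengths`.
#' @export
gen_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "founders"), {
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    lens <- stats::setNames(rep(config$chrom_length_bp, length(chroms)), chroms)
    n_auto <- config$n_genes - if (config$include_mt) config$n_mt_genes else 0L
    if (config$include_mt) {
      chroms <- c(chroms, "chrMT")
      lens <- c(lens, chrMT = config$mt_length_bp)
    }

    # genes per chromosome: autosomes near-evenly, MT its own quota
    per_chrom <- diff(round(seq(0, n_auto, length.out = config$n_chromosomes + 1L)))
    if (config$include_mt) per_chrom <- c(per_chrom, config$n_mt_genes)

    skel <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
      n <- per_chrom[ci]
      if (n == 0L) return(NULL)
      L <- lens[ci]
      lrange <- seq.int(config$transcript_length_range[1],
                        config$transcript_length_range[2])
      tl <- lrange[sample.int(length(lrange), n, replace = TRUE)]
      if (sum(tl) + n > L)
        stop(sprintf("chromosome %s (%d bp) cannot hold %d transcripts",
                     chroms[ci], L, n), call. = FALSE)
      free <- L - sum(tl)
      gaps <- diff(c(0, sort(sample.int(free, n))))
      starts <- cumsum(gaps) + cumsum(c(0L, tl[-n])) + 1L
      data.frame(chromosome = chroms[ci], start = starts,
                 end = starts + tl - 1L, stringsAsFactors = FALSE)
    }))
    skel <- skel[order(match(skel$chromosome, chroms), skel$start), ]
    skel$transcript_id <- sprintf("tx%04d", seq_len(nrow(skel)))
    skel$gene_id <- sprintf("gene%04d", seq_len(nrow(skel)))
    skel <- skel[, c("transcript_id", "gene_id", "chromosome", "start", "end")]
    rownames(skel) <- NULL

    # reference (founder B) sequences and segregating sites
    tl <- skel$end - skel$start + 1L
    ref_seq <- vapply(tl, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))

    snp_list <- lapply(seq_len(nrow(skel)), function(i) {
      pos <- which(stats::runif(tl[i]) < config$snp_rate)
      if (!length(pos)) return(NULL)
      refb <- substring(ref_seq[i], pos, pos)
      altb <- vapply(refb, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1),
        USE.NAMES = FALSE)
      carrier <- matrix(stats::runif(length(pos) * 7L) < 0.5, ncol = 7L)
      out <- data.frame(
        transcript_id = skel$transcript_id[i],
        chromosome = skel$chromosome[i],
        position = skel$start[i] + pos - 1L,
        pos_in_tx = pos, ref = refb, alt = altb,
        stringsAsFactors = FALSE)
      carriers <- cbind(A = carrier[, 1], B = FALSE, C = carrier[, 2],
                        D = carrier[, 3], E = carrier[, 4], F = carrier[, 5],
                        G = carrier[, 6], H = carrier[, 7])
      cbind(out, as.data.frame(carriers))
    })
    snps <- do.call(rbind, snp_list)
    if (is.null(snps))
      snps <- cbind(
        data.frame(transcript_id = character(), chromosome = character(),
                   position = integer(), pos_in_tx = integer(),
                   ref = character(), alt = character(),
                   stringsAsFactors = FALSE),
        as.data.frame(matrix(logical(), 0, 8,
                             dimnames = list(NULL, FOUNDER_CODES))))
    rownames(snps) <- NULL

    founders <- lapply(FOUNDER_CODES, function(code) {
      seqs <- ref_seq
      if (nrow(snps)) {
        carry <- snps[snps[[code]], , drop = FALSE]
        if (nrow(carry)) {
          for (i in seq_len(nrow(carry))) {
            k <- match(carry$transcript_id[i], skel$transcript_id)
            substring(seqs[k], carry$pos_in_tx[i], carry$pos_in_tx[i]) <-
              carry$alt[i]
          }
        }
      }
      out <- skel
      out$sequence <- seqs
      out
    })
    names(founders) <- FOUNDER_CODES

    structure(list(founders = founders, skeleton = skel, snps = snps,
                   chrom_lengths = lens),
              class = "founder_set")
  })
}

#' @export
print.founder_set <- function(x, ...) {
  cat("founder_set: 8 founders,", nrow(x$skeleton), "transcripts,",
      nrow(x$snps), "segregating SNPs\n")
  invisible(x)
}

#' Generate a recombinant-inbred haplotype mosaic
#'
#' Each autosome is partitioned into `n_blocks_per_chrom` contiguous,
#' non-overlapping blocks with uniform-random breakpoints; each block is
#' labeled with a founder code drawn uniformly from the eight founders.
#' chrMT (if present) is a single block. Block-length realism is not
#' claimed: breakpoints are uniform, not drawn from a recombination map.
#'
#' @param config a [sim_config()].
#' @param strain_id label for the simulated CC strain (also seeds its
#'   private RNG stream, so different strains get different mosaics).
#' @return object of class `haplotype_mosaic`: list with `strain_id`,
#'   `blocks` (data.frame `chromosome, start, end, founder_code`, 1-based
#'   inclusive) and `chrom_lengths`.
#' @export
gen_mosaic <- function(config, strain_id = "CC001") {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, paste0("mosaic:", strain_id)), {
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    lens <- stats::setNames(rep(config$chrom_length_bp, length(chroms)), chroms)
    if (config$include_mt) lens <- c(lens, chrMT = config$mt_length_bp)
    blocks <- do.call(rbind, lapply(names(lens), function(ch) {
      L <- lens[[ch]]
      nb <- if (ch == "chrMT") 1L else config$n_blocks_per_chrom
      cuts <- if (nb > 1L) sort(sample.int(L - 1L, nb - 1L)) else integer()
      start <- c(1L, cuts + 1L)
      end <- c(cuts, L)
      data.frame(chromosome = ch, start = start, end = end,
                 founder_code = sample(FOUNDER_CODES, nb, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    rownames(blocks) <- NULL
    structure(list(strain_id = strain_id, blocks = blocks,
                   chrom_lengths = lens),
              class = "haplotype_mosaic")
  })
}

#' @export
print.haplotype_mosaic <- function(x, ...) {
  cat("haplotype_mosaic:", x$strain_id, "-", nrow(x$blocks), "blocks on",
      length(x$chrom_lengths), "chromosomes\n")
  invisible(x)
}

#' Simulate an F1 cross between a hemizygous carrier and a CC male
#'
#' Emulates the breeding design: female transgene hemizygotes on the B6
#' background crossed to Collaborative Cross males, so each offspring
#' carries the transgene independently with probability
#' `transgene_carrier_prob` (0.5 under Mendelian segregation of a
#' hemizygous locus). Sex is Bernoulli(0.5), age is assigned from {4, 12}
#' months (balanced in expectation), and each sample gets correlated
#' sequencing-QC metrics with a planted batch direction from which
#' sequencing PCs can be computed.
#'
#' @param config a [sim_config()].
#' @param mosaic a [gen_mosaic()] result; its `strain_id` becomes the line.
#' @return data.frame of sample metadata: `sample_id, line, genotype`
#'   (`"WT"`/`"5x"`), `sex` (`"F"`/`"M"`), `age_months`,
#'   `qc_metric_1..k`, plus a hidden ground-truth `batch` column.
#' @export
simulate_cross <- function(config, mosaic) {
  stopifnot(inherits(config, "sim_config"), inherits(mosaic, "haplotype_mosaic"))
  with_seed(derive_seed(config$seed, paste0("cross:", mosaic$strain_id)), {
    n <- config$n_offspring
    carrier <- stats::rbinom(n, 1L, config$transgene_carrier_prob)
    sex <- ifelse(stats::rbinom(n, 1L, 0.5) == 1L, "M", "F")
    age <- sample(c(4L, 12L), n, replace = TRUE)
    batch <- stats::rbinom(n, 1L, 0.5)
    k <- config$n_qc_metrics
    loadings <- stats::runif(k, 0.5, 1.5) * 2
    qc <- sapply(seq_len(k), function(j)
      loadings[j] * batch + stats::rnorm(n))
    colnames(qc) <- paste0("qc_metric_", seq_len(k))
    out <- data.frame(
      sample_id = sprintf("%s_s%03d", mosaic$strain_id, seq_len(n)),
      line = mosaic$strain_id,
      genotype = ifelse(carrier == 1L, "5x", "WT"),
      sex = sex, age_months = age, stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(qc))
    out$batch <- batch
    out
  })
}

#' Simulate reads from a diploid transcriptome with known abundances
#'
#' Reads are drawn single-end: a transcript-allele entry is chosen with
#' probability proportional to `weight * (length - read_length + 1)` (so
#' weights are molar abundances and longer transcripts yield more reads),
#' the start position is uniform, and the read is the exact substring;
#' optional per-base substitution errors are applied at
#' `sequencing_error_rate`. The true origin of every read is recorded.
#'
#' @param diploid a [build_f1_diploid()] result (or any data.frame with
#'   `entry_id` and `sequence` columns).
#' @param abundances named nonnegative weights over `entry_id` (entries
#'   missing from the vector get weight 0).
#' @param config a [sim_config()]; uses `read_length`, `n_reads`,
#'   `sequencing_error_rate` and the master seed.
#' @return list with `reads` (named character vector of read sequences) and
#'   `origin` (data.frame `read_id, entry_id, start`).
#' @export
simulate_reads <- function(diploid, abundances, config) {
  stopifnot(inherits(config, "sim_config"))
  entries <- as.data.frame(diploid)
  rl <- config$read_length
  lens <- nchar(entries$sequence)
  if (any(lens < rl)) {
    bad <- entries$entry_id[which.min(lens)]
    stop(sprintf("read_length %d exceeds the length of transcript '%s' (%d bp)",
                 rl, bad, min(lens)), call. = FALSE)
  }
  w <- abundances[entries$entry_id]
  w[is.na(w)] <- 0
  if (any(w < 0)) stop("abundance weights must be >= 0", call. = FALSE)
  eff <- lens - rl + 1L
  p <- w * eff
  if (sum(p) <= 0) stop("all abundance weights are zero", call. = FALSE)
  with_seed(derive_seed(config$seed, "reads"), {
    n <- config$n_reads
    idx <- sample.int(nrow(entries), n, replace = TRUE, prob = p)
    start <- floor(stats::runif(n) * eff[idx]) + 1L
    reads <- substring(entries$sequence[idx], start, start + rl - 1L)
    if (config$sequencing_error_rate > 0) {
      nerr <- stats::rbinom(n, rl, config$sequencing_error_rate)
      for (i in which(nerr > 0)) {
        pos <- sample.int(rl, nerr[i])
        for (pp in pos) {
          b <- substring(reads[i], pp, pp)
          substring(reads[i], pp, pp) <- sample(setdiff(c("A","C","G","T"), b), 1L)
        }
      }
    }
    ids <- sprintf("read%06d", seq_len(n))
    names(reads) <- ids
    list(reads = reads,
         origin = data.frame(read_id = ids, entry_id = entries$entry_id[idx],
                             start = start, stringsAsFactors = FALSE))
  })
}

#' Generate a log2 expression matrix with planted structure
#'
#' Emulates what co-expression analysis assumes of real data: each planted
#' module m has a latent per-sample factor `f_m ~ N(0, 1)`; member genes are
#' `loading * f_m + covariate effects + N(0, noise_sd)`, with loadings
#' `factor_effect_sd * U(0.8, 1.2)` (positive, so modules are coherent in a
#' signed network). Non-module genes carry covariate effects and noise only.
#' Covariate effects (`config$covariate_effects`) touch a random subset of
#' genes per covariate with per-gene effect sizes `N(mean, sd)` multiplied
#' by the 0/1-coded covariate (genotype WT=0/5x=1, sex F=0/M=1, age
#' 4=0/12=1, batch as simulated).
#'
#' @param config a [sim_config()].
#' @param metadata data.frame from [simulate_cross()].
#' @return object of class `expression_sim`: list with `matrix` (genes x
#'   samples, log2 scale), `metadata`, and `truth` (module labels, loadings,
#'   latent factors, per-covariate affected genes and effect sizes).
#' @export
gen_expression <- function(config, metadata) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(metadata))
  with_seed(derive_seed(config$seed, "expression"), {
    ng <- config$n_genes
    ns <- nrow(metadata)
    genes <- sprintf("gene%04d", seq_len(ng))
    base <- stats::runif(ng, 2, 8)
    mat <- matrix(stats::rnorm(ng * ns, sd = config$noise_sd), ng, ns,
                  dimnames = list(genes, metadata$sample_id)) + base

    labels <- stats::setNames(rep(0L, ng), genes)
    loadings <- stats::setNames(rep(0, ng), genes)
    nm <- length(config$module_spec)
    factors <- matrix(0, nm, ns,
                      dimnames = list(if (nm) paste0("M", seq_len(nm)), NULL))
    nxt <- 1L
    for (m in seq_len(nm)) {
      spec <- config$module_spec[[m]]
      size <- as.integer(spec$module_size)
      f <- stats::rnorm(ns)
      factors[m, ] <- f
      members <- nxt:(nxt + size - 1L)
      nxt <- nxt + size
      lam <- spec$factor_effect_sd * stats::runif(size, 0.8, 1.2)
      mat[members, ] <- mat[members, ] + outer(lam, f)
      labels[members] <- m
      loadings[members] <- lam
    }

    codes <- list(
      genotype = as.numeric(metadata$genotype == "5x"),
      sex = as.numeric(metadata$sex == "M"),
      age = as.numeric(metadata$age_months == 12),
      batch = if ("batch" %in% names(metadata)) metadata$batch else NULL)
    cov_truth <- list()
    for (cv in names(config$covariate_effects)) {
      code <- codes[[cv]]
      if (is.null(code))
        stop(sprintf("unknown covariate '%s' in covariate_effects", cv),
             call. = FALSE)
      spec <- config$covariate_effects[[cv]]
      idx <- sample.int(ng, max(1L, round((spec$prop %||% 0.1) * ng)))
      eff <- stats::rnorm(length(idx), spec$mean %||% 0, spec$sd %||% 1)
      mat[idx, ] <- mat[idx, ] + outer(eff, code)
      cov_truth[[cv]] <- data.frame(gene = genes[idx], effect = eff,
                                    stringsAsFactors = FALSE)
    }

    structure(list(matrix = mat, metadata = metadata,
                   truth = list(module_labels = labels, loadings = loadings,
                                factors = factors,
                                covariate_effects = cov_truth)),
              class = "expression_sim")
  })
}

#' @export
print.expression_sim <- function(x, ...) {
  cat("expression_sim:", nrow(x$matrix), "genes x", ncol(x$matrix),
      "samples;", sum(x$truth$module_labels > 0), "genes in",
      length(unique(x$truth$module_labels[x$truth$module_labels > 0])),
      "planted modules\n")
  invisible(x)
}
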