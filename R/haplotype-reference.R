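# Haplotype-mosaic reference construction: CC strain transcriptomes stitched
# from founder transcriptomes, F1 diploid combination with the maternal B6
# copy, and founder-of-origin contribution at gene loci.

#' Parse and validate a haplotype mosaic TSV
#'
#' The dialect is tab-separated with header columns `strain, chromosome,
#' start, end, founder_code` and 1-based inclusive coordinates. Within each
#' chromosome, blocks must start at 1, be sorted, non-overlapping, and
#' gap-free up to the chromosome end.
#'
#' @param path mosaic TSV file.
#' @return a `haplotype_mosaic` object.
#' @export
parse_mosaic <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "chromosome", "start", "end", "founder_code")
  if (!all(need %in% names(df)))
    stop(sprintf("mosaic header must contain: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  bad <- setdiff(unique(df$founder_code), FOUNDER_CODES)
  if (length(bad))
    stop(sprintf("unknown founder code(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  strain <- unique(df$strain)
  if (length(strain) != 1L)
    stop("mosaic file must describe a single strain", call. = FALSE)
  blocks <- df[order(df$chromosome, df$start),
               c("chromosome", "start", "end", "founder_code")]
  validate_mosaic_blocks(blocks)
  lens <- tapply(blocks$end, blocks$chromosome, max)
  structure(list(strain_id = strain, blocks = blocks,
                 chrom_lengths = lens[unique(blocks$chromosome)]),
            class = "haplotype_mosaic")
}

# sort/coverage/overlap checks, with offending coordinates in the message
validate_mosaic_blocks <- function(blocks) {
  for (ch in unique(blocks$chromosome)) {
    b <- blocks[blocks$chromosome == ch, ]
    b <- b[order(b$start), ]
    if (any(b$end < b$start))
      stop(sprintf("%s: block end before start at position %d",
                   ch, b$start[which(b$end < b$start)[1]]), call. = FALSE)
    if (b$start[1] != 1L)
      stop(sprintf("%s: first block starts at %d, not 1", ch, b$start[1]),
           call. = FALSE)
    if (nrow(b) > 1L) {
      gap <- b$start[-1] - b$end[-nrow(b)] - 1L
      if (any(gap < 0)) {
        i <- which(gap < 0)[1]
        stop(sprintf("%s: overlapping blocks at position %d", ch, b$start[i + 1]),
             call. = FALSE)
      }
      if (any(gap > 0)) {
        i <- which(gap > 0)[1]
        stop(sprintf("%s: coverage gap between %d and %d",
                     ch, b$end[i], b$start[i + 1]), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Stitch a CC strain transcriptome from founder transcriptomes
#'
#' Each transcript's sequence is taken whole from the founder whose mosaic
#' block(s) cover the largest number of its base pairs (ties broken by the
#' block with the smaller start coordinate). CC strains are treated as fully
#' inbred, so the output is haploid: one sequence per transcript with its
#' source founder recorded.
#'
#' @param mosaic a `haplotype_mosaic`.
#' @param founders a `founder_set` from [gen_founders()] (or a named list
#'   A..H of transcript tables sharing a coordinate skeleton).
#' @return data.frame `transcript_id, gene_id, chromosome, start, end,
#'   source_founder, sequence` with attribute `strain_id`.
#' @export
build_strain_transcriptome <- function(mosaic, founders) {
  stopifnot(inherits(mosaic, "haplotype_mosaic"))
  flist <- if (inherits(founders, "founder_set")) founders$founders else founders
  skel <- flist[["B"]][, c("transcript_id", "gene_id", "chromosome",
                           "start", "end")]
  src <- character(nrow(skel))
  for (i in seq_len(nrow(skel))) {
    b <- mosaic$blocks[mosaic$blocks$chromosome == skel$chromosome[i], ]
    ov <- pmin(b$end, skel$end[i]) - pmax(b$start, skel$start[i]) + 1L
    keep <- ov > 0
    if (!any(keep))
      stop(sprintf("transcript '%s' overlaps no haplotype block",
                   skel$transcript_id[i]), call. = FALSE)
    b <- b[keep, , drop = FALSE]
    ov <- ov[keep]
    # founder totals; tie broken by the earliest-starting block's founder
    tot <- tapply(ov, b$founder_code, sum)
    best <- names(tot)[tot == max(tot)]
    if (length(best) > 1L) {
      cand <- b[b$founder_code %in% best, ]
      best <- cand$founder_code[which.min(cand$start)]
    }
    src[i] <- best
  }
  out <- skel
  out$source_founder <- src
  out$sequence <- vapply(seq_len(nrow(skel)), function(i) {
    f <- flist[[src[i]]]
    f$sequence[match(skel$transcript_id[i], f$transcript_id)]
  }, character(1))
  attr(out, "strain_id") <- mosaic$strain_id
  out
}

# chromosomes treated as maternal-only (B6 mitochondria in all F1 mice)
is_mt_chrom <- function(chrom) toupper(chrom) %in% c("CHRMT", "CHRM", "MT", "M")

#' Combine maternal and paternal transcript sets into an F1 diploid reference
#'
#' The maternal copy is the C57BL/6J (founder B) transcriptome, the paternal
#' copy the stitched CC mosaic transcriptome. Transcript IDs are suffixed
#' `_M` / `_P`. Mitochondrial transcripts are emitted maternal-only, because
#' the F1 cross uses B6 dams and mitochondria are maternally inherited.
#'
#' @param paternal stitched strain transcriptome ([build_strain_transcriptome()]).
#' @param maternal maternal transcript table; defaults to founder B if a
#'   `founder_set` is supplied via `founders`.
#' @param founders optional `founder_set` used to obtain the maternal B copy.
#' @return object of class `diploid_transcriptome`: data.frame `entry_id,
#'   transcript_id, gene_id, chromosome, allele, source_founder, sequence`
#'   with attributes `strain_id` and `maternal_strain`.
#' @export
build_f1_diploid <- function(paternal, maternal = NULL, founders = NULL) {
  if (is.null(maternal)) {
    if (is.null(founders))
      stop("supply either 'maternal' or 'founders'", call. = FALSE)
    flist <- if (inherits(founders, "founder_set")) founders$founders else founders
    maternal <- flist[["B"]]
    maternal$source_founder <- "B"
  }
  if (is.null(maternal$source_founder)) maternal$source_founder <- "B"
  key <- function(d) paste(d$transcript_id, d$chromosome, d$start, d$end)
  mism <- union(setdiff(key(paternal), key(maternal)),
                setdiff(key(maternal), key(paternal)))
  if (length(mism)) {
    ids <- unique(sub(" .*", "", mism))
    stop(sprintf("maternal/paternal transcript skeletons differ for: %s",
                 paste(ids, collapse = ", ")), call. = FALSE)
  }
  maternal <- maternal[match(paternal$transcript_id, maternal$transcript_id), ]
  mk <- function(d, allele) {
    data.frame(entry_id = paste0(d$transcript_id, "_", allele),
               transcript_id = d$transcript_id, gene_id = d$gene_id,
               chromosome = d$chromosome, allele = allele,
               source_founder = d$source_founder, sequence = d$sequence,
               stringsAsFactors = FALSE)
  }
  m <- mk(maternal, "M")
  p <- mk(paternal[!is_mt_chrom(paternal$chromosome), ], "P")
  out <- rbind(m, p)
  out <- out[order(out$transcript_id, out$allele), ]
  rownames(out) <- NULL
  structure(out, class = c("diploid_transcriptome", "data.frame"),
            strain_id = attr(paternal, "strain_id") %||% "unknown",
            maternal_strain = "B")
}

#' Founder-of-origin contribution at gene loci
#'
#' For each locus, the fraction of its base pairs covered by blocks of each
#' of the eight founder strains. For a fully inbred mosaic each row is
#' one-hot unless the locus straddles a haplotype breakpoint.
#'
#' @param mosaic a `haplotype_mosaic`.
#' @param loci data.frame with `gene_id, chromosome, start, end` (1-based
#'   inclusive).
#' @return matrix loci x 8 founders; rows sum to 1.
#' @export
founder_contribution <- function(mosaic, loci) {
  stopifnot(inherits(mosaic, "haplotype_mosaic"))
  loci <- as.data.frame(loci)
  out <- matrix(0, nrow(loci), length(FOUNDER_CODES),
                dimnames = list(loci$gene_id, FOUNDER_CODES))
  for (i in seq_len(nrow(loci))) {
    ch <- loci$chromosome[i]
    if (!ch %in% mosaic$blocks$chromosome)
      stop(sprintf("locus '%s': chromosome %s not in mosaic",
                   loci$gene_id[i], ch), call. = FALSE)
    chr_end <- max(mosaic$blocks$end[mosaic$blocks$chromosome == ch])
    if (loci$start[i] < 1L || loci$end[i] > chr_end ||
        loci$end[i] < loci$start[i])
      stop(sprintf("locus '%s' [%d, %d] lies outside chromosome %s (1..%d)",
                   loci$gene_id[i], loci$start[i], loci$end[i], ch, chr_end),
           call. = FALSE)
    b <- mosaic$blocks[mosaic$blocks$chromosome == ch, ]
    ov <- pmax(0L, pmin(b$end, loci$end[i]) - pmax(b$start, loci$start[i]) + 1L)
    width <- loci$end[i] - loci$start[i] + 1L
    frac <- tapply(ov / width, b$founder_code, sum)
    out[i, names(frac)] <- frac
  }
  out
}

#' Write a founder contribution matrix as TSV
#' @param contrib matrix from [founder_contribution()].
#' @param path output file.
#' @export
write_contribution_tsv <- function(contrib, path) {
  df <- data.frame(gene_id = rownames(contrib), contrib, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
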