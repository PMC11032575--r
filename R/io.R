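# File formats: FASTA (via Biostrings, 60-column wrap), the mosaic TSV
# dialect, metadata / expression matrix TSV, and GMT gene-set files.

#' Write transcript sequences to FASTA
#'
#' @param x data.frame with a sequence column and an identifier column
#'   (`entry_id` if present, else `transcript_id`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transcript_fasta <- function(x, path) {
  x <- as.data.frame(x)
  ids <- x$entry_id %||% x$transcript_id
  ss <- Biostrings::DNAStringSet(stats::setNames(x$sequence, ids))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA file.
#' @return data.frame with `entry_id` and `sequence`.
#' @export
read_transcript_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  data.frame(entry_id = names(ss), sequence = as.character(ss),
             stringsAsFactors = FALSE)
}

#' Write reads to FASTA
#' @param reads named character vector (names become record ids).
#' @param path output file.
#' @export
write_reads_fasta <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read reads from FASTA
#' @param path FASTA file.
#' @return named character vector of read sequences.
#' @export
read_reads_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' Write a haplotype mosaic TSV
#'
#' Dialect: tab-separated with header `strain chromosome start end
#' founder_code`; coordinates 1-based inclusive.
#'
#' @param mosaic a `haplotype_mosaic`.
#' @param path output file.
#' @export
write_mosaic <- function(mosaic, path) {
  stopifnot(inherits(mosaic, "haplotype_mosaic"))
  out <- cbind(strain = mosaic$strain_id, mosaic$blocks)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an expression matrix TSV (genes x samples)
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path file path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Write / read sample metadata TSV
#' @param metadata data.frame from [simulate_cross()].
#' @param path file path.
#' @export
write_metadata_tsv <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read / write GMT gene-set files
#'
#' GMT: one set per line - set name, description, then tab-separated gene
#' identifiers.
#'
#' @param path file path.
#' @return for `read_gmt`, a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% rep("na", length(sets))
  lines <- mapply(function(nm, d, g) paste(c(nm, d, g), collapse = "\t"),
                  names(sets), desc, sets)
  writeLines(lines, path)
  invisible(path)
}
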