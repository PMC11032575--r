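# Allele-aware EM quantification: reads -> equivalence classes ->
# transcript-allele abundance -> gene TPM.

#' Map reads to compatible transcript-alleles (equivalence classes)
#'
#' Exact-substring compatibility at desk scale: every window of length
#' `read_length` in every diploid entry is hashed, and a read's equivalence
#' class is the set of (transcript, allele) entries containing it. Reads
#' matching no entry are counted as unmapped.
#'
#' @param reads character vector of fixed-length reads.
#' @param diploid a `diploid_transcriptome` (or data.frame with `entry_id`,
#'   `transcript_id`, `gene_id`, `allele`, `sequence`).
#' @return object of class `eqc_set`: list with `members` (list of integer
#'   index vectors into `entries`), `counts` (reads per class), `entries`
#'   (per transcript-allele: ids, length, effective length), `read_length`,
#'   `total_reads` (mapped) and `n_unmapped`.
#' @export
compat_map <- function(reads, diploid) {
  entries <- as.data.frame(diploid)
  if (nrow(entries) == 0L) stop("empty diploid index", call. = FALSE)
  rl <- unique(nchar(reads))
  if (length(rl) != 1L)
    stop("reads must all have the same length", call. = FALSE)
  lens <- nchar(entries$sequence)
  if (any(lens < rl)) {
    bad <- entries$entry_id[which.min(lens)]
    stop(sprintf("read length %d exceeds transcript '%s' (%d bp)",
                 rl, bad, min(lens)), call. = FALSE)
  }
  nk <- lens - rl + 1L
  entry_rep <- rep.int(seq_len(nrow(entries)), nk)
  starts <- sequence(nk)
  kmers <- substring(entries$sequence[entry_rep], starts, starts + rl - 1L)
  uk <- unique(kmers)
  ki <- match(kmers, uk)
  members_by_kmer <- lapply(
    split(entry_rep, factor(ki, levels = seq_along(uk))),
    function(v) sort.int(unique(v)))

  ridx <- match(reads, uk)
  mapped <- !is.na(ridx)
  keys <- vapply(members_by_kmer[ridx[mapped]], paste, character(1),
                 collapse = ",")
  tab <- table(keys)
  members <- lapply(strsplit(names(tab), ",", fixed = TRUE), as.integer)

  structure(list(
    members = members,
    counts = as.integer(tab),
    entries = data.frame(entry_id = entries$entry_id,
                         transcript_id = entries$transcript_id %||% entries$entry_id,
                         gene_id = entries$gene_id %||% entries$entry_id,
                         allele = entries$allele %||% NA_character_,
                         length = lens,
                         eff_length = pmax(1L, nk),
                         stringsAsFactors = FALSE),
    read_length = rl,
    total_reads = sum(mapped),
    n_unmapped = sum(!mapped)
  ), class = "eqc_set")
}

#' @export
print.eqc_set <- function(x, ...) {
  cat("eqc_set:", length(x$counts), "equivalence classes,", x$total_reads,
      "mapped reads (", x$n_unmapped, "unmapped ),",
      nrow(x$entries), "transcript-alleles\n")
  invisible(x)
}

#' EM abundance estimation over equivalence classes
#'
#' Iterates the standard transcript-abundance EM in read-fraction
#' coordinates: the E-step splits each class's count among its members t in
#' proportion to `eta_t / l_t` (l = effective length = length - read_length
#' + 1, floored at 1), the M-step sets `eta_t` to t's total assigned read
#' fraction, until the largest absolute change in eta falls below `tol` or
#' `max_iter` sweeps. The per-class data log-likelihood
#' `sum_c n_c log(sum_{t in c} eta_t / l_t)` is non-decreasing at every
#' sweep. The returned abundance `theta` is the length-normalized molar
#' fraction `(eta/l) / sum(eta/l)`; with uniquely mapped reads it equals
#' direct count-over-effective-length normalization after one sweep.
#'
#' @param eq an `eqc_set` from [compat_map()].
#' @param tol convergence tolerance on max-abs change in read fractions.
#' @param max_iter maximum EM sweeps; non-convergence sets a flag and warns,
#'   it is not an error.
#' @param unique_only drop ambiguous classes first (strict unique-read
#'   quantification).
#' @return list with `theta` (named molar abundance, sums to 1), `eta`
#'   (read fractions), `n_iter`, `loglik`, `loglik_trace`, `converged`.
#' @export
em_quantify <- function(eq, tol = 1e-8, max_iter = 1000L, unique_only = FALSE) {
  stopifnot(inherits(eq, "eqc_set"))
  members <- eq$members
  counts <- eq$counts
  if (unique_only) {
    keep <- lengths(members) == 1L
    members <- members[keep]
    counts <- counts[keep]
  }
  if (!length(members)) stop("no equivalence classes to quantify", call. = FALSE)
  Tn <- nrow(eq$entries)
  ell <- pmax(1, eq$entries$eff_length)
  N <- sum(counts)

  cls <- rep.int(seq_along(members), lengths(members))
  mem <- unlist(members, use.names = FALSE)

  eta <- rep(1 / Tn, Tn)
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- eta[mem] / ell[mem]
    s <- as.numeric(rowsum(r, cls, reorder = FALSE))
    ll_trace <- c(ll_trace, sum(counts * log(s)))
    contrib <- r * (counts / s)[cls]
    assigned <- numeric(Tn)
    agg <- rowsum(contrib, mem)
    assigned[as.integer(rownames(agg))] <- agg[, 1]
    eta_new <- assigned / N
    delta <- max(abs(eta_new - eta))
    eta <- eta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("EM did not converge in %d iterations", max_iter))
  th <- eta / ell
  theta <- th / sum(th)
  names(theta) <- names(eta) <- eq$entries$entry_id
  list(theta = theta, eta = eta, n_iter = iter,
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
       converged = converged)
}

#' Aggregate transcript-allele abundance to gene TPM
#'
#' Alleles (maternal + paternal) are pooled per gene before scaling; the
#' column is scaled to sum to 1e6.
#'
#' @param theta molar abundance vector from [em_quantify()].
#' @param eq the `eqc_set` used for quantification (supplies the
#'   transcript-to-gene map).
#' @param gene_map optional named vector transcript_id -> gene_id
#'   overriding the map in `eq`; every transcript must be mapped.
#' @return named numeric vector of gene TPM (sums to 1e6).
#' @export
gene_tpm <- function(theta, eq, gene_map = NULL) {
  stopifnot(inherits(eq, "eqc_set"))
  genes <- eq$entries$gene_id
  if (!is.null(gene_map)) {
    genes <- gene_map[eq$entries$transcript_id]
    if (anyNA(genes)) {
      orphan <- unique(eq$entries$transcript_id[is.na(genes)])
      stop(sprintf("transcript(s) not mapped to a gene: %s",
                   paste(orphan, collapse = ", ")), call. = FALSE)
    }
  }
  if (anyNA(genes)) stop("entries carry no gene_id", call. = FALSE)
  agg <- rowsum(theta[eq$entries$entry_id], genes)
  tpm <- agg[, 1] / sum(agg[, 1]) * 1e6
  stats::setNames(tpm, rownames(agg))
}

#' One-call quantification of a read set against a diploid reference
#'
#' Convenience wrapper: [compat_map()] then [em_quantify()] then
#' [gene_tpm()].
#'
#' @inheritParams compat_map
#' @inheritParams em_quantify
#' @return list with `tpm` (gene TPM), `fit` (EM result) and `eq`.
#' @export
quantify_sample <- function(reads, diploid, tol = 1e-8, max_iter = 1000L,
                            unique_only = FALSE) {
  eq <- compat_map(reads, diploid)
  fit <- em_quantify(eq, tol = tol, max_iter = max_iter,
                     unique_only = unique_only)
  list(tpm = gene_tpm(fit$theta, eq), fit = fit, eq = eq)
}
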