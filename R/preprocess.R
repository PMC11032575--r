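# Preprocessing: low-expression filtering, sequencing PCs from QC metrics,
# and covariate residualization by per-gene ordinary least squares.

#' Remove low-expressed genes
#'
#' A gene is retained iff its abundance exceeds `tpm_min` in strictly more
#' than `min_frac` of samples (the default mirrors removing genes not
#' expressed in 80 percent of samples, with "expressed" operationalized as
#' TPM > 0.1).
#'
#' @param mat genes x samples numeric matrix (TPM scale).
#' @param min_frac retention requires expression in > this fraction of
#'   samples.
#' @param tpm_min expression call threshold (strictly greater than).
#' @return list with `matrix` (filtered) and `removed` (dropped gene IDs).
#' @export
filter_low_expressed <- function(mat, min_frac = 0.2, tpm_min = 0.1) {
  stopifnot(is.matrix(mat), nrow(mat) > 0)
  frac <- rowMeans(mat > tpm_min)
  keep <- frac > min_frac
  if (!any(keep))
    stop("all genes removed by the low-expression filter; review thresholds",
         call. = FALSE)
  list(matrix = mat[keep, , drop = FALSE],
       removed = rownames(mat)[!keep])
}

#' Sequencing principal components from QC metrics
#'
#' Metrics are z-scored per column (constant columns dropped with a
#' warning), and the top-k principal component scores are returned with a
#' deterministic sign convention: the loading with the largest magnitude on
#' each component is made positive.
#'
#' @param qc_metrics samples x metrics numeric matrix or data.frame (e.g.
#'   the `qc_metric_*` columns of [simulate_cross()] metadata).
#' @param k number of components (default 5).
#' @return samples x k matrix with columns `seq_pc_1..k`.
#' @export
compute_seq_pcs <- function(qc_metrics, k = 5L) {
  qc <- as.matrix(qc_metrics)
  if (ncol(qc) < k)
    stop(sprintf("need >= %d metrics for %d PCs", k, k), call. = FALSE)
  if (nrow(qc) < k + 1L)
    stop(sprintf("need >= %d samples for %d PCs", k + 1L, k), call. = FALSE)
  sds <- apply(qc, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping constant metric column(s): %s",
                    paste(colnames(qc)[sds == 0], collapse = ", ")))
    qc <- qc[, sds > 0, drop = FALSE]
    if (ncol(qc) < k)
      stop(sprintf("fewer than %d non-constant metrics", k), call. = FALSE)
  }
  z <- scale(qc)
  pr <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("seq_pc_", seq_len(k))
  rownames(scores) <- rownames(qc)
  scores
}

#' Residualize expression against sample covariates
#'
#' Per-gene ordinary least squares of (log2-scale) expression on the
#' dummy-coded design built from the requested metadata terms; residuals
#' plus the gene grand mean are returned so the matrix stays on an
#' interpretable scale. The stated full model is
#' `expression ~ line + genotype + sex + age + seq_pc_1..5`; pass a subset
#' of terms (e.g. only the sequencing PCs) when the removed factors are to
#' be tested downstream.
#'
#' @param mat genes x samples matrix, log2 scale (use [log2_transform()] on
#'   TPM first).
#' @param metadata data.frame with one row per sample, matched by the
#'   `sample_id` column to `colnames(mat)`; factors are treatment-coded.
#' @param terms character vector of metadata columns to regress out.
#' @return list with `matrix` (residualized, grand mean added back),
#'   `design` (model matrix) and `coefficients` (terms x genes).
#' @export
regress_covariates <- function(mat, metadata,
                               terms = c("line", "genotype", "sex", "age_months",
                                         paste0("seq_pc_", 1:5))) {
  stopifnot(is.matrix(mat))
  metadata <- as.data.frame(metadata)
  if (!is.null(metadata$sample_id)) {
    idx <- match(colnames(mat), metadata$sample_id)
    if (anyNA(idx)) stop("samples missing from metadata", call. = FALSE)
    metadata <- metadata[idx, , drop = FALSE]
  } else if (nrow(metadata) != ncol(mat)) {
    stop("metadata rows do not match matrix columns", call. = FALSE)
  }
  miss <- setdiff(terms, names(metadata))
  if (length(miss))
    stop(sprintf("metadata lacks term(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  dat <- metadata[, terms, drop = FALSE]
  for (cl in names(dat)) if (is.character(dat[[cl]])) dat[[cl]] <- factor(dat[[cl]])
  X <- stats::model.matrix(~ ., data = dat)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop(sprintf("design matrix is rank-deficient; aliased column(s): %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  Y <- t(mat)                      # samples x genes
  coef <- qr.coef(qx, Y)
  resid <- Y - X %*% coef
  out <- t(resid) + rowMeans(mat)
  list(matrix = out, design = X, coefficients = coef)
}

#' log2(TPM + 1) transform
#' @param mat TPM-scale matrix.
#' @return log2(mat + 1).
#' @export
log2_transform <- function(mat) log2(mat + 1)
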