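# Differential expression: per-gene Welch t tests on log2 expression with
# Benjamini-Hochberg control, DEG thresholding and volcano classes,
# pairwise line-divergence DEG count matrices, and conserved-DEG
# intersection across strains.

#' Two-group differential expression (Welch t on log2 expression)
#'
#' A dependency-free per-gene Welch two-sample t test with BH FDR across
#' all tested genes. `log2_fc` is the difference of group means on the log2
#' scale (group2 - group1). Classification follows the volcano convention:
#' `DEG` iff |log2FC| > `lfc` and FDR < `fdr`; `FC-only` and `FDR-only`
#' mark genes passing a single threshold; `NS` otherwise. Genes with zero
#' variance in both groups get p = 1 when the means agree and p = 0
#' otherwise.
#'
#' @param mat genes x samples matrix on the log2 scale.
#' @param group_labels length-ncol factor/character with exactly 2 levels;
#'   the second level is the "treatment" (group2).
#' @param lfc absolute log2 fold-change threshold (default 1).
#' @param fdr FDR threshold (default 0.05).
#' @return object of class `de_result`: data.frame `gene, log2_fc,
#'   statistic, p_value, fdr, class`.
#' @export
de_test <- function(mat, group_labels, lfc = 1, fdr = 0.05) {
  stopifnot(is.matrix(mat))
  g <- factor(group_labels)
  if (nlevels(g) != 2L)
    stop("group_labels must have exactly 2 levels", call. = FALSE)
  n <- table(g)
  if (any(n < 2L))
    stop(sprintf("group '%s' has fewer than 2 samples",
                 names(n)[which.min(n)]), call. = FALSE)
  i1 <- g == levels(g)[1]
  i2 <- g == levels(g)[2]
  x1 <- mat[, i1, drop = FALSE]; x2 <- mat[, i2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  diffm <- m2 - m1
  tstat <- diffm / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- se2 == 0
  if (any(degen)) {
    tstat[degen] <- ifelse(diffm[degen] == 0, 0, sign(diffm[degen]) * Inf)
    p[degen] <- ifelse(diffm[degen] == 0, 1, 0)
  }
  q <- stats::p.adjust(p, method = "BH")
  cls <- ifelse(abs(diffm) > lfc & q < fdr, "DEG",
         ifelse(abs(diffm) > lfc, "FC-only",
         ifelse(q < fdr, "FDR-only", "NS")))
  structure(data.frame(gene = rownames(mat) %||% as.character(seq_len(nrow(mat))),
                       log2_fc = diffm, statistic = tstat, p_value = p,
                       fdr = q, class = cls, stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("de_result", "data.frame"),
            groups = levels(g), lfc = lfc, fdr_thresh = fdr)
}

#' Extract the DEG set of a `de_result`
#' @param de a `de_result`.
#' @param direction `"both"`, `"up"` (log2FC > lfc) or `"down"`.
#' @return character vector of gene IDs.
#' @export
deg_set <- function(de, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  lfc <- attr(de, "lfc") %||% 1
  thr <- attr(de, "fdr_thresh") %||% 0.05
  sig <- de$fdr < thr
  sel <- switch(direction,
                both = sig & abs(de$log2_fc) > lfc,
                up = sig & de$log2_fc > lfc,
                down = sig & de$log2_fc < -lfc)
  de$gene[sel]
}

#' Pairwise DEG count matrix across lines
#'
#' For every unordered pair of lines, the number of DEGs (|log2FC| >
#' `lfc`, FDR < `fdr`) between their samples; mirrors the strain-divergence
#' heatmaps. Lines with fewer than 2 samples are excluded with a warning.
#' With `stratify_by = "sex"`, a matrix is returned per sex.
#'
#' @param mat genes x samples log2 expression matrix.
#' @param metadata matched metadata with `sample_id`, `line` and optionally
#'   `sex` columns.
#' @param stratify_by `"none"` or `"sex"`.
#' @inheritParams de_test
#' @return symmetric integer matrix lines x lines (or a named list of them
#'   when stratified).
#' @export
deg_count_matrix <- function(mat, metadata, stratify_by = c("none", "sex"),
                             lfc = 1, fdr = 0.05) {
  stratify_by <- match.arg(stratify_by)
  metadata <- as.data.frame(metadata)
  idx <- match(colnames(mat), metadata$sample_id)
  stopifnot(!anyNA(idx))
  metadata <- metadata[idx, ]
  if (stratify_by == "sex") {
    return(lapply(split(seq_len(ncol(mat)), metadata$sex), function(ii)
      deg_count_matrix(mat[, ii, drop = FALSE], metadata[ii, ],
                       stratify_by = "none", lfc = lfc, fdr = fdr)))
  }
  counts <- table(metadata$line)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    warning(sprintf("excluding line(s) with < 2 samples: %s",
                    paste(small, collapse = ", ")))
  }
  lines <- setdiff(names(counts), small)
  if (length(lines) < 2L) stop("need >= 2 lines with >= 2 samples", call. = FALSE)
  out <- matrix(0L, length(lines), length(lines),
                dimnames = list(lines, lines))
  for (i in seq_along(lines)) for (j in seq_along(lines)) {
    if (j <= i) next
    sel <- metadata$line %in% c(lines[i], lines[j])
    de <- de_test(mat[, sel, drop = FALSE], metadata$line[sel],
                  lfc = lfc, fdr = fdr)
    out[i, j] <- out[j, i] <- length(deg_set(de))
  }
  out
}

#' Conserved DEGs across comparisons
#'
#' Intersection of the DEG sets of several `de_result`s, requiring the sign
#' of the fold change to be concordant across all comparisons.
#'
#' @param de_results list of `de_result` objects (>= 2).
#' @return character vector of conserved gene IDs, with attribute
#'   `direction` (+1 / -1 per gene).
#' @export
conserved_degs <- function(de_results) {
  stopifnot(length(de_results) >= 2L)
  sets <- lapply(de_results, deg_set)
  common <- Reduce(intersect, sets)
  if (!length(common))
    return(structure(character(), direction = integer()))
  signs <- sapply(de_results, function(de)
    sign(de$log2_fc[match(common, de$gene)]))
  if (is.null(dim(signs))) signs <- matrix(signs, nrow = 1)
  concord <- apply(signs, 1, function(s) all(s == s[1]))
  structure(common[concord],
            direction = as.integer(signs[concord, 1]))
}
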