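# Consensus signed weighted co-expression networks: biweight
# midcorrelation, signed beta-power adjacency, topological overlap,
# quantile-scaled component-wise-minimum consensus, dynamic dendrogram
# module detection with eigengene merging and kME pruning, and
# module-trait correlation.

#' Network analysis configuration
#'
#' @param beta soft-thresholding power for the signed adjacency (16 for the
#'   age/sex consensus network, 14 for the genotype network).
#' @param consensus_quantile off-diagonal TOM quantile equalized across
#'   datasets before the component-wise minimum (default 0.2).
#' @param deep_split split sensitivity 0..4 (4 = most aggressive).
#' @param cut_height static dendrogram cut height (default 0.999).
#' @param min_module_size smallest admissible module (default 100).
#' @param merge_thresh modules whose eigengene dissimilarity `1 - cor(ME)`
#'   is below this are merged (0.25 or 0.2).
#' @param kme_min genes with own-module kME below this are unassigned.
#' @param pam_stage reserved; no post-hoc reassignment is performed
#'   (`FALSE`).
#' @return object of class `network_config`.
#' @export
network_config <- function(beta = 16, consensus_quantile = 0.2,
                           deep_split = 4L, cut_height = 0.999,
                           min_module_size = 100L, merge_thresh = 0.25,
                           kme_min = 0.7, pam_stage = FALSE) {
  if (beta < 1) stop("'beta' must be >= 1", call. = FALSE)
  if (consensus_quantile <= 0 || consensus_quantile >= 1)
    stop("'consensus_quantile' must be in (0, 1)", call. = FALSE)
  if (!deep_split %in% 0:4) stop("'deep_split' must be 0..4", call. = FALSE)
  if (cut_height <= 0 || cut_height > 1)
    stop("'cut_height' must be in (0, 1]", call. = FALSE)
  if (merge_thresh <= 0 || merge_thresh > 1)
    stop("'merge_thresh' must be in (0, 1]", call. = FALSE)
  if (kme_min < 0 || kme_min > 1) stop("'kme_min' must be in [0, 1]", call. = FALSE)
  structure(list(beta = beta, consensus_quantile = consensus_quantile,
                 deep_split = as.integer(deep_split),
                 cut_height = cut_height,
                 min_module_size = as.integer(min_module_size),
                 merge_thresh = merge_thresh, kme_min = kme_min,
                 pam_stage = isTRUE(pam_stage)),
            class = "network_config")
}

#' Biweight midcorrelation matrix
#'
#' Robust correlation for all gene pairs: with `u_i = (x_i - med(x)) /
#' (9 MAD(x))` (MAD unscaled), weights `w_i = (1 - u_i^2)^2 1[|u_i| < 1]`
#' and `x~_i = (x_i - med(x)) w_i`, the biweight midcorrelation is
#' `sum(x~ y~) / (||x~|| ||y~||)`. Genes with MAD = 0 but non-constant
#' values fall back to Pearson weighting (mean-centered, unit weights) for
#' every pair they enter, with a message; constant genes are dropped with a
#' warning.
#'
#' @param mat genes x samples matrix (>= 4 samples).
#' @return symmetric gene x gene correlation matrix in [-1, 1] with unit
#'   diagonal.
#' @export
bicor_matrix <- function(mat) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 4L) stop("need >= 4 samples for bicor", call. = FALSE)
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant gene(s)", sum(sds == 0)))
    mat <- mat[sds > 0, , drop = FALSE]
  }
  med <- apply(mat, 1, stats::median)
  madv <- apply(abs(mat - med), 1, stats::median)   # unscaled MAD
  xc <- mat - med
  xt <- matrix(0, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  ok <- madv > 0
  if (any(ok)) {
    u <- xc[ok, , drop = FALSE] / (9 * madv[ok])
    w <- (1 - u^2)^2 * (abs(u) < 1)
    xt[ok, ] <- xc[ok, , drop = FALSE] * w
  }
  if (any(!ok)) {
    message(sprintf("MAD = 0 for %d gene(s); Pearson fallback for their pairs",
                    sum(!ok)))
    xt[!ok, ] <- mat[!ok, , drop = FALSE] - rowMeans(mat[!ok, , drop = FALSE])
  }
  nrm <- sqrt(rowSums(xt^2))
  xt <- xt / nrm
  b <- tcrossprod(xt)
  b[b > 1] <- 1; b[b < -1] <- -1
  diag(b) <- 1
  b
}

#' Signed adjacency from a correlation matrix
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta`, zero diagonal.
#'
#' @param cor_mat correlation matrix in [-1, 1].
#' @param beta soft power.
#' @return adjacency matrix in [0, 1] with zero diagonal.
#' @export
signed_adjacency <- function(cor_mat, beta) {
  a <- ((1 + cor_mat) / 2)^beta
  diag(a) <- 0
  a
}

#' Signed topological overlap matrix
#'
#' From the signed adjacency `a` (zero diagonal, connectivity
#' `k_i = sum_u a_iu`):
#' `tom_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`,
#' with unit diagonal.
#'
#' @inheritParams signed_adjacency
#' @return TOM in [0, 1], symmetric, unit diagonal.
#' @export
signed_tom <- function(cor_mat, beta) {
  a <- signed_adjacency(cor_mat, beta)
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom[tom > 1] <- 1; tom[tom < 0] <- 0
  tom
}

#' Consensus topological overlap across datasets
#'
#' Each dataset's TOM is power-scaled so that its off-diagonal
#' `quantile`-quantile matches dataset 1's
#' (`tom_s' = tom_s^(log q_1 / log q_s)`), keeping values in [0, 1]; the
#' consensus is the element-wise minimum of the scaled TOMs.
#'
#' @param toms list of TOM matrices over identical gene sets.
#' @param quantile scaling quantile (default 0.2).
#' @return consensus TOM matrix.
#' @export
consensus_tom <- function(toms, quantile = 0.2) {
  stopifnot(length(toms) >= 1L)
  dims <- vapply(toms, nrow, 0L)
  if (length(unique(dims)) != 1L)
    stop("all TOMs must cover the same gene set", call. = FALSE)
  off <- function(m) m[upper.tri(m)]
  qs <- vapply(toms, function(m) stats::quantile(off(m), quantile, names = FALSE), 0)
  if (any(qs == 0))
    stop("degenerate network: scaling quantile of a TOM is 0", call. = FALSE)
  scaled <- lapply(seq_along(toms), function(s) {
    if (s == 1L) toms[[1L]] else toms[[s]]^(log(qs[1L]) / log(qs[s]))
  })
  out <- Reduce(pmin, scaled)
  diag(out) <- 1
  out
}

# ---- dynamic dendrogram cut --------------------------------------------

# Recursive largest-gap splitting of an average-linkage dendrogram of
# 1 - TOM. A branch splits when the largest gap between consecutive sorted
# merge heights, relative to the branch's height range, exceeds a
# deep_split-mapped sensitivity (deep_split 0..4 -> 0.5 down to 0.1); the
# tree is then cut at the midpoint of that gap and each piece is recursed.
# Final branches smaller than min_module_size are unassigned, as is a root
# branch that was never separated from anything (no evidence of structure).
dynamic_cut <- function(hc, dissim, deep_split = 4L, cut_height = 0.999,
                        min_size = 100L) {
  n <- ncol(dissim)
  gamma <- c(0.5, 0.4, 0.3, 0.2, 0.1)[deep_split + 1L]
  labels <- integer(n)
  static <- stats::cutree(hc, h = cut_height)
  pieces <- split(seq_len(n), static)

  recurse <- function(members) {
    if (length(members) < 2L * min_size) return(list(members))
    sub <- stats::hclust(stats::as.dist(dissim[members, members, drop = FALSE]),
                         method = "average")
    h <- sort(sub$height)
    rng <- h[length(h)] - h[1L]
    if (rng <= 0) return(list(members))
    gaps <- diff(h)
    gi <- which.max(gaps)
    if (gaps[gi] / rng <= gamma) return(list(members))
    cutat <- (h[gi] + h[gi + 1L]) / 2
    cl <- stats::cutree(sub, h = cutat)
    unlist(lapply(split(members, cl), recurse), recursive = FALSE)
  }

  branches <- unlist(lapply(pieces, recurse), recursive = FALSE)
  nxt <- 1L
  for (b in branches) {
    if (length(b) >= min_size && length(b) < n) {
      labels[b] <- nxt
      nxt <- nxt + 1L
    }
  }
  labels
}

# first principal component of the z-scored module submatrix,
# sign-anchored so the mean gene correlation with it is positive;
# unit norm over samples
module_eigengene <- function(zmat, members) {
  sub <- zmat[members, , drop = FALSE]
  sv <- svd(sub, nu = 0, nv = 1)
  me <- sv$v[, 1]
  if (mean(stats::cor(me, t(sub))) < 0) me <- -me
  me / sqrt(sum(me^2))
}

#' Detect consensus modules by dynamic dendrogram cutting
#'
#' Clusters `1 - consensus TOM` by average linkage, applies a recursive
#' largest-gap dynamic cut (honoring `cut_height`, `deep_split`,
#' `min_module_size`; no post-hoc reassignment), iteratively merges modules
#' whose eigengene dissimilarity `1 - cor(ME)` falls below `merge_thresh`,
#' computes module eigengenes (first PC of the z-scored module submatrix
#' over the per-dataset z-scored, sample-concatenated expression), the kME
#' table (Pearson gene-eigengene correlations), and removes genes whose
#' own-module kME is below `kme_min`. Module labels are color names ordered
#' by module size (largest = turquoise); unassigned genes are `grey`.
#'
#' @param ctom consensus TOM from [consensus_tom()] (or a single dataset's
#'   TOM).
#' @param config a [network_config()].
#' @param expr_list list of genes x samples expression matrices (one per
#'   dataset, same genes in the same order as `ctom`).
#' @return object of class `module_assignment`: list with `labels` (named
#'   color per gene), `numeric_labels` (0 = unassigned), `eigengenes`
#'   (samples x modules, unit-norm columns), `kme` (genes x modules),
#'   `module_sizes`, and `config`.
#' @export
detect_modules <- function(ctom, config, expr_list) {
  stopifnot(inherits(config, "network_config"))
  if (is.matrix(expr_list)) expr_list <- list(expr_list)
  genes <- rownames(expr_list[[1]])
  n <- nrow(ctom)
  stopifnot(all(vapply(expr_list, nrow, 0L) == n))

  zmat <- do.call(cbind, lapply(expr_list, function(m) t(scale(t(m)))))
  colnames(zmat) <- make.unique(unlist(lapply(expr_list, colnames)),
                                sep = "_rep")

  if (n < config$min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned")
    return(empty_assignment(genes, zmat, config))
  }
  dissim <- 1 - ctom
  hc <- stats::hclust(stats::as.dist(dissim), method = "average")
  lab <- dynamic_cut(hc, dissim, config$deep_split, config$cut_height,
                     config$min_module_size)
  if (!any(lab > 0L)) {
    warning("no modules detected; all genes unassigned")
    return(empty_assignment(genes, zmat, config))
  }

  # iterative eigengene merging
  repeat {
    ids <- sort(unique(lab[lab > 0L]))
    mes <- sapply(ids, function(k) module_eigengene(zmat, which(lab == k)))
    if (length(ids) < 2L) break
    d <- 1 - stats::cor(mes)
    diag(d) <- Inf
    if (min(d) >= config$merge_thresh) break
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    lab[lab == ids[ij[2]]] <- ids[ij[1]]
  }

  # relabel by size, largest first
  ids <- sort(unique(lab[lab > 0L]))
  sizes <- vapply(ids, function(k) sum(lab == k), 0L)
  ord <- ids[order(-sizes)]
  newlab <- integer(length(lab))
  for (r in seq_along(ord)) newlab[lab == ord[r]] <- r
  lab <- newlab

  ids <- seq_len(max(lab))
  mes <- sapply(ids, function(k) module_eigengene(zmat, which(lab == k)))
  colors <- MODULE_COLORS[ids]
  colnames(mes) <- paste0("ME", colors)
  rownames(mes) <- colnames(zmat)

  kme <- stats::cor(t(zmat), mes)
  rownames(kme) <- genes
  colnames(kme) <- colors

  # kME pruning against the final eigengenes
  for (k in ids) {
    own <- lab == k
    weak <- own & kme[, k] < config$kme_min
    lab[weak] <- 0L
  }

  labels <- ifelse(lab == 0L, "grey", MODULE_COLORS[lab])
  names(labels) <- genes
  structure(list(labels = labels, numeric_labels = stats::setNames(lab, genes),
                 eigengenes = mes, kme = kme,
                 module_sizes = table(labels[labels != "grey"]),
                 config = config),
            class = "module_assignment")
}

empty_assignment <- function(genes, zmat, config) {
  structure(list(labels = stats::setNames(rep("grey", length(genes)), genes),
                 numeric_labels = stats::setNames(integer(length(genes)), genes),
                 eigengenes = matrix(0, ncol(zmat), 0,
                                     dimnames = list(colnames(zmat), NULL)),
                 kme = matrix(0, length(genes), 0,
                              dimnames = list(genes, NULL)),
                 module_sizes = table(character()), config = config),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  k <- ncol(x$eigengenes)
  cat("module_assignment:", k, "modules;",
      sum(x$labels == "grey"), "of", length(x$labels), "genes unassigned\n")
  if (k) print(x$module_sizes)
  invisible(x)
}

#' Module eigengene - trait correlations
#'
#' Pearson correlation of each module eigengene with each numeric-coded
#' trait, p from the t distribution with n - 2 df, BH FDR over the whole
#' table; a correlation is flagged significant iff FDR < 0.05 and |r| >=
#' 0.1.
#'
#' @param assignment a `module_assignment`.
#' @param traits samples x traits numeric data.frame/matrix, rows matched
#'   to the eigengene rows (code age 4/12 -> 0/1, sex F/M -> 0/1, genotype
#'   WT/5x -> 0/1).
#' @return data.frame `module, trait, r, p, fdr, significant`.
#' @export
module_trait_cor <- function(assignment, traits) {
  stopifnot(inherits(assignment, "module_assignment"))
  traits <- as.matrix(traits)
  if (any(apply(traits, 2, stats::sd) == 0))
    stop("constant trait column", call. = FALSE)
  mes <- assignment$eigengenes
  stopifnot(nrow(traits) == nrow(mes))
  n <- nrow(mes)
  r <- stats::cor(mes, traits)
  tt <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  out <- data.frame(
    module = rep(sub("^ME", "", rownames(r)), ncol(r)),
    trait = rep(colnames(traits), each = nrow(r)),
    r = as.vector(r), p = as.vector(p), stringsAsFactors = FALSE)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$fdr < 0.05 & abs(out$r) >= 0.1
  out
}

#' Eigengenes of existing module definitions on new samples
#'
#' Applies a module assignment to another expression matrix (e.g. a sample
#' subset or time point) and recomputes each module's eigengene there -
#' the "synthetic eigengene" used to trace module trajectories.
#'
#' @param assignment a `module_assignment`.
#' @param mat genes x samples matrix containing the assigned genes.
#' @return samples x modules eigengene matrix.
#' @export
synthetic_eigengenes <- function(assignment, mat) {
  z <- t(scale(t(mat)))
  labs <- assignment$labels[rownames(mat)]
  mods <- setdiff(colnames(assignment$kme), NULL)
  mes <- sapply(mods, function(cl) {
    members <- which(labs == cl)
    if (length(members) < 2L) return(rep(NA_real_, ncol(mat)))
    module_eigengene(z, members)
  })
  rownames(mes) <- colnames(mat)
  colnames(mes) <- paste0("ME", mods)
  mes
}
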