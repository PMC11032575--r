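# Gene-set enrichment (two-sided Fisher via hypergeometric enumeration),
# directional DEG overlap, DEG-signature correlation, gene-set eigengenes,
# and permutation module preservation with Z-summary bands.

#' Build a gene-set collection over a background universe
#'
#' Sets are harmonized to the universe; empty sets (before or after
#' harmonization) are rejected.
#'
#' @param sets named list of character vectors of gene IDs.
#' @param universe character vector: all analyzed genes.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe) {
  stopifnot(is.list(sets), length(names(sets)) == length(sets))
  universe <- unique(universe)
  harm <- lapply(sets, function(s) intersect(unique(s), universe))
  empty <- lengths(harm) == 0L
  if (any(empty))
    stop(sprintf("empty gene set(s) after harmonization: %s",
                 paste(names(sets)[empty], collapse = ", ")), call. = FALSE)
  structure(list(sets = harm, universe = universe),
            class = "gene_set_collection")
}

# Two-sided Fisher p for a 2x2 table with margins fixed: sum of
# hypergeometric point probabilities no larger than the observed one
# (with the customary relative tolerance).
fisher_p2 <- function(a, set_size, universe_size, query_size) {
  lo <- max(0L, query_size + set_size - universe_size)
  hi <- min(query_size, set_size)
  x <- lo:hi
  d <- stats::dhyper(x, set_size, universe_size - set_size, query_size)
  obs <- stats::dhyper(a, set_size, universe_size - set_size, query_size)
  min(1, sum(d[d <= obs * (1 + 1e-7)]))
}

#' Two-sided Fisher's exact gene-set enrichment
#'
#' For each set, the 2x2 table of query/set membership over the universe is
#' tested with a two-sided Fisher's exact test (p computed by summing
#' hypergeometric point probabilities not exceeding the observed table's);
#' the odds ratio is `ad/bc` with a 0.5 continuity correction applied to
#' all cells when any cell is zero (the p-value is never corrected).
#' BH FDR is applied across the collection.
#'
#' @param query character vector of gene IDs (subset of the universe).
#' @param collection a [gene_set_collection()].
#' @return object of class `enrichment_result`: data.frame `set, set_size,
#'   query_size, overlap, odds_ratio, p, fdr`.
#' @export
fisher_enrich <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- collection$universe
  query <- intersect(unique(query), universe)
  if (!length(query) && length(collection$sets))
    stop("query has no genes in the universe", call. = FALSE)
  N <- length(universe)
  nq <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    s <- collection$sets[[nm]]
    a <- length(intersect(query, s))
    b <- nq - a
    cc <- length(s) - a
    d <- N - a - b - cc
    p <- fisher_p2(a, length(s), N, nq)
    cells <- c(a, b, cc, d)
    if (any(cells == 0)) cells <- cells + 0.5
    orr <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    data.frame(set = nm, set_size = length(s), query_size = nq, overlap = a,
               odds_ratio = orr, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  structure(out, class = c("enrichment_result", "data.frame"))
}

#' Direction-separated DEG enrichment
#'
#' Splits a differential expression result into up- (log2FC > lfc, FDR <
#' fdr) and down-regulated DEG sets and enriches each against the
#' collection separately. An empty direction yields rows with overlap 0 and
#' p = 1.
#'
#' @param de a `de_result`.
#' @param collection a [gene_set_collection()].
#' @return list with elements `up` and `down`, each an
#'   `enrichment_result`.
#' @export
directional_overlap <- function(de, collection) {
  run <- function(q) {
    if (!length(q)) {
      out <- data.frame(set = names(collection$sets),
                        set_size = lengths(collection$sets),
                        query_size = 0L, overlap = 0L, odds_ratio = NA_real_,
                        p = 1, fdr = 1, stringsAsFactors = FALSE)
      rownames(out) <- NULL
      return(structure(out, class = c("enrichment_result", "data.frame")))
    }
    fisher_enrich(q, collection)
  }
  list(up = run(deg_set(de, "up")), down = run(deg_set(de, "down")))
}

#' Correlate a DE log2FC vector with module expression signatures
#'
#' Pearson correlation between the per-gene log2 fold changes and each
#' signature's per-gene effect vector over shared genes; correlations are
#' flagged when |r| >= 0.20 and p < 0.05. Results with fewer than 10
#' shared genes are marked unreliable.
#'
#' @param de a `de_result`.
#' @param signatures named list of numeric vectors, each named by gene ID.
#' @return data.frame `signature, n_shared, r, p, flagged, reliable`.
#' @export
deg_module_correlation <- function(de, signatures) {
  lfc <- stats::setNames(de$log2_fc, de$gene)
  rows <- lapply(names(signatures), function(nm) {
    sig <- signatures[[nm]]
    shared <- intersect(names(sig), names(lfc))
    if (length(shared) < 3L)
      return(data.frame(signature = nm, n_shared = length(shared),
                        r = NA_real_, p = NA_real_, flagged = FALSE,
                        reliable = FALSE, stringsAsFactors = FALSE))
    ct <- stats::cor.test(lfc[shared], sig[shared], method = "pearson")
    data.frame(signature = nm, n_shared = length(shared),
               r = unname(ct$estimate), p = ct$p.value,
               flagged = abs(ct$estimate) >= 0.20 && ct$p.value < 0.05,
               reliable = length(shared) >= 10L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gene-set eigengene (PC1 of a gene list)
#'
#' First principal component of the z-scored submatrix of the listed genes,
#' sign-fixed so the mean gene correlation with it is positive; per-group
#' means and standard errors are reported when a grouping is supplied.
#'
#' @param mat genes x samples expression matrix.
#' @param gene_list character vector of gene IDs (>= 3 must be present).
#' @param grouping optional factor/character over samples.
#' @return list with `scores` (per-sample PC1, unit norm), `group_summary`
#'   (data.frame group, mean, sem, n) or NULL, `n_genes_used`, `missing`.
#' @export
geneset_eigengene <- function(mat, gene_list, grouping = NULL) {
  present <- intersect(gene_list, rownames(mat))
  if (length(present) < 3L)
    stop(sprintf("fewer than 3 listed genes present; missing: %s",
                 paste(setdiff(gene_list, rownames(mat)), collapse = ", ")),
         call. = FALSE)
  z <- t(scale(t(mat[present, , drop = FALSE])))
  scores <- module_eigengene(z, seq_len(nrow(z)))
  names(scores) <- colnames(mat)
  gs <- NULL
  if (!is.null(grouping)) {
    g <- factor(grouping)
    gs <- do.call(rbind, lapply(levels(g), function(lv) {
      v <- scores[g == lv]
      data.frame(group = lv, mean = mean(v),
                 sem = stats::sd(v) / sqrt(length(v)), n = length(v),
                 stringsAsFactors = FALSE)
    }))
  }
  list(scores = scores, group_summary = gs, n_genes_used = length(present),
       missing = setdiff(gene_list, rownames(mat)))
}

#' Assign preservation bands from Z-summary scores
#'
#' Bands: `< 2` not preserved, `[2, 5)` moderately preserved, `[5, 10]`
#' preserved, `> 10` highly preserved.
#'
#' @param z numeric vector of Z-summary scores.
#' @return character vector of bands.
#' @export
preservation_band <- function(z) {
  ifelse(z > 10, "highly_preserved",
  ifelse(z >= 5, "preserved",
  ifelse(z >= 2, "moderate", "not_preserved")))
}

#' Permutation module preservation (Z-summary)
#'
#' For each module, two observed statistics on the shared gene universe:
#' density (mean within-module signed adjacency in the test data, adjacency
#' `((1 + bicor)/2)^beta` as in the network construction) and connectivity
#' preservation (Pearson correlation between intramodular connectivity
#' vectors in reference vs test). A null of `n_perm` random same-size gene
#' sets yields `Z = (obs - mean(null)) / sd(null)` per statistic;
#' `Z_summary` is their mean and is banded by [preservation_band()].
#' Modules with fewer than 3 shared genes are skipped with a warning.
#'
#' @param ref_expr reference genes x samples matrix.
#' @param test_expr test genes x samples matrix.
#' @param labels named module labels per gene (`grey`/`0` = unassigned).
#' @param beta soft power for the adjacency.
#' @param n_perm number of null permutations (>= 50).
#' @param seed RNG seed for the permutation null.
#' @return object of class `preservation_result`: data.frame `module, size,
#'   Z_density, Z_connectivity, Z_summary, band`.
#' @export
module_preservation <- function(ref_expr, test_expr, labels, beta = 16,
                                n_perm = 100L, seed = 1L) {
  if (n_perm < 50L) stop("n_perm must be >= 50", call. = FALSE)
  shared <- intersect(rownames(ref_expr), rownames(test_expr))
  labels <- labels[names(labels) %in% shared]
  mods <- setdiff(unique(labels), c("grey", "0", 0))
  adj_ref <- signed_adjacency(bicor_matrix(ref_expr[shared, , drop = FALSE]), beta)
  adj_test <- signed_adjacency(bicor_matrix(test_expr[shared, , drop = FALSE]), beta)
  rownames(adj_ref) <- colnames(adj_ref) <- shared
  rownames(adj_test) <- colnames(adj_test) <- shared

  stat_pair <- function(genes) {
    at <- adj_test[genes, genes]
    ar <- adj_ref[genes, genes]
    dens <- mean(at[upper.tri(at)])
    conn <- suppressWarnings(stats::cor(rowSums(ar), rowSums(at)))
    c(density = dens, connectivity = if (is.na(conn)) 0 else conn)
  }

  rows <- list()
  for (m in mods) {
    genes <- names(labels)[labels == m]
    if (length(genes) < 3L) {
      warning(sprintf("module '%s' has < 3 shared genes; skipped", m))
      next
    }
    obs <- stat_pair(genes)
    null <- with_seed(derive_seed(seed, paste0("preserve:", m)), {
      t(replicate(n_perm, stat_pair(sample(shared, length(genes)))))
    })
    mu <- colMeans(null)
    sdv <- apply(null, 2, stats::sd)
    z <- (obs - mu) / sdv
    # degenerate null (e.g. connectivity when test == reference): no spread
    # around an identical observed value carries no evidence either way
    deg <- sdv < 1e-12
    z[deg] <- ifelse(abs(obs - mu)[deg] < 1e-8, 0,
                     sign((obs - mu)[deg]) * Inf)
    zs <- mean(z)
    rows[[m]] <- data.frame(module = m, size = length(genes),
                            Z_density = z["density"],
                            Z_connectivity = z["connectivity"],
                            Z_summary = zs, band = preservation_band(zs),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("preservation_result", "data.frame"))
}
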