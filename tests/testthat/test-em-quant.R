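# Equivalence-class mapping against a brute-force substring scan, EM
# properties (monotone likelihood, symmetry, grid-search maximizer), and
# TPM aggregation.

test_that("compat_map equals a brute-force substring scan on a small fixture", {
  ref <- small_reference(seed = 61)
  dip <- ref$diploid[1:20, ]
  cfg <- ref$config
  w <- setNames(rep(1, nrow(dip)), dip$entry_id)
  rs <- simulate_reads(dip, w, cfg)
  reads <- rs$reads[1:300]
  eq <- compat_map(reads, dip)

  # oracle: scan every transcript for every distinct read
  key_of <- function(read) paste(sort(which(vapply(
    dip$sequence, grepl, TRUE, pattern = read, fixed = TRUE,
    USE.NAMES = FALSE))), collapse = ",")
  oracle_keys <- vapply(unique(reads), key_of, character(1))
  oracle <- table(oracle_keys[match(reads, unique(reads))])
  got_keys <- vapply(eq$members, paste, character(1), collapse = ",")
  expect_setequal(got_keys, names(oracle))
  expect_identical(eq$counts[match(names(oracle), got_keys)],
                   as.integer(oracle))
  expect_identical(eq$total_reads + eq$n_unmapped, length(reads))
})

test_that("reads spanning an M/P SNP map to one allele, shared regions to both", {
  ref <- small_reference(seed = 67)
  dip <- ref$diploid
  st <- ref$strain
  snps <- ref$founders$snps
  # pick a non-MT transcript whose paternal founder carries >= 1 alt allele
  cand <- st[!grepl("MT", st$chromosome), ]
  tx <- NULL
  for (i in seq_len(nrow(cand))) {
    hit <- snps$transcript_id == cand$transcript_id[i] &
      snps[[cand$source_founder[i]]]
    if (any(hit)) { tx <- cand$transcript_id[i]; pos <- snps$pos_in_tx[hit][1]; break }
  }
  skip_if(is.null(tx), "fixture produced no SNP-bearing transcript")
  rl <- ref$config$read_length
  mseq <- dip$sequence[dip$transcript_id == tx & dip$allele == "M"]
  # read covering the SNP: compatible with exactly the maternal allele
  start <- max(1, pos - rl + 1)
  read_m <- substring(mseq, start, start + rl - 1)
  eq <- compat_map(setNames(read_m, "r1"), dip)
  hits <- eq$entries$entry_id[eq$members[[1]]]
  expect_identical(hits, paste0(tx, "_M"))
  # read from a SNP-free window: compatible with both alleles
  snp_pos <- snps$pos_in_tx[snps$transcript_id == tx]
  windows <- setdiff(seq_len(nchar(mseq) - rl + 1),
                     unlist(lapply(snp_pos, function(p) (p - rl + 1):p)))
  skip_if(!length(windows), "no SNP-free window")
  read_b <- substring(mseq, windows[1], windows[1] + rl - 1)
  eqb <- compat_map(setNames(read_b, "r1"), dip)
  hitsb <- eqb$entries$entry_id[eqb$members[[1]]]
  expect_true(all(paste0(tx, c("_M", "_P")) %in% hitsb))
})

test_that("EM: unique reads reduce to count/length normalization in one sweep", {
  eq <- structure(list(
    members = list(1L, 2L, 3L),
    counts = c(60L, 30L, 10L),
    entries = data.frame(entry_id = c("t1", "t2", "t3"),
                         transcript_id = c("t1", "t2", "t3"),
                         gene_id = c("g1", "g2", "g3"),
                         allele = "M", length = c(140L, 240L, 540L),
                         eff_length = c(100L, 200L, 500L)),
    read_length = 41L, total_reads = 100L, n_unmapped = 0L),
    class = "eqc_set")
  fit <- em_quantify(eq)
  direct <- c(60 / 100, 30 / 200, 10 / 500)
  expect_equal(unname(fit$theta), direct / sum(direct), tolerance = 1e-12)
  expect_lte(fit$n_iter, 2L)
})

test_that("EM: full ambiguity between equal-length transcripts splits evenly", {
  eq <- structure(list(
    members = list(c(1L, 2L)),
    counts = 500L,
    entries = data.frame(entry_id = c("a", "b"), transcript_id = c("a", "b"),
                         gene_id = c("ga", "gb"), allele = "M",
                         length = c(100L, 100L), eff_length = c(58L, 58L)),
    read_length = 43L, total_reads = 500L, n_unmapped = 0L),
    class = "eqc_set")
  fit <- em_quantify(eq)
  expect_equal(unname(fit$theta), c(0.5, 0.5), tolerance = 1e-10)
})

test_that("EM matches a grid-search likelihood maximizer on a 3-transcript fixture", {
  ell <- c(100, 150, 200)
  members <- list(1L, c(1L, 2L), c(2L, 3L), 3L, c(1L, 2L, 3L))
  counts <- c(40L, 25L, 20L, 10L, 5L)
  eq <- structure(list(
    members = members, counts = counts,
    entries = data.frame(entry_id = c("t1", "t2", "t3"),
                         transcript_id = c("t1", "t2", "t3"),
                         gene_id = c("g1", "g2", "g3"), allele = "M",
                         length = ell + 42, eff_length = ell),
    read_length = 43L, total_reads = sum(counts), n_unmapped = 0L),
    class = "eqc_set")
  fit <- em_quantify(eq, tol = 1e-12, max_iter = 5000)

  # independent oracle: grid search over the read-fraction simplex
  loglik <- function(eta) {
    s <- vapply(members, function(m) sum(eta[m] / ell[m]), 0)
    sum(counts * log(s))
  }
  grid <- seq(0.001, 0.998, by = 0.001)
  best <- c(-Inf, NA, NA)
  for (e1 in grid) {
    e2 <- seq(0.001, 0.999 - e1, by = 0.001)
    ll <- vapply(e2, function(x) loglik(c(e1, x, 1 - e1 - x)), 0)
    j <- which.max(ll)
    if (ll[j] > best[1]) best <- c(ll[j], e1, e2[j])
  }
  expect_equal(unname(fit$eta), c(best[2], best[3], 1 - best[2] - best[3]),
               tolerance = 2e-3)  # grid resolution
  expect_gte(fit$loglik, best[1] - 1e-6)

  # likelihood is monotone non-decreasing every sweep
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))
})

test_that("EM is invariant to read order and flags non-convergence", {
  ref <- small_reference(seed = 71)
  w <- setNames(runif(nrow(ref$diploid)) + 0.2, ref$diploid$entry_id)
  rs <- simulate_reads(ref$diploid, w, ref$config)
  eq1 <- compat_map(rs$reads, ref$diploid)
  eq2 <- compat_map(rev(rs$reads), ref$diploid)
  f1 <- em_quantify(eq1)
  f2 <- em_quantify(eq2)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-10)
  expect_warning(fit <- em_quantify(eq1, tol = 0, max_iter = 3),
                 "did not converge")
  expect_false(fit$converged)
})

test_that("gene TPM pools alleles, scales to 1e6, and rejects orphans", {
  ref <- small_reference(seed = 73)
  w <- setNames(rep(1, nrow(ref$diploid)), ref$diploid$entry_id)
  rs <- simulate_reads(ref$diploid, w, ref$config)
  res <- quantify_sample(rs$reads, ref$diploid)
  expect_equal(sum(res$tpm), 1e6, tolerance = 1e-3)
  expect_true(all(res$tpm >= 0))
  # proportional split across genes
  theta <- setNames(c(0.75, 0.25), c("tA_M", "tB_M"))
  eq <- structure(list(
    members = list(1L, 2L), counts = c(1L, 1L),
    entries = data.frame(entry_id = c("tA_M", "tB_M"),
                         transcript_id = c("tA", "tB"),
                         gene_id = c("gA", "gB"), allele = "M",
                         length = c(100L, 100L), eff_length = c(58L, 58L)),
    read_length = 43L, total_reads = 2L, n_unmapped = 0L),
    class = "eqc_set")
  expect_equal(unname(gene_tpm(theta, eq)), c(750000, 250000))
  expect_error(gene_tpm(theta, eq, gene_map = c(tA = "gA")), "tB")
})

test_that("allele balance is recovered from SNP-bearing transcripts", {
  ref <- small_reference(seed = 79)
  dip <- ref$diploid
  auto <- dip[!grepl("MT", dip$chromosome), ]
  # keep transcripts whose M and P copies actually differ (identifiable)
  differs <- vapply(split(auto$sequence, auto$transcript_id),
                    function(s) length(unique(s)) == 2L, TRUE)
  auto <- auto[differs[auto$transcript_id], ]
  w <- setNames(ifelse(auto$allele == "M", 0.7, 0.3), auto$entry_id)
  cfg <- small_config(seed = 79, n_reads = 20000L)
  rs <- simulate_reads(auto, w, cfg)
  res <- quantify_sample(rs$reads, auto)
  th <- res$fit$theta
  m_share <- sum(th[auto$entry_id[auto$allele == "M"]])
  expect_lt(abs(m_share - 0.7), 0.05)
})
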