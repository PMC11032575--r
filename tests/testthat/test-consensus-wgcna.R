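# bicor / TOM / consensus oracles, dynamic module detection, merging,
# kME pruning, trait correlation.

# scalar reference implementation of the biweight midcorrelation
bicor_scalar <- function(x, y) {
  tr <- function(v) {
    u <- (v - median(v)) / (9 * median(abs(v - median(v))))
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (v - median(v)) * w
  }
  xt <- tr(x); yt <- tr(y)
  sum(xt * yt) / sqrt(sum(xt^2) * sum(yt^2))
}

test_that("bicor matches the scalar formula, with expected symmetries", {
  set.seed(127)
  mat <- matrix(rnorm(6 * 8), 6, 8, dimnames = list(paste0("g", 1:6), NULL))
  colnames(mat) <- paste0("s", 1:8)
  b <- bicor_matrix(mat)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(b[i, j], bicor_scalar(mat[i, ], mat[j, ]), tolerance = 1e-12)
  expect_equal(diag(b), setNames(rep(1, 6), rownames(mat)))
  expect_identical(b, t(b))
  # y = -x gives exactly -1
  m2 <- rbind(a = mat[1, ], b = -mat[1, ])
  expect_equal(bicor_matrix(m2)["a", "b"], -1, tolerance = 1e-12)
  # constant genes dropped, MAD-0 genes fall back to Pearson
  m3 <- rbind(mat, const = rep(2, 8))
  expect_warning(b3 <- bicor_matrix(m3), "constant")
  expect_false("const" %in% rownames(b3))
  m4 <- rbind(x = mat[1, ], spiky = c(rep(0, 7), 5))
  expect_message(b4 <- bicor_matrix(m4), "Pearson")
  tr1 <- local({
    v <- mat[1, ]
    u <- (v - median(v)) / (9 * median(abs(v - median(v))))
    (v - median(v)) * (1 - u^2)^2 * (abs(u) < 1)
  })
  cs <- m4[2, ] - mean(m4[2, ])   # Pearson weighting for the MAD-0 gene
  expect_equal(b4["x", "spiky"],
               sum(tr1 * cs) / sqrt(sum(tr1^2) * sum(cs^2)),
               tolerance = 1e-12)
  expect_error(bicor_matrix(mat[, 1:3]), ">= 4 samples")
})

test_that("signed TOM matches a brute-force triple loop and saturates", {
  set.seed(131)
  for (n in c(6, 10)) {
    cmat <- cov2cor(crossprod(matrix(rnorm(n * n), n)))
    beta <- 6
    tom <- signed_tom(cmat, beta)
    a <- ((1 + cmat) / 2)^beta; diag(a) <- 0
    k <- rowSums(a)
    brute <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      s <- 0
      for (u in 1:n) s <- s + a[i, u] * a[u, j]
      brute[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
    diag(brute) <- 1
    expect_lt(max(abs(tom - brute)), 1e-12)
    expect_true(all(tom >= 0 & tom <= 1))
  }
  # 2-gene closed form: empty neighbour sum, min-connectivity a, so
  # tom_12 = (0 + a) / (a + 1 - a) = a
  c2 <- matrix(c(1, 0.6, 0.6, 1), 2)
  t2 <- signed_tom(c2, 4)
  a12 <- 0.8^4
  expect_equal(t2[1, 2], a12, tolerance = 1e-12)
  # perfect module saturates at 1
  ones <- matrix(1, 5, 5)
  expect_true(all(abs(signed_tom(ones, 16)[upper.tri(ones)] - 1) < 1e-12))
})

test_that("consensus TOM is the element-wise min of quantile-scaled TOMs", {
  set.seed(137)
  toms <- lapply(1:3, function(s) {
    cmat <- cov2cor(crossprod(matrix(rnorm(100), 10)))
    signed_tom(cmat, 4)
  })
  cons <- consensus_tom(toms, quantile = 0.2)
  q <- vapply(toms, function(m) quantile(m[upper.tri(m)], 0.2, names = FALSE), 0)
  scaled <- list(toms[[1]],
                 toms[[2]]^(log(q[1]) / log(q[2])),
                 toms[[3]]^(log(q[1]) / log(q[3])))
  brute <- pmin(scaled[[1]], pmin(scaled[[2]], scaled[[3]]))
  diag(brute) <- 1
  expect_equal(cons, brute, tolerance = 1e-12)
  for (s in 1:3) {
    off <- upper.tri(cons)
    expect_true(all(cons[off] <= scaled[[s]][off] + 1e-12))
  }
  # single dataset and identical datasets are identities
  expect_equal(consensus_tom(toms[1]), toms[[1]])
  expect_equal(consensus_tom(list(toms[[1]], toms[[1]])), toms[[1]],
               tolerance = 1e-12)
})

test_that("planted modules are recovered and pure noise stays unassigned", {
  d1 <- planted_expression(seed = 139, strain = "CC1")
  d2 <- planted_expression(seed = 140, strain = "CC2")
  cfg <- network_config(beta = 16, min_module_size = 100)
  toms <- lapply(list(d1$matrix, d2$matrix),
                 function(m) signed_tom(bicor_matrix(m), cfg$beta))
  ctom <- consensus_tom(toms, cfg$consensus_quantile)
  ma <- detect_modules(ctom, cfg, list(d1$matrix, d2$matrix))
  expect_gte(rand_index_adj(ma$numeric_labels, d1$truth$module_labels), 0.9)
  # eigengene unit norm and kME contract after pruning
  expect_equal(unname(colSums(ma$eigengenes^2)),
               rep(1, ncol(ma$eigengenes)), tolerance = 1e-9)
  for (cl in colnames(ma$kme)) {
    own <- ma$labels == cl
    expect_true(all(ma$kme[own, cl] >= cfg$kme_min))
  }
  # module labels are the standard palette prefix (size-ordered pre-prune)
  expect_setequal(names(table(ma$labels[ma$labels != "grey"])),
                  ccf1tx:::MODULE_COLORS[seq_len(ncol(ma$eigengenes))])

  # pure noise: nearly everything unassigned
  cfg0 <- sim_config(seed = 141, n_genes = 600, n_offspring = 50, noise_sd = 1)
  d0 <- gen_expression(cfg0, simulate_cross(cfg0, gen_mosaic(cfg0, "N")))
  tom0 <- signed_tom(bicor_matrix(d0$matrix), 16)
  ma0 <- suppressWarnings(detect_modules(tom0, cfg, list(d0$matrix)))
  expect_gte(mean(ma0$labels == "grey"), 0.95)
})

test_that("module detection is invariant to gene order", {
  d <- planted_expression(seed = 149, n_genes = 360, n_modules = 3,
                          module_size = 110, strain = "CCp")
  cfg <- network_config(min_module_size = 100)
  tom <- signed_tom(bicor_matrix(d$matrix), cfg$beta)
  ma <- detect_modules(tom, cfg, list(d$matrix))
  set.seed(151)
  perm <- sample(nrow(d$matrix))
  mp <- d$matrix[perm, ]
  tomp <- signed_tom(bicor_matrix(mp), cfg$beta)
  map <- detect_modules(tomp, cfg, list(mp))
  expect_gte(rand_index_adj(ma$numeric_labels[rownames(mp)],
                            map$numeric_labels), 0.999)
})

test_that("highly correlated modules merge under the eigengene threshold", {
  # two gene blocks driven by nearly the same factor: ME cor ~ 0.95
  cfg <- sim_config(seed = 157, n_genes = 500, n_offspring = 60, noise_sd = 0.25)
  md <- simulate_cross(cfg, gen_mosaic(cfg, "CCm"))
  ns <- nrow(md)
  f <- rnorm(ns)
  set.seed(158)
  f2 <- 0.97 * f + sqrt(1 - 0.97^2) * rnorm(ns)
  f3 <- rnorm(ns)
  mat <- matrix(rnorm(500 * ns, sd = 0.25), 500, ns,
                dimnames = list(sprintf("g%03d", 1:500), md$sample_id))
  mat[1:120, ] <- mat[1:120, ] + outer(runif(120, 0.8, 1.2), f)
  mat[121:240, ] <- mat[121:240, ] + outer(runif(120, 0.8, 1.2), f2)
  mat[241:360, ] <- mat[241:360, ] + outer(runif(120, 0.8, 1.2), f3)
  ncfg <- network_config(min_module_size = 100, merge_thresh = 0.25)
  tom <- signed_tom(bicor_matrix(mat), ncfg$beta)
  ma <- detect_modules(tom, ncfg, list(mat))
  # blocks 1 and 2 end up in one module (1 - 0.97 < 0.25); block 3 separate
  l3 <- names(sort(table(ma$labels[241:360]), decreasing = TRUE))[1]
  expect_identical(names(sort(table(ma$labels[1:120]), decreasing = TRUE))[1],
                   names(sort(table(ma$labels[121:240]), decreasing = TRUE))[1])
  expect_false(identical(l3, names(sort(table(ma$labels[1:120]),
                                        decreasing = TRUE))[1]))
})

test_that("module-trait correlation flags only genuinely associated traits", {
  d <- planted_expression(seed = 163, n_genes = 360, n_modules = 3,
                          module_size = 110, n_samples = 60, strain = "CCt")
  cfg <- network_config(min_module_size = 100)
  tom <- signed_tom(bicor_matrix(d$matrix), cfg$beta)
  ma <- detect_modules(tom, cfg, list(d$matrix))
  skip_if(ncol(ma$eigengenes) < 2, "fixture did not yield 2+ modules")
  # traits: the first planted factor (strongly associated) + pure noise
  set.seed(164)
  traits <- cbind(factor1 = d$truth$factors[1, ], noise = rnorm(60))
  tc <- module_trait_cor(ma, traits)
  f1 <- tc[tc$trait == "factor1", ]
  expect_true(any(f1$significant & abs(f1$r) > 0.8))
  # trait = an ME itself gives r = 1
  tc2 <- module_trait_cor(ma, cbind(self = ma$eigengenes[, 1]))
  expect_equal(max(tc2$r), 1, tolerance = 1e-9)
  expect_error(module_trait_cor(ma, cbind(flat = rep(1, 60))), "constant")
})

test_that("synthetic eigengenes on a sample subset track the planted factor", {
  d <- planted_expression(seed = 167, n_genes = 360, n_modules = 3,
                          module_size = 110, n_samples = 60, strain = "CCu")
  cfg <- network_config(min_module_size = 100)
  tom <- signed_tom(bicor_matrix(d$matrix), cfg$beta)
  ma <- detect_modules(tom, cfg, list(d$matrix))
  skip_if(ncol(ma$eigengenes) < 1, "no modules")
  sub <- d$matrix[, 1:30]
  se <- synthetic_eigengenes(ma, sub)
  # the module holding planted block 1 should track factor 1 on the subset
  cl <- names(sort(table(ma$labels[d$truth$module_labels == 1]),
                   decreasing = TRUE))[1]
  r <- abs(cor(se[, paste0("ME", cl)], d$truth$factors[1, 1:30]))
  expect_gt(r, 0.9)
})
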