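# Marker scans, permutation thresholds, forward regression, intervals.

test_that("scan P-values equal per-marker lm() P-values with and without covariates", {
  set.seed(101)
  n <- 60
  G <- matrix(rbinom(n * 12, 1, 0.5), nrow = n,
              dimnames = list(NULL, sprintf("m%02d", 1:12)))
  y <- G[, 3] * 0.8 + rnorm(n)
  p <- marker_scan(y, G)
  for (j in seq_len(ncol(G))) {
    fit <- summary(lm(y ~ G[, j]))
    expect_equal(unname(p[j]), fit$coefficients[2, 4], tolerance = 1e-10)
  }
  # conditional scan
  p_c <- marker_scan(y, G, covariates = "m03")
  for (j in setdiff(seq_len(ncol(G)), 3)) {
    fit <- summary(lm(y ~ G[, 3] + G[, j]))
    expect_equal(unname(p_c[j]), fit$coefficients[3, 4], tolerance = 1e-10)
  }
  expect_equal(unname(p_c["m03"]), 1)
})

test_that("scan P-values equal the two-sample t-test on hand-sized vectors", {
  y <- c(1.2, 0.4, 2.2, 3.1, 0.9)
  g <- c(0L, 0L, 1L, 1L, 0L)
  G <- cbind(m1 = g)
  p <- marker_scan(y, G)
  oracle <- t.test(y[g == 1], y[g == 0], var.equal = TRUE)$p.value
  expect_equal(unname(p[1]), oracle, tolerance = 1e-12)
})

test_that("perfect association is the scan minimum and degenerate inputs give P = 1", {
  set.seed(102)
  G <- matrix(rbinom(50 * 8, 1, 0.5), nrow = 50,
              dimnames = list(NULL, sprintf("m%d", 1:8)))
  p <- marker_scan(as.numeric(G[, 5]), G)
  expect_equal(unname(which.min(p)), 5)
  expect_lt(p[5], 1e-30)
  expect_true(all(marker_scan(rep(2, 50), G) == 1))
})

test_that("null scan P-values are approximately uniform", {
  set.seed(103)
  n <- 80
  G <- matrix(rbinom(n * 40, 1, 0.5), nrow = n,
              dimnames = list(NULL, sprintf("m%02d", 1:40)))
  ps <- as.vector(replicate(25, marker_scan(rnorm(n), G)))
  expect_gt(ks.test(ps, "punif")$p.value, 1e-4)
})

test_that("the permutation threshold is the k-th order statistic of scan minima", {
  set.seed(104)
  G <- matrix(rbinom(40 * 10, 1, 0.5), nrow = 40,
              dimnames = list(NULL, sprintf("m%02d", 1:10)))
  y <- rnorm(40)
  thr <- permutation_threshold(y, G, n_perm = 200, quantile = 0.05, seed = 1)
  minima <- attr(thr, "min_p")
  expect_equal(as.numeric(thr), sort(minima)[floor(0.05 * 200)])
  # quantile = 1 admits every observed minimum
  thr1 <- permutation_threshold(y, G, n_perm = 50, quantile = 1, seed = 2)
  expect_equal(as.numeric(thr1), max(attr(thr1, "min_p")))
})

test_that("exhaustive permutations match an independent enumeration oracle", {
  set.seed(105)
  y <- c(0.3, -1.2, 0.8, 1.9, -0.4, 0.1)
  G <- cbind(m1 = c(0L, 1L, 0L, 1L, 1L, 0L), m2 = c(1L, 1L, 0L, 0L, 1L, 0L))
  perms <- t(all_perms(6))
  thr <- permutation_threshold(y, G, permutations = perms, quantile = 0.05)
  # oracle: per permutation, min of the two lm P-values
  oracle_min <- apply(perms, 2, function(idx) {
    yy <- y[idx]
    min(summary(lm(yy ~ G[, 1]))$coefficients[2, 4],
        summary(lm(yy ~ G[, 2]))$coefficients[2, 4])
  })
  expect_equal(sort(attr(thr, "min_p")), sort(oracle_min), tolerance = 1e-10)
  expect_equal(as.numeric(thr), sort(oracle_min)[floor(0.05 * 720)],
               tolerance = 1e-10)
})

test_that("drop intervals follow the -log10 P rule", {
  p <- 10^-c(5.5, 6.5, 7.5, 8, 7.5, 6.5, 5.5)
  expect_equal(drop_interval(p, 4, drop = 2), c(2, 6))
  expect_equal(drop_interval(10^-3, 1), c(1, 1))
  flat <- rep(0.01, 9)
  expect_equal(drop_interval(flat, 5), c(1, 9))
})

test_that("forward scans recover two planted unlinked loci and stay quiet on noise", {
  map <- make_marker_map(4, 12, 400000, seed = 111)
  geno <- simulate_cross(map, 300, 1, seed = 112)
  y <- geno[, "chr01_m0006"] + 0.8 * geno[, "chr03_m0004"] +
    rnorm(300, 0, 0.4)
  fs <- forward_scan(y, geno, map, n_perm = 200, seed = 113)
  expect_lte(max(fs$detections$stage), 2)
  got <- fs$detections
  for (mk in c("chr01_m0006", "chr03_m0004")) {
    chr <- map$chrom[map$marker_id == mk]
    pos <- map$pos[map$marker_id == mk]
    hit <- got[got$chrom == chr, ]
    expect_gte(nrow(hit), 1)
    expect_true(any(hit$ci_start_pos <= pos & hit$ci_end_pos >= pos))
  }
  # constant phenotype: nothing detectable
  fs0 <- forward_scan(rep(1, 300), geno, map, n_perm = 100, seed = 114)
  expect_equal(nrow(fs0$detections), 0)
})

test_that("forward scans are deterministic under a fixed seed", {
  map <- tiny_map(3, 8)
  geno <- simulate_cross(map, 100, 1, seed = 121)
  y <- geno[, 5] * 0.7 + rnorm(100, 0, 0.5)
  a <- forward_scan(y, geno, map, n_perm = 100, seed = 7)
  b <- forward_scan(y, geno, map, n_perm = 100, seed = 7)
  expect_identical(a$detections, b$detections)
  expect_identical(a$stage_thresholds, b$stage_thresholds)
})

test_that("stage-1 admissions equal an exhaustive single-marker oracle", {
  map <- tiny_map(2, 5)
  set.seed(131)
  geno <- simulate_cross(map, 12, 1, seed = 132)
  y <- rnorm(12) + geno[, 2]
  fs <- forward_scan(y, geno, map, n_perm = 50, quantile = 0.2, seed = 133)
  thr <- fs$stage_thresholds[1]
  p_oracle <- sapply(seq_len(ncol(geno)), function(j) {
    g <- geno[, j]
    if (var(g) == 0) return(1)
    summary(lm(y ~ g))$coefficients[2, 4]
  })
  stage1 <- fs$detections[fs$detections$stage == 1, ]
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    j <- idx[which.min(p_oracle[idx])]
    should <- p_oracle[j] <= thr
    expect_equal(j %in% stage1$peak_index, should)
  }
})

test_that("covariate peaks cannot be re-admitted on their own chromosome", {
  map <- tiny_map(2, 6)
  geno <- simulate_cross(map, 200, 1, seed = 141)
  y <- 2 * geno[, 3] + rnorm(200, 0, 0.3)
  fs <- forward_scan(y, geno, map, n_perm = 100, seed = 142)
  peaks <- fs$detections$peak_index
  expect_equal(anyDuplicated(peaks), 0)
})

test_that("variance explained reports R2 relative to heritability", {
  set.seed(151)
  G <- matrix(rbinom(100 * 6, 1, 0.5), nrow = 100,
              dimnames = list(NULL, sprintf("m%d", 1:6)))
  y <- G[, 1] - 2 * G[, 4]
  expect_equal(suppressWarnings(variance_explained(y, G, c(1, 4), h2 = 1)),
               100)
  expect_equal(variance_explained(y, G, integer(0), h2 = 0.5), 0)
  expect_error(variance_explained(y, G, 1, h2 = 0), "positive")
  yn <- y + rnorm(100)
  r2 <- summary(lm(yn ~ G[, c(1, 4)]))$r.squared
  expect_equal(variance_explained(yn, G, c(1, 4), 0.8), 100 * r2 / 0.8)
})
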