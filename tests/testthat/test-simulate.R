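# Synthetic-data generator: meiosis, effect models, barcodes, experiments.

test_that("marker maps satisfy their invariants and reject bad input", {
  map <- tiny_map(3, 20)
  expect_false(anyDuplicated(map$marker_id) > 0)
  for (chr in unique(map$chrom))
    expect_true(all(diff(map$pos[map$chrom == chr]) > 0))
  expect_error(simulate_cross(map[0, ], 5), "empty")
})

test_that("a cross without recombination yields whole parental chromosomes", {
  map <- tiny_map(2, 15)
  geno <- simulate_cross(map, 20, expected_crossovers = 0, seed = 1)
  for (chr in unique(map$chrom)) {
    block <- geno[, map$chrom == chr]
    expect_true(all(apply(block, 1, function(r) length(unique(r)) == 1)))
  }
})

test_that("marginal allele frequencies are balanced in a large cross", {
  map <- tiny_map(4, 15)
  geno <- simulate_cross(map, 2000, 2, seed = 7)
  freq <- colMeans(geno)
  # binomial(2000, 0.5) 99.99% bounds
  expect_true(all(freq > 0.45 & freq < 0.55))
})

test_that("crossover counts recover the Poisson mean", {
  map <- make_marker_map(1, 200, 750000, seed = 3)
  geno <- simulate_cross(map, 1000, expected_crossovers = 1, seed = 4)
  switches <- rowSums(geno[, -1] != geno[, -ncol(geno)])
  # dense markers make double-crossover masking negligible; se ~ 0.032
  expect_lt(abs(mean(switches) - 1), 0.1)
})

test_that("cross output is bit-reproducible under a fixed seed", {
  map <- tiny_map()
  expect_identical(simulate_cross(map, 30, 2, seed = 9),
                   simulate_cross(map, 30, 2, seed = 9))
})

test_that("effect models have the required sign structure", {
  map <- make_marker_map(16, 10, 750000, seed = 21)
  em <- simulate_effect_model(map, 10, 8, 0.15, seed = 22)
  expect_equal(nrow(em$loci), 18)
  expect_equal(sum(em$loci$class == "general"), 10)
  expect_equal(sum(em$loci$class == "antagonistic"), 8)
  nonbrain <- setdiff(colnames(em$s), "brain")
  for (k in seq_len(18)) {
    signs <- sign(em$s[k, ])
    if (em$loci$class[k] == "general") {
      expect_true(all(signs == signs[1]))
    } else {
      expect_true(all(signs[nonbrain] == -signs["brain"]))
    }
  }
  # loci on distinct markers, respecting the per-chromosome cap
  expect_false(anyDuplicated(em$loci$marker_id) > 0)
  expect_true(all(table(em$loci$chrom) <= 2))
})

test_that("effect-model edge cases error or degenerate cleanly", {
  map <- tiny_map()
  em0 <- simulate_effect_model(map, 0, 0, 0.1, seed = 1)
  expect_equal(nrow(em0$loci), 0)
  one_marker <- data.frame(marker_id = "m1", chrom = 1L, pos = 100L)
  expect_error(simulate_effect_model(one_marker, 2, 0, 0.1,
                                     max_per_chromosome = 1), "loci")
  expect_error(simulate_effect_model(map, 1, 1, 0), "positive")
})

test_that("barcode assignments are unique, well separated, and replicated", {
  asg <- make_barcode_assignment(sprintf("s%03d", 1:60), n_triplicated = 10,
                                 seed = 31)
  expect_equal(nrow(asg), 60 + 20)
  expect_false(anyDuplicated(asg$barcode) > 0)
  expect_true(all(nchar(asg$barcode) == 20))
  counts <- table(asg$segregant_id)
  expect_equal(sum(counts == 3), 10)
  expect_equal(sum(counts == 1), 50)
  # pairwise Hamming separation > 2 * default clustering radius
  mat <- do.call(rbind, strsplit(asg$barcode, ""))
  dmin <- min(vapply(seq_len(nrow(mat) - 1), function(i)
    min(colSums(t(mat[-seq_len(i), , drop = FALSE]) != mat[i, ])),
    numeric(1)))
  expect_gte(dmin, 7)
})

test_that("count rows sum to the sequencing depth and reproduce exactly", {
  fx <- small_sim()
  organ_rows <- fx$sim$meta$type == "organ"
  totals <- rowSums(fx$sim$counts)
  expect_true(all(totals[!organ_rows] == fx$des$depth))
  # organ samples can only fall short if the bottleneck founders are empty
  expect_true(all(totals[organ_rows] %in% c(0, fx$des$depth)))
  sim2 <- simulate_experiment(fx$geno, fx$asg, fx$em, fx$des, seed = 505)
  expect_identical(fx$sim$counts, sim2$counts)
})

test_that("a neutral experiment leaves expected frequencies at the pool", {
  fx <- small_sim()
  em0 <- simulate_effect_model(fx$map, 0, 0, 0.1, seed = 1)
  sim <- simulate_experiment(fx$geno, fx$asg, em0, fx$des,
                             plate_sd = 0, seed = 61)
  p0 <- sim$truth$p0
  for (i in seq_len(nrow(sim$meta)))
    expect_lt(max(abs(sim$truth$expected_freq[i, ] - p0)), 1e-12)
})

test_that("positive selection raises carrier frequency from day 1 to day 5", {
  fx <- small_sim()
  map <- fx$map
  em <- simulate_effect_model(map, 1, 0, 0.3, seed = 71)
  sim <- simulate_experiment(fx$geno, fx$asg, em, fx$des, seed = 72)
  beneficial_allele <- if (em$s[1, "brain"] > 0) 1L else 0L
  carriers <- fx$geno[fx$asg$segregant_id, em$loci$marker_id] == beneficial_allele
  meta <- sim$meta
  for (org in fx$des$organs) {
    f <- function(day) {
      rows <- meta$type == "organ" & meta$organ == org & meta$day == day
      mean(rowSums(sim$truth$expected_freq[rows, carriers, drop = FALSE]))
    }
    expect_gt(f(5), f(1))
  }
})

test_that("low-CFU organs lose replicate information relative to high-CFU organs", {
  fx <- small_sim()
  pm <- compute_persistence(fx$sim$counts, fx$sim$meta)
  filt <- significance_filter(pm, fx$asg)
  organ <- fx$sim$meta$organ[match(filt$sample_id, fx$sim$meta$sample_id)]
  h2_brain <- mean(filt$H2[organ == "brain"], na.rm = TRUE)
  h2_liver <- mean(filt$H2[organ == "liver"], na.rm = TRUE)
  expect_lt(h2_brain, h2_liver)
})

test_that("observed-call noise model matches its closed form", {
  map <- make_marker_map(2, 400, 750000, seed = 81)
  geno <- simulate_cross(map, 60, 2, seed = 82)
  obs <- simulate_observed_calls(geno, mean_coverage = 2,
                                 per_read_error = 0.05, seed = 83)
  calls <- threshold_calls(obs)
  # closed form: P(missing or wrong majority) under depth ~ Pois(2),
  # per-read error 0.05; fraction == 0.5 counts as missing
  p_bad <- 0
  for (d in 0:30) {
    pd <- dpois(d, 2)
    if (d == 0) p_bad <- p_bad + pd
    else {
      k <- 0:d
      pk <- dbinom(k, d, 0.05)  # erroneous reads
      p_bad <- p_bad + pd * sum(pk[k / d >= 0.5])
    }
  }
  bad <- mean(is.na(calls) | calls != geno)
  expect_lt(abs(bad - p_bad), 0.01)
})

test_that("observed calls converge to truth at high coverage and no error", {
  map <- tiny_map()
  geno <- simulate_cross(map, 10, 2, seed = 91)
  obs <- simulate_observed_calls(geno, mean_coverage = 50,
                                 per_read_error = 0, seed = 92)
  nonmiss <- !is.na(obs)
  expect_true(all(obs[nonmiss] == geno[nonmiss]))
  expect_error(simulate_observed_calls(geno, 0, 0.05), "coverage")
  expect_error(simulate_observed_calls(geno, 2, 0.5), "error")
})

test_that("experiment design validates and enumerates the full factorial", {
  des <- make_experiment_design()
  meta <- simulate_experiment(simulate_cross(tiny_map(), 5, 1, seed = 1),
                              make_barcode_assignment(sprintf("seg%04d", 1:5),
                                                      0, seed = 2),
                              simulate_effect_model(tiny_map(), 0, 0, 0.1),
                              des, seed = 3)$meta
  expect_equal(sum(meta$type == "organ"), 5 * 2 * 2 * 3 * 3)
  expect_equal(sum(meta$type == "T0"), 1)
  expect_error(make_experiment_design(depth = 0), "depth")
})
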