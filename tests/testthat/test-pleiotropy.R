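# Locus classification, allele doses, combinatorial and time-course tests.

test_that("quadrant classification assigns classes and beneficial alleles", {
  a <- classify_locus(0.3, 0.1)
  expect_equal(a$class, "general")
  expect_equal(a$brain_beneficial, "3S")
  expect_equal(a$nonbrain_beneficial, "3S")
  b <- classify_locus(0.3, -0.1)
  expect_equal(b$class, "antagonistic")
  expect_equal(b$brain_beneficial, "3S")
  expect_equal(b$nonbrain_beneficial, "BY")
  c_ <- classify_locus(-0.2, -0.2)
  expect_equal(c_$class, "general")
  expect_equal(c_$brain_beneficial, "BY")
})

test_that("classification is antisymmetric and flags degenerate zeros", {
  set.seed(301)
  for (rep in 1:20) {
    d <- rnorm(2, 0, 0.3)
    base <- classify_locus(d[1], d[2])
    expect_equal(classify_locus(-d[1], -d[2])$class, base$class)
    flipped <- classify_locus(-d[1], d[2])$class
    expect_equal(flipped, setdiff(c("general", "antagonistic"), base$class))
  }
  z <- classify_locus(0, 0.4)
  expect_true(z$degenerate)
  expect_equal(z$class, "general")
  expect_error(classify_locus(0, 0), "zero")
})

test_that("allele doses count beneficial alleles and apply thresholds", {
  geno <- rbind(all3s = rep(1L, 5), allby = rep(0L, 5),
                mixed = c(1L, 0L, 1L, 0L, 1L))
  colnames(geno) <- sprintf("m%d", 1:5)
  classified <- data.frame(
    locus_id = sprintf("L%d", 1:5), marker_id = sprintf("m%d", 1:5),
    class = c("general", "general", "general", "antagonistic", "antagonistic"),
    brain_beneficial = c("3S", "3S", "BY", "3S", "BY"),
    nonbrain_beneficial = c("3S", "3S", "BY", "BY", "3S"),
    stringsAsFactors = FALSE)
  dose <- allele_dose(geno, classified, general_enriched = 2,
                      general_depleted = 1, brain_enriched = 2,
                      brain_depleted = 1)
  expect_equal(dose$n_general_beneficial, c(2L, 1L, 1L))
  expect_equal(dose$n_brain_favoring, c(1L, 1L, 0L))
  expect_equal(dose$general_class, c("enriched", "neither", "neither"))
  none <- allele_dose(geno, classified[0, ])
  expect_true(all(none$n_general_beneficial == 0))
  expect_true(all(none$general_class == "neither"))
})

test_that("neutral crosses spread general-allele doses binomially", {
  map <- make_marker_map(10, 3, 500000, seed = 311)
  geno <- simulate_cross(map, 822, 2, seed = 312)
  # one locus per chromosome -> independent loci
  markers <- map$marker_id[unique(map$chrom) * 3 - 1]
  classified <- data.frame(locus_id = markers, marker_id = markers,
                           class = "general", brain_beneficial = "3S",
                           nonbrain_beneficial = "3S",
                           stringsAsFactors = FALSE)
  dose <- allele_dose(geno, classified)
  counts <- dose$n_general_beneficial
  expect_lt(abs(mean(counts) - 5), 3 * sqrt(2.5 / 822) * 3)
  expect_lt(abs(var(counts) - 2.5), 0.6)
  expect_gt(suppressWarnings(chisq.test(
    table(factor(counts, levels = 0:10)),
    p = dbinom(0:10, 10, 0.5))$p.value), 1e-4)
})

test_that("threshold auto-tuning respects the coverage cap", {
  set.seed(321)
  counts <- rbinom(500, 10, 0.5)
  thr <- tune_enrichment_thresholds(counts, max_fraction = 0.25)
  expect_lte(mean(counts >= thr$enriched), 0.25)
  expect_lte(mean(counts < thr$depleted), 0.25)
  # most permissive: one step looser violates the cap
  expect_gt(mean(counts >= thr$enriched - 1), 0.25)
  expect_gt(mean(counts < thr$depleted + 1), 0.25)
})

test_that("dose regression matches lm and its null expectation", {
  set.seed(331)
  cnt <- rbinom(100, 10, 0.5)
  y <- 0.2 * cnt + rnorm(100, 0, 0.1)
  r <- dose_regression(y, cnt)
  fit <- summary(lm(y ~ cnt))
  expect_equal(r$r_squared, fit$r.squared)
  expect_equal(r$P, fit$coefficients[2, 4])
  exact <- suppressWarnings(dose_regression(2 * cnt + 3, cnt))
  expect_equal(exact$r_squared, 1)
  expect_error(dose_regression(y, rep(4, 100)), "constant")
  # E[R2] under the null is ~ 1/(n-1)
  null_r2 <- replicate(300, dose_regression(rnorm(100), cnt)$r_squared)
  expect_lt(abs(mean(null_r2) - 1 / 99), 0.005)
})

test_that("time slopes are OLS slopes on days", {
  expect_equal(time_slope(c(0, 0.8), c(1, 5)), 0.2)
  expect_equal(time_slope(rep(0.3, 6), rep(c(1, 2, 5), 2)), 0)
  v <- c(0.1, 0.5, 0.2, 0.9, 0.4, 1.2)
  d <- c(1, 2, 1, 5, 2, 5)
  expect_equal(time_slope(v, d), unname(coef(lm(v ~ d))[2]))
  expect_error(time_slope(c(1, 2), c(3, 3)), "distinct")
})

test_that("the 2x2 chi-square equals its closed-form oracle", {
  even <- enrichment_contingency(rep(c(TRUE, FALSE), each = 50),
                                 rep(c(TRUE, FALSE), 50))
  expect_equal(even$chisq, 0)
  expect_equal(even$P, 1)
  set.seed(341)
  for (rep in 1:20) {
    e <- runif(200) < 0.4
    s <- runif(200) < (0.3 + 0.4 * e)
    res <- tryCatch(enrichment_contingency(e, s), error = function(err) NULL)
    if (is.null(res)) next
    tab <- res$table
    a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
    n <- a + b + c_ + d
    oracle <- n * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    expect_equal(res$chisq, unname(oracle), tolerance = 1e-12)
  }
  expect_error(enrichment_contingency(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)),
               "margin")
})

test_that("the worked 2x2 table gives its hand-computed statistic", {
  e <- rep(c(TRUE, TRUE, FALSE, FALSE), c(30, 10, 10, 30))
  s <- rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 10, 30))
  res <- enrichment_contingency(e, s)
  expect_equal(res$chisq, 80 * (30 * 30 - 10 * 10)^2 / (40 * 40 * 40 * 40))
})

test_that("time-course summaries normalize day 5 to day 1 per focal group", {
  fx <- small_sim()
  pm <- compute_persistence(fx$sim$counts, fx$sim$meta)
  meta <- fx$sim$meta
  brain <- meta$sample_id[meta$type == "organ" & meta$organ == "brain"]
  fb <- fx$asg[fx$asg$replicate_index == 1, ]
  fb <- fb[match(rownames(fx$geno), fb$segregant_id), ]
  dose <- data.frame(segregant_id = fb$segregant_id,
                     general_class = rep(c("enriched", "neither"),
                                         length.out = nrow(fb)),
                     brain_class = rep(c("enriched", "neither", "depleted"),
                                       length.out = nrow(fb)),
                     stringsAsFactors = FALSE)
  tc <- timecourse_summary(pm, brain, dose, fb$barcode, n_boot = 50, seed = 2)
  expect_true(all(c("mean_change", "se", "n") %in% names(tc)))
  expect_equal(sum(tc$n), nrow(fb))
  boots <- attr(tc, "boot")
  expect_equal(length(boots), nrow(tc))
  # singleton-group bootstrap replicates are constant
  expect_error(timecourse_summary(pm, brain[1], dose, fb$barcode),
               "day")
})
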