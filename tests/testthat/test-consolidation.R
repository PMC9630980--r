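# Interval consolidation and allele effect sizes.

det <- function(chrom, start, end, scan = "s", P = 0.001, peak = NA) {
  data.frame(scan_id = scan, chrom = chrom, ci_start_pos = start,
             ci_end_pos = end, P = P,
             peak_marker = ifelse(is.na(peak), sprintf("m_%d_%d", chrom, start),
                                  peak),
             peak_pos = (start + end) %/% 2, stringsAsFactors = FALSE)
}

test_that("overlapping intervals merge with union and intersection bounds", {
  cons <- consolidate(rbind(det(1, 10, 20), det(1, 15, 30)))
  expect_equal(nrow(cons$loci), 1)
  expect_equal(cons$loci$union_start, 10)
  expect_equal(cons$loci$union_end, 30)
  expect_equal(cons$loci$int_start, 15)
  expect_equal(cons$loci$int_end, 20)
  expect_false(cons$loci$intersection_empty)
  expect_equal(cons$loci$n_detections, 2)
})

test_that("disjoint intervals stay separate and shared endpoints merge", {
  cons <- consolidate(rbind(det(1, 10, 20), det(1, 30, 40)))
  expect_equal(nrow(cons$loci), 2)
  touch <- consolidate(rbind(det(1, 10, 20), det(1, 20, 40)))
  expect_equal(nrow(touch$loci), 1)
})

test_that("chains merge transitively and empty intersections are flagged", {
  cons <- consolidate(rbind(det(1, 10, 20), det(1, 18, 28), det(1, 26, 36)))
  expect_equal(nrow(cons$loci), 1)
  expect_equal(cons$loci$union_start, 10)
  expect_equal(cons$loci$union_end, 36)
  expect_true(cons$loci$intersection_empty)
})

test_that("consolidation matches a connected-components oracle on random intervals", {
  set.seed(201)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    start <- sample(1:100, n, replace = TRUE)
    end <- start + sample(1:30, n, replace = TRUE)
    cons <- consolidate(det(1, start, end))
    comp <- brute_force_components(start, end)
    expect_equal(nrow(cons$loci), length(unique(comp)))
    # membership matches: same oracle component iff same locus_id
    ids <- cons$members$locus_id
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      expect_equal(ids[i] == ids[j], comp[i] == comp[j])
  }
})

test_that("consolidation is idempotent, order-invariant, and conserves detections", {
  set.seed(202)
  d <- det(rep(1:3, each = 4), sample(1:200, 12, TRUE), 0)
  d$ci_end_pos <- d$ci_start_pos + sample(5:50, 12, TRUE)
  a <- consolidate(d)
  b <- consolidate(d[sample(nrow(d)), ])
  ord <- function(x) x$loci[order(x$loci$locus_id),
                            c("chrom", "union_start", "union_end",
                              "int_start", "int_end", "n_detections")]
  expect_equal(ord(a), ord(b), ignore_attr = TRUE)
  expect_equal(sum(a$loci$n_detections), nrow(d))
})

test_that("the effect marker is the smallest-P member detection", {
  d <- rbind(det(1, 10, 30, P = 0.01, peak = "weak"),
             det(1, 20, 40, P = 1e-6, peak = "strong"))
  cons <- consolidate(d)
  expect_equal(cons$loci$effect_marker, "strong")
})

test_that("locus effects are class mean differences with sign semantics", {
  eff <- locus_effect(c(1, 2, 0), c(1L, 1L, 0L))
  expect_equal(eff$delta, 1.5)
  expect_equal(locus_effect(c(3, 3, 3, 3), c(0L, 1L, 0L, 1L))$delta, 0)
  expect_error(locus_effect(c(1, 2), c(1L, 1L)), "non-empty")
  # antisymmetry under allele recoding
  y <- rnorm(30); a <- rbinom(30, 1, 0.5)
  expect_equal(locus_effect(y, a)$delta, -locus_effect(y, 1L - a)$delta)
})

test_that("bootstrap intervals collapse for zero-variance classes and converge", {
  ci <- bootstrap_ci(c(rep(2, 10), rep(1, 8)), c(rep(1L, 10), rep(0L, 8)),
                     n_boot = 200, seed = 1)
  expect_equal(unname(ci), c(1, 1), ignore_attr = TRUE)
  y <- c(rnorm(100), rnorm(100) + 1)
  a <- rep(c(0L, 1L), each = 100)
  ci_small <- bootstrap_ci(y, a, n_boot = 100, seed = 5)
  ci_big <- bootstrap_ci(y, a, n_boot = 5000, seed = 5)
  exact <- locus_effect(y, a)$delta
  expect_lt(abs(mean(ci_big) - exact), abs(mean(ci_small) - exact) + 0.05)
  expect_error(bootstrap_ci(y, a, n_boot = 10), "100")
})

test_that("bootstrap intervals cover the true difference at the nominal rate", {
  set.seed(203)
  cover <- replicate(200, {
    y <- c(rnorm(60), rnorm(60) + 1)
    a <- rep(c(0L, 1L), each = 60)
    ci <- bootstrap_ci(y, a, n_boot = 200)
    ci[["low"]] <= 1 && 1 <= ci[["high"]]
  })
  expect_gt(mean(cover), 0.88)
  expect_lt(mean(cover), 1)
})

test_that("the effect table runs over loci and contexts with planted signs", {
  fx <- small_sim()
  pm <- compute_persistence(fx$sim$counts, fx$sim$meta)
  meta <- fx$sim$meta
  organ <- meta$sample_id[meta$type == "organ"]
  m <- meta[match(organ, meta$sample_id), ]
  agg <- aggregate_persistence(pm, organ[m$organ == "brain"],
                               organ[m$organ %in% c("kidney", "liver", "spleen")])
  fb <- fx$asg[fx$asg$replicate_index == 1, ]
  fb <- fb[match(rownames(fx$geno), fb$segregant_id), ]
  agg <- agg[match(fb$barcode, agg$barcode), ]
  d <- det(fx$em$loci$chrom, fx$em$loci$pos - 10, fx$em$loci$pos + 10,
           peak = fx$em$loci$marker_id)
  d$peak_pos <- fx$em$loci$pos
  cons <- consolidate(d)
  tab <- locus_effect_table(cons, fx$geno,
                            list(brain = agg$brain, nonbrain = agg$nonbrain),
                            n_boot = 200, seed = 3)
  expect_equal(nrow(tab), 2 * nrow(cons$loci))
  expect_true(all(tab$ci_low <= tab$delta & tab$delta <= tab$ci_high))
  # planted signs are recovered in the nonbrain context (well-measured organs)
  for (i in seq_len(nrow(fx$em$loci))) {
    id <- cons$members$locus_id[match(fx$em$loci$marker_id[i], d$peak_marker)]
    delta <- tab$delta[tab$locus_id == id & tab$context == "nonbrain"]
    expect_equal(sign(delta), sign(fx$em$s[i, "kidney"]))
  }
})
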