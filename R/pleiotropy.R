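# Classification of loci as general versus antagonistically pleiotropic,
# allele-dose summaries, and combinatorial/time-course analyses.

#' Classify a locus from its brain and nonbrain effects
#'
#' Quadrant classification of the (brain delta, nonbrain delta) plane:
#' same-sign effects are general (the same allele is beneficial everywhere),
#' opposite-sign effects are antagonistically pleiotropic. The beneficial
#' allele in a context is 3S when the delta is positive, BY when negative.
#' An exactly zero delta is a measure-zero boundary: the locus is classified
#' by the other context's sign and flagged degenerate.
#'
#' @param brain_delta,nonbrain_delta 3S-minus-BY effects in the two contexts.
#' @return list: `class` ("general"/"antagonistic"), `brain_beneficial`,
#'   `nonbrain_beneficial` ("3S"/"BY"), `degenerate`.
#' @export
classify_locus <- function(brain_delta, nonbrain_delta) {
  if (is.na(brain_delta) || is.na(nonbrain_delta))
    stop("both deltas must be finite")
  degenerate <- brain_delta == 0 || nonbrain_delta == 0
  sb <- sign(brain_delta); sn <- sign(nonbrain_delta)
  if (sb == 0 && sn == 0)
    stop("both deltas are exactly zero; locus has no classifiable effect")
  if (sb == 0) sb <- sn
  if (sn == 0) sn <- sb
  list(class = if (sb == sn) "general" else "antagonistic",
       brain_beneficial = if (sb > 0) "3S" else "BY",
       nonbrain_beneficial = if (sn > 0) "3S" else "BY",
       degenerate = degenerate)
}

#' Classify a table of loci
#'
#' @param effects data.frame with columns `locus_id`, `brain_delta`,
#'   `nonbrain_delta` and optionally `marker_id`.
#' @return the input with `class`, `brain_beneficial`, `nonbrain_beneficial`,
#'   `degenerate` columns appended.
#' @export
classify_loci <- function(effects) {
  stopifnot(all(c("locus_id", "brain_delta", "nonbrain_delta") %in% names(effects)))
  cls <- lapply(seq_len(nrow(effects)), function(i)
    classify_locus(effects$brain_delta[i], effects$nonbrain_delta[i]))
  effects$class <- vapply(cls, `[[`, "", "class")
  effects$brain_beneficial <- vapply(cls, `[[`, "", "brain_beneficial")
  effects$nonbrain_beneficial <- vapply(cls, `[[`, "", "nonbrain_beneficial")
  effects$degenerate <- vapply(cls, `[[`, TRUE, "degenerate")
  effects
}

#' Per-segregant beneficial allele doses and enrichment classes
#'
#' Counts, for each segregant, the generally beneficial alleles it carries
#' across general loci and the brain-favoring alleles it carries across
#' antagonistic loci, then applies enrichment thresholds. Defaults follow
#' the study's cutoffs: enriched for general alleles at >= 7 of 10, depleted
#' below 3; enriched for brain alleles at >= 6 of 8, depleted below 3.
#'
#' @param genotypes segregants x markers 0/1 matrix.
#' @param classified data.frame from [classify_loci()] with a `marker_id`
#'   column locating each locus.
#' @param general_enriched,general_depleted thresholds on the general count
#'   (enriched: count >= general_enriched; depleted: count < general_depleted).
#' @param brain_enriched,brain_depleted thresholds on the brain-favoring
#'   count at antagonistic loci.
#' @return data.frame per segregant: counts and enrichment classes
#'   (`enriched` / `depleted` / `neither`).
#' @export
allele_dose <- function(genotypes, classified, general_enriched = 7,
                        general_depleted = 3, brain_enriched = 6,
                        brain_depleted = 3) {
  stopifnot("marker_id" %in% names(classified))
  n <- nrow(genotypes)
  count_beneficial <- function(rows, beneficial_col) {
    if (!length(rows)) return(rep(0L, n))
    cnt <- rep(0L, n)
    for (i in rows) {
      a <- genotypes[, classified$marker_id[i]]
      hit <- if (classified[[beneficial_col]][i] == "3S") a == 1L else a == 0L
      cnt <- cnt + as.integer(hit)
    }
    cnt
  }
  gen_rows <- which(classified$class == "general")
  ant_rows <- which(classified$class == "antagonistic")
  # generally beneficial allele is the same in both contexts; use brain side
  n_general <- count_beneficial(gen_rows, "brain_beneficial")
  n_brain <- count_beneficial(ant_rows, "brain_beneficial")
  cls <- function(cnt, enr, dep, n_loci) {
    if (n_loci == 0L) return(rep("neither", length(cnt)))
    ifelse(cnt >= enr, "enriched", ifelse(cnt < dep, "depleted", "neither"))
  }
  data.frame(segregant_id = rownames(genotypes),
             n_general_beneficial = n_general,
             n_brain_favoring = n_brain,
             general_class = cls(n_general, general_enriched,
                                 general_depleted, length(gen_rows)),
             brain_class = cls(n_brain, brain_enriched, brain_depleted,
                               length(ant_rows)),
             stringsAsFactors = FALSE)
}

#' Auto-tune enrichment thresholds to a coverage cap
#'
#' Chooses the most permissive symmetric thresholds such that no more than
#' `max_fraction` of segregants fall in the enriched class and no more than
#' `max_fraction` in the depleted class, mirroring the study's stated 25%
#' cap.
#'
#' @param counts integer vector of per-segregant beneficial-allele counts.
#' @param max_fraction coverage cap per class (default 0.25).
#' @return list with `enriched` and `depleted` cutoffs usable in
#'   [allele_dose()].
#' @export
tune_enrichment_thresholds <- function(counts, max_fraction = 0.25) {
  n <- length(counts)
  enr <- min(counts)
  while (mean(counts >= enr) > max_fraction) enr <- enr + 1L
  dep <- max(counts) + 1L
  while (mean(counts < dep) > max_fraction) dep <- dep - 1L
  list(enriched = enr, depleted = dep)
}

#' Regression of aggregate persistence on allele dose
#'
#' Simple OLS `phenotype ~ count`; returns the slope, its P-value (1-df
#' F-test), and the model R-squared.
#'
#' @param phenotype per-segregant aggregate persistence.
#' @param count per-segregant beneficial-allele count.
#' @return list with `slope`, `r_squared`, `P`, `n`.
#' @export
dose_regression <- function(phenotype, count) {
  ok <- !is.na(phenotype) & !is.na(count)
  if (sum(ok) < 3) stop("need at least 3 segregants")
  if (stats::var(count[ok]) == 0) stop("allele-dose count is constant")
  fit <- stats::lm(phenotype[ok] ~ count[ok])
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]), r_squared = sm$r.squared,
       P = unname(sm$coefficients[2, 4]), n = sum(ok))
}

#' Per-segregant persistence-over-time slope
#'
#' OLS slope of a segregant's persistence values on days post-injection.
#'
#' @param values persistence of one segregant across samples.
#' @param days matching days post-injection.
#' @return slope (change in persistence per day).
#' @export
time_slope <- function(values, days) {
  ok <- !is.na(values) & !is.na(days)
  if (length(unique(days[ok])) < 2)
    stop("need samples from at least 2 distinct days")
  unname(stats::coef(stats::lm(values[ok] ~ days[ok]))[2])
}

#' 2x2 contingency test of enrichment versus increasing persistence
#'
#' Pearson chi-squared test (1 df, no continuity correction by default) of
#' the table {enriched for both general and context-appropriate pleiotropic
#' alleles vs not} x {positive time slope vs not}.
#'
#' @param enriched_both logical per segregant.
#' @param positive_slope logical per segregant.
#' @param correct apply Yates continuity correction.
#' @return list with `chisq`, `P`, `table`.
#' @export
enrichment_contingency <- function(enriched_both, positive_slope,
                                   correct = FALSE) {
  ok <- !is.na(enriched_both) & !is.na(positive_slope)
  tab <- table(factor(enriched_both[ok], levels = c(TRUE, FALSE)),
               factor(positive_slope[ok], levels = c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has a zero margin")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chisq = unname(ht$statistic), P = unname(ht$p.value), table = tab)
}

#' Time-course summary of focal enrichment groups
#'
#' For each of the four focal groups (general enrichment class x brain
#' enrichment class, enriched vs not-enriched), computes each segregant's
#' mean day-1 and day-5 persistence in the requested samples, normalizes the
#' day-5 mean by subtracting the day-1 mean, and summarizes the group with
#' its mean normalized change, standard error, and bootstrap replicate
#' means.
#'
#' @param pm object from [compute_persistence()].
#' @param samples sample ids to use (e.g. significant brain samples).
#' @param dose data.frame from [allele_dose()] (rows align with the barcode
#'   columns used, via `barcodes`).
#' @param barcodes barcode column of `pm` for each row of `dose` (one
#'   barcode per segregant).
#' @param n_boot bootstrap replicates of the group mean.
#' @param seed optional RNG seed.
#' @return data.frame per focal group: `general_enriched`, `brain_enriched`,
#'   `n`, `mean_change`, `se`, plus a `boot` attribute (list of replicate
#'   mean vectors). Empty groups are omitted with a warning.
#' @export
timecourse_summary <- function(pm, samples, dose, barcodes, n_boot = 1000,
                               seed = NULL) {
  stopifnot(inherits(pm, "persistence_matrix"))
  meta <- pm$meta[match(samples, pm$meta$sample_id), ]
  d1 <- samples[meta$day == 1]
  d5 <- samples[meta$day == 5]
  if (!length(d1) || !length(d5))
    stop("need samples at both day 1 and day 5")
  m1 <- colMeans(pm$persistence[d1, barcodes, drop = FALSE], na.rm = TRUE)
  m5 <- colMeans(pm$persistence[d5, barcodes, drop = FALSE], na.rm = TRUE)
  change <- m5 - m1
  groups <- expand.grid(general_enriched = c(TRUE, FALSE),
                        brain_enriched = c(TRUE, FALSE))
  out <- list(); boots <- list()
  for (gi in seq_len(nrow(groups))) {
    in_g <- (dose$general_class == "enriched") == groups$general_enriched[gi] &
      (dose$brain_class == "enriched") == groups$brain_enriched[gi]
    vals <- change[in_g & !is.na(change)]
    if (!length(vals)) {
      warning("empty focal group omitted")
      next
    }
    bm <- with_seed(derive_seed(seed, gi) %||% NULL, vapply(
      seq_len(n_boot), function(b) mean(sample(vals, replace = TRUE)),
      numeric(1)))
    key <- sprintf("gen%s_brain%s", groups$general_enriched[gi],
                   groups$brain_enriched[gi])
    boots[[key]] <- bm
    out[[key]] <- data.frame(
      general_enriched = groups$general_enriched[gi],
      brain_enriched = groups$brain_enriched[gi], n = length(vals),
      mean_change = mean(vals),
      se = stats::sd(vals) / sqrt(length(vals)), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "boot") <- boots
  res
}
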