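# Broad-sense heritability as a sum-of-squares ratio from replicated
# observations, and ANOVA-based filtering of samples with significant
# genetic variation.

#' Broad-sense heritability from replicated observations
#'
#' One-way decomposition with genotype identity as the grouping factor:
#' `H2 = SS_genotype / SS_total`, where
#' `SS_genotype = sum_g n_g (mean_g - mean)^2` and `SS_total` is the total
#' sum of squares. The F-test P-value of the genotype term is attached. Note
#' this ratio is the between-group share of the observed sum of squares; with
#' r replicates per genotype its expectation is
#' `(G-1)(r*vg + ve) / ((N-1)(vg + ve))`, which exceeds the underlying
#' genetic-variance fraction for small r.
#'
#' @param values numeric observations.
#' @param genotype grouping vector (replicated genotype identity).
#' @return object of class `h2_estimate`: list with `H2`, `SS_genotype`,
#'   `SS_total`, `P`, `n_observations`, `n_genotypes`.
#' @export
h2_from_replicates <- function(values, genotype) {
  ok <- !is.na(values) & !is.na(genotype)
  values <- values[ok]
  genotype <- factor(genotype[ok])
  genotype <- droplevels(genotype)
  G <- nlevels(genotype); N <- length(values)
  if (G < 2) stop("need at least 2 genotypes")
  if (N <= G) stop("need replication: more observations than genotypes")
  grand <- mean(values)
  gm <- tapply(values, genotype, mean)
  ng <- as.numeric(table(genotype))
  ss_g <- sum(ng * (gm - grand)^2)
  ss_tot <- sum((values - grand)^2)
  if (ss_tot == 0)
    return(structure(list(H2 = NA_real_, SS_genotype = 0, SS_total = 0,
                          P = NA_real_, n_observations = N, n_genotypes = G,
                          degenerate = TRUE), class = "h2_estimate"))
  h2 <- ss_g / ss_tot
  f <- (ss_g / (G - 1)) / ((ss_tot - ss_g) / (N - G))
  p <- stats::pf(f, G - 1, N - G, lower.tail = FALSE)
  structure(list(H2 = h2, SS_genotype = ss_g, SS_total = ss_tot, P = p,
                 n_observations = N, n_genotypes = G, degenerate = FALSE),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("H2 = %.3f (%d genotypes, %d observations), F-test P = %.3g\n",
              x$H2, x$n_genotypes, x$n_observations, x$P))
  invisible(x)
}

#' Filter samples by significance of among-genotype variation
#'
#' For each sample, performs a one-way ANOVA of the replicated-barcode
#' persistence values on genotype identity and keeps samples whose P-value
#' passes a Bonferroni-corrected threshold `alpha / n_samples_tested`.
#'
#' @param pm object from [compute_persistence()], or a samples x barcodes
#'   persistence matrix.
#' @param assignment barcode assignment data.frame (`barcode`,
#'   `segregant_id`, `replicate_index`); only segregants with >= 2 barcodes
#'   enter the ANOVA.
#' @param alpha family-wise significance level (default 0.05).
#' @param n_samples_tested Bonferroni denominator; defaults to the number of
#'   samples tested here.
#' @param exclude sample ids to drop a priori (e.g. known distorted
#'   libraries).
#' @return data.frame with one row per sample: `sample_id`, `H2`, `P`,
#'   `threshold`, `keep`, `reason`.
#' @export
significance_filter <- function(pm, assignment, alpha = 0.05,
                                n_samples_tested = NULL, exclude = character()) {
  mat <- if (inherits(pm, "persistence_matrix")) pm$persistence else pm
  reps <- assignment[assignment$segregant_id %in%
                       names(which(table(assignment$segregant_id) >= 2)), ]
  if (!nrow(reps)) stop("no replicated segregants in the assignment")
  samples <- setdiff(rownames(mat), exclude)
  n_tested <- n_samples_tested %||% length(samples)
  thr <- alpha / n_tested
  res <- lapply(samples, function(s) {
    vals <- mat[s, reps$barcode]
    ok <- !is.na(vals)
    geno <- reps$segregant_id[ok]
    if (length(unique(geno)) < 2 || sum(table(geno) >= 2) == 0)
      return(data.frame(sample_id = s, H2 = NA_real_, P = NA_real_,
                        threshold = thr, keep = FALSE,
                        reason = "no replicated genotypes",
                        stringsAsFactors = FALSE))
    est <- h2_from_replicates(vals[ok], geno)
    keep <- !is.na(est$P) && est$P <= thr
    data.frame(sample_id = s, H2 = est$H2, P = est$P, threshold = thr,
               keep = keep,
               reason = if (keep) "" else "not significant",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (length(exclude))
    out <- rbind(out, data.frame(sample_id = exclude, H2 = NA_real_,
                                 P = NA_real_, threshold = thr, keep = FALSE,
                                 reason = "excluded a priori",
                                 stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Drop organs with too few significant samples
#'
#' Organs represented by fewer than `min_replicates` significant samples
#' (e.g. a lone significant gonad sample) cannot support within-organ
#' replication and are removed from the kept set.
#'
#' @param filter_table output of [significance_filter()].
#' @param meta sample metadata with `sample_id` and `organ`.
#' @param min_replicates minimum significant samples per organ (default 2).
#' @return the filter table with under-replicated organs flipped to
#'   `keep = FALSE` (reason "organ lacks replicates").
#' @export
drop_unreplicated_organs <- function(filter_table, meta, min_replicates = 2) {
  organ <- meta$organ[match(filter_table$sample_id, meta$sample_id)]
  kept_by_organ <- table(organ[filter_table$keep])
  weak <- names(kept_by_organ)[kept_by_organ < min_replicates]
  flip <- filter_table$keep & organ %in% weak
  filter_table$keep[flip] <- FALSE
  filter_table$reason[flip] <- "organ lacks replicates"
  filter_table
}

#' Broad-sense heritability across samples
#'
#' Same sum-of-squares decomposition as [h2_from_replicates()], with
#' segregant identity as the grouping factor and samples as the replicate
#' observations. Use one barcode per segregant (the first replicate) so that
#' within-pool barcode replication does not enter twice.
#'
#' @param mat samples x segregants (or barcodes) persistence matrix.
#' @return object of class `h2_estimate`.
#' @export
across_sample_h2 <- function(mat) {
  if (nrow(mat) < 2) stop("need at least 2 samples")
  values <- as.vector(mat)
  genotype <- rep(colnames(mat) %||% as.character(seq_len(ncol(mat))),
                  each = nrow(mat))
  h2_from_replicates(values, genotype)
}
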