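# Cross-sample locus consolidation by confidence-interval overlap, and
# per-context allele effect sizes with bootstrap intervals.

#' Consolidate detections into distinct loci
#'
#' Builds, per chromosome, the overlap graph on confidence intervals (closed
#' intervals; a shared endpoint counts as overlap) and merges its connected
#' components into consolidated loci, so overlap is transitive along chains.
#' Each locus records the union (min start, max end) and intersection
#' (max start, min end) of its member intervals; a chain whose intersection
#' is empty keeps the crossed bounds and is flagged, mirroring loci that
#' fractionate into linked sub-intervals.
#'
#' @param detections data.frame with columns `chrom`, `ci_start_pos`,
#'   `ci_end_pos` and (optionally) `scan_id`, `P`, `peak_marker`, `peak_pos`
#'   — e.g. row-bound `detections` tables from [forward_scan()] objects.
#' @return list of class `consolidated_loci` with `loci` (one row per locus:
#'   locus_id, chrom, union/intersection bounds, n_detections, effect marker
#'   chosen as the smallest-P member peak) and `members` (the input with a
#'   `locus_id` column).
#' @export
consolidate <- function(detections) {
  req <- c("chrom", "ci_start_pos", "ci_end_pos")
  if (!all(req %in% names(detections)))
    stop("detections must have columns: ", paste(req, collapse = ", "))
  det <- detections
  det$locus_id <- NA_character_
  loci <- list()
  for (chr in sort(unique(det$chrom))) {
    rows <- which(det$chrom == chr)
    ord <- rows[order(det$ci_start_pos[rows], det$ci_end_pos[rows])]
    comp <- integer(length(ord))
    comp[1] <- 1L
    reach <- det$ci_end_pos[ord[1]]
    for (k in seq_along(ord)[-1]) {
      # sorted sweep: a new component starts when the next interval begins
      # strictly beyond everything reachable so far (closed-interval overlap)
      if (det$ci_start_pos[ord[k]] > reach) comp[k] <- comp[k - 1] + 1L
      else comp[k] <- comp[k - 1]
      reach <- max(reach, det$ci_end_pos[ord[k]])
    }
    for (cc in unique(comp)) {
      members <- ord[comp == cc]
      id <- sprintf("chr%02d_locus%02d", chr, cc)
      det$locus_id[members] <- id
      int_start <- max(det$ci_start_pos[members])
      int_end <- min(det$ci_end_pos[members])
      best <- if ("P" %in% names(det))
        members[which.min(det$P[members])] else members[1]
      loci[[id]] <- data.frame(
        locus_id = id, chrom = chr,
        union_start = min(det$ci_start_pos[members]),
        union_end = max(det$ci_end_pos[members]),
        int_start = int_start, int_end = int_end,
        intersection_empty = int_start > int_end,
        n_detections = length(members),
        effect_marker = if ("peak_marker" %in% names(det))
          det$peak_marker[best] else NA_character_,
        effect_marker_pos = if ("peak_pos" %in% names(det))
          det$peak_pos[best] else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  loci <- do.call(rbind, c(loci, list(make.row.names = FALSE)))
  if (is.null(loci))
    loci <- data.frame(locus_id = character(), chrom = integer(),
                       union_start = integer(), union_end = integer(),
                       int_start = integer(), int_end = integer(),
                       intersection_empty = logical(),
                       n_detections = integer(),
                       effect_marker = character(),
                       effect_marker_pos = integer(), stringsAsFactors = FALSE)
  structure(list(loci = loci, members = det), class = "consolidated_loci")
}

#' @export
print.consolidated_loci <- function(x, ...) {
  cat(sprintf("%d consolidated loci from %d detections\n",
              nrow(x$loci), nrow(x$members)))
  print(x$loci)
  invisible(x)
}

#' Allele effect of a locus in a context
#'
#' Splits the phenotype by genotype at the locus marker and returns
#' mean(3S) - mean(BY). A positive delta means the 3S (allele 1) carriers
#' persist better in that context.
#'
#' @param phenotype numeric vector over segregants (NA dropped).
#' @param allele 0/1 genotype codes at the locus marker, same order.
#' @return list with `delta`, `mean_3s`, `mean_by`, `n_3s`, `n_by`.
#' @export
locus_effect <- function(phenotype, allele) {
  ok <- !is.na(phenotype) & !is.na(allele)
  y <- phenotype[ok]; a <- allele[ok]
  if (!sum(a == 1) || !sum(a == 0))
    stop("both allele classes must be non-empty")
  m1 <- mean(y[a == 1]); m0 <- mean(y[a == 0])
  list(delta = m1 - m0, mean_3s = m1, mean_by = m0,
       n_3s = sum(a == 1), n_by = sum(a == 0))
}

#' Bootstrap confidence interval for an allele effect
#'
#' Resamples each allele class with replacement `n_boot` times, recomputes
#' the 3S-minus-BY mean difference, and returns the 2.5th and 97.5th
#' percentiles of the bootstrap deltas.
#'
#' @param phenotype,allele as in [locus_effect()].
#' @param n_boot bootstrap replicates (>= 100; the study used 1,000).
#' @param seed optional RNG seed.
#' @return named numeric `c(low, high)` with attribute `deltas` (the
#'   bootstrap replicates).
#' @export
bootstrap_ci <- function(phenotype, allele, n_boot = 1000, seed = NULL) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  ok <- !is.na(phenotype) & !is.na(allele)
  y1 <- phenotype[ok][allele[ok] == 1]
  y0 <- phenotype[ok][allele[ok] == 0]
  if (!length(y1) || !length(y0))
    stop("both allele classes must be non-empty")
  deltas <- with_seed(seed, vapply(seq_len(n_boot), function(b)
    mean(sample(y1, replace = TRUE)) - mean(sample(y0, replace = TRUE)),
    numeric(1)))
  ci <- stats::quantile(deltas, c(0.025, 0.975), names = FALSE)
  structure(stats::setNames(ci, c("low", "high")), deltas = deltas)
}

#' Effects of consolidated loci across contexts
#'
#' Convenience wrapper: for each consolidated locus and each phenotype
#' context (a named list of per-segregant phenotype vectors), computes the
#' 3S-minus-BY effect and a bootstrap interval at the locus's effect marker.
#'
#' @param cons object from [consolidate()].
#' @param genotypes segregants x markers matrix.
#' @param contexts named list of phenotype vectors aligned with the
#'   genotype rows.
#' @param n_boot,seed passed to [bootstrap_ci()].
#' @return data.frame: locus_id, context, delta, ci_low, ci_high, n_3s, n_by.
#' @export
locus_effect_table <- function(cons, genotypes, contexts, n_boot = 1000,
                               seed = NULL) {
  stopifnot(inherits(cons, "consolidated_loci"), is.list(contexts))
  rows <- list()
  for (i in seq_len(nrow(cons$loci))) {
    mk <- cons$loci$effect_marker[i]
    allele <- genotypes[, mk]
    for (ctx in names(contexts)) {
      eff <- locus_effect(contexts[[ctx]], allele)
      ci <- bootstrap_ci(contexts[[ctx]], allele, n_boot = n_boot,
                         seed = derive_seed(seed, i * 131 + match(ctx, names(contexts))))
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = cons$loci$locus_id[i], context = ctx, delta = eff$delta,
        ci_low = ci[["low"]], ci_high = ci[["high"]],
        n_3s = eff$n_3s, n_by = eff$n_by, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
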