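# Forward-regression linkage mapping: vectorized single-marker scans with
# optional covariate loci, permutation-derived family-wise thresholds,
# -log10(P)-drop confidence intervals, and variance-explained summaries.

# Core engine: P-values for every marker (columns of G) against every
# phenotype column of Y, conditioning on covariate columns X (which always
# include an intercept). Both G and Y are residualized against X, after
# which the focal-locus F-test (1 df) is a monotone function of the squared
# partial correlation: t^2 = r^2 * df / (1 - r^2), df = n - rank(X) - 1.
# Markers colinear with the covariates (residual norm ~ 0) get P = 1.
scan_engine <- function(G, Y, covariates = NULL) {
  n <- nrow(G)
  X <- cbind(rep(1, n), covariates)
  qx <- qr(X)
  df <- n - qx$rank - 1L
  if (df < 1) stop("not enough observations for the requested covariates")
  Gres <- qr.resid(qx, G)
  Yres <- qr.resid(qx, Y)
  gn <- sqrt(colSums(Gres^2))
  yn <- sqrt(colSums(Yres^2))
  R <- crossprod(Gres, Yres)
  gn_safe <- ifelse(gn < 1e-7, Inf, gn)
  yn_safe <- ifelse(yn < 1e-12, Inf, yn)
  R <- R / gn_safe
  R <- sweep(R, 2, yn_safe, "/")
  r2 <- pmin(R * R, 1)
  P <- stats::pf(r2 * df / pmax(1 - r2, 0), 1, df, lower.tail = FALSE)
  P[gn < 1e-7, ] <- 1
  P[, yn < 1e-12] <- 1
  dimnames(P) <- list(colnames(G), colnames(Y))
  P
}

drop_incomplete <- function(phenotype, genotypes) {
  ok <- !is.na(phenotype)
  list(y = phenotype[ok], G = genotypes[ok, , drop = FALSE], n = sum(ok))
}

#' Single-marker genome scan
#'
#' For each non-covariate marker, fits phenotype ~ covariates + marker by
#' OLS and returns the two-sided P-value of the focal marker term (F-test on
#' 1 df). Markers colinear with the covariates — including the covariate
#' markers themselves — get P = 1. Segregants with missing phenotype are
#' dropped listwise.
#'
#' @param phenotype numeric vector, one value per segregant (NA allowed).
#' @param genotypes segregants x markers 0/1 matrix.
#' @param covariates optional marker ids or column indices to condition on.
#' @return named numeric vector of P-values, one per marker.
#' @export
marker_scan <- function(phenotype, genotypes, covariates = NULL) {
  if (length(phenotype) != nrow(genotypes))
    stop("phenotype length must equal the number of segregants")
  d <- drop_incomplete(phenotype, genotypes)
  C <- if (length(covariates)) d$G[, covariates, drop = FALSE] else NULL
  P <- scan_engine(d$G, matrix(d$y, ncol = 1), C)
  stats::setNames(P[, 1], colnames(genotypes))
}

# column maxima via max.col (used to turn an m x p P/r2 matrix into per-
# phenotype scan minima)
col_max <- function(M) {
  idx <- max.col(t(M), ties.method = "first")
  M[cbind(idx, seq_len(ncol(M)))]
}

#' Permutation threshold for a genome scan
#'
#' Shuffles the phenotype vector while holding the genotype matrix (and any
#' covariate loci) fixed, rescans, and records the minimum P-value of each
#' permuted scan. The threshold is the empirical `quantile` (default the
#' fifth percentile) of those minima — the k-th order statistic with
#' k = floor(quantile * n_perm) — so that a scan minimum at or below it has
#' family-wise error ~ `quantile` under the null.
#'
#' @param phenotype numeric vector (NA allowed; dropped listwise).
#' @param genotypes segregants x markers matrix.
#' @param covariates optional covariate marker ids/indices (kept aligned
#'   with the genotypes, not permuted).
#' @param n_perm number of permutations (>= 20; the study used 1,000).
#' @param quantile which quantile of the minima to return.
#' @param seed optional RNG seed.
#' @param permutations optional integer matrix (n x n_perm) of explicit
#'   permutation orderings, for exhaustive enumeration on tiny instances.
#' @return threshold P-value (scalar) with attribute `min_p` holding the
#'   permutation minima.
#' @export
permutation_threshold <- function(phenotype, genotypes, covariates = NULL,
                                  n_perm = 1000, quantile = 0.05, seed = NULL,
                                  permutations = NULL) {
  d <- drop_incomplete(phenotype, genotypes)
  if (is.null(permutations)) {
    if (n_perm < 20) stop("n_perm must be at least 20")
    perms <- with_seed(seed, replicate(n_perm, sample.int(d$n)))
  } else {
    perms <- permutations
    if (nrow(perms) != d$n) stop("permutation rows must match usable segregants")
    n_perm <- ncol(perms)
  }
  Y <- matrix(d$y[perms], nrow = d$n, ncol = n_perm)
  C <- if (length(covariates)) d$G[, covariates, drop = FALSE] else NULL
  P <- scan_engine(d$G, Y, C)
  min_p <- -col_max(-P)
  k <- max(1L, floor(quantile * n_perm))
  thr <- sort(min_p, partial = k)[k]
  attr(thr, "min_p") <- min_p
  thr
}

#' -log10(P)-drop confidence interval around a peak
#'
#' The maximal contiguous run of markers containing the peak in which
#' -log10(P) stays within `drop` units of the peak value (the LOD-drop
#' analogue; default drop = 2 gives the conservative 95% intervals used for
#' locus consolidation).
#'
#' @param p_values per-marker P-values of one chromosome, position order.
#' @param peak_index index of the peak (minimum-P) marker within the vector.
#' @param drop drop in -log10(P) units.
#' @return integer vector `c(start, end)` of marker indices.
#' @export
drop_interval <- function(p_values, peak_index, drop = 2) {
  lp <- -log10(pmax(p_values, .Machine$double.xmin))
  lp[is.na(lp)] <- 0
  cut <- lp[peak_index] - drop
  lo <- peak_index
  while (lo > 1 && lp[lo - 1] >= cut) lo <- lo - 1
  hi <- peak_index
  while (hi < length(lp) && lp[hi + 1] >= cut) hi <- hi + 1
  c(lo, hi)
}

#' Forward-regression genome scan
#'
#' Iterative linkage mapping: each stage scans all markers conditional on
#' the peaks admitted so far, recomputes a permutation threshold with the
#' same covariates, and admits at most one locus per chromosome (the
#' minimum-P marker, ties broken by lowest index) whose P-value passes the
#' stage threshold. Admitted peaks join the covariates and scanning repeats
#' until a stage admits nothing.
#'
#' @param phenotype numeric vector over segregants (NA dropped listwise).
#' @param genotypes segregants x markers matrix.
#' @param marker_map map data.frame aligned with the genotype columns.
#' @param n_perm permutations per stage threshold.
#' @param quantile permutation quantile for the threshold.
#' @param drop -log10(P) drop for confidence intervals.
#' @param max_stages safety cap on stages (warns when reached).
#' @param seed optional RNG seed (per-stage permutation seeds are derived
#'   from it deterministically).
#' @param scan_id label stored with the detections.
#' @return object of class `forward_scan`: list with `detections` (one row
#'   per admitted locus: stage, chrom, peak marker/index/position, P,
#'   threshold, CI marker indices and positions), `stage_thresholds`,
#'   `profile` (stage-1 P-values), `n_used`, `marker_map`, `scan_id`.
#' @export
forward_scan <- function(phenotype, genotypes, marker_map, n_perm = 1000,
                         quantile = 0.05, drop = 2, max_stages = 20,
                         seed = NULL, scan_id = "scan") {
  validate_marker_map(marker_map)
  if (ncol(genotypes) != nrow(marker_map))
    stop("genotypes and marker map disagree on marker count")
  detections <- list()
  covariates <- integer(0)
  thresholds <- numeric(0)
  profile1 <- NULL
  for (stage in seq_len(max_stages)) {
    thr <- permutation_threshold(phenotype, genotypes, covariates,
                                 n_perm = n_perm, quantile = quantile,
                                 seed = derive_seed(seed, stage))
    p <- marker_scan(phenotype, genotypes, covariates)
    if (stage == 1L) profile1 <- p
    thresholds <- c(thresholds, as.numeric(thr))
    admitted <- integer(0)
    for (chr in unique(marker_map$chrom)) {
      idx <- which(marker_map$chrom == chr)
      j <- idx[which.min(p[idx])]  # which.min: lowest index on ties
      if (!is.na(p[j]) && p[j] <= thr && p[j] < 1) {
        ci <- drop_interval(p[idx], match(j, idx), drop)
        detections[[length(detections) + 1L]] <- data.frame(
          scan_id = scan_id, stage = stage, chrom = chr,
          peak_marker = marker_map$marker_id[j], peak_index = j,
          peak_pos = marker_map$pos[j], P = unname(p[j]),
          threshold = as.numeric(thr),
          ci_start_index = idx[ci[1]], ci_end_index = idx[ci[2]],
          ci_start_pos = marker_map$pos[idx[ci[1]]],
          ci_end_pos = marker_map$pos[idx[ci[2]]],
          stringsAsFactors = FALSE)
        admitted <- c(admitted, j)
      }
    }
    if (!length(admitted)) break
    covariates <- c(covariates, admitted)
    if (stage == max_stages)
      warning("forward scan stopped at max_stages with loci still detectable")
  }
  det <- if (length(detections)) do.call(rbind, detections) else
    data.frame(scan_id = character(), stage = integer(), chrom = integer(),
               peak_marker = character(), peak_index = integer(),
               peak_pos = integer(), P = numeric(), threshold = numeric(),
               ci_start_index = integer(), ci_end_index = integer(),
               ci_start_pos = integer(), ci_end_pos = integer(),
               stringsAsFactors = FALSE)
  structure(list(detections = det, stage_thresholds = thresholds,
                 profile = profile1, n_used = sum(!is.na(phenotype)),
                 marker_map = marker_map, scan_id = scan_id,
                 peaks = det$peak_index,
                 phenotype = phenotype, genotypes_dim = dim(genotypes)),
            class = "forward_scan")
}

#' @export
print.forward_scan <- function(x, ...) {
  cat(sprintf("Forward scan '%s': %d loci in %d stage(s), n = %d segregants\n",
              x$scan_id, nrow(x$detections), length(x$stage_thresholds),
              x$n_used))
  if (nrow(x$detections))
    print(x$detections[, c("stage", "chrom", "peak_marker", "peak_pos", "P",
                           "threshold", "ci_start_pos", "ci_end_pos")])
  invisible(x)
}

#' @export
summary.forward_scan <- function(object, ...) {
  det <- object$detections
  cat(sprintf("Forward-regression scan '%s'\n", object$scan_id))
  cat(sprintf("  segregants used: %d\n", object$n_used))
  cat(sprintf("  stages run: %d (thresholds: %s)\n",
              length(object$stage_thresholds),
              paste(signif(object$stage_thresholds, 3), collapse = ", ")))
  cat(sprintf("  loci detected: %d on %d chromosome(s)\n", nrow(det),
              length(unique(det$chrom))))
  if (nrow(det)) {
    ci_kb <- (det$ci_end_pos - det$ci_start_pos) / 1000
    cat(sprintf("  median CI width: %.1f kb\n", stats::median(ci_kb)))
  }
  invisible(object)
}

#' Plot a forward-scan profile
#'
#' Stage-1 -log10(P) profile by genomic position with chromosome boundaries,
#' the stage-1 permutation threshold, and admitted peaks marked.
#'
#' @param x a `forward_scan` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.forward_scan <- function(x, ...) {
  map <- x$marker_map
  offs <- c(0, cumsum(tapply(map$pos, map$chrom, max)))
  gx <- map$pos + offs[match(map$chrom, unique(map$chrom))]
  lp <- -log10(pmax(x$profile, .Machine$double.xmin))
  graphics::plot(gx, lp, pch = 16, cex = 0.4,
                 col = c("grey30", "grey60")[1 + map$chrom %% 2],
                 xlab = "genome position (bp)", ylab = "-log10(P)",
                 main = sprintf("scan '%s'", x$scan_id), ...)
  graphics::abline(h = -log10(x$stage_thresholds[1]), col = "red", lty = 2)
  det <- x$detections
  if (nrow(det))
    graphics::points(gx[det$peak_index], lp[det$peak_index] + 0,
                     col = "red", pch = 1, cex = 1.2)
  invisible(x)
}

#' Effect coefficients of the detected loci
#'
#' Joint OLS fit of the phenotype on all admitted peak markers; returns the
#' fitted coefficients (named by peak marker).
#' @param object a `forward_scan` object.
#' @param genotypes the genotype matrix used for the scan.
#' @param ... unused.
#' @export
coef.forward_scan <- function(object, genotypes, ...) {
  det <- object$detections
  if (!nrow(det)) return(numeric(0))
  d <- drop_incomplete(object$phenotype, genotypes)
  fit <- stats::lm(d$y ~ d$G[, det$peak_index, drop = FALSE])
  stats::setNames(stats::coef(fit)[-1], det$peak_marker)
}

#' Fraction of heritability explained by detected loci
#'
#' R-squared of the joint OLS fit of the phenotype on all detected peak
#' markers, divided by the across-sample broad-sense heritability of the
#' phenotype, reported as a percentage.
#'
#' @param phenotype numeric vector over segregants.
#' @param genotypes segregants x markers matrix.
#' @param peak_markers marker ids or column indices of the detected peaks.
#' @param h2 across-sample broad-sense heritability (in (0, 1]).
#' @return percentage of H2 explained.
#' @export
variance_explained <- function(phenotype, genotypes, peak_markers, h2) {
  if (is.na(h2) || h2 <= 0) stop("H2 must be positive")
  if (!length(peak_markers)) return(0)
  d <- drop_incomplete(phenotype, genotypes)
  fit <- stats::lm(d$y ~ d$G[, peak_markers, drop = FALSE])
  100 * summary(fit)$r.squared / h2
}
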