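# Persistence phenotypes: fractional change in barcode frequency relative to
# the initial pool, residualized against rich-medium plate controls, with
# time correction and brain/nonbrain aggregation.

#' Raw frequency-change phenotype
#'
#' Computes `(f_TF - f_T0) / f_T0`, the fractional change of a barcode's
#' frequency in a sample relative to the initial pool. Barcodes absent from
#' the initial pool (f_T0 = 0) are unmeasurable and return NA; extinction in
#' a sample (f_TF = 0) is a valid observation with value -1.
#'
#' @param f_tf frequency in the final sample.
#' @param f_t0 frequency in the initial pool.
#' @return numeric vector of raw phenotypes.
#' @export
raw_phenotype <- function(f_tf, f_t0) {
  out <- (f_tf - f_t0) / f_t0
  out[!is.na(f_t0) & f_t0 == 0] <- NA_real_
  out
}

#' Residualize a sample's phenotypes against plate controls
#'
#' Ordinary least squares of the sample phenotype on the mean control
#' phenotype across barcodes; the residuals are the persistence values.
#' Pairs with a missing value in either vector get NA residuals. If the
#' control regressor is constant the fit degenerates to intercept-only and
#' the residuals are the centered sample phenotypes.
#'
#' @param sample_phenotype raw phenotypes in one sample, one per barcode.
#' @param control_mean mean raw control phenotypes, same barcodes.
#' @return numeric residual vector (persistence), same length and names.
#' @export
plate_correct <- function(sample_phenotype, control_mean) {
  if (length(sample_phenotype) != length(control_mean))
    stop("sample and control vectors must align")
  ok <- !is.na(sample_phenotype) & !is.na(control_mean)
  if (sum(ok) < 3)
    stop("need at least 3 barcodes with both sample and control phenotypes")
  x <- control_mean[ok]; y <- sample_phenotype[ok]
  vx <- stats::var(x)
  b <- if (is.na(vx) || vx == 0) 0 else stats::cov(x, y) / vx
  a <- mean(y) - b * mean(x)
  out <- rep(NA_real_, length(sample_phenotype))
  out[ok] <- y - (a + b * x)
  names(out) <- names(sample_phenotype)
  out
}

#' Compute the persistence matrix from counts and sample metadata
#'
#' Full phenotyping path: normalize counts to frequencies, take initial-pool
#' frequencies from the T0 sample, compute raw frequency-change phenotypes
#' for plate controls and organ samples, average the plate controls per
#' barcode, and residualize every organ sample against that control mean.
#' Barcode replicates of triplicated segregants are kept as separate columns
#' throughout; merging to one barcode per segregant happens only where
#' mapping requires it.
#'
#' @param counts samples x barcodes matrix of raw counts.
#' @param meta sample metadata data.frame with columns `sample_id`, `type`
#'   (`T0`, `plate_control`, `organ`), `organ`, `day`, `replicate`.
#' @return object of class `persistence_matrix`: list with `raw` (control +
#'   organ samples x barcodes), `persistence` (organ samples x barcodes
#'   residuals), `control_mean`, `f_t0`, `meta`, and `unusable` (samples with
#'   no reads, excluded).
#' @export
compute_persistence <- function(counts, meta) {
  stopifnot(all(c("sample_id", "type", "organ", "day") %in% names(meta)))
  meta <- meta[match(rownames(counts), meta$sample_id), ]
  if (anyNA(meta$sample_id)) stop("every count row needs metadata")
  if (sum(meta$type == "T0") != 1L) stop("exactly one T0 sample is required")
  freq <- normalize_counts(counts)
  unusable <- attr(freq, "unusable")
  f_t0 <- freq[meta$type == "T0", ]
  use <- meta$type %in% c("plate_control", "organ") &
    !(meta$sample_id %in% unusable)
  raw <- t(apply(freq[use, , drop = FALSE], 1, raw_phenotype, f_t0 = f_t0))
  meta_use <- meta[use, ]
  ctrl <- raw[meta_use$type == "plate_control", , drop = FALSE]
  if (nrow(ctrl) == 0L) stop("no usable plate-control samples")
  control_mean <- colMeans(ctrl)
  organ_rows <- which(meta_use$type == "organ")
  persistence <- matrix(NA_real_, nrow = length(organ_rows), ncol = ncol(raw),
                        dimnames = list(rownames(raw)[organ_rows],
                                        colnames(raw)))
  for (k in seq_along(organ_rows))
    persistence[k, ] <- plate_correct(raw[organ_rows[k], ], control_mean)
  structure(list(raw = raw, persistence = persistence,
                 control_mean = control_mean, f_t0 = f_t0,
                 meta = meta_use, unusable = unusable),
            class = "persistence_matrix")
}

#' @export
print.persistence_matrix <- function(x, ...) {
  cat(sprintf("Persistence matrix: %d organ samples x %d barcodes (%d plate controls)\n",
              nrow(x$persistence), ncol(x$persistence),
              sum(x$meta$type == "plate_control")))
  if (length(x$unusable))
    cat("Unusable (zero-read) samples:", paste(x$unusable, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate persistence into brain and nonbrain means
#'
#' Time-corrects the raw organ phenotypes (dividing by days since injection),
#' residualizes each sample against the plate-control means, then averages
#' per barcode over the brain-group and nonbrain-group samples. The
#' brain-minus-nonbrain difference isolates organ-contrasting (pleiotropic)
#' effects.
#'
#' @param pm object from [compute_persistence()].
#' @param brain_samples,nonbrain_samples sample ids defining the two groups
#'   (typically the significance-filtered brain and kidney/liver/spleen
#'   samples).
#' @return data.frame with one row per barcode: `barcode`, `brain`,
#'   `nonbrain`, `difference`. A barcode missing from every sample of a group
#'   gets NA for that aggregate.
#' @export
aggregate_persistence <- function(pm, brain_samples, nonbrain_samples) {
  stopifnot(inherits(pm, "persistence_matrix"))
  if (!length(brain_samples) || !length(nonbrain_samples))
    stop("both groups need at least one sample")
  all_s <- c(brain_samples, nonbrain_samples)
  missing_s <- setdiff(all_s, rownames(pm$raw))
  if (length(missing_s))
    stop("unknown samples: ", paste(missing_s, collapse = ", "))
  group_mean <- function(samples) {
    resid <- sapply(samples, function(s) {
      day <- pm$meta$day[pm$meta$sample_id == s]
      if (is.na(day) || day <= 0) stop("group samples must be organ samples with a day")
      plate_correct(pm$raw[s, ] / day, pm$control_mean)
    })
    rowMeans(resid, na.rm = TRUE)
  }
  brain <- group_mean(brain_samples)
  nonbrain <- group_mean(nonbrain_samples)
  brain[is.nan(brain)] <- NA_real_
  nonbrain[is.nan(nonbrain)] <- NA_real_
  data.frame(barcode = colnames(pm$raw), brain = brain, nonbrain = nonbrain,
             difference = brain - nonbrain, row.names = NULL,
             stringsAsFactors = FALSE)
}
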