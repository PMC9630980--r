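# Read-record quantification: quality/flank filtering, UMI deduplication,
# Hamming-radius assignment to a known barcode whitelist, and per-sample
# frequency normalization.

#' Filter reads and collapse PCR duplicates
#'
#' Removes reads whose mean quality in the barcoded region falls below the
#' threshold (kept if >= min_quality) or that lack the landing-pad flank,
#' then keeps a single read per distinct UMI within each sample.
#'
#' @param reads data.frame with columns `sample_id`, `barcode`, `umi`,
#'   `quality`, `flank_ok`.
#' @param min_quality Phred-scale quality threshold (default 30).
#' @return filtered data.frame, at most one row per (sample, UMI).
#' @export
filter_and_dedup <- function(reads, min_quality = 30) {
  req <- c("sample_id", "barcode", "umi", "quality", "flank_ok")
  if (!all(req %in% names(reads)))
    stop("reads must have columns: ", paste(req, collapse = ", "))
  keep <- reads$quality >= min_quality & reads$flank_ok
  out <- reads[keep, , drop = FALSE]
  if (nrow(out)) {
    out <- out[!duplicated(paste(out$sample_id, out$umi, sep = "\r")), ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Assign reads to known barcodes within a Hamming radius
#'
#' Each read's barcode is assigned to the unique whitelist barcode within
#' `max_hamming` substitutions; reads matching no whitelist entry at that
#' radius are discarded. The whitelist must be separated by more than
#' `2 * max_hamming` so assignment is unambiguous (checked).
#'
#' @param reads filtered data.frame (see [filter_and_dedup()]).
#' @param known_barcodes character vector of whitelist barcodes, all one
#'   length.
#' @param max_hamming maximum allowed Hamming distance (study values: 2 for
#'   barcode determination, 3 for sample quantification).
#' @return object of class `count_table`: integer matrix samples x barcodes
#'   of raw counts, with attributes `discarded` (reads assigned to nothing)
#'   and `max_hamming`.
#' @export
cluster_to_known <- function(reads, known_barcodes, max_hamming = 3) {
  if (anyDuplicated(known_barcodes)) stop("known barcodes must be unique")
  ref <- seq_char_matrix(known_barcodes)
  if (length(known_barcodes) > 1) {
    viol <- barcode_separation_violators(ref, 2 * max_hamming + 1)
    if (length(viol))
      stop("known barcodes are closer than 2*max_hamming + 1; ",
           "assignment would be ambiguous")
  }
  samples <- unique(reads$sample_id)
  counts <- matrix(0L, nrow = length(samples), ncol = length(known_barcodes),
                   dimnames = list(samples, known_barcodes))
  discarded <- 0L
  if (nrow(reads)) {
    uniq <- unique(reads$barcode)
    uniq <- uniq[nchar(uniq) == ncol(ref)]
    target <- rep(NA_integer_, length(uniq))
    exact <- match(uniq, known_barcodes)
    target[!is.na(exact)] <- exact[!is.na(exact)]
    todo <- which(is.na(target))
    for (j in todo) {
      d <- hamming_to_refs(strsplit(uniq[j], "")[[1]], ref)
      hit <- which(d <= max_hamming)
      if (length(hit) == 1L) target[j] <- hit
    }
    assigned <- target[match(reads$barcode, uniq)]  # NA: wrong length or no hit
    discarded <- sum(is.na(assigned))
    ok <- !is.na(assigned)
    if (any(ok)) {
      tab <- table(factor(reads$sample_id[ok], levels = samples),
                   factor(assigned[ok], levels = seq_along(known_barcodes)))
      counts[] <- as.integer(tab)
    }
  }
  structure(counts, discarded = discarded, max_hamming = max_hamming,
            class = c("count_table", class(counts)))
}

#' Normalize a count table to per-sample frequencies
#'
#' Divides each sample's counts by its total barcode reads. Samples with a
#' zero total have undefined frequencies; they are returned as NA rows and
#' flagged in the `unusable` attribute.
#'
#' @param counts samples x barcodes matrix of raw counts.
#' @return numeric matrix of frequencies (rows sum to 1 for usable samples),
#'   with attribute `unusable` naming all-zero samples.
#' @export
normalize_counts <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- rowSums(counts)
  freq <- sweep(counts, 1, totals, "/")
  freq[totals == 0, ] <- NA_real_
  attr(freq, "unusable") <- rownames(counts)[totals == 0]
  freq
}
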