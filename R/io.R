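# Plain TSV readers/writers for every table the pipeline exchanges.
# All tables carry header rows; genomic coordinates are 1-based inclusive;
# missing values are written as "NA".

write_tsv <- function(x, path, row_label = NULL) {
  if (!is.null(row_label)) {
    x <- data.frame(tmp = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
    names(x)[1] <- row_label
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write / read a marker map TSV
#' @param map marker map data.frame.
#' @param path file path.
#' @export
write_marker_map <- function(map, path) write_tsv(map, path)

#' @rdname write_marker_map
#' @export
read_marker_map <- function(path) {
  map <- read_tsv(path)
  validate_marker_map(map)
  map
}

#' Write / read a genotype (or observed-fraction) matrix TSV
#'
#' Segregants x markers with a leading `segregant_id` column and marker ids
#' as the remaining headers; NA encodes missing.
#' @param mat matrix with segregant rownames and marker colnames.
#' @param path file path.
#' @export
write_genotypes <- function(mat, path) write_tsv(as.data.frame(mat), path,
                                                 row_label = "segregant_id")

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- read_tsv(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Write / read a barcode assignment TSV
#' @param assignment assignment data.frame.
#' @param path file path.
#' @export
write_assignment <- function(assignment, path) write_tsv(assignment, path)

#' @rdname write_assignment
#' @export
read_assignment <- function(path) read_tsv(path)

#' Write / read a count (or frequency) table TSV
#'
#' Samples x barcodes with a leading `sample_id` column.
#' @param counts matrix with sample rownames and barcode colnames.
#' @param path file path.
#' @export
write_counts <- function(counts, path) write_tsv(as.data.frame(unclass(counts)),
                                                 path, row_label = "sample_id")

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Write / read sample metadata TSV
#' @param meta metadata data.frame.
#' @param path file path.
#' @export
write_sample_meta <- function(meta, path) write_tsv(meta, path)

#' @rdname write_sample_meta
#' @export
read_sample_meta <- function(path) read_tsv(path)

#' Write / read an effect model (simulation ground truth) TSV
#'
#' One row per planted locus with its class and per-organ selection
#' coefficients in `s_<organ>` columns; sufficient to score detections.
#' @param model `effect_model` object.
#' @param path file path.
#' @export
write_effect_model <- function(model, path) {
  stopifnot(inherits(model, "effect_model"))
  s <- model$s
  colnames(s) <- paste0("s_", colnames(s))
  write_tsv(cbind(model$loci, as.data.frame(s)), path)
}

#' @rdname write_effect_model
#' @export
read_effect_model <- function(path) {
  df <- read_tsv(path)
  s_cols <- grep("^s_", names(df), value = TRUE)
  s <- as.matrix(df[, s_cols, drop = FALSE])
  colnames(s) <- sub("^s_", "", s_cols)
  rownames(s) <- df$locus_id
  structure(list(loci = df[, setdiff(names(df), s_cols)], s = s),
            class = "effect_model")
}
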