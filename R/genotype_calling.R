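# Genotype correction for low-coverage haploid segregant sequencing:
# threshold the observed 3S-read fraction at each SNP, correct and impute
# with a 2-state hidden Markov model along each chromosome, and collapse
# adjacent markers that carry identical information.

#' HMM parameters for genotype correction
#'
#' Two hidden states (BY = 0, 3S = 1). The chain is strongly persistent
#' (stay probability 0.9999) so isolated discordant calls are treated as
#' sequencing error rather than double crossovers; emissions are symmetric,
#' with the observed call matching the hidden state with probability 0.75.
#'
#' @param stay probability of remaining in the current state between adjacent
#'   markers.
#' @param concordant probability that an observed call matches the hidden
#'   state.
#' @return list of class `hmm_params`.
#' @export
hmm_params <- function(stay = 0.9999, concordant = 0.75) {
  stop_if_not_prob(stay, "stay")
  stop_if_not_prob(concordant, "concordant")
  structure(list(stay = stay, switch = 1 - stay,
                 concordant = concordant, discordant = 1 - concordant),
            class = "hmm_params")
}

#' Threshold observed 3S fractions into preliminary calls
#'
#' Sites with a 3S-read fraction above 0.5 are called 3S (1), below 0.5 BY
#' (0). Missing fractions stay missing; a fraction of exactly 0.5 carries no
#' evidence either way and is also treated as missing, to be imputed by the
#' HMM.
#'
#' @param fractions numeric vector or matrix of observed 3S fractions in
#'   [0, 1], NA allowed.
#' @return integer calls (0/1/NA) with the same shape and dimnames.
#' @export
threshold_calls <- function(fractions) {
  rng <- range(fractions, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
    stop("fractions must lie in [0, 1]")
  out <- ifelse(is.na(fractions), NA_integer_,
                ifelse(fractions > 0.5, 1L, ifelse(fractions < 0.5, 0L,
                                                   NA_integer_)))
  if (is.matrix(fractions))
    out <- matrix(out, nrow = nrow(fractions), dimnames = dimnames(fractions))
  out
}

# Viterbi decoding of one chromosome's preliminary calls (0/1/NA).
# Missing sites emit with likelihood 1 under both states, so they are purely
# imputed. Ties (including fully missing chromosomes) resolve to state 0.
viterbi_chromosome <- function(calls, params) {
  n <- length(calls)
  if (n == 0L) return(integer(0))
  l_stay <- log(params$stay); l_switch <- log(params$switch)
  l_con <- log(params$concordant); l_dis <- log(params$discordant)
  emis <- function(obs) {
    if (is.na(obs)) return(c(0, 0))
    if (obs == 0L) c(l_con, l_dis) else c(l_dis, l_con)
  }
  delta <- log(c(0.5, 0.5)) + emis(calls[1])
  psi <- matrix(1L, nrow = n, ncol = 2)
  if (n > 1) {
    for (t in 2:n) {
      e <- emis(calls[t])
      new <- numeric(2)
      for (s in 1:2) {
        cand <- delta + c(if (s == 1) l_stay else l_switch,
                          if (s == 2) l_stay else l_switch)
        psi[t, s] <- which.max(cand)  # first index on ties -> state 0
        new[s] <- cand[psi[t, s]] + e[s]
      }
      delta <- new
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path - 1L
}

#' Correct and impute genotype calls with a 2-state HMM
#'
#' Runs Viterbi decoding of the most probable hidden parental-state path
#' along each chromosome, turning noisy thresholded calls into a legal mosaic
#' of parental blocks. Every site receives a call: missing sites are imputed
#' from their flanking blocks, and isolated discordant calls are corrected
#' (a single flip costs two 1e-4 transitions versus one 0.25 emission, so
#' persistence wins).
#'
#' @param calls segregants x markers matrix of preliminary calls (0/1/NA),
#'   or a single vector for one segregant.
#' @param marker_map data.frame with `chrom` ordering the columns; markers
#'   must be position-ordered within chromosome.
#' @param params [hmm_params()].
#' @return integer matrix (or vector) of corrected calls, no missing values.
#' @export
hmm_correct <- function(calls, marker_map, params = hmm_params()) {
  stopifnot(inherits(params, "hmm_params"))
  vec <- !is.matrix(calls)
  if (vec) calls <- matrix(calls, nrow = 1)
  if (ncol(calls) != nrow(marker_map))
    stop("calls and marker map disagree on marker count")
  out <- calls
  for (chr in unique(marker_map$chrom)) {
    idx <- which(marker_map$chrom == chr)
    for (i in seq_len(nrow(calls)))
      out[i, idx] <- viterbi_chromosome(calls[i, idx], params)
  }
  storage.mode(out) <- "integer"
  if (vec) out[1, ] else out
}

#' Collapse adjacent markers lacking recombination
#'
#' Maximal runs of adjacent markers whose genotype columns are identical
#' across all segregants carry identical mapping information; each run is
#' replaced by its first marker. The reduced map records the extent (first
#' and last position) and size of each collapsed run.
#'
#' @param genotypes fully called segregants x markers matrix.
#' @param marker_map matching marker map.
#' @return list with `genotypes` (reduced matrix) and `marker_map` (reduced
#'   map with `start_pos`, `end_pos`, `n_collapsed` columns).
#' @export
collapse_markers <- function(genotypes, marker_map) {
  if (anyNA(genotypes)) stop("genotypes must be fully called before collapsing")
  if (ncol(genotypes) != nrow(marker_map))
    stop("genotypes and marker map disagree on marker count")
  m <- ncol(genotypes)
  if (m == 0L) return(list(genotypes = genotypes, marker_map = marker_map))
  same <- rep(FALSE, m)
  if (m > 1) {
    same_geno <- colSums(genotypes[, -1, drop = FALSE] !=
                           genotypes[, -m, drop = FALSE]) == 0
    same_chrom <- marker_map$chrom[-1] == marker_map$chrom[-m]
    same[-1] <- same_geno & same_chrom
  }
  group <- cumsum(!same)
  keep <- which(!same)
  red_map <- marker_map[keep, c("marker_id", "chrom", "pos")]
  red_map$start_pos <- as.integer(tapply(marker_map$pos, group, min)[as.character(seq_along(keep))])
  red_map$end_pos <- as.integer(tapply(marker_map$pos, group, max)[as.character(seq_along(keep))])
  red_map$n_collapsed <- as.integer(table(group))
  rownames(red_map) <- NULL
  list(genotypes = genotypes[, keep, drop = FALSE], marker_map = red_map)
}
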