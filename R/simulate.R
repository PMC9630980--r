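# Synthetic-data generator: meiosis, effect models, barcoded pools, and
# organ-sampling experiments with the statistical structure the downstream
# analysis assumes (selection on log-frequency, recovery bottlenecks,
# multinomial sequencing noise).

#' Organs used throughout the package
#'
#' The five organs sampled in the experimental design. "Nonbrain" throughout
#' the package means kidney, liver, and spleen; the gonads are carried through
#' phenotyping but are typically removed by the significance filter because of
#' their very low yeast recovery.
#' @export
PERSIST_ORGANS <- c("brain", "gonad", "kidney", "liver", "spleen")

#' Default expected colony-forming units recovered per organ sample
#'
#' Average CFU recovered per organ in the study design the generator emulates.
#' These set the recovery bottleneck: each organ sample's founder cells are a
#' multinomial draw of this size from the within-host pool, which is what
#' limits measurable strain diversity (and hence heritability) in low-recovery
#' organs such as the brain and gonads.
#' @export
PERSIST_DEFAULT_CFU <- c(brain = 1741, gonad = 69, kidney = 3843,
                         liver = 69150, spleen = 32032)

#' Build a marker map
#'
#' Creates a map of biallelic SNP markers evenly spread (with positional
#' jitter) along equally sized chromosomes. The default dimensions mirror a
#' dense yeast cross map: 16 chromosomes and ~900 markers each (14,352 total,
#' close to the 14,347 collapsed markers of a typical BY x 3S panel); tests
#' and examples use far smaller maps.
#'
#' @param n_chromosomes number of chromosomes.
#' @param markers_per_chromosome markers per chromosome.
#' @param chromosome_length chromosome length in base pairs.
#' @param seed optional RNG seed for the positional jitter.
#' @return data.frame with columns `marker_id`, `chrom` (integer), `pos`
#'   (1-based, strictly increasing within chromosome).
#' @export
make_marker_map <- function(n_chromosomes = 16, markers_per_chromosome = 897,
                            chromosome_length = 750000, seed = NULL) {
  stopifnot(n_chromosomes >= 1, markers_per_chromosome >= 1,
            chromosome_length >= markers_per_chromosome)
  with_seed(seed, {
    maps <- lapply(seq_len(n_chromosomes), function(chr) {
      spacing <- chromosome_length / (markers_per_chromosome + 1)
      pos <- round(spacing * seq_len(markers_per_chromosome) +
                     stats::runif(markers_per_chromosome, -0.3, 0.3) * spacing)
      pos <- sort(unique(pmax(1, pos)))
      # enforce strict monotonicity after rounding
      while (any(duplicated(pos))) pos <- sort(unique(pos + cumsum(duplicated(pos))))
      data.frame(marker_id = sprintf("chr%02d_m%04d", chr, seq_along(pos)),
                 chrom = chr, pos = as.integer(pos),
                 stringsAsFactors = FALSE)
    })
    map <- do.call(rbind, maps)
    rownames(map) <- NULL
    validate_marker_map(map)
    map
  })
}

validate_marker_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("marker_id", "chrom", "pos") %in% names(map)))
  if (nrow(map) == 0L) stop("marker map is empty")
  if (anyDuplicated(map$marker_id)) stop("marker_ids must be unique")
  ok <- tapply(map$pos, map$chrom, function(p) all(diff(p) > 0))
  if (!all(unlist(ok))) stop("positions must be strictly increasing within a chromosome")
  invisible(map)
}

#' Simulate a haploid two-parent cross
#'
#' Generates segregant genotypes as Markov mosaics of the two parental
#' chromosomes. Crossover counts per chromosome are Poisson with the given
#' mean and breakpoints are uniform along the chromosome (no interference);
#' the starting parental allele of each chromosome is a fair coin flip, so
#' marginal allele frequencies are ~0.5 at every marker.
#'
#' @param marker_map data.frame from [make_marker_map()].
#' @param n_segregants number of haploid progeny to generate.
#' @param expected_crossovers expected crossovers per chromosome per meiosis.
#' @param seed optional RNG seed.
#' @return integer matrix (segregants x markers) of allele codes, 0 for the
#'   reference (BY) parent and 1 for the clinical (3S) parent, with segregant
#'   ids as rownames and marker ids as colnames.
#' @export
simulate_cross <- function(marker_map, n_segregants,
                           expected_crossovers = 3, seed = NULL) {
  validate_marker_map(marker_map)
  stopifnot(n_segregants >= 1, expected_crossovers >= 0)
  chroms <- unique(marker_map$chrom)
  with_seed(seed, {
    geno <- matrix(0L, nrow = n_segregants, ncol = nrow(marker_map),
                   dimnames = list(sprintf("seg%04d", seq_len(n_segregants)),
                                   marker_map$marker_id))
    for (chr in chroms) {
      idx <- which(marker_map$chrom == chr)
      pos <- marker_map$pos[idx]
      len <- max(pos)
      for (i in seq_len(n_segregants)) {
        n_co <- stats::rpois(1L, expected_crossovers)
        start <- stats::rbinom(1L, 1L, 0.5)
        if (n_co == 0L) {
          geno[i, idx] <- start
        } else {
          breaks <- sort(stats::runif(n_co, 0, len))
          # phase at a marker flips once per crossover to its left
          nleft <- findInterval(pos, breaks)
          geno[i, idx] <- (start + nleft) %% 2L
        }
      }
    }
    storage.mode(geno) <- "integer"
    geno
  })
}

#' Simulate a ground-truth effect model
#'
#' Plants loci with per-organ selection coefficients on distinct markers.
#' General loci receive same-sign coefficients in every organ; antagonistic
#' loci receive opposite signs in the brain versus all nonbrain organs.
#' Selection coefficients are per-day log-frequency advantages of the 3S
#' allele (positive s means the 3S allele is beneficial in that organ).
#'
#' @param marker_map data.frame from [make_marker_map()].
#' @param n_general,n_antagonistic number of loci of each class.
#' @param effect_scale magnitude of the per-day selection coefficient; every
#'   locus gets |s| = effect_scale up to a mild per-organ jitter (U[0.9,
#'   1.1]), so the parameter directly sets the planted effect size.
#' @param organs organ contexts (first match of "brain" defines the brain
#'   context; all others take the opposing sign for antagonistic loci).
#' @param min_distance_bp minimum distance between planted loci on the same
#'   chromosome.
#' @param max_per_chromosome cap on planted loci per chromosome.
#' @param seed optional RNG seed.
#' @return object of class `effect_model`: a list with `loci` (data.frame of
#'   locus_id, marker_id, chrom, pos, class) and `s` (loci x organs matrix of
#'   selection coefficients).
#' @export
simulate_effect_model <- function(marker_map, n_general = 10,
                                  n_antagonistic = 8, effect_scale = 0.15,
                                  organs = PERSIST_ORGANS,
                                  min_distance_bp = 100000,
                                  max_per_chromosome = 2, seed = NULL) {
  validate_marker_map(marker_map)
  if (effect_scale <= 0) stop("effect_scale must be positive")
  stopifnot(n_general >= 0, n_antagonistic >= 0, max_per_chromosome >= 1)
  n_loci <- n_general + n_antagonistic
  n_chrom <- length(unique(marker_map$chrom))
  if (n_loci > n_chrom * max_per_chromosome)
    stop("requested more loci than the map can hold at this per-chromosome cap")
  brain <- organs[grepl("brain", organs)][1]
  if (is.na(brain)) stop("organs must include a brain context")
  with_seed(seed, {
    if (n_loci == 0L) {
      loci <- data.frame(locus_id = character(), marker_id = character(),
                         chrom = integer(), pos = integer(),
                         class = character(), stringsAsFactors = FALSE)
      s <- matrix(numeric(0), nrow = 0, ncol = length(organs),
                  dimnames = list(NULL, organs))
      return(structure(list(loci = loci, s = s), class = "effect_model"))
    }
    cand <- sample.int(nrow(marker_map))
    chosen <- integer(0)
    per_chrom <- integer(n_chrom + max(marker_map$chrom))
    for (j in cand) {
      if (length(chosen) == n_loci) break
      chr <- marker_map$chrom[j]
      if (per_chrom[chr] >= max_per_chromosome) next
      same <- chosen[marker_map$chrom[chosen] == chr]
      if (length(same) &&
          any(abs(marker_map$pos[same] - marker_map$pos[j]) < min_distance_bp))
        next
      chosen <- c(chosen, j)
      per_chrom[chr] <- per_chrom[chr] + 1L
    }
    if (length(chosen) < n_loci)
      stop("could not place all loci at the requested spacing and cap")
    chosen <- chosen[order(marker_map$chrom[chosen], marker_map$pos[chosen])]
    cls <- sample(rep(c("general", "antagonistic"), c(n_general, n_antagonistic)))
    loci <- data.frame(locus_id = sprintf("L%02d", seq_len(n_loci)),
                       marker_id = marker_map$marker_id[chosen],
                       chrom = marker_map$chrom[chosen],
                       pos = marker_map$pos[chosen],
                       class = cls, stringsAsFactors = FALSE)
    s <- matrix(0, nrow = n_loci, ncol = length(organs),
                dimnames = list(loci$locus_id, organs))
    for (k in seq_len(n_loci)) {
      a <- effect_scale
      sign_brain <- sample(c(-1, 1), 1)
      for (org in organs) {
        jit <- stats::runif(1, 0.9, 1.1)
        sgn <- if (org == brain || cls[k] == "general") sign_brain else -sign_brain
        s[k, org] <- sgn * a * jit
      }
    }
    structure(list(loci = loci, s = s), class = "effect_model")
  })
}

#' @export
print.effect_model <- function(x, ...) {
  cat(sprintf("Effect model: %d loci (%d general, %d antagonistic)\n",
              nrow(x$loci), sum(x$loci$class == "general"),
              sum(x$loci$class == "antagonistic")))
  print(cbind(x$loci, round(x$s, 4)))
  invisible(x)
}

#' Assign random barcodes to segregants
#'
#' Generates unique random barcodes (default 20-mers) with a guaranteed
#' minimum pairwise Hamming separation so that whitelist assignment within a
#' Hamming radius is unambiguous, and assigns them to segregants. A leading
#' subset of segregants is triplicated (three distinct barcodes each),
#' providing the internal replication used for within-sample heritability.
#'
#' @param segregant_ids character vector of segregant ids.
#' @param n_triplicated number of segregants carrying 3 barcodes.
#' @param barcode_length barcode length in nucleotides.
#' @param min_separation minimum pairwise Hamming distance between barcodes
#'   (default 7 = 2 x the default clustering radius + 1).
#' @param seed optional RNG seed.
#' @return data.frame with columns `barcode`, `segregant_id`,
#'   `replicate_index`.
#' @export
make_barcode_assignment <- function(segregant_ids, n_triplicated = 86,
                                    barcode_length = 20, min_separation = 7,
                                    seed = NULL) {
  n_seg <- length(segregant_ids)
  stopifnot(n_seg >= 1, n_triplicated >= 0, n_triplicated <= n_seg)
  n_bc <- n_seg + 2L * n_triplicated
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    mat <- matrix(sample(bases, n_bc * barcode_length, replace = TRUE),
                  nrow = n_bc)
    # iteratively regenerate rows violating the pairwise separation
    for (iter in 1:200) {
      bad <- barcode_separation_violators(mat, min_separation)
      if (!length(bad)) break
      mat[bad, ] <- sample(bases, length(bad) * barcode_length, replace = TRUE)
      if (iter == 200)
        stop("could not generate barcodes at the requested separation")
    }
    barcodes <- apply(mat, 1, paste0, collapse = "")
    seg <- c(segregant_ids,
             rep(segregant_ids[seq_len(n_triplicated)], each = 2L))
    rep_idx <- c(rep(1L, n_seg),
                 rep(c(2L, 3L), times = n_triplicated))
    ord <- order(match(seg, segregant_ids), rep_idx)
    data.frame(barcode = barcodes, segregant_id = seg[ord],
               replicate_index = rep_idx[ord], stringsAsFactors = FALSE)
  })
}

# rows of `mat` whose nearest neighbour is closer than min_separation
barcode_separation_violators <- function(mat, min_separation) {
  n <- nrow(mat); len <- ncol(mat)
  shared <- matrix(0, n, n)
  for (b in c("A", "C", "G", "T")) {
    ind <- (mat == b) * 1
    shared <- shared + tcrossprod(ind)
  }
  d <- len - shared
  diag(d) <- Inf
  which(apply(d, 1, min) < min_separation)
}

#' Describe the pooled-infection experimental design
#'
#' Full-factorial organ sampling (organs x sexes x treatments x days x
#' replicates) plus one sequenced initial-pool (T0) sample and replicate
#' rich-medium plate controls.
#'
#' @param organs organs sampled.
#' @param sexes,treatments factor levels for host sex and immunosuppression.
#' @param days harvest days post-injection.
#' @param replicates host replicates per cell of the design.
#' @param cfu named vector of expected CFU recovered per organ (the recovery
#'   bottleneck).
#' @param depth sequencing reads per sample.
#' @param n_plate_controls number of plate-control samples.
#' @param control_cells cells plated per control (default 1e5, the density
#'   whose controls feed the plate-growth correction).
#' @return object of class `experiment_design`.
#' @export
make_experiment_design <- function(organs = PERSIST_ORGANS,
                                   sexes = c("F", "M"),
                                   treatments = c("dex", "water"),
                                   days = c(1, 2, 5), replicates = 3,
                                   cfu = PERSIST_DEFAULT_CFU,
                                   depth = 5e5, n_plate_controls = 3,
                                   control_cells = 1e5) {
  if (depth <= 0) stop("sequencing depth must be positive")
  if (!all(organs %in% names(cfu)))
    stop("cfu must be named for every organ")
  structure(list(organs = organs, sexes = sexes, treatments = treatments,
                 days = days, replicates = replicates, cfu = cfu[organs],
                 depth = depth, n_plate_controls = n_plate_controls,
                 control_cells = control_cells),
            class = "experiment_design")
}

#' Simulate a pooled barcode-sequencing infection experiment
#'
#' Generates per-sample barcode read counts under a multiplicative selection
#' model. The expected frequency of barcode i in an organ sample at day t is
#' proportional to `p0_i * exp(g_i + t * S_i(organ))`, where `p0` are the
#' initial-pool frequencies (equimolar with mild log-normal jitter), `g` is a
#' per-segregant on-plate growth coefficient shared between plate controls
#' and organ samples (so the plate-growth residualization is identifiable by
#' construction), and `S_i(organ)` sums the planted selection coefficients
#' over the alleles the segregant carries. Organ samples pass through a
#' multinomial recovery bottleneck at the organ's CFU scale before multinomial
#' read sampling at the design depth; plate controls bottleneck at the plated
#' cell count.
#'
#' @param genotypes segregants x markers matrix from [simulate_cross()].
#' @param assignment barcode table from [make_barcode_assignment()].
#' @param effect_model object from [simulate_effect_model()].
#' @param design object from [make_experiment_design()].
#' @param t0_log_sd log-normal jitter of initial pool frequencies.
#' @param plate_sd standard deviation of the per-segregant on-plate growth
#'   coefficient.
#' @param seed optional RNG seed.
#' @return list of class `persist_sim` with elements `counts` (samples x
#'   barcodes integer matrix), `meta` (sample metadata data.frame), and
#'   `truth` (p0, plate coefficients, per-segregant organ fitness, expected
#'   pre-bottleneck frequencies, and the effect model) sufficient to score
#'   downstream detections.
#' @export
simulate_experiment <- function(genotypes, assignment, effect_model, design,
                                t0_log_sd = 0.1, plate_sd = 0.2, seed = NULL) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(effect_model, "effect_model"))
  if (!all(assignment$segregant_id %in% rownames(genotypes)))
    stop("all barcoded segregants must be genotyped")
  nb <- nrow(assignment)
  seg_of <- match(assignment$segregant_id, rownames(genotypes))
  organs <- design$organs
  with_seed(seed, {
    p0 <- exp(stats::rnorm(nb, 0, t0_log_sd))
    p0 <- p0 / sum(p0)
    g_seg <- stats::rnorm(nrow(genotypes), 0, plate_sd)
    if (nrow(effect_model$loci)) {
      A <- genotypes[, effect_model$loci$marker_id, drop = FALSE]
      S_seg <- A %*% effect_model$s[, organs, drop = FALSE]
    } else {
      S_seg <- matrix(0, nrow(genotypes), length(organs),
                      dimnames = list(rownames(genotypes), organs))
    }
    g_bc <- g_seg[seg_of]
    S_bc <- S_seg[seg_of, , drop = FALSE]

    meta <- build_sample_meta(design)
    counts <- matrix(0L, nrow = nrow(meta), ncol = nb,
                     dimnames = list(meta$sample_id, assignment$barcode))
    expected <- matrix(NA_real_, nrow = nrow(meta), ncol = nb,
                       dimnames = dimnames(counts))
    for (i in seq_len(nrow(meta))) {
      type <- meta$type[i]
      if (type == "T0") {
        q <- p0
        expected[i, ] <- q
      } else if (type == "plate_control") {
        q <- p0 * exp(g_bc)
        q <- q / sum(q)
        expected[i, ] <- q
        cells <- stats::rmultinom(1, design$control_cells, q)[, 1]
        q <- cells / sum(cells)
      } else {
        day <- meta$day[i]
        w <- p0 * exp(g_bc + day * S_bc[, meta$organ[i]])
        q <- w / sum(w)
        expected[i, ] <- q
        founders <- stats::rmultinom(1, round(design$cfu[[meta$organ[i]]]), q)[, 1]
        if (sum(founders) == 0) next
        q <- founders / sum(founders)
      }
      counts[i, ] <- stats::rmultinom(1, design$depth, q)[, 1]
    }
    truth <- list(p0 = stats::setNames(p0, assignment$barcode),
                  plate_coef = stats::setNames(g_seg, rownames(genotypes)),
                  fitness = S_seg, expected_freq = expected,
                  effect_model = effect_model)
    structure(list(counts = counts, meta = meta, truth = truth,
                   assignment = assignment), class = "persist_sim")
  })
}

build_sample_meta <- function(design) {
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      day = design$days, treatment = design$treatments,
                      sex = design$sexes, organ = design$organs,
                      stringsAsFactors = FALSE)
  organ_meta <- data.frame(
    sample_id = sprintf("%s_%s_%s_d%d_r%d", grid$organ, grid$sex,
                        grid$treatment, grid$day, grid$replicate),
    type = "organ", organ = grid$organ, sex = grid$sex,
    treatment = grid$treatment, day = grid$day, replicate = grid$replicate,
    stringsAsFactors = FALSE)
  ctrl <- data.frame(
    sample_id = sprintf("plate_control_r%d", seq_len(design$n_plate_controls)),
    type = "plate_control", organ = NA_character_, sex = NA_character_,
    treatment = NA_character_, day = NA_real_,
    replicate = seq_len(design$n_plate_controls), stringsAsFactors = FALSE)
  t0 <- data.frame(sample_id = "T0", type = "T0", organ = NA_character_,
                   sex = NA_character_, treatment = NA_character_,
                   day = NA_real_, replicate = 1L, stringsAsFactors = FALSE)
  rbind(t0, ctrl, organ_meta)
}

#' Simulate noisy per-site genotype observations
#'
#' Emulates low-coverage whole-genome sequencing of segregants: per-site read
#' depth is Poisson(mean_coverage), each read reports the true allele with
#' probability `1 - per_read_error`, and the observed value is the fraction of
#' reads supporting the 3S allele. Zero-depth sites are missing (NA).
#'
#' @param genotypes segregants x markers 0/1 matrix (the truth).
#' @param mean_coverage mean per-site read depth (> 0).
#' @param per_read_error per-read miscall probability in [0, 0.5).
#' @param seed optional RNG seed.
#' @return numeric matrix of observed 3S fractions with NA at zero-depth
#'   sites, same dimnames as `genotypes`.
#' @export
simulate_observed_calls <- function(genotypes, mean_coverage, per_read_error,
                                    seed = NULL) {
  if (!is.numeric(mean_coverage) || mean_coverage <= 0)
    stop("mean_coverage must be positive")
  if (per_read_error < 0 || per_read_error >= 0.5)
    stop("per_read_error must be in [0, 0.5)")
  with_seed(seed, {
    n <- length(genotypes)
    depth <- stats::rpois(n, mean_coverage)
    p <- ifelse(genotypes == 1L, 1 - per_read_error, per_read_error)
    k <- stats::rbinom(n, depth, p)
    frac <- ifelse(depth > 0, k / depth, NA_real_)
    matrix(frac, nrow = nrow(genotypes), dimnames = dimnames(genotypes))
  })
}

#' Simulate replicated phenotype observations with a known genetic fraction
#'
#' Draws `n_genotypes` genotypic values and `n_replicates` observations per
#' genotype such that the genetic variance fraction of an observation is
#' exactly `genetic_fraction` in expectation. Used to check the broad-sense
#' heritability estimator against planted truth.
#'
#' @param n_genotypes,n_replicates grouping structure.
#' @param genetic_fraction fraction of observation variance that is genetic,
#'   in [0, 1].
#' @param seed optional RNG seed.
#' @return data.frame with columns `genotype` (factor) and `value`.
#' @export
simulate_replicated_phenotypes <- function(n_genotypes, n_replicates,
                                           genetic_fraction, seed = NULL) {
  stopifnot(n_genotypes >= 2, n_replicates >= 1,
            genetic_fraction >= 0, genetic_fraction <= 1)
  with_seed(seed, {
    g <- stats::rnorm(n_genotypes, 0, sqrt(genetic_fraction))
    e <- stats::rnorm(n_genotypes * n_replicates, 0, sqrt(1 - genetic_fraction))
    data.frame(genotype = factor(rep(seq_len(n_genotypes), each = n_replicates)),
               value = rep(g, each = n_replicates) + e)
  })
}

#' Expand a count table into synthetic sequencing read records
#'
#' Produces per-read records (sample, barcode, UMI, quality, flank flag) from
#' a small count table so the read-level quantification path (UMI
#' deduplication, quality filtering, Hamming-radius barcode assignment) can be
#' exercised. PCR duplicates share a UMI; a configurable fraction of reads is
#' mutated within the barcode, assigned low quality, or stripped of the
#' landing-pad flank.
#'
#' @param counts samples x barcodes integer matrix (keep small: one row per
#'   read is generated).
#' @param duplication_rate expected extra PCR duplicates per unique molecule.
#' @param error_rate per-read probability of 1-3 substitutions in the barcode.
#' @param low_quality_rate fraction of reads below the quality threshold.
#' @param missing_flank_rate fraction of reads lacking the flank sequence.
#' @param umi_length UMI length in nucleotides.
#' @param seed optional RNG seed.
#' @return data.frame with columns `sample_id`, `barcode`, `umi`, `quality`,
#'   `flank_ok`.
#' @export
simulate_read_records <- function(counts, duplication_rate = 0.2,
                                  error_rate = 0.02, low_quality_rate = 0.02,
                                  missing_flank_rate = 0.01, umi_length = 10,
                                  seed = NULL) {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    out <- vector("list", nrow(counts))
    for (i in seq_len(nrow(counts))) {
      n_mol <- counts[i, ]
      bc <- rep(colnames(counts), n_mol)
      n <- length(bc)
      if (!n) next
      umi <- vapply(seq_len(n), function(j)
        paste0(sample(bases, umi_length, replace = TRUE), collapse = ""), "")
      dup <- stats::rpois(n, duplication_rate)
      idx <- rep(seq_len(n), dup + 1L)
      bc <- bc[idx]; umi <- umi[idx]
      mut <- stats::runif(length(bc)) < error_rate
      if (any(mut)) {
        bc[mut] <- vapply(bc[mut], function(b) {
          ch <- strsplit(b, "")[[1]]
          at <- sample(length(ch), sample(1:3, 1))
          ch[at] <- sample(bases, length(at), replace = TRUE)
          paste0(ch, collapse = "")
        }, "")
      }
      lowq <- stats::runif(length(bc)) < low_quality_rate
      quality <- ifelse(lowq, stats::runif(length(bc), 10, 29.9),
                        stats::runif(length(bc), 30, 40))
      flank_ok <- stats::runif(length(bc)) >= missing_flank_rate
      out[[i]] <- data.frame(sample_id = rownames(counts)[i], barcode = bc,
                             umi = umi, quality = quality, flank_ok = flank_ok,
                             stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    if (is.null(res))
      res <- data.frame(sample_id = character(), barcode = character(),
                        umi = character(), quality = numeric(),
                        flank_ok = logical(), stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
  })
}
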