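# End-to-end runner: simulation (or TSV input) -> persistence -> sample
# filtering -> aggregate and per-sample linkage scans -> consolidation ->
# pleiotropy classification and combinatorial summaries, with a run
# manifest and (on simulated input) a truth-vs-detection scorecard.

#' Assemble and validate a pipeline configuration
#'
#' All parameters of an end-to-end run in one validated list. Either the
#' simulation block is used (the default) or the `*_file` paths point at
#' input TSVs written by the package's writers.
#'
#' @param n_segregants,n_triplicated pool composition.
#' @param n_chromosomes,markers_per_chromosome marker-map dimensions.
#' @param expected_crossovers crossovers per chromosome per meiosis.
#' @param n_general,n_antagonistic,effect_scale planted effect model.
#' @param depth sequencing reads per sample.
#' @param cfu named per-organ expected CFU.
#' @param days,replicates design factors.
#' @param alpha significance level for the sample filter (Bonferroni over
#'   the samples tested).
#' @param n_perm,quantile permutation-threshold settings (the study used
#'   1,000 permutations at the fifth percentile; fewer than 1,000 triggers a
#'   warning).
#' @param drop confidence-interval drop in -log10(P) units.
#' @param min_replicates minimum significant samples per organ.
#' @param exclude sample ids excluded a priori.
#' @param general_enriched,general_depleted,brain_enriched,brain_depleted
#'   allele-dose thresholds.
#' @param scan_samples also run per-sample forward scans and consolidate
#'   them (the aggregate scans always run).
#' @param n_boot bootstrap replicates for effect intervals.
#' @param seed master RNG seed; all stage seeds derive from it.
#' @param out_dir output directory for TSVs and the manifest, or NULL to
#'   skip writing.
#' @param genotypes_file,marker_map_file,assignment_file,counts_file,meta_file
#'   optional input TSVs replacing simulation.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_segregants = 822, n_triplicated = 86,
                            n_chromosomes = 16, markers_per_chromosome = 40,
                            expected_crossovers = 3,
                            n_general = 10, n_antagonistic = 8,
                            effect_scale = 0.15, depth = 5e5,
                            cfu = PERSIST_DEFAULT_CFU, days = c(1, 2, 5),
                            replicates = 3, alpha = 0.05, n_perm = 1000,
                            quantile = 0.05, drop = 2, min_replicates = 2,
                            exclude = character(),
                            general_enriched = 7, general_depleted = 3,
                            brain_enriched = 6, brain_depleted = 3,
                            scan_samples = TRUE, n_boot = 1000, seed = 1,
                            out_dir = NULL,
                            genotypes_file = NULL, marker_map_file = NULL,
                            assignment_file = NULL, counts_file = NULL,
                            meta_file = NULL) {
  stop_if_not_prob(alpha, "alpha")
  stop_if_not_prob(quantile, "quantile")
  stopifnot(drop > 0, n_perm >= 20, seed >= 0, seed == floor(seed))
  if (n_perm < 1000)
    warning("n_perm = ", n_perm,
            " is below the recommended 1,000 permutations")
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full persistence-mapping pipeline
#'
#' Stages: (1) simulate or load inputs; (2) persistence phenotypes with
#' plate correction; (3) within-sample heritability and the ANOVA
#' significance filter (dropping under-replicated organs); (4) across-sample
#' heritability; (5) aggregate brain/nonbrain/difference phenotypes and
#' their forward scans; (6) optional per-sample forward scans consolidated
#' across samples; (7) effect sizes, general-versus-antagonistic
#' classification, allele doses, dose regressions, time-slope contingency
#' tests, and time-course summaries; (8) outputs, manifest, and — when the
#' input is simulated — a truth-versus-detection scorecard.
#'
#' @param config a [pipeline_config()].
#' @param verbose print one line per stage.
#' @return a result bundle (list of class `pipeline_result`).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  t_start <- Sys.time()

  ## stage 1: inputs
  if (!is.null(config$counts_file)) {
    marker_map <- read_marker_map(config$marker_map_file)
    genotypes <- read_genotypes(config$genotypes_file)
    assignment <- read_assignment(config$assignment_file)
    counts <- read_counts(config$counts_file)
    meta <- read_sample_meta(config$meta_file)
    truth <- NULL
    say("inputs: loaded %d samples x %d barcodes from files",
        nrow(counts), ncol(counts))
  } else {
    marker_map <- make_marker_map(config$n_chromosomes,
                                  config$markers_per_chromosome,
                                  seed = derive_seed(config$seed, 1))
    genotypes <- simulate_cross(marker_map, config$n_segregants,
                                config$expected_crossovers,
                                seed = derive_seed(config$seed, 2))
    model <- simulate_effect_model(marker_map, config$n_general,
                                   config$n_antagonistic,
                                   config$effect_scale,
                                   seed = derive_seed(config$seed, 3))
    assignment <- make_barcode_assignment(rownames(genotypes),
                                          config$n_triplicated,
                                          seed = derive_seed(config$seed, 4))
    design <- make_experiment_design(cfu = config$cfu, depth = config$depth,
                                     days = config$days,
                                     replicates = config$replicates)
    sim <- simulate_experiment(genotypes, assignment, model, design,
                               seed = derive_seed(config$seed, 5))
    counts <- sim$counts; meta <- sim$meta; truth <- sim$truth
    say("simulate: %d segregants, %d markers, %d planted loci, %d samples",
        nrow(genotypes), nrow(marker_map), nrow(model$loci), nrow(counts))
  }

  ## stage 2: persistence
  pm <- compute_persistence(counts, meta)
  say("phenotype: %d organ samples x %d barcodes (%d unusable)",
      nrow(pm$persistence), ncol(pm$persistence), length(pm$unusable))

  ## stage 3: significance filter
  filt <- significance_filter(pm, assignment, alpha = config$alpha,
                              exclude = config$exclude)
  filt <- drop_unreplicated_organs(filt, meta,
                                   min_replicates = config$min_replicates)
  kept <- filt$sample_id[filt$keep]
  organ_of <- meta$organ[match(kept, meta$sample_id)]
  brain_samples <- kept[organ_of == "brain"]
  nonbrain_samples <- kept[organ_of %in% c("kidney", "liver", "spleen")]
  say("filter: %d of %d samples significant (%d brain, %d nonbrain)",
      length(kept), nrow(filt), length(brain_samples),
      length(nonbrain_samples))
  if (length(brain_samples) < 1 || length(nonbrain_samples) < 1)
    stop("significance filter left an empty brain or nonbrain group")

  ## one barcode per segregant for everything genetic
  first_bc <- assignment[assignment$replicate_index == 1, ]
  first_bc <- first_bc[match(rownames(genotypes), first_bc$segregant_id), ]

  ## stage 4: across-sample heritability (kept samples, first replicate)
  mat_kept <- pm$persistence[kept, first_bc$barcode, drop = FALSE]
  colnames(mat_kept) <- first_bc$segregant_id
  h2_all <- across_sample_h2(mat_kept)
  h2_brain <- across_sample_h2(mat_kept[brain_samples, , drop = FALSE])
  h2_nonbrain <- across_sample_h2(mat_kept[nonbrain_samples, , drop = FALSE])
  say("heritability: across-sample H2 = %.3f (brain %.3f, nonbrain %.3f)",
      h2_all$H2, h2_brain$H2, h2_nonbrain$H2)

  ## stage 5: aggregate phenotypes and scans
  agg_bc <- aggregate_persistence(pm, brain_samples, nonbrain_samples)
  agg <- agg_bc[match(first_bc$barcode, agg_bc$barcode), ]
  agg$segregant_id <- first_bc$segregant_id
  scans <- list()
  for (ph in c("brain", "nonbrain", "difference")) {
    scans[[ph]] <- forward_scan(agg[[ph]], genotypes, marker_map,
                                n_perm = config$n_perm,
                                quantile = config$quantile,
                                drop = config$drop,
                                seed = derive_seed(config$seed, 10 + match(
                                  ph, c("brain", "nonbrain", "difference"))),
                                scan_id = ph)
    say("scan[%s]: %d loci in %d stage(s)", ph,
        nrow(scans[[ph]]$detections), length(scans[[ph]]$stage_thresholds))
  }
  agg_detections <- do.call(rbind, lapply(scans, function(s) s$detections))
  agg_cons <- consolidate(agg_detections)
  say("aggregate consolidation: %d unique loci from %d detections",
      nrow(agg_cons$loci), nrow(agg_detections))

  ## difference-measurement H2 via deterministic sample pairing
  h2_diff <- difference_h2(mat_kept, brain_samples, nonbrain_samples)
  varexp <- c(
    brain = variance_explained(agg$brain, genotypes,
                               scans$brain$detections$peak_index, h2_brain$H2),
    nonbrain = variance_explained(agg$nonbrain, genotypes,
                                  scans$nonbrain$detections$peak_index,
                                  h2_nonbrain$H2),
    difference = variance_explained(agg$difference, genotypes,
                                    scans$difference$detections$peak_index,
                                    h2_diff))
  say("variance explained: brain %.1f%%, nonbrain %.1f%%, difference %.1f%%",
      varexp["brain"], varexp["nonbrain"], varexp["difference"])

  ## stage 6: per-sample scans
  sample_scans <- NULL; sample_cons <- NULL
  if (isTRUE(config$scan_samples)) {
    sample_scans <- lapply(seq_along(kept), function(k) {
      y <- pm$persistence[kept[k], first_bc$barcode]
      forward_scan(y, genotypes, marker_map, n_perm = config$n_perm,
                   quantile = config$quantile, drop = config$drop,
                   seed = derive_seed(config$seed, 100 + k),
                   scan_id = kept[k])
    })
    names(sample_scans) <- kept
    sample_detections <- do.call(rbind,
                                 lapply(sample_scans, function(s) s$detections))
    if (!is.null(sample_detections) && nrow(sample_detections)) {
      sample_cons <- consolidate(sample_detections)
      say("per-sample scans: %d detections -> %d consolidated loci",
          nrow(sample_detections), nrow(sample_cons$loci))
    } else say("per-sample scans: no detections")
  }

  ## stage 7: effects, classification, combinatorics
  contexts <- list(brain = agg$brain, nonbrain = agg$nonbrain)
  eff_tab <- locus_effect_table(agg_cons, genotypes, contexts,
                                n_boot = config$n_boot,
                                seed = derive_seed(config$seed, 20))
  eff_wide <- data.frame(
    locus_id = agg_cons$loci$locus_id,
    marker_id = agg_cons$loci$effect_marker,
    chrom = agg_cons$loci$chrom,
    brain_delta = eff_tab$delta[eff_tab$context == "brain"],
    nonbrain_delta = eff_tab$delta[eff_tab$context == "nonbrain"],
    stringsAsFactors = FALSE)
  classified <- classify_loci(eff_wide)
  say("classification: %d general, %d antagonistic",
      sum(classified$class == "general"),
      sum(classified$class == "antagonistic"))
  dose <- allele_dose(genotypes, classified,
                      general_enriched = config$general_enriched,
                      general_depleted = config$general_depleted,
                      brain_enriched = config$brain_enriched,
                      brain_depleted = config$brain_depleted)
  dose_reg <- run_dose_regressions(agg, dose)
  slopes <- segregant_time_slopes(pm, first_bc, brain_samples,
                                  nonbrain_samples, meta)
  conting <- run_contingency(dose, slopes)
  # empty focal groups simply drop out of the summary here
  tc_brain <- tryCatch(
    suppressWarnings(
      timecourse_summary(pm, brain_samples, dose, first_bc$barcode,
                         n_boot = config$n_boot,
                         seed = derive_seed(config$seed, 21))),
    error = function(e) NULL)

  ## stage 8: scorecard + outputs
  scorecard <- if (!is.null(truth))
    score_detections(truth$effect_model, agg_detections, genotypes,
                     contexts) else NULL
  if (!is.null(scorecard))
    say("scorecard: recall %.2f, sign concordance %.2f",
        scorecard$recall, scorecard$sign_concordance)

  result <- structure(list(
    config = config, marker_map = marker_map, genotypes = genotypes,
    assignment = assignment, counts = counts, meta = meta, truth = truth,
    persistence = pm, filter = filt, kept_samples = kept,
    brain_samples = brain_samples, nonbrain_samples = nonbrain_samples,
    h2 = list(all = h2_all, brain = h2_brain, nonbrain = h2_nonbrain,
              difference = h2_diff),
    aggregate = agg, scans = scans, agg_detections = agg_detections,
    agg_consolidated = agg_cons, sample_scans = sample_scans,
    sample_consolidated = sample_cons, effects = eff_tab,
    classified = classified, dose = dose, dose_regressions = dose_reg,
    time_slopes = slopes, contingency = conting,
    timecourse_brain = tc_brain, variance_explained = varexp,
    scorecard = scorecard,
    elapsed = as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  say("done in %.1f s", result$elapsed)
  result
}

# H2 of the brain-minus-nonbrain difference measurement: deterministic
# pairing of kept brain and nonbrain samples (sorted order, recycled) gives
# per-pair difference replicates over which the usual across-sample
# decomposition applies.
difference_h2 <- function(mat_kept, brain_samples, nonbrain_samples) {
  nb <- sort(brain_samples); nn <- sort(nonbrain_samples)
  k <- max(length(nb), length(nn))
  bi <- rep_len(seq_along(nb), k); ni <- rep_len(seq_along(nn), k)
  diffs <- mat_kept[nb[bi], , drop = FALSE] - mat_kept[nn[ni], , drop = FALSE]
  rownames(diffs) <- sprintf("pair%03d", seq_len(k))
  across_sample_h2(diffs)$H2
}

run_dose_regressions <- function(agg, dose) {
  out <- list()
  for (ctx in c("brain", "nonbrain")) {
    for (cnt in c("n_general_beneficial", "n_brain_favoring")) {
      r <- tryCatch(dose_regression(agg[[ctx]], dose[[cnt]]),
                    error = function(e) NULL)
      if (!is.null(r))
        out[[paste(ctx, cnt, sep = ".")]] <- data.frame(
          context = ctx, count = cnt, slope = r$slope,
          r_squared = r$r_squared, P = r$P, n = r$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

segregant_time_slopes <- function(pm, first_bc, brain_samples,
                                  nonbrain_samples, meta) {
  slope_in <- function(samples) {
    days <- meta$day[match(samples, meta$sample_id)]
    apply(pm$persistence[samples, first_bc$barcode, drop = FALSE], 2,
          function(v) tryCatch(time_slope(v, days), error = function(e) NA_real_))
  }
  data.frame(segregant_id = first_bc$segregant_id,
             brain_slope = slope_in(brain_samples),
             nonbrain_slope = slope_in(nonbrain_samples),
             row.names = NULL, stringsAsFactors = FALSE)
}

run_contingency <- function(dose, slopes) {
  res <- list()
  # context-appropriate pleiotropic enrichment: many brain-favoring alleles
  # for the brain, few for the nonbrain organs
  both_brain <- dose$general_class == "enriched" & dose$brain_class == "enriched"
  both_nonbrain <- dose$general_class == "enriched" & dose$brain_class == "depleted"
  res$brain <- tryCatch(
    enrichment_contingency(both_brain, slopes$brain_slope > 0),
    error = function(e) NULL)
  res$nonbrain <- tryCatch(
    enrichment_contingency(both_nonbrain, slopes$nonbrain_slope > 0),
    error = function(e) NULL)
  res
}

#' Score aggregate detections against simulation truth
#'
#' A planted locus is recovered when some aggregate-scan detection on its
#' chromosome covers the planted marker with its confidence interval or
#' peaks within `match_window` of it. Sign concordance classifies the
#' matched detection at its own peak marker (general versus antagonistic
#' from the brain/nonbrain allele effects there) and compares with the
#' planted class; classifying at the peak rather than at a consolidated
#' locus keeps linked planted loci that merge during consolidation
#' separately scorable. Peak distance is the matched peak-to-truth distance.
#'
#' @param effect_model planted `effect_model`.
#' @param detections row-bound aggregate detection table.
#' @param genotypes segregants x markers matrix.
#' @param contexts named list with `brain` and `nonbrain` aggregate
#'   phenotype vectors aligned with the genotype rows.
#' @param match_window max peak-to-truth distance (bp) counted as a match.
#' @return list: `recall`, `sign_concordance`, `ci_coverage`, `per_locus`
#'   data.frame.
#' @export
score_detections <- function(effect_model, detections, genotypes, contexts,
                             match_window = 50000) {
  loci <- effect_model$loci
  if (!nrow(loci))
    return(list(recall = NA_real_, sign_concordance = NA_real_,
                ci_coverage = NA_real_, per_locus = NULL))
  # each detection belongs to the planted locus nearest its peak, so a wide
  # interval from one locus cannot claim recovery of a linked neighbour
  owner <- vapply(seq_len(nrow(detections)), function(k) {
    same <- which(loci$chrom == detections$chrom[k])
    if (!length(same)) return(NA_integer_)
    same[which.min(abs(loci$pos[same] - detections$peak_pos[k]))]
  }, integer(1))
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    cand <- detections[!is.na(owner) & owner == i, , drop = FALSE]
    if (!nrow(cand))
      return(data.frame(locus_id = loci$locus_id[i], recovered = FALSE,
                        in_ci = NA, peak_distance = NA_real_,
                        class_match = NA, stringsAsFactors = FALSE))
    dist <- abs(cand$peak_pos - loci$pos[i])
    j <- which.min(dist)
    in_ci <- cand$ci_start_pos[j] <= loci$pos[i] &
      cand$ci_end_pos[j] >= loci$pos[i]
    recovered <- in_ci || dist[j] <= match_window
    cls <- NA
    if (recovered) {
      allele <- genotypes[, cand$peak_marker[j]]
      est <- classify_locus(
        locus_effect(contexts$brain, allele)$delta,
        locus_effect(contexts$nonbrain, allele)$delta)
      cls <- est$class == loci$class[i]
    }
    data.frame(locus_id = loci$locus_id[i], recovered = recovered,
               in_ci = in_ci, peak_distance = dist[j], class_match = cls,
               stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, rows)
  rec <- per_locus$recovered
  list(recall = mean(rec),
       sign_concordance = if (any(rec, na.rm = TRUE))
         mean(per_locus$class_match[rec], na.rm = TRUE) else NA_real_,
       ci_coverage = if (any(rec, na.rm = TRUE))
         mean(per_locus$in_ci[rec], na.rm = TRUE) else NA_real_,
       per_locus = per_locus)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_marker_map(result$marker_map, p("marker_map.tsv"))
  write_genotypes(result$genotypes, p("genotypes.tsv"))
  write_assignment(result$assignment, p("barcodes.tsv"))
  write_counts(result$counts, p("counts.tsv"))
  write_sample_meta(result$meta, p("sample_meta.tsv"))
  write_counts(result$persistence$persistence, p("persistence.tsv"))
  write_tsv(result$filter, p("sample_filter.tsv"))
  write_tsv(result$aggregate, p("aggregate_phenotypes.tsv"))
  write_tsv(result$agg_detections, p("aggregate_detections.tsv"))
  write_tsv(result$agg_consolidated$loci, p("aggregate_loci.tsv"))
  if (!is.null(result$sample_consolidated)) {
    write_tsv(result$sample_consolidated$members, p("sample_detections.tsv"))
    write_tsv(result$sample_consolidated$loci, p("sample_loci.tsv"))
  }
  write_tsv(result$effects, p("locus_effects.tsv"))
  write_tsv(result$classified, p("locus_classes.tsv"))
  write_tsv(result$dose, p("allele_dose.tsv"))
  if (!is.null(result$dose_regressions))
    write_tsv(result$dose_regressions, p("dose_regressions.tsv"))
  write_tsv(result$time_slopes, p("time_slopes.tsv"))
  if (!is.null(result$truth))
    write_effect_model(result$truth$effect_model, p("truth_effect_model.tsv"))
  if (!is.null(result$scorecard))
    write_tsv(result$scorecard$per_locus, p("scorecard.tsv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("persistqtl")),
    seed = result$config$seed,
    config = result$config[!vapply(result$config, is.null, TRUE) &
                             !names(result$config) %in% "cfu"],
    cfu = as.list(result$config$cfu),
    records = list(samples = nrow(result$counts),
                   barcodes = ncol(result$counts),
                   markers = nrow(result$marker_map),
                   kept_samples = length(result$kept_samples),
                   aggregate_detections = nrow(result$agg_detections),
                   aggregate_loci = nrow(result$agg_consolidated$loci)),
    h2 = list(all = result$h2$all$H2, brain = result$h2$brain$H2,
              nonbrain = result$h2$nonbrain$H2,
              difference = result$h2$difference),
    variance_explained = as.list(result$variance_explained))
  manifest$config$out_dir <- NULL
  class(manifest$config) <- NULL
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("persistqtl pipeline result\n")
  cat(sprintf("  samples: %d (%d kept: %d brain, %d nonbrain)\n",
              nrow(x$counts), length(x$kept_samples),
              length(x$brain_samples), length(x$nonbrain_samples)))
  cat(sprintf("  across-sample H2: all %.3f, brain %.3f, nonbrain %.3f\n",
              x$h2$all$H2, x$h2$brain$H2, x$h2$nonbrain$H2))
  cat(sprintf("  aggregate loci: %d (%d general, %d antagonistic)\n",
              nrow(x$classified), sum(x$classified$class == "general"),
              sum(x$classified$class == "antagonistic")))
  cat(sprintf("  variance explained: brain %.1f%%, nonbrain %.1f%%, difference %.1f%%\n",
              x$variance_explained["brain"], x$variance_explained["nonbrain"],
              x$variance_explained["difference"]))
  if (!is.null(x$scorecard))
    cat(sprintf("  scorecard: recall %.2f, sign concordance %.2f, CI coverage %.2f\n",
                x$scorecard$recall, x$scorecard$sign_concordance,
                x$scorecard$ci_coverage))
  invisible(x)
}

#' Run a small end-to-end demonstration
#'
#' Simulates a reduced instance of the full design (fewer segregants and
#' markers, fewer permutations) and runs the complete pipeline, writing all
#' outputs to `out_dir`. Two runs with the same seed produce byte-identical
#' outputs.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param verbose print stage progress.
#' @return the `pipeline_result`, invisibly.
#' @export
run_demo <- function(out_dir, seed = 1, verbose = TRUE) {
  cfg <- suppressWarnings(pipeline_config(
    n_segregants = 240, n_triplicated = 40, markers_per_chromosome = 12,
    depth = 1e5, n_perm = 200, n_boot = 200, scan_samples = FALSE,
    seed = seed, out_dir = out_dir))
  invisible(run_pipeline(cfg, verbose = verbose))
}
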