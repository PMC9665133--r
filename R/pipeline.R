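# End-to-end orchestration: run every stage on a synthetic study (or
# user-supplied tables) with one config, collect filter audits and test
# results into a machine-readable run report.

#' Default pipeline run configuration
#'
#' Every analysis threshold with its standard default: CHiCAGO-style score
#' minimum 5, SRI/LRI boundary 1 Mb, retention bound 2 Mb, 50-kb
#' concordance bins with a 10-interaction minimum, 100-kb compartment bins
#' with 3-bin smoothing, 10,000 permutations, top 5000 genes for
#' time-point matching, MAF >= 0.05, HWE p >= 1e-5, info >= 0.8,
#' LD R^2 < 0.2, FDR 0.05 and expressed-fraction 0.90. All values are
#' recorded in the run report.
#'
#' @param seed Integer seed used for the simulation and the permutation
#'   test.
#' @param ... Overrides for any listed threshold.
#' @return Named list of thresholds.
#' @export
run_config <- function(seed = 1, ...) {
  cfg <- list(seed = seed, score_min = 5, sri_max = 1e6, lri_max = 2e6,
              concordance_bin = 5e4, min_union = 10,
              compartment_bin = 1e5, smoothing_window = 3,
              n_permutations = 10000, top_n = 5000,
              maf_min = 0.05, hwe_p_min = 1e-5, info_min = 0.8,
              r2_max = 0.2, fdr = 0.05, expressed_fraction = 0.90,
              expressed_threshold = 0)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  cfg
}

#' Run the full downstream pipeline on a synthetic study
#'
#' Simulates a study from the seed (or accepts a pre-built one), then runs
#' every stage in dependency order: significance filtering with audit,
#' replicate concordance, time-point sharing, read-support summaries, LRI
#' proportion fold changes, TAD classification and state coverage with the
#' quiescent rank-sum test, boundary crossing, the marker-gene category
#' test, A/B compartment calling and B-in-LRI-TAD enrichment, feature
#' permutation and hypergeometric enrichment, the expression tests, and
#' the interaction-restricted eQTL analysis.
#'
#' @param config From [run_config()].
#' @param study Optional pre-built [simulate_study()] output; by default
#'   one is simulated from `synthetic_config(seed = config$seed)`.
#' @return Run report: nested list with a `thresholds` element recording
#'   every threshold used, per-stage results, and all filter audits.
#'   Serialize with [jsonlite::toJSON()] for a machine-readable record.
#' @export
run_pipeline <- function(config = run_config(), study = NULL) {
  if (is.null(study)) {
    study <- simulate_study(synthetic_config(seed = config$seed))
  }
  scfg <- study$config
  tps <- scfg$timepoints
  report <- list(thresholds = config)

  ## -- interactions stage ------------------------------------------------
  filt <- lapply(tps, function(tp) {
    lapply(study$interactions[[tp]], function(rep) {
      filter_significant(rep, config$score_min,
                         max_distance = config$lri_max)
    })
  })
  names(filt) <- tps
  report$interactions <- lapply(tps, function(tp) {
    f1 <- filt[[tp]]$rep1
    conc <- replicate_concordance(f1, filt[[tp]]$rep2,
                                  config$concordance_bin, config$min_union)
    cls <- classify_distance(f1, config$sri_max, config$lri_max)
    rs <- read_support_summary(f1, config$sri_max, config$lri_max)
    list(filter_audit = as.list(attr(f1, "filter_audit")),
         n_significant = nrow(f1),
         lri_proportion = mean(cls == "LRI"),
         concordance_median = stats::median(conc$proportion, na.rm = TRUE),
         read_support = rs)
  })
  names(report$interactions) <- tps
  lri_prop <- vapply(report$interactions, `[[`, 0, "lri_proportion")
  report$lri_fold_changes <- stats::setNames(
    proportion_fold_change(lri_prop[-length(lri_prop)], lri_prop[-1]),
    paste(tps[-length(tps)], tps[-1], sep = "_to_"))
  report$sharing <- timepoint_sharing(
    stats::setNames(lapply(tps, function(tp) filt[[tp]]$rep1), tps),
    restrict_to = "LRI",
    sri_max = config$sri_max, lri_max = config$lri_max)

  ## -- TAD stage ---------------------------------------------------------
  ends_of <- function(x, class = NULL) {
    if (!is.null(class)) {
      x <- x[classify_distance(x, config$sri_max, config$lri_max) == class, ]
    }
    data.frame(chrom = c(x$bait_chrom, x$oe_chrom),
               start = c(x$bait_start, x$oe_start),
               end = c(x$bait_end, x$oe_end), stringsAsFactors = FALSE)
  }
  lri_ends <- stats::setNames(
    lapply(tps, function(tp) ends_of(filt[[tp]]$rep1, "LRI")), tps)
  all_ends <- do.call(rbind, lapply(tps, function(tp) ends_of(filt[[tp]]$rep1)))
  ann <- classify_tads(lri_ends, all_ends, study$layout$tads)
  cat_counts <- table(ann$category)
  n_lri_tads <- sum(!ann$category %in% c("excluded", "non-LRI"))
  catp <- category_percentages(ann)
  report$tads <- list(
    category_counts = as.list(cat_counts),
    n_lri_tads = n_lri_tads,
    pct_by_timepoints = catp,
    pct_two_timepoints = if (2 %in% catp$n_timepoints)
      catp$percent[catp$n_timepoints == 2] else 0,
    boundary_crossing = boundary_crossing_fraction(filt[[tps[1]]]$rep1,
                                                   study$layout$tads))
  cov <- tad_state_coverage(study$layout$tads, study$states)
  is_lri_tad <- !ann$category %in% c("excluded", "non-LRI")
  is_non <- ann$category == "non-LRI"
  report$tads$quiescent_test <- compare_tad_coverage(
    cov$quiescent[is_lri_tad], cov$quiescent[is_non])

  mk <- generate_markers_and_features(scfg, study$layout, ann)
  report$tads$marker_test <- tryCatch({
    r <- marker_gene_category_test(mk$markers, ann, study$layout$tads)
    list(statistic = r$statistic, dof = r$dof, p_value = r$p_value,
         dropped = r$dropped_categories)
  }, error = function(e) list(error = conditionMessage(e)))

  ## -- compartments ------------------------------------------------------
  acc <- study$accessibility
  bins <- bin_accessibility(acc$reads, study$layout$chrom_lengths,
                            config$compartment_bin)
  bins <- normalize_and_correct(bins, acc$meta)
  bins <- call_compartments(bins, config$smoothing_window)
  called <- bins$bins$label != "excluded"
  agree <- mean(bins$bins$label[called] ==
                acc$truth_labels$label[called])
  report$compartments <- list(
    n_bins = nrow(bins$bins), n_called = sum(called),
    planted_label_agreement = max(agree, 1 - agree),
    degenerate_chroms = bins$degenerate_chroms)
  b_enr <- compartment_lri_tad_enrichment(bins, ann, study$layout$tads)
  b_enr$coverage <- NULL
  report$compartments$lri_tad_b_enrichment <- b_enr

  ## -- feature enrichment ------------------------------------------------
  eligible <- ann$tad_id[ann$category != "excluded"]
  lri_ids <- ann$tad_id[is_lri_tad]
  perm <- permutation_test(mk$features, study$layout$tads, lri_ids,
                           eligible_tad_ids = eligible,
                           n_permutations = config$n_permutations,
                           seed = config$seed)
  k <- count_feature_tad_cooccurrence(mk$features, study$layout$tads,
                                      lri_ids)
  report$enrichment <- list(
    observed = perm$observed, permutation_p = perm$p_value,
    n_permutations = perm$n_permutations,
    hypergeometric_p = tryCatch(
      hypergeometric_test(k, nrow(mk$features), length(lri_ids),
                          length(eligible)),
      error = function(e) conditionMessage(e)))

  ## -- expression --------------------------------------------------------
  expr <- study$expression
  match_res <- match_timepoints_by_correlation(expr$reference, expr$query,
                                               config$top_n)
  report$expression <- list(timepoint_match = as.list(match_res$best))
  last_tp <- tps[length(tps)]
  classes <- classify_genes_by_interaction(study$layout$genes,
                                           filt[[last_tp]]$rep1,
                                           config$sri_max, config$lri_max)
  report$expression$class_counts <- as.list(table(classes$class))
  report$expression$expressed_fraction_test <- tryCatch({
    r <- expressed_fraction_test(classes, expr$query, last_tp,
                                 config$expressed_threshold)
    list(statistic = r$statistic, p_value = r$p_value)
  }, error = function(e) list(error = conditionMessage(e)))
  tp_map <- stats::setNames(tps, tps)  # query columns named by time point
  report$expression$level_test <-
    expression_level_test(classes, expr$query, tp_map)
  report$expression$bystander_test <- tryCatch(
    bystander_gene_test(study$layout$genes, classes, ann,
                        study$layout$tads, expr$query, tp_map),
    error = function(e) list(error = conditionMessage(e)))

  ## -- eQTL --------------------------------------------------------------
  eq <- run_eqtl(expr$individual, study$geno, study$layout$genes,
                 filt[[last_tp]]$rep1,
                 min_fraction = config$expressed_fraction,
                 maf_min = config$maf_min, hwe_p_min = config$hwe_p_min,
                 info_min = config$info_min, r2_max = config$r2_max,
                 fdr = config$fdr)
  sig_long <- eq$long[!is.na(eq$long$p_adj) & eq$long$p_adj < 0.05, ,
                      drop = FALSE]
  pe <- study$truth$planted_eqtl
  report$eqtl <- list(
    n_supported_long = nrow(eq$long), n_supported_short = nrow(eq$short),
    n_independent = if (nrow(eq$long)) eq$long$n_independent[1] else 0,
    n_significant_long = nrow(sig_long),
    snp_filter_audit = as.list(eq$snp_filter_audit),
    planted_detected = !is.null(pe) && !is.na(pe$snp_id) &&
      any(sig_long$snp_id == pe$snp_id & sig_long$gene_id == pe$gene_id))
  report
}

#' Serialize a run report to JSON
#'
#' @param report Output of [run_pipeline()].
#' @param path Output file path.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
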