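# Integration of external RNA-seq with the interaction classes: matching
# time points by rank correlation, and the SRI-vs-LRI expression tests.

#' Match query time points to reference time points by expression
#'
#' For each query column, takes the `top_n` most highly expressed genes of
#' each reference column (by that reference column's values, over the genes
#' shared between the matrices), computes the Spearman correlation between
#' query and reference over those genes, and reports the best reference
#' column together with the full correlation profile.
#'
#' @param reference,query Expression matrices (genes x samples, gene ids as
#'   row names, non-negative values).
#' @param top_n Number of top expressed genes per reference column
#'   (default 5000; lowered with a warning when fewer genes are shared).
#' @return List: `best` (named character vector query -> reference) and
#'   `profile` (query x reference correlation matrix).
#' @export
match_timepoints_by_correlation <- function(reference, query, top_n = 5000) {
  shared <- intersect(rownames(reference), rownames(query))
  if (!length(shared)) stop("no shared genes", call. = FALSE)
  if (length(shared) < top_n) {
    warning("only ", length(shared), " shared genes; lowering top_n")
    top_n <- length(shared)
  }
  ref <- reference[shared, , drop = FALSE]
  qry <- query[shared, , drop = FALSE]
  profile <- matrix(NA_real_, ncol(qry), ncol(ref),
                    dimnames = list(colnames(qry), colnames(ref)))
  for (j in seq_len(ncol(ref))) {
    top <- order(ref[, j], decreasing = TRUE)[seq_len(top_n)]
    for (i in seq_len(ncol(qry))) {
      profile[i, j] <- stats::cor(qry[top, i], ref[top, j],
                                  method = "spearman")
    }
  }
  best <- colnames(ref)[apply(profile, 1, which.max)]
  names(best) <- rownames(profile)
  list(best = best, profile = profile)
}

#' Classify genes by the distance class of their promoter interactions
#'
#' A gene's class is determined by the interactions whose bait is the
#' gene's promoter fragment: `SRI-only`, `LRI-only`, `both`, or `neither`
#' (no baited interaction). Interactions in the `excluded` distance class
#' are ignored.
#'
#' @param genes Gene table with `gene_id` and `bait_fragment_id`.
#' @param interactions Filtered, intra-chromosomal interaction table.
#' @param sri_max,lri_max Distance-class bounds.
#' @return Data.frame `gene_id`, `class`.
#' @export
classify_genes_by_interaction <- function(genes, interactions,
                                          sri_max = 1e6, lri_max = 2e6) {
  cls <- classify_distance(interactions, sri_max, lri_max)
  sri_baits <- unique(interactions$bait_id[cls == "SRI"])
  lri_baits <- unique(interactions$bait_id[cls == "LRI"])
  in_sri <- genes$bait_fragment_id %in% sri_baits
  in_lri <- genes$bait_fragment_id %in% lri_baits
  data.frame(gene_id = genes$gene_id,
             class = ifelse(in_sri & in_lri, "both",
                     ifelse(in_sri, "SRI-only",
                     ifelse(in_lri, "LRI-only", "neither"))),
             stringsAsFactors = FALSE)
}

arm_values <- function(classes, expr, column, threshold = NULL) {
  pick <- function(label) {
    g <- intersect(classes$gene_id[classes$class == label], rownames(expr))
    expr[g, column]
  }
  list(sri = pick("SRI-only"), lri = pick("LRI-only"))
}

#' Are LRI genes less likely to be expressed than SRI genes?
#'
#' Builds the 2x2 table of expressed (value above `threshold` in the
#' matched time point) by interaction class (SRI-only vs LRI-only; genes in
#' both classes are excluded) and applies the Pearson chi-square test
#' without continuity correction.
#'
#' @param classes Output of [classify_genes_by_interaction()].
#' @param expr Expression matrix (genes x time-point columns).
#' @param timepoint_column Column of `expr` matched to the interaction
#'   time point.
#' @param threshold Expression cutoff; expressed means value strictly
#'   greater (default 0).
#' @return List: `table` (2x2 class x expressed), `statistic`, `p_value`.
#' @export
expressed_fraction_test <- function(classes, expr, timepoint_column,
                                    threshold = 0) {
  av <- arm_values(classes, expr, timepoint_column)
  if (!length(av$sri) || !length(av$lri)) {
    stop("need non-empty SRI-only and LRI-only classes", call. = FALSE)
  }
  tab <- rbind(SRI = table(factor(av$sri > threshold, c(FALSE, TRUE))),
               LRI = table(factor(av$lri > threshold, c(FALSE, TRUE))))
  colnames(tab) <- c("not_expressed", "expressed")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table (zero margin)", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, statistic = unname(ht$statistic), p_value = ht$p.value)
}

welch_log2 <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    return(list(t = NA_real_, p_value = NA_real_,
                mean_diff_log2 = NA_real_))
  }
  la <- log2(a + 1); lb <- log2(b + 1)
  if (stats::sd(la) == 0 && stats::sd(lb) == 0 && mean(la) == mean(lb)) {
    return(list(t = 0, p_value = 1, mean_diff_log2 = 0))
  }
  ht <- stats::t.test(la, lb)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       mean_diff_log2 = mean(la) - mean(lb))
}

#' Expression level of LRI vs SRI genes, per time point
#'
#' Welch two-sample t-test on log2(value + 1) between LRI-only and
#' SRI-only genes at each time point, with Bonferroni adjustment over the
#' time points tested (`p_adj = min(1, p * n_timepoints)`); optionally
#' Benjamini-Hochberg.
#'
#' @param classes Output of [classify_genes_by_interaction()].
#' @param expr Expression matrix.
#' @param timepoint_map Named character vector: interaction time point ->
#'   column of `expr`.
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @return Data.frame per time point: `timepoint`, `n_lri`, `n_sri`, `t`
#'   (LRI minus SRI direction), `mean_diff_log2`, `p_value`, `p_adj`.
#' @export
expression_level_test <- function(classes, expr, timepoint_map,
                                  adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  rows <- lapply(names(timepoint_map), function(tp) {
    av <- arm_values(classes, expr, timepoint_map[[tp]])
    w <- welch_log2(av$lri, av$sri)
    data.frame(timepoint = tp, n_lri = length(av$lri),
               n_sri = length(av$sri), t = w$t,
               mean_diff_log2 = w$mean_diff_log2, p_value = w$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust == "bonferroni") {
    pmin(1, out$p_value * sum(!is.na(out$p_value)))
  } else {
    stats::p.adjust(out$p_value, "BH")
  }
  out
}

#' Bystander-gene expression test
#'
#' Tests whether genes inside LRI TADs, but not themselves involved in
#' LRIs (SRI-only genes), are expressed lower than SRI-only genes in
#' non-LRI TADs — per time point, with the same Welch/log2 machinery and
#' Bonferroni adjustment as [expression_level_test()]. Arm membership uses
#' the TAD's LRI flag at the matching time point.
#'
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`).
#' @param classes Output of [classify_genes_by_interaction()].
#' @param annotations TAD annotation table from [classify_tads()].
#' @param tads TAD table.
#' @param expr Expression matrix.
#' @param timepoint_map Named character vector: time point -> expr column.
#' @return Data.frame per time point: `timepoint`, `n_in_lri_tad`,
#'   `n_in_non_lri_tad`, `t` (LRI-TAD minus non-LRI-TAD), `mean_diff_log2`,
#'   `p_value`, `p_adj`.
#' @export
bystander_gene_test <- function(genes, classes, annotations, tads, expr,
                                timepoint_map) {
  sri_only <- classes$gene_id[classes$class == "SRI-only"]
  g <- genes[genes$gene_id %in% sri_only, , drop = FALSE]
  idx <- assign_to_intervals(g$chrom, interval_midpoint(g$start, g$end), tads)
  g <- g[!is.na(idx), , drop = FALSE]
  tad_of_gene <- tads$tad_id[idx[!is.na(idx)]]
  ann <- annotations[match(tad_of_gene, annotations$tad_id), ]
  rows <- lapply(names(timepoint_map), function(tp) {
    flag_col <- paste0("lri_", tp)
    if (!flag_col %in% names(ann)) {
      stop("no LRI flag for time point ", tp, call. = FALSE)
    }
    eligible <- ann$category != "excluded"
    in_lri <- eligible & ann[[flag_col]]
    in_non <- eligible & !ann[[flag_col]]
    if (!any(in_lri) || !any(in_non)) {
      stop("all genes fall in one arm at time point ", tp, call. = FALSE)
    }
    col <- timepoint_map[[tp]]
    a <- expr[intersect(g$gene_id[in_lri], rownames(expr)), col]
    b <- expr[intersect(g$gene_id[in_non], rownames(expr)), col]
    w <- welch_log2(a, b)
    data.frame(timepoint = tp, n_in_lri_tad = length(a),
               n_in_non_lri_tad = length(b), t = w$t,
               mean_diff_log2 = w$mean_diff_log2, p_value = w$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_value * sum(!is.na(out$p_value)))
  out
}
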