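# TAD-level annotation: which TADs contain LRI ends per time point, what
# fraction of each TAD the grouped chromHMM states cover, and whether cell
# type marker genes distribute differentially across LRI-TAD categories.

#' Default grouping of the Roadmap 25-state chromHMM model
#'
#' Maps chromHMM state labels to the four summary groups used in TAD
#' coverage analysis. States not listed fall into `"other"`.
#'
#' @return Named character vector: state label -> group in
#'   `{promoter, active, enhancer, quiescent}`.
#' @export
default_state_groups <- function() {
  c(TssA = "promoter", PromU = "promoter", PromD1 = "promoter",
    PromD2 = "promoter",
    "Tx5'" = "active", Tx = "active", "Tx3'" = "active", TxWk = "active",
    TxReg = "active", "TxEnh5'" = "active", "TxEnh3'" = "active",
    TxEnhW = "active",
    EnhA1 = "enhancer", EnhA2 = "enhancer", EnhAF = "enhancer",
    EnhW1 = "enhancer", EnhW2 = "enhancer", EnhAc = "enhancer",
    Quies = "quiescent")
}

state_group_of <- function(states, groups = default_state_groups()) {
  g <- unname(groups[states])
  g[is.na(g)] <- "other"
  g
}

# tie-break order for fragment state assignment (first wins)
.group_order <- c("quiescent", "promoter", "enhancer", "active", "other")

#' Classify TADs by their long-range interaction content
#'
#' A fragment lies "within" a TAD when its midpoint falls inside the TAD
#' interval. A TAD is an LRI TAD at a time point when at least one LRI end
#' (bait or other-end fragment of a long-range interaction) lies within it.
#' TADs with no interaction ends at all are `excluded`; TADs with
#' interaction ends but no LRI ends are `non-LRI`; otherwise the category
#' names the time points contributing LRI ends (`all` when every time point
#' does).
#'
#' @param lri_ends_by_timepoint Named list (one element per time point) of
#'   fragment tables (`chrom`, `start`, `end`) holding the ends of LRIs.
#' @param all_interaction_ends Fragment table of the ends of every
#'   significant interaction (any class, any time point).
#' @param tads TAD table: `chrom`, `start`, `end`, `tad_id`.
#' @return Data.frame with `tad_id`, one logical `lri_<timepoint>` column
#'   per time point, `has_any_interaction`, `n_timepoints` and `category`.
#' @export
classify_tads <- function(lri_ends_by_timepoint, all_interaction_ends, tads) {
  tps <- names(lri_ends_by_timepoint)
  stopifnot(!is.null(tps), all(nzchar(tps)), !anyDuplicated(tads$tad_id))
  in_tad <- function(frags) {
    idx <- assign_to_intervals(frags$chrom,
                               interval_midpoint(frags$start, frags$end),
                               tads)
    tads$tad_id %in% tads$tad_id[idx[!is.na(idx)]]
  }
  flags <- vapply(lri_ends_by_timepoint, in_tad, logical(nrow(tads)))
  flags <- matrix(flags, nrow = nrow(tads),
                  dimnames = list(NULL, tps))
  has_any <- in_tad(all_interaction_ends)
  n_tp <- rowSums(flags)
  category <- ifelse(!has_any, "excluded",
              ifelse(n_tp == 0, "non-LRI",
              ifelse(n_tp == length(tps), "all",
                     apply(flags, 1, function(f) {
                       if (sum(f) == 1) paste(tps[f], "only")
                       else paste(tps[f], collapse = " and ")
                     }))))
  out <- data.frame(tad_id = tads$tad_id, stringsAsFactors = FALSE)
  for (tp in tps) out[[paste0("lri_", tp)]] <- flags[, tp]
  out$has_any_interaction <- has_any
  out$n_timepoints <- n_tp
  out$category <- category
  out
}

# total bp of `segments` of each group overlapping [start, end) on chrom
group_overlap_bp <- function(chrom, start, end, segments, groups) {
  on <- segments[segments$chrom == chrom &
                 segments$end > start & segments$start < end, , drop = FALSE]
  if (!nrow(on)) return(stats::setNames(numeric(length(.group_order)),
                                        .group_order))
  ov <- pmin(on$end, end) - pmax(on$start, start)
  g <- factor(state_group_of(on$state, groups), levels = .group_order)
  vapply(split(ov, g), sum, 0)
}

#' Summarize LRI-TAD categories
#'
#' Counts LRI TADs (TADs whose category is neither `excluded` nor
#' `non-LRI`) by the number of contributing time points and expresses each
#' count as a percentage of the LRI-TAD total.
#'
#' @param annotations TAD annotation table from [classify_tads()].
#' @return Data.frame with `n_timepoints`, `count`, `percent` (of LRI
#'   TADs, to full precision).
#' @export
category_percentages <- function(annotations) {
  lri <- annotations[!annotations$category %in% c("excluded", "non-LRI"), ]
  n_tp <- sort(unique(lri$n_timepoints))
  counts <- vapply(n_tp, function(k) sum(lri$n_timepoints == k), 0L)
  data.frame(n_timepoints = n_tp, count = counts,
             percent = 100 * counts / nrow(lri))
}

#' Assign a chromHMM state group to a restriction fragment
#'
#' Computes, per state group, the fraction of the fragment covered by
#' segments of that group, and returns the group with the highest coverage.
#' Ties are broken deterministically in the order quiescent > promoter >
#' enhancer > active > other. A fragment overlapped by no segment is
#' `"other"`.
#'
#' @param fragments Fragment table (`chrom`, `start`, `end`).
#' @param segments chromHMM segment table (`chrom`, `start`, `end`, `state`).
#' @param groups State-to-group map, as [default_state_groups()].
#' @return Character vector of group labels, one per fragment.
#' @export
fragment_state_assignment <- function(fragments, segments,
                                      groups = default_state_groups()) {
  vapply(seq_len(nrow(fragments)), function(i) {
    cov <- group_overlap_bp(fragments$chrom[i], fragments$start[i],
                            fragments$end[i], segments, groups)
    if (all(cov == 0)) return("other")
    .group_order[which.max(cov)]  # which.max takes the first max: tie-break
  }, "")
}

#' chromHMM state-group coverage of TADs
#'
#' Fraction of each TAD's length covered by segments of each state group.
#'
#' @param tads TAD table (`chrom`, `start`, `end`, `tad_id`).
#' @param segments chromHMM segment table.
#' @param groups State-to-group map.
#' @return Data.frame: `tad_id` plus one coverage column per group
#'   (`quiescent`, `promoter`, `enhancer`, `active`), each in [0, 1].
#' @export
tad_state_coverage <- function(tads, segments,
                               groups = default_state_groups()) {
  cov <- t(vapply(seq_len(nrow(tads)), function(i) {
    group_overlap_bp(tads$chrom[i], tads$start[i], tads$end[i],
                     segments, groups) / (tads$end[i] - tads$start[i])
  }, stats::setNames(numeric(length(.group_order)), .group_order)))
  out <- data.frame(tad_id = tads$tad_id, stringsAsFactors = FALSE)
  for (g in setdiff(.group_order, "other")) out[[g]] <- cov[, g]
  out
}

#' Compare state coverage between LRI and non-LRI TADs
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction, no continuity correction) on per-TAD coverage of one state
#' group, plus the direction of the median difference.
#'
#' @param lri_coverage,non_lri_coverage Numeric coverage vectors for the
#'   two arms; both must be non-empty.
#' @return List: `statistic` (rank-sum W), `p_value`, `direction`
#'   (`"LRI higher"`, `"non-LRI higher"` or `"none"`), `median_lri`,
#'   `median_non_lri`.
#' @export
compare_tad_coverage <- function(lri_coverage, non_lri_coverage) {
  if (!length(lri_coverage) || !length(non_lri_coverage)) {
    stop("both arms must be non-empty", call. = FALSE)
  }
  m1 <- stats::median(lri_coverage); m2 <- stats::median(non_lri_coverage)
  if (all(lri_coverage == lri_coverage[1]) &&
      all(non_lri_coverage == lri_coverage[1])) {
    return(list(statistic = NA_real_, p_value = 1, direction = "none",
                median_lri = m1, median_non_lri = m2))
  }
  ht <- stats::wilcox.test(lri_coverage, non_lri_coverage,
                           exact = FALSE, correct = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       direction = if (m1 > m2) "LRI higher"
                   else if (m1 < m2) "non-LRI higher" else "none",
       median_lri = m1, median_non_lri = m2)
}

#' Fraction of interactions crossing TAD boundaries
#'
#' An interaction crosses a boundary when its two fragment midpoints fall
#' in different TADs, or one falls inside a TAD and the other outside all
#' TADs. Pairs with both midpoints outside any TAD do not count as
#' crossing.
#'
#' @param interactions Intra-chromosomal interaction table.
#' @param tads TAD table.
#' @return Fraction in [0, 1] (NA for an empty table).
#' @export
boundary_crossing_fraction <- function(interactions, tads) {
  if (!nrow(interactions)) return(NA_real_)
  b <- assign_to_intervals(interactions$bait_chrom,
         interval_midpoint(interactions$bait_start, interactions$bait_end),
         tads)
  o <- assign_to_intervals(interactions$oe_chrom,
         interval_midpoint(interactions$oe_start, interactions$oe_end),
         tads)
  cross <- (!is.na(b) & !is.na(o) & b != o) | xor(is.na(b), is.na(o))
  mean(cross)
}

#' Marker-gene distribution across LRI-TAD categories
#'
#' Builds the contingency table of cell-type marker genes (rows: cell
#' types; columns: LRI-TAD categories of the TAD containing each gene's
#' midpoint), drops categories whose expected count under independence
#' falls below `min_expected` in any row, and applies the Pearson
#' chi-square test without continuity correction.
#'
#' @param marker_genes Named list (one element per cell type) of gene
#'   tables (`gene_id`, `chrom`, `start`, `end`).
#' @param annotations TAD annotation table from [classify_tads()].
#' @param tads TAD table (for gene-to-TAD assignment).
#' @param min_expected Expected-count threshold for keeping a category
#'   (default 5).
#' @return List: `table` (kept contingency table), `dropped_categories`,
#'   `n_outside` (markers outside every TAD, per cell type), `statistic`,
#'   `dof`, `p_value`, `proportions` (column proportions per row).
#' @export
marker_gene_category_test <- function(marker_genes, annotations, tads,
                                      min_expected = 5) {
  cat_of_tad <- stats::setNames(annotations$category, annotations$tad_id)
  rows <- lapply(marker_genes, function(g) {
    idx <- assign_to_intervals(g$chrom, interval_midpoint(g$start, g$end),
                               tads)
    list(cats = unname(cat_of_tad[tads$tad_id[idx[!is.na(idx)]]]),
         outside = sum(is.na(idx)))
  })
  all_cats <- sort(unique(unlist(lapply(rows, `[[`, "cats"))))
  if (length(all_cats) < 2) {
    stop("fewer than 2 categories survive the expected-count rule",
         call. = FALSE)
  }
  tab <- matrix(unlist(lapply(rows, function(r)
    as.numeric(table(factor(r$cats, levels = all_cats))))),
    nrow = length(rows), byrow = TRUE,
    dimnames = list(names(marker_genes), all_cats))

  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  keep <- apply(expected >= min_expected, 2, all)
  dropped <- colnames(tab)[!keep]
  tab2 <- tab[, keep, drop = FALSE]
  if (ncol(tab2) < 2) {
    stop("fewer than 2 categories survive the expected-count rule",
         call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab2, correct = FALSE))
  list(table = tab2, dropped_categories = dropped,
       n_outside = vapply(rows, `[[`, 0L, "outside"),
       statistic = unname(ht$statistic), dof = unname(ht$parameter),
       p_value = ht$p.value,
       proportions = sweep(tab2, 1, rowSums(tab2), "/"))
}
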