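# Distance-class analysis of significant pCHi-C interactions:
# SRI (< 1 Mb) vs LRI (1-2 Mb) classification, 50-kb binned replicate
# concordance, cross-time-point sharing, and read-support summaries.

#' Genomic distance spanned by an interaction
#'
#' Distance between the midpoints of the bait and other-end fragments
#' (midpoint = floor((start + end) / 2)). Symmetric in the two fragments.
#'
#' @param interactions Interaction table (see [read_interaction_table()]).
#' @return Integer vector of distances in bp.
#' @export
interaction_distance <- function(interactions) {
  if (any(interactions$inter_chromosomal)) {
    stop("interaction_distance is undefined for inter-chromosomal pairs; ",
         "filter them first", call. = FALSE)
  }
  abs(interval_midpoint(interactions$bait_start, interactions$bait_end) -
      interval_midpoint(interactions$oe_start, interactions$oe_end))
}

#' Classify interactions by distance
#'
#' Short-range (SRI) below `sri_max`, long-range (LRI) from `sri_max`
#' (inclusive: a distance of exactly 1 Mb is an LRI) up to but excluding
#' `lri_max`, and `excluded` at `lri_max` and beyond.
#'
#' @param interactions Interaction table (intra-chromosomal).
#' @param sri_max SRI/LRI boundary in bp (default 1 Mb).
#' @param lri_max Upper retention bound in bp (default 2 Mb).
#' @return Factor with levels `SRI`, `LRI`, `excluded`.
#' @export
classify_distance <- function(interactions, sri_max = 1e6, lri_max = 2e6) {
  d <- interaction_distance(interactions)
  factor(ifelse(d < sri_max, "SRI", ifelse(d < lri_max, "LRI", "excluded")),
         levels = c("SRI", "LRI", "excluded"))
}

#' Filter interactions to the significant analysis set
#'
#' Applies, in fixed order, the four retention rules used throughout the
#' package: caller score at or above the threshold, intra-chromosomal only,
#' neither fragment overlapping an exclusion region (e.g. an outlier locus
#' such as a histone-gene cluster), and distance below `max_distance`.
#'
#' @param interactions Interaction table; every row must carry a score.
#' @param score_threshold Minimum caller score (default 5).
#' @param exclusion_regions Optional data.frame of intervals
#'   (`chrom`,`start`,`end`); an interaction is removed when either fragment
#'   overlaps any of them by >= 1 bp.
#' @param max_distance Maximum retained midpoint distance in bp (default 2 Mb).
#' @return The retained interaction table, with a `filter_audit` attribute:
#'   a named integer vector of rows removed by each rule, in application
#'   order (`score`, `inter_chromosomal`, `exclusion`, `distance`).
#' @export
filter_significant <- function(interactions, score_threshold = 5,
                               exclusion_regions = NULL, max_distance = 2e6) {
  if (anyNA(interactions$score)) {
    stop("missing caller score: cannot apply significance filter",
         call. = FALSE)
  }
  audit <- c(score = 0L, inter_chromosomal = 0L, exclusion = 0L,
             distance = 0L)
  keep <- interactions$score >= score_threshold
  audit["score"] <- sum(!keep)
  x <- interactions[keep, , drop = FALSE]

  keep <- !x$inter_chromosomal
  audit["inter_chromosomal"] <- sum(!keep)
  x <- x[keep, , drop = FALSE]

  if (!is.null(exclusion_regions) && nrow(exclusion_regions) > 0 && nrow(x)) {
    hit <- rep(FALSE, nrow(x))
    for (i in seq_len(nrow(exclusion_regions))) {
      e <- exclusion_regions[i, ]
      hit <- hit |
        overlap_length(x$bait_chrom, x$bait_start, x$bait_end,
                       e$chrom, e$start, e$end) > 0 |
        overlap_length(x$oe_chrom, x$oe_start, x$oe_end,
                       e$chrom, e$start, e$end) > 0
    }
    audit["exclusion"] <- sum(hit)
    x <- x[!hit, , drop = FALSE]
  }

  if (nrow(x)) {
    keep <- interaction_distance(x) < max_distance
    audit["distance"] <- sum(!keep)
    x <- x[keep, , drop = FALSE]
  }
  if (!nrow(x)) warning("no interactions retained after filtering")
  attr(x, "filter_audit") <- audit
  x
}

# Canonical identity of an interaction: the unordered fragment-id pair.
pair_key <- function(interactions) {
  a <- pmin(interactions$bait_id, interactions$oe_id)
  b <- pmax(interactions$bait_id, interactions$oe_id)
  paste(a, b, sep = "\r")
}

#' Replicate concordance by distance bin
#'
#' Stratifies the union of two replicates' interactions into fixed-width
#' distance bins and reports, per bin, the proportion of distinct
#' interactions (unordered fragment-id pairs) observed in both replicates.
#' Bins whose union holds fewer than `min_union` interactions get `NA`
#' (too few to estimate), matching the usual reporting convention.
#'
#' @param rep_a,rep_b Filtered interaction tables for the two biological
#'   replicates, on the same fragment map.
#' @param bin_width Distance bin width in bp (default 50 kb).
#' @param min_union Minimum union count for a defined proportion (default 10).
#' @param denominator `"union"` (default; shared / union) or `"mean"`
#'   (2*shared / (|A| + |B|)).
#' @return Data.frame with one row per bin from 0 to the maximum observed
#'   distance: `bin_start`, `bin_end`, `n_a`, `n_b`, `n_shared`, `n_union`,
#'   `proportion`.
#' @export
replicate_concordance <- function(rep_a, rep_b, bin_width = 5e4,
                                  min_union = 10,
                                  denominator = c("union", "mean")) {
  denominator <- match.arg(denominator)
  # same fragment id must mean the same coordinates in both replicates
  frag <- rbind(
    data.frame(id = c(rep_a$bait_id, rep_a$oe_id),
               key = c(paste(rep_a$bait_chrom, rep_a$bait_start, rep_a$bait_end),
                       paste(rep_a$oe_chrom, rep_a$oe_start, rep_a$oe_end))),
    data.frame(id = c(rep_b$bait_id, rep_b$oe_id),
               key = c(paste(rep_b$bait_chrom, rep_b$bait_start, rep_b$bait_end),
                       paste(rep_b$oe_chrom, rep_b$oe_start, rep_b$oe_end))))
  frag <- unique(frag)
  if (anyDuplicated(frag$id)) {
    stop("replicates disagree on fragment coordinates for shared ids",
         call. = FALSE)
  }

  dedup <- function(x) x[!duplicated(pair_key(x)), , drop = FALSE]
  a <- dedup(rep_a); b <- dedup(rep_b)
  ka <- pair_key(a); kb <- pair_key(b)
  da <- interaction_distance(a); db <- interaction_distance(b)

  union_key <- c(ka, kb[!(kb %in% ka)])
  union_dist <- c(da, db[!(kb %in% ka)])
  shared <- union_key %in% ka & union_key %in% kb

  max_d <- if (length(union_dist)) max(union_dist) else 0L
  n_bins <- max(1L, ceiling((max_d + 1) / bin_width))
  bin_of <- function(d) pmin(floor(d / bin_width) + 1L, n_bins)
  tab <- function(d, w = NULL) {
    tabulate(bin_of(d), nbins = n_bins)
  }
  n_union <- tab(union_dist)
  n_shared <- tabulate(bin_of(union_dist)[shared], nbins = n_bins)
  n_a <- tab(da); n_b <- tab(db)

  prop <- if (denominator == "union") n_shared / n_union else
    2 * n_shared / (n_a + n_b)
  prop[n_union < min_union] <- NA_real_
  data.frame(bin_start = (seq_len(n_bins) - 1L) * bin_width,
             bin_end = seq_len(n_bins) * bin_width,
             n_a = n_a, n_b = n_b, n_shared = n_shared, n_union = n_union,
             proportion = prop)
}

#' Sharing of interactions across time points
#'
#' Counts each distinct interaction (unordered fragment-id pair) once and
#' tallies how many time points contain it.
#'
#' @param sets Named list of interaction tables, one per time point (>= 2).
#' @param restrict_to Optional distance class (`"SRI"` or `"LRI"`): only
#'   interactions of that class (classified per time point) are counted.
#' @param sri_max,lri_max Distance-class bounds, as in [classify_distance()].
#' @return List with `counts` (named integer vector: number of interactions
#'   present in exactly 1, 2, ... time points) and `fraction_shared_2plus`.
#' @export
timepoint_sharing <- function(sets, restrict_to = NULL,
                              sri_max = 1e6, lri_max = 2e6) {
  stopifnot(length(sets) >= 2)
  keys <- lapply(sets, function(x) {
    if (!is.null(restrict_to)) {
      x <- x[classify_distance(x, sri_max, lri_max) == restrict_to, ,
             drop = FALSE]
    }
    unique(pair_key(x))
  })
  n_tp <- table(factor(unlist(keys), levels = unique(unlist(keys))))
  counts <- tabulate(n_tp, nbins = length(sets))
  names(counts) <- as.character(seq_along(sets))
  total <- sum(counts)
  list(counts = counts,
       fraction_shared_2plus = if (total) sum(counts[-1]) / total else NA_real_)
}

#' Read-support summary per distance class
#'
#' Median and quartiles of the supporting read count, per distance class.
#' Quantiles use the linear-interpolation definition (R type 7).
#'
#' @param interactions Filtered interaction table with `read_count`.
#' @param sri_max,lri_max Distance-class bounds.
#' @return Data.frame with rows SRI and LRI: `n`, `q1`, `median`, `q3`
#'   (`NA` for an empty class).
#' @export
read_support_summary <- function(interactions, sri_max = 1e6, lri_max = 2e6) {
  cls <- classify_distance(interactions, sri_max, lri_max)
  one <- function(label) {
    x <- interactions$read_count[cls == label]
    if (!length(x)) return(c(n = 0, q1 = NA, median = NA, q3 = NA))
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    c(n = length(x), q1 = q[1], median = q[2], q3 = q[3])
  }
  out <- as.data.frame(rbind(SRI = one("SRI"), LRI = one("LRI")))
  out$class <- rownames(out)
  out[, c("class", "n", "q1", "median", "q3")]
}

#' Fold change between two proportions
#'
#' @param p_from,p_to Proportions (any common unit); `p_from` must be > 0.
#' @return `p_to / p_from`.
#' @examples
#' proportion_fold_change(1.1, 2.6)  # 2.36..., i.e. 2.4 to one decimal
#' @export
proportion_fold_change <- function(p_from, p_to) {
  if (any(p_from <= 0)) stop("p_from must be positive", call. = FALSE)
  p_to / p_from
}
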