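# Co-occurrence of genomic features (e.g. super-enhancers) with LRI TADs:
# an empirical label-shuffling permutation null and a hypergeometric test.

#' Count features landing in LRI TADs
#'
#' A feature lands in a TAD when its midpoint lies inside the TAD interval.
#'
#' @param features Interval table (`chrom`, `start`, `end`).
#' @param tads TAD table (`chrom`, `start`, `end`, `tad_id`).
#' @param lri_tad_ids Character vector of LRI-TAD ids.
#' @return Integer count of features whose midpoint lies in an LRI TAD.
#' @export
count_feature_tad_cooccurrence <- function(features, tads, lri_tad_ids) {
  idx <- assign_to_intervals(features$chrom,
                             interval_midpoint(features$start, features$end),
                             tads)
  sum(tads$tad_id[idx[!is.na(idx)]] %in% lri_tad_ids)
}

#' Permutation test of feature / LRI-TAD co-occurrence
#'
#' Shuffles which TADs carry the LRI label: each permutation draws a
#' uniform random subset of the eligible TADs (by default all supplied
#' TADs; pass the interaction-containing subset to respect the exclusion
#' of interaction-free TADs) of the same size as the observed LRI set, and
#' recounts the features landing in labelled TADs. The p-value uses the
#' add-one rule p = (1 + #\{null >= observed\}) / (1 + n_permutations), so
#' it is never exactly zero.
#'
#' @param features,tads,lri_tad_ids As in
#'   [count_feature_tad_cooccurrence()].
#' @param eligible_tad_ids TADs over which the label is shuffled (default:
#'   all of `tads`). Must contain `lri_tad_ids`.
#' @param n_permutations Number of label shuffles (default 10,000).
#' @param seed Integer seed; the result is reproducible from it.
#' @return List: `observed`, `null_counts` (length `n_permutations`),
#'   `p_value`, `n_permutations`.
#' @export
permutation_test <- function(features, tads, lri_tad_ids,
                             eligible_tad_ids = tads$tad_id,
                             n_permutations = 10000, seed = 1) {
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  stopifnot(all(lri_tad_ids %in% eligible_tad_ids),
            length(lri_tad_ids) <= length(eligible_tad_ids))
  idx <- assign_to_intervals(features$chrom,
                             interval_midpoint(features$start, features$end),
                             tads)
  feat_tad <- tads$tad_id[idx[!is.na(idx)]]
  observed <- sum(feat_tad %in% lri_tad_ids)
  k <- length(lri_tad_ids)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  null_counts <- vapply(seq_len(n_permutations), function(i) {
    lab <- sample(eligible_tad_ids, k)
    sum(feat_tad %in% lab)
  }, 0L)
  list(observed = observed, null_counts = null_counts,
       p_value = (1 + sum(null_counts >= observed)) / (1 + n_permutations),
       n_permutations = n_permutations)
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Hypergeometric test of feature / LRI-TAD co-occurrence
#'
#' Upper-tail probability P(X >= k) of seeing at least the observed number
#' of features in LRI TADs when each feature independently lands in one of
#' the eligible TADs: population = eligible TAD count, success states =
#' LRI TAD count, draws = number of features.
#'
#' @param k Observed features in LRI TADs.
#' @param n_features Total features drawn.
#' @param n_lri_tads,n_eligible_tads Success and population counts.
#' @return Upper-tail p-value.
#' @export
hypergeometric_test <- function(k, n_features, n_lri_tads, n_eligible_tads) {
  if (k < 0 || k > n_features || n_lri_tads > n_eligible_tads ||
      k > n_lri_tads) {
    stop("impossible counts for hypergeometric test", call. = FALSE)
  }
  stats::phyper(k - 1, n_lri_tads, n_eligible_tads - n_lri_tads, n_features,
                lower.tail = FALSE)
}
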