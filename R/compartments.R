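# A/B compartment calling from binned chromatin accessibility.
#
# Procedure, per chromosome: bin read midpoints into fixed-width bins
# (default 100 kb), normalise to bins-per-million (BPM), correct
# log2(BPM + pseudocount) for the per-sample FRiP quality metric, take the
# Spearman correlation matrix of bins across samples, extract its leading
# eigenvector, orient it so that A compartments (positive values) are
# negatively correlated with bin connectivity (B compartments are the more
# correlated ones), smooth with a 3-bin moving average, and call A/B by
# sign.

#' Bin accessibility reads into fixed-width genomic bins
#'
#' A read contributes to the bin containing its midpoint. Reads whose
#' midpoint falls in a blacklist region are dropped; bins fully contained
#' in blacklist regions are marked excluded. The last bin of each
#' chromosome is truncated to the chromosome end.
#'
#' @param reads Named list (one element per sample) of read tables with
#'   `chrom` and either `pos` (midpoint) or `start`/`end` columns.
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param bin_size Bin width in bp (default 100 kb).
#' @param blacklist Optional interval table (`chrom`, `start`, `end`).
#' @return List of class `compartment_bins`: `bins` (data.frame `chrom`,
#'   `start`, `end`, `excluded`) and `counts` (bins x samples matrix).
#' @export
bin_accessibility <- function(reads, chrom_lengths, bin_size = 1e5,
                              blacklist = NULL) {
  stopifnot(length(names(chrom_lengths)) == length(chrom_lengths))
  bins <- do.call(rbind, lapply(names(chrom_lengths), function(cc) {
    n <- ceiling(chrom_lengths[[cc]] / bin_size)
    data.frame(chrom = cc, start = (seq_len(n) - 1) * bin_size,
               end = pmin(seq_len(n) * bin_size, chrom_lengths[[cc]]),
               stringsAsFactors = FALSE)
  }))
  excluded <- rep(FALSE, nrow(bins))
  if (!is.null(blacklist) && nrow(blacklist)) {
    for (i in seq_len(nrow(blacklist))) {
      b <- blacklist[i, ]
      excluded <- excluded | (bins$chrom == b$chrom &
                              bins$start >= b$start & bins$end <= b$end)
    }
  }
  counts <- vapply(reads, function(r) {
    pos <- if ("pos" %in% names(r)) r$pos else
      interval_midpoint(r$start, r$end)
    off_end <- pos >= chrom_lengths[r$chrom] | pos < 0 |
      !(r$chrom %in% names(chrom_lengths))
    if (any(off_end, na.rm = TRUE)) {
      warning(sum(off_end), " reads beyond declared chromosome ends dropped")
      r <- r[!off_end, , drop = FALSE]
      pos <- pos[!off_end]
    }
    if (!is.null(blacklist) && nrow(blacklist) && nrow(r)) {
      drop <- !is.na(assign_to_intervals(r$chrom, pos, blacklist))
      r <- r[!drop, , drop = FALSE]; pos <- pos[!drop]
    }
    idx <- assign_to_intervals(r$chrom, pos, bins)
    tabulate(idx, nbins = nrow(bins))
  }, numeric(nrow(bins)))
  colnames(counts) <- names(reads)
  bins$excluded <- excluded
  structure(list(bins = bins, counts = counts), class = "compartment_bins")
}

#' Normalise bin counts and correct for FRiP
#'
#' Computes bins-per-million (BPM = raw count / (total mapped reads / 1e6))
#' per sample, then removes the per-sample quality trend: for each bin,
#' log2(BPM + pseudocount) is regressed on the samples' FRiP values by
#' ordinary least squares and replaced by the residuals plus the bin mean.
#' With fewer than 3 samples the regression is underdetermined and the
#' correction reduces to the centred log2 BPM (with a warning).
#'
#' @param x `compartment_bins` object from [bin_accessibility()].
#' @param meta Sample metadata: data.frame with `sample_id`, `frip`
#'   (in (0, 1]) and `total_reads` (> 0), one row per sample, in any order.
#' @param pseudocount Added to BPM before log2 (default 1).
#' @return `x` with `bpm` and `corrected` matrices added.
#' @export
normalize_and_correct <- function(x, meta, pseudocount = 1) {
  stopifnot(!is.null(colnames(x$counts)),
            all(colnames(x$counts) %in% meta$sample_id),
            all(meta$total_reads > 0),
            all(meta$frip > 0 & meta$frip <= 1))
  meta <- meta[match(colnames(x$counts), meta$sample_id), ]
  bpm <- sweep(x$counts, 2, meta$total_reads / 1e6, "/")
  lv <- log2(bpm + pseudocount)
  frip <- meta$frip
  if (ncol(lv) < 3 || stats::sd(frip) == 0) {
    if (ncol(lv) < 3) {
      warning("fewer than 3 samples: FRiP correction skipped")
    }
    corrected <- lv  # slope fixed at 0: residual + bin mean = log2 BPM
  } else {
    fc <- frip - mean(frip)
    slope <- (lv %*% fc) / sum(fc^2)          # per-bin OLS slope
    corrected <- lv - slope %*% t(fc)          # residual + bin mean
  }
  x$bpm <- bpm
  x$corrected <- corrected
  x
}

#' Spearman correlation matrix of bins
#'
#' Pairwise Spearman rank correlation between bins (rows) across samples.
#' Zero-variance bins cannot be ranked against anything and are excluded.
#'
#' @param values Bins x samples matrix (>= 3 bins, >= 3 samples).
#' @return List: `corr` (symmetric matrix with unit diagonal over usable
#'   bins), `used` (row indices of `values` kept).
#' @export
spearman_correlation_matrix <- function(values) {
  if (nrow(values) < 3) stop("need >= 3 bins", call. = FALSE)
  if (ncol(values) < 3) stop("need >= 3 samples", call. = FALSE)
  v <- apply(values, 1, stats::var)
  used <- which(v > 0)
  if (length(used) < 3) stop("fewer than 3 non-constant bins", call. = FALSE)
  corr <- stats::cor(t(values[used, , drop = FALSE]), method = "spearman")
  list(corr = corr, used = used)
}

#' Leading eigenvector by power iteration
#'
#' Eigenvector of the largest-magnitude eigenvalue of a symmetric matrix,
#' by power iteration from the normalised all-ones vector, tolerance 1e-10
#' (sign-invariant), at most 10,000 iterations. The sign of the result is
#' arbitrary at this stage. When the second eigenvalue magnitude is within
#' a relative 1e-6 of the first, the attribute `degenerate` is set (the
#' eigenvector is then not unique, e.g. for the identity matrix).
#'
#' @param corr Symmetric numeric matrix, all finite.
#' @param tol,max_iter Convergence controls.
#' @return Unit-norm eigenvector with attributes `eigenvalue` and
#'   `degenerate`.
#' @export
leading_eigenvector <- function(corr, tol = 1e-10, max_iter = 10000) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr), all(is.finite(corr)))
  n <- nrow(corr)
  v <- rep(1, n) / sqrt(n)
  lambda <- NA_real_
  for (it in seq_len(max_iter)) {
    w <- drop(corr %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) { # v in the null space: restart off-axis deterministically
      v <- seq_len(n) / sqrt(sum(seq_len(n)^2)); next
    }
    w <- w / nw
    if (min(sum((w - v)^2), sum((w + v)^2)) < tol^2 * n) {
      v <- w; lambda <- drop(v %*% corr %*% v); break
    }
    v <- w
    if (it == max_iter) {
      stop("power iteration did not converge", call. = FALSE)
    }
  }
  if (is.na(lambda)) lambda <- drop(v %*% corr %*% v)
  # estimate the runner-up eigenvalue on the deflated matrix
  defl <- corr - lambda * tcrossprod(v)
  u <- seq_len(n) - mean(seq_len(n))
  u <- u - drop(crossprod(u, v)) * v
  l2 <- 0
  if (sqrt(sum(u^2)) > 1e-12) {
    u <- u / sqrt(sum(u^2))
    for (i in 1:50) {
      u2 <- drop(defl %*% u)
      if (sqrt(sum(u2^2)) < 1e-14) break
      u <- u2 / sqrt(sum(u2^2))
    }
    l2 <- abs(drop(u %*% defl %*% u))
  }
  attr(v, "eigenvalue") <- lambda
  attr(v, "degenerate") <- abs(lambda) > 0 && (l2 >= abs(lambda) * (1 - 1e-6))
  v
}

#' Orient and smooth a compartment eigenvector
#'
#' Computes each bin's connectivity (sum of its correlations with all other
#' bins on the chromosome), flips the eigenvector sign if it is positively
#' correlated with connectivity (so that A compartments, positive values,
#' are the less-connected ones), and applies a centred moving average of
#' width `window`, truncated at the chromosome ends.
#'
#' @param eigvec Eigenvector over the bins of one chromosome.
#' @param corr Matching correlation matrix.
#' @param window Moving-average width (default 3).
#' @return Oriented, smoothed numeric vector.
#' @export
orient_and_smooth <- function(eigvec, corr, window = 3) {
  stopifnot(length(eigvec) == nrow(corr))
  if (stats::sd(eigvec) == 0) {
    stop("eigenvector has zero variance; cannot orient", call. = FALSE)
  }
  connectivity <- rowSums(corr) - diag(corr)
  if (stats::sd(connectivity) > 0 &&
      stats::cor(eigvec, connectivity) > 0) {
    eigvec <- -eigvec
  }
  half <- (window - 1) %/% 2
  n <- length(eigvec)
  vapply(seq_len(n), function(i) {
    mean(eigvec[max(1, i - half):min(n, i + half)])
  }, 0)
}

#' Call A/B compartments
#'
#' Runs the per-chromosome pipeline (Spearman correlation, leading
#' eigenvector, orientation, smoothing) on normalised bins and labels each
#' bin `A` (positive smoothed eigenvector), `B` (negative) or `excluded`
#' (blacklisted, zero variance, skipped chromosome, or an exact zero after
#' smoothing).
#'
#' @param x `compartment_bins` object after [normalize_and_correct()].
#' @param window Smoothing window (default 3).
#' @return `x` with `eigen`, `connectivity` and `label` columns added to
#'   `x$bins`, plus `degenerate_chroms` listing chromosomes with a
#'   non-unique leading eigenvector.
#' @export
call_compartments <- function(x, window = 3) {
  stopifnot(!is.null(x$corrected))
  bins <- x$bins
  bins$eigen <- NA_real_
  bins$connectivity <- NA_real_
  bins$label <- "excluded"
  degenerate <- character()
  for (cc in unique(bins$chrom)) {
    rows <- which(bins$chrom == cc & !bins$excluded)
    if (length(rows) < 3) {
      warning("chromosome ", cc, " skipped: fewer than 3 usable bins")
      next
    }
    sc <- tryCatch(
      spearman_correlation_matrix(x$corrected[rows, , drop = FALSE]),
      error = function(e) {
        warning("chromosome ", cc, " skipped: ", conditionMessage(e)); NULL
      })
    if (is.null(sc)) next
    ev <- leading_eigenvector(sc$corr)
    if (isTRUE(attr(ev, "degenerate"))) degenerate <- c(degenerate, cc)
    sm <- orient_and_smooth(as.numeric(ev), sc$corr, window)
    use <- rows[sc$used]
    bins$eigen[use] <- sm
    bins$connectivity[use] <- rowSums(sc$corr) - diag(sc$corr)
    bins$label[use] <- ifelse(sm > 0, "A", ifelse(sm < 0, "B", "excluded"))
  }
  x$bins <- bins
  x$degenerate_chroms <- degenerate
  x
}

#' B-compartment coverage of TADs and LRI-TAD enrichment
#'
#' Per TAD, the fraction of its length covered by B-labelled bins; the LRI
#' and non-LRI arms (from [classify_tads()] categories) are compared with
#' the same rank-sum machinery as [compare_tad_coverage()].
#'
#' @param x `compartment_bins` object after [call_compartments()].
#' @param annotations TAD annotation table.
#' @param tads TAD table.
#' @return List: `coverage` (data.frame `tad_id`, `b_coverage`, `arm`),
#'   plus the [compare_tad_coverage()] fields for LRI vs non-LRI arms.
#' @export
compartment_lri_tad_enrichment <- function(x, annotations, tads) {
  bbins <- x$bins[x$bins$label == "B", , drop = FALSE]
  b_cov <- vapply(seq_len(nrow(tads)), function(i) {
    if (!nrow(bbins)) return(0)
    sum(overlap_length(tads$chrom[i], tads$start[i], tads$end[i],
                       bbins$chrom, bbins$start, bbins$end)) /
      (tads$end[i] - tads$start[i])
  }, 0)
  ann <- annotations[match(tads$tad_id, annotations$tad_id), ]
  arm <- ifelse(ann$category == "excluded", NA,
                ifelse(ann$category == "non-LRI", "non-LRI", "LRI"))
  cov <- data.frame(tad_id = tads$tad_id, b_coverage = b_cov, arm = arm,
                    stringsAsFactors = FALSE)
  test <- compare_tad_coverage(cov$b_coverage[!is.na(arm) & arm == "LRI"],
                               cov$b_coverage[!is.na(arm) & arm == "non-LRI"])
  c(list(coverage = cov), test)
}
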