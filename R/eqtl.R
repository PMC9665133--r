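# Interaction-restricted long-range cis-eQTL mapping.
#
# SNP-gene pairs within 1 Mb of either gene end are "short" cis pairs;
# pairs 1-2 Mb away are "long". Long pairs are only tested when a physical
# interaction supports them: the SNP lies in the other-end fragment of an
# interaction whose bait is the gene's promoter fragment. Multiple-testing
# correction is Bonferroni over the number of independent signals after
# greedy LD pruning at R^2 < 0.2.

#' Filter genes by expressed fraction
#'
#' Keeps genes expressed (value > 0) in strictly more than `min_fraction`
#' of individuals.
#'
#' @param expr Genes x individuals matrix, gene ids as row names.
#' @param min_fraction Strict lower bound on the expressed fraction
#'   (default 0.90).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed_genes <- function(expr, min_fraction = 0.90) {
  frac <- rowMeans(expr > 0)
  rownames(expr)[frac > min_fraction]
}

#' Quality-filter SNPs
#'
#' Applies the standard imputation-era inclusion rules: imputation info
#' score >= `info_min` (skipped when no info is available), minor allele
#' frequency >= `maf_min` (MAF from mean dosage / 2, folded to <= 0.5), and
#' Hardy-Weinberg equilibrium chi-square p >= `hwe_p_min` (1 d.o.f., on
#' genotype counts after rounding dosages to the nearest integer).
#'
#' @param geno List with `snps` (data.frame `snp_id`, `chrom`, `pos` and
#'   optional `info`) and `dosages` (SNPs x individuals matrix in [0, 2],
#'   SNP ids as row names).
#' @param maf_min,hwe_p_min,info_min Thresholds.
#' @return `geno` restricted to passing SNPs, with a `filter_audit`
#'   attribute (named counts removed per rule, applied in order info ->
#'   maf -> hwe).
#' @export
filter_snps <- function(geno, maf_min = 0.05, hwe_p_min = 1e-5,
                        info_min = 0.8) {
  snps <- geno$snps
  dos <- geno$dosages
  audit <- c(info = 0L, maf = 0L, hwe = 0L)
  keep <- rep(TRUE, nrow(snps))
  if ("info" %in% names(snps) && !all(is.na(snps$info))) {
    fail <- !is.na(snps$info) & snps$info < info_min
    audit["info"] <- sum(fail & keep)
    keep <- keep & !fail
  }
  p_alt <- rowMeans(dos) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  fail <- maf < maf_min
  audit["maf"] <- sum(fail & keep)
  keep <- keep & !fail

  hard <- round(dos)
  n <- ncol(dos)
  n_aa <- rowSums(hard == 2); n_ab <- rowSums(hard == 1)
  p <- (2 * n_aa + n_ab) / (2 * n)
  hwe_p <- vapply(seq_len(nrow(dos)), function(i) {
    exp_counts <- n * c((1 - p[i])^2, 2 * p[i] * (1 - p[i]), p[i]^2)
    obs <- c(n - n_aa[i] - n_ab[i], n_ab[i], n_aa[i])
    if (any(exp_counts == 0)) return(1)  # monomorphic: caught by MAF rule
    chi <- sum((obs - exp_counts)^2 / exp_counts)
    stats::pchisq(chi, df = 1, lower.tail = FALSE)
  }, 0)
  fail <- hwe_p < hwe_p_min
  audit["hwe"] <- sum(fail & keep)
  keep <- keep & !fail

  out <- list(snps = snps[keep, , drop = FALSE],
              dosages = dos[keep, , drop = FALSE])
  attr(out, "filter_audit") <- audit
  out
}

#' Single SNP-gene OLS association
#'
#' Ordinary least squares of expression on dosage, covariates and an
#' intercept — the additive linear eQTL model. Reports the dosage effect,
#' its t statistic and the two-sided p-value from the t distribution with
#' the residual degrees of freedom.
#'
#' @param snp_dosages Numeric vector (one value per individual).
#' @param gene_expr Numeric response vector of the same length.
#' @param covariates Optional individuals x covariates matrix.
#' @return List: `beta`, `se`, `t_stat`, `p_value`, `df`.
#' @export
ols_association <- function(snp_dosages, gene_expr, covariates = NULL) {
  n <- length(gene_expr)
  stopifnot(length(snp_dosages) == n)
  X <- cbind(intercept = 1, dosage = snp_dosages, covariates)
  if (n <= ncol(X)) stop("too few individuals for the model", call. = FALSE)
  fit <- stats::lm.fit(X, gene_expr)
  if (any(is.na(fit$coefficients))) {
    stop("rank-deficient design (zero-variance dosage after covariate ",
         "projection?)", call. = FALSE)
  }
  df <- n - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtX_inv <- solve(crossprod(X))
  se <- sqrt(sigma2 * XtX_inv[2, 2])
  beta <- unname(fit$coefficients["dosage"])
  if (se == 0) {
    t_stat <- if (beta == 0) 0 else sign(beta) * Inf
  } else {
    t_stat <- beta / se
  }
  list(beta = beta, se = se, t_stat = t_stat,
       p_value = 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE), df = df)
}

#' Enumerate candidate cis SNP-gene pairs
#'
#' Distance is the minimum over the two gene ends of the absolute
#' difference between the SNP position and that end; SNPs inside the gene
#' body have distance 0. Pairs under `short_max` are `short`, pairs from
#' `short_max` up to (excluding) `long_max` are `long`; more distant pairs
#' are not enumerated.
#'
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`).
#' @param snps SNP table (`snp_id`, `chrom`, `pos`).
#' @param short_max,long_max Window bounds in bp (defaults 1 Mb, 2 Mb).
#' @return Data.frame: `snp_id`, `gene_id`, `distance`, `window_class`.
#' @export
enumerate_candidate_pairs <- function(genes, snps, short_max = 1e6,
                                      long_max = 2e6) {
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    same <- snps$chrom == g$chrom
    if (!any(same)) return(NULL)
    pos <- snps$pos[same]
    inside <- pos >= g$start & pos < g$end
    d <- pmin(abs(pos - g$start), abs(pos - g$end))
    d[inside] <- 0L
    keep <- d < long_max
    if (!any(keep)) return(NULL)
    data.frame(snp_id = snps$snp_id[same][keep], gene_id = g$gene_id,
               distance = d[keep],
               window_class = ifelse(d[keep] < short_max, "short", "long"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(snp_id = character(), gene_id = character(),
                      distance = integer(), window_class = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Flag candidate pairs supported by a physical interaction
#'
#' A pair is supported when some interaction has the gene's promoter
#' fragment as bait, contains the SNP position inside its other-end
#' fragment (half-open), and has the distance class matching the pair's
#' window (long pairs need LRIs, short pairs need SRIs).
#'
#' @param pairs Candidate pairs from [enumerate_candidate_pairs()].
#' @param interactions Filtered interaction table.
#' @param genes Gene table carrying `bait_fragment_id`.
#' @param snps SNP table.
#' @param sri_max,lri_max Distance-class bounds.
#' @return `pairs` with an `interaction_supported` logical column; the
#'   `n_genes_without_bait` audit count is attached as an attribute.
#' @export
restrict_pairs_by_interaction <- function(pairs, interactions, genes, snps,
                                          sri_max = 1e6, lri_max = 2e6) {
  cls <- as.character(classify_distance(interactions, sri_max, lri_max))
  bait_of_gene <- stats::setNames(genes$bait_fragment_id, genes$gene_id)
  pos_of_snp <- stats::setNames(snps$pos, snps$snp_id)
  chrom_of_snp <- stats::setNames(snps$chrom, snps$snp_id)
  supported <- vapply(seq_len(nrow(pairs)), function(i) {
    bait <- bait_of_gene[[pairs$gene_id[i]]]
    if (is.null(bait) || is.na(bait)) return(FALSE)
    want <- if (pairs$window_class[i] == "long") "LRI" else "SRI"
    hits <- interactions$bait_id == bait & cls == want &
      interactions$oe_chrom == chrom_of_snp[[pairs$snp_id[i]]] &
      interactions$oe_start <= pos_of_snp[[pairs$snp_id[i]]] &
      pos_of_snp[[pairs$snp_id[i]]] < interactions$oe_end
    any(hits)
  }, TRUE)
  no_bait <- sum(is.na(bait_of_gene[pairs$gene_id]))
  out <- pairs
  out$interaction_supported <- supported
  attr(out, "n_genes_without_bait") <- no_bait
  out
}

#' Squared-correlation LD matrix
#'
#' @param dosages SNPs x individuals dosage matrix.
#' @return Symmetric matrix of squared Pearson correlations between SNP
#'   dosage vectors (unit diagonal); zero-variance SNPs get NA rows.
#' @export
ld_r2_matrix <- function(dosages) {
  r <- suppressWarnings(stats::cor(t(dosages)))
  r2 <- r^2
  diag(r2) <- 1
  r2
}

#' LD-pruned Bonferroni adjustment
#'
#' Counts independent association signals by greedy pruning — SNPs in
#' ascending p-value order, accepting a SNP only when its LD R^2 with
#' every previously accepted SNP is below `r2_max` — and sets
#' `p_adj = min(1, p * n_independent)` on every result.
#'
#' @param results Association results: data.frame with `snp_id` and
#'   `p_value`.
#' @param ld R^2 matrix covering all SNPs in `results` (dimnames required).
#' @param r2_max Independence threshold (default 0.2).
#' @return `results` with `n_independent` and `p_adj` columns; accepted
#'   (index) SNPs flagged in `is_index_snp`.
#' @export
count_independent_and_adjust <- function(results, ld, r2_max = 0.2) {
  snps <- unique(results$snp_id)
  if (!all(snps %in% rownames(ld))) {
    stop("LD matrix missing entries for tested SNPs", call. = FALSE)
  }
  best_p <- vapply(split(results$p_value, results$snp_id), min, 0)[snps]
  ord <- snps[order(best_p)]
  accepted <- character()
  for (s in ord) {
    if (!length(accepted) || all(ld[s, accepted] < r2_max, na.rm = TRUE)) {
      accepted <- c(accepted, s)
    }
  }
  out <- results
  out$n_independent <- length(accepted)
  out$p_adj <- pmin(1, out$p_value * length(accepted))
  out$is_index_snp <- out$snp_id %in% accepted
  out
}

#' Short-range FDR cross-check for long-range eQTL SNPs
#'
#' For each long-range eQTL SNP, checks whether any interaction-supported
#' short-range pair involving that SNP is significant at the given FDR
#' (Benjamini-Hochberg q-values computed over all short-range tests).
#'
#' @param long_snp_ids SNP ids of long-range results to check.
#' @param short_results Short-range association results: `snp_id`,
#'   `p_value`, `interaction_supported`.
#' @param fdr q-value threshold (default 0.05).
#' @return Named logical vector over `long_snp_ids`.
#' @export
short_range_fdr_check <- function(long_snp_ids, short_results, fdr = 0.05) {
  q <- stats::p.adjust(short_results$p_value, "BH")
  hit <- short_results$interaction_supported & q < fdr
  flagged <- unique(short_results$snp_id[hit])
  stats::setNames(long_snp_ids %in% flagged, long_snp_ids)
}

#' Run the interaction-restricted eQTL analysis
#'
#' Convenience wrapper: filters genes and SNPs, enumerates candidate
#' pairs, restricts them by interaction support, fits the OLS model on
#' log2(expression + 1) for every supported pair, and applies the
#' LD-pruned Bonferroni adjustment to the long-range results (and BH to
#' the short-range results).
#'
#' @param expr Genes x individuals expression matrix (raw scale).
#' @param geno Genotype list (`snps`, `dosages`).
#' @param genes Gene table with `bait_fragment_id`.
#' @param interactions Filtered interaction table.
#' @param covariates Optional individuals x covariates matrix.
#' @param min_fraction,maf_min,hwe_p_min,info_min,r2_max,fdr Thresholds.
#' @return List: `long` (supported long-range results with `p_adj`),
#'   `short` (supported short-range results with `q_value`),
#'   `short_range_flag` (per long SNP), `n_tested`, audits.
#' @export
run_eqtl <- function(expr, geno, genes, interactions, covariates = NULL,
                     min_fraction = 0.90, maf_min = 0.05, hwe_p_min = 1e-5,
                     info_min = 0.8, r2_max = 0.2, fdr = 0.05) {
  keep_genes <- filter_expressed_genes(expr, min_fraction)
  geno <- filter_snps(geno, maf_min, hwe_p_min, info_min)
  genes <- genes[genes$gene_id %in% keep_genes, , drop = FALSE]
  pairs <- enumerate_candidate_pairs(genes, geno$snps)
  pairs <- restrict_pairs_by_interaction(pairs, interactions, genes,
                                         geno$snps)
  pairs <- pairs[pairs$interaction_supported, , drop = FALSE]
  if (!nrow(pairs)) {
    warning("no interaction-supported candidate pairs")
    return(list(long = pairs, short = pairs, short_range_flag = logical(),
                n_tested = 0, snp_filter_audit = attr(geno, "filter_audit")))
  }
  lexpr <- log2(expr + 1)
  fits <- lapply(seq_len(nrow(pairs)), function(i) {
    ols_association(geno$dosages[pairs$snp_id[i], ],
                    lexpr[pairs$gene_id[i], ], covariates)
  })
  pairs$beta <- vapply(fits, `[[`, 0, "beta")
  pairs$t_stat <- vapply(fits, `[[`, 0, "t_stat")
  pairs$p_value <- vapply(fits, `[[`, 0, "p_value")

  long <- pairs[pairs$window_class == "long", , drop = FALSE]
  short <- pairs[pairs$window_class == "short", , drop = FALSE]
  if (nrow(long)) {
    ld <- ld_r2_matrix(geno$dosages[unique(long$snp_id), , drop = FALSE])
    long <- count_independent_and_adjust(long, ld, r2_max)
  }
  if (nrow(short)) short$q_value <- stats::p.adjust(short$p_value, "BH")
  flag <- short_range_fdr_check(unique(long$snp_id), short, fdr)
  list(long = long, short = short, short_range_flag = flag,
       n_tested = nrow(pairs),
       snp_filter_audit = attr(geno, "filter_audit"))
}
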