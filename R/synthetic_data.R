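# Synthetic miniature study with planted ground truth: genome layout
# (restriction fragments, TADs, genes), significant-interaction replicates
# with distance decay and planted repressed-TAD LRIs, chromHMM-like state
# segmentations, expression matrices, binned-accessibility reads with
# compartment blocks, and genotypes with LD blocks and one planted
# long-range eQTL. Every generator is a pure function of (config, seed).

#' Configuration for the synthetic study generator
#'
#' Defaults define the study conditions every recovery test runs under;
#' see the methods vignette for the rationale behind each value.
#'
#' @param seed Master integer seed; each generator derives a fixed offset
#'   from it.
#' @param n_chromosomes,chrom_length Genome size (default 4 x 15 Mb).
#' @param fragment_mean_length Mean restriction-fragment length (4 kb).
#' @param tad_mean_length Mean TAD length (800 kb).
#' @param frac_repressed_tads Fraction of TADs planted as repressed, drawn
#'   as contiguous runs of 3 TADs (~2.4 Mb) so that 1-2 Mb pairs can have
#'   both ends repressed anywhere in a run (0.25).
#' @param n_genes_per_chrom Genes (promoter baits) per chromosome (200).
#' @param timepoints Time-point labels, in differentiation order.
#' @param interactions_per_replicate Significant calls per replicate (5000).
#' @param distance_decay_exponent Within-class power-law exponent (1.0).
#' @param min_distance,max_drawn_distance Distance support in bp
#'   (20 kb to 2.5 Mb, so the > 2 Mb retention filter is exercised).
#' @param lri_rate Named per-time-point LRI proportion
#'   (PAd 0.011, Diff 0.026, Adip 0.035).
#' @param excluded_rate Proportion of calls beyond 2 Mb (0.02).
#' @param lri_frac_in_repressed Fraction of LRIs drawn from the planted
#'   pool of repressed-TAD pairs, with both ends inside repressed TADs;
#'   the pool persists across time points so planted LRIs recur (0.9).
#' @param replicate_retention Named per-class probability that a call is
#'   re-observed in the second replicate (SRI 0.75, LRI 0.55,
#'   excluded 0.1).
#' @param decoy_rate Fraction of extra sub-threshold-score rows (0.1).
#' @param sri_read_mean,lri_read_mean Shifted-Poisson read-support means
#'   (11 and 5.5, giving medians 12 and 6).
#' @param expr_mean,expr_sd Baseline log2 expression distribution (5, 1).
#' @param expr_noise_sd Per-observation log2 noise (0.5).
#' @param repression_multiplier Expression multiplier for genes in
#'   repressed TADs and for planted-LRI bait genes (0.5).
#' @param dropout_base,dropout_repressed Zero-inflation rates (0.05, 0.4).
#' @param compartment_block_length A/B block length in bp (2.5 Mb,
#'   multi-megabase blocks as compartments are).
#' @param n_access_samples Accessibility samples (12: the full replicate
#'   set pooled across the time course).
#' @param access_mean_a,access_mean_b Mean reads per 100-kb bin (200, 60).
#' @param access_loading_a,access_loading_b Per-label loadings on the
#'   shared per-sample factor (-0.4, 0.9), opposite signs so the two
#'   compartments anticorrelate.
#' @param access_noise_sd_a,access_noise_sd_b Per-bin log-intensity noise
#'   (0.45, 0.2): open (A) bins carry more sample-specific variability, so
#'   B bins are the more strongly co-varying ones — the asymmetry the
#'   eigenvector orientation rule relies on.
#' @param n_individuals Genotyped individuals (300).
#' @param eqtl_beta Planted effect in units of the gene's log2 SD (0.8).
#' @param eqtl_maf Planted-SNP minor allele frequency (0.3).
#' @param ld_block_length LD-block length in bp (100 kb).
#' @param snp_spacing Background SNP spacing in bp (25 kb).
#' @param ld_mutation_rate Per-SNP founder-copy flip rate (0.03).
#' @param n_markers Named marker-gene counts (PAd 60, Adip 80).
#' @param n_features Super-enhancer-like features, placed uniformly at
#'   random, i.e. a null feature generator (40, below the TAD count so
#'   the count-based hypergeometric model stays well defined).
#' @param feature_width Feature width in bp (20 kb).
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_chromosomes = 4,
                             chrom_length = 1.5e7,
                             fragment_mean_length = 4000,
                             tad_mean_length = 8e5,
                             frac_repressed_tads = 0.25,
                             n_genes_per_chrom = 200,
                             timepoints = c("PAd", "Diff", "Adip"),
                             interactions_per_replicate = 5000,
                             distance_decay_exponent = 1.0,
                             min_distance = 2e4,
                             max_drawn_distance = 2.5e6,
                             lri_rate = c(PAd = 0.011, Diff = 0.026,
                                          Adip = 0.035),
                             excluded_rate = 0.02,
                             lri_frac_in_repressed = 0.9,
                             replicate_retention = c(SRI = 0.75, LRI = 0.55,
                                                     excluded = 0.1),
                             decoy_rate = 0.1,
                             sri_read_mean = 11,
                             lri_read_mean = 5.5,
                             expr_mean = 5, expr_sd = 1,
                             expr_noise_sd = 0.5,
                             repression_multiplier = 0.5,
                             dropout_base = 0.05,
                             dropout_repressed = 0.4,
                             compartment_block_length = 2.5e6,
                             n_access_samples = 12,
                             access_mean_a = 200, access_mean_b = 60,
                             access_loading_a = -0.4,
                             access_loading_b = 0.9,
                             access_noise_sd_a = 0.45,
                             access_noise_sd_b = 0.2,
                             n_individuals = 300,
                             eqtl_beta = 0.8,
                             eqtl_maf = 0.3,
                             ld_block_length = 1e5,
                             snp_spacing = 2.5e4,
                             ld_mutation_rate = 0.03,
                             n_markers = c(PAd = 60, Adip = 80),
                             n_features = 40,
                             feature_width = 2e4) {
  cfg <- as.list(environment())
  probs <- c(cfg$frac_repressed_tads, cfg$lri_rate, cfg$excluded_rate,
             cfg$lri_frac_in_repressed, cfg$replicate_retention,
             cfg$decoy_rate, cfg$dropout_base, cfg$dropout_repressed,
             cfg$eqtl_maf, cfg$ld_mutation_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all probability parameters must lie in [0, 1]", call. = FALSE)
  }
  lens <- c(cfg$chrom_length, cfg$fragment_mean_length, cfg$tad_mean_length,
            cfg$compartment_block_length, cfg$ld_block_length)
  if (any(lens <= 0)) stop("lengths must be positive", call. = FALSE)
  stopifnot(all(cfg$timepoints %in% names(cfg$lri_rate)))
  class(cfg) <- "synthetic_config"
  cfg
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  expr
}

# partition [0, total) into intervals with lengths ~ min_len + geometric
partition_lengths <- function(total, mean_len, min_len) {
  n_guess <- ceiling(total / mean_len * 2) + 10
  lens <- min_len + stats::rgeom(n_guess, 1 / (mean_len - min_len + 1))
  ends <- cumsum(lens)
  lens <- lens[ends < total]
  c(lens, total - sum(lens))
}

#' Generate the synthetic genome layout
#'
#' Restriction fragments and TADs each partition every chromosome exactly;
#' genes are anchored on distinct promoter bait fragments; a configured
#' fraction of TADs is marked repressed in the planted truth.
#'
#' @param config A [synthetic_config()].
#' @return List: `fragments` (`chrom`,`start`,`end`,`fragment_id`), `tads`
#'   (`chrom`,`start`,`end`,`tad_id`), `genes` (`gene_id`,`chrom`,`start`,
#'   `end`,`strand`,`bait_fragment_id`), `chrom_lengths`, and `truth` with
#'   `repressed_tad_ids`.
#' @export
generate_genome_layout <- function(config) {
  with_seed(config$seed + 101L, {
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    chrom_lengths <- stats::setNames(rep(config$chrom_length,
                                         length(chroms)), chroms)
    part <- function(mean_len, min_len, prefix) {
      do.call(rbind, lapply(chroms, function(cc) {
        lens <- partition_lengths(config$chrom_length, mean_len, min_len)
        data.frame(chrom = cc,
                   start = cumsum(c(0, lens[-length(lens)])),
                   end = cumsum(lens), stringsAsFactors = FALSE)
      }))
    }
    fragments <- part(config$fragment_mean_length, 500)
    fragments$fragment_id <- sprintf("frag%06d", seq_len(nrow(fragments)))
    tads <- part(config$tad_mean_length, 2e5)
    tads$tad_id <- sprintf("tad%04d", seq_len(nrow(tads)))

    genes <- do.call(rbind, lapply(chroms, function(cc) {
      fr <- fragments[fragments$chrom == cc, ]
      # keep promoters away from the chromosome ends so both interaction
      # directions stay on-chromosome
      ok <- fr$start > 1e5 & fr$end < config$chrom_length - 1e5
      pick <- fr[sample(which(ok), config$n_genes_per_chrom), ]
      len <- pmax(2000, round(stats::rlnorm(nrow(pick), log(2e4), 0.7)))
      data.frame(chrom = cc, start = pick$start,
                 end = pmin(pick$start + len, config$chrom_length),
                 strand = sample(c("+", "-"), nrow(pick), replace = TRUE),
                 bait_fragment_id = pick$fragment_id,
                 stringsAsFactors = FALSE)
    }))
    genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
    genes <- genes[, c("gene_id", "chrom", "start", "end", "strand",
                       "bait_fragment_id")]
    # repressed TADs come in contiguous runs of 2-3 so that 1-2 Mb pairs
    # can have both ends inside the repressed region
    n_rep <- round(config$frac_repressed_tads * nrow(tads))
    repressed <- character()
    if (n_rep > 0) {
      taken <- rep(FALSE, nrow(tads))
      attempts <- 0
      while (sum(taken) < n_rep && attempts < 1000) {
        attempts <- attempts + 1
        run <- 3L  # ~2.4 Mb: every TAD of a run is reachable at 1-2 Mb
        s <- sample(nrow(tads) - run + 1, 1)
        rows <- s:(s + run - 1)
        if (any(taken[rows]) ||
            length(unique(tads$chrom[rows])) > 1) next
        rows <- rows[seq_len(min(run, n_rep - sum(taken)))]
        taken[rows] <- TRUE
      }
      while (sum(taken) < n_rep) taken[sample(which(!taken), 1)] <- TRUE
      repressed <- sort(tads$tad_id[taken])
    }
    layout <- list(fragments = fragments, tads = tads, genes = genes,
                   chrom_lengths = chrom_lengths,
                   truth = list(repressed_tad_ids = repressed))
    # a repressed TAD must be reachable by a planted 1-2 Mb pair (as the
    # target stretch or as the home TAD of a pair's bait gene); TADs the
    # geometry leaves unreachable are dropped from the planted truth
    if (length(repressed)) {
      slots <- repressed_lri_slots(layout)
      covered <- character()
      if (!is.null(slots)) {
        gene_tad <- assign_to_intervals(
          genes$chrom[slots$gene],
          interval_midpoint(genes$start[slots$gene], genes$end[slots$gene]),
          tads)
        covered <- union(slots$tad_id, tads$tad_id[gene_tad[!is.na(gene_tad)]])
      }
      layout$truth$repressed_tad_ids <- intersect(repressed, covered)
    }
    layout
  })
}

# inverse-CDF sample from a d^-alpha density on [dmin, dmax)
sample_decay_distance <- function(n, dmin, dmax, alpha) {
  u <- stats::runif(n)
  if (abs(alpha - 1) < 1e-12) {
    round(dmin * (dmax / dmin)^u)
  } else {
    a <- 1 - alpha
    round((dmin^a + u * (dmax^a - dmin^a))^(1 / a))
  }
}

# candidate placements for planted LRIs: genes whose bait midpoint lies in
# a repressed TAD, paired with stretches of (possibly another) repressed
# TAD lying 1-2 Mb away, so both LRI ends fall in repressed chromatin
repressed_lri_slots <- function(layout, sri_max = 1e6, lri_max = 2e6) {
  tads <- layout$tads
  rep_tads <- tads[tads$tad_id %in% layout$truth$repressed_tad_ids, ,
                   drop = FALSE]
  if (!nrow(rep_tads)) return(NULL)
  genes <- layout$genes
  frag <- layout$fragments
  gene_mid <- interval_midpoint(
    frag$start[match(genes$bait_fragment_id, frag$fragment_id)],
    frag$end[match(genes$bait_fragment_id, frag$fragment_id)])
  gene_tad <- assign_to_intervals(genes$chrom, gene_mid, tads)
  gene_repressed <- !is.na(gene_tad) &
    tads$tad_id[gene_tad] %in% layout$truth$repressed_tad_ids
  # at most two anchor promoters per repressed TAD carry planted LRIs;
  # the TAD's remaining genes stay bystanders
  anchor <- rep(FALSE, nrow(genes))
  for (tid in unique(tads$tad_id[gene_tad[gene_repressed]])) {
    members <- which(gene_repressed & tads$tad_id[gene_tad] == tid)
    anchor[utils::head(members, 2)] <- TRUE
  }
  gene_repressed <- gene_repressed & anchor
  # the placement must be long-range under both distance conventions:
  # fragment-midpoint distance (interaction classes) and distance from the
  # nearest gene end (eQTL windows); a 30-kb margin absorbs fragment and
  # gene-body offsets
  margin <- 3e4
  out <- list()
  for (i in seq_len(nrow(rep_tads))) {
    td <- rep_tads[i, ]
    on_c <- which(genes$chrom == td$chrom & gene_repressed)
    for (g in on_c) {
      m <- gene_mid[g]
      gs <- genes$start[g]; ge <- genes$end[g]
      for (side in c(-1, 1)) {
        if (side > 0) {
          lo <- max(m, ge) + sri_max + margin
          hi <- min(m, gs) + lri_max - margin
        } else {
          hi <- min(m, gs) - sri_max - margin
          lo <- max(m, ge) - lri_max + margin
        }
        s <- max(td$start, lo); e <- min(td$end, hi)
        if (e > s) {
          out[[length(out) + 1]] <- data.frame(
            gene = g, tad_id = td$tad_id, lo = s, hi = e, width = e - s)
        }
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# persistent pool of planted LRI pairs: pair identity (gene, other-end
# fragment) is fixed once, so time points sampling from the pool share
# interactions
build_planted_pool <- function(config, layout, slots, pool_size) {
  if (is.null(slots) || pool_size < 1) return(NULL)
  frag <- layout$fragments
  genes <- layout$genes
  got <- NULL
  for (attempt in 1:5) {
    need <- pool_size - (if (is.null(got)) 0 else nrow(got))
    if (need <= 0) break
    pick <- sample(nrow(slots), need * 2, replace = TRUE,
                   prob = slots$width)
    pos <- slots$lo[pick] +
      floor(stats::runif(length(pick)) * (slots$hi[pick] - slots$lo[pick]))
    oe_row <- assign_to_intervals(genes$chrom[slots$gene[pick]], pos, frag)
    ok <- !is.na(oe_row) &
      frag$fragment_id[oe_row] != genes$bait_fragment_id[slots$gene[pick]]
    cand <- data.frame(gene = slots$gene[pick][ok], oe_row = oe_row[ok])
    got <- unique(rbind(got, cand))
  }
  if (is.null(got) || !nrow(got)) return(NULL)
  # put one pair per distinct target TAD first, so truncation to the pool
  # size never leaves a repressed TAD without planted pairs
  frag <- layout$fragments
  oe_tad <- assign_to_intervals(
    frag$chrom[got$oe_row],
    interval_midpoint(frag$start[got$oe_row], frag$end[got$oe_row]),
    layout$tads)
  first <- !duplicated(oe_tad)
  got <- rbind(got[first, , drop = FALSE], got[!first, , drop = FALSE])
  utils::head(got, pool_size)
}

#' Generate per-time-point, per-replicate interaction calls
#'
#' Baits are gene promoter fragments. Each call's distance class is drawn
#' with the configured per-time-point probabilities (LRI proportion rising
#' across the time course, a small beyond-2-Mb class so the retention
#' filter is exercised) and, within each class, distance follows the
#' power-law decay. A configured fraction of LRIs is planted with the
#' other end inside a repressed TAD. Read support is shifted Poisson with
#' a lower mean for LRIs than SRIs; scores are >= 5 with a fraction of
#' sub-threshold decoy rows added. The second replicate is the first
#' thinned by the per-class retention probability.
#'
#' @param config A [synthetic_config()].
#' @param layout Output of [generate_genome_layout()].
#' @return List per time point of lists `rep1`, `rep2` (interaction
#'   tables), plus attribute-free `truth`: `planted_lri_pairs` (per time
#'   point, data.frame of bait/other-end fragment ids planted in repressed
#'   TADs) and `planted_bait_gene_ids`.
#' @export
generate_interaction_replicates <- function(config, layout) {
  with_seed(config$seed + 202L, {
    frag <- layout$fragments
    genes <- layout$genes
    bait_rows <- match(genes$bait_fragment_id, frag$fragment_id)
    bait_mid <- interval_midpoint(frag$start[bait_rows], frag$end[bait_rows])
    n <- config$interactions_per_replicate
    # heterogeneous promoter interactivity (Zipf-like): some promoters
    # interact heavily, many rarely — so LRI-only genes exist
    bait_w <- 1 / sample(seq_len(nrow(genes)))
    slots <- repressed_lri_slots(layout)
    quotas <- vapply(config$timepoints, function(tp) {
      round(round(n * config$lri_rate[[tp]]) *
              config$lri_frac_in_repressed)
    }, 0)
    pool <- build_planted_pool(config, layout, slots,
                               ceiling(1.3 * max(quotas)))
    out <- list()
    truth <- list(planted_lri_pairs = list(), planted_bait_gene_ids = character())
    # non-planted LRIs cluster at a few persistent hot loci (interaction-
    # dense regions like histone-gene clusters), shared across time points
    hot_genes <- sample(nrow(genes), 3, prob = bait_w)
    hot_target <- stats::setNames(
      sample_decay_distance(3, 1.1e6, 1.9e6,
                            config$distance_decay_exponent) *
        sample(c(-1L, 1L), 3, replace = TRUE),
      hot_genes)

    for (tp in config$timepoints) {
      n_lri <- round(n * config$lri_rate[[tp]])
      n_exc <- round(n * config$excluded_rate)
      n_sri <- n - n_lri - n_exc
      n_planted <- if (is.null(pool)) 0L else min(quotas[[tp]], nrow(pool))
      n_free_lri <- n_lri - n_planted

      draw_free <- function(m, dmin, dmax, from_hot = FALSE) {
        if (!m) return(NULL)
        if (from_hot) {
          # each hot locus loops to one tight target region
          g <- sample(hot_genes, m, replace = TRUE)
          d <- abs(hot_target[as.character(g)]) +
            round(stats::rnorm(m, 0, 5e4))
          side <- sign(hot_target[as.character(g)])
        } else {
          g <- sample(nrow(genes), m, replace = TRUE, prob = bait_w)
          d <- sample_decay_distance(m, dmin, dmax,
                                     config$distance_decay_exponent)
          side <- sample(c(-1L, 1L), m, replace = TRUE)
        }
        pos <- bait_mid[g] + side * d
        # reflect draws that leave the chromosome
        flip <- pos < 0 | pos >= config$chrom_length
        pos[flip] <- bait_mid[g][flip] - side[flip] * d[flip]
        pos <- pmax(0, pmin(pos, config$chrom_length - 1))
        oe_row <- assign_to_intervals(genes$chrom[g], pos, frag)
        ok <- !is.na(oe_row) &
          frag$fragment_id[oe_row] != genes$bait_fragment_id[g]
        data.frame(gene = g[ok], oe_row = oe_row[ok])
      }
      # class ranges are buffered by 25 kb so snapping a draw to its
      # fragment midpoint cannot move it across a class boundary
      placed <- rbind(
        draw_free(n_sri, config$min_distance, 1e6 - 2.5e4),
        draw_free(n_free_lri, 1e6, 2e6, from_hot = TRUE),
        draw_free(n_exc, 2e6 + 2.5e4, config$max_drawn_distance))
      planted <- if (n_planted > 0) {
        if (tp == config$timepoints[length(config$timepoints)]) {
          # terminal time point: repression fully established — the
          # coverage-ordered pool head touches every repressed TAD
          pool[seq_len(n_planted), , drop = FALSE]
        } else {
          pool[sample(nrow(pool), n_planted), , drop = FALSE]
        }
      } else NULL
      all_pl <- rbind(placed, planted)
      planted_flag <- c(rep(FALSE, if (is.null(placed)) 0 else nrow(placed)),
                        rep(TRUE, if (is.null(planted)) 0 else nrow(planted)))
      oe_row <- all_pl$oe_row
      g <- all_pl$gene
      br <- bait_rows[g]
      cls_lri <- abs(interval_midpoint(frag$start[br], frag$end[br]) -
                     interval_midpoint(frag$start[oe_row], frag$end[oe_row])) >= 1e6
      rc <- 1L + stats::rpois(length(g),
                              ifelse(cls_lri, config$lri_read_mean,
                                     config$sri_read_mean))
      tab <- data.frame(
        bait_chrom = frag$chrom[br], bait_start = frag$start[br],
        bait_end = frag$end[br], bait_id = frag$fragment_id[br],
        oe_chrom = frag$chrom[oe_row], oe_start = frag$start[oe_row],
        oe_end = frag$end[oe_row], oe_id = frag$fragment_id[oe_row],
        read_count = rc,
        score = 5 + stats::rexp(length(g), 1 / 3),
        timepoint = tp, replicate = "rep1",
        stringsAsFactors = FALSE)
      # decoys below the significance threshold
      n_dec <- round(nrow(tab) * config$decoy_rate)
      if (n_dec > 0) {
        dec <- tab[sample(nrow(tab), n_dec, replace = TRUE), , drop = FALSE]
        dec$score <- stats::runif(n_dec, 0, 4.999)
        tab <- rbind(tab, dec)
      }
      tab <- new_interactions(tab)
      dup <- duplicated(paste(pair_key(tab), tab$score >= 5))
      tab <- tab[!dup, , drop = FALSE]

      cls <- as.character(classify_distance(tab))
      keep2 <- stats::runif(nrow(tab)) <
        config$replicate_retention[cls]
      rep2 <- tab[keep2, , drop = FALSE]
      if (nrow(rep2)) rep2$replicate <- "rep2"
      out[[tp]] <- list(rep1 = tab, rep2 = rep2)

      planted_keys <- unique(data.frame(
        bait_id = frag$fragment_id[br[planted_flag]],
        oe_id = frag$fragment_id[oe_row[planted_flag]],
        stringsAsFactors = FALSE))
      truth$planted_lri_pairs[[tp]] <- planted_keys
      truth$planted_bait_gene_ids <- union(
        truth$planted_bait_gene_ids,
        genes$gene_id[g[planted_flag]])
    }
    attr(out, "truth") <- truth
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a chromHMM-like state segmentation
#'
#' Segments tile each chromosome. Within repressed TADs the quiescent
#' (Quies) fraction of segment length is drawn from Beta(8, 2) (mean 0.8);
#' elsewhere from Beta(2, 6) (mean 0.25). Non-quiescent segments sample a
#' state from the active, enhancer and promoter groups.
#'
#' @param config A [synthetic_config()].
#' @param layout Output of [generate_genome_layout()].
#' @return Segment table `chrom`, `start`, `end`, `state`.
#' @export
generate_chromatin_states <- function(config, layout) {
  with_seed(config$seed + 303L, {
    other_states <- c("Tx", "TxWk", "EnhA1", "EnhW1", "TssA", "PromU")
    other_w <- c(0.3, 0.2, 0.2, 0.1, 0.1, 0.1)
    segs <- lapply(seq_len(nrow(layout$tads)), function(i) {
      td <- layout$tads[i, ]
      repressed <- td$tad_id %in% layout$truth$repressed_tad_ids
      q <- if (repressed) stats::rbeta(1, 8, 2) else stats::rbeta(1, 2, 6)
      lens <- partition_lengths(td$end - td$start, 5000, 500)
      st <- ifelse(stats::runif(length(lens)) < q, "Quies",
                   sample(other_states, length(lens), replace = TRUE,
                          prob = other_w))
      data.frame(chrom = td$chrom,
                 start = td$start + cumsum(c(0, lens[-length(lens)])),
                 end = td$start + cumsum(lens), state = st,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, segs)
  })
}

# which genes are repression targets: genes whose midpoint lies in a
# repressed TAD, plus the bait genes of planted repressed-TAD LRIs
repressed_gene_ids <- function(layout, interaction_truth = NULL) {
  g <- layout$genes
  idx <- assign_to_intervals(g$chrom, interval_midpoint(g$start, g$end),
                             layout$tads)
  in_rep <- !is.na(idx) &
    layout$tads$tad_id[idx] %in% layout$truth$repressed_tad_ids
  ids <- g$gene_id[in_rep]
  if (!is.null(interaction_truth)) {
    ids <- union(ids, interaction_truth$planted_bait_gene_ids)
  }
  ids
}

#' Generate expression matrices
#'
#' Builds (i) a query matrix with one column per pCHi-C time point, (ii) a
#' reference matrix emulating an external differentiation course (columns
#' 0d, 1d, 3d, 7d, 14d; the query time points track stages 1d, 3d and
#' 14d), and (iii) a per-individual matrix for the eQTL analysis. Values
#' are 2^x with x Gaussian on the log2 scale; genes in repressed TADs and
#' planted-LRI bait genes are multiplied by `repression_multiplier` and
#' zero-inflated at the higher dropout rate.
#'
#' @param config A [synthetic_config()].
#' @param layout Output of [generate_genome_layout()].
#' @param interaction_truth Optional `truth` attribute of
#'   [generate_interaction_replicates()] (adds planted bait genes to the
#'   repression targets).
#' @return List: `query`, `reference`, `individual` (matrices with gene id
#'   row names), `timepoint_map` (query time point -> reference column),
#'   `repressed_gene_ids`.
#' @export
generate_expression <- function(config, layout, interaction_truth = NULL) {
  with_seed(config$seed + 404L, {
    g <- layout$genes
    ng <- nrow(g)
    mu <- stats::rnorm(ng, config$expr_mean, config$expr_sd)
    stages <- c("0d", "1d", "3d", "7d", "14d")
    traj <- t(apply(matrix(stats::rnorm(ng * length(stages), 0, 0.7), ng),
                    1, cumsum))
    query_stage <- c(PAd = 2L, Diff = 3L, Adip = 5L)
    rep_ids <- repressed_gene_ids(layout, interaction_truth)
    is_rep <- g$gene_id %in% rep_ids
    shift <- log2(config$repression_multiplier)

    noise <- function(n) stats::rnorm(n, 0, config$expr_noise_sd)
    mk <- function(stage_idx, repress) {
      x <- mu + traj[, stage_idx] + noise(ng)
      if (repress) x[is_rep] <- x[is_rep] + shift
      drop_p <- ifelse(repress & is_rep, config$dropout_repressed,
                       config$dropout_base)
      val <- 2^x
      val[stats::runif(ng) < drop_p] <- 0
      val
    }
    query <- vapply(config$timepoints,
                    function(tp) mk(query_stage[[tp]], TRUE), numeric(ng))
    reference <- vapply(seq_along(stages),
                        function(s) mk(s, FALSE), numeric(ng))
    colnames(reference) <- stages
    rownames(query) <- rownames(reference) <- g$gene_id

    ind <- matrix(stats::rnorm(ng * config$n_individuals, 0, 1), ng)
    ind <- (mu + ifelse(is_rep, shift, 0)) + ind
    val <- 2^ind
    val[matrix(stats::runif(length(val)) < 0.02, nrow(val))] <- 0
    rownames(val) <- g$gene_id
    colnames(val) <- sprintf("ind%03d", seq_len(config$n_individuals))

    list(query = query, reference = reference, individual = val,
         timepoint_map = stats::setNames(stages[query_stage],
                                         names(query_stage)),
         repressed_gene_ids = rep_ids)
  })
}

#' Generate accessibility reads with planted A/B compartment blocks
#'
#' Chromosomes alternate A/B blocks of the configured length (A first).
#' Per 100-kb bin and sample, the read count is Poisson with log intensity
#' base + loading x sample factor + noise: B bins carry the larger loading
#' on the shared per-sample factor (they co-vary more strongly, the fact
#' the orientation rule relies on) and a lower mean count. Counts are
#' emitted as uniformly placed read midpoints.
#'
#' @param config A [synthetic_config()].
#' @param layout Output of [generate_genome_layout()] (chromosome set).
#' @return List: `reads` (named list per sample of `chrom`,`pos` tables),
#'   `meta` (sample metadata with `sample_id`, `timepoint`, `frip`,
#'   `total_reads`), `truth_labels` (data.frame `chrom`, `start`, `end`,
#'   `label` per 100-kb bin).
#' @export
generate_accessibility <- function(config, layout) {
  with_seed(config$seed + 505L, {
    bin_size <- 1e5
    chroms <- names(layout$chrom_lengths)
    bins <- do.call(rbind, lapply(chroms, function(cc) {
      n <- ceiling(layout$chrom_lengths[[cc]] / bin_size)
      data.frame(chrom = cc, start = (seq_len(n) - 1) * bin_size,
                 end = pmin(seq_len(n) * bin_size,
                            layout$chrom_lengths[[cc]]),
                 stringsAsFactors = FALSE)
    }))
    block <- floor(interval_midpoint(bins$start, bins$end) /
                   config$compartment_block_length)
    bins$label <- ifelse(block %% 2 == 0, "A", "B")

    ns <- config$n_access_samples
    # shared factor standardized to unit realized spread, so the planted
    # co-variation strength does not wobble with the sample draw
    fac <- as.numeric(scale(stats::rnorm(ns)))
    frip <- stats::runif(ns, 0.25, 0.45)
    base <- ifelse(bins$label == "A", log(config$access_mean_a),
                   log(config$access_mean_b))
    loading <- ifelse(bins$label == "A", config$access_loading_a,
                      config$access_loading_b)
    noise_sd <- ifelse(bins$label == "A", config$access_noise_sd_a,
                       config$access_noise_sd_b)
    reads <- list()
    total <- integer(ns)
    for (s in seq_len(ns)) {
      lam <- exp(base + loading * fac[s] +
                 stats::rnorm(nrow(bins), 0, noise_sd) +
                 1.5 * (frip[s] - 0.35))
      cnt <- stats::rpois(nrow(bins), lam)
      pos <- unlist(lapply(which(cnt > 0), function(i) {
        bins$start[i] +
          floor(stats::runif(cnt[i]) * (bins$end[i] - bins$start[i]))
      }))
      reads[[sprintf("s%02d", s)]] <- data.frame(
        chrom = rep(bins$chrom, cnt), pos = as.integer(pos),
        stringsAsFactors = FALSE)
      total[s] <- sum(cnt)
    }
    meta <- data.frame(sample_id = names(reads),
                       timepoint = rep(config$timepoints,
                                       length.out = length(reads)),
                       frip = frip, total_reads = total,
                       stringsAsFactors = FALSE)
    list(reads = reads, meta = meta,
         truth_labels = bins[, c("chrom", "start", "end", "label")])
  })
}

#' Generate genotypes with LD blocks and one planted long-range eQTL
#'
#' Background SNPs sit on a regular grid; one extra SNP is planted inside
#' the other-end fragment of each planted repressed-TAD LRI of the last
#' time point, so long-range candidate pairs are interaction-supported by
#' construction. Within each LD block, individuals' haplotypes copy one of
#' two founder haplotypes (mixing probability per block), then flip per
#' SNP at the mutation rate: R^2 decays within blocks and is near zero
#' across blocks. One planted SNP-gene pair (`truth$planted_eqtl`) gets an
#' additive effect of `eqtl_beta` log2-SD units per dosage added to the
#' individual expression matrix by [simulate_study()].
#'
#' @param config A [synthetic_config()].
#' @param layout Output of [generate_genome_layout()].
#' @param interaction_truth `truth` attribute of
#'   [generate_interaction_replicates()].
#' @return List: `geno` (list `snps`, `dosages`), `truth` (`planted_eqtl`:
#'   `snp_id`, `gene_id`, `beta`).
#' @export
generate_genotypes <- function(config, layout, interaction_truth) {
  with_seed(config$seed + 606L, {
    frag <- layout$fragments
    genes <- layout$genes
    chroms <- names(layout$chrom_lengths)
    grid <- do.call(rbind, lapply(chroms, function(cc) {
      pos <- seq(config$snp_spacing / 2, layout$chrom_lengths[[cc]] - 1,
                 by = config$snp_spacing)
      data.frame(chrom = cc, pos = as.integer(pos), stringsAsFactors = FALSE)
    }))
    # planted SNPs inside other ends of planted LRIs (last time point):
    # two per fragment, so long-range candidate pairs are plentiful; the
    # causal fragment gets a single SNP at its midpoint
    tp <- config$timepoints[length(config$timepoints)]
    planted_pairs <- interaction_truth$planted_lri_pairs[[tp]]
    planted <- NULL
    causal_oe <- NA_character_
    if (!is.null(planted_pairs) && nrow(planted_pairs)) {
      causal_oe <- planted_pairs$oe_id[1]
      oe <- frag[match(setdiff(unique(planted_pairs$oe_id), causal_oe),
                       frag$fragment_id), ]
      w <- oe$end - oe$start
      planted <- data.frame(
        chrom = c(oe$chrom, oe$chrom,
                  frag$chrom[frag$fragment_id == causal_oe]),
        pos = c(oe$start + floor(w / 3), oe$start + floor(2 * w / 3),
                interval_midpoint(frag$start[frag$fragment_id == causal_oe],
                                  frag$end[frag$fragment_id == causal_oe])),
        stringsAsFactors = FALSE)
    }
    snps <- rbind(grid, planted)
    snps <- snps[order(snps$chrom, snps$pos), ]
    snps <- snps[!duplicated(paste(snps$chrom, snps$pos)), ]
    snps$snp_id <- sprintf("snp%05d", seq_len(nrow(snps)))
    snps$info <- round(stats::runif(nrow(snps), 0.75, 1), 3)

    # the causal pair: the first planted LRI of the last time point
    causal_snp <- NA_character_; causal_gene <- NA_character_
    if (!is.na(causal_oe)) {
      co <- frag[frag$fragment_id == causal_oe, ]
      causal_snp <- snps$snp_id[snps$chrom == co$chrom &
                                snps$pos == interval_midpoint(co$start, co$end)]
      causal_gene <- genes$gene_id[match(planted_pairs$bait_id[1],
                                         genes$bait_fragment_id)]
    }
    snps$info[snps$snp_id %in% causal_snp] <- 0.99

    block <- paste(snps$chrom,
                   floor(snps$pos / config$ld_block_length))
    n_ind <- config$n_individuals
    dos <- matrix(0L, nrow(snps), n_ind,
                  dimnames = list(snps$snp_id,
                                  sprintf("ind%03d", seq_len(n_ind))))
    for (b in unique(block)) {
      rows <- which(block == b)
      m <- length(rows)
      hA <- stats::rbinom(m, 1, stats::runif(m, 0.1, 0.9))
      hB <- stats::rbinom(m, 1, stats::runif(m, 0.1, 0.9))
      theta <- stats::runif(1, 0.2, 0.8)
      has_causal <- any(snps$snp_id[rows] %in% causal_snp)
      if (has_causal) {
        theta <- config$eqtl_maf
        i <- which(snps$snp_id[rows] %in% causal_snp)
        hA[i] <- 1L; hB[i] <- 0L
      }
      for (h in 1:2) {
        pickA <- stats::rbinom(n_ind, 1, theta)
        hap <- outer(hA, pickA) + outer(hB, 1 - pickA)  # m x n_ind
        flip <- matrix(stats::rbinom(m * n_ind, 1,
                                     config$ld_mutation_rate), m)
        if (has_causal) flip[which(snps$snp_id[rows] %in% causal_snp), ] <- 0L
        hap <- (hap + flip) %% 2
        dos[rows, ] <- dos[rows, ] + hap
      }
    }
    list(geno = list(snps = snps[, c("snp_id", "chrom", "pos", "info")],
                     dosages = dos),
         truth = list(planted_eqtl = list(snp_id = causal_snp,
                                          gene_id = causal_gene,
                                          beta = config$eqtl_beta)))
  })
}

#' Sample marker genes and feature intervals
#'
#' Marker genes for the first and last time points are sampled with
#' weights keyed to the realized LRI-TAD category of each gene's TAD
#' (early markers favour always- or transiently-repressed TADs, late
#' markers favour non-LRI TADs). Features (super-enhancer stand-ins) are
#' placed uniformly at random: a null feature generator.
#'
#' @param config A [synthetic_config()].
#' @param layout Genome layout.
#' @param annotations TAD annotation table from [classify_tads()].
#' @return List: `markers` (named list of gene tables), `features`
#'   (interval table).
#' @export
generate_markers_and_features <- function(config, layout, annotations) {
  with_seed(config$seed + 707L, {
    g <- layout$genes
    idx <- assign_to_intervals(g$chrom, interval_midpoint(g$start, g$end),
                               layout$tads)
    cat_of <- rep(NA_character_, nrow(g))
    cat_of[!is.na(idx)] <- annotations$category[
      match(layout$tads$tad_id[idx[!is.na(idx)]], annotations$tad_id)]
    tps <- config$timepoints
    early <- tps[1]; late <- tps[length(tps)]
    w_early <- ifelse(cat_of %in% c("all", paste(tps[2], "only")), 4, 1)
    w_late <- ifelse(cat_of %in% "non-LRI", 4, 1)
    pick <- function(w, n) g[sample(nrow(g), min(n, nrow(g)), prob = w),
                             c("gene_id", "chrom", "start", "end")]
    markers <- list(pick(w_early, config$n_markers[[early]]),
                    pick(w_late, config$n_markers[[late]]))
    names(markers) <- c(early, late)

    features <- do.call(rbind, lapply(seq_len(config$n_features), function(i) {
      cc <- sample(names(layout$chrom_lengths), 1)
      s <- floor(stats::runif(1) *
                 (layout$chrom_lengths[[cc]] - config$feature_width))
      data.frame(chrom = cc, start = s, end = s + config$feature_width,
                 stringsAsFactors = FALSE)
    }))
    list(markers = markers, features = features)
  })
}

#' Generate the complete synthetic study
#'
#' Runs every generator and wires the planted eQTL effect into the
#' per-individual expression matrix.
#'
#' @param config A [synthetic_config()].
#' @param components Character vector choosing what to generate (any of
#'   `"interactions"`, `"states"`, `"expression"`, `"accessibility"`,
#'   `"genotypes"`); the layout is always generated.
#' @return List: `config`, `layout`, `interactions`, `states`,
#'   `expression`, `accessibility`, `geno`, `truth` (merged planted truth).
#' @export
simulate_study <- function(config = synthetic_config(),
                           components = c("interactions", "states",
                                          "expression", "accessibility",
                                          "genotypes")) {
  layout <- generate_genome_layout(config)
  out <- list(config = config, layout = layout,
              truth = layout$truth)
  if ("interactions" %in% components ||
      any(c("expression", "genotypes") %in% components)) {
    out$interactions <- generate_interaction_replicates(config, layout)
    out$truth <- c(out$truth, attr(out$interactions, "truth"))
  }
  if ("states" %in% components) {
    out$states <- generate_chromatin_states(config, layout)
  }
  if ("expression" %in% components) {
    out$expression <- generate_expression(config, layout,
                                          attr(out$interactions, "truth"))
  }
  if ("accessibility" %in% components) {
    out$accessibility <- generate_accessibility(config, layout)
    out$truth$compartment_labels <- out$accessibility$truth_labels
  }
  if ("genotypes" %in% components) {
    gg <- generate_genotypes(config, layout,
                             attr(out$interactions, "truth"))
    out$geno <- gg$geno
    out$truth$planted_eqtl <- gg$truth$planted_eqtl
    pe <- gg$truth$planted_eqtl
    if (!is.na(pe$snp_id) && "expression" %in% components &&
        pe$gene_id %in% rownames(out$expression$individual)) {
      dos <- out$geno$dosages[pe$snp_id, ]
      x <- out$expression$individual[pe$gene_id, ]
      lx <- log2(x + 1)
      lx <- lx + pe$beta * 1 * dos  # per-individual log2 SD is 1
      out$expression$individual[pe$gene_id, ] <- pmax(0, 2^lx - 1)
    }
  }
  out
}
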