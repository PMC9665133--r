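test_that("config validation rejects bad probabilities and lengths", {
  expect_error(synthetic_config(frac_repressed_tads = 1.2), "probability")
  expect_error(synthetic_config(chrom_length = -1), "positive")
  expect_s3_class(synthetic_config(), "synthetic_config")
})

test_that("fragments and TADs partition every chromosome; seeds reproduce", {
  cfg <- synthetic_config(seed = 3, n_chromosomes = 2, chrom_length = 4e6)
  lay <- generate_genome_layout(cfg)
  for (cc in names(lay$chrom_lengths)) {
    for (part in list(lay$fragments, lay$tads)) {
      p <- part[part$chrom == cc, ]
      p <- p[order(p$start), ]
      expect_equal(p$start[1], 0)
      expect_equal(p$end[nrow(p)], unname(lay$chrom_lengths[cc]))
      expect_true(all(p$start[-1] == p$end[-nrow(p)]))  # no gaps/overlaps
    }
  }
  expect_false(anyDuplicated(lay$fragments$fragment_id) > 0)
  expect_false(anyDuplicated(lay$genes$gene_id) > 0)
  lay2 <- generate_genome_layout(cfg)
  expect_identical(lay, lay2)

  none <- generate_genome_layout(synthetic_config(seed = 3,
                                                  frac_repressed_tads = 0))
  expect_length(none$truth$repressed_tad_ids, 0)
})

test_that("replicate retention drives concordance as configured", {
  cfg1 <- synthetic_config(seed = 4, interactions_per_replicate = 1500,
                           replicate_retention = c(SRI = 1, LRI = 1,
                                                   excluded = 1))
  st1 <- simulate_study(cfg1, components = "interactions")
  cc1 <- replicate_concordance(
    filter_significant(st1$interactions$PAd$rep1),
    filter_significant(st1$interactions$PAd$rep2))
  expect_true(all(cc1$proportion[!is.na(cc1$proportion)] == 1))

  cfg0 <- synthetic_config(seed = 4, interactions_per_replicate = 1500,
                           replicate_retention = c(SRI = 0, LRI = 0,
                                                   excluded = 0))
  st0 <- simulate_study(cfg0, components = "interactions")
  expect_equal(nrow(st0$interactions$PAd$rep2), 0L)
})

test_that("planted LRI proportions rise by the configured fold change", {
  study <- simulate_study(synthetic_config(seed = 5),
                          components = "interactions")
  f <- lapply(c("PAd", "Diff"), function(tp)
    filter_significant(study$interactions[[tp]]$rep1))
  prop <- vapply(f, function(x) mean(classify_distance(x) == "LRI"), 0)
  fc <- proportion_fold_change(prop[1], prop[2])
  expect_lt(abs(fc - 2.6 / 1.1) / (2.6 / 1.1), 0.15)
})

test_that("interaction generator output satisfies the reader invariants", {
  study <- simulate_study(synthetic_config(seed = 6),
                          components = "interactions")
  x <- study$interactions$Diff$rep1
  expect_true(all(x$bait_start < x$bait_end))
  expect_true(all(x$oe_start < x$oe_end))
  expect_true(all(x$bait_id != x$oe_id))
  expect_true(all(x$read_count >= 1))
  # decoys exist below the score threshold and are filtered out
  expect_gt(sum(x$score < 5), 0)
  f <- filter_significant(x)
  expect_true(all(f$score >= 5))
  # round-trip through the ibed writer is exact
  path <- withr::local_tempfile(fileext = ".ibed")
  write_interaction_table(x, path)
  y <- read_interaction_table(path, "ibed")
  expect_equal(y$bait_id, x$bait_id)
  expect_equal(y$score, x$score)
})

test_that("chromatin states tile the genome with planted quiescence", {
  cfg <- synthetic_config(seed = 7)
  study <- simulate_study(cfg, components = "states")
  segs <- study$states
  for (cc in names(study$layout$chrom_lengths)) {
    s <- segs[segs$chrom == cc, ]
    s <- s[order(s$start), ]
    expect_equal(sum(s$end - s$start),
                 unname(study$layout$chrom_lengths[cc]))
    expect_true(all(s$start[-1] == s$end[-nrow(s)]))
  }
  cov <- tad_state_coverage(study$layout$tads, segs)
  rep_ids <- study$truth$repressed_tad_ids
  in_rep <- cov$tad_id %in% rep_ids
  # Beta(8,2) vs Beta(2,6): means 0.8 and 0.25
  expect_equal(mean(cov$quiescent[in_rep]), 0.8, tolerance = 0.12)
  expect_equal(mean(cov$quiescent[!in_rep]), 0.25, tolerance = 0.12)
})

test_that("expression generator plants the repression multiplier", {
  cfg <- synthetic_config(seed = 8, dropout_base = 0, dropout_repressed = 0)
  study <- simulate_study(cfg, components = c("interactions", "expression"))
  ex <- study$expression
  rep_ids <- ex$repressed_gene_ids
  lq <- log2(ex$query + 1)
  diff <- mean(lq[rownames(lq) %in% rep_ids, "Adip"]) -
    mean(lq[!rownames(lq) %in% rep_ids, "Adip"])
  # multiplier 0.5 is one log2 unit down
  expect_equal(diff, -1, tolerance = 0.35)

  # multiplier 1: arms indistinguishable
  cfg1 <- synthetic_config(seed = 8, repression_multiplier = 1,
                           dropout_base = 0, dropout_repressed = 0)
  st1 <- simulate_study(cfg1, components = c("interactions", "expression"))
  l1 <- log2(st1$expression$query + 1)
  r1 <- st1$expression$repressed_gene_ids
  p <- t.test(l1[rownames(l1) %in% r1, "Adip"],
              l1[!rownames(l1) %in% r1, "Adip"])$p.value
  expect_gt(p, 0.01)
})

test_that("genotypes: dosage range, HWE-consistent blocks, LD structure", {
  study <- simulate_study(synthetic_config(seed = 9),
                          components = c("interactions", "genotypes"))
  dos <- study$geno$dosages
  expect_true(all(dos %in% 0:2))
  pe <- study$truth$planted_eqtl
  expect_equal(mean(dos[pe$snp_id, ]) / 2, 0.3, tolerance = 0.08)

  # within-block r2 exceeds across-block r2 on average
  snps <- study$geno$snps
  blk <- paste(snps$chrom, floor(snps$pos / 1e5))
  one_block <- names(which(table(blk) >= 3))[1]
  rows <- which(blk == one_block)
  sub <- dos[rows[1:3], ]
  r2_in <- ld_r2_matrix(sub)
  other <- which(blk != one_block)[1:3]
  r2_across <- cor(t(dos[c(rows[1], other[1]), ]))[1, 2]^2
  expect_gt(mean(r2_in[upper.tri(r2_in)], na.rm = TRUE),
            min(1, r2_across + 0.05))

  # the planted SNP sits inside a planted LRI other end and is supported
  f <- filter_significant(study$interactions$Adip$rep1)
  pairs <- data.frame(snp_id = pe$snp_id, gene_id = pe$gene_id,
                      distance = 1.5e6, window_class = "long")
  sup <- restrict_pairs_by_interaction(pairs, f, study$layout$genes,
                                       study$geno$snps)
  expect_true(sup$interaction_supported)
})

test_that("accessibility generator marks meta invariants and block truth", {
  study <- simulate_study(synthetic_config(seed = 10),
                          components = "accessibility")
  meta <- study$accessibility$meta
  expect_true(all(meta$frip > 0 & meta$frip <= 1))
  expect_true(all(meta$total_reads > 0))
  expect_equal(meta$total_reads,
               vapply(study$accessibility$reads, nrow, 0L),
               ignore_attr = TRUE)
  labels <- study$accessibility$truth_labels
  expect_true(all(labels$label %in% c("A", "B")))
  # blocks alternate at the configured length (2.5 Mb by default)
  chr1 <- labels[labels$chrom == "chr1", ]
  expect_equal(unique(chr1$label[chr1$start < 2.5e6]), "A")
  expect_equal(unique(chr1$label[chr1$start >= 2.5e6 & chr1$start < 5e6]),
               "B")
})

test_that("the full study is a pure function of the seed", {
  a <- simulate_study(synthetic_config(seed = 11))
  b <- simulate_study(synthetic_config(seed = 11))
  expect_identical(a, b)
  c2 <- simulate_study(synthetic_config(seed = 12))
  expect_false(identical(a$layout$fragments, c2$layout$fragments))
})
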