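test_that("expressed-fraction gene filter is strict", {
  m <- rbind(all10 = rep(1, 10),
             nine = c(rep(1, 9), 0),
             exactly9of10 = c(rep(2, 9), 0))
  expect_equal(filter_expressed_genes(m, 0.90), "all10")
  m2 <- rbind(g1 = rep(1, 10))
  expect_equal(filter_expressed_genes(m2), "g1")
})

test_that("SNP filters: info, MAF folding, HWE on rounded dosages", {
  n <- 100
  dos <- rbind(
    mono = rep(0, n),
    common = rep(c(0, 1, 2), length.out = n),
    lowinfo = rep(c(0, 1), n / 2),
    nohet = c(rep(0, n / 2), rep(2, n / 2)),
    folded = rep(2, n) - rep(c(0, 1, 2), length.out = n))
  snps <- data.frame(snp_id = rownames(dos), chrom = "chr1",
                     pos = 1:5 * 1000,
                     info = c(1, 1, 0.79, 1, 1))
  g <- filter_snps(list(snps = snps, dosages = dos))
  audit <- attr(g, "filter_audit")
  expect_false("mono" %in% g$snps$snp_id)     # MAF 0
  expect_false("lowinfo" %in% g$snps$snp_id)  # info < 0.8
  expect_false("nohet" %in% g$snps$snp_id)    # HWE chi-square = n
  expect_true(all(c("common", "folded") %in% g$snps$snp_id))
  expect_equal(unname(audit["info"]), 1L)
  expect_equal(unname(audit["hwe"]), 1L)

  # 50/50 hom-ref / hom-alt with no hets: chi-square equals n
  p <- 0.5
  expected <- n * c(0.25, 0.5, 0.25)
  chi <- sum((c(50, 0, 50) - expected)^2 / expected)
  expect_equal(chi, n)
  expect_lt(pchisq(chi, 1, lower.tail = FALSE), 1e-5)
})

test_that("OLS association is exact on constructed inputs", {
  dos <- c(0, 1, 2, 0, 1, 2, 1, 0)
  r <- ols_association(dos, 2 * dos)
  expect_equal(r$beta, 2)
  expect_lt(r$p_value, 1e-12)

  # response orthogonal to centred dosage: beta exactly 0
  y <- c(1, -2, 1, 1, -2, 1, -2, 2)
  y <- y - mean(y)
  y <- y - sum(y * (dos - mean(dos))) / sum((dos - mean(dos))^2) *
    (dos - mean(dos))
  r0 <- ols_association(dos, y)
  expect_equal(r0$beta, 0, tolerance = 1e-12)

  expect_error(ols_association(rep(1, 10), rnorm(10)), "rank-deficient")
})

test_that("OLS matches the normal-equations oracle on random instances", {
  set.seed(14)
  for (i in 1:30) {
    n <- sample(20:60, 1)
    dos <- rbinom(n, 2, 0.4)
    if (var(dos) == 0) next
    cov <- matrix(rnorm(n * 2), n)
    y <- 0.3 * dos + cov %*% c(1, -2) + rnorm(n)
    got <- ols_association(dos, as.numeric(y), cov)
    X <- cbind(1, dos, cov)
    bh <- solve(t(X) %*% X, t(X) %*% y)
    res <- y - X %*% bh
    s2 <- sum(res^2) / (n - ncol(X))
    se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
    expect_equal(got$beta, bh[2], tolerance = 1e-10)
    expect_equal(got$t_stat, bh[2] / se, tolerance = 1e-10)
    expect_equal(got$p_value,
                 2 * pt(abs(bh[2] / se), n - ncol(X), lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("candidate pairs use min distance from either gene end", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1",
                      start = 5e6, end = 5.02e6)
  snps <- data.frame(snp_id = paste0("s", 1:5), chrom = "chr1",
                     pos = c(4.5e6,   # 500 kb upstream: short
                             5.01e6,  # inside the gene: distance 0
                             6.52e6,  # 1.5 Mb downstream: long
                             7.02e6,  # exactly 2 Mb: excluded
                             3.2e6))  # 1.8 Mb upstream: long
  pr <- enumerate_candidate_pairs(genes, snps)
  expect_equal(pr$snp_id, c("s1", "s2", "s3", "s5"))
  expect_equal(pr$window_class, c("short", "short", "long", "long"))
  expect_equal(pr$distance[pr$snp_id == "s2"], 0L)
})

test_that("interaction support needs bait match, containment and class", {
  frags <- rbind(make_frag("chr1", 5e6, 5.004e6, "bait"),
                 make_frag("chr1", 6.5e6, 6.504e6, "oe_long"),
                 make_frag("chr1", 5.5e6, 5.504e6, "oe_short"))
  ints <- make_interactions(frags, c("bait", "bait"),
                            c("oe_long", "oe_short"))
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(5e6, 5e6), end = c(5.02e6, 5.02e6),
                      bait_fragment_id = c("bait", NA))
  snps <- data.frame(snp_id = paste0("s", 1:4), chrom = "chr1",
                     pos = c(6.5e6,          # inside oe_long
                             6.504e6,        # 1 bp past the half-open end
                             6.503999e6 + 1, # still outside
                             5.5e6))         # inside oe_short
  pairs <- data.frame(
    snp_id = c("s1", "s2", "s1", "s4"),
    gene_id = c("g1", "g1", "g2", "g1"),
    distance = c(1.49e6, 1.49e6, 1.49e6, 4.9e5),
    window_class = c("long", "long", "long", "short"))
  out <- restrict_pairs_by_interaction(pairs, ints, genes, snps)
  expect_equal(out$interaction_supported, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(attr(out, "n_genes_without_bait"), 1L)
})

test_that("greedy LD pruning counts independent signals", {
  ld <- function(m, ids) { dimnames(m) <- list(ids, ids); m }
  res <- data.frame(snp_id = c("a", "b", "c"),
                    p_value = c(0.001, 0.01, 0.02))
  # all in perfect LD: one signal
  m1 <- ld(matrix(1, 3, 3), res$snp_id)
  expect_equal(count_independent_and_adjust(res, m1)$n_independent[1], 1L)
  # no LD: three signals
  m0 <- ld(diag(3), res$snp_id)
  r0 <- count_independent_and_adjust(res, m0)
  expect_equal(r0$n_independent[1], 3L)
  expect_equal(r0$p_adj, pmin(1, res$p_value * 3))
  # chain: r2(a,b)=0.5 blocks b; c independent -> {a, c}
  mc <- ld(matrix(c(1, 0.5, 0.1,
                    0.5, 1, 0.1,
                    0.1, 0.1, 1), 3, byrow = TRUE), res$snp_id)
  rc <- count_independent_and_adjust(res, mc)
  expect_equal(rc$n_independent[1], 2L)
  expect_equal(rc$is_index_snp, c(TRUE, FALSE, TRUE))
  # missing entries error
  expect_error(count_independent_and_adjust(res, ld(diag(2), c("a", "b"))),
               "missing")
})

test_that("LD matrix is squared Pearson correlation of dosages", {
  set.seed(15)
  dos <- matrix(rbinom(40, 2, 0.5), 4,
                dimnames = list(paste0("s", 1:4), NULL))
  r2 <- ld_r2_matrix(dos)
  expect_equal(r2[1, 2], cor(dos[1, ], dos[2, ])^2)
  expect_equal(diag(r2), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(r2 >= 0 & r2 <= 1, na.rm = TRUE))
})

test_that("short-range FDR check follows hand-computed BH q-values", {
  short <- data.frame(snp_id = c("a", "b", "c", "d"),
                      p_value = c(0.01, 0.02, 0.04, 0.5),
                      interaction_supported = TRUE)
  q <- p.adjust(short$p_value, "BH")
  expect_equal(q, c(0.04, 0.04, 4 * 0.04 / 3, 0.5))
  flags <- short_range_fdr_check(c("a", "c", "d", "zz"), short)
  expect_equal(unname(flags), c(TRUE, FALSE, FALSE, FALSE))
  # unsupported pairs never flag
  short$interaction_supported <- FALSE
  expect_false(any(short_range_fdr_check("a", short)))
})

test_that("the planted long-range eQTL is recovered end to end", {
  study <- simulate_study(synthetic_config(seed = 2),
                          components = c("interactions", "expression",
                                         "genotypes"))
  f <- filter_significant(study$interactions$Adip$rep1)
  eq <- run_eqtl(study$expression$individual, study$geno,
                 study$layout$genes, f)
  pe <- study$truth$planted_eqtl
  hit <- eq$long[eq$long$snp_id == pe$snp_id &
                 eq$long$gene_id == pe$gene_id, ]
  expect_equal(nrow(hit), 1L)
  expect_lt(hit$p_adj, 0.05)
  expect_gt(hit$beta, 0)
  expect_gte(nrow(eq$long), 100)  # plenty of null pairs alongside
})
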