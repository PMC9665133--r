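tads3 <- data.frame(chrom = "chr1", start = c(0, 1e6, 2e6),
                    end = c(1e6, 2e6, 3e6), tad_id = c("t1", "t2", "t3"),
                    stringsAsFactors = FALSE)
frag_at <- function(pos, chrom = "chr1") {
  data.frame(chrom = rep(chrom, length(pos)), start = pos, end = pos + 4000,
             stringsAsFactors = FALSE)
}

test_that("TADs are categorized by which time points contribute LRI ends", {
  lri_ends <- list(PAd = frag_at(5e5), Diff = frag_at(numeric()),
                   Adip = frag_at(numeric()))
  all_ends <- rbind(frag_at(5e5), frag_at(1.5e6))
  ann <- classify_tads(lri_ends, all_ends, tads3)
  expect_equal(ann$category, c("PAd only", "non-LRI", "excluded"))
  expect_equal(ann$has_any_interaction, c(TRUE, TRUE, FALSE))

  # all three time points
  lri_all <- list(PAd = frag_at(5e5), Diff = frag_at(5.2e5),
                  Adip = frag_at(5.4e5))
  ann2 <- classify_tads(lri_all, frag_at(5e5), tads3)
  expect_equal(ann2$category[1], "all")

  # two named time points
  lri_two <- list(PAd = frag_at(numeric()), Diff = frag_at(5e5),
                  Adip = frag_at(5.4e5))
  ann3 <- classify_tads(lri_two, frag_at(5e5), tads3)
  expect_equal(ann3$category[1], "Diff and Adip")
})

test_that("every TAD gets exactly one category and counts sum", {
  set.seed(5)
  study <- simulate_study(synthetic_config(seed = 5),
                          components = "interactions")
  tps <- c("PAd", "Diff", "Adip")
  filt <- lapply(tps, function(tp)
    filter_significant(study$interactions[[tp]]$rep1))
  names(filt) <- tps
  ends <- function(x, cl = NULL) {
    if (!is.null(cl)) x <- x[classify_distance(x) == cl, ]
    data.frame(chrom = c(x$bait_chrom, x$oe_chrom),
               start = c(x$bait_start, x$oe_start),
               end = c(x$bait_end, x$oe_end))
  }
  ann <- classify_tads(
    stats::setNames(lapply(filt, ends, "LRI"), tps),
    do.call(rbind, lapply(filt, ends)), study$layout$tads)
  expect_equal(nrow(ann), nrow(study$layout$tads))
  expect_equal(sum(table(ann$category)), nrow(ann))
  # the invariant linking category to flags
  expect_true(all((ann$category == "excluded") == !ann$has_any_interaction))
  expect_true(all((ann$category == "non-LRI") ==
                  (ann$has_any_interaction & ann$n_timepoints == 0)))
})

test_that("fragment state assignment picks the top-coverage group", {
  segs <- data.frame(chrom = "chr1",
                     start = c(0, 6000), end = c(6000, 10000),
                     state = c("EnhA1", "TssA"), stringsAsFactors = FALSE)
  # 60% enhancer / 40% promoter
  expect_equal(fragment_state_assignment(
    data.frame(chrom = "chr1", start = 0, end = 10000), segs), "enhancer")
  # exact 50/50: promoter wins by the documented tie-break
  segs5050 <- data.frame(chrom = "chr1", start = c(0, 5000),
                         end = c(5000, 10000),
                         state = c("TssA", "EnhA1"))
  expect_equal(fragment_state_assignment(
    data.frame(chrom = "chr1", start = 0, end = 10000), segs5050),
    "promoter")
  # fully quiescent
  expect_equal(fragment_state_assignment(
    data.frame(chrom = "chr1", start = 100, end = 1100),
    data.frame(chrom = "chr1", start = 0, end = 5000, state = "Quies")),
    "quiescent")
  # no overlap at all
  expect_equal(fragment_state_assignment(
    data.frame(chrom = "chr2", start = 0, end = 1000), segs), "other")
})

test_that("fragment state assignment matches a per-base majority oracle", {
  set.seed(21)
  groups <- default_state_groups()
  states <- c(names(groups), "Unknown")
  order_rank <- stats::setNames(seq_along(lriscape:::.group_order),
                                lriscape:::.group_order)
  for (i in 1:40) {
    # random tiling of [0, 10 kb) and a random fragment inside
    cuts <- sort(sample(1:9999, sample(3:12, 1)))
    seg <- data.frame(chrom = "chr1", start = c(0, cuts),
                      end = c(cuts, 10000),
                      state = sample(states, length(cuts) + 1,
                                     replace = TRUE))
    fr <- sort(sample(0:10000, 2))
    if (fr[1] == fr[2]) next
    frag <- data.frame(chrom = "chr1", start = fr[1], end = fr[2])
    got <- fragment_state_assignment(frag, seg, groups)
    # oracle: per-base group labels, majority with fixed-order tie-break
    base_group <- character(fr[2] - fr[1])
    for (j in seq_len(nrow(seg))) {
      lo <- max(seg$start[j], fr[1]); hi <- min(seg$end[j], fr[2])
      if (hi > lo) {
        g <- groups[seg$state[j]]
        base_group[(lo - fr[1] + 1):(hi - fr[1])] <-
          ifelse(is.na(g), "other", g)
      }
    }
    tab <- table(base_group)
    best <- names(tab)[tab == max(tab)]
    want <- best[order(order_rank[best])][1]
    expect_equal(got, want)
  }
})

test_that("TAD state coverage sums overlaps over group segments", {
  tad <- data.frame(chrom = "chr1", start = 0, end = 1e5, tad_id = "t1")
  segs <- data.frame(chrom = "chr1", start = c(10000, 40000, 50000),
                     end = c(40000, 50000, 65000),
                     state = c("Quies", "EnhA1", "EnhA2"))
  cov <- tad_state_coverage(tad, segs)
  expect_equal(cov$quiescent, 0.3)
  expect_equal(cov$enhancer, 0.25)
  expect_equal(cov$promoter, 0)
  # fully tiled by active states
  segs2 <- data.frame(chrom = "chr1", start = 0, end = 1e5, state = "Tx")
  cov2 <- tad_state_coverage(tad, segs2)
  expect_equal(cov2$active, 1)
  expect_equal(cov2$quiescent, 0)
})

test_that("rank-sum comparison reports direction and sane p-values", {
  r <- compare_tad_coverage(c(0.9, 0.8, 0.7), c(0.1, 0.2, 0.3))
  expect_equal(r$direction, "LRI higher")
  # independent normal-approximation oracle (no ties, no correction):
  # W = 9, E[W] = 4.5, Var = n1 n2 (N+1) / 12
  z <- (9 - 4.5) / sqrt(3 * 3 * 7 / 12)
  expect_equal(r$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-12)

  same <- compare_tad_coverage(rep(0.5, 4), rep(0.5, 6))
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, "none")
  expect_error(compare_tad_coverage(numeric(), 1:3), "non-empty")

  # large-sample agreement with the exact test
  set.seed(1)
  a <- runif(60); b <- runif(60) + 0.3
  approx_p <- compare_tad_coverage(a, b)$p_value
  exact_p <- wilcox.test(a, b, exact = TRUE)$p.value
  expect_equal(approx_p, exact_p, tolerance = 0.05)
})

test_that("boundary crossing counts midpoint pairs in different TADs", {
  frags <- grid_frags(30, width = 2e5) # fragments of 200 kb for spread
  same <- make_interactions(frags, c("f1", "f2"), c("f3", "f4"))
  expect_equal(boundary_crossing_fraction(same, tads3), 0)
  crossing <- make_interactions(frags, c("f1", "f2"), c("f7", "f8"))
  expect_equal(boundary_crossing_fraction(crossing, tads3), 1)
  mixed <- rbind(same, same, same, crossing[1, ])
  expect_equal(boundary_crossing_fraction(mixed, tads3), 1 / 7)
})

test_that("marker-gene category test drops low-expected categories", {
  # genes placed directly: categories all/none via constructed annotations
  tads <- data.frame(chrom = "chr1", start = (0:3) * 1e6,
                     end = (1:4) * 1e6, tad_id = paste0("t", 1:4))
  ann <- data.frame(tad_id = paste0("t", 1:4),
                    category = c("all", "non-LRI", "all", "Diff only"),
                    stringsAsFactors = FALSE)
  gene_at <- function(pos, n) {
    data.frame(gene_id = paste0("g", seq_len(n), "_", pos),
               chrom = "chr1", start = pos, end = pos + 1000)
  }
  markers <- list(
    PAd = rbind(gene_at(5e5, 30), gene_at(1.5e6, 10)),
    Adip = rbind(gene_at(5e5, 10), gene_at(1.5e6, 30)))
  r <- marker_gene_category_test(markers, ann, tads)
  # Pearson chi-square on the 2x2 [[30,10],[10,30]]: n(ad-bc)^2/(r1r2c1c2)
  want <- 80 * (30 * 30 - 10 * 10)^2 / (40 * 40 * 40 * 40)
  expect_equal(unname(r$statistic), want)
  expect_equal(unname(r$dof), 1)
  expect_equal(r$p_value, pchisq(want, 1, lower.tail = FALSE))

  flat <- list(PAd = rbind(gene_at(5e5, 10), gene_at(1.5e6, 10)),
               Adip = rbind(gene_at(5e5, 10), gene_at(1.5e6, 10)))
  r2 <- marker_gene_category_test(flat, ann, tads)
  expect_equal(unname(r2$statistic), 0)
  expect_equal(r2$p_value, 1)

  # a category with expected count < 5 in either row is dropped
  markers3 <- list(
    PAd = rbind(gene_at(5e5, 30), gene_at(1.5e6, 10), gene_at(3.5e6, 3)),
    Adip = rbind(gene_at(5e5, 10), gene_at(1.5e6, 30), gene_at(3.5e6, 2)))
  r3 <- marker_gene_category_test(markers3, ann, tads)
  expect_true("Diff only" %in% r3$dropped_categories)
  expect_equal(colnames(r3$table), c("all", "non-LRI"))

  # fewer than two surviving categories errors
  one_cat <- list(PAd = gene_at(5e5, 20), Adip = gene_at(5e5, 20))
  expect_error(marker_gene_category_test(one_cat, ann, tads), "categories")
})

test_that("category percentages divide by the LRI-TAD total", {
  ann <- data.frame(
    tad_id = sprintf("t%03d", 1:700),
    category = c(rep("all", 177), rep("Diff and Adip", 148),
                 rep("PAd only", 250), rep("non-LRI", 100),
                 rep("excluded", 25)),
    n_timepoints = c(rep(3L, 177), rep(2L, 148), rep(1L, 250),
                     rep(0L, 125)),
    stringsAsFactors = FALSE)
  cp <- category_percentages(ann)
  expect_equal(cp$count[cp$n_timepoints == 2], 148L)
  expect_equal(round(cp$percent[cp$n_timepoints == 2], 1), 25.7)
  expect_equal(round(cp$percent[cp$n_timepoints == 3], 1), 30.8)
  expect_equal(sum(cp$count), 575L)
})
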