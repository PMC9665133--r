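# Compact builders for interaction tables and interval sets used across
# the unit tests. All coordinates 0-based half-open.

make_frag <- function(chrom, start, end, id) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             fragment_id = id, stringsAsFactors = FALSE)
}

# interactions from a compact description: one row per pair of fragment rows in
# `frags` (by id), with optional score/read_count
make_interactions <- function(frags, bait_ids, oe_ids, score = 6,
                              read_count = 10, timepoint = "PAd",
                              replicate = "rep1") {
  b <- frags[match(bait_ids, frags$fragment_id), ]
  o <- frags[match(oe_ids, frags$fragment_id), ]
  df <- data.frame(
    bait_chrom = b$chrom, bait_start = b$start, bait_end = b$end,
    bait_id = b$fragment_id,
    oe_chrom = o$chrom, oe_start = o$start, oe_end = o$end,
    oe_id = o$fragment_id,
    read_count = read_count, score = score,
    timepoint = timepoint, replicate = replicate,
    stringsAsFactors = FALSE)
  df$inter_chromosomal <- df$bait_chrom != df$oe_chrom
  df
}

# a fragment map laid out on one chromosome at fixed width
grid_frags <- function(n, width = 4000, chrom = "chr1", prefix = "f") {
  make_frag(chrom, (seq_len(n) - 1) * width, seq_len(n) * width,
            paste0(prefix, seq_len(n)))
}

# brute-force per-bin concordance oracle: explicit set arithmetic
concordance_oracle <- function(rep_a, rep_b, bin_width = 5e4,
                               min_union = 10) {
  key <- function(x) paste(pmin(x$bait_id, x$oe_id),
                           pmax(x$bait_id, x$oe_id))
  mid <- function(s, e) floor((s + e) / 2)
  dist_of <- function(x) abs(mid(x$bait_start, x$bait_end) -
                             mid(x$oe_start, x$oe_end))
  a <- rep_a[!duplicated(key(rep_a)), ]; b <- rep_b[!duplicated(key(rep_b)), ]
  all_d <- c(dist_of(a), dist_of(b))
  n_bins <- max(1, ceiling((max(all_d) + 1) / bin_width))
  out <- data.frame(bin = seq_len(n_bins), n_shared = 0L, n_union = 0L,
                    proportion = NA_real_)
  for (i in seq_len(n_bins)) {
    lo <- (i - 1) * bin_width; hi <- i * bin_width
    ka <- key(a)[dist_of(a) >= lo & dist_of(a) < hi]
    kb <- key(b)[dist_of(b) >= lo & dist_of(b) < hi]
    u <- union(ka, kb); s <- intersect(ka, kb)
    out$n_union[i] <- length(u); out$n_shared[i] <- length(s)
    if (length(u) >= min_union) out$proportion[i] <- length(s) / length(u)
  }
  out
}

# random intra-chromosomal interaction set on a shared fragment grid
random_interactions <- function(frags, n) {
  i <- sample(nrow(frags), n, replace = TRUE)
  j <- sample(nrow(frags), n, replace = TRUE)
  ok <- i != j
  make_interactions(frags, frags$fragment_id[i[ok]], frags$fragment_id[j[ok]])
}
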