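# All coordinates inside the package are 0-based half-open [start, end),
# the BED convention. Readers of 1-based formats convert on the way in.

#' Length of the overlap between two genomic intervals
#'
#' Computes the number of base pairs shared by two half-open intervals.
#' Intervals on different chromosomes never overlap; abutting intervals
#' (a ends where b starts) share zero bases.
#'
#' @param a_chrom,b_chrom Chromosome names.
#' @param a_start,a_end,b_start,b_end Interval coordinates (0-based,
#'   half-open). Vectors are recycled in the usual way.
#' @return Integer vector of overlap lengths in bp (never negative).
#' @examples
#' overlap_length("chr1", 0, 100, "chr1", 50, 150)  # 50
#' overlap_length("chr1", 0, 100, "chr1", 100, 200) # 0
#' @export
overlap_length <- function(a_chrom, a_start, a_end, b_chrom, b_start, b_end) {
  ov <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  ov[a_chrom != b_chrom] <- 0L
  as.integer(ov)
}

#' Midpoint of an interval
#'
#' @param start,end Interval coordinates (0-based half-open).
#' @return floor((start + end) / 2), the convention used for all
#'   point-in-interval assignments in the package.
#' @export
interval_midpoint <- function(start, end) {
  as.integer(floor((start + end) / 2))
}

check_intervals <- function(chrom, start, end, what = "interval",
                            line = NULL) {
  bad <- which(!(start >= 0 & start < end & nzchar(chrom)))
  if (length(bad)) {
    where <- if (is.null(line)) bad[1] else line[bad[1]]
    stop(sprintf("invalid %s at line %d: start=%s end=%s (need 0 <= start < end)",
                 what, where, start[bad[1]], end[bad[1]]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a BED3/BED4 file of genomic intervals
#'
#' @param path Path to a BED file (tab- or space-delimited, no header;
#'   lines starting with `#`, `track` or `browser` are skipped).
#' @param with_name If `TRUE`, a fourth column is required and returned as
#'   `name`.
#' @param one_based If `TRUE`, input start coordinates are 1-based inclusive
#'   and are shifted to the internal 0-based half-open convention.
#' @return A data.frame with columns `chrom`, `start`, `end` (and `name`),
#'   rows in file order.
#' @export
read_bed_intervals <- function(path, with_name = FALSE, one_based = FALSE) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
    if (with_name) out$name <- character()
    return(out)
  }
  fields <- strsplit(lines, "[ \t]+")
  ncol <- vapply(fields, length, 1L)
  need <- if (with_name) 4L else 3L
  if (any(ncol < need)) {
    stop(sprintf("line %d: expected >= %d fields, got %d",
                 lineno[which(ncol < need)[1]], need, min(ncol)), call. = FALSE)
  }
  getcol <- function(i) vapply(fields, `[[`, "", i)
  start <- suppressWarnings(as.integer(getcol(2)))
  end <- suppressWarnings(as.integer(getcol(3)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("line %d: non-integer coordinates",
                 lineno[which(is.na(start) | is.na(end))[1]]), call. = FALSE)
  }
  if (one_based) start <- start - 1L
  out <- data.frame(chrom = getcol(1), start = start, end = end,
                    stringsAsFactors = FALSE)
  check_intervals(out$chrom, out$start, out$end, "BED interval", lineno)
  if (with_name) out$name <- getcol(4)
  out
}

#' Write intervals as BED
#'
#' @param intervals Data.frame with `chrom`, `start`, `end` and optionally
#'   `name` columns.
#' @param path Output path.
#' @export
write_bed_intervals <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  utils::write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

interaction_columns <- c("bait_chrom", "bait_start", "bait_end", "bait_id",
                         "oe_chrom", "oe_start", "oe_end", "oe_id",
                         "read_count", "score", "timepoint", "replicate",
                         "inter_chromosomal")

new_interactions <- function(df) {
  for (col in setdiff(interaction_columns, names(df))) {
    df[[col]] <- switch(col,
                        read_count = NA_integer_,
                        score = NA_real_,
                        timepoint = NA_character_,
                        replicate = NA_character_,
                        inter_chromosomal = df$bait_chrom != df$oe_chrom,
                        NA)
  }
  df$inter_chromosomal <- df$bait_chrom != df$oe_chrom
  if (any(df$bait_id == df$oe_id, na.rm = TRUE)) {
    stop("interaction with identical bait and other-end fragment ids",
         call. = FALSE)
  }
  if (any(df$read_count < 0, na.rm = TRUE)) {
    stop("negative read_count", call. = FALSE)
  }
  df[, interaction_columns]
}

#' Read a significant-interaction table
#'
#' Parses CHiCAGO-style interaction calls into the package's interaction
#' table: one row per bait-fragment / other-end-fragment pair with read
#' support and caller score.
#'
#' Two dialects are supported:
#' \describe{
#'   \item{ibed}{Headered, tab-delimited with columns `bait_chr`,
#'     `bait_start`, `bait_end`, `bait_name`, `otherEnd_chr`,
#'     `otherEnd_start`, `otherEnd_end`, `otherEnd_name`, `N_reads`,
#'     `score`.}
#'   \item{bedpe}{Headerless BEDPE: `chrom1 start1 end1 chrom2 start2 end2
#'     name score` with optional further columns; `name` of the form
#'     `baitID:oeID` supplies fragment ids, read count in column 9 when
#'     present.}
#' }
#' Fragment ids default to `chrom:start-end` strings when absent.
#' Inter-chromosomal rows are retained and flagged in the
#' `inter_chromosomal` column; the score/distance filters in
#' [filter_significant()] remove them explicitly and auditably.
#'
#' @param path File path.
#' @param format_hint `"ibed"` or `"bedpe"`.
#' @param timepoint,replicate Labels attached to every row.
#' @return Interaction table: data.frame with columns `bait_chrom`,
#'   `bait_start`, `bait_end`, `bait_id`, `oe_chrom`, `oe_start`, `oe_end`,
#'   `oe_id`, `read_count`, `score`, `timepoint`, `replicate`,
#'   `inter_chromosomal`.
#' @export
read_interaction_table <- function(path, format_hint = c("ibed", "bedpe"),
                                   timepoint = NA_character_,
                                   replicate = NA_character_) {
  format_hint <- match.arg(format_hint)
  stopifnot(file.exists(path))
  if (format_hint == "ibed") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("bait_chr", "bait_start", "bait_end", "otherEnd_chr",
              "otherEnd_start", "otherEnd_end")
    if (!all(need %in% names(df))) {
      stop("ibed file missing columns: ",
           paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
    }
    out <- data.frame(
      bait_chrom = df$bait_chr,
      bait_start = as.integer(df$bait_start),
      bait_end = as.integer(df$bait_end),
      bait_id = if ("bait_name" %in% names(df)) as.character(df$bait_name) else
        paste0(df$bait_chr, ":", df$bait_start, "-", df$bait_end),
      oe_chrom = df$otherEnd_chr,
      oe_start = as.integer(df$otherEnd_start),
      oe_end = as.integer(df$otherEnd_end),
      oe_id = if ("otherEnd_name" %in% names(df)) as.character(df$otherEnd_name) else
        paste0(df$otherEnd_chr, ":", df$otherEnd_start, "-", df$otherEnd_end),
      read_count = if ("N_reads" %in% names(df)) as.integer(df$N_reads) else NA_integer_,
      score = if ("score" %in% names(df)) as.numeric(df$score) else NA_real_,
      stringsAsFactors = FALSE)
    lineno <- seq_len(nrow(out)) + 1L  # header is line 1
  } else {
    raw <- utils::read.table(path, stringsAsFactors = FALSE)
    if (ncol(raw) < 6) stop("BEDPE needs >= 6 columns", call. = FALSE)
    name <- if (ncol(raw) >= 7) as.character(raw[[7]]) else
      rep(NA_character_, nrow(raw))
    ids <- strsplit(ifelse(is.na(name), "", name), ":", fixed = TRUE)
    two_ids <- vapply(ids, length, 1L) == 2L
    bait_id <- ifelse(two_ids, vapply(ids, `[`, "", 1L),
                      paste0(raw[[1]], ":", raw[[2]], "-", raw[[3]]))
    oe_id <- ifelse(two_ids, vapply(ids, `[`, "", 2L),
                    paste0(raw[[4]], ":", raw[[5]], "-", raw[[6]]))
    out <- data.frame(
      bait_chrom = raw[[1]], bait_start = as.integer(raw[[2]]),
      bait_end = as.integer(raw[[3]]), bait_id = bait_id,
      oe_chrom = raw[[4]], oe_start = as.integer(raw[[5]]),
      oe_end = as.integer(raw[[6]]), oe_id = oe_id,
      read_count = if (ncol(raw) >= 9) as.integer(raw[[9]]) else NA_integer_,
      score = if (ncol(raw) >= 8) as.numeric(raw[[8]]) else NA_real_,
      stringsAsFactors = FALSE)
    lineno <- seq_len(nrow(out))
  }
  check_intervals(out$bait_chrom, out$bait_start, out$bait_end,
                  "bait fragment", lineno)
  check_intervals(out$oe_chrom, out$oe_start, out$oe_end,
                  "other-end fragment", lineno)
  out$timepoint <- timepoint
  out$replicate <- replicate
  new_interactions(out)
}

#' Write an interaction table in the ibed dialect
#'
#' Inverse of [read_interaction_table()] for `format_hint = "ibed"`:
#' reading the written file back reproduces all coordinate, id, read-count
#' and score fields.
#'
#' @param interactions Interaction table.
#' @param path Output path.
#' @export
write_interaction_table <- function(interactions, path) {
  df <- data.frame(
    bait_chr = interactions$bait_chrom,
    bait_start = interactions$bait_start,
    bait_end = interactions$bait_end,
    bait_name = interactions$bait_id,
    otherEnd_chr = interactions$oe_chrom,
    otherEnd_start = interactions$oe_start,
    otherEnd_end = interactions$oe_end,
    otherEnd_name = interactions$oe_id,
    N_reads = interactions$read_count,
    score = interactions$score,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Assign points to non-overlapping intervals of one table.
# Returns the row index of the containing interval, NA when none.
assign_to_intervals <- function(chrom, pos, intervals) {
  idx <- rep(NA_integer_, length(pos))
  for (cc in unique(chrom)) {
    rows <- which(intervals$chrom == cc)
    if (!length(rows)) next
    ord <- rows[order(intervals$start[rows])]
    sel <- which(chrom == cc)
    j <- findInterval(pos[sel], intervals$start[ord])
    hit <- j >= 1 & pos[sel] < intervals$end[ord][pmax(j, 1L)]
    idx[sel[hit]] <- ord[j[hit]]
  }
  idx
}
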