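#' Genomic intervals as tibbles
#'
#' All seloop functions exchange genomic intervals as plain tibbles with at
#' least the columns `chrom` (character), `start` and `end` (0-based,
#' half-open, so a one-base interval at position 100 is `start = 100,
#' end = 101`). Extra columns ride along untouched. `check_intervals()`
#' validates the convention and is called by every consumer.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`.
#' @param arg Name used in error messages.
#' @return `x` as a tibble, invisibly validated.
#' @export
check_intervals <- function(x, arg = "x") {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame of intervals", arg))
  }
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`%s` is missing interval column(s): %s",
      arg, paste(missing_cols, collapse = ", ")
    ))
  }
  x <- as_tibble(x)
  if (nrow(x) == 0) {
    return(x)
  }
  if (any(is.na(x$chrom) | !nzchar(x$chrom))) {
    abort(sprintf("`%s`: chrom must be non-empty", arg))
  }
  if (any(is.na(x$start) | is.na(x$end))) {
    abort(sprintf("`%s`: start/end must not be NA", arg))
  }
  if (any(x$start < 0)) {
    abort(sprintf("`%s`: start must be >= 0", arg))
  }
  if (any(x$start >= x$end)) {
    bad <- which(x$start >= x$end)[1]
    abort(sprintf(
      "`%s`: start must be < end (violated at row %d: [%s, %s))",
      arg, bad, format(x$start[bad], scientific = FALSE),
      format(x$end[bad], scientific = FALSE)
    ))
  }
  x
}

# GRanges bridge: 0-based half-open tibble -> 1-based closed GRanges.
# `seqlevels` lets two collections share a universe so findOverlaps does
# not warn when their chromosome sets are disjoint.
as_granges0 <- function(x, seqlevels = NULL) {
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = seqlevels %||% unique(x$chrom)),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Find all overlapping pairs between two interval sets
#'
#' Reports every pair `(i in a, j in b)` sharing at least one base
#' (same chromosome and `max(starts) < min(ends)`). Backed by the
#' IRanges interval tree.
#'
#' @param a,b Interval tibbles (see [check_intervals()]).
#' @return A tibble with one row per overlapping pair: `chrom`,
#'   `start_a`, `end_a`, `start_b`, `end_b` and the source row indices
#'   `row_a`, `row_b`, sorted by coordinates.
#' @export
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 10)
#' b <- tibble::tibble(chrom = "chr1", start = c(5, 10), end = c(15, 20))
#' overlap_query(a, b) # only [5,15) overlaps; [10,20) is adjacent
overlap_query <- function(a, b) {
  a <- check_intervals(a, "a")
  b <- check_intervals(b, "b")
  empty <- tibble(
    chrom = character(), start_a = numeric(), end_a = numeric(),
    start_b = numeric(), end_b = numeric(),
    row_a = integer(), row_b = integer()
  )
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(empty)
  }
  lv <- union(unique(a$chrom), unique(b$chrom))
  hits <- GenomicRanges::findOverlaps(as_granges0(a, lv), as_granges0(b, lv))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  tibble(
    chrom = a$chrom[qi],
    start_a = a$start[qi], end_a = a$end[qi],
    start_b = b$start[si], end_b = b$end[si],
    row_a = qi, row_b = si
  ) |>
    arrange(.data$chrom, .data$start_a, .data$end_a, .data$start_b,
            .data$end_b, .data$row_a, .data$row_b)
}

#' Merge intervals that lie within a gap of each other
#'
#' Any two intervals on the same chromosome whose edge-to-edge distance is
#' at most `gap` are transitively unioned (ROSE-style stitching semantics:
#' a gap exactly equal to `gap` merges). `gap = 0` merges overlapping and
#' book-ended intervals.
#'
#' @param x Interval tibble.
#' @param gap Non-negative maximum edge-to-edge distance in bases.
#' @return Tibble of disjoint merged intervals sorted by coordinate, with a
#'   list-column `rows` giving the input row indices absorbed into each
#'   merged interval.
#' @export
merge_within <- function(x, gap) {
  x <- check_intervals(x)
  if (length(gap) != 1 || is.na(gap) || gap < 0) {
    abort("`gap` must be a single non-negative number")
  }
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  rows = list()))
  }
  red <- GenomicRanges::reduce(as_granges0(x), min.gapwidth = gap + 1,
                               with.revmap = TRUE)
  tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1,
    end = as.numeric(GenomicRanges::end(red)),
    rows = lapply(S4Vectors::mcols(red)$revmap, as.integer)
  ) |>
    arrange(.data$chrom, .data$start, .data$end)
}

#' Distance from a point to an interval
#'
#' Edge-to-edge gap between a single genomic position (e.g. a TSS) and a
#' half-open interval: 0 when the point falls inside or is book-ended, the
#' number of intervening bases otherwise. Vectorised over all arguments.
#'
#' @param pos 0-based positions.
#' @param start,end Interval bounds (0-based half-open).
#' @return Numeric distances.
#' @keywords internal
point_interval_distance <- function(pos, start, end) {
  pmax(0, pos - end, start - pos - 1)
}

#' Integrate a signal track over query regions
#'
#' A signal track is an interval tibble with a `value` column (coverage
#' density per base, e.g. rpm/bp) whose intervals are non-overlapping;
#' uncovered positions have value 0. The integral over a region is
#' `sum(value * overlapping bases)`.
#'
#' @param track Signal-track tibble (`chrom`, `start`, `end`, `value`).
#' @param regions Interval tibble of query regions.
#' @return Numeric vector of integrals, one per region row.
#' @export
track_integral <- function(track, regions) {
  track <- check_intervals(track, "track")
  regions <- check_intervals(regions, "regions")
  if (!"value" %in% names(track)) {
    abort("`track` must have a `value` column")
  }
  if (nrow(track) > 0 && any(track$value < 0)) {
    abort("`track` values must be >= 0")
  }
  out <- numeric(nrow(regions))
  if (nrow(track) == 0 || nrow(regions) == 0) {
    return(out)
  }
  lv <- union(unique(regions$chrom), unique(track$chrom))
  hits <- GenomicRanges::findOverlaps(as_granges0(regions, lv),
                                      as_granges0(track, lv))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  width <- pmin(regions$end[qi], track$end[si]) -
    pmax(regions$start[qi], track$start[si])
  contrib <- width * track$value[si]
  agg <- tapply(contrib, qi, sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}
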