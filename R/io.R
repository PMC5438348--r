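#' Read genomic interval files
#'
#' Line-oriented readers for the plain-text interval formats the pipeline
#' consumes. All coordinates come back 0-based half-open. Malformed lines
#' raise an error naming the offending line number.
#'
#' * `bed`: BED3/6 -> `chrom, start, end` (+ `name, score, strand` if present)
#' * `narrowPeak`: BED6+4 -> adds `signal_value, p_value, q_value, peak`
#' * `gappedPeak`: BED12+3 -> adds block structure as integer list-columns
#'   `block_sizes`, `block_starts` (offsets relative to `start`)
#' * `bedgraph`: signal track -> `chrom, start, end, value`, sorted;
#'   overlapping intervals within a chromosome are rejected
#' * `bedpe`: anchor pairs -> `chrom1, start1, end1, chrom2, start2, end2`
#'   (+ `name, score, strand1, strand2` if present)
#'
#' @param path Path to the file.
#' @param format One of `"bed"`, `"narrowPeak"`, `"gappedPeak"`,
#'   `"bedgraph"`, `"bedpe"`.
#' @return A tibble of records in the layout described above.
#' @export
read_intervals <- function(path,
                           format = c("bed", "narrowPeak", "gappedPeak",
                                      "bedgraph", "bedpe")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  lineno <- which(keep)
  switch(format,
    bed = parse_bed(fields, lineno, path),
    narrowPeak = parse_narrowpeak(fields, lineno, path),
    gappedPeak = parse_gappedpeak(fields, lineno, path),
    bedgraph = parse_bedgraph(fields, lineno, path),
    bedpe = parse_bedpe(fields, lineno, path)
  )
}

parse_fail <- function(path, lineno, what) {
  abort(sprintf("parse error in %s at line %d: %s", path, lineno, what))
}

check_nfields <- function(fields, lineno, path, minimum) {
  nf <- lengths(fields)
  bad <- which(nf < minimum)
  if (length(bad) > 0) {
    parse_fail(path, lineno[bad[1]],
               sprintf("expected >= %d fields, found %d", minimum, nf[bad[1]]))
  }
  invisible(nf)
}

num_col <- function(fields, idx, lineno, path, what, integerish = TRUE) {
  raw <- vapply(fields, function(f) if (length(f) >= idx) f[idx] else NA_character_,
                character(1))
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(val) & !is.na(raw))
  if (length(bad) > 0) {
    parse_fail(path, lineno[bad[1]],
               sprintf("non-numeric %s '%s'", what, raw[bad[1]]))
  }
  val
}

chr_col <- function(fields, idx) {
  vapply(fields, function(f) if (length(f) >= idx) f[idx] else NA_character_,
         character(1))
}

validate_coords <- function(start, end, lineno, path) {
  bad <- which(start < 0 | start >= end)
  if (length(bad) > 0) {
    parse_fail(path, lineno[bad[1]],
               sprintf("invalid interval [%s, %s)",
                       format(start[bad[1]], scientific = FALSE),
                       format(end[bad[1]], scientific = FALSE)))
  }
}

parse_bed <- function(fields, lineno, path) {
  check_nfields(fields, lineno, path, 3)
  out <- tibble(
    chrom = chr_col(fields, 1),
    start = num_col(fields, 2, lineno, path, "start"),
    end = num_col(fields, 3, lineno, path, "end")
  )
  validate_coords(out$start, out$end, lineno, path)
  nf <- lengths(fields)
  if (all(nf >= 4)) out$name <- chr_col(fields, 4)
  if (all(nf >= 5)) out$score <- num_col(fields, 5, lineno, path, "score")
  if (all(nf >= 6)) out$strand <- chr_col(fields, 6)
  out
}

parse_narrowpeak <- function(fields, lineno, path) {
  check_nfields(fields, lineno, path, 10)
  out <- tibble(
    chrom = chr_col(fields, 1),
    start = num_col(fields, 2, lineno, path, "start"),
    end = num_col(fields, 3, lineno, path, "end"),
    name = chr_col(fields, 4),
    score = num_col(fields, 5, lineno, path, "score"),
    strand = chr_col(fields, 6),
    signal_value = num_col(fields, 7, lineno, path, "signalValue"),
    p_value = num_col(fields, 8, lineno, path, "pValue"),
    q_value = num_col(fields, 9, lineno, path, "qValue"),
    peak = num_col(fields, 10, lineno, path, "peak")
  )
  validate_coords(out$start, out$end, lineno, path)
  neg <- which(out$score < 0)
  if (length(neg) > 0) {
    parse_fail(path, lineno[neg[1]], "negative score")
  }
  out
}

parse_int_list <- function(s) {
  as.integer(strsplit(sub(",$", "", s), ",")[[1]])
}

parse_gappedpeak <- function(fields, lineno, path) {
  check_nfields(fields, lineno, path, 15)
  out <- tibble(
    chrom = chr_col(fields, 1),
    start = num_col(fields, 2, lineno, path, "start"),
    end = num_col(fields, 3, lineno, path, "end"),
    name = chr_col(fields, 4),
    score = num_col(fields, 5, lineno, path, "score"),
    strand = chr_col(fields, 6),
    block_count = num_col(fields, 10, lineno, path, "blockCount"),
    block_sizes = lapply(chr_col(fields, 11), parse_int_list),
    block_starts = lapply(chr_col(fields, 12), parse_int_list),
    signal_value = num_col(fields, 13, lineno, path, "signalValue"),
    p_value = num_col(fields, 14, lineno, path, "pValue"),
    q_value = num_col(fields, 15, lineno, path, "qValue")
  )
  validate_coords(out$start, out$end, lineno, path)
  for (i in seq_len(nrow(out))) {
    if (length(out$block_sizes[[i]]) != out$block_count[i] ||
        length(out$block_starts[[i]]) != out$block_count[i]) {
      parse_fail(path, lineno[i], "block count does not match block lists")
    }
    if (max(out$block_starts[[i]] + out$block_sizes[[i]]) >
        out$end[i] - out$start[i]) {
      parse_fail(path, lineno[i], "blocks extend beyond the span")
    }
  }
  out
}

parse_bedgraph <- function(fields, lineno, path) {
  check_nfields(fields, lineno, path, 4)
  out <- tibble(
    chrom = chr_col(fields, 1),
    start = num_col(fields, 2, lineno, path, "start"),
    end = num_col(fields, 3, lineno, path, "end"),
    value = num_col(fields, 4, lineno, path, "value")
  )
  validate_coords(out$start, out$end, lineno, path)
  neg <- which(out$value < 0)
  if (length(neg) > 0) {
    parse_fail(path, lineno[neg[1]], "negative track value")
  }
  out <- arrange(out, .data$chrom, .data$start)
  overl <- out |>
    group_by(.data$chrom) |>
    filter(.data$start < dplyr::lag(.data$end, default = -Inf)) |>
    ungroup()
  if (nrow(overl) > 0) {
    abort(sprintf("bedGraph %s has overlapping intervals on %s near %s",
                  path, overl$chrom[1],
                  format(overl$start[1], scientific = FALSE)))
  }
  out
}

parse_bedpe <- function(fields, lineno, path) {
  check_nfields(fields, lineno, path, 6)
  out <- tibble(
    chrom1 = chr_col(fields, 1),
    start1 = num_col(fields, 2, lineno, path, "start1"),
    end1 = num_col(fields, 3, lineno, path, "end1"),
    chrom2 = chr_col(fields, 4),
    start2 = num_col(fields, 5, lineno, path, "start2"),
    end2 = num_col(fields, 6, lineno, path, "end2")
  )
  validate_coords(out$start1, out$end1, lineno, path)
  validate_coords(out$start2, out$end2, lineno, path)
  nf <- lengths(fields)
  if (all(nf >= 7)) out$name <- chr_col(fields, 7)
  if (all(nf >= 8)) out$score <- num_col(fields, 8, lineno, path, "score")
  if (all(nf >= 10)) {
    out$strand1 <- chr_col(fields, 9)
    out$strand2 <- chr_col(fields, 10)
  }
  out
}

fmt_num <- function(x) {
  ifelse(x == round(x),
         format(x, scientific = FALSE, trim = TRUE),
         formatC(x, format = "fg", digits = 15))
}

write_lines_file <- function(lines, path) {
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write genomic interval files
#'
#' Writers matching the [read_intervals()] formats; tab-separated,
#' newline-terminated records, coordinates never in scientific notation.
#'
#' @param x Tibble in the layout produced by the corresponding reader.
#' @param path Output path.
#' @return The path, invisibly.
#' @name interval-writers
NULL

#' @rdname interval-writers
#' @export
write_bed <- function(x, path) {
  x <- check_intervals(x)
  cols <- list(x$chrom, fmt_num(x$start), fmt_num(x$end))
  if ("name" %in% names(x)) cols <- c(cols, list(x$name))
  if ("score" %in% names(x)) cols <- c(cols, list(fmt_num(x$score)))
  if ("strand" %in% names(x)) cols <- c(cols, list(x$strand))
  write_lines_file(do.call(paste, c(cols, sep = "\t")), path)
}

#' @rdname interval-writers
#' @export
write_narrowpeak <- function(x, path) {
  x <- check_intervals(x)
  lines <- paste(x$chrom, fmt_num(x$start), fmt_num(x$end), x$name,
                 fmt_num(x$score), x$strand, fmt_num(x$signal_value),
                 fmt_num(x$p_value), fmt_num(x$q_value), fmt_num(x$peak),
                 sep = "\t")
  write_lines_file(lines, path)
}

#' @rdname interval-writers
#' @export
write_gappedpeak <- function(x, path) {
  x <- check_intervals(x)
  sizes <- vapply(x$block_sizes, paste, character(1), collapse = ",")
  starts <- vapply(x$block_starts, paste, character(1), collapse = ",")
  lines <- paste(x$chrom, fmt_num(x$start), fmt_num(x$end), x$name,
                 fmt_num(x$score), x$strand, fmt_num(x$start), fmt_num(x$end),
                 "0", fmt_num(x$block_count), sizes, starts,
                 fmt_num(x$signal_value), fmt_num(x$p_value),
                 fmt_num(x$q_value), sep = "\t")
  write_lines_file(lines, path)
}

#' @rdname interval-writers
#' @export
write_bedgraph <- function(x, path) {
  x <- check_intervals(x)
  lines <- paste(x$chrom, fmt_num(x$start), fmt_num(x$end), fmt_num(x$value),
                 sep = "\t")
  write_lines_file(lines, path)
}

#' @rdname interval-writers
#' @export
write_bedpe <- function(x, path) {
  cols <- list(x$chrom1, fmt_num(x$start1), fmt_num(x$end1),
               x$chrom2, fmt_num(x$start2), fmt_num(x$end2))
  if ("name" %in% names(x)) cols <- c(cols, list(x$name))
  if ("score" %in% names(x)) cols <- c(cols, list(fmt_num(x$score)))
  if (all(c("strand1", "strand2") %in% names(x))) {
    cols <- c(cols, list(x$strand1, x$strand2))
  }
  write_lines_file(do.call(paste, c(cols, sep = "\t")), path)
}
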