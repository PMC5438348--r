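#' Stitch peaks into enhancer candidate regions
#'
#' Peaks on the same chromosome whose edge-to-edge distance is at most
#' `window` are transitively merged into a single stitched region, the
#' ROSE recipe with a 4 kb default window. Peaks inside promoter regions
#' are deliberately retained: no promoter exclusion is applied.
#'
#' @param peaks Interval tibble of peaks; an optional `name` column supplies
#'   constituent identifiers (row numbers are used otherwise).
#' @param window Stitching window in bases (default 4000).
#' @return Tibble of stitched regions: `chrom`, `start`, `end`, `region_id`,
#'   `n_constituents` and a list-column `constituents` of peak identifiers.
#' @export
stitch_peaks <- function(peaks, window = 4000) {
  peaks <- check_intervals(peaks, "peaks")
  if (length(window) != 1 || is.na(window) || window < 0) {
    abort("`window` must be a single non-negative number")
  }
  ids <- if ("name" %in% names(peaks)) peaks$name else as.character(seq_len(nrow(peaks)))
  merged <- merge_within(peaks, window)
  merged |>
    mutate(
      region_id = sprintf("stitched_%05d", row_number()),
      n_constituents = lengths(.data$rows),
      constituents = lapply(.data$rows, function(i) ids[i])
    ) |>
    select("chrom", "start", "end", "region_id", "n_constituents",
           "constituents", "rows")
}

#' Input-corrected signal of stitched regions
#'
#' Integrates rpm-normalised treatment and control coverage over each
#' region and takes the difference. The net signal is not floored at
#' zero; regions with more control than treatment coverage go negative
#' and simply rank last, as in the ROSE arithmetic.
#'
#' @param regions Interval tibble of stitched regions.
#' @param treatment,control Signal-track tibbles (`chrom,start,end,value`).
#' @return `regions` with `treatment_signal`, `control_signal`,
#'   `net_signal` columns appended.
#' @export
compute_region_signal <- function(regions, treatment, control) {
  regions <- check_intervals(regions, "regions")
  regions |>
    mutate(
      treatment_signal = track_integral(treatment, regions),
      control_signal = track_integral(control, regions),
      net_signal = .data$treatment_signal - .data$control_signal
    )
}

#' Tangent-line cutoff separating super-enhancers from typical enhancers
#'
#' Sorts the net signals ascending as \eqn{y_1 \le \dots \le y_n}, takes
#' the average slope \eqn{s = (y_n - y_1)/n} of the rank curve, and slides
#' a line of that slope through each point \eqn{(i, y_i)}: the tangent
#' point \eqn{i^*} is the one whose line leaves the fewest points strictly
#' below it (ties resolved to the largest index). The cutoff is
#' \eqn{y_{i^*}}; regions with signal strictly above it are
#' super-enhancers. The search is exhaustive over candidate indices, so
#' the result is deterministic and scale-covariant. A flat signal vector
#' (\eqn{y_n = y_1}) is degenerate: the cutoff is \eqn{y_n} and nothing
#' is called super.
#'
#' @param net_signals Numeric vector of region signals, length >= 2.
#' @return An object of class `se_cutoff`: a list with `cutoff_value`,
#'   `tangent_index` (index into the ascending sort), `slope`,
#'   `signals_sorted`, `n_super`.
#' @export
#' @examples
#' cut <- find_cutoff(c(1:9, 100))
#' glance(cut)
find_cutoff <- function(net_signals) {
  if (length(net_signals) < 2) {
    abort("`net_signals` must contain at least 2 values")
  }
  if (any(is.na(net_signals))) {
    abort("`net_signals` must not contain NA")
  }
  y <- sort(net_signals)
  n <- length(y)
  s <- (y[n] - y[1]) / n
  if (y[n] == y[1]) {
    res <- list(cutoff_value = y[n], tangent_index = n, slope = 0,
                signals_sorted = y, n_super = 0L)
    class(res) <- "se_cutoff"
    return(res)
  }
  # points below the line through (i, y_i) with slope s:
  # y_j < s*j + (y_i - s*i)  <=>  (y_j - s*j) < (y_i - s*i)
  d <- y - s * seq_len(n)
  counts <- rank(d, ties.method = "min") - 1L
  i_star <- max(which(counts == min(counts)))
  cutoff <- y[i_star]
  res <- list(
    cutoff_value = cutoff,
    tangent_index = i_star,
    slope = s,
    signals_sorted = y,
    n_super = sum(y > cutoff)
  )
  class(res) <- "se_cutoff"
  res
}

#' @export
print.se_cutoff <- function(x, ...) {
  cat("Tangent-line super-enhancer cutoff\n")
  cat(sprintf("  regions: %d   cutoff: %.4g (index %d of ascending sort)\n",
              length(x$signals_sorted), x$cutoff_value, x$tangent_index))
  cat(sprintf("  slope: %.4g signal/rank   super-enhancers: %d\n",
              x$slope, x$n_super))
  invisible(x)
}

#' @describeIn find_cutoff One row per region on the ranked signal curve
#'   (`rank` 1 = highest signal), with the super/typical label implied by
#'   the cutoff.
#' @param x An `se_cutoff` object.
#' @param ... Unused.
#' @method tidy se_cutoff
#' @export
tidy.se_cutoff <- function(x, ...) {
  y <- rev(x$signals_sorted)
  tibble(
    rank = seq_along(y),
    net_signal = y,
    is_super = y > x$cutoff_value
  )
}

#' @describeIn find_cutoff One-row summary of the cutoff fit.
#' @method glance se_cutoff
#' @export
glance.se_cutoff <- function(x, ...) {
  tibble(
    n = length(x$signals_sorted),
    cutoff_value = x$cutoff_value,
    tangent_index = x$tangent_index,
    slope = x$slope,
    n_super = x$n_super
  )
}

#' @describeIn find_cutoff Hockey-stick rank plot with the cutoff marked.
#' @param object An `se_cutoff` object.
#' @method autoplot se_cutoff
#' @export
autoplot.se_cutoff <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = rev(.data$rank), y = .data$net_signal,
                                    colour = .data$is_super)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$cutoff_value, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "#7f8c8d"),
                                 name = "super-enhancer") +
    ggplot2::labs(x = "region rank (ascending signal)",
                  y = "input-corrected signal",
                  title = "Ranked enhancer signal and tangent cutoff")
}

#' Call super-enhancers from peaks and coverage tracks
#'
#' End-to-end H3K27ac workflow: stitch peaks ([stitch_peaks()]), compute
#' input-corrected signal ([compute_region_signal()]), locate the tangent
#' cutoff ([find_cutoff()]), and label each stitched region. Ranks run
#' from 1 (highest net signal) with ties broken by `(chrom, start)`.
#'
#' @inheritParams stitch_peaks
#' @param treatment,control rpm-normalised signal-track tibbles.
#' @return Tibble of stitched regions with `treatment_signal`,
#'   `control_signal`, `net_signal`, `rank`, `is_super`; the `se_cutoff`
#'   object is attached as attribute `"cutoff"`.
#' @export
call_super_enhancers <- function(peaks, treatment, control, window = 4000) {
  regions <- stitch_peaks(peaks, window = window) |>
    compute_region_signal(treatment, control)
  if (nrow(regions) < 2) {
    abort("need at least 2 stitched regions to place a cutoff")
  }
  cut <- find_cutoff(regions$net_signal)
  out <- regions |>
    mutate(is_super = .data$net_signal > cut$cutoff_value) |>
    arrange(dplyr::desc(.data$net_signal), .data$chrom, .data$start) |>
    mutate(rank = row_number()) |>
    arrange(.data$chrom, .data$start) |>
    select(-"rows")
  attr(out, "cutoff") <- cut
  out
}
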