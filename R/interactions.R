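#' Canonicalise loop anchor order
#'
#' Orders the two anchors of every loop so that the lexicographically
#' smaller `(chrom, start, end)` triple is anchor 1, and assigns a
#' `loop_id` when absent. All downstream loop operations assume this
#' ordering.
#'
#' @param loops BEDPE-style tibble (`chrom1,start1,end1,chrom2,start2,end2`).
#' @return The canonically ordered tibble with a `loop_id` column.
#' @export
canonicalize_loops <- function(loops) {
  needed <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  miss <- setdiff(needed, names(loops))
  if (length(miss) > 0) {
    abort(sprintf("`loops` missing column(s): %s", paste(miss, collapse = ", ")))
  }
  loops <- as_tibble(loops)
  swap <- (loops$chrom2 < loops$chrom1) |
    (loops$chrom2 == loops$chrom1 & loops$start2 < loops$start1) |
    (loops$chrom2 == loops$chrom1 & loops$start2 == loops$start1 &
       loops$end2 < loops$end1)
  if (any(swap)) {
    tmp <- loops[swap, c("chrom1", "start1", "end1")]
    loops[swap, c("chrom1", "start1", "end1")] <-
      loops[swap, c("chrom2", "start2", "end2")]
    loops[swap, c("chrom2", "start2", "end2")] <- tmp
  }
  if (!"loop_id" %in% names(loops)) {
    loops$loop_id <- sprintf("loop_%05d", seq_len(nrow(loops)))
  }
  loops
}

anchor_tbl <- function(loops, which) {
  if (which == 1) {
    tibble(chrom = loops$chrom1, start = loops$start1, end = loops$end1,
           loop_row = seq_len(nrow(loops)))
  } else {
    tibble(chrom = loops$chrom2, start = loops$start2, end = loops$end2,
           loop_row = seq_len(nrow(loops)))
  }
}

anchor_pairs_overlap <- function(x, y, wx, wy) {
  # rows (i in x-loops, j in y-loops) whose chosen anchors share >= 1 base
  ov <- overlap_query(anchor_tbl(x, wx), anchor_tbl(y, wy))
  tibble(i = ov$row_a, j = ov$row_b) |> distinct()
}

#' Replicate-reproducible chromatin interactions
#'
#' Keeps a loop from `rep1` iff some loop in `rep2` matches it with at
#' least 1 bp overlap on both anchors, in either orientation (the
#' BEDTools `pairToPair` "both" rule). Output carries `rep1`
#' coordinates, de-duplicated and coordinate-sorted.
#'
#' @param rep1,rep2 BEDPE-style tibbles; canonicalised on entry.
#' @return The reproducible subset of `rep1`.
#' @export
intersect_replicates <- function(rep1, rep2) {
  rep1 <- canonicalize_loops(rep1)
  rep2 <- canonicalize_loops(rep2)
  if (nrow(rep1) == 0 || nrow(rep2) == 0) {
    return(rep1[integer(0), ])
  }
  same <- inner_join(anchor_pairs_overlap(rep1, rep2, 1, 1),
                     anchor_pairs_overlap(rep1, rep2, 2, 2),
                     by = c("i", "j"))
  cross <- inner_join(anchor_pairs_overlap(rep1, rep2, 1, 2),
                      anchor_pairs_overlap(rep1, rep2, 2, 1),
                      by = c("i", "j"))
  keep <- sort(unique(c(same$i, cross$i)))
  rep1[keep, ] |>
    arrange(.data$chrom1, .data$start1, .data$end1,
            .data$chrom2, .data$start2, .data$end2)
}

#' Associate elements with chromatin interactions
#'
#' An element is involved in a loop when it overlaps at least one of the
#' loop's anchors; `interaction_count` counts distinct loops (overlapping
#' both anchors of the same loop counts once).
#'
#' @param elements Interval tibble; an `element_id` column is added from
#'   row numbers when absent.
#' @param loops Canonicalisable BEDPE tibble.
#' @return `elements` with `involved` (logical) and `interaction_count`.
#' @export
associate_elements <- function(elements, loops) {
  elements <- check_intervals(elements, "elements")
  if (!"element_id" %in% names(elements)) {
    elements$element_id <- as.character(seq_len(nrow(elements)))
  }
  loops <- canonicalize_loops(loops)
  counts <- element_loop_pairs(elements, loops) |>
    distinct(.data$element_row, .data$loop_row) |>
    dplyr::count(.data$element_row)
  n_loops <- integer(nrow(elements))
  n_loops[counts$element_row] <- counts$n
  elements |>
    mutate(interaction_count = n_loops, involved = n_loops > 0)
}

# every (element row, loop row, matched anchor side)
element_loop_pairs <- function(elements, loops) {
  if (nrow(elements) == 0 || nrow(loops) == 0) {
    return(tibble(element_row = integer(), loop_row = integer(),
                  side = integer()))
  }
  ov1 <- overlap_query(elements, anchor_tbl(loops, 1))
  ov2 <- overlap_query(elements, anchor_tbl(loops, 2))
  bind_rows(
    tibble(element_row = ov1$row_a, loop_row = ov1$row_b, side = 1L),
    tibble(element_row = ov2$row_a, loop_row = ov2$row_b, side = 2L)
  )
}

#' Loop-mediated target genes of regulatory elements
#'
#' For every loop with one anchor overlapping the element, genes whose
#' TSS lies within `window` bases (edge-to-edge, inclusive) of the other
#' anchor become loop-mediated targets. Targets are de-duplicated per
#' `(element, gene)`; the reported TSS is the matched one closest to the
#' target-side anchor. `distance` runs from the element centre
#' (`floor((start+end)/2)`) to that TSS, and `skipped_tss_count` is the
#' number of distinct retained TSS positions strictly between the centre
#' and the target TSS — genes the loop "skips over".
#'
#' @param elements Interval tibble (optionally with `element_id`).
#' @param loops BEDPE tibble.
#' @param tss TSS tibble (see [load_tss()]).
#' @param window Anchor-to-TSS assignment window in bases (default 4000,
#'   matching the proximity threshold).
#' @return Tibble: `element_id`, `gene_id`, `tss`, `distance`,
#'   `skipped_tss_count`, `loop_id` (one loop witnessing the assignment).
#' @export
loop_targets <- function(elements, loops, tss, window = 4000) {
  elements <- check_intervals(elements, "elements")
  if (!"element_id" %in% names(elements)) {
    elements$element_id <- as.character(seq_len(nrow(elements)))
  }
  loops <- canonicalize_loops(loops)
  empty <- tibble(element_id = character(), gene_id = character(),
                  tss = numeric(), distance = numeric(),
                  skipped_tss_count = integer(), loop_id = character())
  pairs <- element_loop_pairs(elements, loops)
  if (nrow(pairs) == 0 || nrow(tss) == 0) {
    return(empty)
  }
  other <- ifelse(pairs$side == 1L, 2L, 1L)
  anchors <- tibble(
    chrom = ifelse(other == 1L, loops$chrom1[pairs$loop_row],
                   loops$chrom2[pairs$loop_row]),
    start = ifelse(other == 1L, loops$start1[pairs$loop_row],
                   loops$start2[pairs$loop_row]),
    end = ifelse(other == 1L, loops$end1[pairs$loop_row],
                 loops$end2[pairs$loop_row]),
    element_row = pairs$element_row,
    loop_id = loops$loop_id[pairs$loop_row]
  )
  tss_iv <- tibble(chrom = tss$chrom, start = tss$tss, end = tss$tss + 1,
                   gene_id = tss$gene_id, pos = tss$tss)
  # widen anchors by `window` so a single overlap join finds every TSS
  # within the assignment window (inclusive <= window rule)
  padded <- anchors |>
    mutate(start = pmax(0, .data$start - window), end = .data$end + window)
  ov <- overlap_query(padded, tss_iv)
  if (nrow(ov) == 0) {
    return(empty)
  }
  hits <- tibble(
    element_row = anchors$element_row[ov$row_a],
    loop_id = anchors$loop_id[ov$row_a],
    anchor_start = anchors$start[ov$row_a],
    anchor_end = anchors$end[ov$row_a],
    gene_id = tss_iv$gene_id[ov$row_b],
    pos = tss_iv$pos[ov$row_b]
  ) |>
    mutate(gap = point_interval_distance(.data$pos, .data$anchor_start,
                                         .data$anchor_end)) |>
    filter(.data$gap <= window)
  if (nrow(hits) == 0) {
    return(empty)
  }
  hits <- hits |>
    mutate(
      center = floor((elements$start[.data$element_row] +
                        elements$end[.data$element_row]) / 2),
      element_id = elements$element_id[.data$element_row],
      distance = abs(.data$pos - .data$center)
    ) |>
    arrange(.data$element_row, .data$gene_id, .data$gap, .data$pos) |>
    distinct(.data$element_row, .data$gene_id, .keep_all = TRUE)
  tss_by_chrom <- split(tss$tss, tss$chrom)
  el_chrom <- elements$chrom[hits$element_row]
  hits$skipped_tss_count <- vapply(seq_len(nrow(hits)), function(i) {
    pos_all <- tss_by_chrom[[el_chrom[i]]]
    if (is.null(pos_all)) return(0L)
    lo <- min(hits$center[i], hits$pos[i])
    hi <- max(hits$center[i], hits$pos[i])
    length(unique(pos_all[pos_all > lo & pos_all < hi]))
  }, integer(1))
  hits |>
    select("element_id", "gene_id", "tss" = "pos", "distance",
           "skipped_tss_count", "loop_id") |>
    arrange(.data$element_id, .data$gene_id)
}

#' Distance profiles: nearest, nearest-active, and looped TSSes
#'
#' For each element, measures from the element centre to (i) the nearest
#' retained TSS, (ii) the nearest TSS of an active gene (expression above
#' `activity_threshold` in the analysis cell type), and (iii) every
#' loop-mediated target TSS. Genes missing from `expression` are treated
#' as inactive (with a warning); when no gene is active the
#' nearest-active distance is `NA`.
#'
#' @inheritParams loop_targets
#' @param expression Tibble with `gene_id`, `value` columns.
#' @param activity_threshold Activity cutoff on `value` (strictly greater;
#'   default 0).
#' @return Long tibble: `element_id`, `kind` in
#'   `{"nearest", "nearest_active", "looped"}`, `distance` (`NA` when
#'   undefined).
#' @export
distance_profiles <- function(elements, loops, tss, expression,
                              activity_threshold = 0, window = 4000) {
  elements <- check_intervals(elements, "elements")
  if (!"element_id" %in% names(elements)) {
    elements$element_id <- as.character(seq_len(nrow(elements)))
  }
  center <- floor((elements$start + elements$end) / 2)
  missing_genes <- setdiff(unique(tss$gene_id), expression$gene_id)
  if (length(missing_genes) > 0) {
    warn(sprintf("%d gene(s) missing from `expression`; treated as inactive",
                 length(missing_genes)))
  }
  active_genes <- expression$gene_id[expression$value > activity_threshold]
  nearest_dist <- function(tss_sub) {
    pos_by_chrom <- split(tss_sub$tss, tss_sub$chrom)
    vapply(seq_len(nrow(elements)), function(i) {
      p <- pos_by_chrom[[elements$chrom[i]]]
      if (is.null(p) || length(p) == 0) return(NA_real_)
      min(abs(p - center[i]))
    }, numeric(1))
  }
  d_near <- nearest_dist(tss)
  d_active <- nearest_dist(tss[tss$gene_id %in% active_genes, , drop = FALSE])
  looped <- loop_targets(elements, loops, tss, window = window)
  bind_rows(
    tibble(element_id = elements$element_id, kind = "nearest",
           distance = d_near),
    tibble(element_id = elements$element_id, kind = "nearest_active",
           distance = d_active),
    tibble(element_id = looped$element_id, kind = "looped",
           distance = looped$distance)
  )
}

#' Equalise element sizes across categories before comparing loop rates
#'
#' Longer elements overlap loop anchors more often by chance alone. To
#' control for this, every element in category `c` is symmetrically
#' extended so each category's mean size matches the largest category
#' mean: the per-element total extension is `max(category means) -
#' mean(size of c)`, split half per side (left half floored, clipped at
#' position 0).
#'
#' @param elements Interval tibble with a `category` column.
#' @return `elements` with extended `start`/`end` (originals preserved as
#'   `start_orig`/`end_orig`).
#' @export
extension_control <- function(elements) {
  elements <- check_intervals(elements, "elements")
  if (!"category" %in% names(elements)) {
    abort("`elements` must have a `category` column")
  }
  sizes <- elements$end - elements$start
  avg <- tapply(sizes, elements$category, mean)
  pad_total <- unname(max(avg) - avg[as.character(elements$category)])
  pad_left <- as.numeric(floor(pad_total / 2))
  pad_right <- as.numeric(round(pad_total) - pad_left)
  elements |>
    mutate(
      start_orig = .data$start,
      end_orig = .data$end,
      start = pmax(0, .data$start - pad_left),
      end = .data$end + pad_right
    )
}

#' Interactions per unit of element signal
#'
#' Normalises an element's interaction count against its total occupancy
#' signal (e.g. Pol II ChIA-PET coverage); non-positive signal yields
#' `NA`.
#'
#' @param interaction_count Non-negative counts.
#' @param element_signal Signal totals.
#' @return `interaction_count / element_signal`, `NA` where
#'   `element_signal <= 0`.
#' @export
normalize_by_signal <- function(interaction_count, element_signal) {
  ifelse(element_signal > 0, interaction_count / element_signal, NA_real_)
}
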