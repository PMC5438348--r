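#' Trim gapped peaks to their block span
#'
#' MACS2 `--broad` gapped peaks carry flanking "broad" regions outside the
#' strong blocks; the analysis span runs from the start of the first block
#' to the end of the last block. Blocks given out of order in the file are
#' handled.
#'
#' @param gapped Tibble from `read_intervals(format = "gappedPeak")` (needs
#'   `chrom`, `start`, `end`, `block_sizes`, `block_starts`).
#' @return Tibble of trimmed spans: `chrom`, `start`, `end`, `name`
#'   (source gapped-peak id), `length`.
#' @export
trim_gapped_peaks <- function(gapped) {
  gapped <- check_intervals(gapped, "gapped")
  if (!all(c("block_sizes", "block_starts") %in% names(gapped))) {
    abort("`gapped` must carry `block_sizes` and `block_starts` list-columns")
  }
  nblocks <- lengths(gapped$block_starts)
  if (any(nblocks == 0)) {
    abort(sprintf("gapped peak at row %d has zero blocks",
                  which(nblocks == 0)[1]))
  }
  first_off <- vapply(gapped$block_starts, min, numeric(1))
  last_end <- mapply(function(st, sz) max(st + sz),
                     gapped$block_starts, gapped$block_sizes)
  ids <- if ("name" %in% names(gapped)) gapped$name else as.character(seq_len(nrow(gapped)))
  tibble(
    chrom = gapped$chrom,
    start = gapped$start + first_off,
    end = gapped$start + last_end,
    name = ids
  ) |>
    mutate(length = .data$end - .data$start)
}

#' Rank domains by length and mark the broad fraction
#'
#' The `k = ceiling(top_fraction * n)` longest domains are labelled broad,
#' the remainder typical. Length ties at the boundary are broken by
#' `(chrom, start)` ascending so that exactly `k` domains are broad;
#' `ties = "all"` instead promotes every domain tied with the k-th.
#'
#' @param domains Interval tibble (a `length` column is recomputed if
#'   absent).
#' @param top_fraction Fraction of domains called broad, in (0, 1);
#'   default 0.05.
#' @param ties `"exact_k"` (default) or `"all"`.
#' @return `domains` with `length`, `length_rank` (1 = longest) and
#'   `is_broad` columns, in the input row order.
#' @export
rank_by_length <- function(domains, top_fraction = 0.05,
                           ties = c("exact_k", "all")) {
  domains <- check_intervals(domains, "domains")
  ties <- match.arg(ties)
  if (!(top_fraction > 0 && top_fraction < 1)) {
    abort("`top_fraction` must be in (0, 1)")
  }
  if (nrow(domains) == 0) {
    abort("`domains` must contain at least one record")
  }
  domains$length <- domains$end - domains$start
  n <- nrow(domains)
  k <- ceiling(top_fraction * n)
  ord <- order(-domains$length, domains$chrom, domains$start)
  rank_vec <- integer(n)
  rank_vec[ord] <- seq_len(n)
  domains$length_rank <- rank_vec
  if (ties == "exact_k") {
    domains$is_broad <- rank_vec <= k
  } else {
    kth_len <- domains$length[ord[k]]
    domains$is_broad <- domains$length >= kth_len
  }
  domains
}

#' Call broad H3K4me3 domains from a gapped-peak file
#'
#' Convenience wrapper: trim to block spans, then rank by trimmed length
#' and take the top fraction as broad domains.
#'
#' @inheritParams trim_gapped_peaks
#' @inheritParams rank_by_length
#' @return Trimmed domain tibble with `length`, `length_rank`, `is_broad`.
#' @export
call_broad_domains <- function(gapped, top_fraction = 0.05,
                               ties = c("exact_k", "all")) {
  trim_gapped_peaks(gapped) |>
    rank_by_length(top_fraction = top_fraction, ties = ties)
}
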