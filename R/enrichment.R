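#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The p-value sums the hypergeometric probabilities of every table with
#' the observed margins whose probability does not exceed that of the
#' observed table (the classic two-sided rule, as in
#' [stats::fisher.test()]). The odds ratio reported is the sample odds
#' ratio `(a*d)/(b*c)` — 0 or infinite tables are allowed — not the
#' conditional MLE.
#'
#' @param a,b,c,d Cell counts: `a`/`b` successes/failures in group 1,
#'   `c`/`d` in group 2.
#' @return Tibble with `p_value` and `odds_ratio`.
#' @export
#' @examples
#' fisher_exact(2, 0, 0, 2) # p = 1/3
fisher_exact <- function(a, b, c, d) {
  cells <- unname(c(a, b, c, d))
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("cells must be non-negative integers")
  }
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    abort("all table margins must be positive")
  }
  p <- stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
  or <- (a * d) / (b * c)
  tibble(p_value = min(p, 1), odds_ratio = or)
}

#' Holm-Sidak step-down multiple-testing correction
#'
#' Sorts the m p-values ascending, adjusts the i-th smallest to
#' `1 - (1 - p)^(m - i + 1)`, enforces monotonicity with a running
#' maximum, caps at 1, and restores the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' holm_sidak(c(0.01, 0.04)) # 1 - 0.99^2 = 0.0199, then 0.04
holm_sidak <- function(p_values) {
  if (length(p_values) == 0) {
    return(numeric(0))
  }
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  ord <- order(p_values)
  sorted <- p_values[ord]
  adj <- 1 - (1 - sorted)^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Average subsample counts for a large control gene set
#'
#' A control set much larger than the case sets (e.g. 3804 housekeeping
#' genes against cancer sets of a few hundred) would dominate a 2x2
#' table. Instead, `sample_size` genes are repeatedly drawn without
#' replacement and a count computed on each draw; the average over `reps`
#' draws is used. The count is `sum(predicate(draw))` — how many sampled
#' genes satisfy the predicate — unless a `counter` function (draw ->
#' single number, e.g. "regions hitting the drawn genes") is supplied.
#' Deterministic given `seed`; the caller's RNG state is untouched.
#'
#' @param genes Character vector, the full control set.
#' @param predicate Vectorised function: gene ids -> logical.
#' @param sample_size Genes per draw (default 500).
#' @param reps Number of draws (default 1000).
#' @param seed Integer seed.
#' @param counter Optional function: drawn gene ids -> numeric count,
#'   overriding `predicate`.
#' @return The average count (a single number).
#' @export
hk_average_counts <- function(genes, predicate = NULL, sample_size = 500,
                              reps = 1000, seed = 1, counter = NULL) {
  if (length(genes) < sample_size) {
    abort(sprintf("control set (%d genes) smaller than sample_size (%d)",
                  length(genes), sample_size))
  }
  if (is.null(counter)) {
    if (is.null(predicate)) {
      abort("supply either `predicate` or `counter`")
    }
    counter <- function(draw) sum(predicate(draw))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  counts <- vapply(seq_len(reps), function(i) {
    counter(genes[sample.int(length(genes), sample_size)])
  }, numeric(1))
  mean(counts)
}

round_half_up <- function(x) floor(x + 0.5)

#' Pairwise gene-set enrichment between region classes
#'
#' Recreates the signed enrichment heat map: for each panel, each pair of
#' region classes, and each gene set, a 2x2 table of (regions hitting the
#' set, regions not hitting) for class A vs class B is tested with
#' [fisher_exact()]; Holm-Sidak correction is applied across all
#' comparisons within a panel; the display score is
#' `sign(log10 OR) * (-log10 p)`.
#'
#' Panels:
#' * `distal_looping` — distal regions involved in interactions; a hit is
#'   a loop-mediated target in the gene set.
#' * `proximal_looping` — proximal involved regions, loop-mediated hits.
#' * `proximal_proximity` — all proximal regions; a hit is a proximal
#'   gene in the set.
#'
#' Housekeeping cells use [hk_average_counts()] (regions hitting a
#' random subsample of the housekeeping set, averaged and rounded
#' half-up) so that the oversized control set enters the table at the
#' same scale as the cancer sets.
#'
#' @param regions Taxonomy tibble from [build_taxonomy()] with an
#'   `involved` column (see [associate_elements()]).
#' @param catalog [derive_gene_sets()] catalog.
#' @param targets_looping Tibble `region_id`, `gene_id` of loop-mediated
#'   targets.
#' @param targets_proximity Tibble `region_id`, `gene_id` of proximal
#'   genes.
#' @param hk_sample_size,hk_reps Subsampling control parameters
#'   (defaults 500 / 1000).
#' @param seed Seed for the housekeeping subsampling.
#' @return An `se_enrichment` tibble: `panel`, `class_a`, `class_b`,
#'   `gene_set`, `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`, `p_adj`,
#'   `signed_score`.
#' @export
enrichment_matrix <- function(regions, catalog, targets_looping,
                              targets_proximity, hk_sample_size = 500,
                              hk_reps = 1000, seed = 1) {
  if (!"involved" %in% names(regions)) {
    abort("`regions` must carry an `involved` column")
  }
  gene_sets <- list(
    TSG = catalog$tumor_suppressors,
    OG = catalog$oncogenes,
    CCG = catalog$census_cancer
  )
  hk_genes <- catalog$housekeeping
  classes <- c("SE_BD", "SE_O", "BD_O", "O_O")
  panels <- list(
    distal_looping = list(
      rows = regions$proximity == "distal" & regions$involved,
      targets = targets_looping
    ),
    proximal_looping = list(
      rows = regions$proximity == "proximal" & regions$involved,
      targets = targets_looping
    ),
    proximal_proximity = list(
      rows = regions$proximity == "proximal",
      targets = targets_proximity
    )
  )
  hk_seed_counter <- 0L
  out <- list()
  for (panel_name in names(panels)) {
    panel <- panels[[panel_name]]
    sub <- regions[panel$rows, ]
    targets <- panel$targets |>
      mutate(gene_id = toupper(.data$gene_id)) |>
      semi_join(tibble(region_id = sub$region_id), by = "region_id")
    class_regions <- split(sub$region_id, factor(sub$region_class,
                                                 levels = classes))
    targets_by_class <- lapply(class_regions, function(ids) {
      targets[targets$region_id %in% ids, ]
    })
    n_hit <- function(cls, gene_subset) {
      tc <- targets_by_class[[cls]]
      dplyr::n_distinct(tc$region_id[tc$gene_id %in% gene_subset])
    }
    present <- classes[vapply(class_regions, length, integer(1)) > 0]
    skipped <- setdiff(classes, present)
    if (length(skipped) > 0) {
      warn(sprintf("panel %s: class(es) %s empty, comparisons skipped",
                   panel_name, paste(skipped, collapse = ", ")))
    }
    if (length(present) < 2) next
    pairs <- utils::combn(present, 2, simplify = FALSE)
    rows <- list()
    for (pair in pairs) {
      ids_a <- class_regions[[pair[1]]]
      ids_b <- class_regions[[pair[2]]]
      for (set_name in c(names(gene_sets), "HKG")) {
        if (set_name == "HKG") {
          hk_seed_counter <- hk_seed_counter + 1L
          hita <- round_half_up(hk_average_counts(
            hk_genes, sample_size = hk_sample_size, reps = hk_reps,
            seed = (seed + 7919L * hk_seed_counter) %% 2147483647L,
            counter = function(draw) n_hit(pair[1], draw)
          ))
          hk_seed_counter <- hk_seed_counter + 1L
          hitb <- round_half_up(hk_average_counts(
            hk_genes, sample_size = hk_sample_size, reps = hk_reps,
            seed = (seed + 7919L * hk_seed_counter) %% 2147483647L,
            counter = function(draw) n_hit(pair[2], draw)
          ))
          hita <- min(hita, length(ids_a))
          hitb <- min(hitb, length(ids_b))
        } else {
          hita <- n_hit(pair[1], gene_sets[[set_name]])
          hitb <- n_hit(pair[2], gene_sets[[set_name]])
        }
        tb <- c(a = hita, b = length(ids_a) - hita,
                c = hitb, d = length(ids_b) - hitb)
        ft <- tryCatch(fisher_exact(tb["a"], tb["b"], tb["c"], tb["d"]),
                       error = function(e) tibble(p_value = NA_real_,
                                                  odds_ratio = NA_real_))
        rows[[length(rows) + 1]] <- tibble(
          panel = panel_name, class_a = pair[1], class_b = pair[2],
          gene_set = set_name, a = tb[["a"]], b = tb[["b"]],
          c = tb[["c"]], d = tb[["d"]],
          odds_ratio = ft$odds_ratio, p_value = ft$p_value
        )
      }
    }
    panel_tbl <- bind_rows(rows)
    ok <- !is.na(panel_tbl$p_value)
    panel_tbl$p_adj <- NA_real_
    panel_tbl$p_adj[ok] <- holm_sidak(panel_tbl$p_value[ok])
    panel_tbl$signed_score <- signed_score(panel_tbl$odds_ratio,
                                           panel_tbl$p_value)
    out[[panel_name]] <- panel_tbl
  }
  res <- bind_rows(out)
  class(res) <- c("se_enrichment", class(res))
  res
}

#' Signed display score for enrichment heat maps
#'
#' `sign(log10(odds_ratio)) * (-log10(p))`: positive for enrichment,
#' negative for depletion, 0 at odds ratio 1; `NA` propagates.
#'
#' @param odds_ratio Sample odds ratios (0 and `Inf` allowed).
#' @param p P-values.
#' @return Numeric scores.
#' @export
signed_score <- function(odds_ratio, p) {
  s <- sign(suppressWarnings(log10(odds_ratio)))
  s[is.nan(s)] <- 0
  out <- s * (-log10(p))
  out[!is.na(odds_ratio) & odds_ratio == 1] <- 0
  out
}

#' @method autoplot se_enrichment
#' @export
autoplot.se_enrichment <- function(object, ...) {
  dat <- as_tibble(object) |>
    mutate(comparison = paste(.data$class_a, "vs", .data$class_b))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$gene_set,
                                    y = .data$comparison,
                                    fill = .data$signed_score)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = "signed\n-log10 p") +
    ggplot2::labs(x = "gene set", y = "region-class comparison",
                  title = "Pairwise gene-set enrichment between region classes")
}

#' Dunn's post-hoc rank test
#'
#' Pairwise z statistics on joint mid-ranks with the standard tie
#' correction: for groups g, h,
#' `z = (meanrank_g - meanrank_h) / sqrt((N(N+1)/12 - T) (1/n_g + 1/n_h))`
#' where `T = sum(t^3 - t) / (12 (N - 1))` over tie groups of size t, and
#' the two-sided p-value comes from the normal distribution. No internal
#' multiple-comparison adjustment is applied; layer [holm_sidak()] on
#' top if required.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding the measurements and
#'   group labels.
#' @return Tibble: `group1`, `group2`, `mean_rank1`, `mean_rank2`, `z`,
#'   `p_value`, for every unordered group pair.
#' @export
dunn_test <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- g[keep]
  n_by <- table(g)
  if (length(n_by) < 2) {
    abort("need at least 2 groups")
  }
  if (any(n_by == 0)) {
    abort("every group must be non-empty")
  }
  N <- length(v)
  if (N < 3) {
    abort("need at least 3 observations in total")
  }
  r <- rank(v) # mid-ranks for ties
  mean_rank <- tapply(r, g, mean)
  tie_sizes <- table(v)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  var_core <- N * (N + 1) / 12 - tie_term
  groups <- names(n_by)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    se <- sqrt(var_core * (1 / n_by[[p[1]]] + 1 / n_by[[p[2]]]))
    z <- if (se == 0) 0 else (mean_rank[[p[1]]] - mean_rank[[p[2]]]) / se
    tibble(
      group1 = p[1], group2 = p[2],
      mean_rank1 = mean_rank[[p[1]]], mean_rank2 = mean_rank[[p[2]]],
      z = z, p_value = 2 * stats::pnorm(-abs(z))
    )
  })
}
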