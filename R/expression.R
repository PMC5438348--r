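#' Average CAGE cluster expression within facets
#'
#' FANTOM-style facets group samples by cell type; the expression of a
#' cluster in a facet is the arithmetic mean of its expression over the
#' facet's samples.
#'
#' @param mat Expression tibble: identifier/coordinate columns plus one
#'   numeric column per sample. Recognised non-sample columns are
#'   `cluster_id`, `chrom`, `start`, `end`, `bidirectional`.
#' @param sample_map Tibble with columns `sample`, `facet` assigning every
#'   sample column of `mat` to exactly one facet.
#' @return Tibble with the identifier/coordinate columns followed by one
#'   numeric column per facet; the facet names are attached as attribute
#'   `"facets"`.
#' @export
facet_means <- function(mat, sample_map) {
  mat <- as_tibble(mat)
  if (!all(c("sample", "facet") %in% names(sample_map))) {
    abort("`sample_map` must have `sample` and `facet` columns")
  }
  if (anyDuplicated(sample_map$sample)) {
    abort("`sample_map` assigns some sample to more than one facet")
  }
  meta_cols <- intersect(c("cluster_id", "chrom", "start", "end",
                           "bidirectional"), names(mat))
  sample_cols <- setdiff(names(mat), meta_cols)
  unmapped <- setdiff(sample_cols, sample_map$sample)
  if (length(unmapped) > 0) {
    abort(sprintf("sample column(s) not mapped to a facet: %s",
                  paste(unmapped, collapse = ", ")))
  }
  if ("cluster_id" %in% names(mat) && anyDuplicated(mat$cluster_id)) {
    abort("`cluster_id` values must be unique")
  }
  vals <- as.matrix(mat[sample_cols])
  if (any(vals < 0, na.rm = TRUE)) {
    abort("expression values must be >= 0")
  }
  facet_of <- setNames(sample_map$facet, sample_map$sample)[sample_cols]
  facets <- unique(sample_map$facet[sample_map$sample %in% sample_cols])
  means <- vapply(facets, function(f) {
    rowMeans(vals[, facet_of == f, drop = FALSE])
  }, numeric(nrow(mat)))
  if (nrow(mat) == 1) means <- matrix(means, nrow = 1,
                                      dimnames = list(NULL, facets))
  out <- bind_cols(mat[meta_cols], as_tibble(means))
  attr(out, "facets") <- facets
  out
}

#' Entropy-based cell-type specificity
#'
#' For a vector `X` of non-negative expression values over `N >= 2`
#' facets, `specificity(X) = 1 - entropy(X / sum(X)) / log2(N)` with the
#' Shannon entropy in bits and the convention `0 * log2(0) = 0`. Uniform
#' expression scores 0, single-facet expression scores 1, and an all-zero
#' vector is undefined (`NA`). The score is invariant to rescaling of
#' `X`.
#'
#' @param x Numeric vector of facet expression values.
#' @return A single value in `[0, 1]`, or `NA` for an all-zero vector.
#' @export
#' @examples
#' specificity(rep(1, 5))        # 0: ubiquitous
#' specificity(c(0, 0, 7, 0))    # 1: one facet only
#' specificity(c(0.5, 0.5, 0, 0)) # 0.5
specificity <- function(x) {
  if (length(x) < 2) {
    abort("specificity needs at least 2 facets")
  }
  if (any(is.na(x)) || any(x < 0)) {
    abort("expression values must be non-negative and non-missing")
  }
  total <- sum(x)
  if (total == 0) {
    return(NA_real_)
  }
  p <- x / total
  p <- p[p > 0]
  entropy <- -sum(p * log2(p))
  1 - entropy / log2(length(x))
}

#' Specificity scores for every cluster of a facet-expression table
#'
#' @param facet_expr Output of [facet_means()].
#' @return Tibble with the identifier columns of `facet_expr` plus a
#'   `specificity` column (`NA` for all-zero rows).
#' @export
specificity_scores <- function(facet_expr) {
  facets <- attr(facet_expr, "facets")
  if (is.null(facets)) {
    meta <- intersect(c("cluster_id", "chrom", "start", "end",
                        "bidirectional"), names(facet_expr))
    facets <- setdiff(names(facet_expr), meta)
  }
  vals <- as.matrix(facet_expr[facets])
  scores <- apply(vals, 1, specificity)
  meta_cols <- setdiff(names(facet_expr), facets)
  bind_cols(facet_expr[meta_cols], tibble(specificity = scores))
}

#' Map CAGE cluster expression onto regulatory elements
#'
#' Assigns every cluster to every element it overlaps (by >= 1 base). In
#' `enhancer_rna_mode` an element counts as transcribed when at least one
#' assigned bidirectional cluster is expressed in the analysis facet:
#' above zero and at least `tpm_threshold` tags per million; with an
#' element `category` column a per-category transcribed fraction is
#' attached as attribute `"category_fractions"`.
#'
#' @param clusters Facet-expression tibble with cluster coordinates (and a
#'   `bidirectional` logical column when `enhancer_rna_mode`).
#' @param elements Interval tibble (optionally with `element_id` and
#'   `category` columns).
#' @param analysis_facet Name of the facet column holding the analysis
#'   cell type's expression.
#' @param enhancer_rna_mode Restrict the transcribed call to bidirectional
#'   (enhancer RNA) clusters.
#' @param tpm_threshold Minimum expression for a cluster to support a
#'   transcribed call (default 0, i.e. any positive expression).
#' @return Tibble: `element_id`, `cluster_id`, `expression` (analysis
#'   facet), `bidirectional` (if available), plus per-element `transcribed`
#'   in a second tibble attached as attribute `"elements"`.
#' @export
map_expression_to_elements <- function(clusters, elements, analysis_facet,
                                       enhancer_rna_mode = FALSE,
                                       tpm_threshold = 0) {
  clusters <- check_intervals(clusters, "clusters")
  elements <- check_intervals(elements, "elements")
  if (!analysis_facet %in% names(clusters)) {
    abort(sprintf("facet column `%s` not found in `clusters`", analysis_facet))
  }
  if (!"element_id" %in% names(elements)) {
    elements$element_id <- as.character(seq_len(nrow(elements)))
  }
  if (!"cluster_id" %in% names(clusters)) {
    clusters$cluster_id <- as.character(seq_len(nrow(clusters)))
  }
  bidir <- if ("bidirectional" %in% names(clusters)) {
    as.logical(clusters$bidirectional)
  } else if (enhancer_rna_mode) {
    abort("enhancer_rna_mode requires a `bidirectional` column")
  } else {
    rep(NA, nrow(clusters))
  }
  ov <- overlap_query(elements, clusters)
  assigned <- tibble(
    element_id = elements$element_id[ov$row_a],
    cluster_id = clusters$cluster_id[ov$row_b],
    expression = clusters[[analysis_facet]][ov$row_b],
    bidirectional = bidir[ov$row_b]
  )
  supports <- assigned$expression > 0 & assigned$expression >= tpm_threshold
  if (enhancer_rna_mode) {
    supports <- supports & assigned$bidirectional %in% TRUE
  }
  transcribed_ids <- unique(assigned$element_id[supports])
  per_element <- elements |>
    mutate(transcribed = .data$element_id %in% transcribed_ids) |>
    select(dplyr::any_of(c("element_id", "category")), "transcribed")
  attr(assigned, "elements") <- per_element
  if ("category" %in% names(elements)) {
    fr <- per_element |>
      group_by(.data$category) |>
      summarise(n = dplyr::n(), transcribed_fraction = mean(.data$transcribed),
                .groups = "drop")
    attr(assigned, "category_fractions") <- fr
  }
  assigned
}
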