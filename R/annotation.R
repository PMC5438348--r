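#' Default transcript biotypes excluded from TSS derivation
#'
#' Small structural RNAs, pseudogene classes of those RNAs, and
#' annotation-artifact biotypes whose 5' ends do not mark regulated
#' promoters.
#'
#' @return Character vector of biotype names.
#' @export
default_excluded_biotypes <- function() {
  c("Mt_rRNA", "Mt_tRNA", "Mt_tRNA_pseudogene", "miRNA",
    "miRNA_pseudogene", "misc_RNA", "misc_RNA_pseudogene", "rRNA",
    "rRNA_pseudogene", "scRNA_pseudogene", "snRNA", "snRNA_pseudogene",
    "snoRNA", "snoRNA_pseudogene", "tRNA", "tRNA_pseudogene", "tRNAscan",
    "retained_intron", "TEC", "disrupted_domain")
}

#' Load transcription start sites from a GTF annotation
#'
#' Reads a Gencode-style GTF (1-based inclusive, converted to the package's
#' 0-based convention on read), keeps transcript records whose biotype is
#' not excluded, and derives the strand-aware TSS: the `start` of a `+`
#' transcript, the last base of a `-` transcript. Records without a usable
#' strand are skipped with a warning.
#'
#' @param path Path to a GTF file.
#' @param excluded_biotypes Biotypes to drop
#'   (default [default_excluded_biotypes()]).
#' @return Tibble with `chrom`, `tss` (0-based position), `strand`,
#'   `gene_id`, `transcript_id`, `gene_name`, `biotype`.
#' @export
load_tss <- function(path, excluded_biotypes = default_excluded_biotypes()) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "transcript"]
  md <- S4Vectors::mcols(gr)
  biotype <- if ("transcript_type" %in% names(md)) {
    md$transcript_type
  } else if ("transcript_biotype" %in% names(md)) {
    md$transcript_biotype
  } else if ("gene_type" %in% names(md)) {
    md$gene_type
  } else {
    rep(NA_character_, length(gr))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  bad_strand <- !strand %in% c("+", "-")
  if (any(bad_strand)) {
    warn(sprintf("skipped %d transcript(s) with unknown strand",
                 sum(bad_strand)))
  }
  keep <- !bad_strand & !(biotype %in% excluded_biotypes)
  gr <- gr[keep]
  strand <- strand[keep]
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr) # exclusive in 0-based
  gene_name <- if ("gene_name" %in% names(S4Vectors::mcols(gr))) {
    S4Vectors::mcols(gr)$gene_name
  } else {
    S4Vectors::mcols(gr)$gene_id
  }
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    tss = ifelse(strand == "+", start0, end0 - 1L),
    strand = strand,
    gene_id = S4Vectors::mcols(gr)$gene_id,
    transcript_id = S4Vectors::mcols(gr)$transcript_id,
    gene_name = gene_name,
    biotype = biotype[keep]
  )
}

#' Classify elements as promoter-proximal or distal
#'
#' An element is proximal when the edge-to-edge distance from the element
#' to some retained TSS is at most `threshold` bases (inclusive; a TSS
#' inside the element gives distance 0), otherwise distal.
#'
#' @param elements Interval tibble.
#' @param tss Tibble with `chrom` and `tss` columns (see [load_tss()]).
#' @param threshold Distance cutoff in bases (default 4000).
#' @return `elements` with `tss_distance` (distance to the nearest TSS,
#'   `NA` if none on any chromosome) and `proximity`
#'   (`"proximal"`/`"distal"`) columns.
#' @export
classify_proximity <- function(elements, tss, threshold = 4000) {
  elements <- check_intervals(elements, "elements")
  if (length(threshold) != 1 || is.na(threshold) || threshold < 0) {
    abort("`threshold` must be a single non-negative number")
  }
  if (nrow(tss) == 0) {
    warn("empty TSS set: all elements classified distal")
    return(mutate(elements, tss_distance = NA_real_, proximity = "distal"))
  }
  lv <- union(unique(elements$chrom), unique(tss$chrom))
  el_gr <- as_granges0(elements, lv)
  tss_gr <- GenomicRanges::GRanges(
    seqnames = factor(tss$chrom, levels = lv),
    ranges = IRanges::IRanges(start = tss$tss + 1L, width = 1L)
  )
  hits <- GenomicRanges::distanceToNearest(el_gr, tss_gr)
  dist <- rep(NA_real_, nrow(elements))
  dist[S4Vectors::queryHits(hits)] <- as.numeric(S4Vectors::mcols(hits)$distance)
  elements |>
    mutate(
      tss_distance = dist,
      proximity = if_else(!is.na(dist) & dist <= threshold,
                          "proximal", "distal")
    )
}

#' Assemble the gene-set catalog used for enrichment testing
#'
#' Tumor suppressors and oncogenes are the genes scored below
#' `tuson_p_threshold` in the respective TUSON-style columns; the
#' leukemia-associated set is extracted from the census catalog by
#' case-insensitive substring match of `leukemia_keywords` against the
#' tumour-type text. Symbols are matched case-insensitively (stored
#' upper-case) and de-duplicated within each set.
#'
#' @param tuson Tibble with columns `symbol`, `p_tsg`, `p_og`.
#' @param census Tibble with columns `symbol`, `tumour_types`.
#' @param housekeeping Tibble with column `symbol`.
#' @param tuson_p_threshold Inclusion threshold, strictly-below rule
#'   (default 0.01).
#' @param leukemia_keywords Keywords for the leukemia subset.
#' @return A `gene_set_catalog`: a named list of upper-cased symbol
#'   vectors `tumor_suppressors`, `oncogenes`, `census_cancer`,
#'   `housekeeping`, `leukemia_associated`.
#' @export
derive_gene_sets <- function(tuson, census, housekeeping,
                             tuson_p_threshold = 0.01,
                             leukemia_keywords = c("leukaemia", "leukemia",
                                                   "AML", "CML", "ALL",
                                                   "CLL")) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      abort(sprintf("`%s` table is missing column(s): %s",
                    what, paste(miss, collapse = ", ")))
    }
  }
  need(tuson, c("symbol", "p_tsg", "p_og"), "tuson")
  need(census, c("symbol", "tumour_types"), "census")
  need(housekeeping, "symbol", "housekeeping")
  norm <- function(x) unique(toupper(x[!is.na(x) & nzchar(x)]))
  kw <- tolower(leukemia_keywords)
  leuk_hit <- vapply(tolower(census$tumour_types), function(txt) {
    any(vapply(kw, function(k) grepl(k, txt, fixed = TRUE), logical(1)))
  }, logical(1))
  catalog <- list(
    tumor_suppressors = norm(tuson$symbol[!is.na(tuson$p_tsg) &
                                            tuson$p_tsg < tuson_p_threshold]),
    oncogenes = norm(tuson$symbol[!is.na(tuson$p_og) &
                                    tuson$p_og < tuson_p_threshold]),
    census_cancer = norm(census$symbol),
    housekeeping = norm(housekeeping$symbol),
    leukemia_associated = norm(census$symbol[leuk_hit])
  )
  class(catalog) <- "gene_set_catalog"
  catalog
}

#' @export
print.gene_set_catalog <- function(x, ...) {
  cat("Gene-set catalog\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %d genes\n", nm, length(x[[nm]])))
  }
  invisible(x)
}
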