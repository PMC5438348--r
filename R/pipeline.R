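#' Genes proximal to elements
#'
#' For each element, the genes with at least one retained TSS within
#' `threshold` bases (edge-to-edge, inclusive).
#'
#' @param elements Interval tibble (optionally with `element_id`).
#' @param tss TSS tibble (see [load_tss()]).
#' @param threshold Distance cutoff in bases (default 4000).
#' @return Tibble `element_id`, `gene_id`.
#' @export
proximal_genes <- function(elements, tss, threshold = 4000) {
  elements <- check_intervals(elements, "elements")
  if (!"element_id" %in% names(elements)) {
    elements$element_id <- as.character(seq_len(nrow(elements)))
  }
  if (nrow(tss) == 0 || nrow(elements) == 0) {
    return(tibble(element_id = character(), gene_id = character()))
  }
  padded <- elements |>
    mutate(start = pmax(0, .data$start - threshold),
           end = .data$end + threshold)
  tss_iv <- tibble(chrom = tss$chrom, start = tss$tss, end = tss$tss + 1)
  ov <- overlap_query(padded, tss_iv)
  gap <- point_interval_distance(tss$tss[ov$row_b],
                                 elements$start[ov$row_a],
                                 elements$end[ov$row_a])
  tibble(
    element_id = elements$element_id[ov$row_a],
    gene_id = tss$gene_id[ov$row_b]
  )[gap <= threshold, ] |>
    distinct() |>
    arrange(.data$element_id, .data$gene_id)
}

#' Analysis parameters and input locations for a pipeline run
#'
#' @param inputs Named list of input file paths: `peaks`, `treatment`,
#'   `control`, `gapped`, `loops_rep1`, `loops_rep2`, `gtf`, `cage`,
#'   `facet_map`, `tuson`, `census`, `housekeeping` (as produced by
#'   [write_fixture()], or pointing at real data in the same formats).
#' @param output_dir Directory for the stage outputs.
#' @param stitch_window Peak stitching window in bases (default 4000).
#' @param proximity_threshold Proximal/distal TSS distance in bases
#'   (default 4000).
#' @param broad_fraction Fraction of H3K4me3 domains called broad
#'   (default 0.05).
#' @param target_window Anchor-to-TSS assignment window (default 4000).
#' @param tuson_p_threshold TUSON inclusion threshold (default 0.01).
#' @param activity_threshold Expression above which a gene counts as
#'   active (default 0).
#' @param tpm_threshold Minimum eRNA expression supporting a transcribed
#'   call (default 0, i.e. any positive expression).
#' @param analysis_facet Facet holding the analysis cell type.
#' @param hk_sample_size,hk_reps Housekeeping subsampling control
#'   (defaults 500 / 1000).
#' @param seed Seed for the only stochastic stage (housekeeping
#'   subsampling).
#' @return A `run_config` list.
#' @export
run_config <- function(inputs, output_dir, stitch_window = 4000,
                       proximity_threshold = 4000, broad_fraction = 0.05,
                       target_window = 4000, tuson_p_threshold = 0.01,
                       activity_threshold = 0, tpm_threshold = 0,
                       analysis_facet = "K562", hk_sample_size = 500,
                       hk_reps = 1000, seed = 1) {
  needed <- c("peaks", "treatment", "control", "gapped", "loops_rep1",
              "loops_rep2", "gtf", "cage", "facet_map", "tuson", "census",
              "housekeeping")
  miss <- setdiff(needed, names(inputs))
  if (length(miss) > 0) {
    abort(sprintf("`inputs` missing: %s", paste(miss, collapse = ", ")))
  }
  for (par in c(stitch_window, proximity_threshold, target_window)) {
    if (par < 0) abort("windows/thresholds must be non-negative")
  }
  if (!(broad_fraction > 0 && broad_fraction < 1)) {
    abort("`broad_fraction` must be in (0, 1)")
  }
  cfg <- list(
    inputs = inputs, output_dir = output_dir,
    stitch_window = stitch_window,
    proximity_threshold = proximity_threshold,
    broad_fraction = broad_fraction, target_window = target_window,
    tuson_p_threshold = tuson_p_threshold,
    activity_threshold = activity_threshold,
    tpm_threshold = tpm_threshold, analysis_facet = analysis_facet,
    hk_sample_size = hk_sample_size, hk_reps = hk_reps,
    seed = as.integer(seed)
  )
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis on in-memory inputs
#'
#' The computational core of [run_pipeline()], operating on tibbles (for
#' example a fixture bundle from [generate_fixture()]): super-enhancer
#' calling, broad-domain calling, proximity annotation,
#' replicate-reproducible loops, element involvement and loop-mediated
#' targets, facet expression and specificity, the SE/BD region taxonomy,
#' and the pairwise enrichment panels.
#'
#' @param inputs Named list of tibbles: `peaks`, `treatment`, `control`,
#'   `gapped`, `loops_rep1`, `loops_rep2`, `tss`, `cage`, `facet_map`,
#'   `tuson`, `census`, `housekeeping`.
#' @inheritParams run_config
#' @param excluded_biotypes Biotypes dropped from the TSS set.
#' @return Named list of stage results: `enhancers`, `cutoff`, `domains`,
#'   `loops`, `se_targets`, `catalog`, `facet_expr`, `specificity`,
#'   `element_expression`, `taxonomy`, `targets_looping`,
#'   `targets_proximity`, `enrichment`.
#' @export
run_analysis <- function(inputs, stitch_window = 4000,
                         proximity_threshold = 4000, broad_fraction = 0.05,
                         target_window = 4000, tuson_p_threshold = 0.01,
                         activity_threshold = 0, tpm_threshold = 0,
                         analysis_facet = "K562",
                         hk_sample_size = 500, hk_reps = 1000, seed = 1,
                         excluded_biotypes = default_excluded_biotypes()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  tss <- stage("annotate", {
    tss <- as_tibble(inputs$tss)
    tss[!tss$biotype %in% excluded_biotypes, ]
  })
  enh0 <- stage("call-se", {
    call_super_enhancers(inputs$peaks, inputs$treatment, inputs$control,
                         window = stitch_window)
  })
  cutoff <- attr(enh0, "cutoff")
  enhancers <- stage("annotate", {
    classify_proximity(enh0, tss, threshold = proximity_threshold)
  })
  domains <- stage("call-broad", {
    call_broad_domains(inputs$gapped, top_fraction = broad_fraction) |>
      classify_proximity(tss, threshold = proximity_threshold)
  })
  loops <- stage("loops", {
    intersect_replicates(inputs$loops_rep1, inputs$loops_rep2)
  })
  enhancers <- stage("loops", {
    associate_elements(rename(enhancers, element_id = "region_id"), loops) |>
      rename(region_id = "element_id")
  })
  se_targets <- stage("loops", {
    loop_targets(
      enhancers |> filter(.data$is_super) |>
        rename(element_id = "region_id"),
      loops, tss, window = target_window
    )
  })
  catalog <- stage("annotate", {
    derive_gene_sets(inputs$tuson, inputs$census, inputs$housekeeping,
                     tuson_p_threshold = tuson_p_threshold)
  })
  facet_expr <- stage("express", facet_means(inputs$cage, inputs$facet_map))
  spec_scores <- stage("express", specificity_scores(facet_expr))
  element_expression <- stage("express", {
    cat_enh <- enhancers |>
      mutate(
        element_id = .data$region_id,
        category = paste0(
          if_else(.data$proximity == "proximal", "P", "D"),
          if_else(.data$is_super, "SE", "TE")
        )
      )
    map_expression_to_elements(facet_expr, cat_enh,
                               analysis_facet = analysis_facet,
                               enhancer_rna_mode = TRUE,
                               tpm_threshold = tpm_threshold)
  })
  taxonomy <- stage("taxonomy", {
    build_taxonomy(enhancers, domains) |>
      (\(tx) associate_elements(
        rename(tx, element_id = "region_id"), loops
      ) |> rename(region_id = "element_id"))()
  })
  targets_looping <- stage("taxonomy", {
    loop_targets(rename(taxonomy, element_id = "region_id"), loops, tss,
                 window = target_window) |>
      rename(region_id = "element_id") |>
      select("region_id", "gene_id")
  })
  targets_proximity <- stage("taxonomy", {
    proximal_genes(rename(taxonomy, element_id = "region_id"), tss,
                   threshold = proximity_threshold) |>
      rename(region_id = "element_id")
  })
  enrichment <- stage("enrich", {
    enrichment_matrix(taxonomy, catalog, targets_looping,
                      targets_proximity, hk_sample_size = hk_sample_size,
                      hk_reps = hk_reps, seed = seed)
  })
  list(
    enhancers = enhancers, cutoff = cutoff, domains = domains,
    loops = loops, se_targets = se_targets, catalog = catalog,
    facet_expr = facet_expr, specificity = spec_scores,
    element_expression = element_expression, taxonomy = taxonomy,
    targets_looping = targets_looping,
    targets_proximity = targets_proximity, enrichment = enrichment
  )
}

#' Run the pipeline from files to a report bundle
#'
#' Reads the inputs named in the config, executes the stages in
#' dependency order (call SE, call broad, annotate, loops, express,
#' taxonomy, enrich), and writes one TSV per stage plus a JSON run
#' manifest (parameter echo, seed, package version) into
#' `config$output_dir`. Deterministic: identical inputs and seed give
#' byte-identical outputs. Any stage error aborts with the stage name.
#'
#' @param config A [run_config()].
#' @return Invisibly, the [run_analysis()] result list with `$paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  msg <- function(...) message(sprintf("[seloop] %s", sprintf(...)))
  read_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  ins <- config$inputs
  msg("reading inputs")
  inputs <- list(
    peaks = read_stage("call-se",
                       read_intervals(ins$peaks, "narrowPeak")),
    treatment = read_stage("call-se",
                           read_intervals(ins$treatment, "bedgraph")),
    control = read_stage("call-se",
                         read_intervals(ins$control, "bedgraph")),
    gapped = read_stage("call-broad",
                        read_intervals(ins$gapped, "gappedPeak")),
    loops_rep1 = read_stage("loops",
                            read_intervals(ins$loops_rep1, "bedpe")),
    loops_rep2 = read_stage("loops",
                            read_intervals(ins$loops_rep2, "bedpe")),
    tss = read_stage("annotate", {
      # keep all biotypes here; run_analysis applies the exclusion list
      load_tss(ins$gtf, excluded_biotypes = character(0))
    }),
    cage = read_stage("express", readr::read_tsv(ins$cage,
                                                 show_col_types = FALSE)),
    facet_map = read_stage("express",
                           readr::read_tsv(ins$facet_map,
                                           show_col_types = FALSE)),
    tuson = read_stage("annotate",
                       readr::read_tsv(ins$tuson, show_col_types = FALSE)),
    census = read_stage("annotate",
                        readr::read_tsv(ins$census, show_col_types = FALSE)),
    housekeeping = read_stage("annotate",
                              readr::read_tsv(ins$housekeeping,
                                              show_col_types = FALSE))
  )
  msg("running analysis stages")
  res <- run_analysis(
    inputs,
    stitch_window = config$stitch_window,
    proximity_threshold = config$proximity_threshold,
    broad_fraction = config$broad_fraction,
    target_window = config$target_window,
    tuson_p_threshold = config$tuson_p_threshold,
    activity_threshold = config$activity_threshold,
    tpm_threshold = config$tpm_threshold,
    analysis_facet = config$analysis_facet,
    hk_sample_size = config$hk_sample_size,
    hk_reps = config$hk_reps,
    seed = config$seed
  )
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$output_dir, f)
  drop_lists <- function(df) df[!vapply(df, is.list, logical(1))]
  paths <- list(
    enhancers = p("enhancers.tsv"), cutoff = p("cutoff_summary.tsv"),
    domains = p("domains.tsv"), loops = p("loops_reproducible.tsv"),
    se_targets = p("se_loop_targets.tsv"),
    specificity = p("cluster_specificity.tsv"),
    element_expression = p("element_expression.tsv"),
    transcribed_fractions = p("transcribed_fractions.tsv"),
    taxonomy = p("taxonomy.tsv"),
    targets_looping = p("taxonomy_targets_looping.tsv"),
    targets_proximity = p("taxonomy_targets_proximity.tsv"),
    enrichment = p("enrichment.tsv"),
    manifest = p("run_manifest.json")
  )
  readr::write_tsv(drop_lists(res$enhancers), paths$enhancers)
  readr::write_tsv(glance(res$cutoff), paths$cutoff)
  readr::write_tsv(drop_lists(res$domains), paths$domains)
  readr::write_tsv(drop_lists(res$loops), paths$loops)
  readr::write_tsv(res$se_targets, paths$se_targets)
  readr::write_tsv(res$specificity, paths$specificity)
  readr::write_tsv(res$element_expression, paths$element_expression)
  fr <- attr(res$element_expression, "category_fractions")
  if (!is.null(fr)) readr::write_tsv(fr, paths$transcribed_fractions)
  readr::write_tsv(drop_lists(res$taxonomy), paths$taxonomy)
  readr::write_tsv(res$targets_looping, paths$targets_looping)
  readr::write_tsv(res$targets_proximity, paths$targets_proximity)
  readr::write_tsv(as_tibble(res$enrichment), paths$enrichment)
  manifest <- list(
    package = "seloop",
    version = as.character(utils::packageVersion("seloop")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("inputs", "output_dir"))],
    inputs = config$inputs,
    n_enhancers = nrow(res$enhancers),
    n_super = sum(res$enhancers$is_super),
    n_domains = nrow(res$domains),
    n_broad = sum(res$domains$is_broad),
    n_reproducible_loops = nrow(res$loops),
    n_regions = nrow(res$taxonomy)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  msg("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  res$paths <- paths
  invisible(res)
}
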