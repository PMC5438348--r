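#' Configuration for the synthetic regulatory-landscape fixture
#'
#' Defines a miniature two-chromosome genome with planted ground truth
#' emulating the pipeline's real inputs: clustered high-signal H3K27ac
#' peaks forming super-enhancers over a log-normal background,
#' length-skewed H3K4me3 gapped peaks, a Gencode-style annotation,
#' replicate ChIA-PET loop sets with partial sharing and jittered
#' anchors, facet-structured CAGE expression with cell-type-specific and
#' housekeeping profiles, and TUSON/census/housekeeping gene-set tables.
#' Genes attach to elements one-per-site so that, under random gene-set
#' labels, region classes have comparable hit structure; planted
#' enrichment multiplies the tumor-suppressor rate at genes in
#' broad-domain-only sites by `planted_tsg_fold`.
#'
#' @param seed Master seed; every component derives its own stream from
#'   it.
#' @param ... Overrides for any default listed below.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    chrom_sizes = c(chrS1 = 10e6, chrS2 = 10e6),
    # H3K27ac peaks
    n_background_peaks = 200,
    peak_width = c(400, 1200),
    signal_meanlog = log(20), signal_sdlog = 0.3,
    control_fraction = c(0.05, 0.25),
    n_planted_se = 15,
    se_constituents = 5,
    se_constituent_width = c(800, 2000),
    se_gap = c(500, 3000),
    se_signal_multiplier = 12,
    # H3K4me3 gapped peaks
    n_gapped_peaks = 1000,
    gapped_meanlog = log(2500), gapped_sdlog = 0.7,
    broad_fraction = 0.05,
    n_se_bd_overlap = 5,
    domain_gene_prob = 0.85,
    # genes and gene sets
    n_random_genes = 80,
    n_structural_genes = 12,
    p_tsg = 0.10, p_og = 0.10, p_ccg = 0.12, p_hk = 0.35,
    planted_tsg_fold = 5,
    leukemia_fraction = 0.3,
    # loops
    n_loops = 240,
    shared_fraction = 0.7,
    loops_per_se = 2,
    n_bd_loops = 20,
    anchor_width = c(800, 1500),
    anchor_jitter = 200,
    loop_span = c(30e3, 1e6),
    # CAGE
    n_facets = 12,
    samples_per_facet = 3,
    analysis_facet = "K562",
    erna_background_fraction = 0.15,
    # enrichment controls at synthetic catalog scale
    hk_sample_size = 50,
    hk_reps = 200,
    planted_enrichment = TRUE
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown fixture_config field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg[names(overrides)] <- overrides
  counts <- c("n_background_peaks", "n_planted_se", "n_gapped_peaks",
              "n_random_genes", "n_loops", "n_facets", "hk_reps")
  for (f in counts) {
    if (cfg[[f]] < 0) abort(sprintf("`%s` must be >= 0", f))
  }
  if (cfg$shared_fraction < 0 || cfg$shared_fraction > 1) {
    abort("`shared_fraction` must be in [0, 1]")
  }
  if (max(cfg$se_gap) >= 4000) {
    abort("`se_gap` must stay below the 4 kb stitch window")
  }
  class(cfg) <- "fixture_config"
  cfg
}

stream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131 + k * 7919) %% 2147483629 + 1)
}

runifi <- function(n, lo, hi) round(stats::runif(n, lo, hi))

# ---- H3K27ac peak layout -------------------------------------------------

gen_peaks <- function(cfg) {
  set.seed(stream_seed(cfg$seed, 1))
  chroms <- names(cfg$chrom_sizes)
  nb_chrom <- diff(round(seq(0, cfg$n_background_peaks,
                             length.out = length(chroms) + 1)))
  nse_chrom <- diff(round(seq(0, cfg$n_planted_se,
                              length.out = length(chroms) + 1)))
  peaks <- list()
  se_rows <- list()
  se_counter <- 0L
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    nb <- nb_chrom[ci]
    ns <- nse_chrom[ci]
    kind <- sample(c(rep("bg", nb), rep("se", ns)))
    n_items <- length(kind)
    if (n_items == 0) next
    item_width <- numeric(n_items)
    item_peaks <- vector("list", n_items)
    for (i in seq_len(n_items)) {
      if (kind[i] == "bg") {
        w <- runifi(1, cfg$peak_width[1], cfg$peak_width[2])
        h <- stats::rlnorm(1, cfg$signal_meanlog, cfg$signal_sdlog)
        item_width[i] <- w
        item_peaks[[i]] <- tibble(off = 0, width = w, height = h)
      } else {
        k <- cfg$se_constituents
        w <- runifi(k, cfg$se_constituent_width[1], cfg$se_constituent_width[2])
        g <- runifi(k - 1, cfg$se_gap[1], cfg$se_gap[2])
        h <- stats::rlnorm(k, cfg$signal_meanlog, cfg$signal_sdlog) *
          cfg$se_signal_multiplier
        off <- cumsum(c(0, w[-k] + g))
        item_width[i] <- off[k] + w[k]
        item_peaks[[i]] <- tibble(off = off, width = w, height = h)
      }
    }
    # wide gaps around planted clusters keep them stitch-isolated
    near_se <- kind == "se" | c("bg", kind[-n_items]) == "se"
    gaps <- ifelse(near_se, runifi(n_items, 8000, 25000),
                   runifi(n_items, 2500, 20000))
    starts <- 50000 + cumsum(gaps + item_width) - item_width
    if (starts[n_items] + item_width[n_items] >
        cfg$chrom_sizes[[ci]] - 50000) {
      abort(sprintf("planted elements exceed capacity of %s", chrom))
    }
    for (i in seq_len(n_items)) {
      p <- item_peaks[[i]]
      is_se <- kind[i] == "se"
      if (is_se) se_counter <- se_counter + 1L
      rows <- tibble(
        chrom = chrom,
        start = starts[i] + p$off,
        end = starts[i] + p$off + p$width,
        height = p$height,
        is_se_constituent = is_se,
        se_id = if (is_se) sprintf("SE%03d", se_counter) else NA_character_
      )
      peaks[[length(peaks) + 1]] <- rows
      if (is_se) {
        se_rows[[se_counter]] <- tibble(
          se_id = sprintf("SE%03d", se_counter), chrom = chrom,
          start = min(rows$start), end = max(rows$end)
        )
      }
    }
  }
  peaks <- bind_rows(peaks) |>
    arrange(.data$chrom, .data$start) |>
    mutate(
      name = sprintf("peak_%05d", row_number()),
      score = pmin(1000, round(.data$height * 10)),
      strand = ".",
      signal_value = round(.data$height, 4),
      p_value = -1, q_value = -1,
      peak = floor((.data$end - .data$start) / 2),
      control_height = .data$height *
        stats::runif(dplyr::n(), cfg$control_fraction[1],
                     cfg$control_fraction[2])
    )
  list(peaks = peaks, se = bind_rows(se_rows))
}

# ---- H3K4me3 gapped peak layout ------------------------------------------

make_blocks <- function(span_len, trim_off, trim_len, n_blocks) {
  if (n_blocks == 1) {
    return(list(sizes = as.integer(trim_len), starts = as.integer(trim_off)))
  }
  cuts <- sort(stats::runif(n_blocks - 1, 0.25, 0.75)) * trim_len
  gap_half <- max(1, min(150, floor(trim_len * 0.04)))
  b_start <- c(0, round(cuts) + gap_half)
  b_end <- c(round(cuts) - gap_half, trim_len)
  ok <- b_end > b_start
  b_start <- b_start[ok]
  b_end <- b_end[ok]
  b_start[1] <- 0
  b_end[length(b_end)] <- trim_len
  list(sizes = as.integer(b_end - b_start),
       starts = as.integer(trim_off + b_start))
}

gen_gapped <- function(cfg, se) {
  set.seed(stream_seed(cfg$seed, 2))
  n <- cfg$n_gapped_peaks
  trim_len <- pmin(pmax(round(stats::rlnorm(n, cfg$gapped_meanlog,
                                            cfg$gapped_sdlog)), 600), 80000)
  flank1 <- runifi(n, 200, 800)
  flank2 <- runifi(n, 200, 800)
  nblocks <- sample(1:3, n, replace = TRUE)
  k <- ceiling(cfg$broad_fraction * n)
  broad_rank <- order(-trim_len)
  is_broad <- logical(n)
  is_broad[broad_rank[seq_len(k)]] <- TRUE
  over_se <- logical(n)
  n_overlay <- min(cfg$n_se_bd_overlap, k, nrow(se))
  overlay_idx <- broad_rank[seq_len(n_overlay)]
  over_se[overlay_idx] <- TRUE

  chroms <- names(cfg$chrom_sizes)
  chrom_of <- character(n)
  t_start <- numeric(n)
  # overlay broads centred on the first planted SEs
  for (j in seq_len(n_overlay)) {
    i <- overlay_idx[j]
    se_row <- se[j, ]
    center <- floor((se_row$start + se_row$end) / 2)
    chrom_of[i] <- se_row$chrom
    t_start[i] <- max(0, center - floor(trim_len[i] / 2))
  }
  # remaining domains fill the free segments between SE exclusion zones
  rest <- which(!over_se)
  chrom_assign <- rep(chroms, length.out = length(rest))
  forbid <- bind_rows(
    se |> mutate(start = .data$start - 2500, end = .data$end + 2500) |>
      select("chrom", "start", "end"),
    tibble(chrom = chrom_of[overlay_idx],
           start = t_start[overlay_idx] - 2500,
           end = t_start[overlay_idx] + trim_len[overlay_idx] + 2500)
  )
  for (chrom in chroms) {
    idx <- rest[chrom_assign == chrom]
    if (length(idx) == 0) next
    fz <- forbid |> filter(.data$chrom == !!chrom) |> arrange(.data$start)
    seg_start <- c(60000, fz$end)
    seg_end <- c(fz$start, cfg$chrom_sizes[[chrom]] - 60000)
    keep <- seg_end > seg_start
    seg_start <- seg_start[keep]
    seg_end <- seg_end[keep]
    si <- 1L
    cursor <- seg_start[1]
    for (i in idx) {
      need <- flank1[i] + trim_len[i] + flank2[i]
      gap <- runifi(1, 3000, 12000)
      repeat {
        if (cursor + gap + need <= seg_end[si]) {
          t_start[i] <- cursor + gap + flank1[i]
          chrom_of[i] <- chrom
          cursor <- cursor + gap + need
          break
        }
        si <- si + 1L
        if (si > length(seg_start)) {
          abort(sprintf("gapped peaks exceed capacity of %s", chrom))
        }
        cursor <- seg_start[si]
      }
    }
  }
  blocks <- lapply(seq_len(n), function(i) {
    make_blocks(flank1[i] + trim_len[i] + flank2[i], flank1[i],
                trim_len[i], nblocks[i])
  })
  has_gene <- !over_se & stats::runif(n) < cfg$domain_gene_prob
  gapped <- tibble(
    chrom = chrom_of,
    start = t_start - flank1,
    end = t_start + trim_len + flank2,
    name = sprintf("dom_%05d", seq_len(n)),
    score = runifi(n, 100, 900),
    strand = ".",
    block_count = vapply(blocks, function(b) length(b$sizes), integer(1)),
    block_sizes = lapply(blocks, `[[`, "sizes"),
    block_starts = lapply(blocks, `[[`, "starts"),
    signal_value = round(stats::rlnorm(n, log(8), 0.5), 3),
    p_value = -1, q_value = -1,
    trimmed_start = t_start,
    trimmed_end = t_start + trim_len,
    planted_broad = is_broad,
    over_se = over_se,
    has_gene = has_gene
  ) |>
    arrange(.data$chrom, .data$start)
  gapped
}

# ---- genes, annotation, gene sets ----------------------------------------

gen_genes <- function(cfg, se, gapped, null_labels) {
  set.seed(stream_seed(cfg$seed, 3))
  origin <- character(0)
  chrom <- character(0)
  tss <- numeric(0)
  bd_only <- logical(0)
  site_id <- character(0)
  if (nrow(se) > 0) {
    origin <- c(origin, rep("se", nrow(se)))
    chrom <- c(chrom, se$chrom)
    tss <- c(tss, runifi(nrow(se), se$start, se$end - 1))
    bd_only <- c(bd_only, rep(FALSE, nrow(se)))
    site_id <- c(site_id, se$se_id)
  }
  gd <- gapped[gapped$has_gene, ]
  origin <- c(origin, rep("domain", nrow(gd)))
  chrom <- c(chrom, gd$chrom)
  tss <- c(tss, runifi(nrow(gd), gd$trimmed_start, gd$trimmed_end - 1))
  bd_only <- c(bd_only, gd$planted_broad & !gd$over_se)
  site_id <- c(site_id, gd$name)
  nr <- cfg$n_random_genes
  rc <- sample(names(cfg$chrom_sizes), nr, replace = TRUE)
  origin <- c(origin, rep("random", nr))
  chrom <- c(chrom, rc)
  tss <- c(tss, runifi(nr, 100000, unname(cfg$chrom_sizes[rc]) - 100000))
  bd_only <- c(bd_only, rep(FALSE, nr))
  site_id <- c(site_id, rep(NA_character_, nr))

  n <- length(tss)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  glen <- runifi(n, 2000, 50000)
  gene_id <- sprintf("GENE%04d", seq_len(n))
  p_tsg <- rep(cfg$p_tsg, n)
  if (!null_labels && cfg$planted_enrichment) {
    p_tsg[bd_only] <- pmin(1, cfg$p_tsg * cfg$planted_tsg_fold)
  }
  tsg <- stats::runif(n) < p_tsg
  og <- stats::runif(n) < cfg$p_og
  ccg <- stats::runif(n) < cfg$p_ccg
  hk <- stats::runif(n) < cfg$p_hk
  genes <- tibble(
    gene_id = gene_id, symbol = gene_id, chrom = chrom, tss = tss,
    strand = strand, length = glen, origin = origin, site_id = site_id,
    bd_only_site = bd_only, tsg = tsg, og = og, ccg = ccg, hk = hk,
    biotype = "protein_coding"
  )
  # structural-RNA genes exercising the biotype exclusion
  ns <- cfg$n_structural_genes
  if (ns > 0) {
    sc <- sample(names(cfg$chrom_sizes), ns, replace = TRUE)
    genes <- bind_rows(genes, tibble(
      gene_id = sprintf("SRNA%03d", seq_len(ns)),
      symbol = sprintf("SRNA%03d", seq_len(ns)),
      chrom = sc,
      tss = runifi(ns, 100000, unname(cfg$chrom_sizes[sc]) - 100000),
      strand = sample(c("+", "-"), ns, replace = TRUE),
      length = runifi(ns, 100, 300),
      origin = "structural", site_id = NA_character_,
      bd_only_site = FALSE, tsg = FALSE, og = FALSE, ccg = FALSE,
      hk = FALSE,
      biotype = sample(c("snRNA", "miRNA", "rRNA", "tRNA"), ns,
                       replace = TRUE)
    ))
  }
  # transcripts: all genes get one; 20% of coding genes a second,
  # slightly shifted TSS
  tx <- genes |>
    mutate(transcript_id = paste0(.data$gene_id, ".1"))
  second <- genes |>
    filter(.data$origin != "structural") |>
    filter(stats::runif(dplyr::n()) < 0.2) |>
    mutate(
      tss = .data$tss + ifelse(.data$strand == "+", 1, -1) *
        runifi(dplyr::n(), 50, 300),
      transcript_id = paste0(.data$gene_id, ".2")
    )
  transcripts <- bind_rows(tx, second) |>
    mutate(
      start = if_else(.data$strand == "+", .data$tss,
                      .data$tss - .data$length + 1),
      end = if_else(.data$strand == "+", .data$tss + .data$length,
                    .data$tss + 1),
      start = pmax(0, .data$start)
    ) |>
    arrange(.data$chrom, .data$start)
  leuk_terms <- c("acute myeloid leukaemia", "chronic myeloid leukaemia",
                  "T-cell ALL")
  other_terms <- c("breast carcinoma", "colorectal cancer", "melanoma",
                   "glioma", "lung adenocarcinoma")
  ccg_genes <- genes$gene_id[genes$ccg]
  n_ccg <- length(ccg_genes)
  leuk <- stats::runif(n_ccg) < cfg$leukemia_fraction
  census <- tibble(
    symbol = ccg_genes,
    tumour_types = ifelse(leuk,
                          sample(leuk_terms, n_ccg, replace = TRUE),
                          sample(other_terms, n_ccg, replace = TRUE))
  )
  tuson <- tibble(
    symbol = genes$gene_id,
    p_tsg = ifelse(genes$tsg, stats::runif(nrow(genes), 1e-4, 0.009),
                   stats::runif(nrow(genes), 0.02, 0.95)),
    p_og = ifelse(genes$og, stats::runif(nrow(genes), 1e-4, 0.009),
                  stats::runif(nrow(genes), 0.02, 0.95))
  )
  housekeeping <- tibble(symbol = genes$gene_id[genes$hk])
  list(genes = genes, transcripts = transcripts, tuson = tuson,
       census = census, housekeeping = housekeeping)
}

# ---- loops ----------------------------------------------------------------

gen_loops <- function(cfg, se, gapped, genes) {
  set.seed(stream_seed(cfg$seed, 4))
  coding <- genes[genes$origin != "structural", ]
  aw <- function(n) runifi(n, cfg$anchor_width[1], cfg$anchor_width[2])
  base <- list()
  targets <- list()
  for (i in seq_len(nrow(se))) {
    center <- floor((se$start[i] + se$end[i]) / 2)
    cand <- coding |>
      filter(.data$chrom == se$chrom[i],
             abs(.data$tss - center) >= cfg$loop_span[1],
             abs(.data$tss - center) <= cfg$loop_span[2])
    if (nrow(cand) == 0) {
      cand <- coding |>
        filter(.data$chrom == se$chrom[i],
               abs(.data$tss - center) >= 10000)
    }
    pick <- cand[sample.int(nrow(cand), min(cfg$loops_per_se, nrow(cand))), ]
    for (j in seq_len(nrow(pick))) {
      wa <- aw(1); wb <- aw(1)
      ca <- center + runifi(1, -1000, 1000)
      cb <- pick$tss[j] + runifi(1, -300, 300)
      base[[length(base) + 1]] <- tibble(
        chrom1 = se$chrom[i], start1 = ca - floor(wa / 2),
        end1 = ca + ceiling(wa / 2),
        chrom2 = se$chrom[i], start2 = cb - floor(wb / 2),
        end2 = cb + ceiling(wb / 2)
      )
      targets[[length(targets) + 1]] <- tibble(
        se_id = se$se_id[i], gene_id = pick$gene_id[j]
      )
    }
  }
  broads <- gapped[gapped$planted_broad, ]
  nb <- min(cfg$n_bd_loops, nrow(broads))
  bpick <- broads[sample.int(nrow(broads), nb), ]
  for (i in seq_len(nb)) {
    center <- floor((bpick$trimmed_start[i] + bpick$trimmed_end[i]) / 2)
    cand <- coding |>
      filter(.data$chrom == bpick$chrom[i],
             abs(.data$tss - center) >= cfg$loop_span[1],
             abs(.data$tss - center) <= cfg$loop_span[2])
    if (nrow(cand) == 0) next
    g <- cand[sample.int(nrow(cand), 1), ]
    wa <- aw(1); wb <- aw(1)
    cb <- g$tss + runifi(1, -300, 300)
    base[[length(base) + 1]] <- tibble(
      chrom1 = bpick$chrom[i], start1 = center - floor(wa / 2),
      end1 = center + ceiling(wa / 2),
      chrom2 = bpick$chrom[i], start2 = cb - floor(wb / 2),
      end2 = cb + ceiling(wb / 2)
    )
  }
  base <- bind_rows(base)
  n_shared <- max(nrow(base), round(cfg$shared_fraction * cfg$n_loops))
  n_rand_shared <- n_shared - nrow(base)
  rand_loops <- function(n) {
    if (n <= 0) {
      return(tibble(chrom1 = character(), start1 = numeric(),
                    end1 = numeric(), chrom2 = character(),
                    start2 = numeric(), end2 = numeric()))
    }
    chrom <- sample(names(cfg$chrom_sizes), n, replace = TRUE)
    size <- unname(cfg$chrom_sizes[chrom])
    span <- runifi(n, cfg$loop_span[1], cfg$loop_span[2])
    ca <- runifi(n, 100000, size - 100000 - span)
    wa <- aw(n); wb <- aw(n)
    tibble(
      chrom1 = chrom, start1 = ca - floor(wa / 2), end1 = ca + ceiling(wa / 2),
      chrom2 = chrom, start2 = ca + span - floor(wb / 2),
      end2 = ca + span + ceiling(wb / 2)
    )
  }
  shared <- bind_rows(base, rand_loops(n_rand_shared))
  n_extra <- max(0, cfg$n_loops - n_shared)
  extra1 <- rand_loops(n_extra)
  extra2 <- rand_loops(n_extra)
  jitter <- function(df) {
    n <- nrow(df)
    d1 <- runifi(n, -cfg$anchor_jitter, cfg$anchor_jitter)
    d2 <- runifi(n, -cfg$anchor_jitter, cfg$anchor_jitter)
    df |>
      mutate(start1 = pmax(0, .data$start1 + d1), end1 = .data$end1 + d1,
             start2 = pmax(0, .data$start2 + d2), end2 = .data$end2 + d2)
  }
  finish <- function(df, tag) {
    df |>
      mutate(
        name = sprintf("%s_loop_%04d", tag, row_number()),
        score = sample(2:40, dplyr::n(), replace = TRUE),
        strand1 = ".", strand2 = "."
      )
  }
  rep1 <- finish(bind_rows(jitter(shared), extra1), "r1")
  rep2 <- finish(bind_rows(jitter(shared), extra2), "r2")
  list(rep1 = rep1, rep2 = rep2, targets = bind_rows(targets),
       n_shared = n_shared, shared = shared)
}

# ---- CAGE expression ------------------------------------------------------

gen_cage <- function(cfg, se, genes, peaks) {
  set.seed(stream_seed(cfg$seed, 5))
  facets <- c(cfg$analysis_facet,
              sprintf("facet%02d", seq_len(cfg$n_facets - 1) + 1))
  coding <- genes[genes$origin != "structural", ]
  prom <- tibble(
    chrom = coding$chrom,
    start = pmax(0, coding$tss - 150),
    end = coding$tss + 151,
    bidirectional = FALSE,
    profile = if_else(coding$hk, "housekeeping", "specific"),
    main_facet = if_else(coding$origin == "se", cfg$analysis_facet,
                         sample(facets, nrow(coding), replace = TRUE)),
    gene_id = coding$gene_id
  )
  se_erna <- tibble(
    chrom = se$chrom,
    start = floor((se$start + se$end) / 2) - 200,
    end = floor((se$start + se$end) / 2) + 200,
    bidirectional = TRUE,
    profile = "specific",
    main_facet = cfg$analysis_facet,
    gene_id = NA_character_
  )
  bg <- peaks |> filter(!.data$is_se_constituent)
  bg <- bg[stats::runif(nrow(bg)) < cfg$erna_background_fraction, ]
  bg_erna <- tibble(
    chrom = bg$chrom,
    start = floor((bg$start + bg$end) / 2) - 150,
    end = floor((bg$start + bg$end) / 2) + 150,
    bidirectional = TRUE,
    profile = "specific",
    main_facet = sample(facets, nrow(bg), replace = TRUE),
    gene_id = NA_character_
  )
  clusters <- bind_rows(prom, se_erna, bg_erna) |>
    arrange(.data$chrom, .data$start) |>
    mutate(cluster_id = sprintf("cage_%05d", row_number()))
  n <- nrow(clusters)
  mu <- matrix(0, n, length(facets), dimnames = list(NULL, facets))
  spec <- clusters$profile == "specific"
  mu[spec, ] <- stats::runif(sum(spec) * length(facets), 0, 0.4)
  main_idx <- match(clusters$main_facet, facets)
  mu[cbind(which(spec), main_idx[spec])] <- stats::runif(sum(spec), 12, 35)
  mu[!spec, ] <- stats::runif(sum(!spec) * length(facets), 4, 10)
  samples <- paste0(rep(facets, each = cfg$samples_per_facet), ".s",
                    rep(seq_len(cfg$samples_per_facet), length(facets)))
  vals <- mu[, rep(seq_along(facets), each = cfg$samples_per_facet)] *
    exp(stats::rnorm(n * length(samples), 0, 0.15))
  vals <- round(vals, 3)
  colnames(vals) <- samples
  mat <- bind_cols(
    clusters |> select("cluster_id", "chrom", "start", "end",
                       "bidirectional"),
    as_tibble(vals)
  )
  facet_map <- tibble(sample = samples,
                      facet = rep(facets, each = cfg$samples_per_facet))
  list(cage = mat, facet_map = facet_map,
       profiles = clusters |> select("cluster_id", "profile", "main_facet",
                                     "gene_id"))
}

# ---- assembly -------------------------------------------------------------

#' Generate a synthetic fixture with planted ground truth
#'
#' Deterministic given `config$seed`: each file type draws from its own
#' seed-derived stream, so regenerating with the same seed is
#' byte-identical and adding a component never perturbs the others. With
#' `dir` set, the bundle is also written out as the standard plain-text
#' formats (narrowPeak, bedGraph x2, gappedPeak, BEDPE x2, GTF, CAGE and
#' gene-set TSVs, JSON truth manifest).
#'
#' @param config A [fixture_config()].
#' @param dir Optional output directory (created if needed).
#' @return A bundle: named list of input tibbles (`peaks`, `treatment`,
#'   `control`, `gapped`, `loops_rep1`, `loops_rep2`, `transcripts`,
#'   `tss`, `cage`, `facet_map`, `tuson`, `census`, `housekeeping`), the
#'   `manifest` of planted truth, the `config`, and (when written)
#'   `paths`.
#' @export
generate_fixture <- function(config = fixture_config(), dir = NULL) {
  build_fixture(config, dir = dir, null_labels = FALSE)
}

#' Synthetic fixture with randomised gene-set labels
#'
#' Identical structure to [generate_fixture()] (same seed gives the same
#' genome, elements, loops and expression), but gene-set membership is
#' drawn at the base rates for every gene regardless of where it sits,
#' destroying any association between region classes and gene sets. Used
#' for type-I-error control of the enrichment panels.
#'
#' @inheritParams generate_fixture
#' @return A bundle as in [generate_fixture()].
#' @export
null_fixture <- function(config = fixture_config(), dir = NULL) {
  build_fixture(config, dir = dir, null_labels = TRUE)
}

build_fixture <- function(config, dir = NULL, null_labels = FALSE) {
  stopifnot(inherits(config, "fixture_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  pk <- gen_peaks(config)
  gp <- gen_gapped(config, pk$se)
  gn <- gen_genes(config, pk$se, gp, null_labels)
  lp <- gen_loops(config, pk$se, gp, gn$genes)
  cg <- gen_cage(config, pk$se, gn$genes, pk$peaks)
  treatment <- pk$peaks |>
    mutate(value = round(.data$height, 4)) |>
    select("chrom", "start", "end", "value")
  control <- pk$peaks |>
    mutate(value = round(.data$control_height, 4)) |>
    select("chrom", "start", "end", "value")
  tss <- gn$transcripts |>
    select("chrom", "tss", "strand", "gene_id", "transcript_id",
           "biotype") |>
    mutate(gene_name = .data$gene_id)
  manifest <- list(
    seed = config$seed,
    null_labels = null_labels,
    se = pk$se,
    broad = gp |>
      filter(.data$planted_broad) |>
      mutate(start = .data$trimmed_start, end = .data$trimmed_end) |>
      select("name", "chrom", "start", "end", "over_se"),
    targets = lp$targets,
    genes = gn$genes |>
      select("gene_id", "origin", "site_id", "bd_only_site", "tsg", "og",
             "ccg", "hk"),
    cluster_profiles = cg$profiles,
    n_shared_loops = lp$n_shared,
    shared_loops = lp$shared
  )
  bundle <- list(
    peaks = pk$peaks, treatment = treatment, control = control,
    gapped = gp, loops_rep1 = lp$rep1, loops_rep2 = lp$rep2,
    transcripts = gn$transcripts, tss = tss, cage = cg$cage,
    facet_map = cg$facet_map, tuson = gn$tuson, census = gn$census,
    housekeeping = gn$housekeeping, manifest = manifest, config = config
  )
  if (!is.null(dir)) {
    bundle$paths <- write_fixture(bundle, dir)
  }
  bundle
}

gtf_lines <- function(transcripts) {
  attr_str <- sprintf(
    paste0('gene_id "%s"; transcript_id "%s"; gene_name "%s"; ',
           'transcript_type "%s";'),
    transcripts$gene_id, transcripts$transcript_id, transcripts$symbol,
    transcripts$biotype
  )
  sprintf("%s\tseloop_sim\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
          transcripts$chrom, as.integer(transcripts$start + 1),
          as.integer(transcripts$end), transcripts$strand, attr_str)
}

#' Write a fixture bundle to standard plain-text files
#'
#' @param bundle A bundle from [generate_fixture()].
#' @param dir Output directory.
#' @return Named list of file paths, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  paths <- list(
    peaks = p("h3k27ac_peaks.narrowPeak"),
    treatment = p("h3k27ac_treatment.bedgraph"),
    control = p("h3k27ac_control.bedgraph"),
    gapped = p("h3k4me3_domains.gappedPeak"),
    loops_rep1 = p("chia_pet_rep1.bedpe"),
    loops_rep2 = p("chia_pet_rep2.bedpe"),
    gtf = p("annotation.gtf"),
    cage = p("cage_expression.tsv"),
    facet_map = p("facet_map.tsv"),
    tuson = p("tuson.tsv"),
    census = p("census.tsv"),
    housekeeping = p("housekeeping.tsv"),
    manifest = p("manifest.json")
  )
  write_narrowpeak(bundle$peaks, paths$peaks)
  write_bedgraph(bundle$treatment, paths$treatment)
  write_bedgraph(bundle$control, paths$control)
  write_gappedpeak(bundle$gapped, paths$gapped)
  write_bedpe(bundle$loops_rep1, paths$loops_rep1)
  write_bedpe(bundle$loops_rep2, paths$loops_rep2)
  readr::write_lines(gtf_lines(bundle$transcripts), paths$gtf)
  readr::write_tsv(bundle$cage, paths$cage)
  readr::write_tsv(bundle$facet_map, paths$facet_map)
  readr::write_tsv(bundle$tuson, paths$tuson)
  readr::write_tsv(bundle$census, paths$census)
  readr::write_tsv(bundle$housekeeping, paths$housekeeping)
  manifest <- bundle$manifest
  manifest$config <- unclass(bundle$config)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

# ---- recovery scoring -----------------------------------------------------

reciprocal_match <- function(called, planted, min_frac = 0.5) {
  if (nrow(called) == 0 || nrow(planted) == 0) {
    return(tibble(call_row = integer(), planted_row = integer()))
  }
  ov <- overlap_query(called, planted)
  w <- pmin(ov$end_a, ov$end_b) - pmax(ov$start_a, ov$start_b)
  ok <- w >= min_frac * (ov$end_a - ov$start_a) &
    w >= min_frac * (ov$end_b - ov$start_b)
  tibble(call_row = ov$row_a[ok], planted_row = ov$row_b[ok])
}

#' Score pipeline calls against the planted truth manifest
#'
#' Intervals match by >= 50% reciprocal overlap; element-to-gene target
#' pairs match by mapping called elements onto planted super-enhancers
#' (same reciprocal-overlap rule) and then comparing gene ids exactly.
#' The false-discovery proportion of an empty call set is reported
#' missing (`NA`), not 0.
#'
#' @param calls Named list with any of: `se` (interval tibble of called
#'   super-enhancers), `broad` (called broad domains), `targets` (tibble
#'   `element_id`, `gene_id`; requires `se` with an `element_id` or
#'   `region_id` column to anchor elements).
#' @param manifest Truth manifest from a fixture bundle.
#' @return Tibble: `stage`, `n_planted`, `n_called`, `n_recovered`,
#'   `recall`, `fdp`.
#' @export
evaluate_recovery <- function(calls, manifest) {
  out <- list()
  score_intervals <- function(called, planted, stage) {
    m <- reciprocal_match(called, planted)
    n_rec <- length(unique(m$planted_row))
    tibble(
      stage = stage,
      n_planted = nrow(planted),
      n_called = nrow(called),
      n_recovered = n_rec,
      recall = if (nrow(planted) > 0) n_rec / nrow(planted) else NA_real_,
      fdp = if (nrow(called) > 0) {
        (nrow(called) - length(unique(m$call_row))) / nrow(called)
      } else {
        NA_real_
      }
    )
  }
  if (!is.null(calls$se)) {
    out$se <- score_intervals(check_intervals(calls$se, "calls$se"),
                              as_tibble(manifest$se), "super_enhancers")
  }
  if (!is.null(calls$broad)) {
    out$broad <- score_intervals(check_intervals(calls$broad, "calls$broad"),
                                 as_tibble(manifest$broad), "broad_domains")
  }
  if (!is.null(calls$targets)) {
    if (is.null(calls$se)) {
      abort("`calls$targets` requires `calls$se` to anchor element ids")
    }
    se_calls <- as_tibble(calls$se)
    if (!"element_id" %in% names(se_calls)) {
      id_col <- intersect(c("region_id", "name"), names(se_calls))
      if (length(id_col) == 0) {
        abort("`calls$se` needs an element_id/region_id/name column")
      }
      se_calls$element_id <- se_calls[[id_col[1]]]
    }
    m <- reciprocal_match(se_calls, as_tibble(manifest$se))
    map <- tibble(
      element_id = se_calls$element_id[m$call_row],
      se_id = as_tibble(manifest$se)$se_id[m$planted_row]
    )
    planted_pairs <- as_tibble(manifest$targets) |>
      distinct(.data$se_id, .data$gene_id)
    all_called <- as_tibble(calls$targets) |>
      distinct(.data$element_id, .data$gene_id)
    good_called <- all_called |>
      inner_join(map, by = "element_id",
                 relationship = "many-to-many") |>
      semi_join(planted_pairs, by = c("se_id", "gene_id")) |>
      distinct(.data$element_id, .data$gene_id)
    rec <- good_called |>
      inner_join(map, by = "element_id", relationship = "many-to-many") |>
      semi_join(planted_pairs, by = c("se_id", "gene_id")) |>
      distinct(.data$se_id, .data$gene_id)
    out$targets <- tibble(
      stage = "loop_targets",
      n_planted = nrow(planted_pairs),
      n_called = nrow(all_called),
      n_recovered = nrow(rec),
      recall = if (nrow(planted_pairs) > 0) {
        nrow(rec) / nrow(planted_pairs)
      } else {
        NA_real_
      },
      fdp = if (nrow(all_called) > 0) {
        1 - nrow(good_called) / nrow(all_called)
      } else {
        NA_real_
      }
    )
  }
  bind_rows(out)
}
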