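# small config keeps the unit tests quick; acceptance uses the default
small_cfg <- function(seed = 1, ...) {
  fixture_config(seed = seed, n_background_peaks = 60, n_planted_se = 6,
                 n_gapped_peaks = 120, n_random_genes = 20, n_loops = 60,
                 n_bd_loops = 6, n_se_bd_overlap = 3, ...)
}

test_that("the same seed regenerates a byte-identical bundle", {
  b1 <- generate_fixture(small_cfg(seed = 7))
  b2 <- generate_fixture(small_cfg(seed = 7))
  expect_identical(b1, b2)
  b3 <- generate_fixture(small_cfg(seed = 8))
  expect_false(identical(b1$peaks, b3$peaks))
  n1 <- null_fixture(small_cfg(seed = 7))
  expect_identical(n1, null_fixture(small_cfg(seed = 7)))
  # null keeps the genome identical, only labels change
  expect_identical(n1$peaks, b1$peaks)
  expect_identical(n1$gapped, b1$gapped)
})

test_that("the manifest lists exactly the planted elements", {
  cfg <- small_cfg(seed = 3)
  b <- generate_fixture(cfg)
  expect_equal(nrow(b$manifest$se), cfg$n_planted_se)
  expect_equal(nrow(b$manifest$broad),
               ceiling(cfg$broad_fraction * cfg$n_gapped_peaks))
  expect_equal(nrow(b$manifest$targets),
               cfg$n_planted_se * cfg$loops_per_se)
  # every planted SE span is exactly the span of its constituent peaks
  for (i in seq_len(nrow(b$manifest$se))) {
    cons <- b$peaks[!is.na(b$peaks$se_id) &
                      b$peaks$se_id == b$manifest$se$se_id[i], ]
    expect_equal(min(cons$start), b$manifest$se$start[i])
    expect_equal(max(cons$end), b$manifest$se$end[i])
  }
  # planted broad intervals are the trimmed spans of generated records
  expect_true(all(b$manifest$broad$start %in% b$gapped$trimmed_start))
})

test_that("emitted files parse back through the readers without warnings", {
  dir <- withr::local_tempdir()
  b <- generate_fixture(small_cfg(seed = 5), dir = dir)
  expect_no_warning({
    peaks <- read_intervals(b$paths$peaks, "narrowPeak")
    treatment <- read_intervals(b$paths$treatment, "bedgraph")
    control <- read_intervals(b$paths$control, "bedgraph")
    gapped <- read_intervals(b$paths$gapped, "gappedPeak")
    r1 <- read_intervals(b$paths$loops_rep1, "bedpe")
    r2 <- read_intervals(b$paths$loops_rep2, "bedpe")
  })
  expect_equal(nrow(peaks), nrow(b$peaks))
  expect_equal(peaks$start, b$peaks$start)
  expect_equal(treatment$value, b$treatment$value)
  expect_equal(nrow(r1), nrow(b$loops_rep1))
  tss <- load_tss(b$paths$gtf)
  expect_true(all(!tss$biotype %in% default_excluded_biotypes()))
  in_mem <- b$tss[!b$tss$biotype %in% default_excluded_biotypes(), ]
  expect_setequal(tss$tss, in_mem$tss)
})

test_that("replicate sharing is recovered at the configured fraction", {
  cfg <- small_cfg(seed = 11, n_loops = 100, shared_fraction = 0.7)
  b <- generate_fixture(cfg)
  rep1 <- b$loops_rep1
  rep2 <- b$loops_rep2
  got <- intersect_replicates(rep1, rep2)
  oracle_keep <- o_pair_to_pair(canonicalize_loops(rep1),
                                canonicalize_loops(rep2))
  expect_equal(nrow(got), sum(oracle_keep))
  # at least every shared loop survives the <=200 bp anchor jitter
  expect_gte(nrow(got), b$manifest$n_shared)
})

test_that("recovery scoring handles the degenerate cases", {
  b <- generate_fixture(small_cfg(seed = 13))
  perfect <- evaluate_recovery(list(se = b$manifest$se,
                                    broad = b$manifest$broad), b$manifest)
  expect_equal(perfect$recall, c(1, 1))
  expect_equal(perfect$fdp, c(0, 0))
  empty <- evaluate_recovery(
    list(se = b$manifest$se[0, ]), b$manifest
  )
  expect_equal(empty$recall, 0)
  expect_true(is.na(empty$fdp))
})

test_that("planted labels enrich BD-only genes; the null destroys it", {
  cfg <- fixture_config(seed = 17)
  b <- generate_fixture(cfg)
  g <- b$manifest$genes
  rate_bd <- mean(g$tsg[g$bd_only_site])
  rate_other <- mean(g$tsg[!g$bd_only_site])
  expect_gt(rate_bd, 2 * rate_other)
  n <- null_fixture(cfg)$manifest$genes
  expect_lt(mean(n$tsg[n$bd_only_site]), 2 * mean(n$tsg[!n$bd_only_site]))
})
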