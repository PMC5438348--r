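gtf_line <- function(chrom, start1, end1, strand, gene, tx, type) {
  sprintf(paste0("%s\tsrc\ttranscript\t%d\t%d\t.\t%s\t.\t",
                 'gene_id "%s"; transcript_id "%s"; gene_name "%s"; ',
                 'transcript_type "%s";'),
          chrom, start1, end1, strand, gene, tx, gene, type)
}

test_that("TSS derivation is strand-aware and biotype-filtered", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    gtf_line("c1", 5001, 7000, "+", "gA", "gA.1", "protein_coding"),
    gtf_line("c1", 5001, 7000, "-", "gB", "gB.1", "protein_coding"),
    gtf_line("c1", 9001, 9100, "+", "gC", "gC.1", "miRNA"),
    gtf_line("c1", 100, 300, ".", "gD", "gD.1", "protein_coding")
  ), path)
  expect_warning(tss <- load_tss(path), "unknown strand")
  expect_equal(nrow(tss), 2) # miRNA excluded, strandless skipped
  # + strand transcript [5000,7000) in 0-based: TSS at 5000
  expect_equal(tss$tss[tss$gene_id == "gA"], 5000)
  # - strand: TSS at 6999
  expect_equal(tss$tss[tss$gene_id == "gB"], 6999)
  all_in <- suppressWarnings(load_tss(path, excluded_biotypes = character(0)))
  expect_true("gC" %in% all_in$gene_id)
})

test_that("proximity uses an inclusive 4 kb edge distance", {
  el <- tibble::tibble(chrom = "c1", start = 1000, end = 2000)
  tss_at <- function(pos) tibble::tibble(chrom = "c1", tss = pos,
                                         gene_id = "g")
  inside <- classify_proximity(el, tss_at(1500))
  expect_equal(inside$tss_distance, 0)
  expect_equal(inside$proximity, "proximal")
  at_limit <- classify_proximity(el, tss_at(6000))
  expect_equal(at_limit$tss_distance, 4000)
  expect_equal(at_limit$proximity, "proximal")
  beyond <- classify_proximity(el, tss_at(6001))
  expect_equal(beyond$tss_distance, 4001)
  expect_equal(beyond$proximity, "distal")
  expect_warning(none <- classify_proximity(el, tss_at(numeric(0))),
                 "empty TSS")
  expect_equal(none$proximity, "distal")
})

test_that("proximity labels match the all-pairs oracle and are monotone", {
  withr::local_seed(37)
  el <- rand_intervals(60, max_pos = 50000)
  tss <- tibble::tibble(chrom = sample(c("c1", "c2"), 30, replace = TRUE),
                        tss = sample.int(60000, 30),
                        gene_id = sprintf("g%d", 1:30))
  got <- classify_proximity(el, tss, threshold = 2000)
  expect_equal(got$proximity, o_classify(el, tss, 2000))
  wider <- classify_proximity(el, tss, threshold = 5000)
  expect_true(all(wider$proximity[got$proximity == "proximal"] ==
                    "proximal"))
  shuffled <- classify_proximity(el[sample(60), ], tss, threshold = 2000)
  expect_setequal(paste(shuffled$start, shuffled$proximity),
                  paste(got$start, got$proximity))
})

test_that("gene-set catalog applies thresholds and keyword rules", {
  tuson <- tibble::tibble(symbol = c("t1", "t2", "o1", "Dup", "dup"),
                          p_tsg = c(0.009, 0.011, 0.5, 0.001, 0.001),
                          p_og = c(0.5, 0.5, 0.0001, 0.9, 0.9))
  census <- tibble::tibble(
    symbol = c("c1", "c2", "c3"),
    tumour_types = c("AML, CML", "breast carcinoma", "chronic lymphocytic leukaemia")
  )
  hk <- tibble::tibble(symbol = sprintf("hk%d", 1:7))
  cat <- derive_gene_sets(tuson, census, hk)
  expect_setequal(cat$tumor_suppressors, c("T1", "DUP"))
  expect_equal(cat$oncogenes, "O1")
  expect_setequal(cat$leukemia_associated, c("C1", "C3"))
  expect_equal(length(cat$housekeeping), 7)
  expect_error(derive_gene_sets(tuson[, 1:2], census, hk), "missing column")
})
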