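mk_loops <- function(chrom1, start1, end1, chrom2, start2, end2) {
  tibble::tibble(chrom1 = chrom1, start1 = start1, end1 = end1,
                 chrom2 = chrom2, start2 = start2, end2 = end2)
}

rand_loops <- function(n, max_pos = 50000) {
  a <- rand_intervals(n, max_pos = max_pos, max_len = 800)
  b <- rand_intervals(n, max_pos = max_pos, max_len = 800)
  mk_loops(a$chrom, a$start, a$end, b$chrom, b$start, b$end)
}

test_that("replicate intersection keeps loops matched in either orientation", {
  l <- mk_loops("c1", 100, 200, "c1", 5000, 5200)
  expect_equal(nrow(intersect_replicates(l, l)), 1)
  swapped <- mk_loops("c1", 5000, 5200, "c1", 100, 200)
  expect_equal(nrow(intersect_replicates(l, swapped)), 1)
  off <- mk_loops("c1", 100, 200, "c1", 9000, 9100)
  expect_equal(nrow(intersect_replicates(l, off)), 0)
})

test_that("replicate intersection matches the pairToPair oracle", {
  withr::local_seed(41)
  for (rep in 1:4) {
    r1 <- rand_loops(60)
    r2 <- rand_loops(60)
    got <- intersect_replicates(r1, r2)
    keep <- o_pair_to_pair(canonicalize_loops(r1), canonicalize_loops(r2))
    expect_equal(nrow(got), sum(keep))
    # self-intersection is the identity on loop membership
    self <- intersect_replicates(r1, r1)
    expect_equal(nrow(self), nrow(r1))
  }
})

test_that("element involvement counts distinct loops", {
  el <- tibble::tibble(chrom = "c1", start = 100, end = 300,
                       element_id = "e1")
  one <- mk_loops("c1", 150, 250, "c1", 9000, 9100)
  got <- associate_elements(el, one)
  expect_true(got$involved)
  expect_equal(got$interaction_count, 1L)
  # overlapping both anchors of the same loop still counts once
  both <- mk_loops("c1", 120, 180, "c1", 200, 280)
  expect_equal(associate_elements(el, both)$interaction_count, 1L)
})

test_that("involvement matches the brute-force oracle", {
  withr::local_seed(43)
  el <- rand_intervals(50, max_pos = 40000)
  loops <- rand_loops(40, max_pos = 40000)
  got <- associate_elements(el, loops)
  expect_equal(got$interaction_count, o_associate(el, loops))
})

test_that("loop targets use the 4 kb anchor window and count skipped TSSes", {
  el <- tibble::tibble(chrom = "c1", start = 1000, end = 3000,
                       element_id = "e1")
  tss <- tibble::tibble(
    chrom = "c1",
    tss = c(52000, 20000, 30000, 49999),
    gene_id = c("target", "skip1", "skip2", "near_target")
  )
  loop_near <- mk_loops("c1", 1500, 2500, "c1", 49000, 50000)
  # anchor end 50000, TSS at 52000: gap 2000 -> target
  got <- loop_targets(el, loop_near, tss)
  expect_setequal(got$gene_id, c("target", "near_target"))
  hit <- got[got$gene_id == "target", ]
  # element center 2000; skip1, skip2 and the near_target TSS lie between
  expect_equal(hit$skipped_tss_count, 3L)
  expect_equal(hit$distance, 50000)
  # anchor 5 kb from the nearest TSS yields nothing
  loop_far <- mk_loops("c1", 1500, 2500, "c1", 6000, 8000)
  far_tss <- tibble::tibble(chrom = "c1", tss = 13001, gene_id = "g")
  expect_equal(nrow(loop_targets(el, loop_far, far_tss)), 0)
})

test_that("loop target pairs match the brute-force oracle", {
  withr::local_seed(47)
  for (rep in 1:3) {
    el <- rand_intervals(30, max_pos = 60000)
    el$element_id <- as.character(seq_len(nrow(el)))
    loops <- rand_loops(30, max_pos = 60000)
    tss <- tibble::tibble(chrom = sample(c("c1", "c2"), 25, replace = TRUE),
                          tss = sample.int(70000, 25),
                          gene_id = sprintf("g%d", 1:25))
    got <- loop_targets(el, loops, tss) |>
      dplyr::transmute(element = as.integer(element_id), gene_id) |>
      dplyr::arrange(element, gene_id)
    oracle <- o_loop_target_pairs(el, loops, tss) |>
      dplyr::arrange(element, gene_id)
    expect_equal(got, oracle)
  }
})

test_that("distance profiles report nearest, nearest-active and looped TSSes", {
  el <- tibble::tibble(chrom = "c1", start = 900, end = 1100,
                       element_id = "e1")
  tss <- tibble::tibble(chrom = "c1", tss = c(1000, 8000),
                        gene_id = c("on_center", "active_far"))
  expr <- tibble::tibble(gene_id = c("on_center", "active_far"),
                         value = c(0, 5))
  prof <- distance_profiles(el, mk_loops("c1", 1, 2, "c1", 3, 4), tss, expr)
  expect_equal(prof$distance[prof$kind == "nearest"], 0)
  expect_equal(prof$distance[prof$kind == "nearest_active"], 7000)
  # all genes inactive: nearest-active is missing
  none <- distance_profiles(el, mk_loops("c1", 1, 2, "c1", 3, 4), tss,
                            dplyr::mutate(expr, value = 0))
  expect_true(is.na(none$distance[none$kind == "nearest_active"]))
})

test_that("extension control equalises category means", {
  el <- tibble::tibble(
    chrom = "c1",
    start = c(10000, 20000, 40000, 60000),
    end = c(11000, 21000, 43000, 63000),
    category = c("small", "small", "big", "big")
  )
  ext <- extension_control(el)
  sizes <- ext$end - ext$start
  # small elements gain 2000 bases in total each
  expect_equal(sizes[1:2], c(3000, 3000))
  expect_equal(sizes[3:4], c(3000, 3000))
  same <- extension_control(dplyr::mutate(el, category = "one"))
  expect_equal(same$start, el$start)
  expect_equal(same$end, el$end)
  withr::local_seed(53)
  r <- rand_intervals(40, max_pos = 1e6, max_len = 8000)
  r$category <- sample(c("a", "b", "c", "d"), 40, replace = TRUE)
  re <- extension_control(r)
  avgs <- tapply(re$end - re$start, re$category, mean)
  expect_lt(max(avgs) - min(avgs), 1 + 1e-9)
})

test_that("signal normalisation is a guarded division", {
  expect_equal(normalize_by_signal(10, 5), 2)
  expect_equal(normalize_by_signal(0, 3), 0)
  expect_true(is.na(normalize_by_signal(4, 0)))
  withr::local_seed(59)
  counts <- rpois(20, 5)
  sig <- runif(20, 1, 10)
  expect_equal(normalize_by_signal(counts, 2 * sig),
               normalize_by_signal(counts, sig) / 2)
})
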