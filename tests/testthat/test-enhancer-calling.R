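const_track <- function(chrom, start, end, value) {
  tibble::tibble(chrom = chrom, start = start, end = end, value = value)
}

test_that("stitching groups peaks by the 4 kb window", {
  peaks <- tibble::tibble(chrom = "c1",
                          start = c(0, 1500, 4000),
                          end = c(500, 2000, 4500))
  # pairwise gaps 1000 and 2000: one region with 3 constituents
  st <- stitch_peaks(peaks, window = 4000)
  expect_equal(nrow(st), 1)
  expect_equal(st$n_constituents, 3L)

  two <- tibble::tibble(chrom = "c1", start = c(0, 13000),
                        end = c(1000, 14000)) # gap 12000
  expect_equal(nrow(stitch_peaks(two, window = 4000)), 2)
  expect_equal(nrow(stitch_peaks(two, window = 12500)), 1)
})

test_that("stitched partitions match the merge oracle on random peaks", {
  withr::local_seed(19)
  peaks <- rand_intervals(100, max_pos = 200000, max_len = 1500)
  st <- stitch_peaks(peaks, window = 4000)
  oracle <- o_merge_fixpoint(peaks, 4000)
  expect_equal(st[c("chrom", "start", "end")], tibble::as_tibble(oracle),
               ignore_attr = TRUE)
  expect_equal(sum(st$n_constituents), nrow(peaks))
  # window 0 returns overlap/book-end merged peaks only
  st0 <- stitch_peaks(peaks, window = 0)
  expect_equal(st0[c("chrom", "start", "end")],
               tibble::as_tibble(o_merge_fixpoint(peaks, 0)),
               ignore_attr = TRUE)
})

test_that("region signal is the track integral, input-corrected", {
  region <- tibble::tibble(chrom = "c1", start = 1000, end = 1100)
  res <- compute_region_signal(region, const_track("c1", 900, 1200, 2),
                               const_track("c1", 0, 1, 0))
  expect_equal(res$treatment_signal, 200)
  expect_equal(res$control_signal, 0)
  expect_equal(res$net_signal, 200)
  tr <- const_track("c1", 950, 1250, 1.7)
  same <- compute_region_signal(region, tr, tr)
  expect_equal(same$net_signal, 0)
})

test_that("tangent cutoff reproduces the worked cases", {
  lin <- find_cutoff(1:10)
  expect_equal(lin$tangent_index, 1L)
  expect_equal(lin$cutoff_value, 1)
  expect_equal(lin$n_super, 9L)

  outlier <- find_cutoff(c(rep(1, 9), 100))
  expect_equal(outlier$cutoff_value, 1)
  expect_equal(outlier$n_super, 1L)

  flat <- find_cutoff(rep(3, 8))
  expect_equal(flat$cutoff_value, 3)
  expect_equal(flat$n_super, 0L)

  expect_error(find_cutoff(5), "at least 2")
})

test_that("tangent cutoff equals exhaustive brute-force line search", {
  withr::local_seed(23)
  for (rep in 1:25) {
    n <- sample(5:200, 1)
    y <- switch(sample(3, 1),
                rlnorm(n, 3, 1),
                c(rlnorm(n, 2, 0.3), rlnorm(3, 6, 0.5)),
                rnorm(n, 10, 4))
    got <- find_cutoff(y)
    oracle <- o_tangent(y)
    expect_equal(got$cutoff_value, oracle$cutoff)
    expect_equal(got$tangent_index, oracle$index)
  }
})

test_that("super-enhancer calls are deterministic and rank-consistent", {
  withr::local_seed(29)
  peaks <- rand_intervals(60, max_pos = 500000, max_len = 1200)
  peaks$name <- sprintf("p%02d", seq_len(60))
  tr <- peaks |> dplyr::mutate(value = rlnorm(60, 3, 0.5)) |>
    dplyr::arrange(chrom, start)
  ctl <- tr |> dplyr::mutate(value = 0)
  calls <- call_super_enhancers(peaks, tr, ctl)
  shuffled <- call_super_enhancers(peaks[sample(60), ], tr, ctl)
  expect_equal(calls, shuffled)
  expect_equal(sort(calls$rank), seq_len(nrow(calls)))
  expect_equal(calls$net_signal[order(calls$rank)],
               sort(calls$net_signal, decreasing = TRUE))
  # all-zero control: identical ordering to treatment-only ranking
  expect_equal(calls$treatment_signal, calls$net_signal)
  # super count is non-increasing in the cutoff value
  cut <- attr(calls, "cutoff")
  for (cv in quantile(calls$net_signal, c(0.1, 0.5, 0.9))) {
    expect_gte(sum(calls$net_signal > min(cv, cut$cutoff_value)),
               sum(calls$net_signal > max(cv, cut$cutoff_value)))
  }
})

test_that("tidy/glance/autoplot expose the cutoff fit", {
  cut <- find_cutoff(c(1:9, 100))
  td <- tidy(cut)
  expect_equal(nrow(td), 10)
  expect_equal(sum(td$is_super), 1)
  gl <- glance(cut)
  expect_equal(gl$n, 10)
  expect_equal(gl$n_super, 1)
  expect_s3_class(autoplot(cut), "ggplot")
})
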