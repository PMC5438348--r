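mk_mat <- function(values, samples) {
  n <- nrow(values)
  dplyr::bind_cols(
    tibble::tibble(cluster_id = sprintf("cl%d", seq_len(n)),
                   chrom = "c1", start = seq_len(n) * 1000,
                   end = seq_len(n) * 1000 + 200,
                   bidirectional = FALSE),
    stats::setNames(tibble::as_tibble(values), samples)
  )
}

test_that("facet means average the assigned samples", {
  mat <- mk_mat(data.frame(s1 = c(2, 1), s2 = c(4, 3), s3 = c(10, 7)),
                c("s1", "s2", "s3"))
  map <- tibble::tibble(sample = c("s1", "s2", "s3"),
                        facet = c("fA", "fA", "fB"))
  fm <- facet_means(mat, map)
  expect_equal(fm$fA, c(3, 2))
  expect_equal(fm$fB, c(10, 7)) # single-sample facet is the identity
  expect_error(facet_means(mat, map[1:2, ]), "not mapped")
  expect_error(facet_means(mat, dplyr::bind_rows(map, map[1, ])),
               "more than one facet")
})

test_that("facet means match the brute-force per-cell mean", {
  withr::local_seed(61)
  vals <- matrix(runif(20 * 9), 20, 9)
  samples <- sprintf("s%d", 1:9)
  map <- tibble::tibble(sample = samples,
                        facet = rep(c("f1", "f2", "f3"), each = 3))
  fm <- facet_means(mk_mat(as.data.frame(vals), samples), map)
  for (f in c("f1", "f2", "f3")) {
    idx <- which(map$facet == f)
    for (i in c(1, 7, 20)) {
      expect_equal(fm[[f]][i], mean(vals[i, idx]), tolerance = 1e-12)
    }
  }
})

test_that("specificity has the analytic values and invariances", {
  expect_equal(specificity(rep(2, 6)), 0, tolerance = 1e-12)
  expect_equal(specificity(c(0, 0, 9, 0)), 1, tolerance = 1e-12)
  expect_equal(specificity(c(0.5, 0.5, 0, 0)), 0.5, tolerance = 1e-12)
  expect_true(is.na(specificity(c(0, 0, 0))))
  expect_error(specificity(3), "at least 2")
  expect_error(specificity(c(-1, 2)), "non-negative")
  withr::local_seed(67)
  for (rep in 1:20) {
    x <- rgamma(sample(2:12, 1), 1, 1)
    s <- specificity(x)
    expect_gte(s, -1e-12)
    expect_lte(s, 1 + 1e-12)
    expect_equal(specificity(7.3 * x), s, tolerance = 1e-12)
    expect_equal(specificity(sample(x)), s, tolerance = 1e-12)
    # moving mass from a low facet onto the max never decreases it
    lo <- which.min(x)
    hi <- which.max(x)
    if (lo != hi) {
      y <- x
      shift <- x[lo] / 2
      y[lo] <- y[lo] - shift
      y[hi] <- y[hi] + shift
      expect_gte(specificity(y), s - 1e-12)
    }
  }
})

test_that("specificity_scores flags all-zero clusters as missing", {
  mat <- mk_mat(data.frame(s1 = c(5, 0), s2 = c(0, 0)), c("s1", "s2"))
  fm <- facet_means(mat, tibble::tibble(sample = c("s1", "s2"),
                                        facet = c("f1", "f2")))
  sc <- specificity_scores(fm)
  expect_equal(sc$specificity[1], 1)
  expect_true(is.na(sc$specificity[2]))
})

test_that("element expression mapping flags transcribed elements", {
  clusters <- tibble::tibble(
    cluster_id = c("a", "b", "c"),
    chrom = "c1", start = c(100, 5000, 9000), end = c(300, 5200, 9100),
    bidirectional = c(TRUE, TRUE, FALSE),
    K562 = c(3, 0, 8)
  )
  elements <- tibble::tibble(
    chrom = "c1", start = c(0, 4900, 8900), end = c(400, 5300, 9500),
    element_id = c("e1", "e2", "e3"), category = c("DSE", "DTE", "DTE")
  )
  got <- map_expression_to_elements(clusters, elements, "K562",
                                    enhancer_rna_mode = TRUE)
  per_el <- attr(got, "elements")
  expect_equal(per_el$transcribed[per_el$element_id == "e1"], TRUE)
  expect_equal(per_el$transcribed[per_el$element_id == "e2"], FALSE)
  # directional cluster never supports an eRNA call
  expect_equal(per_el$transcribed[per_el$element_id == "e3"], FALSE)
  fr <- attr(got, "category_fractions")
  expect_equal(fr$transcribed_fraction[fr$category == "DSE"], 1)
  expect_equal(fr$transcribed_fraction[fr$category == "DTE"], 0)
  # a threshold above every value zeroes all fractions
  high <- map_expression_to_elements(clusters, elements, "K562",
                                     enhancer_rna_mode = TRUE,
                                     tpm_threshold = 100)
  fr2 <- attr(high, "category_fractions")
  expect_true(all(fr2$transcribed_fraction == 0))
})
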