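test_that("Fisher's exact test reproduces enumerable tables", {
  expect_equal(fisher_exact(5, 5, 5, 5)$p_value, 1.0)
  expect_equal(fisher_exact(1, 0, 0, 1)$p_value, 1.0)
  expect_equal(fisher_exact(2, 0, 0, 2)$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(fisher_exact(2, 0, 0, 2)$odds_ratio, Inf)
  expect_equal(fisher_exact(4, 2, 2, 4)$odds_ratio, 4)
  expect_error(fisher_exact(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact(0, 0, 3, 4), "margins")
})

test_that("Fisher p equals exhaustive hypergeometric enumeration", {
  withr::local_seed(73)
  for (rep in 1:60) {
    repeat {
      cells <- as.integer(rmultinom(1, sample(4:60, 1), rep(0.25, 4)))
      a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
      if ((a + b) > 0 && (c + d) > 0 && (a + c) > 0 && (b + d) > 0) break
    }
    expect_equal(fisher_exact(a, b, c, d)$p_value, o_fisher_p(a, b, c, d),
                 tolerance = 1e-7)
  }
})

test_that("Holm-Sidak matches closed forms and stays monotone", {
  expect_equal(holm_sidak(0.04), 0.04)
  expect_equal(holm_sidak(c(0.01, 0.04)), c(1 - 0.99^2, 0.04))
  expect_equal(holm_sidak(c(0.05, 0.05, 0.05)), rep(1 - 0.95^3, 3))
  expect_equal(holm_sidak(c(0.05, 0.05, 0.05))[1], 0.142625)
  expect_error(holm_sidak(c(0.1, 1.2)), "0, 1")
  withr::local_seed(79)
  for (rep in 1:20) {
    p <- runif(sample(2:5, 1))
    adj <- holm_sidak(p)
    expect_equal(adj, o_holm_sidak(p))
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    expect_equal(order(adj[order(p)]), seq_along(p))
  }
})

test_that("housekeeping subsample averaging behaves hypergeometrically", {
  genes <- sprintf("g%03d", 1:200)
  # sample size equal to the set: every draw is the exhaustive count
  pred <- function(x) grepl("g0[0-4]", x)
  exact <- hk_average_counts(genes, pred, sample_size = 200, reps = 5,
                             seed = 1)
  expect_equal(exact, sum(pred(genes)))
  expect_equal(hk_average_counts(genes, function(x) rep(TRUE, length(x)),
                                 sample_size = 60, reps = 10, seed = 2), 60)
  expect_error(hk_average_counts(genes, pred, sample_size = 500),
               "smaller than sample_size")
  # expectation: 50 * fraction, within Monte Carlo error
  f <- mean(pred(genes))
  avg <- hk_average_counts(genes, pred, sample_size = 50, reps = 400,
                           seed = 3)
  n_draw <- 50
  se_mc <- sqrt(n_draw * f * (1 - f) * (200 - n_draw) / 199 / 400)
  expect_lt(abs(avg - n_draw * f), 3 * se_mc)
  # bit-identical under the same seed, RNG state untouched
  withr::local_seed(99)
  before <- .Random.seed
  again <- hk_average_counts(genes, pred, sample_size = 50, reps = 400,
                             seed = 3)
  expect_identical(avg, again)
  expect_identical(before, .Random.seed)
})

test_that("signed score carries the odds-ratio sign and vanishes at OR 1", {
  expect_equal(signed_score(1, 0.01), 0)
  expect_equal(signed_score(4, 0.01), 2)
  expect_equal(signed_score(0.25, 0.1), -1)
  expect_equal(signed_score(0, 0.1), -1)
  expect_equal(signed_score(Inf, 0.1), 1)
})

test_that("Dunn's test matches hand-computed rank arithmetic", {
  same <- dunn_test(tibble::tibble(v = rep(c(1, 2, 3), 2),
                                   g = rep(c("a", "b"), each = 3)), v, g)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)

  # groups {1,2,3} vs {4,5,6}: mean ranks 2 and 5, no ties
  d <- dunn_test(tibble::tibble(v = 1:6, g = rep(c("a", "b"), each = 3)),
                 v, g)
  se <- sqrt((6 * 7 / 12) * (1 / 3 + 1 / 3))
  expect_equal(d$z, (2 - 5) / se, tolerance = 1e-12)
  expect_equal(d$p_value, 2 * pnorm((2 - 5) / se), tolerance = 1e-12)

  # three groups with ties: mean ranks equal the mid-rank oracle
  vals <- c(1, 2, 2, 3, 3, 3, 5, 6)
  grp <- c("a", "a", "b", "b", "c", "c", "c", "c")
  got <- dunn_test(tibble::tibble(v = vals, g = grp), v, g)
  r <- rank(vals)
  expect_equal(got$mean_rank1[got$group1 == "a" & got$group2 == "b"],
               mean(r[grp == "a"]))
  expect_equal(got$mean_rank2[got$group1 == "b" & got$group2 == "c"],
               mean(r[grp == "c"]))
  tie_sizes <- table(vals)
  Tt <- sum(tie_sizes^3 - tie_sizes) / (12 * (8 - 1))
  se_ab <- sqrt((8 * 9 / 12 - Tt) * (1 / 2 + 1 / 2))
  expect_equal(got$z[1], (mean(r[grp == "a"]) - mean(r[grp == "b"])) / se_ab,
               tolerance = 1e-12)
  expect_error(dunn_test(tibble::tibble(v = 1:3, g = "a"), v, g),
               "2 groups")
})

test_that("enrichment panels detect identical classes as null", {
  regions <- tibble::tibble(
    region_id = sprintf("r%02d", 1:40),
    region_class = rep(c("BD_O", "O_O"), each = 20),
    proximity = "proximal",
    involved = TRUE
  )
  # identical hit fractions and sizes: OR 1, signed score 0
  targets <- tibble::tibble(
    region_id = regions$region_id[c(1:5, 21:25)],
    gene_id = rep(sprintf("T%d", 1:5), 2)
  )
  catalog <- list(tumor_suppressors = sprintf("T%d", 1:5),
                  oncogenes = "none", census_cancer = "none",
                  housekeeping = sprintf("H%d", 1:80))
  res <- suppressWarnings(enrichment_matrix(
    regions, catalog, targets, targets, hk_sample_size = 20, hk_reps = 50,
    seed = 5
  ))
  tsg <- res[res$gene_set == "TSG" & res$panel == "proximal_proximity", ]
  expect_equal(tsg$odds_ratio, 1)
  expect_equal(tsg$signed_score, 0)
  expect_equal(tsg$p_value, 1)
  expect_true(all(res$p_adj >= res$p_value - 1e-12, na.rm = TRUE))
})
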