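# Brute-force oracles, deliberately independent of the package's
# IRanges-backed implementations: plain double loops and closed forms.

rand_intervals <- function(n, chroms = c("c1", "c2"), max_pos = 10000,
                           max_len = 500) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_len, n, replace = TRUE)
  )
}

o_overlap_pairs <- function(a, b) {
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          max(a$start[i], b$start[j]) < min(a$end[i], b$end[j])) {
        pairs[[length(pairs) + 1]] <- c(i, j)
      }
    }
  }
  if (length(pairs) == 0) {
    return(matrix(integer(0), ncol = 2))
  }
  m <- do.call(rbind, pairs)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# repeated pairwise merging until fixpoint; returns sorted disjoint spans
o_merge_fixpoint <- function(x, gap) {
  iv <- lapply(seq_len(nrow(x)),
               function(i) list(chrom = x$chrom[i], start = x$start[i],
                                end = x$end[i]))
  alive <- rep(TRUE, length(iv))
  repeat {
    merged_any <- FALSE
    for (i in seq_along(iv)) {
      if (!alive[i]) next
      for (j in seq_along(iv)) {
        if (i == j || !alive[j]) next
        a <- iv[[i]]; b <- iv[[j]]
        if (a$chrom == b$chrom &&
            max(a$start, b$start) - min(a$end, b$end) <= gap) {
          iv[[i]] <- list(chrom = a$chrom, start = min(a$start, b$start),
                          end = max(a$end, b$end))
          alive[j] <- FALSE
          merged_any <- TRUE
        }
      }
    }
    if (!merged_any) break
  }
  iv <- iv[alive]
  out <- tibble::tibble(
    chrom = vapply(iv, `[[`, character(1), "chrom"),
    start = vapply(iv, `[[`, numeric(1), "start"),
    end = vapply(iv, `[[`, numeric(1), "end")
  )
  out[order(out$chrom, out$start), ]
}

o_point_dist <- function(pos, start, end) {
  if (pos >= start && pos < end) return(0)
  if (pos >= end) return(pos - end)
  start - pos - 1
}

o_classify <- function(elements, tss, threshold) {
  vapply(seq_len(nrow(elements)), function(i) {
    d <- Inf
    for (j in seq_len(nrow(tss))) {
      if (tss$chrom[j] != elements$chrom[i]) next
      d <- min(d, o_point_dist(tss$tss[j], elements$start[i],
                               elements$end[i]))
    }
    if (d <= threshold) "proximal" else "distal"
  }, character(1))
}

o_iv_overlap <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 && max(s1, s2) < min(e1, e2)
}

o_pair_to_pair <- function(rep1, rep2) {
  keep <- logical(nrow(rep1))
  for (i in seq_len(nrow(rep1))) {
    for (j in seq_len(nrow(rep2))) {
      same <- o_iv_overlap(rep1$chrom1[i], rep1$start1[i], rep1$end1[i],
                           rep2$chrom1[j], rep2$start1[j], rep2$end1[j]) &&
        o_iv_overlap(rep1$chrom2[i], rep1$start2[i], rep1$end2[i],
                     rep2$chrom2[j], rep2$start2[j], rep2$end2[j])
      cross <- o_iv_overlap(rep1$chrom1[i], rep1$start1[i], rep1$end1[i],
                            rep2$chrom2[j], rep2$start2[j], rep2$end2[j]) &&
        o_iv_overlap(rep1$chrom2[i], rep1$start2[i], rep1$end2[i],
                     rep2$chrom1[j], rep2$start1[j], rep2$end1[j])
      if (same || cross) {
        keep[i] <- TRUE
        break
      }
    }
  }
  keep
}

o_associate <- function(elements, loops) {
  counts <- integer(nrow(elements))
  for (i in seq_len(nrow(elements))) {
    for (j in seq_len(nrow(loops))) {
      hit <- o_iv_overlap(elements$chrom[i], elements$start[i],
                          elements$end[i], loops$chrom1[j],
                          loops$start1[j], loops$end1[j]) ||
        o_iv_overlap(elements$chrom[i], elements$start[i], elements$end[i],
                     loops$chrom2[j], loops$start2[j], loops$end2[j])
      if (hit) counts[i] <- counts[i] + 1L
    }
  }
  counts
}

o_loop_target_pairs <- function(elements, loops, tss, window = 4000) {
  pairs <- list()
  for (i in seq_len(nrow(elements))) {
    for (j in seq_len(nrow(loops))) {
      for (side in 1:2) {
        ac <- loops[[paste0("chrom", side)]][j]
        as_ <- loops[[paste0("start", side)]][j]
        ae <- loops[[paste0("end", side)]][j]
        if (!o_iv_overlap(elements$chrom[i], elements$start[i],
                          elements$end[i], ac, as_, ae)) {
          next
        }
        other <- 3 - side
        oc <- loops[[paste0("chrom", other)]][j]
        os <- loops[[paste0("start", other)]][j]
        oe <- loops[[paste0("end", other)]][j]
        for (k in seq_len(nrow(tss))) {
          if (tss$chrom[k] == oc &&
              o_point_dist(tss$tss[k], os, oe) <= window) {
            pairs[[length(pairs) + 1]] <-
              tibble::tibble(element = i, gene_id = tss$gene_id[k])
          }
        }
      }
    }
  }
  if (length(pairs) == 0) {
    return(tibble::tibble(element = integer(), gene_id = character()))
  }
  dplyr::distinct(dplyr::bind_rows(pairs))
}

o_track_integral <- function(track, chrom, start, end) {
  total <- 0
  for (pos in seq(start, end - 1)) {
    for (j in seq_len(nrow(track))) {
      if (track$chrom[j] == chrom && pos >= track$start[j] &&
          pos < track$end[j]) {
        total <- total + track$value[j]
        break
      }
    }
  }
  total
}

# exhaustive tangent-line search as specified: all candidate indices,
# explicit O(n^2) count of points strictly below each line
o_tangent <- function(y) {
  y <- sort(y)
  n <- length(y)
  s <- (y[n] - y[1]) / n
  if (y[n] == y[1]) {
    return(list(cutoff = y[n], index = n))
  }
  counts <- integer(n)
  tol <- 1e-9 * max(abs(y), 1) # "strictly below" robust to rounding:
  for (i in seq_len(n)) {      # a point is never below its own line
    intercept <- y[i] - s * i
    counts[i] <- sum(y < s * seq_len(n) + intercept - tol)
  }
  i_star <- max(which(counts == min(counts)))
  list(cutoff = y[i_star], index = i_star)
}

# exhaustive two-sided Fisher p over all tables with the observed margins
o_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

o_holm_sidak <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    val <- 1 - (1 - p[ord[i]])^(m - i + 1)
    running <- max(running, val)
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# taxonomy oracle: transitive overlap-merge of labelled elements by
# repeated pairwise merging, then class/proximity from member kinds
o_taxonomy_classes <- function(members, gap = 0) {
  comp <- seq_len(nrow(members))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(members))) {
      for (j in seq_len(nrow(members))) {
        if (comp[i] != comp[j] &&
            members$chrom[i] == members$chrom[j] &&
            max(members$start[i], members$start[j]) -
              min(members$end[i], members$end[j]) <= gap) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  cls <- vapply(unique(comp), function(cc) {
    kinds <- members$kind[comp == cc]
    if (any(kinds == "SE") && any(kinds == "BD")) "SE_BD"
    else if (any(kinds == "SE")) "SE_O"
    else if (any(kinds == "BD")) "BD_O"
    else "O_O"
  }, character(1))
  sort(table(factor(cls, levels = c("SE_BD", "SE_O", "BD_O", "O_O"))))
}

# independent sweep-line transitive merge (sort + walk), classifying each
# merged run by its member kinds; much faster than the pairwise oracle
o_taxonomy_sweep <- function(members) {
  ord <- order(members$chrom, members$start, members$end)
  m <- members[ord, ]
  cls <- character(0)
  cur_chrom <- ""
  cur_end <- -Inf
  kinds <- character(0)
  flush <- function(kinds) {
    if (length(kinds) == 0) return(NULL)
    if (any(kinds == "SE") && any(kinds == "BD")) "SE_BD"
    else if (any(kinds == "SE")) "SE_O"
    else if (any(kinds == "BD")) "BD_O"
    else "O_O"
  }
  for (i in seq_len(nrow(m))) {
    if (m$chrom[i] != cur_chrom || m$start[i] > cur_end) {
      cls <- c(cls, flush(kinds))
      kinds <- character(0)
      cur_chrom <- m$chrom[i]
      cur_end <- m$end[i]
    }
    kinds <- c(kinds, m$kind[i])
    cur_end <- max(cur_end, m$end[i])
  }
  cls <- c(cls, flush(kinds))
  table(factor(cls, levels = c("SE_BD", "SE_O", "BD_O", "O_O")))
}

called_members <- function(res) {
  dplyr::bind_rows(
    dplyr::transmute(res$enhancers, chrom, start, end,
                     kind = ifelse(is_super, "SE", "TE")),
    dplyr::transmute(res$domains, chrom, start, end,
                     kind = ifelse(is_broad, "BD", "TD"))
  )
}

# one full default-condition analysis per seed, shared across test blocks
.fixture_cache <- new.env(parent = emptyenv())
cached_analysis <- function(seed) {
  key <- as.character(seed)
  if (is.null(.fixture_cache[[key]])) {
    bundle <- generate_fixture(fixture_config(seed = seed))
    res <- suppressWarnings(run_analysis(
      bundle,
      analysis_facet = bundle$config$analysis_facet,
      hk_sample_size = bundle$config$hk_sample_size,
      hk_reps = bundle$config$hk_reps,
      seed = seed + 10000L
    ))
    .fixture_cache[[key]] <- list(bundle = bundle, res = res)
  }
  .fixture_cache[[key]]
}
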