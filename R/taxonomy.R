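#' Merge enhancer and H3K4me3 element calls into a region taxonomy
#'
#' Overlapping elements from the H3K27ac call set (super/typical
#' enhancers, SE/TE) and the H3K4me3 call set (broad/typical domains,
#' BD/TD) are transitively merged. Each merged region is classified by
#' its member kinds: `SE_BD` (has both a super-enhancer and a broad
#' domain), `SE_O` (super-enhancer only), `BD_O` (broad domain only),
#' `O_O` (typical elements only). A region of the first three classes is
#' proximal when it contains at least one proximal SE or proximal BD
#' member; an `O_O` region is proximal when it contains at least one
#' proximal (typical) member.
#'
#' @param enhancers Tibble from [call_super_enhancers()] +
#'   [classify_proximity()]: needs `chrom`, `start`, `end`, `is_super`,
#'   `proximity` (and optionally `region_id`).
#' @param domains Tibble from [call_broad_domains()] +
#'   [classify_proximity()]: needs `chrom`, `start`, `end`, `is_broad`,
#'   `proximity` (and optionally `name`).
#' @return Tibble of merged regions: `chrom`, `start`, `end`,
#'   `region_id`, `region_class`, `proximity`, and a `members`
#'   list-column of tibbles (`element_id`, `kind`, `proximity`).
#' @export
build_taxonomy <- function(enhancers, domains) {
  enhancers <- check_intervals(enhancers, "enhancers")
  domains <- check_intervals(domains, "domains")
  for (col in c("is_super", "proximity")) {
    if (!col %in% names(enhancers)) {
      abort(sprintf("`enhancers` missing `%s`", col))
    }
  }
  for (col in c("is_broad", "proximity")) {
    if (!col %in% names(domains)) {
      abort(sprintf("`domains` missing `%s`", col))
    }
  }
  e_ids <- if ("region_id" %in% names(enhancers)) {
    enhancers$region_id
  } else {
    sprintf("enh_%05d", seq_len(nrow(enhancers)))
  }
  d_ids <- if ("name" %in% names(domains)) {
    domains$name
  } else {
    sprintf("dom_%05d", seq_len(nrow(domains)))
  }
  members <- bind_rows(
    tibble(chrom = enhancers$chrom, start = enhancers$start,
           end = enhancers$end, element_id = e_ids,
           kind = if_else(enhancers$is_super, "SE", "TE"),
           proximity = enhancers$proximity),
    tibble(chrom = domains$chrom, start = domains$start,
           end = domains$end, element_id = d_ids,
           kind = if_else(domains$is_broad, "BD", "TD"),
           proximity = domains$proximity)
  )
  merged <- merge_within(members, gap = 0)
  ridx <- rep(seq_len(nrow(merged)), lengths(merged$rows))
  m <- members[unlist(merged$rows), c("element_id", "kind", "proximity")]
  f <- factor(ridx, levels = seq_len(nrow(merged)))
  any_by <- function(x) as.logical(tapply(x, f, any))
  has_se <- any_by(m$kind == "SE")
  has_bd <- any_by(m$kind == "BD")
  marker_prox <- any_by(m$proximity == "proximal" & m$kind %in% c("SE", "BD"))
  any_prox <- any_by(m$proximity == "proximal")
  cls <- dplyr::case_when(
    has_se & has_bd ~ "SE_BD",
    has_se ~ "SE_O",
    has_bd ~ "BD_O",
    TRUE ~ "O_O"
  )
  prox <- if_else(cls == "O_O", any_prox, marker_prox)
  merged |>
    mutate(
      region_id = sprintf("region_%05d", row_number()),
      region_class = cls,
      proximity = if_else(prox, "proximal", "distal"),
      members = unname(split(m, f))
    ) |>
    select("chrom", "start", "end", "region_id", "region_class",
           "proximity", "members")
}
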