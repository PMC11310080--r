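#' Filter candidate guides on score, exclusion and splice-site rules
#'
#' Keeps guides with `efficacy > 0.15`, `top5 < 47` and `top10 < 50` (all
#' strict), whose 20-nt protospacer interval does not overlap any exclusion
#' interval, and whose cut site lies at least `min_splice_dist` bp from every
#' splice site. Input order is preserved.
#'
#' @param guides Tibble of candidate guides (`guide_id`, `chrom`, `cut_site`,
#'   `strand`, `protospacer`, `efficacy`, `top5`, `top10`).
#' @param exclusions Optional tibble of 0-based half-open intervals
#'   (`chrom`, `start`, `end`) the protospacer must not overlap.
#' @param splice_sites Optional tibble (`chrom`, `pos`) of splice-site
#'   coordinates.
#' @param thresholds Named list overriding the score cut-offs
#'   (`efficacy`, `top5`, `top10`).
#' @param min_splice_dist Minimum distance (bp) between cut site and any
#'   splice site; default 10.
#' @return The filtered guide tibble.
#' @export
filter_guides <- function(guides, exclusions = NULL, splice_sites = NULL,
                          thresholds = list(efficacy = 0.15, top5 = 47,
                                            top10 = 50),
                          min_splice_dist = 10L) {
  if (nrow(guides) == 0) return(guides)
  thr <- utils::modifyList(list(efficacy = 0.15, top5 = 47, top10 = 50),
                           as.list(thresholds))
  missing_score <- !stats::complete.cases(guides[, c("efficacy", "top5", "top10")])
  if (any(missing_score)) {
    abort(sprintf("guide(s) missing scores: %s",
                  paste(guides$guide_id[missing_score], collapse = ", ")))
  }
  keep <- guides$efficacy > thr$efficacy &
    guides$top5 < thr$top5 &
    guides$top10 < thr$top10

  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    # protospacer genomic interval from cut site and strand:
    # plus strand: [cut-17, cut+3); minus strand: [cut-3, cut+17)
    ps <- ifelse(guides$strand == "+", guides$cut_site - 17L,
                 guides$cut_site - 3L)
    pe <- ps + 20L
    overlaps <- map_int(seq_len(nrow(guides)), function(i) {
      any(exclusions$chrom == guides$chrom[i] &
            exclusions$start < pe[i] & exclusions$end > ps[i])
    })
    keep <- keep & !as.logical(overlaps)
  }

  if (!is.null(splice_sites) && nrow(splice_sites) > 0) {
    near <- map_int(seq_len(nrow(guides)), function(i) {
      ss <- splice_sites$pos[splice_sites$chrom == guides$chrom[i]]
      length(ss) > 0 && min(abs(ss - guides$cut_site[i])) < min_splice_dist
    })
    keep <- keep & !as.logical(near)
  }

  guides[keep, , drop = FALSE]
}

# Rank guides within one flank: efficacy descending, then distance to the
# region boundary ascending, then guide_id (deterministic tie-break).
rank_flank <- function(guides, boundary) {
  guides |>
    mutate(.dist = abs(.data$cut_site - boundary)) |>
    arrange(desc(.data$efficacy), .data$.dist, .data$guide_id) |>
    select(-".dist")
}

pair_tibble <- function() {
  tibble(pair_id = character(), region_id = character(),
         strategy = character(),
         guide_id_u6 = character(), protospacer_u6 = character(),
         cut_u6 = integer(),
         guide_id_h1 = character(), protospacer_h1 = character(),
         cut_h1 = integer(),
         chrom = character(), del_start = integer(), del_end = integer())
}

make_pairs <- function(region, up, down, strategy) {
  if (nrow(up) == 0 || nrow(down) == 0) return(pair_tibble())
  grid <- tidyr::expand_grid(i = seq_len(nrow(up)), j = seq_len(nrow(down)))
  tibble(
    pair_id = NA_character_,
    region_id = region$region_id,
    strategy = strategy,
    guide_id_u6 = up$guide_id[grid$i],
    protospacer_u6 = up$protospacer[grid$i],
    cut_u6 = up$cut_site[grid$i],
    guide_id_h1 = down$guide_id[grid$j],
    protospacer_h1 = down$protospacer[grid$j],
    cut_h1 = down$cut_site[grid$j],
    chrom = region$chrom,
    del_start = pmin(up$cut_site[grid$i], down$cut_site[grid$j]),
    del_end = pmax(up$cut_site[grid$i], down$cut_site[grid$j]))
}

#' Design flanking guide pairs for a target region
#'
#' Selects up to `max_per_flank` filtered guides whose cut sites fall in the
#' 200-bp windows immediately upstream and downstream of the region and emits
#' their Cartesian product, so a region with abundant candidates receives
#' exactly `max_per_flank^2` (default 25) pairs. Each pair's expected deletion
#' spans both cut sites and therefore contains the whole region. The upstream
#' guide is expressed from U6, the downstream guide from H1.
#'
#' @param region One-row tibble (`region_id`, `chrom`, `start`, `end`).
#' @param guides Filtered candidate guides (see [filter_guides()]).
#' @param flank_bp Flank width in bp (default 200).
#' @param max_per_flank Maximum guides selected per flank (default 5), ranked
#'   by efficacy, then proximity to the region boundary, then `guide_id`.
#' @return Tibble of guide pairs (possibly empty, with a warning when a flank
#'   has no usable guide).
#' @export
design_flanking_pairs <- function(region, guides, flank_bp = 200L,
                                  max_per_flank = 5L) {
  g <- guides[guides$chrom == region$chrom, , drop = FALSE]
  up <- g[g$cut_site >= region$start - flank_bp & g$cut_site < region$start, ,
          drop = FALSE]
  down <- g[g$cut_site >= region$end & g$cut_site < region$end + flank_bp, ,
            drop = FALSE]
  if (nrow(up) == 0 || nrow(down) == 0) {
    warn(sprintf("region %s: undesignable by flanking strategy (%d upstream, %d downstream guides)",
                 region$region_id, nrow(up), nrow(down)))
    return(pair_tibble())
  }
  up <- head(rank_flank(up, region$start), max_per_flank)
  down <- head(rank_flank(down, region$end), max_per_flank)
  pairs <- make_pairs(region, up, down, "flanking")
  pairs$pair_id <- sprintf("%s_f%02d", region$region_id, seq_len(nrow(pairs)))
  pairs
}

#' Design internal guide pairs for a target region
#'
#' Fallback strategy for regions with unusable flanks: guides cutting inside
#' the region are split into a 5'-proximal and a 3'-proximal half at the
#' region midpoint, one guide is taken from each half, and up to `n_target`
#' pairs whose expected deletion contains the midpoint are returned, widest
#' deletion first (ties broken by guide ids).
#'
#' @inheritParams design_flanking_pairs
#' @param n_target Maximum number of pairs to emit (default 14).
#' @return Tibble of guide pairs (possibly empty, with a warning).
#' @export
design_internal_pairs <- function(region, guides, n_target = 14L) {
  g <- guides[guides$chrom == region$chrom &
                guides$cut_site >= region$start &
                guides$cut_site < region$end, , drop = FALSE]
  mid <- (region$start + region$end) / 2
  left <- g[g$cut_site < mid, , drop = FALSE]
  right <- g[g$cut_site >= mid, , drop = FALSE]
  if (nrow(left) == 0 || nrow(right) == 0) {
    warn(sprintf("region %s: undesignable by internal strategy (%d guides 5' of midpoint, %d 3')",
                 region$region_id, nrow(left), nrow(right)))
    return(pair_tibble())
  }
  pairs <- make_pairs(region, left, right, "internal")
  pairs <- pairs[pairs$del_start <= mid & pairs$del_end > mid, , drop = FALSE]
  if (nrow(pairs) == 0) {
    warn(sprintf("region %s: no internal pair contains the midpoint",
                 region$region_id))
    return(pair_tibble())
  }
  pairs <- pairs |>
    mutate(.span = .data$del_end - .data$del_start) |>
    arrange(desc(.data$.span), .data$guide_id_u6, .data$guide_id_h1) |>
    select(-".span") |>
    slice_head(n = n_target)
  pairs$pair_id <- sprintf("%s_i%02d", region$region_id, seq_len(nrow(pairs)))
  pairs
}
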