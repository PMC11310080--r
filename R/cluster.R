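#' Assign target regions to enhancer clusters by midpoint containment
#'
#' A region belongs to the cluster whose interval contains its midpoint
#' (0-based half-open: assigned iff `start <= mid < end`). Overlapping cluster
#' intervals are an ambiguous annotation and raise an error. Regions falling
#' in no interval are reported as unassigned (they form implicit singletons
#' excluded from cluster testing).
#'
#' @param regions Tibble `region_id`, `chrom`, `start`, `end`.
#' @param cluster_bed Tibble `chrom`, `start`, `end`, `cluster_id` (BED-style,
#'   0-based half-open).
#' @return Tibble `region_id`, `cluster_id` (NA when unassigned).
#' @export
map_regions_to_clusters <- function(regions, cluster_bed) {
  stopifnot(all(cluster_bed$end > cluster_bed$start))
  # overlapping intervals on the same chromosome are ambiguous
  by_chrom <- split(cluster_bed, cluster_bed$chrom)
  for (cb in by_chrom) {
    cb <- cb[order(cb$start), ]
    if (nrow(cb) > 1 && any(cb$start[-1] < cb$end[-nrow(cb)])) {
      abort("overlapping cluster intervals: annotation is ambiguous")
    }
  }
  mid <- (regions$start + regions$end) / 2
  cluster_id <- map_chr(seq_len(nrow(regions)), function(i) {
    hit <- which(cluster_bed$chrom == regions$chrom[i] &
                   cluster_bed$start <= mid[i] & mid[i] < cluster_bed$end)
    if (length(hit) == 0) NA_character_ else cluster_bed$cluster_id[hit[1]]
  })
  tibble(region_id = regions$region_id, cluster_id = cluster_id)
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score for one cluster:
# regions ranked by score descending, member increments |score|^weight
# (normalised), non-member decrements 1/(N - k); es is the signed extremum.
gsea_es <- function(is_member, scores_desc, weight = 1) {
  n <- length(is_member)
  k <- sum(is_member)
  w <- abs(scores_desc)^weight
  hit <- ifelse(is_member, w, 0)
  sum_hit <- sum(hit)
  if (sum_hit == 0) hit <- ifelse(is_member, 1 / k, 0) else hit <- hit / sum_hit
  miss <- ifelse(is_member, 0, 1 / (n - k))
  run <- cumsum(hit - miss)
  run[which.max(abs(run))]
}

#' Cluster-level depletion test by weighted-KS enrichment (GSEA)
#'
#' Ranks all regions by a signed depletion score (descending; use e.g. the
#' negative log fold change so depletion ranks high), computes a weighted
#' Kolmogorov-Smirnov running-sum enrichment score per cluster, and estimates
#' a one-sided permutation p-value toward depletion by resampling cluster
#' membership labels. BH correction is applied across clusters. Clusters of
#' size 1 are tested but flagged.
#'
#' @param region_scores Tibble `region_id`, `score` (higher = more depleted).
#' @param clusters Tibble `region_id`, `cluster_id` (NA rows ignored), e.g.
#'   from [map_regions_to_clusters()].
#' @param weight Exponent on |score| in the running sum (default 1).
#' @param n_perm Number of membership permutations.
#' @param seed Integer seed.
#' @return Tibble `cluster_id`, `k`, `es`, `p`, `fdr`, `small` (size-1 flag),
#'   sorted by `p` then decreasing `es`.
#' @export
cluster_depletion_gsea <- function(region_scores, clusters, weight = 1,
                                   n_perm = 1000L, seed = 1L) {
  dat <- region_scores |>
    inner_join(clusters |> filter(!is.na(.data$cluster_id)), by = "region_id") |>
    arrange(desc(.data$score))
  n <- nrow(region_scores)
  ord_scores <- sort(region_scores$score, decreasing = TRUE)
  cluster_ids <- unique(dat$cluster_id)

  # member positions of each cluster in the global descending ranking
  rank_of <- match(dat$region_id,
                   region_scores$region_id[order(region_scores$score,
                                                 decreasing = TRUE)])
  res <- map(cluster_ids, function(cl) {
    pos <- rank_of[dat$cluster_id == cl]
    k <- length(pos)
    member <- rep(FALSE, n); member[pos] <- TRUE
    es <- gsea_es(member, ord_scores, weight)
    null_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      mb <- rep(FALSE, n); mb[sample.int(n, k)] <- TRUE
      gsea_es(mb, ord_scores, weight)
    }, numeric(1)))
    tibble(cluster_id = cl, k = k, es = es,
           p = (1 + sum(null_es >= es)) / (n_perm + 1),
           small = k < 2)
  }) |> list_rbind()
  res |>
    mutate(fdr = p.adjust(.data$p, "BH")) |>
    relocate("fdr", .after = "p") |>
    arrange(.data$p, desc(.data$es), .data$cluster_id)
}

#' Cluster-level depletion test by alpha-RRA
#'
#' Pools the guide pairs of every member region of each cluster and delegates
#' to [alpha_rra()] with the cluster map in place of the region map; BH
#' correction across clusters comes from `alpha_rra` itself.
#'
#' @param scores Guide rank tibble from [score_guides()] (with `region_id`).
#' @param clusters Tibble `region_id`, `cluster_id` (NA rows excluded).
#' @param alpha,n_perm,seed,rho_cutoff Passed to [alpha_rra()].
#' @return A `pairdel_rra` tibble keyed by `cluster_id`.
#' @export
cluster_depletion_rra <- function(scores, clusters, alpha = 0.25,
                                  n_perm = 1000L, seed = 1L,
                                  rho_cutoff = 0.01) {
  if (!"region_id" %in% names(scores)) abort("scores must carry region_id")
  pair_map <- scores |>
    select("pair_id", "region_id") |>
    left_join(clusters, by = "region_id") |>
    select("pair_id", region_id = "cluster_id")
  res <- alpha_rra(scores, region_map = pair_map, alpha = alpha,
                   n_perm = n_perm, seed = seed, rho_cutoff = rho_cutoff)
  res |> rename(cluster_id = "region_id")
}

#' Clusters ranked in the top k by both methods
#'
#' Intersects the `top_k` clusters of the GSEA ranking (by p, then decreasing
#' es) and of the RRA ranking (by p, then rho); the result is ordered by the
#' joint rank sum, so it is symmetric in the two arguments.
#'
#' @param gsea_results Output of [cluster_depletion_gsea()].
#' @param rra_results Output of [cluster_depletion_rra()].
#' @param top_k Number of top clusters per method (default 20; capped at the
#'   number of clusters with a warning).
#' @return Character vector of shared cluster ids.
#' @export
select_shared_top <- function(gsea_results, rra_results, top_k = 20L) {
  n_cl <- min(nrow(gsea_results), nrow(rra_results))
  if (top_k > n_cl) {
    warn(sprintf("top_k = %d exceeds the %d available clusters; capped", top_k, n_cl))
    top_k <- n_cl
  }
  # rank by the columns each result shape carries, so the selection is
  # symmetric in its two arguments
  rank_results <- function(res) {
    if (all(c("p_perm", "rho") %in% names(res))) {
      arrange(res, .data$p_perm, .data$rho, .data$cluster_id)
    } else {
      arrange(res, .data$p, desc(.data$es), .data$cluster_id)
    }
  }
  ord_g <- rank_results(gsea_results)
  ord_r <- rank_results(rra_results)
  top_g <- ord_g$cluster_id[seq_len(top_k)]
  top_r <- ord_r$cluster_id[seq_len(top_k)]
  shared <- intersect(top_g, top_r)
  joint <- match(shared, ord_g$cluster_id) + match(shared, ord_r$cluster_id)
  shared[order(joint, shared)]
}
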