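sample_columns <- function(counts) {
  setdiff(names(counts)[vapply(counts, is.numeric, logical(1))],
          c("del_start", "del_end", "cut_u6", "cut_h1"))
}

#' Median-ratio normalization of a pair count matrix
#'
#' Computes one size factor per sample as the median, over pairs with strictly
#' positive counts in every sample, of the ratio between the sample's count
#' and the pair's geometric mean across samples; counts are divided by the
#' size factor. This is the standard size-factor construction for pooled
#' screen counts.
#'
#' @param counts Wide tibble (`pair_id`, optional `region_id`, one numeric
#'   column per sample).
#' @return Tibble of the same shape with normalized counts; size factors in
#'   the `size_factors` attribute (see [size_factors()]).
#' @export
normalize_median_ratio <- function(counts) {
  samp <- sample_columns(counts)
  if (length(samp) < 2) abort("need at least 2 samples to normalize")
  m <- as.matrix(counts[, samp])
  allpos <- rowSums(m > 0) == ncol(m)
  if (!any(allpos)) {
    abort("no pair has positive counts in all samples; consider adding a pseudocount upstream")
  }
  loggeo <- rowMeans(log(m[allpos, , drop = FALSE]))
  sf <- apply(m[allpos, , drop = FALSE], 2,
              function(col) median(exp(log(col) - loggeo)))
  out <- counts
  for (j in seq_along(samp)) out[[samp[j]]] <- counts[[samp[j]]] / sf[j]
  attr(out, "size_factors") <- sf
  out
}

#' @rdname normalize_median_ratio
#' @param x A normalized count tibble.
#' @return `size_factors()` returns the named numeric vector of size factors.
#' @export
size_factors <- function(x) attr(x, "size_factors")

#' Score guide pairs by log2 fold change and rank them
#'
#' `score = log2((norm_b + pseudocount) / (norm_a + pseudocount))`, ranked
#' ascending so the most depleted pair has rank 1; ties are broken by
#' `pair_id` for determinism. The percentile `u = rank / m` feeds
#' [alpha_rra()].
#'
#' @param norm Normalized count tibble (see [normalize_median_ratio()]).
#' @param sample_a Reference sample (e.g. day 0).
#' @param sample_b Comparison sample (e.g. day 15).
#' @param pseudocount Added to both sides of the ratio (default 1).
#' @return Tibble: `pair_id`, optional `region_id`, `score`, `rank`,
#'   `percentile`.
#' @export
score_guides <- function(norm, sample_a, sample_b, pseudocount = 1) {
  for (s in c(sample_a, sample_b)) {
    if (!s %in% names(norm)) abort(sprintf("sample '%s' not found", s))
  }
  out <- norm |>
    mutate(score = log2((.data[[sample_b]] + pseudocount) /
                          (.data[[sample_a]] + pseudocount))) |>
    arrange(.data$score, .data$pair_id) |>
    mutate(rank = row_number(), percentile = .data$rank / n())
  keep <- intersect(c("pair_id", "region_id", "score", "rank", "percentile"),
                    names(out))
  out[, keep]
}

# rho for one region: sorted percentiles u, total k pairs, keep only u < alpha;
# rho = min_j P(Beta(j, k - j + 1) <= u_(j)), or 1 when no percentile < alpha.
rra_rho <- function(u, alpha) {
  u <- sort(u)
  k <- length(u)
  j <- which(u < alpha)
  if (length(j) == 0) return(1)
  min(pbeta(u[j], j, k - j + 1))
}

# Seeded null rho values for region size k: n_perm random k-subsets of the
# global percentile pool (shared across regions of equal k).
rra_null <- function(percentiles, k, alpha, n_perm) {
  vapply(seq_len(n_perm),
         function(i) rra_rho(sample(percentiles, k), alpha),
         numeric(1))
}

#' Alpha-robust rank aggregation of guide-pair depletion to regions
#'
#' For each region with k scored pairs and sorted percentiles
#' u(1) <= ... <= u(k), only percentiles below `alpha` are considered and the
#' region score is `rho = min_j P(Beta(j, k-j+1) <= u(j))`; regions with no
#' percentile below `alpha` receive `rho = 1`. Permutation p-values compare
#' each region's rho against seeded random k-subsets of the global percentile
#' pool (with add-one smoothing); BH correction is applied across regions.
#' A region is called significant when `rho < rho_cutoff` (default 0.01).
#'
#' @param scores Guide rank tibble from [score_guides()] (needs `pair_id`,
#'   `percentile`, and `region_id` unless `region_map` is given).
#' @param region_map Optional tibble `pair_id`, `region_id` overriding the
#'   mapping in `scores` (used e.g. for cluster-level aggregation).
#' @param alpha Fraction of the ranking considered informative (default 0.25).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation null.
#' @param rho_cutoff Significance cut-off on rho (default 0.01).
#' @return A `pairdel_rra` object: tibble `region_id`, `k`, `rho`, `p_perm`,
#'   `fdr`, `significant`, with the call parameters as attributes.
#' @export
alpha_rra <- function(scores, region_map = NULL, alpha = 0.25,
                      n_perm = 1000L, seed = 1L, rho_cutoff = 0.01) {
  if (n_perm < 100) abort("n_perm must be >= 100")
  if (is.null(region_map)) {
    if (!"region_id" %in% names(scores)) {
      abort("scores must carry region_id, or supply region_map")
    }
    region_map <- scores[, c("pair_id", "region_id")]
  }
  region_map <- region_map |> filter(!is.na(.data$region_id))
  if (anyDuplicated(region_map$pair_id)) {
    abort("each scored pair must map to at most one region")
  }
  dat <- scores |>
    select("pair_id", "percentile") |>
    inner_join(region_map, by = "pair_id")
  empty <- setdiff(unique(region_map$region_id), unique(dat$region_id))
  if (length(empty) > 0) {
    warn(sprintf("%d region(s) with no scored pairs excluded: %s",
                 length(empty), paste(head(empty, 5), collapse = ", ")))
  }

  by_region <- dat |>
    group_by(.data$region_id) |>
    summarise(k = n(), rho = rra_rho(.data$percentile, alpha))

  pool <- scores$percentile
  nulls <- with_seed(seed, {
    ks <- sort(unique(by_region$k))
    setNames(lapply(ks, function(k) rra_null(pool, k, alpha, n_perm)), ks)
  })
  by_region$p_perm <- map_dbl(seq_len(nrow(by_region)), function(i) {
    null_i <- nulls[[as.character(by_region$k[i])]]
    (1 + sum(null_i <= by_region$rho[i])) / (n_perm + 1)
  })
  by_region <- by_region |>
    mutate(fdr = p.adjust(.data$p_perm, "BH"),
           significant = .data$rho < rho_cutoff) |>
    arrange(.data$rho, .data$p_perm, .data$region_id)

  structure(by_region,
            class = c("pairdel_rra", class(by_region)),
            alpha = alpha, n_perm = n_perm, seed = seed,
            rho_cutoff = rho_cutoff)
}

#' Per-condition beta selection coefficients for regions
#'
#' For every region and condition, beta is the median over the region's pairs
#' of the log2 fold change of normalized counts (condition vs baseline,
#' pseudocount 1), a robust selection coefficient; samples belonging to the
#' same condition are averaged first. When both a treated and an untreated
#' condition are present, the differential beta (treated minus untreated) is
#' added.
#'
#' @param norm Normalized count tibble with `region_id`.
#' @param conditions Named character vector mapping sample column to
#'   condition; exactly one sample set must map to `baseline`.
#' @param baseline,treated,untreated Condition labels (defaults `"day0"`,
#'   `"treated"`, `"untreated"`).
#' @param pseudocount Added to normalized counts before the ratio.
#' @return A `pairdel_beta` object: tibble `region_id`, one `beta_<condition>`
#'   column per non-baseline condition, and `differential` when both treated
#'   and untreated exist; per-condition means/sds in the `condition_stats`
#'   attribute.
#' @export
estimate_beta_scores <- function(norm, conditions, baseline = "day0",
                                 treated = "treated", untreated = "untreated",
                                 pseudocount = 1) {
  if (!"region_id" %in% names(norm)) abort("norm must carry region_id")
  if (!baseline %in% conditions) {
    abort(sprintf("conditions must include the baseline '%s'", baseline))
  }
  conds <- setdiff(unique(conditions), baseline)
  if (length(conds) == 0) abort("need at least one non-baseline condition")
  cond_mean <- function(cond) {
    cols <- names(conditions)[conditions == cond]
    rowMeans(as.matrix(norm[, cols, drop = FALSE]))
  }
  base <- cond_mean(baseline)
  keep <- !is.na(norm$region_id)
  ids <- norm$region_id[keep]
  betas <- tibble(region_id = unique(ids))
  for (cond in conds) {
    lfc <- log2((cond_mean(cond)[keep] + pseudocount) /
                  (base[keep] + pseudocount))
    med <- tibble(region_id = ids, lfc = lfc) |>
      group_by(.data$region_id) |>
      summarise(beta = median(.data$lfc))
    names(med)[2] <- paste0("beta_", cond)
    betas <- left_join(betas, med, by = "region_id")
  }
  if (all(c(treated, untreated) %in% conds)) {
    betas$differential <- betas[[paste0("beta_", treated)]] -
      betas[[paste0("beta_", untreated)]]
  }
  stats_tbl <- tibble(
    condition = conds,
    mean = map_dbl(conds, ~ mean(betas[[paste0("beta_", .x)]])),
    sd = map_dbl(conds, ~ sd(betas[[paste0("beta_", .x)]])))
  if ("differential" %in% names(betas)) {
    stats_tbl <- bind_rows(stats_tbl,
                           tibble(condition = "differential",
                                  mean = mean(betas$differential),
                                  sd = sd(betas$differential)))
  }
  structure(betas, class = c("pairdel_beta", class(betas)),
            condition_stats = stats_tbl,
            treated = treated, untreated = untreated)
}

#' Classify drug-gene-element interactions from beta scores
#'
#' A region is called `resistant` when its treated beta exceeds the treated
#' population mean by more than `k_treated_sd` standard deviations, its
#' untreated beta stays within `k_control_sd` standard deviations of the
#' untreated mean, and its differential beta (treated minus untreated) exceeds
#' the differential mean by more than `k_diff_sd` standard deviations;
#' `sensitizing` is the mirrored rule, and everything else is `none`.
#'
#' @param betas A `pairdel_beta` with treated and untreated columns.
#' @param k_treated_sd,k_control_sd,k_diff_sd Rule multipliers (defaults
#'   2, 1, 1).
#' @return Tibble `region_id`, `call`, plus the beta columns used.
#' @export
classify_drug_interactions <- function(betas, k_treated_sd = 2,
                                       k_control_sd = 1, k_diff_sd = 1) {
  treated <- attr(betas, "treated") %||% "treated"
  untreated <- attr(betas, "untreated") %||% "untreated"
  bt_col <- paste0("beta_", treated)
  bu_col <- paste0("beta_", untreated)
  for (col in c(bt_col, bu_col, "differential")) {
    if (!col %in% names(betas)) {
      abort(sprintf("betas is missing '%s'; both conditions are required", col))
    }
  }
  bt <- betas[[bt_col]]; bu <- betas[[bu_col]]; bd <- betas$differential
  mt <- mean(bt); st <- sd(bt)
  mu <- mean(bu); su <- sd(bu)
  md <- mean(bd); sdd <- sd(bd)
  resistant <- bt > mt + k_treated_sd * st &
    abs(bu - mu) <= k_control_sd * su &
    bd > md + k_diff_sd * sdd
  sensitizing <- bt < mt - k_treated_sd * st &
    abs(bu - mu) <= k_control_sd * su &
    bd < md - k_diff_sd * sdd
  tibble(region_id = betas$region_id,
         call = dplyr::case_when(resistant ~ "resistant",
                                 sensitizing ~ "sensitizing",
                                 TRUE ~ "none"),
         !!bt_col := bt, !!bu_col := bu, differential = bd)
}
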