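counts_fixture <- function(m) {
  tibble::tibble(pair_id = sprintf("p%02d", seq_len(nrow(m))),
                 region_id = rep("R1", nrow(m))) |>
    dplyr::bind_cols(tibble::as_tibble(m))
}

test_that("median-ratio size factors match hand calculation and DESeq2", {
  m <- matrix(c(10, 20, 40,
                100, 200, 400,
                12, 30, 44), nrow = 3, byrow = TRUE,
              dimnames = list(NULL, c("s1", "s2", "s3")))
  cnt <- counts_fixture(m)
  norm <- normalize_median_ratio(cnt)
  # hand calculation: geometric means per row, column medians of ratios
  gm <- apply(m, 1, function(r) exp(mean(log(r))))
  sf_hand <- apply(m / gm, 2, median)
  expect_equal(unname(size_factors(norm)), unname(sf_hand))
  # independent cross-check against DESeq2's estimator
  skip_if_not_installed("DESeq2")
  sf_deseq <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(size_factors(norm)), unname(sf_deseq))
})

test_that("normalization fixes scaling and is exact on proportional columns", {
  m <- matrix(c(5, 10, 80, 33, 7, 120), ncol = 1)
  cnt <- counts_fixture(cbind(s1 = m[, 1], s2 = m[, 1]))
  norm <- normalize_median_ratio(cnt)
  expect_equal(unname(size_factors(norm)), c(1, 1))
  expect_equal(norm$s1, cnt$s1)

  cnt2 <- counts_fixture(cbind(a = m[, 1], b = 2 * m[, 1]))
  norm2 <- normalize_median_ratio(cnt2)
  sf <- size_factors(norm2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(norm2$a, norm2$b)

  zero <- counts_fixture(cbind(a = c(0, 5), b = c(3, 0)))
  expect_error(normalize_median_ratio(zero), "pseudocount")
})

test_that("guide scores use the pseudocounted log2 ratio with deterministic ties", {
  cnt <- counts_fixture(cbind(day0 = c(100, 50, 50), day15 = c(25, 50, 50)))
  norm <- normalize_median_ratio(cnt)
  sc <- score_guides(norm, "day0", "day15")
  # size factors are (1, 1) for this fixture, so the raw counts feed the ratio
  expect_equal(unname(size_factors(norm)), c(1, 1))
  expect_equal(sc$score[sc$pair_id == "p01"], log2(26 / 101))
  expect_equal(sc$score[sc$pair_id == "p02"], 0)
  # ties broken by pair_id
  expect_equal(sc$pair_id[sc$score == 0], c("p02", "p03"))
  expect_equal(sc$rank[order(sc$pair_id)][2:3], c(2L, 3L))
  expect_equal(sort(sc$percentile), sc$rank[order(sc$rank)] / 3)
})

test_that("rho follows the Beta order-statistic arithmetic", {
  # k = 5 pairs at global ranks 1-5 of m = 1000
  u <- (1:5) / 1000
  rho_expected <- min(pbeta(u, 1:5, 5:1 + 0)) # j, k - j + 1 with k = 5
  rho_expected2 <- min(vapply(1:5, function(j) pbeta(u[j], j, 5 - j + 1),
                              numeric(1)))
  expect_equal(rho_expected, rho_expected2)
  scores <- tibble::tibble(
    pair_id = sprintf("p%04d", 1:1000),
    region_id = c(rep("hit", 5), rep(NA, 995)),
    percentile = (1:1000) / 1000)
  res <- alpha_rra(scores, n_perm = 100, seed = 1)
  expect_equal(res$rho[res$region_id == "hit"], rho_expected2)
  expect_lt(res$rho[res$region_id == "hit"], 1e-6)
  expect_true(res$significant[res$region_id == "hit"])
})

test_that("regions with no percentile below alpha get rho 1 and are not significant", {
  scores <- tibble::tibble(
    pair_id = sprintf("p%03d", 1:100),
    region_id = c(rep(NA, 90), rep("late", 10)),
    percentile = (1:100) / 100)
  res <- alpha_rra(scores, alpha = 0.25, n_perm = 100, seed = 2)
  expect_equal(res$rho[res$region_id == "late"], 1)
  expect_false(res$significant[res$region_id == "late"])
})

test_that("permutation p-values converge to the exhaustive enumeration oracle", {
  # m = 6 percentiles, one region of k = 2: all C(6,2) = 15 subsets enumerable
  u <- c(0.02, 0.10, 0.35, 0.50, 0.70, 0.95)
  scores <- tibble::tibble(pair_id = sprintf("p%d", 1:6),
                           region_id = c("A", "A", NA, NA, NA, NA),
                           percentile = u)
  rho_obs <- oracle_rho(u[1:2], alpha = 0.25)
  combos <- utils::combn(6, 2)
  rho_all <- apply(combos, 2, function(ix) oracle_rho(u[ix], alpha = 0.25))
  p_exact <- mean(rho_all <= rho_obs)
  n_perm <- 4000
  res <- alpha_rra(scores, alpha = 0.25, n_perm = n_perm, seed = 3)
  mc_se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  # 3 MC s.e.: this fixed-seed assertion should not fail on an ordinary
  # 2-sigma Monte-Carlo fluctuation
  expect_lt(abs(res$p_perm[res$region_id == "A"] - p_exact),
            3 * mc_se + 2 / n_perm)
})

test_that("on fully null screens the BH-significant fraction stays controlled", {
  frac <- replicate(10, {
    seedling <- sample.int(1e6, 1)
    pairs <- tidyr::expand_grid(region_id = sprintf("R%02d", 1:40), g = 1:4) |>
      dplyr::mutate(pair_id = paste0(region_id, "_", g)) |>
      dplyr::select(pair_id, region_id)
    truth <- simulate_truth(dplyr::distinct(pairs, region_id),
                            frac_essential = 0, seed = seedling)
    cnt <- simulate_screen_counts(pairs, truth, depth_per_sample = 200L * 160L,
                                  seed = seedling + 1)
    norm <- normalize_median_ratio(cnt)
    sc <- score_guides(norm, "day0", "day15_untreated")
    res <- alpha_rra(sc, n_perm = 150, seed = seedling + 2)
    mean(res$fdr < 0.05)
  })
  n_total <- 10 * 40
  expect_lte(mean(frac), 0.05 + 2 * sqrt(0.05 * 0.95 / n_total))
})

test_that("beta scores recover planted selection coefficients", {
  set.seed(31)
  pairs <- tidyr::expand_grid(region_id = sprintf("R%02d", 1:40), g = 1:5) |>
    dplyr::mutate(pair_id = paste0(region_id, "_", g)) |>
    dplyr::select(pair_id, region_id)
  truth <- simulate_truth(dplyr::distinct(pairs, region_id),
                          frac_essential = 0, frac_resistant = 0.05,
                          drug_effect = 2 / 15, seed = 32)
  cnt <- simulate_screen_counts(pairs, truth, seed = 33)
  norm <- normalize_median_ratio(cnt)
  betas <- estimate_beta_scores(
    norm, c(day0 = "day0", day15_untreated = "untreated",
            day15_treated = "treated"))
  res_ids <- truth$region_id[truth$drug_class == "resistant"]
  expect_gt(length(res_ids), 0)
  expect_equal(mean(betas$beta_treated[betas$region_id %in% res_ids]), 2,
               tolerance = 0.2)
  expect_equal(mean(betas$beta_untreated[betas$region_id %in% res_ids]), 0,
               tolerance = 0.2)
  # differential is the definitional difference for every region
  expect_equal(betas$differential,
               betas$beta_treated - betas$beta_untreated)
  # a flat region has beta ~ 0 in all conditions
  null_ids <- truth$region_id[truth$drug_class == "none"]
  expect_lt(max(abs(betas$beta_untreated[betas$region_id %in% null_ids])), 0.5)
})

test_that("drug-interaction calls follow the threshold rules", {
  # constructed 100-region table: sd-scaled rules evaluated directly
  set.seed(41)
  n <- 100
  bt <- rnorm(n, 0, 0.2); bu <- rnorm(n, 0, 0.2)
  bt[1] <- mean(bt[-1]) + 3 * sd(bt[-1]) + 1 # clear resistant pattern
  bu[1] <- mean(bu[-1])
  betas <- structure(
    tibble::tibble(region_id = sprintf("R%03d", 1:n),
                   beta_treated = bt, beta_untreated = bu,
                   differential = bt - bu),
    class = c("pairdel_beta", "tbl_df", "tbl", "data.frame"),
    treated = "treated", untreated = "untreated")
  calls <- classify_drug_interactions(betas)
  expect_equal(calls$call[1], "resistant")
  expect_true(all(calls$call[-1] == "none"))

  # all betas identical -> sd 0 -> nothing called
  flat <- structure(
    tibble::tibble(region_id = c("a", "b"), beta_treated = c(1, 1),
                   beta_untreated = c(0, 0), differential = c(1, 1)),
    class = c("pairdel_beta", "tbl_df", "tbl", "data.frame"),
    treated = "treated", untreated = "untreated")
  expect_true(all(classify_drug_interactions(flat)$call == "none"))

  # equal strong depletion in both arms has differential ~ 0 -> none
  bt2 <- bt; bu2 <- bt
  both <- structure(
    tibble::tibble(region_id = sprintf("R%03d", 1:n), beta_treated = bt2,
                   beta_untreated = bu2, differential = bt2 - bu2),
    class = c("pairdel_beta", "tbl_df", "tbl", "data.frame"),
    treated = "treated", untreated = "untreated")
  expect_true(all(classify_drug_interactions(both)$call == "none"))

  # invariance to adding a constant to one condition's betas
  shifted <- betas
  shifted$beta_untreated <- shifted$beta_untreated + 5
  shifted$differential <- shifted$beta_treated - shifted$beta_untreated
  expect_identical(classify_drug_interactions(shifted)$call, calls$call)
})

test_that("tidy and glance expose results and autoplot returns ggplot objects", {
  scores <- tibble::tibble(pair_id = sprintf("p%03d", 1:100),
                           region_id = rep(sprintf("R%02d", 1:20), each = 5),
                           percentile = (1:100) / 100)
  res <- alpha_rra(scores, n_perm = 100, seed = 5)
  expect_s3_class(tidy(res), "tbl_df")
  expect_false(inherits(tidy(res), "pairdel_rra"))
  expect_equal(glance(res)$n_regions, 20)
  expect_s3_class(autoplot(res), "ggplot")

  flat <- structure(
    tibble::tibble(region_id = c("a", "b"), beta_treated = c(1, 0),
                   beta_untreated = c(0, 0), differential = c(1, 0)),
    class = c("pairdel_beta", "tbl_df", "tbl", "data.frame"),
    treated = "treated", untreated = "untreated",
    condition_stats = tibble::tibble(condition = c("treated", "untreated"),
                                     mean = c(0.5, 0), sd = c(0.7, 0)))
  expect_s3_class(autoplot(flat), "ggplot")
  expect_equal(glance(flat)$n_regions, 2)
})
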