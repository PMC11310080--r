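cap_matrix <- function(...) {
  # build a small pair x cell capture matrix from named cell columns
  cols <- list(...)
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  m
}

test_that("assignment follows the min-UMI + dominance rule with fate conservation", {
  cap <- cap_matrix(c1 = c(P1 = 10, P2 = 0, P3 = 0),
                    c2 = c(P1 = 10, P2 = 9, P3 = 0),
                    c3 = c(P1 = 0, P2 = 0, P3 = 0),
                    c4 = c(P1 = 2, P2 = 0, P3 = 0),
                    c5 = c(P1 = 40, P2 = 2, P3 = 1))
  expr <- matrix(rpois(3 * 5, 5), nrow = 3,
                 dimnames = list(paste0("g", 1:3), colnames(cap)))
  asg <- assign_perturbations(cap, expr)
  expect_equal(asg$label[asg$cell == "c1"], "P1")       # single pair, 10 UMIs
  expect_equal(asg$label[asg$cell == "c2"], "multiplet") # 10/19 < 0.8
  expect_equal(asg$label[asg$cell == "c3"], "unassigned")
  expect_equal(asg$label[asg$cell == "c4"], "unassigned") # below min_umi
  expect_equal(asg$label[asg$cell == "c5"], "P1")       # 40/43 > 0.8
  expect_equal(nrow(asg), ncol(cap)) # every cell gets exactly one label
  expect_true(all(is.finite(asg$log_genes_on)))
})

test_that("guide-level capture features aggregate through the design to pairs", {
  design <- tibble::tibble(pair_id = c("P1", "P2"),
                           guide_id_u6 = c("gA", "gC"),
                           guide_id_h1 = c("gB", "gD"))
  cap <- cap_matrix(c1 = c(gA = 4, gB = 5, gC = 0, gD = 0),
                    c2 = c(gA = 0, gB = 0, gC = 1, gD = 1))
  expr <- matrix(1, nrow = 2, ncol = 2,
                 dimnames = list(c("g1", "g2"), c("c1", "c2")))
  asg <- assign_perturbations(cap, expr, design = design)
  expect_equal(asg$label, c("P1", "unassigned"))
  expect_equal(asg$top_umi[1], 9) # 4 + 5 summed to pair level

  bad_cap <- cap; colnames(bad_cap) <- c("c1", "cX")
  expect_error(assign_perturbations(bad_cap, expr), "mismatch")
})

test_that("log-normalization matches its closed form and is depth invariant", {
  counts <- matrix(c(0, 5, 5, 10), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("c1", "c2")))
  norm <- lognormalize_cells(counts)
  expect_equal(norm[1, 1], 0)
  expect_equal(norm[2, 1], log(1 + 1e4)) # count equals the cell total
  expect_equal(norm[1, 2], log(1 + 1e4 * 5 / 15))
  # doubling all counts in a cell leaves values unchanged
  norm2 <- lognormalize_cells(counts %*% diag(c(2, 1)))
  expect_equal(as.matrix(norm2), as.matrix(norm), ignore_attr = TRUE)
  # zero-total cells are dropped with a warning
  counts0 <- cbind(counts, c3 = c(0, 0))
  expect_warning(norm0 <- lognormalize_cells(counts0), "zero-total")
  expect_equal(ncol(norm0), 2)
})

test_that("hurdle DE skips low-expression genes and recovers planted knockdowns", {
  ce <- tibble::tibble(pair_id = "T1", gene = "gene_010", knockdown = 0.5)
  sim <- simulate_single_cell("T1", cells_per_target = 120,
                              control_pairs = sprintf("AAVS1_p%02d", 1:5),
                              n_control_cells = 500, n_genes = 40,
                              cis_effects = ce, seed = 51)
  asg <- assign_perturbations(sim$capture, sim$expression)
  norm <- lognormalize_cells(sim$expression)
  de <- hurdle_de(norm, asg, "T1", sprintf("AAVS1_p%02d", 1:5))
  expect_s3_class(de, "pairdel_hurdle")
  expect_true(all(de$p > 0 & de$p <= 1))
  hit <- de[de$gene == "gene_010", ]
  expect_lt(hit$padj, 0.05)
  expect_lt(hit$lfc, -0.5)

  # a gene with mean normalized expression below 0.01 is skipped
  norm2 <- norm
  norm2["gene_001", ] <- 0
  norm2["gene_001", 1] <- 0.001
  de2 <- hurdle_de(norm2, asg, "T1", sprintf("AAVS1_p%02d", 1:5))
  expect_false("gene_001" %in% de2$gene)

  expect_error(hurdle_de(norm, asg, "no_such_pair",
                         sprintf("AAVS1_p%02d", 1:5)), "2 cells")
})

test_that("planted knockdown gradations recover monotone fold changes", {
  ce <- tibble::tibble(pair_id = c("T1", "T2", "T3"),
                       gene = c("gene_010", "gene_010", "gene_010"),
                       knockdown = c(0.25, 0.5, 0.75))
  for (rep_seed in c(61, 62, 63)) {
    sim <- simulate_single_cell(c("T1", "T2", "T3"), cells_per_target = 100,
                                control_pairs = sprintf("AAVS1_p%02d", 1:5),
                                n_control_cells = 400, n_genes = 30,
                                cis_effects = ce, seed = rep_seed)
    asg <- assign_perturbations(sim$capture, sim$expression)
    norm <- lognormalize_cells(sim$expression)
    lfcs <- vapply(c("T1", "T2", "T3"), function(t) {
      de <- hurdle_de(norm, asg, t, sprintf("AAVS1_p%02d", 1:5))
      de$lfc[de$gene == "gene_010"]
    }, numeric(1))
    expect_true(all(diff(lfcs) < 0)) # deeper knockdown, lower LFC
  }
})

test_that("hurdle LRT is calibrated on permuted labels (QQ slope near 1)", {
  set.seed(71)
  sim <- simulate_single_cell("T1", cells_per_target = 250,
                              control_pairs = "C1", n_control_cells = 250,
                              n_genes = 400, cis_effects = NULL, seed = 72)
  asg <- assign_perturbations(sim$capture, sim$expression)
  # permute labels among assigned cells to build an exact null
  assigned <- asg$label %in% c("T1", "C1")
  asg$label[assigned] <- sample(asg$label[assigned])
  norm <- lognormalize_cells(sim$expression)
  de <- hurdle_de(norm, asg, "T1", "C1")
  lrt2 <- de$lrt[de$df == 2]
  qq_obs <- quantile(lrt2, probs = seq(0.1, 0.9, by = 0.1))
  qq_exp <- qchisq(seq(0.1, 0.9, by = 0.1), df = 2)
  slope <- unname(coef(lm(qq_obs ~ 0 + qq_exp)))
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})

test_that("complete separation in the detection part falls back to 1 df, flagged", {
  set.seed(81)
  n_t <- 30; n_c <- 30
  cells <- sprintf("c%03d", 1:(n_t + n_c))
  asg <- tibble::tibble(cell = cells,
                        label = c(rep("T1", n_t), rep("C1", n_c)),
                        top_umi = 10L, top_frac = 1,
                        log_genes_on = log1p(rpois(n_t + n_c, 50)),
                        log_guide_umi = log1p(rpois(n_t + n_c, 10)))
  # gene g1: detected in every target cell, never in controls -> separation
  m <- rbind(g1 = c(rlnorm(n_t, 1, 0.2), rep(0, n_c)),
             g2 = rlnorm(n_t + n_c, 1, 0.3))
  colnames(m) <- cells
  norm <- as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  de <- hurdle_de(norm, asg, "T1", "C1")
  g1 <- de[de$gene == "g1", ]
  expect_equal(g1$df, 1L)
  expect_equal(g1$flag, "fallback_1df")
})

test_that("cis windows honour TAD boundaries and the +/- 1 Mb fallback", {
  region <- tibble::tibble(region_id = "R1", chrom = "chr1",
                           start = 5e6, end = 5.001e6)
  genes <- tibble::tibble(
    gene = c("near", "far", "adjacent_tad"),
    chrom = "chr1",
    start = c(5.5e6, 6.6e6, 4.2e6),
    end = c(5.51e6, 6.61e6, 4.21e6))
  res <- tibble::tibble(gene = genes$gene, lfc = c(-1, 0.2, 0.1),
                        p = c(0.001, 0.5, 0.6), padj = c(0.003, 0.6, 0.7))
  # no TADs: the +/- 1 Mb window keeps near (0.5 Mb) and adjacent_tad (0.8 Mb)
  rep_win <- cis_window_report(res, region, genes)
  expect_setequal(rep_win$gene, c("near", "adjacent_tad"))
  expect_true(all(rep_win$mode == "window"))
  # with a TAD covering [4.5, 6] Mb, adjacent_tad (in the neighbouring TAD,
  # though within 1 Mb) is excluded
  tads <- tibble::tibble(chrom = "chr1",
                         start = c(3e6, 4.5e6), end = c(4.5e6, 6e6))
  rep_tad <- cis_window_report(res, region, genes, tads = tads)
  expect_setequal(rep_tad$gene, "near")
  expect_true(all(rep_tad$mode == "tad"))
  expect_equal(rep_tad$lfc[rep_tad$gene == "near"], -1)
  # region outside all TADs falls back to the window with a warning
  region_out <- tibble::tibble(region_id = "R2", chrom = "chr1",
                               start = 8e6, end = 8.001e6)
  expect_warning(rep_fb <- cis_window_report(res, region_out, genes,
                                             tads = tads), "falling back")
  expect_true(all(rep_fb$mode == "window"))
})

test_that("assignment conservation and multiplet rate hold on simulated data", {
  sim <- simulate_single_cell(c("T1", "T2"), cells_per_target = 200,
                              control_pairs = "C1", n_control_cells = 400,
                              n_genes = 20, multiplet_rate = 0.05, seed = 91)
  asg <- assign_perturbations(sim$capture, sim$expression)
  expect_equal(nrow(asg), ncol(sim$expression))
  frac_mult <- mean(asg$label == "multiplet")
  n <- nrow(asg)
  expect_lt(abs(frac_mult - 0.05), 2 * sqrt(0.05 * 0.95 / n) + 0.01)
})
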