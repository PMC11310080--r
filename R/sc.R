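#' Assign deletion perturbations to single cells
#'
#' Per cell, guide-capture UMIs are summed to pair level (the two guides of a
#' pair), and the cell is assigned to its top pair when that pair has at least
#' `min_umi` UMIs and holds at least a `dominance` fraction of all pair UMIs
#' in the cell. Cells with two or more pairs passing `min_umi` but no dominant
#' pair are multiplets; cells with no pair passing are unassigned. Per-cell
#' covariates for the hurdle model (log total expressed genes, log total guide
#' UMIs) are computed from the expression matrix.
#'
#' @param capture Guide-capture UMI matrix (features x cells). Rows may be
#'   pair ids, or guide ids resolvable through `design` (columns
#'   `guide_id_u6`, `guide_id_h1`).
#' @param expression Gene expression count matrix (genes x cells) sharing the
#'   cell barcodes of `capture`.
#' @param design Optional design tibble used to map guide-level rows to pairs.
#' @param min_umi Minimum pair UMIs for a pair to count as present (default 3).
#' @param dominance Minimum fraction of the cell's pair UMIs held by the top
#'   pair for assignment (default 0.8).
#' @return Tibble: `cell`, `label` (pair id, `"multiplet"` or
#'   `"unassigned"`), `top_umi`, `top_frac`, `log_genes_on`, `log_guide_umi`.
#' @export
assign_perturbations <- function(capture, expression, design = NULL,
                                 min_umi = 3L, dominance = 0.8) {
  capture <- as_sparse(capture)
  expression <- as_sparse(expression)
  missing <- setdiff(colnames(capture), colnames(expression))
  if (length(missing) > 0 || ncol(capture) != ncol(expression)) {
    abort(sprintf("capture/expression barcode mismatch; %d capture barcodes missing from expression (e.g. %s)",
                  length(missing), paste(head(missing, 3), collapse = ", ")))
  }
  expression <- expression[, colnames(capture), drop = FALSE]

  feats <- rownames(capture)
  if (!is.null(design) && any(feats %in% c(design$guide_id_u6,
                                           design$guide_id_h1))) {
    pair_of <- c(setNames(design$pair_id, design$guide_id_u6),
                 setNames(design$pair_id, design$guide_id_h1))
    unknown <- setdiff(feats, names(pair_of))
    if (length(unknown) > 0) {
      abort(sprintf("capture features not in the design: %s",
                    paste(head(unknown, 3), collapse = ", ")))
    }
    grp <- factor(pair_of[feats])
    agg <- Matrix::sparseMatrix(i = as.integer(grp), j = seq_along(feats),
                                x = 1, dims = c(nlevels(grp), length(feats)))
    pair_umi <- as_sparse(agg %*% capture)
    rownames(pair_umi) <- levels(grp)
  } else {
    pair_umi <- capture
  }

  dense <- as.matrix(pair_umi)
  total <- unname(colSums(dense))
  top_idx <- unname(apply(dense, 2, which.max))
  top_umi <- unname(dense[cbind(top_idx, seq_len(ncol(dense)))])
  top_frac <- ifelse(total > 0, top_umi / total, 0)
  n_pass <- unname(colSums(dense >= min_umi))

  label <- ifelse(top_umi >= min_umi & top_frac >= dominance,
                  rownames(dense)[top_idx],
                  ifelse(n_pass >= 2, "multiplet", "unassigned"))

  tibble(cell = colnames(pair_umi),
         label = label,
         top_umi = as.integer(top_umi),
         top_frac = top_frac,
         log_genes_on = log1p(Matrix::colSums(expression > 0)),
         log_guide_umi = log1p(total))
}

#' Log-normalize a single-cell expression matrix
#'
#' Per-cell depth normalization followed by log transform:
#' `ln(1 + 10000 * count / cell_total)`. Zero counts map to zero and the
#' transform is invariant to rescaling a cell's depth. Zero-total cells are
#' dropped with a warning.
#'
#' @param counts Gene x cell count matrix (dense or sparse).
#' @param scale_factor Depth scale factor (default 10,000).
#' @return Sparse normalized matrix (genes x cells).
#' @export
lognormalize_cells <- function(counts, scale_factor = 1e4) {
  counts <- as_sparse(counts)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    warn(sprintf("dropping %d zero-total cell(s)", sum(totals == 0)))
    counts <- counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / totals)
  norm@x <- log1p(norm@x)
  colnames(norm) <- colnames(counts)
  rownames(norm) <- rownames(counts)
  norm
}

# Gaussian log-likelihood of an lm fit given residual sum of squares.
gauss_ll <- function(rss, n) -n / 2 * (log(2 * pi) + log(rss / n) + 1)

#' Two-part hurdle-model differential expression for one perturbation
#'
#' Compares cells assigned to `target_pairs` against cells assigned to
#' `control_pairs`. Genes with mean normalized expression below
#' `min_mean_expr` across the tested cells, or detected in fewer than
#' `min_detect_frac` of cells in both groups, are skipped. For each remaining
#' gene two models are fitted, both with the per-cell covariates
#' `log_genes_on` and `log_guide_umi`: a logistic regression of detection on
#' group, and a Gaussian linear model of normalized expression among detected
#' cells. The test statistic is the summed likelihood-ratio deviance drop from
#' removing the group term in both parts, referred to a chi-square with 2
#' degrees of freedom. When the detection part is degenerate (complete
#' separation) or the continuous part is inestimable, the statistic falls back
#' to the available part with 1 df and the gene is flagged. BH correction is
#' applied across tested genes.
#'
#' @param norm Normalized matrix from [lognormalize_cells()].
#' @param assignment Tibble from [assign_perturbations()].
#' @param target_pairs Pair id(s) defining the perturbed group.
#' @param control_pairs Pair id(s) defining the control group.
#' @param min_mean_expr Mean normalized expression filter (default 0.01).
#' @param min_detect_frac Detection-fraction filter (default 0.05).
#' @return A `pairdel_hurdle` tibble: `gene`, `lrt`, `df`, `p`, `padj`,
#'   `lfc` (log2 ratio of group means of normalized expression),
#'   `coef_detection`, `coef_continuous`, `flag`.
#' @export
hurdle_de <- function(norm, assignment, target_pairs, control_pairs,
                      min_mean_expr = 0.01, min_detect_frac = 0.05) {
  cells_t <- assignment$cell[assignment$label %in% target_pairs]
  cells_c <- assignment$cell[assignment$label %in% control_pairs]
  if (length(cells_t) < 2 || length(cells_c) < 2) {
    abort("need at least 2 cells per group")
  }
  cells <- c(cells_t, cells_c)
  group <- c(rep(1, length(cells_t)), rep(0, length(cells_c)))
  sub <- as.matrix(norm[, cells, drop = FALSE])
  cov <- assignment[match(cells, assignment$cell), ]

  mean_all <- rowMeans(sub)
  det_t <- rowMeans(sub[, group == 1, drop = FALSE] > 0)
  det_c <- rowMeans(sub[, group == 0, drop = FALSE] > 0)
  test_genes <- which(mean_all >= min_mean_expr &
                        (det_t >= min_detect_frac | det_c >= min_detect_frac))

  X1 <- cbind(1, group, cov$log_genes_on, cov$log_guide_umi)
  X0 <- X1[, -2, drop = FALSE]
  colnames(X1) <- c("(Intercept)", "group", "log_genes_on", "log_guide_umi")

  fit_gene <- function(y) {
    flag <- ""
    detected <- y > 0
    # detection part
    f1 <- suppressWarnings(glm.fit(X1, detected, family = binomial()))
    f0 <- suppressWarnings(glm.fit(X0, detected, family = binomial()))
    lrt_det <- max(0, f0$deviance - f1$deviance)
    coef_det <- f1$coefficients[["group"]]
    separated <- !f1$converged || abs(coef_det) > 15 ||
      all(detected) || !any(detected)
    # continuous part among detected cells
    lrt_cont <- NA_real_
    coef_cont <- NA_real_
    nd <- sum(detected)
    both_groups <- nd > 4 && length(unique(group[detected])) == 2
    if (both_groups) {
      Xd1 <- X1[detected, , drop = FALSE]
      Xd0 <- X0[detected, , drop = FALSE]
      yd <- y[detected]
      l1 <- lm.fit(Xd1, yd)
      l0 <- lm.fit(Xd0, yd)
      rss1 <- sum(l1$residuals^2)
      rss0 <- sum(l0$residuals^2)
      if (rss1 > 0) {
        lrt_cont <- max(0, 2 * (gauss_ll(rss1, nd) - gauss_ll(rss0, nd)))
        coef_cont <- l1$coefficients[["group"]]
      }
    }
    if (separated && !is.na(lrt_cont)) {
      flag <- "detection_separated"
      lrt <- lrt_cont; df <- 1L
    } else if (is.na(lrt_cont)) {
      flag <- "continuous_unfit"
      lrt <- lrt_det; df <- 1L
    } else {
      lrt <- lrt_det + lrt_cont; df <- 2L
    }
    c(lrt = lrt, df = df, coef_detection = coef_det,
      coef_continuous = coef_cont, flagged = as.integer(nzchar(flag)))
  }

  res <- t(vapply(test_genes, function(g) fit_gene(sub[g, ]), numeric(5)))
  rownames(res) <- NULL
  genes <- unname(rownames(sub)[test_genes] %||% as.character(test_genes))
  # fold change of the group means of depth-normalized (linear-scale)
  # expression, reported in log2
  mean_t <- rowMeans(expm1(sub[test_genes, group == 1, drop = FALSE]))
  mean_c <- rowMeans(expm1(sub[test_genes, group == 0, drop = FALSE]))
  out <- tibble(
    gene = genes,
    lrt = res[, "lrt"],
    df = as.integer(res[, "df"]),
    p = pchisq(res[, "lrt"], df = res[, "df"], lower.tail = FALSE),
    lfc = log2(mean_t / mean_c),
    coef_detection = res[, "coef_detection"],
    coef_continuous = res[, "coef_continuous"],
    flag = ifelse(res[, "flagged"] == 1, "fallback_1df", "")) |>
    mutate(padj = p.adjust(.data$p, "BH")) |>
    relocate("padj", .after = "p") |>
    arrange(.data$p, .data$gene)
  structure(out, class = c("pairdel_hurdle", class(out)),
            n_target = length(cells_t), n_control = length(cells_c))
}

#' Report cis-window neighbours of a region with their DE results
#'
#' Selects genes whose bodies intersect the TAD containing the region
#' (midpoint containment) when TADs are supplied, or the +/- `window_bp`
#' interval around the region otherwise; a region outside all TADs falls back
#' to the window with a warning. DE results are attached by gene and the
#' report is ordered by genomic position.
#'
#' @param results A `pairdel_hurdle` tibble (or any tibble with `gene` and
#'   test columns).
#' @param region One-row tibble `region_id`, `chrom`, `start`, `end`.
#' @param gene_annotations Tibble `gene`, `chrom`, `start`, `end`.
#' @param tads Optional tibble `chrom`, `start`, `end`.
#' @param window_bp Half-width of the fallback window (default 1e6).
#' @return Tibble of neighbour genes with coordinates, `lfc`, `p`, `padj`
#'   (NA when untested) and the window mode used.
#' @export
cis_window_report <- function(results, region, gene_annotations, tads = NULL,
                              window_bp = 1e6) {
  mid <- (region$start + region$end) / 2
  mode <- "window"
  win_start <- region$start - window_bp
  win_end <- region$end + window_bp
  if (!is.null(tads) && nrow(tads) > 0) {
    hit <- which(tads$chrom == region$chrom & tads$start <= mid &
                   mid < tads$end)
    if (length(hit) > 0) {
      mode <- "tad"
      win_start <- tads$start[hit[1]]
      win_end <- tads$end[hit[1]]
    } else {
      warn(sprintf("region %s lies outside all TADs; falling back to +/- %g bp window",
                   region$region_id, window_bp))
    }
  }
  neigh <- gene_annotations |>
    filter(.data$chrom == region$chrom,
           .data$start < win_end, .data$end > win_start) |>
    arrange(.data$start)
  res_cols <- intersect(c("lfc", "p", "padj"), names(results))
  neigh |>
    left_join(as_tibble(results)[, c("gene", res_cols)], by = "gene") |>
    mutate(region_id = region$region_id, mode = mode,
           window_start = win_start, window_end = win_end)
}
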