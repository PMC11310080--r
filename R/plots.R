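#' Plot region-level rank-aggregation results
#'
#' Rank plot of -log10(rho) per region with the significance cut-off drawn as
#' a dashed line (the screen's Manhattan-style overview).
#'
#' @param object A `pairdel_rra`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pairdel_rra
#' @export
autoplot.pairdel_rra <- function(object, ...) {
  cutoff <- attr(object, "rho_cutoff") %||% 0.01
  df <- tidy(object) |>
    arrange(.data$rho) |>
    mutate(idx = row_number(),
           neglog = -log10(pmax(.data$rho, 1e-16)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$neglog,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(cutoff), linetype = "dashed") +
    ggplot2::labs(x = "regions (ranked)", y = expression(-log[10](rho)),
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Plot beta scores with drug-interaction calls
#'
#' Treated versus untreated beta scores per region; when a call table from
#' [classify_drug_interactions()] is supplied, points are coloured by call.
#'
#' @param object A `pairdel_beta`.
#' @param calls Optional call tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pairdel_beta
#' @export
autoplot.pairdel_beta <- function(object, calls = NULL, ...) {
  treated <- attr(object, "treated") %||% "treated"
  untreated <- attr(object, "untreated") %||% "untreated"
  df <- tidy(object)
  if (!is.null(calls)) {
    df <- left_join(df, calls |> select("region_id", "call"), by = "region_id")
  } else {
    df$call <- "none"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[paste0("beta_", untreated)]],
                                   y = .data[[paste0("beta_", treated)]],
                                   colour = .data$call)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = sprintf("beta (%s)", untreated),
                  y = sprintf("beta (%s)", treated)) +
    ggplot2::theme_minimal()
}

#' Volcano plot of hurdle-model differential expression
#'
#' @param object A `pairdel_hurdle`.
#' @param padj_cutoff Highlight threshold (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pairdel_hurdle
#' @export
autoplot.pairdel_hurdle <- function(object, padj_cutoff = 0.05, ...) {
  df <- tidy(object) |>
    mutate(sig = .data$padj < padj_cutoff)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lfc,
                                   y = -log10(pmax(.data$p, 1e-300)),
                                   colour = .data$sig)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(log[2] ~ "fold change"),
                  y = expression(-log[10](p)), colour = "significant") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
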