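#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and summarize fitted screen objects
#'
#' `tidy()` returns the per-unit result table as a plain tibble; `glance()`
#' returns a one-row summary.
#'
#' @param x A `pairdel_rra`, `pairdel_beta` or `pairdel_hurdle` object.
#' @param ... Unused.
#' @return A tibble.
#' @name pairdel-tidiers
NULL

#' @rdname pairdel-tidiers
#' @method tidy pairdel_rra
#' @export
tidy.pairdel_rra <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @rdname pairdel-tidiers
#' @method glance pairdel_rra
#' @export
glance.pairdel_rra <- function(x, ...) {
  tibble(n_regions = nrow(x),
         n_significant = sum(x$significant),
         alpha = attr(x, "alpha"),
         n_perm = attr(x, "n_perm"),
         rho_cutoff = attr(x, "rho_cutoff"))
}

#' @rdname pairdel-tidiers
#' @method tidy pairdel_beta
#' @export
tidy.pairdel_beta <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @rdname pairdel-tidiers
#' @method glance pairdel_beta
#' @export
glance.pairdel_beta <- function(x, ...) {
  stats <- attr(x, "condition_stats")
  tidyr::pivot_wider(stats, names_from = "condition",
                     values_from = c("mean", "sd")) |>
    mutate(n_regions = nrow(x))
}

#' @rdname pairdel-tidiers
#' @method tidy pairdel_hurdle
#' @export
tidy.pairdel_hurdle <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @rdname pairdel-tidiers
#' @method glance pairdel_hurdle
#' @export
glance.pairdel_hurdle <- function(x, ...) {
  tibble(n_genes_tested = nrow(x),
         n_significant = sum(x$padj < 0.05),
         n_flagged = sum(nzchar(x$flag)),
         n_target_cells = attr(x, "n_target"),
         n_control_cells = attr(x, "n_control"))
}

unclass_result <- function(x) {
  cls <- class(x)
  class(x) <- cls[!startsWith(cls, "pairdel_")]
  x
}
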