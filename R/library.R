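#' Build a complete paired-guide deletion library
#'
#' Runs the full design pipeline: score/exclusion filtering, flanking-pair
#' design with internal-pair fallback per region, deduplication of identical
#' protospacer pairs, barcode assignment (v2) and oligo assembly, plus
#' user-supplied control pairs.
#'
#' @param regions Tibble of target regions (`region_id`, `chrom`, `start`,
#'   `end`, optional `kind`).
#' @param guide_table Tibble of pre-scored candidate guides (see
#'   [filter_guides()] for required columns).
#' @param version Cassette/oligo version, `"v2"` (default) or `"v1"`.
#' @param controls Optional tibble of explicit control guide pairs with the
#'   same columns as designed pairs (`region_id` may name a control class);
#'   taken verbatim, strategy set to `"control"`.
#' @param exclusions,splice_sites,thresholds Passed to [filter_guides()].
#' @param flank_bp,max_per_flank Passed to [design_flanking_pairs()].
#' @param n_internal Passed to [design_internal_pairs()] as `n_target`.
#' @param barcode_seed Seed for the barcode generator (v2).
#' @return An object of class `pairdel_library`: a list with tibbles
#'   `regions`, `pairs` (designed + controls, with `strategy`), `oligos`,
#'   and a `summary` tibble of per-region strategy and pair counts.
#' @export
build_library <- function(regions, guide_table, version = c("v2", "v1"),
                          controls = NULL, exclusions = NULL,
                          splice_sites = NULL,
                          thresholds = list(efficacy = 0.15, top5 = 47,
                                            top10 = 50),
                          flank_bp = 200L, max_per_flank = 5L,
                          n_internal = 14L, barcode_seed = 1L) {
  version <- match.arg(version)
  if (anyDuplicated(regions$region_id)) {
    abort(sprintf("duplicate region_id: %s",
                  paste(unique(regions$region_id[duplicated(regions$region_id)]),
                        collapse = ", ")))
  }
  guides <- filter_guides(guide_table, exclusions = exclusions,
                          splice_sites = splice_sites,
                          thresholds = thresholds)
  # drop guides that cannot be synthesized (type-IIS site in protospacer)
  has_site <- vapply(guides$protospacer, function(p) {
    any(vapply(FORBIDDEN_SITES, grepl, logical(1), x = toupper(p)))
  }, logical(1))
  n_dropped_sites <- sum(has_site)
  guides <- guides[!has_site, , drop = FALSE]

  pairs <- vector("list", nrow(regions))
  strategy <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    region <- regions[i, ]
    p <- withCallingHandlers(
      design_flanking_pairs(region, guides, flank_bp = flank_bp,
                            max_per_flank = max_per_flank),
      warning = function(w) invokeRestart("muffleWarning"))
    if (nrow(p) == 0) {
      p <- withCallingHandlers(
        design_internal_pairs(region, guides, n_target = n_internal),
        warning = function(w) invokeRestart("muffleWarning"))
    }
    strategy[i] <- if (nrow(p) == 0) "undesignable" else p$strategy[1]
    pairs[[i]] <- p
  }
  pairs <- list_rbind(pairs)

  # deduplicate identical protospacer pairs (keep first pair_id)
  pairs <- pairs[!duplicated(pairs[, c("protospacer_u6", "protospacer_h1")]), ,
                 drop = FALSE]

  if (!is.null(controls) && nrow(controls) > 0) {
    controls <- controls |> mutate(strategy = "control")
    pairs <- bind_rows(pairs, controls)
  } else {
    warn("no control pairs supplied; library has an empty control section")
  }
  if (anyDuplicated(pairs$pair_id)) {
    abort("duplicate pair_id after adding controls")
  }

  barcodes <- if (version == "v2") {
    generate_barcodes(nrow(pairs), seed = barcode_seed)
  } else {
    rep("", nrow(pairs))
  }
  oligos <- list_rbind(map(seq_len(nrow(pairs)), function(i) {
    assemble_oligo(pairs[i, ], version = version,
                   barcode = if (version == "v2") barcodes[i] else NULL)
  }))

  summary <- tibble(region_id = regions$region_id, strategy = strategy) |>
    left_join(pairs |> filter(.data$strategy != "control") |>
                dplyr::count(.data$region_id, name = "n_pairs"),
              by = "region_id") |>
    mutate(n_pairs = tidyr::replace_na(.data$n_pairs, 0L))

  structure(list(regions = regions, pairs = pairs, oligos = oligos,
                 summary = summary, version = version,
                 n_guides_dropped_restriction = n_dropped_sites),
            class = "pairdel_library")
}

#' @export
print.pairdel_library <- function(x, ...) {
  cat(sprintf("<pairdel_library %s>: %d regions, %d pairs (%d controls), %d oligos\n",
              x$version, nrow(x$regions), nrow(x$pairs),
              sum(x$pairs$strategy == "control"), nrow(x$oligos)))
  print(x$summary, n = 5)
  invisible(x)
}

#' Write / read a library design table
#'
#' The design TSV is the hand-off between design and counting: one row per
#' pair with region, strategy, both guide sequences, barcode and expected
#' deletion interval (0-based half-open).
#'
#' @param library A `pairdel_library` from [build_library()].
#' @param path Output TSV path.
#' @return `write_design()` returns `path` invisibly; `read_design()` returns
#'   the design tibble.
#' @export
write_design <- function(library, path) {
  design <- library$pairs |>
    left_join(library$oligos |> select("pair_id", "barcode"), by = "pair_id")
  readr::write_tsv(design, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(barcode = readr::col_character())) |>
    mutate(barcode = dplyr::coalesce(.data$barcode, ""))
}

#' Write the oligo pool as FASTA
#'
#' @param library A `pairdel_library`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_oligo_fasta <- function(library, path) {
  seqs <- Biostrings::DNAStringSet(library$oligos$sequence)
  names(seqs) <- library$oligos$pair_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Expected per-construct screen coverage
#'
#' Simple screen-planning arithmetic: the expected number of transduced cells
#' carrying each construct, `cells_infected * moi / n_constructs`.
#'
#' @param cells_infected Number of cells exposed to the library.
#' @param moi Multiplicity of infection.
#' @param n_constructs Number of distinct guide pairs in the library.
#' @return Expected fold coverage (cells per construct).
#' @export
#' @examples
#' screen_coverage(1.5e8, 0.2, 63879)
screen_coverage <- function(cells_infected, moi, n_constructs) {
  cells_infected * moi / n_constructs
}
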