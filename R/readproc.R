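#' Extract the 20-nt protospacer from an amplicon read
#'
#' Locates the side's promoter anchor (U6: `ATATATCTTGTGGAAAGGACGAAA`, H1:
#' `ATAAGTTCTGTATGAGACCACTCTT`) anywhere in the read allowing up to
#' `max_anchor_mismatches`, skips the fixed junction bases (`CACCG` / `TCCCG`),
#' and takes the next 20 nt as the protospacer. The following 20 bp must match
#' the scaffold prefix with at most one mismatch; when that fails, positions
#' 21-30 of the scaffold (the tracrRNA identifying sequence `AAGTTAAAAT`) are
#' checked as a fallback. Reads failing the anchor search are fated
#' `no_anchor`; reads failing the scaffold check (or too short to contain
#' protospacer + scaffold) are fated `no_scaffold`.
#'
#' @param reads Character vector or `DNAStringSet` of reads.
#' @param side `"U6"` or `"H1"`.
#' @param max_anchor_mismatches Mismatches tolerated in the anchor (default 1).
#' @return Tibble with columns `protospacer` (NA on failure) and `status`
#'   (`"ok"`, `"no_anchor"` or `"no_scaffold"`).
#' @export
extract_protospacer <- function(reads, side = c("U6", "H1"),
                                max_anchor_mismatches = 1L) {
  side <- match.arg(side)
  anchor <- if (side == "U6") U6_ANCHOR else H1_ANCHOR
  junction <- if (side == "U6") U6_JUNCTION else H1_JUNCTION
  if (!methods::is(reads, "DNAStringSet")) {
    reads <- Biostrings::DNAStringSet(toupper(as.character(reads)))
  }
  n <- length(reads)
  if (n == 0) return(tibble(protospacer = character(), status = character()))

  m <- Biostrings::vmatchPattern(anchor, reads,
                                 max.mismatch = max_anchor_mismatches)
  starts <- Biostrings::startIndex(m)
  a_start <- vapply(starts, function(s) if (is.null(s) || length(s) == 0)
    NA_integer_ else s[1], integer(1))

  status <- rep("ok", n)
  proto <- rep(NA_character_, n)
  status[is.na(a_start)] <- "no_anchor"

  idx <- which(!is.na(a_start))
  if (length(idx) > 0) {
    rs <- as.character(reads[idx])
    p_start <- a_start[idx] + nchar(anchor) + nchar(junction)
    too_short <- nchar(rs) < p_start + 40 - 1
    status[idx[too_short]] <- "no_scaffold"
    ok <- which(!too_short)
    if (length(ok) > 0) {
      i <- idx[ok]
      ps <- p_start[ok]
      prot <- substr(rs[ok], ps, ps + 19)
      scaf20 <- substr(rs[ok], ps + 20, ps + 39)
      tracr10 <- substr(rs[ok], ps + 40, ps + 49)
      pass <- hamming_to(scaf20, SCAFFOLD_PREFIX) <= 1
      # fallback: tracrRNA identifying sequence at scaffold positions 21-30
      need_fb <- !pass & nchar(tracr10) == 10
      if (any(need_fb)) {
        pass[need_fb] <- hamming_to(tracr10[need_fb], TRACR_ID) <= 1
      }
      proto[i[pass]] <- prot[pass]
      status[i[!pass]] <- "no_scaffold"
    }
  }
  tibble(protospacer = proto, status = status)
}

#' Build a paired protospacer reference from a design table
#'
#' @param design Design tibble (from [read_design()] or
#'   `pairdel_library$pairs`) with `pair_id`, `protospacer_u6`,
#'   `protospacer_h1`.
#' @return An object of class `paired_reference` used by [match_pair()] and
#'   [count_sample()].
#' @export
paired_reference <- function(design) {
  stopifnot(!anyDuplicated(design$pair_id),
            all(nchar(design$protospacer_u6) == 20),
            all(nchar(design$protospacer_h1) == 20))
  u6 <- toupper(design$protospacer_u6)
  h1 <- toupper(design$protospacer_h1)
  structure(list(
    pair_id = design$pair_id,
    u6_seqs = unique(u6), h1_seqs = unique(h1),
    u6_of_pair = match(u6, unique(u6)),
    h1_of_pair = match(h1, unique(h1))),
    class = "paired_reference")
}

# For each side, map an assigned unique guide index to the set of pair ids
# carrying that guide. Returns a list of integer vectors (pair row indices).
side_pair_sets <- function(ref, side) {
  key <- if (side == "U6") ref$u6_of_pair else ref$h1_of_pair
  split(seq_along(ref$pair_id), key)
}

#' Classify one extracted protospacer pair against the reference
#'
#' Each protospacer is matched to the reference guides of its side allowing up
#' to `max_mismatches`; a side is assigned only when exactly one reference
#' guide attains the minimal distance (unique best). Both sides assigned to a
#' common pair gives `matched`; both assigned but to different pairs gives
#' `recombinant`; a distance tie gives `ambiguous`; otherwise `unmatched`.
#'
#' @param p_u6,p_h1 20-nt protospacer strings (scalar).
#' @param ref A [paired_reference()].
#' @param max_mismatches Mismatches tolerated per protospacer (default 1).
#' @return One-row tibble: `fate`, `pair_id` (for matched), `u6_pair_id`,
#'   `h1_pair_id` (for recombinant).
#' @export
match_pair <- function(p_u6, p_h1, ref, max_mismatches = 1L) {
  res <- match_pairs_vec(p_u6, p_h1, ref, max_mismatches)
  res[1, , drop = FALSE]
}

# Vectorised fate assignment for extracted protospacers (NA = extraction
# failure already fated by the caller).
match_pairs_vec <- function(p_u6, p_h1, ref, max_mismatches = 1L) {
  mu <- match_protospacers(toupper(p_u6), ref$u6_seqs, max_mismatches)
  mh <- match_protospacers(toupper(p_h1), ref$h1_seqs, max_mismatches)
  u6_sets <- side_pair_sets(ref, "U6")
  h1_sets <- side_pair_sets(ref, "H1")

  n <- length(p_u6)
  fate <- character(n)
  pair_id <- rep(NA_character_, n)
  u6_pair <- rep(NA_character_, n)
  h1_pair <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (mu$status[i] == "ambiguous" || mh$status[i] == "ambiguous") {
      fate[i] <- "ambiguous"
    } else if (mu$status[i] != "assigned" || mh$status[i] != "assigned") {
      fate[i] <- "unmatched"
    } else {
      su <- u6_sets[[mu$idx[i]]]
      sh <- h1_sets[[mh$idx[i]]]
      common <- intersect(su, sh)
      if (length(common) > 0) {
        fate[i] <- "matched"
        pair_id[i] <- ref$pair_id[min(common)]
      } else {
        fate[i] <- "recombinant"
        u6_pair[i] <- ref$pair_id[min(su)]
        h1_pair[i] <- ref$pair_id[min(sh)]
      }
    }
  }
  tibble(fate = fate, pair_id = pair_id,
         u6_pair_id = u6_pair, h1_pair_id = h1_pair)
}

#' Count guide pairs in one sequenced sample
#'
#' Applies [extract_protospacer()] to both mates of every read pair, classifies
#' the extracted protospacers with the unique-best-match rule, and tallies
#' matched pairs and read fates. Deterministic for fixed input; the fate
#' tallies always sum to the total number of read pairs.
#'
#' @param r1,r2 Paths to the U6-side and H1-side FASTQ files (optionally
#'   gzipped), or `DNAStringSet`s of reads.
#' @param ref A [paired_reference()].
#' @param sample_id Sample label used for the count column.
#' @param max_anchor_mismatches,max_mismatches Matching tolerances.
#' @return List with `counts` (tibble `pair_id`, `<sample_id>` with one row
#'   per reference pair) and `fates` (tibble `fate`, `n` over all six fates).
#' @export
count_sample <- function(r1, r2, ref, sample_id = "sample",
                         max_anchor_mismatches = 1L, max_mismatches = 1L) {
  reads_u6 <- if (methods::is(r1, "DNAStringSet")) r1 else
    Biostrings::readDNAStringSet(r1, format = "fastq")
  reads_h1 <- if (methods::is(r2, "DNAStringSet")) r2 else
    Biostrings::readDNAStringSet(r2, format = "fastq")
  if (length(reads_u6) != length(reads_h1)) {
    abort(sprintf("unequal read counts: %d (U6 side) vs %d (H1 side)",
                  length(reads_u6), length(reads_h1)))
  }
  n <- length(reads_u6)
  eu <- extract_protospacer(reads_u6, "U6", max_anchor_mismatches)
  eh <- extract_protospacer(reads_h1, "H1", max_anchor_mismatches)

  fate <- rep(NA_character_, n)
  fate[eu$status == "no_scaffold" | eh$status == "no_scaffold"] <- "no_scaffold"
  fate[eu$status == "no_anchor" | eh$status == "no_anchor"] <- "no_anchor"
  todo <- which(is.na(fate))

  pair_id <- rep(NA_character_, n)
  if (length(todo) > 0) {
    res <- match_pairs_vec(eu$protospacer[todo], eh$protospacer[todo], ref,
                           max_mismatches)
    fate[todo] <- res$fate
    pair_id[todo] <- res$pair_id
  }

  counts <- tibble(pair_id = ref$pair_id)
  tab <- table(factor(pair_id, levels = ref$pair_id))
  counts[[sample_id]] <- as.integer(tab)
  fate_tally <- as.integer(table(factor(fate, levels = READ_FATES)))
  fates <- tibble(fate = READ_FATES, n = fate_tally)
  list(counts = counts, fates = fates)
}

#' Count several samples into a pair-by-sample matrix
#'
#' @param samples Named list of `list(r1 = , r2 = )` per sample.
#' @param ref A [paired_reference()].
#' @param design Optional design tibble; when given, `region_id` is carried
#'   into the output.
#' @param ... Passed to [count_sample()].
#' @return List with `counts` (wide tibble: `pair_id`, optional `region_id`,
#'   one integer column per sample) and `fates` (long tibble with `sample`).
#' @export
count_samples <- function(samples, ref, design = NULL, ...) {
  stopifnot(length(names(samples)) == length(samples))
  counts <- tibble(pair_id = ref$pair_id)
  fates <- list()
  for (s in names(samples)) {
    res <- count_sample(samples[[s]]$r1, samples[[s]]$r2, ref,
                        sample_id = s, ...)
    counts <- left_join(counts, res$counts, by = "pair_id")
    fates[[s]] <- res$fates |> mutate(sample = s)
  }
  if (!is.null(design)) {
    counts <- counts |>
      left_join(design |> select("pair_id", "region_id"), by = "pair_id") |>
      relocate("region_id", .after = "pair_id")
  }
  list(counts = counts, fates = list_rbind(fates))
}

#' Drop guide pairs with low reference-sample coverage
#'
#' Removes pair rows whose count in the reference (day-0) sample is below
#' `min_count` and reports, per region, how many pairs were retained and the
#' fraction of regions retaining at least one pair.
#'
#' @param counts Wide count tibble (`pair_id`, optional `region_id`, sample
#'   columns).
#' @param min_count Minimum reference count for a pair to be kept (default 5).
#' @param reference_sample Name of the reference sample column.
#' @return The filtered tibble, with a `coverage_report` attribute: a list of
#'   `per_region` (tibble `region_id`, `n_retained`) and
#'   `frac_regions_retained`.
#' @export
filter_low_coverage <- function(counts, min_count = 5L,
                                reference_sample = "day0") {
  if (min_count < 0) abort("min_count must be >= 0")
  if (!reference_sample %in% names(counts)) {
    abort(sprintf("reference sample '%s' not found", reference_sample))
  }
  kept <- counts[counts[[reference_sample]] >= min_count, , drop = FALSE]
  report <- NULL
  if ("region_id" %in% names(counts)) {
    per_region <- counts |>
      distinct(.data$region_id) |>
      left_join(kept |> dplyr::count(.data$region_id, name = "n_retained"),
                by = "region_id") |>
      mutate(n_retained = tidyr::replace_na(.data$n_retained, 0L))
    report <- list(per_region = per_region,
                   frac_regions_retained = mean(per_region$n_retained >= 1))
  }
  attr(kept, "coverage_report") <- report
  kept
}
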