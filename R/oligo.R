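#' Assemble the synthesized oligo for a guide pair
#'
#' Emits the exact ordered-oligo string for one pair under the v1 or v2
#' template grammar. Both versions start with the fixed U6-side flank and end
#' with the fixed H1-side flank; the H1 guide is embedded as its reverse
#' complement. v2 additionally carries a 10-nt barcode between two
#' BsmBI-bearing linkers. Protospacers containing a BsmBI/BbsI recognition
#' site are rejected because those enzymes open the vector during cloning.
#'
#' @param pair One-row guide-pair tibble (needs `pair_id`, `protospacer_u6`,
#'   `protospacer_h1`).
#' @param version `"v1"` or `"v2"`.
#' @param barcode 10-nt barcode (required for v2, ignored for v1).
#' @return One-row tibble: `pair_id`, `version`, `barcode`, `sequence`.
#' @seealso [parse_oligo()] for the inverse operation.
#' @export
assemble_oligo <- function(pair, version = c("v2", "v1"), barcode = NULL) {
  version <- match.arg(version)
  p1 <- check_dna(pair$protospacer_u6, "ACGT", "U6 protospacer")
  p2 <- check_dna(pair$protospacer_h1, "ACGT", "H1 protospacer")
  stopifnot(nchar(p1) == 20, nchar(p2) == 20)
  for (proto in c(p1, p2)) {
    hit <- FORBIDDEN_SITES[vapply(FORBIDDEN_SITES, grepl, logical(1), x = proto)]
    if (length(hit) > 0) {
      abort(sprintf("pair %s: protospacer %s contains forbidden restriction site %s",
                    pair$pair_id, proto, hit[1]))
    }
  }
  if (version == "v1") {
    seq <- paste0(OLIGO_FLANK5, p1, OLIGO_LINKER_V1, revcomp(p2), OLIGO_FLANK3)
    barcode <- ""
  } else {
    if (is.null(barcode) || is.na(barcode) || nchar(barcode) == 0) {
      abort(sprintf("pair %s: v2 oligos require a 10-nt barcode", pair$pair_id))
    }
    barcode <- check_dna(barcode, "ACGT", "barcode")
    stopifnot(nchar(barcode) == 10)
    seq <- paste0(OLIGO_FLANK5, p1, OLIGO_LINKER_V2A, barcode,
                  OLIGO_LINKER_V2B, revcomp(p2), OLIGO_FLANK3)
  }
  tibble(pair_id = pair$pair_id, version = version, barcode = barcode,
         sequence = seq)
}

#' Parse a synthesized oligo back into its components
#'
#' Inverse of [assemble_oligo()]: matches the version's template grammar
#' (case-insensitively) and recovers the U6 protospacer, the H1 protospacer
#' (un-reverse-complemented) and, for v2, the barcode.
#'
#' @param sequence Oligo DNA string.
#' @param version `"v1"` or `"v2"`.
#' @return One-row tibble `protospacer_u6`, `protospacer_h1`, `barcode`, or an
#'   error if the sequence does not match the grammar.
#' @export
parse_oligo <- function(sequence, version = c("v2", "v1")) {
  version <- match.arg(version)
  s <- toupper(sequence)
  if (version == "v1") {
    pat <- paste0("^", OLIGO_FLANK5, "([ACGT]{20})", OLIGO_LINKER_V1,
                  "([ACGT]{20})", OLIGO_FLANK3, "$")
    m <- regmatches(s, regexec(pat, s))[[1]]
    if (length(m) != 3) abort("sequence does not match the v1 oligo grammar")
    tibble(protospacer_u6 = m[2], protospacer_h1 = revcomp(m[3]),
           barcode = "")
  } else {
    pat <- paste0("^", OLIGO_FLANK5, "([ACGT]{20})", OLIGO_LINKER_V2A,
                  "([ACGT]{10})", OLIGO_LINKER_V2B, "([ACGT]{20})",
                  OLIGO_FLANK3, "$")
    m <- regmatches(s, regexec(pat, s))[[1]]
    if (length(m) != 4) abort("sequence does not match the v2 oligo grammar")
    tibble(protospacer_u6 = m[2], protospacer_h1 = revcomp(m[4]),
           barcode = m[3])
  }
}

#' Build the post-cloning dual-sgRNA expression cassette
#'
#' Returns the final expression cassette for one pair: convergent U6 and H1
#' promoters drive the two sgRNAs toward each other, with two full tracrRNA
#' scaffolds separated by a neutral spacer. The spacer (scaffold gap) is
#' exactly 50 bp for v1 and 200 bp for v2 cassettes. The cassette contains the
#' two promoter anchor substrings used by the read processor: the U6 anchor on
#' the plus strand and the H1 anchor on the minus strand.
#'
#' @inheritParams assemble_oligo
#' @return One-row tibble: `pair_id`, `version`, `sequence`, `scaffold_gap`.
#' @export
build_expression_cassette <- function(pair, version = c("v2", "v1")) {
  version <- match.arg(version)
  p1 <- check_dna(pair$protospacer_u6, "ACGT", "U6 protospacer")
  p2 <- check_dna(pair$protospacer_h1, "ACGT", "H1 protospacer")
  gap <- SCAFFOLD_GAP[[version]]
  spacer <- substr(CASSETTE_SPACER, 1, gap)
  seq <- paste0(
    CASSETTE_PAD5, U6_ANCHOR, U6_JUNCTION, p1, SGRNA_SCAFFOLD,
    spacer,
    revcomp(paste0(H1_ANCHOR, H1_JUNCTION, p2, SGRNA_SCAFFOLD)),
    CASSETTE_PAD3)
  tibble(pair_id = pair$pair_id, version = version, sequence = seq,
         scaffold_gap = gap)
}

#' Generate a set of distinct 10-nt barcodes
#'
#' Deterministic (seeded) greedy sampler: candidate barcodes are drawn
#' uniformly, rejected if they contain a homopolymer of length >= 4 or a
#' BsmBI/BbsI site, and accepted only when at pairwise Hamming distance >= 2
#' from every barcode accepted so far.
#'
#' @param n Number of barcodes.
#' @param width Barcode width (default 10).
#' @param min_hamming Minimum pairwise Hamming distance (default 2).
#' @param seed Integer seed.
#' @return Character vector of `n` barcodes.
#' @export
generate_barcodes <- function(n, width = 10L, min_hamming = 2L, seed = 1L) {
  if (n == 0) return(character())
  with_seed(seed, {
    accepted <- character(0)
    accepted_mat <- NULL
    tries <- 0L
    max_tries <- max(10000L, 200L * n)
    while (length(accepted) < n) {
      tries <- tries + 1L
      if (tries > max_tries) {
        abort(sprintf("barcode space exhausted after %d attempts (%d/%d found)",
                      tries - 1L, length(accepted), n))
      }
      cand <- random_dna(width)
      if (grepl("AAAA|CCCC|GGGG|TTTT", cand)) next
      if (any(vapply(FORBIDDEN_SITES, grepl, logical(1), x = cand))) next
      ci <- utf8ToInt(cand)
      if (!is.null(accepted_mat)) {
        d <- colSums(accepted_mat != ci)
        if (min(d) < min_hamming) next
      }
      accepted <- c(accepted, cand)
      accepted_mat <- cbind(accepted_mat, ci)
    }
    accepted
  })
}
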