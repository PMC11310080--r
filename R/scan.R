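#' Scan a sequence for candidate Cas9 protospacers
#'
#' Finds every 20-nt window immediately 5' of a PAM match on either strand.
#' The blunt Cas9 cut falls between protospacer positions 17 and 18, i.e. 3 bp
#' 5' of the PAM; `cut_site` is reported as the 0-based genomic coordinate of
#' the first base 3' of the cut on the plus strand, so for a plus-strand hit
#' `cut_site = pam_start - 3`.
#'
#' Efficacy and off-target scores are not computed here; they are joined from
#' an external score table before filtering (see [filter_guides()]).
#'
#' @param seq DNA string (ACGTN only).
#' @param offset 0-based genomic start coordinate of `seq` (default 0).
#' @param pam_pattern IUPAC PAM pattern, default `"NGG"`.
#' @param chrom Chromosome name recorded on each candidate.
#' @return Tibble with one row per candidate guide: `guide_id`, `chrom`,
#'   `cut_site`, `strand`, `protospacer`, and unset score columns
#'   (`efficacy`, `top5`, `top10`, all `NA`).
#' @export
#' @examples
#' scan_protospacers(paste0(strrep("A", 25), "TGG", strrep("A", 10)))
scan_protospacers <- function(seq, offset = 0L, pam_pattern = "NGG",
                              chrom = "chr_sim") {
  seq <- check_dna(seq, allow = "ACGTN", what = "input sequence")
  pam_pattern <- check_dna(pam_pattern, allow = "ACGTNRYSWKMBDHV",
                           what = "PAM pattern")
  subj <- Biostrings::DNAString(seq)
  pam_w <- nchar(pam_pattern)

  hits <- function(pattern) {
    m <- Biostrings::matchPattern(pattern, subj, fixed = FALSE)
    Biostrings::start(m)
  }

  rows <- list()
  # plus strand: protospacer is the 20 nt ending right before the PAM
  for (p in hits(pam_pattern)) {
    if (p >= 21) {
      proto <- substr(seq, p - 20, p - 1)
      if (!grepl("N", proto, fixed = TRUE)) {
        pam_start0 <- p - 1L # 0-based within seq
        rows[[length(rows) + 1L]] <- list(
          strand = "+",
          cut_site = offset + pam_start0 - 3L,
          protospacer = proto)
      }
    }
  }
  # minus strand: PAM on the reverse strand appears as revcomp(PAM) on plus
  for (p in hits(revcomp(pam_pattern))) {
    if (p + pam_w - 1L + 20L <= nchar(seq)) {
      proto_plus <- substr(seq, p + pam_w, p + pam_w + 19L)
      if (!grepl("N", proto_plus, fixed = TRUE)) {
        # cut 3 bp 5' of the PAM on the minus strand
        rows[[length(rows) + 1L]] <- list(
          strand = "-",
          cut_site = offset + (p - 1L) + pam_w + 3L,
          protospacer = revcomp(proto_plus))
      }
    }
  }

  if (length(rows) == 0) {
    return(tibble(guide_id = character(), chrom = character(),
                  cut_site = integer(), strand = character(),
                  protospacer = character(), efficacy = double(),
                  top5 = double(), top10 = double()))
  }
  out <- list_rbind(map(rows, as_tibble)) |>
    arrange(.data$cut_site, .data$strand) |>
    mutate(chrom = chrom,
           guide_id = sprintf("%s_%d_%s", chrom, .data$cut_site, .data$strand),
           efficacy = NA_real_, top5 = NA_real_, top10 = NA_real_) |>
    select("guide_id", "chrom", "cut_site", "strand", "protospacer",
           "efficacy", "top5", "top10")
  out
}
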