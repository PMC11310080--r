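#' Reverse-complement DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that keeps
#' plain character vectors in and out.
#'
#' @param x Character vector of DNA sequences (ACGTN, case-insensitive).
#' @return Character vector of reverse complements, uppercase.
#' @export
#' @examples
#' revcomp("ACCGT")
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

# Validate a DNA string against an allowed alphabet; returns uppercase.
check_dna <- function(x, allow = "ACGTN", what = "sequence") {
  x <- toupper(x)
  bad <- grepl(sprintf("[^%s]", allow), x)
  if (any(bad)) {
    abort(sprintf("%s contains non-DNA characters (allowed: %s): %s",
                  what, allow, substr(x[bad][1], 1, 40)))
  }
  x
}

# Hamming distance between equal-length strings and one pattern, vectorised
# over x.  Used for junction/scaffold checks on fixed-width slices.
hamming_to <- function(x, pattern) {
  n <- nchar(pattern)
  stopifnot(all(nchar(x) == n | is.na(x)))
  if (length(x) == 0) return(integer())
  xm <- matrix(utf8ToInt(paste(ifelse(is.na(x), strrep("N", n), x), collapse = "")),
               nrow = n)
  pm <- utf8ToInt(pattern)
  out <- colSums(xm != pm)
  out[is.na(x)] <- NA_integer_
  as.integer(out)
}

# Encode fixed-width DNA strings as an integer matrix (width x n).
dna_int_matrix <- function(x, width) {
  matrix(utf8ToInt(paste(x, collapse = "")), nrow = width)
}

# Match `queries` (20-nt strings) against reference guide sequences of one
# side.  A query is assigned iff exactly one reference sequence attains the
# minimal distance and that distance <= max_mismatches.  Returns an integer
# index into `refs` with NA for unassigned and the per-query status:
# "assigned", "ambiguous" or "unmatched".
match_protospacers <- function(queries, refs, max_mismatches = 1L) {
  idx <- match(queries, refs)
  status <- ifelse(is.na(idx), "unmatched", "assigned")
  todo <- which(is.na(idx) & !is.na(queries))
  if (length(todo) > 0 && max_mismatches > 0) {
    w <- nchar(refs[1])
    refm <- dna_int_matrix(refs, w)
    for (i in todo) {
      q <- utf8ToInt(queries[i])
      if (length(q) != w) next
      d <- colSums(refm != q)
      dmin <- min(d)
      if (dmin <= max_mismatches) {
        hits <- which(d == dmin)
        if (length(hits) == 1L) {
          idx[i] <- hits
          status[i] <- "assigned"
        } else {
          status[i] <- "ambiguous"
        }
      }
    }
  }
  list(idx = idx, status = status)
}

# Deterministic pseudo-random DNA of length n (RNG-stream local).
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Coerce dense or sparse input to CsparseMatrix, tolerating base matrices.
as_sparse <- function(x) {
  if (methods::is(x, "CsparseMatrix")) return(x)
  methods::as(Matrix::Matrix(as.matrix(x), sparse = TRUE), "CsparseMatrix")
}
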