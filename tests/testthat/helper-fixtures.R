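# Independent brute-force protospacer scan used as oracle for scan tests:
# plain loops over every position and both strands, no shared code with the
# package implementation.
brute_scan <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  rc1 <- function(x) chartr("ACGT", "TGCA", x)
  out <- list()
  for (p in seq_len(n - 2)) { # 1-based PAM start, plus strand (NGG)
    if (ch[p + 1] == "G" && ch[p + 2] == "G" && p >= 21) {
      proto <- substr(seq, p - 20, p - 1)
      if (!grepl("N", proto)) {
        out[[length(out) + 1]] <- data.frame(
          strand = "+", cut_site = (p - 1) - 3, protospacer = proto)
      }
    }
  }
  for (p in seq_len(n - 2)) { # CCN on plus = NGG on minus
    if (ch[p] == "C" && ch[p + 1] == "C" && p + 2 + 20 <= n) {
      proto_plus <- substr(seq, p + 3, p + 22)
      if (!grepl("N", proto_plus)) {
        rcp <- paste(rev(strsplit(rc1(proto_plus), "")[[1]]), collapse = "")
        out[[length(out) + 1]] <- data.frame(
          strand = "-", cut_site = (p - 1) + 3 + 3, protospacer = rcp)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(strand = character(), cut_site = integer(),
                      protospacer = character()))
  }
  do.call(rbind, out)
}

# Independent rho calculation for enumeration oracles (straight from the
# order-statistic definition).
oracle_rho <- function(u, alpha) {
  u <- sort(u)
  k <- length(u)
  below <- which(u < alpha)
  if (length(below) == 0) return(1)
  min(pbeta(u[below], below, k - below + 1))
}

# A guide table flanking and filling a region [start, end) on one chromosome,
# with n_up / n_down / n_in guides at evenly spaced cut sites, all passing the
# score filters.
toy_guides <- function(region, n_up = 5, n_down = 5, n_in = 0, seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed({
    cut_up <- if (n_up > 0)
      as.integer(seq(region$start - 180, region$start - 5, length.out = n_up)) else integer()
    cut_down <- if (n_down > 0)
      as.integer(seq(region$end + 5, region$end + 180, length.out = n_down)) else integer()
    cut_in <- if (n_in > 0)
      as.integer(seq(region$start + 5, region$end - 5, length.out = n_in)) else integer()
    cuts <- c(cut_up, cut_down, cut_in)
    n <- length(cuts)
    tibble::tibble(
      guide_id = sprintf("g%03d", seq_len(n)),
      chrom = region$chrom,
      cut_site = cuts,
      strand = "+",
      protospacer = vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""),
        character(1)),
      efficacy = runif(n, 0.5, 1),
      top5 = runif(n, 0, 40),
      top10 = runif(n, 0, 45))
  })
}

toy_region <- function(region_id = "R1", chrom = "chr1",
                       start = 1000L, end = 1400L) {
  tibble::tibble(region_id = region_id, chrom = chrom,
                 start = start, end = end, kind = "predicted_enhancer")
}

# Drop restriction-site-bearing protospacers from a toy guide table so
# library assembly never trips the type-IIS guard in fixtures.
strip_sites <- function(guides) {
  bad <- grepl("CGTCTC|GAGACG|GAAGAC|GTCTTC", guides$protospacer)
  guides[!bad, , drop = FALSE]
}
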