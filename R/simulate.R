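plant_pams <- function(seq_chars, pam_starts0) {
  # force an NGG PAM at each 0-based start position (plus strand)
  for (p in pam_starts0) {
    seq_chars[p + 2] <- "G"
    seq_chars[p + 3] <- "G"
  }
  seq_chars
}

#' Simulate design inputs: region sequences, intervals and scored guides
#'
#' Generates one synthetic contig per target region (two `flank_bp` flanks
#' around a `region_bp` core) with plus-strand PAM sites planted at regular
#' spacing so each flank and the region core are guaranteed at least the
#' requested number of candidate protospacers. Scores are drawn so the
#' threshold filters have predictable pass rates: efficacy ~ Uniform(0,1)
#' (pass rate 0.85 against the 0.15 cut-off), top5 ~ Uniform(0,94) and
#' top10 ~ Uniform(0,100) (pass rate 0.5 each). Optionally, the first
#' `min_passing_per_flank` candidates per flank are given scores that pass all
#' filters, for constructing designable fixtures.
#'
#' @param n_regions Number of target regions.
#' @param guides_per_flank PAM sites planted per flank (and per region core).
#' @param region_bp,flank_bp Region and flank sizes in bp (defaults 300/200).
#' @param min_passing_per_flank Guides per flank forced to pass all score
#'   filters (default 0 = all scores random).
#' @param seed Integer seed; output is fully deterministic given the seed.
#' @param out_dir Optional directory; when given, writes `regions.bed`,
#'   `guides.tsv` and `contigs.fa`.
#' @return List: `regions` (tibble `region_id`, `chrom`, `start`, `end`,
#'   `kind`), `guides` (scored candidate tibble), `sequences` (named character
#'   vector of contigs).
#' @export
simulate_design_inputs <- function(n_regions, guides_per_flank = 10L,
                                   region_bp = 300L, flank_bp = 200L,
                                   min_passing_per_flank = 0L, seed = 1L,
                                   out_dir = NULL) {
  empty <- list(
    regions = tibble(region_id = character(), chrom = character(),
                     start = integer(), end = integer(), kind = character()),
    guides = scan_protospacers("AAAAA")[0, ],
    sequences = character())
  if (n_regions == 0) return(empty)

  res <- with_seed(seed, {
    regions <- list(); guides <- list(); seqs <- character()
    for (r in seq_len(n_regions)) {
      region_id <- sprintf("region_%03d", r)
      chrom <- sprintf("ctg_%03d", r)
      total <- 2L * flank_bp + region_bp
      ch <- strsplit(random_dna(total), "")[[1]]
      # plant PAMs so protospacer and cut site fall inside each window:
      # PAM start p (0-based) gives cut at p - 3 and protospacer [p-20, p)
      plant_in <- function(w_start, w_end, n) {
        lo <- max(w_start + 4L, 21L)
        hi <- w_end + 2L
        if (hi - lo < n) hi <- lo + n
        as.integer(round(seq(lo, min(hi, total - 3L), length.out = n)))
      }
      pams <- c(plant_in(0L, flank_bp, guides_per_flank),
                plant_in(flank_bp, flank_bp + region_bp, guides_per_flank),
                plant_in(flank_bp + region_bp, total, guides_per_flank))
      ch <- plant_pams(ch, unique(pams))
      seq <- paste(ch, collapse = "")
      seqs[chrom] <- seq

      g <- scan_protospacers(seq, offset = 0L, chrom = chrom)
      g$efficacy <- runif(nrow(g))
      g$top5 <- runif(nrow(g), 0, 94)
      g$top10 <- runif(nrow(g), 0, 100)
      if (min_passing_per_flank > 0) {
        for (w in list(c(0L, flank_bp),
                       c(flank_bp + region_bp, total))) {
          in_w <- which(g$cut_site >= w[1] & g$cut_site < w[2])
          force_pass <- head(in_w, min_passing_per_flank)
          g$efficacy[force_pass] <- runif(length(force_pass), 0.5, 1)
          g$top5[force_pass] <- runif(length(force_pass), 0, 40)
          g$top10[force_pass] <- runif(length(force_pass), 0, 45)
        }
      }
      regions[[r]] <- tibble(region_id = region_id, chrom = chrom,
                             start = flank_bp, end = flank_bp + region_bp,
                             kind = "predicted_enhancer")
      guides[[r]] <- g
    }
    list(regions = list_rbind(regions), guides = list_rbind(guides),
         sequences = seqs)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_bed(res$regions |>
                select("chrom", "start", "end", name = "region_id"),
              file.path(out_dir, "regions.bed"))
    readr::write_tsv(res$guides, file.path(out_dir, "guides.tsv"))
    fa <- Biostrings::DNAStringSet(res$sequences)
    Biostrings::writeXStringSet(fa, file.path(out_dir, "contigs.fa"))
  }
  res
}

#' Simulation ground truth for a screen
#'
#' Assigns essentiality and drug-interaction effects to regions. Effects are
#' log2 fold changes per day of culture: essential regions deplete at
#' `essential_effect` per day in every day-15 sample; resistant/sensitizing
#' regions gain `drug_effect` / `-drug_effect` per day under treatment only.
#'
#' @param regions Region tibble (needs `region_id`).
#' @param frac_essential Fraction of essential regions (default 0.05).
#' @param essential_effect Per-day log2 depletion of essential regions
#'   (default -1, i.e. 2-fold per day).
#' @param frac_resistant,frac_sensitizing Fractions of drug-interacting
#'   regions (drawn from the non-essential ones).
#' @param drug_effect Per-day log2 effect under treatment (default 2/15, i.e.
#'   a +2 beta shift over a 15-day window).
#' @param seed Integer seed.
#' @return Tibble `region_id`, `essential`, `growth_effect`, `drug_class`
#'   (`none`/`resistant`/`sensitizing`), `drug_effect`.
#' @export
simulate_truth <- function(regions, frac_essential = 0.05,
                           essential_effect = -1,
                           frac_resistant = 0, frac_sensitizing = 0,
                           drug_effect = 2 / 15, seed = 1L) {
  n <- nrow(regions)
  with_seed(seed, {
    essential <- rep(FALSE, n)
    essential[sample.int(n, round(frac_essential * n))] <- TRUE
    drug_class <- rep("none", n)
    pool <- which(!essential)
    n_res <- round(frac_resistant * n)
    n_sen <- round(frac_sensitizing * n)
    picks <- sample(pool, min(length(pool), n_res + n_sen))
    drug_class[picks[seq_len(n_res)]] <- "resistant"
    if (n_sen > 0) drug_class[picks[n_res + seq_len(n_sen)]] <- "sensitizing"
    tibble(region_id = regions$region_id,
           essential = essential,
           growth_effect = ifelse(essential, essential_effect, 0),
           drug_class = drug_class,
           drug_effect = dplyr::case_when(drug_class == "resistant" ~ drug_effect,
                                          drug_class == "sensitizing" ~ -drug_effect,
                                          TRUE ~ 0))
  })
}

#' Simulate a pair-by-sample screen count matrix
#'
#' Day-0 counts are Dirichlet-multinomial (concentration `dirichlet_conc`
#' around a uniform base). Day-15 samples multiply each pair's expected
#' abundance by `2^(effect x days)` per the truth table (growth effect in both
#' arms, plus the drug effect under treatment), renormalize across pairs, and
#' draw negative-binomial counts at the given dispersion.
#'
#' @param pairs Design tibble (`pair_id`, `region_id`; control pairs may have
#'   `region_id` NA or absent from `truth` and get zero effect).
#' @param truth Truth tibble from [simulate_truth()].
#' @param depth_per_sample Total reads per sample (default 400x the number of
#'   pairs).
#' @param days Culture window in days (default 15).
#' @param dispersion Negative-binomial dispersion (default 0.05; 0 = Poisson).
#' @param dirichlet_conc Dirichlet concentration for day-0 abundances.
#' @param seed Integer seed.
#' @return Wide count tibble (`pair_id`, `region_id`, `day0`,
#'   `day15_untreated`, `day15_treated`) with `truth` attached as an
#'   attribute.
#' @export
simulate_screen_counts <- function(pairs, truth,
                                   depth_per_sample = 400L * nrow(pairs),
                                   days = 15, dispersion = 0.05,
                                   dirichlet_conc = 3, seed = 1L) {
  eff <- pairs |>
    left_join(truth, by = "region_id") |>
    mutate(growth_effect = tidyr::replace_na(.data$growth_effect, 0),
           drug_effect = tidyr::replace_na(.data$drug_effect, 0))
  n <- nrow(eff)
  with_seed(seed, {
    p0 <- rgamma(n, shape = dirichlet_conc, rate = 1)
    p0 <- p0 / sum(p0)
    day0 <- as.integer(rmultinom(1, depth_per_sample, p0))
    draw <- function(mu) {
      if (dispersion > 0) rnbinom(n, mu = mu, size = 1 / dispersion)
      else rpois(n, mu)
    }
    q_unt <- p0 * 2^(eff$growth_effect * days)
    q_trt <- p0 * 2^((eff$growth_effect + eff$drug_effect) * days)
    out <- tibble(pair_id = eff$pair_id, region_id = eff$region_id,
                  day0 = day0,
                  day15_untreated = draw(depth_per_sample * q_unt / sum(q_unt)),
                  day15_treated = draw(depth_per_sample * q_trt / sum(q_trt)))
    attr(out, "truth") <- truth
    out
  })
}

#' Simulate paired-end amplicon reads from a library
#'
#' Each read pair is drawn from a designed construct following `abundances`;
#' with probability `recomb_rate` the H1-side protospacer is swapped for that
#' of another construct (emulating lentiviral template switching). Reads embed
#' the exact cassette grammar (stagger prefix, promoter anchor, junction,
#' protospacer, scaffold), with optional per-base substitution errors.
#'
#' @param design Design tibble (`pair_id`, `protospacer_u6`,
#'   `protospacer_h1`).
#' @param n_reads Number of read pairs.
#' @param abundances Optional per-pair probabilities (aligned with `design`;
#'   default uniform).
#' @param recomb_rate Probability a read pair is recombinant (default 0).
#' @param error_rate Per-base substitution error rate (default 0).
#' @param stagger_set Character vector of stagger prefixes cycled randomly
#'   across reads (default the 8 prefixes of length 0-7 of a fixed sequence,
#'   mirroring staggered PCR primers).
#' @param scaffold_bases Scaffold bases retained after the protospacer
#'   (default 41).
#' @param seed Integer seed.
#' @param out_r1,out_r2 Optional FASTQ paths (written with constant quality).
#' @return List: `r1`, `r2` (`DNAStringSet`s), `truth` (tibble `read_id`,
#'   `pair_id`, `recombinant`, `h1_pair_id`).
#' @export
simulate_amplicon_reads <- function(design, n_reads, abundances = NULL,
                                    recomb_rate = 0, error_rate = 0,
                                    stagger_set = substring("ACGTACGT", 1, 0:7),
                                    scaffold_bases = 41L, seed = 1L,
                                    out_r1 = NULL, out_r2 = NULL) {
  if (is.null(abundances)) abundances <- rep(1 / nrow(design), nrow(design))
  stopifnot(abs(sum(abundances) - 1) < 1e-8,
            length(abundances) == nrow(design))
  scaf <- substr(SGRNA_SCAFFOLD, 1, scaffold_bases)

  res <- with_seed(seed, {
    idx <- sample.int(nrow(design), n_reads, replace = TRUE,
                      prob = abundances)
    h1_idx <- idx
    recomb <- runif(n_reads) < recomb_rate
    if (any(recomb)) {
      # swap with a construct carrying a different H1 protospacer
      for (i in which(recomb)) {
        repeat {
          j <- sample.int(nrow(design), 1)
          if (design$protospacer_h1[j] != design$protospacer_h1[idx[i]]) break
        }
        h1_idx[i] <- j
      }
    }
    st1 <- sample(stagger_set, n_reads, replace = TRUE)
    st2 <- sample(stagger_set, n_reads, replace = TRUE)
    r1 <- paste0(st1, U6_ANCHOR, U6_JUNCTION,
                 toupper(design$protospacer_u6[idx]), scaf)
    r2 <- paste0(st2, H1_ANCHOR, H1_JUNCTION,
                 toupper(design$protospacer_h1[h1_idx]), scaf)
    if (error_rate > 0) {
      mutate_reads <- function(reads) {
        vapply(reads, function(s) {
          n <- nchar(s)
          nmut <- rbinom(1, n, error_rate)
          if (nmut == 0) return(s)
          pos <- sample.int(n, nmut)
          ch <- strsplit(s, "")[[1]]
          for (p in pos) {
            ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
          }
          paste(ch, collapse = "")
        }, character(1), USE.NAMES = FALSE)
      }
      r1 <- mutate_reads(r1)
      r2 <- mutate_reads(r2)
    }
    read_id <- sprintf("read_%06d", seq_len(n_reads))
    r1 <- Biostrings::DNAStringSet(setNames(r1, read_id))
    r2 <- Biostrings::DNAStringSet(setNames(r2, read_id))
    list(r1 = r1, r2 = r2,
         truth = tibble(read_id = read_id,
                        pair_id = design$pair_id[idx],
                        recombinant = recomb,
                        h1_pair_id = design$pair_id[h1_idx]))
  })
  if (!is.null(out_r1)) write_fastq(res$r1, out_r1)
  if (!is.null(out_r2)) write_fastq(res$r2, out_r2)
  res
}

#' Simulate single-cell expression and guide-capture matrices
#'
#' Baseline gene counts are negative binomial with gene-specific means and a
#' per-cell depth factor; cells perturbed for a pair scale the means of its
#' cis-target genes by `1 - knockdown`. The capture matrix places each cell's
#' pair at a high UMI count over sparse background noise; multiplets carry two
#' pairs at high UMI.
#'
#' @param target_pairs Character vector of perturbation pair ids.
#' @param cells_per_target Perturbed cells per pair (default 150).
#' @param control_pairs Character vector of control pair ids.
#' @param n_control_cells Total control cells (default 4000), split evenly
#'   over `control_pairs`.
#' @param n_genes Number of genes (default 100).
#' @param cis_effects Tibble `pair_id`, `gene`, `knockdown` (fraction in
#'   [0,1]); genes are `gene_001` ... `gene_<n>`.
#' @param multiplet_rate Fraction of cells carrying a second pair (default 0).
#' @param mean_log,sd_log Log-normal parameters of baseline gene mean counts.
#' @param nb_size Negative-binomial size (inverse dispersion) of counts.
#' @param capture_umi Mean UMI count of the resident pair (Poisson, floored
#'   at 3).
#' @param seed Integer seed.
#' @return List: `expression` (sparse genes x cells), `capture` (sparse pairs
#'   x cells), `cells` (tibble `cell`, `true_label`), `truth` (the
#'   `cis_effects` tibble).
#' @export
simulate_single_cell <- function(target_pairs, cells_per_target = 150L,
                                 control_pairs = sprintf("AAVS1_p%02d", 1:10),
                                 n_control_cells = 4000L, n_genes = 100L,
                                 cis_effects = NULL, multiplet_rate = 0,
                                 mean_log = log(0.5), sd_log = 1,
                                 nb_size = 2, capture_umi = 15, seed = 1L) {
  genes <- sprintf("gene_%03d", seq_len(n_genes))
  all_pairs <- c(target_pairs, control_pairs)
  with_seed(seed, {
    labels <- c(rep(target_pairs, each = cells_per_target),
                sample(control_pairs, n_control_cells, replace = TRUE))
    n_cells <- length(labels)
    cells <- sprintf("cell_%05d", seq_len(n_cells))

    gene_mean <- rlnorm(n_genes, mean_log, sd_log)
    if (!is.null(cis_effects) && nrow(cis_effects) > 0) {
      # cis-target genes are drawn as expressed genes (>= 1 count/cell at unit
      # depth): a knockdown on an undetectable gene is not a usable condition
      cis_idx <- match(unique(cis_effects$gene), genes)
      gene_mean[cis_idx] <- pmax(gene_mean[cis_idx], 1)
    }
    depth <- rlnorm(n_cells, 0, 0.3)
    mu <- outer(gene_mean, depth)
    if (!is.null(cis_effects) && nrow(cis_effects) > 0) {
      for (i in seq_len(nrow(cis_effects))) {
        gi <- match(cis_effects$gene[i], genes)
        ci <- which(labels == cis_effects$pair_id[i])
        mu[gi, ci] <- mu[gi, ci] * (1 - cis_effects$knockdown[i])
      }
    }
    counts <- matrix(rnbinom(length(mu), mu = mu, size = nb_size),
                     nrow = n_genes, dimnames = list(genes, cells))

    # guide capture: resident pair high, background sparse noise
    is_multiplet <- runif(n_cells) < multiplet_rate
    cap <- matrix(rbinom(length(all_pairs) * n_cells, 1, 0.01) *
                    rpois(length(all_pairs) * n_cells, 1),
                  nrow = length(all_pairs),
                  dimnames = list(all_pairs, cells))
    resident <- match(labels, all_pairs)
    cap[cbind(resident, seq_len(n_cells))] <-
      pmax(3L, rpois(n_cells, capture_umi))
    second <- rep(NA_character_, n_cells)
    if (any(is_multiplet)) {
      for (i in which(is_multiplet)) {
        alt <- sample(setdiff(seq_along(all_pairs), resident[i]), 1)
        cap[alt, i] <- pmax(3L, rpois(1, capture_umi))
        second[i] <- all_pairs[alt]
      }
    }
    list(expression = as_sparse(counts),
         capture = as_sparse(cap),
         cells = tibble(cell = cells,
                        true_label = ifelse(is_multiplet, "multiplet", labels),
                        resident_pair = labels, second_pair = second),
         truth = cis_effects %||% tibble(pair_id = character(),
                                         gene = character(),
                                         knockdown = double()))
  })
}
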