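# Sequence grammar of the dual-CRISPR system.
#
# The expression cassette places human U6 and H1 Pol III promoters in
# convergent orientation; each drives one sgRNA.  Amplicon reads are anchored
# on the promoter 3' ends, so the anchors below double as the read-processing
# landmarks.  All comparisons in the package are case-insensitive; constants
# are stored uppercase.

# Promoter anchors used by the read extractor (3' ends of U6 / H1).
U6_ANCHOR <- "ATATATCTTGTGGAAAGGACGAAA"
H1_ANCHOR <- "ATAAGTTCTGTATGAGACCACTCTT"

# Fixed junction bases between each promoter anchor and the 20-nt protospacer
# (from the cloning grammar: ...GACGAAACACCG-N20 and ...CACTCTTTCCCG-N20).
U6_JUNCTION <- "CACCG"
H1_JUNCTION <- "TCCCG"

# Full 76-nt sgRNA (tracrRNA) scaffold.  Positions 1-20 are the scaffold
# prefix checked downstream of every protospacer; positions 21-30 are the
# tracrRNA identifying sequence used as fallback check.
SGRNA_SCAFFOLD <- "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTGGCACCGAGTCGGTGC"
SCAFFOLD_PREFIX <- substr(SGRNA_SCAFFOLD, 1, 20)
TRACR_ID <- substr(SGRNA_SCAFFOLD, 21, 30) # AAGTTAAAAT

# Synthesized-oligo templates.
# v1: 5'flank - guide1(20) - linker - revcomp(guide2)(20) - 3'flank
# v2: 5'flank - guide1(20) - linkerA - barcode(10) - linkerB -
#     revcomp(guide2)(20) - 3'flank
OLIGO_FLANK5 <- "ATCTTGTGGAAAGGACGAAACACCG"
OLIGO_LINKER_V1 <- "GTTTTGAGACGGGATCCCGTCTCAAAAC"
OLIGO_LINKER_V2A <- "GTTTTAGAGCTAGAAATAGCAAGTTGAGACG"
OLIGO_LINKER_V2B <- "CGTCTCAACTTGCTATTTCTAGCTCTAAAAC"
OLIGO_FLANK3 <- "CGGGAAAGAGTGGTCTCATACAGAACTTAT"

# Type-IIS recognition sites used to open the vector during the two-step
# cloning; protospacers must not contain them (either strand covered below).
BSMBI_SITES <- c("CGTCTC", "GAGACG")
BBSI_SITES <- c("GAAGAC", "GTCTTC")
FORBIDDEN_SITES <- c(BSMBI_SITES, BBSI_SITES)

# Deterministic neutral ("nonsense") spacer separating the two scaffolds in
# the expression cassette: GC 54%, no homopolymer >= 4, shares no 6-mer with
# any promoter/scaffold/template anchor, no BsmBI/BbsI site.  v2 cassettes use
# all 200 nt, v1 cassettes the first 50 nt.
CASSETTE_SPACER <- paste0(
  "GTAGAGTCACTCGTGTGTGACACGTGCTTACCGGCTCGCGAGTGAGAATC",
  "CTATATAGGAAATGATTAGGCGACAGATGCTGCAGCGAAGTCACGCCTGG",
  "TCGCCGCCCGGCTCTGCATGACCGCCATTTGTTAGGCGCGTTTAAGACAT",
  "TCGGGCCGATGAATCGAGTTGGGACCTTTATCCGCTGCGTACTATCATGT")

SCAFFOLD_GAP <- c(v1 = 50L, v2 = 200L)

# Short neutral pads standing in for the promoter bodies 5' of each anchor in
# the assembled cassette (the full promoters are vector sequence, not part of
# the synthesized oligo; only the anchors matter to the toolkit).
CASSETTE_PAD5 <- "TGTACAAAAAAGCAGGCTTTAAAGGAACCAATTCAGTCGACTGGATCCGGTACCAAGG"
CASSETTE_PAD3 <- "CCTTGGTACCGGATCCAGTCGACTGAATTGGTTCC"

#' Read fates recognised by the paired-amplicon read processor
#'
#' Every read pair is assigned exactly one fate: `matched` (both protospacers
#' uniquely match the same designed pair), `recombinant` (both match, but to
#' different pairs), `no_anchor`, `no_scaffold`, `ambiguous` (a protospacer
#' ties between reference guides at minimal distance) or `unmatched`.
#'
#' @format Character vector of the six fate labels.
#' @export
READ_FATES <- c("matched", "recombinant", "no_anchor", "no_scaffold",
                "ambiguous", "unmatched")
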