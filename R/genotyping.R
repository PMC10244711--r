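.checkDNA <- function(seq, what = "sequence") {
  if (length(seq) != 1L || !nzchar(seq))
    stop(sprintf("%s must be a non-empty string", what))
  if (grepl("[^ACGTacgt]", seq))
    stop(sprintf("%s contains characters outside A/C/G/T", what))
  seq
}

#' Find restriction-site matches on a DNA strand
#'
#' Case-insensitive scan for all (possibly overlapping) occurrences of a
#' recognition sequence on the given strand, backed by
#' [Biostrings::matchPattern()]. Positions are 0-based. Scanning a single
#' strand suffices for BspHI: its TCATGA recognition sequence is its own
#' reverse complement.
#'
#' @param seq DNA string over A/C/G/T (case-insensitive).
#' @param recognition recognition sequence, e.g. "TCATGA" for BspHI.
#' @return integer vector of 0-based match start positions.
#' @examples
#' findSites("TCATGATCATGA", "TCATGA")  # 0 and 6
#' @export
findSites <- function(seq, recognition) {
  .checkDNA(seq); .checkDNA(recognition, "recognition")
  m <- Biostrings::matchPattern(toupper(recognition),
                                Biostrings::DNAString(toupper(seq)))
  as.integer(Biostrings::start(m) - 1L)
}

#' In-silico restriction digest of a linear sequence
#'
#' Cuts at every recognition-site start plus `cutOffset` (default 1,
#' the BspHI cut T^CATGA; a standard enzyme datum). With no sites the
#' result is one fragment of the full sequence length. Fragment lengths
#' always sum to the input length.
#'
#' @param seq DNA string over A/C/G/T.
#' @param recognition recognition sequence.
#' @param cutOffset cut position within the site, `0 <= cutOffset <=
#'   nchar(recognition)`.
#' @return list with `cut_positions` (0-based site starts, increasing) and
#'   `fragment_lengths` (bp).
#' @export
digestSequence <- function(seq, recognition, cutOffset = 1L) {
  .checkDNA(seq)
  if (cutOffset < 0 || cutOffset > nchar(recognition))
    stop("cutOffset must lie within the recognition sequence")
  sites <- findSites(seq, recognition)
  n <- nchar(seq)
  cuts <- sort(unique(sites + as.integer(cutOffset)))
  cuts <- cuts[cuts > 0 & cuts < n]
  list(cut_positions = sites,
       fragment_lengths = diff(c(0L, cuts, n)))
}

#' Hamming distance between equal-length DNA strings
#'
#' Positional mismatch count, case-insensitive. The G51D knock-in turns the
#' glycine-51 codon GGA into the aspartate codon GAT, a 2-bp edit.
#'
#' @param a,b DNA strings of equal length.
#' @return integer mismatch count.
#' @examples
#' hammingDistance("GGA", "GAT")  # 2
#' @export
hammingDistance <- function(a, b) {
  .checkDNA(a, "a"); .checkDNA(b, "b")
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  sum(strsplit(toupper(a), "")[[1L]] != strsplit(toupper(b), "")[[1L]])
}

#' Chi-square test of Mendelian genotype ratios
#'
#' Pearson chi-square of observed (WT, heterozygous, homozygous) counts
#' against an expected ratio (default 1:2:1 for a heterozygous intercross),
#' backed by [stats::chisq.test()].
#'
#' @param counts integer vector of length 3: (n_WT, n_het, n_hom).
#' @param ratio expected ratio, default `c(1, 2, 1)`.
#' @return list with `chi2`, `df` and `p`, plus the `expected` counts.
#' @examples
#' mendelianChisq(c(11, 22, 11))  # exact 1:2:1 split of 44 pups, chi2 = 0
#' @export
mendelianChisq <- function(counts, ratio = c(1, 2, 1)) {
  if (length(counts) != length(ratio))
    stop("counts and ratio must have the same length")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) <= 0) stop("total count must be positive")
  ht <- suppressWarnings(stats::chisq.test(counts, p = ratio / sum(ratio)))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, expected = unname(ht$expected))
}

#' The published G51D gRNA and donor oligonucleotide sequences
#'
#' Reads the 20-nt gRNA protospacer and the 80-nt single-stranded donor
#' oligonucleotide (the 2-bp GGA-to-GAT codon edit shown in lower case) from
#' the package's FASTA fixture. The edit creates a BspHI site (TCATGA)
#' absent from the wild-type allele, the basis of the PCR-digest genotyping
#' assay.
#'
#' @return named character vector with elements `gRNA` and `donor`
#'   (case preserved as printed).
#' @export
g51dOligos <- function() {
  path <- system.file("extdata", "g51d_oligos.fasta", package = "dopaPET",
                      mustWork = TRUE)
  ss <- Biostrings::readBStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("_.*$", "", names(ss))
  c(gRNA = unname(out[["gRNA"]]), donor = unname(out[["donor"]]))
}
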