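#' @import methods
#' @importFrom stats rmultinom runif setNames
#' @importFrom utils read.delim write.table head
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges IRanges
#' @useDynLib sRNAcascade, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

#' Convert sequences to the package's internal DNA alphabet
#'
#' All sequences are stored over \{A,C,G,T\}; RNA input (U) is converted at
#' ingest, and case is normalised.
#'
#' @param x character vector of nucleotide sequences (DNA or RNA).
#' @return character vector over the DNA alphabet.
#' @export
asDNA <- function(x) chartr("Uu", "Tt", toupper(x))

#' Reverse complement of character sequences
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
reverseComplementSeq <- function(x) {
  stri_reverse <- stringi::stri_reverse
  chartr("ACGTN", "TGCAN", stri_reverse(asDNA(x)))
}

## Hamming distance between two equal-length sequences.
hammingDist <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hammingDist() needs equal-length sequences")
  sum(charToRaw(a) != charToRaw(b))
}

## Internal check that sequences contain only A/C/G/T (N optionally allowed).
assertDNA <- function(x, allowN = FALSE, what = "sequence") {
  pat <- if (allowN) "[^ACGTN]" else "[^ACGT]"
  bad <- stringi::stri_detect_regex(x, pat)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside the %s alphabet",
                 what, if (allowN) "A/C/G/T/N" else "A/C/G/T"))
  }
  invisible(TRUE)
}

## Deterministic random DNA string(s).
randomDNA <- function(n, width) {
  vapply(rep(width, length.out = n), function(w) {
    paste(sample(DNA_BASES4, w, replace = TRUE), collapse = "")
  }, character(1))
}

## Substitute k random positions of a sequence with different bases.
mutateSeq <- function(x, k) {
  ch <- strsplit(x, "")[[1]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(DNA_BASES4, ch[p]), 1)
  paste(ch, collapse = "")
}
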