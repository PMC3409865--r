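#' Read raw reads from a FASTQ file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; qualities are carried
#' by the file but unused by the pipeline.
#'
#' @param path FASTQ file.
#' @return character vector of read sequences.
#' @export
readReadsFastq <- function(path) {
  unname(as.character(Biostrings::readDNAStringSet(path, format = "fastq")))
}

#' Write reads to FASTQ with constant quality
#'
#' @param reads character vector of read sequences.
#' @param path output file.
#' @param qualityChar single Phred+33 quality character applied to every base.
#' @export
writeReadsFastq <- function(reads, path, qualityChar = "I") {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("read%07d", seq_along(reads))
  q <- Biostrings::BStringSet(strrep(qualityChar, nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Write collapsed unique reads as FASTA
#'
#' Headers follow the collapsed-read convention `>seq<i>_x<count>`.
#'
#' @param collapsed data.frame (`sequence`, `count`), e.g. from
#'   [collapseUnique()].
#' @param path output file.
#' @export
writeCollapsedFasta <- function(collapsed, path) {
  x <- Biostrings::DNAStringSet(collapsed$sequence)
  names(x) <- sprintf("seq%d_x%d", seq_len(nrow(collapsed)), collapsed$count)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write all libraries of a ReferenceBundle as FASTA files
#'
#' One file per non-empty library, named `<slot>.fasta`.
#'
#' @param bundle a [ReferenceBundle].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
writeBundleFasta <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (sl in c("chloroplast", "matureMirna", "precursorMirna", "homologMirna",
               "ncrna", "repeats", "genes", "transgene", "downstream",
               "genomeContigs", "relatedContigs", "targetTranscripts")) {
    x <- slot(bundle, sl)
    if (!length(x)) next
    f <- file.path(dir, paste0(sl, ".fasta"))
    Biostrings::writeXStringSet(x, f)
    out[sl] <- f
  }
  out
}

## TSV writer shared by the pipeline outputs.
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
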