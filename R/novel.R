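#' Fold a candidate precursor sequence
#'
#' Predicts a minimum-free-energy secondary structure.  The default backend
#' is the package's dynamic program (non-crossing AU/GC/GU pairs, a simple
#' nearest-neighbor stack table, loop penalties, minimum hairpin loop of
#' three bases; energies in kcal/mol).  Any function taking a sequence and
#' returning `list(pairs, mfe)` can replace it — e.g.
#' [viennaFoldBackend()] when the ViennaRNA `RNAfold` binary is available.
#'
#' @param sequence nucleotide sequence (DNA or RNA alphabet; non-ACGT/U
#'   characters are an error).
#' @param backend folding backend function, or `NULL` for the built-in.
#' @return a [FoldResult].
#' @export
foldHairpin <- function(sequence, backend = NULL) {
  sequence <- asDNA(sequence)
  assertDNA(sequence)
  res <- if (is.null(backend)) .foldEnergyCpp(sequence) else backend(sequence)
  new("FoldResult", sequence = sequence,
      pairs = as.integer(res$pairs), mfe = as.numeric(res$mfe))
}

#' ViennaRNA folding backend
#'
#' Returns a backend for [foldHairpin()] that shells out to `RNAfold`.
#' Purely optional: the package never requires it.
#'
#' @param binary path to the RNAfold executable.
#' @return function usable as the `backend` argument of [foldHairpin()].
#' @export
viennaFoldBackend <- function(binary = "RNAfold") {
  if (Sys.which(binary) == "")
    stop("RNAfold binary not found")
  function(sequence) {
    out <- system2(binary, c("--noPS"), input = sequence, stdout = TRUE)
    line <- out[2L]
    db <- sub(" .*$", "", line)
    mfe <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", line))
    list(pairs = parseDotBracket(db), mfe = mfe)
  }
}

#' Map cascade-unassigned reads onto genomic/EST contigs
#'
#' Primary-species contigs are searched with a 1-substitution budget;
#' reads that fail there are searched in related-species contigs with up
#' to 2 substitutions.  Primary hits always take precedence.
#'
#' @param reads character vector (or [UniqueReadSet]) of unassigned reads.
#' @param primary,related contig sets ([Biostrings::DNAStringSet] or named
#'   character).
#' @param primaryMismatch,relatedMismatch substitution budgets.
#' @return data.frame of loci: `sequence`, `feature` (contig), `strand`,
#'   `position`, `mismatches`, `contigSet` (`primary`/`related`).
#' @export
mapUnassigned <- function(reads, primary, related = NULL,
                          primaryMismatch = 1L, relatedMismatch = 2L) {
  if (is(reads, "UniqueReadSet")) reads <- readSequences(reads)
  hits <- matchReads(reads, primary, primaryMismatch, c("+", "-"))
  hits$contigSet <- rep("primary", nrow(hits))
  rest <- setdiff(reads, hits$sequence)
  if (!is.null(related) && length(rest)) {
    h2 <- matchReads(rest, related, relatedMismatch, c("+", "-"))
    if (nrow(h2)) {
      h2$contigSet <- "related"
      hits <- rbind(hits, h2)
    }
  }
  `rownames<-`(hits, NULL)
}

#' Candidate precursor windows around a mapped read
#'
#' Emits a 5'-arm-biased and a 3'-arm-biased window around the read locus
#' (the hairpin may lie on either side), clipped at the contig ends; every
#' window contains the read locus.  For minus-strand loci the window
#' sequence is reverse-complemented so the read always lies on the
#' returned strand.
#'
#' @param contig contig sequence.
#' @param start,end 1-based read locus on the contig's + strand.
#' @param strand locus strand.
#' @param flank window extent (nt) on the hairpin side of the read.
#' @param near short extent (nt) on the read's own side.
#' @return data.frame: `window` (`arm5`/`arm3`), `start`, `end` (contig
#'   coordinates), `readStart`, `readEnd` (read position inside the window
#'   sequence), `sequence`.
#' @export
extractPrecursorWindow <- function(contig, start, end, strand = "+",
                                   flank = 150L, near = 20L) {
  if (is(contig, "DNAStringSet")) contig <- as.character(contig)[1]
  L <- nchar(contig)
  stopifnot(start >= 1L, end <= L, start <= end)
  win <- data.frame(
    window = c("arm5", "arm3"),
    start = pmax(1L, c(start - near, start - flank)),
    end = pmin(L, c(end + flank, end + near)))
  win$sequence <- substring(contig, win$start, win$end)
  win$readStart <- start - win$start + 1L
  win$readEnd <- end - win$start + 1L
  if (strand == "-") {
    w <- nchar(win$sequence)
    rs <- w - win$readEnd + 1L
    win$readEnd <- w - win$readStart + 1L
    win$readStart <- rs
    win$sequence <- reverseComplementSeq(win$sequence)
    win$window <- rev(win$window)
  }
  win
}

## Does the read lie on a single, well-paired hairpin arm?
armPairedOk <- function(pairs, readStart, readEnd, minFraction = 0.6) {
  span <- readStart:readEnd
  partners <- pairs[span]
  paired <- partners > 0L
  if (mean(paired) < minFraction) return(FALSE)
  pp <- partners[paired]
  all(pp < readStart) || all(pp > readEnd)
}

## Longest open reading frame (codons) overlapping a locus, 3 forward frames.
longestOrfCodons <- function(sequence, readStart, readEnd) {
  best <- 0L
  n <- nchar(sequence)
  for (fr in 0:2) {
    codons <- substring(sequence, seq(1L + fr, n - 2L, by = 3L),
                        seq(3L + fr, n, by = 3L))
    isStart <- codons == "ATG"
    isStop <- codons %in% c("TAA", "TAG", "TGA")
    open <- NA_integer_
    for (k in seq_along(codons)) {
      if (is.na(open) && isStart[k]) open <- k
      if (!is.na(open) && isStop[k]) {
        a <- (open - 1L) * 3L + 1L + fr
        b <- k * 3L + fr
        if (a <= readEnd && b >= readStart) best <- max(best, k - open + 1L)
        open <- NA_integer_
      }
    }
  }
  best
}

#' Screen novel miRNA candidates
#'
#' Applies the discovery filters to folded candidates: a candidate fails
#' when its read maps into the repeat set (`fail_repeat`), when the hairpin
#' MFE does not clear the threshold — strictly lower than -18 kcal/mol by
#' default (`fail_mfe`) — or when the read does not lie on a single hairpin
#' arm with at least `armPairedFraction` of its bases paired
#' (`fail_hairpin`); otherwise it passes.  When `candidates` carries an
#' `mfe` column but no fold objects (externally supplied energies), only
#' the repeat and MFE rules apply.
#'
#' @param candidates data.frame with `sequence` (the read), `mfe`, and
#'   optionally `fold` (list of [FoldResult]), `readStart`, `readEnd`.
#' @param mfeThreshold MFE cut (kcal/mol); pass requires `mfe < threshold`.
#' @param repeatSet repeat/TE library, or `NULL` to skip the repeat rule.
#' @param armPairedFraction minimum fraction of read bases paired.
#' @return the input with a `verdict` column (`pass`, `fail_repeat`,
#'   `fail_mfe`, `fail_hairpin`).
#' @export
filterCandidates <- function(candidates, mfeThreshold = -18,
                             repeatSet = NULL, armPairedFraction = 0.6) {
  inRepeat <- rep(FALSE, nrow(candidates))
  if (!is.null(repeatSet) && length(repeatSet) && nrow(candidates)) {
    hits <- matchReads(candidates$sequence, repeatSet, 0L, c("+", "-"))
    inRepeat <- candidates$sequence %in% hits$sequence
  }
  verdict <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    verdict[i] <- if (inRepeat[i]) "fail_repeat"
    else if (!(candidates$mfe[i] < mfeThreshold)) "fail_mfe"
    else if (!is.null(candidates$fold) &&
             !armPairedOk(pairTable(candidates$fold[[i]]),
                          candidates$readStart[i], candidates$readEnd[i],
                          armPairedFraction)) "fail_hairpin"
    else "pass"
  }
  candidates$verdict <- verdict
  candidates
}

#' Discover novel miRNA candidates from unassigned reads
#'
#' The full discovery path: map the cascade remainder onto genomic/EST
#' contigs (primary species 1 substitution, related species 2), extract
#' arm-biased precursor windows, fold each window, keep the window giving
#' the lower MFE with the read on a single arm, and apply the repeat, MFE
#' and hairpin filters.  An open-reading-frame flag (>= `orfCodons` codons
#' spanning the locus) marks likely protein-coding windows.
#'
#' @param reads a [UniqueReadSet] of cascade-unassigned reads, or a
#'   character vector.
#' @param bundle a [ReferenceBundle] (contigs + repeat set).
#' @param flank precursor window extent per side (nt).
#' @param mfeThreshold MFE pass threshold (kcal/mol, strict).
#' @param armPairedFraction minimum paired fraction of the read.
#' @param orfCodons ORF length (codons) that flags a window.
#' @param backend folding backend, see [foldHairpin()].
#' @return data.frame of candidates: read, locus, window, `mfe`, `verdict`,
#'   `orfFlag`, plus a `fold` list-column of [FoldResult] objects.
#' @export
discoverNovelMirnas <- function(reads, bundle, flank = 150L,
                                mfeThreshold = -18, armPairedFraction = 0.6,
                                orfCodons = 80L, backend = NULL) {
  loci <- mapUnassigned(reads, bundle@genomeContigs, bundle@relatedContigs)
  if (!nrow(loci)) return(data.frame())
  ## one locus per read: primary before related, then fewest mismatches
  loci <- loci[order(match(loci$contigSet, c("primary", "related")),
                     loci$mismatches), ]
  loci <- loci[!duplicated(loci$sequence), , drop = FALSE]
  contigs <- c(setNames(as.character(bundle@genomeContigs),
                        names(bundle@genomeContigs)),
               setNames(as.character(bundle@relatedContigs),
                        names(bundle@relatedContigs)))
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    rd <- loci$sequence[i]
    e <- loci$position[i] + nchar(rd) - 1L
    win <- extractPrecursorWindow(contigs[[loci$feature[i]]],
                                  loci$position[i], e, loci$strand[i], flank)
    folds <- lapply(win$sequence, foldHairpin, backend = backend)
    armOk <- vapply(seq_len(nrow(win)), function(k)
      armPairedOk(pairTable(folds[[k]]), win$readStart[k], win$readEnd[k],
                  armPairedFraction), logical(1))
    mfes <- vapply(folds, mfe, numeric(1))
    k <- order(!armOk, mfes)[1L]   # prefer windows with the read on an arm
    rows[[i]] <- data.frame(
      sequence = rd, contig = loci$feature[i], contigSet = loci$contigSet[i],
      strand = loci$strand[i], locusStart = loci$position[i], locusEnd = e,
      window = win$window[k], readStart = win$readStart[k],
      readEnd = win$readEnd[k], mfe = mfes[k],
      orfFlag = longestOrfCodons(win$sequence[k], win$readStart[k],
                                 win$readEnd[k]) >= orfCodons)
    rows[[i]]$fold <- I(list(folds[[k]]))
  }
  out <- do.call(rbind, rows)
  filterCandidates(out, mfeThreshold, bundle@repeats, armPairedFraction)
}
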