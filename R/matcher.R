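#' Map reads onto reference sequences with a substitution budget
#'
#' Reports every alignment of a full read within a reference sequence with at
#' most `maxMismatch` substitutions (no indels), on the requested strands.
#' Minus-strand alignments are found by matching the reverse complement of
#' the read against the forward reference; positions are always reported
#' 1-based on the reference's + strand, at the leftmost base of the aligned
#' window.  Empty reads never map.
#'
#' Exact matching (budget 0) runs as a fixed-string search over a
#' concatenated reference; budgets above 0 use
#' [Biostrings::vmatchPattern()].  Both routes are checked against a
#' brute-force sliding Hamming scan in the package tests.
#'
#' @param reads character vector of read sequences.
#' @param subjects named character vector or [Biostrings::DNAStringSet] of
#'   reference sequences.
#' @param maxMismatch substitution budget.
#' @param strands strands to search: subset of `c("+", "-")`.
#' @param minLength reads shorter than this never map.
#' @return data.frame: `sequence`, `feature`, `strand`, `position`,
#'   `mismatches` (zero rows when nothing maps).
#' @export
matchReads <- function(reads, subjects, maxMismatch = 0L,
                       strands = c("+", "-"), minLength = 1L) {
  subjects <- if (is(subjects, "DNAStringSet")) {
    setNames(as.character(subjects), names(subjects))
  } else asDNA(subjects)
  if (is.null(names(subjects)) && length(subjects))
    names(subjects) <- sprintf("seq%d", seq_along(subjects))
  if (!length(subjects)) stop("empty reference library")
  reads <- asDNA(unique(reads))
  reads <- reads[nchar(reads) >= max(minLength, 1L)]
  empty <- data.frame(sequence = character(0), feature = character(0),
                      strand = character(0), position = integer(0),
                      mismatches = integer(0))
  if (!length(reads)) return(empty)

  res <- list()
  for (st in strands) {
    qry <- if (st == "+") reads else reverseComplementSeq(reads)
    hits <- if (maxMismatch == 0L) {
      .matchExact(qry, subjects)
    } else {
      .matchHamming(qry, subjects, maxMismatch)
    }
    if (nrow(hits)) {
      hits$sequence <- reads[hits$readIdx]
      hits$strand <- st
      res[[st]] <- hits[, c("sequence", "feature", "strand", "position",
                            "mismatches")]
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(match(out$sequence, reads), out$feature, out$strand,
            out$position), , drop = FALSE] |> `rownames<-`(NULL)
}

## Exact multi-pattern search: one fixed-string scan over the concatenated
## reference (separator cannot match any read).
.matchExact <- function(qry, subjects) {
  sep <- "#"
  big <- paste(subjects, collapse = sep)
  offsets <- c(0L, cumsum(nchar(subjects) + 1L))[seq_along(subjects)]
  ends <- offsets + nchar(subjects)
  loc <- stringi::stri_locate_all_fixed(big, qry, omit_no_match = TRUE)
  n <- vapply(loc, nrow, integer(1))
  if (!sum(n)) return(data.frame(readIdx = integer(0), feature = character(0),
                                 position = integer(0), mismatches = integer(0)))
  starts <- unlist(lapply(loc, function(m) m[, 1L]), use.names = FALSE)
  readIdx <- rep(seq_along(qry), n)
  subjIdx <- findInterval(starts, offsets + 1L)
  data.frame(readIdx = readIdx, feature = names(subjects)[subjIdx],
             position = as.integer(starts - offsets[subjIdx]),
             mismatches = 0L)
}

## Mismatch-tolerant search per read via Biostrings; out-of-bounds
## alignments (pattern hanging off the subject) are discarded so that the
## full read always lies within the reference.
.matchHamming <- function(qry, subjects, maxMismatch) {
  sset <- Biostrings::DNAStringSet(subjects)
  rows <- list()
  for (i in seq_along(qry)) {
    q <- qry[i]
    m <- Biostrings::vmatchPattern(q, sset, max.mismatch = maxMismatch,
                                   with.indels = FALSE, fixed = TRUE)
    for (j in seq_along(m)) {
      st <- Biostrings::startIndex(m)[[j]]
      if (is.null(st) || !length(st)) next
      keep <- st >= 1L & st + nchar(q) - 1L <= nchar(subjects[j])
      st <- st[keep]
      if (!length(st)) next
      mm <- vapply(st, function(s)
        hammingDist(q, substr(subjects[j], s, s + nchar(q) - 1L)), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        readIdx = i, feature = names(subjects)[j], position = as.integer(st),
        mismatches = as.integer(mm))
    }
  }
  if (!length(rows)) return(data.frame(readIdx = integer(0),
                                       feature = character(0),
                                       position = integer(0),
                                       mismatches = integer(0)))
  do.call(rbind, rows)
}
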