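#' Call a miRNA-guided cleavage position from a degradome tag
#'
#' miRNA-guided cleavage cuts the target between the nucleotides pairing
#' miRNA positions p and p+1 (canonically 10/11), so the 5' portion of the
#' remaining 3'-fragment tag is the reverse complement of miRNA positions
#' p..1.  For each candidate p the tag is tested after allowing up to
#' `maxOffsetSlack` extra 5' tag bases (flagged, not silent); calls with
#' less slack take precedence, then the smallest p.  The complementary
#' span tolerates no mismatches and credits no G:U wobble.
#'
#' @param tag degradome tag sequence (DNA or RNA alphabet).
#' @param mirna guiding miRNA sequence.
#' @param positions candidate cleavage positions p (label "p/p+1").
#' @param minSpan minimum complementary prefix length; shorter tags are
#'   never called.
#' @param maxOffsetSlack extra 5' tag bases tolerated before the
#'   complementary block.
#' @return one-row data.frame (`mirna` NA, `tag`, `position` label,
#'   `p`, `slack`, `matchedSpan`) or `NULL` when no position passes.
#' @export
callCleavage <- function(tag, mirna, positions = 10:15, minSpan = 10L,
                         maxOffsetSlack = 1L) {
  tag <- asDNA(tag)
  mirna <- asDNA(mirna)
  if (nchar(tag) < minSpan) return(NULL)
  for (slack in 0:maxOffsetSlack) {
    for (p in sort(positions)) {
      if (p < minSpan || p > nchar(mirna)) next
      if (nchar(tag) < slack + p) next
      block <- reverseComplementSeq(substr(mirna, 1L, p))
      if (substr(tag, slack + 1L, slack + p) == block) {
        return(data.frame(mirna = NA_character_, tag = tag,
                          position = sprintf("%d/%d", p, p + 1L),
                          p = p, slack = slack, matchedSpan = p))
      }
    }
  }
  NULL
}

#' Call cleavage positions for all tag/miRNA pairs
#'
#' @param tags character vector (or data.frame with a `tag` column) of
#'   degradome tags.
#' @param mirnas named character vector of guiding miRNAs.
#' @param ... passed to [callCleavage()].
#' @return data.frame of calls (zero rows when none).
#' @export
degradomeCalls <- function(tags, mirnas, ...) {
  if (is.data.frame(tags)) tags <- tags$tag
  tags <- unique(asDNA(tags))
  rows <- list()
  for (m in names(mirnas)) {
    for (tg in tags) {
      cl <- callCleavage(tg, mirnas[[m]], ...)
      if (!is.null(cl)) {
        cl$mirna <- m
        rows[[length(rows) + 1L]] <- cl
      }
    }
  }
  if (!length(rows))
    return(data.frame(mirna = character(0), tag = character(0),
                      position = character(0), p = integer(0),
                      slack = integer(0), matchedSpan = integer(0)))
  `rownames<-`(do.call(rbind, rows), NULL)
}

#' Locate degradome tags in a transcript set
#'
#' Exact forward-strand substring search; tags found in several
#' transcripts report all of them.  Reverse-complement occurrences are not
#' hits; they are returned separately as antisense matches.
#'
#' @param tags character vector of tags.
#' @param transcripts transcript set ([Biostrings::DNAStringSet] or named
#'   character).
#' @return list: `hits` (tag, transcript, position) and `antisense`
#'   (same shape, minus-strand-only occurrences).
#' @export
assignTags <- function(tags, transcripts) {
  tags <- unique(asDNA(tags))
  fwd <- matchReads(tags, transcripts, 0L, "+")
  rev <- matchReads(tags, transcripts, 0L, "-")
  list(hits = data.frame(tag = fwd$sequence, transcript = fwd$feature,
                         position = fwd$position),
       antisense = data.frame(tag = rev$sequence, transcript = rev$feature,
                              position = rev$position))
}

#' Per-miRNA degradome validation summary
#'
#' @param calls data.frame from [degradomeCalls()].
#' @param mirnas named character vector of all candidate miRNAs (so
#'   non-validated ones appear with zero tags).
#' @param tagHits optional `hits` table from [assignTags()] to list the
#'   transcripts of origin.
#' @return data.frame: `mirna`, `nTags`, `positions` (comma-separated),
#'   `transcripts`, `validated`.
#' @export
summarizeDegradome <- function(calls, mirnas, tagHits = NULL) {
  rows <- lapply(names(mirnas), function(m) {
    cl <- calls[calls$mirna == m, , drop = FALSE]
    tx <- ""
    if (!is.null(tagHits) && nrow(cl)) {
      tx <- paste(sort(unique(tagHits$transcript[tagHits$tag %in% cl$tag])),
                  collapse = ",")
    }
    data.frame(mirna = m, nTags = length(unique(cl$tag)),
               positions = paste(unique(cl$position[order(cl$p)]),
                                 collapse = ","),
               transcripts = tx, validated = nrow(cl) > 0L)
  })
  `rownames<-`(do.call(rbind, rows), NULL)
}
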