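#' Remove artifact reads before trimming
#'
#' Drops reads containing one or more `N` calls and reads that are a
#' single-nucleotide homopolymer over their whole length (poly-A/T/C/G).
#' All other reads pass through unchanged.
#'
#' @param reads character vector of raw read sequences.
#' @return list with `reads` (survivors), and `removed`, a named integer
#'   vector of removal counts per reason (`n_containing`, `homopolymer`).
#' @export
filterArtifactReads <- function(reads) {
  reads <- asDNA(reads)
  hasN <- stringi::stri_detect_fixed(reads, "N")
  first <- substr(reads, 1L, 1L)
  homo <- !hasN & reads == strrep(first, nchar(reads))
  list(reads = reads[!hasN & !homo],
       removed = c(n_containing = sum(hasN), homopolymer = sum(homo)))
}

#' Trim the 3' adapter from fixed-length reads
#'
#' Scans each read for the 3' adapter.  A hit at 1-based position `s` aligns
#' the adapter prefix against the read from `s` to the read end; at least
#' `minMatch` bases must align (so positions beyond `width - minMatch + 1`
#' are never considered) with at most `maxMismatch` mismatches, counted only
#' over aligned bases.  The primary scan starts at `searchStart`; reads with
#' no primary hit are rescanned permissively from position 1, which recovers
#' short inserts (0-16 nt) including pure-adapter reads.  The leftmost hit of
#' a pass wins.
#'
#' @param reads character vector of equal-width reads (no `N`).
#' @param adapter3 the 3' adapter sequence (DNA or RNA alphabet).
#' @param minMatch minimum number of aligned adapter bases for a hit.
#' @param maxMismatch maximum substitutions tolerated over the aligned bases.
#' @param searchStart first 1-based read position of the primary scan.
#' @param secondaryScan rescan unmatched reads from position 1 (on by
#'   default); with `FALSE` only the primary pass runs.
#' @return data.frame with one row per read: `status` (`trimmed`,
#'   `adapter_only` or `untrimmed`), `insert`, `adapterStart` (NA when
#'   untrimmed), `mismatches`, and `pass` (`primary`/`secondary`).
#' @export
trimAdapter <- function(reads, adapter3, minMatch = 10L, maxMismatch = 1L,
                        searchStart = 18L, secondaryScan = TRUE) {
  adapter3 <- asDNA(adapter3)
  if (nchar(adapter3) < minMatch)
    stop("adapter is shorter than the minimum match length")
  reads <- asDNA(reads)
  w <- unique(nchar(reads))
  if (length(w) == 0L) {
    return(data.frame(status = character(0), insert = character(0),
                      adapterStart = integer(0), mismatches = integer(0),
                      pass = character(0)))
  }
  if (length(w) != 1L) stop("trimAdapter() expects equal-width reads")
  assertDNA(reads, what = "read")

  n <- length(reads)
  ## byte matrix: one column per read
  m <- matrix(charToRaw(paste(reads, collapse = "")), nrow = w)
  araw <- charToRaw(adapter3)
  lastStart <- w - minMatch + 1L

  adapterStart <- rep(NA_integer_, n)
  mismatches <- rep(NA_integer_, n)
  pass <- rep(NA_character_, n)

  scan <- function(positions, open, passLabel) {
    for (s in positions) {
      if (!any(open)) break
      L <- min(nchar(adapter3), w - s + 1L)
      mm <- colSums(m[s:(s + L - 1L), open, drop = FALSE] != araw[1:L])
      hit <- mm <= maxMismatch
      if (any(hit)) {
        idx <- which(open)[hit]
        adapterStart[idx] <<- s
        mismatches[idx] <<- mm[hit]
        pass[idx] <<- passLabel
        open[idx] <<- FALSE
      }
    }
    open
  }

  open <- rep(TRUE, n)
  if (searchStart <= lastStart)
    open <- scan(seq.int(searchStart, lastStart), open, "primary")
  if (secondaryScan && searchStart > 1L)
    open <- scan(seq.int(1L, min(searchStart - 1L, lastStart)), open, "secondary")

  status <- ifelse(is.na(adapterStart), "untrimmed",
                   ifelse(adapterStart == 1L, "adapter_only", "trimmed"))
  insert <- ifelse(is.na(adapterStart), NA_character_,
                   substr(reads, 1L, pmax(adapterStart - 1L, 0L)))
  data.frame(status = status, insert = insert, adapterStart = adapterStart,
             mismatches = mismatches, pass = pass)
}

#' Discard untrimmed reads
#'
#' Keeps the inserts of reads in which the adapter was found (including
#' length-0 inserts from pure-adapter reads, which populate the length-0 row
#' of the size-distribution tables) and logs the discards.
#'
#' @param trimmed data.frame from [trimAdapter()].
#' @return character vector of inserts with attribute `removed` giving the
#'   number of untrimmed reads discarded.
#' @export
removeUntrimmed <- function(trimmed) {
  keep <- trimmed$status %in% c("trimmed", "adapter_only")
  structure(trimmed$insert[keep], removed = sum(!keep))
}

#' Collapse reads to unique sequences with counts
#'
#' @param inserts character vector of trimmed insert sequences (may repeat).
#' @return data.frame (`sequence`, `count`) sorted by descending count then
#'   lexicographically; `sum(count) == length(inserts)`.
#' @export
collapseUnique <- function(inserts) {
  if (!length(inserts))
    return(data.frame(sequence = character(0), count = integer(0)))
  tb <- table(inserts)
  out <- data.frame(sequence = names(tb), count = as.integer(tb))
  out[order(-out$count, out$sequence), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Combine per-group collapsed reads into a UniqueReadSet
#'
#' @param ... named data.frames from [collapseUnique()], one per group.
#' @return a [UniqueReadSet] over the union of sequences.
#' @export
buildUniqueReadSet <- function(...) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1]]) &&
      !is.data.frame(groups[[1]])) groups <- groups[[1]]
  stopifnot(length(groups) >= 1L, !is.null(names(groups)))
  seqs <- sort(unique(unlist(lapply(groups, `[[`, "sequence"))))
  cnt <- vapply(groups, function(g) {
    v <- setNames(g$count, g$sequence)
    out <- v[seqs]
    out[is.na(out)] <- 0L
    as.integer(out)
  }, integer(length(seqs)))
  cnt <- matrix(cnt, ncol = length(groups),
                dimnames = list(NULL, names(groups)))
  UniqueReadSet(seqs, cnt)
}

#' Thresholded size-distribution table
#'
#' For each read length 0..`maxLength` and each read-count threshold,
#' tabulates the number of unique reads with count >= threshold (limit
#' included) and their summed read count, with a totals row appended.
#' Untrimmed full-length reads can be folded in as a diagnostic length-36
#' row; they are excluded from all downstream classification.
#'
#' @param collapsed data.frame (`sequence`, `count`) for one group.
#' @param thresholds integer read-count thresholds.
#' @param maxLength last length row of the table.
#' @param untrimmed optional data.frame (`sequence`, `count`) of untrimmed
#'   full-width reads to report in the `maxLength` row (diagnostics only).
#' @return data.frame with a `length` column (`"total"` for the final row)
#'   and `unique_t<t>` / `count_t<t>` columns per threshold.
#' @export
sizeDistribution <- function(collapsed, thresholds = c(1L, 4L, 10L),
                             maxLength = 36L, untrimmed = NULL) {
  if (any(thresholds < 1L)) stop("thresholds must be >= 1")
  if (!is.null(untrimmed) && nrow(untrimmed)) {
    untrimmed$sequence <- paste0(untrimmed$sequence, "*")  # keep rows distinct
    collapsed <- rbind(collapsed, untrimmed)
  }
  len <- nchar(sub("\\*$", "", collapsed$sequence))
  out <- data.frame(length = c(0:maxLength, "total"))
  for (t in sort(thresholds)) {
    keep <- collapsed$count >= t
    u <- tabulate(len[keep] + 1L, nbins = maxLength + 1L)
    cc <- vapply(0:maxLength, function(l)
      sum(collapsed$count[keep & len == l]), numeric(1))
    out[[sprintf("unique_t%d", t)]] <- c(u, sum(u))
    out[[sprintf("count_t%d", t)]] <- c(cc, sum(cc))
  }
  out
}

#' Preprocess raw FASTQ libraries into a UniqueReadSet
#'
#' Full preprocessing for any number of groups: artifact filtering, adapter
#' trimming ([trimAdapter()]), removal of untrimmed reads, unique-read
#' collapsing and size-distribution tabulation.
#'
#' @param fastq named character vector of FASTQ paths (names = group labels),
#'   or a named list of in-memory read vectors.
#' @param adapter3 3' adapter sequence.
#' @param thresholds read-count thresholds for the size tables.
#' @param ... passed to [trimAdapter()].
#' @return list with `reads` (a [UniqueReadSet]), `sizeDistribution` (per
#'   group), and `log` (per-group accounting: raw, artifact, untrimmed,
#'   trimmed read totals).
#' @export
preprocessReads <- function(fastq, adapter3, thresholds = c(1L, 4L, 10L), ...) {
  stopifnot(!is.null(names(fastq)))
  perGroup <- list()
  sizes <- list()
  log <- list()
  for (g in names(fastq)) {
    raw <- if (is.character(fastq[[g]]) && length(fastq[[g]]) == 1L &&
               file.exists(fastq[[g]])) readReadsFastq(fastq[[g]]) else fastq[[g]]
    flt <- filterArtifactReads(raw)
    tr <- trimAdapter(flt$reads, adapter3, ...)
    inserts <- removeUntrimmed(tr)
    col <- collapseUnique(inserts)
    untr <- collapseUnique(flt$reads[tr$status == "untrimmed"])
    perGroup[[g]] <- col
    sizes[[g]] <- sizeDistribution(col, thresholds, untrimmed = untr)
    log[[g]] <- c(raw = length(raw), removed_artifact = sum(flt$removed),
                  untrimmed = attr(inserts, "removed"),
                  trimmed = length(inserts))
  }
  ## length-0 (pure-adapter) inserts populate the size tables' 0 row but
  ## carry no sequence to classify; they are excluded from the read set
  nonEmpty <- lapply(perGroup, function(g) g[nchar(g$sequence) > 0L, ])
  list(reads = buildUniqueReadSet(nonEmpty), sizeDistribution = sizes,
       log = log)
}
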