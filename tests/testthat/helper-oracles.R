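## Independent brute-force oracles the implementation is checked against.

oracleRevcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(ch)
    paste(rev(ch), collapse = ""), character(1)))
}

## Sliding-window Hamming scan: every alignment of the full read within the
## subjects with <= maxMismatch substitutions, both strands.
oracleMatch <- function(read, subjects, maxMismatch = 0L,
                        strands = c("+", "-")) {
  rows <- list()
  for (st in strands) {
    q <- if (st == "+") read else oracleRevcomp(read)
    qc <- strsplit(q, "")[[1]]
    for (f in names(subjects)) {
      sc <- strsplit(subjects[[f]], "")[[1]]
      w <- length(qc)
      if (w == 0 || w > length(sc)) next
      for (s in seq_len(length(sc) - w + 1L)) {
        mm <- sum(sc[s:(s + w - 1L)] != qc)
        if (mm <= maxMismatch)
          rows[[length(rows) + 1L]] <- data.frame(
            sequence = read, feature = f, strand = st, position = s,
            mismatches = mm)
      }
    }
  }
  if (!length(rows))
    return(data.frame(sequence = character(0), feature = character(0),
                      strand = character(0), position = integer(0),
                      mismatches = integer(0)))
  do.call(rbind, rows)
}

## Exhaustive (position, mismatch) enumeration of the adapter scan.
oracleTrim <- function(read, adapter, minMatch = 10L, maxMismatch = 1L,
                       searchStart = 18L) {
  w <- nchar(read)
  rc <- strsplit(read, "")[[1]]
  ac <- strsplit(adapter, "")[[1]]
  hits <- data.frame(pos = integer(0), mm = integer(0))
  for (s in seq_len(w - minMatch + 1L)) {
    L <- min(length(ac), w - s + 1L)
    mm <- sum(rc[s:(s + L - 1L)] != ac[1:L])
    if (mm <= maxMismatch) hits <- rbind(hits, data.frame(pos = s, mm = mm))
  }
  prim <- hits[hits$pos >= searchStart, , drop = FALSE]
  sec <- hits[hits$pos < searchStart, , drop = FALSE]
  if (nrow(prim)) {
    list(status = if (prim$pos[1] == 1L) "adapter_only" else "trimmed",
         start = prim$pos[1], pass = "primary")
  } else if (nrow(sec)) {
    list(status = if (sec$pos[1] == 1L) "adapter_only" else "trimmed",
         start = sec$pos[1], pass = "secondary")
  } else {
    list(status = "untrimmed", start = NA_integer_, pass = NA_character_)
  }
}

## sort-and-scan collapsing oracle (no hashing)
oracleCollapse <- function(inserts) {
  s <- sort(inserts)
  r <- rle(s)
  out <- data.frame(sequence = r$values, count = r$lengths)
  out[order(-out$count, out$sequence), , drop = FALSE]
}

randomReads <- function(n, width = 36L) {
  vapply(rep(width, length.out = n), function(w)
    paste(sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = ""),
    character(1))
}

## A shared small bundle (built once per test run).
.testEnv <- new.env()
testBundle <- function() {
  if (is.null(.testEnv$bundle))
    .testEnv$bundle <- generateReferenceBundle(seed = 42L)
  .testEnv$bundle
}

## A hand-built minimal bundle for cascade precedence tests.
toyBundle <- function(matureMirna = character(0), repeats = character(0),
                      ncrna = character(0), genes = character(0),
                      chloroplast = character(0)) {
  dss <- function(x) Biostrings::DNAStringSet(x)
  emptyDf <- data.frame()
  new("ReferenceBundle",
      chloroplast = dss(chloroplast), matureMirna = dss(matureMirna),
      precursorMirna = dss(character(0)), homologMirna = dss(character(0)),
      ncrna = dss(ncrna), repeats = dss(repeats), genes = dss(genes),
      transgene = dss(character(0)), downstream = dss(character(0)),
      genomeContigs = dss(character(0)), relatedContigs = dss(character(0)),
      targetTranscripts = dss(character(0)),
      matureMap = data.frame(mature = character(0), precursor = character(0),
                             start = integer(0), end = integer(0)),
      ncrnaFamily = rep("misc", length(ncrna)),
      repeatClass = rep("unclassified", length(repeats)),
      dominantTrna = character(0), targetSites = emptyDf,
      features = emptyDf, seed = NA_integer_)
}

## Perfect-stem precursor helper: arm + loop + revcomp(arm).
perfectHairpin <- function(armLen = 30L, loopLen = 8L) {
  arm <- paste(sample(c("A", "C", "G", "T"), armLen, TRUE), collapse = "")
  loop <- paste(sample(c("A", "C", "G", "T"), loopLen, TRUE), collapse = "")
  paste0(arm, loop, oracleRevcomp(arm))
}
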