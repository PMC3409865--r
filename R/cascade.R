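#' Default cascade configuration
#'
#' The classification order, fixed by the analysis design: chloroplast
#' genome (0 mismatches, both strands) first, then species mature miRNAs
#' (0 mismatches, reads >= 17 nt), homologous miRNAs (0), ncRNA families
#' (2 mismatches, the only relaxed stage), repeats (0, reads >= 20 nt),
#' the reverse strand of nuclear genes (antisense siRNAs, 0), and the
#' transgene set (transgene plus regulated downstream genes, 0, both
#' strands).  Reads mapped at a stage are removed before the next.
#'
#' @return a [CascadeConfig].
#' @export
cascadeConfig <- function() {
  new("CascadeConfig", stages = data.frame(
    stage = c("chloroplast", "mirna", "homolog_mirna", "ncrna", "repeats",
              "genes_antisense", "transgene"),
    library = c("chloroplast", "matureMirna", "homologMirna", "ncrna",
                "repeats", "genes", "transgeneSet"),
    maxMismatch = c(0L, 0L, 0L, 2L, 0L, 0L, 0L),
    strands = c("both", "+", "+", "both", "both", "-", "both"),
    minLength = c(1L, 17L, 17L, 1L, 20L, 1L, 1L)
  ))
}

## Resolve a stage's library name to sequences from the bundle.
cascadeLibrary <- function(bundle, library) {
  if (library == "transgeneSet")
    return(c(bundle@transgene, bundle@downstream))
  slot(bundle, library)
}

#' Run the ordered classification cascade
#'
#' Applies every stage of `config` in order: reads passing the stage's
#' length filter are matched against the stage library within its mismatch
#' budget; mapped reads are labelled with the stage and removed from the
#' stream so each unique read receives at most one library label.  Reads no
#' stage claims are returned as the unassigned remainder (the input to
#' novel-miRNA discovery).
#'
#' @param reads a [UniqueReadSet].
#' @param bundle a [ReferenceBundle].
#' @param config a [CascadeConfig]; the default order is part of the method.
#' @return a [CascadeResult].
#' @export
runCascade <- function(reads, bundle, config = cascadeConfig()) {
  validObject(config)
  st <- config@stages
  cnt <- readCounts(reads)
  seqs <- readSequences(reads)
  remaining <- seqs
  asn <- list()
  summ <- list()
  for (j in seq_len(nrow(st))) {
    lib <- cascadeLibrary(bundle, st$library[j])
    eligible <- remaining[nchar(remaining) >= st$minLength[j]]
    hits <- if (length(eligible) && length(lib)) {
      strands <- if (st$strands[j] == "both") c("+", "-") else st$strands[j]
      matchReads(eligible, lib, st$maxMismatch[j], strands)
    } else {
      data.frame(sequence = character(0), feature = character(0),
                 strand = character(0), position = integer(0),
                 mismatches = integer(0))
    }
    mapped <- unique(hits$sequence)
    if (nrow(hits)) {
      hits$stage <- st$stage[j]
      nFeat <- tapply(hits$feature, hits$sequence, function(x)
        length(unique(x)))
      hits$multi <- nFeat[hits$sequence] > 1L
      asn[[st$stage[j]]] <- hits[, c("sequence", "stage", "feature", "strand",
                                     "position", "mismatches", "multi")]
    }
    idx <- match(mapped, seqs)
    summ[[st$stage[j]]] <- data.frame(
      stage = st$stage[j], unique = length(mapped),
      t(colSums(cnt[idx, , drop = FALSE])))
    remaining <- setdiff(remaining, mapped)
  }
  idx <- match(remaining, seqs)
  summ[["unassigned"]] <- data.frame(
    stage = "unassigned", unique = length(remaining),
    t(colSums(cnt[idx, , drop = FALSE])))
  summary <- do.call(rbind, summ)
  rownames(summary) <- NULL
  assignments <- if (length(asn)) do.call(rbind, asn) else
    data.frame(sequence = character(0), stage = character(0),
               feature = character(0), strand = character(0),
               position = integer(0), mismatches = integer(0),
               multi = logical(0))
  rownames(assignments) <- NULL
  new("CascadeResult", assignments = assignments, summary = summary,
      unassigned = remaining, config = config)
}

#' Partition reads into chloroplast and non-chloroplast streams
#'
#' Zero-mismatch, both-strand mapping against the chloroplast genome; the
#' two outputs partition the input exactly at the unique-read and
#' read-count level.
#'
#' @param reads a [UniqueReadSet].
#' @param chloroplast chloroplast genome ([Biostrings::DNAStringSet] or
#'   character).
#' @return list: `chloroplast` and `nonChloroplast` (both [UniqueReadSet]),
#'   plus `summary` (per-stream unique reads and counts per group).
#' @export
partitionChloroplast <- function(reads, chloroplast) {
  hits <- matchReads(readSequences(reads), chloroplast, 0L, c("+", "-"))
  isCp <- readSequences(reads) %in% hits$sequence
  cnt <- readCounts(reads)
  summary <- data.frame(
    stream = c("chloroplast", "non_chloroplast"),
    unique = c(sum(isCp), sum(!isCp)),
    rbind(colSums(cnt[isCp, , drop = FALSE]),
          colSums(cnt[!isCp, , drop = FALSE])))
  list(chloroplast = reads[isCp, ], nonChloroplast = reads[!isCp, ],
       summary = summary)
}

#' Count reads matching known mature miRNAs
#'
#' Exact (0-mismatch, forward-strand) mapping of reads of at least
#' `minLength` nt against the mature miRNA library; per-miRNA read counts
#' per group are reported and reads hitting several matures are flagged.
#'
#' @param reads a [UniqueReadSet] (non-chloroplast stream).
#' @param matureSet mature miRNA library.
#' @param minLength minimum read length entering miRNA mapping.
#' @return list: `table` (per-miRNA sequence + per-group counts +
#'   `unique` reads + `multi` flag) and `mapped` (sequences claimed).
#' @export
profileKnownMirnas <- function(reads, matureSet, minLength = 17L) {
  if (is(matureSet, "DNAStringSet"))
    matureSet <- setNames(as.character(matureSet), names(matureSet))
  hits <- matchReads(readSequences(reads), matureSet, 0L, "+",
                     minLength = minLength)
  cnt <- readCounts(reads)
  seqs <- readSequences(reads)
  groups <- colnames(cnt)
  nFeat <- if (nrow(hits)) tapply(hits$feature, hits$sequence,
                                  function(x) length(unique(x))) else integer(0)
  tab <- lapply(names(matureSet), function(m) {
    rs <- unique(hits$sequence[hits$feature == m])
    idx <- match(rs, seqs)
    row <- data.frame(mirna = m, sequence = matureSet[[m]],
                      unique = length(rs),
                      multi = any(nFeat[rs] > 1L))
    for (g in groups) row[[g]] <- sum(cnt[idx, g])
    row
  })
  tab <- do.call(rbind, tab)
  list(table = tab[order(-tab[[groups[1]]]), , drop = FALSE] |>
         `rownames<-`(NULL),
       mapped = unique(hits$sequence))
}

#' Theoretical star sequence of a mature miRNA
#'
#' Given a precursor, the mature's position on it, and a secondary
#' structure, returns the opposite-arm segment whose duplex with the mature
#' leaves the canonical 2-nt 3' overhang on each strand.  The mature's
#' paired bases anchor the duplex (with the outermost paired bases defining
#' it when ends are unpaired); a mature with no paired base, or one
#' spanning the loop, has no star.
#'
#' @param precursor precursor sequence.
#' @param matureStart,matureEnd 1-based mature coordinates on the precursor.
#' @param fold a [FoldResult] for the precursor, or `NULL` to fold with
#'   [foldHairpin()].
#' @return list: `sequence`, `start`, `end` of the star on the precursor.
#' @export
inferStarSequence <- function(precursor, matureStart, matureEnd, fold = NULL) {
  precursor <- asDNA(precursor)
  if (is.null(fold)) fold <- foldHairpin(precursor)
  p <- pairTable(fold)
  N <- nchar(precursor)
  m1 <- matureStart; m2 <- matureEnd
  paired <- which(p[m1:m2] > 0L) + m1 - 1L
  if (!length(paired)) stop("mature is unpaired in the structure; no star")
  partners <- p[paired]
  if (any(partners >= m1 & partners <= m2))
    stop("mature pairs with itself (spans the loop); no star")
  ## extrapolated partner of x from the nearest paired mature base; on a
  ## nested (non-crossing) stem, partner coordinates run antiparallel
  partnerAt <- function(x) {
    a <- paired[which.min(abs(paired - x))]
    p[a] - (x - a)
  }
  s1 <- partnerAt(m2 - 2L)
  s2 <- partnerAt(m1) + 2L
  lo <- min(s1, s2); hi <- max(s1, s2)
  if (lo < 1L || hi > N || (hi >= m1 && lo <= m2))
    stop("star coordinates fall outside the opposite arm")
  list(sequence = substr(precursor, lo, hi), start = lo, end = hi)
}

#' Detect isomiRs on miRNA precursors
#'
#' A read (not itself claimed by exact mature matching) is an isomiR of a
#' miRNA when it aligns within the miRNA's precursor with at most one
#' substitution and its alignment overlaps the mature locus — covering 5'/3'
#' end extensions and truncations as well as single-substitution variants.
#' Reads aligning to several precursors are assigned to all and flagged.
#'
#' @param reads a [UniqueReadSet] of reads not matching any mature exactly.
#' @param precursors precursor library.
#' @param matureMap data.frame `mature`/`precursor`/`start`/`end` (as in a
#'   [ReferenceBundle]).
#' @param matureSet the mature library (exact matures are excluded).
#' @return list: `hits` (read-level calls) and `table` (per-precursor
#'   unique-read and per-group read-count summary).
#' @export
detectIsomirs <- function(reads, precursors, matureMap, matureSet = NULL) {
  if (is(precursors, "DNAStringSet"))
    precursors <- setNames(as.character(precursors), names(precursors))
  matSeq <- if (is.null(matureSet)) character(0) else as.character(matureSet)
  seqs <- readSequences(reads)
  seqs <- setdiff(seqs, matSeq)
  hits <- matchReads(seqs, precursors, maxMismatch = 1L, strands = "+")
  if (nrow(hits)) {
    ok <- logical(nrow(hits))
    for (i in seq_len(nrow(hits))) {
      mm <- matureMap[matureMap$precursor == hits$feature[i], , drop = FALSE]
      e <- hits$position[i] + nchar(hits$sequence[i]) - 1L
      ok[i] <- nrow(mm) && any(hits$position[i] <= mm$end & e >= mm$start)
    }
    hits <- hits[ok, , drop = FALSE]
  }
  cnt <- readCounts(reads)
  all <- readSequences(reads)
  groups <- colnames(cnt)
  nPre <- if (nrow(hits)) tapply(hits$feature, hits$sequence,
                                 function(x) length(unique(x))) else integer(0)
  tab <- lapply(unique(hits$feature), function(pr) {
    rs <- unique(hits$sequence[hits$feature == pr])
    idx <- match(rs, all)
    row <- data.frame(precursor = pr, unique = length(rs),
                      ambiguous = sum(nPre[rs] > 1L))
    for (g in groups) row[[g]] <- sum(cnt[idx, g])
    row
  })
  tab <- if (length(tab)) do.call(rbind, tab) else
    data.frame(precursor = character(0), unique = integer(0),
               ambiguous = integer(0))
  if (nrow(tab)) tab <- tab[order(-tab[[groups[1]]]), , drop = FALSE]
  list(hits = hits, table = `rownames<-`(tab, NULL))
}

#' Cluster reads by perfect inclusion
#'
#' Greedy clustering of reads that are exact substrings of each other:
#' reads are sorted by decreasing length (ties lexicographic, so the result
#' is independent of input order), each read joins the first cluster whose
#' representative contains it, otherwise it founds a new cluster with
#' itself as representative.
#'
#' @param reads character vector of read sequences.
#' @return data.frame: `sequence`, `cluster` (integer id), `representative`.
#' @export
clusterByInclusion <- function(reads) {
  reads <- unique(asDNA(reads))
  reads <- reads[order(-nchar(reads), reads)]
  reps <- character(0)
  cl <- integer(length(reads))
  for (i in seq_along(reads)) {
    hit <- which(stringi::stri_detect_fixed(reps, reads[i]))
    if (length(hit)) {
      cl[i] <- hit[1L]
    } else {
      reps <- c(reps, reads[i])
      cl[i] <- length(reps)
    }
  }
  data.frame(sequence = reads, cluster = cl, representative = reps[cl])
}

#' Per-position read coverage of a feature
#'
#' Fraction of unique reads (or of the read count) covering each position
#' of a feature sequence, strand-resolved — the per-gene coverage profile
#' used for the transgene and the dominant tRNA.
#'
#' @param reads a [UniqueReadSet].
#' @param feature a single reference sequence (character or DNAStringSet).
#' @param weightByCount weight positions by read counts instead of unique
#'   reads.
#' @return data.frame: `position`, `strand`, `fraction` (denominator: all
#'   unique reads, or all read counts, hitting that strand).
#' @export
coverageProfile <- function(reads, feature, weightByCount = FALSE) {
  if (is(feature, "DNAStringSet")) feature <- as.character(feature)[1]
  hits <- matchReads(readSequences(reads), c(feat = asDNA(feature)), 0L,
                     c("+", "-"))
  cnt <- readCounts(reads)
  seqs <- readSequences(reads)
  out <- list()
  for (st in c("+", "-")) {
    h <- hits[hits$strand == st, , drop = FALSE]
    cov <- numeric(nchar(feature))
    denom <- 0
    if (nrow(h)) {
      for (i in seq_len(nrow(h))) {
        w <- if (weightByCount) sum(cnt[match(h$sequence[i], seqs), ]) else 1
        span <- h$position[i]:(h$position[i] + nchar(h$sequence[i]) - 1L)
        cov[span] <- cov[span] + w
      }
      denom <- if (weightByCount)
        sum(cnt[match(unique(h$sequence), seqs), ]) else
        length(unique(h$sequence))
    }
    out[[st]] <- data.frame(position = seq_len(nchar(feature)), strand = st,
                            fraction = if (denom > 0) cov / denom else cov)
  }
  `rownames<-`(do.call(rbind, out), NULL)
}

#' Sense and antisense profile of the transgene set
#'
#' Exact-match hits per strand per gene per group over the transgene and
#' its downstream genes, with per-position coverage profiles and detection
#' of overlapping sense/antisense hit intervals.
#'
#' @param reads a [UniqueReadSet].
#' @param genes the transgene set (transgene + downstream genes).
#' @return list: `hits` (per gene/strand/group counts), `coverage` (named
#'   list of [coverageProfile()] tables), `overlaps` (gene/strand interval
#'   overlaps between sense and antisense hits).
#' @export
profileTransgene <- function(reads, genes) {
  if (is(genes, "DNAStringSet"))
    genes <- setNames(as.character(genes), names(genes))
  hits <- matchReads(readSequences(reads), genes, 0L, c("+", "-"))
  cnt <- readCounts(reads)
  seqs <- readSequences(reads)
  groups <- colnames(cnt)
  rows <- list()
  overlaps <- list()
  for (g in names(genes)) for (st in c("+", "-")) {
    h <- hits[hits$feature == g & hits$strand == st, , drop = FALSE]
    idx <- match(unique(h$sequence), seqs)
    row <- data.frame(gene = g, strand = st, unique = length(idx))
    for (gr in groups) row[[gr]] <- sum(cnt[idx, gr])
    rows[[paste(g, st)]] <- row
  }
  for (g in names(genes)) {
    hp <- hits[hits$feature == g & hits$strand == "+", , drop = FALSE]
    hm <- hits[hits$feature == g & hits$strand == "-", , drop = FALSE]
    if (nrow(hp) && nrow(hm)) {
      for (i in seq_len(nrow(hp))) for (j in seq_len(nrow(hm))) {
        e1 <- hp$position[i] + nchar(hp$sequence[i]) - 1L
        e2 <- hm$position[j] + nchar(hm$sequence[j]) - 1L
        if (hp$position[i] <= e2 && hm$position[j] <= e1)
          overlaps[[length(overlaps) + 1L]] <- data.frame(
            gene = g, senseStart = hp$position[i], senseEnd = e1,
            antisenseStart = hm$position[j], antisenseEnd = e2)
      }
    }
  }
  cov <- lapply(setNames(names(genes), names(genes)), function(g)
    coverageProfile(reads, genes[[g]]))
  list(hits = `rownames<-`(do.call(rbind, rows), NULL),
       coverage = cov,
       overlaps = if (length(overlaps)) do.call(rbind, overlaps) else
         data.frame())
}
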