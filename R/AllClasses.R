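#' @include AllGenerics.R
NULL

#' Reference libraries for the classification cascade
#'
#' A `ReferenceBundle` holds the ordered set of reference libraries a small-RNA
#' read can be assigned to: the chloroplast genome, the species' mature miRNAs
#' with their precursor hairpins, mature miRNAs of other species ("homologs"),
#' family-labelled ncRNAs (tRNA, rRNA, snoRNA, U6), repeat/transposable-element
#' sequences, nuclear gene transcripts, the transgene with its regulated
#' downstream genes, and genomic/EST contigs used for novel-miRNA discovery.
#' All sequences are stored over the DNA alphabet; every mature miRNA is an
#' exact substring of one arm of its precursor.
#'
#' The `features` slot is the generator's ground-truth registry: one row per
#' designed read species (insert sequence, class label, source feature), which
#' downstream tests use to score cascade recovery.  Bundles read from FASTA
#' files have an empty registry.
#'
#' @slot chloroplast,matureMirna,precursorMirna,homologMirna,ncrna,repeats,genes,transgene,downstream,genomeContigs,relatedContigs
#'   named [Biostrings::DNAStringSet] objects (some possibly empty).
#' @slot matureMap data.frame mapping each mature miRNA to its precursor and
#'   1-based coordinates (`mature`, `precursor`, `start`, `end`).
#' @slot ncrnaFamily,repeatClass character vectors of family/class labels
#'   parallel to `ncrna` and `repeats`.
#' @slot dominantTrna name of the ncRNA entry whose 5' fragment is designed to
#'   dominate the tRNA-derived fraction (emulating tRNA-His(GTG)).
#' @slot targetSites data.frame of implanted miRNA complementary sites used by
#'   the degradome generator (`mirna`, `gene`, `start`).
#' @slot features data.frame ground-truth registry (may have zero rows).
#' @slot seed integer seed the bundle was generated from (NA for file input).
#' @aliases ReferenceBundle
#' @export
setClass("ReferenceBundle", representation(
  chloroplast = "DNAStringSet",
  matureMirna = "DNAStringSet",
  precursorMirna = "DNAStringSet",
  homologMirna = "DNAStringSet",
  ncrna = "DNAStringSet",
  repeats = "DNAStringSet",
  genes = "DNAStringSet",
  transgene = "DNAStringSet",
  downstream = "DNAStringSet",
  genomeContigs = "DNAStringSet",
  relatedContigs = "DNAStringSet",
  targetTranscripts = "DNAStringSet",
  matureMap = "data.frame",
  ncrnaFamily = "character",
  repeatClass = "character",
  dominantTrna = "character",
  targetSites = "data.frame",
  features = "data.frame",
  seed = "integer"
))

setValidity("ReferenceBundle", function(object) {
  for (sl in c("chloroplast", "matureMirna", "precursorMirna", "homologMirna",
               "ncrna", "repeats", "genes", "transgene", "downstream",
               "genomeContigs", "relatedContigs", "targetTranscripts")) {
    s <- as.character(slot(object, sl))
    if (length(s) && any(stringi::stri_detect_regex(s, "[^ACGT]")))
      return(sprintf("library '%s' contains non-ACGT characters", sl))
  }
  mm <- object@matureMap
  if (nrow(mm)) {
    pre <- as.character(object@precursorMirna)
    for (i in seq_len(nrow(mm))) {
      p <- pre[[mm$precursor[i]]]
      if (substr(p, mm$start[i], mm$end[i]) !=
          as.character(object@matureMirna)[[mm$mature[i]]])
        return(sprintf("mature '%s' is not at %d..%d of its precursor",
                       mm$mature[i], mm$start[i], mm$end[i]))
    }
  }
  TRUE
})

setMethod("show", "ReferenceBundle", function(object) {
  cat("ReferenceBundle\n")
  for (sl in c("chloroplast", "matureMirna", "precursorMirna", "homologMirna",
               "ncrna", "repeats", "genes", "transgene", "downstream",
               "genomeContigs", "relatedContigs", "targetTranscripts")) {
    x <- slot(object, sl)
    cat(sprintf("  %-15s %4d sequence(s), %7d nt total\n", sl, length(x),
                sum(Biostrings::width(x))))
  }
  if (nrow(object@features))
    cat(sprintf("  ground truth: %d designed read species in %d classes\n",
                nrow(object@features), length(unique(object@features$class))))
})

#' Designed read composition of one sequencing library
#'
#' A `GroupProfile` describes one group's library: the expected read count per
#' designed feature (on the scale of the library total, net of artifact reads),
#' the designed log2 fold change of each feature relative to the control group
#' (on the normalized scale), the library size, the adapters, and the read
#' geometry.  `artifactFraction`, `adapterOnlyFraction` and `untrimmedFraction`
#' are the proportions of reads emitted as homopolymer/N artifacts, pure
#' adapter (length-0 insert) reads, and adapter-free 36-mers.
#'
#' @aliases GroupProfile
#' @export
setClass("GroupProfile", representation(
  groupLabel = "character",
  featureAbundance = "numeric",
  designedLog2 = "numeric",
  totalReads = "integer",
  adapter3 = "character",
  adapter5 = "character",
  readLength = "integer",
  insertLengthRange = "integer",
  artifactFraction = "numeric",
  adapterOnlyFraction = "numeric",
  untrimmedFraction = "numeric",
  seed = "integer"
))

setValidity("GroupProfile", function(object) {
  if (any(object@featureAbundance < 0)) return("expected counts must be >= 0")
  if (is.null(names(object@featureAbundance))) return("featureAbundance must be named")
  if (any(!is.finite(object@designedLog2))) return("designed log2 ratios must be finite")
  if (object@totalReads < 0L) return("totalReads must be >= 0")
  fr <- object@artifactFraction + object@adapterOnlyFraction + object@untrimmedFraction
  if (fr < 0 || fr >= 1) return("artifact fractions must sum to [0, 1)")
  if (length(object@insertLengthRange) != 2L ||
      object@insertLengthRange[1] < 17L)
    return("insert lengths below 17 nt are not supported")
  TRUE
})

setMethod("show", "GroupProfile", function(object) {
  cat(sprintf("GroupProfile '%s': %d reads, %d features, adapter3 %s...\n",
              object@groupLabel, object@totalReads,
              length(object@featureAbundance),
              substr(object@adapter3, 1, 10)))
})

#' Collapsed unique reads with per-group counts
#'
#' The pipeline's central container: one row per distinct trimmed read
#' sequence, one column per sequencing library (group), with a single
#' `counts` assay.  Extends [SummarizedExperiment::SummarizedExperiment];
#' `rowData()` carries the read sequence and its length.
#'
#' @param sequences character vector of distinct trimmed read sequences.
#' @param counts integer matrix, `length(sequences)` rows and one column per
#'   group (column names are the group labels).
#' @param x a `UniqueReadSet`.
#' @return `UniqueReadSet()` returns a new object; `readSequences()` the
#'   character vector of sequences; `readCounts()` the counts matrix.
#' @aliases UniqueReadSet readSequences,UniqueReadSet-method
#'   readCounts,UniqueReadSet-method
#' @export
setClass("UniqueReadSet", contains = "SummarizedExperiment")

#' @rdname UniqueReadSet-class
#' @export
UniqueReadSet <- function(sequences, counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  stopifnot(length(sequences) == nrow(counts))
  rd <- S4Vectors::DataFrame(sequence = as.character(sequences),
                             length = nchar(sequences))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd)
  rownames(se) <- sprintf("ur%06d", seq_along(sequences))
  new("UniqueReadSet", se)
}

setValidity("UniqueReadSet", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("must carry a 'counts' assay")
  sq <- SummarizedExperiment::rowData(object)$sequence
  if (is.null(sq)) return("rowData must carry the read sequences")
  if (anyDuplicated(sq)) return("read sequences must be unique")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (any(cnt < 0)) return("counts must be >= 0")
  TRUE
})

setMethod("readSequences", "UniqueReadSet", function(x)
  SummarizedExperiment::rowData(x)$sequence)

setMethod("readCounts", "UniqueReadSet", function(x)
  SummarizedExperiment::assay(x, "counts"))

setMethod("show", "UniqueReadSet", function(object) {
  cnt <- readCounts(object)
  cat(sprintf("UniqueReadSet: %d unique reads x %d group(s) [%s]; %d reads total\n",
              nrow(object), ncol(cnt), paste(colnames(cnt), collapse = ", "),
              sum(cnt)))
})

#' Ordered mapping stages of the classification cascade
#'
#' The cascade maps reads to reference libraries in a fixed order, removing
#' mapped reads after every stage so each unique read receives at most one
#' library label.  Each stage carries its own mismatch budget, strand set and
#' minimum read length.
#'
#' @aliases CascadeConfig
#' @export
setClass("CascadeConfig", representation(stages = "data.frame"))

setValidity("CascadeConfig", function(object) {
  st <- object@stages
  need <- c("stage", "library", "maxMismatch", "strands", "minLength")
  if (!all(need %in% names(st))) return("stages must have stage/library/maxMismatch/strands/minLength")
  if (any(st$maxMismatch < 0)) return("mismatch budgets must be >= 0")
  if (anyDuplicated(st$stage)) return("stage labels must be unique")
  if (!all(st$strands %in% c("+", "-", "both"))) return("strands must be '+', '-' or 'both'")
  TRUE
})

setMethod("show", "CascadeConfig", function(object) {
  cat("CascadeConfig (applied in order, mapped reads removed):\n")
  st <- object@stages
  for (i in seq_len(nrow(st)))
    cat(sprintf("  %d. %-16s mm<=%d strand=%-4s minLen=%d\n", i, st$stage[i],
                st$maxMismatch[i], st$strands[i], st$minLength[i]))
})

#' Result of the classification cascade
#'
#' @slot assignments data.frame with one row per (read, feature) alignment at
#'   the read's assigned stage: `sequence`, `stage`, `feature`, `strand`,
#'   `position` (1-based on the feature's + strand), `mismatches`, `multi`.
#' @slot summary per-stage unique-read and read-count totals per group.
#' @slot unassigned sequences of reads no stage claimed.
#' @slot config the [CascadeConfig] used.
#' @aliases CascadeResult assignments,CascadeResult-method
#'   unassignedReads,CascadeResult-method stageSummary,CascadeResult-method
#' @export
setClass("CascadeResult", representation(
  assignments = "data.frame",
  summary = "data.frame",
  unassigned = "character",
  config = "CascadeConfig"
))

setMethod("assignments", "CascadeResult", function(x) x@assignments)
setMethod("unassignedReads", "CascadeResult", function(x) x@unassigned)
setMethod("stageSummary", "CascadeResult", function(x) x@summary)

setMethod("show", "CascadeResult", function(object) {
  cat("CascadeResult\n")
  print(object@summary, row.names = FALSE)
})

#' Predicted RNA secondary structure
#'
#' Pair table plus minimum free energy, as returned by [foldHairpin()].  The
#' pair table maps each base to its partner (0 = unpaired); pairs are
#' non-crossing and restricted to AU/GC/GU.
#'
#' @param x a `FoldResult`.
#' @aliases FoldResult dotBracket,FoldResult-method pairTable,FoldResult-method
#'   mfe,FoldResult-method
#' @export
setClass("FoldResult", representation(
  sequence = "character",
  pairs = "integer",
  mfe = "numeric"
))

setValidity("FoldResult", function(object) {
  p <- object@pairs
  if (length(p) != nchar(object@sequence)) return("pair table length mismatch")
  idx <- which(p > 0)
  if (any(p[p[idx]] != idx)) return("pair table is not symmetric")
  TRUE
})

setMethod("pairTable", "FoldResult", function(x) x@pairs)
setMethod("mfe", "FoldResult", function(x) x@mfe)

setMethod("dotBracket", "FoldResult", function(x) {
  p <- x@pairs
  db <- rep(".", length(p))
  db[p > seq_along(p)] <- "("
  db[p > 0 & p < seq_along(p)] <- ")"
  paste(db, collapse = "")
})

#' Parse a dot-bracket string into a pair table
#'
#' Inverse of [dotBracket()]; round-trips the pair table exactly.
#'
#' @param db dot-bracket string over `.()`.
#' @return integer pair table (0 = unpaired).
#' @export
parseDotBracket <- function(db) {
  ch <- strsplit(db, "")[[1]]
  p <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j; p[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  p
}

setMethod("show", "FoldResult", function(object) {
  cat(sprintf("FoldResult: %d nt, MFE %.2f kcal/mol\n%s\n%s\n",
              nchar(object@sequence), object@mfe, object@sequence,
              dotBracket(object)))
})

#' A two-group normalization factor
#'
#' Multiplying the second group's read counts by `value` equalises the two
#' library totals (`value = numeratorTotal / denominatorTotal`).
#'
#' @aliases NormalizationFactor
#' @export
setClass("NormalizationFactor", representation(
  value = "numeric", numeratorTotal = "numeric", denominatorTotal = "numeric"))

setValidity("NormalizationFactor", function(object) {
  if (!isTRUE(all.equal(object@value,
                        object@numeratorTotal / object@denominatorTotal)))
    return("value must equal numeratorTotal / denominatorTotal")
  TRUE
})

setMethod("show", "NormalizationFactor", function(object) {
  cat(sprintf("NormalizationFactor: %.9f (= %s / %s)\n", object@value,
              format(object@numeratorTotal, big.mark = ","),
              format(object@denominatorTotal, big.mark = ",")))
})
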