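## Adapters of the emulated library preparation (RNA ligation adapters,
## stored over the DNA alphabet).  Only the 3' adapter appears inside reads;
## the 5' adapter is consumed upstream of sequencing.
ADAPTER3_DEFAULT <- "TCGTATGCCGTCTTCTGCTTGT"
ADAPTER5_DEFAULT <- "GTTCAGAGTTCTACAGTCCGACGATC"

## Constant bases appended after the 3' adapter when a template is shorter
## than the 36-cycle read (the sequenced molecule downstream of the adapter
## is invariant, so identical inserts give identical raw reads).
PAD_SEQUENCE <- "GTCCAGACGTGACTTAGCCATGCGATCCAGTTCAGACGGTTACCAGTGCAGT"

## Evaluate expr under a fixed RNG state, restoring the caller's state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic reference bundle with ground truth
#'
#' Builds every reference library the classification cascade needs, together
#' with a ground-truth registry of designed read species (the `features`
#' slot): chloroplast locus windows, mature miRNAs (two of them designed to
#' dominate, as miR156/miR168 do in barley leaf libraries), star and isomiR
#' variants, homologous miRNAs, tRNAs including one whose 5' 19-20 nt
#' fragment dominates the tRNA-derived fraction (the tRNA-His(GTG)
#' phenomenon), other ncRNA families, transposable-element windows, sense
#' and nested antisense gene windows, a TaDREB3-like transgene with
#' CBF/DHN-like downstream genes, and novel miRNA hairpins embedded in
#' genomic contigs with complementary target sites implanted in dedicated
#' target transcripts for degradome validation.
#'
#' miRNA precursors are built as perfect inverted repeats (arm + loop +
#' reverse-complemented arm) so that every mature lies on one hairpin arm
#' and the theoretical star sequence exists.  Generation is fully
#' deterministic for a given seed.
#'
#' @param seed integer seed; the same seed reproduces the bundle exactly.
#' @param nMirna,nHomolog,nTrna,nOtherNcrna,nRepeats,nGenes,nNovel library sizes.
#' @param chloroplastLength length (nt) of the toy chloroplast contig.
#' @param nChloroplastLoci number of designed chloroplast read loci.
#' @param matureLengthRange mature miRNA length range; the minimum may not
#'   be below 17 nt (shorter species are removed before miRNA mapping).
#' @param check run the ground-truth self-check (each designed insert must
#'   be recoverable from its own library and absent from all earlier ones).
#' @return a [ReferenceBundle].
#' @export
generateReferenceBundle <- function(seed = 1L, nMirna = 20L, nHomolog = 10L,
                                    nTrna = 10L, nOtherNcrna = 5L,
                                    nRepeats = 5L, nGenes = 12L, nNovel = 5L,
                                    chloroplastLength = 20000L,
                                    nChloroplastLoci = 60L,
                                    matureLengthRange = c(20L, 24L),
                                    check = TRUE) {
  if (matureLengthRange[1] < 17L)
    stop("feature lengths below the 17 nt read minimum are not supported")
  stopifnot(nMirna >= 2L, nTrna >= 1L, nGenes >= 4L, nNovel >= 1L)
  ## rare cross-library collisions are rejected and the draw repeated from
  ## a deterministic follow-up seed, so any seed yields a valid bundle
  if (check) {
    for (attempt in 0:4) {
      drawSeed <- (as.numeric(seed) + 1000003 * attempt) %% .Machine$integer.max
      b <- tryCatch(
        generateReferenceBundle(drawSeed, nMirna, nHomolog, nTrna,
                                nOtherNcrna, nRepeats, nGenes, nNovel,
                                chloroplastLength, nChloroplastLoci,
                                matureLengthRange, check = FALSE),
        error = function(e) NULL)
      if (!is.null(b) && isTRUE(tryCatch(checkBundleTruth(b),
                                         error = function(e) FALSE)))
        return(b)
    }
    stop("could not draw a collision-free bundle from this seed")
  }
  withSeed(seed, {
    feats <- list()
    addFeat <- function(feature, class, insert, expectedStage, weight,
                        designedLog2 = 0, specific = "") {
      feats[[length(feats) + 1L]] <<- data.frame(
        feature = feature, class = class, insert = insert,
        expectedStage = expectedStage, weight = weight,
        designedLog2 = designedLog2, specific = specific)
    }

    ## --- chloroplast contig and read loci ------------------------------
    chloro <- randomDNA(1L, chloroplastLength)
    lociStart <- sort(sample.int(chloroplastLength - 40L, nChloroplastLoci))
    lociLen <- sample(19:24, nChloroplastLoci, replace = TRUE)
    lociW <- exp(stats::rnorm(nChloroplastLoci, 0, 1))
    lociD <- sample(c(0, 1.2, -1.2), nChloroplastLoci, replace = TRUE,
                    prob = c(0.8, 0.1, 0.1))
    for (i in seq_len(nChloroplastLoci)) {
      ins <- substr(chloro, lociStart[i], lociStart[i] + lociLen[i] - 1L)
      if (i %% 5L == 0L) ins <- reverseComplementSeq(ins)  # minus-strand loci
      addFeat(sprintf("cploc%03d", i), "chloroplast", ins, "chloroplast",
              lociW[i] / sum(lociW), lociD[i])
    }

    ## --- miRNAs: perfect-stem precursors, matures on one arm ------------
    matures <- character(nMirna)
    precs <- character(nMirna)
    mmap <- list()
    starSeq <- character(0)
    for (i in seq_len(nMirna)) {
      armLen <- sample(32:40, 1L)
      M <- sample(matureLengthRange[1]:matureLengthRange[2], 1L)
      arm <- randomDNA(1L, armLen)
      f5 <- randomDNA(1L, sample(8:12, 1L))
      loop <- randomDNA(1L, sample(8:12, 1L))
      f3 <- randomDNA(1L, sample(8:12, 1L))
      pre <- paste0(f5, arm, loop, reverseComplementSeq(arm), f3)
      on5 <- i %% 2L == 1L
      off <- sample(3:(armLen - M - 2L), 1L)  # margins leave room for the star
      if (on5) {
        m1 <- nchar(f5) + off
      } else {
        m1 <- nchar(f5) + armLen + nchar(loop) + off
      }
      mat <- substr(pre, m1, m1 + M - 1L)
      matures[i] <- mat
      precs[i] <- pre
      mmap[[i]] <- data.frame(mature = sprintf("syn-miR%03d", i),
                              precursor = sprintf("syn-MIR%03d", i),
                              start = m1, end = m1 + M - 1L)
      if (i <= 2L) {
        ## theoretical star: opposite-arm partner with 2-nt 3' overhangs
        N <- nchar(pre)
        a1 <- nchar(f5) + 1L; b1 <- nchar(f5) + armLen + nchar(loop) + 1L
        partner <- function(x) {
          if (on5) b1 + armLen - (x - a1) - 1L else a1 + armLen - (x - b1) - 1L
        }
        s1 <- partner(m1 + M - 1L - 2L); s2 <- partner(m1) + 2L
        starSeq[sprintf("syn-miR%03d*", i)] <- substr(pre, s1, s2)
      }
    }
    names(matures) <- sprintf("syn-miR%03d", seq_len(nMirna))
    names(precs) <- sprintf("syn-MIR%03d", seq_len(nMirna))

    ## abundances: two dominant species, the rest low; ~30% designed DE
    mirW <- c(0.18, 0.22, exp(stats::rnorm(nMirna - 2L, 0, 1)))
    mirW[-(1:2)] <- mirW[-(1:2)] / sum(mirW[-(1:2)]) * 0.06
    mirD <- rep(0, nMirna)
    mirD[1] <- 1.0; mirD[2] <- -0.8
    deIdx <- seq(3L, nMirna, by = 3L)
    mirD[deIdx] <- rep(c(1.39, -1.57, -1.71), length.out = length(deIdx))
    spec <- rep("", nMirna)
    spec[nMirna] <- "control"         # a control-specific, low-copy miRNA
    mirW[nMirna] <- 0.0004
    for (i in seq_len(nMirna))
      addFeat(names(matures)[i], "mirna", matures[i], "mirna", mirW[i],
              mirD[i], spec[i])
    for (nm in names(starSeq))
      addFeat(nm, "star", starSeq[[nm]], "unassigned", 0.002)
    ## isomiRs of the first three miRNAs: 3' extension (one precursor base),
    ## 5' truncation (claimed by exact mature matching), one substitution
    for (i in 1:3) {
      mm <- mmap[[i]]; pre <- precs[i]; mat <- matures[i]
      ext <- substr(pre, mm$start, mm$end + 1L)
      addFeat(sprintf("%s.iso3p", names(matures)[i]), "isomir", ext,
              "unassigned", 0.003, c(0, 1.1, -1.2)[i])
      addFeat(sprintf("%s.iso5p", names(matures)[i]), "isomir",
              substr(mat, 2L, nchar(mat)), "mirna", 0.002)
      addFeat(sprintf("%s.isosub", names(matures)[i]), "isomir",
              mutateSeq(mat, 1L), "unassigned", 0.001)
    }

    ## --- homologous miRNAs (other species) ------------------------------
    homolog <- setNames(randomDNA(nHomolog, sample(20:24, nHomolog, TRUE)),
                        sprintf("hom-miR%03d", seq_len(nHomolog)))
    homW <- exp(stats::rnorm(nHomolog, 0, 1)); homW <- homW / sum(homW) * 0.03
    homD <- rep(0, nHomolog); homD[2] <- -1.2; homD[4] <- 1.3
    homSpec <- rep("", nHomolog); homSpec[nHomolog] <- "control"
    for (i in seq_len(nHomolog))
      addFeat(names(homolog)[i], "homolog", homolog[i], "homolog_mirna",
              homW[i], homD[i], homSpec[i])

    ## --- ncRNAs: tRNAs (one dominant 5' fragment), rRNA/snoRNA/U6 -------
    trna <- setNames(randomDNA(nTrna, sample(72:80, nTrna, TRUE)),
                     c("tRNA-His-GTG", sprintf("tRNA-%03d", seq_len(nTrna - 1L))))
    other <- setNames(randomDNA(nOtherNcrna, sample(90:150, nOtherNcrna, TRUE)),
                      sprintf("ncRNA-%s", head(c("rRNA5S", "snoRNA14", "U6",
                                                 "snRNA-U2", "rRNA5.8S",
                                                 sprintf("misc%d", 1:20)),
                                               nOtherNcrna)))
    ncrna <- c(trna, other)
    ncrnaFam <- c(rep("tRNA", nTrna),
                  sub("^ncRNA-", "", sub("[0-9.]*$", "", names(other))))
    addFeat("tRNA-His-GTG.5p19", "tsrna", substr(trna[1], 1L, 19L), "ncrna",
            0.10, -1.3)
    addFeat("tRNA-His-GTG.5p20", "tsrna", substr(trna[1], 1L, 20L), "ncrna",
            0.04, -1.3)
    for (i in 2:nTrna)
      addFeat(sprintf("%s.frag", names(trna)[i]), "tsrna",
              substr(trna[i], 25L, 45L), "ncrna", 0.002)
    for (i in seq_len(nOtherNcrna)) {
      w0 <- sample(10:60, 1L)
      addFeat(sprintf("%s.frag", names(other)[i]), "ncrna",
              substr(other[i], w0, w0 + 21L), "ncrna", 0.004)
    }
    ## variants exercising the family stage's 2-mismatch budget
    addFeat("ncRNA.var1", "ncrna", mutateSeq(substr(other[1], 20L, 41L), 1L),
            "ncrna", 0.002)
    addFeat("ncRNA.var2", "ncrna", mutateSeq(substr(other[1], 50L, 71L), 2L),
            "ncrna", 0.002)

    ## --- repeats / transposable elements --------------------------------
    reps <- setNames(randomDNA(nRepeats, sample(300:600, nRepeats, TRUE)),
                     sprintf("TE-%03d", seq_len(nRepeats)))
    repClass <- sample(c("retrotransposon", "DNA_transposon", "unclassified"),
                       nRepeats, replace = TRUE, prob = c(0.45, 0.4, 0.15))
    for (i in seq_len(nRepeats)) {
      for (k in 1:2) {
        w0 <- sample(10:250, 1L)
        addFeat(sprintf("%s.w%d", names(reps)[i], k), "rasirna",
                substr(reps[i], w0, w0 + sample(20:23, 1L)), "repeats",
                0.0012, if (i %% 2L == 0L && k == 1L) -1.2 else 0)
      }
    }

    ## --- genes: sense windows and nested antisense chains ---------------
    genes <- setNames(randomDNA(nGenes, sample(400:700, nGenes, TRUE)),
                      sprintf("gene%03d", seq_len(nGenes)))
    for (i in seq_len(min(6L, nGenes))) {
      w0 <- sample(30:300, 1L)
      addFeat(sprintf("%s.sense", names(genes)[i]), "gene_sense",
              substr(genes[i], w0, w0 + sample(20:21, 1L)), "unassigned",
              0.003)
    }
    for (i in seq_len(4L)) {                 # nested antisense chains
      w0 <- sample(50:300, 1L)
      win <- substr(genes[i], w0, w0 + 23L)  # 24 nt
      addFeat(sprintf("%s.as24", names(genes)[i]), "natsirna",
              reverseComplementSeq(win), "genes_antisense", 0.003,
              if (i == 1L) -1.4 else 0)
      addFeat(sprintf("%s.as21", names(genes)[i]), "natsirna",
              reverseComplementSeq(substr(genes[i], w0 + 2L, w0 + 22L)),
              "genes_antisense", 0.002)
      addFeat(sprintf("%s.as19", names(genes)[i]), "natsirna",
              reverseComplementSeq(substr(genes[i], w0 + 3L, w0 + 21L)),
              "genes_antisense", 0.001)
    }

    ## --- transgene and downstream (CBF/DHN-like) genes -------------------
    transgene <- setNames(randomDNA(1L, 800L), "TaDREB3-like")
    downstream <- setNames(randomDNA(2L, c(500L, 520L)),
                           c("CBF-like", "DHN-like"))
    for (k in 1:3) {
      w0 <- sample(30:700, 1L)
      addFeat(sprintf("TaDREB3.s%d", k), "transgene_sense",
              substr(transgene[1], w0, w0 + sample(19:23, 1L)), "transgene",
              0.006, 0, "transgenic")
    }
    w0 <- sample(100:600, 1L)
    asWin <- substr(transgene[1], w0, w0 + 21L)
    addFeat("TaDREB3.as1", "transgene_antisense", reverseComplementSeq(asWin),
            "transgene", 0.003, 0, "transgenic")
    addFeat("CBF-like.s1", "downstream", substr(downstream[1], 40L, 61L),
            "transgene", 0.004, 1.5)
    addFeat("CBF-like.s2", "downstream", substr(downstream[1], 200L, 220L),
            "transgene", 0.002)
    addFeat("DHN-like.s1", "downstream", substr(downstream[2], 90L, 110L),
            "transgene", 0.003, 0, "control")  # detected only in control

    ## --- novel miRNA hairpins in genomic contigs -------------------------
    novelM <- character(nNovel)
    contigs <- character(nNovel)
    novelW <- c(0.002, 0.03, 0.01, 0.0008, 0.001)[seq_len(nNovel) %% 5 + 1]
    novelD <- c(0, 0, -1.66, 1.79, 0.15)[seq_len(nNovel) %% 5 + 1]
    for (i in seq_len(nNovel)) {
      armLen <- sample(50:60, 1L)
      M <- sample(21:24, 1L)
      arm <- randomDNA(1L, armLen)
      loop <- randomDNA(1L, sample(8:10, 1L))
      hp <- paste0(arm, loop, reverseComplementSeq(arm))
      off <- sample(3:(armLen - M - 2L), 1L)
      novelM[i] <- substr(arm, off, off + M - 1L)
      contigs[i] <- paste0(randomDNA(1L, sample(60:100, 1L)), hp,
                           randomDNA(1L, sample(60:100, 1L)))
      addFeat(sprintf("syn-novel%02d", i), "novel", novelM[i], "unassigned",
              novelW[i], novelD[i])
    }
    names(contigs) <- sprintf("contig%02d", seq_len(nNovel))
    related <- setNames(randomDNA(2L, 800L), c("related1", "related2"))

    ## degradome target transcripts: complementary site per novel miRNA
    targets <- character(nNovel)
    siteStart <- integer(nNovel)
    for (i in seq_len(nNovel)) {
      s <- 60L
      t0 <- randomDNA(1L, 160L)
      site <- reverseComplementSeq(novelM[i])
      targets[i] <- paste0(substr(t0, 1L, s - 1L), site,
                           substr(t0, s + nchar(site), 160L))
      siteStart[i] <- s
    }
    names(targets) <- sprintf("target%02d", seq_len(nNovel))
    targetSites <- data.frame(mirna = sprintf("syn-novel%02d", seq_len(nNovel)),
                              gene = names(targets), start = siteStart)

    ## --- artifact / adapter-only / untrimmed pools -----------------------
    for (b in DNA_BASES4)
      addFeat(paste0("homopolymer", b), "artifact_homopolymer", strrep(b, 36L),
              "removed", 0.25)
    for (i in 1:3) {
      x <- randomDNA(1L, 36L)
      np <- sample(5:30, 1L)
      substr(x, np, np) <- "N"
      addFeat(sprintf("nread%d", i), "artifact_n", x, "removed", 1 / 3)
    }
    addFeat("adapter_only", "adapter_only", "", "length0", 1)
    for (i in 1:20)
      addFeat(sprintf("untrimmed%02d", i), "untrimmed", randomDNA(1L, 36L),
              "untrimmed", 1 / 20)

    features <- do.call(rbind, feats)
    rownames(features) <- NULL
    if (anyDuplicated(features$insert[features$insert != ""]))
      stop("internal: designed inserts collide; try another seed")

    bundle <- new("ReferenceBundle",
      chloroplast = Biostrings::DNAStringSet(setNames(chloro, "chloroplast")),
      matureMirna = Biostrings::DNAStringSet(matures),
      precursorMirna = Biostrings::DNAStringSet(precs),
      homologMirna = Biostrings::DNAStringSet(homolog),
      ncrna = Biostrings::DNAStringSet(ncrna),
      repeats = Biostrings::DNAStringSet(reps),
      genes = Biostrings::DNAStringSet(genes),
      transgene = Biostrings::DNAStringSet(transgene),
      downstream = Biostrings::DNAStringSet(downstream),
      genomeContigs = Biostrings::DNAStringSet(contigs),
      relatedContigs = Biostrings::DNAStringSet(related),
      targetTranscripts = Biostrings::DNAStringSet(targets),
      matureMap = do.call(rbind, mmap),
      ncrnaFamily = ncrnaFam,
      repeatClass = repClass,
      dominantTrna = "tRNA-His-GTG",
      targetSites = targetSites,
      features = features,
      seed = as.integer(seed))
    if (check) checkBundleTruth(bundle)
    bundle
  })
}

## Self-check: every designed insert must classify at its expected stage when
## the cascade libraries are scanned in order (brute substring/Hamming scan
## through matchReads).  Guards against accidental cross-library collisions.
checkBundleTruth <- function(bundle) {
  cfg <- cascadeConfig()@stages
  feats <- bundle@features
  feats <- feats[!feats$class %in% c("artifact_homopolymer", "artifact_n",
                                     "adapter_only", "untrimmed"), ]
  for (i in seq_len(nrow(feats))) {
    ins <- feats$insert[i]
    got <- "unassigned"
    for (j in seq_len(nrow(cfg))) {
      if (nchar(ins) < cfg$minLength[j]) next
      lib <- cascadeLibrary(bundle, cfg$library[j])
      strands <- if (cfg$strands[j] == "both") c("+", "-") else cfg$strands[j]
      if (nrow(matchReads(ins, lib, cfg$maxMismatch[j], strands))) {
        got <- cfg$stage[j]
        break
      }
    }
    if (got != feats$expectedStage[i])
      stop(sprintf("bundle self-check: '%s' classifies as '%s', expected '%s'",
                   feats$feature[i], got, feats$expectedStage[i]))
  }
  invisible(TRUE)
}

#' Designed per-group read-composition profiles
#'
#' Derives the two [GroupProfile] objects (control and transgenic) from a
#' bundle's ground-truth registry.  Expected counts split the library total
#' (net of artifact, adapter-only and untrimmed fractions) between the
#' chloroplast and non-chloroplast streams, then among features by their
#' designed weights.  Transgenic weights apply each feature's designed log2
#' fold change; the non-differential features are then rescaled so the total
#' designed transgenic relative abundance is 1, which makes every designed
#' log2 exactly recoverable after total-count normalization.  The returned
#' profiles carry the final (rebalanced) designed log2 values for all shared
#' non-chloroplast features.
#'
#' @param bundle a generated [ReferenceBundle] (needs the ground-truth registry).
#' @param totalReads named integer vector: reads per group.
#' @param chloroplastShare named numeric: fraction of (non-artifact) reads
#'   drawn from the chloroplast stream per group; the transgenic library is
#'   designed chloroplast-heavy.
#' @param artifactFraction,adapterOnlyFraction,untrimmedFraction artifact
#'   read proportions (poly-N/homopolymer, pure adapter, adapter-free).
#' @param seed base seed; each group's sampling seed derives from it.
#' @return named list of two [GroupProfile] objects.
#' @export
defaultGroupProfiles <- function(bundle,
                                 totalReads = c(control = 100000L,
                                                transgenic = 80000L),
                                 chloroplastShare = c(control = 0.42,
                                                      transgenic = 0.56),
                                 artifactFraction = 0.01,
                                 adapterOnlyFraction = 0.03,
                                 untrimmedFraction = 0.02,
                                 seed = bundle@seed) {
  feats <- bundle@features
  if (!nrow(feats)) stop("bundle has no ground-truth registry")
  isArt <- feats$class %in% c("artifact_homopolymer", "artifact_n")
  isAd <- feats$class == "adapter_only"
  isUn <- feats$class == "untrimmed"
  isCp <- feats$class == "chloroplast"
  isNc <- !(isArt | isAd | isUn | isCp)

  out <- list()
  groups <- names(totalReads)
  stopifnot(length(groups) == 2L)
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    tg <- g == groups[2L]
    present <- !(feats$specific == "control" & tg) &
               !(feats$specific == "transgenic" & !tg)
    w <- feats$weight
    d2 <- setNames(rep(NA_real_, nrow(feats)), feats$feature)

    nc <- isNc & present
    wNc <- w[nc]
    if (tg) {
      shared <- nc & feats$specific == ""
      v <- w * 2^feats$designedLog2
      de <- shared & feats$designedLog2 != 0
      flat <- shared & feats$designedLog2 == 0
      tgOnly <- nc & feats$specific == "transgenic"
      ## rebalance the flat features: designed transgenic mass equals the
      ## shared control mass, so log2 ratios survive normalization exactly
      sharedW <- sum(w[isNc & feats$specific == ""])
      csW <- sum(w[isNc & feats$specific == "control"])
      sFlat <- (sharedW + csW - sum(v[de]) - sum(w[tgOnly])) / sum(w[flat])
      if (sFlat <= 0) stop("designed fold changes leave no flat mass")
      v[flat] <- w[flat] * sFlat
      v[tgOnly] <- w[tgOnly]
      wNc <- v[nc]
      d2[shared] <- log2(v[shared] / w[shared])
    } else {
      d2[isNc & feats$specific == ""] <- 0
    }

    frac <- artifactFraction + adapterOnlyFraction + untrimmedFraction
    insertReads <- totalReads[[g]] * (1 - frac)
    cpReads <- insertReads * chloroplastShare[[g]]
    ncReads <- insertReads - cpReads
    ab <- setNames(numeric(nrow(feats)), feats$feature)
    cp <- isCp & present
    ab[cp] <- cpReads * (w[cp] * 2^(if (tg) feats$designedLog2[cp] else 0)) /
      sum(w[cp] * 2^(if (tg) feats$designedLog2[cp] else 0))
    ab[nc] <- ncReads * wNc / sum(wNc)
    ab[isArt] <- totalReads[[g]] * artifactFraction * w[isArt] / sum(w[isArt])
    ab[isAd] <- totalReads[[g]] * adapterOnlyFraction
    ab[isUn] <- totalReads[[g]] * untrimmedFraction * w[isUn] / sum(w[isUn])
    ab <- ab[present | isArt | isAd | isUn]

    out[[g]] <- new("GroupProfile",
      groupLabel = g,
      featureAbundance = ab,
      designedLog2 = d2[!is.na(d2)],
      totalReads = as.integer(totalReads[[g]]),
      adapter3 = ADAPTER3_DEFAULT,
      adapter5 = ADAPTER5_DEFAULT,
      readLength = 36L,
      insertLengthRange = c(17L, 30L),
      artifactFraction = artifactFraction,
      adapterOnlyFraction = adapterOnlyFraction,
      untrimmedFraction = untrimmedFraction,
      seed = as.integer(seed) + gi)
  }
  out
}

#' Draw a raw read library from a profile
#'
#' Per-feature read counts are drawn multinomially with the profile's
#' expected proportions (the joint distribution of independent Poisson
#' counts conditioned on the library total, so each feature's count is
#' Poisson-like while the counts sum to `totalReads` exactly).  Each raw
#' read is the feature's insert followed by the 3' adapter and a constant
#' pad, truncated to the 36-base read length; artifact and untrimmed
#' features are emitted verbatim.  The read order is shuffled.
#'
#' @param bundle the [ReferenceBundle] the profile refers to.
#' @param profile a [GroupProfile].
#' @return list: `reads` (character vector of raw 36-base reads), `truth`
#'   (data.frame feature/class/expectedStage/insert/count), and `profile`.
#' @export
generateReadLibrary <- function(bundle, profile) {
  if (profile@totalReads == 0L) stop("totalReads must be positive")
  feats <- bundle@features
  ab <- profile@featureAbundance
  miss <- setdiff(names(ab), feats$feature)
  if (length(miss)) stop("profile features absent from bundle: ",
                         paste(head(miss, 3), collapse = ", "))
  feats <- feats[match(names(ab), feats$feature), ]
  withSeed(profile@seed, {
    counts <- as.integer(rmultinom(1L, profile@totalReads, ab / sum(ab)))
    raw <- ifelse(
      feats$class %in% c("artifact_homopolymer", "artifact_n", "untrimmed"),
      feats$insert,
      substr(paste0(feats$insert, profile@adapter3, PAD_SEQUENCE), 1L,
             profile@readLength))
    reads <- rep(raw, counts)
    reads <- reads[sample.int(length(reads))]
    truth <- data.frame(feature = feats$feature, class = feats$class,
                        expectedStage = feats$expectedStage,
                        insert = feats$insert, count = counts)
    list(reads = reads, truth = truth, profile = profile)
  })
}

#' Generate degradome (PARE) tags with known cleavage positions
#'
#' For every implanted miRNA complementary site of the bundle, emits the
#' 20-21 nt 3'-fragment signature of miRNA-guided cleavage: cleavage between
#' the target nucleotides pairing miRNA positions p and p+1 leaves a
#' fragment whose 5' portion is the reverse complement of miRNA positions
#' p..1.  Canonically p = 10; a configurable fraction of tags uses
#' alternative positions 11-15.  Sites too close to the transcript 3' end
#' are skipped with a warning.
#'
#' @param bundle a [ReferenceBundle] with target sites.
#' @param alternativeFraction fraction of tags at alternative positions.
#' @param seed integer seed.
#' @return data.frame: `tag`, `mirna`, `transcript`, `designedPosition`
#'   (the p of p/p+1), `count`.
#' @export
generateDegradomeTags <- function(bundle, alternativeFraction = 0,
                                  seed = bundle@seed + 99L) {
  sites <- bundle@targetSites
  if (!nrow(sites)) stop("bundle has no implanted target sites")
  tx <- setNames(as.character(bundle@targetTranscripts),
                 names(bundle@targetTranscripts))
  mir <- setNames(as.character(bundle@matureMirna), names(bundle@matureMirna))
  mir <- c(mir, setNames(bundle@features$insert[bundle@features$class == "novel"],
                         bundle@features$feature[bundle@features$class == "novel"]))
  withSeed(seed, {
    rows <- list()
    for (i in seq_len(nrow(sites))) {
      m <- mir[[sites$mirna[i]]]
      t <- tx[[sites$gene[i]]]
      L <- nchar(m)
      p <- if (runif(1) < alternativeFraction) sample(11:15, 1L) else 10L
      tagLen <- sample(20:21, 1L)
      tagStart <- sites$start[i] + L - p
      if (tagStart + tagLen - 1L > nchar(t)) {
        warning(sprintf("site for %s too close to the transcript 3' end; skipped",
                        sites$mirna[i]))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tag = substr(t, tagStart, tagStart + tagLen - 1L),
        mirna = sites$mirna[i], transcript = sites$gene[i],
        designedPosition = p, count = sample(1:5, 1L))
    }
    do.call(rbind, rows)
  })
}
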