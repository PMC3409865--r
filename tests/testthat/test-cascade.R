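test_that("chloroplast partition is conservative and recovers ground truth", {
  b <- testBundle()
  prof <- defaultGroupProfiles(b, totalReads = c(control = 15000L,
                                                 transgenic = 12000L))
  libs <- lapply(prof, function(p) generateReadLibrary(b, p))
  prep <- preprocessReads(lapply(libs, `[[`, "reads"),
                          prof$control@adapter3)
  part <- partitionChloroplast(prep$reads, b@chloroplast)
  expect_equal(nrow(part$chloroplast) + nrow(part$nonChloroplast),
               nrow(prep$reads))
  expect_equal(colSums(readCounts(part$chloroplast)) +
                 colSums(readCounts(part$nonChloroplast)),
               colSums(readCounts(prep$reads)))
  ## every chloroplast-designed insert with nonzero count lands chloroplast-side
  truthCp <- unique(libs$control$truth$insert[
    libs$control$truth$class == "chloroplast" & libs$control$truth$count > 0])
  expect_true(all(truthCp %in% readSequences(part$chloroplast)))
  ## a read disjoint from the genome stays non-chloroplast
  expect_false("TTTTACGTACGTACGTAAAA" %in% readSequences(part$chloroplast))
})

test_that("cascade removal gives exclusive labels, conserves counts, obeys order", {
  b <- testBundle()
  prof <- defaultGroupProfiles(b, totalReads = c(control = 15000L,
                                                 transgenic = 12000L))
  libs <- lapply(prof, function(p) generateReadLibrary(b, p))
  prep <- preprocessReads(lapply(libs, `[[`, "reads"), prof$control@adapter3)
  casc <- runCascade(prep$reads, b)
  asn <- assignments(casc)
  ## exclusivity: one stage per read
  expect_true(all(tapply(asn$stage, asn$sequence,
                         function(x) length(unique(x))) == 1L))
  ## conservation: per-stage summary counts sum back to the input
  sm <- stageSummary(casc)
  for (g in colnames(readCounts(prep$reads)))
    expect_equal(sum(sm[[g]]), sum(readCounts(prep$reads)[, g]))
  expect_equal(sum(sm$unique), nrow(prep$reads))

  ## empty input gives empty summaries
  empty <- runCascade(UniqueReadSet(character(0),
                                    matrix(integer(0), 0, 2,
                                           dimnames = list(NULL, c("a", "b")))),
                      b)
  expect_equal(sum(stageSummary(empty)$unique), 0L)
  expect_equal(nrow(assignments(empty)), 0L)
})

test_that("a read present in two libraries takes the earlier stage's label", {
  read <- randomReads(1, 21L)
  tb <- toyBundle(matureMirna = c(m1 = paste0("ACG", read, "TGC")),
                  repeats = c(r1 = paste0(randomReads(1, 30L), read,
                                          randomReads(1, 30L))))
  urs <- UniqueReadSet(read, matrix(c(3L, 2L), 1, 2,
                                    dimnames = list(NULL, c("a", "b"))))
  casc <- runCascade(urs, tb)
  expect_equal(unique(assignments(casc)$stage), "mirna")
})

test_that("known-miRNA profiling counts exact matches and applies the length floor", {
  b <- testBundle()
  mats <- as.character(b@matureMirna)
  reads <- c(mats[1], substr(mats[2], 1, 16), randomReads(1, 21L))
  urs <- UniqueReadSet(reads, matrix(c(10L, 5L, 7L, 1L, 2L, 3L), 3, 2,
                                     dimnames = list(NULL, c("ctrl", "tg"))))
  prof <- profileKnownMirnas(urs, b@matureMirna)
  tab <- prof$table
  expect_equal(tab$ctrl[tab$mirna == names(mats)[1]], 10L)
  ## 16-nt prefix excluded by the length filter despite being a substring
  expect_equal(tab$ctrl[tab$mirna == names(mats)[2]], 0L)
  expect_false(substr(mats[2], 1, 16) %in% prof$mapped)
})

test_that("star inference matches the perfect-stem closed form and is involutive", {
  set.seed(21)
  for (rep in 1:20) {
    armLen <- sample(28:36, 1)
    pre <- perfectHairpin(armLen, sample(6:10, 1))
    M <- sample(20:22, 1)
    off <- sample(3:(armLen - M - 2), 1)
    m1 <- off; m2 <- off + M - 1L
    st <- inferStarSequence(pre, m1, m2)
    ## closed form on a perfect stem
    expect_identical(st$sequence,
                     oracleRevcomp(substr(pre, m1 - 2L, m2 - 2L)))
    ## involution: the star of the star is the mature
    st2 <- inferStarSequence(pre, st$start, st$end)
    expect_identical(st2$sequence, substr(pre, m1, m2))
  }
  ## mature spanning the loop has no star
  pre <- perfectHairpin(20L, 8L)
  expect_error(inferStarSequence(pre, 15L, 34L), "star")
})

test_that("isomiR detection accepts end variants and single substitutions only", {
  b <- testBundle()
  mm <- b@matureMap[1, ]
  pre <- as.character(b@precursorMirna)[[mm$precursor]]
  mat <- as.character(b@matureMirna)[[mm$mature]]
  ext <- substr(pre, mm$start, mm$end + 1L)        # 3' extension
  ch <- strsplit(mat, "")[[1]]
  ch[5] <- setdiff(c("A", "C", "G", "T"), ch[5])[1]
  sub1 <- paste(ch, collapse = "")                 # one substitution
  ch[9] <- setdiff(c("A", "C", "G", "T"), ch[9])[1]
  sub2 <- paste(ch, collapse = "")                 # two substitutions
  far <- randomReads(1, 21L)
  urs <- UniqueReadSet(c(ext, sub1, sub2, far),
                       matrix(c(4L, 3L, 2L, 1L, 0L, 0L, 0L, 0L), 4, 2,
                              dimnames = list(NULL, c("ctrl", "tg"))))
  iso <- detectIsomirs(urs, b@precursorMirna, b@matureMap, b@matureMirna)
  expect_setequal(iso$hits$sequence, c(ext, sub1))
  tab <- iso$table
  expect_equal(tab$unique[tab$precursor == mm$precursor], 2L)
  expect_equal(tab$ctrl[tab$precursor == mm$precursor], 7L)
})

test_that("inclusion clustering is greedy, deterministic and order-invariant", {
  expect_equal(max(clusterByInclusion(c("ABCDE", "BCD", "CD"))$cluster), 1L)
  cl <- clusterByInclusion(c("ACGTACGTAA", "CCCCGGGG"))
  expect_equal(max(cl$cluster), 2L)
  set.seed(22)
  reads <- unique(c(randomReads(10, 24L), randomReads(20, 19L)))
  reads <- c(reads, substr(reads[1], 2, 20), substr(reads[1], 3, 18))
  base <- clusterByInclusion(reads)
  for (k in 1:20) {
    sh <- clusterByInclusion(sample(reads))
    expect_identical(sh, base)
  }
})

test_that("transgene profiling separates strands and flags sense/antisense overlap", {
  gene <- c(tg = randomReads(1, 200L))
  sense <- substr(gene, 50, 70)
  anti <- oracleRevcomp(substr(gene, 60, 80))
  urs <- UniqueReadSet(c(sense, anti),
                       matrix(c(0L, 0L, 4L, 2L), 2, 2,
                              dimnames = list(NULL, c("ctrl", "tg"))))
  pr <- profileTransgene(urs, gene)
  hp <- pr$hits[pr$hits$strand == "+", ]
  hm <- pr$hits[pr$hits$strand == "-", ]
  expect_equal(hp$ctrl, 0L)    # absent from control by design
  expect_equal(hp$tg, 4L)
  expect_equal(hm$tg, 2L)
  expect_gt(nrow(pr$overlaps), 0L)
  cov <- pr$coverage$tg
  expect_true(all(cov$fraction >= 0 & cov$fraction <= 1))
  expect_gte(sum(cov$fraction[cov$strand == "+"]), 1)
})
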