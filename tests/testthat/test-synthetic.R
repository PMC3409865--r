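test_that("bundle generation is deterministic in the seed and seed-sensitive", {
  b1 <- generateReferenceBundle(seed = 5L, check = FALSE)
  b2 <- generateReferenceBundle(seed = 5L, check = FALSE)
  b3 <- generateReferenceBundle(seed = 6L, check = FALSE)
  expect_identical(as.character(b1@chloroplast), as.character(b2@chloroplast))
  expect_identical(b1@features, b2@features)
  expect_false(identical(as.character(b1@matureMirna),
                         as.character(b3@matureMirna)))
  expect_error(generateReferenceBundle(matureLengthRange = c(15L, 20L)),
               "17 nt")
})

test_that("mature miRNAs are precursor substrings and absent from other libraries", {
  b <- testBundle()
  validObject(b)   # includes the mature-in-precursor invariant
  mats <- as.character(b@matureMirna)
  for (lib in list(as.character(b@repeats), as.character(b@ncrna),
                   as.character(b@genes))) {
    for (m in mats) {
      for (s in lib) {
        expect_false(grepl(m, s, fixed = TRUE))
        expect_false(grepl(oracleRevcomp(m), s, fixed = TRUE))
      }
    }
  }
})

test_that("read libraries reproduce exactly, conserve totals, and are Poisson-like", {
  b <- testBundle()
  prof <- defaultGroupProfiles(b, totalReads = c(control = 20000L,
                                                 transgenic = 16000L))
  l1 <- generateReadLibrary(b, prof$control)
  l2 <- generateReadLibrary(b, prof$control)
  expect_identical(l1$reads, l2$reads)
  expect_equal(sum(l1$truth$count), 20000L)
  expect_equal(length(l1$reads), 20000L)
  expect_true(all(nchar(l1$reads) == 36L))

  ## a feature with expectation ~1000: realized counts within 5 SD, 20 seeds
  ab <- prof$control@featureAbundance
  f <- names(ab)[which.min(abs(ab - 1000))]
  expectF <- ab[[f]] / sum(ab) * 20000
  devs <- vapply(1:20, function(s) {
    p <- prof$control
    p@seed <- 1000L + s
    lib <- generateReadLibrary(b, p)
    lib$truth$count[lib$truth$feature == f] - expectF
  }, numeric(1))
  expect_true(all(abs(devs) <= 5 * sqrt(expectF)))
})

test_that("artifact fractions of zero silence the artifact classes", {
  b <- testBundle()
  prof <- defaultGroupProfiles(b, totalReads = c(control = 5000L,
                                                 transgenic = 5000L),
                               artifactFraction = 0,
                               adapterOnlyFraction = 0,
                               untrimmedFraction = 0)
  lib <- generateReadLibrary(b, prof$control)
  bad <- lib$truth$class %in% c("artifact_homopolymer", "artifact_n",
                                "adapter_only", "untrimmed")
  expect_true(all(lib$truth$count[bad] == 0L))
  expect_false(any(grepl("N", lib$reads, fixed = TRUE)))
})

test_that("degradome tags carry the designed cleavage geometry", {
  b <- testBundle()
  tags <- generateDegradomeTags(b, alternativeFraction = 0, seed = 3L)
  expect_true(all(nchar(tags$tag) %in% c(20L, 21L)))
  expect_true(all(tags$designedPosition == 10L))
  novel <- setNames(b@features$insert[b@features$class == "novel"],
                    b@features$feature[b@features$class == "novel"])
  ## canonical geometry: tag prefix = revcomp of miRNA positions 10..1
  for (i in seq_len(nrow(tags))) {
    m <- novel[[tags$mirna[i]]]
    expect_identical(substr(tags$tag[i], 1, 10),
                     oracleRevcomp(substr(m, 1, 10)))
  }
  ## tags resolve to their source transcripts
  asn <- assignTags(tags$tag, b@targetTranscripts)
  expect_setequal(asn$hits$tag, tags$tag)
  ## a site too close to the 3' end is skipped with a warning
  b2 <- b
  b2@targetSites$start[1] <- nchar(as.character(b2@targetTranscripts)[1]) - 5L
  expect_warning(generateDegradomeTags(b2, seed = 3L), "skipped")
})

test_that("the worked cleavage-site example reproduces by construction", {
  ## miRNA with complementary site implanted: tag must start GGCGTCATTC
  m <- "GAATGACGCCGGGTCCGAAAG"
  target <- paste0(randomReads(1, 40L), oracleRevcomp(m), randomReads(1, 40L))
  s <- 41L
  tagStart <- s + nchar(m) - 10L
  tag <- substr(target, tagStart, tagStart + 19L)
  expect_identical(substr(tag, 1, 10), "GGCGTCATTC")
  cl <- callCleavage(tag, m)
  expect_equal(cl$position, "10/11")
  expect_equal(cl$slack, 0L)
})
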