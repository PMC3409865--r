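test_that("cleavage calling reproduces the canonical 10/11 geometry", {
  m <- "GAATGACGCCGGGTCCGAAAG"
  ## published-style tag with one extra 5' base: slack 1, still 10/11
  cl <- callCleavage("AGGCGTCATTCAAATTTCTG", m)
  expect_equal(cl$position, "10/11")
  expect_equal(cl$slack, 1L)
  ## constructed canonical case: exact revcomp of positions 10..1 + tail
  tag <- paste0(oracleRevcomp(substr(m, 1, 10)), "ACGTACGTAC")
  cl0 <- callCleavage(tag, m)
  expect_equal(cl0$position, "10/11")
  expect_equal(cl0$slack, 0L)
  ## involution: the called prefix reverse-complements back onto the miRNA
  expect_identical(oracleRevcomp(substr(tag, 1, cl0$p)), substr(m, 1, cl0$p))
  ## tags below the minimum complementary span are never called
  expect_null(callCleavage("AGGCGTCAT", m))
  ## RNA-alphabet input converts at ingest
  expect_equal(callCleavage("AGGCGUCAUUCAAAUUUCUG", m)$position, "10/11")
})

test_that("alternative cleavage positions are labelled p/p+1 with slack priority", {
  m <- "AGTGACGCGCATGAATGGATT"
  tag12 <- paste0(oracleRevcomp(substr(m, 1, 12)), "AATTAGATG")
  cl <- callCleavage(tag12, m)
  ## an exact 12-block also matches p=11 with slack 1; less slack wins
  expect_equal(cl$position, "12/13")
  expect_equal(cl$slack, 0L)
  ## positions outside the configured range are not called
  tag9 <- paste0(oracleRevcomp(substr(m, 1, 9)), "CCCCCCCCCCC")
  expect_null(callCleavage(tag9, m))
})

test_that("tag assignment is strand-aware and reports multi-transcript hits", {
  set.seed(51)
  tag <- randomReads(1, 20L)
  tx <- c(t1 = paste0(randomReads(1, 30L), tag, randomReads(1, 30L)),
          t2 = paste0(randomReads(1, 50L), tag, randomReads(1, 10L)),
          t3 = paste0(randomReads(1, 30L), oracleRevcomp(tag),
                      randomReads(1, 30L)))
  asn <- assignTags(tag, tx)
  expect_setequal(asn$hits$transcript, c("t1", "t2"))
  expect_equal(asn$antisense$transcript, "t3")
})

test_that("synthetic canonical tags validate every targeted miRNA at 10/11", {
  b <- testBundle()
  tags <- generateDegradomeTags(b, alternativeFraction = 0, seed = 7L)
  novel <- setNames(b@features$insert[b@features$class == "novel"],
                    b@features$feature[b@features$class == "novel"])
  calls <- degradomeCalls(tags, novel)
  own <- merge(tags, calls, by.x = c("mirna", "tag"),
               by.y = c("mirna", "tag"))
  expect_equal(nrow(own), nrow(tags))
  expect_true(all(own$position == "10/11"))
  summ <- summarizeDegradome(calls, novel,
                             assignTags(tags$tag, b@targetTranscripts)$hits)
  expect_true(all(summ$validated))
  expect_true(all(nchar(summ$transcripts) > 0))
  ## a miRNA with no matching tag is not validated
  extra <- c(novel, phantom = "ACGGATTTACCGGATCAACGT")
  summ2 <- summarizeDegradome(degradomeCalls(tags, extra), extra)
  expect_false(summ2$validated[summ2$mirna == "phantom"])
  ## multiple observed positions are all listed
  tagsAlt <- generateDegradomeTags(b, alternativeFraction = 1, seed = 8L)
  callsAll <- degradomeCalls(rbind(tags, tagsAlt), novel)
  summ3 <- summarizeDegradome(callsAll, novel)
  expect_true(any(grepl(",", summ3$positions)))
})
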