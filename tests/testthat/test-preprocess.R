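adapter <- sRNAcascade:::ADAPTER3_DEFAULT

test_that("artifact filter removes homopolymers and N reads, keeps the rest", {
  mixed <- randomReads(5)
  out <- filterArtifactReads(c(strrep("A", 36), strrep("g", 36), mixed,
                               paste0(substr(mixed[1], 1, 17), "N",
                                      substr(mixed[1], 19, 36))))
  expect_setequal(out$reads, mixed)
  expect_equal(out$removed[["homopolymer"]], 2L)
  expect_equal(out$removed[["n_containing"]], 1L)
  empty <- filterArtifactReads(character(0))
  expect_length(empty$reads, 0L)
})

test_that("adapter scan finds exact, mismatched and truncated adapters by the stated rules", {
  set.seed(11)
  insert20 <- randomReads(1, 20L)
  read <- substr(paste0(insert20, adapter, strrep("A", 20)), 1, 36)
  tr <- trimAdapter(read, adapter)
  expect_equal(tr$status, "trimmed")
  expect_equal(tr$adapterStart, 21L)
  expect_equal(nchar(tr$insert), 20L)
  expect_equal(tr$pass, "primary")

  ## two mismatches within the first 10 aligned bases defeat the scan
  bad <- adapter
  substr(bad, 3, 3) <- "A"; substr(bad, 4, 4) <- "A"
  stopifnot(sum(strsplit(bad, "")[[1]] != strsplit(adapter, "")[[1]]) == 2)
  read2 <- substr(paste0(insert20, bad, strrep("A", 20)), 1, 36)
  expect_equal(trimAdapter(read2, adapter)$status, "untrimmed")

  ## leftmost hit wins when the adapter prefix occurs twice
  pre <- substr(adapter, 1, 6)
  read3 <- paste0(randomReads(1, 18L), substr(adapter, 1, 18))
  stopifnot(nchar(read3) == 36)
  tr3 <- trimAdapter(read3, adapter)
  expect_equal(tr3$adapterStart, 19L)

  ## pure-adapter read: found by the secondary pass, insert length 0
  read4 <- substr(paste0(adapter, strrep("C", 20)), 1, 36)
  tr4 <- trimAdapter(read4, adapter)
  expect_equal(tr4$status, "adapter_only")
  expect_equal(tr4$adapterStart, 1L)
  expect_equal(tr4$pass, "secondary")

  expect_error(trimAdapter(read, substr(adapter, 1, 8)), "shorter")
})

test_that("adapter scan agrees with exhaustive position/mismatch enumeration", {
  set.seed(12)
  reads <- c(
    vapply(1:300, function(i) {
      ins <- randomReads(1, sample(0:30, 1))
      ad <- adapter
      nm <- sample(0:2, 1)
      ch <- strsplit(ad, "")[[1]]
      for (p in sample(nchar(ad), nm)) ch[p] <- sample(c("A","C","G","T"), 1)
      substr(paste0(ins, paste(ch, collapse = ""), strrep("T", 40)), 1, 36)
    }, character(1)),
    randomReads(100))
  got <- trimAdapter(reads, adapter)
  for (i in seq_along(reads)) {
    want <- oracleTrim(reads[i], adapter)
    expect_identical(got$status[i], want$status, info = reads[i])
    if (want$status != "untrimmed")
      expect_identical(got$adapterStart[i], want$start, info = reads[i])
  }
})

test_that("collapsing conserves reads, ignores order, and matches a sort-and-scan oracle", {
  expect_equal(collapseUnique(c("X", "X", "Y"))$count, c(2L, 1L))
  set.seed(13)
  pool <- randomReads(200, 21L)
  inserts <- sample(pool, 20000, replace = TRUE,
                    prob = exp(rnorm(200, 0, 2)))
  col <- collapseUnique(inserts)
  expect_equal(sum(col$count), length(inserts))
  ## round trip: expanding restores the multiset
  expect_setequal(rep(col$sequence, col$count), inserts)
  ## order invariance
  col2 <- collapseUnique(sample(inserts))
  expect_identical(col, col2)
  ## hash-free oracle
  expect_equal(col$count, oracleCollapse(inserts)$count)
  expect_equal(col$sequence, oracleCollapse(inserts)$sequence)
})

test_that("size-distribution tables respect thresholds, totals and monotonicity", {
  set.seed(14)
  col <- collapseUnique(sample(randomReads(50, sample(17:26, 50, TRUE)),
                               3000, replace = TRUE))
  sd <- sizeDistribution(col)
  body <- sd$length != "total"
  for (cn in setdiff(names(sd), "length")) {
    expect_equal(sum(sd[[cn]][body]), sd[[cn]][!body][1])
    if (grepl("t10", cn)) {
      expect_true(all(sd[[cn]] <= sd[[sub("t10", "t4", cn)]]))
      expect_true(all(sd[[sub("t10", "t4", cn)]] <= sd[[sub("t10", "t1", cn)]]))
    }
  }
  ## all counts exactly 5: thresholds 1 and 4 identical, 10 empty
  col5 <- data.frame(sequence = randomReads(8, 20L), count = rep(5L, 8))
  sd5 <- sizeDistribution(col5)
  expect_equal(sd5$unique_t1, sd5$unique_t4)
  expect_equal(sd5$count_t1, sd5$count_t4)
  expect_true(all(sd5$count_t10 == 0))
  expect_error(sizeDistribution(col5, thresholds = 0L), ">= 1")
})

test_that("preprocessing conserves every raw read across its accounting", {
  b <- testBundle()
  prof <- defaultGroupProfiles(b, totalReads = c(control = 8000L,
                                                 transgenic = 6000L))
  for (g in names(prof)) {
    lib <- generateReadLibrary(b, prof[[g]])
    prep <- preprocessReads(setNames(list(lib$reads), g),
                            prof[[g]]@adapter3)
    lg <- prep$log[[g]]
    sd <- prep$sizeDistribution[[g]]
    body <- sd$length != "total"
    ## untrimmed reads sit in the diagnostic length-36 row; subtract them
    trimmedCount <- sd$count_t1[!body] - lg[["untrimmed"]]
    expect_equal(lg[["raw"]],
                 lg[["removed_artifact"]] + lg[["untrimmed"]] + trimmedCount)
    expect_equal(trimmedCount, lg[["trimmed"]])
  }
})
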