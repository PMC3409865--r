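test_that("matcher agrees with the brute-force Hamming oracle across budgets", {
  set.seed(7)
  subjects <- setNames(randomReads(3, c(60L, 45L, 80L)), c("s1", "s2", "s3"))
  for (budget in 0:2) {
    reads <- character(0)
    for (k in 1:40) {
      src <- sample(3, 1)
      w <- sample(18:24, 1)
      s <- sample(nchar(subjects[src]) - w, 1)
      rd <- substr(subjects[src], s, s + w - 1L)
      nmut <- sample(0:3, 1)
      ch <- strsplit(rd, "")[[1]]
      for (p in sample(w, nmut)) ch[p] <- sample(c("A", "C", "G", "T"), 1)
      rd <- paste(ch, collapse = "")
      if (k %% 4 == 0) rd <- oracleRevcomp(rd)
      reads <- c(reads, rd)
    }
    reads <- c(reads, randomReads(10, 20L))
    for (rd in unique(reads)) {
      got <- matchReads(rd, subjects, budget)
      want <- oracleMatch(rd, subjects, budget)
      ord <- function(d) d[order(d$feature, d$strand, d$position),
                           c("feature", "strand", "position", "mismatches")]
      expect_equal(unname(as.matrix(ord(got))), unname(as.matrix(ord(want))),
                   info = sprintf("budget %d read %s", budget, rd))
    }
  }
})

test_that("minus-strand mapping equals plus-strand mapping of the reverse complement", {
  set.seed(8)
  subjects <- setNames(randomReads(2, 70L), c("a", "b"))
  reads <- randomReads(30, 20L)
  reads <- c(reads, substr(subjects[1], 11, 31), oracleRevcomp(substr(subjects[2], 5, 26)))
  for (rd in reads) {
    minus <- matchReads(rd, subjects, 1L, strands = "-")
    plus <- matchReads(oracleRevcomp(rd), subjects, 1L, strands = "+")
    expect_equal(minus[, c("feature", "position", "mismatches")],
                 plus[, c("feature", "position", "mismatches")],
                 ignore_attr = TRUE)
  }
})

test_that("mismatch budgets gate borderline reads and length filters apply", {
  lib <- c(ref = "ACGTACGTAAGGCCTTAACCGGTTACGATCGA")
  rd <- substr(lib, 5, 26)
  ch <- strsplit(rd, "")[[1]]; ch[10] <- setdiff(c("A","C","G","T"), ch[10])[1]
  rd1 <- paste(ch, collapse = "")
  expect_equal(nrow(matchReads(rd1, lib, 0L)), 0L)
  expect_equal(nrow(matchReads(rd1, lib, 2L)), 1L)
  expect_equal(matchReads(rd1, lib, 2L)$mismatches, 1L)
  ## empty and short reads never map
  expect_equal(nrow(matchReads("", lib, 0L)), 0L)
  expect_equal(nrow(matchReads("ACGTACG", lib, 0L, minLength = 17L)), 0L)
})
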