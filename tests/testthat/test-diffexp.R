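test_that("normalization factor is exact, reciprocal and guarded", {
  f <- normalizationFactor(3575645, 2585109)
  expect_equal(f@value, 3575645 / 2585109, tolerance = 0)
  expect_equal(round(f@value, 2), 1.38)
  expect_equal(normalizationFactor(12345, 12345)@value, 1)
  expect_equal(f@value * normalizationFactor(2585109, 3575645)@value, 1)
  expect_error(normalizationFactor(0, 10), "positive")
  expect_equal(normalizeCount(0, f), 0)
  expect_error(normalizeCount(-1, f), "non-negative")
})

test_that("log2 ratios follow the zero-count sentinel rules", {
  f <- normalizationFactor(3575645, 2585109)
  expect_equal(log2Ratio(140769, normalizeCount(213440, f)), 1.068479308,
               tolerance = 1e-9)
  expect_true(is.na(log2Ratio(1, 0)))
  expect_equal(log2Ratio(77, 77), 0)
  expect_warning(log2Ratio(0, 0), "zero")
  cls <- deClassify(c(1, 0, 10, 10, 10), c(0, 3, 1, 40, 10), f)
  expect_equal(as.character(cls)[1:2], c("A-specific", "B-specific"))
  expect_equal(as.character(cls)[3:5],
               c("common-DE-down", "common-DE-up", "common-flat"))
})

test_that("group summaries are antisymmetric, self-neutral and threshold-monotone", {
  set.seed(31)
  n <- 400
  a <- rpois(n, exp(rnorm(n, 2, 1.5)))
  bcnt <- rpois(n, exp(rnorm(n, 2, 1.5)))
  urs <- UniqueReadSet(randomReads(n, 21L),
                       cbind(ctrl = a, tg = bcnt))
  s <- summarizeGroups(urs)
  ## swapping group roles swaps the accounting
  urs2 <- UniqueReadSet(readSequences(urs),
                        cbind(ctrl = bcnt, tg = a))
  s2 <- summarizeGroups(urs2)
  expect_equal(s$de_ctrl, s2$de_tg)
  expect_equal(s$specific_ctrl, s2$specific_tg)
  expect_equal(s$common, s2$common)
  ## a library against itself: nothing specific, nothing differential
  urs3 <- UniqueReadSet(readSequences(urs), cbind(ctrl = a, tg = a))
  s3 <- summarizeGroups(urs3)
  expect_true(all(s3$specific_ctrl == 0 & s3$specific_tg == 0))
  expect_true(all(s3$de_sum == 0))
  ## the common-read set shrinks with the threshold; DE reads at a higher
  ## threshold are DE at every lower threshold (same factor throughout)
  expect_true(all(diff(s$common) <= 0))
  expect_true(all(diff(s$de_sum) <= 0))
  ## normalization equalizes totals when the factor comes from this stream
  f <- normalizationFactor(sum(a), sum(bcnt))
  expect_equal(sum(normalizeCount(bcnt, f)), sum(a))
  expect_error(summarizeGroups(urs, thresholds = 0L), ">= 1")
})

test_that("a designed 30% DE fraction is recovered within 2 points at 10^4 reads", {
  set.seed(32)
  nFeat <- 250
  nUp <- 38; nDown <- 38             # 30.4% differential overall
  designed <- c(rep(2, nUp), rep(-2, nDown), rep(0, nFeat - nUp - nDown))
  ## weights chosen so both libraries have the same designed total: up
  ## features rise 1 -> 4, down features fall 4 -> 1, the rest stay flat
  wA <- c(rep(1, nUp), rep(4, nDown), rep(1, nFeat - nUp - nDown))
  wB <- wA * 2^designed
  stopifnot(abs(sum(wA) - sum(wB)) < 1e-9)
  tot <- 10000L
  a <- rpois(nFeat, wA / sum(wA) * tot)
  bcnt <- rpois(nFeat, wB / sum(wB) * tot)
  urs <- UniqueReadSet(randomReads(nFeat, 21L), cbind(ctrl = a, tg = bcnt))
  s <- summarizeGroups(urs, thresholds = 1L)
  expect_lt(abs(s$de_percent - 100 * (nUp + nDown) / nFeat), 2)
})
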