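test_that("folding recovers forced hairpins and leaves unpairable sequences open", {
  stem <- strrep("G", 25)
  hp <- paste0(stem, "TTTT", strrep("C", 25))
  f <- foldHairpin(hp)
  expect_lt(mfe(f), -18)
  p <- pairTable(f)
  expect_true(all(p[1:25] > 29))      # the GC stem pairs arm to arm
  expect_equal(sum(p[26:29] > 0), 0L) # the loop stays open
  fa <- foldHairpin(strrep("A", 60))
  expect_true(all(pairTable(fa) == 0L))
  expect_gte(mfe(fa), 0)
  expect_error(foldHairpin("ACGTXACGT"), "A/C/G/T")
})

test_that("pair tables are legal, non-crossing and round-trip dot-bracket", {
  set.seed(41)
  legal <- c("AT", "TA", "GC", "CG", "GT", "TG")
  for (k in 1:100) {
    sq <- randomReads(1, sample(40:90, 1))
    f <- foldHairpin(sq)
    p <- pairTable(f)
    idx <- which(p > 0)
    ## symmetry and one partner per base
    expect_identical(p[p[idx]], idx)
    ## legal pairs only
    ch <- strsplit(sq, "")[[1]]
    expect_true(all(paste0(ch[idx], ch[p[idx]]) %in% legal))
    ## non-crossing
    op <- idx[p[idx] > idx]
    if (length(op) > 1) {
      for (i in head(seq_along(op), -1)) for (j in (i + 1):length(op)) {
        a <- op[i]; b <- p[op[i]]; x <- op[j]; y <- p[op[j]]
        expect_true((x > a && y < b) || x > b)
      }
    }
    ## dot-bracket serialization round-trips the pair table exactly
    expect_identical(parseDotBracket(dotBracket(f)), p)
  }
})

test_that("unassigned-read mapping respects per-contig-set budgets and precedence", {
  set.seed(42)
  primary <- setNames(randomReads(1, 120L), "chr")
  related <- setNames(randomReads(1, 120L), "rel")
  rd <- substr(primary, 40, 61)
  mut <- function(x, k) {
    ch <- strsplit(x, "")[[1]]
    for (p in sample(nchar(x), k)) ch[p] <- setdiff(c("A","C","G","T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  rd1 <- mut(rd, 1)          # 1 substitution: primary hit
  rd2 <- mut(rd, 3)          # beyond the primary budget
  rdRel <- mut(substr(related, 50, 71), 2)
  loci <- mapUnassigned(c(rd1, rd2, rdRel), primary, related)
  expect_equal(loci$contigSet[loci$sequence == rd1], "primary")
  expect_false(rd2 %in% loci$sequence[loci$contigSet == "primary"])
  expect_equal(loci$contigSet[loci$sequence == rdRel], "related")
})

test_that("precursor windows clip at contig ends and always contain the locus", {
  contig <- randomReads(1, 300L)
  w <- extractPrecursorWindow(contig, 10, 31)
  expect_true(all(w$start >= 1 & w$end <= 300))
  expect_true(all(w$readStart >= 1))
  for (k in 1:2)
    expect_identical(substr(w$sequence[k], w$readStart[k], w$readEnd[k]),
                     substr(contig, 10, 31))
  ## minus-strand loci give the read on the returned (folded) strand
  wm <- extractPrecursorWindow(contig, 150, 171, strand = "-")
  for (k in 1:2)
    expect_identical(substr(wm$sequence[k], wm$readStart[k], wm$readEnd[k]),
                     oracleRevcomp(substr(contig, 150, 171)))
})

test_that("candidate filters apply the strict MFE rule, repeat veto and arm test", {
  ## boundary: exactly -18 fails ("lower than" is strict)
  cand <- data.frame(sequence = randomReads(3, 21L),
                     mfe = c(-18, -18.01, -10))
  v <- filterCandidates(cand)$verdict
  expect_equal(v, c("fail_mfe", "pass", "fail_mfe"))
  ## monotone in the threshold: tightening never adds passes
  set.seed(43)
  cand2 <- data.frame(sequence = randomReads(50, 21L),
                      mfe = -runif(50, 0, 60))
  pass30 <- filterCandidates(cand2, mfeThreshold = -30)$verdict == "pass"
  pass18 <- filterCandidates(cand2, mfeThreshold = -18)$verdict == "pass"
  expect_true(all(!pass30 | pass18))
  ## a read inside a transposable element is vetoed regardless of energy
  te <- setNames(randomReads(1, 200L), "TE1")
  inTe <- data.frame(sequence = substr(te, 50, 71), mfe = -100)
  expect_equal(filterCandidates(inTe, repeatSet = te)$verdict, "fail_repeat")
})

test_that("planted hairpin candidates are recovered and pass the screen", {
  b <- testBundle()
  novel <- b@features$insert[b@features$class == "novel"]
  urs <- UniqueReadSet(novel,
                       matrix(5L, length(novel), 2,
                              dimnames = list(NULL, c("ctrl", "tg"))))
  cand <- discoverNovelMirnas(urs, b)
  expect_setequal(cand$sequence, novel)
  expect_true(all(cand$verdict == "pass"))
  expect_true(all(cand$mfe < -18))
  expect_true(all(!cand$orfFlag))
  ## reads matching nothing are absent from the candidate list
  none <- discoverNovelMirnas(randomReads(3, 21L), b)
  expect_equal(nrow(none), 0L)
})
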