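test_that("scan finds the exact reverse-complement site with zero mismatches", {
  set.seed(51)
  mir <- "GCUGGCGACGUCCAUGGCGCU"
  site <- revComp(chartr("U", "T", mir), alphabet = "DNA")
  tseq <- paste0(strrep("A", 30), site, strrep("A", 30))
  aln <- scanTargets(mir, tseq)
  perfect <- aln[vapply(aln$scores, sum, 1) == 0, ]
  expect_gte(nrow(perfect), 1L)
  expect_true(any(perfect$targetStart == 31L & perfect$targetEnd == 51L))
  ## equal lengths: exactly one alignment per orientation
  aln1 <- scanTargets(mir, site)
  expect_equal(nrow(aln1), 2L)
  expect_setequal(aln1$orientation, c("sense", "antisense"))
  ## too-short transcript
  expect_equal(nrow(scanTargets(mir, "ACGT")), 0L)
  expect_error(scanTargets("ACGU", "ACGTACGT"), "20-22")
})

test_that("scan equals a straightforward window-by-window oracle", {
  set.seed(52)
  comp <- c(A = "T", C = "G", G = "C", U = "A")
  for (i in 1:20) {
    mir <- randomRNA(21)
    tseq <- randomDNA(60)
    aln <- scanTargets(mir, tseq)
    want <- bruteForceTargets(mir, tseq)
    got <- aln[order(aln$orientation, aln$targetStart), ]
    expect_equal(nrow(got), nrow(want))
    ## per-alignment total scores agree (match on sorted multisets per
    ## orientation since coordinate conventions differ)
    for (o in c("sense", "antisense")) {
      expect_equal(sort(vapply(got$scores[got$orientation == o], sum, 1)),
                   sort(want$total[want$orientation == o]))
    }
  }
})

test_that("filter applies every published rule with the right reason codes", {
  mir <- "GCUGGCGACGUCCAUGGCGCU"
  k <- nchar(mir)
  site <- function(mm = integer(0)) {
    nonpair <- c(A = "A", C = "C", G = "A", U = "C")
    t <- rev(strsplit(revComp(mir), "")[[1]])  # t[q] pairs miRNA position q
    for (q in mm) t[q] <- nonpair[[substr(mir, q, q)]]
    paste(rev(t), collapse = "")
  }
  ok <- scoreTargetAlignment(mir, site())
  expect_true(ok$passed)
  expect_equal(ok$totalScore, 0)
  expect_lte(ok$duplexMfe, -30)
  ## single mismatch at the cleavage site: completely excluded
  bad10 <- scoreTargetAlignment(mir, site(10L))
  expect_false(bad10$passed)
  expect_true("CLEAVAGE" %in% bad10$failReasons)
  ## seed mismatch at position 3
  bad3 <- scoreTargetAlignment(mir, site(3L))
  expect_true("SEED" %in% bad3$failReasons)
  ## three consecutive mismatches
  bad13 <- scoreTargetAlignment(mir, site(13:15))
  expect_true("CONSECUTIVE" %in% bad13$failReasons)
  ## four scattered mismatches exceed the 3.0 budget
  bad4 <- scoreTargetAlignment(mir, site(c(1L, 8L, 13L, 19L)))
  expect_true("TOTAL_MM" %in% bad4$failReasons)
  ## a perfect AU-rich duplex fails only on energy
  au <- "AUUAUAAUCUAAUAUUAAUAU"
  weak <- scoreTargetAlignment(au, revComp(au))
  expect_equal(weak$failReasons, "MFE")
})

test_that("a G:U wobble scores 0.5 and a single seed wobble is tolerated", {
  mir <- "GCUGGCGACGUCCAUGGCGCU"
  t <- rev(strsplit(revComp(mir), "")[[1]])
  ## position 4 of the miRNA is G; aligning it to U makes a wobble
  expect_equal(substr(mir, 4, 4), "G")
  t[4] <- "U"
  one <- scoreTargetAlignment(mir, paste(rev(t), collapse = ""))
  expect_equal(one$totalScore, 0.5)
  expect_true(one$passed)
  ## a second seed wobble breaks the seed rule: position 5 is G too
  expect_equal(substr(mir, 5, 5), "G")
  t[5] <- "U"
  two <- scoreTargetAlignment(mir, paste(rev(t), collapse = ""))
  expect_true("SEED" %in% two$failReasons)
  ## strict policy rejects even one seed wobble
  p <- targetDefaults(); p$seed_policy <- "strict"
  oneStrict <- scoreTargetAlignment(mir, {
    t2 <- rev(strsplit(revComp(mir), "")[[1]]); t2[4] <- "U"
    paste(rev(t2), collapse = "")
  }, p)
  expect_true("SEED" %in% oneStrict$failReasons)
})

test_that("filter is monotone: extra mismatches never rescue a failing site", {
  set.seed(53)
  mir <- "GCUGGCGACGUCCAUGGCGCU"
  nonpair <- c(A = "A", C = "C", G = "A", U = "C")
  for (i in 1:25) {
    mm <- sort(sample(21L, sample(1:5, 1)))
    t <- rev(strsplit(revComp(mir), "")[[1]])
    for (q in mm) t[q] <- nonpair[[substr(mir, q, q)]]
    base <- scoreTargetAlignment(mir, paste(rev(t), collapse = ""))
    if (!base$passed) {
      extra <- setdiff(seq_len(21L), mm)
      q <- sample(extra, 1)
      t[q] <- nonpair[[substr(mir, q, q)]]
      worse <- scoreTargetAlignment(mir, paste(rev(t), collapse = ""))
      expect_false(worse$passed)
    }
  }
})

test_that("planted target set resolves to the expected verdicts", {
  ts <- generateTargetSet(seed = 57, nPerPattern = 2)
  hits <- predictTargets(ts$mirnas, ts$transcripts, includeFailed = TRUE)
  for (i in seq_len(nrow(ts$truth))) {
    tr <- ts$truth[i, ]
    h <- hits[hits$mirna_id == tr$mirna_id &
              hits$target_id == tr$target_id &
              hits$targetStart == tr$siteStart, ]
    expect_equal(nrow(h), 1L, info = tr$pattern)
    expect_equal(h$passed, tr$expect_pass, info = tr$pattern)
    if (!tr$expect_pass)
      expect_match(h$fail_reasons, tr$expect_reason, info = tr$pattern)
  }
})

test_that("target report prints energies and hides failures by default", {
  ts <- generateTargetSet(seed = 58, nPerPattern = 1)
  hits <- predictTargets(ts$mirnas, ts$transcripts, includeFailed = TRUE)
  f <- withr::local_tempfile(fileext = ".tsv")
  reportTargets(hits, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), sum(hits$passed))
  expect_true(all(grepl("^-?\\d+\\.\\d$", tab$mfe_kcal_mol)))
  reportTargets(hits, f, includeFailed = TRUE)
  tab2 <- read.delim(f)
  expect_true("fail_reasons" %in% names(tab2))
  expect_gt(nrow(tab2), nrow(tab))
})
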