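test_that("window enumeration covers both strands at the configured step", {
  w <- scanWindows(randomDNA(120), 120L, 20L)
  expect_equal(nrow(w), 2L)
  expect_setequal(w$direction, c("plus", "minus"))
  set.seed(8)
  w <- scanWindows(randomDNA(360), 120L, 30L)
  expect_equal(nrow(w), 18L)  # 9 starts x 2 directions
  expect_equal(unique(w$end - w$start + 1L), 120L)
  ## short transcript: empty with a log message
  expect_message(w0 <- scanWindows(randomDNA(80)), "shorter")
  expect_equal(nrow(w0), 0L)
  ## windows containing N are skipped
  seq <- paste0(randomDNA(60), "N", randomDNA(120))
  w <- scanWindows(seq, 120L, 20L)
  expect_true(all(w$start > 61L | w$end < 61L))
})

test_that("planted compliant hairpin windows are accepted with full diagnostics", {
  set.seed(21)
  for (i in 1:5) {
    hp <- makeHairpinWindow(stemLen = sample(22:28, 1),
                            loopLen = sample(5:8, 1),
                            mismatches = sample(0:2, 1))
    ev <- evaluateWindow(asRNA(hp$window))
    expect_true(ev$accepted)
    expect_lte(ev$starMismatches, 5L)
    expect_gte(ev$mfe, -57); expect_lte(ev$mfe, -32)
    expect_gte(ev$auPre, 30); expect_lte(ev$auPre, 70)
    expect_true((ev$matureEnd - ev$matureStart + 1L) %in% 20:22)
  }
})

test_that("each decoy kind is rejected for its engineered reason", {
  set.seed(22)
  expect_equal(evaluateWindow(
    asRNA(makeDecoyHairpin("au_high")$window))$rejectReason, "AU_RANGE")
  expect_equal(evaluateWindow(
    asRNA(makeDecoyHairpin("au_low")$window))$rejectReason, "AU_RANGE")
  expect_equal(evaluateWindow(
    asRNA(makeDecoyHairpin("weak_stem")$window))$rejectReason, "MFE_RANGE")
  expect_equal(evaluateWindow(
    asRNA(makeDecoyHairpin("many_mismatches")$window))$rejectReason,
    "STAR_MISMATCH")
})

test_that("an unstructured random window fails the energy criterion", {
  set.seed(23)
  w <- paste(sample(c("A", "C"), 120, replace = TRUE), collapse = "")
  ev <- evaluateWindow(asRNA(w))
  expect_false(ev$accepted)
  expect_equal(ev$rejectReason, "MFE_RANGE")
  expect_error(evaluateWindow("ACGU"), "120")
})

test_that("overlap collapse keeps the lowest-energy window, labels disjoint ones", {
  cands <- data.frame(
    transcript_id = "t", windowStart = c(1L, 21L, 201L),
    windowEnd = c(120L, 140L, 320L), mfe = c(-40, -45, -35))
  out <- selectBest(cands)
  expect_equal(nrow(out), 2L)
  expect_equal(out$mfe, c(-45, -35))
  expect_equal(selectBest(cands[0, ]), cands[0, ])
})

test_that("SSR annotation joins motifs and enforces SSR-bearing mode", {
  hits <- suppressWarnings(c(
    findSSRs(paste0(strrep("AG", 6), strrep("C", 20), strrep("GGT", 5)),
             id = "t1"),
    findSSRs(strrep("TCC", 6), id = "t2")))
  cands <- data.frame(transcript_id = c("t1", "t2", "t3"),
                      label = c("t1", "t2", "t3"),
                      stringsAsFactors = FALSE)
  out <- attachSSRs(cands, hits)
  expect_equal(out$motifs, c("AG,GGT", "TCC", ""))
  out2 <- attachSSRs(cands, hits, ssrBearing = TRUE)
  expect_equal(out2$transcript_id, c("t1", "t2"))
})

test_that("candidate discovery recovers planted hairpins and rejects decoys", {
  sim <- generateSynthetic(synthConfig(n_hairpin = 8L, n_decoy = 4L,
                                       n_background = 1L, seed = 29L))
  hits <- findSSRsAll(sim$transcripts)
  res <- suppressMessages(
    predictCandidates(sim$transcripts, ssrHits = hits, ssrBearing = FALSE))
  cand <- res$candidates
  ht <- sim$truth$hairpins
  recovered <- vapply(seq_len(nrow(ht)), function(i)
    any(cand$transcript_id == ht$transcript_id[i] &
        cand$windowStart <= ht$hairpinEnd[i] &
        cand$windowEnd >= ht$hairpinStart[i]), logical(1))
  expect_true(all(recovered[ht$compliant]))
  dt <- sim$truth$decoys
  decoyHit <- vapply(seq_len(nrow(dt)), function(i)
    any(cand$transcript_id == dt$transcript_id[i] &
        cand$windowStart <= dt$windowEnd[i] &
        cand$windowEnd >= dt$windowStart[i]), logical(1))
  expect_false(any(decoyHit))
  ## every accepted candidate satisfies all five criteria simultaneously
  expect_true(all(cand$mfe >= -57 & cand$mfe <= -32))
  expect_true(all(cand$auPre >= 30 & cand$auPre <= 70))
  expect_true(all(cand$starMismatches <= 5))
  expect_true(all((cand$matureEnd - cand$matureStart + 1L) %in% 20:22))
  ## determinism: identical inputs give identical candidate tables
  res2 <- suppressMessages(
    predictCandidates(sim$transcripts, ssrHits = hits, ssrBearing = FALSE))
  expect_identical(res$candidates, res2$candidates)
})

test_that("minus-direction candidates report plus-strand coordinates", {
  set.seed(31)
  ## a hairpin is strand-symmetric, so force minus-only discovery with G:U
  ## wobbles: they pair on one strand but read as A-C mismatches on the
  ## other, which pushes the plus-strand fold out of the energy band
  hp <- makeHairpinWindow(26L, 6L, 0L)
  w <- strsplit(hp$window, "")[[1]]
  a5 <- hp$hairpinStart:(hp$hairpinStart + 25L)
  a3 <- hp$hairpinEnd:(hp$hairpinEnd - 25L)   # a3[k] pairs a5[k]
  gpos <- which(w[a5] == "G")
  for (k in gpos[seq(1, length(gpos), length.out = 3)]) w[a3[k]] <- "T"
  wob <- paste(w, collapse = "")
  expect_true(evaluateWindow(asRNA(wob))$accepted)
  expect_false(evaluateWindow(revComp(asRNA(wob)))$accepted)
  ## embed the reverse complement: discovery must happen on the minus strand
  tx <- Biostrings::DNAStringSet(c(
    m1 = paste0(strrep("A", 40), revComp(wob, alphabet = "DNA"),
                strrep("A", 40))))
  res <- suppressMessages(predictCandidates(tx))
  cand <- res$candidates
  expect_gte(nrow(cand), 1L)
  expect_true(all(cand$direction == "minus"))
  expect_true(all(cand$matureStart >= cand$windowStart &
                  cand$matureEnd <= cand$windowEnd))
  ## the mature sequence is the reverse complement of the plus-strand slice
  seq <- as.character(tx[["m1"]])
  slice <- substr(seq, cand$matureStart[1], cand$matureEnd[1])
  expect_equal(cand$matureSeq[1], revComp(asRNA(slice)))
})
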