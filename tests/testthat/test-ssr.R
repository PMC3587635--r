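test_that("textbook tracts: threshold, primitivity, palindromic class", {
  hits <- findSSRs("AGAGAGAGAG")
  expect_length(hits, 1L)
  expect_equal(S4Vectors::mcols(hits)$motif, "AG")
  expect_equal(S4Vectors::mcols(hits)$iterations, 5L)
  expect_equal(GenomicRanges::start(hits), 1L)
  expect_equal(GenomicRanges::end(hits), 10L)
  ## four iterations: below threshold
  expect_length(findSSRs("AGAGAGAG"), 0L)
  ## AT x 6, never reported as ATAT x 3 or as a longer period
  hits <- findSSRs("ATATATATATAT")
  expect_length(hits, 1L)
  expect_equal(S4Vectors::mcols(hits)$motif, "AT")
  expect_equal(S4Vectors::mcols(hits)$iterations, 6L)
  ## homopolymers are not dimers
  expect_length(findSSRs(strrep("A", 30)), 0L)
  ## partial trailing copy is not counted and not included
  hits <- findSSRs("TCCTCCTCCTCCTCCTC")
  expect_equal(S4Vectors::mcols(hits)$iterations, 5L)
  expect_equal(GenomicRanges::end(hits), 15L)
  ## tracts containing N are skipped
  expect_length(findSSRs("AGAGANAGAGAGAG"), 0L)
  expect_error(findSSRs("ACGT", minMotif = 0L), "invalid")
})

test_that("scanner equals the brute-force oracle on random sequences", {
  set.seed(101)
  for (i in 1:60) {
    seq <- randomDNA(sample(40:200, 1))
    ## seed short tandem arrays sometimes so hits are not vanishingly rare
    if (i %% 3 == 0) {
      m <- sample(c("AG", "TTA", "CCG", "GT"), 1)
      seq <- paste0(substr(seq, 1, 20), strrep(m, sample(5:8, 1)),
                    substr(seq, 21, nchar(seq)))
    }
    got <- as.data.frame(findSSRs(seq))
    want <- bruteForceSSRs(seq)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      got <- got[order(got$start, got$motif),
                 c("start", "end", "motif", "iterations")]
      want <- want[order(want$start, want$motif), ]
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("hits never duplicate an (interval, motif) and same-motif hits are disjoint", {
  set.seed(77)
  for (i in 1:20) {
    seq <- paste0(randomDNA(60), strrep("AG", 6), randomDNA(10),
                  strrep("GGT", 7), randomDNA(60))
    df <- as.data.frame(findSSRs(seq))
    key <- paste(df$start, df$end, df$motif)
    expect_equal(anyDuplicated(key), 0L)
    for (m in unique(df$motif)) {
      d <- df[df$motif == m, ]
      if (nrow(d) > 1) {
        d <- d[order(d$start), ]
        expect_true(all(d$start[-1] > d$end[-nrow(d)]))
      }
    }
  }
})

test_that("canonical classes pair reverse complements without merging phases", {
  expect_equal(canonicalClass("GA"), "GA/TC")
  expect_equal(canonicalClass("TC"), "GA/TC")
  expect_equal(canonicalClass("CT"), "AG/CT")
  expect_equal(canonicalClass("TA"), "TA")
  expect_equal(canonicalClass("CCG"), "CCG/CGG")
  expect_error(canonicalClass("AXG"), "motif")
  ## involution: class(m) == class(revcomp(m)) for all dimers and trimers
  for (k in 2:3) {
    motifs <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), k)),
                    1, paste, collapse = "")
    for (m in motifs)
      expect_equal(canonicalClass(m),
                   canonicalClass(revComp(m, alphabet = "DNA")))
  }
})

test_that("summary recovers planted per-class counts and density", {
  set.seed(5)
  tx <- Biostrings::DNAStringSet(c(
    t1 = paste0(cleanBackground(50), strrep("AG", 6), cleanBackground(50)),
    t2 = paste0(cleanBackground(40), strrep("TTG", 5), cleanBackground(20),
                strrep("AG", 7), cleanBackground(40)),
    t3 = cleanBackground(80)))
  hits <- findSSRsAll(tx)
  sm <- summarizeSSRs(hits, sum(Biostrings::width(tx)))
  expect_equal(sm$n_total, 3L)
  expect_equal(sm$count_by_length_class$di, 2L)
  expect_equal(sm$count_by_length_class$tri, 1L)
  expect_equal(sm$n_transcripts_with_ssr, 2L)
  expect_equal(sm$n_transcripts_multi_motif, 1L)
  expect_equal(sm$density, 3 / (sum(Biostrings::width(tx)) / 1e6))
  expect_equal(sm$iteration_histogram$`5`, 1L)
  ## empty scan
  sm0 <- summarizeSSRs(hits[0], 1000L)
  expect_equal(sm0$n_total, 0L)
  expect_equal(sm0$density, 0)
  expect_error(summarizeSSRs(hits, 0), "positive")
})

test_that("printed survey counts reproduce the published percentages", {
  pc <- publishedCounts()
  expect_equal(round(100 * pc$di_TA / pc$total_ssrs, 2), 15.72)
  expect_equal(round(100 * pc$ssr_unigenes / pc$total_unigenes, 2), 2.78)
  expect_equal(round(100 * pc$di / pc$total_ssrs, 1), 44.7)
  expect_equal(pc$di + pc$tri + pc$tetra + pc$penta, pc$total_ssrs)
})
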