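test_that("generation is deterministic given the seed", {
  cfg <- synthConfig(n_hairpin = 4L, n_decoy = 2L, n_background = 1L,
                     seed = 91L)
  a <- generateSynthetic(cfg)
  b <- generateSynthetic(cfg)
  expect_identical(as.character(a$transcripts), as.character(b$transcripts))
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  ## a different seed changes the sequences
  c2 <- generateSynthetic(synthConfig(n_hairpin = 4L, n_decoy = 2L,
                                      n_background = 1L, seed = 92L))
  expect_false(identical(as.character(a$transcripts),
                         as.character(c2$transcripts)))
})

test_that("truth tables are consistent with the FASTA they describe", {
  sim <- generateSynthetic(synthConfig(n_hairpin = 6L, n_decoy = 2L,
                                       n_background = 1L, seed = 93L))
  tr <- sim$truth$ssrs
  for (i in seq_len(nrow(tr))) {
    seq <- as.character(sim$transcripts[[tr$transcript_id[i]]])
    tract <- substr(seq, tr$start[i], tr$end[i])
    expect_equal(tract, strrep(tr$motif[i], tr$iterations[i]))
  }
  ht <- sim$truth$hairpins
  expect_true(all(ht$windowEnd - ht$windowStart + 1L == 120L))
  expect_true(all(ht$hairpinStart >= ht$windowStart &
                  ht$hairpinEnd <= ht$windowEnd))
  ## planted SSRs keep >= 10 nt clearance from the hairpin window
  m <- merge(tr, ht, by = "transcript_id")
  gap <- ifelse(m$placement == "downstream",
                m$start - m$windowEnd, m$windowStart - m$end)
  expect_true(all(gap >= 10L))
})

test_that("planted tracts are recovered exactly and exclusively", {
  set.seed(94)
  ## dedicated fixture: SSR-free background with K planted tracts
  K <- 6L
  motifs <- c("AG", "TTG", "CCG", "GT", "TAGC", "AAG")
  seqs <- character(0)
  truth <- NULL
  for (i in 1:3) {
    parts <- cleanBackground(40)
    placed <- NULL
    for (m in sample(motifs, 2)) {
      it <- sample(5:9, 1)
      tract <- strrep(m, it)
      ## guard bases so the junction cannot extend the tract in any phase
      lg <- setdiff(c("A", "C", "G", "T"),
                    substr(m, nchar(m), nchar(m)))[1]
      rg <- setdiff(c("A", "C", "G", "T"), substr(m, 1, 1))[1]
      placed <- rbind(placed, data.frame(motif = m, iterations = it,
                                         start = nchar(parts) + 2L))
      parts <- paste0(parts, lg, tract, rg, cleanBackground(38))
    }
    id <- paste0("fx", i)
    seqs[id] <- parts
    placed$transcript_id <- id
    truth <- rbind(truth, placed)
  }
  tx <- Biostrings::DNAStringSet(seqs)
  hits <- as.data.frame(findSSRsAll(tx))
  expect_equal(nrow(hits), nrow(truth))
  got <- hits[order(hits$seqnames, hits$start),
              c("seqnames", "start", "motif", "iterations")]
  want <- truth[order(truth$transcript_id, truth$start),
                c("transcript_id", "start", "motif", "iterations")]
  expect_equal(as.character(got$seqnames), want$transcript_id)
  expect_equal(got$start, want$start)
  expect_equal(got$motif, want$motif)
  expect_equal(got$iterations, want$iterations)
})

test_that("downstream placement fraction concentrates around its target", {
  cfg <- synthConfig(n_hairpin = 60L, n_decoy = 0L, n_background = 0L,
                     seed = 95L)
  sim <- generateSynthetic(cfg)
  frac <- mean(sim$truth$ssrs$placement == "downstream")
  ci <- binom.test(sum(sim$truth$ssrs$placement == "downstream"),
                   nrow(sim$truth$ssrs))$conf.int
  expect_true(ci[1] <= 0.7 && 0.7 <= ci[2])
})

test_that("generator writes FASTA, counts and truth JSON to disk", {
  d <- withr::local_tempdir()
  sim <- generateSynthetic(synthConfig(n_hairpin = 2L, n_decoy = 1L,
                                       n_background = 1L, seed = 96L),
                           outdir = d)
  expect_true(file.exists(file.path(d, "transcripts.fasta")))
  back <- readTranscripts(file.path(d, "transcripts.fasta"))
  expect_equal(as.character(back), as.character(sim$transcripts))
  counts <- readCountTable(file.path(d, "counts.tsv"))
  expect_equal(counts$gene_id, sim$counts$gene_id)
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_named(truth, c("ssrs", "hairpins", "decoys"))
})

test_that("decoy windows violate exactly the engineered margin", {
  set.seed(97)
  expect_gte(auContent(makeDecoyHairpin("au_high")$window), 80)
  expect_lte(auContent(makeDecoyHairpin("au_low")$window), 20)
  w <- makeDecoyHairpin("weak_stem")$window
  expect_gt(mfe(foldMFE(asRNA(w))), -32)
})
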