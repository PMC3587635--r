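#' Default configuration for the synthetic transcriptome generator
#'
#' The defaults emulate unigene-like transcripts: lengths 300-600 nt with
#' plant-like balanced base composition (50% GC), planted stem-loop
#' hairpins with 22-28 bp stems of half-GC composition, 5-8 nt loops and
#' 0-2 arm mismatches (placed outside the intended mature span), planted
#' SSR tracts with motifs of 2-5 nt and 5-16 iterations following the
#' decaying iteration frequencies seen in transcriptome SSR surveys, a 0.7
#' downstream placement fraction of SSRs relative to their hairpin, and
#' negative-binomial read counts.
#'
#' @param n_hairpin transcripts carrying one compliant-style hairpin each
#' @param n_decoy transcripts carrying one decoy window each (kinds cycle
#'   through au_low, au_high, weak_stem, many_mismatches)
#' @param n_background plain background transcripts
#' @param seed RNG seed
#' @return config list understood by [generateSynthetic()]
#' @export
synthConfig <- function(n_hairpin = 20L, n_decoy = 8L, n_background = 5L,
                        seed = 1L) {
  list(
    n_hairpin = n_hairpin, n_decoy = n_decoy, n_background = n_background,
    length_range = c(300L, 600L),
    gc_background = 0.5,
    hairpin_spec = list(stem_len = c(22L, 28L), loop = c(5L, 8L),
                        arm_mismatches = c(0L, 2L)),
    ssr_spec = list(
      motifs = c("AG", "TA", "TC", "GA", "CT", "TG", "AAG", "CCG", "TCC",
                 "CTC", "AGG", "AAAG", "TTCT", "ATGTA"),
      iterations = 5L:16L,
      iteration_weights = c(61.26, 21.67, 9.12, 3.09, 2.17, 1.46, 1.02,
                            0.20, 0.03, 0.01, 0.01, 0.03),
      downstream_fraction = 0.7),
    count_spec = list(N_total = 1e6, dispersion = 0.3),
    seed = seed)
}

.BASES_DNA <- c("A", "C", "G", "T")

.randomSeq <- function(n, gc = 0.5, alphabet = .BASES_DNA) {
  if (length(alphabet) == 4L) {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  } else p <- rep(1 / length(alphabet), length(alphabet))
  paste(sample(alphabet, n, replace = TRUE, prob = p), collapse = "")
}

## arm of `len` bases with an exactly half-GC shuffled composition, so stem
## energies land reliably inside the acceptance band
.balancedArm <- function(len) {
  nGC <- len %/% 2L
  pool <- c(sample(c("G", "C"), nGC, replace = TRUE),
            sample(c("A", "T"), len - nGC, replace = TRUE))
  paste(sample(pool), collapse = "")
}

## a base that neither Watson-Crick- nor wobble-pairs with `x` (DNA)
.nonPairing <- function(x) {
  opts <- switch(x, A = c("A", "C", "G"), C = c("A", "C", "T"),
                 G = c("A", "G"), T = c("C", "T"))
  sample(opts, 1L)
}

#' Construct a 120-nt window containing one planted hairpin
#'
#' The 3' arm is the reverse complement of the 5' arm, degraded by exactly
#' `mismatches` substitutions at stem positions opposite the 5' arm but
#' outside the intended mature span (5' arm positions 3 onward, 22 nt)
#' unless `allowInMature`. Loop and flanks are drawn from a non-pairing
#' alphabet so the planted stem is the dominant structure.
#'
#' @param stemLen stem length in bp
#' @param loopLen loop length in nt
#' @param mismatches number of arm mismatches to introduce
#' @param allowInMature permit mismatches opposite the mature span
#' @return list: `window` (120-nt DNA string), `hairpinStart`,
#'   `hairpinEnd` (1-based within the window), `matureStart`, `matureEnd`
#'   (intended mature span within the window, on the 5' arm)
#' @export
makeHairpinWindow <- function(stemLen = 24L, loopLen = 6L, mismatches = 0L,
                              allowInMature = FALSE) {
  arm5 <- .balancedArm(stemLen)
  arm3 <- revComp(arm5, alphabet = "DNA")
  matureRel <- 3L:min(stemLen, 24L)  # mature span, positions on the 5' arm
  if (mismatches > 0L) {
    ## arm3 position k sits opposite arm5 position stemLen - k + 1
    allowed <- which(!(stemLen - seq_len(stemLen) + 1L) %in% matureRel)
    if (allowInMature || length(allowed) < mismatches)
      allowed <- seq_len(stemLen)
    pos <- sample(allowed, mismatches)
    a3 <- strsplit(arm3, "")[[1]]
    a5 <- strsplit(arm5, "")[[1]]
    for (k in pos) a3[k] <- .nonPairing(a5[stemLen - k + 1L])
    arm3 <- paste(a3, collapse = "")
  }
  loop <- .randomSeq(loopLen, alphabet = c("A", "C"))
  core <- paste0(arm5, loop, arm3)
  pad <- 120L - nchar(core)
  if (pad < 0L) stop("stem/loop too large for a 120-nt window")
  padL <- pad %/% 2L
  flankL <- .randomSeq(padL, alphabet = c("A", "C"))
  flankR <- .randomSeq(pad - padL, alphabet = c("A", "C"))
  list(window = paste0(flankL, core, flankR),
       hairpinStart = padL + 1L,
       hairpinEnd = padL + nchar(core),
       matureStart = padL + matureRel[1L],
       matureEnd = padL + matureRel[length(matureRel)])
}

#' Construct a decoy 120-nt window violating exactly one criterion
#'
#' * `au_low`: GC-only stem with homopolymer-C loop and flanks; folds in
#'   the energy band but A+U is near 0.
#' * `au_high`: AU-only stem with A flanks; folds in the band, A+U > 90.
#' * `weak_stem`: 5-bp stem in an unpairable A/C background; folding energy
#'   far above -32.
#' * `many_mismatches`: periodically interrupted stem (runs of 4 pairs
#'   split by 2+2 interior loops) whose energy stays in the band while
#'   every 20-22 nt arm placement spans at least six unpaired positions.
#'
#' @param kind decoy kind
#' @return list as in [makeHairpinWindow()] (no mature fields)
#' @export
makeDecoyHairpin <- function(kind = c("au_low", "au_high", "weak_stem",
                                      "many_mismatches")) {
  kind <- match.arg(kind)
  if (kind == "au_low") {
    ## fixed GC stem whose model energy sits inside the acceptance band,
    ## so the A+U criterion is the one that rejects it
    arm5 <- "GCCGGCGCCGGCGCC"
    core <- paste0(arm5, "CCCC", revComp(arm5, alphabet = "DNA"))
    pad <- 120L - nchar(core)
    window <- paste0(strrep("C", pad %/% 2L), core,
                     strrep("C", pad - pad %/% 2L))
  } else if (kind == "au_high") {
    arm5 <- paste(sample(c("A", "T"), 40L, replace = TRUE), collapse = "")
    core <- paste0(arm5, "AAAAA", revComp(arm5, alphabet = "DNA"))
    pad <- 120L - nchar(core)
    window <- paste0(strrep("A", pad %/% 2L), core,
                     strrep("A", pad - pad %/% 2L))
  } else if (kind == "weak_stem") {
    arm5 <- "GGGGG"
    core <- paste0(arm5, "AACAA", revComp(arm5, alphabet = "DNA"))
    pad <- 120L - nchar(core)
    window <- paste0(.randomSeq(pad %/% 2L, alphabet = c("A", "C")), core,
                     .randomSeq(pad - pad %/% 2L, alphabet = c("A", "C")))
  } else {
    ## one arm segment of 2-bp helix runs split by 1x1 mismatches (small,
    ## defect-clean, but >= 6 unpaired under any 20-22 nt placement) plus
    ## one segment of strong 4-bp runs split by 2+2 interior loops; the
    ## energy stays in the acceptance band while no mature placement
    ## survives. All gap bases are A (an A opposite an A pairs in neither
    ## orientation) and the run contents are aperiodic so no shifted
    ## register forms an accidental clean helix.
    rc <- function(x) revComp(x, alphabet = "DNA")
    runs2 <- c("GC", "CG", "GC", "GC", "CG", "CG", "GC", "CG")
    runs4 <- c("GGCC", "CCGG", "GCGC", "CGCG", "GGCG")
    arm5 <- paste0(paste(runs2, collapse = "A"), "AA",
                   paste(runs4, collapse = "AA"))
    arm3 <- paste0(paste(rev(vapply(runs4, rc, "")), collapse = "AA"), "AA",
                   paste(rev(vapply(runs2, rc, "")), collapse = "A"))
    core <- paste0(arm5, "AACAA", arm3)
    pad <- 120L - nchar(core)
    window <- paste0(strrep("A", pad %/% 2L), core,
                     strrep("A", pad - pad %/% 2L))
  }
  list(window = window, kind = kind)
}

## plant a tract at position p in a character vector, with non-extending
## guard bases on both sides
.plantTract <- function(chars, p, motif, iterations) {
  tract <- strrep(motif, iterations)
  len <- nchar(tract)
  chars[p:(p + len - 1L)] <- strsplit(tract, "")[[1]]
  mfirst <- substr(motif, 1L, 1L)
  mlast <- substr(motif, nchar(motif), nchar(motif))
  if (p > 1L && chars[p - 1L] == mlast)
    chars[p - 1L] <- sample(setdiff(.BASES_DNA, mlast), 1L)
  if (p + len <= length(chars) && chars[p + len] == mfirst)
    chars[p + len] <- sample(setdiff(.BASES_DNA, mfirst), 1L)
  chars
}

#' Generate a seeded synthetic transcriptome with planted ground truth
#'
#' Produces hairpin-bearing transcripts (each with one planted stem-loop in
#' a scan-aligned 120-nt window and one SSR tract placed upstream or
#' downstream of it), decoy transcripts (one criterion-violating window
#' each, in an unpairable A/C background), plain background transcripts,
#' and a negative-binomial count table. Every planted feature is recorded
#' with exact coordinates in the truth tables; hairpin compliance is
#' assessed by running the window filter on the planted window.
#'
#' @param config from [synthConfig()]
#' @param outdir optional directory; when given, writes `transcripts.fasta`,
#'   `counts.tsv` and `truth.json`
#' @return list: `transcripts` (`DNAStringSet`), `counts` (data.frame),
#'   `truth` (list of data.frames `ssrs`, `hairpins`, `decoys`)
#' @export
generateSynthetic <- function(config = synthConfig(), outdir = NULL) {
  set.seed(config$seed)
  hs <- config$hairpin_spec
  ss <- config$ssr_spec
  seqs <- character(0)
  ssrTruth <- list()
  hairpinTruth <- list()
  decoyTruth <- list()
  step <- 20L  # default scan step; planted windows are aligned to it
  for (i in seq_len(config$n_hairpin)) {
    id <- sprintf("synth_hp%03d", i)
    L <- sample(config$length_range[1]:config$length_range[2], 1L)
    L <- (L %/% step) * step
    ## window start aligned to the scan grid, leaving both flanks >= 60 nt
    wchoices <- seq.int(61L, L - 120L - 59L, by = step)
    w <- sample(wchoices, 1L)
    hp <- makeHairpinWindow(
      stemLen = sample(hs$stem_len[1]:hs$stem_len[2], 1L),
      loopLen = sample(hs$loop[1]:hs$loop[2], 1L),
      mismatches = sample(hs$arm_mismatches[1]:hs$arm_mismatches[2], 1L))
    chars <- strsplit(.randomSeq(L, config$gc_background), "")[[1]]
    chars[w:(w + 119L)] <- strsplit(hp$window, "")[[1]]
    ## one SSR tract, downstream of the window with probability
    ## downstream_fraction, separated from it by >= 10 nt
    motif <- sample(ss$motifs, 1L)
    downstream <- stats::runif(1) < ss$downstream_fraction
    segment <- if (downstream) c(w + 120L + 10L, L - 10L) else c(11L, w - 11L)
    avail <- segment[2] - segment[1] + 1L
    if (avail < nchar(motif) * 5L)
      stop("infeasible packing in transcript ", id)
    iter <- sample(ss$iterations, 1L,
                   prob = ss$iteration_weights[seq_along(ss$iterations)])
    iter <- min(iter, avail %/% nchar(motif))
    tractLen <- nchar(motif) * iter
    p <- sample(segment[1]:(segment[2] - tractLen + 1L), 1L)
    chars <- .plantTract(chars, p, motif, iter)
    seqs[id] <- paste(chars, collapse = "")
    ## compliance of the planted window under the pipeline's own filter
    wseq <- substr(seqs[id], w, w + 119L)
    ev <- evaluateWindow(asRNA(wseq))
    hairpinTruth[[i]] <- data.frame(
      transcript_id = id, windowStart = w, windowEnd = w + 119L,
      hairpinStart = w + hp$hairpinStart - 1L,
      hairpinEnd = w + hp$hairpinEnd - 1L,
      compliant = ev$accepted,
      reason = if (ev$accepted) "" else ev$rejectReason,
      mfe = ev$mfe, au = ev$auPre, stringsAsFactors = FALSE)
    ssrTruth[[i]] <- data.frame(
      transcript_id = id, motif = motif, iterations = iter,
      start = p, end = p + tractLen - 1L,
      placement = if (downstream) "downstream" else "upstream",
      stringsAsFactors = FALSE)
  }
  kinds <- c("au_low", "au_high", "weak_stem", "many_mismatches")
  for (i in seq_len(config$n_decoy)) {
    id <- sprintf("synth_decoy%03d", i)
    kind <- kinds[(i - 1L) %% 4L + 1L]
    L <- sample(config$length_range[1]:config$length_range[2], 1L)
    L <- (L %/% step) * step
    w <- sample(seq.int(21L, L - 120L - 19L, by = step), 1L)
    dk <- makeDecoyHairpin(kind)
    ## adversarial scaffold, not realistic sequence: a homopolymer-A
    ## background can pair with nothing in the A/G/C decoy cores on either
    ## strand, so the planted window is the only structure offered
    chars <- strsplit(strrep("A", L), "")[[1]]
    chars[w:(w + 119L)] <- strsplit(dk$window, "")[[1]]
    seqs[id] <- paste(chars, collapse = "")
    decoyTruth[[i]] <- data.frame(
      transcript_id = id, kind = kind, windowStart = w,
      windowEnd = w + 119L, stringsAsFactors = FALSE)
  }
  for (i in seq_len(config$n_background)) {
    id <- sprintf("synth_bg%03d", i)
    L <- sample(config$length_range[1]:config$length_range[2], 1L)
    seqs[id] <- .randomSeq(L, config$gc_background)
  }
  transcripts <- Biostrings::DNAStringSet(seqs)
  lens <- nchar(seqs)
  mu <- config$count_spec$N_total * lens / sum(lens)
  C <- stats::rnbinom(length(lens), mu = mu,
                      size = 1 / config$count_spec$dispersion)
  counts <- data.frame(gene_id = names(seqs), count = C, length = lens,
                       stringsAsFactors = FALSE)
  truth <- list(
    ssrs = if (length(ssrTruth)) do.call(rbind, ssrTruth) else NULL,
    hairpins = if (length(hairpinTruth)) do.call(rbind, hairpinTruth)
               else NULL,
    decoys = if (length(decoyTruth)) do.call(rbind, decoyTruth) else NULL)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeTranscripts(transcripts, file.path(outdir, "transcripts.fasta"))
    utils::write.table(counts, file.path(outdir, "counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                         dataframe = "rows", pretty = TRUE)
  }
  list(transcripts = transcripts, counts = counts, truth = truth)
}

#' Generate a miRNA/target set with planted sites and expected verdicts
#'
#' Two mature miRNAs are used: a GC-biased 21-mer for the mismatch
#' patterns and an AU-rich 21-mer whose perfect site fails only the duplex
#' energy cutoff. Each target transcript carries one planted antisense
#' site in an unpairable A/C background:
#' `compliant_perfect`, `compliant_2mm` (benign mismatches at positions 8
#' and 18), `cleavage_mm10`, `seed_mm3`, `consecutive_mm13_15`,
#' `total_4mm` (positions 1, 8, 13, 19) and `mfe_weak`.
#'
#' @param seed RNG seed
#' @param nPerPattern planted sites per pattern
#' @return list: `mirnas` (named RNA strings), `transcripts`
#'   (`DNAStringSet`), `truth` (data.frame with expected pass/fail and
#'   reason)
#' @export
generateTargetSet <- function(seed = 1L, nPerPattern = 2L) {
  set.seed(seed)
  ## fixed mature sequences with documented energy margins: the GC-biased
  ## 21-mer keeps a perfect duplex well below -30 kcal/mol even after two
  ## benign mismatches; the AU-rich one stays above -30 when perfectly
  ## paired, so its sites fail on energy alone
  mirGC <- "GCUGGCGACGUCCAUGGCGCU"
  mirAU <- "AUUAUAAUCUAAUAUUAAUAU"
  mirnas <- c(mir_gc = mirGC, mir_au = mirAU)
  patterns <- list(
    compliant_perfect = list(mir = "mir_gc", mm = integer(0),
                             pass = TRUE, reason = ""),
    compliant_2mm = list(mir = "mir_gc", mm = c(8L, 18L),
                         pass = TRUE, reason = ""),
    cleavage_mm10 = list(mir = "mir_gc", mm = 10L,
                         pass = FALSE, reason = "CLEAVAGE"),
    seed_mm3 = list(mir = "mir_gc", mm = 3L,
                    pass = FALSE, reason = "SEED"),
    consecutive_mm13_15 = list(mir = "mir_gc", mm = 13L:15L,
                               pass = FALSE, reason = "CONSECUTIVE"),
    total_4mm = list(mir = "mir_gc", mm = c(1L, 8L, 13L, 19L),
                     pass = FALSE, reason = "TOTAL_MM"),
    mfe_weak = list(mir = "mir_au", mm = integer(0),
                    pass = FALSE, reason = "MFE"))
  seqs <- character(0)
  truth <- list()
  for (pname in names(patterns)) {
    pat <- patterns[[pname]]
    mir <- strsplit(mirnas[[pat$mir]], "")[[1]]
    k <- length(mir)
    for (r in seq_len(nPerPattern)) {
      ## plus-strand site = reverse complement of the miRNA (DNA), then
      ## mutated: miRNA position q maps to site position k - q + 1
      site <- strsplit(revComp(chartr("U", "T", mirnas[[pat$mir]]),
                               alphabet = "DNA"), "")[[1]]
      for (q in pat$mm)
        site[k - q + 1L] <- .nonPairing(chartr("U", "T", mir[q]))
      id <- sprintf("synth_tgt_%s_%d", pname, r)
      L <- 200L
      chars <- strsplit(.randomSeq(L, alphabet = c("A", "C")), "")[[1]]
      p <- sample(30L:(L - k - 30L), 1L)
      chars[p:(p + k - 1L)] <- site
      seqs[id] <- paste(chars, collapse = "")
      truth[[length(truth) + 1L]] <- data.frame(
        mirna_id = pat$mir, target_id = id, pattern = pname,
        siteStart = p, siteEnd = p + k - 1L,
        expect_pass = pat$pass, expect_reason = pat$reason,
        stringsAsFactors = FALSE)
    }
  }
  list(mirnas = mirnas, transcripts = Biostrings::DNAStringSet(seqs),
       truth = do.call(rbind, truth))
}
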