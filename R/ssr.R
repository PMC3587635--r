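#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

## A motif is primitive when it is not a whole-number repetition of a shorter
## motif; this also rejects homopolymer "dimers" such as AA.
.isPrimitive <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        motif == paste(rep(substr(motif, 1L, d), k / d), collapse = ""))
      return(FALSE)
  }
  TRUE
}

#' Detect perfect simple sequence repeats in one transcript
#'
#' Reports every maximal perfect tandem tract of a primitive motif of length
#' `minMotif`..`maxMotif` with at least `minIterations` full iterations.
#' Partial trailing copies are neither counted nor included in the interval.
#' Mononucleotide runs are never reported (a homopolymer is not a primitive
#' dimer), and a tract is described only by its shortest period, so an
#' `AT x 6` tract is never also reported as `ATAT x 3`. Tracts containing N
#' are skipped.
#'
#' @param seq DNA string (or a `DNAString`), or a single element of the set
#'   returned by [readTranscripts()]
#' @param id transcript identifier used in the output
#' @param minMotif,maxMotif motif length bounds (defaults 2 and 5:
#'   dimers through pentamers)
#' @param minIterations minimum number of full motif copies (default 5)
#' @return a `GRanges` (seqnames = `id`, 1-based inclusive ranges) with
#'   mcols `motif`, `iterations`, `canonicalClass`
#' @examples
#' findSSRs("AGAGAGAGAG", id = "u1")   # one AG x 5 tract
#' @export
findSSRs <- function(seq, id = "seq1", minMotif = 2L, maxMotif = 5L,
                     minIterations = 5L) {
  if (minMotif < 1L || maxMotif < minMotif)
    stop("invalid motif length bounds")
  seq <- toupper(as.character(seq))
  if (nchar(seq) == 0L) stop("empty transcript")
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  res <- list()
  for (k in seq.int(max(minMotif, 2L), maxMotif)) {
    if (n < k * minIterations) next
    eq <- b[seq_len(n - k)] == b[seq_len(n - k) + k]
    r <- rle(eq)
    pos <- cumsum(c(1L, r$lengths))
    for (ri in which(r$values)) {
      a <- pos[ri]                       # run start (1-based)
      len <- r$lengths[ri] + k           # tandem span length
      iter <- len %/% k
      if (iter < minIterations) next
      motif <- substr(seq, a, a + k - 1L)
      if (grepl("N", substr(seq, a, a + len - 1L), fixed = TRUE)) next
      if (!.isPrimitive(motif)) next
      res[[length(res) + 1L]] <- data.frame(
        start = a, end = a + k * iter - 1L, motif = motif,
        iterations = iter, stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L)
    return(GenomicRanges::GRanges(
      seqnames = character(0), ranges = IRanges::IRanges(),
      motif = character(0), iterations = integer(0),
      canonicalClass = character(0)))
  df <- do.call(rbind, res)
  df <- df[order(df$start, nchar(df$motif)), , drop = FALSE]
  GenomicRanges::GRanges(
    seqnames = id,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    motif = df$motif, iterations = df$iterations,
    canonicalClass = vapply(df$motif, canonicalClass, ""))
}

#' Scan a transcript collection for SSRs
#'
#' @param transcripts named `DNAStringSet`
#' @inheritParams findSSRs
#' @return a `GRanges` combining per-transcript results, with `seqlengths`
#'   set from the transcript lengths
#' @export
findSSRsAll <- function(transcripts, minMotif = 2L, maxMotif = 5L,
                        minIterations = 5L) {
  hits <- lapply(names(transcripts), function(id)
    findSSRs(transcripts[[id]], id = id, minMotif = minMotif,
             maxMotif = maxMotif, minIterations = minIterations))
  gr <- suppressWarnings(do.call(c, hits))
  if (is.null(gr)) gr <- findSSRs("ACGT", id = "x")[0]
  GenomeInfoDb::seqlevels(gr) <- names(transcripts)
  GenomeInfoDb::seqlengths(gr) <- Biostrings::width(transcripts)
  gr
}

#' Canonical motif class pairing a motif with its reverse complement
#'
#' Rotational phases are not merged: `GA` and `AG` head different classes,
#' matching the reporting convention of transcriptome SSR surveys. A motif
#' equal to its own reverse complement (e.g. `TA`) forms a singleton class;
#' otherwise the class label is `X/Y` with X the lexicographically smaller
#' of the motif and its reverse complement.
#'
#' @param motif DNA motif, 2-5 nt
#' @return character(1) class label
#' @examples
#' canonicalClass("GA")   # "GA/TC"
#' canonicalClass("TA")   # "TA"
#' @export
canonicalClass <- function(motif) {
  motif <- toupper(motif)
  if (!grepl("^[ACGT]{2,5}$", motif))
    stop("motif must be 2-5 nt over A,C,G,T: ", motif)
  rc <- revComp(motif, alphabet = "DNA")
  if (motif == rc) return(motif)
  pair <- sort(c(motif, rc))
  paste0(pair[1], "/", pair[2])
}

#' Summary statistics over a set of SSR hits
#'
#' @param hits `GRanges` of SSR hits (as from [findSSRsAll()])
#' @param totalScannedNt total nucleotides scanned (density denominator)
#' @return list with counts by motif-length class and canonical class, the
#'   iteration histogram, transcript tallies, and `density` in SSRs per Mb
#' @export
summarizeSSRs <- function(hits, totalScannedNt) {
  if (totalScannedNt <= 0) stop("totalScannedNt must be positive")
  mc <- S4Vectors::mcols(hits)
  lenClass <- c(`2` = "di", `3` = "tri", `4` = "tetra", `5` = "penta")
  byLen <- table(factor(lenClass[as.character(nchar(mc$motif))],
                        levels = c("di", "tri", "tetra", "penta")))
  perTx <- split(mc$motif, as.character(GenomicRanges::seqnames(hits)))
  list(
    n_total = length(hits),
    count_by_length_class = as.list(byLen),
    count_by_canonical_class =
      as.list(table(mc$canonicalClass)),
    iteration_histogram = as.list(table(mc$iterations)),
    n_transcripts_with_ssr = length(perTx),
    n_transcripts_multi_motif =
      sum(vapply(perTx, function(m) length(unique(m)) > 1L, logical(1))),
    density = length(hits) / (totalScannedNt / 1e6))
}
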