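#' Classify an SSR's position relative to a pre-miRNA candidate
#'
#' Classification is interval arithmetic in the candidate's transcriptional
#' orientation: for a plus-direction candidate an SSR entirely before the
#' window is upstream and entirely after is downstream; for a minus
#' candidate the two labels swap. Any overlap with the window is "within".
#'
#' @param ssrStart,ssrEnd SSR interval (1-based inclusive, plus strand)
#' @param windowStart,windowEnd candidate window (same convention)
#' @param direction candidate direction, "plus" or "minus"
#' @return one of "upstream", "within", "downstream"
#' @export
classifyPosition <- function(ssrStart, ssrEnd, windowStart, windowEnd,
                             direction = "plus") {
  stopifnot(ssrStart <= ssrEnd, windowStart <= windowEnd)
  klass <- if (ssrEnd < windowStart) "upstream"
           else if (ssrStart > windowEnd) "downstream"
           else "within"
  if (direction == "minus") {
    klass <- switch(klass, upstream = "downstream",
                    downstream = "upstream", within = "within")
  }
  klass
}

#' Position calls for every (SSR, candidate) pair sharing a transcript
#'
#' @param ssrHits `GRanges` of SSR hits
#' @param cands candidate data.frame from [predictCandidates()]
#' @return data.frame with one row per co-transcript pair: transcript id,
#'   SSR motif and interval, candidate label and window, and `klass`
#' @export
positionCalls <- function(ssrHits, cands) {
  rows <- list()
  ssrTx <- as.character(GenomicRanges::seqnames(ssrHits))
  for (i in seq_len(nrow(cands))) {
    idx <- which(ssrTx == cands$transcript_id[i])
    for (j in idx) {
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = cands$transcript_id[i],
        motif = S4Vectors::mcols(ssrHits)$motif[j],
        ssrStart = GenomicRanges::start(ssrHits)[j],
        ssrEnd = GenomicRanges::end(ssrHits)[j],
        label = cands$label[i],
        windowStart = cands$windowStart[i],
        windowEnd = cands$windowEnd[i],
        direction = cands$direction[i],
        klass = classifyPosition(
          GenomicRanges::start(ssrHits)[j], GenomicRanges::end(ssrHits)[j],
          cands$windowStart[i], cands$windowEnd[i], cands$direction[i]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(transcript_id = character(0), motif = character(0),
                      ssrStart = integer(0), ssrEnd = integer(0),
                      label = character(0), windowStart = integer(0),
                      windowEnd = integer(0), direction = character(0),
                      klass = character(0)))
  do.call(rbind, rows)
}

#' Summarize the upstream/within/downstream distribution of SSRs
#'
#' Counts and proportions per class, with a two-sided exact binomial test
#' of downstream versus upstream counts under a null of equal probability
#' ("within" calls are excluded from the test). With no upstream or
#' downstream calls at all the test is undefined and p = 1 is reported with
#' a warning.
#'
#' @param calls data.frame from [positionCalls()] (needs a `klass` column)
#' @return list: `n_upstream`, `n_within`, `n_downstream`, `proportions`
#'   (named, summing to 1), `p_value`
#' @export
#' @importFrom stats binom.test
biasSummary <- function(calls) {
  if (nrow(calls) == 0L) stop("no position calls")
  counts <- table(factor(calls$klass,
                         levels = c("upstream", "within", "downstream")))
  nUp <- unname(counts["upstream"]); nDn <- unname(counts["downstream"])
  if (nUp + nDn == 0L) {
    warning("no upstream/downstream calls; bias test undefined")
    p <- 1.0
  } else {
    p <- stats::binom.test(nDn, nUp + nDn, p = 0.5,
                           alternative = "two.sided")$p.value
  }
  list(n_upstream = as.integer(counts["upstream"]),
       n_within = as.integer(counts["within"]),
       n_downstream = as.integer(counts["downstream"]),
       proportions = as.numeric(counts) / sum(counts),
       p_value = p)
}
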