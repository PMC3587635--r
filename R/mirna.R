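#' Default pre-miRNA discovery parameters
#'
#' Window length 120 nt (the span every reported candidate window has in
#' published surveys of this kind), scan step 20 nt so any 120-nt hairpin is
#' fully contained in some window, folding energy window -57..-32 kcal/mol,
#' A+U band 30-70% on the pre-miRNA window, fewer than six mature/star
#' mismatches (implemented as <= 5), mature lengths 20-22 nt, and no
#' bulge/interior defect larger than 3 nt within the mature span.
#'
#' @return named list of parameters
#' @export
mirnaDefaults <- function() {
  list(window_len = 120L, step = 20L,
       mfe_min = -57, mfe_max = -32,
       au_min = 30, au_max = 70,
       max_star_mismatch = 5L,
       mature_lengths = c(20L, 21L, 22L),
       max_defect = 3L)
}

#' Enumerate scan windows over a transcript
#'
#' Plus-strand windows start at 1, 1+step, ... while a full window fits;
#' each window is also evaluated on the reverse complement (direction
#' minus). Windows containing N are skipped.
#'
#' @param seq transcript DNA string
#' @param windowLen window length in nt
#' @param step offset between consecutive windows
#' @return data.frame with `start`, `end` (1-based inclusive, plus strand)
#'   and `direction` ("plus"/"minus"); zero rows when the transcript is
#'   shorter than one window
#' @export
scanWindows <- function(seq, windowLen = 120L, step = 20L) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      direction = character(0))
  if (n < windowLen) {
    message("transcript shorter than one window (", n, " nt), skipped")
    return(empty)
  }
  starts <- seq.int(1L, n - windowLen + 1L, by = step)
  keep <- !vapply(starts, function(s)
    grepl("N", substr(seq, s, s + windowLen - 1L), fixed = TRUE), logical(1))
  starts <- starts[keep]
  if (length(starts) == 0L) return(empty)
  data.frame(start = rep(starts, each = 2L),
             end = rep(starts + windowLen - 1L, each = 2L),
             direction = rep(c("plus", "minus"), length(starts)))
}

## stem chain of the hairpin whose innermost pair is (i, j):
## matrix with one row per pair, outermost first, columns p5 / p3
.stemChain <- function(pairs, i, j) {
  n <- length(pairs)
  chain <- list(c(i, j))
  a <- i; b <- j
  repeat {
    pl <- a - 1L
    while (pl >= 1L && pairs[pl] == 0L) pl <- pl - 1L
    qr <- b + 1L
    while (qr <= n && pairs[qr] == 0L) qr <- qr + 1L
    if (pl >= 1L && qr <= n && pairs[pl] == qr) {
      chain[[length(chain) + 1L]] <- c(pl, qr)
      a <- pl; b <- qr
    } else break
  }
  do.call(rbind, rev(chain))
}

## defects (bulges/interior loops) along a stem chain; per defect the total
## unpaired size plus the position runs on each arm
.stemDefects <- function(chain) {
  if (nrow(chain) < 2L) return(list())
  out <- list()
  for (t in seq_len(nrow(chain) - 1L)) {
    g5 <- chain[t + 1L, 1L] - chain[t, 1L] - 1L
    g3 <- chain[t, 2L] - chain[t + 1L, 2L] - 1L
    if (g5 + g3 > 0L)
      out[[length(out) + 1L]] <- list(
        size = g5 + g3,
        pos5 = if (g5 > 0L) (chain[t, 1L] + 1L):(chain[t + 1L, 1L] - 1L)
               else integer(0),
        pos3 = if (g3 > 0L) (chain[t + 1L, 2L] + 1L):(chain[t, 2L] - 1L)
               else integer(0))
  }
  out
}

#' Evaluate one 120-nt window against the five pre-miRNA criteria
#'
#' The window is folded with [foldMFE()] and rejected with `MFE_RANGE`
#' unless its energy lies in `[mfe_min, mfe_max]`, with `AU_RANGE` unless
#' its A+U content lies in `[au_min, au_max]`, and with `NO_HAIRPIN` when
#' the structure has no terminal stem-loop. Mature placements of 20-22 nt
#' are slid over the full hairpin span; a placement fails when it overlaps
#' the hairpin loop or covers a bulge/interior defect larger than
#' `max_defect` (`LOOP_BREAK`), or when it has six or more mismatches with
#' the opposite arm (`STAR_MISMATCH`; an unpaired mature position counts as
#' one mismatch, a G:U pair as zero). The best surviving placement (fewest
#' mismatches, then 5'-most) is returned.
#'
#' @param wseq window sequence (RNA or DNA), length `window_len`, no N
#' @param params parameter list, see [mirnaDefaults()]
#' @return list with `accepted` (logical); on acceptance `matureStart`,
#'   `matureEnd` (1-based within the window, in the window's own
#'   orientation), `matureSeq`, `starMismatches`, `mfe`, `auPre`,
#'   `auMature`, `hairpin` (one-row data.frame); otherwise `rejectReason`
#' @export
evaluateWindow <- function(wseq, params = mirnaDefaults()) {
  wseq <- asRNA(as.character(wseq))
  if (nchar(wseq) != params$window_len)
    stop("window must be ", params$window_len, " nt")
  s <- foldMFE(wseq)
  e <- mfe(s)
  auPre <- auContent(wseq)
  rejection <- function(reason)
    list(accepted = FALSE, rejectReason = reason, mfe = e, auPre = auPre)
  if (e < params$mfe_min || e > params$mfe_max) return(rejection("MFE_RANGE"))
  if (auPre < params$au_min || auPre > params$au_max)
    return(rejection("AU_RANGE"))
  hp <- extractHairpins(s)
  if (nrow(hp) == 0L) return(rejection("NO_HAIRPIN"))
  p <- pairTable(s)
  best <- NULL
  sawPlacement <- FALSE
  sawLoopClean <- FALSE
  for (h in seq_len(nrow(hp))) {
    chain <- .stemChain(p, hp$arm5End[h], hp$arm3Start[h])
    defects <- .stemDefects(chain)
    loopPos <- if (hp$loopSize[h] > 0L)
      (hp$arm5End[h] + 1L):(hp$arm3Start[h] - 1L) else integer(0)
    for (len in params$mature_lengths) {
      if (hp$end[h] - hp$start[h] + 1L < len) next
      for (st in hp$start[h]:(hp$end[h] - len + 1L)) {
        span <- st:(st + len - 1L)
        sawPlacement <- TRUE
        if (length(intersect(span, loopPos)) > 0L) next
        onArm5 <- all(span <= hp$arm5End[h])
        onArm3 <- all(span >= hp$arm3Start[h])
        if (!onArm5 && !onArm3) next  # straddles the loop region
        defBad <- any(vapply(defects, function(d) {
          hitPos <- if (onArm5) d$pos5 else d$pos3
          d$size > params$max_defect && length(intersect(span, hitPos)) > 0L
        }, logical(1)))
        if (defBad) next
        sawLoopClean <- TRUE
        mm <- sum(p[span] == 0L)
        if (mm > params$max_star_mismatch) next
        if (is.null(best) || mm < best$starMismatches ||
            (mm == best$starMismatches && st < best$matureStart)) {
          best <- list(matureStart = st, matureEnd = st + len - 1L,
                       starMismatches = mm, hairpinRow = h)
        }
      }
    }
  }
  if (is.null(best)) {
    if (sawLoopClean) return(rejection("STAR_MISMATCH"))
    if (sawPlacement) return(rejection("LOOP_BREAK"))
    return(rejection("NO_MATURE"))
  }
  matureSeq <- substr(wseq, best$matureStart, best$matureEnd)
  list(accepted = TRUE,
       matureStart = best$matureStart, matureEnd = best$matureEnd,
       matureSeq = matureSeq, starMismatches = best$starMismatches,
       mfe = e, auPre = auPre, auMature = auContent(matureSeq),
       hairpin = hp[best$hairpinRow, , drop = FALSE])
}

#' Collapse overlapping accepted windows to the lowest-energy one
#'
#' Non-overlapping candidates on a transcript are all kept; overlapping
#' window sets are represented by their lowest-free-energy member.
#'
#' @param cands candidate data.frame (one transcript) with `windowStart`,
#'   `windowEnd`, `mfe`
#' @return the surviving rows, ordered by window start
#' @export
selectBest <- function(cands) {
  if (nrow(cands) <= 1L) return(cands)
  ord <- order(cands$mfe, cands$windowStart)
  kept <- integer(0)
  for (i in ord) {
    overlaps <- any(cands$windowStart[i] <= cands$windowEnd[kept] &
                    cands$windowEnd[i] >= cands$windowStart[kept])
    if (!overlaps) kept <- c(kept, i)
  }
  out <- cands[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate candidates with the SSR motifs of their transcripts
#'
#' @param cands candidate data.frame from [predictCandidates()]
#' @param ssrHits `GRanges` of SSR hits on the same transcript id space
#' @param ssrBearing when TRUE, candidates on SSR-free transcripts are
#'   dropped (the "SSR-bearing" pipeline mode)
#' @return `cands` with a `motifs` column (comma-separated, in order of
#'   first occurrence on the transcript)
#' @export
attachSSRs <- function(cands, ssrHits, ssrBearing = FALSE) {
  motifTab <- vapply(split(
    S4Vectors::mcols(ssrHits)$motif,
    as.character(GenomicRanges::seqnames(ssrHits))),
    function(m) paste(unique(m), collapse = ","), "")
  cands$motifs <- unname(motifTab[cands$transcript_id])
  if (ssrBearing) cands <- cands[!is.na(cands$motifs), , drop = FALSE]
  cands$motifs[is.na(cands$motifs)] <- ""
  rownames(cands) <- NULL
  cands
}

#' Predict SSR-bearing pre-miRNA candidates over a transcript collection
#'
#' Runs the window scan and five-criterion evaluation over every transcript
#' (both orientations), collapses overlapping acceptances to the lowest
#' energy structure, labels multiple disjoint candidates on one transcript
#' with letter suffixes, and annotates SSR motifs. The filter funnel
#' (transcripts -> SSR-bearing -> retained after exclusion -> accepted
#' candidates) is reported via `message()`.
#'
#' @param transcripts named `DNAStringSet`
#' @param ssrHits optional `GRanges` of SSR hits; required for
#'   `ssrBearing = TRUE`
#' @param params see [mirnaDefaults()]
#' @param ssrBearing restrict to transcripts carrying at least one SSR
#' @param excludeIds transcript ids to drop (e.g. database-annotated ones)
#' @return list with `candidates` (data.frame; plus-strand 1-based
#'   coordinates, `label` carrying the a/b/c suffixes) and `rejects`
#'   (data.frame of rejected windows with reasons)
#' @export
predictCandidates <- function(transcripts, ssrHits = NULL,
                              params = mirnaDefaults(),
                              ssrBearing = FALSE, excludeIds = NULL) {
  n0 <- length(transcripts)
  ids <- names(transcripts)
  if (ssrBearing) {
    if (is.null(ssrHits)) stop("ssrBearing mode needs ssrHits")
    ids <- intersect(ids,
                     unique(as.character(GenomicRanges::seqnames(ssrHits))))
  }
  n1 <- length(ids)
  if (!is.null(excludeIds)) ids <- setdiff(ids, excludeIds)
  n2 <- length(ids)
  accepted <- list()
  rejects <- list()
  for (id in ids) {
    seq <- as.character(transcripts[[id]])
    wins <- scanWindows(seq, params$window_len, params$step)
    perTx <- list()
    for (w in seq_len(nrow(wins))) {
      ws <- wins$start[w]; we <- wins$end[w]; dir <- wins$direction[w]
      sub <- substr(seq, ws, we)
      wseq <- if (dir == "plus") asRNA(sub) else revComp(asRNA(sub))
      ev <- evaluateWindow(wseq, params)
      if (!ev$accepted) {
        rejects[[length(rejects) + 1L]] <- data.frame(
          transcript_id = id, windowStart = ws, windowEnd = we,
          direction = dir, reason = ev$rejectReason,
          mfe = ev$mfe, stringsAsFactors = FALSE)
        next
      }
      ## mature span in plus-strand coordinates
      if (dir == "plus") {
        ms <- ws + ev$matureStart - 1L
        me <- ws + ev$matureEnd - 1L
      } else {
        ms <- we - ev$matureEnd + 1L
        me <- we - ev$matureStart + 1L
      }
      perTx[[length(perTx) + 1L]] <- data.frame(
        transcript_id = id, windowStart = ws, windowEnd = we,
        direction = dir, matureStart = ms, matureEnd = me,
        matureSeq = ev$matureSeq, mfe = ev$mfe, auPre = ev$auPre,
        auMature = ev$auMature, starMismatches = ev$starMismatches,
        loopSize = ev$hairpin$loopSize,
        hairpinStart = if (dir == "plus") ws + ev$hairpin$start - 1L
                       else we - ev$hairpin$end + 1L,
        hairpinEnd = if (dir == "plus") ws + ev$hairpin$end - 1L
                     else we - ev$hairpin$start + 1L,
        stringsAsFactors = FALSE)
    }
    if (length(perTx)) {
      txc <- selectBest(do.call(rbind, perTx))
      accepted[[length(accepted) + 1L]] <- txc
    }
  }
  cands <- if (length(accepted)) do.call(rbind, accepted) else
    data.frame(transcript_id = character(0), windowStart = integer(0),
               windowEnd = integer(0), direction = character(0),
               matureStart = integer(0), matureEnd = integer(0),
               matureSeq = character(0), mfe = numeric(0),
               auPre = numeric(0), auMature = numeric(0),
               starMismatches = integer(0), loopSize = integer(0),
               hairpinStart = integer(0), hairpinEnd = integer(0))
  ## letter suffixes for multiple disjoint candidates on one transcript
  cands$label <- cands$transcript_id
  if (nrow(cands)) {
    for (id in unique(cands$transcript_id)) {
      rows <- which(cands$transcript_id == id)
      if (length(rows) > 1L) {
        rows <- rows[order(cands$windowStart[rows])]
        cands$label[rows] <- paste0(id, letters[seq_along(rows)])
      }
    }
  }
  if (!is.null(ssrHits)) cands <- attachSSRs(cands, ssrHits, ssrBearing)
  else cands$motifs <- ""
  rej <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(transcript_id = character(0), windowStart = integer(0),
               windowEnd = integer(0), direction = character(0),
               reason = character(0), mfe = numeric(0))
  rownames(cands) <- NULL
  message("funnel: ", n0, " transcripts -> ", n1,
          if (ssrBearing) " SSR-bearing" else " retained", " -> ", n2,
          " after exclusions -> ", nrow(cands), " accepted candidates")
  list(candidates = cands, rejects = rej)
}
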