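#' Default target-filtering parameters
#'
#' Plant miRNA complementarity rules: total mismatch score at most 3 (G:U
#' wobble = 0.5), a seed (positions 2-6 from the miRNA 5' end) allowing at
#' most one mispair and only if it is a G:U wobble, perfect Watson-Crick
#' pairing at the cleavage site (positions 10-11), no more than two
#' consecutive non-Watson-Crick positions, and duplex energy at or below
#' -30 kcal/mol.
#'
#' @return named list of parameters
#' @export
targetDefaults <- function() {
  list(max_total_mm = 3.0,
       seed_range = c(2L, 6L),
       seed_policy = c("one_wobble", "strict"),
       cleavage_positions = c(10L, 11L),
       max_consecutive = 2L,
       duplex_mfe_cutoff = -30)
}

## per-position classification of a gap-free antisense alignment:
## 0 = Watson-Crick pair, 0.5 = G:U wobble, 1 = mismatch.
## q: miRNA 5'->3'; t: target window 5'->3' (aligned antiparallel)
.alignmentScores <- function(q, t) {
  qb <- strsplit(asRNA(q), "")[[1]]
  tb <- rev(strsplit(asRNA(t), "")[[1]])
  stopifnot(length(qb) == length(tb))
  vapply(seq_along(qb), function(k) {
    pt <- .pairType(qb[k], tb[k])
    if (is.na(pt)) 1.0 else if (pt >= 5L) 0.5 else 0.0
  }, numeric(1))
}

#' Scan a transcript for candidate miRNA target alignments
#'
#' Aligns the miRNA (gap-free, antisense) against every window of equal
#' length on the transcript and on its reverse complement. Each alignment
#' records per-position pairing scores indexed from the miRNA 5' end.
#'
#' @param mirna mature miRNA string (RNA or DNA), 20-22 nt
#' @param seq target transcript sequence (DNA string)
#' @param targetId identifier used in reports
#' @return data.frame with one row per alignment: `targetStart`,
#'   `targetEnd` (1-based on the given sequence), `orientation`
#'   ("sense"/"antisense" target strand), and a `scores` list-column of
#'   per-position values (0 / 0.5 / 1)
#' @export
scanTargets <- function(mirna, seq, targetId = "target") {
  m <- asRNA(as.character(mirna))
  k <- nchar(m)
  if (k < 20L || k > 22L) stop("miRNA must be 20-22 nt")
  seq <- asRNA(as.character(seq))
  n <- nchar(seq)
  if (n < k) return(data.frame(targetStart = integer(0),
                               targetEnd = integer(0),
                               orientation = character(0)))
  rows <- list()
  for (orient in c("sense", "antisense")) {
    s <- if (orient == "sense") seq else revComp(seq)
    for (st in seq_len(n - k + 1L)) {
      win <- substr(s, st, st + k - 1L)
      sc <- .alignmentScores(m, win)
      ## report plus-strand coordinates of the bound window
      if (orient == "sense") { ts <- st; te <- st + k - 1L }
      else { ts <- n - (st + k - 1L) + 1L; te <- n - st + 1L }
      rows[[length(rows) + 1L]] <-
        data.frame(target_id = targetId, targetStart = ts, targetEnd = te,
                   orientation = orient, window = win,
                   stringsAsFactors = FALSE)
      rows[[length(rows)]]$scores <- list(sc)
    }
  }
  do.call(rbind, rows)
}

#' Score and filter one miRNA/target alignment
#'
#' @param mirna mature miRNA string
#' @param window the aligned target window (5'->3'), same length
#' @param params see [targetDefaults()]
#' @return list: `totalScore`, `seedScore`, `cleavageOk`,
#'   `maxConsecutive`, `duplexMfe`, `passed`, `failReasons`
#'   (subset of TOTAL_MM, SEED, CLEAVAGE, CONSECUTIVE, MFE)
#' @export
scoreTargetAlignment <- function(mirna, window, params = targetDefaults()) {
  sc <- .alignmentScores(mirna, window)
  seedPolicy <- match.arg(params$seed_policy, c("one_wobble", "strict"))
  fails <- character(0)
  total <- sum(sc)
  if (total > params$max_total_mm) fails <- c(fails, "TOTAL_MM")
  seed <- sc[params$seed_range[1]:params$seed_range[2]]
  seedBad <- if (seedPolicy == "strict") any(seed > 0)
             else any(seed == 1) || sum(seed == 0.5) > 1L
  if (seedBad) fails <- c(fails, "SEED")
  cleavageOk <- all(sc[params$cleavage_positions] == 0)
  if (!cleavageOk) fails <- c(fails, "CLEAVAGE")
  runs <- rle(sc > 0)
  maxRun <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  if (maxRun > params$max_consecutive) fails <- c(fails, "CONSECUTIVE")
  dE <- duplexEnergy(mirna, window)
  if (dE > params$duplex_mfe_cutoff) fails <- c(fails, "MFE")
  list(totalScore = total,
       seedScore = sum(seed),
       cleavageOk = cleavageOk,
       maxConsecutive = as.integer(maxRun),
       duplexMfe = dE,
       passed = length(fails) == 0L,
       failReasons = fails)
}

#' Predict and filter miRNA targets across a transcript collection
#'
#' @param mirnas named character vector (or `RNAStringSet`) of mature
#'   miRNAs, 20-22 nt
#' @param transcripts named `DNAStringSet` of target candidates
#' @param params see [targetDefaults()]
#' @return data.frame of scored target hits (one row per alignment that
#'   passed, plus failed alignments with a `fail_reasons` column when
#'   `includeFailed`), sorted by duplex energy
#' @param includeFailed keep failing alignments (with reasons) in the output
#' @export
predictTargets <- function(mirnas, transcripts, params = targetDefaults(),
                           includeFailed = FALSE) {
  ids <- names(mirnas)
  if (is.null(ids)) ids <- paste0("mirna", seq_along(mirnas))
  mirnas <- setNames(asRNA(as.character(mirnas)), ids)
  rows <- list()
  for (mid in names(mirnas)) {
    for (tid in names(transcripts)) {
      aln <- scanTargets(mirnas[[mid]], as.character(transcripts[[tid]]),
                         targetId = tid)
      for (i in seq_len(nrow(aln))) {
        sc <- scoreTargetAlignment(mirnas[[mid]], aln$window[i], params)
        if (!sc$passed && !includeFailed) next
        ## drop hopeless alignments even in failed mode: keep anything
        ## scoring at most twice the mismatch budget, so reports stay small
        if (!sc$passed && sc$totalScore > 2 * params$max_total_mm) next
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mid, target_id = tid,
          targetStart = aln$targetStart[i], targetEnd = aln$targetEnd[i],
          orientation = aln$orientation[i],
          total_mismatch = sc$totalScore, seed_mismatch = sc$seedScore,
          cleavage_ok = sc$cleavageOk, max_consecutive = sc$maxConsecutive,
          duplex_mfe = sc$duplexMfe, passed = sc$passed,
          fail_reasons = paste(sc$failReasons, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(0), target_id = character(0),
               targetStart = integer(0), targetEnd = integer(0),
               orientation = character(0), total_mismatch = numeric(0),
               seed_mismatch = numeric(0), cleavage_ok = logical(0),
               max_consecutive = integer(0), duplex_mfe = numeric(0),
               passed = logical(0), fail_reasons = character(0))
  out <- out[order(out$duplex_mfe, out$mirna_id, out$target_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a target report (published-survey layout)
#'
#' Columns: miRNA unigene, target gene id, duplex MFE (kcal/mol) and, in
#' failed mode, the failure reasons. Passed hits only unless
#' `includeFailed`.
#'
#' @param hits data.frame from [predictTargets()]
#' @param path output TSV
#' @param includeFailed include failing rows with their reason codes
#' @export
reportTargets <- function(hits, path, includeFailed = FALSE) {
  if (!includeFailed) hits <- hits[hits$passed, , drop = FALSE]
  df <- data.frame(mirna_unigene = hits$mirna_id,
                   target_gene_id = hits$target_id,
                   mfe_kcal_mol = sprintf("%.1f", hits$duplex_mfe),
                   stringsAsFactors = FALSE)
  if (includeFailed) df$fail_reasons <- hits$fail_reasons
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
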