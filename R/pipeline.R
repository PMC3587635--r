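#' Full pipeline configuration with documented defaults
#'
#' Union of the module parameter sets: `ssr` (motif length bounds and
#' minimum iterations), `mirna` (see [mirnaDefaults()]), `target` (see
#' [targetDefaults()]), `synth` (see [synthConfig()]) and a global `seed`.
#'
#' @return nested named list
#' @export
pipelineDefaults <- function() {
  list(seed = 1L,
       ssr = list(min_motif = 2L, max_motif = 5L, min_iterations = 5L),
       mirna = mirnaDefaults(),
       target = targetDefaults(),
       synth = synthConfig())
}

.mergeConfig <- function(defaults, override, path = "") {
  for (key in names(override)) {
    if (!key %in% names(defaults))
      stop("unknown config key: ", paste0(path, key))
    if (is.list(defaults[[key]]) && is.list(override[[key]]))
      defaults[[key]] <- .mergeConfig(defaults[[key]], override[[key]],
                                      paste0(path, key, "."))
    else defaults[[key]] <- override[[key]]
  }
  defaults
}

#' Read a YAML pipeline configuration
#'
#' Values override [pipelineDefaults()]; unknown keys are rejected.
#'
#' @param path YAML file, or NULL for pure defaults
#' @return config list
#' @export
readPipelineConfig <- function(path = NULL) {
  cfg <- pipelineDefaults()
  if (!is.null(path)) {
    override <- yaml::read_yaml(path)
    cfg <- .mergeConfig(cfg, override)
  }
  cfg
}

#' Run SSR mining on a FASTA file
#'
#' @param fasta input transcript FASTA
#' @param out output SSR table (TSV)
#' @param config pipeline config
#' @return (invisibly) list with `hits` and `summary`
#' @export
runSSR <- function(fasta, out, config = pipelineDefaults()) {
  tx <- readTranscripts(fasta)
  message("ssr: ", length(tx), " transcripts, ",
          sum(Biostrings::width(tx)), " nt scanned")
  hits <- findSSRsAll(tx, config$ssr$min_motif, config$ssr$max_motif,
                      config$ssr$min_iterations)
  writeSsrTable(hits, out)
  sm <- summarizeSSRs(hits, sum(Biostrings::width(tx)))
  message("ssr: ", sm$n_total, " hits on ", sm$n_transcripts_with_ssr,
          " transcripts (density ", sprintf("%.2f", sm$density), "/Mb)")
  invisible(list(hits = hits, summary = sm))
}

#' Run pre-miRNA candidate discovery
#'
#' @param fasta input transcript FASTA
#' @param out candidate table (TSV, published-report layout)
#' @param ssrBearing restrict to SSR-bearing transcripts
#' @param excludeFile optional file of transcript ids (one per line) to
#'   drop, e.g. database-annotated ones
#' @param gff optional GFF3 output of SSR/pre-miRNA/miRNA features
#' @param config pipeline config
#' @return (invisibly) the [predictCandidates()] result
#' @export
runMirna <- function(fasta, out, ssrBearing = TRUE, excludeFile = NULL,
                     gff = NULL, config = pipelineDefaults()) {
  tx <- readTranscripts(fasta)
  if (length(tx) == 0L) stop("no transcripts in ", fasta)
  hits <- findSSRsAll(tx, config$ssr$min_motif, config$ssr$max_motif,
                      config$ssr$min_iterations)
  exclude <- if (!is.null(excludeFile)) readLines(excludeFile) else NULL
  res <- predictCandidates(tx, ssrHits = hits, params = config$mirna,
                           ssrBearing = ssrBearing, excludeIds = exclude)
  writeCandidateTable(res$candidates, out)
  if (!is.null(gff)) {
    feats <- candidateFeatures(res$candidates, hits, tx)
    writeGFF3(feats, gff)
  }
  invisible(res)
}

#' Assemble SSR / pre-miRNA / mature-miRNA features as a GRanges
#'
#' @param cands candidate data.frame
#' @param ssrHits SSR `GRanges`
#' @param transcripts `DNAStringSet` providing seqlengths
#' @return `GRanges` with `type`, `ID` and `Parent` attribute columns
#' @export
candidateFeatures <- function(cands, ssrHits, transcripts) {
  grs <- list()
  if (length(ssrHits)) {
    g <- ssrHits
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(
      type = "SSR",
      ID = sprintf("ssr_%04d", seq_along(g)),
      Parent = NA_character_,
      Name = S4Vectors::mcols(g)$motif)
    grs[["ssr"]] <- g
  }
  if (nrow(cands)) {
    pre <- GenomicRanges::GRanges(
      cands$transcript_id,
      IRanges::IRanges(cands$windowStart, cands$windowEnd),
      strand = ifelse(cands$direction == "plus", "+", "-"),
      type = "pre_miRNA", ID = paste0("pre_", cands$label),
      Parent = NA_character_, Name = cands$label)
    mat <- GenomicRanges::GRanges(
      cands$transcript_id,
      IRanges::IRanges(cands$matureStart, cands$matureEnd),
      strand = ifelse(cands$direction == "plus", "+", "-"),
      type = "miRNA", ID = paste0("mir_", cands$label),
      Parent = paste0("pre_", cands$label), Name = cands$label)
    grs[["pre"]] <- pre
    grs[["mat"]] <- mat
  }
  if (length(grs) == 0L)
    return(GenomicRanges::GRanges())
  out <- suppressWarnings(do.call(c, unname(grs)))
  GenomeInfoDb::seqlevels(out) <- names(transcripts)
  GenomeInfoDb::seqlengths(out) <- Biostrings::width(transcripts)
  out
}

#' Run miRNA target prediction between two FASTA files
#'
#' @param mirnaFasta FASTA of mature miRNAs (20-22 nt)
#' @param transcriptFasta FASTA of target candidate transcripts
#' @param out output TSV
#' @param includeFailed keep failing alignments with reasons
#' @param config pipeline config
#' @return (invisibly) the scored hit data.frame
#' @export
runTargets <- function(mirnaFasta, transcriptFasta, out,
                       includeFailed = FALSE,
                       config = pipelineDefaults()) {
  mir <- readTranscripts(mirnaFasta)
  tx <- readTranscripts(transcriptFasta)
  mirs <- setNames(asRNA(as.character(mir)), names(mir))
  hits <- predictTargets(mirs, tx, params = config$target,
                         includeFailed = includeFailed)
  reportTargets(hits, out, includeFailed = includeFailed)
  message("targets: ", sum(hits$passed), " passing site(s) for ",
          length(mirs), " miRNA(s) over ", length(tx), " transcripts")
  invisible(hits)
}

#' Positional-bias analysis from an SSR table and a candidate table
#'
#' @param ssrTable TSV written by [runSSR()]
#' @param candTable TSV written by [runMirna()]
#' @param out output TSV of per-pair position calls; a JSON summary is
#'   written next to it (same name, `.summary.json`)
#' @return (invisibly) list with `calls` and `summary`
#' @export
runPosition <- function(ssrTable, candTable, out) {
  ssr <- utils::read.table(ssrTable, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  hits <- GenomicRanges::GRanges(
    ssr$transcript_id,
    IRanges::IRanges(ssr$start_1based, ssr$end_1based),
    motif = ssr$motif, iterations = ssr$iterations,
    canonicalClass = ssr$canonical_class)
  cand <- utils::read.table(candTable, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  pos <- do.call(rbind, strsplit(cand$premirna_position, "-"))
  cands <- data.frame(
    transcript_id = sub("[a-z]$", "", cand$unigene_id),
    label = cand$unigene_id,
    windowStart = as.integer(pos[, 1]), windowEnd = as.integer(pos[, 2]),
    direction = tolower(cand$direction), stringsAsFactors = FALSE)
  calls <- positionCalls(hits, cands)
  utils::write.table(calls, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sm <- if (nrow(calls)) biasSummary(calls) else
    list(n_upstream = 0L, n_within = 0L, n_downstream = 0L,
         proportions = c(0, 0, 0), p_value = NA_real_)
  jsonlite::write_json(sm, paste0(out, ".summary.json"), auto_unbox = TRUE,
                       digits = NA)
  message("position: up ", sm$n_upstream, " / within ", sm$n_within,
          " / down ", sm$n_downstream,
          " (binomial p = ", signif(sm$p_value, 3), ")")
  invisible(list(calls = calls, summary = sm))
}

#' RPKM computation and expression classes from a count table
#'
#' @param countsFile TSV with gene_id, count, length
#' @param out output TSV with rpkm and class columns
#' @param N optional library total (defaults to the column sum)
#' @return (invisibly) the augmented data.frame
#' @export
runRPKM <- function(countsFile, out, N = NULL) {
  counts <- readCountTable(countsFile)
  res <- rpkmTable(counts, N = N)
  utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  message("rpkm: ", nrow(res), " genes (",
          paste(names(table(res$class)), table(res$class),
                sep = "=", collapse = ", "), ")")
  invisible(res)
}

#' Write a synthetic dataset to a directory
#'
#' @param outdir output directory
#' @param config pipeline config (its `synth` section and `seed` are used)
#' @return (invisibly) the [generateSynthetic()] result
#' @export
runSimulate <- function(outdir, config = pipelineDefaults()) {
  sc <- config$synth
  sc$seed <- config$seed
  res <- generateSynthetic(sc, outdir = outdir)
  message("simulate: ", length(res$transcripts), " transcripts -> ", outdir)
  invisible(res)
}

#' End-to-end pipeline on a (simulated or provided) dataset
#'
#' Simulates a transcriptome when no FASTA is given, then runs SSR mining,
#' candidate discovery, positional analysis and RPKM, writing all reports
#' into `outdir`.
#'
#' @param outdir output directory
#' @param fasta optional input FASTA; when NULL a synthetic dataset is
#'   generated into `outdir`
#' @param config pipeline config
#' @return (invisibly) list of per-stage results
#' @export
runAll <- function(outdir, fasta = NULL, config = pipelineDefaults()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- NULL
  countsFile <- NULL
  if (is.null(fasta)) {
    sim <- runSimulate(outdir, config)
    fasta <- file.path(outdir, "transcripts.fasta")
    countsFile <- file.path(outdir, "counts.tsv")
  }
  ssr <- runSSR(fasta, file.path(outdir, "ssr_table.tsv"), config)
  mir <- runMirna(fasta, file.path(outdir, "candidates.tsv"),
                  ssrBearing = TRUE, gff = file.path(outdir, "features.gff3"),
                  config = config)
  pos <- if (nrow(mir$candidates))
    runPosition(file.path(outdir, "ssr_table.tsv"),
                file.path(outdir, "candidates.tsv"),
                file.path(outdir, "position_calls.tsv"))
  else NULL
  expr <- if (!is.null(countsFile))
    runRPKM(countsFile, file.path(outdir, "rpkm.tsv")) else NULL
  invisible(list(sim = sim, ssr = ssr, mirna = mir, position = pos,
                 expression = expr))
}
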