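#' Read unigene transcripts from a multi-FASTA file
#'
#' Sequences are stored in the DNA alphabet: U is converted to T and
#' lowercase to uppercase on ingest. The identifier is the FASTA header up
#' to the first whitespace; any description after it is kept in the
#' `description` metadata column.
#'
#' @param path path to a FASTA file
#' @return a [Biostrings::DNAStringSet] named by transcript id, with a
#'   `description` metadata column
#' @export
#' @importFrom Biostrings readBStringSet DNAStringSet
#' @importFrom S4Vectors mcols mcols<- DataFrame
readTranscripts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    warning("empty FASTA file: ", path)
    return(Biostrings::DNAStringSet())
  }
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), NA_character_)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate transcript id: ", dup[1])
  seqs <- chartr("uU", "tT", toupper(as.character(raw)))
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    w <- which(bad > 0)[1]
    stop("non-IUPAC character in '", ids[w], "' at position ", bad[w])
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

#' Write transcripts to FASTA
#' @param transcripts a named `DNAStringSet`
#' @param path output file
#' @export
writeTranscripts <- function(transcripts, path) {
  Biostrings::writeXStringSet(transcripts, path)
  invisible(path)
}

#' Write an SSR hit table as TSV
#'
#' Coordinates are reported 1-based inclusive (the native `GRanges`
#' convention). Rows are sorted by (transcript, start).
#'
#' @param hits a `GRanges` from [findSSRs()] (seqnames = transcript ids,
#'   mcols: motif, iterations, canonicalClass)
#' @param path output TSV path
#' @export
writeSsrTable <- function(hits, path) {
  df <- data.frame(
    transcript_id = as.character(GenomicRanges::seqnames(hits)),
    motif = S4Vectors::mcols(hits)$motif,
    canonical_class = S4Vectors::mcols(hits)$canonicalClass,
    iterations = S4Vectors::mcols(hits)$iterations,
    start_1based = GenomicRanges::start(hits),
    end_1based = GenomicRanges::end(hits),
    tract_length = GenomicRanges::width(hits),
    stringsAsFactors = FALSE)
  df <- df[order(df$transcript_id, df$start_1based), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pre-miRNA candidate table (published-report layout)
#'
#' Columns follow the field's reporting convention for such surveys:
#' unigene id, SSR motifs on the transcript, pre-miRNA window position,
#' folding delta G printed as an unsigned magnitude, direction, mature miRNA
#' position and sequence, and mature A+U content to two decimals. All
#' positions are 1-based inclusive on the plus strand.
#'
#' @param cands candidate data.frame from [predictCandidates()]
#' @param path output TSV path
#' @export
writeCandidateTable <- function(cands, path) {
  if (nrow(cands) == 0L) {
    df <- data.frame(unigene_id = character(0), ssr_motif = character(0),
                     premirna_position = character(0), delta_g = character(0),
                     direction = character(0), mature_position = character(0),
                     mature_sequence = character(0), au_content = character(0))
  } else {
    df <- data.frame(
      unigene_id = cands$label,
      ssr_motif = cands$motifs,
      premirna_position = sprintf("%d-%d", cands$windowStart,
                                  cands$windowEnd),
      delta_g = sprintf("%.2f", abs(cands$mfe)),
      direction = ifelse(cands$direction == "plus", "Plus", "Minus"),
      mature_position = sprintf("%d-%d", cands$matureStart,
                                cands$matureEnd),
      mature_sequence = cands$matureSeq,
      au_content = sprintf("%.2f", cands$auMature),
      stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write SSR / pre-miRNA / miRNA features as GFF3
#'
#' @param features a `GRanges` whose mcols contain at least `type`
#'   (SSR, pre_miRNA or miRNA); optional `ID` and `Parent` columns link
#'   pre-miRNAs to their mature miRNAs. Additional mcols become GFF3
#'   attributes. `seqlengths` on the object, when set, are used to check
#'   that features lie inside their transcripts.
#' @param path output GFF3 path
#' @export
#' @importFrom GenomicRanges seqnames start end width strand
#' @importFrom rtracklayer export
writeGFF3 <- function(features, path) {
  sl <- GenomeInfoDb::seqlengths(features)
  if (any(!is.na(sl))) {
    lim <- sl[as.character(GenomicRanges::seqnames(features))]
    bad <- !is.na(lim) & GenomicRanges::end(features) > lim
    if (any(bad))
      stop("feature outside transcript: ",
           as.character(GenomicRanges::seqnames(features))[which(bad)[1]])
  }
  rtracklayer::export(features, path, format = "gff3")
  invisible(path)
}

#' Read a per-gene read-count table
#'
#' Expects a TSV with columns `gene_id`, `count` and `length` (header
#' required). `N`, the library total, is taken as the sum of counts unless
#' supplied separately to [rpkmTable()].
#'
#' @param path TSV path
#' @return data.frame with gene_id, count, length
#' @export
readCountTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "count", "length")
  if (!all(need %in% names(df)))
    stop("count table needs columns: ", paste(need, collapse = ", "))
  df[need]
}

#' Published SSR-bearing pre-miRNA candidate set (black pepper leaf unigenes)
#'
#' Loads the bundled table of 43 SSR-bearing pre-miRNA candidates reported
#' for a black pepper (*Piper nigrum*) leaf transcriptome survey: unigene
#' label, SSR motif(s), 1-based pre-miRNA window, reported folding delta G
#' magnitude, direction, mature miRNA position and sequence, and reported
#' mature A+U content. Two rows carry typographic mature positions exactly
#' as published (one exceeds its window, one is reversed); they are kept
#' verbatim since the table is reference input, not pipeline output.
#'
#' @return data.frame with 43 rows
#' @export
publishedCandidates <- function() {
  path <- system.file("extdata", "blackpepper_candidates.tsv",
                      package = "ssrmir", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
}

#' Published survey counts (black pepper leaf transcriptome)
#'
#' The headline counts of the same survey, used to recompute its percentage
#' statistics: unigene totals, SSR counts by motif length, the most frequent
#' dinucleotide classes, and the candidate funnel
#' (transcripts -> SSR-bearing -> unannotated -> accepted candidates).
#'
#' @return named list of integers
#' @export
publishedCounts <- function() {
  list(
    total_unigenes = 128157L,
    total_nt = 57481660L,
    ssr_unigenes = 3564L,
    multi_motif_unigenes = 309L,
    total_ssrs = 3913L,
    di = 1750L, tri = 2091L, tetra = 63L, penta = 9L,
    di_TA = 615L, di_GA_TC = 399L, di_CT_AG = 397L,
    di_TG_CA = 208L, di_AC_GT = 118L, di_CG = 13L,
    unannotated_ssr_unigenes = 183L,
    candidates = 43L)
}
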