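#' RPKM: reads per kilobase of transcript per million mapped reads
#'
#' `rpkm = 1e9 * C / (N * L)` where C is the number of reads uniquely
#' aligned to the gene, N the total uniquely aligned reads and L the gene
#' length in bases.
#'
#' @param C reads uniquely aligned to the gene (>= 0)
#' @param N total uniquely aligned reads (> 0)
#' @param L gene length in bases (> 0)
#' @return numeric RPKM value(s)
#' @examples
#' rpkm(10, 1e6, 1000)  # 10
#' @export
rpkm <- function(C, N, L) {
  if (any(N <= 0)) stop("N must be positive")
  if (any(L <= 0)) stop("L must be positive")
  if (any(C < 0)) stop("C must be non-negative")
  1e9 * as.numeric(C) / (as.numeric(N) * as.numeric(L))
}

#' Expression class of an RPKM value
#'
#' low: below 100; moderate: 100 to 1000 (inclusive both ends); high:
#' above 1000 up to 10000; very_high: above 10000.
#'
#' @param x RPKM value(s), >= 0
#' @return character vector of class labels
#' @examples
#' expressionClass(c(50, 100, 5000, 29348.92))
#' @export
expressionClass <- function(x) {
  if (any(x < 0)) stop("RPKM must be non-negative")
  cut(x, breaks = c(-Inf, 100, 1000, 10000, Inf),
      labels = c("low", "moderate", "high", "very_high"),
      right = FALSE) -> cl
  ## boundary convention: 100 and 1000 are moderate, 10000 is high
  out <- as.character(cl)
  out[x == 1000] <- "moderate"
  out[x == 10000] <- "high"
  out
}

#' RPKM table from per-gene counts
#'
#' @param counts data.frame with `gene_id`, `count`, `length` (see
#'   [readCountTable()])
#' @param N library total; defaults to `sum(counts$count)`
#' @return the input with `rpkm` and `class` columns appended
#' @export
rpkmTable <- function(counts, N = NULL) {
  if (is.null(N)) N <- sum(counts$count)
  counts$rpkm <- rpkm(counts$count, N, counts$length)
  counts$class <- expressionClass(counts$rpkm)
  counts
}
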