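#' RNAStructure: a nested secondary structure with its free energy
#'
#' Holds one RNA sequence together with a pair table and the free energy of
#' the structure under the package's nearest-neighbour model. The pair table
#' is 1-based: `pairs[i] == j` when i pairs with j, and `0` when i is
#' unpaired. Structures are nested (no pseudoknots), every pair is
#' Watson-Crick (AU, GC) or a G:U wobble, and hairpin loops hold at least
#' three unpaired nucleotides.
#'
#' @slot seq character(1), RNA sequence over A, C, G, U.
#' @slot pairs integer vector, same length as the sequence.
#' @slot energy numeric(1), kcal/mol; 0 for a fully unpaired structure,
#'   otherwise the model free energy.
#'
#' @examples
#' s <- foldMFE("GGGGGAAAACCCCC")
#' pairTable(s)
#' dotBracket(s)
#' mfe(s)
#' @export
setClass("RNAStructure",
  representation(seq = "character", pairs = "integer", energy = "numeric"))

setValidity("RNAStructure", function(object) {
  n <- nchar(object@seq)
  p <- object@pairs
  if (length(p) != n) return("pair table length != sequence length")
  if (!all(strsplit(object@seq, "")[[1]] %in% c("A", "C", "G", "U")))
    return("sequence must be RNA over A,C,G,U")
  paired <- which(p != 0L)
  if (any(p[paired] < 1L | p[paired] > n)) return("pair index out of range")
  if (!all(p[p[paired]] == paired)) return("pair table is not an involution")
  b <- strsplit(object@seq, "")[[1]]
  for (i in paired[p[paired] > paired]) {
    j <- p[i]
    if (is.na(.pairType(b[i], b[j]))) return("non-canonical base pair")
    if (j - i - 1L < 3L) return("hairpin loop shorter than 3 nt")
  }
  ## nestedness: no crossing pairs
  open <- integer(0)
  for (i in seq_len(n)) {
    if (p[i] > i) open <- c(open, i)
    else if (p[i] != 0L && p[i] < i) {
      if (length(open) == 0L || open[length(open)] != p[i])
        return("pseudoknotted (crossing) pairs")
      open <- open[-length(open)]
    }
  }
  TRUE
})

#' @describeIn RNAStructure pair table accessor (0 = unpaired)
#' @param x,object an `RNAStructure`
#' @export
pairTable <- function(x) x@pairs

#' @describeIn RNAStructure minimum free energy of the structure (kcal/mol)
#' @export
mfe <- function(x) x@energy

#' @describeIn RNAStructure the folded sequence
#' @export
structureSeq <- function(x) x@seq

#' Dot-bracket rendering of a nested structure
#'
#' @param x an `RNAStructure`
#' @return character(1) in dot-bracket notation
#' @export
dotBracket <- function(x) {
  p <- pairTable(x)
  out <- rep(".", length(p))
  out[p != 0L & p > seq_along(p)] <- "("
  out[p != 0L & p < seq_along(p)] <- ")"
  paste(out, collapse = "")
}

setMethod("show", "RNAStructure", function(object) {
  cat("RNAStructure of", nchar(object@seq), "nt, ",
      sprintf("%.2f kcal/mol\n", object@energy))
  cat(" ", object@seq, "\n ", dotBracket(object), "\n")
})
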