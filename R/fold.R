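#' @useDynLib ssrmir, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

.BASE_CODE <- c(A = 0L, C = 1L, G = 2L, U = 3L)

.checkRNA <- function(seq) {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq))
    stop("seq must be a single character string")
  b <- strsplit(seq, "")[[1]]
  bad <- which(!b %in% names(.BASE_CODE))
  if (length(bad))
    stop("invalid RNA character '", b[bad[1]], "' at position ", bad[1])
  b
}

#' Convert a DNA string to the RNA alphabet
#' @param x character vector of DNA (or RNA) strings
#' @return same strings with T replaced by U, uppercased
#' @export
asRNA <- function(x) chartr("tT", "uU", toupper(x))

#' Reverse complement of an RNA or DNA string
#' @param x character vector
#' @param alphabet "RNA" or "DNA"
#' @return reverse-complemented strings in the same alphabet
#' @export
revComp <- function(x, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  x <- toupper(x)
  comp <- if (alphabet == "RNA") chartr("ACGU", "UGCA", x)
          else chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, ""), function(b) paste(rev(b), collapse = ""), "")
}

#' Fold an RNA sequence into its minimum-free-energy structure
#'
#' Computes the lowest-energy nested secondary structure of `seq` under the
#' package's nearest-neighbour model (stacking energies for Watson-Crick and
#' G:U pairs, size-dependent hairpin/bulge/interior loop penalties, linear
#' multiloop penalty; minimum hairpin loop 3 nt, lonely pairs allowed). The
#' result is deterministic: ties are resolved by a fixed traceback order that
#' prefers the paired state and the 5'-most branch.
#'
#' @param seq RNA string (A, C, G, U), 1 to 500 nt. Sequences too short to
#'   form a hairpin return the all-unpaired structure with energy 0.
#' @return an [RNAStructure-class]
#' @examples
#' foldMFE("GGGGGAAAACCCCC")
#' @export
foldMFE <- function(seq) {
  seq <- asRNA(seq)
  b <- .checkRNA(seq)
  n <- length(b)
  if (n > 500) stop("sequences longer than 500 nt are not supported")
  lv <- .loopVectors(n)
  res <- .foldMFE_cpp(unname(.BASE_CODE[b]), .STACK, lv$hairpin, lv$bulge,
                      lv$interior, .ML_CLOSE, .ML_BRANCH, .ML_UNPAIRED,
                      .MAX_LOOP)
  new("RNAStructure", seq = seq, pairs = as.integer(res$pairs),
      energy = res$energy)
}

#' Score a given nested structure under the folding energy model
#'
#' Decomposes a structure (pair table, 0 = unpaired) into its loops and sums
#' the same energy terms used by [foldMFE()]: stacking for helix steps,
#' hairpin/bulge/interior penalties by loop size, and the linear multiloop
#' penalty. Useful for enumerative cross-checks of the DP.
#'
#' @param seq RNA string
#' @param pairs integer pair table (1-based, 0 = unpaired)
#' @return numeric(1), kcal/mol (0 for the empty structure)
#' @export
structureEnergy <- function(seq, pairs) {
  b <- .checkRNA(asRNA(seq))
  n <- length(b)
  stopifnot(length(pairs) == n)
  if (all(pairs == 0L)) return(0)
  e <- 0
  opening <- which(pairs > seq_len(n))
  for (i in opening) {
    j <- pairs[i]
    ## children: pairs directly enclosed by (i,j)
    kids <- list()
    k <- i + 1L
    unpaired <- 0L
    while (k < j) {
      if (pairs[k] > k) {
        kids[[length(kids) + 1L]] <- c(k, pairs[k])
        k <- pairs[k] + 1L
      } else {
        unpaired <- unpaired + 1L
        k <- k + 1L
      }
    }
    if (length(kids) == 0L) {
      e <- e + .loopPenalty(j - i - 1L, .HAIRPIN_LOOP)
    } else if (length(kids) == 1L) {
      k <- kids[[1]][1]; l <- kids[[1]][2]
      up5 <- k - i - 1L; up3 <- j - l - 1L
      pt <- .pairType(b[i], b[j]); ptin <- .pairType(b[k], b[l])
      if (up5 == 0L && up3 == 0L) e <- e + .STACK[pt, ptin]
      else if (up5 == 0L || up3 == 0L)
        e <- e + .loopPenalty(up5 + up3, .BULGE_LOOP)
      else e <- e + .loopPenalty(up5 + up3, .INTERIOR_LOOP)
    } else {
      e <- e + .ML_CLOSE + .ML_BRANCH * (1L + length(kids)) +
        .ML_UNPAIRED * unpaired
    }
  }
  e
}

#' Extract terminal stem-loops (hairpins) from a folded structure
#'
#' A hairpin is a maximal helix run enclosing exactly one hairpin loop,
#' extended outward through bulges and interior loops until a multiloop or
#' the exterior loop is reached. `largestDefect` is the total unpaired size
#' of the biggest bulge/interior loop inside that extension.
#'
#' @param s an [RNAStructure-class]
#' @return data.frame with one row per hairpin, all coordinates 1-based
#'   inclusive within the folded sequence: `start`, `end` of the full span,
#'   arm intervals (`arm5Start`, `arm5End`, `arm3Start`, `arm3End`),
#'   `loopSize`, `stemPairs`, `largestDefect`.
#' @export
extractHairpins <- function(s) {
  p <- pairTable(s)
  n <- length(p)
  out <- list()
  ## innermost pairs: (i,j) paired with no paired position strictly inside
  for (i in which(p > seq_len(n))) {
    j <- p[i]
    if (j - i > 1L && all(p[(i + 1L):(j - 1L)] == 0L)) {
      a <- i; b2 <- j
      stem <- 1L
      defect <- 0L
      repeat {
        pl <- a - 1L
        while (pl >= 1L && p[pl] == 0L) pl <- pl - 1L
        qr <- b2 + 1L
        while (qr <= n && p[qr] == 0L) qr <- qr + 1L
        if (pl >= 1L && qr <= n && p[pl] == qr) {
          defect <- max(defect, (a - 1L - pl) + (qr - b2 - 1L))
          a <- pl; b2 <- qr
          stem <- stem + 1L
        } else break
      }
      out[[length(out) + 1L]] <- data.frame(
        start = a, end = b2,
        arm5Start = a, arm5End = i,    # outer 5' pair .. inner 5' pair
        arm3Start = j, arm3End = b2,
        loopSize = j - i - 1L, stemPairs = stem, largestDefect = defect)
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      arm5Start = integer(0), arm5End = integer(0),
                      arm3Start = integer(0), arm3End = integer(0),
                      loopSize = integer(0), stemPairs = integer(0),
                      largestDefect = integer(0)))
  do.call(rbind, out)
}

#' Duplex free energy of a gap-free antisense alignment
#'
#' The query (miRNA, 5'->3') is aligned without gaps against a target window
#' of equal length read 3'->5'. Stacking terms are summed over consecutive
#' Watson-Crick-paired steps only: G:U wobbles and mismatches interrupt
#' stacking and contribute nothing. There is no initiation term, so a fully
#' mismatched alignment scores exactly 0.
#'
#' @param q query RNA string (mature miRNA, 5'->3')
#' @param t target RNA string of the same length, given 5'->3' (the function
#'   aligns q against the reverse of t)
#' @return numeric(1), kcal/mol
#' @export
duplexEnergy <- function(q, t) {
  qb <- .checkRNA(asRNA(q))
  tb <- rev(.checkRNA(asRNA(t)))  # antiparallel
  if (length(qb) != length(tb)) stop("query and target lengths differ")
  wc <- c(AU = TRUE, UA = TRUE, CG = TRUE, GC = TRUE, GU = FALSE, UG = FALSE)
  pt <- vapply(seq_along(qb), function(k) .pairType(qb[k], tb[k]), integer(1))
  paired <- !is.na(pt) & wc[pt]
  e <- 0
  for (k in seq_len(length(qb) - 1L)) {
    if (isTRUE(paired[k]) && isTRUE(paired[k + 1L]))
      e <- e + .STACK[pt[k], pt[k + 1L]]
  }
  e
}

#' A+U content of a sequence, in percent
#'
#' @param seq DNA or RNA string; T counts as U
#' @return numeric(1): 100 * (A + U) / length
#' @examples
#' auContent("AGCGCGAGUUCGCCUUCGCCGU")  # 31.82 (rounded to 2 dp)
#' @export
auContent <- function(seq) {
  if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
    stop("seq must be a non-empty string")
  b <- strsplit(asRNA(seq), "")[[1]]
  100 * sum(b %in% c("A", "U")) / length(b)
}
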