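## Independent brute-force oracles used to cross-check the DP/scanning code.

## every nested structure of seq (as list of pair tables), minimum hairpin
## loop 3, canonical + wobble pairs only — pure enumeration, no DP
enumerateStructures <- function(seq) {
  b <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  n <- length(b)
  canPair <- function(x, y)
    paste0(x, y) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  rec <- function(i, j) {
    if (i > j) return(list(list()))
    out <- list()
    for (s in rec(i + 1L, j)) out[[length(out) + 1L]] <- s  # i unpaired
    if (j - i >= 4L) {
      for (k in (i + 4L):j) {
        if (canPair(b[i], b[k])) {
          inner <- rec(i + 1L, k - 1L)
          after <- rec(k + 1L, j)
          for (s1 in inner) for (s2 in after)
            out[[length(out) + 1L]] <- c(list(c(i, k)), s1, s2)
        }
      }
    }
    out
  }
  structs <- rec(1L, n)
  lapply(structs, function(s) {
    p <- integer(n)
    for (pr in s) { p[pr[1]] <- pr[2]; p[pr[2]] <- pr[1] }
    p
  })
}

## minimum energy over full enumeration, scored with the package's own
## loop-decomposition scorer (the minimisation is what is independent)
bruteForceMFE <- function(seq) {
  structs <- enumerateStructures(seq)
  e <- vapply(structs, function(p) structureEnergy(seq, p), numeric(1))
  min(0, min(e))
}

## brute-force SSR scanner: tests every (start, motif length, iterations)
## triple for perfect tandem identity, keeps maximal primitive tracts
bruteForceSSRs <- function(seq, minMotif = 2L, maxMotif = 5L, minIter = 5L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  prim <- function(m) {
    k <- nchar(m)
    !any(vapply(seq_len(k - 1L), function(d)
      k %% d == 0L &&
        m == paste(rep(substr(m, 1, d), k / d), collapse = ""), logical(1)))
  }
  out <- NULL
  for (k in minMotif:maxMotif) {
    for (st in seq_len(n)) {
      motif <- substr(seq, st, st + k - 1L)
      if (nchar(motif) < k || grepl("[^ACGT]", motif) || !prim(motif)) next
      it <- 1L
      while (substr(seq, st + it * k, st + (it + 1L) * k - 1L) == motif &&
             st + (it + 1L) * k - 1L <= n) it <- it + 1L
      if (it < minIter) next
      ## maximal: the periodic run must not extend one base to the left
      ## (otherwise the tract is a phase-shifted piece of a longer run)
      if (st > 1L &&
          substr(seq, st - 1L, st - 1L) == substr(motif, k, k)) next
      out <- rbind(out, data.frame(start = st, end = st + it * k - 1L,
                                   motif = motif, iterations = it,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

## straightforward target scan: all equal-length windows, both orientations,
## scored position by position with simple string comparison
bruteForceTargets <- function(mirna, tseq) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  m <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  k <- length(m)
  revcomp <- function(s) paste(rev(vapply(
    strsplit(chartr("T", "U", toupper(s)), "")[[1]],
    function(x) comp[[x]], "")), collapse = "")
  res <- NULL
  for (orient in c("sense", "antisense")) {
    s <- if (orient == "sense") chartr("T", "U", toupper(tseq))
         else chartr("U", "T", revcomp(tseq))  # keep DNA-ish input shape
    s <- chartr("T", "U", s)
    n <- nchar(s)
    if (n < k) next
    for (st in seq_len(n - k + 1L)) {
      win <- strsplit(substr(s, st, st + k - 1L), "")[[1]]
      sc <- numeric(k)
      for (q in seq_len(k)) {
        t <- win[k - q + 1L]  # antiparallel
        sc[q] <- if (comp[[m[q]]] == t) 0
                 else if ((m[q] == "G" && t == "U") ||
                          (m[q] == "U" && t == "G")) 0.5 else 1
      }
      res <- rbind(res, data.frame(orientation = orient, start = st,
                                   total = sum(sc),
                                   scores = I(list(sc))))
    }
  }
  res
}

## random RNA string
randomRNA <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                      replace = TRUE), collapse = "")

## random DNA string
randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

## background DNA guaranteed free of SSR hits (rejection sampling)
cleanBackground <- function(n, gc = 0.5) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
               collapse = "")
    if (length(findSSRs(s)) == 0L) return(s)
  }
}
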