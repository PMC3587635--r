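# ssrmir

Mining simple sequence repeats (SSRs) and SSR-bearing pre-miRNA candidates
in plant transcriptome unigenes.

## What it does, and for whom

Transcriptome surveys of non-model plants (the motivating system is a black
pepper, *Piper nigrum*, leaf transcriptome) routinely ask three linked
questions: which transcripts carry microsatellites, which unannotated
SSR-bearing transcripts fold into miRNA-precursor-like stem-loops, and
where do the repeats sit relative to those precursors. `ssrmir` is a
tested, reusable R implementation of that screening chain for
bioinformaticians who want the procedure without re-assembling someone
else's pipeline of one-off scripts:

* **SSR mining** — every maximal perfect tandem repeat with a primitive
  motif of 2–5 nt and ≥ 5 iterations, with reverse-complement motif
  classes, iteration histograms and per-Mb density
  (`findSSRs`, `summarizeSSRs`).
* **MFE folding** — a Zuker-style dynamic programme (Rcpp) over a frozen
  nearest-neighbour parameter table: stacking for Watson–Crick and G:U
  pairs, loop-size penalties, multiloop penalty
  (`foldMFE`, `extractHairpins`, `structureEnergy`).
* **Pre-miRNA discovery** — 120-nt windows on both strands pass five
  criteria: a hairpin hosting a 20–22 nt mature in one arm; fewer than six
  mature/star mismatches; folding energy in [−57, −32] kcal/mol; window
  A+U in [30, 70]%; no large loop or break in the mature span
  (`predictCandidates`).
* **Target prediction** — gap-free antisense scan with plant rules: total
  mismatch score ≤ 3 (G:U = 0.5), clean seed (positions 2–6), perfect
  cleavage site (positions 10–11), ≤ 2 consecutive mispairs, duplex energy
  ≤ −30 kcal/mol (`predictTargets`).
* **Positional bias** — upstream/within/downstream classification of each
  SSR relative to each candidate, in candidate orientation, with an exact
  binomial test of the downstream bias (`positionCalls`, `biasSummary`).
* **Expression** — RPKM = 10⁹·C/(N·L) and the low/moderate/high/very-high
  classes (`rpkm`, `expressionClass`).
* **Synthetic data** — a seeded generator that plants SSR tracts, compliant
  hairpins, criterion-violating decoys and target sites with exact truth
  tables, so every stage is validated against known ground truth
  (`generateSynthetic`, `generateTargetSet`).

## Worked example

```r
library(ssrmir)

## a transcript with a planted AG repeat and a planted hairpin
set.seed(1)
hp <- makeHairpinWindow(stemLen = 24, loopLen = 6, mismatches = 1)
bg <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
tx <- Biostrings::DNAStringSet(c(
  u1 = paste0(bg(60), hp$window, bg(20), strrep("AG", 6), bg(20))))

findSSRs(tx[["u1"]], id = "u1")
#> GRanges object with 1 range and 3 metadata columns:
#>       seqnames    ranges strand |       motif iterations canonicalClass
#>          <Rle> <IRanges>  <Rle> | <character>  <integer>    <character>
#>   [1]       u1   200-213      * |          GA          7          GA/TC

res <- predictCandidates(tx, ssrHits = findSSRsAll(tx))
#> funnel: 1 transcripts -> 1 retained -> 1 after exclusions -> 1 accepted candidates
res$candidates[, c("label","windowStart","windowEnd","direction",
                   "mfe","auPre","starMismatches")]
#>   label windowStart windowEnd direction       mfe    auPre starMismatches
#> 1    u1          41       160      plus -51.39866 45.83333              0

calls <- positionCalls(findSSRsAll(tx), res$candidates)
calls$klass
#> [1] "downstream"
```

The planted `AG x 6` tract is reported as `GA x 7` at 200–213: the random
base before it happened to be a G, which extends the maximal tract by one
full copy in the other phase — exactly the maximality rule at work. The
one accepted window folds at −51.4 kcal/mol (inside the −57..−32 band)
with 45.8% A+U (inside 30–70%) and zero mature/star mismatches (the single
planted arm mismatch sits outside the chosen mature placement); the repeat
lies downstream of the 41–160 candidate window. A shell front end wrapping the same
functions ships as `inst/scripts/ssrmir`
(`ssrmir ssr|mirna|targets|position|rpkm|simulate|all`).

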