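---
title: "Mining SSR-bearing pre-miRNA candidates: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining SSR-bearing pre-miRNA candidates: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrmir)
```

## The problem

Plant transcriptome surveys repeatedly find simple sequence repeats (SSRs,
microsatellites) inside transcribed sequences, and a small fraction of
unannotated, SSR-bearing transcripts fold into stem-loops that look like
miRNA precursors. `ssrmir` implements the complete in-silico chain used in
such surveys of assembled unigenes (the motivating system is a black pepper
leaf transcriptome): perfect-repeat mining, hairpin prediction under
explicit filtering criteria, plant-style target prediction, positional
statistics of SSRs relative to the predicted precursors, and RPKM
expression classes. Every stage is exercised against planted ground truth
from the package's own synthetic-transcriptome generator, so the pipeline
is testable without any external data download.

## SSR mining

An SSR here is a perfect (uninterrupted) tandem repetition of a primitive
motif of 2--5 nt with at least five full iterations; `findSSRs()` reports
every maximal tract exactly once. Three conventions matter:

* *Primitivity.* A tract is described only by its shortest period: an
  `AT x 6` tract is never also reported as `ATAT x 3`, and a homopolymer is
  never reported as a degenerate dimer (`AA` is a whole-number repetition
  of `A`). This prevents double counting in motif-class summaries.
* *Maximality.* Tracts cannot be extended by a full motif copy on either
  side; partial trailing copies are not counted as iterations and are not
  part of the reported interval.
* *Classes.* `canonicalClass()` pairs a motif with its reverse complement
  (`GA` and `TC` fall in `GA/TC`) but does not merge rotational phases:
  `GA/TC` and `AG/CT` are distinct classes, matching how transcriptome SSR
  surveys tabulate dinucleotide families. Self-reverse-complementary
  motifs (e.g. `TA`) form singleton classes.

Density is reported as SSRs per Mb of scanned sequence with the
denominator supplied by the caller; no assumption is made about how much
of a survey's sequence was actually scanned.

## The folding energy model

`foldMFE()` computes the minimum-free-energy nested secondary structure of
windows up to 500 nt with a Zuker-style dynamic programme (implemented in
C++): nearest-neighbour stacking over the six admissible pair types (AU,
UA, CG, GC and the G:U wobbles), hairpin/bulge/interior loop penalties
looked up by size with Jacobson--Stockmayer extrapolation beyond the
tables, and a linear multiloop penalty. The parameter values are a frozen,
package-internal table in the style of the published Turner parameters.
Conventions: minimum hairpin loop 3 nt, lonely pairs permitted, no
dangling-end or terminal-AU terms, bulge/interior loops capped at 30
unpaired nt, and deterministic tie-breaking in the traceback (paired
before unpaired, 5'-most branch first).

Two properties are enforced by tests rather than assumed: the DP energy
equals brute-force enumeration over all nested structures for sequences up
to 20 nt, and `structureEnergy()` (the loop-decomposition scorer that the
enumeration uses) scores the DP's own traceback back to the DP energy.

Energies from any fixed nearest-neighbour model agree only qualitatively
with a specific external folding program. Published delta G values from
surveys that used such programs are therefore treated as context, not as
reproduction targets; all criteria in this package that involve energies
are thresholds or properties, evaluated within the package's own model.

`duplexEnergy()` scores gap-free antisense duplexes by summing stacking
terms across consecutive Watson--Crick-paired steps only; G:U wobbles and
mismatches interrupt stacking and contribute nothing, and there is no
initiation term. This deliberately simple model makes regression values
exact and is used solely against the -30 kcal/mol target-filter cutoff.

## Pre-miRNA candidate discovery

Transcripts are scanned in 120-nt windows (the span that published
candidate tables consistently show) on both strands; the default step of
20 nt guarantees that any hairpin of up to 100 nt is fully contained in
some window. Each window faces five criteria, in this order:

1. fold into a hairpin that can host the mature miRNA in one arm;
2. fewer than six mature/star mismatches (implemented as <= 5, where an
   unpaired mature position counts 1 and a G:U pair 0 --- G:U is a
   legitimate RNA pair);
3. folding energy between -57 and -32 kcal/mol;
4. A+U content of the 120-nt window between 30 and 70%;
5. no large loop or break in the mature span, operationalised as: the
   mature placement may not overlap the hairpin loop and may not cover a
   bulge/interior defect larger than 3 nt (`max_defect`, configurable).

Criterion 5 has no published numeric value; 3 nt matches common plant
miRNA annotation practice. Mature placements of 20--22 nt are slid over
both arms and the best survivor (fewest mismatches, then 5'-most) is
kept. When several accepted windows overlap, the lowest-energy one
represents them; disjoint candidates on one transcript are labelled with
`a`, `b`, `c` suffixes. The A+U filter applies to the window; the reported
`A+U content` column is additionally computed on the mature sequence,
because published candidate tables print the mature-sequence value (their
printed A+U can therefore exceed 70% while the window still passed).
Minus-strand candidates are discovered on the reverse complement but
reported in plus-strand coordinates.

## Target prediction

`scanTargets()` aligns a 20--22 nt mature miRNA without gaps against every
equal-length window of each transcript and its reverse complement.
Positions are numbered from the miRNA 5' end; each position scores 0
(Watson--Crick), 0.5 (G:U wobble) or 1 (mismatch). A site passes when all
of the following hold: total score <= 3; the seed (positions 2--6) has no
outright mismatch and at most one wobble (the published rule "maximum 1
and 0.5 for G-U" is ambiguous; this reading matches psRNATarget-style
practice, and a `strict` policy with zero seed mispairs is available);
positions 10--11 (the cleavage site) are perfectly paired; no more than
two consecutive non-Watson--Crick positions; duplex energy <= -30
kcal/mol. Gap-free alignment is used because the rules are stated purely
in terms of mismatch counts. The filter is monotone --- adding a mismatch
can never rescue a failing site --- and this is covered by a property
test.

## Positional analysis

For every (SSR, candidate) pair on one transcript, the SSR is upstream,
within, or downstream of the candidate window, evaluated in the
candidate's transcriptional orientation (minus-strand candidates swap
upstream and downstream). "Within" means any overlap, which is the only
boundary rule that keeps the three classes mutually exclusive and
exhaustive. The downstream-versus-upstream bias is quantified with a
two-sided exact binomial test under a null of 0.5 ("within" calls are
excluded); the test is this package's addition --- small-count validity is
the reason for choosing the exact test --- since surveys typically assert
the bias from a figure without a formal test.

## Expression classes

RPKM is `1e9 * C / (N * L)`. Class boundaries follow the published
wording: low below 100; moderate from 100 to 1000 inclusive; high above
1000 up to 10000; very high above 10000. Finer survey-specific bin schemes
(e.g. 21 arbitrary classes) are out of scope.

## The synthetic-transcriptome generator

`generateSynthetic()` emulates the statistical shape of unigene data the
pipeline is meant for, with one planted feature set per transcript and a
machine-readable truth table:

* transcript lengths 300--600 nt at 50% GC (plant-like, and keeping
  compliant hairpins inside the 30--70% A+U band);
* hairpins with 22--28 bp stems of exactly half-GC shuffled composition
  (this pins stem energies reliably inside the -57..-32 band), 5--8 nt
  loops, and 0--2 arm mismatches applied to the 3' arm outside the
  intended mature span;
* SSR tracts with motifs of 2--5 nt and iteration counts 5--16 drawn with
  the steeply decaying frequencies reported in transcriptome SSR surveys
  (61% five iterations, 22% six, ...), planted with non-extending guard
  bases and at least 10 nt of clearance from other features, downstream of
  the hairpin with probability 0.7;
* negative-binomial read counts proportional to length.

Planted hairpin windows are aligned to the default scan grid, and their
compliance flag is computed by running the package's own window filter on
the planted window --- the recovery experiments therefore validate the
scanning, collapsing and reporting machinery around that filter, not the
filter against itself.

Decoy windows violate exactly one criterion by a safe margin: `au_high`
and `au_low` fold in the energy band but sit far outside the A+U band;
`weak_stem` folds far above -32 kcal/mol; `many_mismatches` keeps its
energy in band while every possible 20--22 nt arm placement carries at
least six unpaired positions. Decoy cores are deterministic, aperiodic
constructions --- early periodic designs produced accidental clean helices
in shifted registers on the minus strand --- and decoy transcripts embed
them in a homopolymer-A scaffold that cannot pair with the A/G/C cores in
either orientation. These scaffolds are adversarial test vehicles, not
realistic sequence, and are documented as such.

What passing these tests shows: the detector finds exactly what the
criteria define, on data where the truth is known by construction. What it
does not show: performance on real assemblies, where hairpins are not
planted on a grid, composition varies, and annotation status is noisy.

## Problem sizes and numerical choices

The bundled experiments use transcriptomes of roughly 50--110 transcripts
(about 50 planted hairpins and 50 decoys) and folding windows of 120 nt;
the DP/enumeration cross-check runs on 100 random sequences of 8--20 nt.
These sizes were chosen so the full validation suite completes in a few
minutes on a single core while keeping every rate estimate's binomial
confidence interval usefully narrow. Energy comparisons use an absolute
tolerance of 1e-9 kcal/mol (the DP and the scorer share constants, so
agreement is exact up to float addition order); the traceback treats
energies within 1e-6 as tied. Degenerate inputs are defined, not special-
cased away: sequences too short to fold return the unpaired structure at
0 kcal/mol, transcripts shorter than one window yield no candidates with a
log entry, and a bias test with no upstream or downstream calls reports
p = 1 with a warning.

## Known limitations

* The energy parameters are frozen package constants; absolute energies
  differ from any specific external folder, so only thresholded and
  property-based statements are made about them.
* Only perfect SSRs are detected; compound or interrupted repeats are out
  of scope.
* Target alignment is gap-free; bulged target sites are not modelled.
* The pipeline does not attempt homology (miRBase) confirmation or
  small-RNA read support; it reproduces an in-silico screening procedure,
  not a validation of miRNA identity.
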