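---
title: "Extended-seed binding-site discovery and conservation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended-seed binding-site discovery and conservation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedtrace)
```

## The model

`seedtrace` implements the in-silico half of a miRNA target-validation
study around the let-7 family. The object of interest is the **extended
antisense seed**: the DNA reverse complement of the 5'-terminal *k*
nucleotides of the mature miRNA (default *k* = 10, giving `TACTACCTCA`
for let-7). Target recognition is modelled purely as contiguous
Watson–Crick complementarity: a binding site is a maximal exact match
between the transcript sense strand and *any* substring of the extended
seed of length at least `min_match` (default 6 bp). This deliberately
simple model — no mismatches, no G:U wobble, no free-energy or context
scoring — reflects the "perfect match" definition the scan realizes; tools
like TargetScan answer a different question and are out of scope.

Three modelling decisions deserve emphasis:

* **Partial matches need not cover the canonical seed core** (miRNA
  positions 2–8). The definition is length-only, so e.g. a 6-mer drawn
  from the 3' half of the extended seed counts. The seed-core restriction
  would be a one-line change (`seed_offset` filtering) but is not the
  implemented definition.
* **Maximality and merging.** A match contained in a longer match at the
  same locus is never reported. Maximal matches whose transcript
  intervals *overlap* are collapsed to one site spanning their union,
  because a site diagram draws one tick per locus; the longest
  constituent's `match_len` and `seed_offset` are recorded, ties broken
  toward the smaller offset. Abutting (touching, non-overlapping)
  matches remain two sites. Whether overlapping matches are one or two
  sites is genuinely ambiguous in this kind of count; the merge is
  therefore a flag (`merge_overlaps`), on by default.
* **`N` never matches**, and RNA input is normalized to DNA (`U`→`T`) on
  ingest so the printed seed string compares directly against targets.

Coordinates are 0-based, half-open everywhere internally (BED-style
arithmetic); the CDS annotation `[cds_start, cds_end)` partitions each
transcript into 5'UTR/CDS/3'UTR, and a site's region label comes from its
start position, with a separate flag for sites straddling a boundary.

## Conservation by positional retention

Conservation of a site between ortholog transcripts is defined as
*retention of its position* under the optimal global pairwise alignment
of the two full-length mRNAs. Operationally: both transcripts are scanned
independently; the pair is aligned once (Needleman–Wunsch with affine
gaps, via `Biostrings::pairwiseAlignment`); and a site on one side is
called conserved when its alignment columns share at least `min_overlap`
columns with some site on the other side. Columns shared means columns
where *both* sequences have bases inside their respective sites, so a
site aligned into a gap contributes nothing.

"Retention of position" is inherently a qualitative criterion, and
interactive alignment tools rarely surface their scoring parameters, so
neither the scoring nor the retention tolerance is hard-coded as "the"
value: scoring defaults are the standard DNA set (match +2, mismatch −1,
gap open −4, gap extend −1; a length-*L* gap costs `open + L·extend`),
and `min_overlap` defaults to the scanner's `min_match` (6), keeping a
single parameter family. All five are exposed. Projection of intervals
through the alignment (`project_interval`) returns the smallest covering
interval on the partner, with an anchored empty interval when a site
aligns wholly to gaps.

## Reporter-mutant design

`design_mutant` makes the smallest deterministic edit set that abolishes
every detectable site in a context: transversions (A↔C, G↔T — chosen over
transitions to maximize pairing disruption) placed left-to-right every
`min_match`-th base within each matched block, so no window of 6 original
bases survives inside a former site. Because edits and flanks can in
principle *create* a new seed substring (or a block remnant can extend
into a flank that happens to continue the seed), the mutant is re-scanned
and any residual match is broken at its centre, iterating to a fixed
point; a position edited twice moves to a third base rather than
reverting. The scanner itself is thus the verifying oracle, and the
constructor of `reporter_insert` re-checks the invariants (equal length,
zero mutant sites, ≥ 1 wild-type site) on every construction. The actual
mutant sequences used in any particular published reporter assay are not
printed anywhere; no equivalence to them is claimed.

## Assay quantification

The quantification layer implements exactly the stated normalizations:
RLU = Firefly/Renilla (error on zero Renilla rather than an arbitrary
ratio); percent chemotaxis = 100 × migrated / matched media-only control,
where "matched" means the control replicate of the same group and
replicate index, so control rows are exactly 100 by construction; qPCR
fold expression 2^−ΔCt against the reference gene (plain ΔCt, no ΔΔCt
calibrator, ideal doubling assumed since no efficiency correction is
stated); and per-day mean ± SEM clinical-score curves on the integer 0–5
EAE scale. Missing animals are excluded from that day's *n* and flagged —
no last-observation-carried-forward, the least-assumption choice. SEM for
*n* = 1 is reported as 0 with a `single_animal` flag rather than NA, for
plotting convenience with honesty preserved. The group test is the
equal-variance two-tailed Student's *t* (not Welch), with stars at
p < 0.05/0.01/0.001/0.0001; constant-data degenerate cases use the closed
form (equal constant groups → p = 1).

## What the synthetic generator emulates — and what it does not

`generate_transcript` draws an i.i.d. background at a requested GC
fraction and **rejection-samples the whole sequence** until the assembled
transcript (planted blocks inserted verbatim, junctions included)
re-scans to exactly the planted site list. Rejection, rather than
post-hoc masking of chance matches, is what makes the ground truth exact;
the retry cap (10,000) fails loudly with a diagnostic. Planted blocks
must sit inside a single region and be ≥ *k* apart, so they can never
merge or interact. `generate_ortholog` applies i.i.d. substitutions and
geometric-length indels; protected blocks are never touched and never
split by an indel, so surviving sites are returned with exact new
coordinates, while `preserve_planted_sites = FALSE` force-ablates blocks
with the same transversion scheme as the reporter designer. Assay tables
are drawn lognormal (luciferase), Poisson (transwell counts), Gaussian
(Ct), and Gaussian-rounded-clipped (clinical scores) around a declared
effect model whose defaults mirror the study conditions qualitatively:
~50% reporter repression by a functional site restored by its mutant,
~3-fold wild-type chemotaxis versus a blunted let-7-overexpressing and an
exaggerated let-7-depleted genotype, matching expression ordering, and
slower disease trajectories under let-7 overexpression, at technical
triplicates and cohort sizes of 7–8 animals.

What the generator does *not* emulate: real base composition and repeat
structure of mammalian UTRs, codon structure in the CDS, correlated
(non-i.i.d.) evolutionary divergence, alignment ambiguity from low
complexity regions, plate effects or heteroscedastic assay noise. Passing
the recovery tests therefore demonstrates algorithmic correctness —
scanner, aligner, projector, designer and quantifiers do what their
definitions say — not that the biological site lists for any real gene
are complete or correct; on real transcripts the results depend on the
user's choice of isoform, which is treated as input.

## Numerical and testing choices

* Scanner: the implementation is a vectorized run-length dynamic program
  over the transcript-by-seed match matrix; tests compare it against an
  independent brute-force oracle (every seed substring at every offset
  via `Biostrings::matchPattern`, maximality filter, independent merge)
  on 1,000 random transcripts of length 50–2,000 plus targeted fixtures.
* Alignment: scores are verified against an independently written affine
  DP (validated in turn against literal enumeration of all alignments on
  tiny strings) on hundreds of random pairs up to length 200, under two
  scoring-parameter sets. Traceback tie-breaking is delegated to
  `Biostrings`' deterministic implementation, so outputs are bit-stable
  across runs.
* The null-hypothesis calibration of the group test uses the generator's
  Gaussian-Ct qPCR arm (two groups, equal folds, *n* = 3) over 1,000
  replicate tables; the empirical rejection rate at the first star
  threshold is checked against 0.05 within three binomial standard
  errors.
* Problem sizes in the test suite (1,000 scanner comparisons, 500 planted
  and 200 seed-free transcripts, 600 alignment pairs, a five-point
  divergence grid × 40 pairs, 500 mutant designs, 1,000 null replicates)
  were chosen to make the property checks statistically meaningful while
  keeping the whole suite around two minutes on one CPU.

## Known limitations

Alignment of very long transcripts (≫ 10 kb) is quadratic in memory via
`pairwiseAlignment`; the conservation criterion is pairwise-only (no
multi-species column scores such as PhastCons); the scanner is
single-seed (no miRNA-family collapsing); and the clinical-score module
intentionally refuses half-point scales — data on 0.5-step scales must be
recoded before import.
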