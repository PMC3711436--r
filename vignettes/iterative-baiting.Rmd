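---
title: "Iterative baiting and mapping: the mitobaitr method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative baiting and mapping: the mitobaitr method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitobaitr)
```

## The problem

Mitochondrial genomes are short (typically 14–20 kb), circular, and present in
large copy-number excess over the nuclear genome, so an ordinary whole-genome
shotgun library already contains the complete mitogenome at high coverage.
`mitobaitr` extracts and assembles it without any dedicated enrichment: starting
from a *seed* — the mitogenome of a related species, or a short barcode such as
a ~650–1200 bp COI fragment — it alternates two steps until the recruited read
count is stationary:

1. **Baiting.** Every read of the *full* pool sharing at least `n` exact,
   strand-symmetric (canonical) k-mers with the current reference is recruited
   (defaults `n = 1`, `k = 31`). Long exact k-mers make this filter highly
   specific; it is what keeps nuclear reads out even though the next step is
   deliberately permissive.
2. **Mapping and consensus.** Recruited reads are placed on the reference by
   free-end-gap overlap alignment and accepted if (a) mismatches — counting
   substitutions *and* inserted/deleted bases — do not exceed 15% of the
   aligned overlap, and (b) a read overhanging a contig end overlaps it by at
   least 30 bases. The reference is then rebuilt as a per-column majority vote
   over the placed read bases; the previous reference base is excluded from the
   vote, so reference bases never leak into the consensus. Accepted edge
   overhangs extend the contigs, which is how the assembly grows by up to
   (read length − 30) bases per end per iteration.

Because baiting always runs against the full original pool and recruited ids
accumulate by union, the recruited count is non-decreasing and bounded by the
pool size: the loop terminates. "Stationary" is implemented as the recruited
count *and* the total assembly length being unchanged across
`convergence_window` successive comparisons (default 1, i.e. two equal
consecutive values); length is included because gaps keep closing for an
iteration or two after the count has plateaued.

A de novo variant (`mode = "denovo"`) replaces the mapping step with a greedy
suffix–prefix overlap assembly of the recruited pool and additionally recruits
the mates of all baited reads (*pair rescue*). Extension per iteration then
reaches the insert-size range rather than the read-length range, which is why
it converges in fewer iterations on well-behaved (repeat-free, contamination
free) data.

## Starting references

With a related full mitogenome, `initial_reference()` first maps the pool
against that distant reference (optionally after a `quick` baiting pre-filter)
and keeps only read-covered columns, excising the rest. The iteration-0
assembly is therefore typically gapped — several contigs over the conserved
regions — and contains no base of the distant reference. With a barcode seed,
the seed itself is the iteration-0 reference.

Mapping candidates are located by exact k-mer anchors (default `anchor_k =
12`) and verified by an exhaustive dynamic-programming alignment in a window
of `band_width` (default 20) around the anchor diagonals. Baited reads carry
a 31-mer exact match by construction, so seed-and-extend is complete for
them; `anchor_k` is smaller so that reads up to ~25% diverged from a distant
reference still anchor with high probability. The trade-off is explicit: a
read whose only homology to the reference lacks any exact 12-mer will not be
placed.

## Circularity

A complete circular genome manifests as a linear contig whose ends carry the
same sequence. `detect_circularity()` looks for an exact occurrence of the
contig's leading 20 bases in its downstream half; a candidate terminal
duplication of at least `circ_min_overlap` (default 100) bases at
`circ_min_identity` (default 0.95) ungapped identity is trimmed and the contig
flagged circular. Circular contigs are subsequently baited and mapped against
a junction-padded copy (the first read-length − 1 bases appended) so
origin-spanning reads are recruit- and placeable. Both thresholds are package
choices: terminal duplications produced by error-free data are exact, and 100
bp is far above chance for mitogenome-scale sequences while remaining
reachable (duplications grow to roughly twice the read length minus edge
overlaps before growth stops).

## Proofreading mode for pooled samples

When the pool mixes reads from several related genomes (multi-species pools,
contaminated samples), the 15% mapping tolerance would happily incorporate
heterospecific reads. Proofreading mode (`proofread = TRUE`; requires a fully
paired library and a single barcode seed taken from the target itself) replaces
the consensus step with a strict, pair-aware extension:

* a read pair is incorporated only if at least one mate aligns with **100%
  identity over its full length** within the current reference;
* the other mate may overhang a reference end and then proposes extension
  columns, provided its overlapping part is also exact over at least
  `ext_min_overlap` (default 20) bases;
* extension columns are committed only while **all** candidates agree
  (unanimity), so the reference always consists of the seed plus unanimously
  committed columns — the trusted mask is all-TRUE by construction;
* a pair whose anchored mate is perfect but whose other mate contradicts the
  committed consensus through a credible (positive-score) alignment is
  rejected and counted (`fp_avoided`);
* if two reads each support two different bases at the next extension column,
  the end is flagged `halted` — the expected behaviour when two genomes in the
  pool share a conserved block longer than the library insert, where blind
  extension would chimerise.

Pairs remain candidates until both mates have been placed perfectly and fully
inside the reference (or the pair was rejected); this matters because a mate
lying beyond the current end at incorporation time still carries extension
information for a later iteration. With ~0.13 pairwise divergence, a foreign
read pair essentially never has a perfectly identical 150 bp mate, while
shared 31-mers do occur — baiting alone would admit such reads, the identity
rule keeps them out. The method's limit is stated by its halting rule:
conserved blocks longer than the insert size cannot be crossed safely.

## The simulator

`simulate_ancestor()` draws i.i.d. bases at a given AT content (default 0.55,
matching the salmonid-like setting; flatworm-like genomes are ~0.62) and can
insert a tandem non-coding repeat (unit 750–800 bp), the feature that
dominates assembly errors on real flatworm mitogenomes. `evolve_genome()`
substitutes each site independently with probability
`p = 3/4 (1 − exp(−4d/3))`, the closed form for an expected K2P distance `d`
under equal transition/transversion weighting (with equal weights K2P
coincides with the one-parameter model; the package reports no ts/tv ratio
because none is assumed). Divergences are additive, so two descendants at
0.065 from one ancestor sit ~0.13 apart — the salmonid-like setting used in
the pooled benchmark; 0.13 per branch reproduces the ~0.26 congener setting.

`simulate_reads()` samples fragment starts uniformly **on the circle** by
default (reads may span the origin); insert lengths are normal(300, 50)
truncated to the read length. A `linear = TRUE` switch reproduces the coverage
deficit toward the sequence ends that simulation from a linear reference
causes — the artefact responsible for the slightly sub-100% recovered lengths
in the original pooled experiment. Errors are substitution-only (the benchmark
uses error rate 0); per-base qualities are a constant placeholder. Reads per
genome default to 6000 (3000 pairs, ~54× on 16.6 kb).

What a green synthetic test does *not* establish: tolerance to indel
sequencing errors, to platform-specific error profiles, to NUMT-rich nuclear
backgrounds, or to genuinely repeat-dense genomes; the repeat generator and
the halting rule probe those regimes only qualitatively.

## Evaluation

`compare_assemblies()` rotates (and if necessary reverse-complements) the
truth to the assembly via a shared-k-mer offset vote, then aligns with free
terminal gaps (banded). It reports substitutions, indel *events* (one
contiguous gap = one event), identity over aligned columns, and the aligned
fraction of the truth (`length_pct`) — rendered in the `subs/indels
(identity%)` table style. A comparison matching less than half of the shorter
sequence is flagged as no credible match. `recruitment_metrics()` computes the
fraction of a target's reads recovered and the foreign fraction among
recruited reads from simulator provenance labels. `kmer_spectrum_stats()`
histograms canonical 20-mer multiplicities; the histogram mode above a noise
cutoff (default 3, motivated by error noise living at low multiplicities)
estimates k-mer coverage, total above-noise k-mer instances divided by the
peak estimate genome size, and the ratio of two pools' peaks estimates
relative copy number (`copy_ratio()`).

## Numerical and design choices

* Alignment scoring is +1/−1/−2 (match/mismatch/gap). Scores only *rank*
  candidate placements; acceptance is decided solely by the 15% and 30 bp
  rules, which is why the scoring choice is not part of the method's contract.
* "Mismatches" include gapped bases — the conservative reading that stops
  gap-riddled placements from slipping under the threshold.
* Ties: placements break ties by lower reference start, then + strand;
  consensus columns alphabetically (a base beats a deletion); greedy merges by
  longer merged contig, then lexicographically smaller id. All output is
  deterministic given the inputs; RNG enters only through the simulator.
* Coordinates are 0-based half-open internally, 1-based inclusive in reports.
* IUPAC ambiguity codes other than N are collapsed to N on input: exact-k-mer
  baiting and the 100%-identity rule are defined over a 4+N alphabet, and N
  matches nothing.
* `min_cov` defaults to 1: any read evidence retains a column, matching the
  gapped-start philosophy; uncovered columns are excised rather than padded
  with reference bases, which would poison later baiting.
* `max_iterations` defaults to 200, above the worst barcode-seeded mapping
  case we expect (~115 iterations at read-length-limited extension on a
  16.6 kb genome).

## Scale and verification

The pooled benchmark (five 16.6 kb genomes, 30 000 pooled reads, five
proofreading runs) completes in minutes on one CPU. The test suite runs the
same protocol at half scale (8.3 kb genomes, 3000 reads each, identical read
geometry, divergence and coverage) purely for speed; `scripts/acceptance.R`
runs the full-scale world and writes the four headline metrics (minimum
accuracy, minimum own-read recovery, mean false-positive fraction, minimum
recovered length) as JSON. All other properties — baiting equivalence with a
brute-force oracle, exact enforcement of the acceptance inequalities,
monotone recruitment and termination, rotation-invariant comparison,
spectrum-based genome-size recovery within ±5% — are asserted directly in the
test suite against independently coded oracles.
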