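# mitobaitr

Reconstruction of complete circular mitochondrial genomes directly from
whole-genome shotgun read pools, by iterative *in silico* baiting and mapping.
Because mitochondria vastly outnumber nuclear genome copies in total DNA,
an ordinary shotgun library already contains the mitogenome at high coverage;
`mitobaitr` fishes those reads out and assembles them, starting from nothing
more than the mitogenome of a related species or a short barcode (e.g. a
COI fragment) as seed.

Intended users: anyone assembling organelle genomes from untargeted Illumina
style data — including metagenomic or pooled multi-species samples, for which
a strict paired-end *proofreading* mode separates the species.

## Method

Each iteration, with current reference *R* and the full read pool *P*:

1. **Bait** — recruit every read of *P* sharing ≥ *n* exact canonical k-mers
   with *R* (defaults *n* = 1, *k* = 31); recruited ids accumulate by union.
2. **Map** — place recruited reads by free-end-gap overlap alignment; accept a
   placement iff mismatches ≤ ⌊0.15 × overlap⌋ (substitutions + indel bases)
   and, for reads overhanging a contig end, overlap ≥ 30 bases.
3. **Consensus** — rebuild *R* as the per-column majority over placed read
   bases (the old reference base casts no vote); accepted overhangs extend the
   contigs; uncovered columns are excised (gapped, multi-contig references are
   normal early on). Terminal self-overlap ≥ 100 bp marks circularity.

Stop when the recruited count and assembly length are stationary. A de novo
mode (`mode = "denovo"`, with pair rescue) assembles the recruited pool
greedily instead of mapping it, extending by up to the insert size per
iteration. In proofreading mode a read pair is incorporated only when one mate
matches the growing reference with 100% identity over its full length, and
extension columns are committed only where all perfectly anchored pairs agree;
conflicting pairs are rejected, and a two-sided conflict halts extension
(the expected outcome when pooled genomes share a conserved block longer than
the library insert).

The package also contains the simulator that generates the benchmark world
(circular genomes at chosen AT content and K2P divergence, optional 750–800 bp
tandem repeat, paired-end reads with normal insert sizes sampled on the
circle) and evaluation tools: truth comparison (`subs/indels (identity%)`),
read-recruitment metrics, k-mer spectrum genome-size / copy-number estimation,
and K2P distances.

## Worked example

Reconstruct a simulated 5 kb circular genome from a 1.2 kb seed in
proofreading mode:

```r
library(mitobaitr)
g    <- evolve_genome(simulate_ancestor(genome_spec(5000, rng_seed = 7)), 0,
                      name = "target")
pool <- simulate_reads(g, sim_config(read_length = 150, insert_mean = 300,
                                     insert_sd = 50, n_reads = 2000,
                                     rng_seed = 3))
seed <- setNames(substr(unname(g), 501, 1700), "barcode")
report <- run_iterations(pool, seed, run_config(proofread = TRUE))
print(report)
compare_assemblies(report$assembly$contigs[[1]], g, circular = TRUE)
recruitment_metrics(report$recruited_ids, pool$provenance, "target")
```

```
<run_report> 18 iteration(s), converged
  recruited reads: 2000
<assembly> 1 contig(s), total 5000 bp, 2000 recruited reads
<contig> barcode: 5000 bp, mean coverage 60.0, circular
0/0 (100.00%)
<recruitment> 100.00% of target reads recovered, 0.00% false positives (n = 2000)
```

Reading the output: the loop needed 18 bait→anchor→extend iterations to reach
a stationary read count; the final contig is circular at the true 5000 bp
length; `0/0 (100.00%)` means zero substitutions, zero indel events, 100%
per-base identity to the truth; all 2000 simulated reads were recovered and no
foreign read was incorporated.

A command-line wrapper with `run`, `bait`, `simulate-*`, `evaluate`,
`recruitment` and `kmerspec` subcommands is installed at
`inst/cli/mitobaitr.R` (run via `Rscript`).

## Acceptance script

`scripts/acceptance.R` re-runs the pooled five-genome benchmark from scratch:
it simulates five ~16.6 kb circular genomes at ~0.13 pairwise divergence,
pools 6000 error-free 150 bp paired reads per genome (insert 300 ± 50),
reconstructs each genome in proofreading mode from a ~1200 bp seed, and writes
per-benchmark summary metrics (minimum per-base accuracy, minimum own-read
recovery, mean false-positive read fraction, minimum recovered length) as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It takes a few minutes on one CPU; all randomness derives from `--seed`.
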