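# barcodegap

Distance-based evaluation of candidate DNA barcode markers.

A DNA barcode is a short, easily amplified genomic region whose sequence
variation discriminates species. Deciding whether a candidate region works as
a barcode for a group — say, picking among ITS, IGS, nLSU, mtSSU and *tef1*
for a genus of mushrooms — comes down to a few quantitative questions:

* Does the region amplify and sequence reliably (PCR and sequencing success
  rates)?
* Are pairwise distances *between* species clearly larger than distances
  *within* species — is there a **barcoding gap**?
* Do conspecific samples form well-supported monophyletic clades in a
  distance tree?

`barcodegap` implements this whole evaluation pipeline for aligned
multi-FASTA input plus a sample→species table, and ships a seeded sequence
simulator so every stage can be exercised and tested without any external
data.

## The statistics at the core

**Kimura 2-parameter (K2P) distance.** For a pair of aligned sequences, let
*P* and *Q* be the proportions of transition (A↔G, C↔T) and transversion
differences over the compared sites (pairwise deletion: a site is compared
only when both residues are unambiguous bases). Then

d = −½ ln[(1 − 2P − Q) √(1 − 2Q)]

with the estimate undefined (saturated) when either bracket is non-positive;
saturated pairs are flagged, never zeroed. The uncorrected p-distance and
percent identity are available as companions.

**Barcoding gap.** Pairwise distances are partitioned into intra-specific and
inter-specific classes by the species map. The global verdict is strict:
*clear gap* iff min(inter) > max(intra), with the margin reported. Per
species, the summary mirrors closest-neighbour analyses: largest
intra-specific distance, smallest inter-specific distance, the species
achieving it, and a per-species gap flag (singletons are scored on
min_inter > 0). Histograms use half-open bins [k·w, (k+1)·w) with
conventional widths per region (0.004 for ITS/nLSU/mtSSU, 0.008 for
IGS/tef1).

**Trees.** Neighbor-joining (Saitou–Nei) with deterministic lexicographic
tie-breaking; exact on additive matrices. Bootstrap supports follow
Felsenstein: resample aligned columns with replacement, rebuild, and score
each reference bipartition by its replicate frequency. Trees are `ape`
`phylo` objects, rooted by outgroup (or midpoint), with per-species monophyly
checks reading clade supports.

**Simulator.** Sequences evolve site-independently under the K2P process
(transition rate κ-fold each transversion rate) down a star species tree —
root → species ancestors (`inter_depth` expected substitutions/site) →
samples (`intra_depth`) — with optional per-sample PCR/sequencing dropout and
an arbitrary species tree as an option. True pairwise distances are returned
alongside the data.

## Worked example

Simulate an ITS-like marker for an 8-species study (34 samples with sizes
1, 3, 8, 6, 3, 6, 5, 2; 600 bp; within-species depth 0.005 vs
between-species depth 0.08) and evaluate it end to end:

```r
library(barcodegap)

sim <- simulate_dataset(sim_config(seed = 42, region = "ITS-like"))
report <- evaluate_marker(sim$alignment, sim$species_map,
                          status = sim$status, B = 200, seed = 42)
report
#> marker ITS-like: 34/34 amplified (100%), 34/34 sequenced (100%)
#>   length 600-600 bp; clear gap (margin +0.1260); 8/8 species monophyletic; min clade support 100%

head(report$species_summary, 3)
#>     species n_samples max_intra min_inter nearest_species gap_present
#> sp1     sp1         1        NA     0.162             sp4        TRUE
#> sp2     sp2         3    0.0118     0.141             sp4        TRUE
#> sp3     sp3         8    0.0152     0.151             sp4        TRUE
```

The report reads: every sample amplified and sequenced (rates 100%/100%);
the smallest between-species distance exceeds the largest within-species
distance by 0.126 substitutions/site (a clear barcoding gap); and all eight
species form monophyletic clades, every multi-sample clade with 100%
bootstrap support. `report$histogram`, `report$monophyly` and `report$tree`
hold the underlying pieces; `rank_markers()` orders several such reports by
sequencing rate, then gap margin.

The same pipeline runs on real data via `read_fasta()`, `read_species_map()`
and `read_region_status()`, or from a shell through the installed CLI:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "barcodegap", package = "barcodegap"))')
Rscript $CLI simulate --seed 42 --region demo --out-dir out
Rscript $CLI evaluate --fasta out/demo.fasta --species-map out/demo.species.tsv \
    --replicates 200 --seed 42 --out-dir out
```

Subcommands: `simulate`, `distances`, `gapstats`, `tree`, `evaluate`; results
go only to files under `--out-dir`, logs to stderr, and identical inputs,
flags and seed give byte-identical outputs.

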