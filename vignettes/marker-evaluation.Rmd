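---
title: "Evaluating DNA barcode markers: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating DNA barcode markers: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

## What the pipeline computes

A candidate barcode region is judged on three kinds of evidence, and the
package computes all three from an aligned multi-FASTA plus a
sample→species map:

1. **Lab success accounting** — PCR and sequencing success rates per region,
   plus the ungapped length range. These are bookkeeping over a per-sample
   status table, not inference: success counts enter as declared input.
2. **Distance structure** — pairwise K2P (or p-) distances, split into
   intra- and inter-specific classes, summarized per species
   (closest-neighbour analysis) and globally (barcoding-gap verdict,
   histograms).
3. **Tree structure** — a neighbor-joining tree with Felsenstein bootstrap
   supports, rooted by outgroup or midpoint, scored for per-species
   monophyly.

`evaluate_marker()` composes all of it into one report; markers are ranked
by sequencing rate, then gap margin. The ranking is a convention of this
package — the underlying fields are all in the report so any other
composite can be formed.

## The distance model

The K2P distance corrects the observed transition proportion $P$ and
transversion proportion $Q$ for multiple hits:

$$d = -\tfrac{1}{2}\ln\!\left[(1-2P-Q)\sqrt{1-2Q}\right]
    = -\tfrac{1}{2}\ln(1-2P-Q) - \tfrac{1}{4}\ln(1-2Q).$$

Assumptions: sites evolve independently under a common stationary process
with equal base frequencies and one transition and one transversion rate.
With $Q=0$ the formula reduces to $-\tfrac12\ln(1-2P)$, and $d \ge$
p-distance always (the correction only inflates).

**Gap treatment.** Sites where either residue of a pair is a gap or an
ambiguity code are excluded for that pair (*pairwise deletion*), the common
default of distance software in this field; *complete deletion* (drop a
column if any sequence has a non-base there) is available as a switch.
Ambiguity codes are treated as missing rather than fractionally resolved —
determinism is worth more here than the sliver of information in an `R` or
`Y`.

**Saturation.** When $1-2P-Q \le 0$ or $1-2Q \le 0$ the log is undefined:
the estimator has saturated. Such pairs are reported as `NA` with a warning
and excluded from partitions and histograms. Substituting an arbitrary
large value would silently distort the gap analysis; propagating the
undefinedness keeps the distortion visible. Tree building refuses matrices
containing `NA` and tells the caller to drop the offending samples, and
bootstrap replicates that saturate are dropped and counted (more than 10%
dropped is an error, since the supports would no longer mean much).

## Gap analysis conventions

* The global verdict is **strict**: a clear gap requires
  $\min(\text{inter}) > \max(\text{intra})$; a tie counts as overlap. The
  margin (possibly negative) is always reported, so "nearly" cases are
  visible.
* **Singleton species** contribute no intra-specific distances. They are
  excluded from the intra histogram, and their per-species verdict uses
  $\min(\text{inter}) > 0$: a single voucher can still be diagnosable if
  nothing else is identical to it. Multi-species studies routinely contain
  such species, so erroring out would be wrong.
* Histogram bins are half-open $[kw, (k+1)w)$ — every distance lands in
  exactly one bin and class totals are conserved. Default widths follow the
  field's display convention per region: 0.004 (ITS, nLSU, mtSSU) and 0.008
  (IGS, tef1), overridable everywhere.
* Nearest-species ties are broken alphabetically and reported, again for
  determinism.
* Both the per-species summary (closest-neighbour view) and the histogram
  (distribution view) are computed from the same K2P distances; similarity
  tools in this space sometimes operate on percent identity instead, which
  `pairwise_matrix(model = "identity")` provides, but distance is used for
  the verdicts.

## Tree building

The NJ agglomeration joins the pair minimizing
$Q(i,j) = (n-2)\,d(i,j) - r_i - r_j$ with the standard branch-length
assignments, and is exact on additive matrices (the four-point condition);
this exactness is what the unit tests lean on. Two choices are local
conventions where the field's software is silent:

* **Tie-breaking**: among equal-minimum pairs, join the pair whose sorted
  cluster labels (a cluster is labelled by its smallest leaf) are
  lexicographically smallest. This makes output identical across platforms
  and input orders.
* **Negative branch lengths** are retained in the `phylo` object — they
  preserve additivity checks — and can be clamped to zero in Newick output
  via a flag.

Bootstrap resampling is by aligned columns, uniform with replacement,
replicate length equal to the original length. Supports are the percentage
of retained replicate trees containing each reference bipartition, rounded
half-up to integers (so `34/34 → 100`, `27/34 → 79`); any display threshold
(e.g. showing only values ≥ 70) is left to report writers. With `B`
replicates and a fixed seed the supports are exactly reproducible.

Monophyly is clade identity on a rooted tree: a species is monophyletic iff
some clade's tip set equals exactly its samples. Singletons are
monophyletic by convention with support n/a. When no outgroup is supplied,
`evaluate_marker()` midpoint-roots the tree; an outgroup, when given, is
excluded from the distance partition and the species scoring.

## Success-rate accounting

Rates are `100 × successes / n`, rounded half-up to whole percentages — the
rounding that reproduces every derivable whole-percentage value in a
34-sample design (27/34 → 79, 24/34 → 71, 28/34 → 82, 21/34 → 62,
33/34 → 97, 32/34 → 94, 23/34 → 68). Sequencing success implies
amplification success, and the constructor enforces it. The bundled
`inst/extdata` tables encode a real 34-sample, five-marker *Lepista* study
design: per-sample sequenced-accession presence/absence per region, plus
the per-region PCR success counts and length ranges that cannot be derived
from accession lists and therefore enter as declared input.

## What the simulator emulates — and what it does not

`simulate_dataset()` draws a uniform root sequence, evolves one ancestor
per species, then each sample from its ancestor, all under the K2P process
with transition rate $\kappa$ times each transversion rate; expected
substitutions/site parameterize branch lengths, so the transition
probabilities are closed-form and the expected $P$ and $Q$ are exactly the
K2P fixed point (feeding them back into the formula returns the generating
depth — one of the self-consistency tests).

Defaults encode the structure of the motivating study design: 8 species
with sample sizes 1, 3, 8, 6, 3, 6, 5, 2 (34 samples), 600 bp (inside the
400–1,000 bp range of typical fungal barcode regions), `intra_depth =
0.005` vs `inter_depth = 0.08` (shallow within-species variation against
roughly tenfold-deeper between-species divergence, the regime in which
barcoding is expected to work), $\kappa = 2$, no dropout. The species tree
is a **star** by default — all species ancestors equidistant from the root —
which keeps true pairwise distances trivial ($2\cdot$intra within,
$2\cdot($inter$+$intra$)$ between); an arbitrary Newick species tree is
accepted for structured radiations (e.g. a three-clade genus). Dropout
flags are independent Bernoulli draws per sample: amplification fails with
`dropout_pcr`, sequencing (given amplification) with `dropout_seq`.

Real data differ in ways the simulator deliberately ignores: no indels
(alignment is assumed done upstream and is exact by construction), no rate
heterogeneity across sites or lineages, no base-composition bias, no
within-species genealogy (samples are independent draws from the species
ancestor). Passing the simulation-based tests therefore shows the pipeline
is correct *given* aligned data under a clean substitution process — it
does not validate alignment quality or model adequacy on empirical
sequences.

## Problem sizes and tolerances

The test suite and the acceptance script use: exact checks at $10^{-9}$ or
tighter for closed forms and additive-matrix recovery; 100 kb branches for
estimator recovery within ±0.01 of a true depth of 0.1; n = 10,000 samples
for dropout-rate recovery within ±0.01; and 100 seeded end-to-end
replicates of the 34-sample design with 200 bootstrap replicates each —
sizes at which the stochastic checks are stable from seed to seed while the
full run stays around two minutes on one core.

## Known limitations

* Only the K2P and p-distance models are implemented (plus percent
  identity); TN93/GTR or maximum-likelihood distances are out of scope, as
  are model selection and likelihood/Bayesian trees.
* No automatic species delimitation (ABGD/GMYC/PTP) — the gap analysis
  scores a *given* species hypothesis.
* The per-species gap rule for singletons is necessarily weaker evidence
  than the multi-sample rule; treat singleton verdicts accordingly.
* Alignment, trimming and editing are upstream concerns; the package
  validates but never modifies residues.
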