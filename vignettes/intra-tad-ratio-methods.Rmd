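---
title: "Methods: the intra-TAD ratio and chromatin domain surface/core analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the intra-TAD ratio and chromatin domain surface/core analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The statistic

Topologically associating domains (TADs) insulate chromatin contacts only
incompletely. One structural reading of that incompleteness is that, in any
individual cell, a TAD-scale domain is a three-dimensional object with an
interior and an exterior: a genomic bin buried in the *core* of its domain
mostly contacts other bins of the same domain, while a bin on the domain
*surface* is exposed to the rest of the nucleus. `tadcore` quantifies this
per-bin "coreness" as the **intra-TAD ratio**: the fraction of a bin's
observed spatial neighbors or interaction partners that belong to the bin's
own TAD. The same quantity is computed from five kinds of data:

* **Multiplex (SPRITE-like) clusters.** For bin $i$ in read cluster $j$,
  $r_{ij} = N_{ij}/(C_j - 1)$, where $C_j$ is the number of unique bins in
  the cluster and $N_{ij}$ the number of co-members sharing $i$'s TAD. The
  bin's ratio $r_i$ is the unweighted mean of $r_{ij}$ over all clusters
  containing it (one cluster, one vote). Clusters are filtered to 2–1000
  unique bins, and bins supported by fewer than 100 clusters are reported
  missing.
* **Bulk contacts.** $r_i$ = (weight of contacts to same-TAD partners) /
  (total contact weight involving $i$), with self-pairs excluded.
* **Single-cell contact lists.** The bulk formula per cell, then an average
  over the cells in which the bin is observed.
* **3D structural models.** Among the $k = 10$ Euclidean nearest neighbors
  of a bin in a model, the fraction in the same TAD (and, for diploid
  models, the same haplotype). Multiple models are averaged per bin; 20 kb
  models can be duplicated onto 10 kb bins.
* **Chromatin-tracing imaging.** Per cell, the fraction of imaged bins
  within a 500 nm sphere of the bin that share its single-cell domain
  (scDomain) — the *intra-scDomain ratio*.

Low values mean surface tendency; high values mean core tendency.

### Surface/core classification

Within each TAD $k$ containing $n_k$ bins, bins with ratio at or below the
$q_k$-th empirical quantile of the TAD's non-missing ratios are labeled
**surface**, the rest **core**, with $q_k = n_k^{-1/3}$. The exponent comes
from the surface-to-volume scaling of a sphere ($S/V \propto V^{-1/3}$); it
is a rationale, not a computation — classification only uses the quantile.
We use the standard linear-interpolation empirical quantile and an inclusive
(`<=`) rule, so threshold ties all become surface and a TAD's surface is
never empty. Classification is therefore invariant to any strictly monotone
transform of the ratios within a TAD (a property the test suite checks).

Because the lowest ratios in a TAD also occur at its 1D boundaries for
trivial reasons, `exclude_boundaries()` can drop the first and last bin of
each TAD plus the adjacent `ceiling(0.10 * n_k)` bins **per flank**. The
fraction could also be read as a total over both flanks; per-flank is the
stricter reading and is the package's choice — conclusions that depend on
this choice should be checked at both settings.

### Enrichment and associations

Feature enrichment on surfaces (or cores) uses bins as sampling units: with
$a$ universe bins, $b$ surface bins, $c$ feature bins in the universe and
$d$ feature bins on surfaces, the fold is $(d/c)/(b/a)$ and the p-value is
the hypergeometric upper tail $P(X \ge d)$. A bin carries a feature category
if it overlaps at least one interval of that category, regardless of other
categories; excluded labels (e.g. "Low-DNase") are dropped beforehand. Raw
p-values are reported; apply `p.adjust()` across many features as needed.

Association analyses include per-TAD Spearman correlation of ratio with
expression over TADs holding at least 5 gene bins (followed by a two-sided
one-sample t-test of the correlation list against zero), two-sided
Mann-Whitney U group comparisons (exact enumeration when both groups have at
most 8 values, normal approximation with tie correction otherwise), OLS
regression of the ratio on two signals and their interaction, and plain
track correlations optionally stratified by interval labels such as
subcompartments.

### The shuffled-TAD null

`shuffle_tads()` collects, per chromosome, the interleaved list of TAD
lengths and gap lengths (including any leading gap), permutes TAD lengths
among the TAD slots and gap lengths among the gap slots, and lays the list
down from the chromosome start. Permuting within slot kinds — rather than
freely permuting the tagged list — is what makes the conservation exact: a
free permutation can place two gaps side by side (they merge in the realized
genome) or after the last TAD (they vanish). As implemented, the multiset of
TAD sizes, the multiset of inter-TAD gap sizes, and the total span are
conserved exactly, which the tests verify over hundreds of random genomes.
Ratios recomputed under shuffled TADs provide a negative control: they
should lose most of their correlation with any structural ground truth.

## Conventions and numerical choices

* Coordinates are 0-based, half-open (BED convention) everywhere inside the
  package; readers convert at the boundary. Bin ids are dense 1-based
  integers ordered by (chromosome, start).
* A bin belongs to a TAD iff its **midpoint** lies in the TAD interval. The
  midpoint rule is symmetric and deterministic; how partial edge overlaps
  are resolved is otherwise an open convention, and bins outside all TADs
  are excluded from ratio computation and from enrichment universes.
* Cluster reads are deduplicated to unique bins, and $C_j$ counts unique
  bins — the only reading under which $r_{ij} \le 1$ always holds.
  TAD-unassigned members stay in $C_j$ (they are genuine parts of the
  complex) but are never emitted as records; unassigned partners likewise
  count only in contact denominators.
* kNN ties at the $k$-th distance are broken by ascending bin id, making the
  structure pathway deterministic.
* Averages over cells or models use available (non-missing) values only;
  every track records per-bin support, and `support == 0` is equivalent to
  "missing".
* All stochastic operations take an explicit integer seed and are
  reproducible byte-for-byte.
* Bulk contact ratios use intra-chromosomal contacts by default
  (`include_trans = FALSE`); multiplex clusters in genome-wide mode keep
  trans members, matching how the two assays are usually summarized. Both
  choices are flags.

## Single-cell domain segmentation and geometry

For imaging data without an external segmentation, `call_scdomains()`
computes a **spatial insulation score** at each position of a cell's
ordered, positioned bins: the median pairwise 3D distance between the `w`
upstream and `w` downstream bins divided by the median pairwise distance
within those windows (defaults: `w = 5` bins, boundary prominence 2,
merge threshold 0.9). Positions that are local maxima of the score within
`w` positions on either side, and exceed the prominence times the cell's
median score, become boundaries — scaling by the median keeps the rule
meaningful both for crumpled structures (baseline score near 1) and for
extended ones, where consecutive windows are intrinsically far apart and
the baseline is higher. Adjacent domains whose cross-domain median distance
falls below the merge threshold times their pooled within-domain median are
merged. This is a
concrete re-specification of insulation-based scDomain calling validated on
synthetic geometry — it is *not* claimed to reproduce any published caller
bin-for-bin, and the merge criterion in particular is a stated stand-in for
the published-but-unquantified "similar patterns" rule. Missing-coordinate
bins are skipped; windows with fewer than 3 usable bins give no score.

`hull_vertices()` marks, per scDomain, the bins whose coordinates are
vertices of the domain's 3D convex hull (computed by a quickhull
implementation cross-checked in the tests against an independent
implementation). Hull vertices are necessarily on the structure's exterior
regardless of the domain's shape. Domains with fewer than 4 points, or with
collinear/coplanar geometry, label all bins vertex by convention.
`geometric_coreness()` (1 minus normalized distance to the domain centroid)
provides a shape-based coreness used as synthetic ground truth.

## What the simulator emulates — and what it does not

`sim_config()` + the `gen_*()` functions build a fully self-contained study:

* One chromosome tiled by ~20 consensus domains of ~50 bins of 10 kb
  (mean sizes drawn with CV 0.1, floor 10 bins).
* Per cell, domain 1D boundaries shift around the consensus by a discretized
  normal with s.d. `boundary_jitter = 1` bin — scDomain boundaries
  approximately follow TADs but vary cell to cell.
* Per cell, each domain is a ball of radius
  `domain_radius_scale * m^{1/3}` nm with `domain_radius_scale = 100`
  (≈370 nm for a 50-bin, 500 kb domain), centers following a
  momentum-smoothed random walk with step equal to the sum of adjacent
  radii, so consecutive domains touch. At this scale the fixed 500 nm
  imaging neighborhood is sub-domain sized, as in real tracing data; a
  smaller physical scale would saturate the intra-scDomain ratio.
* Each bin has a persistent normalized radial target (ball-uniform
  marginal); its per-cell radius mixes that target with fresh ball-uniform
  noise at weight `coreness_persistence = 0.8`. Ground-truth coreness is 1
  minus the radial target.
* Read-outs are sampled from the geometry: clusters as bins within
  `cluster_radius = 250` nm of a random anchor in a random cell, subsampled
  to a log-uniform size in [2, 1000]; contacts as all bin pairs within
  `contact_threshold = 250` nm per cell; log-expression as
  `intercept + expression_effect * coreness + N(0, noise_sd)` with a
  negative effect by default; features implanted so that the expected
  measured surface enrichment fold equals `feature_fold` exactly
  (each feature bin lands on the truth-surface set with probability
  `fold * b/a`).

The generator is deliberately *not* a polymer model: domains are balls, not
chains; there is no loop extrusion, no compartment checkerboard, no
haplotype structure by default, and no imaging noise or detection dropout
unless injected. Passing tests therefore show that the statistics recover
the structure the generator encodes under realistic geometry — they do not
certify performance on real Hi-C/SPRITE/imaging data, whose noise and shape
irregularities are richer. Because domain shapes in real cells need not be
globular, all recovery criteria are phrased as rank correlations and
directions of effect, never as absolute geometric values.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` run the full default study — 20
domains × ~50 bins × 500 cells, 100,000 clusters, ~10⁵ accumulated contact
pairs, 500 kNN models, 40 imaging cells, 50–100 TAD shuffles — in a few
minutes on one CPU; module tests use ~6-domain, ~30-cell miniatures. All
randomness descends from one seed through fixed per-stage offsets, so any
single artifact (genome, structures, clusters, signals) can be regenerated
in isolation. Subsampled-cell correlation analyses (`subsample_correlation`)
re-draw cells without replacement under their own seed and are byte-stable.

## Known limitations

* The scDomain caller is a re-specification, tuned and validated on
  synthetic geometry only; on real imaging data its boundaries will differ
  from published callers in detail.
* The per-flank reading of the 10% boundary exclusion is one of two
  defensible readings (see above).
* Whether cluster averaging should weight clusters by size is left as a
  flagged design choice; the default gives each cluster one vote, matching
  the per-cluster normalization by $C_j - 1$.
* Enrichment sampling units are bins, not base pairs; features much smaller
  than a bin inherit the bin's resolution.
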