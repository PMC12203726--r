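# tadcore

Quantifying where genomic loci sit in the 3D structures of their chromatin
domains — core or surface — from five kinds of data.

## The problem

Topologically associating domains (TADs) insulate chromatin contacts only
incompletely. If, in each single cell, a TAD-scale domain is a 3D object,
then loci buried in the domain **core** interact mostly within the domain,
while loci on the domain **surface** are exposed to the outside — to loci of
other domains, and to nuclear factors. That per-locus "coreness" is
invisible in a contact-map heatmap but has direct regulatory consequences:
highly expressed genes and active cis-regulatory elements tend to sit on
domain surfaces.

`tadcore` computes a per-bin **intra-TAD ratio** that measures coreness, for
anyone with TAD calls plus any one of: SPRITE-style multiplex clusters, bulk
Hi-C contacts, single-cell Hi-C `.pairs` files, 3D structural models, or
chromatin-tracing imaging coordinates. On top of the ratio it provides
surface/core classification, feature enrichment statistics, association
analyses, a shuffled-TAD null, single-cell domain segmentation and
convex-hull geometry, and a synthetic single-cell simulator so that the
whole pipeline is testable without any external download.

## The statistic

For a genomic bin *i* in multiplex cluster *j* with *C<sub>j</sub>* unique
bins,

> r<sub>ij</sub> = N<sub>ij</sub> / (C<sub>j</sub> − 1)

where N<sub>ij</sub> counts cluster co-members in the same TAD as *i*; the
bin's intra-TAD ratio r<sub>i</sub> is the mean of r<sub>ij</sub> over all
clusters containing it. For pairwise contacts, r<sub>i</sub> is the same-TAD
contact weight over the total weight involving *i*; for structural models it
is the same-TAD fraction of the *k* = 10 nearest neighbors; for imaging it
is the same-scDomain fraction of imaged loci within 500 nm (the
intra-scDomain ratio). Within each TAD *k*, bins at or below the
q<sub>k</sub> = n<sub>k</sub><sup>−1/3</sup> quantile of the ratio are
classified as **surface** (the surface-to-volume scaling of a sphere), the
rest as **core**; feature enrichment on surfaces is fold
(d/c)/(b/a) with a hypergeometric upper-tail p-value. The methods vignette
(`vignettes/intra-tad-ratio-methods.Rmd`) documents every convention.

## Worked example

```r
library(tadcore)

# a compact synthetic study: 10 domains x ~50 bins of 10 kb, 80 cells
cfg <- sim_config(seed = 42, n_domains = 10, bins_per_domain = 50,
                  n_cells = 80, clusters_per_cell = 150, n_features = 100)
genome <- gen_genome(cfg)
structures <- gen_structures(cfg, genome)

# intra-TAD ratio from SPRITE-like multiplex clusters
clusters <- gen_sprite(cfg, structures)
track <- sprite_ratio(clusters, genome$tads, genome$index)
print(track)
#> <ratio_track> 475 bins, 475 non-missing, mean 0.9254

# recovery of the ground-truth coreness tendency
cor(track$value, structures$tendency, method = "spearman", use = "pairwise")
#> [1] 0.7152978

# surface/core classification at the n^(-1/3) quantile
labels <- classify_surface_core(track, genome$tads)
table(labels$label)
#>    core surface
#>     342     133

# enrichment of implanted features on domain surfaces
signals <- gen_signals(cfg, genome, structures$tendency)
surface <- labels[label == "surface", bin]
enrichment(signals$feature_bins, labels$bin, surface)
#>        a     b     c     d     fold      p_value
#>    <int> <int> <int> <int>    <num>        <num>
#> 1:   232   133   100    61 2.178571 2.941915e-15
```

Reading the output: the Spearman correlation of 0.72 says the cluster-based
ratio ranks bins close to their true radial tendency in the generator's
geometry. 133 of 475 TAD bins are called surface (each TAD contributes its
n<sub>k</sub><sup>−1/3</sup> quantile, ≈27% at 50 bins). The features were
implanted at 3-fold surface enrichment against the *true* surface; measured
against the classification derived from the computed ratio the fold is
attenuated to 2.18 — classification noise always pulls the measured fold
toward 1, which is why the package's calibration checks measure enrichment
against the ground-truth surface set.

Real data enter through `read_tads()`, `read_sprite()`,
`read_contacts_coo()`, `read_pairs()`, `read_structure()`,
`read_imaging()`, `read_signal()` and `read_intervals()`; a thin
command-line wrapper (`inst/cli/tadcore-cli.R`) chains
`simulate` / `ratio` / `scdomains` / `classify` / `shuffle` / `enrich` and
writes a JSON manifest per run.

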