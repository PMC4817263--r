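# phylogeodiv

Phylogeographic diversity analysis for strain collections genotyped at a
single locus.

Microbial biogeography is usually measured at taxonomic resolutions far
too coarse to detect dispersal limitation and regional diversification by
drift. Surveys that isolate physiologically similar strains from
ecologically similar sites and sequence one informative locus can detect
these processes — but the analysis chain behind such studies (tree-based
OTUs, community phylogenetics with permutation nulls, distance-decay
tests, haplotype networks with nested clade analysis) is scattered across
legacy desktop tools. `phylogeodiv` re-implements that chain as one
tested, scriptable R package, for microbial ecologists and molecular
epidemiologists who have an alignment, a rooted gene tree, site metadata
and a strain-to-site mapping.

## What it computes

Given aligned haplotypes, a rooted tree (branch lengths in
substitutions/site), a site table and a strain map:

* **OTUs from patristic distance** — maximal clades whose tips lie within
  *θ*/2 of the clade root (default *θ* = 0.01), or complete-linkage
  clusters cut at *θ*; plus Good's coverage *C* = 1 − *f*₁/*N* and
  rarefaction with the exact hypergeometric expectation
  E[*S_d*] = Σᵢ (1 − C(*N*−*n*ᵢ, *d*)/C(*N*, *d*)).
* **Alpha phylodiversity per site** — Faith's PD (root-inclusive), mean
  root distance, and NRI/NTI: the negated standardized effect sizes
  −(obs − E_null)/SD_null of MPD/MNTD under a null that redraws each
  site's richness without replacement from the full taxon pool (999
  permutations), with two-sided smoothed p-values; Welch/Mann-Whitney
  contrasts between glaciated and nonglaciated sites and Spearman
  correlations with colonization-time rank.
* **Beta diversity and distance decay** — unweighted and
  abundance-weighted UniFrac, weighted/unweighted Bray-Curtis views,
  haversine geographic distance, environmental distance on z-scores;
  Mantel tests (Pearson r on distances, one-sided permutation p) and
  single-variable PERMANOVA (Gower-centred pseudo-F, R² = SS_model/SS_total),
  exact by enumeration for small n; the full diversity × environment
  correlation matrix.
* **OTU-sharing network** — bipartite site-OTU graph (single-site OTUs
  excluded), OTUs classed glacial/nonglacial when >90% of their strains
  come from one site class *and* a two-sided Fisher exact test rejects
  random assortment; GraphML export.
* **Haplotype networks and nested clade analysis** — statistical-parsimony
  networks (single-mutation edges, inferred intermediates, connection
  limit from a documented multiple-hit criterion), deterministic loop
  resolution (frequency > topology > geography), hierarchical nesting,
  clade/nested-clade distances Dc and Dn on spherical centroids,
  permutation significance, and a pluggable inference table
  distinguishing contiguous range expansion from restricted gene flow
  with isolation by distance.
* **A synthetic-data generator** — Yule trees, Jukes-Cantor sequences,
  and site occupancy under panmixia, kin-structured founder range
  expansion, or subtree clustering, with ground truth; every statistical
  stage of the package is validated against it without any downloads.

`runAll()` drives the whole pipeline from one config (or YAML file) and
writes every table-shaped output plus a seeds-and-versions manifest;
`withAndWithout()` re-runs with a site exclusion set and flags
conclusions that flip.

## Worked example

Simulate a six-site latitudinal range expansion, call OTUs, and test the
diversity gradient and distance decay:

```r
library(phylogeodiv)

cfg <- scenarioConfig(n_haplotypes = 64, n_sites = 6,
                      latitudes = seq(30, 60, length.out = 6),
                      strains_per_site = 40, founder_fraction = 0.5,
                      seed = 42)
data <- generateDataset(cfg, "example_data")

otus <- clusterOtus(data$tree, threshold = 0.01)
strains <- data$strains
strains$otu_id <- otus$otu_id[match(strains$haplotype_id,
                                    otus$haplotype_id)]
comm <- communityFromStrains(strains, taxon_col = "otu_id")

alpha <- siteDiversity(otuRepresentativeTree(data$tree, otus), comm,
                       n_perm = 999, seed = 1)
print(alpha, digits = 3)
#>   site_id richness     pd    nri p_nri  nti p_nti   mrd
#> 1     S01       21 0.2931 -0.149 0.891 1.40 0.155  6.95
#> 2     S02       17 0.2298  3.219 0.003 1.78 0.075  7.12
#> 3     S03       10 0.1283  5.900 0.001 2.63 0.006  8.40
#> 4     S04        6 0.0653  7.521 0.001 3.64 0.001  9.33
#> 5     S05        2 0.0300  3.647 0.015 3.73 0.013  9.50
#> 6     S06        1 0.0237     NA    NA   NA    NA 10.00

mantelTest(brayCurtisMatrix(comm), haversineMatrix(data$sites),
           n_perm = 1000, seed = 1)
#> mantel_r = 0.6833, R2 = 0.467, p = 0.006944 (719 permutations)
```

Reading the output: moving poleward from the source site S01, Faith's PD
collapses (0.293 → 0.024 substitutions/site of tree spanned), the net
relatedness index turns significantly positive (phylogenetic clustering
of founder kin, p ≤ 0.015 at S02–S05), mean root distance rises, and
richness falls to a single OTU at the range edge — while community
dissimilarity increases with great-circle distance (Mantel r = 0.68,
p = 0.007; with six sites the permutation set is enumerated completely).
That is the latitudinal-gradient signature the expansion scenario is
built to produce; under `scenario = "panmixia"` the same statistics stay
at their null expectations.

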