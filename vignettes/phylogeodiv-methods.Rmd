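---
title: "Methods: phylogeographic diversity analysis with phylogeodiv"
author: "phylogeodiv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogeographic diversity analysis with phylogeodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylogeodiv)
```

## Scope and data model

`phylogeodiv` analyses the phylogeography of a strain collection genotyped
at a single aligned locus. Four inputs define a study:

* an **alignment** of haplotype sequences, uniform length, as a
  `DNAStringSet` (FASTA on disk);
* a **rooted gene tree** over those haplotypes with branch lengths in
  expected substitutions per site (`ape::phylo`, Newick on disk);
* a **site table** (`SiteTable`): coordinates, pH, soil organic matter,
  mean annual temperature, annual precipitation, a glaciation flag, and a
  colonization-time rank (1 = longest time available for colonization);
* a **strain map** linking every strain to a site and a haplotype.

From these the pipeline derives operational taxonomic units (OTUs),
per-site alpha phylodiversity, beta-diversity distance decay, an
OTU-sharing network partitioned by glaciation history, and
statistical-parsimony haplotype networks with nested clade analysis.
Alignment construction and tree inference are deliberately out of scope:
the package consumes an alignment and a rooted tree.

## OTU definition on patristic distance

OTUs are clusters of haplotypes on the *tree*, not on pairwise sequence
identity. The threshold (default 0.01 substitutions/site, roughly a
species boundary for housekeeping loci in actinomycetes) is interpreted by
one of two rules, because published tree-collapsing tools do not always
state theirs:

* `node_depth` (default): OTUs are the maximal clades in which every tip
  lies within `threshold/2` of the clade root. The radius convention
  bounds within-OTU divergence by the threshold for ultrametric clades
  and makes OTUs monophyletic by construction.
* `max_pairwise`: complete-linkage agglomeration on the patristic matrix
  cut at `threshold`, which bounds the maximum within-OTU tip-pair
  distance directly but need not respect monophyly.

The choice is recorded in the OTU assignment's attributes and in the run
manifest. Ties in the agglomeration are fixed by sorting tips
lexicographically before clustering, so both rules are deterministic.

## Alpha phylodiversity

Faith's PD is the summed branch length of the union of root-to-tip paths
of the taxa present (root-inclusive; the convention is stated here and in
the output metadata because published values rarely say which was used).
Mean root distance (MRD) is the average number of nodes between each
present tip and the root (root counted, tip not); larger values mean more
derived assemblages.

NRI and NTI are negated standardized effect sizes of MPD and MNTD,
presence-based, computed against the null model in which each site's
richness is redrawn **without replacement from the pool of all taxa in
the community matrix** (999 draws by default). Positive values indicate
phylogenetic clustering. p-values are two-sided permutation ranks with
the `(1 + b)/(1 + n)` smoothed estimator; a degenerate null (a site
holding the entire pool) reports index 0 with a flag rather than NA or a
division by zero. For small pools the null can be enumerated exhaustively
(`null = "exhaustive"`), which the test suite uses as its oracle. In the
pipeline these statistics are computed on one representative tip per OTU;
an abundance-weighted variant is deliberately not provided (the site's
taxon set, not strain counts, carries the signal being tested).

Group contrasts (glaciated vs nonglaciated) report means, SDs (n−1
denominator) and both Welch-t and Mann-Whitney two-sided p-values; Welch
is the headline test, but both are always computed because the choice is
rarely stated in published tables. With a singleton group Welch is
undefined and the Mann-Whitney p is used with a warning. Rank
correlations with colonization time use Spearman's rho with mid-rank
ties; p is exact for n ≤ 10 without ties, otherwise the t approximation.

## Beta diversity and distance decay

* **Unweighted UniFrac**: branch length unique to either site's taxa
  divided by the branch length of their union, root-inclusive, matching
  the PD convention. An abundance-weighted variant weights each branch by
  the absolute difference of abundance fractions beneath it, normalized
  to stay in [0, 1].
* **Bray-Curtis** on strain counts. "Weighted" vs "unweighted" is a
  *view*, never a second stored matrix: weighted uses all strain records;
  unweighted collapses duplicate haplotypes within an OTU at a site, so
  each OTU contributes its distinct sequence variants once.
* **Geographic distance**: great-circle (haversine) kilometres with
  Earth radius 6371.0088 km.
* **Environmental distance**: Euclidean on z-scored variables. z-scores
  use the population SD (divide by the root-mean-square deviation), so
  two sites standardize exactly to −1 and +1; zero-variance variables are
  dropped with a warning.

The Mantel test is the Pearson correlation of off-diagonal entries with a
one-sided permutation p (≥ observed, +1 smoothing), jointly permuting
rows and columns of the second matrix; the reported `r_squared` is the
square of the Mantel r, with the signed r kept alongside, since "Mantel
R²" in the literature rarely defines itself. PERMANOVA uses the
Gower-centred inner-product formulation (`G = J(−D²/2)J`,
`SS_model = tr(HG)`), one explanatory variable per call, with p by
permutation of the variable. For n ≤ 8 an exhaustive mode enumerates all
n! relabelings and the p-value is exact. With semimetric dissimilarities
(Bray-Curtis, UniFrac) the centred matrix can have negative eigenvalues,
so R² may fall slightly outside [0, 1]; this is a property of the method,
not an error, and is documented on the result class.

UniFrac significance permutes the site labels of individual strain
records (holding site sample sizes), which is the sharpest null for
"random taxon assortment between sites".

## OTU-sharing network and glaciation classes

The bipartite site-OTU graph drops OTUs found at fewer than two sites.
An OTU is labelled glacial (or nonglacial) only if **both** more than 90%
of its strains come from that site class **and** a two-sided Fisher exact
test (strain counts, this OTU vs all other retained OTUs, point-probability
method) rejects random assortment at 0.05. The 2×2 construction counts
strains rather than site presences because the 90% rule is phrased in
sequences; the granularity is isolated in one function so a site-presence
variant can be swapped in. Raising the threshold can only shrink the
classified set (a tested monotonicity).

## Statistical parsimony and nested clade analysis

**Connection limit.** Haplotype pairs are connected only while the
probability that their observed differences arose without superimposed
(homoplastic) change exceeds the confidence level (default 0.95). The
package's criterion: for `j` observed differences over `m` sites, the
Jukes-Cantor-corrected divergence implies `m·d_JC − j` expected unseen
substitutions; treating that excess as a Poisson mean, the parsimony
probability is `exp(−(m·d_JC − j))`, and the limit is the largest `j`
keeping it above the confidence (floored at one step, which is always
trusted). The criterion is monotone in `m` and tends to 1 step as the
confidence tends to 1. It is this package's own documented rule — simpler
than the classical coalescent-based recursion of the statistical
parsimony literature and somewhat more conservative (5 steps at 95% for a
377-bp locus).

**Network construction.** Pairs are joined in order of increasing Hamming
distance, inserting unsampled intermediate nodes so each edge is exactly
one mutational step. Within one distance class all joins between the
snapshot components are added, so equally parsimonious alternatives
survive as loops; joining stops beyond the connection limit. Loops are
then broken deterministically, preferring to keep connections to
higher-frequency haplotypes, then to more interior (higher-degree) nodes,
then to geographically closer haplotypes, with a lexicographic tie-break
— frequency before topology before geography, the order recommended in
the loop-resolution literature. Loops are resolved *before* nesting.

**Nesting.** Level-0 units are the nodes (haplotypes and inferred
intermediates). At each level, unassigned degree-1 units union with their
neighbour, tips first in label order; stranded units become singleton
clades; the procedure iterates on the clade graph until each component is
one clade. This pairwise rule is stricter than diameter-2 star nesting,
fully deterministic, and terminates in at most as many levels as nodes.

**Geographic statistics.** A clade's centre is the strain-weighted
spherical centroid of its members' site coordinates (mean of unit
vectors, renormalized — planar averaging distorts at continental scale).
Dc is the mean great-circle distance of members to their own clade
centre, Dn to the nesting clade's centre (for outermost clades, the
component's centroid). Within every nesting clade with at least two
strain-bearing daughters, daughter membership is permuted over strain
observations (default 1000 permutations); Dc and Dn are flagged
significantly large or small at the smoothed one-sided 0.05 level, and
interior-minus-tip contrasts are tested with the same permutations.

**Inference.** Flag patterns are interpreted through a pluggable,
JSON-editable decision table. The shipped table contains only the two
chains this pipeline reports — tip Dc small with interior Dc (or the I-T
contrast) large ⇒ *restricted gene flow with isolation by distance*;
reversed pattern (tip Dc large or interior Dc small) ⇒ *contiguous range
expansion* — plus the unconditional outcomes *no significant
association* and *inconclusive*. The full published inference key is
intentionally not hard-coded; additional chains are data, not code.

## The synthetic-data generator

`generateDataset()` produces a complete, cross-consistent study from a
`ScenarioConfig`: a Yule tree (`birth_rate` 1/lineage/unit time),
Jukes-Cantor sequences, site metadata and a strain map, plus a
ground-truth JSON. The emitted tree carries branch lengths in
substitutions per site (time × `substitution_rate`), the units of an
estimated gene tree and of the OTU threshold. Everything is a pure
function of the config; the same seed gives byte-identical files.

Three scenarios fix the site-occupancy structure:

* **panmixia** — every strain drawn from the full haplotype pool; the
  true-negative case used to calibrate the NRI, Mantel and NCA nulls;
* **expansion** — sites ordered by latitude; the lowest-latitude site
  uses the full pool and each higher-latitude site a founder subset of
  its nearest lower-latitude neighbour, recursively. Founder subsets are
  *kin-structured*: a seed haplotype drawn at random plus its nearest
  patristic relatives, floored at two lineages. Colonization by related
  lineages is what creates phylogenetic clustering at derived sites — a
  uniform random founder subset would leave the SES null exactly
  calibrated and NRI centred on zero, producing poorer but not clustered
  assemblages;
* **clustered** — each site samples one randomly chosen subtree's tips.

Defaults describe a continental survey: 208 haplotypes of a 377-bp
locus, 12 sites from 28°N to 65°N, 77 strains per site, glaciation above
40°N (the approximate southern limit of late-Pleistocene ice),
`substitution_rate` 0.008 and `founder_fraction` 0.75. The last two were
chosen once so that the default dataset has a realistic shape: most tip
sequences unique, roughly half as many OTUs as haplotypes at the 0.01
cutoff, about 3.5% maximal divergence, and every site retaining at least
a handful of OTUs (a steeper founder fraction over eleven serial
colonization steps collapses high-latitude sites to a single OTU, where
clustering indices are undefined). Latitude is the only simulated driver;
pH, organic matter, temperature and precipitation are uncorrelated noise,
giving environmental-distance tests a true-negative case. Under
expansion, colonization-time rank follows ascending latitude; otherwise
it is a random permutation.

What the generator does *not* emulate: recombination, selection,
explicit spatial diffusion, rate heterogeneity (GTR+I+G realism is not
needed to exercise the statistics), pH-structured habitat filtering, or
measurement noise in coordinates. Passing tests therefore demonstrate
that the statistics recover the imposed occupancy structure, not that
real soil surveys behave this way.

## Numerical and reproducibility conventions

* Every permutation p-value uses the smoothed `(1 + b)/(1 + n)`
  estimator, so p ∈ (0, 1] always.
* All randomness flows through explicit seeds; library functions restore
  the caller's RNG state, and the pipeline derives a distinct child seed
  per stage from the master seed, so re-running with a different seed
  changes permutation p-values but never an observed statistic.
* Floating-point comparisons inside permutation counts use a small
  tolerance so exact ties (e.g. the identity permutation) are counted.
* Degenerate inputs fail loudly and early: empty sites, unknown taxa,
  missing branch lengths, malformed tables and non-scalar graph
  attributes are rejected with the offending record named.

The test suite exercises every statistic against an independent oracle
(brute-force path walks, edge unions, exhaustive permutation or subset
enumeration, closed-form hypergeometric sums, and cross-checks against
picante, vegan and adonis2), calibrates the NRI, Mantel and NCA nulls on
panmictic data (400 site-level tests, 400 matrix pairs, and 60 networks
respectively), and verifies the expansion signatures (declining PD,
positive NRI at the range edge, positive distance decay) over 100
replicates at founder fraction 0.2 across 6 sites. These problem sizes
keep the default suite under a minute while leaving the Monte-Carlo
bands at ±2 percentage points.

## Known limitations

* The parsimony connection limit is this package's own multiple-hit
  criterion, not a re-derivation of the classical recursion; limits are
  comparable in spirit but not numerically interchangeable with legacy
  desktop tools.
* The nesting rule's pairwise unions produce more, smaller low-level
  clades than diameter-2 nesting; Dc/Dn tests at level 1 are
  correspondingly conservative.
* PERMANOVA is single-variable by design (matching single-factor
  published tables); no sequential multi-term partitioning.
* The shipped inference table covers only the range-expansion and
  isolation-by-distance chains; other demographic histories return
  "inconclusive" unless chains are added.
* Median-joining networks, partial Mantel tests and canonical
  correspondence analysis are out of scope.
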