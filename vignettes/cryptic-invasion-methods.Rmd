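---
title: "Methods: COI population structure and thermal niches of cryptic invaders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: COI population structure and thermal niches of cryptic invaders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coipop)
```

## The scientific problem

Fouling bryozoans of the genus *Watersipora* have spread worldwide on ship
hulls, and what looks like one invading species is in fact a set of deeply
diverged mitochondrial COI clades — cryptic lineages that cannot be told
apart morphologically. Two questions follow. First, how is molecular
variation partitioned within and among the invaded regions (haplotype
structure, divergence between clades, departures from neutral expectations)?
Second, do the cryptic clades occupy different *thermal* niches — is clade
identity at a site predicted by the site's mean sea-surface temperature
(SST) once spatial proximity is accounted for? `coipop` implements that
whole analysis chain as composable, tested functions, plus a synthetic-data
generator that reproduces the statistical structure the analysis assumes so
every stage can be validated without sequence downloads.

## Sequence handling and haplotypes

Alignments are held as an `aligned_seq_set` (equal-length sequences, unique
labels, optional population per sequence). Column windows are addressed
0-based and half-open (`trim_to_window(x, 0, 489)` keeps the first 489
columns), which keeps window arithmetic unambiguous when fixed-length
barcode segments (489 or 388 nucleotides in the shipped workflow) are cut
from longer reads.

`collapse_haplotypes()` pools identical sequences. Its default ambiguity
policy is `mask`: any column carrying an IUPAC ambiguity code, `N`, or a
gap in *any* sequence is removed set-wide before identity comparison. This
matches the behaviour of the haplotype collapsers used in barcoding
practice, guarantees that downstream Hamming distances are defined on a
common set of fully resolved columns, and makes the collapse idempotent. A
`strict` mode turns ambiguity into an error for auditing. Gaps are treated
as ambiguity because COI is protein-coding and indels are not expected;
input is assumed already oriented (no reverse-complement detection).

## Distances and divergence

`k2p_distance()` implements the Kimura 2-parameter distance
`d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` with `P` and `Q` the transition
and transversion fractions over pairwise-complete sites. Ambiguous sites
are deleted *pairwise*, not list-wise, which maximises usable signal and is
the convention of the standard distance tools (the test suite cross-checks
against `ape::dist.dna(model = "K80", pairwise.deletion = TRUE)`). When
`1 - 2P - Q` or `1 - 2Q` is non-positive the distance is undefined and the
functions raise a saturation error naming the offending pair rather than
returning `NaN`.

Between-clade divergence is reported net of within-clade polymorphism:
`d_net = d_between - (d_within_X + d_within_Y) / 2`, with the within-group
mean defined as 0 for singleton groups (the mean over zero pairs is
otherwise undefined, and singleton clades do occur in real surveys).

## Diversity indices and Tajima's D

`diversity_indices()` returns the classic per-population summary: `n`,
haplotype number `K`, segregating sites `S` (columns with two or more
distinct unambiguous bases), `S/n`, nucleotide diversity `pi` (mean
pairwise proportion of differing sites, with the Nei (1987) sampling
standard deviation), and Tajima's `D`. `D` uses the 1989 constants with
`pi` as the mean pairwise difference *count*; it is flagged undefined when
`S = 0` or `n < 4`.

Significance of `D` is judged against a simulated null
(`tajima_null_test()`): neutral Kingman genealogies at the observed `n`,
with exactly the observed `S` mutations multinomially distributed over
branches in proportion to branch length (fixed-S conditioning). Fixed-S
removes the nuisance mutation-rate parameter and matches the convention of
the classic neutrality-test software; a fixed-theta mode is available via
the `theta` argument. P-values use the add-one rule
`(1 + b) / (m + 1)` so a Monte-Carlo test never reports zero, and ties
count toward both tails, which is why `p_upper + p_lower >= 1`.

## AMOVA

`amova()` partitions squared-distance variation following the
Excoffier-Smouse-Quattro sums of squares (`SSD` over a set of `N`
individuals is `sum(d^2) / (2N)` summed over ordered pairs). The flat
design yields `Phi_ST`; the hierarchical design (populations nested in
groups) yields `Phi_CT`, `Phi_SC` and `Phi_ST` with the usual unbalanced-
design coefficients. Negative variance components are reported as-is —
truncating them would hide exactly the spatially-dispersed-but-locally-
structured pattern (negative `Phi_CT`) that motivates reporting them.
Each statistic has its own permutation scheme: individuals among all
populations (`Phi_ST`), individuals among populations within groups
(`Phi_SC`), and whole populations among groups (`Phi_CT`); 5,000
permutations by default. With few populations per group the `Phi_CT`
permutation distribution is coarse and its attainable p-values bounded
away from zero — that is a property of the design, not the implementation.
The default distance input is the K2P matrix ("nucleotide" AMOVA); passing
a 0/1 haplotype mismatch matrix gives the frequency-only variant.

## Median-joining networks and the connection limit

`median_joining()` follows Bandelt, Forster & Roehl (1999): build the
epsilon-relaxed minimum spanning network on Hamming distances (at
`epsilon = 0`, the union of all minimum spanning trees, obtained from the
single-linkage merge levels), then repeatedly add the columnwise
majority-consensus median of node triplets connected in the current
network whenever it reduces connection cost, and finally delete median
vectors left with fewer than three links. Character states are restricted
to A/C/G/T — ambiguous columns must be masked upstream, which
`collapse_haplotypes()` does by default. Ties (all three states distinct
in a column) resolve to the first (hub) sequence's state, and candidate
medians are inserted in lexicographic order, so output is independent of
input order and platform.

The 95% connection criterion is computed per network from the analysed
window length, not hard-coded. `parsimony_limit()` uses a closed-form
statistical-parsimony probability: substitutions hit sites as independent
Poisson processes under a Jukes-Cantor kernel with plug-in per-site rate
`j/m`; a `j`-step connection is parsimonious when every observed
difference is a single hit and no site carries hidden changes, giving

`P(parsimony | j) = (lambda e^-lambda)^j e^(-lambda (m - j)) / (a^j (1-a)^(m-j))`,
`a = 3/4 (1 - e^(-4 lambda / 3))`.

The limit is the largest `j` with probability above the confidence level
(about 7 steps at 489 sites, 6 at 388). This is a deliberate design
choice: the historical recursion used by the parsimony-network programs is
described only in its original paper, so the package states and implements
an explicit, reproducible model of the same quantity; `flag_edges()` also
accepts any fixed step limit if a different criterion is preferred.
Flagging marks edges as confident or not; it never removes them.

## Thermal-niche analysis

The packaged occurrence table (`watersipora_table1.csv`) records, for each
site-by-phylogroup combination, the site coordinates, mean annual SST and
colony count from a global survey of five COI phylogroups. Clade thermal
regimes are summarised by the colony-count-weighted median SST
(`weighted_median_sst()`; even-sized multisets take the mean of the two
middle values) with a bootstrap CI (`bootstrap_median_ci()`): 20 units
resampled with replacement, 1,000 replicates, 2.5/97.5 inverse-ECDF
percentiles so reported endpoints are attainable medians. The default
resampling unit is the colony (draws weighted by count); a site-level mode
exists because "resampling populations of individuals" can be read either
way.

Association between clade identity and SST is tested with rank-based
partial Mantel tests (`partial_mantel()`): lower-triangle vectors of the
clade dissimilarity and SST distance matrices are rank-transformed (mean
ranks for ties, which linearises monotone relationships), correlated
partialling out geographic distance, and tested by simultaneously
permuting rows and columns of the clade matrix (10,000 permutations,
one-sided greater by default, add-one rule). Geographic distance is the
Euclidean distance on raw decimal-degree coordinates — deliberately planar
rather than great-circle, since the correction only needs a monotone proxy
of spatial proximity and the rank transform absorbs monotone distortion; a
haversine alternative would change nothing material at these scales.
`clade_sst_tests()` wraps the all-groups test (0/1 phylogroup mismatch
between colony units) and all pairwise presence/absence tests. The default
analysis unit is the colony (rows expanded by count), matching the
sample sizes a colony-level survey reports; a site-level mode is provided.

## Zooid morphometrics

Zooid and orifice areas use the ellipse approximation `(pi/4) L W`; since
the ANCOVA works on log10 areas, any fixed shape constant shifts
intercepts only, and a rectangle mode is provided to make that explicit.
`ancova_log_areas()` fits `log10(orifice area) ~ log10(zooid area) +
group` and tests the group term and the slope-heterogeneity interaction by
nested-model F comparisons, with a Bartlett test of residual variance
homogeneity reported as a diagnostic. `length_sst_regression()` is
ordinary least squares of zooid length on SST. The data model stores four
zooid dimensions (length, maximum width, orifice length, orifice width) —
the measurement protocol in the source surveys names five dimensions but
lists four, and four is what the analyses use.

## The synthetic generator

`sim_config()` fixes the study conditions; all generators are pure
functions of `(config, seed)`.

* **Sequences** (`simulate_sequences()`): clade ancestors sit on a star
  with branch depth `target/2` expected substitutions per site, so every
  clade pair nets the configured divergence (default 0.15, matching the
  order of divergence — 12-24% — seen between the real COI phylogroups).
  Within clades, a neutral coalescent (`ape::rcoal`) with locus-wide
  `theta = 5` (nucleotide diversity of order 0.01 at the default 500
  sites) supplies shallow variation; mutations follow a Kimura kernel with
  transition/transversion rate ratio 4, typical of invertebrate
  mitochondrial DNA. Tips are shuffled before labelling so sample labels
  carry no topological information (the simulator's tip numbering is not
  exchangeable, and an exchangeable null is exactly what the permutation
  tests assume).
* **Occurrence** (`simulate_occurrence()`): 12 sites along a poleward-cold
  gradient spanning 10-26 degrees C; each clade's count per site is
  binomial(20, p) with a Gaussian niche `p = 0.9 exp(-(sst - centre)^2 /
  (2 width^2))` (centres 12 and 18, width 2 by default). Binomial rather
  than Poisson counts keep sampling bounded by effort, mirroring
  fixed-effort dock surveys; empty rows are dropped as they would be in a
  field table.
* **Zooids** (`simulate_zooids()`): `L_z = 1.2 - 0.02 sst + N(0, 0.1)` mm,
  i.e. roughly 15-20% longer colonies at the cold end, with width and
  orifice dimensions allometric to length with 8% log-normal noise —
  magnitudes a bryozoan morphometric study would consider realistic.

What the generator emulates: deep clade divergence with shallow
within-clade variation, thermal-niche-driven occupancy, and a linear
temperature-size cline. What it does not: selection, migration matrices,
temporal invasion dynamics, sequencing error, or spatial autocorrelation
of SST beyond the monotone gradient. Passing tests therefore demonstrate
the statistical machinery is correct and well-calibrated under these
assumptions, not that any biological conclusion about real surveys is
automatic.

## Numerical choices and degenerate inputs

* Saturated K2P pairs, empty alignments, windows outside the alignment,
  single-group partitions, all-zero distance matrices, constant
  regressors, and zero-variance Mantel triangles all raise typed errors
  naming the offending object; nothing silently returns `NaN`.
* Permutation and bootstrap p-values/CIs are reproducible under an integer
  seed; seeded code restores the caller's RNG state.
* Problem sizes in the shipped workflow and tests — e.g. 10-40 sequences
  of 500 sites, 200-replicate calibrations, 500-replicate neutral checks,
  199-999 permutations in tests and the published defaults (5,000 AMOVA /
  D, 10,000 Mantel, 1,000 bootstrap) in the analysis scripts — were chosen
  so each stage is statistically informative at desk scale.
* Under the panmictic setting the permutation tests hold their nominal
  size (type-I error 5% within Monte-Carlo tolerance at alpha = 0.05),
  and Tajima's D averages near zero over neutral simulations; both are
  enforced by the test suite.

## Known limitations

* The connection-limit model is an explicit reconstruction of the
  statistical-parsimony criterion, not a line-by-line port of the
  original recursion; limits are in the same range but need not match the
  historical programs step-for-step.
* The colony-level Mantel matrices treat colonies at one site as
  exchangeable replicates with zero geographic distance; site-level mode
  trades that granularity for independence.
* Real GenBank alignments are not redistributed with the package, so the
  haplotype counts and between-clade divergences of the original surveys
  are exercised by the synthetic pipeline, not reproduced bit-for-bit.
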