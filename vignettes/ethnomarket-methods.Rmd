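---
title: "Methods: quantitative analysis of medicinal-plant market surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative analysis of medicinal-plant market surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethnomarket)
```

## The data model

The unit of observation is the **use report**: a plant species sold in a
market for an ailment filed under an illness category. A survey is a
validated collection of such reports plus three registries: the ordered
market list, the category vocabulary with its medicinal/non-medicinal
flags, and the listing index.

A **listing** is a binomial as filed under a family. Printed inventories
are organized by family, and the same binomial occasionally appears under
two families (a determination revised between field campaigns, or a genus
moved between families by competing classifications), or even twice under
one family with different vernacular names. The package keeps listings
distinct and defines the counting units explicitly:

* *species total*: distinct (family, binomial) pairs — a binomial filed
  under two families counts twice, a repeated listing within one family
  counts once;
* *per-family counts*: listings per as-filed family — this is how printed
  family tables are tallied, so a repeated within-family listing counts
  each time;
* *medicinal species total*: listings with at least one medicinal report —
  again the tabulation convention of printed inventories, where each
  listing line is classified as medicinal or not.

These conventions were chosen because they are the only combination under
which the packaged Bogotá inventory reproduces its published totals (409
species, 402 medicinal, Solanaceae 15) simultaneously; they are applied
uniformly to any survey the package reads.

Scientific names are canonicalized to "Genus epithet": authorities and
infraspecific ranks are stripped, determination qualifiers (`aff.`, `cf.`)
and hybrid markers are recorded as flags, and genus-level determinations
receive the placeholder epithet `sp.`. Ailment strings are compared
case-insensitively after whitespace trimming, with no stemming: ailments
are treated as labels, not as language. Category typos in the packaged
transcription are preserved literally and resolved through a shipped alias
map, so the data stay faithful to their source while statistics see
canonical labels.

### The packaged Bogotá inventory

The package ships a structured transcription of a 24-market inventory of
medicinal plants sold in Bogotá, Colombia: 410 listings, 409 species, 319
genera, roughly 120 families (122 under the as-filed-excluding-algae
convention; see `family_count_conventions()`), 19 medicinal use categories
plus 5 non-medicinal ones. The source records each listing's uses and
markets as two separate sets, without linking individual uses to
individual markets. Loading therefore crosses every use with every market
of a listing. Species-by-market statistics are exact under this
convention; use-by-market statistics (the LIC index, use-level incidence)
are upper bounds, which is why the published LIC ranking that accompanies
the inventory (`bogota_lic_table()`) is shipped as a reference table
rather than recomputed — with a complete dataset, where each report
carries its own market, `species_lic()` computes the index exactly. The
reference ranking also carries one internal inconsistency of its source,
kept verbatim: it lists *Sambucus nigra* while the inventory files only
*Sambucus peruviana*.

## The logarithmic informant consensus index

For each use $u$ the informant consensus is

$$IC_u = \frac{FC_u - NS_u}{FC_u - 1},$$

where $FC_u$ is the total number of occurrence reports of the use and
$NS_u$ the number of distinct species reported for it. The occurrence unit
is the (species, market) pair: markets, not vendors, are the informants.
$IC_u = 1$ when all reports converge on a single species and $0$ when
every report names a different species. At $FC_u = 1$ the formula is
$0/0$; we define $IC_u = 0$ there, following the degenerate-case handling
of the consensus-factor literature — a single report carries no
information about agreement.

The species score sums consensus over the species' uses, weighted by the
log of how widely that species is reported for each use:

$$LIC_s = \sum_u IC_u \, \ln(FC_{us}),$$

with $FC_{us}$ the number of markets reporting species $s$ for use $u$.
The natural logarithm makes a species sold everywhere for an agreed-on use
score high, while any single-market single-use species scores exactly 0.
We read the subscript in $FC_{us}$ as per-species (the frequency of *this*
species for the use), not as a repetition of the species-independent
$FC_u$: under the alternative reading the score would no longer
distinguish widely-sold from rarely-sold species within a use, defeating
the index's purpose.

A "use" is an ailment label by default. The category level is offered as
an option (`level = "category"`) because coarser vocabularies are common
in comparative work; the two levels give different consensus values by
construction, as pooling ailments raises $FC_u$ faster than $NS_u$.

Percentile thresholding (`lic_threshold()`) returns species strictly above
the empirical $q$-quantile computed with linear interpolation between
order statistics (R's default type-7 quantile); on a score vector
$0,1,\dots,19$ the 0.95 threshold is 18.05, leaving exactly the top score.

## Market comparison

Markets are compared at three item levels: species (binomials), uses
(species–ailment pairs), and categories (species–category pairs).
Incidence matrices are binary — the data record occurrence, not abundance
— and distances are plain Euclidean on the 0/1 rows, so the squared
distance between two markets equals the number of items found in exactly
one of them. No standardization is applied: with presence/absence data any
row standardization would reweight markets by richness, which is exactly
the signal the size-association test examines separately.

The "plant space" used for ordination concatenates the species-level and
use-level indicator blocks unweighted. This is the simplest reading of
ordination "in plant species and their respective uses"; a weighted
concatenation can be built by scaling the blocks before
`euclidean_distances()`.

Per-market uniqueness (`shared_unique()`) counts items whose column sum is
1; the per-plant unique-use percentage (`unique_use_percent()`) is defined
only for plants occurring in at least two markets, since a use can only be
"unique to" a market in contrast with the plant's other markets.

## Ordination and permutation tests

Ordination is principal coordinates analysis (classical scaling): Gower
double-centering of $-\tfrac12 d^2$, eigendecomposition, coordinates
scaled by square roots of non-negative eigenvalues. PCoA was chosen over
stress-minimizing alternatives because it is deterministic (no random
starts), exact for Euclidean-embeddable input — reconstructed distances
match to numerical precision — and directly paired with the Euclidean
distances used throughout. Negative eigenvalues (impossible for distances
produced by this package, possible for user-supplied matrices) are dropped
and their absolute mass reported; a Lingoes additive correction is
available behind the `correction` argument.

Two permutation tests accompany the ordination:

* `permutation_group_test()` — a distance-based pseudo-F comparing
  between- and within-group sums of squared distances, with significance
  by free permutation of group labels. This is the standard approach when
  only a distance matrix and a grouping factor are available.
* `size_association_test()` — a Mantel-style correlation between market
  distances and absolute market-size differences, permuting market
  identities jointly.

Both use the add-one convention $p = (1 + \#\{T^* \ge T\})/(1 + B)$, so p
is never zero and never below $1/(B+1)$, and both require an explicit seed
— permutation p-values are estimates, and estimates should be
reproducible. The pseudo-F agrees with independent PERMANOVA
implementations to numerical precision on the statistic and to Monte Carlo
error on the p-value; on five to seven markets the Monte Carlo p converges
to exact enumeration over all label arrangements.

The packaged inventory carries no zone or locality assignment of its
markets — that grouping is not part of the published record — so
geographic hypothesis tests on it require a user-supplied group map. The
calibration evidence for the tests therefore comes from synthetic surveys,
where the true grouping is known by construction.

## The synthetic survey generator

`generate_survey()` draws a full survey from an explicit model of how
market inventories are structured:

* a species pool of configurable size, partitioned into a shared pool and
  per-market private pools; the `overlap` parameter is the probability
  that a market's species draw comes from the shared pool. Overlap 0 makes
  markets pairwise disjoint (uniqueness 1 everywhere); overlap 1 removes
  private species entirely;
* Zipf-weighted draws from the shared pool (`zipf_exponent`), reproducing
  the empirical occupancy spectrum of real inventories — few widespread
  species, many singletons. In the packaged Bogotá data 49% of species
  occur in a single market and the mean occupancy is 2.5 of 24 markets;
* a category → ailment hierarchy with category-prefixed ailment tokens, so
  the hierarchy is recoverable from the generated labels; a configurable
  fraction of repertoire slots is non-medicinal;
* per-species use repertoires, from which each (species, market)
  occurrence samples a shifted-Poisson number of uses (at least one — no
  empty occurrence exists). Repertoires make a species' uses consistent
  across markets, without which use-level sharing between markets would
  be an accident of vocabulary size.

All randomness flows from one seed set once per survey, so generation is
deterministic and byte-identical on re-runs. Infeasible configurations —
expected private draws exceeding the private pool — raise a sizing error
at validation; stochastic overflow of a private pool during generation
falls back to the shared pool, keeping the total pool bounded.

`bogota_preset()` anchors the scale parameters at the packaged inventory
(24 markets, a 400-species pool, 19 medicinal categories, 318 medicinal
ailment tokens, strong skew, low overlap). Mean market size is kept at 12
species so the partitioned pool remains feasible at low overlap: the
preset is scale-anchored, not a fit — real markets are larger (mean 42
species) but owe their uniqueness to occupancy skew rather than to
strictly private species, a structure the partition model reproduces only
at reduced market size. `generate_grouped_survey()` adds geographic
structure: markets in a group share a group-specific pool whose overlap
with other groups' pools shrinks as `divergence` grows from 0 (no signal)
to 1 (disjoint pools).

What the generator does *not* emulate: vendor-level replication within
markets (the package counts markets as occurrences, so vendors never enter
any statistic), spatial autocorrelation between nearby markets, seasonal
turnover, and vernacular-name structure. Tests passing on synthetic
surveys therefore certify the statistical machinery — counting,
consensus, distances, test calibration — not the ecological realism of
any particular parameter choice.

## Numerical and design choices

* Percentages are rounded half-up to one decimal at presentation; internal
  values are exact. Ranked tables break count ties alphabetically, making
  every table deterministic.
* Quantiles use linear interpolation (type 7); the LIC threshold is a
  strict exceedance.
* Duplicate reports — identical (listing, species, market, category,
  ailment) rows — are collapsed at read time with a logged count;
  deduplication is idempotent.
* Family merging through a user map is restricted to idempotent maps
  (chains and cycles rejected); the default map pools the three legume
  subfamilies into Fabaceae.
* Degenerate inputs error early with classed conditions: schema errors
  (missing columns), vocabulary errors (unknown categories under a closed
  registry), parameter errors (percentile outside (0,1), one group,
  zero-variance sizes, missing seed), dimension errors (single-market
  distances, ordination of fewer than 3 markets), sizing errors
  (infeasible generator configurations).

## Calibration problem sizes

The shipped calibration suite runs, at the preset scale of 24 markets:
type-I error of the group test over 500 null replicates with 99
permutations each (rejection at 0.05 must land in the 95% binomial
interval around 0.05); power over 20 replicates at maximal divergence with
9999 permutations (all must reject); and the overlap–uniqueness response
over a 5-point grid with 100 replicates per point at 8 markets (grid means
strictly decreasing, Spearman −1). These sizes were chosen to keep the
whole suite in the low minutes on a single core while leaving the binomial
intervals tight enough to detect miscalibration of a few percentage
points.

## Known limitations

* Use-level statistics on the packaged inventory inherit the
  use-by-market cross-product convention described above; they are
  provided for structure, not as reproductions of published per-use
  values.
* The published family total (122) depends on counting conventions the
  source does not state; `family_count_conventions()` reports all four
  candidates rather than privileging one.
* The ailment vocabulary of the source is typo-laden ("Apena",
  "Adstringent"); the transcription preserves it, normalization folds only
  case and whitespace, so ailment-level tables are diagnostics rather
  than clean nosology.
* `canonicalize_binomial()` is a heuristic (first lower-case token after
  the genus); it handles the authority formats that occur in practice but
  is not a nomenclature resolver, by design.
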