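# ethnomarket

Quantitative analysis of ethnobotanical market surveys in R.

Urban plant markets are a primary interface between traditional medical
knowledge and city populations, and comparative questions about them —
which species and uses are shared between markets, which are unique to
one, whether geography or market size explains composition, which species
command the widest agreement — all reduce to statistics over one simple
record type: *a species, sold in a market, for an ailment, within an
illness category*. `ethnomarket` implements that pipeline end to end for
ethnobotanists and biodiversity informaticians: ingest and validation of
long-format use reports, taxon/family/category summaries, an informant
consensus index, incidence-based market comparison, ordination,
permutation tests, and a synthetic survey generator for calibration.

The package ships a structured transcription of a 24-market medicinal
plant inventory from Bogotá, Colombia (409 species, 319 genera, ~120
families, 19 medicinal use categories) as a worked, fully reproducible
dataset.

## The core index

Species importance is scored by the **logarithmic informant consensus**
(LIC), with markets as the occurrence unit. For each use *u*:

    ICu = (FCu − NSu) / (FCu − 1)

where `FCu` is the number of (species, market) occurrence reports of the
use and `NSu` the number of distinct species reported for it (`ICu = 0`
when `FCu = 1`). Each species *s* then scores

    LICs = Σu ICu · ln(FCus)

with `FCus` the number of markets reporting species *s* for use *u*. A
species sold in many markets for well-agreed-on uses scores high; any
single-market, single-use species scores exactly 0.

Market comparison works on binary markets × items incidence matrices at
three levels — species, species–ailment pairs ("uses"), species–category
pairs — with Euclidean distances, shared/unique decompositions, principal
coordinates ordination, a PERMANOVA-style pseudo-F permutation test of
market groupings and a Mantel-style test of size association.

## Worked example

```r
library(ethnomarket)

sv <- bogota_survey()
sv
#> <market_survey> 410 listings, 405 binomials, 24 markets, 10617 use reports
#> provenance: packaged Bogota market inventory transcription

count_taxa(sv)
#> # A tibble: 1 × 6
#>   n_listings n_species n_genera n_families n_markets n_medicinal_species
#>        <int>     <int>    <int>      <int>     <int>               <int>
#> 1        410       409      319        123        24                 402

head(family_table(merge_families(sv)), 3)
#> # A tibble: 3 × 3
#>   label      n_species   pct
#>   <chr>          <int> <dbl>
#> 1 Fabaceae          43  10.5
#> 2 Asteraceae        34   8.3
#> 3 Lamiaceae         24   5.9
```

The inventory reproduces its published totals: 409 species in 319 genera
across 24 markets, 402 of them medicinal, with Fabaceae (43 species,
10.5%) the largest family after pooling the legume subfamilies. Markets
are strikingly dissimilar — on average 19% of a market's medicinal
species are found in no other market:

```r
med <- filter_medicinal(sv)
su  <- shared_unique(incidence_matrix(med, "species"))
round(mean(su$per_market$prop_unique), 3)
#> [1] 0.189

d <- euclidean_distances(plantspace_matrix(med))
pcoa(d, n_axes = 2)
#> <ordination> PCoA (classical scaling): 24 markets, 2 axes kept
#> relative eigenvalues: 0.173 0.083 0.069 0.063 0.061
#> negative eigenvalue mass: 0.000
```

The flat eigenvalue spectrum (the first axis carries only 17% of the
variation) is itself a finding: market composition does not collapse onto
one or two gradients. Grouping hypotheses can be tested once a group map
is supplied:

```r
groups <- setNames(rep(c("north", "center", "south"), 8), labels(d))
permutation_group_test(d, groups, n_permutations = 9999, seed = 1)
```

Synthetic surveys with known structure support calibration and power
studies:

```r
cfg <- synthetic_config(n_markets = 24, n_species_pool = 400,
                        mean_species_per_market = 12, overlap = 1,
                        zipf_exponent = 1.2, seed = 7,
                        group_structure = list(n_groups = 3, divergence = 1))
out <- generate_grouped_survey(cfg)
dd  <- euclidean_distances(incidence_matrix(out$survey, "species"))
permutation_group_test(dd, out$groups, n_permutations = 9999, seed = 1)$p_value
#> [1] 1e-04
```

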