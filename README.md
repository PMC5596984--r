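# barcodiv

Divergence diagnosis, haplogroup clustering and molecular-clock dating for
single-marker DNA barcode alignments.

## What it is for

DNA barcoding studies (typically on the 658-bp 5' fragment of
mitochondrial *COI*) ask three recurring questions about a set of aligned
samples: are there diagnosable lineages, how divergent are they, and how
old are they? `barcodiv` implements the two standard divergence criteria
used to answer the first two —

* the number of **fixed (diagnostic) substitutions** between two groups:
  sites invariant within each group but different between them,
* the **minimal inter-group uncorrected p-distance**: the two genetically
  closest samples of a group pair are selected and the proportion of
  differing sites between them (fixed and non-fixed) is reported —

plus distance-threshold **single-linkage haplogroup clustering** with
detection of taxon/haplogroup **discordance** (mitochondrial introgression
candidates), and **clock dating** by dividing an uncorrected p-distance by
a pairwise rate calibration, t = p / r, with a pair of rates giving an age
interval (defaults 1.5 and 2.3 % uncorrected pairwise distance per Myr).

The package also ships a synthetic-data module: a constructive fixture
generator that plants exact divergence statistics into a five-haplogroup,
658-site alignment modelled on the *Melitaea persea* species complex
(including a 3-of-25 introgressed minority), and a seeded Jukes–Cantor
simulator for parameter-recovery studies. Everything is tidyverse-native:
alignments, groupings and results are tibbles; result classes have
`autoplot()`, `tidy()` and `glance()` methods.

## Worked example

```r
library(barcodiv)
library(dplyr)

fx <- make_fixture(seed = 1)      # 93 samples x 658 sites, planted truth
divergence_summary(fx$alignment, fx$haplogroups) |>
  filter(group_b == "P1")
#>   group_a group_b fixed_count evaluated_sites      min_p min_p_percent
#> 1      P2      P1           7             658 0.01975684         2.0 %
#> 2      P3      P1          10             658 0.02279635         2.3 %
#> 3       A      P1          11             658 0.02431611         2.4 %
#> 4       H      P1          10             658 0.02431611         2.4 %
```

Each row compares one haplogroup against the reference haplogroup P1:
haplogroup A differs by 11 fixed substitutions and its closest sample pair
differs at 16 of 658 sites (2.4 %). Clustering the full alignment at the
default 1 % threshold recovers the planted structure and exposes the
introgressed samples — *acentria*-labelled samples sitting in the
Lebanese-*persea* haplogroup cluster:

```r
d  <- distance_matrix(fx$alignment)
cl <- single_linkage_clusters(d, threshold = 0.01)
length(unique(cl$cluster))
#> [1] 9                       # 5 complex haplogroups + 4 outgroups
discordant_samples(cl, fx$taxa)
#>   sample_id    taxon cluster majority_taxon majority_tied
#> 1     ACE23 acentria      C7 persea_lebanon          TRUE
#> 2     ACE24 acentria      C7 persea_lebanon          TRUE
#> 3     ACE25 acentria      C7 persea_lebanon          TRUE
```

Dating the 2.4 % divergence under the two default calibrations:

```r
divergence_interval(2.4)
#> Divergence time for p = 2.4 %: 1.0-1.6 Myr
#>   rate 2.3 %/Myr (2.3 %/Myr): t = 1.0435 Myr
#>   rate 1.5 %/Myr (1.5 %/Myr): t = 1.6000 Myr
```

The haplogroup carrying that divergence is therefore estimated to have
originated roughly 1–1.6 million years ago.

See `vignettes/barcode-divergence.Rmd` for the methods, the missing-data
policies, the fixture construction and the simulator's assumptions.

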