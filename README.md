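# npscout

Prioritization of natural-extract libraries by structural-novelty
potential.

A laboratory that profiles a collection of crude natural-product extracts
by untargeted LC-MS/MS can annotate a good fraction of the detected
features against spectral libraries, in-silico databases and
formula/structure predictors — but the extracts worth months of isolation
work are the ones whose chemistry those tools *cannot* explain. `npscout`
ranks a library by condensing the evidence into one **Priority Score** per
extract:

    PS = w_fc·FC + w_lc·LC + w_cc·CC + w_sc·SC        (default weights w = 1)

* **FC — Feature Component**: the fraction of the extract's detected
  features that are *specific* to it (≥ 90 % of their row-normalized peak
  area, optionally shared across up to N extracts of the same species) and
  carry no annotation from any source.  **FS** is the same ratio ignoring
  annotations.
* **LC — Literature Component**: `1 − (w_sp·rcs/20 + w_g·rcg/100 + w_f·rcf/500)`,
  a penalty built from the number of compounds reported for the species,
  genus and family in an offline occurrence table; 1 means never studied,
  heavily studied taxa go negative.
* **CC — Class Component**: 0.5 if a recurrent, confidently predicted
  chemical class (natural-product-classifier ontology) is unreported for
  the species, plus 0.5 for the genus; compared by canonicalized string
  set subtraction.
* **SC — Similarity Component**: 1 if the extract is a spectral outlier.
  MS2 spectra are vectorized into counts of binned fragment peaks
  (`peak@283.15`) and neutral losses (`loss@162.05`), blank-injection
  words are removed, and an ensemble of local outlier factor, one-class
  SVM (leave-one-out novelty detection) and isolation forest votes on the
  Bray–Curtis dissimilarity matrix; one vote suffices.

Inputs are the standard working files of a feature-based molecular
networking study: an MZmine-style aligned feature CSV (ion-identity
networks are collapsed to their best ion), an extract metadata table,
GNPS / in-silico / formula-prediction annotation TSVs, a CANOPUS-style
class-prediction TSV, an offline per-taxon occurrence TSV, and MGF
spectra. A deterministic synthetic-data generator
(`fixture_spec()` → `generate_bundle()`) produces complete bundles with
planted ground truth, so the whole pipeline can be exercised and validated
without any instrument data.

## Worked example

```r
library(npscout)
library(dplyr)

# a 6-extract synthetic library: 45% of each extract's features specific,
# half of those annotated; extracts 1, 3, 4, 6 carry an unreported class;
# extract 6 is a planted spectral outlier
b <- generate_bundle(fixture_spec(
  n_extracts = 6, n_features = 120,
  fraction_specific = 0.45, fraction_annotated = 0.5,
  plant_new_class = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
  outlier_index = 6, seed = 17
))

res <- prioritize_extracts(
  b$feature_table, b$metadata,
  gnps = b$gnps, isdb = b$isdb, sirius = b$sirius,
  predictions = b$predictions, occurrence = b$occurrence,
  spectra = b$spectra
)

tidy(res) |>
  select(rank, filename, organ, FS, FC, LC, rcs, rcg, CC, SC, PS) |>
  mutate(across(c(FS, FC, LC, PS), ~round(.x, 2)))
#> # A tibble: 6 × 11
#>    rank filename   organ      FS    FC    LC   rcs   rcg    CC    SC    PS
#>   <int> <chr>      <chr>   <dbl> <dbl> <dbl> <int> <int> <dbl> <int> <dbl>
#> 1     1 extract_06 leaves   0.45  0.22 -0.16    17    26     1     1  2.07
#> 2     2 extract_01 roots    0.45  0.22 -0.43    20    94     1     0  0.79
#> 3     3 extract_04 flowers  0.45  0.22 -0.92    19   244     1     0  0.31
#> 4     4 extract_03 stems    0.45  0.22 -1.17    17   329     1     0  0.06
#> 5     5 extract_05 roots    0.45  0.22 -0.72     1   275     0     0 -0.49
#> 6     6 extract_02 leaves   0.45  0.22 -0.88     2   317     0     0 -0.65
```

Reading the top row: 45 % of extract 6's features are specific to it (FS)
and half of those are unannotated (FC 0.22); its taxon has few reported
compounds (LC barely negative, 17 species / 26 genus reports); a recurrent
predicted class is new to both species and genus (CC 1); and its overall
MS2 fingerprint is an outlier in the set (SC 1). The equally weighted sum
puts it first — exactly the profile of an isolation candidate. Extracts
2 and 5 end last: same feature structure, but nothing novel at class level
and genera with hundreds of reported compounds.

Per-extract detail for the isolation shortlist:

```r
glance(res)
#> # A tibble: 1 × 6
#>   n_extracts n_features n_outliers mean_FC top_extract top_PS
#>        <int>      <int>      <int>   <dbl> <chr>        <dbl>
#> 1          6        390          1   0.225 extract_06    2.07

m <- ion_map(res, "extract_06")   # feature status vs rt / m/z / area
table(m$category)
#>          nonspecific   specific_annotated specific_unannotated
#>                   66                   27                   27
autoplot(m)                        # blue points = isolation candidates
```

`write_results_table()` and `write_ion_map()` emit the TSV reports; a thin
command-line front end is available as `exec/npscout`
(`npscout run --feature-table … --metadata … --out DIR`, plus
`npscout fixtures` for synthetic bundles).

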