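# foodscreen

Virtual screening of food compound libraries: curation filters,
cumulative ADMET scoring with top-k ranking, and consensus target
prediction with bipartite network export — plus the bioassay ratio
statistics used to validate hits, and a synthetic-data module so the
whole pipeline runs and tests offline.

## Who this is for

Food chemists and natural-product researchers triaging a database export
(e.g. the thousands of constituents a FooDB-style resource lists for a
single plant) down to a handful of drug-like, non-toxic ingredients worth
assaying, and then asking which disease-relevant protein targets those
ingredients might engage. The package was built around a screen of
bilberry constituents for neuroprotective anthocyanins; everything is
configuration-driven and reusable for other libraries.

## The method

1. **Curation cascade.** Three auditable filters: tag-driven removal of
   glycerolipid classes, removal of water/inorganics (entries tagged
   `inorganic` or containing no carbon), and a molecular-weight cut
   (MW < 100 Da removed; small molecules bind without specificity).
   Every stage reports `n_in`, `n_out` and the removed identifiers, and
   the counts chain across stages.

2. **Cumulative scoring.** For compound *i* with rule set
   *R* = {(property_r, test_r, w_r)}:

   score_i = Σ_r  w_r · 1[ test_r passes on compound i ],

   over seven physicochemical descriptors (MW, nHA, nHD, nRot, nRing,
   fChar, LogP) and eight ADMET toxicity endpoints (hERG, H-HT, Ames,
   ROA, carcinogenicity, respiratory, and two carcinogenicity subtypes;
   pass = predicted negative, probability < 0.5). Rules with missing
   inputs are `not_evaluable` and leave the attainable maximum, so the
   normalized score stays comparable. Compounds are ranked by raw score
   (ties: normalized score, then compound id) and the top k = 10 go
   forward.

3. **Consensus target voting.** Ranked hit lists from multiple
   prediction tools are reduced to four states per (compound, target,
   tool) — hit within the first 20 hits, hit beyond that window, no hit,
   or target not covered by the tool — and the consensus vote for a pair
   is the number of tools voting *hit*. Votes become a weighted bipartite
   compound-target network (edge-list TSV + GraphML). A built-in
   Tanimoto-similarity predictor (ECFP4-style hashed circular
   fingerprints) stands in for web services when running offline.

4. **Assay statistics.** Fluorescence ratio `100·F/F0`, JC-1
   monomer/aggregate ratio (mitochondrial membrane potential),
   percent-of-control normalisation, single-sample t-tests
   (mean ± SD, n = 3), and a thioflavin-T lag-time summariser.

## Worked example

The package ships a 50-compound synthetic fixture (10 planted
rule-passing actives, 6 simulated prediction tools, 3 targets):

```r
library(foodscreen)
cfg <- system.file("extdata", "fixture", "config.yaml",
                   package = "foodscreen")
res <- run_screening(cfg, out_dir = "screen_out")
res$report
#> <screening_report> seed 101
#>   class                50 ->   33
#>   inorganic            33 ->   31
#>   molecular_weight     31 ->   31
#>   scored: 31 | selected: 10
#>   network: 13 nodes, 30 edges
```

50 compounds enter; 17 fall to the lipid-class filter, 2 to the
inorganic filter, none here to the MW cut; 31 are scored and the 10
highest cumulative scores are selected — exactly the planted actives,
each passing all 15 rules:

```r
head(res$top[, c("compound_id", "raw_score", "normalized_score", "rank")], 3)
#>   compound_id raw_score normalized_score rank
#> 1       C_009        15                1    1
#> 2       C_010        15                1    2
#> 3       C_012        15                1    3

head(consensus_votes(res$votematrix), 3)
#>   compound_id target_id votes
#> 1       C_009    P05067     5
#> 2       C_009    P22303     5
#> 3       C_009    P42574     6
```

`votes` counts how many of the six simulated tools place that target in
the compound's first 20 hits; the bipartite network (13 nodes, 30 edges)
is written as `edge_list.tsv` and `network.graphml`.

Descriptors work directly on structures; an anthocyanin chloride salt is
profiled on its flavylium cation:

```r
smi <- "[Cl-].COc1cc(-c2[o+]c3cc(O)cc(O)c3cc2OC2OC(CO)C(O)C(O)C2O)cc(OC)c1O"
compute_descriptors(strip_counterions(smi))
#>         mw n_ha n_hd n_rot n_ring f_char   logp
#> 1 493.4374   12    7     6      4      1 0.6936
```

The positive formal charge (+1) is the flavylium oxygen; MW 493.44 Da is
malvidin-3-O-galactoside without its chloride counter-ion.

A command-line front end with verbs `screen`, `simulate`,
`aggregate-targets`, `assay` and `export-network` is installed under
`inst/cli/foodscreen.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","foodscreen.R",package="foodscreen"))')" \
    screen --config inst/extdata/fixture/config.yaml --out-dir screen_out
```

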