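---
title: "Screening methods: curation, cumulative ADMET scoring and consensus target voting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodscreen)
```

## The screening problem

Food-constituent databases export thousands of entries per organism, most
of them unusable as pharmacological leads: storage lipids, water,
minerals, and fragments too small to bind anything specifically. The goal
of this package is a reproducible version of the in-silico funnel used in
natural-product screening campaigns: curate such a library, score the
survivors for drug-likeness and predicted safety, take the top handful of
ingredients forward, and ask several independent target-prediction tools
which disease-relevant proteins those ingredients might engage. The
package grew out of a screen of bilberry (*Vaccinium myrtillus*)
constituents for neuroprotective anthocyanins, and its defaults reflect
that setting, but every stage is configuration-driven.

## Curation cascade

Three filters run in sequence, each producing an auditable
`filter_stage_report` whose counts chain (`n_out` of stage *i* equals
`n_in` of stage *i+1*):

1. **Class exclusion** (`filter_by_class`): tag-driven removal of
   glycerolipid-type classes (triacylglycerols, diacylglycerols,
   phosphatidylethanolamines by default). Tags, not substructures, drive
   this stage because food databases ship ontology classes and the
   excluded families are named, not defined by SMARTS patterns. The tag
   list is part of the configuration; unknown tags warn and are ignored.
2. **Inorganic removal** (`filter_inorganic`): drops entries tagged
   `inorganic` plus parsed structures containing no carbon atom (water,
   simple salts). The carbon heuristic is deliberate: there is no crisp
   chemical definition of "inorganic" in this context, and the
   carbon-free rule covers the observed removals (water, minerals)
   without a curated blacklist.
3. **Molecular-weight cut** (`filter_by_molecular_weight`): removes
   compounds with MW strictly below 100 Da. Very small molecules bind
   promiscuously and are useless as specific leads; the boundary value
   itself is retained (a compound at exactly 100 Da survives), and the
   cut-off is configurable.

Records whose structures fail to parse are never silently dropped: they
carry `parse_ok = FALSE`, pass through the descriptor-dependent stages
untouched, and remain visible in every report.

## Descriptors

`compute_descriptors()` produces the seven properties the filters and
rules consume: average-mass MW (Da), hydrogen-bond acceptors `n_ha`,
donors `n_hd`, rotatable bonds `n_rot`, ring count `n_ring`, net formal
charge `f_char` (elementary charges) and a Wildman–Crippen
atom-contribution `logp`. Salts are reduced to their largest fragment
first (`strip_counterions`; ties broken by molecular weight, then by
canonical SMILES), so an anthocyanin chloride is profiled on its
flavylium cation — which duly reports `f_char = +1`.

Two hydrogen-bond conventions exist in the wild. The default here is the
Lipinski-style count (acceptors = N + O atoms; donors = N/O atoms bearing
at least one hydrogen), which is what rule-of-five-type filters assume.
The SMARTS-based surface-chemistry definition of the Open Babel backend
(`hbond_convention = "openbabel"`) is selectable; it differs for
pyrrole-type nitrogens and charged oxygens. Ring count is the cyclomatic
number of the molecular graph, identical to the size of a smallest set of
smallest rings; a rotatable bond is a non-ring single bond between two
non-terminal heavy atoms with amide C–N bonds excluded; MW uses average
atomic masses, matching drug-likeness usage. The integer descriptors and
MW agree exactly (MW to 0.01 Da) with an independent toolkit on a
20-molecule verification panel kept in the test suite. The `logp`
estimator is deterministic and shared with the backend toolkit; its
treatment of N–H hydrogens differs slightly between implementations of
the same contribution scheme, which is why the panel compares `logp` only
where the implementations define identical atom types.

## Cumulative scoring

`evaluate_rules()` scores each compound against a configurable ruleset of
threshold tests over descriptors and ADMET toxicity endpoints. Each rule
contributes its weight when passed; the cumulative (raw) score is the sum
over passed rules, and ranking (`rank_and_select`) is by raw score, then
normalized score, then compound identifier — fully deterministic, with
boundary ties reported.

The shipped `default_ruleset()` is a **reconstructed** default, not a
published table: molecular size restricted to 100–600 Da, `n_ha` ≤ 12,
`n_hd` ≤ 7, `n_rot` ≤ 11, at least one ring, |`f_char`| ≤ 1, 0 ≤ `logp`
≤ 5, and all eight toxicity endpoints (hERG, H-HT, Ames, ROA,
carcinogenicity, respiratory, and the two carcinogenicity subtypes)
predicted negative, i.e. probability < 0.5. The guiding principles are
the usual ones for a first pass over food ingredients: restrict size,
restrict toxicity, limit only basic physicochemical properties; strict
ADMET profiles belong to lead optimisation, not library triage. All
thresholds, weights and the endpoint probability cut-off are overridable
through a YAML ruleset file, and the active ruleset is echoed into the
run report so a screen is interpretable from its artifacts alone.

Missing endpoint predictions make the corresponding rule
`not_evaluable`; the rule's weight is removed from the attainable
maximum, so the normalized score remains comparable across compounds with
different prediction coverage, while the raw score is reported alongside.

## Consensus target voting

Ranked hit lists from several prediction tools are aggregated per
(compound, target) pair into four states: `hit` (within the tool's first
*k* hits; *k* = 20 by default, a deliberately loose window because score
semantics differ across tools and ranks are the only comparable
currency), `hit_beyond_topk`, `no_hit` (covered but absent) and
`not_covered` (outside the tool's target universe). The consensus vote is
the number of `hit` tools; the states always sum to the number of tools,
an invariant the test suite checks on a thousand randomized inputs.

Distinguishing `no_hit` from `not_covered` requires knowing a tool's
universe. When a manifest declares the universe unknown, the package
refuses to guess unless the configuration explicitly chooses a fallback —
silently mislabelling coverage is the classic way consensus votes become
incomparable. Similarly, `hit_beyond_topk` requires the tool's full list;
truncated exports degrade absent targets to `no_hit` by construction.

`build_network()` renders the votes as a bipartite compound–target graph
(edge iff votes ≥ `min_votes`, weight = votes, per-tool states annotated
on the edge) and exports a deterministic edge-list TSV plus GraphML.

A built-in similarity predictor (`similarity_target_predictor`) provides
an offline stand-in for web-service predictors: hashed circular
fingerprints (extended-connectivity, radius 2; folded to 2048 bits by
default), max-Tanimoto per target over a reference ligand set, ranked
deterministically. It is plumbing for pipelines without network access,
not a re-implementation of any particular service.

## Assay statistics

The bioassay module implements the measurement arithmetic of the
validation experiments: the percent fluorescence ratio `100 * F / F0`
(hydroxyl-radical probe and intracellular ROS readouts), the JC-1
monomer/aggregate ratio for mitochondrial membrane potential,
percent-of-control normalisation, and the single-sample *t*-test used for
group comparisons (each treated group against the control mean,
two-sided; `n = 3` replicates is the default design). The single-sample
form is implemented literally because that is the stated analysis;
Welch's two-sample test is available as a configurable alternative, and a
Bonferroni switch exists but defaults to off because the original
analysis applies no multiplicity correction. Degenerate inputs are
explicit: zero variance with mean equal to the reference gives `t = 0, p
= 1`; zero variance away from the reference is flagged and reported as
`p = 0` with a warning rather than crashing or silently passing.

The thioflavin-T summariser `tht_lag_time()` defines the nucleation lag
as the first threshold crossing — by linear interpolation between
samples — of the baseline-corrected intensity at 10% of the
baseline-to-plateau rise (baseline = first sample, plateau = maximum).
The 10% fraction is this package's own operational definition, exposed as
a parameter, since aggregation narratives describe phases rather than
defining a cut. A flat series returns `NA` ("no transition") rather than
a number.

## Synthetic data and what it does (not) show

`generate_library()` draws descriptor vectors and endpoint probabilities
directly, plants `n_planted` actives inside every rule window with a
margin, and gives each decoy at least one recorded rule violation, also
by a margin — so the planted set is identifiable by construction and
top-*k* selection must recover it exactly. Class tags follow the
configured mix (defaults: 60% organic drug-like classes, 35% excluded
lipid classes, 5% inorganic, echoing the shape of a food export where
lipids dominate the raw list). Each record carries a small valid
structure of the right kind (carbon-free for inorganics) so the parsing
and inorganic stages exercise real chemistry, but the *tabulated*
descriptors drive the numeric stages, emulating a workflow in which
properties arrive as a precomputed table. The simulator therefore
validates the pipeline's bookkeeping, determinism and selection logic; it
does not claim that real descriptor distributions, real class frequencies
or real ADMET model outputs look like its samples, and passing tests on
synthetic data say nothing about the biological merit of any real
compound.

`generate_predictions()` simulates `n_tools` predictors with per-tool
coverage, sensitivity (probability a true pair lands in the retention
window) and false-hit rate. With full coverage the consensus vote for a
true pair is Binomial(`n_tools`, sensitivity) by construction; the test
suite checks the empirical mean and the two-plus-vote probability against
that closed form within three Monte-Carlo standard errors at 2,000 pairs
(at the default 6 tools and sensitivity 0.8: mean 4.8, P(votes ≥ 2) ≈
0.9984). `generate_assay_data()` produces replicate groups (true mean +
Gaussian noise, `n = 3`) and a logistic aggregation time course sampled
at the assay's measurement grid (0–96 h, midpoint 24 h, rate 0.12 h⁻¹ —
chosen so the noise-free curve shows the familiar ~6 h lag and a plateau
from ~48 h); the analytic threshold-crossing time is returned with the
data, and the estimator recovers it within one sampling interval on
noise-free curves.

All generators derive their RNG stream from one master seed keyed by
generator name, so identical seeds give byte-identical artifacts and
adding a generator never perturbs existing ones.

## Numerical and design choices

* Ranking tie-breaks are lexicographic on `compound_id` everywhere a tie
  is possible, making top-*k* selection bit-reproducible; ties at a
  selection boundary are logged.
* The MW cut removes *below*-threshold compounds with the boundary
  retained. A removal (not retention) of small molecules is the only
  reading consistent with its own rationale — small molecules lack
  specificity — and with a funnel whose counts shrink at every stage.
* Probability endpoints threshold at 0.5 by default, configurable per
  rule.
* Problem sizes in the tests (100–200 compounds, 20 repeated libraries,
  1,000 randomized vote sets, 2,000 calibration pairs) were chosen as the
  smallest scales at which the statistical checks have negligible
  Monte-Carlo ambiguity.
* The whole pipeline is text-in/text-out (CSV/TSV/YAML/JSON/GraphML);
  no binary artifacts are produced or required.

## Known limitations

* ADMET endpoint values are *ingested*, never predicted: the package
  contains no QSAR models and does not emulate any prediction platform's
  internals.
* The six web-service target predictors are represented by adapters and
  by the generic built-in similarity predictor; no service-specific
  statistics (similarity ensembles, pharmacophore matching, chemical
  genomics models) are reimplemented.
* Molecular docking, and any use of proprietary modelling software, is
  out of scope.
* The curation stage trusts the library's class ontology; a mislabelled
  entry will be filtered (or kept) according to its tag.
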