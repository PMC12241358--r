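---
title: "Constructing species-level trophic metawebs from mixed-rank records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing species-level trophic metawebs from mixed-rank records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metawebr)
library(dplyr)
```

## The problem

A metaweb is the aggregate network of all potential trophic interactions
among the species of a region; any local food web is a subset of it.
Empirical diet records, however, arrive at mixed taxonomic resolution: a
well-studied moth may be documented on a single host plant species, while a
spider's prey is only known "to family". Mixing resolutions distorts
topology metrics and creates artificial redundancies (a genus *A* eating
species *C* alongside a record of species *B* in *A* eating *C*). This
package turns a taxonomic checklist plus mixed-rank interaction records
into a species-level metaweb by applying explicit, rule-based expansions,
and supplies the supporting machinery: habitat and vertical-stratum
association inference, gap diagnostics, error-rate validation statistics,
and residual-based comparison with other published metawebs.

Throughout the package, records are directed consumer → resource:
`Source_Name` is the consumer and `Target_Name` the resource. Statements
about "missing outgoing/incoming energy flow" translate into this
convention as: a taxon with no diet never appears as a *source*; a taxon
with no predators never appears as a *target*.

## The expansion rules

Three rules lift coarse records to species level; everything else is
retained at its original resolution so no information is discarded.

1. **Genus expansion.** A record with a species-rank consumer and a
   genus-rank resource is replaced by one species–species record per
   checklist species of the genus (tag `Source_Species_Target_Genus`).
   The mirrored case (genus-rank consumer) is expanded symmetrically
   (`Source_Genus_Target_Species`). A genus with no checklist species
   leaves the record untouched.
2. **Family expansion for licensed consumers, trimmed by co-occurrence.**
   Family-rank resources are expanded only when the consumer is licensed:
   its family is listed as a generalist *Predator* family in the diet-range
   table, or the consumer is a *Polylectic* pollinator (documented broad
   floral diet). After enumeration, pairs whose consumer and resource share
   no habitat class or no vertical stratum are removed; the rationale is
   that a generalist predator can only plausibly eat what it can encounter.
   Expansion above family rank is never attempted: phenotypic variation
   within insect families is too large for blanket inference, which is why
   the default rules stop at genus except for these two licensed cases.
3. **Feeding-guild links.** Families documented as generalist feeders on a
   basal guild (fungi, detritus, POM, algae, ...) have each member species
   linked to the guild node directly, so the family's species stay at
   species resolution on their consumer side.

After expansion, assembly deduplicates on the (consumer, resource) pair:
an empirical record always beats an inferred one (it keeps `Inference =
NA`, its interaction type and life stages), and citation sets are merged
so provenance is never lost. A coarse record that expanded to at least one
species-level record is dropped (configurable); one that expanded to
nothing is retained. `ID_og` always preserves the original pre-expansion
pair, so every inferred link traces back to its evidence.

### Numerical and tie-break choices

* Collisions among inferred records keep the first record in a
  deterministic (inference tag, original pair) order; citations merge.
* Conflicting interaction types on a merge resolve in favour of the kept
  (empirical) record, with a message.
* Self-loops created by expansion (a species inside its own prey genus)
  are retained: obligate cannibals are real, and the diagnostics stage
  reports them.
* Life stages on expanded records are copied verbatim from the coarse
  record: expansion adds no stage information.

## Habitat and stratum associations

Associations drive the link-2 trimming, so they must exist for every
species before family expansion runs — the pipeline orders the stages
accordingly. Map-derived candidate associations come from intersecting
occurrence points with habitat patches (axis-aligned rectangles stand in
for a real polygonal habitat map; the intersection operation is a
documented extension point). The filters then compose in the order they
are defined:

1. keep map-derived habitats with at least `min_count_retain` occurrences
   (default 100), plus every literature-documented habitat — literature
   associations are exempt from all count thresholds;
2. species with `generalist_threshold` (default 3) or more candidates are
   *generalists*: they keep only map-derived habitats with counts strictly
   above the median of their candidate counts (a literature-only candidate
   enters the median with count 0, the only value the data provide);
3. *specialists* keep map-derived habitats documented at least
   `specialist_min_count` times (default 5).

"Strictly above the median" for generalists and "at or above the median
share" for the taxonomic inference below follow the respective rule
wordings; both comparisons are exposed in `association_config()`.
The median over an even number of values is the usual midpoint.

Species that end up with no associations are filled by **median-share
inference**: pool the association sets of informed congeners, count for
each label how many congeners carry it, and keep labels whose share is at
or above the median share; failing a genus with informed members, the same
rule runs at family level, and the result is flagged `Genus` or `Family`
in the checklist's provenance columns. Strata use the identical machinery
on stratum labels. Plants are assigned strata from their Raunkiær life
form: hydrophytes and pleustophytes are "in water", epiphytes "on
vegetation", and all other life forms occupy the three terrestrial plant
strata so that animal–plant links trim correctly.

## Diagnostics and gap filling

`detect_improper_positions()` compares the web's apparent basal and apex
taxa with declared *true* basal taxa (plants, basal guilds) and *true*
apex taxa: a non-basal taxon that never appears as a consumer is missing
diet data; a non-apex taxon that never appears as a resource is missing
predator data; a taxon whose only record is a self-loop is an obligate
cannibal. The true sets are inputs — identifying them is expert work, not
something this package re-derives.

Gaps can then be filled from documented ecological similarity
(`apply_special_cases()`: copy a donor species' diet or predators, tagged
`special_case`, citations merged with the case's own) or from broad
statements like "hedgehogs feed on diplopods"
(`connect_family_to_generalist_consumers()`, optionally trimmed by shared
habitat and stratum). `most_shared_consumers()` ranks candidate donors by
how many members of a focal group they already consume, with
lexicographic tie-breaks for determinism.

## Validation statistics

The error-validation machinery treats extraction error as a binomial
proportion. The sample size needed to estimate an error rate `p` with
margin `e` at quantile `z` is `n = z² p (1 − p) / e²`, rounded up; at
`z = 1.96`, `e = 0.01`, `p = 0.07` this gives `n = 2501`. Observed errors
are summarised with the Wilson score interval, which behaves well near
zero (3 errors in 2501 checks gives 0.04%–0.35% at 95%). Sampling plans
draw `n` records from the manually transcribed (analogue) pool and a
fixed small number per script-extracted (digital) source, reproducibly
under a seed; records whose pair is supported by two or more independent
sources are auto-confirmed before any manual checking.

One honest caveat the tests document: at parameters as extreme as
`n = 2501`, `p = 0.0012`, the Wilson interval's exact coverage is 96.65%
(it covers for 0–6 observed errors, and that event has probability
0.9665), so a Monte-Carlo check against a 95% ± 1.5 pp band fails by a
small margin. This is a property of the interval at extreme proportions,
not an implementation defect; the corresponding test asserts both the
exact value and, faithfully, the stated band.

## Cross-metaweb comparison

Mean total degree (in + out links per node) and its standard deviation
scale with richness and sampling effort, so raw values are not comparable
across metawebs. `residual_outlier_analysis()` regresses each metric on
log10 richness with the network type (bitrophic vs multitrophic) as a
grouping effect and flags webs whose residual falls outside
mean ± 2 SD. The grouping effect is a random intercept via `lme4::lmer()`
by default, with per-group fixed intercepts in an ordinary `lm()` as the
fallback; the outlier decision is required (and tested) to be robust to
that choice. An exact fit (all residuals numerically zero) flags nothing:
floating-point noise is not standardised into z-scores. The "relative"
responses are taken as untransformed degree metrics against log richness —
the one concrete anchor available — and the raw-richness variant is a
switch away (`log_richness = FALSE`).

## The synthetic world

`generate_world()` builds a fully self-contained test bed: a
family–genus–species taxonomy with collision-free names (`Fam1`,
`Gen1.2`, `Gen1.2 sp1.2.3`), guild nodes, mixed-rank interaction records
with a controllable coarse fraction, one planted habitat/stratum set per
species, diet-range and special-case tables, and occurrence points
clustered in rectangular habitat patches. Planted habitats receive
`points_per_species` points (default 60) while occasional stray clusters
get about a tenth of that, so count thresholds scaled to the synthetic
budget (candidate rule at 30, specialist rule at 5) recover the planted
sets sharply while still exercising the threshold edges. A configurable
fraction of species has its checklist associations blanked to exercise
the genus/family inference path.

The ground truth is computed by `oracle_expand()`, a deliberately naive
triple-loop re-implementation of the expansion rules that shares no code
with the expansion module; agreement between the two on random worlds is
the package's central correctness property. What the generator does *not*
emulate: realistic degree distributions, taxonomic composition, spatial
autocorrelation of occurrences, or citation structure. A green test
therefore establishes rule-faithfulness of the implementation, not
ecological realism of any particular output.

## Worked example

```{r example}
world <- generate_world(synthetic_spec(seed = 1))
cfg <- pipeline_config(
  checklist = world$checklist, records = world$records,
  diet_ranges = world$diet_ranges, guild_map = world$guild_map,
  points = world$points, patches = world$patches,
  association = association_config(min_count_retain = 30))
res <- run_pipeline(cfg)
res$web
glance(res$web)
res$report
glance(res$gaps)
```

## Known limitations

* Geometry is axis-aligned rectangles; real GIS intersection against a
  polygonal habitat map is out of scope (swap in a precomputed
  species × habitat count table instead).
* No probabilistic or trait-based link prediction: expansion is purely
  rule-based, and no taxonomic name resolution against external backbones
  is attempted.
* The closed vocabulary of inference tags generalises the two documented
  values; deposits using a richer tag grammar should be reconciled at
  ingest.
* Whether the specialist ≥ 5 rule should also bind literature-derived
  associations is ambiguous in the rule wording; this implementation
  exempts literature associations from all count thresholds, documented
  in `filter_habitat_associations()`.
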