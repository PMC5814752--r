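---
title: "Objective chemical-probe assessment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objective chemical-probe assessment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probescore)
```

## The problem

A chemical probe is a small molecule used to interrogate the function of a
protein. Whether a compound deserves that label depends on measurable
properties — how potently it binds the intended target, how selective it is
against everything else it has been tested on, whether it works in cells,
whether its chemical series shows structure-activity relationships (SAR)
and inactive control analogs, and whether its scaffold is prone to assay
artifacts (PAINS). `probescore` turns a table of raw bioactivity
measurements into an objective, reproducible assessment of these
properties: six component scores and a weighted Global Score per
compound–reference-target pair, plus target-level summaries.

## Aggregation model

All activity values convertible to nM (IC50, Ki, Kd, EC50, ...) are placed
on the pActivity scale, $-\log_{10}$ of the molar concentration, so 100 nM
corresponds to pActivity 7. Per compound–target pair we report the median
pActivity over all measurements and its raw median absolute deviation
(MAD, no consistency constant) as a dispersion diagnostic. Choices that
matter:

* **Censored records.** Qualifiers distinguish exact (`=`) from
  greater-than (`>`) measurements. `>` records enter the median at face
  value — the recorded concentration bounds the potency from above, so
  treating it as the potency is conservative. A pair is **conflicting**
  when its `=`-only median says active (pActivity > 5) while at least one
  `>` record reports ≥ 10,000 nM, an explicit claim of inactivity;
  conflicting pairs are classified inactive. The precise conflict rule is
  a package decision: the underlying scoring scheme declares conflicting
  pairs inactive without defining "conflicting".
* **Cap at 10.** Sub-0.1-nM medians are capped at pActivity 10 because
  such values are rare but would dominate the potency normalization. The
  cap applies to the aggregated median, not to individual measurements, so
  the MAD still reflects raw dispersion.
* **Activity threshold.** Active means capped median pActivity strictly
  greater than 5 (better than 10 µM). A median of exactly 5 is inactive.
* **Even-sized sets** use the arithmetic mean of the two central values.

## The six scores

* **Potency** (weight b = 4): linear from 0 at pActivity 5 to 1 at
  pActivity ≥ 10, i.e. $(p - 5)/5$ clamped to $[0,1]$. Only active pairs
  are scored.
* **Selectivity** (weight a = 8): the mean of three factors, forced to 0
  when the compound has no off-target data of any kind. The off-target set
  is every *other* target with any aggregated record for the compound —
  screened against, regardless of outcome — and inactive or conflicting
  off-target pairs contribute their capped medians to the margins
  $\Delta = p_{ref} - p_{off}$.
  * *First factor*: fraction of off-targets with $\Delta \ge 1$
    (10-fold selectivity).
  * *Second factor*: the Selectivity Information Richness
    $SIC = \sum_i (\Delta_i - 1)$ — positive terms reward selective data,
    negative terms penalize unselective data — divided by the number of
    co-modulated proteins (unselective off-targets plus the reference),
    then min–max normalized within each reference target's cohort of
    scored compounds. Per-target normalization matters because broadly
    profiled families (e.g. kinases) have very different SIC ranges from
    sparsely profiled ones. Degenerate cohorts (singleton or all equal)
    normalize to 0: no compound earns selectivity credit the data cannot
    support.
  * *Third factor*: screened breadth, $(n_{off}+1)/n_{liganded}$, clamped
    at 1. The liganded-target count defaults to the number of targets with
    at least one active compound in the loaded dataset and is
    configurable (a public-database-scale analysis would use a value near
    2,220).
* **Cell** (c = 2): 1 if the compound's median activity in *any* cell
  line beats 10 µM (strictly), independent of target; untested compounds
  get 0. The 10 µM cut-off limits credit for non-specific toxicity.
* **SAR** (d = 1): 1 if another compound with the identical level-1
  scaffold is active on the reference target and shares a publication
  (PubMed id) with the query compound's records on that target.
* **Inactive analog** (e = 1): 1 if a same-scaffold compound is reported
  inactive (median pActivity < 5, or conflicting) on the reference target.
  Unlike SAR there is no same-publication restriction — none is stated for
  this score — and we surface that asymmetry rather than harmonize it.
* **PAINS** (f = 1): 0 if the structure matches any pattern of the
  published pan-assay-interference families A/B/C, 1 otherwise.

The **Global Score** is the weighted mean with defaults
$a{=}8, b{=}4, c{=}2, d{=}e{=}f{=}1$ (selectivity twice potency, potency
twice cell activity, and so on); it is invariant under uniform rescaling
of the weights, and setting a weight to 0 removes that factor (e.g.
`probe_weights(f = 0)` neutralizes PAINS, yielding rankings identical to
forcing every PAINS score to 1). Rankings are descending by the chosen
key with ascending compound id as the tie-break, so outputs are
bit-reproducible.

## Structure handling

R has no installed cheminformatics toolkit, so scaffolds and PAINS matching
are delegated to RDKit via a bundled Python helper
(`inst/python/chem_backend.py`), called once per batch of unique SMILES and
memoised per session. Decisions:

* **Level-1 scaffold.** The scaffold tree is rooted at a single ring
  (level 0); level 1 is the two-ring scaffold obtained by prioritized ring
  removal from the Murcko framework, and frameworks with ≤ 2 rings are
  their own level-1 scaffold. The scheme we score never defines the level
  numbering, so this convention is recorded here. The removal
  prioritization implements the core of the published rule set
  (3-membered heterocycles removed first; macrocycles of ≥ 12 atoms
  retained while smaller rings can go; parents with fewer acyclic linker
  bonds preferred; heteroatom-poor rings removed before heteroatom-rich
  ones) with residual ties broken by canonical-SMILES order — determinism
  over fidelity to unstated intent. The bridged/spiro special cases of the
  full published rule set are not implemented; none of the bundled
  fixtures reach them.
* **PAINS patterns** default to RDKit's built-in copy of the published
  filter families rather than a file bundled here; a plain-text SMARTS
  file can be supplied to replace them (`pains_smarts` argument,
  `--pains-file` flag).
* **Degenerate structures.** Salts/mixtures reduce to the largest covalent
  fragment. An unparseable SMILES gets PAINS score 1 — no alert is
  observable — and an empty scaffold (excluded from analog matching), with
  a warning. A dataset with *no* structures at all runs in degraded mode:
  SAR, inactive-analog and PAINS are emitted as 0 with a warning, so a
  structure-free run under-reports rather than fails.

## Target-level summaries

* **Information Richness** of a target: over the compounds *active*
  against it, the total number of targets each compound was tested
  against (equivalently: number of active compounds plus the number of
  other targets each was screened against; the two formulations are
  arithmetically identical and tested as such). The headline definition
  collects active compounds; a screened-compound variant appears in some
  descriptions, and we follow the active-compound reading.
  The percentile anchors the maximum at 100 and the minimum at 0
  (strictly-smaller-count rank interpolation); an all-equal cohort maps to
  0 everywhere and a singleton to 100.
* **Icons.** Seven per-target booleans, each true when ≥ 1 compound meets
  the criterion: selectivity (≥ 1 off-target screened and 10-fold
  selectivity against *at least one*), potency (≥ 100 nM, i.e. pActivity
  ≥ 7), cell (< 10 µM in a cell line), minimum standard, SAR, inactive
  analog, and non-PAINS. Note the selectivity icon's *any*-off-target
  reading versus the minimum standard's *all*-off-targets reading below —
  the two sources genuinely differ, and both semantics are kept where each
  is specified.
* **Minimum standard**: median pActivity ≥ 7 *and* cell score 1 *and* ≥ 1
  screened off-target *and* 10-fold selectivity against **all** screened
  off-targets. One text variant states the potency condition as
  "pActivity ≤ 7"; that contradicts both the icon table ("pActivity ≥ 7")
  and the 100-nM-or-better narrative, so ≥ 7 is implemented (an erratum
  reading).
* **Danger flag**: per-pair, true when at least one screened off-target
  fails 10-fold selectivity. Absence of data is not flagged — the flag
  reports observed failure, not ignorance. A minimum-standard pair can
  never carry the flag.
* **Proteome summary**: counts of liganded / potent / potent-and-selective
  / minimum-standard targets (nested by construction) with fractions over
  a configurable proteome size (default 20,171, a curated human-proteome
  count that changes over time and is therefore never hard-coded).

## The synthetic landscape generator

`landscape_spec()` + `generate_landscape()` produce deterministic raw
measurement tables for testing. The generator emulates exactly the
features the scores depend on: heterogeneous per-compound panels
(1 + Poisson(2) targets), pActivity draws spanning clearly-inactive to
capped (uniform on [3.5, 10.5]), replicate noise (sd 0.15 pActivity
units, 1 + Poisson(0.4) replicates), 10% censored `>` records, 30% of
compounds with a cell-line record, and structures built by decorating a
small PAINS-free scaffold library so scaffold equivalence classes are
known by construction. Values are drawn in pActivity space and emitted in
nM, so medians round-trip exactly; one seeded RNG stream per artifact
(panels, activities, structures) keeps perturbations local to the field
changed. These defaults were chosen once as a plausible small slice of
public medicinal-chemistry data and are not tuned to test outcomes.

A *planted probe* is constructed to dominate strictly: capped potency on
its reference target, the full off-target panel at margins wider than any
random compound can reach (the generator clamps random draws, so
dominance is structural, not probabilistic), cell activity at 1 µM, a
same-publication active analog and an inactive analog. Planted probes
therefore satisfy the minimum standard and rank first under default
weights by construction — which is what makes them a usable end-to-end
oracle.

What a green test does **not** establish: the generator does not mimic
real databases' marginal distributions, annotation errors (cell EC50s
recorded as biochemical IC50s, mutant/wild-type confusions), panel
correlation structure within target families, or publication-level
biases. Results on synthetic landscapes validate the arithmetic and the
pipeline plumbing, not database-scale scientific claims; the headline
counts of any particular public-database snapshot are out of scope here.

## Numerical and boundary choices

* pActivity uses log base 10 (100 nM ↔ 7 fixes the base).
* Boundary cases are strict where the prose says strict: pActivity exactly
  5 is inactive; a cell median of exactly 10,000 nM scores 0; an off-target
  margin of exactly 1 log unit *is* selective (≥ 1).
* `(n_{off}+1)/n_{liganded}` is clamped at 1 so the selectivity score stays
  in $[0,1]$ when a compound has been screened against the entire liganded
  set.
* The combined selectivity equation is read as the mean of the three
  factors (the flattened typesetting is ambiguous; the accompanying prose
  — the factors are added and the result normalized — supports the mean),
  and the second factor's "+1" is part of the denominator (the prose
  "plus the target of interest" names the co-modulated set being counted).
* Ingestion never silently drops data: every malformed row lands in a
  rejects table with a reason.

## Limitations

* SAR/inactive-analog detection is only as good as the level-1 scaffold
  convention; the simplified ring-removal prioritization can differ from
  the full published rule set on bridged or spiro polycyclics.
* The PAINS score is a single substructure method, by design.
* Commercial availability is treated as an optional pass-through
  annotation, not a score, and no external database ingestion is included.
* With `>`-only pairs the median is an optimistic bound on potency; the
  qualifier composition columns (`has_equal`, `has_greater`) let users
  audit such pairs.
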