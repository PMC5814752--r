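# probescore

Objective, reproducible fitness assessment of chemical probes from raw
compound–target bioactivity data.

Chemical biology depends on small-molecule probes whose potency,
selectivity and cell activity are actually supported by data — yet weak or
promiscuous historical compounds remain in wide use. `probescore` is for
chemical biologists and cheminformaticians who want a transparent,
data-driven ranking of candidate probes per protein target instead of
anecdote: it aggregates raw measurements, scores six fitness factors per
compound–target pair, combines them into a customizable Global Score, and
summarizes probe quality per target.

## The model

All activities convertible to nM are placed on the pActivity scale
(−log10 molar; 100 nM ↔ 7). Per compound–target pair the median pActivity
(capped at 10) and its MAD are computed, distinguishing `=` from censored
`>` records; pairs with conflicting `=`/`>` evidence are inactive, and
*active* means median pActivity > 5. Each active pair then receives:

* **Potency** = (pActivity − 5)/5, clamped to [0, 1]
* **Selectivity** = (First + Second<sub>norm</sub> + Third)/3, where
  First = (# 10-fold-selective off-targets)/(# off-targets),
  SIC = Σᵢ (p_ref − p_off,i − 1),
  Second = SIC/(# unselective off-targets + 1) min–max normalized per
  target, Third = (# off-targets + 1)/(# liganded targets); 0 with no
  off-target data
* **Cell** ∈ {0,1}: active below 10 µM in ≥ 1 cell line
* **SAR** ∈ {0,1}: a same-level-1-scaffold, same-publication analog active
  on the target
* **Inactive analog** ∈ {0,1}: a same-scaffold analog inactive on the
  target
* **PAINS** ∈ {0,1}: 0 on any pan-assay-interference alert

**GlobalScore** = (a·Sel + b·Pot + c·Cell + d·SAR + e·IA + f·PAINS)/(a+…+f),
defaults a=8, b=4, c=2, d=e=f=1. Target-level outputs include seven quality
icons, minimum-standard probe counts (pActivity ≥ 7, cell-active, 10-fold
selective vs *all* screened off-targets), Information Richness with
percentile, and liganded-proteome summaries.

Structure operations (level-1 scaffold-tree scaffolds, PAINS) are
delegated to RDKit through a bundled Python helper; `python` with `rdkit`
must be on the PATH (or set `options(probescore.python = ...)`).

## Worked example

```r
library(probescore)

toy <- worked_toy_target("five_compound_kinase")   # 5 compounds x 4 kinases
tf <- tempfile(fileext = ".tsv")
data.table::fwrite(toy$measurements, tf, sep = "\t")

m   <- parse_bioactivity_table(tf)
res <- score_dataset(m)
res$scores[target_accession == "KIN1",
           .(compound_id, median_pactivity, potency, selectivity, cell,
             sar, inactive_analog, pains, global, rank, danger_flag)]
#>    compound_id median_pactivity potency selectivity  cell   sar
#>         <char>            <num>   <num>       <num> <int> <int>
#> 1:          C1                8     0.6   1.0000000     1     1
#> 2:          C2                7     0.4   0.2222222     0     1
#>    inactive_analog pains    global  rank danger_flag
#>              <int> <int>     <num> <int>      <lgcl>
#> 1:               1     1 0.9058824     1       FALSE
#> 2:               1     1 0.3751634     2        TRUE
```

C1 (10 nM on KIN1, fully 10-fold selective over its two off-targets,
active in cells, with a same-publication analog and an inactive analog,
no PAINS alert) scores 0.906 and ranks first; C2 is equipotent on an
off-target (Δ = 0), so its selectivity collapses to the breadth terms, it
carries the red-triangle danger flag, and it ranks second at 0.375.

```r
assess_targets(res$scores, res$aggregates)[
  , .(target_accession, potency, cell, minimum_standard,
      n_minimum_standard_compounds, information_richness_percentile)]
#>    target_accession potency   cell minimum_standard
#>              <char>  <lgcl> <lgcl>           <lgcl>
#> 1:             KIN1    TRUE   TRUE             TRUE
#> 2:             KIN2    TRUE   TRUE             TRUE
#> 3:             KIN3    TRUE  FALSE            FALSE
#> 4:             KIN4   FALSE  FALSE            FALSE
#>    n_minimum_standard_compounds information_richness_percentile
#>                           <int>                           <num>
#> 1:                            1                        66.66667
#> 2:                            1                       100.00000
#> 3:                            0                        33.33333
#> 4:                            0                         0.00000
```

KIN1 and KIN2 each have one compound meeting the minimum probe standard;
KIN3's only active compound is a PAINS hit with no cell data, so the
target has data but no credible probe.

Synthetic benchmarks with a known answer:

```r
spec <- landscape_spec(n_targets = 20, n_compounds = 200, seed = 7,
                       planted_probes = list(list(compound_id = "PROBE1",
                                                  target = "T005")))
ls <- generate_landscape(spec)      # deterministic; planted probe must rank #1
```

## Command line

```sh
probescore score --input measurements.tsv --out run/ --weights f=0
probescore probe-card --run run/ --compound C1 --target KIN1
probescore simulate --out landscape/ --seed 3 --planted PROBE1:T001
probescore summarize --run run/
```

(`exec/probescore` is installed with the package; equivalently
`Rscript -e 'probescore::probescore_cli()' score --input ...`.)

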