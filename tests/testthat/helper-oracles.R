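# Independent brute-force oracles and small fixture builders. The oracles
# deliberately share no code with the package implementation paths they
# check.

# sort-based median: mean of the two central values for even sizes
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_mad <- function(x) {
  oracle_median(abs(x - oracle_median(x)))
}

# per-off-target summation, one term at a time
oracle_sic <- function(profile, reference) {
  total <- 0
  for (nm in names(profile)) {
    if (nm == reference) next
    total <- total + (profile[[reference]] - profile[[nm]] - 1)
  }
  total
}

# Information Richness by the "compounds plus other targets" decomposition
oracle_ir_decomposed <- function(aggregates, target) {
  agg <- data.table::as.data.table(aggregates)
  actives <- agg[target_accession == target & active == TRUE, compound_id]
  n_other <- vapply(actives, function(cid) {
    length(unique(agg[compound_id == cid, target_accession])) - 1L
  }, 1L)
  length(actives) + sum(n_other)
}

# one raw measurement row in the ingest dialect
raw_row <- function(compound_id, target, value_nM, qualifier = "=",
                    units = "nM", kind = "biochemical",
                    cell_line = NA_character_, pubmed = NA_character_,
                    smiles = NA_character_) {
  data.table::data.table(
    compound_id = compound_id,
    target_accession = if (kind == "cell") NA_character_ else target,
    assay_kind = kind, cell_line_id = cell_line, qualifier = qualifier,
    value = value_nM, units = units, activity_type = "IC50",
    pubmed_id = pubmed, smiles = smiles
  )
}

# write a raw table and parse it back through the real ingest path
ingest_rows <- function(...) {
  tab <- data.table::rbindlist(list(...), use.names = TRUE, fill = TRUE)
  tf <- withr::local_tempfile(fileext = ".tsv",
                              .local_envir = parent.frame())
  data.table::fwrite(tab, tf, sep = "\t")
  suppressMessages(parse_bioactivity_table(tf))
}

# random per-target median-pActivity profile for oracle tests
random_profile <- function(n_targets) {
  stats::setNames(stats::runif(n_targets, 3, 10.5),
                  paste0("T", seq_len(n_targets)))
}
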