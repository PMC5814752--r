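# Deterministic synthetic bioactivity landscapes.
#
# The generator emulates the qualitative structure of public
# medicinal-chemistry data that the scores depend on: heterogeneous
# per-compound target panels, replicate measurements with noise, pActivity
# draws spanning clearly-inactive (<5) to capped (>10), a fraction of
# censored '>' records, sparse cell-line testing, and compounds built by
# decorating a small scaffold library so scaffold equivalence classes are
# known by construction. It makes no attempt to mimic real databases'
# marginal distributions beyond these features.
#
# Determinism: one seeded RNG stream per artifact (panel assignment,
# activities, structures), so changing one spec field perturbs only its own
# draws; identical spec + seed gives byte-identical output.

.default_scaffold_library <- c(
  biphenyl      = "c1ccc(-c2ccccc2)cc1",
  naphthalene   = "c1ccc2ccccc2c1",
  quinoline     = "c1ccc2ncccc2c1",
  benzene       = "c1ccccc1",
  phenylpiperidine = "c1ccc(CN2CCCCC2)cc1",
  phenylpyrimidine = "c1ccc(-c2ncccn2)cc1"
)

# substituents that are valid SMILES prefixes of an aromatic-carbon-first core
.default_substituents <- c("", "C", "CC", "CCC", "CO", "CCO", "N", "O",
                           "Cl", "F", "Br", "CN", "FC(F)(F)", "CC(=O)")

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic bioactivity landscape
#'
#' Collects the generator parameters with defaults chosen to resemble a
#' small slice of public bioactivity data: 20 targets x 200 compounds,
#' panel sizes of 1 + Poisson(2) targets per compound, uniform pActivity
#' draws on [3.5, 10.5] (spanning inactive to capped), replicate noise of
#' 0.15 pActivity units, 10\% censored '>' records and 30\% of compounds
#' tested in a cell line.
#'
#' @param n_targets,n_compounds landscape dimensions.
#' @param panel_lambda Poisson rate; each compound is tested against
#'   \code{1 + Poisson(panel_lambda)} targets (capped at \code{n_targets}).
#' @param activity_range pActivity range of the uniform true-activity draw.
#' @param replicate_lambda replicate count per pair is
#'   \code{1 + Poisson(replicate_lambda)}.
#' @param replicate_sd replicate noise (pActivity units); replicate draws
#'   are clamped to \code{activity_range} widened by 0.5 on each side.
#' @param censored_fraction per-record probability of a '>' qualifier.
#' @param cell_tested_fraction fraction of compounds with a cell-line
#'   record.
#' @param scaffold_library named character vector of core SMILES (first atom
#'   aromatic carbon so substituent prefixes stay valid).
#' @param substituents decoration prefixes defining analogs within a
#'   scaffold class.
#' @param planted_probes list of \code{list(compound_id=, target=)} entries;
#'   each plants a compound constructed to dominate every fitness factor on
#'   its target (full panel, capped potency, maximal selectivity margins,
#'   cell activity, one same-publication active analog, one inactive
#'   analog), plus the two analog compounds. Planted probes satisfy the
#'   minimum standard by construction.
#' @param seed integer seed.
#' @return a \code{landscape_spec} list.
#' @export
landscape_spec <- function(n_targets = 20, n_compounds = 200,
                           panel_lambda = 2, activity_range = c(3.5, 10.5),
                           replicate_lambda = 0.4, replicate_sd = 0.15,
                           censored_fraction = 0.1,
                           cell_tested_fraction = 0.3,
                           scaffold_library = .default_scaffold_library,
                           substituents = .default_substituents,
                           planted_probes = list(), seed = 1) {
  spec <- list(n_targets = as.integer(n_targets),
               n_compounds = as.integer(n_compounds),
               panel_lambda = panel_lambda, activity_range = activity_range,
               replicate_lambda = replicate_lambda,
               replicate_sd = replicate_sd,
               censored_fraction = censored_fraction,
               cell_tested_fraction = cell_tested_fraction,
               scaffold_library = scaffold_library,
               substituents = substituents,
               planted_probes = planted_probes, seed = as.integer(seed))
  class(spec) <- "landscape_spec"
  validate_landscape_spec(spec)
  spec
}

#' @rdname landscape_spec
#' @param spec a \code{landscape_spec}.
#' @export
validate_landscape_spec <- function(spec) {
  stopifnot(spec$n_targets >= 1, spec$n_compounds >= 1,
            length(spec$activity_range) == 2,
            diff(spec$activity_range) > 0,
            spec$censored_fraction >= 0, spec$censored_fraction <= 1,
            spec$cell_tested_fraction >= 0, spec$cell_tested_fraction <= 1,
            length(spec$scaffold_library) >= 1)
  targets <- .landscape_targets(spec)
  for (pp in spec$planted_probes) {
    if (is.null(pp$compound_id) || is.null(pp$target)) {
      stop("planted probe entries need compound_id and target")
    }
    if (!(pp$target %in% targets)) {
      stop("planted probe on unknown target: ", pp$target)
    }
    if (spec$n_targets < 2) {
      stop("a planted probe needs at least 2 targets (off-target data)")
    }
  }
  invisible(spec)
}

.landscape_targets <- function(spec) sprintf("T%03d", seq_len(spec$n_targets))

#' Generate a synthetic bioactivity landscape
#'
#' Draws a full raw measurement table (in the ingest dialect, values emitted
#' in nM so they round-trip exactly through \code{\link{compute_pactivity}}),
#' a SMILES table, and a truth record: per-pair emitted median pActivities
#' (capped), qualifier composition, and the planted-probe register.
#'
#' @param spec a \code{\link{landscape_spec}}.
#' @return list with \code{measurements} (raw table: compound_id,
#'   target_accession, assay_kind, cell_line_id, qualifier, value, units,
#'   activity_type, pubmed_id, smiles), \code{smiles}
#'   (compound_id, smiles, scaffold class), and \code{truth}
#'   (list: \code{pair_medians}, \code{planted}).
#' @export
generate_landscape <- function(spec) {
  validate_landscape_spec(spec)
  targets <- .landscape_targets(spec)
  compounds <- sprintf("CPD%04d", seq_len(spec$n_compounds))
  lo <- spec$activity_range[1]; hi <- spec$activity_range[2]

  # stream 1: panel assignment
  panels <- .with_seed(spec$seed, {
    lapply(seq_len(spec$n_compounds), function(i) {
      k <- min(spec$n_targets, 1L + stats::rpois(1L, spec$panel_lambda))
      sort(sample(targets, k))
    })
  })

  # stream 2: activities, replicates, qualifiers, publications, cell assays
  meas <- .with_seed(spec$seed + 1L, {
    rows <- vector("list", spec$n_compounds)
    for (i in seq_len(spec$n_compounds)) {
      pan <- panels[[i]]
      true_p <- stats::runif(length(pan), lo, hi)
      reps <- 1L + stats::rpois(length(pan), spec$replicate_lambda)
      pact <- unlist(lapply(seq_along(pan), function(j) {
        pmin(hi + 0.5, pmax(lo - 0.5,
          true_p[j] + stats::rnorm(reps[j], 0, spec$replicate_sd)))
      }))
      tgt <- rep(pan, reps)
      qual <- ifelse(stats::runif(length(pact)) < spec$censored_fraction,
                     ">", "=")
      pm <- paste0("PMID", match(tgt, targets) * 100L +
                     sample(3L, length(tgt), replace = TRUE))
      rows[[i]] <- data.table::data.table(
        compound_id = compounds[i], target_accession = tgt,
        assay_kind = "biochemical", cell_line_id = NA_character_,
        qualifier = qual, value = 10^(9 - pact), units = "nM",
        activity_type = "IC50", pubmed_id = pm
      )
    }
    bio <- data.table::rbindlist(rows)
    in_cells <- stats::runif(spec$n_compounds) < spec$cell_tested_fraction
    cell <- if (any(in_cells)) {
      cp <- stats::runif(sum(in_cells), lo, hi)
      data.table::data.table(
        compound_id = compounds[in_cells], target_accession = NA_character_,
        assay_kind = "cell",
        cell_line_id = sprintf("CL%02d", sample(5L, sum(in_cells), TRUE)),
        qualifier = "=", value = 10^(9 - cp), units = "nM",
        activity_type = "EC50", pubmed_id = NA_character_
      )
    } else NULL
    data.table::rbindlist(list(bio, cell), use.names = TRUE)
  })

  # stream 3: structures
  structures <- .with_seed(spec$seed + 2L, {
    sc <- sample(length(spec$scaffold_library), spec$n_compounds, TRUE)
    su <- sample(spec$substituents, spec$n_compounds, TRUE)
    data.table::data.table(
      compound_id = compounds,
      smiles = paste0(su, unname(spec$scaffold_library[sc])),
      scaffold_class = names(spec$scaffold_library)[sc]
    )
  })

  # planted probes: strict dominance on every fitness factor by construction
  planted_rows <- list(); planted_struct <- list()
  for (k in seq_along(spec$planted_probes)) {
    pp <- spec$planted_probes[[k]]
    ref <- pp$target
    off <- setdiff(targets, ref)
    core <- unname(spec$scaffold_library[1L])
    pmid <- paste0("PMIDPP", k)
    planted_rows[[k]] <- data.table::rbindlist(list(
      data.table::data.table(    # capped potency on the reference target
        compound_id = pp$compound_id, target_accession = ref,
        assay_kind = "biochemical", cell_line_id = NA_character_,
        qualifier = "=", value = 10^(9 - (hi)), units = "nM",
        activity_type = "IC50", pubmed_id = pmid),
      data.table::data.table(    # full off-target panel, maximal margins
        compound_id = pp$compound_id, target_accession = off,
        assay_kind = "biochemical", cell_line_id = NA_character_,
        qualifier = "=", value = 10^(9 - (lo - 1)), units = "nM",
        activity_type = "IC50", pubmed_id = pmid),
      data.table::data.table(    # cell activity at 1 uM
        compound_id = pp$compound_id, target_accession = NA_character_,
        assay_kind = "cell", cell_line_id = "CL_PP",
        qualifier = "=", value = 1000, units = "nM",
        activity_type = "EC50", pubmed_id = NA_character_),
      data.table::data.table(    # same-publication active analog (SAR = 1)
        compound_id = paste0(pp$compound_id, "_SAR"), target_accession = ref,
        assay_kind = "biochemical", cell_line_id = NA_character_,
        qualifier = "=", value = 10^(9 - 7.5), units = "nM",
        activity_type = "IC50", pubmed_id = pmid),
      data.table::data.table(    # inactive analog (IA = 1)
        compound_id = paste0(pp$compound_id, "_IA"), target_accession = ref,
        assay_kind = "biochemical", cell_line_id = NA_character_,
        qualifier = "=", value = 10^(9 - 4), units = "nM",
        activity_type = "IC50", pubmed_id = pmid)
    ))
    planted_struct[[k]] <- data.table::data.table(
      compound_id = c(pp$compound_id, paste0(pp$compound_id, "_SAR"),
                      paste0(pp$compound_id, "_IA")),
      smiles = paste0(c("", "C", "CC"), core),
      scaffold_class = names(spec$scaffold_library)[1L]
    )
  }
  if (length(planted_rows)) {
    meas <- data.table::rbindlist(c(list(meas), planted_rows),
                                  use.names = TRUE)
    structures <- data.table::rbindlist(c(list(structures), planted_struct),
                                        use.names = TRUE)
  }
  meas[, smiles := structures$smiles[match(compound_id, structures$compound_id)]]

  bio <- meas[assay_kind == "biochemical"]
  truth_pairs <- bio[, .(
    true_median_pactivity = min(10, stats::median(9 - log10(value))),
    uncensored = all(qualifier == "=")
  ), by = .(compound_id, target_accession)]

  list(
    measurements = meas[],
    smiles = structures[],
    truth = list(
      pair_medians = truth_pairs[],
      planted = lapply(spec$planted_probes, function(pp) {
        list(compound_id = pp$compound_id, target = pp$target,
             expected_scores = list(potency = 1, selectivity = 1, cell = 1,
                                    sar = 1, inactive_analog = 1, pains = 1),
             expected_rank = 1L, minimum_standard = TRUE)
      }),
      spec = spec
    )
  )
}

#' Write a generated landscape to disk
#'
#' @param landscape result of \code{\link{generate_landscape}}.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(measurements = file.path(dir, "measurements.tsv"),
             smiles = file.path(dir, "compounds.smi"),
             truth = file.path(dir, "truth.json"))
  data.table::fwrite(landscape$measurements, paths[["measurements"]],
                     sep = "\t")
  writeLines(paste(landscape$smiles$smiles, landscape$smiles$compound_id,
                   sep = "\t"), paths[["smiles"]])
  jsonlite::write_json(
    list(pair_medians = landscape$truth$pair_medians,
         planted = landscape$truth$planted,
         seed = landscape$truth$spec$seed),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# ---------------------------------------------------------------------------
# Hand-written worked fixtures: the package's primary regression surface.
# Every expectation below was computed by hand on the stated rules (and is
# re-derived independently in the test suite's oracle helpers).

.toy_measurement <- function(compound_id, target, value_nM, qualifier = "=",
                             pubmed = NA_character_, kind = "biochemical",
                             cell_line = NA_character_) {
  data.table::data.table(
    compound_id = compound_id,
    target_accession = if (kind == "cell") NA_character_ else target,
    assay_kind = kind, cell_line_id = cell_line, qualifier = qualifier,
    value = value_nM, units = "nM", activity_type = "IC50",
    pubmed_id = pubmed
  )
}

.toy_registry <- function() {
  list(
    five_compound_kinase = function() {
      m <- data.table::rbindlist(list(
        .toy_measurement("C1", "KIN1", 10, pubmed = "P1"),
        .toy_measurement("C1", "KIN2", 1000, pubmed = "P1"),
        .toy_measurement("C1", "KIN3", 10000, pubmed = "P1"),
        .toy_measurement("C1", NA, 1000, kind = "cell", cell_line = "CLA"),
        .toy_measurement("C2", "KIN1", 100, pubmed = "P1"),
        .toy_measurement("C2", "KIN2", 100, pubmed = "P2"),
        .toy_measurement("C3", "KIN1", 50000, pubmed = "P2"),
        .toy_measurement("C4", "KIN2", 10, pubmed = "P3"),
        .toy_measurement("C4", "KIN4", 10000, pubmed = "P3"),
        .toy_measurement("C4", NA, 500, kind = "cell", cell_line = "CLB"),
        .toy_measurement("C5", "KIN3", 100, pubmed = "P4")
      ))
      smi <- data.table::data.table(
        compound_id = c("C1", "C2", "C3", "C4", "C5"),
        smiles = c("c1ccc(-c2ccccc2)cc1", "Cc1ccc(-c2ccccc2)cc1",
                   "CCc1ccc(-c2ccccc2)cc1", "c1ccc2ccccc2c1", "Oc1ccccc1O")
      )
      m[, smiles := smi$smiles[match(compound_id, smi$compound_id)]]
      # hand-computed expectations under default weights,
      # liganded count = 3 (KIN1, KIN2, KIN3)
      expected <- data.table::data.table(
        compound_id = c("C1", "C2", "C1", "C2", "C4", "C5"),
        target_accession = c("KIN1", "KIN1", "KIN2", "KIN2", "KIN2", "KIN3"),
        median_pactivity = c(8, 7, 6, 7, 8, 7),
        potency = c(0.6, 0.4, 0.2, 0.4, 0.6, 0.4),
        first_factor = c(1, 0, 0.5, 0, 1, 0),
        sic = c(3, -1, -3, -1, 2, 0),
        second_factor_raw = c(3, -0.5, -1.5, -0.5, 2, 0),
        second_factor_norm = c(1, 0, 0, 1 / 3.5, 1, 0),
        third_factor = c(1, 2 / 3, 1, 2 / 3, 2 / 3, 1 / 3),
        selectivity = c(1, 2 / 9, 0.5, (1 / 3.5 + 2 / 3) / 3,
                        (1 + 1 + 2 / 3) / 3, 0),
        cell = c(1L, 0L, 1L, 0L, 1L, 0L),
        sar = c(1L, 1L, 0L, 0L, 0L, 0L),
        inactive_analog = c(1L, 1L, 0L, 0L, 0L, 0L),
        pains = c(1L, 1L, 1L, 1L, 1L, 0L),
        danger_flag = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE),
        minimum_standard = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
        rank = c(1L, 2L, 2L, 3L, 1L, 1L)
      )
      expected[, global := (8 * selectivity + 4 * potency + 2 * cell +
                              sar + inactive_analog + pains) / 17]
      list(
        measurements = m[], smiles = smi,
        expected = list(
          scores = expected[],
          liganded_target_count = 3L,
          information_richness = c(KIN1 = 5L, KIN2 = 7L, KIN3 = 1L, KIN4 = 0L),
          ir_percentile = c(KIN1 = 200 / 3, KIN2 = 100, KIN3 = 100 / 3,
                            KIN4 = 0),
          proteome = list(liganded = 3L, potent = 3L, potent_selective = 2L,
                          minimum_standard = 2L)
        )
      )
    },
    conflict_cases = function() {
      m <- data.table::rbindlist(list(
        .toy_measurement("K1", "T1", 10),                     # '=' 10 nM
        .toy_measurement("K1", "T1", 10000, qualifier = ">"), # conflict
        .toy_measurement("K2", "T1", 10),
        .toy_measurement("K2", "T1", 100, qualifier = ">"),   # weak '>': ok
        .toy_measurement("K3", "T1", 50000),                  # '=' inactive
        .toy_measurement("K3", "T1", 10000, qualifier = ">"), # no conflict
        .toy_measurement("K4", "T1", 1, qualifier = ">"),     # '>' only
        .toy_measurement("K5", "T1", 10000)                   # boundary p=5
      ))
      list(
        measurements = m[], smiles = NULL,
        expected = list(aggregates = data.table::data.table(
          compound_id = c("K1", "K2", "K3", "K4", "K5"),
          median_pactivity = c(6.5, 7.5, (compute_pactivity(50000) + 5) / 2,
                               9, 5),
          conflicting = c(TRUE, FALSE, FALSE, FALSE, FALSE),
          active = c(FALSE, TRUE, FALSE, TRUE, FALSE)
        ))
      )
    },
    no_offtarget = function() {
      m <- .toy_measurement("C1", "T1", 10)
      list(measurements = m, smiles = NULL,
           expected = list(selectivity = 0, n_off_targets = 0L))
    }
  )
}

#' Bundled hand-written worked fixtures
#'
#' Small fixtures with hand-computed expected outputs for every operation;
#' the package's primary regression surface. Available names:
#' \code{"five_compound_kinase"} (5 compounds x 4 targets with full expected
#' score vectors), \code{"conflict_cases"} (every '='/'>' conflict branch),
#' \code{"no_offtarget"} (the selectivity-0 path).
#'
#' @param name fixture name.
#' @return list with \code{measurements} (raw ingest-dialect table),
#'   \code{smiles} (or NULL), and \code{expected} values.
#' @export
worked_toy_target <- function(name) {
  reg <- .toy_registry()
  if (!name %in% names(reg)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  }
  reg[[name]]()
}
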