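# The six fitness-factor scores, the weighted Global Score, and the scoring
# pipeline that applies them to every active compound-reference-target pair.

#' Global Score weights
#'
#' Non-negative weights of the six component scores in the weighted-mean
#' Global Score. The defaults encode selectivity twice as important as
#' potency, potency twice as important as cell activity, and cell activity
#' twice as important as the SAR, inactive-analog and PAINS scores.
#'
#' @param a selectivity weight (default 8).
#' @param b potency weight (default 4).
#' @param c cell weight (default 2).
#' @param d SAR weight (default 1).
#' @param e inactive-analog weight (default 1).
#' @param f PAINS weight (default 1; set 0 to remove PAINS influence).
#' @return named numeric vector of class \code{probe_weights}.
#' @export
probe_weights <- function(a = 8, b = 4, c = 2, d = 1, e = 1, f = 1) {
  w <- c(a = a, b = b, c = c, d = d, e = e, f = f)
  if (any(!is.finite(w) | w < 0)) stop("weights must be non-negative and finite")
  if (sum(w) == 0) stop("at least one weight must be positive")
  structure(w, class = "probe_weights")
}

#' Potency score of an aggregated pair
#'
#' Linear normalization of the capped median pActivity from 0 (pActivity 5,
#' the 10 uM activity threshold) to 1 (pActivity >= 10, i.e. 0.1 nM or
#' better): \code{(pActivity - 5) / 5}, clamped to [0, 1]. Only active pairs
#' are scored as probes; passing an inactive pair is a contract violation.
#'
#' @param median_pactivity numeric vector of capped median pActivities.
#' @param active logical vector (default TRUE); any FALSE raises an error.
#' @return numeric vector in [0, 1].
#' @export
potency_score <- function(median_pactivity, active = TRUE) {
  if (!all(active)) stop("potency_score is defined for active pairs only")
  pmin(1, pmax(0, (median_pactivity - 5) / 5))
}

#' Cell score of a compound
#'
#' 1 when the compound is active in at least one cell line -- median
#' cell-line pActivity strictly above 5 (10 uM cut-off, chosen to avoid
#' counting non-specific toxicity at high concentration) -- independent of
#' which target it binds; 0 otherwise, including compounds never tested in
#' cells.
#'
#' @param cell_aggregates cell aggregate table for one compound
#'   (\code{\link{aggregate_pairs}} with \code{kind = "cell"}); may have
#'   zero rows.
#' @return integer 0 or 1.
#' @export
cell_score <- function(cell_aggregates) {
  if (is.null(cell_aggregates) || nrow(cell_aggregates) == 0L) return(0L)
  as.integer(any(cell_aggregates$median_pactivity > 5))
}

#' Weighted Global Score
#'
#' Weighted arithmetic mean of the six component scores:
#' \deqn{(a S_{sel} + b S_{pot} + c S_{cell} + d S_{SAR} + e S_{IA} +
#'   f S_{PAINS}) / (a+b+c+d+e+f)}
#' Invariant under uniform rescaling of the weights.
#'
#' @param selectivity,potency,cell,sar,inactive_analog,pains component score
#'   vectors in [0, 1].
#' @param weights a \code{\link{probe_weights}} object.
#' @return numeric vector in [0, 1].
#' @export
global_score <- function(selectivity, potency, cell, sar, inactive_analog,
                         pains, weights = probe_weights()) {
  w <- unclass(weights)
  if (sum(w) == 0) stop("all-zero weights")
  (w[["a"]] * selectivity + w[["b"]] * potency + w[["c"]] * cell +
     w[["d"]] * sar + w[["e"]] * inactive_analog + w[["f"]] * pains) / sum(w)
}

#' Rank scored compounds for one target
#'
#' Orders the scored table of one reference target descending by the chosen
#' key with a deterministic tie-break (ascending compound identifier) and
#' assigns dense 1-based ranks over positions.
#'
#' @param scored scored pair table (see \code{\link{score_dataset}}) --
#'   either already restricted to one target or filtered via \code{target}.
#' @param target optional target accession to filter on.
#' @param order_key one of \code{"global"}, \code{"potency"},
#'   \code{"selectivity"}, \code{"cell"}.
#' @return the ordered table with a \code{rank} column.
#' @export
rank_compounds <- function(scored, target = NULL,
                           order_key = c("global", "potency", "selectivity",
                                         "cell")) {
  order_key <- match.arg(order_key)
  s <- data.table::as.data.table(scored)
  if (!is.null(target)) s <- s[target_accession == target]
  if (nrow(s) == 0L) stop("no scored compounds to rank")
  data.table::setorderv(s, c(order_key, "compound_id"),
                        order = c(-1L, 1L))
  s[, rank := seq_len(.N)]
  s[]
}

#' Score every active compound-reference-target pair
#'
#' The core pipeline: aggregates biochemical and cell measurements, attaches
#' structure properties, computes the six fitness-factor scores with all
#' selectivity intermediates, the Global Score, the per-target rank under
#' \code{order_key}, the danger flag and the minimum-standard call for every
#' active pair (capped median pActivity > 5, not conflicting).
#'
#' When no structure information is available at all, the run degrades
#' gracefully: SAR, inactive-analog and PAINS scores are emitted as 0 with a
#' warning so downstream consumers see the reduced evidence rather than a
#' failure.
#'
#' @param measurements measurement table
#'   (\code{\link{parse_bioactivity_table}} output or equivalent).
#' @param weights \code{\link{probe_weights}}.
#' @param chem optional precomputed \code{\link{chem_properties}} table; by
#'   default computed from the SMILES carried in \code{measurements}.
#' @param liganded_target_count denominator of the third selectivity factor;
#'   default: number of distinct targets with at least one active compound
#'   in this dataset.
#' @param order_key ranking key (see \code{\link{rank_compounds}}).
#' @param pains_smarts optional custom PAINS SMARTS file (see
#'   \code{\link{chem_properties}}).
#' @param python python interpreter for the structure backend.
#' @return list with elements \code{scores} (one row per active pair with
#'   all score components, intermediates, \code{global}, \code{rank},
#'   \code{danger_flag}, \code{minimum_standard}), \code{aggregates},
#'   \code{cell_aggregates}, \code{chem}, \code{rejects},
#'   \code{liganded_target_count}, \code{weights}.
#' @export
score_dataset <- function(measurements, weights = probe_weights(),
                          chem = NULL, liganded_target_count = NULL,
                          order_key = "global", pains_smarts = NULL,
                          python = getOption("probescore.python", "python")) {
  m <- data.table::as.data.table(measurements)
  agg <- aggregate_pairs(m, kind = "biochemical")
  cell_agg <- aggregate_pairs(m, kind = "cell")

  # structure properties (one row per compound)
  if (is.null(chem)) {
    cmp_smiles <- unique(m[!is.na(smiles) & assay_kind == "biochemical",
                           .(compound_id, smiles)])
    cmp_smiles <- cmp_smiles[!duplicated(compound_id)]
    chem <- if (nrow(cmp_smiles)) {
      chem_properties(cmp_smiles$compound_id, cmp_smiles$smiles,
                      python = python, pains_smarts = pains_smarts)
    } else NULL
  } else {
    chem <- data.table::as.data.table(chem)
  }
  degraded <- is.null(chem) || nrow(chem) == 0L
  if (degraded) {
    warning("no structures available: SAR, inactive-analog and PAINS ",
            "scores are emitted as 0")
  }

  if (is.null(liganded_target_count)) {
    liganded_target_count <- max(1L, length(unique(
      agg[active == TRUE, target_accession])))
  }

  scores <- agg[active == TRUE,
                .(compound_id, target_accession, median_pactivity, mad, n)]
  if (nrow(scores) == 0L) {
    scores[, `:=`(potency = numeric(), n_off_targets = integer(),
                  n_selective_off_targets = integer(),
                  n_unselective_off_targets = integer(),
                  first_factor = numeric(), sic = numeric(),
                  second_factor_raw = numeric(),
                  second_factor_norm = numeric(), third_factor = numeric(),
                  selectivity = numeric(), danger_flag = logical(),
                  cell = integer(), sar = integer(),
                  inactive_analog = integer(), pains = integer(),
                  global = numeric(), minimum_standard = logical(),
                  rank = integer())]
    return(list(scores = scores, aggregates = agg, cell_aggregates = cell_agg,
                chem = chem, rejects = ingest_rejects(m),
                liganded_target_count = liganded_target_count,
                weights = weights))
  }

  scores[, potency := potency_score(median_pactivity)]

  # selectivity: expand each active pair against the compound's full profile
  prof <- agg[, .(compound_id, off_target = target_accession,
                  med_off = median_pactivity)]
  ex <- merge(scores[, .(compound_id, target_accession,
                         med_ref = median_pactivity)],
              prof, by = "compound_id", allow.cartesian = TRUE)
  ex <- ex[off_target != target_accession]
  sel <- ex[, {
    delta <- med_ref[1L] - med_off
    .(n_off_targets = .N,
      n_selective_off_targets = sum(delta >= 1),
      sic = sum(delta - 1))
  }, by = .(compound_id, target_accession)]
  scores <- merge(scores, sel, by = c("compound_id", "target_accession"),
                  all.x = TRUE)
  scores[is.na(n_off_targets),
         `:=`(n_off_targets = 0L, n_selective_off_targets = 0L, sic = 0)]
  scores[, n_unselective_off_targets := n_off_targets - n_selective_off_targets]
  scores[, first_factor := ifelse(n_off_targets > 0,
                                  n_selective_off_targets / n_off_targets, 0)]
  scores[, second_factor_raw := second_factor_raw(sic, n_unselective_off_targets)]
  scores[, second_factor_norm := normalize_second_factor(second_factor_raw),
         by = target_accession]
  scores[, third_factor := third_factor(n_off_targets, liganded_target_count)]
  scores[, selectivity := selectivity_score(first_factor, second_factor_norm,
                                            third_factor, n_off_targets)]
  scores[, danger_flag := danger_flag(n_off_targets, n_selective_off_targets)]

  # cell score: per compound, any cell line active below 10 uM
  cell_pos <- unique(cell_agg[median_pactivity > 5, compound_id])
  scores[, cell := as.integer(compound_id %in% cell_pos)]

  # structure-dependent scores
  if (!degraded) {
    analog <- .analog_scores(agg, chem, m)
    scores <- merge(scores, analog, by = c("compound_id", "target_accession"),
                    all.x = TRUE)
    scores[is.na(sar), sar := 0L]
    scores[is.na(inactive_analog), inactive_analog := 0L]
    scores[, pains := chem$pains_score[match(compound_id, chem$compound_id)]]
    scores[is.na(pains), pains := 0L]
  } else {
    scores[, `:=`(sar = 0L, inactive_analog = 0L, pains = 0L)]
  }

  scores[, global := global_score(selectivity, potency, cell, sar,
                                  inactive_analog, pains, weights)]
  scores[, minimum_standard := minimum_standard(
    median_pactivity, cell, n_off_targets, n_selective_off_targets)]
  scores <- scores[, rank_compounds(.SD, order_key = order_key),
                   by = target_accession]
  data.table::setorderv(scores, c("target_accession", "rank"))

  list(scores = scores[], aggregates = agg, cell_aggregates = cell_agg,
       chem = chem, rejects = ingest_rejects(m),
       liganded_target_count = liganded_target_count, weights = weights)
}
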