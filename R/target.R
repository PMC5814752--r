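# Target-level aggregation: Information Richness and its percentile, the
# seven quality icons, minimum-standard probe counting and liganded-proteome
# summary statistics.

#' Minimum-standard call for scored pairs
#'
#' A compound-target pair meets the minimum chemical-probe standard when all
#' of: median pActivity >= 7 (100 nM potency or better), cell score 1
#' (active below 10 uM in at least one cell line), screened against at least
#' one off-target, and 10-fold selective against every off-target screened.
#' Note the all-off-targets reading here, versus the any-off-target reading
#' of the selectivity icon (\code{\link{target_icons}}); the two genuinely
#' differ and both are implemented where each is specified.
#'
#' @param median_pactivity capped median pActivity vector.
#' @param cell cell score vector (0/1).
#' @param n_off_targets,n_selective_off_targets selectivity breakdown
#'   vectors.
#' @return logical vector.
#' @export
minimum_standard <- function(median_pactivity, cell, n_off_targets,
                             n_selective_off_targets) {
  median_pactivity >= 7 & cell == 1 & n_off_targets >= 1 &
    n_selective_off_targets == n_off_targets
}

#' Information Richness of targets
#'
#' For each target: over all compounds active against it, the sum of the
#' number of targets each compound has been tested against (including the
#' reference, regardless of activity level). Equivalently, the number of
#' active compounds plus the number of other targets each was screened
#' against.
#'
#' @param aggregates biochemical aggregate table
#'   (\code{\link{aggregate_pairs}}).
#' @param targets optional character vector restricting/ordering the result;
#'   unknown accessions raise an error.
#' @return data.table with columns \code{target_accession},
#'   \code{information_richness} (0 for targets with no active compound).
#' @export
information_richness <- function(aggregates, targets = NULL) {
  agg <- data.table::as.data.table(aggregates)
  panel <- agg[, .(n_targets_tested = data.table::uniqueN(target_accession)),
               by = compound_id]
  ir <- merge(agg[active == TRUE], panel, by = "compound_id")[
    , .(information_richness = sum(n_targets_tested)), by = target_accession]
  all_t <- data.table::data.table(
    target_accession = unique(agg$target_accession))
  ir <- merge(all_t, ir, by = "target_accession", all.x = TRUE)
  ir[is.na(information_richness), information_richness := 0L]
  if (!is.null(targets)) {
    unknown <- setdiff(targets, ir$target_accession)
    if (length(unknown)) stop("unknown target(s): ",
                              paste(unknown, collapse = ", "))
    ir <- ir[match(targets, target_accession)]
  }
  data.table::setorder(ir, target_accession)
  ir[]
}

#' Rank-based percentile of Information Richness values
#'
#' Anchored so the maximum-information target(s) map to 100 and the minimum
#' to 0; ties share a value. Percentile of value v is
#' \code{100 * (number of strictly smaller values) / (n - 1)}. Degenerate
#' cases: a single target scores 100 (it is the highest-information target);
#' an all-equal cohort scores 0 everywhere (no target can claim
#' above-average information).
#'
#' @param ir_values numeric vector of Information Richness values.
#' @return numeric vector in [0, 100], parallel to the input.
#' @export
information_richness_percentile <- function(ir_values) {
  n <- length(ir_values)
  if (n == 0L) return(numeric())
  if (n == 1L) return(100)
  below <- vapply(ir_values, function(v) sum(ir_values < v), 0)
  100 * below / (n - 1)
}

#' Per-target quality icons and assessment
#'
#' Derives, for every target in a scored dataset, the seven icon booleans,
#' the active and minimum-standard compound counts, and the Information
#' Richness value and percentile.
#'
#' Icon semantics (each TRUE when at least one compound meets the
#' criterion):
#' \itemize{
#'   \item \code{selectivity}: screened against >= 1 other target with
#'     10-fold selectivity against at least one of them (the
#'     any-off-target reading).
#'   \item \code{potency}: binds the target at 100 nM or better
#'     (median pActivity >= 7).
#'   \item \code{cell}: active in a cell line below 10 uM.
#'   \item \code{minimum_standard}: the aggregate standard of
#'     \code{\link{minimum_standard}} (all-off-targets selectivity).
#'   \item \code{sar}, \code{inactive_analog}: the analog-based scores.
#'   \item \code{non_pains}: at least one compound with no PAINS alert.
#' }
#'
#' @param scored scored pair table from \code{\link{score_dataset}}.
#' @param aggregates matching biochemical aggregate table.
#' @return data.table, one row per target, with icon columns,
#'   \code{n_active_compounds}, \code{n_minimum_standard_compounds},
#'   \code{information_richness} and \code{information_richness_percentile}.
#' @export
assess_targets <- function(scored, aggregates) {
  s <- data.table::as.data.table(scored)
  if (nrow(s) == 0L) {
    ir <- information_richness(aggregates)
    ir[, `:=`(selectivity = FALSE, potency = FALSE, cell = FALSE,
              minimum_standard = FALSE, sar = FALSE,
              inactive_analog = FALSE, non_pains = FALSE,
              n_active_compounds = 0L, n_minimum_standard_compounds = 0L)]
    ir[, information_richness_percentile :=
         information_richness_percentile(information_richness)]
    return(ir[])
  }
  icons <- s[, .(
    selectivity = any(n_off_targets >= 1 & n_selective_off_targets >= 1),
    potency = any(median_pactivity >= 7),
    cell = any(cell == 1),
    minimum_standard = any(minimum_standard),
    sar = any(sar == 1),
    inactive_analog = any(inactive_analog == 1),
    non_pains = any(pains == 1),
    n_active_compounds = .N,
    n_minimum_standard_compounds = sum(minimum_standard)
  ), by = target_accession]
  ir <- information_richness(aggregates)
  out <- merge(ir, icons, by = "target_accession", all.x = TRUE)
  bool_cols <- c("selectivity", "potency", "cell", "minimum_standard",
                 "sar", "inactive_analog", "non_pains")
  for (col in bool_cols) out[is.na(get(col)), (col) := FALSE]
  out[is.na(n_active_compounds), n_active_compounds := 0L]
  out[is.na(n_minimum_standard_compounds), n_minimum_standard_compounds := 0L]
  out[, information_richness_percentile :=
        information_richness_percentile(information_richness)]
  data.table::setorder(out, target_accession)
  out[]
}

#' Liganded-proteome summary
#'
#' Counts and proteome fractions of nested target classes: liganded
#' (>= 1 active compound), potently liganded (>= 1 active compound at
#' median pActivity >= 7), potent-and-selective (>= 1 potent compound also
#' 10-fold selective against all >= 1 screened off-targets) and
#' minimum-standard (adds the cell-activity requirement). The classes nest
#' by construction.
#'
#' @param scored scored pair table from \code{\link{score_dataset}}.
#' @param aggregates matching biochemical aggregate table.
#' @param proteome_size reference proteome size for the fractions (default
#'   20171, a curated human proteome count; configurable since such counts
#'   change over time).
#' @return list with per-class counts, fractions, and \code{proteome_size}.
#' @export
proteome_summary <- function(scored, aggregates, proteome_size = 20171) {
  if (proteome_size < 1) stop("proteome_size must be positive")
  agg <- data.table::as.data.table(aggregates)
  s <- data.table::as.data.table(scored)
  liganded <- unique(agg[active == TRUE, target_accession])
  potent <- unique(s[median_pactivity >= 7, target_accession])
  potent_selective <- unique(s[median_pactivity >= 7 & n_off_targets >= 1 &
                                 n_selective_off_targets == n_off_targets,
                               target_accession])
  min_std <- unique(s[minimum_standard == TRUE, target_accession])
  if (proteome_size < length(liganded)) {
    warning("proteome_size is smaller than the liganded target count; ",
            "fractions exceed 1")
  }
  counts <- c(liganded = length(liganded), potent = length(potent),
              potent_selective = length(potent_selective),
              minimum_standard = length(min_std))
  list(
    n_targets_liganded = counts[["liganded"]],
    n_targets_potent = counts[["potent"]],
    n_targets_potent_selective = counts[["potent_selective"]],
    n_targets_minimum_standard = counts[["minimum_standard"]],
    fraction_liganded = counts[["liganded"]] / proteome_size,
    fraction_potent = counts[["potent"]] / proteome_size,
    fraction_potent_selective = counts[["potent_selective"]] / proteome_size,
    fraction_minimum_standard = counts[["minimum_standard"]] / proteome_size,
    n_compounds_minimum_standard = length(unique(
      s[minimum_standard == TRUE, compound_id])),
    proteome_size = proteome_size
  )
}
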