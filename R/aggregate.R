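# Aggregation of raw measurements into per-pair median pActivities.
#
# Censored handling: '=' and '>' records are distinguished. '>' records
# (upper bounds on potency) enter the median at face value -- conservative,
# since the true pActivity is at most the recorded one. A pair is
# "conflicting" when its '='-only evidence classifies it active
# (median pActivity > 5) while at least one '>' record claims >= 10,000 nM,
# an explicit statement of inactivity; conflicting pairs are inactive.
# The cap at 10 (sub-0.1 nM potencies) is applied to the aggregated median,
# not the individual measurements, so MAD reflects raw dispersion.

.INACTIVITY_NM <- 10000       # 10 uM <-> pActivity 5
.PACTIVITY_CAP <- 10          # 0.1 nM

.aggregate_stats <- function(pact, qualifier, value_nM) {
  eq <- qualifier == "="
  med_raw <- stats::median(pact)
  eq_med <- if (any(eq)) stats::median(pact[eq]) else -Inf
  conflicting <- any(eq) && any(!eq) && eq_med > 5 &&
    any(value_nM[!eq] >= .INACTIVITY_NM)
  med <- min(med_raw, .PACTIVITY_CAP)
  list(
    median_pactivity = med,
    mad = compute_mad(pact),
    n = length(pact),
    has_equal = any(eq),
    has_greater = any(!eq),
    conflicting = conflicting,
    active = med > 5 && !conflicting
  )
}

#' Aggregate all measurements of one compound-target pair
#'
#' Computes per-measurement pActivities, their median (capped at 10) and raw
#' MAD, the qualifier composition, the conflict flag and the active call
#' (capped median pActivity > 5 and not conflicting).
#'
#' @param measurements measurement table (see
#'   \code{\link{parse_bioactivity_table}}) whose rows all share one
#'   compound and one target key.
#' @return one-row data.table with columns \code{compound_id},
#'   \code{target_accession}, \code{median_pactivity}, \code{mad}, \code{n},
#'   \code{has_equal}, \code{has_greater}, \code{conflicting}, \code{active}.
#' @export
aggregate_pair <- function(measurements) {
  m <- data.table::as.data.table(measurements)
  if (nrow(m) == 0L) stop("empty measurement collection")
  key_col <- if (all(m$assay_kind == "cell")) "cell_line_id" else "target_accession"
  if (length(unique(m$compound_id)) != 1L ||
      length(unique(m[[key_col]])) != 1L) {
    stop("aggregate_pair requires a single compound-target (or cell) pair")
  }
  s <- .aggregate_stats(m$pactivity, m$qualifier, m$value_nM)
  data.table::data.table(
    compound_id = m$compound_id[1L],
    target_accession = m[[key_col]][1L],
    median_pactivity = s$median_pactivity, mad = s$mad, n = s$n,
    has_equal = s$has_equal, has_greater = s$has_greater,
    conflicting = s$conflicting, active = s$active
  )
}

#' Aggregate a measurement table into per-pair activities
#'
#' Groups biochemical measurements by (compound, target) -- or cell
#' measurements by (compound, cell line) with \code{kind = "cell"} -- and
#' applies \code{\link{aggregate_pair}}'s statistics to every group.
#'
#' @param measurements measurement table.
#' @param kind \code{"biochemical"} (default) or \code{"cell"}.
#' @return data.table with one row per pair, columns as in
#'   \code{\link{aggregate_pair}} (for cell aggregates,
#'   \code{target_accession} is replaced by \code{cell_line_id}).
#' @export
aggregate_pairs <- function(measurements, kind = c("biochemical", "cell")) {
  kind <- match.arg(kind)
  m <- data.table::as.data.table(measurements)[assay_kind == kind]
  key <- if (kind == "cell") "cell_line_id" else "target_accession"
  if (nrow(m) == 0L) {
    out <- data.table::data.table(
      compound_id = character(), .pair_key = character(),
      median_pactivity = numeric(), mad = numeric(), n = integer(),
      has_equal = logical(), has_greater = logical(),
      conflicting = logical(), active = logical()
    )
    data.table::setnames(out, ".pair_key", key)
    return(out)
  }
  out <- m[, .aggregate_stats(pactivity, qualifier, value_nM),
           by = c("compound_id", key)]
  data.table::setorderv(out, c("compound_id", key))
  out[]
}

#' Write the normalized aggregate table
#'
#' TSV export of \code{\link{aggregate_pairs}} output (the documented
#' normalized interchange format).
#'
#' @param aggregates aggregate table.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_aggregate_table <- function(aggregates, path) {
  data.table::fwrite(aggregates, path, sep = "\t")
  invisible(path)
}
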