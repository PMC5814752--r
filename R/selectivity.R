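# The selectivity score and its three factors.
#
# A compound's "off-targets" for a reference target are all other protein
# targets with any aggregated record for that compound -- screened against,
# regardless of outcome -- and their capped median pActivities enter the
# delta computations. An off-target is 10-fold selective when
# pActivity_ref - pActivity_off >= 1.

#' First selectivity factor
#'
#' Fraction of a compound's off-targets that are 10-fold selective
#' (\eqn{\Delta = pActivity_{ref} - pActivity_{off} \ge 1}).
#'
#' @param profile named numeric vector of median pActivities, one entry per
#'   target the compound has aggregated records for (names are accessions).
#' @param reference name of the reference target (must be in
#'   \code{profile}).
#' @return list with \code{first_factor} (0 when there are no off-targets),
#'   \code{n_off_targets}, \code{n_selective_off_targets}.
#' @export
first_factor <- function(profile, reference) {
  stopifnot(reference %in% names(profile))
  off <- profile[setdiff(names(profile), reference)]
  delta <- unname(profile[[reference]] - off)
  n_sel <- sum(delta >= 1)
  list(
    first_factor = if (length(off)) n_sel / length(off) else 0,
    n_off_targets = length(off),
    n_selective_off_targets = n_sel
  )
}

#' Selectivity Information Richness (SIC)
#'
#' Sum over all off-targets of
#' \eqn{pActivity_{ref} - pActivity_{off} - 1}: each 10-fold-selective
#' off-target contributes positively, each unselective one negatively, so
#' unselective data compensate for selective data. Empty profile sums to 0.
#'
#' @inheritParams first_factor
#' @return numeric scalar (may be negative).
#' @export
selectivity_information_richness <- function(profile, reference) {
  stopifnot(reference %in% names(profile))
  off <- profile[setdiff(names(profile), reference)]
  if (!length(off)) return(0)
  sum(profile[[reference]] - off - 1)
}

#' Raw second selectivity factor
#'
#' SIC divided by the number of proteins that would be co-modulated: the
#' unselective off-targets (\eqn{\Delta < 1}) plus the reference target
#' itself.
#'
#' @param sic Selectivity Information Richness value.
#' @param n_unselective_off_targets count of off-targets with
#'   \eqn{\Delta < 1}.
#' @return numeric scalar.
#' @export
second_factor_raw <- function(sic, n_unselective_off_targets) {
  stopifnot(n_unselective_off_targets >= 0)
  sic / (n_unselective_off_targets + 1)
}

#' Per-target normalization of the second factor
#'
#' Min-max normalization of the raw second factors over the cohort of
#' compounds scored for one reference target (different targets have very
#' different SIC ranges, e.g. broadly profiled kinases). Degenerate cohorts
#' -- singletons or all-equal values -- map to 0 for every member, so no
#' compound earns selectivity credit the data cannot support.
#'
#' @param second_factor_raw numeric vector of raw second factors for all
#'   compounds scored against one reference target.
#' @return numeric vector in [0, 1], parallel to the input.
#' @export
normalize_second_factor <- function(second_factor_raw) {
  if (!length(second_factor_raw)) return(numeric())
  rng <- range(second_factor_raw)
  if (diff(rng) == 0) return(rep(0, length(second_factor_raw)))
  (second_factor_raw - rng[1]) / diff(rng)
}

#' Third selectivity factor
#'
#' Fraction of the liganded proteome the compound has been screened
#' against: \code{(n_off_targets + 1) / n_liganded_targets}, clamped at 1 in
#' the exhaustive-screening limit.
#'
#' @param n_off_targets non-negative integer.
#' @param n_liganded_targets positive integer; by default the pipeline uses
#'   the number of distinct targets with at least one active compound in the
#'   loaded dataset, overridable by configuration.
#' @return numeric in (0, 1].
#' @export
third_factor <- function(n_off_targets, n_liganded_targets) {
  if (any(n_liganded_targets < 1)) stop("n_liganded_targets must be >= 1")
  pmin(1, (n_off_targets + 1) / n_liganded_targets)
}

#' Combined selectivity score
#'
#' Mean of the first factor, the per-target-normalized second factor and the
#' third factor; forced to 0 when the compound has no off-target information
#' of any kind.
#'
#' @param first_factor,second_factor_norm,third_factor the three factors in
#'   [0, 1].
#' @param n_off_targets off-target count (0 forces the score to 0).
#' @return numeric in [0, 1].
#' @export
selectivity_score <- function(first_factor, second_factor_norm, third_factor,
                              n_off_targets) {
  ifelse(n_off_targets == 0, 0,
         (first_factor + second_factor_norm + third_factor) / 3)
}

#' Selectivity danger flag
#'
#' TRUE when a compound has off-target data and at least one tested
#' off-target fails the 10-fold selectivity criterion -- the red-triangle
#' warning. Absence of off-target data is not flagged (no evidence either
#' way).
#'
#' @param n_off_targets,n_selective_off_targets integer vectors.
#' @return logical vector.
#' @export
danger_flag <- function(n_off_targets, n_selective_off_targets) {
  n_off_targets > 0 & n_selective_off_targets < n_off_targets
}
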