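# Unit handling and the pActivity transform. Everything downstream works on
# the -log10 molar (pActivity) scale; 100 nM <-> pActivity 7.

# nM per one unit; names are matched after lower-casing and mapping the
# micro sign / 'u' prefix onto a single spelling.
.unit_factors <- c(pm = 1e-3, nm = 1, um = 1e3, mm = 1e6, m = 1e9)

.normalize_unit <- function(units) {
  u <- tolower(trimws(units))
  u <- gsub("µ|μ", "u", u)   # micro sign / greek mu -> 'u'
  u
}

#' Convert a concentration to nanomolar
#'
#' Exact scaling between the convertible concentration units
#' (pM, nM, \eqn{\mu}M, mM, M) and nanomolar, the package's working unit.
#'
#' @param value positive numeric vector of concentrations.
#' @param units character vector (recycled) of unit labels; one of
#'   \code{"pM"}, \code{"nM"}, \code{"uM"}/\code{"µM"}, \code{"mM"},
#'   \code{"M"} (case-insensitive).
#' @return numeric vector of concentrations in nM.
#' @examples
#' to_nanomolar(1, "uM")    # 1000
#' to_nanomolar(50, "pM")   # 0.05
#' @export
to_nanomolar <- function(value, units) {
  u <- .normalize_unit(units)
  bad <- !(u %in% names(.unit_factors))
  if (any(bad)) {
    stop("non-convertible units: ", paste(unique(units[bad]), collapse = ", "))
  }
  value * unname(.unit_factors[u])
}

#' Test whether unit labels are convertible to nM
#' @param units character vector of unit labels.
#' @return logical vector.
#' @export
is_convertible_unit <- function(units) {
  .normalize_unit(units) %in% names(.unit_factors)
}

#' pActivity of a concentration
#'
#' \eqn{-\log_{10}} of the activity expressed in molar units, so 100 nM maps
#' to 7 and 0.1 nM to 10. No cap is applied here; the cap at 10 is an
#' aggregation-stage policy (see \code{\link{aggregate_pairs}}).
#'
#' @param conc_nM positive numeric vector of concentrations in nM.
#' @return numeric vector of pActivities.
#' @examples
#' compute_pactivity(100)   # 7
#' compute_pactivity(0.1)   # 10
#' @export
compute_pactivity <- function(conc_nM) {
  if (any(!is.finite(conc_nM) | conc_nM <= 0)) {
    stop("concentration must be positive and finite")
  }
  9 - log10(conc_nM)
}

#' Median absolute deviation without scale factor
#'
#' \code{median(|x - median(x)|)}: the raw MAD reported alongside every
#' aggregated median pActivity as a dispersion diagnostic (no consistency
#' constant).
#'
#' @param pactivities non-empty numeric vector.
#' @return non-negative scalar.
#' @export
compute_mad <- function(pactivities) {
  if (length(pactivities) == 0L) stop("empty input")
  stats::median(abs(pactivities - stats::median(pactivities)))
}
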