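# Ingestion of raw bioactivity tables. A "measurement" links one compound to
# one protein target (biochemical assay) or one cell line (cell assay) with a
# qualified ('='/'>') activity value that must be convertible to nM.
# Ingestion never silently loses data: malformed rows are collected in a
# machine-readable rejects table attached to the result.

.measurement_fields <- c(
  "compound_id", "target_accession", "assay_kind", "cell_line_id",
  "qualifier", "value", "units", "activity_type", "pubmed_id", "smiles"
)

#' Parse a delimited bioactivity table
#'
#' Reads a TSV (default) or CSV table of raw bioactivity records, validates
#' each row against the measurement contract and normalizes activity values
#' to nM. Well-formed rows become measurements; malformed rows are rejected
#' with a reason and surfaced via \code{attr(x, "rejects")} and
#' \code{\link{ingest_rejects}} -- never silently dropped.
#'
#' Mandatory columns (after renaming through \code{col_map}):
#' \code{compound_id}, \code{qualifier}, \code{value}, \code{units}.
#' \code{assay_kind} (\code{"biochemical"}/\code{"cell"}) defaults to
#' biochemical when the column is absent. Biochemical rows require
#' \code{target_accession}; cell rows require \code{cell_line_id}.
#' Optional columns: \code{activity_type}, \code{pubmed_id}, \code{smiles}.
#'
#' Row-level rejection reasons: \code{"non-convertible units"},
#' \code{"non-positive or unparseable value"}, \code{"bad qualifier"},
#' \code{"missing target_accession"}, \code{"missing cell_line_id"},
#' \code{"unknown assay_kind"}, \code{"missing compound_id"}.
#'
#' @param path path to the delimited file.
#' @param sep field separator, \code{"\t"} (default) or \code{","}.
#' @param col_map optional named character vector mapping file header names
#'   to measurement field names, e.g. \code{c(molecule = "compound_id")}.
#' @param smiles_file optional path to a two-column headerless
#'   SMILES file (\code{smiles<TAB>compound_id}, the usual .smi layout) used
#'   to attach structures when the table has no \code{smiles} column.
#' @return a \code{data.table} of measurements with columns
#'   \code{compound_id}, \code{target_accession}, \code{assay_kind},
#'   \code{cell_line_id}, \code{qualifier}, \code{value_nM},
#'   \code{pactivity}, \code{activity_type}, \code{pubmed_id},
#'   \code{smiles}; attribute \code{rejects} holds the rejected rows.
#' @export
parse_bioactivity_table <- function(path, sep = "\t", col_map = NULL,
                                    smiles_file = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- data.table::fread(path, sep = sep, colClasses = "character",
                           header = TRUE, na.strings = c("NA", ""))
  if (!is.null(col_map)) {
    hit <- names(raw) %in% names(col_map)
    data.table::setnames(raw, names(raw)[hit],
                         unname(col_map[names(raw)[hit]]))
  }
  mandatory <- c("compound_id", "qualifier", "value", "units")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (opt in setdiff(.measurement_fields, names(raw))) {
    raw[, (opt) := NA_character_]
  }
  raw[is.na(assay_kind), assay_kind := "biochemical"]
  raw[, row_id := seq_len(.N)]

  if (!is.null(smiles_file)) {
    smi <- read_smiles_file(smiles_file)
    raw[, smiles := smi$smiles[match(compound_id, smi$compound_id)]]
  }

  reason <- rep(NA_character_, nrow(raw))
  num_value <- suppressWarnings(as.numeric(raw$value))
  bad <- function(cond, why) reason[is.na(reason) & cond] <<- why
  bad(is.na(raw$compound_id), "missing compound_id")
  bad(!(raw$assay_kind %in% c("biochemical", "cell")), "unknown assay_kind")
  bad(raw$assay_kind == "biochemical" & is.na(raw$target_accession),
      "missing target_accession")
  bad(raw$assay_kind == "cell" & is.na(raw$cell_line_id),
      "missing cell_line_id")
  bad(!(raw$qualifier %in% c("=", ">")), "bad qualifier")
  bad(is.na(num_value) | num_value <= 0, "non-positive or unparseable value")
  bad(is.na(raw$units) | !is_convertible_unit(ifelse(is.na(raw$units), "", raw$units)),
      "non-convertible units")

  keep <- is.na(reason)
  rejects <- data.table::data.table(
    row = raw$row_id[!keep],
    compound_id = raw$compound_id[!keep],
    reason = reason[!keep]
  )
  out <- raw[keep]
  out[, value := num_value[keep]]
  out[, value_nM := to_nanomolar(value, units)]
  out[, pactivity := compute_pactivity(value_nM)]
  out <- out[, c("compound_id", "target_accession", "assay_kind",
                 "cell_line_id", "qualifier", "value_nM", "pactivity",
                 "activity_type", "pubmed_id", "smiles"), with = FALSE]
  data.table::setattr(out, "rejects", rejects)
  if (nrow(rejects)) {
    message(nrow(rejects), " of ", nrow(raw), " rows rejected during ingestion")
  }
  out[]
}

#' Rejected rows of an ingested table
#' @param measurements result of \code{\link{parse_bioactivity_table}}.
#' @return data.table with columns \code{row}, \code{compound_id},
#'   \code{reason} (zero rows when nothing was rejected).
#' @export
ingest_rejects <- function(measurements) {
  r <- attr(measurements, "rejects")
  if (is.null(r)) {
    r <- data.table::data.table(row = integer(), compound_id = character(),
                                reason = character())
  }
  r
}

#' Read a SMILES file
#'
#' Headerless whitespace- or tab-separated file with the structure first and
#' the compound identifier second (the conventional .smi layout).
#'
#' @param path file path.
#' @return data.table with columns \code{compound_id}, \code{smiles}.
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) stop("SMILES file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad)) stop("SMILES file lines without an identifier: ",
                     paste(which(bad), collapse = ", "))
  data.table::data.table(
    compound_id = vapply(parts, `[[`, "", 2L),
    smiles = vapply(parts, `[[`, "", 1L)
  )
}

#' Read compound structures from an SDF file
#'
#' Molecule titles map to compound identifiers; parsing is delegated to the
#' RDKit backend.
#'
#' @param path SDF file path.
#' @param python python interpreter (see \code{\link{chem_properties}}).
#' @return data.table with columns \code{compound_id}, \code{smiles}
#'   (canonical SMILES; unparseable records are dropped with a warning).
#' @export
read_sdf_file <- function(path, python = getOption("probescore.python", "python")) {
  res <- .run_chem_backend(path, python = python, sdf = TRUE)
  if (any(!res$parse_ok)) {
    warning(sum(!res$parse_ok), " SDF record(s) could not be parsed")
  }
  res[parse_ok == TRUE, .(compound_id, smiles = canonical_smiles)]
}
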