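# Structure-level computations: level-1 scaffold-tree assignment (the analog
# class used by the SAR and inactive-analog scores) and PAINS substructure
# alerting. Chemistry is delegated to RDKit through a bundled Python helper
# (inst/python/chem_backend.py), invoked once per batch of unique SMILES;
# results are memoised per session so repeated scoring runs are cheap.

.chem_cache <- new.env(parent = emptyenv())

.find_python <- function(python) {
  path <- Sys.which(python)
  if (!nzchar(path)) {
    stop("python interpreter not found ('", python, "'); set option ",
         "'probescore.python' or put python with rdkit on the PATH")
  }
  path
}

.backend_script <- function() {
  p <- system.file("python", "chem_backend.py", package = "probescore")
  if (!nzchar(p)) stop("bundled chem_backend.py not found; reinstall probescore")
  p
}

.run_chem_backend <- function(infile, python, pains_smarts = NULL, sdf = FALSE) {
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(out), add = TRUE)
  args <- c(.backend_script(), infile, out)
  if (!is.null(pains_smarts)) args <- c(args, "--pains-file", pains_smarts)
  if (sdf) args <- c(args, "--sdf")
  status <- system2(.find_python(python), shQuote(args),
                    stdout = FALSE, stderr = "")
  if (status != 0L || !file.exists(out)) {
    stop("structure backend failed (exit status ", status, ")")
  }
  data.table::fread(out, sep = "\t", header = TRUE,
                    colClasses = list(character = c("compound_id",
                                                    "level1_scaffold",
                                                    "pains_alerts",
                                                    "canonical_smiles")),
                    na.strings = NULL)
}

#' Scaffold and PAINS properties for a set of structures
#'
#' Computes, for every compound, the canonical level-1 scaffold-tree
#' scaffold (empty for acyclic molecules), the ring count of its Murcko
#' framework, the matched PAINS filter names and the binary PAINS score
#' (0 on any alert, 1 otherwise). Salts/mixtures are reduced to the largest
#' covalent fragment first. Unparseable structures yield
#' \code{parse_ok = FALSE}, an empty scaffold (excluding them from
#' SAR/inactive-analog matching) and PAINS score 1 -- no alert is observable
#' -- with a warning so the degradation is auditable.
#'
#' @param compound_id character vector of identifiers.
#' @param smiles character vector of SMILES, parallel to \code{compound_id}.
#' @param python python interpreter with RDKit available (default option
#'   \code{probescore.python}, falling back to \code{"python"}).
#' @param pains_smarts optional path to a plain-text SMARTS pattern file
#'   (lines \code{SMARTS<TAB>name}, \code{#} comments) replacing the default
#'   built-in published PAINS families A/B/C.
#' @param cache memoise per-SMILES results for the session (default TRUE;
#'   bypassed automatically when \code{pains_smarts} is supplied).
#' @return data.table with columns \code{compound_id}, \code{smiles},
#'   \code{parse_ok}, \code{n_rings}, \code{level1_scaffold},
#'   \code{pains_alerts} (semicolon-separated), \code{pains_score}.
#' @export
chem_properties <- function(compound_id, smiles,
                            python = getOption("probescore.python", "python"),
                            pains_smarts = NULL, cache = is.null(pains_smarts)) {
  stopifnot(length(compound_id) == length(smiles))
  if (length(smiles) == 0L) {
    return(data.table::data.table(
      compound_id = character(), smiles = character(), parse_ok = logical(),
      n_rings = integer(), level1_scaffold = character(),
      pains_alerts = character(), pains_score = integer()
    ))
  }
  smiles <- as.character(smiles)
  uniq <- unique(smiles[!is.na(smiles)])
  todo <- if (cache) uniq[!vapply(uniq, exists, TRUE, envir = .chem_cache)] else uniq
  if (length(todo)) {
    infile <- tempfile(fileext = ".tsv")
    on.exit(unlink(infile), add = TRUE)
    writeLines(c("compound_id\tsmiles",
                 paste(seq_along(todo), todo, sep = "\t")), infile)
    res <- .run_chem_backend(infile, python = python,
                             pains_smarts = pains_smarts)
    res[, smiles := todo[as.integer(compound_id)]]
    for (i in seq_len(nrow(res))) {
      assign(res$smiles[i], res[i], envir = if (cache) .chem_cache else new.env())
    }
    if (!cache) lookup <- res
  }
  rows <- lapply(seq_along(smiles), function(i) {
    s <- smiles[i]
    if (is.na(s)) {
      return(data.table::data.table(
        parse_ok = FALSE, n_rings = 0L, level1_scaffold = "",
        pains_alerts = "", pains_score = 1L, canonical_smiles = ""
      ))
    }
    r <- if (cache) get(s, envir = .chem_cache) else lookup[smiles == s][1L]
    r[, .(parse_ok, n_rings, level1_scaffold, pains_alerts, pains_score,
          canonical_smiles)]
  })
  out <- data.table::rbindlist(rows)
  out[, compound_id := compound_id]
  out[, smiles := smiles]
  if (any(!out$parse_ok & !is.na(smiles))) {
    warning(sum(!out$parse_ok & !is.na(smiles)),
            " structure(s) could not be parsed; their PAINS score defaults ",
            "to 1 and they are excluded from scaffold matching")
  }
  out[, .(compound_id, smiles, parse_ok, n_rings, level1_scaffold,
          pains_alerts, pains_score)]
}

#' Level-1 scaffold-tree scaffold of structures
#'
#' Convenience wrapper around \code{\link{chem_properties}} returning the
#' scaffold assignment only. The scaffold tree is rooted at a single ring
#' (level 0); level 1 is the two-ring scaffold chosen by the prioritized
#' ring-removal rules, and Murcko frameworks with at most two rings are
#' their own level-1 scaffold. Acyclic molecules get an empty scaffold and
#' are excluded from analog matching.
#'
#' @inheritParams chem_properties
#' @return data.table with columns \code{compound_id},
#'   \code{level1_scaffold}, \code{n_rings}.
#' @export
level1_scaffold <- function(compound_id, smiles,
                            python = getOption("probescore.python", "python")) {
  chem_properties(compound_id, smiles, python = python)[
    , .(compound_id, level1_scaffold, n_rings)]
}

#' PAINS alerting for structures
#'
#' Matches each structure against the published pan-assay-interference
#' (PAINS) substructure families A/B/C and assigns the binary PAINS score:
#' 0 on any alert, 1 otherwise.
#'
#' @inheritParams chem_properties
#' @return data.table with columns \code{compound_id}, \code{alerts}
#'   (semicolon-separated matched filter names, empty when clean),
#'   \code{pains_score}.
#' @export
pains_score <- function(compound_id, smiles,
                        python = getOption("probescore.python", "python"),
                        pains_smarts = NULL) {
  chem_properties(compound_id, smiles, python = python,
                  pains_smarts = pains_smarts)[
    , .(compound_id, alerts = pains_alerts, pains_score)]
}

# Analog-based scores ---------------------------------------------------

#' SAR score of a compound for a reference target
#'
#' A compound-reference-target pair has structure-activity-relationship
#' evidence (score 1) when at least one other compound with the identical
#' level-1 scaffold is active on the reference target (median pActivity > 5)
#' and was reported in the same publication -- i.e. the two compounds share
#' at least one PubMed identifier among their measurements on that target.
#' Compounds without a scaffold (acyclic/unparseable) or without any
#' publication identifier score 0.
#'
#' @param compound_id compound being evaluated.
#' @param reference_target target accession.
#' @param aggregates biochemical aggregate table
#'   (\code{\link{aggregate_pairs}}).
#' @param scaffolds scaffold assignment (\code{\link{level1_scaffold}} or
#'   \code{\link{chem_properties}} output).
#' @param measurements raw measurement table (for PubMed identifiers).
#' @return integer 0 or 1.
#' @export
sar_score <- function(compound_id, reference_target, aggregates, scaffolds,
                      measurements) {
  cid <- compound_id; tgt <- reference_target
  tab <- .analog_scores(aggregates, scaffolds, measurements)
  tab[tab$compound_id == cid & tab$target_accession == tgt, ]$sar
}

#' Inactive-analog score of a compound for a reference target
#'
#' Score 1 when at least one other compound with the identical level-1
#' scaffold is reported inactive on the reference target: aggregated median
#' pActivity below 5, or conflicting '='/'>' records classifying it
#' inactive. Unlike the SAR score there is no same-publication requirement.
#'
#' @inheritParams sar_score
#' @return integer 0 or 1.
#' @export
inactive_analog_score <- function(compound_id, reference_target, aggregates,
                                  scaffolds, measurements = NULL) {
  cid <- compound_id; tgt <- reference_target
  tab <- .analog_scores(aggregates, scaffolds, measurements)
  tab[tab$compound_id == cid & tab$target_accession == tgt, ]$inactive_analog
}

# SAR and inactive-analog flags for every aggregated pair.
# Scaffold classes come from 'scaffolds'; publication links from the raw
# measurements (may be NULL -> SAR is 0 everywhere).
.analog_scores <- function(aggregates, scaffolds, measurements = NULL) {
  agg <- data.table::as.data.table(aggregates)
  sc <- data.table::as.data.table(scaffolds)[
    !is.na(level1_scaffold) & nzchar(level1_scaffold),
    .(compound_id, scaffold = level1_scaffold)]
  out <- agg[, .(compound_id, target_accession)]
  out[, `:=`(sar = 0L, inactive_analog = 0L)]
  if (nrow(sc) == 0L) return(out)
  a <- merge(agg, sc, by = "compound_id")

  # inactive analog: another compound, same scaffold, inactive on the target
  inact <- a[median_pactivity < 5 | conflicting,
             .(target_accession, scaffold, other = compound_id)]
  if (nrow(inact)) {
    hit <- merge(a[, .(compound_id, target_accession, scaffold)], inact,
                 by = c("target_accession", "scaffold"),
                 allow.cartesian = TRUE)[compound_id != other]
    out[unique(hit[, .(compound_id, target_accession)]),
        inactive_analog := 1L, on = c("compound_id", "target_accession")]
  }

  # SAR: another same-scaffold compound, active on the target, sharing a
  # publication with the query compound's measurements on that target
  if (!is.null(measurements)) {
    m <- data.table::as.data.table(measurements)
    pubs <- unique(m[assay_kind == "biochemical" & !is.na(pubmed_id),
                     .(compound_id, target_accession, pubmed_id)])
    pubs <- merge(pubs, sc, by = "compound_id")
    if (nrow(pubs)) {
      pairs <- merge(pubs, pubs,
                     by = c("target_accession", "pubmed_id", "scaffold"),
                     allow.cartesian = TRUE,
                     suffixes = c("", ".other"))[compound_id != compound_id.other]
      if (nrow(pairs)) {
        act <- a[active == TRUE, .(compound_id, target_accession)]
        pairs <- merge(pairs,
                       act[, .(compound_id.other = compound_id, target_accession)],
                       by = c("compound_id.other", "target_accession"))
        out[unique(pairs[, .(compound_id, target_accession)]),
            sar := 1L, on = c("compound_id", "target_accession")]
      }
    }
  }
  out
}
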