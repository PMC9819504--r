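#' Estimate log Kow from a SMILES string
#'
#' Convenience estimator for compounds lacking a measured or
#' literature-supplied log Kow, using the atom-contribution logP implemented
#' in Open Babel (via the \pkg{ChemmineOB} package). The SMILES is
#' canonicalized before estimation so equivalent encodings of one molecule
#' yield identical values. This is a labelled, open-source estimator, not a
#' reimplementation of any proprietary fragment method; values supplied by
#' the user take precedence and are never overwritten (see
#' [fill_missing_log_kow()]).
#'
#' @param smiles Character vector of SMILES strings.
#' @return Data frame with \code{smiles}, \code{log_kow}, \code{source}
#'   (always \code{"ESTIMATED"}) and \code{method_label}.
#' @examples
#' \dontrun{
#' estimate_log_kow(c("CCO", "CCCCCCCCO"))
#' }
#' @export
estimate_log_kow <- function(smiles) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("estimate_log_kow requires the ChemmineOB package", call. = FALSE)
  stopifnot(is.character(smiles), length(smiles) >= 1)
  est_one <- function(s) {
    if (is.na(s) || !nzchar(trimws(s)))
      stop("cannot parse SMILES: empty string", call. = FALSE)
    can <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s)),
      error = function(e) "")
    can <- trimws(strsplit(can, "[\t\n]")[[1]][1])
    if (is.na(can) || !nzchar(can))
      stop("cannot parse SMILES: '", s, "'", call. = FALSE)
    props <- ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", can, identity))
    as.numeric(props$logP)
  }
  data.frame(smiles = smiles,
             log_kow = vapply(smiles, est_one, numeric(1), USE.NAMES = FALSE),
             source = "ESTIMATED",
             method_label = "OpenBabel logP (atom contribution)",
             stringsAsFactors = FALSE)
}

#' Fill missing log Kow values by estimation
#'
#' Estimates log Kow from SMILES only for records where \code{log_kow} is
#' missing; user-supplied values are never overwritten. Provenance is
#' recorded in a \code{log_kow_source} column (\code{USER_SUPPLIED} or
#' \code{ESTIMATED}).
#'
#' @param data Compound data frame with a \code{smiles} column for the rows
#'   to fill.
#' @return The data frame with \code{log_kow} filled where possible and
#'   \code{log_kow_source} appended.
#' @export
fill_missing_log_kow <- function(data) {
  data <- as_compound_table(data)
  src <- ifelse(is.na(data$log_kow), NA_character_, "USER_SUPPLIED")
  todo <- which(is.na(data$log_kow) & !is.na(data$smiles))
  if (length(todo)) {
    est <- estimate_log_kow(data$smiles[todo])
    data$log_kow[todo] <- est$log_kow
    src[todo] <- "ESTIMATED"
  }
  data$log_kow_source <- src
  data
}

#' Validate the descriptor column of a compound table
#'
#' Pure QC scan (never mutates its input): reports records with no log Kow
#' and no SMILES to estimate one from (\code{MISSING_DESCRIPTOR}), log Kow
#' magnitudes beyond 12 (\code{OUT_OF_RANGE}; the plausible environmental
#' range ends well below that), and tables mixing user-supplied and
#' estimated provenance (\code{MIXED_PROVENANCE}, table-level, row
#' \code{NA}).
#'
#' @param data Compound data frame.
#' @return Data frame of findings: \code{row}, \code{code}, \code{message};
#'   zero rows when the table is clean.
#' @examples
#' validate_descriptor_table(organophosphate_esters())  # clean
#' @export
validate_descriptor_table <- function(data) {
  data <- as_compound_table(data)
  findings <- list()
  note <- function(row, code, message)
    findings[[length(findings) + 1L]] <<- data.frame(
      row = row, code = code, message = message, stringsAsFactors = FALSE)
  for (i in which(is.na(data$log_kow) & is.na(data$smiles)))
    note(i, "MISSING_DESCRIPTOR",
         paste0("'", data$name[i], "': no log_kow and no SMILES"))
  for (i in which(!is.na(data$log_kow) & abs(data$log_kow) > 12))
    note(i, "OUT_OF_RANGE",
         sprintf("'%s': |log_kow| = %g exceeds 12", data$name[i],
                 abs(data$log_kow[i])))
  if ("log_kow_source" %in% names(data)) {
    src <- unique(stats::na.omit(data$log_kow_source))
    if (length(src) > 1)
      note(NA_integer_, "MIXED_PROVENANCE",
           paste("table mixes descriptor sources:",
                 paste(src, collapse = ", ")))
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(row = integer(0), code = character(0),
                  message = character(0), stringsAsFactors = FALSE)
}
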