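#' Read a compound table from CSV or TSV
#'
#' Reads the standard compound schema: required column \code{name}; optional
#' identifier columns \code{cas}, \code{abbreviation}, \code{smiles};
#' descriptor column \code{log_kow}; endpoint columns among
#' \code{lc50_mg_per_l}, \code{log_lc50}, \code{noec_mg_per_l},
#' \code{log_noec}. Headers are matched case-insensitively after trimming;
#' unknown columns pass through untouched. The delimiter (comma or tab) is
#' sniffed from the header line unless given; a UTF-8 BOM is tolerated and
#' Unicode minus signs are normalized before numeric parsing. Malformed
#' numeric cells never abort the read: the cell becomes \code{NA} and a
#' finding is recorded.
#'
#' @param path Path to the file.
#' @param sep Field separator; \code{NULL} (default) sniffs comma vs tab.
#' @return A compound data frame (see [as_compound_table()]) with attribute
#'   \code{"parse_findings"}: a data frame of \code{row} (1-based, header
#'   excluded), \code{column}, \code{message}.
#' @examples
#' path <- system.file("extdata", "organophosphate_esters.csv",
#'                     package = "troqsar")
#' head(read_compounds_csv(path))
#' @export
read_compounds_csv <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L, encoding = "UTF-8", warn = FALSE)
    sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
               lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))))
      "\t" else ","
  }
  raw <- utils::read.csv(path, sep = sep, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8-BOM",
                         strip.white = TRUE)
  names(raw) <- tolower(trimws(names(raw)))
  if (!"name" %in% names(raw))
    stop("missing required column(s): name", call. = FALSE)
  findings <- list()
  note <- function(row, column, message)
    findings[[length(findings) + 1L]] <<- data.frame(
      row = row, column = column, message = message, stringsAsFactors = FALSE)
  numeric_cols <- intersect(
    c("log_kow", "lc50_mg_per_l", "log_lc50", "noec_mg_per_l", "log_noec",
      "reported_log_tro"),
    names(raw))
  for (col in numeric_cols) {
    cell <- normalize_minus(raw[[col]])
    # decimal commas are a locale trap; reject with a pointer, never guess
    dec_comma <- grepl("^-?[0-9]+,[0-9]+$", cell)
    parsed <- suppressWarnings(as.numeric(cell))
    bad <- which((is.na(parsed) & nzchar(cell) & !is.na(cell)) | dec_comma)
    for (r in bad)
      note(r, col, if (dec_comma[r])
        sprintf("decimal comma in '%s'; use '.' as decimal separator", cell[r])
        else sprintf("cannot parse '%s' as a number", cell[r]))
    parsed[dec_comma] <- NA_real_
    raw[[col]] <- parsed
  }
  for (col in intersect(c("cas", "abbreviation", "smiles"), names(raw)))
    raw[[col]][!nzchar(trimws(raw[[col]])) | is.na(raw[[col]])] <- NA_character_
  out <- as_compound_table(raw)
  attr(out, "parse_findings") <- if (length(findings))
    do.call(rbind, findings)
  else data.frame(row = integer(0), column = character(0),
                  message = character(0), stringsAsFactors = FALSE)
  out
}

# map U+2212 (minus sign) and U+2013 (en dash) to ASCII hyphen-minus
normalize_minus <- function(x) {
  gsub("−|–", "-", x)
}

#' Write a compound table to CSV
#'
#' Inverse of [read_compounds_csv()]: recognized and passthrough columns are
#' written with full precision; missing values become empty cells, so a
#' read/write cycle is idempotent on recognized columns.
#'
#' @param data Compound data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_compounds_csv <- function(data, path) {
  data <- as_compound_table(data)
  drop <- intersect(c("parse_findings"), names(data))
  utils::write.csv(data[, setdiff(names(data), drop), drop = FALSE],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Curated organophosphate ester dataset
#'
#' Twelve literature records of organophosphate and phthalate esters with
#' log Kow, acute log LC50 and chronic log NOEC (both log10 mg/L), plus the
#' log TRO value and MOA type letter reported in the source compilation
#' (columns \code{reported_log_tro}, \code{reported_type}). The reported
#' values are carried verbatim, including their internal inconsistencies:
#' diethyl phthalate appears twice, the reported tripropyl phosphate log TRO
#' (1.36) differs from the endpoint difference (1.33), and the reported
#' tricresyl phosphate value (0.30) is irreconcilable with its endpoints
#' (|-0.84 - (-8.15)| = 7.31, which classifies as reactive). Use
#' [reported_concordance()] to enumerate the discrepancies.
#'
#' @return Compound data frame of 12 rows in source order.
#' @examples
#' organophosphate_esters()[1:3, 1:6]
#' @export
organophosphate_esters <- function() {
  path <- system.file("extdata", "organophosphate_esters.csv",
                      package = "troqsar", mustWork = TRUE)
  read_compounds_csv(path)
}

#' Recomputed vs reported TRO concordance
#'
#' Recomputes log TRO and the MOA class from the endpoint columns and lines
#' them up against the dataset's reported values, so that discrepancies in a
#' source compilation are enumerated rather than silently tolerated.
#' Comparison uses 2-decimal half-up rounding, the display precision of the
#' reported values.
#'
#' @param data Compound data frame carrying \code{reported_log_tro} and
#'   \code{reported_type} columns (as [organophosphate_esters()] does).
#' @inheritParams evaluate_tro
#' @return Data frame with one row per record: recomputed and reported
#'   log TRO, \code{log_tro_match}, recomputed MOA, reported type letter
#'   expanded to the class name, and \code{moa_match}.
#' @examples
#' conc <- reported_concordance(organophosphate_esters())
#' subset(conc, !log_tro_match)
#' @export
reported_concordance <- function(data, thresholds = moa_thresholds(),
                                 convention = "absolute") {
  stopifnot(all(c("reported_log_tro", "reported_type") %in% names(data)))
  ev <- evaluate_tro(data, thresholds, convention)
  type_map <- c(N = "NARCOSIS", T = "TRANSITION", R = "REACTIVE")
  reported_moa <- unname(type_map[as.character(data$reported_type)])
  recomputed_2dp <- round_half_up(ev$log_tro, 2)
  data.frame(name = ev$name,
             abbreviation = ev$abbreviation,
             recomputed_log_tro = recomputed_2dp,
             reported_log_tro = data$reported_log_tro,
             log_tro_match = recomputed_2dp == data$reported_log_tro,
             recomputed_moa = as.character(ev$moa),
             reported_moa = reported_moa,
             moa_match = as.character(ev$moa) == reported_moa,
             stringsAsFactors = FALSE)
}

# round half away from zero at `digits` decimals (display convention of the
# source tables; base round() is half-to-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

qsar_fit_to_list <- function(m) {
  list(slope = m$slope, intercept = m$intercept, r_squared = m$r_squared,
       sdep = m$sdep, n = m$n)
}

#' Export / import a fitted QSAR line as JSON
#'
#' Serializes the model summary (slope, intercept, R-squared, SDEP, n) with
#' full numeric precision.
#'
#' @param model A [fit_qsar()] object.
#' @param path Output (input) path.
#' @return \code{write_qsar_model}: \code{path} invisibly;
#'   \code{read_qsar_model}: a \code{qsar_fit} object usable with
#'   \code{predict} (training data and residuals are not serialized).
#' @export
write_qsar_model <- function(model, path) {
  stopifnot(inherits(model, "qsar_fit"))
  jsonlite::write_json(qsar_fit_to_list(model), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_qsar_model
#' @export
read_qsar_model <- function(path) {
  m <- jsonlite::fromJSON(path)
  structure(list(slope = m$slope, intercept = m$intercept,
                 r_squared = m$r_squared, sdep = m$sdep, n = m$n,
                 residuals = NULL, fitted = NULL, x = NULL, y = NULL,
                 flags = if (m$n < 5) "SMALL_SAMPLE" else character(0)),
            class = "qsar_fit")
}

record_columns <- c("name", "cas", "abbreviation", "log_kow", "log_lc50",
                    "log_noec", "log_tro_signed", "log_tro_abs", "log_tro",
                    "moa", "tro_flags")

#' Write a screening report
#'
#' Serializes a [tro_qsar()] result. The JSON form holds both model
#' summaries, the improvement under both denominator conventions, and the
#' retained/excluded record tables at full numeric precision; it round-trips
#' through [read_report()]. The CSV form is flat: one row per record with
#' its TRO (full precision and a 2-dp display column), MOA class, retained
#' status, exclusion reason, and the screened-fit residual for records in
#' the screened model.
#'
#' @param report A \code{tro_qsar} object.
#' @param path Output path.
#' @param format \code{"json"} (default) or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  stopifnot(inherits(report, "tro_qsar"))
  format <- match.arg(format)
  if (format == "json") {
    pick <- function(d) {
      cols <- intersect(c(record_columns, "exclusion_reason"), names(d))
      d <- d[, cols, drop = FALSE]
      d$moa <- as.character(d$moa)
      d
    }
    obj <- list(
      model_initial = qsar_fit_to_list(report$model_initial),
      model_screened = qsar_fit_to_list(report$model_screened),
      improvement = list(
        r2_initial = report$improvement$r2_initial,
        r2_improved = report$improvement$r2_improved,
        as_defined_pct = report$improvement$as_defined_pct,
        as_reported_pct = report$improvement$as_reported_pct),
      retained = pick(report$retained),
      excluded = pick(report$excluded),
      settings = list(narcosis_upper = report$thresholds$narcosis_upper,
                      reactive_lower = report$thresholds$reactive_lower,
                      retain = as.list(report$retain),
                      convention = report$convention,
                      dedupe = report$dedupe,
                      descriptor = report$descriptor))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  } else {
    ret <- report$retained
    exc <- report$excluded
    res <- rep(NA_real_, nrow(ret))
    used <- which(!is.na(ret$log_lc50) & !is.na(ret[[report$descriptor]]))
    res[used] <- report$model_screened$residuals
    flat <- function(d, retained, reason, residual) {
      data.frame(name = d$name, cas = d$cas, moa = as.character(d$moa),
                 log_tro = d$log_tro,
                 log_tro_2dp = round_half_up(d$log_tro, 2),
                 retained = retained, exclusion_reason = reason,
                 residual = residual, stringsAsFactors = FALSE)
    }
    out <- rbind(flat(ret, TRUE, NA_character_, res),
                 if (nrow(exc)) flat(exc, FALSE, exc$exclusion_reason,
                                     NA_real_))
    utils::write.csv(out, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read back a JSON screening report
#'
#' @param path Path written by [write_report()] with \code{format = "json"}.
#' @return The report as a list mirroring the JSON structure (record tables
#'   as data frames).
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
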