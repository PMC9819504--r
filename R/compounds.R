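# Compound tables are plain data frames. Recognized columns (matched
# case-insensitively on read): name (required), cas, abbreviation, smiles,
# log_kow, lc50_mg_per_l, log_lc50, noec_mg_per_l, log_noec. Unknown columns
# pass through untouched. All concentrations are mg/L; logs are base 10.

recognized_columns <- c("name", "cas", "abbreviation", "smiles", "log_kow",
                        "lc50_mg_per_l", "log_lc50",
                        "noec_mg_per_l", "log_noec")

#' Validate and normalize a compound table
#'
#' Checks the minimal contract a compound data frame must satisfy: a
#' non-empty \code{name} column, CAS numbers (when present) shaped like
#' \code{digits-digits-digit}, and strictly positive concentrations. Missing
#' optional columns are added as \code{NA} so downstream code can rely on
#' their presence.
#'
#' @param data A data frame with at least a \code{name} column.
#' @return The normalized data frame (invisibly the same rows, recognized
#'   columns guaranteed present).
#' @examples
#' as_compound_table(data.frame(name = "ethanol", log_kow = -0.3,
#'                              log_lc50 = 4.1, log_noec = 3.9))
#' @export
as_compound_table <- function(data) {
  stopifnot(is.data.frame(data))
  if (!"name" %in% names(data))
    stop("compound table requires a 'name' column", call. = FALSE)
  data$name <- as.character(data$name)
  if (any(is.na(data$name) | !nzchar(trimws(data$name))))
    stop("every compound needs a non-empty name", call. = FALSE)
  for (col in setdiff(recognized_columns, names(data))) {
    data[[col]] <- if (col %in% c("cas", "abbreviation", "smiles"))
      rep(NA_character_, nrow(data)) else rep(NA_real_, nrow(data))
  }
  data$cas <- as.character(data$cas)
  bad_cas <- !is.na(data$cas) & nzchar(data$cas) &
    !grepl("^[0-9]+-[0-9]+-[0-9]$", data$cas)
  if (any(bad_cas))
    stop("malformed CAS number(s): ",
         paste(unique(data$cas[bad_cas]), collapse = ", "), call. = FALSE)
  for (col in c("log_kow", "lc50_mg_per_l", "log_lc50",
                "noec_mg_per_l", "log_noec")) {
    data[[col]] <- as.numeric(data[[col]])
  }
  for (col in c("lc50_mg_per_l", "noec_mg_per_l")) {
    if (any(!is.na(data[[col]]) & data[[col]] <= 0))
      stop(col, " must be strictly positive (mg/L)", call. = FALSE)
  }
  data
}

# Resolve per-row log endpoints from whichever of the log / concentration
# columns are present. The log column wins when both are present; if the two
# disagree by more than 1e-6 in log units the row gets a CONFLICTING_ENDPOINT
# flag (the log value is still used: the method works in log space).
resolve_endpoints <- function(data) {
  data <- as_compound_table(data)
  n <- nrow(data)
  flags <- rep("", n)
  pick <- function(log_col, conc_col) {
    logv <- data[[log_col]]
    concv <- data[[conc_col]]
    from_conc <- is.na(logv) & !is.na(concv)
    out <- logv
    out[from_conc] <- log10(concv[from_conc])
    conflict <- logical(n)
    both <- which(!is.na(logv) & !is.na(concv))
    conflict[both] <- abs(log10(concv[both]) - logv[both]) > 1e-6
    list(value = out, conflict = conflict)
  }
  lc <- pick("log_lc50", "lc50_mg_per_l")
  no <- pick("log_noec", "noec_mg_per_l")
  flags <- add_flag(flags, lc$conflict | no$conflict, "CONFLICTING_ENDPOINT")
  flags <- add_flag(flags, is.na(lc$value) | is.na(no$value), "MISSING_ENDPOINT")
  data.frame(log_lc50 = lc$value, log_noec = no$value, flags = flags,
             stringsAsFactors = FALSE)
}
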