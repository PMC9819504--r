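#' Mode-of-action classification thresholds
#'
#' The log-TRO cut points separating the three modes of action (MOA).
#' Compounds with \code{|log TRO|} below \code{narcosis_upper} are baseline
#' (narcosis) toxicants; compounds at or above \code{reactive_lower} are
#' reactive; the interval between is the transition class.
#'
#' @param narcosis_upper Upper bound (exclusive) of the narcosis class, in
#'   log10 units. Default 1.
#' @param reactive_lower Lower bound (inclusive) of the reactive class, in
#'   log10 units. Default 3.
#' @return An object of class \code{"moa_thresholds"}.
#' @examples
#' moa_thresholds()
#' moa_thresholds(narcosis_upper = 0.8)
#' @export
moa_thresholds <- function(narcosis_upper = 1, reactive_lower = 3) {
  stopifnot(is.numeric(narcosis_upper), length(narcosis_upper) == 1L,
            is.numeric(reactive_lower), length(reactive_lower) == 1L)
  if (!is.finite(narcosis_upper) || !is.finite(reactive_lower))
    stop("thresholds must be finite", call. = FALSE)
  if (!(narcosis_upper > 0 && reactive_lower > narcosis_upper))
    stop("require 0 < narcosis_upper < reactive_lower", call. = FALSE)
  structure(list(narcosis_upper = narcosis_upper,
                 reactive_lower = reactive_lower),
            class = "moa_thresholds")
}

#' @export
print.moa_thresholds <- function(x, ...) {
  cat(sprintf("MOA thresholds: narcosis |log TRO| < %g <= transition < %g <= reactive\n",
              x$narcosis_upper, x$reactive_lower))
  invisible(x)
}

moa_levels <- c("NARCOSIS", "TRANSITION", "REACTIVE", "UNCLASSIFIED")

check_convention <- function(convention) {
  match.arg(convention, c("absolute", "signed"))
}

#' Compute log TRO from log-scale endpoints
#'
#' The toxicity rank order (TRO) is the ratio of the acute endpoint (LC50) to
#' the chronic endpoint (NOEC); in log space it is the difference
#' \code{log10(LC50) - log10(NOEC)}. Under the default \code{"absolute"}
#' convention the absolute difference is returned, which is the form used for
#' mode-of-action classification; the \code{"signed"} convention preserves the
#' sign, which is negative when NOEC exceeds LC50.
#'
#' @param log_lc50 Numeric vector, base-10 log of acute LC50 in mg/L.
#' @param log_noec Numeric vector, base-10 log of chronic NOEC in mg/L.
#' @param convention \code{"absolute"} (default) or \code{"signed"}.
#' @return Numeric vector of log TRO values (dimensionless).
#' @examples
#' compute_log_tro(-0.10, -0.73)            # 0.63 (triphenyl phosphate)
#' compute_log_tro(0.20, 0.50, "signed")    # -0.30
#' @seealso [classify_moa()], [log_tro_from_concentrations()]
#' @export
compute_log_tro <- function(log_lc50, log_noec, convention = c("absolute", "signed")) {
  convention <- check_convention(convention)
  if (!is.numeric(log_lc50) || any(!is.finite(log_lc50)))
    stop("log_lc50 must be finite numeric", call. = FALSE)
  if (!is.numeric(log_noec) || any(!is.finite(log_noec)))
    stop("log_noec must be finite numeric", call. = FALSE)
  d <- log_lc50 - log_noec
  if (convention == "absolute") abs(d) else d
}

#' Compute log TRO from concentrations
#'
#' Convenience wrapper taking concentrations in mg/L rather than their logs.
#' Both endpoints must be in the same units; the ratio itself is unit-free.
#'
#' @param lc50 Acute LC50 concentration(s), mg/L, strictly positive.
#' @param noec Chronic NOEC concentration(s), mg/L, strictly positive.
#' @inheritParams compute_log_tro
#' @return Numeric vector of log TRO values.
#' @examples
#' log_tro_from_concentrations(100, 1, "signed")  # 2
#' @export
log_tro_from_concentrations <- function(lc50, noec, convention = c("absolute", "signed")) {
  convention <- check_convention(convention)
  if (!is.numeric(lc50) || any(!is.finite(lc50)) || any(lc50 <= 0))
    stop("lc50 must be finite and strictly positive", call. = FALSE)
  if (!is.numeric(noec) || any(!is.finite(noec)) || any(noec <= 0))
    stop("noec must be finite and strictly positive", call. = FALSE)
  compute_log_tro(log10(lc50), log10(noec), convention)
}

#' Classify mode of action from log TRO
#'
#' Assigns each compound to one of three modes of action by the magnitude of
#' its log TRO: narcosis for \code{|log TRO|} in \code{[0, narcosis_upper)},
#' transition for \code{[narcosis_upper, reactive_lower)}, and reactive for
#' \code{[reactive_lower, Inf)}. Signed input is accepted; its absolute value
#' is classified.
#'
#' @param log_tro Numeric vector of log TRO values (finite).
#' @param thresholds A [moa_thresholds()] object.
#' @return Factor with levels \code{NARCOSIS}, \code{TRANSITION},
#'   \code{REACTIVE}, \code{UNCLASSIFIED} (the last never produced here; it is
#'   reserved for records whose endpoints do not allow a TRO).
#' @examples
#' classify_moa(c(0.63, 1.36, 7.31))
#' @export
classify_moa <- function(log_tro, thresholds = moa_thresholds()) {
  stopifnot(inherits(thresholds, "moa_thresholds"))
  if (!is.numeric(log_tro) || any(!is.finite(log_tro)))
    stop("log_tro must be finite numeric", call. = FALSE)
  a <- abs(log_tro)
  cls <- ifelse(a < thresholds$narcosis_upper, "NARCOSIS",
         ifelse(a < thresholds$reactive_lower, "TRANSITION", "REACTIVE"))
  factor(cls, levels = moa_levels)
}

#' Evaluate TRO and mode of action for a compound table
#'
#' Row-wise TRO evaluation that never fails on incomplete records: rows whose
#' endpoints are insufficient are returned with class \code{UNCLASSIFIED} and
#' a \code{MISSING_ENDPOINT} flag instead of an error. Rows where the chronic
#' NOEC exceeds the acute LC50 (negative signed log TRO) are flagged
#' \code{NOEC_EXCEEDS_LC50}; such inversions usually indicate mixed species,
#' endpoints, or transposed columns in the source data.
#'
#' @param data A compound data frame (see [read_compounds_csv()] for the
#'   recognized columns); endpoint columns may be logs (\code{log_lc50},
#'   \code{log_noec}) or concentrations (\code{lc50_mg_per_l},
#'   \code{noec_mg_per_l}).
#' @inheritParams classify_moa
#' @param convention Convention used for the reported \code{log_tro} column
#'   and for classification; see [compute_log_tro()].
#' @return \code{data} with columns appended: \code{log_tro_signed},
#'   \code{log_tro_abs}, \code{log_tro} (per the convention), \code{moa}
#'   (factor) and \code{tro_flags} (semicolon-separated QC flags, \code{""}
#'   when clean).
#' @examples
#' evaluate_tro(organophosphate_esters())[, c("abbreviation", "log_tro", "moa")]
#' @export
evaluate_tro <- function(data, thresholds = moa_thresholds(),
                         convention = c("absolute", "signed")) {
  convention <- check_convention(convention)
  stopifnot(is.data.frame(data))
  ep <- resolve_endpoints(data)
  signed <- ep$log_lc50 - ep$log_noec
  absv <- abs(signed)
  flags <- ep$flags
  flags <- add_flag(flags, !is.na(signed) & signed < 0, "NOEC_EXCEEDS_LC50")
  moa <- factor(rep("UNCLASSIFIED", nrow(data)), levels = moa_levels)
  ok <- !is.na(signed)
  if (any(ok)) moa[ok] <- classify_moa(absv[ok], thresholds)
  out <- data
  out$log_lc50 <- ep$log_lc50
  out$log_noec <- ep$log_noec
  out$log_tro_signed <- signed
  out$log_tro_abs <- absv
  out$log_tro <- if (convention == "absolute") absv else signed
  out$moa <- moa
  out$tro_flags <- flags
  out
}

# append a flag code to rows selected by `where`
add_flag <- function(flags, where, code) {
  where <- which(where)
  flags[where] <- ifelse(flags[where] == "", code,
                         paste(flags[where], code, sep = ";"))
  flags
}

has_flag <- function(flags, code) {
  vapply(strsplit(flags, ";", fixed = TRUE),
         function(f) code %in% f, logical(1))
}
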