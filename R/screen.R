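#' Screen a compound table by TRO mode-of-action class
#'
#' Partitions a compound table into records retained for QSAR fitting and
#' records excluded, applying (in order) CAS-keyed deduplication, TRO
#' evaluation, and the retained-class filter. Every input row lands in
#' exactly one of the two outputs; exclusion reasons are \code{DUPLICATE},
#' \code{UNCLASSIFIED} (endpoints insufficient for a TRO) or
#' \code{MOA_CLASS_NOT_RETAINED}.
#'
#' @param data Compound data frame (see [read_compounds_csv()]).
#' @inheritParams evaluate_tro
#' @param retain Character vector of MOA classes to keep; default
#'   \code{"NARCOSIS"}, the class for which the log Kow 2D model is valid.
#' @param dedupe Drop later rows sharing a CAS number with an earlier row
#'   (default \code{TRUE}); rows without a CAS are never deduplicated.
#' @return List with data frames \code{retained} and \code{excluded} (the
#'   latter with an \code{exclusion_reason} column), both carrying the
#'   [evaluate_tro()] columns and preserving input order.
#' @examples
#' s <- screen_compounds(organophosphate_esters())
#' nrow(s$retained); s$excluded[, c("abbreviation", "exclusion_reason")]
#' @export
screen_compounds <- function(data, thresholds = moa_thresholds(),
                             retain = "NARCOSIS",
                             convention = c("absolute", "signed"),
                             dedupe = TRUE) {
  convention <- check_convention(convention)
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) stop("empty compound table", call. = FALSE)
  retain <- match.arg(retain, moa_levels[1:3], several.ok = TRUE)
  ev <- evaluate_tro(data, thresholds, convention)
  reason <- rep(NA_character_, nrow(ev))
  if (dedupe) {
    has_cas <- !is.na(ev$cas) & nzchar(ev$cas)
    dup <- has_cas & duplicated(ev$cas)
    reason[dup] <- "DUPLICATE"
  }
  uncl <- is.na(reason) & ev$moa == "UNCLASSIFIED"
  reason[uncl] <- "UNCLASSIFIED"
  drop_cls <- is.na(reason) & !(as.character(ev$moa) %in% retain)
  reason[drop_cls] <- "MOA_CLASS_NOT_RETAINED"
  ev$exclusion_reason <- reason
  keep <- is.na(reason)
  retained <- ev[keep, setdiff(names(ev), "exclusion_reason"), drop = FALSE]
  excluded <- ev[!keep, , drop = FALSE]
  rownames(retained) <- NULL
  rownames(excluded) <- NULL
  list(retained = retained, excluded = excluded)
}

#' Descriptor tier recommended for a mode-of-action class
#'
#' Narcosis (baseline) toxicants are well modelled by hydrophobicity alone,
#' so the 2D log Kow regression applies. Reactive compounds act through
#' specific interactions and call for quantum-chemical / 3D descriptors,
#' which this package does not fit. Transition compounds sit between the two
#' mechanisms; the 2D model may be used with caution.
#'
#' @param moa Character or factor vector of MOA classes.
#' @return Character vector of tier recommendations.
#' @examples
#' select_descriptor_tier(c("NARCOSIS", "REACTIVE"))
#' @export
select_descriptor_tier <- function(moa) {
  moa <- as.character(moa)
  bad <- !moa %in% moa_levels
  if (any(bad))
    stop("unknown MOA class: ", paste(unique(moa[bad]), collapse = ", "),
         call. = FALSE)
  unname(c(NARCOSIS = "2D: log KOW",
           TRANSITION = "2D with caution: mixed mechanism, correction deferred",
           REACTIVE = "3D/quantum descriptors (not fittable by this package)",
           UNCLASSIFIED = "insufficient data")[moa])
}

#' Fit the TRO-screened QSAR model
#'
#' The end-to-end procedure: evaluate TRO for every compound, classify mode
#' of action, fit the baseline-toxicity line \code{log LC50 ~ log Kow} on all
#' TRO-computable (deduplicated) records, refit on the screened subset of
#' retained classes, and report the R-squared improvement under both
#' denominator conventions.
#'
#' @param formula Model formula; currently the response must be
#'   \code{log_lc50} (resolved from log or concentration endpoint columns)
#'   and the right-hand side a single descriptor column, default
#'   \code{log_lc50 ~ log_kow}.
#' @param data Compound data frame.
#' @inheritParams screen_compounds
#' @return Object of class \code{"tro_qsar"}: list with \code{model_initial}
#'   and \code{model_screened} ([fit_qsar()] objects), \code{retained} and
#'   \code{excluded} record tables, \code{improvement}
#'   ([improvement_percent()] result), \code{tro} (full evaluation table) and
#'   the call/settings. Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{residuals}, \code{plot}.
#' @examples
#' fit <- tro_qsar(data = organophosphate_esters())
#' fit
#' coef(fit)
#' @export
tro_qsar <- function(formula = log_lc50 ~ log_kow, data,
                     thresholds = moa_thresholds(),
                     retain = "NARCOSIS",
                     convention = c("absolute", "signed"),
                     dedupe = TRUE) {
  convention <- check_convention(convention)
  vars <- all.vars(formula)
  if (length(vars) != 2 || vars[1] != "log_lc50")
    stop("formula must be of the form log_lc50 ~ <descriptor>", call. = FALSE)
  descriptor <- vars[2]
  scr <- screen_compounds(data, thresholds, retain, convention, dedupe)
  ev <- rbind(cbind(scr$retained, exclusion_reason = NA_character_),
              scr$excluded)
  fit_on <- function(d, stage) {
    ok <- !is.na(d$log_lc50) & !is.na(d[[descriptor]]) &
      is.finite(d$log_lc50) & is.finite(d[[descriptor]])
    d <- d[ok, , drop = FALSE]
    tryCatch(fit_qsar(d[[descriptor]], d$log_lc50),
             error = function(e) stop(stage, " fit failed: ",
                                      conditionMessage(e), call. = FALSE))
  }
  # "initial" = everything TRO-computable after dedup, all MOA classes
  pool <- ev[is.na(ev$exclusion_reason) |
               ev$exclusion_reason == "MOA_CLASS_NOT_RETAINED", , drop = FALSE]
  model_initial <- fit_on(pool, "initial (unscreened)")
  model_screened <- fit_on(scr$retained, "screened")
  improvement <- improvement_percent(model_initial$r_squared,
                                     model_screened$r_squared)
  structure(list(model_initial = model_initial,
                 model_screened = model_screened,
                 retained = scr$retained,
                 excluded = scr$excluded,
                 improvement = improvement,
                 descriptor = descriptor,
                 thresholds = thresholds,
                 retain = retain,
                 convention = convention,
                 dedupe = dedupe,
                 call = match.call()),
            class = "tro_qsar")
}

#' @export
print.tro_qsar <- function(x, ...) {
  cat("TRO-screened QSAR fit (log LC50 ~", x$descriptor, ")\n")
  cat(sprintf("  records: %d retained (%s), %d excluded\n",
              nrow(x$retained), paste(x$retain, collapse = "+"),
              nrow(x$excluded)))
  cat("  unscreened: "); print(x$model_initial)
  cat("  screened:   "); print(x$model_screened)
  cat("  ")
  print(x$improvement)
  invisible(x)
}

#' @export
summary.tro_qsar <- function(object, ...) {
  structure(list(fit = object), class = "summary.tro_qsar")
}

#' @export
print.summary.tro_qsar <- function(x, ...) {
  f <- x$fit
  print(f)
  if (nrow(f$excluded)) {
    cat("\nExcluded records:\n")
    cols <- intersect(c("name", "cas", "moa", "log_tro", "exclusion_reason"),
                      names(f$excluded))
    print(f$excluded[, cols], row.names = FALSE)
  }
  cls <- table(factor(f$retained$moa, levels = moa_levels))
  cat("\nRetained class counts:\n")
  print(cls[cls > 0 | names(cls) %in% f$retain])
  invisible(x)
}

#' @export
coef.tro_qsar <- function(object, ...) {
  rbind(initial = coef(object$model_initial),
        screened = coef(object$model_screened))
}

#' @param model Which fitted line to use: \code{"screened"} (default) or
#'   \code{"initial"}.
#' @rdname tro_qsar
#' @param object,newdata,... Standard predict arguments; \code{newdata} is a
#'   numeric vector of descriptor values or a data frame holding the
#'   descriptor column.
#' @export
predict.tro_qsar <- function(object, newdata = NULL,
                             model = c("screened", "initial"), ...) {
  model <- match.arg(model)
  m <- if (model == "screened") object$model_screened else object$model_initial
  if (is.data.frame(newdata)) newdata <- newdata[[object$descriptor]]
  predict(m, newdata = newdata)
}

#' @export
residuals.tro_qsar <- function(object, model = c("screened", "initial"), ...) {
  model <- match.arg(model)
  if (model == "screened") object$model_screened$residuals
  else object$model_initial$residuals
}

#' @export
plot.tro_qsar <- function(x, ..., legend_pos = "topright") {
  ev <- rbind(cbind(x$retained, exclusion_reason = NA_character_), x$excluded)
  ok <- !is.na(ev$log_lc50) & !is.na(ev[[x$descriptor]])
  ev <- ev[ok, , drop = FALSE]
  cols <- c(NARCOSIS = "steelblue4", TRANSITION = "darkorange2",
            REACTIVE = "firebrick3", UNCLASSIFIED = "grey60")
  graphics::plot(ev[[x$descriptor]], ev$log_lc50,
                 col = cols[as.character(ev$moa)], pch = 19,
                 xlab = "log Kow", ylab = "log LC50 (mg/L)", ...)
  graphics::abline(x$model_initial$intercept, x$model_initial$slope,
                   col = "grey40", lty = 2, lwd = 2)
  graphics::abline(x$model_screened$intercept, x$model_screened$slope,
                   col = "red3", lwd = 2)
  graphics::legend(legend_pos, bty = "n",
                   legend = c(names(cols)[names(cols) %in% as.character(ev$moa)],
                              "unscreened fit", "screened fit"),
                   col = c(cols[names(cols) %in% as.character(ev$moa)],
                           "grey40", "red3"),
                   pch = c(rep(19, sum(names(cols) %in% as.character(ev$moa))),
                           NA, NA),
                   lty = c(rep(NA, sum(names(cols) %in% as.character(ev$moa))),
                           2, 1))
  invisible(x)
}
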