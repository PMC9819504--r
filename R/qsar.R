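#' Fit the two-dimensional baseline-toxicity QSAR line
#'
#' Ordinary least squares of log LC50 (mg/L, base-10 log) on log Kow, the
#' single-descriptor model used for narcosis-type (baseline) toxicants.
#' Reported alongside slope and intercept are the coefficient of
#' determination R-squared and SDEP, the standard deviation of prediction
#' errors, computed as the root mean square of the residuals (population
#' denominator).
#'
#' @param x Numeric vector of log Kow values (dimensionless).
#' @param y Numeric vector of log LC50 values (log10 mg/L), same length.
#' @return An object of class \code{"qsar_fit"}: a list with \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{sdep}, \code{n},
#'   \code{residuals}, \code{fitted}, \code{x}, \code{y} and \code{flags}
#'   (contains \code{"SMALL_SAMPLE"} when n < 5).
#' @details When the response has zero variance, R-squared is defined as 0
#'   and a warning is issued; a constant descriptor is an error since the
#'   slope is unidentifiable.
#' @examples
#' fit <- fit_qsar(c(1, 2, 3, 4, 5), c(1.6, 1.1, 0.4, 0.2, -0.4))
#' coef(fit)
#' fit$r_squared
#' @seealso [tro_qsar()] for the full screen-then-fit pipeline.
#' @export
fit_qsar <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y))
    stop("x and y must be numeric", call. = FALSE)
  if (length(x) != length(y))
    stop("x and y lengths differ (", length(x), " vs ", length(y), ")",
         call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least 2 observations to fit a line", call. = FALSE)
  if (diff(range(x)) == 0)
    stop("descriptor x is constant; slope unidentifiable", call. = FALSE)
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  res <- stats::residuals(fit)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot == 0) {
    warning("response has zero variance; R-squared defined as 0")
    0
  } else 1 - sum(res^2) / sstot
  flags <- if (n < 5) "SMALL_SAMPLE" else character(0)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 sdep = sqrt(mean(res^2)),
                 n = n,
                 residuals = unname(res),
                 fitted = unname(stats::fitted(fit)),
                 x = x, y = y,
                 flags = flags),
            class = "qsar_fit")
}

#' @export
print.qsar_fit <- function(x, digits = 4, ...) {
  cat(sprintf("QSAR line: log LC50 = %s + %s * log Kow   (n = %d)\n",
              format(x$intercept, digits = digits),
              format(x$slope, digits = digits), x$n))
  cat(sprintf("  R-squared = %s   SDEP = %s log10 mg/L\n",
              format(x$r_squared, digits = digits),
              format(x$sdep, digits = digits)))
  if ("SMALL_SAMPLE" %in% x$flags)
    cat("  warning flag: SMALL_SAMPLE (n < 5)\n")
  invisible(x)
}

#' @export
coef.qsar_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict log LC50 from a fitted QSAR line
#'
#' @param object A \code{qsar_fit} object.
#' @param newdata Numeric vector of log Kow values, or a data frame with a
#'   \code{log_kow} column. Omitted: the training descriptors.
#' @param ... Unused.
#' @return Numeric vector of predicted log LC50 (log10 mg/L).
#' @export
predict.qsar_fit <- function(object, newdata = NULL, ...) {
  xv <- if (is.null(newdata)) object$x
        else if (is.data.frame(newdata)) newdata$log_kow
        else newdata
  if (!is.numeric(xv) || any(!is.finite(xv)))
    stop("newdata must supply finite log Kow values", call. = FALSE)
  object$intercept + object$slope * xv
}

#' @export
residuals.qsar_fit <- function(object, ...) object$residuals

#' Simulate responses from a fitted QSAR line
#'
#' Parametric simulation: new log LC50 values at the training descriptors,
#' drawn as fitted value plus Gaussian noise with standard deviation equal to
#' the fit's SDEP.
#'
#' @param object A \code{qsar_fit} object.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data frame with \code{nsim} columns, \code{object$n} rows.
#' @export
simulate.qsar_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(replicate(nsim, object$fitted +
                                   stats::rnorm(object$n, 0, object$sdep)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.qsar_fit <- function(x, ...,
                          xlab = "log Kow", ylab = "log LC50 (mg/L)") {
  graphics::plot(x$x, x$y, xlab = xlab, ylab = ylab, pch = 19, ...)
  graphics::abline(x$intercept, x$slope, col = "red3", lwd = 2)
  invisible(x)
}

#' R-squared improvement from training-set screening
#'
#' Percentage gain in the coefficient of determination when a QSAR model is
#' refit after screening. Two denominator conventions are in circulation, so
#' both are reported: \code{as_defined_pct} divides the gain by the initial
#' R-squared, \code{as_reported_pct} by the improved R-squared.
#'
#' @param r2_initial R-squared of the unscreened fit, in (0, 1].
#' @param r2_improved R-squared of the screened fit, in (0, 1].
#' @return Object of class \code{"tro_improvement"}: list with
#'   \code{r2_initial}, \code{r2_improved}, \code{as_defined_pct},
#'   \code{as_reported_pct}.
#' @examples
#' improvement_percent(0.74, 0.81)  # 9.46% / 8.64%
#' @export
improvement_percent <- function(r2_initial, r2_improved) {
  stopifnot(is.numeric(r2_initial), length(r2_initial) == 1L,
            is.numeric(r2_improved), length(r2_improved) == 1L)
  if (!is.finite(r2_initial) || r2_initial <= 0)
    stop("r2_initial must be in (0, 1]", call. = FALSE)
  if (!is.finite(r2_improved) || r2_improved <= 0 || r2_improved > 1)
    stop("r2_improved must be in (0, 1]", call. = FALSE)
  if (r2_initial > 1) stop("r2_initial must be in (0, 1]", call. = FALSE)
  gain <- r2_improved - r2_initial
  structure(list(r2_initial = r2_initial,
                 r2_improved = r2_improved,
                 as_defined_pct = gain / r2_initial * 100,
                 as_reported_pct = gain / r2_improved * 100),
            class = "tro_improvement")
}

#' @export
print.tro_improvement <- function(x, ...) {
  cat(sprintf("R-squared %0.4f -> %0.4f: +%0.2f%% (initial denom) / +%0.2f%% (improved denom)\n",
              x$r2_initial, x$r2_improved, x$as_defined_pct, x$as_reported_pct))
  invisible(x)
}
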