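#' Configuration for the synthetic compound generator
#'
#' Parameters of the generative model behind [simulate_compounds()]. The
#' defaults describe a plausible baseline-toxicity study: narcosis compounds
#' scattered with Gaussian noise about a linear log LC50 vs log Kow line
#' over the hydrophobicity span typical of organophosphate/phthalate esters,
#' plus contaminating reactive compounds displaced below that line (excess
#' toxicity) with a wide acute-chronic separation.
#'
#' @param n_narcosis,n_transition,n_reactive Class counts (default 30/0/10).
#' @param slope,intercept True baseline line, log LC50 = intercept + slope *
#'   log Kow (defaults -0.5 and 2.0 log10 mg/L).
#' @param kow_range Uniform sampling range for log Kow (default c(1, 8.5)).
#' @param noise_sd Gaussian residual SD about the line, log10 mg/L
#'   (default 0.3).
#' @param narcosis_acr_range,transition_acr_range Uniform ranges for the
#'   acute-chronic log separation (the log TRO) of each class; defaults
#'   c(0, 0.9) and c(1.0, 2.9) keep every record inside its class interval.
#' @param reactive_acr_min Minimum acute-chronic separation of reactive
#'   records (default 3.0); separations are drawn uniformly on
#'   \code{[reactive_acr_min, reactive_acr_min + 2]}.
#' @param excess_toxicity_range Uniform range of the downward log LC50
#'   displacement of reactive records from the baseline line (default
#'   c(1, 3) log units; reactive compounds are more toxic than baseline).
#' @param negative_tro_fraction Fraction of narcosis records whose endpoints
#'   are swapped to produce NOEC > LC50 QC anomalies (default 0).
#' @param seed Integer RNG seed (default 1).
#' @return Object of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_narcosis = 30, n_transition = 0,
                             n_reactive = 10,
                             slope = -0.5, intercept = 2.0,
                             kow_range = c(1.0, 8.5), noise_sd = 0.3,
                             narcosis_acr_range = c(0, 0.9),
                             transition_acr_range = c(1.0, 2.9),
                             reactive_acr_min = 3.0,
                             excess_toxicity_range = c(1.0, 3.0),
                             negative_tro_fraction = 0,
                             seed = 1L) {
  cfg <- list(n_narcosis = n_narcosis, n_transition = n_transition,
              n_reactive = n_reactive, slope = slope, intercept = intercept,
              kow_range = kow_range, noise_sd = noise_sd,
              narcosis_acr_range = narcosis_acr_range,
              transition_acr_range = transition_acr_range,
              reactive_acr_min = reactive_acr_min,
              excess_toxicity_range = excess_toxicity_range,
              negative_tro_fraction = negative_tro_fraction,
              seed = as.integer(seed))
  for (f in c("n_narcosis", "n_transition", "n_reactive")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != round(v))
      stop("invalid config field '", f, "': need a count >= 0", call. = FALSE)
  }
  for (f in c("kow_range", "narcosis_acr_range", "transition_acr_range",
              "excess_toxicity_range")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 2 || any(!is.finite(v)) || v[1] > v[2])
      stop("invalid config field '", f, "': need an increasing [lo, hi]",
           call. = FALSE)
  }
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd < 0)
    stop("invalid config field 'noise_sd': need >= 0", call. = FALSE)
  if (!is.finite(cfg$reactive_acr_min) || cfg$reactive_acr_min < 0)
    stop("invalid config field 'reactive_acr_min': need >= 0", call. = FALSE)
  if (cfg$negative_tro_fraction < 0 || cfg$negative_tro_fraction > 1)
    stop("invalid config field 'negative_tro_fraction': need in [0, 1]",
         call. = FALSE)
  # class separations must land in the class intervals of the default
  # thresholds; a config that violates them is a design error, not noise
  th <- moa_thresholds()
  if (cfg$n_narcosis > 0 && cfg$narcosis_acr_range[2] >= th$narcosis_upper)
    stop("narcosis_acr_range must stay below ", th$narcosis_upper,
         call. = FALSE)
  if (cfg$n_transition > 0 &&
      (cfg$transition_acr_range[1] < th$narcosis_upper ||
       cfg$transition_acr_range[2] >= th$reactive_lower))
    stop("transition_acr_range must lie in [", th$narcosis_upper, ", ",
         th$reactive_lower, ")", call. = FALSE)
  if (cfg$n_reactive > 0 && cfg$reactive_acr_min < th$reactive_lower)
    stop("reactive_acr_min must be >= ", th$reactive_lower, call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("synthetic compound config: %d narcosis / %d transition / %d reactive\n",
              x$n_narcosis, x$n_transition, x$n_reactive))
  cat(sprintf("  baseline: log LC50 = %g %+g * log Kow, noise SD %g; seed %d\n",
              x$intercept, x$slope, x$noise_sd, x$seed))
  invisible(x)
}

#' Generate a synthetic compound table with known structure
#'
#' Draws compounds by class: log Kow uniform over \code{kow_range}; narcosis
#' and transition log LC50 on the baseline line plus Gaussian noise, with
#' log NOEC below log LC50 by a uniform draw from the class's acute-chronic
#' range; reactive log LC50 additionally displaced downward by a uniform
#' excess-toxicity draw, with separation at least \code{reactive_acr_min}.
#' By construction every record's |log TRO| lands inside its class interval.
#' Fully reproducible from \code{config$seed}.
#'
#' @param config A [synthetic_config()] object.
#' @return Compound data frame with ground-truth columns \code{true_class}
#'   and synthetic identifiers; attributes \code{"true_line"} (named vector
#'   \code{intercept}, \code{slope}) and \code{"config"}.
#' @examples
#' d <- simulate_compounds(synthetic_config(seed = 7))
#' table(d$true_class)
#' @export
simulate_compounds <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  draw <- function(n, class, acr_lo, acr_hi, excess = FALSE) {
    if (n == 0) return(NULL)
    kow <- stats::runif(n, config$kow_range[1], config$kow_range[2])
    lc <- config$intercept + config$slope * kow +
      stats::rnorm(n, 0, config$noise_sd)
    if (excess)
      lc <- lc - stats::runif(n, config$excess_toxicity_range[1],
                              config$excess_toxicity_range[2])
    acr <- stats::runif(n, acr_lo, acr_hi)
    data.frame(log_kow = kow, log_lc50 = lc, log_noec = lc - acr,
               true_class = class, stringsAsFactors = FALSE)
  }
  parts <- rbind(
    draw(config$n_narcosis, "NARCOSIS",
         config$narcosis_acr_range[1], config$narcosis_acr_range[2]),
    draw(config$n_transition, "TRANSITION",
         config$transition_acr_range[1], config$transition_acr_range[2]),
    draw(config$n_reactive, "REACTIVE",
         config$reactive_acr_min, config$reactive_acr_min + 2,
         excess = TRUE))
  n <- nrow(parts)
  if (config$negative_tro_fraction > 0) {
    narc <- which(parts$true_class == "NARCOSIS")
    k <- floor(config$negative_tro_fraction * length(narc))
    if (k > 0) {
      swap <- narc[seq_len(k)]
      tmp <- parts$log_lc50[swap]
      parts$log_lc50[swap] <- parts$log_noec[swap]
      parts$log_noec[swap] <- tmp
    }
  }
  out <- data.frame(
    name = sprintf("synthetic-compound-%03d", seq_len(n)),
    cas = sprintf("999%03d-%02d-%d", seq_len(n), seq_len(n) %% 100,
                  seq_len(n) %% 10),
    stringsAsFactors = FALSE)
  out <- cbind(out, parts)
  out <- as_compound_table(out)
  attr(out, "true_line") <- c(intercept = config$intercept,
                              slope = config$slope)
  attr(out, "config") <- config
  out
}

#' Parameter-recovery experiment over replicated synthetic datasets
#'
#' Repeatedly generates contaminated datasets, fits the QSAR line with and
#' without TRO screening, and summarizes how often screening improves the
#' fit and how much closer the screened slope is to the generating slope.
#'
#' @param config A [synthetic_config()]; replicate r reuses it with seed
#'   \code{base_seed + r}.
#' @param n_replicates Number of replicates (>= 1).
#' @param base_seed Base RNG seed.
#' @inheritParams tro_qsar
#' @return Object of class \code{"tro_recovery"}: list with
#'   \code{replicates} (per-replicate slope/intercept/R-squared for both
#'   fits), \code{win_rate} (fraction with screened R-squared strictly
#'   greater), \code{mean_abs_slope_error_screened},
#'   \code{mean_abs_slope_error_unscreened}, and \code{true_line}.
#' @examples
#' recovery_experiment(n_replicates = 5, base_seed = 42)
#' @export
recovery_experiment <- function(config = synthetic_config(),
                                n_replicates = 100, base_seed = 1000L,
                                thresholds = moa_thresholds(),
                                retain = "NARCOSIS",
                                convention = "absolute") {
  stopifnot(inherits(config, "synthetic_config"), n_replicates >= 1)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + r)
    d <- simulate_compounds(cfg)
    fit <- tryCatch(
      tro_qsar(data = d, thresholds = thresholds, retain = retain,
               convention = convention),
      error = function(e) stop("replicate ", r, ": ", conditionMessage(e),
                               call. = FALSE))
    rows[[r]] <- data.frame(
      replicate = r, seed = cfg$seed,
      slope_unscreened = fit$model_initial$slope,
      intercept_unscreened = fit$model_initial$intercept,
      r2_unscreened = fit$model_initial$r_squared,
      slope_screened = fit$model_screened$slope,
      intercept_screened = fit$model_screened$intercept,
      r2_screened = fit$model_screened$r_squared)
  }
  reps <- do.call(rbind, rows)
  structure(list(
    replicates = reps,
    win_rate = mean(reps$r2_screened > reps$r2_unscreened),
    mean_abs_slope_error_screened =
      mean(abs(reps$slope_screened - config$slope)),
    mean_abs_slope_error_unscreened =
      mean(abs(reps$slope_unscreened - config$slope)),
    true_line = c(intercept = config$intercept, slope = config$slope),
    config = config, n_replicates = n_replicates, base_seed = base_seed),
    class = "tro_recovery")
}

#' @export
print.tro_recovery <- function(x, ...) {
  cat(sprintf("TRO screening recovery over %d replicates:\n",
              x$n_replicates))
  cat(sprintf("  screened R2 > unscreened R2 in %.1f%% of replicates\n",
              100 * x$win_rate))
  cat(sprintf("  mean |slope - true|: screened %.4f, unscreened %.4f (true %g)\n",
              x$mean_abs_slope_error_screened,
              x$mean_abs_slope_error_unscreened, x$true_line["slope"]))
  invisible(x)
}
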