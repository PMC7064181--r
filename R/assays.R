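# Estimators for the in-vivo / in-vitro assays: mutation-selection-balance
# mutator strength from equilibrium resistant-mutant frequencies, and
# competitive-fitness decline slopes from marked-clone count series.

# generations-per-day conventions used throughout:
#   19 / day in the mouse gut;
#   10 / day for 1,000-fold serial dilution in vitro (log2(1000) ~ 10);
#   25 / passage for single colony growth to ~1e8 cells on a plate.

#' Generation-conversion constants
#' @format named numeric vector with elements \code{gut_per_day},
#'   \code{serial_dilution_per_day}, \code{plate_passage}.
#' @export
generation_conventions <- c(gut_per_day = 19,
                            serial_dilution_per_day = 10,
                            plate_passage = 25)

#' A resistant-frequency time series
#'
#' @param replicate replicate identifier.
#' @param time time points (any unit; only used for bookkeeping here).
#' @param resistant_count,total_count colony counts per time point.
#' @return a data.frame of class \code{frequency_series} with an added
#'   \code{frequency} column.
#' @export
frequency_series <- function(replicate, time, resistant_count, total_count) {
  stopifnot(length(time) == length(resistant_count),
            length(time) == length(total_count),
            all(resistant_count >= 0), all(total_count > 0),
            all(resistant_count <= total_count))
  out <- data.frame(replicate = replicate, time = time,
                    resistant_count = resistant_count,
                    total_count = total_count,
                    frequency = resistant_count / total_count)
  class(out) <- c("frequency_series", class(out))
  out
}

#' Mutation-selection-balance mutator strength
#'
#' Under mutation-selection balance the equilibrium frequency of resistant
#' mutants is proportional to the mutation rate, so the ratio of mean
#' resistant frequency in a test clone to that in a reference clone
#' estimates the mutation-rate fold change. The mean is taken over all
#' replicates and time points; a log-scale variant (geometric mean of
#' frequencies, back-transformed) is available because frequencies are
#' commonly log10-transformed for inference.
#'
#' @param test,reference lists of \code{\link{frequency_series}} (or single
#'   series).
#' @param scale \code{"arithmetic"} (default) or \code{"log"}.
#' @return the fold change (dimensionless).
#' @export
msb_mutator_strength <- function(test, reference, scale = c("arithmetic", "log")) {
  scale <- match.arg(scale)
  pool <- function(x) {
    if (is.data.frame(x)) x <- list(x)
    if (length(x) == 0L) stop("empty series list")
    unlist(lapply(x, function(s) s$frequency))
  }
  ft <- pool(test); fr <- pool(reference)
  if (scale == "log") {
    if (any(ft <= 0) || any(fr <= 0))
      stop("log scale requires strictly positive frequencies")
    return(exp(mean(log(ft)) - mean(log(fr))))
  }
  mr <- mean(fr)
  if (mr <= 0) stop("reference mean frequency must be > 0")
  mean(ft) / mr
}

#' Log ratio of two marked-clone count series
#'
#' Computes \code{ln(A_t / B_t)} per time point. Where clone A falls below
#' the detection limit (count 0) and the floor rule is on, the count is
#' replaced by 1 and the point is flagged, so a downstream slope is a
#' minimum (bound on the) selection coefficient rather than an estimate.
#'
#' @param countsA,countsB colony counts of the two clones per time point.
#' @param detection_floor_rule replace zero A counts by 1 (default TRUE).
#' @return data.frame with \code{log_ratio} and \code{detection_limited}.
#' @export
log_ratio_series <- function(countsA, countsB, detection_floor_rule = TRUE) {
  stopifnot(length(countsA) == length(countsB), all(countsA >= 0))
  if (any(countsB <= 0)) stop("countsB must be > 0 at all time points")
  flagged <- countsA == 0
  if (any(flagged)) {
    if (!detection_floor_rule)
      stop("zero countsA with detection_floor_rule = FALSE: ratio undefined")
    countsA[flagged] <- 1
  }
  data.frame(log_ratio = log(countsA / countsB), detection_limited = flagged)
}

#' Selection coefficient from a log-ratio series
#'
#' Ordinary least-squares slope of \code{ln(A/B)} against elapsed
#' generations (\code{time * generations_per_day}); a negative slope is a
#' fitness decline of clone A relative to B, per generation.
#'
#' @param log_ratio per-time-point \code{ln(A/B)} values (numeric vector or
#'   the data.frame from \code{\link{log_ratio_series}}).
#' @param times time points in days.
#' @param generations_per_day conversion constant (see
#'   \code{\link{generation_conventions}}).
#' @return list of class \code{slope_estimate}: \code{slope} (per
#'   generation), \code{intercept}, \code{n_points},
#'   \code{detection_limited} (TRUE if any point was floored, in which case
#'   the slope is a bound, not an estimate).
#' @export
fitness_slope <- function(log_ratio, times, generations_per_day = 19) {
  limited <- FALSE
  if (is.data.frame(log_ratio)) {
    limited <- any(log_ratio$detection_limited)
    log_ratio <- log_ratio$log_ratio
  }
  if (length(log_ratio) < 2L) stop("need at least 2 time points")
  stopifnot(length(times) == length(log_ratio), generations_per_day > 0)
  gen <- times * generations_per_day
  fit <- stats::lm.fit(cbind(1, gen), log_ratio)
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 n_points = length(log_ratio),
                 detection_limited = limited),
            class = "slope_estimate")
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("fitness slope: %.4g per generation (%d points)%s\n",
              x$slope, x$n_points,
              if (x$detection_limited) " [detection-limited: minimum selection coefficient]" else ""))
  invisible(x)
}
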