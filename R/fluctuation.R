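# Luria-Delbruck fluctuation analysis: mutant-count distribution, the
# Ma-Sandri-Sarkar (MSS) maximum-likelihood estimate of the expected
# number of mutational events m per culture, and mutation rates with
# Stewart-style 95% confidence intervals (the FALCOR conventions).

#' Luria-Delbruck mutant-count distribution
#'
#' Probability of observing r resistant mutants in a culture in which
#' mutational events occur with expectation \code{m}, by the standard MSS
#' recursion: \code{p0 = exp(-m)},
#' \code{p_r = (m / r) * sum_{i=0}^{r-1} p_i / (r - i + 1)}.
#'
#' @param m expected number of mutational events per culture (>= 0).
#' @param r_max truncation index; probabilities for r = 0..r_max are
#'   returned.
#' @return numeric vector of length \code{r_max + 1}; entries are >= 0 and
#'   sum to at most 1 (the deficit is the mass beyond \code{r_max}).
#' @export
ld_pmf <- function(m, r_max) {
  stopifnot(m >= 0, r_max >= 0)
  p <- numeric(r_max + 1)
  p[1] <- exp(-m)
  if (m == 0 || r_max == 0) return(p)
  for (r in seq_len(r_max)) {
    i <- 0:(r - 1)
    p[r + 1] <- (m / r) * sum(p[i + 1] / (r - i + 1))
  }
  p
}

# truncation large enough that the omitted tail is negligible for
# likelihood work at the observed counts
ld_rmax <- function(m, r_obs_max = 0) {
  max(100L, r_obs_max * 2L + 10L, ceiling(m * 50))
}

#' Bundle parallel-culture counts into a fluctuation experiment
#'
#' @param Nt final (total) cell count per culture; recycled if scalar.
#' @param r resistant-colony count per culture.
#' @param plating_fraction fraction of each culture plated (fixed at 1
#'   here; the field exists for forward compatibility).
#' @return a \code{fluctuation_experiment} object.
#' @export
fluctuation_experiment <- function(Nt, r, plating_fraction = 1) {
  if (length(Nt) == 1L) Nt <- rep(Nt, length(r))
  stopifnot(length(Nt) == length(r), all(Nt > 0), all(r >= 0), all(r <= Nt),
            plating_fraction > 0, plating_fraction <= 1)
  structure(list(Nt = Nt, r = as.integer(r),
                 plating_fraction = plating_fraction),
            class = "fluctuation_experiment")
}

#' Simulate parallel cultures of a fluctuation assay
#'
#' Resistant counts are drawn from the Luria-Delbruck distribution with
#' \code{m = rate * Nt} expected mutational events per culture (tail beyond
#' the truncation lumped by renormalised sampling).
#'
#' @param rate mutation rate per cell per generation.
#' @param Nt final cell count per culture.
#' @param n_cultures number of parallel cultures.
#' @return a \code{\link{fluctuation_experiment}}.
#' @export
simulate_cultures <- function(rate, Nt, n_cultures) {
  stopifnot(rate >= 0, Nt > 0, n_cultures >= 1)
  m <- rate * Nt
  if (m > 500)
    stop("m = rate * Nt > 500: the mutant-count recursion underflows; ",
         "assay a smaller culture (lower Nt), as done experimentally by ",
         "plating dilutions")
  if (m == 0) return(fluctuation_experiment(Nt, rep(0L, n_cultures)))
  p <- ld_pmf(m, ld_rmax(m))
  r <- sample.int(length(p), n_cultures, replace = TRUE, prob = p) - 1L
  fluctuation_experiment(Nt, r)
}

mss_loglik <- function(m, r) {
  p <- ld_pmf(m, ld_rmax(m, max(r)))
  lp <- log(pmax(p[r + 1L], 1e-300))
  sum(lp)
}

#' MSS maximum-likelihood estimate of m and the mutation rate
#'
#' Maximises the Luria-Delbruck log-likelihood of the observed resistant
#' counts over \code{m} (bounded scalar search; ties broken toward smaller
#' m). The mutation rate is \code{m_hat / mean(Nt)} per cell per
#' generation, with a 95\% confidence interval from the Stewart
#' log-normal approximation used by FALCOR:
#' \code{sigma_ln(m) = 1.225 * m_hat^(-0.315) / sqrt(C)} for C cultures,
#' and rate CI = rate * exp(+-1.96 * sigma).
#'
#' @param exp_ a \code{\link{fluctuation_experiment}} with >= 2 cultures.
#' @return list of class \code{mutation_rate_estimate}: \code{m_hat},
#'   \code{rate}, \code{ci_low}, \code{ci_high}, \code{n_cultures},
#'   \code{degenerate} (TRUE when all counts are zero and the CI is not
#'   meaningful).
#' @export
estimate_m_mss <- function(exp_) {
  stopifnot(inherits(exp_, "fluctuation_experiment"))
  r <- exp_$r
  C <- length(r)
  if (C < 2L) stop("need at least 2 cultures")
  mean_Nt <- mean(exp_$Nt)
  if (all(r == 0L)) {
    out <- list(m_hat = 0, rate = 0, ci_low = 0, ci_high = 0,
                n_cultures = C, degenerate = TRUE)
    return(structure(out, class = "mutation_rate_estimate"))
  }
  # bracket: m cannot plausibly exceed a few times the mean count
  upper <- max(2, mean(r) * 4, max(r))
  opt <- stats::optimize(function(m) -mss_loglik(m, r),
                         interval = c(1e-8, upper), tol = 1e-6)
  m_hat <- opt$minimum
  rate <- m_hat / mean_Nt
  sigma <- 1.225 * m_hat^(-0.315) / sqrt(C)
  out <- list(m_hat = m_hat, rate = rate,
              ci_low = rate * exp(-1.96 * sigma),
              ci_high = rate * exp(1.96 * sigma),
              n_cultures = C, degenerate = FALSE)
  structure(out, class = "mutation_rate_estimate")
}

#' @export
print.mutation_rate_estimate <- function(x, ...) {
  cat(sprintf("MSS estimate: m = %.4g, rate = %.3g [%.3g, %.3g] per cell per generation (C = %d)%s\n",
              x$m_hat, x$rate, x$ci_low, x$ci_high, x$n_cultures,
              if (isTRUE(x$degenerate)) " [degenerate: all counts 0]" else ""))
  invisible(x)
}

#' Mutator strength (mutation-rate fold change)
#'
#' @param rate estimated mutation rate of the clone of interest.
#' @param reference_rate rate of the reference (ancestral) clone (> 0).
#' @return \code{rate / reference_rate}.
#' @export
mutator_strength <- function(rate, reference_rate) {
  if (any(reference_rate <= 0)) stop("reference_rate must be > 0")
  rate / reference_rate
}

#' Do two rate estimates differ significantly?
#'
#' The working significance rule for fluctuation assays: two clones differ
#' in mutation rate when their 95\% confidence intervals do not overlap.
#'
#' @param a,b \code{mutation_rate_estimate} objects.
#' @return logical.
#' @export
rates_differ <- function(a, b) {
  stopifnot(inherits(a, "mutation_rate_estimate"),
            inherits(b, "mutation_rate_estimate"))
  a$ci_high < b$ci_low || b$ci_high < a$ci_low
}
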