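#' Distribution-of-fitness-effects model
#'
#' Constructs a specification of the distribution of fitness effects (DFE)
#' used by all forward simulators. Four kinds are supported:
#' \describe{
#'   \item{\code{fixed}}{every mutation is deleterious with the same effect
#'     \code{s_d}.}
#'   \item{\code{fixed_with_neutral}}{a fraction \code{f_neut} of mutations
#'     is neutral, the rest deleterious with fixed effect \code{s_d}.}
#'   \item{\code{exponential_deleterious}}{deleterious effects drawn from an
#'     exponential distribution with mean \code{s_d}.}
#'   \item{\code{exponential_mixture}}{a fraction \code{f_ben} of mutations
#'     is beneficial with exponentially distributed effect (mean
#'     \code{s_b}); the rest deleterious, exponential with mean \code{s_d};
#'     an optional neutral fraction is allowed.}
#' }
#'
#' Effects are dimensionless selection coefficients per generation, stored
#' as positive magnitudes; deleterious mutations multiply fitness by
#' \code{1 - s}, beneficial ones by \code{1 + s}.
#'
#' @param kind one of \code{"fixed"}, \code{"fixed_with_neutral"},
#'   \code{"exponential_deleterious"}, \code{"exponential_mixture"}.
#' @param s_d mean (or fixed) deleterious effect, >= 0.
#' @param f_neut neutral fraction in \[0, 1\].
#' @param f_ben beneficial fraction in \[0, 1\].
#' @param s_b mean beneficial effect, >= 0.
#' @return an object of class \code{"dfe_model"}.
#' @examples
#' dfe_model("fixed", s_d = 0.001)
#' dfe_model("exponential_mixture", s_d = 1e-4, f_ben = 0.01, s_b = 0.01)
#' @export
dfe_model <- function(kind = c("fixed", "fixed_with_neutral",
                               "exponential_deleterious",
                               "exponential_mixture"),
                      s_d = 0, f_neut = 0, f_ben = 0, s_b = 0) {
  kind <- match.arg(kind)
  if (!is.finite(s_d) || s_d < 0) stop("s_d must be finite and >= 0")
  if (!is.finite(s_b) || s_b < 0) stop("s_b must be finite and >= 0")
  if (f_neut < 0 || f_neut > 1) stop("f_neut must be in [0, 1]")
  if (f_ben < 0 || f_ben > 1) stop("f_ben must be in [0, 1]")
  if (f_neut + f_ben > 1) stop("f_neut + f_ben must be <= 1")
  if (f_neut > 0 && kind %in% c("fixed", "exponential_deleterious"))
    stop("f_neut > 0 requires kind 'fixed_with_neutral' or 'exponential_mixture'")
  if (f_ben > 0 && kind != "exponential_mixture")
    stop("f_ben > 0 requires kind 'exponential_mixture'")
  structure(list(kind = kind, s_d = s_d, f_neut = f_neut,
                 f_ben = f_ben, s_b = s_b),
            class = "dfe_model")
}

#' @export
print.dfe_model <- function(x, ...) {
  cat("DFE model:", x$kind, "\n")
  cat(sprintf("  s_d = %g, f_neut = %g, f_ben = %g, s_b = %g\n",
              x$s_d, x$f_neut, x$f_ben, x$s_b))
  invisible(x)
}

is_fixed_dfe <- function(dfe) {
  dfe$kind %in% c("fixed", "fixed_with_neutral")
}

#' Sample per-mutation fitness effects from a DFE
#'
#' Draws \code{k} mutation effects. Categories (neutral / beneficial /
#' deleterious) are drawn with probabilities \code{(f_neut, f_ben,
#' 1 - f_neut - f_ben)}; magnitudes are the fixed \code{s_d} for the fixed
#' kinds and exponential with the stated means otherwise. Effects are
#' independent across mutations (multiplicative, non-epistatic model).
#'
#' @param dfe a \code{\link{dfe_model}}.
#' @param k number of new mutations (>= 0).
#' @return a data.frame with columns \code{category} (factor with levels
#'   deleterious/neutral/beneficial) and \code{magnitude} (>= 0; 0 for
#'   neutral).
#' @export
sample_effects <- function(dfe, k) {
  stopifnot(inherits(dfe, "dfe_model"))
  if (length(k) != 1L || is.na(k) || k < 0) stop("k must be a single count >= 0")
  k <- as.integer(k)
  lev <- c("deleterious", "neutral", "beneficial")
  if (k == 0L) {
    return(data.frame(category = factor(character(), levels = lev),
                      magnitude = numeric()))
  }
  u <- stats::runif(k)
  cat_idx <- ifelse(u < dfe$f_neut, 2L,
                    ifelse(u < dfe$f_neut + dfe$f_ben, 3L, 1L))
  mag <- numeric(k)
  del <- cat_idx == 1L
  ben <- cat_idx == 3L
  if (is_fixed_dfe(dfe)) {
    mag[del] <- dfe$s_d
  } else {
    mag[del] <- stats::rexp(sum(del), rate = 1 / dfe$s_d)
  }
  if (any(ben)) mag[ben] <- stats::rexp(sum(ben), rate = 1 / dfe$s_b)
  data.frame(category = factor(lev[cat_idx], levels = lev), magnitude = mag)
}

#' Multiplicative fitness factor of a set of mutation effects
#'
#' Total fitness is the product over mutations of \code{1 - s} for
#' deleterious and \code{1 + s} for beneficial effects (neutral mutations
#' contribute 1). Exponential draws are unbounded, so a deleterious
#' magnitude above 1 can occur; the product is clamped below at 0 (a
#' non-positive factor means the genotype is lethal and contributes no
#' sampling weight).
#'
#' @param effects a data.frame as returned by \code{\link{sample_effects}}.
#' @return a single non-negative fitness factor.
#' @export
fitness_multiplier <- function(effects) {
  if (nrow(effects) == 0L) return(1)
  f <- rep(1, nrow(effects))
  del <- effects$category == "deleterious"
  ben <- effects$category == "beneficial"
  f[del] <- 1 - effects$magnitude[del]
  f[ben] <- 1 + effects$magnitude[ben]
  if (any(f <= 0)) return(0)
  prod(f)
}

# Per-effect log-fitness increments with the lethal clamp deferred:
# deleterious magnitudes >= 1 return -Inf so that exp() gives fitness 0.
log_fitness_increment <- function(category, magnitude) {
  out <- numeric(length(magnitude))
  del <- category == 1L | category == "deleterious"
  ben <- category == 3L | category == "beneficial"
  out[del] <- ifelse(magnitude[del] >= 1, -Inf, log1p(-magnitude[del]))
  out[ben] <- log1p(magnitude[ben])
  out
}
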