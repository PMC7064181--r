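# ---- population state ------------------------------------------------------
#
# Two interchangeable representations of the genetic composition of a
# clonal population:
#
#  * "classes": individuals are binned by (deleterious count i, neutral
#    count j); exact for fixed-effect DFEs and cheap even at N = 1e6
#    because fitness depends only on i.
#  * "individuals": per-individual accumulated log fitness and per-category
#    mutation counts; required for continuous (exponential) DFEs.

#' Create a mutation-free population
#'
#' @param N population size (individuals).
#' @param dfe a \code{\link{dfe_model}}; fixed-effect kinds get the exact
#'   class-based representation, continuous kinds the individual-based one.
#' @param representation \code{"auto"} (default), \code{"classes"} or
#'   \code{"individuals"}.
#' @return a \code{population_state} object.
#' @export
new_population <- function(N, dfe,
                           representation = c("auto", "classes", "individuals")) {
  representation <- match.arg(representation)
  stopifnot(inherits(dfe, "dfe_model"), N >= 1)
  if (representation == "auto")
    representation <- if (is_fixed_dfe(dfe)) "classes" else "individuals"
  if (representation == "classes" && !is_fixed_dfe(dfe))
    stop("classes representation requires a fixed-effect DFE")
  st <- if (representation == "classes") {
    list(representation = "classes",
         i = 0L, j = 0L, n = as.numeric(N),
         N = N, generation = 0L, extinct = FALSE)
  } else {
    list(representation = "individuals",
         log_fitness = numeric(N),
         n_del = integer(N), n_neut = integer(N), n_ben = integer(N),
         N = N, generation = 0L, extinct = FALSE)
  }
  structure(st, class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Wright-Fisher population: N = %g, generation = %d (%s)%s\n",
              x$N, x$generation, x$representation,
              if (x$extinct) " [EXTINCT]" else ""))
  invisible(x)
}

# truncation of the per-offspring Poisson(U) mutation kick; the discarded
# tail mass is < 1e-12
poisson_support <- function(U) {
  if (U <= 0) return(list(k = 0L, p = 1))
  kmax <- max(1L, stats::qpois(1 - 1e-12, U))
  p <- stats::dpois(0:kmax, U)
  list(k = 0:kmax, p = p / sum(p))
}

class_log_fitness <- function(i, s_d) {
  if (s_d <= 0) return(numeric(length(i)))
  if (s_d >= 1) return(ifelse(i > 0, -Inf, 0))
  i * log1p(-s_d)
}

# spread offspring of each class across Poisson(U) mutation increments and
# re-aggregate; key = i * 2^20 + j stays well under 2^53
spread_classes <- function(i, j, n, supd, supn) {
  nd <- length(supd$k); nn <- length(supn$k)
  if (nd == 1L && nn == 1L) return(list(i = i, j = j, n = n))
  pj <- as.vector(outer(supd$p, supn$p))
  di <- rep(supd$k, times = nn)
  dj <- rep(supn$k, each = nd)
  m <- length(i)
  out_i <- vector("list", m); out_j <- vector("list", m); out_n <- vector("list", m)
  for (c in seq_len(m)) {
    cnt <- as.vector(stats::rmultinom(1L, n[c], pj))
    keep <- cnt > 0L
    out_i[[c]] <- i[c] + di[keep]
    out_j[[c]] <- j[c] + dj[keep]
    out_n[[c]] <- cnt[keep]
  }
  ii <- unlist(out_i); jj <- unlist(out_j); nn2 <- unlist(out_n)
  key <- ii * 1048576 + jj
  agg <- rowsum(nn2, key, reorder = TRUE)
  k <- as.numeric(rownames(agg))
  list(i = as.integer(k %/% 1048576), j = as.integer(k %% 1048576),
       n = as.vector(agg))
}

step_classes <- function(state, U, dfe) {
  logw <- class_log_fitness(state$i, dfe$s_d)
  w <- state$n * exp(logw)
  tot <- sum(w)
  if (tot <= 0) { state$extinct <- TRUE; return(state) }
  off <- as.vector(stats::rmultinom(1L, state$N, w))
  keep <- off > 0L
  Ud <- U * (1 - dfe$f_neut)
  Un <- U * dfe$f_neut
  sp <- spread_classes(state$i[keep], state$j[keep], off[keep],
                       poisson_support(Ud), poisson_support(Un))
  state$i <- sp$i; state$j <- sp$j; state$n <- sp$n
  state$generation <- state$generation + 1L
  state
}

step_individuals <- function(state, U, dfe) {
  w <- exp(state$log_fitness)
  if (all(w <= 0)) { state$extinct <- TRUE; return(state) }
  N <- state$N
  # multinomial offspring counts per parent (O(parents), unlike weighted
  # sample.int which is O(parents * N))
  cnt <- as.vector(stats::rmultinom(1L, N, w))
  idx <- rep.int(seq_along(w), cnt)
  logw <- state$log_fitness[idx]
  n_del <- state$n_del[idx]; n_neut <- state$n_neut[idx]; n_ben <- state$n_ben[idx]
  k <- stats::rpois(N, U)
  tot <- sum(k)
  if (tot > 0L) {
    owner <- rep.int(seq_len(N), k)
    u <- stats::runif(tot)
    cat_idx <- ifelse(u < dfe$f_neut, 2L,
                      ifelse(u < dfe$f_neut + dfe$f_ben, 3L, 1L))
    mag <- numeric(tot)
    del <- cat_idx == 1L; ben <- cat_idx == 3L
    if (is_fixed_dfe(dfe)) mag[del] <- dfe$s_d
    else mag[del] <- stats::rexp(sum(del), rate = 1 / dfe$s_d)
    if (any(ben)) mag[ben] <- stats::rexp(sum(ben), rate = 1 / dfe$s_b)
    dlog <- log_fitness_increment(cat_idx, mag)
    inc <- rowsum(cbind(dlog, cat_idx == 1L, cat_idx == 2L, ben),
                  owner, reorder = FALSE)
    who <- as.integer(rownames(inc))
    logw[who] <- logw[who] + inc[, 1L]
    n_del[who] <- n_del[who] + as.integer(inc[, 2L])
    n_neut[who] <- n_neut[who] + as.integer(inc[, 3L])
    n_ben[who] <- n_ben[who] + as.integer(inc[, 4L])
  }
  state$log_fitness <- logw
  state$n_del <- n_del; state$n_neut <- n_neut; state$n_ben <- n_ben
  state$generation <- state$generation + 1L
  state
}

#' Advance a population by one Wright-Fisher generation
#'
#' One generation consists of (1) multinomial resampling of \code{N}
#' offspring with weights proportional to parental absolute fitness, then
#' (2) each offspring acquiring \code{Poisson(U)} new mutations with
#' effects drawn from the DFE. A population whose total fitness weight is
#' zero (all genotypes lethal) is flagged extinct and no longer advanced.
#'
#' @param state a \code{population_state}.
#' @param U genomic mutation rate per genome per generation (>= 0).
#' @param dfe a \code{\link{dfe_model}}.
#' @return the updated \code{population_state}.
#' @export
step_generation <- function(state, U, dfe) {
  stopifnot(inherits(state, "population_state"), U >= 0,
            inherits(dfe, "dfe_model"))
  if (state$extinct) return(state)
  if (state$representation == "classes") step_classes(state, U, dfe)
  else step_individuals(state, U, dfe)
}

#' Summary statistics of a population state
#'
#' Reports the recorded quantities: mean and standard deviation of fitness
#' and of the per-individual total mutation count, and the number of
#' mutations carried by the least-loaded class (the minimum present).
#'
#' @param state a \code{population_state}.
#' @param dfe the \code{\link{dfe_model}} the population evolves under
#'   (needed to evaluate class fitness in the classes representation).
#' @return a one-row data.frame: \code{generation}, \code{mean_fitness},
#'   \code{sd_fitness}, \code{mean_mutations}, \code{sd_mutations},
#'   \code{least_loaded}, \code{extinct}.
#' @export
summarize_population <- function(state, dfe) {
  stopifnot(inherits(state, "population_state"))
  if (state$representation == "classes") {
    wcl <- exp(class_log_fitness(state$i, dfe$s_d))
    ntot <- sum(state$n)
    p <- state$n / ntot
    mut <- state$i + state$j
    mf <- sum(p * wcl); sf <- sqrt(max(0, sum(p * wcl^2) - mf^2))
    mm <- sum(p * mut); sm <- sqrt(max(0, sum(p * mut^2) - mm^2))
    ll <- min(mut)
  } else {
    w <- exp(state$log_fitness)
    mut <- state$n_del + state$n_neut + state$n_ben
    mf <- mean(w); sf <- stats::sd(w)
    mm <- mean(mut); sm <- stats::sd(mut)
    ll <- min(mut)
  }
  data.frame(generation = state$generation, mean_fitness = mf,
             sd_fitness = sf, mean_mutations = mm, sd_mutations = sm,
             least_loaded = ll, extinct = state$extinct)
}

#' Per-class mutation-count spectrum
#'
#' Aggregates a population into total-mutation-count classes and their
#' relative frequencies (the quantity shaded in Muller-style plots).
#'
#' @param state a \code{population_state}.
#' @return data.frame with columns \code{mutations} and \code{freq},
#'   sorted by mutation count.
#' @export
class_spectrum <- function(state) {
  if (state$representation == "classes") {
    mut <- state$i + state$j; n <- state$n
  } else {
    mut <- state$n_del + state$n_neut + state$n_ben
    n <- rep(1, length(mut))
  }
  agg <- rowsum(n, mut, reorder = TRUE)
  data.frame(mutations = as.integer(rownames(agg)),
             freq = as.vector(agg) / sum(n))
}

#' Largest mutation-count class at or above a frequency cutoff
#'
#' @param state a \code{population_state}.
#' @param min_freq within-population frequency cutoff (default 1\%,
#'   roughly the smallest class visible on a Muller plot).
#' @return the maximum mutation count among classes with frequency
#'   >= \code{min_freq} (NA for an empty population).
#' @export
top_class_at_freq <- function(state, min_freq = 0.01) {
  sp <- class_spectrum(state)
  ok <- sp$freq >= min_freq
  if (!any(ok)) return(NA_integer_)
  max(sp$mutations[ok])
}

#' Simulate a monoclonal population
#'
#' Runs \code{\link{step_generation}} for a fixed number of generations,
#' recording summaries at checkpoints. The representation is chosen
#' automatically: exact mutation-count classes for fixed-effect DFEs,
#' per-individual records for continuous DFEs.
#'
#' @param N population size.
#' @param U genomic mutation rate per genome per generation.
#' @param dfe a \code{\link{dfe_model}}.
#' @param generations number of generations to simulate.
#' @param record_every checkpoint interval in generations; the final
#'   generation is always recorded.
#' @param representation forwarded to \code{\link{new_population}}.
#' @param keep_state if TRUE, the final \code{population_state} is attached
#'   as attribute \code{"state"}.
#' @return data.frame of summaries (one row per checkpoint).
#' @export
simulate_population <- function(N, U, dfe, generations,
                                record_every = generations,
                                representation = "auto",
                                keep_state = FALSE) {
  stopifnot(generations >= 0, record_every >= 1)
  st <- new_population(N, dfe, representation)
  out <- vector("list", 0L)
  if (generations == 0L) out <- list(summarize_population(st, dfe))
  for (t in seq_len(generations)) {
    st <- step_generation(st, U, dfe)
    if (st$extinct || t %% record_every == 0L || t == generations) {
      out[[length(out) + 1L]] <- summarize_population(st, dfe)
      if (st$extinct) break
    }
  }
  res <- do.call(rbind, out)
  res <- res[!duplicated(res$generation), , drop = FALSE]
  rownames(res) <- NULL
  if (keep_state) attr(res, "state") <- st
  res
}

#' Deterministic infinite-population oracle for the fixed-effect model
#'
#' Under deterministic mutation-selection dynamics with Poisson-distributed
#' mutation counts, the mean count follows the recursion
#' \code{lambda[t+1] = lambda[t] * (1 - s_d) + U} from \code{lambda[0] = 0},
#' and the mean fitness is \code{exp(-s_d * lambda[t])}. This is exact in
#' the absence of drift and is used as an independent check on the
#' stochastic engine.
#'
#' @param U genomic mutation rate.
#' @param s_d fixed deleterious effect, in \[0, 1).
#' @param t number of generations.
#' @param path if TRUE return the whole trajectory (length \code{t + 1}).
#' @return list with \code{mean_mutations} and \code{mean_fitness}.
#' @export
poisson_recursion_oracle <- function(U, s_d, t, path = FALSE) {
  stopifnot(s_d >= 0, s_d < 1, t >= 0, U >= 0)
  lam <- numeric(t + 1)
  for (k in seq_len(t)) lam[k + 1] <- lam[k] * (1 - s_d) + U
  if (path) list(mean_mutations = lam, mean_fitness = exp(-s_d * lam))
  else list(mean_mutations = lam[t + 1], mean_fitness = exp(-s_d * lam[t + 1]))
}

#' Does a simulated mutation count fit the observed range?
#'
#' The fit criterion used on the simulation grids: a parameter combination
#' "fits" if the simulated mean number of accumulated mutations lies within
#' the (inclusive) range observed across sequenced clones.
#'
#' @param summary a summary row from \code{\link{simulate_population}} or a
#'   bare numeric mean mutation count.
#' @param observed_min,observed_max inclusive range bounds.
#' @return logical.
#' @export
fits_observed_range <- function(summary, observed_min, observed_max) {
  if (observed_min > observed_max) stop("observed_min must be <= observed_max")
  x <- if (is.data.frame(summary)) summary$mean_mutations else summary
  x >= observed_min & x <= observed_max
}
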