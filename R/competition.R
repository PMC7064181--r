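# Two-subpopulation competition: a marker locus determines the genomic
# mutation rate (U1 vs U2); an optional negative frequency-dependent
# selection (NFDS) term acts on the marker.

#' Configuration of a two-clone competition
#'
#' @param N total population size (constant).
#' @param U1,U2 genomic mutation rates of subpopulations 1 and 2.
#' @param dfe a \code{\link{dfe_model}} shared by both subpopulations.
#' @param s_freq NFDS strength on the marker locus (0 disables NFDS).
#' @param init_freq1 initial frequency of subpopulation 1.
#' @param generations number of generations to simulate.
#' @return a \code{competition_config} object.
#' @export
competition_config <- function(N, U1, U2, dfe, s_freq = 0,
                               init_freq1 = 0.5, generations = 1000L) {
  stopifnot(inherits(dfe, "dfe_model"), N >= 2, U1 >= 0, U2 >= 0,
            s_freq >= 0, init_freq1 >= 0, init_freq1 <= 1, generations >= 0)
  structure(list(N = N, U1 = U1, U2 = U2, dfe = dfe, s_freq = s_freq,
                 init_freq1 = init_freq1,
                 generations = as.integer(generations)),
            class = "competition_config")
}

#' Frequency-dependent fitness multipliers
#'
#' The NFDS term multiplies the total fitness of subpopulation 1 by
#' \code{1 + s_freq * (1 - p1)} and that of subpopulation 2 by
#' \code{1 + s_freq * p1}: each clone gains when rare.
#'
#' @param p1 current frequency of subpopulation 1 in \[0, 1\].
#' @param s_freq NFDS strength (>= 0).
#' @return numeric vector \code{c(m1, m2)}.
#' @export
nfds_weights <- function(p1, s_freq) {
  stopifnot(p1 >= 0, p1 <= 1, s_freq >= 0)
  c(1 + s_freq * (1 - p1), 1 + s_freq * p1)
}

# total fitness weight of a subpopulation state (0 for an absorbed one)
subpop_weight <- function(state, dfe) {
  if (is.null(state) || state$N == 0) return(0)
  if (state$representation == "classes")
    sum(state$n * exp(class_log_fitness(state$i, dfe$s_d)))
  else sum(exp(state$log_fitness))
}

# resample a subpopulation to a new size and mutate offspring; the
# within-subpopulation step is multinomial conditional on the drawn size
# (the standard conditional decomposition of full multinomial sampling)
resample_subpop <- function(state, new_size, U, dfe) {
  if (new_size == 0) { state$N <- 0L; state$n <- numeric(0)
    state$i <- integer(0); state$j <- integer(0)
    state$log_fitness <- numeric(0)
    state$n_del <- integer(0); state$n_neut <- integer(0); state$n_ben <- integer(0)
    return(state) }
  state$N <- new_size
  step_generation(state, U, dfe)
}

#' Simulate a two-clone competition with optional NFDS
#'
#' Each generation: total subpopulation fitnesses \code{W1}, \code{W2} are
#' computed (sums of individual or class fitness weights); the next-generation
#' size of subpopulation 1 is drawn \code{Binomial(N, p)} with
#' \code{p = m1 W1 / (m1 W1 + m2 W2)} where \code{(m1, m2)} are the
#' \code{\link{nfds_weights}} (both 1 when \code{s_freq = 0});
#' \code{N2 = N - N1}. Within each subpopulation, offspring are then drawn
#' multinomially with fitness-proportional weights conditional on the new
#' size and mutated at the subpopulation's own rate. A subpopulation that
#' reaches size 0 is absorbed.
#'
#' @param cfg a \code{\link{competition_config}}.
#' @param representation \code{"auto"}, \code{"classes"} or
#'   \code{"individuals"} (applied to both subpopulations).
#' @param stop_at_loss optional minority-frequency threshold in (0, 0.5);
#'   when given, the run halts as soon as coexistence is lost (the
#'   minority clone drops below the threshold), truncating the
#'   trajectory.
#' @return a \code{competition_trajectory}: list with \code{trajectory}
#'   (data.frame: generation, N1, N2, p1, per-subpopulation mean fitness
#'   and mean mutation count), \code{state1}, \code{state2} (final
#'   \code{population_state}s) and \code{cfg}.
#' @export
simulate_competition <- function(cfg, representation = "auto",
                                 stop_at_loss = NULL) {
  stopifnot(inherits(cfg, "competition_config"))
  if (!is.null(stop_at_loss))
    stopifnot(stop_at_loss > 0, stop_at_loss < 0.5)
  dfe <- cfg$dfe
  N <- cfg$N
  N1 <- as.integer(round(N * cfg$init_freq1)); N2 <- N - N1
  s1 <- if (N1 > 0) new_population(N1, dfe, representation) else NULL
  s2 <- if (N2 > 0) new_population(N2, dfe, representation) else NULL
  gens <- cfg$generations
  tr <- data.frame(generation = 0:gens, N1 = NA_real_, N2 = NA_real_,
                   p1 = NA_real_, mean_fitness1 = NA_real_,
                   mean_fitness2 = NA_real_, mean_mutations1 = NA_real_,
                   mean_mutations2 = NA_real_)
  record <- function(row, t) {
    tr$N1[row] <<- N1; tr$N2[row] <<- N2; tr$p1[row] <<- N1 / N
    if (N1 > 0) { sm <- summarize_population(s1, dfe)
      tr$mean_fitness1[row] <<- sm$mean_fitness
      tr$mean_mutations1[row] <<- sm$mean_mutations }
    if (N2 > 0) { sm <- summarize_population(s2, dfe)
      tr$mean_fitness2[row] <<- sm$mean_fitness
      tr$mean_mutations2[row] <<- sm$mean_mutations }
  }
  record(1L, 0L)
  for (t in seq_len(gens)) {
    W1 <- subpop_weight(s1, dfe) * (N1 > 0)
    W2 <- subpop_weight(s2, dfe) * (N2 > 0)
    if (W1 + W2 <= 0) {
      tr <- tr[1:t, , drop = FALSE]
      return(structure(list(trajectory = tr, state1 = s1, state2 = s2,
                            cfg = cfg, extinct = TRUE),
                       class = "competition_trajectory"))
    }
    if (N1 == 0L) { p <- 0 } else if (N2 == 0L) { p <- 1 } else {
      m <- nfds_weights(N1 / N, cfg$s_freq)
      p <- m[1] * W1 / (m[1] * W1 + m[2] * W2)
    }
    N1 <- stats::rbinom(1L, N, p); N2 <- N - N1
    if (N1 > 0) s1 <- resample_subpop(s1, N1, cfg$U1, dfe)
    if (N2 > 0) s2 <- resample_subpop(s2, N2, cfg$U2, dfe)
    record(t + 1L, t)
    if (!is.null(stop_at_loss) && min(N1, N2) / N < stop_at_loss) {
      tr <- tr[1:(t + 1L), , drop = FALSE]
      break
    }
  }
  structure(list(trajectory = tr, state1 = s1, state2 = s2, cfg = cfg,
                 extinct = FALSE),
            class = "competition_trajectory")
}

#' @export
print.competition_trajectory <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  cat(sprintf("Competition trajectory: %d generations, final p1 = %.3f%s\n",
              last$generation, last$p1,
              if (isTRUE(x$extinct)) " [EXTINCT]" else ""))
  invisible(x)
}

#' First generation at which coexistence is lost
#'
#' Coexistence is considered lost once the minority clone drops below the
#' given frequency threshold (an absorbed subpopulation, frequency 0, also
#' counts).
#'
#' @param traj a \code{competition_trajectory}.
#' @param threshold minority-frequency cutoff in (0, 0.5); default 1\%.
#' @return the first generation with \code{min(p1, 1 - p1) < threshold},
#'   or NA if coexistence holds throughout.
#' @export
time_to_loss <- function(traj, threshold = 0.01) {
  stopifnot(inherits(traj, "competition_trajectory"),
            threshold > 0, threshold < 0.5)
  p1 <- traj$trajectory$p1
  hit <- which(pmin(p1, 1 - p1) < threshold)
  if (length(hit) == 0L) return(NA_integer_)
  traj$trajectory$generation[hit[1L]]
}

#' Time-averaged frequency of subpopulation 1
#'
#' @param traj a \code{competition_trajectory}.
#' @param from_gen,to_gen inclusive generation window.
#' @return mean of \code{p1} over the window.
#' @export
mean_frequency <- function(traj, from_gen, to_gen) {
  stopifnot(inherits(traj, "competition_trajectory"))
  g <- traj$trajectory$generation
  if (from_gen < min(g) || to_gen > max(g) || from_gen > to_gen)
    stop("window [from_gen, to_gen] outside the recorded trajectory")
  sel <- g >= from_gen & g <= to_gen
  mean(traj$trajectory$p1[sel])
}

#' Deterministic NFDS equilibrium frequency
#'
#' With a constant per-capita fitness deficit \code{delta} in subpopulation
#' 1 and NFDS strength \code{s_freq}, the deterministic expectation map has
#' a fixed point solving
#' \code{(1 + s_freq (1 - p)) (1 - delta) = 1 + s_freq p}. Used as an
#' oracle against simulated equilibria.
#'
#' @param s_freq NFDS strength (> 0).
#' @param delta per-capita relative fitness deficit of subpopulation 1.
#' @return equilibrium frequency of subpopulation 1 (clamped to \[0, 1\]).
#' @export
nfds_equilibrium <- function(s_freq, delta = 0) {
  stopifnot(s_freq > 0)
  p <- ((1 + s_freq) * (1 - delta) - 1) / (s_freq * (2 - delta))
  min(1, max(0, p))
}
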