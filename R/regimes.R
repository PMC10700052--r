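#' Fitness regimes
#'
#' A fitness regime is a rule mapping (generation index, current allele
#' frequency, regime state, randomness) to the mutant's relative fitness for
#' that generation. Regimes are plugged into [wf_sim()] and the batch
#' drivers; all of them are vectorised over replicates so that large
#' experiments can be run without per-replicate loops.
#'
#' Available regimes:
#' \describe{
#'   \item{`regime_constant(f)`}{fitness `f` every generation.}
#'   \item{`regime_block(f1, f2, n_switch)`}{`f1` for generations
#'     `1..n_switch`, `f2` afterwards.}
#'   \item{`regime_alternating(f_odd, f_even)`}{`f_odd` in odd generations,
#'     `f_even` in even ones.}
#'   \item{`regime_markov_switch(f1, f2, switch_prob)`}{a two-state Markov
#'     chain: the initial fitness is `f1` or `f2` with equal probability and
#'     from generation 2 onward the state switches with probability
#'     `switch_prob` before selection acts. With `switch_prob = 0.05` the
#'     waiting time between switches is geometric with mean 20 generations.}
#'   \item{`regime_poisson_block(f1, f2, mean_block = 20)`}{block durations
#'     drawn from a Poisson distribution with the given mean (durations of 0
#'     are redrawn as 1); provided as a variant of the Markov-switching
#'     regime with Poisson rather than geometric waiting times.}
#'   \item{`regime_frequency_dependent(f_low, f_high, threshold)`}{fitness
#'     `f_low` while the frequency is below `threshold`, `f_high` at or
#'     above it. The canonical example is `f_low = 1.01`, `f_high = 0.9`,
#'     `threshold = 0.99`: beneficial at intermediate frequency,
#'     deleterious only when nearly fixed.}
#'   \item{`regime_target_delta(delta_schedule)`}{per-generation target
#'     selection-driven frequency changes; each generation the fitness is
#'     recomputed from the current frequency via [fitness_for_delta()] so
#'     the realised expected change equals the schedule regardless of
#'     drift. Generations beyond the schedule are neutral (f = 1).}
#' }
#'
#' @param f,f1,f2,f_odd,f_even,f_low,f_high relative fitness values
#'   (strictly positive).
#' @param n_switch generation index at which a block regime changes from
#'   `f1` to `f2`.
#' @param switch_prob per-generation probability of switching state, in
#'   \[0, 1\].
#' @param mean_block mean of the Poisson block-length distribution.
#' @param threshold frequency threshold in (0, 1) for the
#'   frequency-dependent regime.
#' @param delta_schedule numeric vector of per-generation target selection
#'   components of frequency change.
#'
#' @return An object of class `wf_regime`.
#' @examples
#' r <- regime_markov_switch(11 / 10, 10 / 11, 0.05)
#' traj <- wf_sim(ne = 1000, init_freq = 0.5, regime = r,
#'                max_generations = 50, seed = 1)
#' summary(traj)
#' @name regimes
NULL

new_regime <- function(kind, ...) {
  structure(list(kind = kind, ...), class = c(paste0("wf_regime_", kind), "wf_regime"))
}

check_fitness <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("relative fitness values must be strictly positive and finite", call. = FALSE)
  invisible(vals)
}

#' @rdname regimes
#' @export
regime_constant <- function(f) {
  check_fitness(f)
  new_regime("constant", f = f)
}

#' @rdname regimes
#' @export
regime_block <- function(f1, f2, n_switch) {
  check_fitness(f1, f2)
  stopifnot(n_switch >= 1)
  new_regime("block", f1 = f1, f2 = f2, n_switch = as.integer(n_switch))
}

#' @rdname regimes
#' @export
regime_alternating <- function(f_odd, f_even) {
  check_fitness(f_odd, f_even)
  new_regime("alternating", f_odd = f_odd, f_even = f_even)
}

#' @rdname regimes
#' @export
regime_markov_switch <- function(f1, f2, switch_prob) {
  check_fitness(f1, f2)
  if (switch_prob < 0 || switch_prob > 1)
    stop("switch_prob must be in [0, 1]", call. = FALSE)
  new_regime("markov_switch", f1 = f1, f2 = f2, switch_prob = switch_prob)
}

#' @rdname regimes
#' @export
regime_poisson_block <- function(f1, f2, mean_block = 20) {
  check_fitness(f1, f2)
  stopifnot(mean_block > 0)
  new_regime("poisson_block", f1 = f1, f2 = f2, mean_block = mean_block)
}

#' @rdname regimes
#' @export
regime_frequency_dependent <- function(f_low, f_high, threshold) {
  check_fitness(f_low, f_high)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  new_regime("frequency_dependent", f_low = f_low, f_high = f_high,
             threshold = threshold)
}

#' @rdname regimes
#' @export
regime_target_delta <- function(delta_schedule) {
  stopifnot(is.numeric(delta_schedule), length(delta_schedule) >= 1,
            all(is.finite(delta_schedule)))
  new_regime("target_delta", delta_schedule = as.numeric(delta_schedule))
}

#' @export
print.wf_regime <- function(x, ...) {
  pars <- x[setdiff(names(x), "kind")]
  pars <- vapply(names(pars), function(nm) {
    v <- pars[[nm]]
    if (length(v) > 4) v <- c(format(v[1:4], digits = 4), "...")
    paste0(nm, " = ", paste(format(v, digits = 6), collapse = ", "))
  }, character(1))
  cat("<wf_regime: ", x$kind, "> ", paste(pars, collapse = "; "), "\n", sep = "")
  invisible(x)
}

## Internal vectorised regime protocol.
##
## regime_init(regime, nrep)           -> state (NULL or a list of vectors
##                                        of length nrep)
## regime_fitness(regime, state, q, gen) -> list(f = <numeric nrep>,
##                                             state = <updated state>)
## State vectors are subset with keep_state() when replicates absorb.

regime_init <- function(regime, nrep) UseMethod("regime_init")
regime_fitness <- function(regime, state, q, gen) UseMethod("regime_fitness")

#' @export
regime_init.wf_regime <- function(regime, nrep) NULL

#' @export
regime_init.wf_regime_markov_switch <- function(regime, nrep) {
  list(in_f1 = stats::runif(nrep) < 0.5)
}

#' @export
regime_init.wf_regime_poisson_block <- function(regime, nrep) {
  list(in_f1 = stats::runif(nrep) < 0.5,
       remaining = pmax(stats::rpois(nrep, regime$mean_block), 1L))
}

keep_state <- function(state, keep) {
  if (is.null(state)) return(NULL)
  lapply(state, function(v) v[keep])
}

#' @export
regime_fitness.wf_regime_constant <- function(regime, state, q, gen) {
  list(f = rep(regime$f, length(q)), state = state)
}

#' @export
regime_fitness.wf_regime_block <- function(regime, state, q, gen) {
  f <- if (gen <= regime$n_switch) regime$f1 else regime$f2
  list(f = rep(f, length(q)), state = state)
}

#' @export
regime_fitness.wf_regime_alternating <- function(regime, state, q, gen) {
  f <- if (gen %% 2 == 1) regime$f_odd else regime$f_even
  list(f = rep(f, length(q)), state = state)
}

#' @export
regime_fitness.wf_regime_markov_switch <- function(regime, state, q, gen) {
  if (gen > 1) {
    flip <- stats::runif(length(q)) < regime$switch_prob
    state$in_f1 <- xor(state$in_f1, flip)
  }
  list(f = ifelse(state$in_f1, regime$f1, regime$f2), state = state)
}

#' @export
regime_fitness.wf_regime_poisson_block <- function(regime, state, q, gen) {
  if (gen > 1) {
    state$remaining <- state$remaining - 1L
    done <- state$remaining <= 0L
    if (any(done)) {
      state$in_f1[done] <- !state$in_f1[done]
      state$remaining[done] <- pmax(stats::rpois(sum(done), regime$mean_block), 1L)
    }
  }
  list(f = ifelse(state$in_f1, regime$f1, regime$f2), state = state)
}

#' @export
regime_fitness.wf_regime_frequency_dependent <- function(regime, state, q, gen) {
  list(f = ifelse(q < regime$threshold, regime$f_low, regime$f_high),
       state = state)
}

#' @export
regime_fitness.wf_regime_target_delta <- function(regime, state, q, gen) {
  if (gen > length(regime$delta_schedule)) {
    f <- rep(1, length(q))
  } else {
    d <- regime$delta_schedule[gen]
    qd <- q + d
    f <- rep(NA_real_, length(q))
    ok <- qd > 0 & qd < 1 & q > 0 & q < 1
    f[ok] <- 1 + d / (q[ok] * (1 - q[ok] - d))
  }
  # NA marks replicates for which no fitness achieves the target change;
  # callers decide whether that is an error (single run) or a discard (batch).
  list(f = f, state = state)
}
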