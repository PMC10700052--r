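#' Vectorised batch simulation
#'
#' Simulates many independent replicate populations in lock-step, one
#' binomial draw per generation across all still-active replicates. This is
#' the engine behind the experiment drivers: it returns per-replicate
#' summaries (not full trajectories), which is what the summary statistics
#' f_G, f_E and C need.
#'
#' `wf_batch_absorb()` runs every replicate to fixation or loss (or to
#' `max_generations`, recording the outcome as `"censored"`).
#' `wf_batch_horizon()` runs a fixed number of generations; replicates that
#' absorb early keep their boundary frequency and stop accumulating fitness
#' and frequency-change terms (the per-replicate `absorbed_gen` records
#' when, `NA` if never).
#'
#' Replicates that hit a generation where a target-delta regime admits no
#' valid fitness (the target change would leave (0, 1)) are recorded with
#' outcome `"invalid"` and are treated as discards by the experiment
#' drivers.
#'
#' @param nrep number of replicates.
#' @param ne haploid population size.
#' @param init_copies,init_freq initial state, as in [wf_sim()].
#' @param regime a [regimes] object.
#' @param generations (horizon variant) number of generations to simulate.
#' @param max_generations (absorbing variant) safety cap; `Inf` by default.
#' @param linear use the linear selection rule of [wf_sim_linear()].
#' @param seed optional integer seed for the whole batch.
#'
#' @return A data frame with one row per replicate, in replicate order:
#'   `outcome` (`fixed`/`lost`/`censored`/`invalid`), `n_generations`
#'   (generations actually simulated), `final_copies`, `sum_delta_s`,
#'   `sum_delta_d`, `sum_log_f`, plus the derived statistics `f_g`, `f_e`
#'   and `c_value` (see [trajectory_metrics()]); the horizon variant also
#'   has `absorbed_gen`.
#' @export
wf_batch_absorb <- function(nrep, ne, init_copies = NULL, init_freq = NULL,
                            regime, max_generations = Inf, linear = FALSE,
                            seed = NULL) {
  wf_batch_impl(nrep, ne, init_copies, init_freq, regime,
                horizon = NULL, max_generations = max_generations,
                linear = linear, seed = seed)
}

#' @rdname wf_batch_absorb
#' @export
wf_batch_horizon <- function(nrep, ne, init_copies = NULL, init_freq = NULL,
                             regime, generations, linear = FALSE,
                             seed = NULL) {
  stopifnot(generations >= 1)
  wf_batch_impl(nrep, ne, init_copies, init_freq, regime,
                horizon = as.integer(generations),
                max_generations = generations, linear = linear, seed = seed)
}

wf_batch_impl <- function(nrep, ne, init_copies, init_freq, regime, horizon,
                          max_generations, linear, seed) {
  stopifnot(inherits(regime, "wf_regime"), nrep >= 1, ne >= 2)
  init_copies <- resolve_init_copies(ne, init_copies, init_freq)
  if (!is.null(seed)) set.seed(seed)

  # Per-replicate accumulators, full length; `active` indexes live replicates.
  q <- rep(init_copies / ne, nrep)
  sum_ds <- sum_dd <- sum_logf <- numeric(nrep)
  ngen <- integer(nrep)
  invalid <- logical(nrep)
  absorbed_gen <- rep(NA_integer_, nrep)
  active <- seq_len(nrep)
  state <- regime_init(regime, nrep)

  gen <- 0L
  while (length(active) > 0L && gen < max_generations) {
    gen <- gen + 1L
    qa <- q[active]
    rf <- regime_fitness(regime, state, qa, gen)
    state <- rf$state
    f <- rf$f

    bad <- is.na(f)
    if (any(bad)) {
      idx <- active[bad]
      invalid[idx] <- TRUE
      absorbed_gen[idx] <- gen
      active <- active[!bad]
      state <- keep_state(state, !bad)
      qa <- qa[!bad]; f <- f[!bad]
      if (length(active) == 0L) break
    }

    p <- if (linear) pmin(pmax(qa * f, 0), 1) else qa * f / (1 + qa * (f - 1))
    qn <- stats::rbinom(length(active), ne, p) / ne
    sum_ds[active] <- sum_ds[active] + (p - qa)
    sum_dd[active] <- sum_dd[active] + (qn - p)
    sum_logf[active] <- sum_logf[active] + log(f)
    ngen[active] <- gen
    q[active] <- qn

    done <- qn == 0 | qn == 1
    if (any(done)) {
      absorbed_gen[active[done]] <- gen
      active <- active[!done]
      state <- keep_state(state, !done)
    }
  }

  outcome <- ifelse(invalid, "invalid",
             ifelse(q == 1, "fixed", ifelse(q == 0, "lost", "censored")))
  mean_ds <- ifelse(ngen > 0, sum_ds / ngen, 0)
  res <- data.frame(
    outcome = outcome,
    n_generations = ngen,
    final_copies = as.integer(round(q * ne)),
    sum_delta_s = sum_ds,
    sum_delta_d = sum_dd,
    sum_log_f = sum_logf,
    f_g = ifelse(ngen > 0, exp(sum_logf / ngen), NA_real_),
    f_e = (0.5 + mean_ds) / (0.5 - mean_ds),
    c_value = relative_selection_effect(sum_ds, sum_dd)
  )
  if (!is.null(horizon)) res$absorbed_gen <- absorbed_gen
  res
}
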