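#' ROC AUC by the rank-sum (Mann-Whitney) formulation
#'
#' The area under the ROC curve for a score predicting a binary outcome,
#' computed as the Mann-Whitney U statistic divided by `n1 * n0`, with ties
#' handled by midranks. Equals the probability that a randomly chosen
#' positive outscores a randomly chosen negative (ties counting one half).
#'
#' @param scores numeric scores; higher predicts the positive class.
#' @param positive logical vector, `TRUE` for the positive class.
#' @return The AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive), is.logical(positive))
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("need both classes present", call. = FALSE)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

new_experiment <- function(name, table, config, records = NULL, extra = list()) {
  structure(c(list(name = name, table = table, config = config,
                   records = records), extra),
            class = "wf_experiment")
}

#' @export
print.wf_experiment <- function(x, ...) {
  cat("<wf_experiment: ", x$name, ">\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

fg1_fe1_regime <- function(scenario, n) {
  switch(scenario,
    block_fg1 = ,
    linear_fg1 = regime_block(5 / 6, 6 / 5, n),
    alternating_fg1 = regime_alternating(5 / 6, 6 / 5),
    block_fe1 = regime_target_delta(c(rep(-0.045, n), rep(0.045, n))),
    stop("unknown scenario: ", scenario, call. = FALSE)
  )
}

#' Controlled f_G = 1 / f_E = 1 frequency-change experiment
#'
#' Simulates a mutant starting at frequency 0.5 in a haploid population
#' through `2n` generations of fluctuating selection engineered so that one
#' fitness summary is exactly 1, and asks whether the mean final frequency
#' has moved away from 0.5. Scenarios:
#' \describe{
#'   \item{`block_fg1`}{fitness 5/6 for the first `n` generations, 6/5 for
#'     the next `n`, so the geometric mean fitness is exactly 1.}
#'   \item{`alternating_fg1`}{fitness 5/6 in odd and 6/5 in even
#'     generations (same multiset, faster cycling).}
#'   \item{`linear_fg1`}{as `block_fg1` but under the hypothetical linear
#'     selection rule `E(q') = f q`, which removes the nonlinearity that
#'     biases geometric-mean fitness.}
#'   \item{`block_fe1`}{each generation's fitness is chosen from the current
#'     frequency so the expected selection-driven change is exactly -0.045
#'     for `n` generations then +0.045 for `n` generations, making the
#'     effective fitness exactly 1.}
#' }
#' Runs in which the mutant fixes or is lost before the end of the `2n`
#' generations (or, in `block_fe1`, where no fitness can achieve the target
#' change) are discarded from the mean but counted.
#'
#' @param n_values values of `n` (half the horizon) to run.
#' @param reps replicates per `n`.
#' @param scenario one of the four scenario names above.
#' @param ne haploid population size.
#' @param init_freq initial frequency.
#' @param seed integer seed for the whole experiment.
#' @param alpha significance level of the two-sided one-sample t-test of the
#'   final frequencies against `init_freq`.
#' @return A `wf_experiment` whose table has, per `n`: `reps`, `n_discarded`,
#'   `mean_final_freq`, `mean_final_count`, `ci_low`, `ci_high`, `t_stat`,
#'   `p_value`, `significant`.
#' @export
run_fg1_fe1_experiment <- function(n_values = 1:7, reps = 500000,
                                   scenario = c("block_fg1", "alternating_fg1",
                                                "linear_fg1", "block_fe1"),
                                   ne = 1000, init_freq = 0.5, seed = NULL,
                                   alpha = 0.05) {
  scenario <- match.arg(scenario)
  stopifnot(reps >= 2)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(n_values, function(n) {
    b <- wf_batch_horizon(reps, ne, init_freq = init_freq,
                          regime = fg1_fe1_regime(scenario, n),
                          generations = 2 * n,
                          linear = scenario == "linear_fg1")
    discarded <- !is.na(b$absorbed_gen) & (b$absorbed_gen < 2 * n |
                                             b$outcome == "invalid")
    q <- b$final_copies[!discarded] / ne
    tt <- stats::t.test(q, mu = init_freq)
    data.frame(n = n, reps = reps, n_discarded = sum(discarded),
               mean_final_freq = mean(q), mean_final_count = ne * mean(q),
               ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
               t_stat = unname(tt$statistic), p_value = tt$p.value,
               significant = tt$p.value < alpha)
  })
  new_experiment(paste0("fg1_fe1/", scenario), do.call(rbind, rows),
                 config = list(scenario = scenario, n_values = n_values,
                               reps = reps, ne = ne, init_freq = init_freq,
                               seed = seed, alpha = alpha))
}

default_fluctuating_regime <- function() {
  regime_markov_switch(11 / 10, 10 / 11, 0.05)
}

#' Conditional final-frequency prediction experiment
#'
#' Simulates 200 generations of Markov-switching fluctuating selection and
#' collects, in run order, the first `n_runs_per_bin` runs whose final
#' frequency equals each target exactly (targets are lattice points: "final
#' frequency 0.100" means a final copy number of exactly `0.1 * ne`). For
#' each collected run the final frequency is then *inferred* from the run's
#' fitness summaries alone: `q_G` from the geometric mean fitness via
#' [predict_freq_from_fg()] and `q_E` from the effective fitness via
#' [predict_freq_from_fe()]. Per bin and per predictor the driver reports
#' bias, bias^2, variance and MSE of the inferred values against the true
#' final frequency (MSE = bias^2 + variance exactly).
#'
#' @param targets target final frequencies (multiples of `1/ne`).
#' @param n_runs_per_bin quota per target bin (0 gives an empty row).
#' @param ne population size.
#' @param init_freq initial frequency (0.01 or 0.5 in the canonical setup).
#' @param generations horizon (200).
#' @param regime fitness regime (default: switch between 11/10 and 10/11
#'   with per-generation probability 0.05).
#' @param seed integer seed.
#' @param batch_size replicates per simulation batch.
#' @param max_total_runs give up (with whatever was collected) after this
#'   many runs.
#' @return A `wf_experiment`; its table has one row per (target, predictor)
#'   with `n_collected`, `attempts`, `bias`, `bias2`, `variance`, `mse`.
#' @export
run_conditional_frequency_experiment <- function(targets = seq(0.1, 0.9, by = 0.1),
                                                 n_runs_per_bin = 500,
                                                 ne = 1000, init_freq = 0.01,
                                                 generations = 200,
                                                 regime = default_fluctuating_regime(),
                                                 seed = NULL,
                                                 batch_size = 20000,
                                                 max_total_runs = 5e7) {
  target_copies <- round(targets * ne)
  if (any(abs(target_copies - targets * ne) > 1e-9))
    stop("targets must be multiples of 1/ne", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  collected <- stats::setNames(
    lapply(seq_along(targets), function(i) list(f_g = numeric(0), f_e = numeric(0))),
    as.character(target_copies))
  attempts <- 0
  while (attempts < max_total_runs &&
         any(vapply(collected, function(z) length(z$f_g), 1L) < n_runs_per_bin)) {
    b <- wf_batch_horizon(batch_size, ne, init_freq = init_freq,
                          regime = regime, generations = generations)
    attempts <- attempts + batch_size
    done_at_end <- is.na(b$absorbed_gen)  # ran the full horizon
    for (i in seq_along(target_copies)) {
      key <- as.character(target_copies[i])
      need <- n_runs_per_bin - length(collected[[key]]$f_g)
      if (need <= 0) next
      hit <- which(done_at_end & b$final_copies == target_copies[i])
      if (length(hit) > need) hit <- hit[seq_len(need)]
      collected[[key]]$f_g <- c(collected[[key]]$f_g, b$f_g[hit])
      collected[[key]]$f_e <- c(collected[[key]]$f_e, b$f_e[hit])
    }
  }
  rows <- list()
  for (i in seq_along(targets)) {
    key <- as.character(target_copies[i])
    truth <- target_copies[i] / ne
    for (pred in c("f_g", "f_e")) {
      vals <- collected[[key]][[pred]]
      if (length(vals) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          target = truth, predictor = pred, n_collected = 0L,
          attempts = attempts, bias = NA_real_, bias2 = NA_real_,
          variance = NA_real_, mse = NA_real_)
        next
      }
      inferred <- if (pred == "f_g")
        predict_freq_from_fg(init_freq, vals, generations)
      else
        suppressWarnings(predict_freq_from_fe(init_freq, vals, generations))
      bias <- mean(inferred) - truth
      variance <- mean((inferred - mean(inferred))^2)
      rows[[length(rows) + 1]] <- data.frame(
        target = truth, predictor = pred, n_collected = length(vals),
        attempts = attempts, bias = bias, bias2 = bias^2,
        variance = variance, mse = mean((inferred - truth)^2))
    }
  }
  new_experiment("conditional_frequency", do.call(rbind, rows),
                 config = list(targets = targets, n_runs_per_bin = n_runs_per_bin,
                               ne = ne, init_freq = init_freq,
                               generations = generations, seed = seed,
                               batch_size = batch_size, attempts = attempts))
}

collect_absorbed_runs <- function(ne, init_copies, regime, quota_fun,
                                  batch_size, max_total_runs,
                                  max_generations = Inf) {
  records <- NULL
  attempts <- 0
  repeat {
    b <- wf_batch_absorb(batch_size, ne, init_copies = init_copies,
                         regime = regime, max_generations = max_generations)
    attempts <- attempts + batch_size
    b$run <- attempts - batch_size + seq_len(batch_size)
    b <- b[b$outcome %in% c("fixed", "lost"), ]
    records <- if (is.null(records)) b else rbind(records, b)
    if (quota_fun(records) || attempts >= max_total_runs) break
  }
  list(records = records, attempts = attempts)
}

#' Fixation/loss outcome prediction experiment
#'
#' Simulates a mutant under fluctuating selection until fixation or loss,
#' records each run's effective fitness `f_e`, geometric mean fitness `f_g`
#' and relative selection effect `C`, and evaluates how well each fitness
#' summary discriminates eventual fixations from losses: the ROC AUC of
#' `f_e` and of `f_g` over the first `n_fixed` fixation runs and first
#' `n_lost` loss runs, plus the fixed:lost composition of the two
#' "contradiction" subsets (the first `n_contradiction` runs with
#' `f_e > 1 & f_g < 1`, and with `f_e < 1 & f_g > 1`).
#'
#' @param ne population size.
#' @param init_copies initial copy number (use `init_freq` alternatively).
#' @param init_freq initial frequency.
#' @param n_fixed,n_lost quotas of fixation and loss runs for the AUC.
#' @param n_contradiction quota per contradiction subset (0 to skip).
#' @param regime fitness regime.
#' @param seed integer seed.
#' @param batch_size replicates per batch.
#' @param max_total_runs safety cap on total simulated runs.
#' @return A `wf_experiment`. Its table has `auc_fe` and `auc_fg`; the
#'   `contradictions` element counts outcomes in each subset; `records`
#'   holds the per-run statistics used.
#' @export
run_outcome_prediction_experiment <- function(ne = 1000, init_copies = NULL,
                                              init_freq = NULL,
                                              n_fixed = 5000, n_lost = 5000,
                                              n_contradiction = 0,
                                              regime = default_fluctuating_regime(),
                                              seed = NULL, batch_size = 20000,
                                              max_total_runs = 2e7) {
  init_copies <- resolve_init_copies(ne, init_copies, init_freq)
  if (!is.null(seed)) set.seed(seed)
  quota_fun <- function(r) {
    sum(r$outcome == "fixed") >= n_fixed && sum(r$outcome == "lost") >= n_lost &&
      (n_contradiction == 0 ||
         (sum(r$f_e > 1 & r$f_g < 1) >= n_contradiction &&
          sum(r$f_e < 1 & r$f_g > 1) >= n_contradiction))
  }
  got <- collect_absorbed_runs(ne, init_copies, regime, quota_fun,
                               batch_size, max_total_runs)
  r <- got$records
  fixed <- r[r$outcome == "fixed", ][seq_len(min(n_fixed, sum(r$outcome == "fixed"))), ]
  lost <- r[r$outcome == "lost", ][seq_len(min(n_lost, sum(r$outcome == "lost"))), ]
  sel <- rbind(fixed, lost)
  pos <- sel$outcome == "fixed"
  tab <- data.frame(n_fixed = nrow(fixed), n_lost = nrow(lost),
                    attempts = got$attempts,
                    auc_fe = roc_auc(sel$f_e, pos),
                    auc_fg = roc_auc(sel$f_g, pos))
  contradictions <- NULL
  if (n_contradiction > 0) {
    sub1 <- r[r$f_e > 1 & r$f_g < 1, ]
    sub2 <- r[r$f_e < 1 & r$f_g > 1, ]
    sub1 <- sub1[seq_len(min(n_contradiction, nrow(sub1))), ]
    sub2 <- sub2[seq_len(min(n_contradiction, nrow(sub2))), ]
    contradictions <- data.frame(
      subset = c("fe>1 & fg<1", "fe<1 & fg>1"),
      n = c(nrow(sub1), nrow(sub2)),
      n_fixed = c(sum(sub1$outcome == "fixed"), sum(sub2$outcome == "fixed")),
      n_lost = c(sum(sub1$outcome == "lost"), sum(sub2$outcome == "lost")))
  }
  new_experiment("outcome_prediction", tab,
                 config = list(ne = ne, init_copies = init_copies,
                               n_fixed = n_fixed, n_lost = n_lost,
                               n_contradiction = n_contradiction, seed = seed,
                               batch_size = batch_size),
                 records = sel,
                 extra = list(contradictions = contradictions))
}

#' New-mutation fate experiment
#'
#' Introduces a single copy of an allele into a haploid population under
#' fluctuating selection, runs each replicate to fixation or loss, and
#' summarises the contribution of selection to each fate through the
#' relative selection effect `C`, the effective fitness `f_e` and the
#' geometric mean fitness `f_g`. Reports, among losses, the fractions with
#' `|C| < 0.5` (drift-dominated losses) and `|C| < cutoff` (effectively
#' neutral), and among fixations the fractions with `C > 0.5` and with
#' `f_e > 1`.
#'
#' @param ne population size.
#' @param regime fitness regime.
#' @param n_fixed quota of fixation runs (0 to analyse losses only;
#'   fixations of a single copy are roughly `1/ne` of runs, so large quotas
#'   are expensive).
#' @param n_lost quota of loss runs.
#' @param neutrality_cutoff `|C|` cutoff for the effectively-neutral call.
#' @param seed integer seed.
#' @param batch_size replicates per batch.
#' @param max_total_runs safety cap.
#' @return A `wf_experiment`; the table has one row per outcome class with
#'   count and fractions; `records` holds the per-run long table
#'   (`outcome`, `c_value`, `f_e`, `f_g`, `n_generations`), ready for
#'   violin-style plots.
#' @export
run_new_mutation_experiment <- function(ne = 1000,
                                        regime = default_fluctuating_regime(),
                                        n_fixed = 5000, n_lost = 5000,
                                        neutrality_cutoff = 0.05, seed = NULL,
                                        batch_size = 20000,
                                        max_total_runs = 2e7) {
  if (!is.null(seed)) set.seed(seed)
  quota_fun <- function(r) {
    sum(r$outcome == "fixed") >= n_fixed && sum(r$outcome == "lost") >= n_lost
  }
  got <- collect_absorbed_runs(ne, 1L, regime, quota_fun, batch_size,
                               max_total_runs)
  r <- got$records
  fixed <- r[r$outcome == "fixed", ][seq_len(min(n_fixed, sum(r$outcome == "fixed"))), ]
  lost <- r[r$outcome == "lost", ][seq_len(min(n_lost, sum(r$outcome == "lost"))), ]
  frac <- function(x) if (length(x) == 0) NA_real_ else mean(x, na.rm = TRUE)
  tab <- data.frame(
    outcome = c("lost", "fixed"),
    n = c(nrow(lost), nrow(fixed)),
    frac_absC_lt_0.5 = c(frac(abs(lost$c_value) < 0.5),
                         frac(abs(fixed$c_value) < 0.5)),
    frac_neutral = c(frac(is_effectively_neutral(lost$c_value, neutrality_cutoff)),
                     frac(is_effectively_neutral(fixed$c_value, neutrality_cutoff))),
    frac_C_gt_0.5 = c(frac(lost$c_value > 0.5), frac(fixed$c_value > 0.5)),
    frac_fe_gt_1 = c(frac(lost$f_e > 1), frac(fixed$f_e > 1)),
    mean_C = c(frac(lost$c_value), frac(fixed$c_value)),
    mean_fe = c(frac(lost$f_e), frac(fixed$f_e)),
    mean_fg = c(frac(lost$f_g), frac(fixed$f_g)))
  keep <- c("outcome", "c_value", "f_e", "f_g", "n_generations")
  new_experiment("new_mutation", tab,
                 config = list(ne = ne, n_fixed = n_fixed, n_lost = n_lost,
                               neutrality_cutoff = neutrality_cutoff,
                               seed = seed, batch_size = batch_size,
                               attempts = got$attempts),
                 records = rbind(fixed[, keep], lost[, keep]))
}
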