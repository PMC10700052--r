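#' Geometric mean fitness
#'
#' The n-th root of the product of per-generation relative fitness values,
#' computed stably in log space. Without drift, fluctuating selection over
#' `n` generations changes allele frequency exactly as constant selection
#' with this value would (the multiplicability of relative fitness); with
#' drift it becomes a biased summary of the overall selective effect.
#'
#' @param fitnesses nonempty numeric vector of strictly positive values.
#' @return The geometric mean.
#' @examples
#' geometric_mean_fitness(c(5 / 6, 6 / 5))  # exactly 1
#' @export
geometric_mean_fitness <- function(fitnesses) {
  if (length(fitnesses) == 0)
    stop("fitnesses must be a nonempty vector", call. = FALSE)
  check_fitness(fitnesses)
  exp(mean(log(fitnesses)))
}

#' Effective fitness
#'
#' The constant relative fitness with which an allele at frequency 0.5
#' would have an expected one-generation selection-driven frequency change
#' equal to the observed mean change \eqn{\bar{\Delta}_s}:
#' \deqn{f_E = \frac{0.5 + \bar{\Delta}_s}{0.5 - \bar{\Delta}_s}.}
#' Unlike geometric mean fitness, it weights each generation's fitness by
#' how much selection could actually move the frequency there, so it
#' remains an (approximately) unbiased summary under drift.
#'
#' @param delta_s_seq numeric vector of per-generation selection components
#'   of frequency change (a single precomputed mean also works).
#' @return The effective fitness; the inverse relation
#'   \eqn{\bar{\Delta}_s = (f_E - 1) / (2 (f_E + 1))} holds to machine
#'   precision.
#' @examples
#' effective_fitness(c(-0.045, 0.045))  # exactly 1
#' @export
effective_fitness <- function(delta_s_seq) {
  if (length(delta_s_seq) == 0)
    stop("delta_s_seq must be nonempty", call. = FALSE)
  m <- mean(delta_s_seq)
  if (!is.finite(m) || abs(m) >= 0.5)
    stop("mean delta_s must lie strictly inside (-0.5, 0.5)", call. = FALSE)
  (0.5 + m) / (0.5 - m)
}

#' Relative selection effect C
#'
#' The signed share of selection in the total allele-frequency change over a
#' period: \deqn{C = \frac{\sum \Delta_{s,i}}{|\sum \Delta_{s,i}| +
#' |\sum \Delta_{d,i}|}.} `C` is positive when selection pushed the
#' frequency up, negative when it pushed it down, lies in \[-1, 1\], and is
#' undefined (returned as `NA`) when both totals are zero.
#'
#' @param sum_delta_s total selection-driven change (vectorised).
#' @param sum_delta_d total drift-driven change (vectorised).
#' @return `C`, or `NA` where undefined.
#' @examples
#' relative_selection_effect(0.1, -0.3)  # 0.25
#' @export
relative_selection_effect <- function(sum_delta_s, sum_delta_d) {
  den <- abs(sum_delta_s) + abs(sum_delta_d)
  ifelse(den > 0, sum_delta_s / den, NA_real_)
}

#' Effective neutrality call
#'
#' An allele's overall behaviour over a period is called effectively neutral
#' when the magnitude of the relative selection effect is below a cutoff
#' (strictly: `|C| < cutoff`), i.e. when drift, not selection, dominated its
#' frequency change. An undefined `C` (`NA`) propagates to `NA`.
#'
#' @param c_value relative selection effect(s) from
#'   [relative_selection_effect()].
#' @param cutoff positive cutoff, 0.05 by default.
#' @return Logical (`NA` where `C` is undefined).
#' @export
is_effectively_neutral <- function(c_value, cutoff = 0.05) {
  stopifnot(cutoff > 0)
  abs(c_value) < cutoff
}

#' Predicted frequency after n generations from a fitness summary
#'
#' `predict_freq_from_fg()` treats the geometric mean fitness as a constant
#' fitness acting deterministically for `n` generations:
#' \deqn{q_G = \frac{q_0 f_G^n}{1 + q_0 (f_G^n - 1)}.}
#' `predict_freq_from_fe()` uses the linear accumulation of the mean
#' selection-driven change implied by the effective fitness:
#' \deqn{q_E = q_0 + n \frac{f_E - 1}{2 (f_E + 1)}.}
#' `q_E` is deliberately not clamped to \[0, 1\] (clamping would bias the
#' bias/variance/MSE comparison between the two predictors); a warning is
#' emitted when any predicted value falls outside the unit interval.
#'
#' @param q0 initial frequency, strictly inside (0, 1).
#' @param f_g,f_e fitness summary (vectorised).
#' @param n number of generations (>= 0).
#' @return Predicted frequency (unclamped for `predict_freq_from_fe`).
#' @export
predict_freq_from_fg <- function(q0, f_g, n) {
  stopifnot(q0 > 0, q0 < 1, n >= 0)
  check_fitness(f_g)
  r <- f_g^n
  q0 * r / (1 + q0 * (r - 1))
}

#' @rdname predict_freq_from_fg
#' @export
predict_freq_from_fe <- function(q0, f_e, n) {
  stopifnot(q0 > 0, q0 < 1, n >= 0)
  check_fitness(f_e)
  q <- q0 + n * (f_e - 1) / (2 * (f_e + 1))
  if (any(q < 0 | q > 1))
    warning("predicted frequency outside [0, 1]; returned unclamped",
            call. = FALSE)
  q
}

#' Per-trajectory summary statistics
#'
#' Computes the summary statistics of a simulated trajectory: the geometric
#' mean fitness `f_g`, the mean selection-driven change and the effective
#' fitness `f_e`, the selection and drift change totals, the relative
#' selection effect `c_value`, and the outcome. `summary()` on a `wf_traj`
#' object dispatches here.
#'
#' All statistics are computed over the generations actually simulated (for
#' a censored trajectory, the period observed); the generation in which the
#' allele fixes or is lost contributes its `delta_s`, computed from the last
#' interior frequency.
#'
#' @param trajectory a `wf_traj` object from [wf_sim()] with at least one
#'   generation.
#' @param object,x,... method arguments.
#' @return An object of class `wf_metrics`: a list with fields
#'   `n_generations`, `f_g`, `mean_delta_s`, `f_e`, `sum_delta_s`,
#'   `sum_delta_d`, `c_value` (`NA` if undefined), `outcome`.
#' @export
trajectory_metrics <- function(trajectory) {
  stopifnot(inherits(trajectory, "wf_traj"))
  g <- trajectory$generations
  if (nrow(g) == 0) stop("trajectory has no generations", call. = FALSE)
  sds <- sum(g$delta_s); sdd <- sum(g$delta_d)
  structure(list(
    n_generations = nrow(g),
    f_g = geometric_mean_fitness(g$fitness),
    mean_delta_s = mean(g$delta_s),
    f_e = effective_fitness(g$delta_s),
    sum_delta_s = sds,
    sum_delta_d = sdd,
    c_value = relative_selection_effect(sds, sdd),
    outcome = trajectory$outcome
  ), class = "wf_metrics")
}

#' @rdname trajectory_metrics
#' @export
summary.wf_traj <- function(object, ...) trajectory_metrics(object)

#' @rdname trajectory_metrics
#' @export
print.wf_metrics <- function(x, ...) {
  cat(sprintf("Trajectory summary over %d generation(s) [%s]\n",
              x$n_generations, x$outcome))
  cat(sprintf("  f_G = %.6g   f_E = %.6g   mean delta_s = %.4g\n",
              x$f_g, x$f_e, x$mean_delta_s))
  cat(sprintf("  sum delta_s = %.6g   sum delta_d = %.6g   C = %s\n",
              x$sum_delta_s, x$sum_delta_d,
              if (is.na(x$c_value)) "undefined" else format(x$c_value, digits = 4)))
  invisible(x)
}
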