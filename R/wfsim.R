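#' One generation of haploid Wright-Fisher evolution
#'
#' Advances an allele at frequency `q` with relative fitness `f` through one
#' generation of selection followed by binomial sampling of `ne` offspring,
#' and decomposes the realised frequency change into a deterministic
#' selection component and a drift residual.
#'
#' After selection the expected frequency is
#' \deqn{p = \frac{qf}{1 + q(f - 1)},}
#' the next generation's copy number is drawn from Binomial(`ne`, p), and
#' \itemize{
#'   \item `delta_s = p - q` (expected change caused by selection),
#'   \item `delta_d = q_next - p` (binomial sampling residual, i.e. drift),
#' }
#' so that `q_next - q = delta_s + delta_d` holds exactly. At the absorbing
#' boundaries `q = 0` and `q = 1` both components are 0 and the frequency is
#' unchanged.
#'
#' @param q current allele frequency in \[0, 1\] (vectorised).
#' @param f relative fitness of the allele, strictly positive (recycled
#'   against `q`).
#' @param ne haploid population size (also the number of binomial trials).
#' @param linear if `TRUE`, use the hypothetical linear rule
#'   `p = min(q * f, 1)` so that the selection component of change is
#'   `(f - 1) * q`; used to show that the bias of geometric-mean fitness
#'   comes from the nonlinearity of selection in `q`.
#'
#' @return A list with numeric components `q_next`, `delta_s`, `delta_d`.
#' @seealso [wf_sim()], [fitness_for_delta()]
#' @examples
#' set.seed(1)
#' wf_step(0.5, 6 / 5, 1000)
#' @export
wf_step <- function(q, f, ne, linear = FALSE) {
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]", call. = FALSE)
  check_fitness(f)
  stopifnot(ne >= 1)
  n <- max(length(q), length(f))
  q <- rep_len(q, n); f <- rep_len(f, n)
  p <- if (linear) pmin(pmax(q * f, 0), 1) else q * f / (1 + q * (f - 1))
  interior <- q > 0 & q < 1
  p[!interior] <- q[!interior]
  q_next <- q
  if (any(interior)) {
    q_next[interior] <- stats::rbinom(sum(interior), ne, p[interior]) / ne
  }
  list(q_next = q_next, delta_s = p - q, delta_d = q_next - p)
}

#' Fitness producing a target selection-driven frequency change
#'
#' Inverts the selection response: returns the unique relative fitness `f`
#' such that the expected one-generation frequency change caused by
#' selection at frequency `q` equals `delta`, i.e.
#' \deqn{f = 1 + \frac{\delta}{q(1 - q - \delta)}.}
#' Used by the target-delta regime to hold the per-generation selection
#' component of change fixed (for instance at -0.045 then +0.045 so that
#' the effective fitness over the run is exactly 1).
#'
#' @param q current frequency, strictly inside (0, 1) (vectorised).
#' @param delta target selection component of frequency change; `q + delta`
#'   must remain inside (0, 1).
#' @return The relative fitness value(s).
#' @examples
#' fitness_for_delta(0.5, -0.045)  # ~ 5/6
#' @export
fitness_for_delta <- function(q, delta) {
  n <- max(length(q), length(delta))
  q <- rep_len(q, n); delta <- rep_len(delta, n)
  if (any(q <= 0 | q >= 1))
    stop("q must be strictly inside (0, 1)", call. = FALSE)
  qd <- q + delta
  if (any(qd <= 0 | qd >= 1))
    stop("q + delta must remain strictly inside (0, 1): no valid fitness",
         call. = FALSE)
  1 + delta / (q * (1 - q - delta))
}

resolve_init_copies <- function(ne, init_copies = NULL, init_freq = NULL) {
  if (is.null(init_copies) == is.null(init_freq))
    stop("supply exactly one of init_copies and init_freq", call. = FALSE)
  if (is.null(init_copies)) {
    init_copies <- round(init_freq * ne)
    if (abs(init_copies - init_freq * ne) > 1e-9)
      stop("init_freq * ne must be an integer (frequencies live on the 1/ne lattice)",
           call. = FALSE)
  }
  init_copies <- as.integer(init_copies)
  if (init_copies < 1L || init_copies > ne - 1L)
    stop("initial copy number must lie in [1, ne - 1]", call. = FALSE)
  init_copies
}

#' Simulate an allele-frequency trajectory
#'
#' Forward simulation of a single mutant allele in a haploid Wright-Fisher
#' population of constant size `ne` under a pluggable fitness regime, with
#' the per-generation selection/drift decomposition of [wf_step()] recorded
#' for every generation.
#'
#' `wf_sim_linear()` is identical except that sampling uses the hypothetical
#' linear selection rule `E(q') = f q` (clamped to \[0, 1\]); it exists to
#' demonstrate that the bias of geometric-mean fitness vanishes when the
#' selection response is linear in the current frequency.
#'
#' @param ne haploid effective (and census) population size.
#' @param init_copies initial number of mutant copies in `[1, ne - 1]`;
#'   alternatively give `init_freq`.
#' @param init_freq initial frequency; `init_freq * ne` must be an integer.
#' @param regime a [regimes] object.
#' @param max_generations stop after this many generations even without
#'   absorption (`Inf` to run to fixation or loss).
#' @param seed optional integer seed; identical `(config, seed)` pairs give
#'   identical trajectories.
#' @param stop_on_absorption terminate when the frequency hits 0 or 1
#'   (default `TRUE`; if `FALSE` the trajectory is padded with boundary
#'   generations that contribute zero selection and drift).
#'
#' @return An object of class `wf_traj`: a list with elements `ne`, `q0`,
#'   `generations` (data frame with columns `generation`, `q_before`,
#'   `fitness`, `delta_s`, `delta_d`, `q_after`), `outcome` (one of
#'   `"fixed"`, `"lost"`, `"censored"`) and `n_generations`. Methods:
#'   `print`, `summary` (returns the [wf_metrics] summary), `plot`,
#'   `as.data.frame`.
#' @examples
#' traj <- wf_sim(ne = 1000, init_freq = 0.5,
#'                regime = regime_block(5 / 6, 6 / 5, 7),
#'                max_generations = 14, seed = 42)
#' traj
#' summary(traj)
#' @export
wf_sim <- function(ne, init_copies = NULL, init_freq = NULL, regime,
                   max_generations = Inf, seed = NULL,
                   stop_on_absorption = TRUE) {
  wf_sim_impl(ne, init_copies, init_freq, regime, max_generations, seed,
              stop_on_absorption, linear = FALSE)
}

#' @rdname wf_sim
#' @export
wf_sim_linear <- function(ne, init_copies = NULL, init_freq = NULL, regime,
                          max_generations = Inf, seed = NULL,
                          stop_on_absorption = TRUE) {
  wf_sim_impl(ne, init_copies, init_freq, regime, max_generations, seed,
              stop_on_absorption, linear = TRUE)
}

wf_sim_impl <- function(ne, init_copies, init_freq, regime, max_generations,
                        seed, stop_on_absorption, linear) {
  stopifnot(inherits(regime, "wf_regime"), ne >= 2, max_generations >= 1)
  init_copies <- resolve_init_copies(ne, init_copies, init_freq)
  if (!is.null(seed)) set.seed(seed)
  q <- init_copies / ne
  q0 <- q
  state <- regime_init(regime, 1L)
  gen_i <- integer(0); q_before <- fit <- ds <- dd <- q_after <- numeric(0)
  gen <- 0L
  while (gen < max_generations) {
    gen <- gen + 1L
    if (stop_on_absorption && (q == 0 || q == 1)) { gen <- gen - 1L; break }
    rf <- regime_fitness(regime, state, q, gen)
    state <- rf$state
    if (is.na(rf$f))
      stop(sprintf("no valid fitness for target delta at generation %d (q = %g)",
                   gen, q), call. = FALSE)
    step <- wf_step(q, rf$f, ne, linear = linear)
    gen_i <- c(gen_i, gen); q_before <- c(q_before, q); fit <- c(fit, rf$f)
    ds <- c(ds, step$delta_s); dd <- c(dd, step$delta_d)
    q <- step$q_next
    q_after <- c(q_after, q)
    if (stop_on_absorption && (q == 0 || q == 1)) break
  }
  outcome <- if (q == 1) "fixed" else if (q == 0) "lost" else "censored"
  structure(list(
    ne = ne, q0 = q0,
    generations = data.frame(generation = gen_i, q_before = q_before,
                             fitness = fit, delta_s = ds, delta_d = dd,
                             q_after = q_after),
    outcome = outcome, n_generations = length(gen_i),
    regime = regime, seed = seed, linear = linear
  ), class = "wf_traj")
}

#' @export
print.wf_traj <- function(x, ...) {
  cat(sprintf("Wright-Fisher trajectory (haploid, Ne = %d)\n", x$ne))
  cat(sprintf("  q0 = %.6g, %d generation(s), outcome: %s\n",
              x$q0, x$n_generations, x$outcome))
  if (x$n_generations > 0) {
    g <- x$generations
    cat(sprintf("  final q = %.6g; sum delta_s = %.6g; sum delta_d = %.6g\n",
                g$q_after[nrow(g)], sum(g$delta_s), sum(g$delta_d)))
  }
  invisible(x)
}

#' @export
as.data.frame.wf_traj <- function(x, ...) x$generations

#' @export
plot.wf_traj <- function(x, ...) {
  g <- x$generations
  plot(c(0, g$generation), c(x$q0, g$q_after), type = "l",
       xlab = "generation", ylab = "allele frequency", ylim = c(0, 1), ...)
  invisible(x)
}
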