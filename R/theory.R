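#' Exact two-generation expectation under selection and drift
#'
#' Computes, by exact enumeration over the binomial distribution of the
#' first generation's copy number, the expected mutant frequency after two
#' generations of selection with drift:
#' \deqn{E(q_2) = \sum_{i=0}^{N_e} \Pr(m_1 = i) \, F(i / N_e), \qquad
#'   F(x) = \frac{x f_2}{1 + x (f_2 - 1)},}
#' where \eqn{m_1 \sim} Binomial\eqn{(N_e, p_1)} and
#' \eqn{p_1 = q_0 f_1 / (1 + q_0 (f_1 - 1))}.
#'
#' Because `F` is strictly concave for `f2 > 1` and strictly convex for
#' `f2 < 1`, Jensen's inequality gives `E(q2) < q2'` when `f2 > 1` and
#' `E(q2) > q2'` when `f2 < 1`, where `q2'` is the drift-free value from
#' [deterministic_q_after()]; the direction depends only on `f2`. This exact
#' enumeration is the package's testable replacement for the analytic
#' argument.
#'
#' @param ne haploid population size (capped at `1e5` so the O(ne) sum stays
#'   exact and fast; no normal approximation is used anywhere).
#' @param q0 initial frequency in \[0, 1\].
#' @param f1,f2 relative fitness in the first and second generation.
#' @return `E(q2)`, exact up to floating point.
#' @examples
#' exact_expected_q2(10, 0.5, 1, 1.2) < deterministic_q_after(0.5, c(1, 1.2))
#' @export
exact_expected_q2 <- function(ne, q0, f1, f2) {
  stopifnot(ne >= 1, q0 >= 0, q0 <= 1)
  check_fitness(f1, f2)
  if (ne > 1e5)
    stop("ne too large for exact enumeration (limit 1e5)", call. = FALSE)
  p1 <- q0 * f1 / (1 + q0 * (f1 - 1))
  x <- (0:ne) / ne
  sum(stats::dbinom(0:ne, ne, p1) * x * f2 / (1 + x * (f2 - 1)))
}

#' Deterministic allele frequency after a fitness sequence
#'
#' Iterates the drift-free recurrence \eqn{q \leftarrow q f / (1 + q (f -
#' 1))} over a sequence of per-generation fitness values. The result depends
#' only on the product of the fitness values (equivalently on their
#' geometric mean) -- the multiplicability of relative fitness -- so any
#' permutation of `fitnesses` gives the same final frequency. For two
#' generations it equals the closed form
#' \eqn{q_2' = q_0 f_1 f_2 / (1 + q_0 (f_1 f_2 - 1))}.
#'
#' @param q0 initial frequency in \[0, 1\].
#' @param fitnesses numeric vector of relative fitness values (may be
#'   empty, in which case `q0` is returned).
#' @return The final frequency.
#' @export
deterministic_q_after <- function(q0, fitnesses) {
  stopifnot(q0 >= 0, q0 <= 1)
  if (length(fitnesses) > 0) check_fitness(fitnesses)
  q <- q0
  for (f in fitnesses) q <- q * f / (1 + q * (f - 1))
  q
}

#' The G(x) spread function
#'
#' Reparameterises a two-generation fluctuating-selection scenario as
#' \eqn{f_1 = e^x f_G}, \eqn{f_2 = e^{-x} f_G}, so that `f1 f2 = f_G^2` is
#' held fixed while `x` controls how different the two generations are
#' (`x = 0` is constant selection with `f_G`). `g_function()` evaluates the
#' exact expected frequency after two generations, `E(q2)`, as a function of
#' `x`. Strict monotonicity of `G` in `x` implies `G(x) != G(0)` for all
#' `x != 0`: with drift, no fluctuating scenario reproduces the constant-
#' `f_G` expectation.
#'
#' @param x spread parameter (vectorised).
#' @param q0 initial frequency.
#' @param f_g geometric mean fitness held fixed.
#' @param ne haploid population size.
#' @return `E(q2)` for each `x`.
#' @export
g_function <- function(x, q0, f_g, ne) {
  vapply(x, function(xi)
    exact_expected_q2(ne, q0, exp(xi) * f_g, exp(-xi) * f_g), numeric(1))
}

#' Monotonicity scan of G(x)
#'
#' Evaluates [g_function()] on a grid of `x` values for a sweep of one
#' parameter (the other two held fixed) and reports whether the sampled
#' sequence is strictly monotone, and in which direction. The three named
#' sweeps are:
#' \describe{
#'   \item{`"q0"`}{q0 = 0.1, ..., 0.9 (step 0.1), f_G = 0.9, Ne = 1000.}
#'   \item{`"fg"`}{log2 f_G = -1, ..., 1 (step 0.2), q0 = 0.3, Ne = 1000.}
#'   \item{`"ne"`}{Ne = 1000, ..., 10000 (step 1000), q0 = 0.3, f_G = 0.9.}
#' }
#' Monotonicity is judged on the sampled grid itself (`x` from -1 to 1 in
#' steps of 0.02 by default), which is the same numerical procedure the
#' question admits short of a symbolic proof.
#'
#' @param grid one of `"q0"`, `"fg"`, `"ne"`, or a data frame with columns
#'   `q0`, `f_g`, `ne` for a custom sweep.
#' @param x_grid grid of spread values.
#' @return A data frame with columns `varied_param`, `value`, `q0`, `f_g`,
#'   `ne`, `is_monotone`, `direction` (`"increasing"`, `"decreasing"`, or
#'   `"none"`).
#' @export
monotonicity_scan <- function(grid = c("q0", "fg", "ne"),
                              x_grid = seq(-1, 1, by = 0.02)) {
  if (is.character(grid)) {
    grid <- match.arg(grid)
    rows <- switch(grid,
      q0 = data.frame(varied_param = "q0", value = seq(0.1, 0.9, by = 0.1),
                      q0 = seq(0.1, 0.9, by = 0.1), f_g = 0.9, ne = 1000L),
      fg = {
        l2 <- seq(-1, 1, by = 0.2)
        data.frame(varied_param = "fg", value = l2, q0 = 0.3, f_g = 2^l2,
                   ne = 1000L)
      },
      ne = data.frame(varied_param = "ne", value = seq(1000L, 10000L, by = 1000L),
                      q0 = 0.3, f_g = 0.9, ne = seq(1000L, 10000L, by = 1000L))
    )
  } else {
    stopifnot(is.data.frame(grid), all(c("q0", "f_g", "ne") %in% names(grid)))
    rows <- grid
    if (is.null(rows$varied_param)) rows$varied_param <- "custom"
    if (is.null(rows$value)) rows$value <- seq_len(nrow(rows))
  }
  res <- lapply(seq_len(nrow(rows)), function(i) {
    g <- g_function(x_grid, rows$q0[i], rows$f_g[i], rows$ne[i])
    d <- diff(g)
    inc <- all(d > 0); dec <- all(d < 0)
    data.frame(varied_param = rows$varied_param[i], value = rows$value[i],
               q0 = rows$q0[i], f_g = rows$f_g[i], ne = rows$ne[i],
               is_monotone = inc || dec,
               direction = if (inc) "increasing" else if (dec) "decreasing" else "none")
  })
  do.call(rbind, res)
}
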