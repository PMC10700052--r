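test_that("geometric_mean_fitness is the log-space mean", {
  expect_equal(geometric_mean_fitness(c(5 / 6, 6 / 5)), 1, tolerance = 1e-14)
  expect_equal(geometric_mean_fitness(rep(0.93, 17)), 0.93, tolerance = 1e-14)
  # permutation invariance
  f <- c(1.2, 0.7, 1.05, 0.99, 1.3)
  expect_equal(geometric_mean_fitness(f), geometric_mean_fitness(rev(f)),
               tolerance = 1e-14)
  expect_error(geometric_mean_fitness(numeric(0)), "nonempty")
  expect_error(geometric_mean_fitness(c(1, 0)), "positive")
})

test_that("effective_fitness maps mean delta_s through the frequency-0.5 response", {
  expect_identical(effective_fitness(c(0, 0, 0)), 1)
  expect_equal(effective_fitness(0.045), 0.545 / 0.455, tolerance = 1e-14)
  expect_equal(effective_fitness(c(-0.045, 0.045)), 1, tolerance = 1e-14)
  # inverse relation and sign property
  for (d in c(-0.3, -0.045, -0.001, 0.001, 0.045, 0.3)) {
    fe <- effective_fitness(d)
    expect_equal((fe - 1) / (2 * (fe + 1)), d, tolerance = 1e-12)
    expect_identical(fe > 1, d > 0)
  }
  expect_error(effective_fitness(0.5), "inside")
})

test_that("relative_selection_effect and the neutrality call", {
  expect_identical(relative_selection_effect(0.2, 0), 1)
  expect_identical(relative_selection_effect(0, 0), NA_real_)
  expect_equal(relative_selection_effect(0.1, -0.3), 0.25, tolerance = 1e-14)
  # C is bounded in [-1, 1] and signed by the selection total
  set.seed(8)
  ds <- stats::rnorm(200); dd <- stats::rnorm(200)
  cc <- relative_selection_effect(ds, dd)
  expect_true(all(abs(cc) <= 1))
  expect_true(all(sign(cc) == sign(ds)))

  expect_true(is_effectively_neutral(0.04))
  expect_false(is_effectively_neutral(0.67))
  expect_false(is_effectively_neutral(-0.05))   # strict inequality
  expect_identical(is_effectively_neutral(NA_real_), NA)
  expect_true(all(is_effectively_neutral(cc, cutoff = 1.0)))  # |C| <= 1 always
})

test_that("frequency predictors match their defining recurrences", {
  expect_identical(predict_freq_from_fg(0.3, 1, 200), 0.3)
  expect_identical(predict_freq_from_fg(0.3, 1.2, 0), 0.3)
  # recurrence oracle: iterate q <- qf/(1+q(f-1)) n times
  q <- 0.01
  for (i in 1:200) q <- q * 1.01 / (1 + q * 0.01)
  expect_equal(predict_freq_from_fg(0.01, 1.01, 200), q, tolerance = 1e-12)

  expect_identical(predict_freq_from_fe(0.3, 1, 200), 0.3)
  # round trip: a constant delta_s accumulates linearly
  d <- 0.00245
  fe <- effective_fitness(rep(d, 200))
  expect_equal(predict_freq_from_fe(0.01, fe, 200), 0.01 + 200 * d,
               tolerance = 1e-12)
  expect_equal(0.01 + 200 * d, 0.5, tolerance = 1e-14)
  expect_warning(predict_freq_from_fe(0.01, 2, 200), "unclamped")
})

test_that("trajectory_metrics matches hand-computed values on the fixture", {
  tr <- make_fixture_traj()
  m <- summary(tr)
  expect_s3_class(m, "wf_metrics")
  expect_identical(m$n_generations, 3L)
  expect_equal(m$f_g, 1, tolerance = 1e-14)
  expect_equal(m$sum_delta_s, 1 / 990, tolerance = 1e-14)
  expect_equal(m$sum_delta_d, -1 / 990 - 1 / 10, tolerance = 1e-14)
  expect_equal(m$mean_delta_s, 1 / 2970, tolerance = 1e-14)
  expect_equal(m$f_e, 743 / 742, tolerance = 1e-14)
  expect_equal(m$c_value, 1 / 101, tolerance = 1e-14)
  expect_identical(m$outcome, "censored")
})

test_that("trajectory_metrics is consistent on simulated trajectories", {
  # neutral: f_g = f_e = 1 and C = 0 (or undefined if nothing moved)
  tr <- wf_sim(200, init_freq = 0.5, regime = regime_constant(1),
               max_generations = 30, seed = 31)
  m <- trajectory_metrics(tr)
  expect_identical(m$f_g, 1)
  expect_identical(m$f_e, 1)
  expect_true(is.na(m$c_value) || m$c_value == 0)

  # drift-sum identity on a selected trajectory
  tr <- wf_sim(500, init_copies = 25, regime = regime_markov_switch(1.1, 1 / 1.1, 0.05),
               max_generations = 400, seed = 32)
  m <- trajectory_metrics(tr)
  g <- tr$generations
  expect_equal(m$sum_delta_d,
               (g$q_after[nrow(g)] - tr$q0) - m$sum_delta_s,
               tolerance = 1e-12)
  if (tr$outcome == "fixed") expect_identical(g$q_after[nrow(g)], 1)
  if (tr$outcome == "lost") expect_identical(g$q_after[nrow(g)], 0)

  expect_error(trajectory_metrics(
    structure(list(generations = data.frame()), class = "wf_traj")),
    "no generations")
})

test_that("multiplicability: drift-free outcome depends only on the fitness multiset", {
  set.seed(9)
  for (rep in 1:5) {
    f <- exp(stats::rnorm(12, sd = 0.2))
    q0 <- stats::runif(1, 0.05, 0.95)
    ref <- deterministic_q_after(q0, f)
    expect_equal(deterministic_q_after(q0, sample(f)), ref, tolerance = 1e-12)
    # the f_G predictor reproduces the drift-free endpoint of any permutation
    expect_equal(predict_freq_from_fg(q0, geometric_mean_fitness(f), length(f)),
                 ref, tolerance = 1e-12)
  }
})
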