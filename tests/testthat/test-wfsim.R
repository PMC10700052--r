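test_that("wf_step: boundaries absorb and the selection component matches theory", {
  set.seed(1)
  s0 <- wf_step(0, 1.5, 100)
  expect_identical(unlist(s0), c(q_next = 0, delta_s = 0, delta_d = 0))
  s1 <- wf_step(1, 0.5, 100)
  expect_identical(unlist(s1), c(q_next = 1, delta_s = 0, delta_d = 0))

  # delta_s = q(1-q)(f-1)/(1+q(f-1)); at q = 0.5, f = 6/5 it is 1/22
  s <- wf_step(0.5, 6 / 5, 1000)
  expect_equal(s$delta_s, 0.5 * 0.5 * 0.2 / 1.1, tolerance = 1e-14)
  expect_equal(s$delta_s, 1 / 22, tolerance = 1e-14)

  # neutrality: f = 1 gives delta_s = 0 exactly and q_next on the lattice
  s <- wf_step(0.3, 1, 1000)
  expect_identical(s$delta_s, 0)
  expect_true(s$q_next * 1000 == round(s$q_next * 1000))

  expect_error(wf_step(-0.1, 1, 100), "q must")
  expect_error(wf_step(0.5, 0, 100), "positive")
  expect_error(wf_step(0.5, -1, 100), "positive")
})

test_that("wf_step linear rule: delta_s = (f-1) q, clamped at the boundary", {
  set.seed(1)
  s <- wf_step(0.5, 6 / 5, 1000, linear = TRUE)
  expect_equal(s$delta_s, 0.1, tolerance = 1e-14)
  # q f > 1 clamps the sampling probability to 1
  s <- wf_step(0.9, 6 / 5, 1000, linear = TRUE)
  expect_equal(s$delta_s, 0.1, tolerance = 1e-14)
  expect_identical(s$q_next, 1)
  # f = 1 is neutral under either rule
  s <- wf_step(0.4, 1, 1000, linear = TRUE)
  expect_identical(s$delta_s, 0)
})

test_that("fitness_for_delta inverts the selection response (round trip)", {
  expect_identical(fitness_for_delta(0.5, 0), 1)
  expect_equal(fitness_for_delta(0.5, -0.045), 0.455 / 0.545, tolerance = 1e-14)
  # ~ 5/6, the value used to engineer f_E = 1
  expect_equal(fitness_for_delta(0.5, -0.045), 5 / 6, tolerance = 2e-3)

  delta_s_of <- function(q, f) q * (1 - q) * (f - 1) / (1 + q * (f - 1))
  for (q in seq(0.1, 0.9, by = 0.1)) {
    for (d in c(-0.05, -0.01, 0.01, 0.1)) {
      if (q + d <= 0 || q + d >= 1) next
      f <- fitness_for_delta(q, d)
      expect_equal(delta_s_of(q, f), d, tolerance = 1e-12)
    }
  }
  expect_error(fitness_for_delta(0.5, 0.6), "no valid fitness")
  expect_error(fitness_for_delta(0.2, -0.2), "no valid fitness")
  expect_error(fitness_for_delta(0, 0.1), "strictly inside")
})

test_that("wf_sim is deterministic and additive in its decomposition", {
  r <- regime_markov_switch(11 / 10, 10 / 11, 0.05)
  t1 <- wf_sim(1000, init_freq = 0.5, regime = r, max_generations = 100, seed = 7)
  t2 <- wf_sim(1000, init_freq = 0.5, regime = r, max_generations = 100, seed = 7)
  expect_identical(t1, t2)

  g <- t1$generations
  expect_lt(max(abs(g$q_after - g$q_before - g$delta_s - g$delta_d)), 1e-14)
  expect_true(all(round(g$q_after * 1000) == g$q_after * 1000))
  expect_true(all(g$q_before[-1] == g$q_after[-nrow(g)]))
})

test_that("wf_sim records outcomes and stops at absorption", {
  # strong negative selection on a single copy at tiny ne: loss is quick
  tr <- wf_sim(10, init_copies = 1, regime = regime_constant(0.5), seed = 3)
  expect_identical(tr$outcome, "lost")
  expect_identical(tr$generations$q_after[tr$n_generations], 0)
  tr <- wf_sim(10, init_copies = 9, regime = regime_constant(3), seed = 4)
  expect_identical(tr$outcome, "fixed")
  # censoring
  tr <- wf_sim(1000, init_freq = 0.5, regime = regime_constant(1),
               max_generations = 5, seed = 5)
  expect_identical(tr$outcome, "censored")
  expect_identical(tr$n_generations, 5L)
  expect_true(all(tr$generations$delta_s == 0))
})

test_that("regimes produce the documented fitness sequences", {
  blk <- wf_sim(1000, init_freq = 0.5, regime = regime_block(5 / 6, 6 / 5, 7),
                max_generations = 14, seed = 11)
  expect_identical(blk$generations$fitness, c(rep(5 / 6, 7), rep(6 / 5, 7)))

  alt <- wf_sim(1000, init_freq = 0.5, regime = regime_alternating(5 / 6, 6 / 5),
                max_generations = 6, seed = 12)
  expect_identical(alt$generations$fitness, rep(c(5 / 6, 6 / 5), 3))

  # markov_switch degenerate cases: never switch / always switch
  never <- wf_sim(1000, init_freq = 0.5,
                  regime = regime_markov_switch(1.1, 0.9, 0),
                  max_generations = 10, seed = 13)
  expect_identical(length(unique(never$generations$fitness)), 1L)
  always <- wf_sim(1000, init_freq = 0.5,
                   regime = regime_markov_switch(1.1, 0.9, 1),
                   max_generations = 10, seed = 14)
  expect_identical(length(unique(always$generations$fitness)), 2L)
  expect_true(all(abs(diff(always$generations$fitness)) > 0))

  # frequency dependence evaluated on the pre-selection frequency
  fd <- wf_sim(100, init_copies = 50,
               regime = regime_frequency_dependent(1.01, 0.9, 0.6),
               max_generations = 200, seed = 15)
  g <- fd$generations
  expect_identical(g$fitness, ifelse(g$q_before < 0.6, 1.01, 0.9))

  # target_delta realises the schedule exactly and errors when impossible
  td <- wf_sim(1000, init_freq = 0.5,
               regime = regime_target_delta(c(-0.045, -0.045, 0.045)),
               max_generations = 3, seed = 16)
  expect_equal(td$generations$delta_s, c(-0.045, -0.045, 0.045),
               tolerance = 1e-12)
  expect_error(
    wf_sim(100, init_freq = 0.7, regime = regime_target_delta(0.4),
           max_generations = 1, seed = 17),
    "generation 1")
})

test_that("batch and single-run simulators agree on summary statistics", {
  r <- regime_block(5 / 6, 6 / 5, 3)
  b <- wf_batch_horizon(500, 1000, init_freq = 0.5, regime = r,
                        generations = 6, seed = 21)
  expect_identical(nrow(b), 500L)
  # no absorption from 0.5 in 6 generations at ne = 1000
  expect_true(all(is.na(b$absorbed_gen)))
  expect_true(all(b$n_generations == 6L))
  # f_g of every replicate is exactly the geometric mean of the block regime
  expect_equal(b$f_g, rep((5 / 6)^(1 / 2) * (6 / 5)^(1 / 2), 500),
               tolerance = 1e-12)
  # decomposition additivity at the batch level
  expect_equal(b$final_copies / 1000 - 0.5, b$sum_delta_s + b$sum_delta_d,
               tolerance = 1e-12)

  ab <- wf_batch_absorb(300, 50, init_copies = 1, regime = regime_constant(1),
                        seed = 22)
  expect_true(all(ab$outcome %in% c("fixed", "lost")))
  expect_true(all(ab$sum_delta_s == 0))  # neutral: selection never moves q
  expect_equal(ab$sum_delta_d, ab$final_copies / 50 - 1 / 50, tolerance = 1e-12)
})
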