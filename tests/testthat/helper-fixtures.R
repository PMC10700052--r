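# Hand-built 3-generation trajectory (ne = 10, q0 = 0.5) with all
# per-generation quantities worked out as exact fractions:
#   gen 1: f = 6/5, p = 6/11,  q_after = 0.6  -> ds = 1/22,  dd = 3/55
#   gen 2: f = 5/6, p = 5/9,   q_after = 0.5  -> ds = -2/45, dd = -1/18
#   gen 3: f = 1,   p = 1/2,   q_after = 0.4  -> ds = 0,     dd = -1/10
# sum ds = 1/990, sum dd = -(1/990) - 1/10, f_G = (6/5 * 5/6 * 1)^(1/3) = 1,
# mean ds = 1/2970, f_E = 743/742, C = (1/990) / (101/990) = 1/101.
make_fixture_traj <- function() {
  g <- data.frame(
    generation = 1:3,
    q_before = c(0.5, 0.6, 0.5),
    fitness = c(6 / 5, 5 / 6, 1),
    delta_s = c(6 / 11 - 0.5, 5 / 9 - 0.6, 0),
    delta_d = c(0.6 - 6 / 11, 0.5 - 5 / 9, -0.1),
    q_after = c(0.6, 0.5, 0.4)
  )
  structure(list(ne = 10L, q0 = 0.5, generations = g, outcome = "censored",
                 n_generations = 3L, regime = NULL, seed = NULL,
                 linear = FALSE),
            class = "wf_traj")
}

# Explicit threshold-sweep trapezoid AUC: independent oracle for the
# rank-based implementation. Sweeps all distinct score cutoffs and
# integrates TPR over FPR by the trapezoid rule (handles ties).
auc_trapezoid <- function(scores, positive) {
  cuts <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(cuts, function(th) mean(scores[positive] >= th), 1))
  fpr <- c(0, vapply(cuts, function(th) mean(scores[!positive] >= th), 1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
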