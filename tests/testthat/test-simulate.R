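test_that("run_generation honours the schedule and accounting contracts", {
  ls <- toy_landscape(noise_sd = 0)
  set.seed(1)
  tr0 <- run_generation(allocation_schedule(0, 50), ls)
  # no exploration: the design never changes and every trial banks the same
  expect_equal(unique(tr0$length), 50)
  expect_equal(unique(tr0$width), 50)
  expect_equal(unique(tr0$thickness), 50)
  mu <- round(expected_score(ls, c(50, 50, 50)))
  expect_equal(attr(tr0, "W"), 50 * mu)
  expect_equal(tr0$cumulative_score[50], 50 * mu)

  set.seed(2)
  tr <- run_generation(allocation_schedule(12, 50), toy_landscape(5))
  expect_equal(sum(tr$action == "explore"), 12)
  expect_equal(tr$action[1], "exploit")
  expect_equal(nrow(tr), 50)
  expect_equal(attr(tr, "W"),
               sum(tr$observed_score[tr$action == "exploit"]))
  expect_true(all(is.na(tr$observed_score[tr$action == "explore"])))
  expect_equal(tr$cumulative_score[50], attr(tr, "W"))
})

test_that("transmission chains hand the final design to the next generation", {
  ls <- toy_landscape(noise_sd = 5)
  set.seed(10)
  ch <- run_chain(12, 8, ls)
  final1 <- as.integer(ch$first[50, c("length", "width", "thickness")])
  first2 <- as.integer(ch$second[1, c("length", "width", "thickness")])
  expect_identical(first2, final1)
  # tau_first = 0: generation 2 starts exactly from the common initial design
  set.seed(11)
  ch0 <- run_chain(0, 8, ls)
  expect_identical(as.integer(ch0$second[1, c("length", "width", "thickness")]),
                   as.integer(ls$initial_design))
  # asocial control: no transmission, both runs start from the initial design
  set.seed(12)
  a1 <- run_generation(allocation_schedule(12, 50), ls)
  a2 <- run_generation(allocation_schedule(12, 50), ls)
  expect_equal(as.integer(a1[1, c("length", "width", "thickness")]),
               as.integer(a2[1, c("length", "width", "thickness")]))
})

test_that("ensemble learning-curve estimation is exact at tau = 0 and reproducible", {
  ls <- toy_landscape(noise_sd = 5)
  g1 <- estimate_learning_curve(ls, n_agents = 80, T = 50, seed = 99)
  expect_equal(g1$tau, 0:24)
  expect_equal(g1$g[1], expected_score(ls, ls$initial_design))
  expect_equal(g1$se[1], 0)
  g2 <- estimate_learning_curve(ls, n_agents = 80, T = 50, seed = 99)
  expect_identical(g1, g2)
  # enlarging the ensemble must not reshuffle earlier agents' substreams
  a40 <- attr(estimate_learning_curve(ls, n_agents = 40, seed = 5,
                                      keep_agents = TRUE), "agents")
  a80 <- attr(estimate_learning_curve(ls, n_agents = 80, seed = 5,
                                      keep_agents = TRUE), "agents")
  expect_identical(a80[1:40, ], a40)
})

test_that("ensemble mean matches exact path enumeration on a tiny instance", {
  ls <- toy_landscape(noise_sd = 0)
  exact <- enumerate_g(ls, T = 10)
  est <- estimate_learning_curve(ls, n_agents = 4000, T = 10, seed = 21)
  expect_equal(est$g[1], exact[1])           # tau = 0 exactly
  tol <- 3.5 * pmax(est$se, 1e-12)
  expect_true(all(abs(est$g - exact) <= tol + 1e-9))
})

test_that("curve-based pay-offs implement the two accounting identities", {
  g <- c(400, 500, 560, 600, 620)
  # empty alternating phase
  expect_equal(payoff_from_curve(g, 0, T = 50, "unrepaid"), 50 * 400)
  expect_equal(payoff_from_curve(g, 0, T = 50, "repaid"), 100 * 400)
  # asocial pay-off is the unrepaid one
  expect_equal(payoff_from_curve(g, 3, T = 50, "asocial"),
               payoff_from_curve(g, 3, T = 50, "unrepaid"))
  # constant curve collapses to (T - tau) * c
  const <- rep(300, 25)
  for (tp in c(0, 5, 24)) {
    expect_equal(payoff_from_curve(const, tp, T = 50, "unrepaid"),
                 (50 - tp) * 300)
  }
  # repaid bonus equals T * g(tau_p) for every tau_p
  for (tp in 0:4) {
    expect_equal(payoff_from_curve(g, tp, 50, "repaid") -
                   payoff_from_curve(g, tp, 50, "unrepaid"),
                 50 * g[tp + 1])
  }
  expect_error(payoff_from_curve(g, 30, T = 50), "tau_p")
  expect_error(payoff_from_curve(g, -1, T = 50), "tau_p")
  expect_error(payoff_from_curve(g, 10, T = 50), "too short")
})

test_that("optimal tau: ties break small, constant curves never explore", {
  expect_equal(optimal_tau(rep(500, 25), T = 50, "unrepaid")$tau_star, 0)
  expect_equal(optimal_tau(rep(500, 25), T = 50, "repaid")$tau_star, 0)
  opt <- optimal_tau(c(100, 900, rep(900, 23)), T = 50, "unrepaid")
  expect_equal(opt$per_trial, opt$payoff / 50)
  expect_length(opt$payoff, 25)
})

test_that("repaid optimum is never earlier than unrepaid on random landscapes", {
  set.seed(31)
  for (i in 1:5) {
    ls <- random_landscape()
    g <- estimate_learning_curve(ls, n_agents = 1500, seed = 100 + i)
    if (max(g$g) - min(g$g) < 1) next  # degenerate flat curve
    tu <- optimal_tau(g, condition = "unrepaid")$tau_star
    tr <- optimal_tau(g, condition = "repaid")$tau_star
    expect_gte(tr, tu)
  }
})

test_that("curve-based expectation agrees with direct Monte-Carlo pay-offs", {
  ls <- default_landscape()
  g <- estimate_learning_curve(ls, n_agents = 4000, seed = 55)
  tau <- optimal_tau(g, condition = "unrepaid")$tau_star
  predicted <- payoff_from_curve(g, tau, T = 50, "unrepaid")
  set.seed(77)
  W <- replicate(300, attr(run_generation(allocation_schedule(tau, 50), ls),
                           "W"))
  se_mc <- stats::sd(W) / sqrt(length(W))
  curve_var <- sum(g$se[seq_len(tau)]^2) + ((50 - 2 * tau) * g$se[tau + 1])^2
  expect_lt(abs(mean(W) - predicted), 3 * sqrt(se_mc^2 + curve_var) + 1)
})

test_that("the allocation strategy space is counted exactly", {
  expect_identical(count_allocation_strategies(50), 2^49)
  expect_equal(count_allocation_strategies(50), 562949953421312)
  expect_equal(count_allocation_strategies(1), 1)
  expect_error(count_allocation_strategies(60), "54")
})
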