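test_that("exploration counting round-trips through schedules and logs", {
  all_exploit <- data.frame(action = rep("exploit", 50))
  expect_equal(exploration_count(all_exploit), 0)
  ls <- toy_landscape(5)
  set.seed(1)
  tr <- run_generation(allocation_schedule(12, 50), ls)
  expect_equal(exploration_count(tr), 12)
  mixed <- data.frame(action = c("explore", "exploit", "explore"))
  expect_equal(exploration_count(mixed), 2)
  expect_error(exploration_count(data.frame(action = c("explore", "rest"))),
               "malformed")
  expect_error(exploration_count(list(1, 2)), "data frame")
})

test_that("Welch comparison matches the hand-coded oracle to 1e-10", {
  set.seed(8)
  cases <- list(
    list(a = c(10, 20, 30), b = c(40, 50, 60)),
    list(a = rnorm(20, 24.6, 5.56), b = rnorm(20, 20.1, 3.51)),
    list(a = rnorm(15, 5, 1), b = rnorm(40, 5.5, 4)),
    list(a = c(1, 1, 1, 2), b = c(5, 6, 7, 8, 9))
  )
  for (cs in cases) {
    got <- compare_groups(cs$a, cs$b, n_comparisons = 2)
    ora <- welch_oracle(cs$a, cs$b)
    expect_equal(got$t, ora$t, tolerance = 1e-10)
    expect_equal(got$df, ora$df, tolerance = 1e-10)
    expect_equal(got$p, ora$p, tolerance = 1e-10)
    expect_equal(got$d, ora$d, tolerance = 1e-10)
    expect_equal(got$alpha, 0.025)
  }
  # the textbook worked example
  ex <- compare_groups(c(10, 20, 30), c(40, 50, 60), n_comparisons = 2)
  expect_equal(ex$t, -3.674, tolerance = 1e-3)
  expect_equal(ex$df, 4)
  expect_equal(ex$p, 0.0213, tolerance = 1e-2)
  expect_equal(ex$d, -3)
  # identical groups: no effect
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$d, 0)
  expect_equal(same$alpha, 0.05)
  expect_error(compare_groups(rep(1, 5), rep(2, 5)), "zero variance")
  expect_error(compare_groups(1, c(2, 3)), "at least two")
})

test_that("payment is the ceil-to-10 conversion plus the show-up fee", {
  expect_equal(payment(0), 700L)
  expect_equal(payment(24912), 1700L)  # 2W/50 = 996.48 -> 1000 -> +700
  expect_equal(payment(25000), 1700L)  # exactly 1000, already a multiple of 10
  expect_equal(payment(1), 710L)       # 0.04 -> 10
  # monotone, never below the show-up fee
  W <- sort(sample(0:50000, 200))
  p <- payment(W)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 700))
})

test_that("parametric synthetic cohorts hit their configured tau distribution", {
  cfg <- default_synth_config(n = 20)
  logs <- synth_participants(cfg, landscape = default_landscape(), seed = 42)
  ppl <- attr(logs, "participants")
  expect_equal(nrow(ppl), 60)
  expect_true(all(ppl$generation == 1))
  # every record is internally consistent: explore rows == drawn tau
  for (pid in ppl$participant_id) {
    d <- logs[logs$participant_id == pid, ]
    expect_equal(exploration_count(d), ppl$tau[ppl$participant_id == pid])
  }
  # CLT bound on the asocial group mean (experiment-calibrated config)
  asoc <- ppl$tau[ppl$condition == "asocial"]
  expect_lt(abs(mean(asoc) - 20.10), 3 * 3.51 / sqrt(20) + 0.5)
  expect_true(all(ppl$tau >= 0 & ppl$tau <= 49))
  # identical seeds give identical cohorts
  logs2 <- synth_participants(cfg, landscape = default_landscape(), seed = 42)
  expect_identical(logs, logs2)
})

test_that("agentic cohorts and chains respect the design contracts", {
  cfg <- default_synth_config(mode = "agentic", n = 3)
  cfg$chain <- TRUE
  logs <- synth_participants(cfg, landscape = default_landscape(), seed = 9)
  ppl <- attr(logs, "participants")
  # fixed rational tau per condition
  expect_true(all(ppl$tau[ppl$condition == "repaid" & ppl$generation == 1] == 22))
  expect_true(all(ppl$tau[ppl$condition == "asocial"] == 12))
  # asocial records exist only in generation 1
  expect_true(all(ppl$generation[ppl$condition == "asocial"] == 1))
  # social conditions got second generations chained to their partner
  expect_true(any(ppl$generation == 2))
  for (pid in unique(ppl$participant_id[ppl$condition == "repaid"])) {
    g1 <- logs[logs$participant_id == pid & logs$generation == 1, ]
    g2 <- logs[logs$participant_id == pid & logs$generation == 2, ]
    expect_identical(as.integer(g2[1, c("length", "width", "thickness")]),
                     as.integer(g1[50, c("length", "width", "thickness")]))
  }
  expect_error(synth_participants(list(mode = "odd", T = 50, groups = list())),
               "parametric")
})

test_that("final efficiency reads the trajectory endpoint", {
  ls <- toy_landscape(0)
  set.seed(2)
  tr0 <- run_generation(allocation_schedule(0, 50), ls)
  expect_equal(final_efficiency(tr0), expected_score(ls, ls$initial_design))
  tr <- run_generation(allocation_schedule(10, 50), ls)
  expect_equal(final_efficiency(tr), tr$expected_score[50])
  # group means are computable from synthetic logs
  logs <- synth_participants(default_synth_config(n = 3), seed = 3)
  eff <- vapply(split(logs, logs$participant_id), final_efficiency, numeric(1))
  expect_true(all(is.finite(eff)) && all(eff >= 0 & eff <= 1000))
})

test_that("trial logs round-trip through CSV unchanged", {
  logs <- synth_participants(default_synth_config(n = 2), seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_logs(logs, path)
  back <- read_trial_logs(path)
  expect_equal(back$participant_id, logs$participant_id)
  expect_equal(back$action, logs$action)
  expect_equal(back$observed_score, logs$observed_score)
  expect_equal(back$expected_score, logs$expected_score, tolerance = 1e-9)
  expect_error(write_trial_logs(data.frame(x = 1), path), "columns")
})

test_that("overshoot fractions detect trajectories crossing the optimum", {
  ls <- fitness_landscape(optimum = c(55, 95, 90), weights = rep(0.07, 3),
                          peak = 1000, noise_sd = 0,
                          initial_design = c(50, 40, 35))
  # length starts 5 below its optimum: one step in + direction overshoots
  cfg <- list(mode = "agentic", T = 50,
              groups = list(list(condition = "asocial", n = 8, tau = 20)),
              chain = FALSE)
  logs <- synth_participants(cfg, landscape = ls, seed = 13)
  ov <- overshoot_fraction(logs, ls)
  expect_true(all(ov$fraction >= 0 & ov$fraction <= 1))
  expect_gt(ov$fraction[ov$attribute == "length"], 0)
  # width needs 11 steps to reach 95: nobody can cross within 20 explorations
  expect_equal(ov$fraction[ov$attribute == "width"], 0)
})

test_that("the analysis pipeline recovers the planted condition contrast", {
  cfg <- default_synth_config(n = 20)
  hits <- c(repaid = 0, unrepaid = 0)
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    logs <- synth_participants(cfg, landscape = default_landscape(),
                               seed = 1000 + r)
    res <- analyze_exploration(logs)
    hits["repaid"] <- hits["repaid"] +
      (res[["repaid:asocial"]]$significant && res[["repaid:asocial"]]$t > 0)
    hits["unrepaid"] <- hits["unrepaid"] + res[["unrepaid:asocial"]]$significant
  }
  expect_gt(hits[["repaid"]], n_rep / 2)
  expect_lt(hits[["unrepaid"]], n_rep / 2)
})
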