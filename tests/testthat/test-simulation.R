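test_that("environment steps respect the configured dynamics", {
  cfg <- game_config(beta = 1)
  m <- assemble_model(cfg)
  env1 <- environment_spec(env_beta = 1)

  # absorbing floor + identity self-worth: (broke, charitable) is fixed
  set.seed(1)
  for (i in 1:25) {
    step <- env_step(c(1L, 1L), "donate", env1, m)
    expect_equal(step$state, c(1L, 1L))
    expect_equal(step$observation[1], 1L)
  }

  # veridical approval: a truly charitable state always draws approval
  set.seed(2)
  approvals <- replicate(200, env_step(c(3L, 1L), "donate",
                                       environment_spec(env_beta = 1),
                                       m)$observation[2])
  expect_true(all(approvals == 1L))

  # wealth cue reports the true level exactly
  set.seed(3)
  for (i in 1:50) {
    step <- env_step(c(5L, 2L), "keep", environment_spec(), m)
    expect_equal(step$observation[1], step$state[1])
  }
})

test_that("attrition rate is recovered by Monte-Carlo sampling at the top level", {
  m <- assemble_model(game_config())
  env <- environment_spec()
  n_samp <- 20000
  set.seed(42)
  drops <- replicate(n_samp,
                     env_step(c(8L, 1L), "keep", env, m)$state[1] == 7L)
  rate <- mean(drops)
  se <- sqrt(0.1 * 0.9 / n_samp)
  expect_lt(abs(rate - 0.1), 3 * se)
})

test_that("run_game is reproducible and handles a zero horizon", {
  cfg <- game_config(alpha = 2, beta = 0.8)
  t1 <- run_game(cfg, seed = 77)
  t2 <- run_game(cfg, seed = 77)
  expect_identical(t1$trials, t2$trials)

  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_trajectory_json(t1, f1)
  write_trajectory_json(t2, f2)
  expect_identical(readLines(f1), readLines(f2))

  t0 <- run_game(game_config(horizon = 0), seed = 1)
  expect_equal(nrow(t0$trials), 0L)
  expect_true(t0$summary$empty)
  expect_equal(t0$summary$final_p_charitable, 1)
  expect_equal(t0$summary$final_wealth, 1L)
})

test_that("true wealth changes per trial have support {-2,-1,0,+1}", {
  deltas <- integer()
  for (s in 1:8) {
    tr <- run_game(game_config(alpha = runif(1, 0, 4),
                               beta = runif(1, 0.5, 1)), seed = s)
    w <- c(tr$config$initial_wealth_index, tr$trials$true_wealth)
    deltas <- c(deltas, diff(w))
  }
  expect_true(all(deltas %in% c(-2L, -1L, 0L, 1L)))
  expect_false(any(deltas >= 2L))
})

test_that("precise likelihoods make beliefs track the true self-worth state", {
  agree <- numeric(32)
  for (s in seq_len(32)) {
    tr <- run_game(game_config(alpha = 6, beta = 0.9), seed = 1000 + s)
    agree[s] <- mean((tr$trials$p_charitable > 0.5) ==
                       (tr$trials$true_selfworth == 1L))
  }
  expect_gt(mean(agree), 0.9)
})

test_that("a precise-approval, weak-prior agent behaves altruistically", {
  for (s in 1:4) {
    tr <- run_game(game_config(alpha = 4, beta = 0.55), seed = s)
    expect_gt(sum(tr$trials$action == "donate"), tr$config$horizon / 2)
  }
})

test_that("summarize_trajectory reproduces hand-computed metrics", {
  fake <- list(trials = data.frame(
    trial = 1:3, action = c("donate", "keep", "keep"),
    true_wealth = c(1L, 2L, 3L), true_selfworth = c(1L, 1L, 2L),
    obs_wealth = c(1L, 2L, 3L), obs_approval = c(1L, 1L, 2L),
    p_charitable = c(0.9, 0.8, 0.4), expected_wealth = c(1, 2, 3),
    g_donate = 0, g_keep = 0))
  s <- summarize_trajectory(fake)
  expect_equal(s$final_p_charitable, 0.4)
  expect_equal(s$final_wealth, 3L)
  expect_equal(s$mean_wealth, 2)
  expect_equal(s$donation_fraction, 1 / 3)
  expect_true(s$donation_fraction >= 0 && s$donation_fraction <= 1)
})
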