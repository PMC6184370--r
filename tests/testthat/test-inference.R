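test_that("predict_states pushes beliefs through the transition model", {
  cfg <- game_config(beta = 1)
  m <- assemble_model(cfg)

  # point mass on (broke, charitable): donating leaves it fixed
  b0 <- belief_state(m$D, m)
  b1 <- predict_states(b0, "donate", m)
  expect_equal(b1$q_joint, m$D)

  # uniform belief maps to the column average of the joint transition
  ns <- nrow(m$states)
  bu <- belief_state(rep(1 / ns, ns), m)
  for (a in m$actions) {
    expect_equal(predict_states(bu, a, m)$q_joint,
                 unname(rowMeans(m$B[[a]])))
  }

  # identity self-worth factor: marginal untouched by either action
  set.seed(3)
  q <- runif(ns); q <- q / sum(q)
  br <- belief_state(q, m)
  for (a in m$actions) {
    expect_equal(predict_states(br, a, m)$q_selfworth, br$q_selfworth)
  }
})

test_that("update_beliefs is exact Bayes with degenerate-evidence guard", {
  cfg <- game_config(alpha = 2, likelihood_floor = 0)
  m <- assemble_model(cfg)
  b0 <- belief_state(m$D, m)

  # point-mass prior with a possible observation stays a point mass
  post <- update_beliefs(b0, c(1L, 1L), m)
  expect_equal(post$q_joint, b0$q_joint)

  # uninformative approval cue leaves the self-worth marginal uniform
  m0 <- assemble_model(game_config(alpha = 0, likelihood_floor = 0))
  ns <- nrow(m0$states)
  bu <- belief_state(rep(1 / ns, ns), m0)
  for (cue in 1:2) {
    expect_equal(update_beliefs(bu, c(4L, cue), m0)$q_selfworth,
                 c(charitable = 0.5, mean = 0.5))
  }

  # an observation impossible under the prior raises a degeneracy error
  expect_error(update_beliefs(b0, c(5L, 1L), m), "degenerate")
  expect_error(update_beliefs(b0, c(99L, 1L), m), "range")
})

test_that("filtering equals brute-force joint-trajectory enumeration", {
  set.seed(1234)
  for (draw in 1:20) {
    cfg <- game_config(alpha = runif(1, 0.2, 4), beta = runif(1, 0.5, 1),
                       likelihood_floor = 0)
    m <- assemble_model(cfg)
    T_ <- sample(1:4, 1)
    rec <- sample_game_record(m, T_)

    belief <- belief_state(m$D, m)
    for (t in seq_len(T_)) {
      belief <- update_beliefs(predict_states(belief, rec$actions[[t]], m),
                               rec$observations[[t]], m)
    }
    expect_equal(belief$q_joint,
                 oracle_filter(m, rec$actions, rec$observations),
                 tolerance = 1e-10)
  }
})

test_that("expected free energy matches direct summation of risk + ambiguity", {
  cfg <- game_config(alpha = 2, beta = 0.7)
  m <- assemble_model(cfg)
  n <- cfg$n_wealth_levels
  # point mass at (mid wealth, charitable)
  q <- numeric(nrow(m$states)); q[4] <- 1
  b <- belief_state(q, m)
  for (a in m$actions) {
    efe <- expected_free_energy(b, a, m)
    expect_equal(efe$G, sum(efe$risk) + sum(efe$ambiguity))
    expect_true(all(efe$risk >= 0) && all(efe$ambiguity >= 0))
    expect_equal(efe$G, oracle_efe(q, a, m), tolerance = 1e-12)
  }
  # multi-step policies against the same oracle
  for (pol in list(c("donate", "keep"), c("keep", "keep", "donate"))) {
    expect_equal(expected_free_energy(b, pol, m)$G, oracle_efe(q, pol, m),
                 tolerance = 1e-12)
  }
})

test_that("ambiguity of the approval cue follows the likelihood precision", {
  set.seed(11)
  q <- runif(16); q <- q / sum(q)
  m0 <- assemble_model(game_config(alpha = 0))
  b0 <- belief_state(q, m0)
  for (a in m0$actions) {
    expect_equal(expected_free_energy(b0, a, m0)$ambiguity[["approval"]],
                 log(2))
  }
  mhi <- assemble_model(game_config(alpha = 12))
  bhi <- belief_state(q, mhi)
  expect_lt(expected_free_energy(bhi, "keep", mhi)$ambiguity[["approval"]],
            1e-3)
})

test_that("G is zero when predictions are preferred and likelihoods sharp", {
  m <- assemble_model(game_config(alpha = Inf, beta = 1, attrition = 0))
  q <- numeric(nrow(m$states)); q[3] <- 1   # (wealth 3, charitable)
  b <- belief_state(q, m)
  # preferences set to the exact predicted outcome distributions under keep
  q_next <- drop(m$B$keep %*% q)
  qm <- matrix(q_next, nrow = m$config$n_wealth_levels)
  ow <- rowSums(qm)
  oa <- drop(m$A_factor$approval %*% colSums(qm))
  m$C$c_wealth <- log(pmax(ow, 1e-300))
  m$C$c_approval <- stats::setNames(log(pmax(oa, 1e-300)),
                                    c("approval", "disapproval"))
  efe <- expected_free_energy(b, "keep", m)
  expect_equal(efe$G, 0, tolerance = 1e-12)
  expect_equal(unname(efe$risk), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(efe$ambiguity), c(0, 0))
})

test_that("policy posterior is normalized and shift-invariant", {
  G <- c(1.3, 0.2, 5.1)
  p <- policy_posterior(G, 8)
  expect_equal(sum(p), 1)
  expect_equal(policy_posterior(G + 100, 8), p)
  # gamma -> large concentrates on the minimum-G policy
  expect_gt(policy_posterior(G, 500)[2], 1 - 1e-10)
  expect_error(policy_posterior(G, 0), "precision")
})

test_that("action selection is deterministic under seed and breaks ties to donate", {
  # symmetric setup: both actions yield identical G at flat preferences
  cfg <- game_config(n_wealth_levels = 2, preference_span = 0, alpha = 0,
                     attrition = 0, selection_mode = "argmax")
  m <- assemble_model(cfg)
  ns <- nrow(m$states)
  bu <- belief_state(rep(1 / ns, ns), m)
  sel <- select_action(bu, m)
  expect_equal(sel$G[1], sel$G[2], tolerance = 1e-12)
  expect_equal(sel$action, "donate")

  cfg2 <- game_config(alpha = 1.5, beta = 0.8)
  m2 <- assemble_model(cfg2)
  b2 <- belief_state(m2$D, m2)
  picks <- vapply(1:5, function(i) select_action(b2, m2, seed = 99)$action,
                  character(1))
  expect_true(all(picks == picks[1]))
})

test_that("policy enumeration is exhaustive and donate-leading first", {
  p1 <- enumerate_policies(1)
  expect_equal(p1, list("donate", "keep"))
  p3 <- enumerate_policies(3)
  expect_equal(length(p3), 8L)
  expect_equal(length(unique(vapply(p3, paste, character(1), collapse = "-"))),
               8L)
  expect_equal(p3[[1]], rep("donate", 3))
  expect_error(enumerate_policies(0), "depth")
})

test_that("beliefs stay normalized under long predict/update interleavings", {
  cfg <- game_config(alpha = 1, beta = 0.8)
  m <- assemble_model(cfg)
  b <- belief_state(m$D, m)
  set.seed(5)
  em <- repgame:::env_matrices(environment_spec(), m)
  true_state <- c(1L, 1L)
  drift <- 0
  for (i in 1:10000) {
    a <- sample(game_actions(), 1)
    step <- repgame:::env_step_fast(true_state, a, em,
                                    cfg$n_wealth_levels)
    true_state <- step$state
    b <- update_beliefs(predict_states(b, a, m), step$observation, m)
    drift <- max(drift, abs(sum(b$q_joint) - 1))
  }
  expect_lt(drift, 1e-9)
})
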