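test_that("approval likelihood bridges the 50-50 and identity regimes", {
  a0 <- build_approval_likelihood(0)
  expect_equal(unname(as.vector(a0)), rep(0.5, 4))

  a3 <- build_approval_likelihood(log(3))
  expect_equal(a3["approval", "charitable"], 0.75)
  expect_equal(a3["disapproval", "mean"], 0.75)

  # strictly increasing in alpha on the diagonal, within [0.5, 1)
  alphas <- seq(0, 10, by = 0.5)
  diag_p <- vapply(alphas, function(a)
    build_approval_likelihood(a)["approval", "charitable"], numeric(1))
  expect_true(all(diff(diag_p) > 0))
  expect_true(all(diag_p >= 0.5 & diag_p < 1))

  # asymptotically the identity mapping
  expect_equal(build_approval_likelihood(Inf)["approval", "charitable"], 1)

  for (a in alphas) {
    expect_equal(colSums(build_approval_likelihood(a)), c(charitable = 1, mean = 1))
  }
  expect_error(build_approval_likelihood(-0.1), "alpha")
})

test_that("self-worth transitions encode action-dependent redemption/decay", {
  for (act in game_actions()) {
    expect_equal(unname(build_selfworth_transition(act, 1)), diag(2))
  }
  b_d <- build_selfworth_transition("donate", 0.5)
  expect_equal(unname(b_d[, "mean"]), c(0.5, 0.5))
  b_d9 <- build_selfworth_transition("donate", 0.9)
  expect_equal(b_d9["charitable", "mean"], 0.1)
  expect_equal(b_d9["charitable", "charitable"], 1.0)
  # keep is the mirror image: mean absorbing, charitable degrades
  b_k9 <- build_selfworth_transition("keep", 0.9)
  expect_equal(b_k9["mean", "charitable"], 0.1)
  expect_equal(b_k9["mean", "mean"], 1.0)
  for (beta in c(0.5, 0.7, 1)) {
    for (act in game_actions()) {
      expect_equal(unname(colSums(build_selfworth_transition(act, beta))),
                   c(1, 1))
    }
  }
  expect_error(build_selfworth_transition("donate", 0), "beta")
  expect_error(build_selfworth_transition("keep", 1.2), "beta")
})

test_that("wealth transitions compose the action shift with attrition", {
  b_d <- build_wealth_transition("donate", 0.1, 8)
  expect_equal(unname(b_d[, 1]), c(1, rep(0, 7)))  # absorbing floor

  b_k <- build_wealth_transition("keep", 0.1, 8)
  # from the top: the shift has no effect, decay drops one level w.p. 0.1
  expect_equal(unname(b_k[8, 8]), 0.9)
  expect_equal(unname(b_k[7, 8]), 0.1)
  # from level 4: shift to 5, then decay back to 4 w.p. 0.1
  expect_equal(unname(b_k[5, 4]), 0.9)
  expect_equal(unname(b_k[4, 4]), 0.1)
  expect_equal(sum(b_k[, 4]), 1)

  # repeated donation reaches the floor with probability 1 in <= n - 1 steps
  p <- diag(8)
  for (k in 1:7) p <- b_d %*% p
  expect_equal(unname(p[1, ]), rep(1, 8), tolerance = 1e-12)

  expect_error(build_wealth_transition("keep", -0.2, 8), "attrition")
  expect_error(build_wealth_transition("keep", 0.1, 1), "n")
})

test_that("preferences are log-linear in wealth with the configured span", {
  prefs <- build_preferences(game_config())
  expect_equal(unname(prefs$c_wealth), seq(0, 4, length.out = 8))
  expect_equal(diff(range(prefs$c_wealth)), 4)
  expect_equal(unname(prefs$c_approval["approval"] -
                        prefs$c_approval["disapproval"]), 4)

  flat <- build_preferences(game_config(preference_span = 0))
  expect_true(all(flat$c_wealth == 0))
  expect_equal(unname(diff(rev(flat$c_approval))), 0)

  for (span in c(0, 1.5, 6)) {
    p <- build_preferences(game_config(preference_span = span))
    expect_equal(unname(p$c_approval["approval"] -
                          p$c_approval["disapproval"]), span)
  }
})

test_that("assembled model has the right shape and factorizes exactly", {
  m <- assemble_model(game_config())
  expect_equal(nrow(m$states), 16L)
  expect_equal(length(m$actions), 2L)
  expect_equal(names(m$A), c("wealth", "approval"))

  m2 <- assemble_model(game_config(n_wealth_levels = 2))
  expect_equal(nrow(m2$states), 4L)
  expect_equal(nrow(validate_model(m2)), 0L)

  set.seed(42)
  for (i in 1:100) {
    cfg <- game_config(alpha = runif(1, 0, 6), beta = runif(1, 0.01, 1),
                       attrition = runif(1), n_wealth_levels = sample(2:8, 1))
    mm <- assemble_model(cfg)
    for (a in mm$actions) {
      expect_equal(unname(colSums(mm$B[[a]])), rep(1, nrow(mm$states)),
                   tolerance = 1e-12)
    }
    expect_equal(unname(colSums(mm$A$approval)), rep(1, nrow(mm$states)),
                 tolerance = 1e-12)
  }
})

test_that("acting on a product-form belief equals factor-wise action", {
  set.seed(7)
  for (i in 1:20) {
    cfg <- game_config(alpha = runif(1, 0, 4), beta = runif(1, 0.5, 1))
    m <- assemble_model(cfg)
    n <- cfg$n_wealth_levels
    qw <- runif(n); qw <- qw / sum(qw)
    qs <- runif(2); qs <- qs / sum(qs)
    q_joint <- as.vector(outer(qw, qs))   # wealth varies fastest
    for (a in m$actions) {
      joint <- drop(m$B[[a]] %*% q_joint)
      factored <- as.vector(outer(drop(m$B_factor$wealth[[a]] %*% qw),
                                  drop(m$B_factor$selfworth[[a]] %*% qs)))
      expect_equal(joint, factored, tolerance = 1e-12)
    }
  }
})

test_that("validate_model reports injected faults by location", {
  m <- assemble_model(game_config())
  expect_equal(nrow(validate_model(m)), 0L)

  m_bad <- m
  m_bad$A$approval[1, 3] <- m_bad$A$approval[1, 3] + 0.01
  rep_bad <- validate_model(m_bad)
  expect_gt(nrow(rep_bad), 0L)
  expect_true(any(rep_bad$component == "A$approval" &
                    grepl("column 3", rep_bad$location)))

  m_bad2 <- m
  m_bad2$B_factor$selfworth$donate <- build_selfworth_transition("donate", 0.6)
  rep_bad2 <- validate_model(m_bad2)
  expect_true(any(grepl("factorize", rep_bad2$message)))
})
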