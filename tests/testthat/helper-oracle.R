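# Independent oracles: brute-force computations that never reuse the
# package's inference code paths.

# Exact filtering posterior over the final hidden state by enumerating every
# joint state trajectory of the game. `actions` and `observations` are
# parallel lists of length T; observations are c(wealth_cue, approval_cue).
oracle_filter <- function(model, actions, observations,
                          floor = model$config$likelihood_floor) {
  ns <- nrow(model$states)
  T_ <- length(actions)
  stopifnot(T_ >= 1L, length(observations) == T_)
  s0 <- which(model$D > 0)
  stopifnot(length(s0) == 1L)  # point-mass initial prior
  lik <- function(obs) {
    la <- model$A$approval[obs[2L], ]
    if (floor > 0) la <- (1 - floor) * la + floor / 2
    model$A$wealth[obs[1L], ] * la
  }
  M <- as.matrix(expand.grid(rep(list(seq_len(ns)), T_),
                             KEEP.OUT.ATTRS = FALSE))
  w <- model$B[[actions[[1L]]]][cbind(M[, 1L], s0)] * lik(observations[[1L]])[M[, 1L]]
  if (T_ > 1L) {
    for (t in 2:T_) {
      w <- w * model$B[[actions[[t]]]][cbind(M[, t], M[, t - 1L])] *
        lik(observations[[t]])[M[, t]]
    }
  }
  post <- vapply(seq_len(ns), function(s) sum(w[M[, T_] == s]), numeric(1L))
  post / sum(post)
}

# Expected free energy of a policy by direct summation of the risk +
# ambiguity decomposition, using explicit loops only.
oracle_efe <- function(q, policy, model) {
  ns <- length(q)
  n <- model$config$n_wealth_levels
  pref <- function(c_vec) exp(c_vec - max(c_vec)) / sum(exp(c_vec - max(c_vec)))
  pw <- pref(model$C$c_wealth)
  pa <- pref(model$C$c_approval)
  G <- 0
  for (action in policy) {
    B <- model$B[[action]]
    q_next <- numeric(ns)
    for (i in seq_len(ns)) {
      for (j in seq_len(ns)) q_next[i] <- q_next[i] + B[i, j] * q[j]
    }
    o_w <- numeric(n)
    o_a <- numeric(2L)
    for (s in seq_len(ns)) {
      o_w[model$states$wealth[s]] <- o_w[model$states$wealth[s]] + q_next[s]
      for (o in 1:2) o_a[o] <- o_a[o] + model$A$approval[o, s] * q_next[s]
    }
    for (k in seq_len(n)) {
      if (o_w[k] > 0) G <- G + o_w[k] * (log(o_w[k]) - log(pw[k]))
    }
    for (o in 1:2) if (o_a[o] > 0) G <- G + o_a[o] * (log(o_a[o]) - log(pa[o]))
    for (s in seq_len(ns)) {
      h <- 0
      for (o in 1:2) {
        p <- model$A$approval[o, s]
        if (p > 0) h <- h - p * log(p)
      }
      G <- G + q_next[s] * h
    }
    q <- q_next
  }
  unname(G)
}

# Sample a short action/observation record from the generative process so
# that observations are always possible under the agent's model.
sample_game_record <- function(model, T_, env = environment_spec()) {
  em <- repgame:::env_matrices(env, model)
  n <- model$config$n_wealth_levels
  s0 <- which(model$D > 0)
  true_state <- c((s0 - 1L) %% n + 1L, (s0 - 1L) %/% n + 1L)
  actions <- sample(game_actions(), T_, replace = TRUE)
  observations <- vector("list", T_)
  for (t in seq_len(T_)) {
    step <- repgame:::env_step_fast(true_state, actions[[t]], em, n)
    true_state <- step$state
    observations[[t]] <- step$observation
  }
  list(actions = as.list(actions), observations = observations)
}
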