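#' Belief state over the joint hidden-state space
#'
#' Wraps a normalized probability vector over joint (wealth, self-worth)
#' states and derives the factor marginals.
#'
#' @param q_joint Non-negative vector over joint states (renormalized if its
#'   sum deviates within tolerance; an unnormalizable vector errors).
#' @param model A `repgame_model` (for dimensions and labels).
#' @return Object of class `repgame_belief`: list with `q_joint`, `q_wealth`,
#'   `q_selfworth`, `p_charitable`, `expected_wealth`.
#' @export
belief_state <- function(q_joint, model) {
  n <- model$config$n_wealth_levels
  if (length(q_joint) != 2L * n) {
    stop("belief dimension mismatch: expected ", 2L * n, " joint states",
         call. = FALSE)
  }
  s <- sum(q_joint)
  if (!is.finite(s) || s <= 0 || any(q_joint < -1e-12)) {
    stop("belief is not normalizable", call. = FALSE)
  }
  q <- q_joint / s
  qm <- matrix(q, nrow = n)
  b <- list(
    q_joint = q,
    q_wealth = rowSums(qm),
    q_selfworth = stats::setNames(colSums(qm), selfworth_states()),
    p_charitable = sum(qm[, 1L]),
    expected_wealth = sum(rowSums(qm) * seq_len(n))
  )
  class(b) <- "repgame_belief"
  b
}

#' @export
print.repgame_belief <- function(x, ...) {
  cat(sprintf("Belief: P(charitable) = %.4f, E[wealth level] = %.3f\n",
              x$p_charitable, x$expected_wealth))
  invisible(x)
}

#' One-step belief prediction through the transition model
#'
#' Pushes the current posterior through the joint transition matrix of the
#' given action to obtain the prior over next-trial states.
#'
#' @param belief A `repgame_belief`.
#' @param action `"donate"` or `"keep"`.
#' @param model A `repgame_model`.
#' @return A `repgame_belief` over next-trial states.
#' @export
predict_states <- function(belief, action = game_actions(), model) {
  action <- match.arg(action)
  belief_state(drop(model$B[[action]] %*% belief$q_joint), model)
}

#' Exact Bayesian belief update from one observation pair
#'
#' Multiplies the prior by the likelihood of the observed wealth cue and
#' approval cue and renormalizes: exact Bayes on the (small) joint space.
#' A configurable floor probability is mixed into the approval likelihood so
#' that an extreme `alpha` cannot produce zero evidence when the environment
#' disagrees with the model; an observation that is impossible under the
#' prior raises an error.
#'
#' @param prior_belief A `repgame_belief`.
#' @param observation Integer vector `c(wealth_cue, approval_cue)`:
#'   1-based wealth level and 1 = approval, 2 = disapproval.
#' @param model A `repgame_model`.
#' @param floor Approval-likelihood floor; defaults to the model
#'   configuration's `likelihood_floor`.
#' @return Posterior `repgame_belief`.
#' @export
update_beliefs <- function(prior_belief, observation, model,
                           floor = model$config$likelihood_floor) {
  n <- model$config$n_wealth_levels
  ow <- as.integer(observation[[1L]])
  oa <- as.integer(observation[[2L]])
  if (is.na(ow) || ow < 1L || ow > n || is.na(oa) || oa < 1L || oa > 2L) {
    stop("observation indices out of range", call. = FALSE)
  }
  lik_w <- model$A$wealth[ow, ]
  lik_a <- model$A$approval[oa, ]
  if (floor > 0) lik_a <- (1 - floor) * lik_a + floor / 2
  post <- prior_belief$q_joint * lik_w * lik_a
  if (sum(post) <= 0) {
    stop("inference degenerate: observation has zero probability under the prior",
         call. = FALSE)
  }
  belief_state(post, model)
}

#' Enumerate policies
#'
#' All ordered action sequences of the given depth, donate-first in
#' lexicographic order (so ties in expected free energy resolve in favour of
#' donating under argmax selection).
#'
#' @param depth Planning depth >= 1.
#' @return List of character vectors of actions.
#' @export
enumerate_policies <- function(depth = 1L) {
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L) stop("policy depth must be >= 1",
                                       call. = FALSE)
  grids <- rep(list(game_actions()), depth)
  m <- as.matrix(do.call(expand.grid,
                         c(rev(grids), KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)))
  lapply(seq_len(nrow(m)), function(i) rev(unname(m[i, ])))
}

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

kl_div <- function(p, q) {
  i <- p > 0
  sum(p[i] * (log(p[i]) - log(q[i])))
}

#' Expected free energy of a policy
#'
#' Scores an action sequence by the standard risk-plus-ambiguity
#' decomposition. For each step the belief is propagated through the
#' transition matrix of that step's action; risk is the KL divergence from
#' the predicted outcome distribution to the preference distribution
#' (softmax of the log preferences, per modality), and ambiguity is the
#' belief-weighted entropy of the likelihood columns. Lower G marks the
#' policy whose expected outcomes better match preferences with less
#' expected observation noise.
#'
#' @param belief Current posterior `repgame_belief`.
#' @param policy Character vector of actions (length >= 1), or a single
#'   action string.
#' @param model A `repgame_model`.
#' @return List with `G` (total, nats) and per-modality `risk` and
#'   `ambiguity` vectors (`wealth`, `approval`), each summed over steps.
#' @export
expected_free_energy <- function(belief, policy, model) {
  if (length(policy) < 1L) stop("policy must contain at least one action",
                                call. = FALSE)
  n <- model$config$n_wealth_levels
  pref_w <- softmax(model$C$c_wealth)
  pref_a <- softmax(model$C$c_approval)
  q <- belief$q_joint
  risk <- c(wealth = 0, approval = 0)
  ambiguity <- c(wealth = 0, approval = 0)
  for (action in policy) {
    q <- drop(model$B[[match.arg(action, game_actions())]] %*% q)
    qm <- matrix(q, nrow = n)
    o_w <- rowSums(qm)                        # identity wealth likelihood
    o_a <- drop(model$A_factor$approval %*% colSums(qm))
    risk[["wealth"]] <- risk[["wealth"]] + kl_div(o_w, pref_w)
    risk[["approval"]] <- risk[["approval"]] + kl_div(o_a, pref_a)
    # wealth likelihood columns are deterministic: zero entropy
    ambiguity[["approval"]] <- ambiguity[["approval"]] +
      sum(q * model$H_approval)
  }
  list(G = sum(risk) + sum(ambiguity), risk = risk, ambiguity = ambiguity)
}

#' Posterior over policies
#'
#' Softmax of negative expected free energy at inverse temperature `gamma`;
#' invariant to adding a constant to all G values.
#'
#' @param G Numeric vector of expected free energies.
#' @param gamma Policy precision (inverse temperature), > 0.
#' @return Probability vector over policies.
#' @export
policy_posterior <- function(G, gamma) {
  if (gamma <= 0) stop("policy precision must be > 0", call. = FALSE)
  softmax(-gamma * G)
}

#' Select an action by expected free energy
#'
#' Enumerates all policies of the configured depth, scores each with
#' [expected_free_energy()], forms the policy posterior and either samples
#' from it (`selection_mode = "sample"`, using R's RNG — seed with
#' `set.seed()` or pass `seed`) or takes its mode (`"argmax"`, ties broken
#' in favour of donating). The first action of the chosen policy is returned.
#'
#' @param belief Current posterior `repgame_belief`.
#' @param model A `repgame_model`.
#' @param seed Optional integer seed applied before sampling.
#' @return List with `action`, `policy` (index of chosen policy), `G`
#'   (vector over policies), `posterior` (policy posterior), `efe` (list of
#'   per-policy breakdowns).
#' @export
select_action <- function(belief, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- model$config
  policies <- enumerate_policies(cfg$policy_depth)
  efe <- lapply(policies, function(p) expected_free_energy(belief, p, model))
  G <- vapply(efe, `[[`, numeric(1L), "G")
  post <- policy_posterior(G, cfg$policy_precision)
  k <- if (cfg$selection_mode == "argmax") {
    which.max(post)   # first maximum: donate-leading policies come first
  } else {
    sample.int(length(post), 1L, prob = post)
  }
  list(action = policies[[k]][1L], policy = k, G = G, posterior = post,
       efe = efe)
}
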