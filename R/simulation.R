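#' Specification of the generative process (environment)
#'
#' The environment that actually emits true states and cues. By default the
#' approval cue is veridical (approval iff the true state is charitable,
#' i.e. `env_alpha = Inf`) while the true self-worth dynamics and wealth
#' attrition follow the agent's own parameters; the manipulated precisions
#' `alpha`/`beta` of the *agent* are then purely subjective. Set
#' `share_with_model = TRUE` to force all environment matrices identical to
#' the agent's generative model.
#'
#' @param env_alpha Approval veridicality (same logistic parameterization as
#'   the agent's `alpha`; default `Inf` = fully precise).
#' @param env_beta True self-worth dynamics parameter in (0, 1]; `NULL`
#'   (default) inherits the agent's `beta`.
#' @param attrition True wealth-decay probability; `NULL` inherits the
#'   agent's.
#' @param share_with_model If `TRUE`, the environment uses the agent's
#'   matrices verbatim (overrides the other fields).
#' @return Object of class `repgame_env`.
#' @export
environment_spec <- function(env_alpha = Inf, env_beta = NULL,
                             attrition = NULL, share_with_model = FALSE) {
  if (!is.null(env_beta) && (env_beta <= 0 || env_beta > 1)) {
    stop("invalid `env_beta`: must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(env_alpha) || length(env_alpha) != 1L || env_alpha < 0) {
    stop("invalid `env_alpha`: must be >= 0", call. = FALSE)
  }
  if (!is.null(attrition) && (attrition < 0 || attrition > 1)) {
    stop("invalid `attrition`: must lie in [0, 1]", call. = FALSE)
  }
  e <- list(env_alpha = env_alpha, env_beta = env_beta,
            attrition = attrition, share_with_model = isTRUE(share_with_model))
  class(e) <- "repgame_env"
  e
}

# Resolve the environment's factor matrices against an agent model.
env_matrices <- function(env, model) {
  cfg <- model$config
  if (env$share_with_model) {
    return(list(
      b_wealth = model$B_factor$wealth,
      b_selfworth = model$B_factor$selfworth,
      p_approval_given = model$A_factor$approval[1L, ]
    ))
  }
  beta <- if (is.null(env$env_beta)) cfg$beta else env$env_beta
  attr_ <- if (is.null(env$attrition)) cfg$attrition else env$attrition
  acts <- stats::setNames(game_actions(), game_actions())
  list(
    b_wealth = lapply(acts, build_wealth_transition, attrition = attr_,
                      n = cfg$n_wealth_levels,
                      decay_before_shift = cfg$decay_before_shift),
    b_selfworth = lapply(acts, build_selfworth_transition, beta = beta),
    p_approval_given = if (is.infinite(env$env_alpha)) c(1, 0)
                       else build_approval_likelihood(env$env_alpha)[1L, ]
  )
}

#' One step of the generative process
#'
#' Samples the next true state from the environment's factor transitions
#' given the chosen action, then emits the observable cues: the wealth cue
#' reports the true wealth level exactly; the approval cue is sampled from
#' the environment's approval mapping given the new true self-worth.
#'
#' @param true_state Integer vector `c(wealth, selfworth)` (1-based;
#'   selfworth 1 = charitable, 2 = mean).
#' @param action `"donate"` or `"keep"`.
#' @param env A `repgame_env`.
#' @param model The agent's `repgame_model` (supplies defaults the
#'   environment inherits).
#' @return List with `state` (next true `c(wealth, selfworth)`) and
#'   `observation` (`c(wealth_cue, approval_cue)`, approval 1 = approval).
#'   Uses R's RNG; seed with `set.seed()` for reproducibility.
#' @export
env_step <- function(true_state, action = game_actions(), env, model) {
  action <- match.arg(action)
  em <- env_matrices(env, model)
  env_step_fast(true_state, action, em, model$config$n_wealth_levels)
}

# Hot-path version: matrices already resolved.
env_step_fast <- function(true_state, action, em, n) {
  w <- sample.int(n, 1L, prob = em$b_wealth[[action]][, true_state[1L]])
  s <- sample.int(2L, 1L, prob = em$b_selfworth[[action]][, true_state[2L]])
  p_app <- em$p_approval_given[s]
  oa <- if (stats::runif(1L) < p_app) 1L else 2L
  list(state = c(w, s), observation = c(w, oa))
}

#' Simulate one complete reputation game
#'
#' Runs `horizon` trials of select-action / environment-step /
#' predict-and-update, recording actions, true states, cues, posterior
#' beliefs and per-policy expected free energies. Bit-reproducible for a
#' fixed seed and selection mode.
#'
#' @param config A [game_config()].
#' @param env An [environment_spec()] (default: veridical approval,
#'   dynamics inherited from the agent).
#' @param seed Integer seed (`NULL` leaves the RNG state untouched).
#' @param init_belief Optional starting `repgame_belief` (default: the
#'   model's initial prior).
#' @param init_true Optional starting true state `c(wealth, selfworth)`
#'   (default: sampled from the initial prior, which is a point mass).
#' @param model Optional pre-assembled `repgame_model` for `config`.
#' @return Object of class `repgame_trajectory`: list with `config`, `env`,
#'   `seed`, `trials` (data frame: trial, action, true_wealth,
#'   true_selfworth, obs_wealth, obs_approval, p_charitable,
#'   expected_wealth, g_donate, g_keep) and `summary`
#'   (see [summarize_trajectory()]).
#' @examples
#' tr <- run_game(game_config(alpha = 4, beta = 0.55, horizon = 8), seed = 1)
#' tr$summary$donation_fraction
#' @export
run_game <- function(config, env = environment_spec(), seed = NULL,
                     init_belief = NULL, init_true = NULL, model = NULL) {
  if (is.null(model)) model <- assemble_model(config)
  config <- model$config
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_wealth_levels
  em <- env_matrices(env, model)

  belief <- if (is.null(init_belief)) belief_state(model$D, model)
            else init_belief
  true_state <- if (is.null(init_true)) {
    s <- which(model$D > 0)[1L]
    c((s - 1L) %% n + 1L, (s - 1L) %/% n + 1L)
  } else as.integer(init_true)

  h <- config$horizon
  trials <- data.frame(
    trial = integer(h), action = character(h), true_wealth = integer(h),
    true_selfworth = integer(h), obs_wealth = integer(h),
    obs_approval = integer(h), p_charitable = numeric(h),
    expected_wealth = numeric(h), g_donate = numeric(h), g_keep = numeric(h)
  )
  first_act <- vapply(enumerate_policies(config$policy_depth),
                      `[[`, character(1L), 1L)
  for (t in seq_len(h)) {
    sel <- select_action(belief, model)
    step <- env_step_fast(true_state, sel$action, em, n)
    true_state <- step$state
    belief <- update_beliefs(predict_states(belief, sel$action, model),
                             step$observation, model)
    trials$trial[t] <- t
    trials$action[t] <- sel$action
    trials$true_wealth[t] <- true_state[1L]
    trials$true_selfworth[t] <- true_state[2L]
    trials$obs_wealth[t] <- step$observation[1L]
    trials$obs_approval[t] <- step$observation[2L]
    trials$p_charitable[t] <- belief$p_charitable
    trials$expected_wealth[t] <- belief$expected_wealth
    trials$g_donate[t] <- min(sel$G[first_act == "donate"])
    trials$g_keep[t] <- min(sel$G[first_act == "keep"])
  }
  traj <- list(config = config, env = env, seed = seed, trials = trials,
               final_belief = belief, final_true_state = true_state)
  traj$summary <- summarize_trajectory(traj)
  class(traj) <- "repgame_trajectory"
  traj
}

#' Summary metrics of a trajectory
#'
#' @param trajectory A `repgame_trajectory` (or the list produced while one
#'   is being built).
#' @return List with `final_p_charitable` (posterior P(charitable) after the
#'   last trial), `final_wealth` (true level), `mean_wealth` (over trials),
#'   `donation_fraction`, `n_trials`, and `empty` (`TRUE` when the horizon
#'   was zero, in which case the metrics are the initial conditions).
#' @export
summarize_trajectory <- function(trajectory) {
  tr <- trajectory$trials
  if (nrow(tr) == 0L) {
    b <- trajectory$final_belief
    return(list(
      final_p_charitable = b$p_charitable,
      final_wealth = trajectory$final_true_state[1L],
      mean_wealth = as.numeric(trajectory$final_true_state[1L]),
      donation_fraction = NA_real_, n_trials = 0L, empty = TRUE))
  }
  list(
    final_p_charitable = tr$p_charitable[nrow(tr)],
    final_wealth = tr$true_wealth[nrow(tr)],
    mean_wealth = mean(tr$true_wealth),
    donation_fraction = mean(tr$action == "donate"),
    n_trials = nrow(tr), empty = FALSE
  )
}

#' @export
summary.repgame_trajectory <- function(object, ...) {
  s <- object$summary
  cat(sprintf(
    "Reputation game (%d trials, alpha = %g, beta = %g)\n",
    s$n_trials, object$config$alpha, object$config$beta))
  cat(sprintf("  donations      : %.0f%%\n", 100 * s$donation_fraction))
  cat(sprintf("  final wealth   : level %d (mean %.2f)\n",
              s$final_wealth, s$mean_wealth))
  cat(sprintf("  P(charitable)  : %.4f\n", s$final_p_charitable))
  invisible(s)
}

#' @export
print.repgame_trajectory <- function(x, ...) {
  summary(x)
  invisible(x)
}
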