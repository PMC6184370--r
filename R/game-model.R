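#' Configuration for the reputation game
#'
#' Bundles every tunable of the donate/keep reputation game. The agent lives
#' on a joint hidden-state space of monetary wealth (`n_wealth_levels` levels,
#' level 1 = broke) crossed with self-worth (charitable vs mean). Two
#' precisions are the quantities of scientific interest: `alpha`, the
#' likelihood precision coupling the hidden self-worth state to the social
#' approval cue, and `beta`, the transition-prior precision governing how
#' strongly the agent's choices are believed to move its self-worth.
#'
#' @param n_wealth_levels Integer >= 2, number of wealth levels (default 8,
#'   from broke to wealthy).
#' @param alpha Likelihood precision, >= 0 (`Inf` allowed: deterministic
#'   approval). `alpha = 0` gives a 50-50 approval cue regardless of
#'   self-worth; large `alpha` approaches an identity mapping.
#' @param beta Transition-prior precision in (0, 1]: the probability that the
#'   action-disfavoured self-worth state persists for one trial. `beta = 1`
#'   yields identity transitions (choices no longer move self-worth);
#'   `beta = 0.5` is maximal imprecision. Values below 0.5 are allowed but are
#'   outside the range in which `beta` acts as a precision.
#' @param attrition Per-trial probability of losing one wealth level (constant
#'   decay; default 0.10).
#' @param preference_span Log prior-preference range in natural-log units
#'   (nats) for both outcome modalities (default 4).
#' @param horizon Number of trials per game (default 16).
#' @param policy_depth Planning depth per decision, >= 1 (default 1).
#' @param policy_precision Inverse temperature gamma for the softmax over
#'   negative expected free energy (default 8).
#' @param selection_mode `"sample"` draws the policy from its posterior;
#'   `"argmax"` takes the maximum with ties broken in favour of donating.
#' @param initial_wealth_index 1-based starting wealth level (default 1 =
#'   broke).
#' @param initial_selfworth Starting self-worth state of the initial prior
#'   (default `"charitable"`).
#' @param decay_before_shift Apply the attrition decay before the action shift
#'   within a trial instead of after (sensitivity check; default `FALSE`).
#' @param likelihood_floor Small probability mixed into the approval
#'   likelihood columns during belief updates so that an extreme `alpha`
#'   cannot zero out the evidence for an observed cue (default 1e-10).
#'
#' @return An object of class `repgame_config` (a validated list).
#' @examples
#' cfg <- game_config(alpha = 2, beta = 0.9)
#' cfg$horizon
#' @export
game_config <- function(n_wealth_levels = 8L,
                        alpha = 2,
                        beta = 0.75,
                        attrition = 0.1,
                        preference_span = 4,
                        horizon = 16L,
                        policy_depth = 1L,
                        policy_precision = 8,
                        selection_mode = c("sample", "argmax"),
                        initial_wealth_index = 1L,
                        initial_selfworth = c("charitable", "mean"),
                        decay_before_shift = FALSE,
                        likelihood_floor = 1e-10) {
  selection_mode <- match.arg(selection_mode)
  initial_selfworth <- match.arg(initial_selfworth)
  cfg <- list(
    n_wealth_levels = as.integer(n_wealth_levels),
    alpha = as.numeric(alpha),
    beta = as.numeric(beta),
    attrition = as.numeric(attrition),
    preference_span = as.numeric(preference_span),
    horizon = as.integer(horizon),
    policy_depth = as.integer(policy_depth),
    policy_precision = as.numeric(policy_precision),
    selection_mode = selection_mode,
    initial_wealth_index = as.integer(initial_wealth_index),
    initial_selfworth = initial_selfworth,
    decay_before_shift = isTRUE(decay_before_shift),
    likelihood_floor = as.numeric(likelihood_floor)
  )
  class(cfg) <- "repgame_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stop_if <- function(bad, key, msg) {
    if (bad) stop(sprintf("invalid `%s`: %s", key, msg), call. = FALSE)
  }
  stop_if(cfg$n_wealth_levels < 2L, "n_wealth_levels", "must be >= 2")
  stop_if(is.na(cfg$alpha) || cfg$alpha < 0, "alpha", "must be >= 0")
  stop_if(is.na(cfg$beta) || cfg$beta <= 0 || cfg$beta > 1, "beta",
          "must lie in (0, 1]")
  stop_if(is.na(cfg$attrition) || cfg$attrition < 0 || cfg$attrition > 1,
          "attrition", "must lie in [0, 1]")
  stop_if(cfg$preference_span < 0, "preference_span", "must be >= 0")
  stop_if(cfg$horizon < 0L, "horizon", "must be >= 0")
  stop_if(cfg$policy_depth < 1L, "policy_depth", "must be >= 1")
  stop_if(cfg$policy_precision <= 0, "policy_precision", "must be > 0")
  stop_if(cfg$initial_wealth_index < 1L ||
            cfg$initial_wealth_index > cfg$n_wealth_levels,
          "initial_wealth_index", "must be a valid 1-based wealth level")
  stop_if(cfg$likelihood_floor < 0 || cfg$likelihood_floor >= 1,
          "likelihood_floor", "must lie in [0, 1)")
  invisible(cfg)
}

#' @export
print.repgame_config <- function(x, ...) {
  cat("Reputation-game configuration\n")
  cat(sprintf("  states    : %d wealth levels x {charitable, mean}\n",
              x$n_wealth_levels))
  cat(sprintf("  alpha     : %g (likelihood precision)\n", x$alpha))
  cat(sprintf("  beta      : %g (transition-prior precision)\n", x$beta))
  cat(sprintf("  attrition : %g, preference span %g nats\n",
              x$attrition, x$preference_span))
  cat(sprintf("  horizon   : %d trials, depth %d, gamma %g, mode %s\n",
              x$horizon, x$policy_depth, x$policy_precision,
              x$selection_mode))
  invisible(x)
}

#' Actions of the reputation game
#'
#' @return Character vector `c("donate", "keep")`.
#' @export
game_actions <- function() c("donate", "keep")

selfworth_states <- function() c("charitable", "mean")

approval_outcomes <- function() c("approval", "disapproval")

#' Approval likelihood factor
#'
#' Maps the hidden self-worth state to the social approval cue with precision
#' `alpha` through the logistic bridge
#' \eqn{p = e^{\alpha} / (e^{\alpha} + 1)}: at `alpha = 0` the cue is 50-50
#' irrespective of self-worth; as `alpha` grows the mapping approaches the
#' identity (approval iff charitable).
#'
#' @param alpha Likelihood precision, >= 0 (`Inf` allowed).
#' @return 2x2 column-stochastic matrix, rows = outcomes (approval,
#'   disapproval), columns = self-worth states (charitable, mean).
#' @examples
#' build_approval_likelihood(0)      # all entries 0.5
#' build_approval_likelihood(log(3)) # P(approval | charitable) = 0.75
#' @export
build_approval_likelihood <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    stop("invalid `alpha`: must be a single non-negative number",
         call. = FALSE)
  }
  p <- stats::plogis(alpha)   # exp(alpha) / (exp(alpha) + 1)
  matrix(c(p, 1 - p, 1 - p, p), nrow = 2L,
         dimnames = list(approval_outcomes(), selfworth_states()))
}

#' Self-worth transition factor
#'
#' Encodes how an action is believed to move self-worth. Donating keeps a
#' charitable state with certainty and redeems a mean state with probability
#' `1 - beta`; keeping is the mirror image (mean is absorbing, charitable
#' degrades with probability `1 - beta`). `beta = 1` gives the identity for
#' either action, de-coupling self-worth from choice; `beta = 0.5` is
#' maximally imprecise.
#'
#' @param action `"donate"` or `"keep"`.
#' @param beta Transition-prior precision in (0, 1].
#' @return 2x2 column-stochastic matrix, rows = next state, columns = previous
#'   state (charitable, mean).
#' @examples
#' build_selfworth_transition("donate", 0.9)
#' build_selfworth_transition("keep", 1)  # identity
#' @export
build_selfworth_transition <- function(action = game_actions(), beta) {
  action <- match.arg(action)
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta <= 0 || beta > 1) {
    stop("invalid `beta`: must be a single number in (0, 1]", call. = FALSE)
  }
  m <- if (action == "donate") {
    # charitable maintained; mean -> charitable w.p. 1 - beta
    matrix(c(1, 0, 1 - beta, beta), nrow = 2L)
  } else {
    # mean absorbing; charitable -> mean w.p. 1 - beta
    matrix(c(beta, 1 - beta, 0, 1), nrow = 2L)
  }
  dimnames(m) <- list(selfworth_states(), selfworth_states())
  m
}

#' Wealth transition factor
#'
#' Composes a deterministic action shift (donate moves one level down with a
#' floor at level 1; keep moves one level up with a ceiling at level `n`) with
#' a constant attrition decay that drops one level with probability
#' `attrition` (level 1 unaffected). By default the decay acts after the shift
#' within a trial; `decay_before_shift` reverses the order.
#'
#' @param action `"donate"` or `"keep"`.
#' @param attrition Per-trial loss probability in [0, 1].
#' @param n Number of wealth levels, >= 2.
#' @param decay_before_shift Compose decay before the shift (default `FALSE`).
#' @return n x n column-stochastic matrix, rows = next level, columns =
#'   previous level.
#' @examples
#' b <- build_wealth_transition("keep", 0.1, 8)
#' b[, 8]  # at the top level: stay w.p. 0.9, drop w.p. 0.1
#' @export
build_wealth_transition <- function(action = game_actions(), attrition = 0.1,
                                    n = 8L, decay_before_shift = FALSE) {
  action <- match.arg(action)
  if (!is.numeric(attrition) || length(attrition) != 1L || is.na(attrition) ||
      attrition < 0 || attrition > 1) {
    stop("invalid `attrition`: must be a single probability in [0, 1]",
         call. = FALSE)
  }
  n <- as.integer(n)
  if (is.na(n) || n < 2L) {
    stop("invalid `n`: need at least 2 wealth levels", call. = FALSE)
  }
  shift <- matrix(0, n, n)
  target <- if (action == "donate") pmax(seq_len(n) - 1L, 1L)
            else pmin(seq_len(n) + 1L, n)
  shift[cbind(target, seq_len(n))] <- 1
  decay <- diag(1 - attrition, n)
  decay[1L, 1L] <- 1
  decay[cbind(pmax(seq_len(n) - 1L, 1L), seq_len(n))] <-
    decay[cbind(pmax(seq_len(n) - 1L, 1L), seq_len(n))] + attrition
  decay[1L, 1L] <- 1   # floor level loses nothing
  m <- if (decay_before_shift) shift %*% decay else decay %*% shift
  lv <- paste0("w", seq_len(n))
  dimnames(m) <- list(lv, lv)
  m
}

#' Log prior preferences over outcomes
#'
#' Builds the C vectors: a log-linear increase in preference across wealth
#' levels and a fixed preference for approval over disapproval, both spanning
#' `preference_span` natural-log units.
#'
#' @param config A [game_config()] object.
#' @return List with `c_wealth` (length `n_wealth_levels`, nondecreasing, max
#'   minus min equal to the span) and `c_approval` (approval, disapproval).
#' @export
build_preferences <- function(config) {
  validate_config(config)
  n <- config$n_wealth_levels
  c_wealth <- seq(0, config$preference_span, length.out = n)
  names(c_wealth) <- paste0("w", seq_len(n))
  c_approval <- c(approval = config$preference_span, disapproval = 0)
  list(c_wealth = c_wealth, c_approval = c_approval)
}

#' Joint-state bookkeeping
#'
#' The joint hidden state flattens wealth and self-worth into a single index
#' with wealth varying fastest: `s = (selfworth - 1) * n_wealth + wealth`.
#'
#' @param n Number of wealth levels.
#' @return Data frame with one row per joint state: `state`, `wealth`
#'   (1-based level), `selfworth` (1 = charitable, 2 = mean).
#' @keywords internal
joint_states <- function(n) {
  data.frame(
    state = seq_len(2L * n),
    wealth = rep(seq_len(n), times = 2L),
    selfworth = rep(1:2, each = n)
  )
}

#' Assemble the full generative model
#'
#' Constructs likelihoods (A), transitions (B), preferences (C) and the
#' initial prior (D) for the reputation game, joining the wealth and
#' self-worth factors by tensor (Kronecker) composition on the flattened
#' joint space. The wealth likelihood is an exact identity mapping; the
#' approval likelihood has precision `alpha`; the self-worth transitions have
#' precision `beta`. The initial prior is a point mass on
#' (`initial_wealth_index`, `initial_selfworth`).
#'
#' @param config A [game_config()] object.
#' @return An object of class `repgame_model`: a list with elements `config`,
#'   `A` (joint-space likelihoods per modality), `A_factor`, `B` (per-action
#'   joint transitions), `B_factor`, `C`, `D`, `states`, `actions`, and
#'   cached approval-column entropies `H_approval` used by the expected free
#'   energy.
#' @examples
#' m <- assemble_model(game_config())
#' dim(m$B$donate)  # 16 x 16 joint transitions
#' @export
assemble_model <- function(config) {
  validate_config(config)
  n <- config$n_wealth_levels
  st <- joint_states(n)
  ns <- nrow(st)

  a_approval_f <- build_approval_likelihood(config$alpha)
  a_wealth <- matrix(0, n, ns, dimnames = list(paste0("w", seq_len(n)), NULL))
  a_wealth[cbind(st$wealth, st$state)] <- 1
  a_approval <- a_approval_f[, st$selfworth, drop = FALSE]
  dimnames(a_approval) <- list(approval_outcomes(), NULL)

  b_factor <- list(
    wealth = lapply(stats::setNames(game_actions(), game_actions()),
                    build_wealth_transition, attrition = config$attrition,
                    n = n, decay_before_shift = config$decay_before_shift),
    selfworth = lapply(stats::setNames(game_actions(), game_actions()),
                       build_selfworth_transition, beta = config$beta)
  )
  b_joint <- lapply(stats::setNames(game_actions(), game_actions()),
                    function(a) kronecker(b_factor$selfworth[[a]],
                                          b_factor$wealth[[a]]))

  prefs <- build_preferences(config)

  d <- numeric(ns)
  sw0 <- match(config$initial_selfworth, selfworth_states())
  d[(sw0 - 1L) * n + config$initial_wealth_index] <- 1

  model <- list(
    config = config,
    A = list(wealth = a_wealth, approval = a_approval),
    A_factor = list(approval = a_approval_f),
    B = b_joint,
    B_factor = b_factor,
    C = prefs,
    D = d,
    states = st,
    actions = game_actions(),
    H_approval = apply(a_approval, 2L, entropy_nats)
  )
  class(model) <- "repgame_model"
  model
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' @export
print.repgame_model <- function(x, ...) {
  cat(sprintf(
    "Reputation-game generative model: %d joint states (%d wealth x 2), 2 actions\n",
    nrow(x$states), x$config$n_wealth_levels))
  cat(sprintf("  alpha = %g, beta = %g, attrition = %g, span = %g\n",
              x$config$alpha, x$config$beta, x$config$attrition,
              x$config$preference_span))
  invisible(x)
}

#' Validate a generative model
#'
#' Checks every structural invariant of the assembled model: likelihood and
#' transition columns are probability vectors, the wealth likelihood is the
#' identity on the wealth component, the joint transitions factorize exactly
#' as the Kronecker product of their factors, the preference spans match the
#' configuration, and the initial prior is a normalized distribution.
#'
#' @param model A `repgame_model`.
#' @param tol Numerical tolerance (default 1e-12).
#' @return Data frame with columns `component`, `location`, `message`, one
#'   row per violation; zero rows iff the model is valid.
#' @examples
#' nrow(validate_model(assemble_model(game_config())))  # 0
#' @export
validate_model <- function(model, tol = 1e-12) {
  bad <- list()
  note <- function(component, location, message) {
    bad[[length(bad) + 1L]] <<- data.frame(
      component = component, location = location, message = message)
  }
  check_stochastic <- function(m, component) {
    cs <- colSums(m)
    off <- which(abs(cs - 1) > tol | apply(m < -tol, 2L, any))
    for (j in off) {
      note(component, sprintf("column %d", j),
           sprintf("not a probability vector (sum = %.15g)", cs[j]))
    }
  }
  check_stochastic(model$A$wealth, "A$wealth")
  check_stochastic(model$A$approval, "A$approval")
  for (a in model$actions) {
    check_stochastic(model$B[[a]], sprintf("B$%s", a))
    kb <- kronecker(model$B_factor$selfworth[[a]], model$B_factor$wealth[[a]])
    if (max(abs(kb - model$B[[a]])) > tol) {
      note(sprintf("B$%s", a), "joint",
           "does not factorize as kronecker(selfworth, wealth)")
    }
  }
  ident <- matrix(0, model$config$n_wealth_levels, nrow(model$states))
  ident[cbind(model$states$wealth, model$states$state)] <- 1
  if (max(abs(model$A$wealth - ident)) > tol) {
    note("A$wealth", "joint", "not the identity on the wealth component")
  }
  span <- model$config$preference_span
  if (abs(diff(range(model$C$c_wealth)) - span) > tol) {
    note("C$c_wealth", "range",
         sprintf("span %.15g != preference_span %.15g",
                 diff(range(model$C$c_wealth)), span))
  }
  if (is.unsorted(model$C$c_wealth)) {
    note("C$c_wealth", "order", "not nondecreasing in wealth level")
  }
  if (abs((model$C$c_approval[["approval"]] -
             model$C$c_approval[["disapproval"]]) - span) > tol) {
    note("C$c_approval", "difference", "approval advantage != preference_span")
  }
  if (abs(sum(model$D) - 1) > tol || any(model$D < -tol)) {
    note("D", "joint", "initial prior is not a probability vector")
  }
  if (length(bad) == 0L) {
    data.frame(component = character(), location = character(),
               message = character())
  } else {
    do.call(rbind, bad)
  }
}

#' Export model matrices to CSV
#'
#' Writes one headered CSV per matrix/vector (A, B factors and joints, C, D)
#' into `dir` for inspection and regression testing.
#'
#' @param model A `repgame_model`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_model_csv <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  put <- function(x, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(as.data.frame(x), p, row.names = TRUE)
    paths <<- c(paths, p)
  }
  put(model$A$wealth, "A_wealth")
  put(model$A$approval, "A_approval")
  for (a in model$actions) {
    put(model$B_factor$wealth[[a]], paste0("B_wealth_", a))
    put(model$B_factor$selfworth[[a]], paste0("B_selfworth_", a))
    put(model$B[[a]], paste0("B_joint_", a))
  }
  put(data.frame(c_wealth = model$C$c_wealth), "C_wealth")
  put(data.frame(c_approval = model$C$c_approval), "C_approval")
  put(data.frame(d = model$D), "D")
  invisible(paths)
}
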