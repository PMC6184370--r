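#' Parameter grid for the precision sweep
#'
#' Defines the (alpha, beta) grid over which synthetic subjects are
#' simulated. Defaults span both quoted regimes of the approval mapping
#' (alpha from 0, a 50-50 cue, to 4, near-veridical) and the range over which
#' beta acts as a precision (0.5, maximally imprecise, to 1, identity
#' transitions).
#'
#' @param alpha_values Ordered numeric vector of likelihood precisions
#'   (default 17 points from 0 to 4).
#' @param beta_values Ordered numeric vector of transition precisions
#'   (default 11 points from 0.5 to 1).
#' @param n_replicates Independent games per grid cell (default 32).
#' @param base_seed Integer from which every cell/replicate seed is derived
#'   (default 1).
#' @return Object of class `repgame_grid`.
#' @export
sweep_grid <- function(alpha_values = seq(0, 4, length.out = 17),
                       beta_values = seq(0.5, 1, length.out = 11),
                       n_replicates = 32L, base_seed = 1L) {
  if (any(alpha_values < 0)) stop("invalid `alpha_values`: must be >= 0",
                                  call. = FALSE)
  if (any(beta_values <= 0 | beta_values > 1)) {
    stop("invalid `beta_values`: must lie in (0, 1]", call. = FALSE)
  }
  if (n_replicates < 1L) stop("invalid `n_replicates`: must be >= 1",
                              call. = FALSE)
  g <- list(alpha_values = as.numeric(alpha_values),
            beta_values = as.numeric(beta_values),
            n_replicates = as.integer(n_replicates),
            base_seed = as.integer(base_seed))
  class(g) <- "repgame_grid"
  g
}

#' Deterministic per-cell replicate seed
#'
#' Seeds depend only on the base seed, the cell index and the replicate
#' index, never on evaluation order, so sweep results are invariant to the
#' order in which cells are run.
#'
#' @param base_seed Integer base seed.
#' @param cell Integer cell index (1-based).
#' @param rep Integer replicate index (1-based).
#' @return A single integer seed in [0, 2^31).
#' @export
cell_seed <- function(base_seed, cell, rep) {
  m <- 2147483647
  s <- (as.numeric(base_seed) %% m) * 48271 %% m
  s <- (s + as.numeric(cell) * 69621) %% m
  s <- (s * 16807 + as.numeric(rep)) %% m
  as.integer(s)
}

#' Sweep the (alpha, beta) precision grid
#'
#' Simulates `n_replicates` independent 16-trial games (or whatever horizon
#' the configuration specifies) for every (alpha, beta) cell and aggregates
#' the final posterior P(charitable), the final true wealth level and the
#' donation fraction. The alpha and beta of `config` are overridden cell by
#' cell; everything else (preferences, horizon, policy precision, ...) is
#' shared across the grid.
#'
#' @param grid A [sweep_grid()].
#' @param config A [game_config()] supplying the shared settings.
#' @param env An [environment_spec()].
#' @param time_averaged Also aggregate the time-averaged true wealth
#'   (always included as `mean_mean_wealth`; this flag retained for clarity).
#' @return Object of class `repgame_sweep`: list with `cells` (data frame:
#'   alpha, beta, mean_p_charitable, sd_p_charitable, mean_final_wealth,
#'   sd_final_wealth, mean_donation_fraction, mean_mean_wealth; rows in
#'   row-major order, alpha varying slowest) and `grid`, `config`, `env`.
#' @export
run_sweep <- function(grid, config = game_config(), env = environment_spec(),
                      time_averaged = TRUE) {
  combos <- expand.grid(beta = grid$beta_values, alpha = grid$alpha_values,
                        KEEP.OUT.ATTRS = FALSE)[, c("alpha", "beta")]
  res <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg <- config
    cfg$alpha <- combos$alpha[i]
    cfg$beta <- combos$beta[i]
    validate_config(cfg)
    model <- assemble_model(cfg)
    p_char <- numeric(grid$n_replicates)
    f_wealth <- numeric(grid$n_replicates)
    m_wealth <- numeric(grid$n_replicates)
    don <- numeric(grid$n_replicates)
    for (r in seq_len(grid$n_replicates)) {
      tr <- run_game(cfg, env, seed = cell_seed(grid$base_seed, i, r),
                     model = model)
      s <- tr$summary
      p_char[r] <- s$final_p_charitable
      f_wealth[r] <- s$final_wealth
      m_wealth[r] <- s$mean_wealth
      don[r] <- s$donation_fraction
    }
    res[[i]] <- data.frame(
      alpha = combos$alpha[i], beta = combos$beta[i],
      mean_p_charitable = mean(p_char), sd_p_charitable = stats::sd(p_char),
      mean_final_wealth = mean(f_wealth), sd_final_wealth = stats::sd(f_wealth),
      mean_donation_fraction = mean(don), mean_mean_wealth = mean(m_wealth)
    )
  }
  out <- list(cells = do.call(rbind, res), grid = grid, config = config,
              env = env)
  class(out) <- "repgame_sweep"
  out
}

#' @export
print.repgame_sweep <- function(x, ...) {
  cat(sprintf(
    "Precision sweep: %d alpha x %d beta cells, %d replicates each\n",
    length(x$grid$alpha_values), length(x$grid$beta_values),
    x$grid$n_replicates))
  cat(sprintf("  P(charitable) range : [%.3f, %.3f]\n",
              min(x$cells$mean_p_charitable), max(x$cells$mean_p_charitable)))
  cat(sprintf("  final wealth range  : [%.2f, %.2f]\n",
              min(x$cells$mean_final_wealth), max(x$cells$mean_final_wealth)))
  invisible(x)
}

#' Export sweep heat maps to long-format CSV
#'
#' Writes one row per (alpha, beta, metric) with columns
#' `alpha, beta, metric, mean, sd` (sd is `NA` for metrics aggregated
#' without one). The CSV round-trips losslessly through
#' [read_heatmap_csv()].
#'
#' @param result A `repgame_sweep`.
#' @param path Output CSV path.
#' @return Invisibly, the long-format data frame written.
#' @export
export_heatmaps <- function(result, path) {
  cells <- result$cells
  long <- rbind(
    data.frame(alpha = cells$alpha, beta = cells$beta,
               metric = "p_charitable", mean = cells$mean_p_charitable,
               sd = cells$sd_p_charitable),
    data.frame(alpha = cells$alpha, beta = cells$beta,
               metric = "final_wealth", mean = cells$mean_final_wealth,
               sd = cells$sd_final_wealth),
    data.frame(alpha = cells$alpha, beta = cells$beta,
               metric = "donation_fraction",
               mean = cells$mean_donation_fraction, sd = NA_real_),
    data.frame(alpha = cells$alpha, beta = cells$beta,
               metric = "mean_wealth", mean = cells$mean_mean_wealth,
               sd = NA_real_)
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(long)
}

#' Read a heat-map CSV written by [export_heatmaps()]
#'
#' @param path CSV path.
#' @return Long-format data frame (alpha, beta, metric, mean, sd).
#' @export
read_heatmap_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Plot sweep heat maps
#'
#' Renders the P(charitable) and final-wealth surfaces with ggplot2
#' (suggested dependency).
#'
#' @param x A `repgame_sweep`.
#' @param metric `"p_charitable"`, `"final_wealth"` or
#'   `"donation_fraction"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.repgame_sweep <- function(x, metric = c("p_charitable", "final_wealth",
                                             "donation_fraction"), ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  metric <- match.arg(metric)
  col <- switch(metric, p_charitable = "mean_p_charitable",
                final_wealth = "mean_final_wealth",
                donation_fraction = "mean_donation_fraction")
  ggplot2::ggplot(x$cells,
                  ggplot2::aes(x = .data[["beta"]], y = .data[["alpha"]],
                               fill = .data[[col]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = metric) +
    ggplot2::labs(x = expression(beta), y = expression(alpha))
}

#' Default developmental stages
#'
#' The staged scenario mirroring the red line drawn across the sweep: an
#' altruistic start (precise approval mapping, imprecise transition priors),
#' a collapse of likelihood precision (lacks remorse), then a rise of
#' transition-prior precision (self-aggrandizing).
#'
#' @param horizon Trials per stage (default 16).
#' @return Data frame with columns `alpha`, `beta`, `n_trials`.
#' @export
default_stages <- function(horizon = 16L) {
  data.frame(alpha = c(4, 0, 0), beta = c(0.55, 0.55, 1.0),
             n_trials = as.integer(horizon))
}

#' Developmental trajectory across precision regimes
#'
#' Runs the staged scenario in which a synthetic subject's precisions change
#' between epochs. Material circumstances persist: by default
#' (`carry = "wealth"`) the true wealth level and the wealth belief carry
#' over from one stage to the next, while the self-worth state and belief
#' re-anchor on the charitable initial prior at each stage onset, so that
#' each stage reports the self-appraisal equilibrium its precision regime
#' supports. `carry = "all"` carries the full belief and true state;
#' `carry = "none"` restarts each stage from the initial prior.
#'
#' @param stages Data frame with columns `alpha`, `beta`, `n_trials`
#'   (default [default_stages()]); at least one row.
#' @param config Shared [game_config()] (alpha/beta/horizon overridden per
#'   stage).
#' @param base_seed Integer seed; replicate seeds derive from it.
#' @param n_replicates Independent subjects to average over (default 1).
#' @param env An [environment_spec()].
#' @param carry One of `"wealth"`, `"all"`, `"none"`.
#' @return Data frame with one row per stage: stage, alpha, beta, n_trials,
#'   mean final/mean wealth, mean final P(charitable), mean donation
#'   fraction across replicates.
#' @export
developmental_trajectory <- function(stages = default_stages(),
                                     config = game_config(),
                                     base_seed = 1L, n_replicates = 1L,
                                     env = environment_spec(),
                                     carry = c("wealth", "all", "none")) {
  carry <- match.arg(carry)
  if (!is.data.frame(stages) || nrow(stages) < 1L ||
      !all(c("alpha", "beta", "n_trials") %in% names(stages))) {
    stop("`stages` must be a data frame with columns alpha, beta, n_trials",
         call. = FALSE)
  }
  n <- config$n_wealth_levels
  sw0 <- match(config$initial_selfworth, selfworth_states())
  acc <- array(0, dim = c(nrow(stages), 4L),
               dimnames = list(NULL, c("final_wealth", "mean_wealth",
                                       "p_charitable", "donation_fraction")))
  models <- lapply(seq_len(nrow(stages)), function(k) {
    cfg <- config
    cfg$alpha <- stages$alpha[k]
    cfg$beta <- stages$beta[k]
    cfg$horizon <- as.integer(stages$n_trials[k])
    validate_config(cfg)
    assemble_model(cfg)
  })
  for (r in seq_len(n_replicates)) {
    belief <- NULL
    true_state <- NULL
    for (k in seq_len(nrow(stages))) {
      model <- models[[k]]
      tr <- run_game(model$config, env,
                     seed = cell_seed(base_seed, k, r),
                     init_belief = belief, init_true = true_state,
                     model = model)
      s <- tr$summary
      acc[k, ] <- acc[k, ] + c(s$final_wealth, s$mean_wealth,
                               s$final_p_charitable, s$donation_fraction)
      belief <- tr$final_belief
      true_state <- tr$final_true_state
      if (carry == "none") {
        belief <- NULL
        true_state <- NULL
      } else if (carry == "wealth") {
        # self-worth re-anchors on the initial prior; wealth persists
        q <- matrix(belief$q_joint, nrow = n)
        qw <- rowSums(q)
        q2 <- matrix(0, n, 2L)
        q2[, sw0] <- qw
        belief <- belief_state(as.vector(q2), model)
        true_state <- c(true_state[1L], sw0)
      }
    }
  }
  acc <- acc / n_replicates
  data.frame(stage = seq_len(nrow(stages)), alpha = stages$alpha,
             beta = stages$beta, n_trials = stages$n_trials,
             final_wealth = acc[, "final_wealth"],
             mean_wealth = acc[, "mean_wealth"],
             p_charitable = acc[, "p_charitable"],
             donation_fraction = acc[, "donation_fraction"])
}
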