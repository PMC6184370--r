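#' Load a run configuration from YAML or JSON
#'
#' Reads a configuration file with up to three top-level sections — `game`
#' (fields of [game_config()]), `environment` (fields of
#' [environment_spec()]) and `sweep` (fields of [sweep_grid()]) — applying
#' defaults for anything absent. Unknown keys, at either level, are
#' rejected by name; validation errors name the offending key. An empty
#' file yields the full default configuration.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `config` ([game_config()]), `env`
#'   ([environment_spec()]) and `grid` ([sweep_grid()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a mapping", call. = FALSE)
  known_sections <- c("game", "environment", "sweep")
  unknown <- setdiff(names(raw), known_sections)
  if (length(unknown) > 0L) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  take <- function(section, fn) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad) > 0L) {
      stop(sprintf("unknown key(s) in `%s`: %s", section,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    do.call(fn, args)
  }
  list(config = take("game", game_config),
       env = take("environment", environment_spec),
       grid = take("sweep", sweep_grid))
}

#' Dump a run configuration to YAML
#'
#' Inverse of [load_config()]: the dumped file loads back to a semantically
#' identical configuration.
#'
#' @param cfg List as returned by [load_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
dump_config <- function(cfg, path) {
  env <- cfg$env
  out <- list(
    game = unclass(cfg$config),
    environment = Filter(Negate(is.null), list(
      env_alpha = env$env_alpha,
      env_beta = env$env_beta, attrition = env$attrition,
      share_with_model = env$share_with_model)),
    sweep = unclass(cfg$grid)
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Serialize a trajectory
#'
#' `write_trajectory_json()` writes the full record (configuration,
#' environment, seed, per-trial table, summary); `write_trajectory_csv()`
#' writes the per-trial table only.
#'
#' @param trajectory A `repgame_trajectory`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory_json <- function(trajectory, path) {
  env <- trajectory$env
  payload <- list(
    config = unclass(trajectory$config),
    environment = list(env_alpha = env$env_alpha, env_beta = env$env_beta,
                       attrition = env$attrition,
                       share_with_model = env$share_with_model),
    seed = trajectory$seed,
    trials = trajectory$trials,
    summary = trajectory$summary
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_trajectory_json
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(trajectory$trials, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration, environment, seeds, package version and an
#' MD5-checksummed inventory of the output files of a run, sufficient to
#' reproduce every output bit-exactly in deterministic modes.
#'
#' @param dir Output directory whose files are inventoried.
#' @param cfg List with `config`, `env` and optionally `grid`.
#' @param seeds Integer vector of seeds used.
#' @param path Manifest path (default `manifest.json` inside `dir`).
#' @return Invisibly, the manifest list.
#' @export
write_run_manifest <- function(dir, cfg, seeds,
                               path = file.path(dir, "manifest.json")) {
  files <- setdiff(list.files(dir, full.names = TRUE), path)
  env <- cfg$env
  manifest <- list(
    package = "repgame",
    version = as.character(utils::packageVersion("repgame")),
    config = unclass(cfg$config),
    environment = list(env_alpha = env$env_alpha, env_beta = env$env_beta,
                       attrition = env$attrition,
                       share_with_model = env$share_with_model),
    grid = if (!is.null(cfg$grid)) unclass(cfg$grid),
    seeds = seeds,
    files = lapply(files, function(f) {
      list(name = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(manifest)
}

cli_usage <- function() {
  paste(
    "usage: repgame <subcommand> [options]",
    "",
    "subcommands:",
    "  run        simulate one game      (--alpha --beta --seed --horizon",
    "                                     --mode --config --out)",
    "  sweep      precision-grid sweep   (--replicates --seed --config --out-dir)",
    "  trajectory staged developmental scenario (--replicates --seed --out)",
    "  appraisal  Gaussian self-appraisal (--scenario)",
    "  validate   build and check the default generative model",
    "",
    "All stochastic subcommands accept --seed; without it a default of 1 is",
    "used and a warning is logged.",
    sep = "\n")
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- args[[i]]
    if (!startsWith(key, "--")) {
      stop("unexpected argument: ", key, call. = FALSE)
    }
    if (i + 1L > length(args)) stop("missing value for ", key, call. = FALSE)
    opts[[substring(key, 3L)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  opts
}

opt_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

cli_seed <- function(opts) {
  if (is.null(opts$seed)) {
    message("no --seed given; defaulting to 1")
    1L
  } else {
    as.integer(opts$seed)
  }
}

#' Command-line entry point
#'
#' Dispatches the subcommands `run`, `sweep`, `trajectory`, `appraisal` and
#' `validate` (see the thin wrapper script installed under `exec/`).
#' Returns 0 on success, 2 on usage errors and 1 on runtime errors.
#'
#' @param argv Character vector of command-line arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly.
#' @export
main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L) {
    cat(cli_usage(), "\n")
    return(invisible(2L))
  }
  sub <- argv[[1L]]
  if (!sub %in% c("run", "sweep", "trajectory", "appraisal", "validate")) {
    cat(cli_usage(), "\n")
    message("unknown subcommand: ", sub)
    return(invisible(2L))
  }
  status <- tryCatch({
    opts <- parse_cli_options(argv[-1L])
    base <- if (!is.null(opts$config)) load_config(opts$config)
            else list(config = game_config(), env = environment_spec(),
                      grid = sweep_grid())
    switch(sub,
      validate = {
        report <- validate_model(assemble_model(base$config))
        if (nrow(report) == 0L) {
          cat("model valid: no violations\n")
          0L
        } else {
          print(report)
          1L
        }
      },
      run = {
        cfg <- base$config
        if (!is.null(opts$alpha)) cfg$alpha <- as.numeric(opts$alpha)
        if (!is.null(opts$beta)) cfg$beta <- as.numeric(opts$beta)
        if (!is.null(opts$horizon)) cfg$horizon <- as.integer(opts$horizon)
        if (!is.null(opts$mode)) cfg$selection_mode <- opts$mode
        validate_config(cfg)
        seed <- cli_seed(opts)
        tr <- run_game(cfg, base$env, seed = seed)
        summary(tr)
        if (!is.null(opts$out)) {
          dir.create(dirname(opts$out), recursive = TRUE,
                     showWarnings = FALSE)
          write_trajectory_json(tr, opts$out)
          write_run_manifest(dirname(opts$out),
                             list(config = cfg, env = base$env), seed)
        }
        0L
      },
      sweep = {
        grid <- base$grid
        if (!is.null(opts$replicates)) {
          grid$n_replicates <- as.integer(opts$replicates)
        }
        grid$base_seed <- cli_seed(opts)
        res <- run_sweep(grid, base$config, base$env)
        print(res)
        if (!is.null(opts[["out-dir"]])) {
          dir.create(opts[["out-dir"]], recursive = TRUE,
                     showWarnings = FALSE)
          export_heatmaps(res, file.path(opts[["out-dir"]], "heatmaps.csv"))
          write_run_manifest(opts[["out-dir"]],
                             list(config = base$config, env = base$env,
                                  grid = grid), grid$base_seed)
        }
        0L
      },
      trajectory = {
        seed <- cli_seed(opts)
        reps <- as.integer(opt_num(opts, "replicates", 32))
        dt <- developmental_trajectory(config = base$config,
                                       base_seed = seed,
                                       n_replicates = reps, env = base$env)
        print(dt, row.names = FALSE)
        if (!is.null(opts$out)) {
          dir.create(dirname(opts$out), recursive = TRUE,
                     showWarnings = FALSE)
          utils::write.csv(dt, opts$out, row.names = FALSE)
        }
        0L
      },
      appraisal = {
        name <- if (is.null(opts$scenario)) "undefended" else opts$scenario
        sc <- scenario(name)
        print(sc)
        0L
      }
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
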