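#' Gaussian belief about self-appraisal
#'
#' A one-dimensional Gaussian over valence: negative means encode shame and
#' worthlessness, positive means encode positive self-regard. Beliefs are
#' parameterized by their mean and precision (inverse variance).
#'
#' @param mean Finite real valence.
#' @param precision Inverse variance, > 0.
#' @return Object of class `repgame_gaussian`.
#' @examples
#' gaussian_belief(-1.5, 4)
#' @export
gaussian_belief <- function(mean, precision) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean)) {
    stop("invalid `mean`: must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(precision) || length(precision) != 1L ||
      is.na(precision) || precision <= 0) {
    stop("invalid `precision`: must be a single positive number",
         call. = FALSE)
  }
  b <- list(mean = as.numeric(mean), precision = as.numeric(precision))
  class(b) <- "repgame_gaussian"
  b
}

#' @export
print.repgame_gaussian <- function(x, ...) {
  cat(sprintf("Gaussian belief: mean %.4f, precision %.4g (sd %.4g)\n",
              x$mean, x$precision, 1 / sqrt(x$precision)))
  invisible(x)
}

#' Precision-weighted fusion of two Gaussian beliefs
#'
#' Exact conjugate update: the posterior precision is the sum of the input
#' precisions and the posterior mean is the precision-weighted average of
#' the input means. Raising the prior's precision relative to the evidence
#' pulls the posterior toward the prior; attenuating the evidence precision
#' leaves the posterior near the prior regardless of what the evidence says.
#'
#' @param prior A [gaussian_belief()].
#' @param likelihood A [gaussian_belief()] summarizing the evidence.
#' @return The posterior [gaussian_belief()].
#' @examples
#' fuse_beliefs(gaussian_belief(1, 1), gaussian_belief(-1, 1))  # mean 0
#' @export
fuse_beliefs <- function(prior, likelihood) {
  if (!inherits(prior, "repgame_gaussian")) {
    prior <- gaussian_belief(prior$mean, prior$precision)
  }
  if (!inherits(likelihood, "repgame_gaussian")) {
    likelihood <- gaussian_belief(likelihood$mean, likelihood$precision)
  }
  tau <- prior$precision + likelihood$precision
  mu <- (prior$precision * prior$mean +
           likelihood$precision * likelihood$mean) / tau
  gaussian_belief(mu, tau)
}

#' Classify the valence of a belief
#'
#' @param belief A [gaussian_belief()].
#' @param threshold Positive half-width of the neutral band (default 0.25).
#'   Means with absolute value up to and including the threshold are
#'   neutral (closed boundary).
#' @return `"negative"`, `"neutral"` or `"positive"`.
#' @export
classify_valence <- function(belief, threshold = 0.25) {
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("invalid `threshold`: must be > 0", call. = FALSE)
  }
  if (belief$mean < -threshold) "negative"
  else if (belief$mean > threshold) "positive"
  else "neutral"
}

appraisal_presets <- function() {
  list(
    undefended = list(
      prior = gaussian_belief(0.5, 1),
      likelihood = gaussian_belief(-1.5, 4)
    ),
    self_aggrandizing = list(
      prior = gaussian_belief(1.5, 16),
      likelihood = gaussian_belief(-1.5, 4)
    ),
    lacks_remorse = list(
      prior = gaussian_belief(0, 1),
      likelihood = gaussian_belief(-1.5, 0.05)
    )
  )
}

#' Self-appraisal scenario presets
#'
#' Three qualitative regimes of precision-weighted self-appraisal on a
#' valence scale of roughly \[-2, 2\]. *Undefended*: a mildly positive but
#' imprecise prior is overpowered by precise negative evidence from the
#' internal working model of the self, yielding a negative posterior.
#' *Self-aggrandizing*: the prior is elevated and afforded high precision,
#' so the posterior stays positive despite the same negative evidence.
#' *Lacks remorse*: the precision of the negative evidence is attenuated,
#' leaving a near-neutral posterior. Preset means/precisions are
#' conventions chosen to realize these regimes and can be overridden.
#'
#' @param name `"undefended"`, `"self_aggrandizing"` or `"lacks_remorse"`.
#' @param prior,likelihood Optional [gaussian_belief()] overrides.
#' @param threshold Neutral-band half-width for the valence label.
#' @return Object of class `repgame_scenario`: list with `name`, `prior`,
#'   `likelihood`, `posterior` (computed by [fuse_beliefs()]) and `valence`.
#' @examples
#' scenario("self_aggrandizing")$valence  # "positive"
#' @export
scenario <- function(name = c("undefended", "self_aggrandizing",
                              "lacks_remorse"),
                     prior = NULL, likelihood = NULL, threshold = 0.25) {
  name <- match.arg(name)
  preset <- appraisal_presets()[[name]]
  if (is.null(prior)) prior <- preset$prior
  if (is.null(likelihood)) likelihood <- preset$likelihood
  posterior <- fuse_beliefs(prior, likelihood)
  out <- list(name = name, prior = prior, likelihood = likelihood,
              posterior = posterior,
              valence = classify_valence(posterior, threshold))
  class(out) <- "repgame_scenario"
  out
}

#' @export
print.repgame_scenario <- function(x, ...) {
  cat(sprintf("Self-appraisal scenario: %s\n", x$name))
  row <- function(lbl, b) {
    cat(sprintf("  %-10s mean %+7.4f  precision %8.4g\n",
                lbl, b$mean, b$precision))
  }
  row("prior", x$prior)
  row("likelihood", x$likelihood)
  row("posterior", x$posterior)
  cat(sprintf("  posterior valence: %s\n", x$valence))
  invisible(x)
}

#' Scenario table
#'
#' @param x A `repgame_scenario`.
#' @return Data frame with one row per distribution (prior, likelihood,
#'   posterior) plus the valence label on the posterior row.
#' @export
scenario_table <- function(x) {
  data.frame(
    distribution = c("prior", "likelihood", "posterior"),
    mean = c(x$prior$mean, x$likelihood$mean, x$posterior$mean),
    precision = c(x$prior$precision, x$likelihood$precision,
                  x$posterior$precision),
    valence = c(NA, NA, x$valence)
  )
}
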