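# Shift analysis of the motor bias function after implicit visuomotor
# adaptation: the frozen baseline model is displaced along the target axis
# (argument shift v) and the bias axis (additive offset h), and (v, h) are
# estimated by least squares on per-target mean aftereffect biases.

# Per-target mean angular error of a trial table, on its own target grid.
per_target_means <- function(trials) {
  angr <- round(trials$target_angle %% 360, 6)
  ang <- sort(unique(angr))
  err <- trial_angular_error(trials)
  list(angles = ang,
       mean_bias = vapply(ang, function(a) mean(err[angr == a]), numeric(1)))
}

shift_objective_factory <- function(angles, mean_bias, baseline_spec, layout) {
  function(vh) {
    pred <- eval_bias(baseline_spec, layout, (angles + vh[1]) %% 360)$angular +
      vh[2]
    sum((mean_bias - pred)^2)
  }
}

#' Fit the post-adaptation shift of the bias function
#'
#' Given a frozen baseline fit, finds the argument shift `v` (degrees along
#' the target axis) and additive offset `h` (degrees of bias) that minimize
#' the squared error between the per-target mean aftereffect biases and
#' `baseline(angle + v) + h`. A pure vertical displacement of the bias
#' function — the signature of implicit adaptation acting downstream of the
#' visuo-proprioceptive transformation — appears as `h != 0`, `v = 0`.
#'
#' @param aftereffect Trial table from the no-feedback aftereffect block.
#' @param baseline_fit A converged `fit_result` for the baseline block
#'   (typically the TR+TG model).
#' @param layout A `reach_layout`.
#' @param v_bounds,h_bounds Search intervals in degrees (default `c(-30, 30)`).
#' @return A list of class `adapt_shift` with `v`, `h` and `sse`.
#' @export
fit_shift <- function(aftereffect, baseline_fit, layout,
                      v_bounds = c(-30, 30), h_bounds = c(-30, 30)) {
  stopifnot(inherits(baseline_fit, "fit_result"))
  if (!isTRUE(baseline_fit$converged)) {
    stop("baseline fit did not converge; refusing to freeze it", call. = FALSE)
  }
  if (nrow(aftereffect) == 0) stop("empty aftereffect table", call. = FALSE)
  m <- per_target_means(aftereffect)
  obj <- shift_objective_factory(m$angles, m$mean_bias, baseline_fit$spec,
                                 layout)
  lower <- c(v_bounds[1], h_bounds[1])
  upper <- c(v_bounds[2], h_bounds[2])
  # grid of v seeds with the conditionally optimal h, then bounded simplex
  v_grid <- seq(lower[1] + 0.5, upper[1] - 0.5, length.out = 13)
  best <- NULL
  for (v0 in v_grid) {
    pred0 <- eval_bias(baseline_fit$spec, layout,
                       (m$angles + v0) %% 360)$angular
    h0 <- min(max(mean(m$mean_bias - pred0), lower[2] + 1e-6),
              upper[2] - 1e-6)
    t0 <- to_unbounded(c(v0, h0), lower, upper)
    opt <- stats::optim(t0, function(t) obj(to_bounded(t, lower, upper)),
                        method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  vh <- to_bounded(best$par, lower, upper)
  structure(list(v = vh[1], h = vh[2], sse = best$value,
                 n_targets = length(m$angles)),
            class = "adapt_shift")
}

#' @export
print.adapt_shift <- function(x, ...) {
  cat(sprintf("<adapt_shift> v = %.3f deg (argument), h = %.3f deg (offset), SSE %.4f\n",
              x$v, x$h, x$sse))
  if (!is.null(x$v_ci)) {
    cat(sprintf("  95%% CI: v [%.3f, %.3f], h [%.3f, %.3f] (%d bootstraps)\n",
                x$v_ci[1], x$v_ci[2], x$h_ci[1], x$h_ci[2], x$n_boot))
  }
  invisible(x)
}

#' Participant bootstrap of the adaptation shift
#'
#' Resamples participants with replacement, recomputes the group-average
#' aftereffect function of each bootstrap sample, refits `(v, h)` against the
#' frozen baseline, and reports percentile 95% confidence intervals alongside
#' the point estimate on the full sample.
#'
#' @inheritParams fit_shift
#' @param cohort Aftereffect trial table covering >= 2 participants.
#' @param n_boot Number of bootstrap resamples (default 200).
#' @param seed Integer seed; the procedure is deterministic given it.
#' @return An `adapt_shift` with `v_ci`, `h_ci`, `v_boot_mean`, `h_boot_mean`,
#'   `n_boot` and `degenerate` (TRUE when only one participant was supplied).
#' @export
bootstrap_shift <- function(cohort, baseline_fit, layout, n_boot = 200,
                            seed = 1, v_bounds = c(-30, 30),
                            h_bounds = c(-30, 30)) {
  stopifnot(n_boot >= 1)
  parts <- unique(cohort$participant_id)
  degenerate <- length(parts) < 2
  if (degenerate) {
    warning("single participant: bootstrap CI is degenerate")
  }
  # participant x target matrix of mean biases; group average = row mean
  angr <- round(cohort$target_angle %% 360, 6)
  ang <- sort(unique(angr))
  err <- trial_angular_error(cohort)
  mat <- t(vapply(parts, function(p) {
    sel <- cohort$participant_id == p
    vapply(ang, function(a) mean(err[sel & angr == a]), numeric(1))
  }, numeric(length(ang))))
  if (any(!is.finite(mat))) {
    stop("every participant must have trials at every target", call. = FALSE)
  }

  fit_means <- function(mean_bias) {
    obj <- shift_objective_factory(ang, mean_bias, baseline_fit$spec, layout)
    lower <- c(v_bounds[1], h_bounds[1])
    upper <- c(v_bounds[2], h_bounds[2])
    best <- NULL
    for (v0 in seq(lower[1] + 0.5, upper[1] - 0.5, length.out = 13)) {
      pred0 <- eval_bias(baseline_fit$spec, layout,
                         (ang + v0) %% 360)$angular
      h0 <- min(max(mean(mean_bias - pred0), lower[2] + 1e-6),
                upper[2] - 1e-6)
      t0 <- to_unbounded(c(v0, h0), lower, upper)
      opt <- stats::optim(t0, function(t) obj(to_bounded(t, lower, upper)),
                          method = "Nelder-Mead",
                          control = list(maxit = 1000, reltol = 1e-12))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    to_bounded(best$par, lower, upper)
  }

  point <- fit_shift(cohort, baseline_fit, layout, v_bounds, h_bounds)
  boots <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      take <- sample.int(length(parts), length(parts), replace = TRUE)
      fit_means(colMeans(mat[take, , drop = FALSE]))
    }, numeric(2))
  })
  point$v_boot_mean <- mean(boots[1, ])
  point$h_boot_mean <- mean(boots[2, ])
  point$v_ci <- unname(stats::quantile(boots[1, ], c(0.025, 0.975)))
  point$h_ci <- unname(stats::quantile(boots[2, ], c(0.025, 0.975)))
  point$n_boot <- n_boot
  point$seed <- seed
  point$degenerate <- degenerate
  point
}
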