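# Seeded synthetic cohorts with the statistical structure the analysis
# assumes: a shared generative bias model, per-participant parameter jitter,
# trial-level Gaussian motor noise, feedback-attenuated blocks, and
# baseline/washout adaptation phases.

#' Configure a synthetic cohort
#'
#' @param n_participants Number of participants (>= 1).
#' @param layout A `reach_layout` defining targets, radius and scenario.
#' @param trials_per_target Trials per target per block (>= 1).
#' @param generator A `model_spec`: the bias model every participant embodies.
#' @param param_jitter Per-parameter SD of the participant-level Gaussian
#'   jitter, as a numeric vector over the generator's free-parameter vector
#'   (see `names(fit_model(...)$params)` ordering). Default: 20% of each
#'   parameter's magnitude. Jittered parameters are clamped inside the
#'   fitting bounds.
#' @param motor_noise_sd Trial-level angular noise SD, degrees.
#' @param radial_noise_sd Trial-level radial noise SD, cm (2-D layouts).
#' @param feedback_attenuation Multiplicative attenuation of the expressed
#'   bias on feedback blocks, in `[0, 1]` (default 0.5).
#' @param blocks List of block descriptors `list(label = , feedback = )`;
#'   default a single no-feedback block.
#' @param experiment Label stored in the trial table.
#' @param seed Integer seed.
#' @return A `cohort_config`.
#' @export
cohort_config <- function(n_participants, layout, trials_per_target,
                          generator, param_jitter = NULL,
                          motor_noise_sd = 4, radial_noise_sd = 0.3,
                          feedback_attenuation = 0.5,
                          blocks = list(list(label = "no_feedback",
                                             feedback = FALSE)),
                          experiment = "synthetic", seed = 1) {
  stopifnot(inherits(layout, "reach_layout"), inherits(generator, "model_spec"))
  if (n_participants < 1 || trials_per_target < 1) {
    stop("`n_participants` and `trials_per_target` must be >= 1", call. = FALSE)
  }
  if (motor_noise_sd < 0 || radial_noise_sd < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  if (feedback_attenuation < 0 || feedback_attenuation > 1) {
    stop("`feedback_attenuation` must lie in [0, 1]", call. = FALSE)
  }
  info <- param_info(generator$model_id)
  par <- spec_to_par(generator, info)
  if (is.null(param_jitter)) {
    param_jitter <- 0.2 * abs(par)
  }
  if (length(param_jitter) != length(par) || any(param_jitter < 0)) {
    stop("`param_jitter` must be a nonnegative vector over the generator's free parameters",
         call. = FALSE)
  }
  structure(
    list(n_participants = as.integer(n_participants), layout = layout,
         trials_per_target = as.integer(trials_per_target),
         generator = generator, param_jitter = param_jitter,
         motor_noise_sd = motor_noise_sd, radial_noise_sd = radial_noise_sd,
         feedback_attenuation = feedback_attenuation, blocks = blocks,
         experiment = experiment, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Draw one participant's jittered generator spec, clamped inside bounds.
draw_participant_spec <- function(cfg) {
  info <- param_info(cfg$generator$model_id)
  par <- spec_to_par(cfg$generator, info) +
    stats::rnorm(nrow(info), 0, cfg$param_jitter)
  eps <- 1e-6 * (info$upper - info$lower)
  par <- pmin(pmax(par, info$lower + eps), info$upper - eps)
  par_to_spec(par, cfg$generator$model_id, info)
}

participant_rows <- function(cfg, spec_p, pid, blocks, extra_bias = 0) {
  layout <- cfg$layout
  two_d <- layout$dimension == "angle_extent"
  pred <- eval_bias(spec_p, layout, layout$target_angles)
  out <- list()
  for (blk in blocks) {
    atten <- if (isTRUE(blk$feedback)) cfg$feedback_attenuation else 1
    shift <- if (is.null(blk$extra_bias)) extra_bias else blk$extra_bias
    for (i in seq_along(layout$target_angles)) {
      nt <- cfg$trials_per_target
      if (!is.null(blk$trials_per_target)) nt <- blk$trials_per_target
      err <- pred$angular[i] * atten + shift +
        stats::rnorm(nt, 0, cfg$motor_noise_sd)
      row <- data.frame(
        participant_id = pid,
        hand = layout$hand,
        experiment = cfg$experiment,
        block = blk$label,
        feedback = isTRUE(blk$feedback),
        target_angle = layout$target_angles[i],
        target_radius = layout$radius,
        reach_angle = (layout$target_angles[i] + err) %% 360
      )
      if (two_d) {
        r_trial <- layout$radius + pred$radial[i] * atten +
          stats::rnorm(nt, 0, cfg$radial_noise_sd)
        a <- row$reach_angle * DEG2RAD
        row$endpoint_x <- layout$start[1] + r_trial * cos(a)
        row$endpoint_y <- layout$start[2] + r_trial * sin(a)
      }
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}

#' Generate a synthetic trial table
#'
#' Per participant, the generator's parameters receive Gaussian jitter; per
#' trial, the expressed bias (attenuated on feedback blocks) receives
#' Gaussian angular noise. 2-D layouts additionally emit endpoints with
#' radial noise. Fully deterministic given the config's seed.
#'
#' @param cfg A `cohort_config`.
#' @return A trial table (`data.frame`) in the standard schema.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_local_seed(cfg$seed, {
    do.call(rbind, lapply(seq_len(cfg$n_participants), function(j) {
      pid <- sprintf("P%03d", j)
      spec_p <- draw_participant_spec(cfg)
      participant_rows(cfg, spec_p, pid, cfg$blocks)
    }))
  })
}

#' Configure a synthetic adaptation experiment
#'
#' Extends [cohort_config()] with the endpoint consequence of a block of
#' clamped-feedback adaptation: in the washout (aftereffect) block each
#' participant's bias function is displaced vertically by a per-participant
#' shift drawn from `N(aftereffect_shift_mean, aftereffect_shift_sd)`, signed
#' by the clamp direction (CW clamp drives a counterclockwise, positive
#' aftereffect). The clamp phase itself is not simulated trial-by-trial.
#'
#' @inheritParams cohort_config
#' @param clamp_direction `"CW"` or `"CCW"`.
#' @param aftereffect_shift_mean Mean vertical shift, degrees (default 12.5).
#' @param aftereffect_shift_sd Between-participant SD of the shift, degrees.
#' @param baseline_trials_per_target,washout_trials_per_target Trials per
#'   target in the two no-feedback blocks (default 10 each).
#' @return An `adapt_config` (also a `cohort_config`).
#' @export
adapt_config <- function(n_participants, layout, generator,
                         clamp_direction = c("CW", "CCW"),
                         aftereffect_shift_mean = 12.5,
                         aftereffect_shift_sd = 2,
                         baseline_trials_per_target = 10,
                         washout_trials_per_target = 10,
                         param_jitter = NULL, motor_noise_sd = 4,
                         experiment = "synthetic_adaptation", seed = 1) {
  clamp_direction <- match.arg(clamp_direction)
  cfg <- cohort_config(
    n_participants, layout, baseline_trials_per_target, generator,
    param_jitter = param_jitter, motor_noise_sd = motor_noise_sd,
    experiment = experiment, seed = seed
  )
  cfg$clamp_direction <- clamp_direction
  cfg$aftereffect_shift_mean <- aftereffect_shift_mean
  cfg$aftereffect_shift_sd <- aftereffect_shift_sd
  cfg$baseline_trials_per_target <- as.integer(baseline_trials_per_target)
  cfg$washout_trials_per_target <- as.integer(washout_trials_per_target)
  class(cfg) <- c("adapt_config", "cohort_config")
  cfg
}

#' Generate baseline and washout blocks of a synthetic adaptation experiment
#'
#' @param cfg An `adapt_config`.
#' @return A trial table with `block` in `{"baseline", "washout"}`.
#' @export
generate_adaptation <- function(cfg) {
  stopifnot(inherits(cfg, "adapt_config"))
  sign <- if (cfg$clamp_direction == "CW") 1 else -1
  with_local_seed(cfg$seed, {
    do.call(rbind, lapply(seq_len(cfg$n_participants), function(j) {
      pid <- sprintf("P%03d", j)
      spec_p <- draw_participant_spec(cfg)
      h_p <- sign * stats::rnorm(1, cfg$aftereffect_shift_mean,
                                 cfg$aftereffect_shift_sd)
      blocks <- list(
        list(label = "baseline", feedback = FALSE,
             trials_per_target = cfg$baseline_trials_per_target,
             extra_bias = 0),
        list(label = "washout", feedback = FALSE,
             trials_per_target = cfg$washout_trials_per_target,
             extra_bias = h_p)
      )
      participant_rows(cfg, spec_p, pid, blocks)
    }))
  })
}
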