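# Maximum-likelihood fitting and BIC model comparison. The optimizer is a
# bounded Nelder-Mead simplex: parameters are mapped to the real line through
# a sine transform (x = lb + (ub - lb) * (sin t + 1) / 2) and optimized
# unconstrained, with multiple seeded restarts and nested-model warm starts.

NOISE_FLOOR <- 1e-6

# ---- parameter packing ------------------------------------------------------

# Free-parameter layout per model: names, default bounds, pack/unpack.
param_info <- function(model_id, bounds = NULL) {
  single <- function(id) {
    switch(id,
      TG = data.frame(name = c("a", "b"),
                      lower = c(0.5, -20), upper = c(44.5, 20)),
      PV = data.frame(name = c("x_e", "y_e"),
                      lower = c(-5, -5), upper = c(5, 5)),
      PJ = data.frame(name = c("theta0", "phi0", "theta_e", "phi_e"),
                      lower = c(1e-3, 1e-3, -0.35, -0.35),
                      upper = c(pi - 1e-3, pi - 1e-3, 0.35, 0.35)),
      TR = data.frame(name = c("x_e", "y_e", "x_r", "y_r"),
                      lower = c(-0.3, -0.3, -60, -60),
                      upper = c(0.3, 0.3, 60, 60)),
      TGD = data.frame(name = c("k", "c"),
                       lower = c(-1, -5), upper = c(1, 5))
    )
  }
  comp <- strsplit(model_id, "+", fixed = TRUE)[[1]]
  info <- do.call(rbind, lapply(comp, function(id) {
    d <- single(id)
    d$component <- tolower(id)
    d
  }))
  if (!is.null(bounds)) {
    key <- paste(info$component, info$name, sep = ".")
    for (nm in names(bounds)) {
      i <- match(nm, if (length(comp) == 1) info$name else key)
      if (is.na(i)) stop(sprintf("unknown bound `%s` for model %s", nm, model_id),
                         call. = FALSE)
      info$lower[i] <- bounds[[nm]][1]
      info$upper[i] <- bounds[[nm]][2]
    }
  }
  info
}

# Build a model_spec from a free-parameter vector (no validation: the
# optimizer may propose postures the model rejects; those are penalized).
par_to_spec <- function(par, model_id, info) {
  comp <- unique(info$component)
  if (length(comp) == 1) {
    params <- as.list(stats::setNames(par, info$name))
    if (model_id == "PJ") { params$l1 <- 24; params$l2 <- 24 }
  } else {
    params <- lapply(comp, function(cc) {
      idx <- info$component == cc
      p <- as.list(stats::setNames(par[idx], info$name[idx]))
      if (cc == "pj") { p$l1 <- 24; p$l2 <- 24 }
      p
    })
    names(params) <- comp
  }
  structure(list(model_id = model_id, params = params), class = "model_spec")
}

spec_to_par <- function(spec, info) {
  comp <- unique(info$component)
  if (length(comp) == 1) {
    unlist(spec$params[info$name], use.names = FALSE)
  } else {
    unlist(lapply(comp, function(cc) {
      unlist(spec$params[[cc]][info$name[info$component == cc]],
             use.names = FALSE)
    }))
  }
}

#' Number of free parameters of a model
#'
#' @param model_id One of [model_ids()]. Counts only the generative model's
#'   free parameters (the Gaussian noise scale is a plug-in estimate): TG and
#'   PV and TGD have 2, PJ and TR have 4, hybrids the sum of their components.
#' @return Integer count.
#' @export
n_free_params <- function(model_id) {
  nrow(param_info(match.arg(model_id, model_ids())))
}

# ---- likelihood -------------------------------------------------------------

trial_angular_error <- function(trials) {
  wrap_angle(trials$reach_angle - trials$target_angle)
}

trial_radial_error <- function(trials, start = c(0, 0)) {
  if (!all(c("endpoint_x", "endpoint_y") %in% names(trials))) {
    stop("2-D likelihood requires `endpoint_x`/`endpoint_y` columns",
         call. = FALSE)
  }
  sqrt((trials$endpoint_x - start[1])^2 + (trials$endpoint_y - start[2])^2) -
    trials$target_radius
}

# Gaussian negLL with ML plug-in scale (RMS of residuals, floored).
gauss_negll <- function(resid) {
  s <- max(sqrt(mean(resid^2)), NOISE_FLOOR)
  list(negll = -sum(stats::dnorm(resid, 0, s, log = TRUE)), sd = s)
}

#' Negative log-likelihood of a model on trial data
#'
#' Residuals are the trial angular errors minus the model-predicted bias at
#' each trial's target; the Gaussian noise scale is the maximum-likelihood
#' plug-in estimate (root-mean-square residual, floored at 1e-6 degrees).
#' For `angle_extent` layouts the radial residuals (cm) contribute a second,
#' independent Gaussian term with its own scale.
#'
#' @param trials A trial table (see [read_trials()] for the schema).
#' @param spec A `model_spec`.
#' @param layout A `reach_layout` describing the experiment.
#' @return A list with `negll` (nats), `noise_sd` (degrees), and for 2-D fits
#'   `radial_sd` (cm).
#' @export
negative_log_likelihood <- function(trials, spec, layout) {
  if (nrow(trials) < 2) stop("need at least 2 trials", call. = FALSE)
  angr <- round(trials$target_angle %% 360, 6)
  ang <- sort(unique(angr))
  idx <- match(angr, ang)
  pred <- eval_bias(spec, layout, ang)
  r_ang <- wrap_angle(trial_angular_error(trials) - pred$angular[idx])
  g <- gauss_negll(r_ang)
  out <- list(negll = g$negll, noise_sd = g$sd)
  if (layout$dimension == "angle_extent") {
    if (is.null(pred$radial)) {
      stop(sprintf("model `%s` makes no movement-extent prediction",
                   spec$model_id), call. = FALSE)
    }
    r_rad <- trial_radial_error(trials, layout$start) - pred$radial[idx]
    g2 <- gauss_negll(r_rad)
    out$negll <- out$negll + g2$negll
    out$radial_sd <- g2$sd
  }
  out
}

# ---- bounded simplex search -------------------------------------------------

to_unbounded <- function(x, lower, upper) {
  frac <- (x - lower) / (upper - lower)
  frac <- pmin(1 - 1e-9, pmax(1e-9, frac))
  asin(2 * frac - 1)
}

to_bounded <- function(t, lower, upper) {
  lower + (upper - lower) * (sin(t) + 1) / 2
}

# Run RNG-dependent code under a local seed without disturbing the caller's
# random stream.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fit a bias model to trial data by maximum likelihood
#'
#' Minimizes the negative log-likelihood with a bounded derivative-free
#' simplex search from multiple seeded starting points. Hybrid models are
#' additionally warm-started from their fitted nested components (with the
#' other component at its neutral value), which guarantees that a hybrid
#' never fits worse than the nested model it contains.
#'
#' @param trials Trial table for a single participant (or pooled).
#' @param model_id One of [model_ids()].
#' @param layout A `reach_layout`.
#' @param bounds Optional named list of `c(lower, upper)` overrides for the
#'   default parameter bounds (names as in `param_info`; for hybrids use
#'   `component.name`, e.g. `tr.x_e`).
#' @param n_restarts Number of random starting points (>= 1, default 20).
#' @param seed Integer seed making the fit deterministic.
#' @return A `fit_result` with the fitted `model_spec`, noise scales, negLL,
#'   BIC, convergence flag and restart count.
#' @export
fit_model <- function(trials, model_id, layout, bounds = NULL,
                      n_restarts = 20, seed = 1) {
  model_id <- match.arg(model_id, model_ids())
  stopifnot(n_restarts >= 1)
  info <- param_info(model_id, bounds)
  lower <- info$lower
  upper <- info$upper
  k <- nrow(info)

  angr <- round(trials$target_angle %% 360, 6)
  ang <- sort(unique(angr))
  idx <- match(angr, ang)
  err <- trial_angular_error(trials)
  two_d <- layout$dimension == "angle_extent"
  rad_err <- if (two_d) trial_radial_error(trials, layout$start)

  pj_ok <- function(par) {
    if (!any(info$name == "theta0")) return(TRUE)
    th <- par[info$name == "theta0"]
    ph <- par[info$name == "phi0"]
    ph > th
  }

  objective <- function(t) {
    par <- to_bounded(t, lower, upper)
    if (!pj_ok(par)) return(1e10)
    spec <- par_to_spec(par, model_id, info)
    pred <- tryCatch(eval_bias(spec, layout, ang), error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred$angular))) return(1e10)
    val <- gauss_negll(wrap_angle(err - pred$angular[idx]))$negll
    if (two_d) {
      if (is.null(pred$radial)) return(1e10)
      val <- val + gauss_negll(rad_err - pred$radial[idx])$negll
    }
    if (!is.finite(val)) 1e10 else val
  }

  # neutral (zero-bias) parameter values used to extend nested warm starts
  neutral <- c(a = 10, b = 0, x_e = 0, y_e = 0, x_r = 10, y_r = -30,
               k = 0, c = 0, theta0 = 50 * DEG2RAD, phi0 = 120 * DEG2RAD,
               theta_e = 0, phi_e = 0)

  warm <- list()
  comp <- strsplit(model_id, "+", fixed = TRUE)[[1]]
  if (length(comp) > 1) {
    for (cc in comp) {
      if (cc == "PJ" && two_d) next  # no extent prediction on its own
      sub <- tryCatch(
        fit_model(trials, cc, layout, bounds = NULL,
                  n_restarts = max(4, ceiling(n_restarts / 2)),
                  seed = seed + match(cc, comp)),
        error = function(e) NULL)
      if (is.null(sub)) next
      start <- neutral[info$name]
      i_sub <- info$component == tolower(cc)
      start[i_sub] <- spec_to_par(sub$spec, param_info(cc))
      warm[[length(warm) + 1]] <- pmin(pmax(start, lower + 1e-8 * (upper - lower)),
                                       upper - 1e-8 * (upper - lower))
    }
  }

  # deterministic feasible start from the canonical demonstration parameters
  canon <- spec_to_par(canonical_spec(model_id), info)
  warm[[length(warm) + 1]] <-
    pmin(pmax(canon, lower + 1e-8 * (upper - lower)),
         upper - 1e-8 * (upper - lower))

  res <- with_local_seed(seed, {
    starts <- warm
    n_random <- n_restarts
    for (i in seq_len(n_random)) {
      starts[[length(starts) + 1]] <- lower + stats::runif(k) * (upper - lower)
    }
    best <- NULL
    any_conv <- FALSE
    for (s in starts) {
      t0 <- to_unbounded(s, lower, upper)
      opt <- stats::optim(t0, objective, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-10))
      if (opt$convergence == 0) any_conv <- TRUE
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    list(best = best, any_conv = any_conv, n_starts = length(starts))
  })
  if (!res$any_conv) {
    warning(sprintf("optimizer did not converge on any restart for model %s",
                    model_id))
  }

  if (res$best$value >= 1e10) {
    stop(sprintf("no feasible parameters found for model %s on this layout",
                 model_id), call. = FALSE)
  }
  par <- to_bounded(res$best$par, lower, upper)
  spec <- par_to_spec(par, model_id, info)
  ll <- negative_log_likelihood(trials, spec, layout)
  n <- nrow(trials)
  structure(
    list(model_id = model_id, spec = spec,
         params = stats::setNames(par, paste0(
           ifelse(rep(length(comp) > 1, k), paste0(info$component, "."), ""),
           info$name)),
         noise_sd = ll$noise_sd, radial_sd = ll$radial_sd,
         negll = ll$negll, n_trials = n, k_params = k,
         bic = bic(ll$negll, k, n),
         converged = res$any_conv, n_restarts_used = res$n_starts,
         seed = seed),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: negLL %.3f, BIC %.3f (k=%d, n=%d), noise %.3f deg%s\n",
              x$model_id, x$negll, x$bic, x$k_params, x$n_trials, x$noise_sd,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(round(x$params, 4))
  invisible(x)
}

#' Bayesian information criterion
#'
#' `BIC = 2 * negLL + k * ln(n)`; lower is better.
#'
#' @param negll Negative log-likelihood in nats (or a `fit_result`).
#' @param k Number of free model parameters.
#' @param n Number of trials (>= 1).
#' @return BIC in nats.
#' @export
bic <- function(negll, k = NULL, n = NULL) {
  if (inherits(negll, "fit_result")) {
    return(bic(negll$negll, negll$k_params, negll$n_trials))
  }
  if (is.null(k) || is.null(n)) stop("`k` and `n` are required", call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  2 * negll + k * log(n)
}

# ---- model comparison -------------------------------------------------------

#' Fit several models per participant and compare them by BIC
#'
#' Every model is fitted to each participant's trials; the per-participant
#' best model is the BIC minimum (ties broken toward fewer parameters, then
#' lexically on the model id). Summed BIC differences are reported relative
#' to the model with the lowest total BIC. Participants with fewer than
#' `max(k) + 2` trials are excluded with a message.
#'
#' @param trials Trial table covering one or more participants.
#' @param ids Character vector of model ids to compare.
#' @param layout A `reach_layout`.
#' @param seed Integer seed (fits are deterministic given it).
#' @param n_restarts Restarts per fit (passed to [fit_model()]).
#' @param bounds Optional bounds overrides (shared across models where names
#'   match).
#' @return A `model_comparison`: per-participant best models and BIC table,
#'   summed `delta_bic` per model, and best-model `frequency`.
#' @export
compare_models <- function(trials, ids, layout, seed = 1, n_restarts = 20,
                           bounds = NULL) {
  ids <- unique(match.arg(ids, model_ids(), several.ok = TRUE))
  parts <- unique(trials$participant_id)
  if (length(parts) < 1) stop("no participants in `trials`", call. = FALSE)
  k_max <- max(vapply(ids, n_free_params, integer(1)))
  counts <- table(trials$participant_id)
  excluded <- names(counts)[counts < k_max + 2]
  if (length(excluded)) {
    message(sprintf("excluding %d participant(s) with < %d trials: %s",
                    length(excluded), k_max + 2,
                    paste(excluded, collapse = ", ")))
    parts <- setdiff(parts, excluded)
  }
  if (length(parts) == 0) stop("no participant has enough trials", call. = FALSE)

  bic_mat <- matrix(NA_real_, length(parts), length(ids),
                    dimnames = list(parts, ids))
  fits <- vector("list", length(parts))
  names(fits) <- parts
  for (p in parts) {
    sub <- trials[trials$participant_id == p, , drop = FALSE]
    fits[[p]] <- lapply(ids, function(id) {
      fit_model(sub, id, layout, bounds = bounds, n_restarts = n_restarts,
                seed = seed + 7919 * match(id, ids) + match(p, parts))
    })
    bic_mat[p, ] <- vapply(fits[[p]], function(f) f$bic, numeric(1))
  }

  kv <- vapply(ids, n_free_params, integer(1))
  best <- apply(bic_mat, 1, function(row) {
    ord <- order(row, kv, ids)   # BIC, then fewer params, then lexical
    ids[ord[1]]
  })
  freq <- table(factor(best, levels = ids))
  total_bic <- colSums(bic_mat)
  delta <- total_bic - min(total_bic)
  structure(
    list(ids = ids, participants = parts, excluded = excluded,
         bic = bic_mat, best_model = best,
         frequency = freq, total_bic = total_bic, delta_bic = delta,
         fits = fits, seed = seed),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %d participants, %d models\n",
              length(x$participants), length(x$ids)))
  cat("best-model frequency:\n")
  print(x$frequency)
  cat("summed delta-BIC (vs best):\n")
  print(round(x$delta_bic, 1))
  invisible(x)
}

#' Group-level fit with variance explained
#'
#' Pools trials across participants, fits the model, and reports R-squared of
#' the predicted bias function against the per-target mean angular biases.
#'
#' @inheritParams fit_model
#' @return A `fit_result` with an extra `r_squared` field (`NA` with a
#'   warning when the per-target means have zero variance).
#' @export
fit_group <- function(trials, model_id, layout, bounds = NULL,
                      n_restarts = 20, seed = 1) {
  fit <- fit_model(trials, model_id, layout, bounds = bounds,
                   n_restarts = n_restarts, seed = seed)
  angr <- round(trials$target_angle %% 360, 6)
  ang <- sort(unique(angr))
  err <- trial_angular_error(trials)
  obs <- vapply(ang, function(a) mean(err[angr == a]), numeric(1))
  pred <- eval_bias(fit$spec, layout, ang)$angular
  ss_tot <- sum((obs - mean(obs))^2)
  if (length(ang) < 2 || ss_tot < 1e-12) {
    warning("R-squared undefined: per-target means have zero variance")
    fit$r_squared <- NA_real_
  } else {
    fit$r_squared <- 1 - sum((obs - pred)^2) / ss_tot
  }
  fit
}
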