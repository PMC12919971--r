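# Generative models of systematic reach bias. Each model maps a target layout
# to a predicted bias function; hybrids either add component biases or compose
# perceptual distortion with the visuo-proprioceptive transformation stage.

#' Supported model identifiers
#'
#' Single-source models: `"TG"` (target bias, attraction toward the diagonal
#' axes), `"PV"` (vector-based proprioceptive bias), `"PJ"` (joint-based
#' proprioceptive bias), `"TR"` (visuo-proprioceptive transformation bias),
#' `"TGD"` (visual depth bias on target and start). Hybrids: `"PV+TG"`,
#' `"PJ+TG"` (bias functions added), `"TR+TG"`, `"TR+TGD"` (perceptual
#' distortion composed with the transformation stage).
#' @export
model_ids <- function() {
  c("TG", "PV", "PJ", "TR", "TGD", "PV+TG", "PJ+TG", "TR+TG", "TR+TGD")
}

#' Bundle a model identifier with its parameters
#'
#' @param model_id One of [model_ids()].
#' @param params Named list of parameters. Expected fields:
#'   * `TG`: `a` (transition-zone half-width, degrees, in (0, 45)),
#'     `b` (peak bias, degrees);
#'   * `PV`: `x_e`, `y_e` (perceived-start error vector, cm);
#'   * `PJ`: `theta0`, `phi0` (initial shoulder/elbow angles, rad),
#'     `theta_e`, `phi_e` (perceived joint-angle errors, rad), optional
#'     `l1`, `l2` (segment lengths, cm, default 24);
#'   * `TR`: `x_e`, `y_e` (transformation error per cm of distance),
#'     `x_r`, `y_r` (reference position, cm);
#'   * `TGD`: `k` (depth gain), `c` (constant depth offset, cm).
#'
#'   Hybrids carry both component records, e.g.
#'   `list(tr = list(...), tg = list(...))`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(model_id, params) {
  model_id <- match.arg(model_id, model_ids())
  check_field <- function(p, fields, what) {
    if (!is.list(p) || !all(fields %in% names(p))) {
      stop(sprintf("%s parameters need fields: %s", what,
                   paste(fields, collapse = ", ")), call. = FALSE)
    }
    vals <- unlist(p[fields])
    if (any(!is.finite(vals))) {
      stop(sprintf("%s parameters must be finite", what), call. = FALSE)
    }
  }
  comp <- strsplit(model_id, "+", fixed = TRUE)[[1]]
  if (length(comp) == 1) {
    params <- switch(model_id,
      TG = { check_field(params, c("a", "b"), "TG")
             if (params$a <= 0 || params$a >= 45)
               stop("TG half-width `a` must lie in (0, 45) degrees", call. = FALSE)
             params },
      PV = { check_field(params, c("x_e", "y_e"), "PV"); params },
      PJ = { check_field(params, c("theta0", "phi0", "theta_e", "phi_e"), "PJ")
             if (is.null(params$l1)) params$l1 <- 24
             if (is.null(params$l2)) params$l2 <- 24
             if (params$l1 <= 0 || params$l2 <= 0)
               stop("PJ segment lengths must be positive", call. = FALSE)
             if (!(pi > params$phi0 && params$phi0 > params$theta0 &&
                   params$theta0 > 0))
               stop("PJ initial posture must satisfy pi > phi0 > theta0 > 0",
                    call. = FALSE)
             params },
      TR = { check_field(params, c("x_e", "y_e", "x_r", "y_r"), "TR"); params },
      TGD = { check_field(params, c("k", "c"), "TGD"); params }
    )
  } else {
    keys <- tolower(comp)
    if (!all(keys %in% names(params))) {
      stop(sprintf("hybrid `%s` needs component records: %s", model_id,
                   paste(keys, collapse = ", ")), call. = FALSE)
    }
    for (i in seq_along(comp)) {
      params[[keys[i]]] <- model_spec(comp[i], params[[keys[i]]])$params
    }
  }
  structure(list(model_id = model_id, params = params), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  flat <- unlist(x$params)
  cat(sprintf("<model_spec> %s: %s\n", x$model_id,
              paste(sprintf("%s=%.4g", names(flat), flat), collapse = ", ")))
  invisible(x)
}

#' Mirror a model specification across the body midline
#'
#' Negates the x-components of all parameter error vectors and reference
#' points, producing the parameterization appropriate for the opposite hand.
#' Target-bias and depth-bias parameters are symmetric and unchanged;
#' joint-model parameters are unchanged because the mirrored kinematic chain
#' is selected by the layout's `hand` field.
#'
#' @param spec A `model_spec`.
#' @return The mirrored `model_spec`.
#' @export
mirror_spec <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  flip <- function(id, p) {
    switch(id,
      PV = { p$x_e <- -p$x_e; p },
      TR = { p$x_e <- -p$x_e; p$x_r <- -p$x_r; p },
      p)
  }
  comp <- strsplit(spec$model_id, "+", fixed = TRUE)[[1]]
  if (length(comp) == 1) {
    spec$params <- flip(spec$model_id, spec$params)
  } else {
    for (k in tolower(comp)) {
      spec$params[[k]] <- flip(toupper(k), spec$params[[k]])
    }
  }
  spec
}

#' Canonical demonstration parameters
#'
#' Parameter values used for scenario simulations and peak-count
#' demonstrations, in the regime where the qualitative shape of each model's
#' prediction is insensitive to the exact values: a moderate diagonal
#' attraction for the target bias, a rightward/near-body proprioceptive error,
#' a leftward-and-downward transformation error anchored at a left-shoulder
#' reference, and a small positive depth gain.
#'
#' @param model_id One of [model_ids()].
#' @return A `model_spec` with the canonical parameters.
#' @export
canonical_spec <- function(model_id) {
  model_id <- match.arg(model_id, model_ids())
  base <- list(
    TG = list(a = 10, b = 5),
    PV = list(x_e = 1.5, y_e = -1),
    PJ = list(theta0 = 50 * DEG2RAD, phi0 = 120 * DEG2RAD,
              theta_e = 2 * DEG2RAD, phi_e = 0, l1 = 24, l2 = 24),
    TR = list(x_e = -0.05, y_e = -0.05, x_r = 10, y_r = -30),
    TGD = list(k = 0.1, c = 0.5)
  )
  comp <- strsplit(model_id, "+", fixed = TRUE)[[1]]
  if (length(comp) == 1) {
    model_spec(model_id, base[[model_id]])
  } else {
    params <- stats::setNames(base[comp], tolower(comp))
    model_spec(model_id, params)
  }
}

# ---- target bias ------------------------------------------------------------

#' Target (diagonal-attraction) bias
#'
#' Piecewise-linear angular distortion of the perceived target direction,
#' periodic with 90 degrees: zero at the cardinal and diagonal axes, rising to
#' `+b` at `a` degrees past a cardinal axis and falling to `-b` at `a` degrees
#' before the next one, so that perceived directions are attracted toward the
#' diagonals (45, 135, 225, 315 degrees).
#'
#' @param angle Target direction(s), degrees.
#' @param a Transition-zone half-width around the cardinal axes, degrees,
#'   in (0, 45).
#' @param b Peak bias, degrees (counterclockwise positive).
#' @return Angular bias in degrees, same length as `angle`.
#' @export
target_bias <- function(angle, a, b) {
  if (!is.finite(a) || a <= 0 || a >= 45) {
    stop("`a` must lie in (0, 45) degrees", call. = FALSE)
  }
  x <- angle %% 90
  ifelse(x < a, b * x / a,
         ifelse(x <= 90 - a, b - (x - a) * b / (45 - a),
                -b * (90 - x) / a))
}

#' Rotate a target to its perceptually distorted position
#'
#' Applies the target bias to the direction of `target` as seen from `start`,
#' preserving the radius.
#'
#' @param target,start Positions, cm (length-2 numeric).
#' @param a,b Target-bias parameters (see [target_bias()]).
#' @return The distorted target position.
#' @export
biased_target_position <- function(target, start, a, b) {
  v <- target - start
  r <- sqrt(sum(v^2))
  if (r == 0) stop("target coincides with start", call. = FALSE)
  ang <- atan2(v[2], v[1]) * RAD2DEG
  new_ang <- (ang + target_bias(ang, a, b)) * DEG2RAD
  start + r * c(cos(new_ang), sin(new_ang))
}

# ---- vector-based proprioceptive bias ---------------------------------------

# Internal engine shared by predict_bias: angular (deg) and radial (cm) bias
# at given target angles. `angles` in degrees; returns list(angular, radial).
eval_pv <- function(angles, radius, x_e, y_e) {
  a <- angles * DEG2RAD
  # motor plan points from the misperceived start toward the target
  px <- radius * cos(a) - x_e
  py <- radius * sin(a) - y_e
  if (any(px^2 + py^2 == 0)) {
    stop("degenerate motor plan: perceived start coincides with a target",
         call. = FALSE)
  }
  list(
    angular = wrap_angle(atan2(py, px) * RAD2DEG - angles),
    radial = sqrt(px^2 + py^2) - radius
  )
}

#' Vector-based proprioceptive bias
#'
#' The unseen start position of the hand is misperceived by an error vector
#' `(x_e, y_e)`; the motor plan is the vector from the perceived start to the
#' target, executed from the true start. Misperceiving the hand rightward of
#' the start biases the reach to the 90-degree target counterclockwise.
#'
#' @param layout A `reach_layout`.
#' @param x_e,y_e Perceived-start error vector, cm.
#' @return A `bias_fn` with angular (and radial) bias at the layout's targets.
#' @export
vector_prop_bias <- function(layout, x_e, y_e) {
  stopifnot(inherits(layout, "reach_layout"))
  res <- eval_pv(layout$target_angles, layout$radius, x_e, y_e)
  bias_function(layout$target_angles, res$angular, res$radial)
}

# ---- two-link kinematics ----------------------------------------------------

#' Forward kinematics of a planar two-link arm
#'
#' Hand position for absolute upper-arm angle `theta` and forearm angle `phi`
#' (shoulder at the origin): `[l1 cos(theta) + l2 cos(phi),
#' l1 sin(theta) + l2 sin(phi)]`.
#'
#' @param theta,phi Segment angles, radians (vectorized).
#' @param l1,l2 Segment lengths, cm.
#' @return A matrix with columns `x`, `y` (cm).
#' @export
forward_kinematics <- function(theta, phi, l1 = 24, l2 = 24) {
  cbind(x = l1 * cos(theta) + l2 * cos(phi),
        y = l1 * sin(theta) + l2 * sin(phi))
}

#' Inverse kinematics of a planar two-link arm
#'
#' Recovers the unique admissible posture (`pi > phi > theta > 0`) reaching a
#' point in the shoulder frame. Points outside the annulus
#' `[|l1 - l2|, l1 + l2]` are unreachable; geometrically reachable points
#' whose unique admissible-branch solution violates the posture constraint
#' raise a "no admissible posture" error. Boundary postures are rejected with
#' a tolerance of 1e-9 rad.
#'
#' @param point Length-2 numeric, cm, shoulder frame.
#' @param l1,l2 Segment lengths, cm.
#' @return `list(theta = , phi = )` in radians.
#' @export
inverse_kinematics <- function(point, l1 = 24, l2 = 24) {
  res <- ik_solve(point[1], point[2], l1, l2)
  if (any(!res$ok)) stop(res$why[!res$ok][1], call. = FALSE)
  list(theta = res$theta, phi = res$phi)
}

# Vectorized IK core; returns ok/why instead of stopping so model fitting can
# treat unreachable configurations as soft failures.
ik_solve <- function(x, y, l1, l2, tol = 1e-9) {
  r2 <- x^2 + y^2
  r <- sqrt(r2)
  ok <- rep(TRUE, length(r))
  why <- rep(NA_character_, length(r))
  bad <- r > l1 + l2 + tol | r < abs(l1 - l2) - tol
  ok[bad] <- FALSE
  why[bad] <- "unreachable: point outside the arm's annulus"
  # interior elbow angle gamma = phi - theta in (0, pi) picks the phi > theta branch
  cg <- pmin(1, pmax(-1, (r2 - l1^2 - l2^2) / (2 * l1 * l2)))
  gamma <- acos(cg)
  beta <- atan2(l2 * sin(gamma), l1 + l2 * cos(gamma))
  theta <- atan2(y, x) - beta
  phi <- theta + gamma
  viol <- ok & !(theta > tol & gamma > tol & phi < pi - tol)
  ok[viol] <- FALSE
  why[viol] <- "no admissible posture: pi > phi > theta > 0 violated"
  list(theta = theta, phi = phi, ok = ok, why = why)
}

#' Joint-based proprioceptive bias
#'
#' Movements are planned as changes in shoulder and elbow angles. The initial
#' posture `(theta0, phi0)` is misperceived by `(theta_e, phi_e)`; the
#' joint-angle changes are solved so that, from the *perceived* posture, the
#' hand would land on the target; executing those changes from the *true*
#' posture produces the bias. Start position is `P(theta0, phi0)` in the
#' shoulder frame; visual targets sit at the layout radius around it.
#'
#' @param layout A `reach_layout`. `hand = "left"` selects the mirrored
#'   kinematic chain.
#' @param theta0,phi0 Initial shoulder/elbow segment angles, radians.
#' @param theta_e,phi_e Perceived joint-angle errors, radians.
#' @param l1,l2 Segment lengths, cm (default 24 each).
#' @param plan_displacement `"target_minus_perceived"` (default) plans the
#'   displacement from the perceived hand to the target; `"as_printed"`
#'   selects the opposite sign of the planned displacement, exposed for
#'   auditing the alternative reading.
#' @return A `bias_fn` (angular component only).
#' @export
joint_prop_bias <- function(layout, theta0, phi0, theta_e, phi_e,
                            l1 = 24, l2 = 24,
                            plan_displacement = c("target_minus_perceived",
                                                  "as_printed")) {
  stopifnot(inherits(layout, "reach_layout"))
  plan_displacement <- match.arg(plan_displacement)
  ang <- eval_pj(layout$target_angles, layout$radius,
                 theta0, phi0, theta_e, phi_e, l1, l2,
                 mirrored = layout$hand == "left",
                 plan_displacement = plan_displacement)
  bias_function(layout$target_angles, ang)
}

eval_pj <- function(angles, radius, theta0, phi0, theta_e, phi_e,
                    l1 = 24, l2 = 24, mirrored = FALSE,
                    plan_displacement = "target_minus_perceived") {
  if (theta_e == 0 && phi_e == 0) {
    return(rep(0, length(angles)))  # perceived = actual: exactly unbiased
  }
  sgn <- if (mirrored) -1 else 1  # mirrored chain: x components negated
  fk <- function(th, ph) {
    cbind(sgn * (l1 * cos(th) + l2 * cos(ph)), l1 * sin(th) + l2 * sin(ph))
  }
  start <- fk(theta0, phi0)
  a <- angles * DEG2RAD
  tx <- start[1] + radius * cos(a)
  ty <- start[2] + radius * sin(a)
  pp <- fk(theta0 + theta_e, phi0 + phi_e)
  # planned displacement in perceived space
  if (plan_displacement == "target_minus_perceived") {
    gx <- tx
    gy <- ty
  } else {
    gx <- 2 * pp[1] - tx
    gy <- 2 * pp[2] - ty
  }
  sol <- ik_solve(sgn * gx, gy, l1, l2)
  if (any(!sol$ok)) stop(sol$why[!sol$ok][1], call. = FALSE)
  dth <- sol$theta - (theta0 + theta_e)
  dph <- sol$phi - (phi0 + phi_e)
  ex <- fk(theta0 + dth, phi0 + dph)
  vx <- ex[, 1] - start[1]
  vy <- ex[, 2] - start[2]
  wrap_angle(atan2(vy, vx) * RAD2DEG - angles)
}

# ---- transformation bias ----------------------------------------------------

#' Transformation error vector at a position
#'
#' The visuo-proprioceptive transformation error has a fixed direction
#' `(x_e, y_e)` (per cm) and a magnitude proportional to the Euclidean
#' distance from the position to the reference point `(x_r, y_r)`, typically
#' near the shoulder.
#'
#' @param points An n x 2 matrix (or length-2 vector) of positions, cm.
#' @param x_e,y_e Error per cm of distance to the reference (dimensionless).
#' @param x_r,y_r Reference position, cm.
#' @return An n x 2 matrix of error vectors, cm.
#' @export
transform_error_vector <- function(points, x_e, y_e, x_r, y_r) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  d <- sqrt((points[, 1] - x_r)^2 + (points[, 2] - y_r)^2)
  cbind(d * x_e, d * y_e)
}

#' Sample the transformation error field on a grid
#'
#' @param grid An n x 2 matrix of positions, cm.
#' @inheritParams transform_error_vector
#' @return A `data.frame` with columns `x`, `y`, `tx`, `ty` suitable for
#'   quiver-style plotting or CSV export.
#' @export
error_map <- function(grid, x_e, y_e, x_r, y_r) {
  if (is.null(dim(grid))) grid <- matrix(grid, ncol = 2)
  tv <- transform_error_vector(grid, x_e, y_e, x_r, y_r)
  data.frame(x = grid[, 1], y = grid[, 2], tx = tv[, 1], ty = tv[, 2])
}

# Transformation-stage planner. Takes the (possibly perceptually distorted)
# target and start positions in the true start-centered frame and returns the
# motor plan per scenario. `targets` n x 2; `start_vis` the displayed start.
plan_transform <- function(targets, start_true, start_vis, scenario,
                           x_e, y_e, x_r, y_r, t_start = "computed") {
  tv <- transform_error_vector(targets, x_e, y_e, x_r, y_r)
  ptgt <- targets + tv
  if (scenario == "hidden") {
    # start sensed proprioceptively: already in motor coordinates, no
    # transformation applied to it
    pstart <- start_true
  } else {
    pstart <- start_vis
    if (t_start == "computed") {
      pstart <- pstart +
        drop(transform_error_vector(matrix(start_vis, ncol = 2),
                                    x_e, y_e, x_r, y_r))
    }
  }
  cbind(ptgt[, 1] - pstart[1], ptgt[, 2] - pstart[2])
}

#' Visuo-proprioceptive transformation bias
#'
#' Both the start and target positions are encoded visually and must be
#' transformed into proprioceptive coordinates for motor planning; the
#' transformation error ([transform_error_vector()]) displaces both, and the
#' plan is the vector between the transformed positions. The layout's
#' `start_visibility` selects the scenario: `"visible"` transforms both
#' positions (two-peaked bias function), `"hidden"` transforms only the
#' target because the unseen start is already sensed proprioceptively
#' (single-peaked function), and `"perturbed"` displaces the displayed start
#' by `layout$start_perturbation` before transforming it.
#'
#' @param layout A `reach_layout`.
#' @param x_e,y_e,x_r,y_r Transformation parameters
#'   (see [transform_error_vector()]).
#' @param t_start `"computed"` (default) evaluates the transformation error at
#'   the displayed start position; `"zero"` forces a null start
#'   transformation, exposed for auditing the alternative reading.
#' @return A `bias_fn` with angular and radial bias.
#' @export
transformation_bias <- function(layout, x_e, y_e, x_r, y_r,
                                t_start = c("computed", "zero")) {
  stopifnot(inherits(layout, "reach_layout"))
  t_start <- match.arg(t_start)
  res <- eval_tr(layout$target_angles, layout, x_e, y_e, x_r, y_r,
                 t_start = t_start)
  bias_function(layout$target_angles, res$angular, res$radial)
}

eval_tr <- function(angles, layout, x_e, y_e, x_r, y_r,
                    tg = NULL, tgd = NULL, t_start = "computed") {
  a <- angles * DEG2RAD
  start <- layout$start
  targets <- cbind(start[1] + layout$radius * cos(a),
                   start[2] + layout$radius * sin(a))
  # optional perceptual distortion applied before the transformation stage
  if (!is.null(tg)) {
    ang2 <- angles + target_bias(angles, tg$a, tg$b)
    targets <- cbind(start[1] + layout$radius * cos(ang2 * DEG2RAD),
                     start[2] + layout$radius * sin(ang2 * DEG2RAD))
  }
  start_vis <- start + layout$start_perturbation
  if (!is.null(tgd)) {
    targets[, 2] <- targets[, 2] + tgd$k * targets[, 2] + tgd$c
    start_vis[2] <- start_vis[2] + tgd$k * start_vis[2] + tgd$c
  }
  plan <- plan_transform(targets, start, start_vis, layout$start_visibility,
                         x_e, y_e, x_r, y_r, t_start)
  len <- sqrt(plan[, 1]^2 + plan[, 2]^2)
  if (any(len == 0)) stop("degenerate motor plan of zero length", call. = FALSE)
  list(
    angular = wrap_angle(atan2(plan[, 2], plan[, 1]) * RAD2DEG - angles),
    radial = len - layout$radius
  )
}

# ---- visual depth bias ------------------------------------------------------

#' Apply the visual depth distortion to a position
#'
#' Viewing the display at an oblique angle compresses or expands perceived
#' depth: the y (away-from-body) coordinate maps to `y + k * y + c`, the x
#' coordinate is unchanged. The same rule applies to target and start.
#'
#' @param point Length-2 numeric or n x 2 matrix, cm.
#' @param k Depth gain (dimensionless).
#' @param c Constant depth offset, cm.
#' @return The distorted position(s).
#' @export
depth_bias_point <- function(point, k, c) {
  if (is.null(dim(point))) {
    point[2] <- point[2] + k * point[2] + c
  } else {
    point[, 2] <- point[, 2] + k * point[, 2] + c
  }
  point
}

eval_tgd <- function(angles, radius, start, k, c) {
  a <- angles * DEG2RAD
  tgt <- depth_bias_point(cbind(start[1] + radius * cos(a),
                                start[2] + radius * sin(a)), k, c)
  st <- depth_bias_point(start, k, c)
  px <- tgt[, 1] - st[1]
  py <- tgt[, 2] - st[2]
  if (any(px^2 + py^2 == 0)) {
    stop("degenerate motor plan of zero length", call. = FALSE)
  }
  list(
    angular = wrap_angle(atan2(py, px) * RAD2DEG - angles),
    radial = sqrt(px^2 + py^2) - radius
  )
}

# ---- dispatch ---------------------------------------------------------------

# Evaluate spec at arbitrary angles (degrees) on a layout's geometry.
# Returns list(angular, radial or NULL). Order follows `angles`.
eval_bias <- function(spec, layout, angles) {
  p <- spec$params
  switch(spec$model_id,
    TG = list(angular = target_bias(angles, p$a, p$b), radial = NULL),
    PV = eval_pv(angles, layout$radius, p$x_e, p$y_e),
    PJ = list(angular = eval_pj(angles, layout$radius, p$theta0, p$phi0,
                                p$theta_e, p$phi_e, p$l1, p$l2,
                                mirrored = layout$hand == "left"),
              radial = NULL),
    TR = eval_tr(angles, layout, p$x_e, p$y_e, p$x_r, p$y_r),
    TGD = eval_tgd(angles, layout$radius, layout$start, p$k, p$c),
    `PV+TG` = {
      r <- eval_pv(angles, layout$radius, p$pv$x_e, p$pv$y_e)
      r$angular <- r$angular + target_bias(angles, p$tg$a, p$tg$b)
      r
    },
    `PJ+TG` = list(
      angular = eval_pj(angles, layout$radius, p$pj$theta0, p$pj$phi0,
                        p$pj$theta_e, p$pj$phi_e, p$pj$l1, p$pj$l2,
                        mirrored = layout$hand == "left") +
        target_bias(angles, p$tg$a, p$tg$b),
      radial = NULL),
    `TR+TG` = eval_tr(angles, layout, p$tr$x_e, p$tr$y_e, p$tr$x_r, p$tr$y_r,
                      tg = p$tg),
    `TR+TGD` = eval_tr(angles, layout, p$tr$x_e, p$tr$y_e, p$tr$x_r, p$tr$y_r,
                       tgd = p$tgd)
  )
}

#' Predict a model's bias function on a layout
#'
#' Dispatches to the generative model named by `spec`. Additive hybrids
#' (`PV+TG`, `PJ+TG`) sum their components' angular biases; compositional
#' hybrids (`TR+TG`, `TR+TGD`) first distort the perceived target (and, for
#' `TR+TGD`, the start) and then run the transformation stage on the
#' distorted positions.
#'
#' @param spec A `model_spec`.
#' @param layout A `reach_layout`. Depth-bias models (`TGD`, `TR+TGD`)
#'   require `dimension = "angle_extent"`.
#' @param angles Optional angles (degrees) at which to evaluate instead of the
#'   layout's target angles; must be sortable into `[0, 360)`.
#' @return A `bias_fn`; models that predict endpoints also carry
#'   `radial_bias_cm`.
#' @export
predict_bias <- function(spec, layout, angles = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(layout, "reach_layout"))
  if (grepl("TGD", spec$model_id) && layout$dimension != "angle_extent") {
    stop(sprintf("model `%s` requires a layout with dimension = \"angle_extent\"",
                 spec$model_id), call. = FALSE)
  }
  if (layout$dimension == "angle_extent" &&
      spec$model_id %in% c("PJ", "PJ+TG")) {
    stop("the joint-based model makes no movement-extent prediction",
         call. = FALSE)
  }
  if (is.null(angles)) angles <- layout$target_angles
  angles <- angles %% 360
  ord <- order(angles)
  res <- eval_bias(spec, layout, angles[ord])
  bias_function(angles[ord], res$angular, res$radial)
}

# ---- peak counting ----------------------------------------------------------

#' Count prominent circular peaks of a bias function
#'
#' A peak is a strict circular local maximum whose prominence (height above
#' the higher of the two adjacent valleys separating it from the neighboring
#' maxima) is at least `prominence_frac` times the function's range. The
#' prominence rule discards floating-point micro-ripples while preserving the
#' qualitative peak count that distinguishes the candidate models (four for
#' the target bias, one for the proprioceptive biases, two for the
#' transformation bias with a visible start, one with a hidden start).
#'
#' @param f A `bias_fn` sampled on a uniform circular grid (>= 8 samples), or
#'   a numeric vector of samples assumed uniform over the circle.
#' @param prominence_frac Minimum prominence as a fraction of `max - min`
#'   (default 0.1).
#' @param component `"angular"` or `"radial"` when `f` is a `bias_fn`.
#' @return Integer peak count (0 for a constant function).
#' @export
count_peaks <- function(f, prominence_frac = 0.1,
                        component = c("angular", "radial")) {
  component <- match.arg(component)
  if (inherits(f, "bias_fn")) {
    ang <- f$angle_deg
    step <- diff(ang)
    if (length(ang) < 8 ||
        max(abs(step - step[1])) > 1e-6 ||
        abs(ang[1] + 360 - ang[length(ang)] - step[1]) > 1e-6) {
      stop("`f` must be sampled on a uniform circular grid with >= 8 points",
           call. = FALSE)
    }
    v <- if (component == "angular") f$angular_bias_deg else f$radial_bias_cm
    if (is.null(v)) stop("bias function has no radial component", call. = FALSE)
  } else {
    v <- as.numeric(f)
    if (length(v) < 8) stop("need >= 8 samples", call. = FALSE)
  }
  n <- length(v)
  rng <- max(v) - min(v)
  if (rng == 0) return(0L)
  up <- v > v[c(n, seq_len(n - 1))]     # greater than left neighbor
  dn <- v > v[c(seq(2, n), 1)]          # greater than right neighbor
  maxima <- which(up & dn)
  if (length(maxima) == 0) return(0L)
  if (length(maxima) == 1) {
    prom <- v[maxima] - min(v)
    return(as.integer(prom >= prominence_frac * rng))
  }
  m <- length(maxima)
  # valley between consecutive maxima (circular)
  valley <- numeric(m)
  for (j in seq_len(m)) {
    i0 <- maxima[j]
    i1 <- maxima[if (j == m) 1 else j + 1]
    idx <- if (i1 > i0) seq(i0, i1) else c(seq(i0, n), seq(1, i1))
    valley[j] <- min(v[idx])
  }
  left_valley <- valley[c(m, seq_len(m - 1))]
  prom <- v[maxima] - pmax(left_valley, valley)
  sum(prom >= prominence_frac * rng)
}
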