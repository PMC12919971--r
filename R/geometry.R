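# Coordinate conventions shared by every model:
#   * angles in degrees, 0 deg = rightward (3 o'clock), counterclockwise positive
#   * positions in cm in a start-centered frame (start = [0, 0]); body reference
#     points (e.g., the shoulder) live in the same frame
#   * angular bias positive = counterclockwise, radial bias in cm

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Wrap an angle into (-180, 180]
#'
#' @param angle Numeric vector of angles in degrees.
#' @return Angles congruent to the input modulo 360, in `(-180, 180]`.
#' @examples
#' wrap_angle(270)   # -90
#' wrap_angle(-190)  # 170
#' @export
wrap_angle <- function(angle) {
  if (!is.numeric(angle) || any(!is.finite(angle))) {
    stop("`angle` must be finite numeric", call. = FALSE)
  }
  w <- angle %% 360
  ifelse(w > 180, w - 360, w)
}

#' Signed angular difference a - b in degrees
#'
#' Antisymmetric: `angular_difference(a, b) == -angular_difference(b, a)`.
#'
#' @param a,b Numeric vectors of angles in degrees.
#' @return `wrap_angle(a - b)`.
#' @export
angular_difference <- function(a, b) {
  wrap_angle(a - b)
}

#' Construct a center-out target layout
#'
#' Targets are evenly spaced on a circle starting at 0 degrees (rightward).
#' The layout also carries the scenario flags that change how the
#' transformation-bias model treats the start position.
#'
#' @param n_targets Number of targets (>= 1).
#' @param radius Target eccentricity in cm (> 0).
#' @param hand `"right"` or `"left"`.
#' @param start Start position, cm (default `c(0, 0)`).
#' @param start_visibility `"visible"`, `"hidden"`, or `"perturbed"`.
#' @param start_perturbation Displacement of the displayed start from the true
#'   hand position, cm; only meaningful when `start_visibility = "perturbed"`.
#' @param dimension `"angle"` for angular-error-only designs (slicing
#'   movements), `"angle_extent"` for designs measuring 2-D endpoints.
#' @param target_angles Optional explicit target angles (degrees), overriding
#'   the even spacing.
#' @return An object of class `reach_layout`.
#' @examples
#' make_layout(24, 8)           # 24 targets, 15-degree spacing, 8 cm
#' make_layout(12, 10, dimension = "angle_extent")
#' @export
make_layout <- function(n_targets, radius, hand = c("right", "left"),
                        start = c(0, 0),
                        start_visibility = c("visible", "hidden", "perturbed"),
                        start_perturbation = c(0, 0),
                        dimension = c("angle", "angle_extent"),
                        target_angles = NULL) {
  hand <- match.arg(hand)
  start_visibility <- match.arg(start_visibility)
  dimension <- match.arg(dimension)
  if (!is.numeric(n_targets) || length(n_targets) != 1 || n_targets < 1 ||
      n_targets != round(n_targets)) {
    stop("`n_targets` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) ||
      radius <= 0) {
    stop("`radius` must be a positive number", call. = FALSE)
  }
  if (is.null(target_angles)) {
    target_angles <- seq(0, 360, length.out = n_targets + 1)[seq_len(n_targets)]
  } else {
    target_angles <- as.numeric(target_angles) %% 360
    if (length(target_angles) != n_targets) {
      stop("`target_angles` length must equal `n_targets`", call. = FALSE)
    }
  }
  if (anyDuplicated(round(target_angles %% 360, 9))) {
    stop("target angles must be unique modulo 360", call. = FALSE)
  }
  if (start_visibility != "perturbed" && any(start_perturbation != 0)) {
    stop("`start_perturbation` must be zero unless start_visibility = \"perturbed\"",
         call. = FALSE)
  }
  structure(
    list(
      n_targets = as.integer(n_targets),
      target_angles = target_angles,
      radius = radius,
      start = as.numeric(start),
      hand = hand,
      start_visibility = start_visibility,
      start_perturbation = as.numeric(start_perturbation),
      dimension = dimension
    ),
    class = "reach_layout"
  )
}

#' @export
print.reach_layout <- function(x, ...) {
  cat(sprintf(
    "<reach_layout> %d targets, radius %.3g cm, %s hand, start %s%s\n",
    x$n_targets, x$radius, x$hand, x$start_visibility,
    if (x$dimension == "angle_extent") ", 2-D endpoints" else ""
  ))
  invisible(x)
}

# Cartesian target positions (n x 2 matrix) in the start-centered frame.
layout_targets <- function(layout) {
  a <- layout$target_angles * DEG2RAD
  cbind(layout$start[1] + layout$radius * cos(a),
        layout$start[2] + layout$radius * sin(a))
}

#' Construct a bias function
#'
#' A bias function tabulates the model-predicted (or empirically measured)
#' reach bias against target direction: the angular component in degrees
#' (counterclockwise positive) and, optionally, the radial component in cm.
#'
#' @param angles Target angles in degrees, strictly increasing within
#'   `[0, 360)`.
#' @param angular_bias Angular bias at each target, degrees.
#' @param radial_bias Optional radial (extent) bias at each target, cm.
#' @return A `data.frame` of class `bias_fn` with columns `angle_deg`,
#'   `angular_bias_deg` and (when supplied) `radial_bias_cm`.
#' @export
bias_function <- function(angles, angular_bias, radial_bias = NULL) {
  angles <- as.numeric(angles)
  angular_bias <- as.numeric(angular_bias)
  if (length(angles) != length(angular_bias)) {
    stop("`angles` and `angular_bias` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(angles)) || any(angles < 0) || any(angles >= 360) ||
      is.unsorted(angles, strictly = TRUE)) {
    stop("`angles` must be strictly increasing within [0, 360)", call. = FALSE)
  }
  if (any(!is.finite(angular_bias))) {
    stop("`angular_bias` must be finite", call. = FALSE)
  }
  out <- data.frame(angle_deg = angles, angular_bias_deg = angular_bias)
  if (!is.null(radial_bias)) {
    radial_bias <- as.numeric(radial_bias)
    if (length(radial_bias) != length(angles)) {
      stop("`radial_bias` must match `angles` in length", call. = FALSE)
    }
    out$radial_bias_cm <- radial_bias
  }
  class(out) <- c("bias_fn", "data.frame")
  out
}

#' Mirror a layout across the vertical meridian
#'
#' Reflects every target direction (`alpha -> 180 - alpha`), the start
#' position, and any start perturbation across the body midline, and swaps
#' the acting hand. Applying it twice restores the original layout.
#'
#' @param layout A `reach_layout`.
#' @return The mirrored `reach_layout`.
#' @export
mirror_layout <- function(layout) {
  stopifnot(inherits(layout, "reach_layout"))
  layout$target_angles <- (180 - layout$target_angles) %% 360
  layout$start[1] <- -layout$start[1]
  layout$start_perturbation[1] <- -layout$start_perturbation[1]
  layout$hand <- if (layout$hand == "right") "left" else "right"
  layout
}

#' Mirror a bias function across the vertical meridian
#'
#' A reflection `alpha -> 180 - alpha` flips the sign of the angular bias
#' (clockwise becomes counterclockwise) and preserves the radial bias.
#' The operation is an involution.
#'
#' @param bias A `bias_fn`.
#' @return The mirrored `bias_fn`, re-sorted on angle.
#' @export
mirror_bias <- function(bias) {
  stopifnot(inherits(bias, "bias_fn"))
  new_angles <- (180 - bias$angle_deg) %% 360
  ord <- order(new_angles)
  bias_function(
    new_angles[ord],
    -bias$angular_bias_deg[ord],
    if ("radial_bias_cm" %in% names(bias)) bias$radial_bias_cm[ord]
  )
}
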