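# Independent brute-force geometric oracle: every bias model is re-derived
# with complex-number arithmetic (positions as x + iy, angles via Arg,
# distances via Mod), and the joint model's inverse kinematics via
# one-dimensional root finding instead of the closed form. Used to verify
# the package's closed-form predictions to 1e-9 degrees.

oracle_wrap <- function(a) {
  w <- a %% 360
  ifelse(w > 180, w - 360, w)
}

oracle_deg <- function(z) Arg(z) * 180 / pi

oracle_tg <- function(angle, a, b) {
  x <- angle %% 90
  stats::approx(c(0, a, 90 - a, 90), c(0, b, -b, 0), xout = x)$y
}

oracle_pv <- function(angles, radius, x_e, y_e) {
  tgt <- radius * exp(1i * angles * pi / 180)
  plan <- tgt - complex(real = x_e, imaginary = y_e)
  list(angular = oracle_wrap(oracle_deg(plan) - angles),
       radial = Mod(plan) - radius)
}

oracle_tr <- function(angles, layout, x_e, y_e, x_r, y_r,
                      tg = NULL, tgd = NULL) {
  ref <- complex(real = x_r, imaginary = y_r)
  e <- complex(real = x_e, imaginary = y_e)
  start <- complex(real = layout$start[1], imaginary = layout$start[2])
  tvec <- function(z) Mod(z - ref) * e
  ang <- angles
  if (!is.null(tg)) ang <- ang + oracle_tg(ang, tg$a, tg$b)
  tgt <- start + layout$radius * exp(1i * ang * pi / 180)
  start_vis <- start + complex(real = layout$start_perturbation[1],
                               imaginary = layout$start_perturbation[2])
  if (!is.null(tgd)) {
    tgt <- complex(real = Re(tgt), imaginary = Im(tgt) * (1 + tgd$k) + tgd$c)
    start_vis <- complex(real = Re(start_vis),
                         imaginary = Im(start_vis) * (1 + tgd$k) + tgd$c)
  }
  perceived_start <- switch(layout$start_visibility,
    hidden = start,
    start_vis + tvec(start_vis))
  plan <- (tgt + tvec(tgt)) - perceived_start
  list(angular = oracle_wrap(oracle_deg(plan) - angles),
       radial = Mod(plan) - layout$radius)
}

oracle_tgd <- function(angles, radius, start, k, c) {
  depth <- function(z) complex(real = Re(z), imaginary = Im(z) * (1 + k) + c)
  s <- complex(real = start[1], imaginary = start[2])
  tgt <- s + radius * exp(1i * angles * pi / 180)
  plan <- depth(tgt) - depth(s)
  list(angular = oracle_wrap(oracle_deg(plan) - angles),
       radial = Mod(plan) - radius)
}

# IK by root finding on the interior elbow angle instead of the closed form.
oracle_ik <- function(p, l1 = 24, l2 = 24) {
  r <- Mod(p)
  f <- function(g) l1^2 + l2^2 + 2 * l1 * l2 * cos(g) - r^2
  g <- stats::uniroot(f, c(1e-12, pi - 1e-12), tol = 1e-14)$root
  theta <- Arg(p) - Arg(complex(real = l1 + l2 * cos(g), imaginary = l2 * sin(g)))
  list(theta = theta, phi = theta + g)
}

oracle_pj <- function(angles, radius, theta0, phi0, theta_e, phi_e,
                      l1 = 24, l2 = 24) {
  fk <- function(th, ph) l1 * exp(1i * th) + l2 * exp(1i * ph)
  start <- fk(theta0, phi0)
  vapply(angles, function(a) {
    tgt <- start + radius * exp(1i * a * pi / 180)
    sol <- oracle_ik(tgt, l1, l2)
    dth <- sol$theta - (theta0 + theta_e)
    dph <- sol$phi - (phi0 + phi_e)
    ex <- fk(theta0 + dth, phi0 + dph)
    oracle_wrap(oracle_deg(ex - start) - a)
  }, numeric(1))
}

# Oracle prediction for any model spec on a layout (angular + radial).
oracle_predict <- function(spec, layout, angles = layout$target_angles) {
  p <- spec$params
  switch(spec$model_id,
    TG = list(angular = oracle_tg(angles, p$a, p$b), radial = NULL),
    PV = oracle_pv(angles, layout$radius, p$x_e, p$y_e),
    PJ = list(angular = oracle_pj(angles, layout$radius, p$theta0, p$phi0,
                                  p$theta_e, p$phi_e, p$l1, p$l2),
              radial = NULL),
    TR = oracle_tr(angles, layout, p$x_e, p$y_e, p$x_r, p$y_r),
    TGD = oracle_tgd(angles, layout$radius, layout$start, p$k, p$c),
    `PV+TG` = {
      r <- oracle_pv(angles, layout$radius, p$pv$x_e, p$pv$y_e)
      r$angular <- r$angular + oracle_tg(angles, p$tg$a, p$tg$b)
      r
    },
    `PJ+TG` = list(
      angular = oracle_pj(angles, layout$radius, p$pj$theta0, p$pj$phi0,
                          p$pj$theta_e, p$pj$phi_e, p$pj$l1, p$pj$l2) +
        oracle_tg(angles, p$tg$a, p$tg$b),
      radial = NULL),
    `TR+TG` = oracle_tr(angles, layout, p$tr$x_e, p$tr$y_e, p$tr$x_r,
                        p$tr$y_r, tg = p$tg),
    `TR+TGD` = oracle_tr(angles, layout, p$tr$x_e, p$tr$y_e, p$tr$x_r,
                         p$tr$y_r, tgd = p$tgd)
  )
}

# One random, always-feasible parameter/layout draw for a model id.
random_draw <- function(id) {
  n <- sample(c(8, 12, 16, 24), 1)
  radius <- stats::runif(1, 5, 10)
  scenario <- "visible"
  perturb <- c(0, 0)
  if (grepl("TR", id)) {
    scenario <- sample(c("visible", "hidden", "perturbed"), 1)
    if (scenario == "perturbed") perturb <- stats::runif(2, -2, 2)
  }
  dim <- if (grepl("TGD", id)) "angle_extent" else "angle"
  layout <- make_layout(n, radius, start_visibility = scenario,
                        start_perturbation = perturb, dimension = dim)
  rp <- function(lo, hi) stats::runif(1, lo, hi)
  base <- list(
    TG = list(a = rp(3, 40), b = rp(-10, 10)),
    PV = list(x_e = rp(-3, 3), y_e = rp(-3, 3)),
    PJ = {
      theta0 <- rp(30, 60) * pi / 180
      gamma0 <- rp(75, 110) * pi / 180
      list(theta0 = theta0, phi0 = theta0 + gamma0,
           theta_e = rp(-5, 5) * pi / 180, phi_e = rp(-5, 5) * pi / 180,
           l1 = 24, l2 = 24)
    },
    TR = list(x_e = rp(-0.1, 0.1), y_e = rp(-0.1, 0.1),
              x_r = rp(-30, 30), y_r = rp(-50, -10)),
    TGD = list(k = rp(-0.3, 0.3), c = rp(-2, 2))
  )
  comp <- strsplit(id, "+", fixed = TRUE)[[1]]
  params <- if (length(comp) == 1) base[[id]] else
    stats::setNames(base[comp], tolower(comp))
  list(spec = model_spec(id, params), layout = layout)
}
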