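test_that("target bias is zero on the axes and piecewise linear between", {
  expect_equal(target_bias(45, 10, 5), 0)
  expect_equal(target_bias(10, 10, 5), 5)
  expect_equal(target_bias(20, 10, 5), 5 - 10 * 5 / 35)
  expect_equal(target_bias(c(0, 90, 180, 270), 10, 5), rep(0, 4))
  # sign flips at the cardinals: attraction toward the diagonals
  expect_equal(target_bias(80, 10, 5), -5)
  expect_error(target_bias(10, 45, 5), "\\(0, 45\\)")
  expect_error(target_bias(10, 0, 5), "\\(0, 45\\)")
})

test_that("biased_target_position rotates about the start, radius preserved", {
  tgt <- 8 * c(cos(45 * pi / 180), sin(45 * pi / 180))
  expect_equal(biased_target_position(tgt, c(0, 0), 10, 5), tgt)
  expect_equal(biased_target_position(c(8, 0), c(0, 0), 10, 5), c(8, 0))
  out <- biased_target_position(8 * c(cos(20 * pi / 180), sin(20 * pi / 180)),
                                c(0, 0), 10, 5)
  expect_equal(sqrt(sum(out^2)), 8)
  expect_equal(atan2(out[2], out[1]) * 180 / pi, 20 + (5 - 10 * 5 / 35))
  expect_error(biased_target_position(c(0, 0), c(0, 0), 10, 5), "coincides")
})

test_that("vector proprioceptive bias matches the planning geometry", {
  lay <- make_layout(4, 8)
  expect_equal(vector_prop_bias(lay, 0, 0)$angular_bias_deg, rep(0, 4))
  b <- vector_prop_bias(lay, 1, 0)
  # rightward misperception biases the 90-degree reach counterclockwise
  expect_equal(b$angular_bias_deg[b$angle_deg == 90],
               atan2(8, -1) * 180 / pi - 90)
  # and produces a pure 1 cm undershoot at the 0-degree target
  expect_equal(b$angular_bias_deg[b$angle_deg == 0], 0)
  expect_equal(b$radial_bias_cm[b$angle_deg == 0], -1)
})

test_that("inverse kinematics recovers the admissible posture", {
  sol <- inverse_kinematics(c(0, 24 * sqrt(2)))
  expect_equal(sol$theta, pi / 4)
  expect_equal(sol$phi, 3 * pi / 4)
  expect_error(inverse_kinematics(c(0, 60)), "unreachable")
  expect_error(inverse_kinematics(c(0, 48)), "admissible|unreachable")
  set.seed(4)
  for (i in 1:100) {
    th <- runif(1, 0.2, 1.2)
    ph <- th + runif(1, 0.5, 1.8)
    if (ph >= pi - 0.01) next
    p <- forward_kinematics(th, ph)
    sol <- inverse_kinematics(as.numeric(p))
    expect_equal(sol$theta, th, tolerance = 1e-9)
    expect_equal(sol$phi, ph, tolerance = 1e-9)
    expect_equal(as.numeric(forward_kinematics(sol$theta, sol$phi)),
                 as.numeric(p), tolerance = 1e-9)
  }
})

test_that("joint proprioceptive bias vanishes with veridical perception", {
  lay <- make_layout(24, 8)
  b0 <- joint_prop_bias(lay, 50 * pi / 180, 120 * pi / 180, 0, 0)
  expect_equal(b0$angular_bias_deg, rep(0, 24))
  b <- joint_prop_bias(lay, 50 * pi / 180, 120 * pi / 180, 2 * pi / 180, 0)
  expect_false(all(b$angular_bias_deg == 0))
  dense <- predict_bias(canonical_spec("PJ"), make_layout(360, 8))
  expect_equal(count_peaks(dense), 1)
})

test_that("transformation error vector scales with distance to the reference", {
  expect_equal(transform_error_vector(c(3, -4), 0.1, 0.2, 3, -4),
               cbind(0, 0))
  expect_equal(transform_error_vector(c(0, 0), -0.05, -0.05, 3, -4),
               cbind(-0.25, -0.25))
  p <- matrix(rnorm(20), ncol = 2)
  expect_equal(transform_error_vector(p, 0.2, -0.1, 5, 5),
               2 * transform_error_vector(p, 0.1, -0.05, 5, 5))
})

test_that("transformation bias scenarios: visible, hidden, perturbed", {
  for (vis in c("visible", "hidden")) {
    lay <- make_layout(8, 8, start_visibility = vis)
    expect_equal(transformation_bias(lay, 0, 0, 10, -30)$angular_bias_deg,
                 rep(0, 8))
  }
  layp <- make_layout(4, 8, start_visibility = "perturbed",
                      start_perturbation = c(1, 0))
  bp <- transformation_bias(layp, 0, 0, 10, -30)
  expect_equal(bp$angular_bias_deg[bp$angle_deg == 90],
               atan2(8, -1) * 180 / pi - 90)
  grid <- seq(0, 359, 1)
  vis_lay <- make_layout(360, 8, target_angles = grid)
  hid_lay <- make_layout(360, 8, target_angles = grid,
                         start_visibility = "hidden")
  expect_equal(count_peaks(transformation_bias(vis_lay, -0.05, -0.05, 10, -30)), 2)
  expect_equal(count_peaks(transformation_bias(hid_lay, -0.05, -0.05, 10, -30)), 1)
})

test_that("depth bias distorts only the y coordinate", {
  expect_equal(depth_bias_point(c(3, 7), 0, 0), c(3, 7))
  expect_equal(depth_bias_point(c(0, 10), 0.1, 0.5), c(0, 11.5))
  expect_equal(depth_bias_point(c(5, 0), 0.3, 1), c(5, 1))
})

test_that("hybrid predictions add or compose their components", {
  lay <- make_layout(24, 8)
  zero <- model_spec("PV+TG", list(pv = list(x_e = 0, y_e = 0),
                                   tg = list(a = 10, b = 0)))
  expect_equal(predict_bias(zero, lay)$angular_bias_deg, rep(0, 24))
  pvtg <- model_spec("PV+TG", list(pv = list(x_e = 1.5, y_e = -1),
                                   tg = list(a = 10, b = 5)))
  expect_equal(predict_bias(pvtg, lay)$angular_bias_deg,
               predict_bias(canonical_spec("PV"), lay)$angular_bias_deg +
                 predict_bias(canonical_spec("TG"), lay)$angular_bias_deg)
  trtg0 <- model_spec("TR+TG", list(tr = canonical_spec("TR")$params,
                                    tg = list(a = 10, b = 0)))
  expect_equal(predict_bias(trtg0, lay), predict_bias(canonical_spec("TR"), lay))
  expect_error(predict_bias(canonical_spec("TGD"), lay), "angle_extent")
  expect_error(predict_bias(canonical_spec("PJ"),
                            make_layout(12, 10, dimension = "angle_extent")),
               "extent")
})

test_that("count_peaks detects prominent circular maxima", {
  g <- seq(0, 359, 1)
  expect_equal(count_peaks(sin(g * pi / 180)), 1)
  expect_equal(count_peaks(sin(2 * g * pi / 180)), 2)
  expect_equal(count_peaks(bias_function(g, target_bias(g, 10, 5))), 4)
  expect_equal(count_peaks(rep(1, 360)), 0)
  # low-prominence ripple on a dominant peak is discarded
  ripple <- sin(g * pi / 180) + 0.01 * sin(8 * g * pi / 180)
  expect_equal(count_peaks(ripple), 1)
  expect_error(count_peaks(bias_function(c(0, 1, 2, 4, 8, 16, 32, 64),
                                         rnorm(8))), "uniform")
})

test_that("error map has fixed direction and distance-scaled magnitude", {
  grid <- as.matrix(expand.grid(x = seq(-10, 10, 5), y = seq(-10, 10, 5)))
  em0 <- error_map(grid, 0, 0, 10, -30)
  expect_true(all(em0$tx == 0 & em0$ty == 0))
  em <- error_map(grid, -0.05, -0.05, 10, -30)
  d <- sqrt((grid[, 1] - 10)^2 + (grid[, 2] + 30)^2)
  expect_equal(sqrt(em$tx^2 + em$ty^2), d * sqrt(2) * 0.05)
  expect_equal(atan2(em$ty, em$tx), rep(atan2(-1, -1), nrow(grid)))
})

test_that("hand symmetry: mirrored parameters on the mirrored layout mirror the bias", {
  set.seed(5)
  for (id in model_ids()) {
    draw <- random_draw(id)
    b <- tryCatch(predict_bias(draw$spec, draw$layout), error = function(e) NULL)
    if (is.null(b)) next
    b_l <- predict_bias(mirror_spec(draw$spec), mirror_layout(draw$layout))
    expect_equal(b_l$angular_bias_deg, mirror_bias(b)$angular_bias_deg,
                 tolerance = 1e-9, info = id)
  }
})

test_that("closed-form predictions agree with the geometric oracle", {
  set.seed(6)
  n_checked <- 0
  for (i in 1:150) {
    id <- sample(model_ids(), 1)
    for (try in 1:50) {
      draw <- random_draw(id)
      b <- tryCatch(predict_bias(draw$spec, draw$layout),
                    error = function(e) NULL)
      if (!is.null(b)) break
    }
    expect_false(is.null(b))
    o <- oracle_predict(draw$spec, draw$layout)
    expect_equal(b$angular_bias_deg, o$angular, tolerance = 1e-9, info = id)
    if (!is.null(o$radial) && "radial_bias_cm" %in% names(b)) {
      expect_equal(b$radial_bias_cm, o$radial, tolerance = 1e-9, info = id)
    }
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 150)
})
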