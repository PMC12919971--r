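trials_from_errors <- function(errors, pid = "P001", target = 0) {
  data.frame(participant_id = pid, target_angle = target, target_radius = 8,
             reach_angle = (target + errors) %% 360)
}

test_that("outlier filter drops only trials beyond the per-participant 3-SD band", {
  # with five trials a single extreme value never exceeds 3 SD of all five
  tt <- trials_from_errors(c(0, 0, 0, 0, 100))
  res <- remove_outliers(tt)
  expect_equal(res$n_removed, 0)
  # in a larger sample the same extreme value is removed
  tt2 <- trials_from_errors(c(rnorm(40, 0, 1), 100))
  res2 <- remove_outliers(tt2)
  expect_equal(res2$n_removed, 1)
  expect_equal(res2$trials$reach_angle, tt2$reach_angle[1:40])
  # degenerate zero-SD participant loses nothing
  res3 <- remove_outliers(trials_from_errors(rep(2, 10)))
  expect_equal(res3$n_removed, 0)
  # per-participant report is kept
  expect_named(res3$report, c("participant_id", "n_trials", "n_removed"))
})

test_that("Gaussian cohorts lose well under 0.5% of trials to the filter", {
  lay <- make_layout(24, 8)
  cfg <- cohort_config(30, lay, 4, canonical_spec("TR+TG"),
                       motor_noise_sd = 4, seed = 71)
  res <- remove_outliers(generate_cohort(cfg))
  expect_lt(res$fraction_removed, 0.005)
})

test_that("noise ceiling follows the split-half formula and is monotone", {
  expect_equal(noise_ceiling(1), 1)
  expect_equal(noise_ceiling(0.5), sqrt(2 / 3))
  expect_equal(noise_ceiling(0.8), sqrt(2 / 2.25))
  expect_error(noise_ceiling(0), "nonzero")
  r <- seq(0.01, 1, length.out = 100)
  expect_true(all(diff(noise_ceiling(r)) > 0))
  expect_equal(noise_ceiling(-0.5), noise_ceiling(0.5))
})

test_that("split-half reliability: perfect for clones, near zero for noise", {
  lay <- make_layout(8, 8)
  pred <- predict_bias(canonical_spec("TR+TG"), lay)$angular_bias_deg
  clones <- do.call(rbind, lapply(1:6, function(j) {
    data.frame(participant_id = sprintf("P%03d", j),
               target_angle = lay$target_angles, target_radius = 8,
               reach_angle = (lay$target_angles + pred) %% 360)
  }))
  expect_equal(split_half(clones, n_boot = 50, seed = 1), 1)
  lay24 <- make_layout(24, 8)
  set.seed(8)
  noise <- do.call(rbind, lapply(1:60, function(j) {
    data.frame(participant_id = sprintf("P%03d", j),
               target_angle = lay24$target_angles, target_radius = 8,
               reach_angle = (lay24$target_angles + rnorm(24, 0, 4)) %% 360)
  }))
  expect_lt(abs(split_half(noise, n_boot = 400, seed = 2)), 0.25)
  expect_error(split_half(clones[clones$participant_id %in%
                                   c("P001", "P002"), ]), ">= 4")
})

test_that("split-half is invariant to participant relabeling", {
  lay <- make_layout(8, 8)
  cfg <- cohort_config(10, lay, 3, canonical_spec("TR+TG"),
                       motor_noise_sd = 4, seed = 81)
  tt <- generate_cohort(cfg)
  r1 <- split_half(tt, n_boot = 100, seed = 3)
  relabeled <- tt
  ids <- unique(tt$participant_id)
  new_ids <- setNames(sprintf("Q%03d", seq_along(ids)), ids)
  relabeled$participant_id <- new_ids[tt$participant_id]
  expect_equal(split_half(relabeled, n_boot = 100, seed = 3), r1)
  expect_true(r1 > 0 && r1 < 1)
})

test_that("normalized correlation divides by the smaller ceiling", {
  lay <- make_layout(24, 8)
  f1 <- predict_bias(canonical_spec("TR+TG"), lay)
  expect_equal(normalized_correlation(f1, f1, 1, 1), 1)
  f2 <- bias_function(f1$angle_deg, -f1$angular_bias_deg)
  expect_equal(normalized_correlation(f1, f2, 0.9, 0.8), -1 / 0.8)
  f3 <- predict_bias(canonical_spec("TR+TG"), make_layout(8, 8))
  expect_error(normalized_correlation(f1, f3, 1, 1), "grid")
})

test_that("within-participant similarity exceeds between-participant similarity", {
  lay <- make_layout(24, 8)
  cfg <- cohort_config(
    12, lay, 4, canonical_spec("TR+TG"), motor_noise_sd = 3,
    blocks = list(list(label = "no_feedback", feedback = FALSE),
                  list(label = "feedback", feedback = TRUE)), seed = 91)
  tt <- generate_cohort(cfg)
  mats <- lapply(split(tt, tt$block), reachbias:::bias_matrix)
  nf <- mats$no_feedback
  fb <- mats$feedback
  within <- mean(sapply(rownames(nf), function(p) cor(nf[p, ], fb[p, ])))
  between <- mean(sapply(rownames(nf), function(p) {
    mean(sapply(setdiff(rownames(fb), p), function(q) cor(nf[p, ], fb[q, ])))
  }))
  expect_gt(within, between)
})

test_that("mirror RMSE identifies mirrored bias structure across hands", {
  lay <- make_layout(8, 8)
  gen <- canonical_spec("TR+TG")
  right <- generate_cohort(cohort_config(10, lay, 4, gen, motor_noise_sd = 0,
                                         param_jitter = rep(0, 6), seed = 1))
  left_lay <- mirror_layout(lay)
  left <- generate_cohort(cohort_config(10, left_lay, 4, mirror_spec(gen),
                                        motor_noise_sd = 0,
                                        param_jitter = rep(0, 6), seed = 2))
  res <- mirror_rmse(left, right)
  expect_equal(max(res$per_participant$rmse_mirrored), 0, tolerance = 1e-9)
  expect_gt(min(res$per_participant$rmse_original), 0)
  expect_equal(res$df, nrow(res$per_participant) * 2 - 2)

  # a mirror-symmetric bias source (pure target bias) shows no mirror
  # advantage: the two hands' maps superimpose
  tg <- canonical_spec("TG")
  r_tg <- generate_cohort(cohort_config(10, lay, 4, tg, motor_noise_sd = 0,
                                        param_jitter = rep(0, 2), seed = 3))
  l_tg <- generate_cohort(cohort_config(10, left_lay, 4, tg, motor_noise_sd = 0,
                                        param_jitter = rep(0, 2), seed = 3))
  res0 <- mirror_rmse(l_tg, r_tg)
  expect_equal(res0$mean_diff, 0, tolerance = 1e-9)

  # noisy mirrored cohorts: positive mean difference and t > 0
  rightn <- generate_cohort(cohort_config(12, lay, 4, gen, motor_noise_sd = 3,
                                          seed = 4))
  leftn <- generate_cohort(cohort_config(12, left_lay, 4, mirror_spec(gen),
                                         motor_noise_sd = 3, seed = 5))
  resn <- mirror_rmse(leftn, rightn)
  expect_gt(resn$mean_diff, 0)
  expect_gt(resn$t_stat, 0)
})
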