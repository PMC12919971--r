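# Reliability statistics for motor-bias functions: outlier filtering,
# split-half noise ceiling, ceiling-normalized correlations, and the
# mirror-RMSE comparison of left- and right-hand bias maps.

#' Remove per-participant 3-SD outlier trials
#'
#' Single pass: for each participant, trials whose angular error deviates
#' from that participant's mean error by more than three sample standard
#' deviations are dropped. A zero-SD participant (all errors equal) loses no
#' trials. Re-running the filter on already-filtered data may remove more
#' trials; the filter is deliberately not iterated.
#'
#' @param trials Trial table.
#' @param n_sd Cutoff in standard deviations (default 3).
#' @return A list with the filtered `trials`, the overall `fraction_removed`,
#'   `n_removed`, and a per-participant `report` data.frame.
#' @export
remove_outliers <- function(trials, n_sd = 3) {
  keep <- rep(TRUE, nrow(trials))
  err <- trial_angular_error(trials)
  parts <- unique(trials$participant_id)
  report <- data.frame(participant_id = parts, n_trials = NA_integer_,
                       n_removed = NA_integer_)
  for (j in seq_along(parts)) {
    sel <- which(trials$participant_id == parts[j])
    if (length(sel) < 2) {
      report$n_trials[j] <- length(sel)
      report$n_removed[j] <- 0L
      next
    }
    e <- err[sel]
    s <- stats::sd(e)
    drop <- if (s > 0) abs(e - mean(e)) > n_sd * s else rep(FALSE, length(e))
    keep[sel[drop]] <- FALSE
    report$n_trials[j] <- length(sel)
    report$n_removed[j] <- sum(drop)
  }
  list(trials = trials[keep, , drop = FALSE],
       n_removed = sum(!keep),
       fraction_removed = mean(!keep),
       report = report)
}

#' Noise ceiling from a split-half correlation
#'
#' The maximal correlation attainable against the true underlying bias
#' function given finite measurement reliability:
#' `r_max = sqrt(2 / (1 + sqrt(1 / r_half^2)))`.
#'
#' @param r_half Split-half correlation (nonzero).
#' @return The ceiling `r_max` in `(0, 1]`.
#' @examples
#' noise_ceiling(0.5)  # sqrt(2/3) = 0.8165
#' @export
noise_ceiling <- function(r_half) {
  if (any(r_half == 0)) stop("`r_half` must be nonzero", call. = FALSE)
  sqrt(2 / (1 + sqrt(1 / r_half^2)))
}

# participant x target matrix of per-target mean angular errors
bias_matrix <- function(trials) {
  parts <- unique(trials$participant_id)
  angr <- round(trials$target_angle %% 360, 6)
  ang <- sort(unique(angr))
  err <- trial_angular_error(trials)
  mat <- t(vapply(parts, function(p) {
    sel <- trials$participant_id == p
    vapply(ang, function(a) mean(err[sel & angr == a]), numeric(1))
  }, numeric(length(ang))))
  rownames(mat) <- parts
  colnames(mat) <- ang
  mat
}

#' Bootstrapped split-half reliability of the group bias function
#'
#' Participants are repeatedly split into random halves; each half's
#' group-mean bias function is computed over the common target grid, and the
#' two are correlated (Pearson). The returned `r_half` is the mean over
#' bootstrap splits (odd cohorts split floor/ceil).
#'
#' @param trials Trial table with >= 4 participants on a shared target grid.
#' @param n_boot Number of random splits (default 2000).
#' @param seed Integer seed.
#' @return Mean split-half correlation.
#' @export
split_half <- function(trials, n_boot = 2000, seed = 1) {
  mat <- bias_matrix(trials)
  n <- nrow(mat)
  if (n < 4) stop("need >= 4 participants", call. = FALSE)
  if (any(!is.finite(mat))) {
    stop("every participant must have trials at every target", call. = FALSE)
  }
  n1 <- floor(n / 2)
  with_local_seed(seed, {
    mean(vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n)
      f1 <- colMeans(mat[idx[seq_len(n1)], , drop = FALSE])
      f2 <- colMeans(mat[idx[seq(n1 + 1, n)], , drop = FALSE])
      if (stats::sd(f1) == 0 || stats::sd(f2) == 0) return(NA_real_)
      stats::cor(f1, f2)
    }, numeric(1)), na.rm = TRUE)
  })
}

#' Ceiling-normalized correlation of two bias functions
#'
#' Pearson correlation between the functions divided by the smaller of the
#' two conditions' noise ceilings. Values may exceed 1 under sampling noise.
#'
#' @param f1,f2 `bias_fn` objects on a common target grid.
#' @param r_max_1,r_max_2 Noise ceilings of the two conditions
#'   (see [noise_ceiling()]).
#' @return `r_norm = cor(f1, f2) / min(r_max_1, r_max_2)`.
#' @export
normalized_correlation <- function(f1, f2, r_max_1, r_max_2) {
  if (!isTRUE(all.equal(f1$angle_deg, f2$angle_deg))) {
    stop("bias functions must share the same target grid", call. = FALSE)
  }
  stats::cor(f1$angular_bias_deg, f2$angular_bias_deg) / min(r_max_1, r_max_2)
}

#' Mirror-RMSE comparison of left- and right-hand bias maps
#'
#' If the bias map reflects body-centered (proprioceptive or transformation)
#' error sources, the left-hand map should be the mirror image of the
#' right-hand map across the vertical meridian. Each participant's bias
#' function is compared (RMSE) against the opposite hand's group-mean map,
#' both as-is and mirror-reversed; a positive difference
#' (original - mirrored) indicates better alignment after mirroring. The test
#' statistic is a pooled-variance two-sample t comparing the original against
#' the mirrored RMSEs across the pooled participants.
#'
#' @param left,right Trial tables for left- and right-hand cohorts sharing a
#'   target grid (the grid must be closed under the reflection
#'   `alpha -> 180 - alpha`).
#' @return A list with the `per_participant` RMSE pairs, `mean_diff`,
#'   `t_stat`, `df` and `p_value`.
#' @export
mirror_rmse <- function(left, right) {
  mat_l <- bias_matrix(left)
  mat_r <- bias_matrix(right)
  if (!identical(colnames(mat_l), colnames(mat_r))) {
    stop("left and right cohorts must share the target grid", call. = FALSE)
  }
  ang <- as.numeric(colnames(mat_l))
  mirror_map <- function(values) {
    b <- mirror_bias(bias_function(ang, values))
    if (!isTRUE(all.equal(b$angle_deg, ang))) {
      stop("target grid is not closed under mirroring", call. = FALSE)
    }
    b$angular_bias_deg
  }
  group_l <- colMeans(mat_l)
  group_r <- colMeans(mat_r)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  one_side <- function(mat, opp_map, hand) {
    data.frame(
      participant_id = rownames(mat), hand = hand,
      rmse_original = apply(mat, 1, rmse, b = opp_map),
      rmse_mirrored = apply(mat, 1, rmse, b = mirror_map(opp_map)),
      row.names = NULL
    )
  }
  per <- rbind(one_side(mat_r, group_l, "right"),
               one_side(mat_l, group_r, "left"))
  per$diff <- per$rmse_original - per$rmse_mirrored
  # pooled-variance two-sample t, tolerant of degenerate (constant) samples
  x <- per$rmse_original
  y <- per$rmse_mirrored
  n <- length(x)
  df <- 2 * n - 2
  se <- sqrt((stats::var(x) + stats::var(y)) / n)
  delta <- mean(x) - mean(y)
  t_stat <- if (se > 0) delta / se else if (delta != 0) Inf * sign(delta)
            else NA_real_
  p <- if (is.na(t_stat)) NA_real_ else 2 * stats::pt(-abs(t_stat), df)
  list(per_participant = per,
       mean_diff = mean(per$diff),
       t_stat = t_stat,
       df = df,
       p_value = p)
}
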