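# Circular statistics: circular mean, mean resultant length, angular
# deviation, and a label-shuffling permutation test for differences between
# two groups of angles.

#' Circular mean of angles
#'
#' Angle of the mean unit vector, wrapped to (-180, 180]. When the resultant
#' is (numerically) zero the mean direction is undefined and `NA` is
#' returned.
#'
#' @param angles angles in degrees.
#' @param na.rm drop `NA` angles first (default TRUE).
#' @return circular mean in degrees, or `NA`.
#' @examples
#' circular_mean(c(10, 350))  # 0
#' @export
circular_mean <- function(angles, na.rm = TRUE) {
  if (na.rm) angles <- angles[!is.na(angles)]
  if (length(angles) == 0L) return(NA_real_)
  rad <- angles * pi / 180
  cx <- mean(cos(rad))
  sx <- mean(sin(rad))
  if (sqrt(cx^2 + sx^2) < 1e-12) return(NA_real_)
  wrap_angle(atan2(sx, cx) * 180 / pi)
}

#' Mean resultant length
#'
#' Length of the average unit vector: 1 for perfectly concentrated angles,
#' 0 for angles balanced around the circle.
#'
#' @inheritParams circular_mean
#' @return value in [0, 1].
#' @export
resultant_length <- function(angles, na.rm = TRUE) {
  if (na.rm) angles <- angles[!is.na(angles)]
  if (length(angles) == 0L) return(NA_real_)
  rad <- angles * pi / 180
  min(1, sqrt(mean(cos(rad))^2 + mean(sin(rad))^2))
}

#' Angular deviation
#'
#' The circular spread measure sqrt(2 * (1 - Rbar)), bounded between 0
#' (all angles identical) and sqrt(2) (angles spread evenly around the
#' circle).
#'
#' @inheritParams circular_mean
#' @return value in [0, sqrt(2)].
#' @export
angular_deviation <- function(angles, na.rm = TRUE) {
  sqrt(2 * (1 - resultant_length(angles, na.rm = na.rm)))
}

#' Circular summary of a sample of angles
#'
#' @inheritParams circular_mean
#' @return object of class `circular_summary`: list with `n`, `circ_mean`,
#'   `resultant_length`, `angular_deviation`.
#' @export
circular_summary <- function(angles, na.rm = TRUE) {
  if (na.rm) angles <- angles[!is.na(angles)]
  structure(list(n = length(angles),
                 circ_mean = circular_mean(angles, na.rm = FALSE),
                 resultant_length = resultant_length(angles, na.rm = FALSE),
                 angular_deviation = angular_deviation(angles, na.rm = FALSE)),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf("n = %d, circular mean = %.2f deg, Rbar = %.3f, angular deviation = %.3f\n",
              x$n, x$circ_mean, x$resultant_length, x$angular_deviation))
  invisible(x)
}

circ_mean_diff <- function(a, b) {
  ma <- circular_mean(a)
  mb <- circular_mean(b)
  if (is.na(ma) || is.na(mb)) return(NA_real_)
  wrap_angle(ma - mb)
}

#' Permutation test for two groups of angles
#'
#' Tests whether the circular mean and the angular deviation differ between
#' two groups by randomly reassigning group labels (preserving group sizes)
#' `n_perm` times. For each shuffle the circular-mean difference (wrapped to
#' (-180, 180]) and the angular-deviation difference are computed; two-sided
#' p-values are the proportion of null draws at least as extreme (in
#' absolute value) as the observed statistic, with the add-one convention
#' (#extreme + 1) / (n_perm + 1) so p is never exactly 0. Null draws whose
#' circular mean is undefined (zero resultant) count as extreme for the mean
#' statistic.
#'
#' @param group_a,group_b angles in degrees (each n >= 2).
#' @param n_perm number of shuffles (default 10000).
#' @param seed integer RNG seed for the shuffles.
#' @return object of class `permutation_result`: list with
#'   `observed_mean_diff`, `observed_dev_diff`, `n_perm`, `p_mean`, `p_dev`,
#'   `seed`.
#' @export
permutation_test <- function(group_a, group_b, n_perm = 10000L,
                             seed = NULL) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop_fc("each group needs at least 2 angles")
  obs_mean <- circ_mean_diff(group_a, group_b)
  obs_dev <- angular_deviation(group_a) - angular_deviation(group_b)
  # Sorting the pooled sample makes the null draws depend only on the pooled
  # multiset, so swapping equally sized groups reproduces the p-values
  # bit-exactly under the same seed.
  pooled <- sort(c(group_a, group_b))
  na <- length(group_a)
  n <- length(pooled)
  with_seed(seed, {
    null_mean <- numeric(n_perm)
    null_dev <- numeric(n_perm)
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n, na)
      a <- pooled[idx]
      b <- pooled[-idx]
      null_mean[i] <- circ_mean_diff(a, b)
      null_dev[i] <- angular_deviation(a) - angular_deviation(b)
    }
    p_of <- function(null, obs) {
      if (is.na(obs)) return(NA_real_)
      extreme <- is.na(null) | abs(null) >= abs(obs)
      (sum(extreme) + 1) / (n_perm + 1)
    }
    structure(list(observed_mean_diff = obs_mean,
                   observed_dev_diff = obs_dev,
                   n_perm = as.integer(n_perm),
                   p_mean = p_of(null_mean, obs_mean),
                   p_dev = p_of(null_dev, obs_dev),
                   seed = seed),
              class = "permutation_result")
  })
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%d shuffles)\n", x$n_perm))
  cat(sprintf("  circular-mean diff: %.2f deg, p = %.4f\n",
              x$observed_mean_diff, x$p_mean))
  cat(sprintf("  angular-dev diff:   %.3f, p = %.4f\n",
              x$observed_dev_diff, x$p_dev))
  invisible(x)
}
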