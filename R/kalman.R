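#' Constant-velocity Kalman filter on (cx, cy, a, h)
#'
#' The motion model used by the tracker: an 8-dimensional state
#' `(cx, cy, a, h, vcx, vcy, va, vh)` with `a = w/h` the aspect ratio, a
#' constant-velocity transition with dt = 1 frame, and direct observation of
#' the first four components. Noise scales follow the de-facto DeepSORT
#' convention: position standard deviations weighted by 1/20 of the box
#' height, velocity standard deviations by 1/160.
#'
#' @name kalman
NULL

KF_STD_POS <- 1 / 20
KF_STD_VEL <- 1 / 160

kf_F <- function() {
  F <- diag(8)
  F[cbind(1:4, 5:8)] <- 1
  F
}
KF_H <- cbind(diag(4), matrix(0, 4, 4))

box_to_meas <- function(b) {
  b <- as_box(b)
  c(b[["cx"]], b[["cy"]], b[["w"]] / b[["h"]], b[["h"]])
}

meas_to_box <- function(z) {
  box(z[1L], z[2L], z[3L] * z[4L], z[4L])
}

#' Initialize a Kalman state from a detection box
#'
#' Position components copy the measurement, velocities start at zero, and
#' the initial covariance is diagonal with standard deviations scaled by the
#' box height.
#'
#' @param b Detection box (center form).
#' @return List of class `kalman_state` with `mean` (length 8) and `cov`
#'   (8x8 symmetric positive-semidefinite matrix).
#' @export
kf_initiate <- function(b) {
  z <- box_to_meas(b)
  h <- z[4L]
  std <- c(2 * KF_STD_POS * h, 2 * KF_STD_POS * h, 1e-2, 2 * KF_STD_POS * h,
           10 * KF_STD_VEL * h, 10 * KF_STD_VEL * h, 1e-5, 10 * KF_STD_VEL * h)
  structure(list(mean = c(z, 0, 0, 0, 0), cov = diag(std^2)),
            class = "kalman_state")
}

#' Kalman prediction step (one frame)
#'
#' Advances position by velocity and inflates the covariance with
#' height-scaled process noise; the covariance trace never decreases.
#'
#' @param s A `kalman_state`.
#' @return Predicted `kalman_state`.
#' @export
kf_predict <- function(s) {
  h <- s$mean[4L]
  std <- c(KF_STD_POS * h, KF_STD_POS * h, 1e-2, KF_STD_POS * h,
           KF_STD_VEL * h, KF_STD_VEL * h, 1e-5, KF_STD_VEL * h)
  F <- kf_F()
  mean <- as.numeric(F %*% s$mean)
  cov <- F %*% s$cov %*% t(F) + diag(std^2)
  structure(list(mean = mean, cov = sym(cov)), class = "kalman_state")
}

sym <- function(M) (M + t(M)) / 2

# Project state onto measurement space; returns innovation covariance too.
kf_project <- function(s) {
  h <- s$mean[4L]
  std <- c(KF_STD_POS * h, KF_STD_POS * h, 1e-1, KF_STD_POS * h)
  mean <- as.numeric(KF_H %*% s$mean)
  S <- KF_H %*% s$cov %*% t(KF_H) + diag(std^2)
  list(mean = mean, S = sym(S))
}

#' Kalman correction step
#'
#' Standard linear update against a measured box `(cx, cy, a, h)`.
#'
#' @param s A `kalman_state` (typically after [kf_predict()]).
#' @param b Measured box.
#' @return Posterior `kalman_state`.
#' @export
kf_update <- function(s, b) {
  z <- box_to_meas(b)
  proj <- kf_project(s)
  K <- t(solve(proj$S, KF_H %*% s$cov))     # 8 x 4 Kalman gain
  innov <- z - proj$mean
  mean <- s$mean + as.numeric(K %*% innov)
  cov <- s$cov - K %*% proj$S %*% t(K)
  structure(list(mean = mean, cov = sym(cov)), class = "kalman_state")
}

#' Squared Mahalanobis distance of boxes to a predicted state
#'
#' Gating distance in the `(cx, cy, a, h)` measurement space under the
#' innovation covariance; used to exclude implausible track-detection pairs
#' (chi-square gating, 4 degrees of freedom).
#'
#' @param s A predicted `kalman_state`.
#' @param boxes Matrix/data.frame of boxes (columns `cx, cy, w, h`).
#' @return Numeric vector of squared distances.
#' @export
kf_gating_distance <- function(s, boxes) {
  B <- box_mat(boxes)
  proj <- kf_project(s)
  Z <- cbind(B[, 1L], B[, 2L], B[, 3L] / B[, 4L], B[, 4L])
  D <- sweep(Z, 2L, proj$mean)
  # d^2 = diag(D S^-1 D')
  rowSums(D * t(solve(proj$S, t(D))))
}

#' Extract the box implied by a Kalman state
#'
#' @param s A `kalman_state`.
#' @return A [box()].
#' @export
kf_box <- function(s) {
  z <- s$mean[1:4]
  # aspect or height can be driven non-positive by an extreme update; floor
  # them so downstream geometry stays valid
  z[3L] <- max(z[3L], 1e-6)
  z[4L] <- max(z[4L], 1e-6)
  meas_to_box(z)
}

#' 0.95 chi-square gating threshold, 4 degrees of freedom
#' @return Scalar threshold (about 9.4877).
#' @export
chi2_gate_95 <- function() stats::qchisq(0.95, df = 4)
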