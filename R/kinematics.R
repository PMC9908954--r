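#' Leg model: joint twists and zero configuration
#'
#' Describes the three-joint (ThC, CTr, FTi) kinematic chain of the 15:1
#' scaled middle leg as a product of exponentials: unit rotation axes
#' `omega_i`, points `q_i` on each axis (mm, body frame), and the foot
#' position `q_end` at the zero configuration. At zero angles the foot frame
#' `g_st` is a pure translation to `q_end`.
#'
#' The default geometry places the ThC axis tilted 37 degrees in the y-z
#' plane and the CTr and FTi axes along +x; the body frame has x
#' anterior-posterior, y lateral (distal along the leg at zero config) and z
#' dorso-ventral.
#'
#' @param omega 3x3 matrix, rows are unit axis directions for joints 1..3.
#' @param q 3x3 matrix, rows are points on each axis, mm.
#' @param q_end foot position at zero configuration, mm.
#' @param scale linear scale factor relative to the animal (default 15).
#' @return An object of class `leg_model`.
#' @export
#' @examples
#' leg <- leg_model()
#' forward_kinematics(c(0, 0, 0), leg)$p  # the zero-configuration foot
leg_model <- function(omega = NULL, q = NULL, q_end = NULL, scale = 15) {
  a37 <- 37 * pi / 180
  if (is.null(omega))
    omega <- rbind(c(0, -sin(a37), -cos(a37)),
                   c(1, 0, 0),
                   c(1, 0, 0))
  if (is.null(q))
    q <- rbind(c(0, 61.34, 15.03),
               c(0, 93.46, 22.36),
               c(0, 230.45, -80.90))
  if (is.null(q_end)) q_end <- c(0, 362.42, -180.99)
  omega <- as.matrix(omega); q <- as.matrix(q)
  stopifnot(all(dim(omega) == c(3, 3)), all(dim(q) == c(3, 3)),
            length(q_end) == 3)
  nrm <- sqrt(rowSums(omega^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("leg_model: each omega row must be a unit vector", call. = FALSE)
  omega <- omega / nrm   # exact renormalization after, e.g., config I/O
  structure(list(omega = omega, q = q, q_end = as.numeric(q_end),
                 scale = scale),
            class = "leg_model")
}

#' @export
print.leg_model <- function(x, ...) {
  cat("3-DOF leg model (product of exponentials), scale", x$scale, ": 1\n")
  cat("zero-configuration foot position (mm):",
      paste(sprintf("%.2f", x$q_end), collapse = ", "), "\n")
  invisible(x)
}

# Rodrigues rotation about unit axis w by angle th.
.rodrigues <- function(w, th) {
  K <- matrix(c(0, w[3], -w[2],
                -w[3], 0, w[1],
                w[2], -w[1], 0), 3, 3)   # column-major: K = [w]_x
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Homogeneous exponential of a revolute twist (axis w through point q):
# x -> q + R (x - q).
.twist_exp <- function(w, q, th) {
  R <- .rodrigues(w, th)
  g <- diag(4)
  g[1:3, 1:3] <- R
  g[1:3, 4] <- q - R %*% q
  g
}

#' Forward kinematics of the leg
#'
#' Evaluates the product-of-exponentials chain
#' `g_d(theta) = exp(xi_1 theta_1) exp(xi_2 theta_2) exp(xi_3 theta_3) g_st`
#' and returns the foot pose decomposed into rotation and position.
#'
#' @param theta numeric length 3, joint angles (ThC, CTr, FTi) in radians.
#' @param leg a [leg_model()].
#' @return list with `R` (3x3 rotation), `p` (foot position, mm), and the
#'   full 4x4 homogeneous matrix `g`.
#' @export
forward_kinematics <- function(theta, leg) {
  stopifnot(inherits(leg, "leg_model"), length(theta) == 3)
  if (!all(is.finite(theta)))
    stop("forward_kinematics: angles must be finite", call. = FALSE)
  gst <- diag(4); gst[1:3, 4] <- leg$q_end
  g <- .twist_exp(leg$omega[1, ], leg$q[1, ], theta[1]) %*%
       .twist_exp(leg$omega[2, ], leg$q[2, ], theta[2]) %*%
       .twist_exp(leg$omega[3, ], leg$q[3, ], theta[3]) %*% gst
  list(R = g[1:3, 1:3], p = as.numeric(g[1:3, 4]), g = g)
}

# Position Jacobian dp/dtheta (3x3). Column i is the instantaneous foot
# velocity of joint i in the current configuration: w_i' x (p - q_i'),
# where w_i', q_i' are the axis direction and point transported by the
# preceding joint exponentials.
.leg_jacobian <- function(theta, leg) {
  g_acc <- diag(4)
  J <- matrix(0, 3, 3)
  axes <- vector("list", 3)
  for (i in 1:3) {
    Racc <- g_acc[1:3, 1:3]
    w_i <- as.numeric(Racc %*% leg$omega[i, ])
    q_i <- as.numeric(g_acc[1:3, 1:3] %*% leg$q[i, ] + g_acc[1:3, 4])
    axes[[i]] <- list(w = w_i, q = q_i)
    g_acc <- g_acc %*% .twist_exp(leg$omega[i, ], leg$q[i, ], theta[i])
  }
  p <- as.numeric(g_acc[1:3, 4] + g_acc[1:3, 1:3] %*% leg$q_end)
  for (i in 1:3) {
    w_i <- axes[[i]]$w; q_i <- axes[[i]]$q
    J[, i] <- .cross3(w_i, p - q_i)
  }
  list(J = J, p = p)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Inverse kinematics by damped Newton root finding
#'
#' Solves `p(theta) - target = 0` for the three joint angles with a damped
#' Newton iteration on the 3x3 position Jacobian (the 3-DOF chain has a
#' locally unique solution). Deterministic for a given starting guess;
#' warm-starting from a neighbouring solution makes path tracking continuous.
#'
#' @param target desired foot position, mm (length 3).
#' @param leg a [leg_model()].
#' @param guess starting joint angles, radians.
#' @param tol convergence tolerance on the position residual, mm.
#' @param maxit maximum iterations.
#' @return Joint angles (radians, length 3) with attribute `residual` (mm).
#'   Throws an error of class `cssim_unreachable` (carrying the best residual)
#'   if the iteration does not converge, e.g. for targets outside the
#'   workspace.
#' @export
inverse_kinematics <- function(target, leg, guess = c(0, 0, 0),
                               tol = 1e-9, maxit = 200L) {
  stopifnot(inherits(leg, "leg_model"), length(target) == 3)
  if (!all(is.finite(target)))
    stop("inverse_kinematics: target must be finite", call. = FALSE)
  th <- as.numeric(guess)
  lambda <- 1e-8   # Levenberg damping, raised on step rejection
  jp <- .leg_jacobian(th, leg)
  r <- jp$p - target
  best <- sqrt(sum(r^2))
  for (it in seq_len(maxit)) {
    if (best < tol) {
      return(structure(th, residual = best))
    }
    step <- tryCatch(
      solve(crossprod(jp$J) + lambda * diag(3), -crossprod(jp$J, r)),
      error = function(e) NULL)
    if (is.null(step)) { lambda <- lambda * 10; next }
    th_new <- th + as.numeric(step)
    jp_new <- .leg_jacobian(th_new, leg)
    r_new <- jp_new$p - target
    nrm_new <- sqrt(sum(r_new^2))
    if (nrm_new < best) {
      th <- th_new; jp <- jp_new; r <- r_new; best <- nrm_new
      lambda <- max(lambda / 10, 1e-12)
    } else {
      lambda <- lambda * 10
      if (lambda > 1e8) break
    }
  }
  if (best < tol) return(structure(th, residual = best))
  cond <- structure(
    class = c("cssim_unreachable", "error", "condition"),
    list(message = sprintf(
      "inverse_kinematics: no solution within tolerance (residual %.3g mm); target may be outside the reachable workspace",
      best),
      call = sys.call(-1), residual = best, target = target))
  stop(cond)
}

#' Track a footpath with inverse kinematics
#'
#' Solves the inverse kinematics for every sample of a footpath, warm-starting
#' each solve from the previous sample's angles so the angle series is
#' continuous (no solution-branch jumps).
#'
#' @param path a [generate_footpath()] result (columns `t`, `x`, `y`, `z`).
#' @param leg a [leg_model()].
#' @param guess starting angles for the first sample.
#' @param max_jump largest allowed per-sample angle change, radians; a larger
#'   jump indicates a branch change and raises an error.
#' @return data frame `t`, `theta1`, `theta2`, `theta3` (radians).
#' @export
path_to_angles <- function(path, leg, guess = c(0, -0.3, -1),
                           max_jump = 0.5) {
  stopifnot(is.data.frame(path), all(c("t", "x", "y", "z") %in% names(path)))
  n <- nrow(path)
  th <- matrix(NA_real_, n, 3)
  g <- guess
  for (i in seq_len(n)) {
    g_new <- tryCatch(
      inverse_kinematics(c(path$x[i], path$y[i], path$z[i]), leg, guess = g),
      cssim_unreachable = function(e) {
        stop(sprintf("path_to_angles: unreachable point at sample %d (t=%.3f s): %s",
                     i, path$t[i], conditionMessage(e)), call. = FALSE)
      })
    if (i > 1 && max(abs(g_new - th[i - 1, ])) > max_jump)
      stop(sprintf("path_to_angles: branch jump at sample %d exceeds %.2f rad",
                   i, max_jump), call. = FALSE)
    th[i, ] <- g_new
    g <- as.numeric(g_new)
  }
  data.frame(t = path$t, theta1 = th[, 1], theta2 = th[, 2], theta3 = th[, 3])
}
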