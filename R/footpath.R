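#' Generate one period of a stepping footpath
#'
#' Builds a C1-continuous periodic foot trajectory for treadmill stepping in
#' the body frame (x anterior-posterior, y lateral, z dorso-ventral; the
#' treadmill surface is the plane `z = z_ground`).
#'
#' Stance (first `duty` fraction of the period) moves the foot rearward along
#' x at the treadmill speed on the ground plane. Swing is a single quintic in
#' x whose boundary conditions (position, velocity equal to the treadmill
#' speed, zero acceleration at both ends) force the foot to overshoot the
#' touchdown point anteriorly and come back onto it already moving rearward
#' at belt speed, so the tangential velocity mismatch at touchdown is zero by
#' construction; z follows a smooth lift bump with zero vertical velocity at
#' lift-off and touchdown.
#'
#' @param step_period full cycle period, seconds (the dynamically scaled
#'   default is 4 s).
#' @param treadmill_speed belt speed, mm/s.
#' @param duty stance fraction of the cycle, in (0, 1).
#' @param fs sampling rate, samples/s.
#' @param x_touchdown anterior-posterior foot position at touchdown, mm.
#' @param y_foot lateral foot position (constant), mm.
#' @param z_ground treadmill plane height, mm.
#' @param apex_height swing lift height above the ground plane, mm.
#' @return A `footpath`: data frame `t`, `x`, `y`, `z`, `phase`
#'   (`"stance"`/`"swing"`), one period sampled at `fs`, stance first.
#' @export
#' @examples
#' fp <- generate_footpath()
#' range(fp$x)
generate_footpath <- function(step_period = 4, treadmill_speed = 50,
                              duty = 0.75, fs = 60,
                              x_touchdown = 0, y_foot = 260,
                              z_ground = -170, apex_height = 40) {
  if (step_period <= 0) stop("generate_footpath: step_period must be > 0",
                             call. = FALSE)
  if (duty <= 0 || duty >= 1)
    stop("generate_footpath: duty must be in (0, 1)", call. = FALSE)
  n <- round(step_period * fs)
  t <- (seq_len(n) - 1) / fs
  ts <- duty * step_period         # stance duration
  tw <- step_period - ts           # swing duration
  A <- treadmill_speed * ts        # stance displacement
  x_lift <- x_touchdown - A
  stance <- t < ts
  x <- numeric(n); z <- rep(z_ground, n)
  x[stance] <- x_touchdown - treadmill_speed * t[stance]
  # swing: quintic x(s), s in [0,1]; x(0)=x_lift, x(1)=x_touchdown,
  # dx/dt = -v at both ends, d2x/dt2 = 0 at both ends.
  s <- (t[!stance] - ts) / tw
  v_n <- -treadmill_speed * tw / A         # normalized end slopes
  # quintic through (0,0) and (1,1) with slopes v_n, curvature 0:
  # h(s) = a3 s^3 + a4 s^4 + a5 s^5 + v_n s, with
  cfs <- solve(rbind(c(1, 1, 1),
                     c(3, 4, 5),
                     c(6, 12, 20)),
               c(1 - v_n, 0, 0))
  h <- v_n * s + cfs[1] * s^3 + cfs[2] * s^4 + cfs[3] * s^5
  x[!stance] <- x_lift + A * h
  z[!stance] <- z_ground + apex_height * 16 * (s * (1 - s))^2
  structure(data.frame(t = t, x = x, y = y_foot, z = z,
                       phase = ifelse(stance, "stance", "swing"),
                       stringsAsFactors = FALSE),
            class = c("footpath", "data.frame"))
}
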