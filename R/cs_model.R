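#' Campaniform sensillum (CS) discharge model parameters
#'
#' Constructs the five-constant parameter set of the adaptive phenomenological
#' CS discharge model,
#' \deqn{y = \max(0,\; a (u - x) + c u + d), \qquad
#'       \tau \dot x = \mathrm{sign}(u - x)\,|u - x|^b,}
#' where `u` is the instantaneous bending load (dimensionless normalized
#' strain, roughly 0--10), `x` the adaptive threshold that chases `u`, and `y`
#' the model discharge in action potentials per second. The power-law
#' threshold dynamic (`b > 1`) produces phasic bursts on load increase,
#' adaptation under tonic load, rate sensitivity and hysteresis.
#'
#' @param a phasic gain on `(u - x)`, output units per input unit.
#' @param b adaptation exponent (dimensionless, > 0).
#' @param c tonic gain, output units per input unit.
#' @param d output offset (may be negative), output units.
#' @param tau adaptation time constant, seconds (> 0).
#' @return An object of class `cs_params`.
#' @seealso [cs_group_params()] for the four named presets,
#'   [simulate_discharge()] to run the model over a load series.
#' @export
#' @examples
#' p <- cs_params(338.9952, 2.2707, 7.1531, -27.9311, 0.025)
#' steady_state_discharge(5, p)
cs_params <- function(a, b, c, d, tau) {
  vals <- c(a = a, b = b, c = c, d = d, tau = tau)
  if (!all(is.finite(vals)))
    stop("cs_params: all parameters must be finite", call. = FALSE)
  if (tau <= 0) stop("cs_params: tau must be > 0", call. = FALSE)
  if (b <= 0) stop("cs_params: b must be > 0", call. = FALSE)
  structure(as.list(vals), class = "cs_params")
}

#' @export
print.cs_params <- function(x, ...) {
  cat(sprintf(
    "CS discharge model parameters: a=%.4f b=%.4f c=%.4f d=%.4f tau=%.4f s\n",
    x$a, x$b, x$c, x$d, x$tau))
  invisible(x)
}

# Parameter table for the four major leg CS groups. Groups 3, 4 and 6B share
# one set; group 6A differs only in the offset d, which lowers its tonic
# threshold -d/c and makes it discharge at loads where 6B stays silent.
.cs_group_table <- list(
  "6B" = c(a = 338.9952, b = 2.2707, c = 7.1531, d = -27.9311, tau = 0.0250),
  "6A" = c(a = 338.9952, b = 2.2707, c = 7.1531, d = -17.9311, tau = 0.0250),
  "3"  = c(a = 338.9952, b = 2.2707, c = 7.1531, d = -27.9311, tau = 0.0250),
  "4"  = c(a = 338.9952, b = 2.2707, c = 7.1531, d = -27.9311, tau = 0.0250)
)

#' Preset CS model parameters for groups 3, 4, 6A and 6B
#'
#' Returns the published parameter set for one of the four modeled CS groups.
#' Groups 3 and 4 sit on the proximal dorsal trochanterofemur (axial and
#' transverse rosette elements), 6B and 6A on the proximal dorsal tibia.
#'
#' @param group one of `"3"`, `"4"`, `"6A"`, `"6B"`.
#' @return A [cs_params()] object.
#' @export
#' @examples
#' cs_group_params("6A")
cs_group_params <- function(group = c("3", "4", "6A", "6B")) {
  group <- match.arg(as.character(group), names(.cs_group_table))
  do.call(cs_params, as.list(.cs_group_table[[group]]))
}

#' All four CS group presets
#'
#' @return Named list of [cs_params()] for groups `"3"`, `"4"`, `"6A"`, `"6B"`.
#' @export
cs_presets <- function() {
  lapply(stats::setNames(nm = names(.cs_group_table)), cs_group_params)
}

#' Steady-state (fully adapted) discharge
#'
#' Analytic limit of the discharge model as the adaptive threshold converges
#' to the held input (`x -> u`): `max(0, c*u + d)`. The smallest input with
#' nonzero tonic output is `-d/c` (see [tonic_threshold()]).
#'
#' @param u input load (normalized strain units), any numeric vector.
#' @param params a [cs_params()] object.
#' @return Discharge in output units, same length as `u`.
#' @export
steady_state_discharge <- function(u, params) {
  stopifnot(inherits(params, "cs_params"))
  if (!all(is.finite(u))) stop("steady_state_discharge: u must be finite",
                               call. = FALSE)
  pmax(0, params$c * u + params$d)
}

#' Tonic discharge threshold
#'
#' The input level `-d/c` above which the fully adapted model discharges
#' tonically. Group 6A's smaller offset gives it a lower threshold than 6B,
#' so 6A fires tonically at loads where 6B is silent.
#'
#' @inheritParams steady_state_discharge
#' @return Input units.
#' @export
tonic_threshold <- function(params) {
  stopifnot(inherits(params, "cs_params"))
  -params$d / params$c
}

# Right side of the threshold ODE, dx/dt = sign(u - x) |u - x|^b / tau.
.cs_xdot <- function(x, u, b, tau) {
  e <- u - x
  sign(e) * abs(e)^b / tau
}

#' Advance the CS model state by one sample
#'
#' Integrates the adaptive threshold over one sampling interval with the input
#' held at `u_next` (zero-order hold), using fixed-step classical Runge-Kutta
#' with `substeps` internal sub-steps, then evaluates the discharge. The
#' threshold is clamped so it never crosses the input within a sub-step (the
#' continuous flow approaches `u` smoothly but a finite step could overshoot).
#'
#' @param state list with elements `u`, `x` (and optionally `y`), as returned
#'   by a previous call; `x` is the adaptive threshold carried between calls.
#' @param u_next input load over the coming interval (normalized strain units).
#' @param dt interval length in seconds (> 0).
#' @param params a [cs_params()] object.
#' @param substeps internal integration sub-steps per call (default 10).
#' @return list with `u`, `x`, `y` after the step.
#' @export
discharge_step <- function(state, u_next, dt, params, substeps = 10L) {
  stopifnot(inherits(params, "cs_params"))
  if (!is.finite(u_next)) stop("discharge_step: non-finite input u_next",
                               call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("discharge_step: dt must be a single value > 0", call. = FALSE)
  x <- state$x
  if (!is.finite(x)) stop("discharge_step: state$x must be finite",
                          call. = FALSE)
  b <- params$b; tau <- params$tau
  h <- dt / substeps
  for (i in seq_len(substeps)) {
    e0 <- u_next - x
    if (e0 == 0) break
    # the true flow approaches u one-sidedly and never crosses it, so every
    # Runge-Kutta stage state is clamped at u; this keeps the power-law
    # derivative bounded for large gaps and enforces the no-overshoot rule
    clamp <- function(z) if (sign(u_next - z) != sign(e0)) u_next else z
    k1 <- .cs_xdot(x, u_next, b, tau)
    k2 <- .cs_xdot(clamp(x + h / 2 * k1), u_next, b, tau)
    k3 <- .cs_xdot(clamp(x + h / 2 * k2), u_next, b, tau)
    k4 <- .cs_xdot(clamp(x + h * k3), u_next, b, tau)
    x <- clamp(x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
  }
  y <- max(0, params$a * (u_next - x) + params$c * u_next + params$d)
  list(u = u_next, x = x, y = y)
}

#' Run the CS discharge model over a load time series
#'
#' Applies [discharge_step()] along a uniformly sampled input series and
#' returns the paired input/threshold/discharge trace. Deterministic: the
#' model has no stochastic component.
#'
#' @param u input load series (normalized strain units), finite numeric.
#' @param t time grid in seconds, uniform spacing, same length as `u`.
#' @param params a [cs_params()] object.
#' @param x0 initial adaptive threshold. The default `u[1]` starts the model
#'   fully adapted to the initial load, avoiding a spurious startup transient.
#' @param substeps internal integration sub-steps per sample.
#' @return A `cs_trace`: data frame with columns `t`, `u`, `x`, `y`.
#' @export
#' @examples
#' t <- seq(0, 3, by = 1 / 60)
#' u <- trapezoid_input(t, amplitude = 5)
#' tr <- simulate_discharge(u, t, cs_group_params("3"))
#' max(tr$y)  # phasic burst during the ramp
simulate_discharge <- function(u, t, params, x0 = u[1], substeps = 10L) {
  stopifnot(inherits(params, "cs_params"))
  n <- length(u)
  if (length(t) != n)
    stop("simulate_discharge: u and t must have equal length", call. = FALSE)
  if (n < 2L) stop("simulate_discharge: need at least two samples",
                   call. = FALSE)
  if (!all(is.finite(u))) stop("simulate_discharge: u must be finite",
                               call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * dt[1])
    stop("simulate_discharge: t must be strictly increasing with uniform step",
         call. = FALSE)
  dt <- dt[1]
  x <- numeric(n); y <- numeric(n)
  x[1] <- x0
  y[1] <- max(0, params$a * (u[1] - x0) + params$c * u[1] + params$d)
  st <- list(u = u[1], x = x0, y = y[1])
  for (i in 2:n) {
    st <- discharge_step(st, u[i], dt, params, substeps = substeps)
    x[i] <- st$x; y[i] <- st$y
  }
  structure(data.frame(t = t, u = u, x = x, y = y),
            class = c("cs_trace", "data.frame"))
}

#' Trapezoidal ramp-hold-release input
#'
#' Convenience builder for the canonical ramp-and-hold-and-release stimulus:
#' zero baseline, linear ramp up, hold, linear ramp down, zero tail.
#'
#' @param t time grid, seconds.
#' @param amplitude hold level, input units.
#' @param t_on ramp onset time, seconds.
#' @param ramp ramp duration, seconds.
#' @param hold hold duration, seconds.
#' @return Numeric vector along `t`.
#' @export
trapezoid_input <- function(t, amplitude = 5, t_on = 0.5, ramp = 0.5,
                            hold = 2) {
  up <- pmin(pmax((t - t_on) / ramp, 0), 1)
  down <- pmin(pmax((t - t_on - ramp - hold) / ramp, 0), 1)
  amplitude * (up - down)
}

#' Run the four-group CS bank over a strain record
#'
#' Maps the four strain channels of a [strain_record] onto the four CS groups
#' (group 3 <- trochanterofemur axial, group 4 <- trochanterofemur transverse,
#' group 6B <- tibia axial, group 6A <- tibia transverse), converts each
#' channel to the model's normalized input scale, and runs
#' [simulate_discharge()] per group.
#'
#' Channels are fed *signed* (positive = compression on that element's
#' direction); rectification happens only at the model output. The axial and
#' transverse elements of one rosette carry opposite signs under a given
#' bending direction, which is how the antagonistic group pairs (3/4, 6B/6A)
#' arise: the transverse group is silent under tonic load but bursts when its
#' negative input rises back toward zero at unloading.
#'
#' @param strains a [strain_record] with the four named channels.
#' @param scales named numeric, input-normalization scale per rosette site,
#'   elements `tf` and `tib` (dimensionless `u` per unit strain). Defaults
#'   calibrated so baseline-stepping peak strain maps to `u` of about 5.
#' @param params named list of [cs_params()] keyed `"3"`, `"4"`, `"6A"`,
#'   `"6B"` (default [cs_presets()]).
#' @param x0 `"auto"` (adapted to the first sample) or a number.
#' @param substeps integration sub-steps per sample.
#' @return Named list of four `cs_trace` objects (`"3"`, `"4"`, `"6B"`, `"6A"`).
#' @export
group_bank <- function(strains, scales = cs_input_scales(),
                       params = cs_presets(), x0 = "auto", substeps = 10L) {
  chans <- c(tf_axial = "3", tf_transverse = "4",
             tib_axial = "6B", tib_transverse = "6A")
  missing_ch <- setdiff(names(chans), names(strains))
  if (length(missing_ch))
    stop("group_bank: strain record lacks channel(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  if (!all(c("tf", "tib") %in% names(scales)))
    stop("group_bank: scales must have elements 'tf' and 'tib'",
         call. = FALSE)
  site <- c(tf_axial = "tf", tf_transverse = "tf",
            tib_axial = "tib", tib_transverse = "tib")
  out <- list()
  for (ch in names(chans)) {
    u <- strains[[ch]] * scales[[site[[ch]]]]
    p <- params[[chans[[ch]]]]
    x0i <- if (identical(x0, "auto")) u[1] else x0
    out[[chans[[ch]]]] <- simulate_discharge(u, strains$t, p, x0 = x0i,
                                             substeps = substeps)
  }
  out[c("3", "4", "6B", "6A")]
}

#' Default input-normalization scales per rosette site
#'
#' Dimensionless `u` per unit strain, one factor per rosette. Calibrated once
#' against the baseline stepping scenario so that each site's peak strain maps
#' to an input of about 5, placing stance loads above the tonic threshold
#' `-d/c` of about 3.9.
#'
#' @return Named numeric vector with elements `tf` and `tib`.
#' @export
cs_input_scales <- function() {
  c(tf = 820, tib = 4190)
}
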