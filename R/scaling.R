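#' Rotational spring-inertia oscillator specification
#'
#' Holds the inertia and stiffness of one joint treated as a torsional
#' spring-inertia oscillator, optionally derived from a slender-rod segment
#' (mass `m`, length `L`) pivoting about its end.
#'
#' @param J rotational inertia about the joint, kg m^2. If `NULL`, derived
#'   from `m` and `L` via [rod_end_inertia()].
#' @param k joint rotational stiffness, N m/rad.
#' @param m segment mass, kg (optional).
#' @param L segment length, m (optional).
#' @return An object of class `oscillator_spec`.
#' @export
#' @examples
#' animal <- animal_fti_spec()
#' natural_period(animal)   # about 0.14 s
oscillator_spec <- function(J = NULL, k, m = NULL, L = NULL) {
  if (is.null(J)) {
    if (is.null(m) || is.null(L))
      stop("oscillator_spec: supply J, or m and L", call. = FALSE)
    J <- rod_end_inertia(m, L)
  }
  if (!is.finite(J) || J <= 0) stop("oscillator_spec: J must be > 0",
                                    call. = FALSE)
  if (!is.finite(k) || k <= 0) stop("oscillator_spec: k must be > 0",
                                    call. = FALSE)
  structure(list(J = J, k = k, m = m, L = L), class = "oscillator_spec")
}

#' Moment of inertia of a slender rod about its end
#'
#' `J = m L^2 / 3`. The insect leg is approximated as a slender rod pivoting
#' at the femur-tibia joint.
#'
#' @param m rod mass, kg (> 0).
#' @param L rod length, m (> 0).
#' @return Inertia in kg m^2.
#' @export
#' @examples
#' rod_end_inertia(11e-6, 0.012)   # about 5.3e-10 kg m^2
rod_end_inertia <- function(m, L) {
  if (!is.numeric(m) || !is.numeric(L) || any(m <= 0) || any(L <= 0))
    stop("rod_end_inertia: m and L must be > 0", call. = FALSE)
  m * L^2 / 3
}

#' Small-oscillation natural period of a torsional spring-inertia system
#'
#' `T_n = 2 pi sqrt(J / k)`. Monotone increasing in `J`, decreasing in `k`.
#'
#' @param spec an [oscillator_spec()], or a number interpreted as `J` when
#'   `k` is also given.
#' @param k stiffness, N m/rad (only when `spec` is numeric).
#' @return Period in seconds.
#' @export
#' @examples
#' natural_period(robot_fti_spec())   # about 0.63 s
natural_period <- function(spec, k = NULL) {
  if (is.numeric(spec)) {
    if (is.null(k)) stop("natural_period: supply k with a numeric J",
                         call. = FALSE)
    spec <- oscillator_spec(J = spec, k = k)
  }
  stopifnot(inherits(spec, "oscillator_spec"))
  2 * pi * sqrt(spec$J / spec$k)
}

#' Dynamically scaled step period
#'
#' The stepping period that keeps the ratio of step period to joint natural
#' period equal between robot and animal. The stick insect steps in about
#' 1 s, roughly six times its femur-tibia natural period, so the default
#' ratio is 6.
#'
#' @param spec an [oscillator_spec()] for the joint that sets the time scale.
#' @param period_ratio step period as a multiple of the natural period
#'   (> 0, default 6).
#' @return Step period in seconds.
#' @export
#' @examples
#' scaled_step_period(robot_fti_spec())   # about 3.8 s, rounds to 4 s
scaled_step_period <- function(spec, period_ratio = 6) {
  if (!is.numeric(period_ratio) || period_ratio <= 0)
    stop("scaled_step_period: period_ratio must be > 0", call. = FALSE)
  period_ratio * natural_period(spec)
}

#' Animal femur-tibia joint specification
#'
#' Slender-rod leg of 11 mg and 1.2 cm about its end, passive muscle-tone
#' joint stiffness 1e-6 N m/rad.
#'
#' @return An [oscillator_spec()].
#' @export
animal_fti_spec <- function() {
  oscillator_spec(k = 1e-6, m = 11e-6, L = 0.012)
}

#' Robot femur-tibia joint specification
#'
#' The 250:1 gearbox makes the servo rotor dominate the joint inertia
#' (about 1e-2 kg m^2); the servo feedback controller acts as a torsional
#' spring of about 1 N m/rad.
#'
#' @return An [oscillator_spec()].
#' @export
robot_fti_spec <- function() {
  oscillator_spec(J = 1e-2, k = 1)
}

#' Body mass fraction of the leg-carriage system
#'
#' Fraction of total mass that does not move relative to the body carriage.
#' With the robot's 800 g total and under 100 g of moving leg mass, at least
#' 87% of the mass is concentrated in the body, comparable to the roughly
#' 83% body-mass fraction of a locust.
#'
#' @param total total mass, kg (> 0).
#' @param moving mass that moves relative to the carriage, kg (>= 0, < total).
#' @return Dimensionless fraction in (0, 1].
#' @export
#' @examples
#' body_mass_fraction(0.8, 0.1)   # 0.875
body_mass_fraction <- function(total = 0.8, moving = 0.1) {
  if (total <= 0 || moving < 0 || moving >= total)
    stop("body_mass_fraction: need 0 <= moving < total", call. = FALSE)
  (total - moving) / total
}

#' Dynamic-scaling derivation table
#'
#' Computes inertia, natural period and scaled step period for the animal and
#' robot femur-tibia joints side by side.
#'
#' @param animal,robot [oscillator_spec()] objects.
#' @param period_ratio step period as a multiple of the natural period.
#' @return data frame with one row per system.
#' @export
scaling_table <- function(animal = animal_fti_spec(),
                          robot = robot_fti_spec(), period_ratio = 6) {
  rows <- list(animal = animal, robot = robot)
  data.frame(
    system = names(rows),
    J_kgm2 = vapply(rows, function(s) s$J, 0),
    k_Nm_per_rad = vapply(rows, function(s) s$k, 0),
    natural_period_s = vapply(rows, natural_period, 0),
    step_period_s = vapply(rows, scaled_step_period, 0,
                           period_ratio = period_ratio),
    row.names = NULL)
}
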