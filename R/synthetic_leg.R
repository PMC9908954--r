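#' Leg segment cross-section
#'
#' Hollow square tube used for every leg segment (default 1 cm outer width,
#' 1 mm wall), with its elastic modulus. Bending strain at a gauge site is
#' computed from the closed-form second moment of area of the section.
#'
#' @param outer outer width, mm.
#' @param wall wall thickness, mm.
#' @param E elastic modulus, Pa (default 2.4 GPa, a stiff printed polymer).
#' @return An object of class `segment_section`.
#' @export
segment_section <- function(outer = 10, wall = 1, E = 2.4e9) {
  if (outer <= 0 || wall <= 0 || 2 * wall >= outer)
    stop("segment_section: need 0 < 2*wall < outer", call. = FALSE)
  if (E <= 0) stop("segment_section: E must be > 0", call. = FALSE)
  structure(list(outer = outer, wall = wall, E = E),
            class = "segment_section")
}

#' Second moment of area of the hollow square section
#'
#' @param section a [segment_section()].
#' @return m^4 (closed form `(a_o^4 - a_i^4) / 12`).
#' @export
section_second_moment <- function(section) {
  stopifnot(inherits(section, "segment_section"))
  ao <- section$outer * 1e-3
  ai <- (section$outer - 2 * section$wall) * 1e-3
  (ao^4 - ai^4) / 12
}

#' Cross-sectional area of the hollow square section
#'
#' @param section a [segment_section()].
#' @return m^2.
#' @export
section_area <- function(section) {
  stopifnot(inherits(section, "segment_section"))
  ao <- section$outer * 1e-3
  ai <- (section$outer - 2 * section$wall) * 1e-3
  ao^2 - ai^2
}

#' Loading state of the leg
#'
#' @param contact logical; is the distal end constrained (stance)? A free
#'   leg produces identically zero quasi-static strain.
#' @param contact_force 3-vector force applied to the foot by the substrate,
#'   N, body frame.
#' @param carriage_mass supported body mass, kg.
#' @param added_mass extra mass on the carriage, kg.
#' @param perturbation_force additional vertical force, N.
#' @return An object of class `load_state`.
#' @export
load_state <- function(contact = TRUE, contact_force = c(0, 0, 0),
                       carriage_mass = 0.8, added_mass = 0,
                       perturbation_force = 0) {
  stopifnot(is.logical(contact), length(contact_force) == 3)
  structure(list(contact = contact,
                 contact_force = as.numeric(contact_force),
                 carriage_mass = carriage_mass, added_mass = added_mass,
                 perturbation_force = perturbation_force),
            class = "load_state")
}

# Current-configuration geometry of the two rosette sites. Each site sits a
# fraction of the way along its segment (proximal dorsal face): the
# trochanterofemur site on the q2->q3 segment (moves with joints 1-2), the
# tibia site on the q3->q_end segment (moves with joints 1-3). Returns, per
# site, the gauge point (mm), the segment long axis u_hat and the dorsal
# face normal n_hat, plus the current foot position.
.gauge_geometry <- function(theta, leg, gauge_frac = 0.1) {
  E1 <- .twist_exp(leg$omega[1, ], leg$q[1, ], theta[1])
  E2 <- .twist_exp(leg$omega[2, ], leg$q[2, ], theta[2])
  E3 <- .twist_exp(leg$omega[3, ], leg$q[3, ], theta[3])
  g2 <- E1 %*% E2         # transports the trochanterofemur
  g3 <- g2 %*% E3         # transports the tibia
  seg_frame <- function(g, p_prox, p_dist) {
    u0 <- (p_dist - p_prox); u0 <- u0 / sqrt(sum(u0^2))
    z <- c(0, 0, 1)
    n0 <- z - sum(z * u0) * u0; n0 <- n0 / sqrt(sum(n0^2))
    R <- g[1:3, 1:3]
    list(p = as.numeric(R %*% (p_prox + gauge_frac * (p_dist - p_prox)) +
                          g[1:3, 4]),
         u = as.numeric(R %*% u0),
         n = as.numeric(R %*% n0))
  }
  tf <- seg_frame(g2, leg$q[2, ], leg$q[3, ])
  tib <- seg_frame(g3, leg$q[3, ], leg$q_end)
  foot <- as.numeric(g3[1:3, 1:3] %*% leg$q_end + g3[1:3, 4])
  list(tf = tf, tib = tib, foot = foot)
}

#' Quasi-static strain at the two rosette sites
#'
#' Computes the surface strain read by the axial and transverse rosette
#' elements on the proximal dorsal trochanterofemur and proximal dorsal
#' tibia, for a leg in a given configuration under a given foot load.
#'
#' Per site, the bending moment of the foot contact force about the gauge
#' section is `M = r x F` (`r` from gauge to foot); its component about the
#' segment-local dorso-ventral bending axis, through the hollow-square beam
#' closed form, gives the dorsal-surface axial strain (sign convention:
#' positive = compression, so a dorsally directed foot force gives positive
#' axial strain). The transverse element reads the Poisson-coupled strain
#' `-poisson * axial`; a dorsal-face rosette sits on the neutral axis for
#' anterior-posterior bending, which therefore contributes nothing. The
#' axial force component adds a small uniform term. Strain is linear in the
#' applied force, and identically zero when the leg is free (quasi-static
#' model: no inertial strain, the dynamically scaled regime).
#'
#' @param theta joint angles, radians (length 3).
#' @param load a [load_state()]; only `contact` and `contact_force` are used.
#' @param leg a [leg_model()].
#' @param section a [segment_section()].
#' @param gauge_frac gauge position along each segment from the proximal
#'   end, fraction of segment length.
#' @param poisson transverse coupling factor of the rosette.
#' @return Named numeric: `tf_axial`, `tf_transverse`, `tib_axial`,
#'   `tib_transverse` (dimensionless strain).
#' @export
strain_at_gauges <- function(theta, load, leg, section,
                             gauge_frac = 0.1, poisson = 0.35) {
  stopifnot(inherits(load, "load_state"), inherits(leg, "leg_model"),
            inherits(section, "segment_section"))
  out <- c(tf_axial = 0, tf_transverse = 0, tib_axial = 0,
           tib_transverse = 0)
  if (!load$contact || all(load$contact_force == 0)) return(out)
  geo <- .gauge_geometry(theta, leg, gauge_frac)
  F <- load$contact_force
  I <- section_second_moment(section)
  A <- section_area(section)
  half_h <- section$outer * 1e-3 / 2
  site_strain <- function(site) {
    r <- (geo$foot - site$p) * 1e-3            # mm -> m
    M <- .cross3(r, F)                         # N m at the gauge section
    bend_axis <- .cross3(site$u, site$n)       # dorso-ventral bending axis
    eps_bend <- sum(M * bend_axis) * half_h / (section$E * I)
    eps_axf <- -sum(F * site$u) / (section$E * A)
    eps_bend + eps_axf
  }
  ax_tf <- site_strain(geo$tf)
  ax_tib <- site_strain(geo$tib)
  c(tf_axial = ax_tf, tf_transverse = -poisson * ax_tf,
    tib_axial = ax_tib, tib_transverse = -poisson * ax_tib)
}

#' Sensor chain parameters
#'
#' Amplifier, ADC and filter settings of the strain signal chain: quarter
#' bridge sensitivity, differential amplifier gain 250, 12-bit ADC, 60
#' samples/s, 13-sample moving median. Noise and offset drift are
#' configurable and seedable.
#'
#' @param fs sampling rate, samples/s.
#' @param gain amplifier gain (dimensionless).
#' @param adc_bits ADC resolution, bits.
#' @param vref ADC reference voltage, V (input range 0..`vref`, strain zero
#'   at mid-range).
#' @param bridge_sens bridge output per unit strain before amplification,
#'   V/strain.
#' @param noise_sd Gaussian noise standard deviation, V.
#' @param drift_amp slow sinusoidal offset drift amplitude, V.
#' @param drift_period drift period, s.
#' @param window moving median window, samples (odd).
#' @return An object of class `sensor_chain_params`.
#' @export
sensor_chain_params <- function(fs = 60, gain = 250, adc_bits = 12,
                                vref = 3.3, bridge_sens = 0.4,
                                noise_sd = 2 * vref / 2^adc_bits,
                                drift_amp = 5 * vref / 2^adc_bits,
                                drift_period = 60, window = 13) {
  if (gain <= 0) stop("sensor_chain_params: gain must be > 0", call. = FALSE)
  if (adc_bits < 1) stop("sensor_chain_params: adc_bits must be >= 1",
                         call. = FALSE)
  if (window %% 2 != 1) stop("sensor_chain_params: window must be odd",
                             call. = FALSE)
  structure(list(fs = fs, gain = gain, adc_bits = adc_bits, vref = vref,
                 bridge_sens = bridge_sens, noise_sd = noise_sd,
                 drift_amp = drift_amp, drift_period = drift_period,
                 window = window),
            class = "sensor_chain_params")
}

#' Emulate the amplifier / ADC / median-filter signal chain
#'
#' Scales a raw strain series to bridge voltage, amplifies it, adds slow
#' sinusoidal offset drift and Gaussian noise, clips to the ADC input range
#' (saturation is flagged, not an error), quantizes to `2^adc_bits` levels,
#' and applies a centred moving median. Deterministic under a fixed seed.
#'
#' @param raw raw strain series (dimensionless).
#' @param params a [sensor_chain_params()].
#' @param seed integer seed for noise and drift phase, or `NULL` to draw
#'   from the current RNG state.
#' @return list with `codes` (filtered ADC codes), `strain` (codes mapped
#'   back to strain units), `volts` (pre-ADC voltage), and `saturated`
#'   (logical, any clipping).
#' @export
sensor_chain <- function(raw, params = sensor_chain_params(), seed = NULL) {
  stopifnot(inherits(params, "sensor_chain_params"))
  n <- length(raw)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  t <- (seq_len(n) - 1) / params$fs
  drift <- if (params$drift_amp > 0)
    params$drift_amp * sin(2 * pi * t / params$drift_period +
                             stats::runif(1, 0, 2 * pi))
  else rep(0, n)
  noise <- if (params$noise_sd > 0) stats::rnorm(n, 0, params$noise_sd)
  else rep(0, n)
  v <- params$vref / 2 + raw * params$bridge_sens * params$gain +
    drift + noise
  clipped <- v < 0 | v > params$vref
  v_cl <- pmin(pmax(v, 0), params$vref)
  nlev <- 2^params$adc_bits
  lsb <- params$vref / nlev
  codes <- pmin(floor(v_cl / lsb), nlev - 1)
  codes_f <- as.numeric(stats::runmed(codes, params$window,
                                      endrule = "median"))
  strain <- (codes_f * lsb - params$vref / 2) /
    (params$bridge_sens * params$gain)
  list(codes = codes_f, strain = strain, volts = v_cl,
       saturated = any(clipped))
}

#' Assemble a strain record
#'
#' Container for a multichannel strain time series with phase labels, as
#' produced by [simulate_stepping()] or read from delimited text.
#'
#' @param t time, seconds, uniform sampling.
#' @param phase character, `"stance"` or `"swing"` per sample.
#' @param tf_axial,tf_transverse,tib_axial,tib_transverse strain channels.
#' @return A `strain_record` data frame.
#' @export
strain_record <- function(t, phase, tf_axial, tf_transverse, tib_axial,
                          tib_transverse) {
  n <- length(t)
  lens <- lengths(list(phase, tf_axial, tf_transverse, tib_axial,
                       tib_transverse))
  if (any(lens != n))
    stop("strain_record: all columns must have the length of t",
         call. = FALSE)
  if (!all(phase %in% c("stance", "swing")))
    stop("strain_record: phase must be 'stance' or 'swing'", call. = FALSE)
  structure(data.frame(t = t, phase = phase, tf_axial = tf_axial,
                       tf_transverse = tf_transverse, tib_axial = tib_axial,
                       tib_transverse = tib_transverse,
                       stringsAsFactors = FALSE),
            class = c("strain_record", "data.frame"))
}

# Rate-limited tracking of a target force profile: rises are limited by a
# forward pass, falls are anticipated by a backward pass so the force
# reaches zero exactly at the target's falling edge (the leg unloads as it
# prepares lift-off). Both at `rate` N/s.
.rate_limit_force <- function(target, rate, dt) {
  n <- length(target)
  f <- numeric(n); b <- numeric(n)
  f[1] <- min(target[1], rate * dt)
  for (i in 2:n) f[i] <- min(target[i], f[i - 1] + rate * dt)
  b[n] <- min(target[n], rate * dt)
  for (i in (n - 1):1) b[i] <- min(target[i], b[i + 1] + rate * dt)
  pmin(f, b)
}

#' Simulate loaded stepping on the treadmill
#'
#' Runs the full synthetic-leg pipeline for `n_steps` identical stepping
#' cycles: inverse kinematics along the footpath, quasi-static gauge strain
#' from the stance contact force, then the sensor chain per channel.
#'
#' During stance the foot supports the carriage weight (plus any added mass
#' and perturbation force) as a vertical contact force; the force transfers
#' at touchdown and lift-off at a fixed, load-independent rate (set by the
#' velocity-matched touchdown kinematics, not by the carried mass). During
#' swing the leg is free and quasi-static strain is identically zero. A slip
#' event transiently breaks foot contact, collapsing the contact force
#' inside the slip window.
#'
#' @param path one-cycle [generate_footpath()] result.
#' @param leg a [leg_model()].
#' @param section a [segment_section()].
#' @param carriage_mass supported body mass, kg.
#' @param added_mass extra carriage mass, kg (0, 0.5 or 1.0 in the standard
#'   load conditions).
#' @param force_rate touchdown/lift-off force transfer rate, N/s.
#' @param perturbation `NULL`, or `list(amp, t0, width)`: a half-sine
#'   vertical force of `amp` N, starting `t0` s into each cycle, `width` s
#'   wide.
#' @param slip `NULL`, or `list(t0, duration)`: foot contact is lost from
#'   `t0` s into each cycle for `duration` s.
#' @param n_steps number of stepping cycles.
#' @param chain a [sensor_chain_params()].
#' @param seed integer seed for sensor noise (deterministic record for a
#'   fixed seed).
#' @param gauge_frac,poisson see [strain_at_gauges()].
#' @return A [strain_record] with attributes `onsets`/`offsets` (ground-truth
#'   stance transition times, s), `force` (the applied vertical contact
#'   force, N), `raw` (pre-chain strain matrix), and `saturated`.
#' @export
simulate_stepping <- function(path = generate_footpath(), leg = leg_model(),
                              section = segment_section(),
                              carriage_mass = 0.8, added_mass = 0,
                              force_rate = 100, perturbation = NULL,
                              slip = NULL, n_steps = 20,
                              chain = sensor_chain_params(), seed = NULL,
                              gauge_frac = 0.1, poisson = 0.35) {
  stopifnot(inherits(path, "footpath"))
  fs <- chain$fs
  nc <- nrow(path)
  dt <- path$t[2] - path$t[1]
  if (abs(dt - 1 / fs) > 1e-9)
    stop("simulate_stepping: footpath sampling must match the chain rate",
         call. = FALSE)
  ang <- path_to_angles(path, leg)
  stance <- path$phase == "stance"
  # strain per unit vertical contact force, one cycle (linearity in force)
  unit <- matrix(0, nc, 4,
                 dimnames = list(NULL, c("tf_axial", "tf_transverse",
                                         "tib_axial", "tib_transverse")))
  unit_load <- load_state(contact = TRUE, contact_force = c(0, 0, 1))
  for (i in which(stance)) {
    unit[i, ] <- strain_at_gauges(
      c(ang$theta1[i], ang$theta2[i], ang$theta3[i]), unit_load, leg,
      section, gauge_frac = gauge_frac, poisson = poisson)
  }
  n <- nc * n_steps
  t <- (seq_len(n) - 1) / fs
  cyc <- rep(seq_len(nc), n_steps)
  tc <- path$t[cyc]                      # time within cycle
  weight <- (carriage_mass + added_mass) * 9.81
  target <- ifelse(stance[cyc], weight, 0)
  if (!is.null(perturbation)) {
    s <- (tc - perturbation$t0) / perturbation$width
    target <- target + ifelse(s >= 0 & s <= 1 & stance[cyc],
                              perturbation$amp * sin(pi * s), 0)
  }
  force <- .rate_limit_force(target, force_rate, 1 / fs)
  if (!is.null(slip)) {
    # contact loss is sudden: zero the force inside the window, then let it
    # recover at the transfer rate (forward pass only, no anticipation)
    inwin <- tc >= slip$t0 & tc < slip$t0 + slip$duration
    force[inwin] <- 0
    for (i in 2:n) force[i] <- min(force[i], force[i - 1] + force_rate / fs)
  }
  raw <- unit[cyc, ] * force
  chans <- list(); sat <- FALSE
  for (j in seq_len(4)) {
    res <- sensor_chain(raw[, j], chain,
                        seed = if (is.null(seed)) NULL else seed + j)
    chans[[colnames(unit)[j]]] <- res$strain
    sat <- sat || res$saturated
  }
  rec <- strain_record(t, path$phase[cyc], chans$tf_axial,
                       chans$tf_transverse, chans$tib_axial,
                       chans$tib_transverse)
  ts <- sum(stance) / fs
  attr(rec, "onsets") <- (seq_len(n_steps) - 1) * (nc / fs)
  attr(rec, "offsets") <- (seq_len(n_steps) - 1) * (nc / fs) + ts
  attr(rec, "force") <- force
  attr(rec, "raw") <- raw
  attr(rec, "saturated") <- sat
  rec
}
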