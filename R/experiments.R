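#' Declarative experiment specification
#'
#' Describes one of the five stepping/loading protocols as a validated
#' parameter list. Protocols and their parameters (all have defaults chosen
#' to match the canonical runs):
#'
#' * `ramp_hold_release_fixed` / `ramp_hold_release_free`: a servo-commanded
#'   angle trapezoid with the distal trochanterofemur end fixed (torque
#'   strains the segment) or free (no strain). Parameters `amp` (rad),
#'   `ramp` (s), `hold` (s), `k_servo` (N m/rad).
#' * `asterisk`: distal leg end fixed; bending forces cycle through 12
#'   directions at 30 degree increments in the trochanterofemur's
#'   dorso-ventral / anterior-posterior plane, returning to centre between
#'   directions. Parameters `force` (N), `dwell` (s), `transition` (s).
#' * `stepping_load`: treadmill stepping with `added_mass` kg (0, 0.5 or
#'   1.0) on the carriage, `n_steps` cycles.
#' * `transient_load`: stepping with a half-sine downward pull of
#'   `amp` N, `width` s wide, starting `t0` s into each cycle.
#' * `slip`: stepping with foot contact lost for `duration` s starting
#'   `t0` s into each cycle.
#'
#' @param name protocol name (one of the six above).
#' @param ... protocol parameters overriding the defaults.
#' @param seed integer seed for the sensor-chain noise.
#' @return An object of class `experiment_spec`.
#' @export
#' @examples
#' experiment_spec("slip", t0 = 1.5, duration = 0.4, seed = 7)
experiment_spec <- function(name, ..., seed = 1L) {
  defaults <- list(
    ramp_hold_release_fixed = list(amp = 1.5, ramp = 0.5, hold = 2,
                                   k_servo = 1, t_pre = 0.5, t_post = 2),
    ramp_hold_release_free = list(amp = 1.5, ramp = 0.5, hold = 2,
                                  k_servo = 1, t_pre = 0.5, t_post = 2),
    asterisk = list(force = 8, dwell = 1, transition = 0.25),
    stepping_load = list(added_mass = 0, n_steps = 20),
    transient_load = list(amp = 4.9, t0 = 1.25, width = 0.5, n_steps = 5),
    slip = list(t0 = 1.5, duration = 0.4, n_steps = 5)
  )
  name <- match.arg(name, names(defaults))
  pars <- defaults[[name]]
  dots <- list(...)
  bad <- setdiff(names(dots), names(pars))
  if (length(bad))
    stop("experiment_spec: unknown parameter(s) for protocol '", name,
         "': ", paste(bad, collapse = ", "), call. = FALSE)
  pars[names(dots)] <- dots
  bad_num <- names(pars)[!vapply(pars, function(p)
    is.numeric(p) && length(p) == 1 && is.finite(p) && p >= 0, TRUE)]
  if (length(bad_num))
    stop("experiment_spec: invalid value for field(s): ",
         paste(bad_num, collapse = ", "), call. = FALSE)
  if (name == "stepping_load" &&
      !isTRUE(all.equal(pars$n_steps, round(pars$n_steps))))
    stop("experiment_spec: invalid value for field(s): n_steps",
         call. = FALSE)
  structure(list(name = name, parameters = pars, seed = as.integer(seed)),
            class = "experiment_spec")
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat("Experiment:", x$name, "(seed", x$seed, ")\n")
  cat(paste(sprintf("  %s = %g", names(x$parameters),
                    unlist(x$parameters)), collapse = "\n"), "\n")
  invisible(x)
}

# Strain record for the ramp-hold-release protocols: a commanded CTr angle
# trapezoid. With the distal trochanterofemur end fixed, the servo torque
# (feedback stiffness k_servo times the angle displacement) bends the
# segment; free, the quasi-static strain is zero.
.run_ramp_hold_release <- function(spec, leg, section, chain, poisson) {
  p <- spec$parameters
  fs <- chain$fs
  total <- p$t_pre + 2 * p$ramp + p$hold + p$t_post
  t <- seq(0, total, by = 1 / fs)
  dtheta <- trapezoid_input(t, amplitude = p$amp, t_on = p$t_pre,
                            ramp = p$ramp, hold = p$hold)
  fixed <- spec$name == "ramp_hold_release_fixed"
  I <- section_second_moment(section)
  half_h <- section$outer * 1e-3 / 2
  eps <- if (fixed) p$k_servo * dtheta * half_h / (section$E * I)
  else rep(0, length(t))
  raw <- cbind(tf_axial = eps, tf_transverse = -poisson * eps,
               tib_axial = 0 * eps, tib_transverse = 0 * eps)
  chans <- list(); sat <- FALSE
  for (j in seq_len(4)) {
    res <- sensor_chain(raw[, j], chain, seed = spec$seed + j)
    chans[[colnames(raw)[j]]] <- res$strain
    sat <- sat || res$saturated
  }
  rec <- strain_record(t, rep(if (fixed) "stance" else "swing", length(t)),
                       chans$tf_axial, chans$tf_transverse,
                       chans$tib_axial, chans$tib_transverse)
  attr(rec, "raw") <- raw
  attr(rec, "saturated") <- sat
  attr(rec, "events") <- data.frame(
    type = c("ramp_on", "hold_on", "release_on", "release_off"),
    t = p$t_pre + c(0, p$ramp, p$ramp + p$hold, 2 * p$ramp + p$hold))
  rec
}

# Asterisk protocol: leg held at the zero configuration, a force of fixed
# magnitude applied at the distal trochanterofemur end, cycling through 12
# directions (30 degree spacing) in the segment's dorso-ventral /
# anterior-posterior plane, returning to centre (zero force) between
# directions. Direction 0 is anterior, 90 dorsal, 180 posterior, 270
# ventral.
.run_asterisk <- function(spec, leg, section, chain, gauge_frac, poisson) {
  p <- spec$parameters
  fs <- chain$fs
  dirs <- seq(0, 330, by = 30)
  geo <- .gauge_geometry(c(0, 0, 0), leg, gauge_frac)
  a_hat <- .cross3(geo$tf$u, geo$tf$n)      # anterior in the segment plane
  a_hat <- a_hat / sqrt(sum(a_hat^2))
  d_hat <- geo$tf$n                         # dorsal
  # force applied at the distal end of the trochanterofemur (q3)
  p_app <- leg$q[3, ]
  I <- section_second_moment(section)
  A <- section_area(section)
  half_h <- section$outer * 1e-3 / 2
  tf_of_force <- function(Fv) {
    r <- (p_app - geo$tf$p) * 1e-3
    M <- .cross3(r, Fv)
    sum(M * .cross3(geo$tf$u, geo$tf$n)) * half_h / (section$E * I) -
      sum(Fv * geo$tf$u) / (section$E * A)
  }
  seg_t <- c()       # per-sample force scale
  seg_dir <- c()     # per-sample direction (NA at centre)
  n_dwell <- round(p$dwell * fs); n_tr <- round(p$transition * fs)
  ramp_up <- seq_len(n_tr) / n_tr
  for (d in dirs) {
    seg_t <- c(seg_t, ramp_up, rep(1, n_dwell), rev(ramp_up),
               rep(0, n_dwell))
    seg_dir <- c(seg_dir, rep(d, 2 * n_tr + n_dwell), rep(NA, n_dwell))
  }
  n <- length(seg_t)
  t <- (seq_len(n) - 1) / fs
  eps_ax <- numeric(n)
  for (d in dirs) {
    Fv <- p$force * (cos(d * pi / 180) * a_hat + sin(d * pi / 180) * d_hat)
    idx <- !is.na(seg_dir) & seg_dir == d
    eps_ax[idx] <- tf_of_force(Fv) * seg_t[idx]
  }
  raw <- cbind(tf_axial = eps_ax, tf_transverse = -poisson * eps_ax,
               tib_axial = 0 * eps_ax, tib_transverse = 0 * eps_ax)
  chans <- list(); sat <- FALSE
  for (j in seq_len(4)) {
    res <- sensor_chain(raw[, j], chain, seed = spec$seed + j)
    chans[[colnames(raw)[j]]] <- res$strain
    sat <- sat || res$saturated
  }
  rec <- strain_record(t, rep("stance", n), chans$tf_axial,
                       chans$tf_transverse, chans$tib_axial,
                       chans$tib_transverse)
  attr(rec, "raw") <- raw
  attr(rec, "saturated") <- sat
  attr(rec, "direction") <- seg_dir
  attr(rec, "hold_scale") <- seg_t
  rec
}

#' Run one experiment protocol end to end
#'
#' Executes the full pipeline (strain synthesis, sensor chain, four-group CS
#' bank) for a protocol described by an [experiment_spec()], deterministically
#' under the spec's seed, and computes the protocol's summary table. The
#' `transient_load` and `slip` protocols also run a matched baseline (same
#' seed, no perturbation/slip) for comparison summaries.
#'
#' @param spec an [experiment_spec()].
#' @param leg a [leg_model()].
#' @param section a [segment_section()].
#' @param cs named list of [cs_params()] per group (default [cs_presets()]).
#' @param chain a [sensor_chain_params()].
#' @param path one-cycle [generate_footpath()] for the stepping protocols.
#' @param scales input-normalization scales, see [group_bank()].
#' @param gauge_frac,poisson see [strain_at_gauges()].
#' @return An object of class `experiment_result`: list with `spec`,
#'   `strain` ([strain_record]), `discharges` (four `cs_trace`s), `events`
#'   (data frame of markers), `summaries` (protocol-specific list), and for
#'   the comparison protocols `baseline` (a nested result).
#' @export
run_experiment <- function(spec, leg = leg_model(),
                           section = segment_section(),
                           cs = cs_presets(),
                           chain = sensor_chain_params(),
                           path = generate_footpath(),
                           scales = cs_input_scales(),
                           gauge_frac = 0.1, poisson = 0.35) {
  stopifnot(inherits(spec, "experiment_spec"))
  p <- spec$parameters
  rec <- switch(
    spec$name,
    ramp_hold_release_fixed = ,
    ramp_hold_release_free =
      .run_ramp_hold_release(spec, leg, section, chain, poisson),
    asterisk = .run_asterisk(spec, leg, section, chain, gauge_frac,
                             poisson),
    stepping_load = simulate_stepping(
      path, leg, section, added_mass = p$added_mass, n_steps = p$n_steps,
      chain = chain, seed = spec$seed, gauge_frac = gauge_frac,
      poisson = poisson),
    transient_load = simulate_stepping(
      path, leg, section,
      perturbation = list(amp = p$amp, t0 = p$t0, width = p$width),
      n_steps = p$n_steps, chain = chain, seed = spec$seed,
      gauge_frac = gauge_frac, poisson = poisson),
    slip = simulate_stepping(
      path, leg, section, slip = list(t0 = p$t0, duration = p$duration),
      n_steps = p$n_steps, chain = chain, seed = spec$seed,
      gauge_frac = gauge_frac, poisson = poisson)
  )
  disch <- group_bank(rec, scales = scales, params = cs)
  events <- data.frame(type = character(), t = numeric())
  if (!is.null(attr(rec, "onsets")))
    events <- rbind(events,
                    data.frame(type = "stance_onset",
                               t = attr(rec, "onsets")),
                    data.frame(type = "stance_offset",
                               t = attr(rec, "offsets")))
  if (!is.null(attr(rec, "events")))
    events <- rbind(events, attr(rec, "events"))
  res <- structure(list(spec = spec, strain = rec, discharges = disch,
                        events = events, summaries = list()),
                   class = "experiment_result")
  res$summaries$peak_discharge <- vapply(disch, function(tr) max(tr$y), 0)
  if (spec$name == "asterisk")
    res$summaries$polar <- asterisk_polar_summary(res)
  if (spec$name %in% c("transient_load", "slip")) {
    base_spec <- experiment_spec("stepping_load", added_mass = 0,
                                 n_steps = p$n_steps, seed = spec$seed)
    res$baseline <- run_experiment(base_spec, leg, section, cs, chain,
                                   path, scales, gauge_frac, poisson)
    win <- if (spec$name == "slip") c(p$t0, p$t0 + p$duration)
    else c(p$t0, p$t0 + p$width)
    res$summaries$window <- win
    res$summaries$window_comparison <-
      .window_comparison(res, res$baseline, win, nrow(path))
  }
  res
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment result:", x$spec$name, "—", nrow(x$strain), "samples\n")
  cat("peak model discharge (AP/s):",
      paste(sprintf("group %s: %.1f", names(x$summaries$peak_discharge),
                    x$summaries$peak_discharge), collapse = ", "), "\n")
  invisible(x)
}

# Per-group discharge extrema inside a within-cycle window, pooled over
# steps, for a run and its matched baseline.
.window_comparison <- function(res, base, win, cycle_n) {
  fs <- 1 / (res$strain$t[2] - res$strain$t[1])
  tc <- ((seq_len(nrow(res$strain)) - 1) %% cycle_n) / fs
  inwin <- tc >= win[1] & tc < win[2]
  do.call(rbind, lapply(names(res$discharges), function(g) {
    data.frame(group = g,
               peak_in_window = max(res$discharges[[g]]$y[inwin]),
               baseline_peak_in_window = max(base$discharges[[g]]$y[inwin]),
               mean_in_window = mean(res$discharges[[g]]$y[inwin]),
               baseline_mean_in_window =
                 mean(base$discharges[[g]]$y[inwin]))
  }))
}

#' Per-direction polar summary of the asterisk protocol
#'
#' Averages each strain channel over the central 60% of every direction's
#' hold window (transition samples excluded), one row per direction.
#'
#' @param result an `experiment_result` from the `asterisk` protocol.
#' @return data frame: `direction_deg` (12 rows, 30 degree spacing) and the
#'   mean strain per channel.
#' @export
asterisk_polar_summary <- function(result) {
  stopifnot(inherits(result, "experiment_result"))
  if (result$spec$name != "asterisk")
    stop("asterisk_polar_summary: result is from protocol '",
         result$spec$name, "', not 'asterisk'", call. = FALSE)
  rec <- result$strain
  dir <- attr(rec, "direction")
  hold <- attr(rec, "hold_scale") == 1
  chans <- c("tf_axial", "tf_transverse", "tib_axial", "tib_transverse")
  dirs <- sort(unique(dir[!is.na(dir)]))
  out <- data.frame(direction_deg = dirs)
  for (ch in chans) out[[ch]] <- NA_real_
  for (k in seq_along(dirs)) {
    idx <- which(!is.na(dir) & dir == dirs[k] & hold)
    # central 60% of the hold window
    m <- length(idx)
    idx <- idx[seq(ceiling(0.2 * m) + 1, floor(0.8 * m))]
    for (ch in chans) out[[ch]][k] <- mean(rec[[ch]][idx])
  }
  out
}

#' Detect stance onset and offset from CS model discharge
#'
#' Operationalizes the observation that the model discharges strongly
#' indicate the beginning and end of stance: stance onset is an upward
#' threshold crossing of the group 3 discharge (trochanterofemur loading
#' burst), stance offset an upward crossing of the group 4 discharge (the
#' unloading rebound burst of the antagonist group). Crossings within
#' `refractory` seconds of the previous event of the same type are merged.
#' If ground-truth transition times are supplied, each detection is matched
#' to the nearest one and the timing error reported.
#'
#' @param discharges four-trace list from [group_bank()].
#' @param threshold discharge threshold in output units, or `NULL` for the
#'   default 10% of the run's peak discharge (per detector group).
#' @param truth optional list with `onsets` and `offsets` (ground-truth
#'   times, s), e.g. the attributes of a [simulate_stepping()] record.
#' @param refractory minimum spacing between events of one type, s.
#' @return data frame with `type` (`"stance_onset"`/`"stance_offset"`),
#'   `t` (detection time, s), and when truth is given `t_truth` and
#'   `error` (s). Zero rows when nothing crosses threshold.
#' @export
stance_event_detector <- function(discharges, threshold = NULL,
                                  truth = NULL, refractory = 1) {
  stopifnot(all(c("3", "4") %in% names(discharges)))
  detect <- function(tr, thr) {
    y <- tr$y
    up <- which(y[-1] >= thr & y[-length(y)] < thr) + 1L
    if (!length(up)) return(numeric())
    keep <- c(TRUE, diff(tr$t[up]) > refractory)
    tr$t[up][keep]
  }
  out <- list()
  map <- c(stance_onset = "3", stance_offset = "4")
  for (nm in names(map)) {
    tr <- discharges[[map[[nm]]]]
    thr <- if (is.null(threshold)) 0.1 * max(tr$y) else threshold
    tt <- detect(tr, thr)
    if (length(tt))
      out[[nm]] <- data.frame(type = nm, t = tt)
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(type = character(), t = numeric())
  rownames(res) <- NULL
  if (!is.null(truth) && nrow(res)) {
    truth_of <- list(stance_onset = truth$onsets,
                     stance_offset = truth$offsets)
    res$t_truth <- NA_real_
    for (i in seq_len(nrow(res))) {
      cand <- truth_of[[res$type[i]]]
      if (length(cand))
        res$t_truth[i] <- cand[which.min(abs(cand - res$t[i]))]
    }
    res$error <- res$t - res$t_truth
  }
  res
}
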