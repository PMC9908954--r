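#' Default simulator configuration
#'
#' Collects every tunable of the pipeline — CS group parameters, leg
#' geometry, footpath, section, sensor chain, input scales — as a plain
#' nested list suitable for YAML round-tripping.
#'
#' @return Nested list.
#' @export
default_config <- function() {
  leg <- leg_model()
  list(
    cs_groups = lapply(.cs_group_table, as.list),
    input_scales = as.list(cs_input_scales()),
    leg = list(omega = apply(leg$omega, 1, as.numeric, simplify = FALSE),
               q = apply(leg$q, 1, as.numeric, simplify = FALSE),
               q_end = leg$q_end, scale = leg$scale),
    footpath = list(step_period = 4, treadmill_speed = 50, duty = 0.75,
                    fs = 60, x_touchdown = 0, y_foot = 260,
                    z_ground = -170, apex_height = 40),
    section = list(outer = 10, wall = 1, E = 2.4e9),
    chain = unclass(sensor_chain_params()),
    gauge_frac = 0.1,
    poisson = 0.35,
    scaling = list(period_ratio = 6)
  )
}

#' Read / write simulator configuration as YAML
#'
#' @param path file path.
#' @param config nested list as from [default_config()].
#' @return `read_config` returns the nested list; `write_config` the path,
#'   invisibly.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 12)
  invisible(path)
}

#' Build CS parameter presets from a configuration list
#'
#' @param config nested list with a `cs_groups` element keyed by group name,
#'   each holding fields `a`, `b`, `c`, `d`, `tau`.
#' @return Named list of [cs_params()].
#' @export
cs_params_from_config <- function(config) {
  lapply(config$cs_groups, function(g)
    cs_params(g$a, g$b, g$c, g$d, g$tau))
}

#' Build a leg model from a configuration list
#'
#' @param config nested list with a `leg` element (`omega`, `q`, `q_end`,
#'   `scale`).
#' @return A [leg_model()].
#' @export
leg_from_config <- function(config) {
  l <- config$leg
  leg_model(omega = do.call(rbind, l$omega), q = do.call(rbind, l$q),
            q_end = l$q_end, scale = l$scale)
}

#' Read and write CS input/output traces as delimited text
#'
#' `read_trace` expects a header `t,u` (input only) or `t,u,x,y`;
#' `write_trace` writes a [simulate_discharge()] trace with the full header.
#' One row per sample.
#'
#' @param path file path.
#' @param trace a `cs_trace` data frame.
#' @return `read_trace` returns a data frame; `write_trace` the path,
#'   invisibly.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t", "u") %in% names(df)))
    stop("read_trace: file must have columns t,u", call. = FALSE)
  df
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Read and write strain records as delimited text
#'
#' Column layout `t,phase,tf_axial,tf_transverse,tib_axial,tib_transverse`,
#' one row per 1/60 s sample.
#'
#' @param path file path.
#' @param record a [strain_record].
#' @return `read_strain_record` returns a [strain_record];
#'   `write_strain_record` the path, invisibly.
#' @export
read_strain_record <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "phase", "tf_axial", "tf_transverse", "tib_axial",
            "tib_transverse")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_strain_record: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  do.call(strain_record, df[need])
}

#' @rdname read_strain_record
#' @export
write_strain_record <- function(record, path) {
  utils::write.csv(as.data.frame(record), path, row.names = FALSE)
  invisible(path)
}
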