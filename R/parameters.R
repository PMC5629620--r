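#' Full parameter set of the neurogenic cascade
#'
#' Bundles everything the branching-process model needs: the Poisson influx
#' intensities, the division laws of amplifying neuroprogenitors (ANP) and
#' neural stem cells (NSC), the shifted-gamma transit times of every stage,
#' and the stage-specific apoptotic rates. This is also the object the
#' genetic-algorithm search operates on.
#'
#' Durations may be given either as \code{\link{shifted_gamma}} objects or as
#' numeric triples \code{c(mean, shape, min)} in hours, the parameterization
#' used for the published search ranges and fitted values.
#'
#' Defaults are the best-fit values of the bundled pulse-chase study; shape
#' parameters the study did not report (all but the neuroblast stage) and the
#' unreported minimum durations default to the midpoint of their search
#' ranges (see the methods vignette).
#'
#' @param influx_anp intensity \eqn{\lambda} of the Poisson influx of newborn
#'   ANPs (cells/hour); the unit default is rescaled by
#'   \code{\link{calibrate_influx}}
#' @param influx_nsc intensity \eqn{\mu} of Poisson NSC activations
#'   (episodes/hour)
#' @param min_div_anp,max_div_anp,p_anp ANP division law (see
#'   \code{\link{progeny_distribution}})
#' @param t_g1_anp,t_s_anp,t_g2m_anp ANP cell-cycle phase durations
#' @param t_anp_nb,t_anp_apop durations of the non-proliferating ANP
#'   transition stages towards neuroblast and towards apoptosis
#' @param t_nb neuroblast stage duration
#' @param t_in immature-neuron stage duration (used only when
#'   \code{include_in = TRUE})
#' @param t_apop residence time of an apoptotic cell before phagocytic
#'   clearance
#' @param t_g1_nsc,t_s_nsc,t_g2m_nsc NSC cell-cycle phase durations
#' @param d_g1,d_s,d_g2m death rates at the end of the ANP cycle phases
#' @param d_anp death rate of a non-proliferating ANP (probability of routing
#'   to the ANP-Apop rather than the ANP-NB transition stage)
#' @param d_nb,d_in death rates at the end of the NB and IN stages
#' @param min_div_nsc,max_div_nsc,p_nsc NSC division law; NSCs divide
#'   asymmetrically (one ANP emitted per division), never die, and become
#'   astrocytes after their final division
#' @param include_in logical; model an explicit immature-neuron compartment
#'   between NB and GC (off by default: NB survivors become granule cells)
#' @return An object of class \code{cascade_parameters}.
#' @examples
#' p <- cascade_parameters()
#' p$d_nb
#' @export
cascade_parameters <- function(influx_anp = 1,
                               influx_nsc = 1,
                               min_div_anp = 1,
                               max_div_anp = 4,
                               p_anp = 0.1,
                               t_g1_anp = c(12, 9, 3),
                               t_s_anp = c(12, 22, 4),
                               t_g2m_anp = c(1, 12, 0.5),
                               t_anp_nb = c(12, 9, 3),
                               t_anp_apop = c(48, 9, 2),
                               t_nb = c(260, 2, 20),
                               t_in = c(120, 2, 20),
                               t_apop = c(1.4, 9, 0.15),
                               t_g1_nsc = c(28, 9, 3.5),
                               t_s_nsc = c(11, 22, 2.5),
                               t_g2m_nsc = c(3, 12, 0.375),
                               d_g1 = 0.14,
                               d_s = 0,
                               d_g2m = 0.02,
                               d_anp = 0.33,
                               d_nb = 0.97,
                               d_in = 0,
                               min_div_nsc = 2,
                               max_div_nsc = 5,
                               p_nsc = 0.57,
                               include_in = FALSE) {
  as_sg <- function(x, what) {
    if (inherits(x, "shifted_gamma")) return(x)
    if (is.numeric(x) && length(x) == 3L)
      return(sg_from_mean(x[1L], x[2L], x[3L]))
    stop("duration '", what,
         "' must be a shifted_gamma or a c(mean, shape, min) triple")
  }
  check_division_law(min_div_anp, max_div_anp, p_anp)
  check_division_law(min_div_nsc, max_div_nsc, p_nsc)
  for (d in c(d_g1 = d_g1, d_s = d_s, d_g2m = d_g2m, d_anp = d_anp,
              d_nb = d_nb, d_in = d_in)) {
    if (!is.finite(d) || d < 0 || d > 1)
      stop("invalid parameter: death rates must lie in [0, 1]")
  }
  if (!is.finite(influx_anp) || influx_anp < 0)
    stop("invalid parameter: influx_anp must be non-negative")
  if (!is.finite(influx_nsc) || influx_nsc < 0)
    stop("invalid parameter: influx_nsc must be non-negative")

  obj <- list(
    influx_anp = influx_anp, influx_nsc = influx_nsc,
    min_div_anp = as.integer(min_div_anp),
    max_div_anp = as.integer(max_div_anp),
    p_anp = p_anp,
    t_g1_anp = as_sg(t_g1_anp, "t_g1_anp"),
    t_s_anp = as_sg(t_s_anp, "t_s_anp"),
    t_g2m_anp = as_sg(t_g2m_anp, "t_g2m_anp"),
    t_anp_nb = as_sg(t_anp_nb, "t_anp_nb"),
    t_anp_apop = as_sg(t_anp_apop, "t_anp_apop"),
    t_nb = as_sg(t_nb, "t_nb"),
    t_in = as_sg(t_in, "t_in"),
    t_apop = as_sg(t_apop, "t_apop"),
    t_g1_nsc = as_sg(t_g1_nsc, "t_g1_nsc"),
    t_s_nsc = as_sg(t_s_nsc, "t_s_nsc"),
    t_g2m_nsc = as_sg(t_g2m_nsc, "t_g2m_nsc"),
    d_g1 = d_g1, d_s = d_s, d_g2m = d_g2m, d_anp = d_anp,
    d_nb = d_nb, d_in = d_in,
    min_div_nsc = as.integer(min_div_nsc),
    max_div_nsc = as.integer(max_div_nsc),
    p_nsc = p_nsc,
    include_in = isTRUE(include_in)
  )
  class(obj) <- "cascade_parameters"
  obj
}

#' @export
print.cascade_parameters <- function(x, ...) {
  cat("Neurogenic-cascade parameters\n")
  cat(sprintf("  ANP divisions: %d..%d, renewal p = %.3g (expected %.2f)\n",
              x$min_div_anp, x$max_div_anp, x$p_anp,
              expected_divisions(x$min_div_anp, x$max_div_anp, x$p_anp)))
  cat(sprintf("  NSC divisions: %d..%d, renewal p = %.3g (expected %.2f)\n",
              x$min_div_nsc, x$max_div_nsc, x$p_nsc,
              expected_divisions(x$min_div_nsc, x$max_div_nsc, x$p_nsc)))
  cat(sprintf("  death rates: G1 %.2f, S %.2f, G2M %.2f, np-ANP %.2f, NB %.2f\n",
              x$d_g1, x$d_s, x$d_g2m, x$d_anp, x$d_nb))
  cat(sprintf("  influx: lambda = %.4g ANP/h, mu = %.4g activations/h\n",
              x$influx_anp, x$influx_nsc))
  cat(sprintf("  immature-neuron compartment: %s\n",
              if (x$include_in) "enabled" else "disabled (NB -> GC)"))
  invisible(x)
}

sg_fields <- c("t_g1_anp", "t_s_anp", "t_g2m_anp", "t_anp_nb", "t_anp_apop",
               "t_nb", "t_in", "t_apop", "t_g1_nsc", "t_s_nsc", "t_g2m_nsc")
scalar_fields <- c("influx_anp", "influx_nsc", "min_div_anp", "max_div_anp",
                   "p_anp", "d_g1", "d_s", "d_g2m", "d_anp", "d_nb", "d_in",
                   "min_div_nsc", "max_div_nsc", "p_nsc", "include_in")

#' Flatten parameters to a named list
#'
#' Durations become \code{<name>_mean}, \code{<name>_shape}, \code{<name>_min}
#' entries; used for YAML serialization and for the genetic-algorithm encoding.
#'
#' @param params a \code{cascade_parameters} object
#' @return named list of scalars
#' @export
params_to_list <- function(params) {
  out <- params[scalar_fields]
  for (f in sg_fields) {
    sg <- params[[f]]
    out[[paste0(f, "_mean")]] <- sg_mean(sg)
    out[[paste0(f, "_shape")]] <- sg$shape
    out[[paste0(f, "_min")]] <- sg$shift
  }
  out
}

#' Rebuild parameters from a flat named list
#'
#' Inverse of \code{\link{params_to_list}}; missing entries keep their
#' defaults.
#'
#' @param x named list or vector of scalars
#' @return a \code{cascade_parameters} object
#' @export
params_from_list <- function(x) {
  x <- as.list(x)
  args <- list()
  for (f in scalar_fields) if (!is.null(x[[f]])) args[[f]] <- x[[f]]
  for (f in sg_fields) {
    keys <- paste0(f, c("_mean", "_shape", "_min"))
    if (all(keys %in% names(x)))
      args[[f]] <- c(x[[keys[1L]]], x[[keys[2L]]], x[[keys[3L]]])
  }
  do.call(cascade_parameters, args)
}

#' Update named entries of a parameter set
#'
#' Convenience for the search and recovery machinery: takes flat names as in
#' \code{\link{params_to_list}} (e.g. \code{d_nb}, \code{t_nb_mean}) and
#' returns a rebuilt, re-validated parameter object.
#'
#' @param params a \code{cascade_parameters} object
#' @param values named list/vector of flat parameter values
#' @export
update_parameters <- function(params, values) {
  flat <- params_to_list(params)
  values <- as.list(values)
  unknown <- setdiff(names(values), names(flat))
  if (length(unknown))
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
  flat[names(values)] <- values
  params_from_list(flat)
}

#' Read / write a parameter set as a flat YAML document
#'
#' @param path file path
#' @rdname params_yaml
#' @export
read_parameters <- function(path) {
  params_from_list(yaml::read_yaml(path))
}

#' @param params a \code{cascade_parameters} object
#' @rdname params_yaml
#' @export
write_parameters <- function(params, path) {
  yaml::write_yaml(params_to_list(params), path)
  invisible(path)
}

#' Expected number of ANPs emitted per NSC activation episode
#'
#' Under asymmetric division each activated NSC releases one ANP per division,
#' so the expected emission count is the mean number of sequential divisions.
#'
#' @param params a \code{cascade_parameters} object
#' @export
nsc_expected_anps <- function(params) {
  expected_division_count(params$min_div_nsc, params$max_div_nsc, params$p_nsc)
}
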