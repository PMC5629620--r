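#' Compartment layout of the cascade
#'
#' Enumerates the model compartments in topological order: optional NSC
#' cell-cycle generations, the ANP cell-cycle generations 1..b (each with G1,
#' S, G2M), the ANP-NB and ANP-Apop transition stages, NB, the optional
#' immature-neuron stage, the apoptotic compartment, and (optionally) the
#' absorbing granule-cell and astrocyte compartments. Because every transition
#' moves strictly forward in this order, the expected-progeny matrix is
#' nilpotent and the renewal series for the expectation matrix terminates.
#'
#' @param params a \code{\link{cascade_parameters}} object
#' @param include_nsc include the NSC generations and their asymmetric
#'   emission of newborn ANPs
#' @param include_in include the immature-neuron compartment between NB and GC
#' @param include_absorbing append absorbing GC and Astro compartments
#' @return data.frame with columns \code{name}, \code{class} (observable
#'   class), \code{lineage}, \code{phase}, \code{gen}, \code{duration} (name
#'   of the duration entry in \code{params}, NA for absorbing compartments).
#' @export
compartment_table <- function(params, include_nsc = TRUE,
                              include_in = params$include_in,
                              include_absorbing = TRUE) {
  rows <- list()
  add <- function(name, class, lineage, phase, gen, duration) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, class = class, lineage = lineage, phase = phase,
      gen = gen, duration = duration, stringsAsFactors = FALSE)
  }
  if (include_nsc) {
    for (g in seq_len(params$max_div_nsc)) {
      add(sprintf("NSC_G1_%d", g), "NSC", "NSC", "G1", g, "t_g1_nsc")
      add(sprintf("NSC_S_%d", g), "NSC", "NSC", "S", g, "t_s_nsc")
      add(sprintf("NSC_G2M_%d", g), "NSC", "NSC", "G2M", g, "t_g2m_nsc")
    }
  }
  for (g in seq_len(params$max_div_anp)) {
    add(sprintf("ANP_G1_%d", g), "ANP", "ANP", "G1", g, "t_g1_anp")
    add(sprintf("ANP_S_%d", g), "ANP", "ANP", "S", g, "t_s_anp")
    add(sprintf("ANP_G2M_%d", g), "ANP", "ANP", "G2M", g, "t_g2m_anp")
  }
  # non-proliferating ANP transition stages still count as ANPs observably
  add("ANP_NB", "ANP", "ANP", "trans", NA, "t_anp_nb")
  add("NB", "NB", "NB", "stage", NA, "t_nb")
  if (include_in) add("IN", "IN", "IN", "stage", NA, "t_in")
  add("ANP_APOP", "ANP", "ANP", "trans", NA, "t_anp_apop")
  add("APOP", "APOP", "APOP", "stage", NA, "t_apop")
  if (include_absorbing) {
    add("GC", "GC", "GC", "absorbing", NA, NA)
    add("ASTRO", "ASTRO", "ASTRO", "absorbing", NA, NA)
  }
  do.call(rbind, rows)
}

#' Expected-progeny (transition) matrix of the cascade
#'
#' Entry \eqn{m_{ij}} is the expected number of type-\eqn{j} cells produced at
#' the end of life of a type-\eqn{i} cell. Cell death is a competing fate at
#' the end of every stage: a cycle-phase row routes \eqn{1 - d_i} forward and
#' \eqn{d_i} to the apoptotic compartment. A surviving ANP G2M cell divides
#' into two daughters; before the minimum division count both daughters
#' continue cycling, between the minimum and the maximum each daughter
#' continues with the renewal probability \eqn{p} and otherwise becomes a
#' non-proliferating ANP that routes to the ANP-NB transition stage with
#' probability \eqn{1 - d_{ANP}} or to ANP-Apop with \eqn{d_{ANP}}; at the
#' maximum division count both daughters are non-proliferating. NSC rows have
#' no death; each NSC G2M division emits one newborn ANP into the first ANP
#' G1 compartment while the NSC itself continues (or becomes an astrocyte
#' after its final division).
#'
#' @inheritParams compartment_table
#' @return A square matrix of class \code{transition_matrix} with compartment
#'   dimnames and attributes \code{compartments} (the layout data.frame) and
#'   \code{durations} (named list of \code{shifted_gamma} objects, NULL for
#'   absorbing compartments).
#' @export
build_transition_matrix <- function(params, include_nsc = TRUE,
                                    include_in = params$include_in,
                                    include_absorbing = TRUE) {
  comp <- compartment_table(params, include_nsc, include_in, include_absorbing)
  n <- nrow(comp)
  m <- matrix(0, n, n, dimnames = list(comp$name, comp$name))
  has <- function(x) x %in% comp$name
  put <- function(i, j, v) if (has(j)) m[i, j] <<- m[i, j] + v else NULL

  a <- params$min_div_anp; b <- params$max_div_anp; p <- params$p_anp
  dbar <- function(d) 1 - d

  for (g in seq_len(b)) {
    g1 <- sprintf("ANP_G1_%d", g); s <- sprintf("ANP_S_%d", g)
    g2m <- sprintf("ANP_G2M_%d", g)
    m[g1, s] <- dbar(params$d_g1); put(g1, "APOP", params$d_g1)
    m[s, g2m] <- dbar(params$d_s); put(s, "APOP", params$d_s)
    surv <- dbar(params$d_g2m)
    put(g2m, "APOP", params$d_g2m)
    # per-daughter continuation probability at the end of division g
    renew <- if (g < a) 1 else if (g < b) p else 0
    if (renew > 0)
      m[g2m, sprintf("ANP_G1_%d", g + 1L)] <- 2 * surv * renew
    stop_p <- 1 - renew
    if (stop_p > 0) {
      m[g2m, "ANP_NB"] <- 2 * surv * stop_p * dbar(params$d_anp)
      m[g2m, "ANP_APOP"] <- 2 * surv * stop_p * params$d_anp
    }
  }
  m["ANP_NB", "NB"] <- 1
  put("ANP_APOP", "APOP", 1)
  nb_next <- if (include_in) "IN" else "GC"
  put("NB", nb_next, dbar(params$d_nb))
  put("NB", "APOP", params$d_nb)
  if (include_in) {
    put("IN", "GC", dbar(params$d_in))
    put("IN", "APOP", params$d_in)
  }

  if (include_nsc) {
    an <- params$min_div_nsc; bn <- params$max_div_nsc; pn <- params$p_nsc
    for (g in seq_len(bn)) {
      g1 <- sprintf("NSC_G1_%d", g); s <- sprintf("NSC_S_%d", g)
      g2m <- sprintf("NSC_G2M_%d", g)
      m[g1, s] <- 1
      m[s, g2m] <- 1
      m[g2m, "ANP_G1_1"] <- 1          # asymmetric emission of one ANP
      renew <- if (g < an) 1 else if (g < bn) pn else 0
      if (renew > 0) m[g2m, sprintf("NSC_G1_%d", g + 1L)] <- renew
      if (renew < 1) put(g2m, "ASTRO", 1 - renew)
    }
  }

  durations <- stats::setNames(vector("list", n), comp$name)
  for (i in seq_len(n)) {
    if (!is.na(comp$duration[i])) durations[[i]] <- params[[comp$duration[i]]]
  }
  structure(m, compartments = comp, durations = durations,
            class = c("transition_matrix", "matrix", "array"))
}

#' Drop absorbing compartments from a transition matrix
#'
#' Returns the sub-matrix over transient (mortal) compartments, used for the
#' stationary state \eqn{\pi = \lambda (I - m)^{-1} E[T]} and for spectral
#' checks.
#'
#' @param m a \code{transition_matrix}
#' @export
transient_submatrix <- function(m) {
  comp <- attr(m, "compartments")
  keep <- comp$phase != "absorbing"
  out <- m[keep, keep, drop = FALSE]
  structure(out, compartments = comp[keep, , drop = FALSE],
            durations = attr(m, "durations")[keep],
            class = class(m))
}
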