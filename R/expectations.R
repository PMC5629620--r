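#' Lebesgue-Stieltjes convolution on a uniform grid
#'
#' Computes \eqn{(f * T)(t) = \int_0^t f(t - \tau)\, dT(\tau)} for a function
#' and a cdf sampled on the same uniform grid, using trapezoidal weighting of
#' \eqn{f} against the cdf increments. FFT-based; internal workhorse of the
#' renewal-equation solver but exported for testing and reuse.
#'
#' @param f numeric vector, \eqn{f(t_i)} on the grid \eqn{t_i = i \Delta}
#' @param cdf numeric vector, \eqn{T(t_i)} on the same grid
#' @return numeric vector of the same length; first element is 0
#' @export
conv_ls <- function(f, cdf) {
  L <- length(f)
  stopifnot(length(cdf) == L)
  if (L < 2L) return(0 * f)
  G <- L - 1L
  dT <- diff(cdf)
  g <- 0.5 * (f[-L] + f[-1L])
  nf <- stats::nextn(2L * G)
  cv <- Re(stats::fft(stats::fft(c(dT, numeric(nf - G))) *
                        stats::fft(c(g, numeric(nf - G))), inverse = TRUE)) / nf
  c(0, cv[seq_len(G)])
}

# multiply every time-slice of M (L x I x I) by the progeny matrix m:
# result[t, i, j] = sum_k m[i, k] M[t, k, j]
tensor_premultiply <- function(m, M) {
  d <- dim(M); L <- d[1L]; I <- d[2L]
  Mk <- matrix(aperm(M, c(2L, 1L, 3L)), I, L * I)
  aperm(array(m %*% Mk, c(I, L, I)), c(2L, 1L, 3L))
}

#' Solve the renewal equation for the expectation matrix M(t)
#'
#' The expected-count matrix of the multitype age-dependent branching process
#' satisfies \eqn{M = T * (m M) + (I - T)}, where \eqn{T} is the diagonal of
#' lifetime cdfs, \eqn{m} the expected-progeny matrix and \eqn{*} the
#' Lebesgue-Stieltjes convolution; its unique locally-bounded-variation
#' solution is the series \eqn{M = \sum_k (T m)^{*k} * (I - T)}. The solver
#' iterates the recursion on a uniform time grid until successive iterates
#' differ by less than \code{tol} in max norm. Because the cascade's
#' compartment graph is acyclic, the series terminates after at most one term
#' per compartment and convergence is exact up to quadrature error.
#'
#' Absorbing compartments (no duration) have \eqn{T \equiv 0}: once entered,
#' they are occupied forever.
#'
#' @param m a \code{\link{build_transition_matrix}} result (carries the
#'   per-compartment durations), or a plain matrix if \code{durations} is
#'   given explicitly
#' @param horizon end of the time grid (hours)
#' @param step grid step \eqn{\Delta} (hours); the default 0.1 h resolves the
#'   shortest stage of the default cascade (apoptotic clearance, ~1.4 h) with
#'   more than ten points
#' @param durations optional named list of \code{\link{shifted_gamma}}
#'   objects (NULL entries = absorbing), overriding the attribute on \code{m}
#' @param tol max-norm convergence tolerance
#' @param max_iter iteration cap; exceeded only for cyclic models
#' @return An object of class \code{expectation_solution}: list with
#'   \code{times}, \code{M} (array time x ancestor x compartment),
#'   \code{iterations}, \code{residual}.
#' @examples
#' p <- cascade_parameters()
#' tm <- build_transition_matrix(p, include_nsc = FALSE)
#' sol <- solve_expectation_matrix(tm, horizon = 24, step = 0.5)
#' dim(sol$M)
#' @export
solve_expectation_matrix <- function(m, horizon, step = 0.1,
                                     durations = attr(m, "durations"),
                                     tol = 1e-10, max_iter = 200L) {
  stopifnot(step > 0, horizon >= step)
  labels <- colnames(m)
  I <- ncol(m)
  if (is.null(durations) || length(durations) != I)
    stop("a duration (or NULL for absorbing) is required for every compartment")
  times <- seq(0, horizon, by = step)
  L <- length(times)
  cdfs <- matrix(0, L, I)
  for (i in seq_len(I)) {
    if (!is.null(durations[[i]])) cdfs[, i] <- sg_cdf(durations[[i]], times)
  }
  one_minus_T <- 1 - cdfs

  M <- array(0, c(L, I, I))
  for (i in seq_len(I)) M[, i, i] <- one_minus_T[, i]

  m_plain <- unclass(m)
  residual <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    P <- tensor_premultiply(m_plain, M)
    Mnew <- array(0, c(L, I, I))
    for (i in seq_len(I)) {
      if (all(cdfs[, i] == 0)) next      # absorbing ancestor: T*(..) term is 0
      Mnew[, i, ] <- apply(P[, i, , drop = FALSE], 3L,
                           function(col) conv_ls(col, cdfs[, i]))
    }
    for (i in seq_len(I)) Mnew[, i, i] <- Mnew[, i, i] + one_minus_T[, i]
    residual <- max(abs(Mnew - M))
    M <- Mnew
    if (residual < tol) break
  }
  if (residual >= tol)
    stop(sprintf(
      "renewal-equation iteration did not converge in %d iterations (residual %.3g)",
      max_iter, residual))
  structure(list(times = times, M = M, labels = labels,
                 compartments = attr(m, "compartments"),
                 iterations = iter, residual = residual),
            class = "expectation_solution")
}

#' @export
print.expectation_solution <- function(x, ...) {
  cat(sprintf(
    "expectation solution: %d compartments, grid 0..%g h (step %g), %d iterations\n",
    length(x$labels), max(x$times), x$times[2L] - x$times[1L], x$iterations))
  invisible(x)
}

#' Expected-count curves from an ancestor weighting
#'
#' Contracts the expectation matrix with a vector of ancestor weights (for
#' instance the labeled stationary state \eqn{\pi_s}), giving the expected
#' number of cells per compartment over time.
#'
#' @param sol an \code{expectation_solution}
#' @param weights named numeric vector of ancestor weights; names must be
#'   compartment labels, missing compartments get weight 0
#' @return data.frame with column \code{time_h} and one column per compartment
#' @export
expectation_curve <- function(sol, weights) {
  w <- stats::setNames(numeric(length(sol$labels)), sol$labels)
  if (is.null(names(weights)))
    stop("weights must be named by compartment")
  unknown <- setdiff(names(weights), sol$labels)
  if (length(unknown))
    stop("unknown compartment(s) in weights: ", paste(unknown, collapse = ", "))
  w[names(weights)] <- weights
  L <- length(sol$times); I <- length(sol$labels)
  out <- matrix(w, 1, I) %*% matrix(aperm(sol$M, c(2L, 1L, 3L)), I, L * I)
  curves <- matrix(out, L, I, dimnames = list(NULL, sol$labels))
  cbind(data.frame(time_h = sol$times), as.data.frame(curves))
}

stationary_from_matrix <- function(m_trans, mean_durations, influx, ancestor_row) {
  I <- nrow(m_trans)
  inv <- tryCatch(solve(diag(I) - unclass(m_trans)),
                  error = function(e)
                    stop("structural error: (I - m) is singular, the model ",
                         "contains a non-dissipative cycle"))
  influx * (inv %*% diag(mean_durations, I))[ancestor_row, ]
}

#' Stationary population state under Poisson influx
#'
#' With a constant Poisson influx of ancestors, the expected steady-state
#' count per transient compartment is
#' \deqn{\pi = \left(\lambda\, (I - m)^{-1} E[T]\right)^{(entry)}}
#' where \eqn{E[T]} is the diagonal matrix of expected durations and
#' \eqn{(\cdot)^{(entry)}} the row of the entry compartment. Absorbing
#' compartments (GC, Astro) have no steady state — their counts grow without
#' bound — and are excluded.
#'
#' Two independent Poisson streams feed the cascade: newborn ANPs arriving at
#' rate \eqn{\lambda} (\code{influx_anp}) into the first ANP G1 compartment,
#' and NSC activations at rate \eqn{\mu} (\code{influx_nsc}) into the first
#' NSC G1 compartment. For \code{ancestor = "combined"} the result is the
#' \eqn{\lambda}-seeded ANP-lineage occupancy plus the \eqn{\mu}-seeded
#' occupancy of the NSC compartments only: \eqn{\lambda} already measures the
#' total arrival rate of newborn ANPs, so the ANPs emitted by the tracked NSC
#' stream are not added a second time.
#'
#' @param params a \code{\link{cascade_parameters}} object
#' @param ancestor \code{"combined"} (default), \code{"anp"} (newborn-ANP
#'   entry only) or \code{"nsc"} (NSC-activation entry, including the emitted
#'   ANP lineage)
#' @param include_in model the immature-neuron compartment
#' @return An object of class \code{stationary_state}: named numeric vector of
#'   expected counts over the transient compartments, with the compartment
#'   layout and the influx intensities as attributes.
#' @examples
#' pi <- stationary_distribution(cascade_parameters())
#' sum(labeled_initial_state(pi))
#' @export
stationary_distribution <- function(params,
                                    ancestor = c("combined", "anp", "nsc"),
                                    include_in = params$include_in) {
  ancestor <- match.arg(ancestor)
  tm <- build_transition_matrix(params, include_nsc = TRUE,
                                include_in = include_in,
                                include_absorbing = TRUE)
  mt <- transient_submatrix(tm)
  comp <- attr(mt, "compartments")
  durs <- attr(mt, "durations")
  ET <- vapply(durs, sg_mean, numeric(1))
  rho <- max(Mod(eigen(unclass(mt), only.values = TRUE)$values))
  if (rho >= 1)
    stop("spectral radius of the transient progeny matrix is ", signif(rho, 4),
         " >= 1: the population is not dissipative and no stationary state exists")
  pi_anp <- stationary_from_matrix(mt, ET, params$influx_anp, "ANP_G1_1")
  pi_nsc <- stationary_from_matrix(mt, ET, params$influx_nsc, "NSC_G1_1")
  pi <- switch(ancestor,
    anp = pi_anp,
    nsc = pi_nsc,
    combined = pi_anp + ifelse(comp$lineage == "NSC", pi_nsc, 0))
  structure(stats::setNames(as.numeric(pi), comp$name),
            compartments = comp,
            influx = c(anp = params$influx_anp, nsc = params$influx_nsc),
            ancestor = ancestor,
            class = "stationary_state")
}

#' @export
print.stationary_state <- function(x, ...) {
  cat(sprintf("stationary state (%s ancestors); total %.4g cells over %d transient compartments\n",
              attr(x, "ancestor"), sum(x), length(x)))
  print(round(unclass(x)[x > 0], 3))
  cat("absorbing compartments (GC, Astro) have no steady state and are excluded\n")
  invisible(x)
}

#' Expected BrdU-labeled cells at the moment of injection
#'
#' A BrdU pulse labels exactly the cells in S phase, so the expected labeled
#' population at \eqn{t = 0} is the stationary state restricted to the
#' S-phase compartments (every ANP generation's S and every NSC generation's
#' S); the total is \eqn{\pi_s}.
#'
#' @param pi a \code{\link{stationary_distribution}} result
#' @return named numeric vector over S-phase compartments
#' @export
labeled_initial_state <- function(pi) {
  comp <- attr(pi, "compartments")
  s <- comp$phase == "S"
  stats::setNames(as.numeric(pi)[s], comp$name[s])
}
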