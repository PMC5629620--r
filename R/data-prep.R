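#' Observed pulse-chase dataset
#'
#' Container for the two measurement tables of a BrdU pulse-and-chase
#' experiment: per-timepoint total and apoptotic BrdU+ cell counts
#' (mean, sem, number of animals) and per-type BrdU+ proportions
#' (NSC/ANP from one staining experiment, NB/GC from another).
#'
#' @param counts data.frame with columns \code{time_h}, \code{n},
#'   \code{total_mean}, \code{total_sem}, \code{apop_mean}, \code{apop_sem}
#' @param proportions data.frame with columns \code{time_h}, \code{n_nscanp},
#'   \code{nsc}, \code{nsc_sem}, \code{anp}, \code{anp_sem}, \code{n_nbgc},
#'   \code{nb}, \code{nb_sem}, \code{gc}, \code{gc_sem}; proportions as
#'   fractions in [0, 1], NA where not measured
#' @return An object of class \code{observed_dataset}.
#' @export
observed_dataset <- function(counts, proportions) {
  need_c <- c("time_h", "n", "total_mean", "total_sem", "apop_mean", "apop_sem")
  need_p <- c("time_h", "n_nscanp", "nsc", "nsc_sem", "anp", "anp_sem",
              "n_nbgc", "nb", "nb_sem", "gc", "gc_sem")
  if (!all(need_c %in% names(counts)))
    stop("counts table lacks column(s): ",
         paste(setdiff(need_c, names(counts)), collapse = ", "))
  if (!all(need_p %in% names(proportions)))
    stop("proportions table lacks column(s): ",
         paste(setdiff(need_p, names(proportions)), collapse = ", "))
  num <- unlist(counts[, setdiff(need_c, "time_h")])
  if (any(num < 0, na.rm = TRUE)) stop("counts must be non-negative")
  pv <- unlist(proportions[, c("nsc", "anp", "nb", "gc")])
  if (any(pv < 0 | pv > 1, na.rm = TRUE))
    stop("proportions must lie in [0, 1]")
  structure(list(counts = counts, proportions = proportions),
            class = "observed_dataset")
}

#' @export
print.observed_dataset <- function(x, ...) {
  cat(sprintf("pulse-chase dataset: %d count timepoints, %d proportion timepoints\n",
              nrow(x$counts), nrow(x$proportions)))
  invisible(x)
}

#' Re-proportion double-labeled ANP/NB fractions
#'
#' At intermediate chase times cells transiting from ANP to NB are picked up
#' by both markers, so the per-type proportions sum to more than one. The
#' correction fixes the NSC, GC and apoptotic proportions as observed, sets
#' the target joint ANP+NB proportion to \eqn{d_t = 1 - (p_{NSC} + p_{GC} +
#' p_{Apop})}, and removes the excess \eqn{e = p_{ANP} + p_{NB} - d_t} from
#' the two classes in the split \eqn{(1-\alpha) : \alpha}:
#' \deqn{ANP' = \alpha X_1 + (\alpha - 1) X_2 + (1 - \alpha) d_t, \qquad
#'       NB' = -\alpha X_1 + (1 - \alpha) X_2 + \alpha d_t.}
#' With no prior knowledge of the double-labeled split, \eqn{\alpha = 1/2}.
#' Standard errors propagate through the linear map (the two input
#' proportions are measured in different animals, so their covariance is
#' taken as zero).
#'
#' @param p_anp,p_nb observed ANP and NB proportions (fractions)
#' @param p_other sum of the remaining observed proportions (NSC + GC +
#'   apoptotic fraction) at the same timepoint
#' @param alpha fraction of the excess attributed to the ANP class
#' @param sem_anp,sem_nb standard errors of the two proportions
#' @return list with \code{p_anp}, \code{p_nb}, \code{sem_anp}, \code{sem_nb},
#'   \code{excess}, and \code{adjusted} (FALSE when there was no excess and
#'   the inputs are returned unchanged)
#' @examples
#' # day-1 measurements: excess removed in equal halves
#' reproportion(0.6014, 0.5194, 0.0568 + 0.002 + 40 / 5392)
#' @export
reproportion <- function(p_anp, p_nb, p_other, alpha = 0.5,
                         sem_anp = NA_real_, sem_nb = NA_real_) {
  stopifnot(length(p_anp) == 1L, length(p_nb) == 1L, length(p_other) == 1L)
  if (any(c(p_anp, p_nb, p_other) < 0) || any(c(p_anp, p_nb, p_other) > 1))
    stop("proportions must lie in [0, 1]")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  d_t <- 1 - p_other
  if (d_t <= 0)
    stop("invalid input: the non-ANP/NB proportions already sum to ",
         p_other, " >= 1, leaving no room for ANP + NB")
  excess <- p_anp + p_nb - d_t
  if (excess < 0) {
    return(list(p_anp = p_anp, p_nb = p_nb,
                sem_anp = sem_anp, sem_nb = sem_nb,
                excess = excess, adjusted = FALSE,
                note = "no double labeling detected; inputs returned unchanged"))
  }
  A <- matrix(c(alpha, -alpha, alpha - 1, 1 - alpha), 2L, 2L)
  adj <- A %*% c(p_anp, p_nb) + c((1 - alpha) * d_t, alpha * d_t)
  Sig <- A %*% diag(c(sem_anp^2, sem_nb^2)) %*% t(A)
  list(p_anp = adj[1L], p_nb = adj[2L],
       sem_anp = sqrt(Sig[1L, 1L]), sem_nb = sqrt(Sig[2L, 2L]),
       excess = excess, adjusted = TRUE)
}

#' Transform a cell-type proportion into a count estimate
#'
#' The number of BrdU+ cells of one type is modeled as binomial given the
#' (Gaussian) total count \eqn{Y} and the (Gaussian) proportion \eqn{P},
#' assumed independent. The marginal moments are
#' \deqn{E[X] = \bar{Y} \bar{P}, \qquad
#'   V[X] = S_P^2 (\bar{Y}^2 + S_Y^2 - \bar{Y}) +
#'          \bar{P}^2 (S_Y^2 - \bar{Y}) + \bar{Y}\bar{P}.}
#' The reported sems enter directly as the \eqn{S} terms. In the rare case
#' the formula goes negative (tiny \eqn{S_P} with \eqn{S_Y^2 < \bar{Y}}) the
#' variance is clamped at the binomial value \eqn{\bar{Y}\bar{P}(1-\bar{P})}
#' with a warning.
#'
#' @param y_mean,y_sem mean and sem of the total BrdU+ count
#' @param p_mean,p_sem mean and sem of the type proportion (fractions);
#'   vectorized over types
#' @return data.frame with columns \code{mean} and \code{sem}
#' @examples
#' counts_from_proportions(5392, 557, 0.5079, 0.0323)  # ~2738 (335)
#' @export
counts_from_proportions <- function(y_mean, y_sem, p_mean, p_sem) {
  stopifnot(all(y_mean > 0), all(p_mean >= 0 & p_mean <= 1))
  m <- y_mean * p_mean
  v <- p_sem^2 * (y_mean^2 + y_sem^2 - y_mean) +
    p_mean^2 * (y_sem^2 - y_mean) + y_mean * p_mean
  neg <- !is.na(v) & v < 0
  if (any(neg)) {
    warning("variance formula negative for ", sum(neg),
            " entr(y/ies); clamped at the binomial variance")
    v[neg] <- (y_mean * p_mean * (1 - p_mean))[neg]
  }
  data.frame(mean = m, sem = sqrt(v))
}

#' Prepare an observed dataset for model fitting
#'
#' Runs the two preprocessing steps of the pipeline on a pulse-chase dataset:
#' re-proportioning of the double-labeled ANP/NB fractions at the
#' intermediate timepoints, and transformation of every available proportion
#' into a count estimate with propagated uncertainty. Returns the adjusted
#' proportion table, the per-type count table, and the flat measurement table
#' (one row per non-zero timepoint/class observation) that the
#' variance-weighted objective consumes.
#'
#' @param observed an \code{\link{observed_dataset}}
#' @param alpha excess split towards the ANP class (default equal split)
#' @param adjust_times_h timepoints (hours) at which the ANP/NB proportions
#'   are double-label corrected
#' @return An object of class \code{adjusted_dataset}: list with
#'   \code{adjusted} (proportions after correction), \code{counts} (per-type
#'   count estimates) and \code{measurements} (\code{time_h}, \code{class},
#'   \code{mean}, \code{sem}; non-zero observations only).
#' @export
prepare_dataset <- function(observed, alpha = 0.5,
                            adjust_times_h = c(24, 48, 96, 192)) {
  stopifnot(inherits(observed, "observed_dataset"))
  cc <- observed$counts
  pp <- observed$proportions
  adj <- merge(pp, cc[, c("time_h", "total_mean", "apop_mean")], by = "time_h")
  adj$apop_frac <- adj$apop_mean / adj$total_mean
  adj$adjusted <- FALSE
  for (i in seq_len(nrow(adj))) {
    if (!(adj$time_h[i] %in% adjust_times_h)) next
    if (is.na(adj$anp[i]) || is.na(adj$nb[i]))
      stop("cannot re-proportion t = ", adj$time_h[i],
           " h: ANP or NB proportion missing")
    other <- sum(adj$nsc[i], adj$gc[i], adj$apop_frac[i], na.rm = TRUE)
    r <- reproportion(adj$anp[i], adj$nb[i], other, alpha = alpha,
                      sem_anp = adj$anp_sem[i], sem_nb = adj$nb_sem[i])
    adj$anp[i] <- r$p_anp; adj$anp_sem[i] <- r$sem_anp
    adj$nb[i] <- r$p_nb; adj$nb_sem[i] <- r$sem_nb
    adj$adjusted[i] <- r$adjusted
  }

  type_cols <- list(NSC = c("nsc", "nsc_sem"), ANP = c("anp", "anp_sem"),
                    NB = c("nb", "nb_sem"), GC = c("gc", "gc_sem"))
  counts_rows <- list()
  for (i in seq_len(nrow(adj))) {
    trow <- cc[cc$time_h == adj$time_h[i], ]
    for (cls in names(type_cols)) {
      p <- adj[[type_cols[[cls]][1L]]][i]
      ps <- adj[[type_cols[[cls]][2L]]][i]
      if (is.na(p)) next
      est <- counts_from_proportions(trow$total_mean, trow$total_sem, p, ps)
      counts_rows[[length(counts_rows) + 1L]] <-
        data.frame(time_h = adj$time_h[i], class = cls,
                   mean = est$mean, sem = est$sem)
    }
  }
  type_counts <- do.call(rbind, counts_rows)

  meas <- rbind(
    data.frame(time_h = cc$time_h, class = "TOTAL",
               mean = cc$total_mean, sem = cc$total_sem),
    data.frame(time_h = cc$time_h, class = "APOP",
               mean = cc$apop_mean, sem = cc$apop_sem),
    type_counts)
  meas <- meas[meas$mean > 0, ]
  meas <- meas[order(meas$time_h, meas$class), ]
  rownames(meas) <- NULL
  structure(list(adjusted = adj, counts = type_counts, measurements = meas),
            class = "adjusted_dataset")
}

#' @export
print.adjusted_dataset <- function(x, ...) {
  cat(sprintf("adjusted dataset: %d re-proportioned timepoints, %d non-zero measurements\n",
              sum(x$adjusted$adjusted), nrow(x$measurements)))
  invisible(x)
}
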