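#' Design of a synthetic pulse-chase experiment
#'
#' Describes a virtual BrdU pulse-and-chase study with the statistical
#' structure the analysis pipeline assumes: a ground-truth cascade, a set of
#' sacrifice timepoints with a fixed number of animals each, multiplicative
#' Gaussian measurement noise, and artificial ANP/NB double-labeling at the
#' intermediate timepoints (a fraction \code{overlap} of the cells occupying
#' the ANP-to-NB transition window is added to both the ANP and the NB
#' proportion, so the per-type proportions sum to more than one and exercise
#' the re-proportioning stage).
#'
#' @param params ground-truth \code{\link{cascade_parameters}}; the default
#'   uses the best-fit cascade at the calibrated influx scale of the bundled
#'   study (labeled cohort of roughly 2700 cells)
#' @param timepoints_h sacrifice times (hours); default the bundled study's
#'   design (2 h, 12 h, 1-32 d)
#' @param n_animals animals per timepoint
#' @param cv coefficient of variation of the multiplicative measurement noise
#' @param overlap double-labeling overlap fraction \eqn{\omega \in [0, 0.5]}
#' @param adjust_times_h timepoints at which the overlap inflation applies
#' @return An object of class \code{synthetic_design}.
#' @export
synthetic_design <- function(params = NULL,
                             timepoints_h = c(2, 12, 24, 48, 72, 96, 192,
                                              264, 360, 432, 528, 768),
                             n_animals = 5L,
                             cv = 0.1,
                             overlap = 0.25,
                             adjust_times_h = c(24, 48, 96, 192)) {
  if (is.null(params))
    params <- update_parameters(load_fixtures()$params,
                                list(influx_anp = 185, influx_nsc = 9))
  stopifnot(n_animals >= 1L, cv >= 0, overlap >= 0, overlap <= 0.5)
  structure(list(params = params, timepoints_h = sort(timepoints_h),
                 n_animals = as.integer(n_animals), cv = cv,
                 overlap = overlap, adjust_times_h = adjust_times_h),
            class = "synthetic_design")
}

#' Generate a synthetic pulse-chase dataset
#'
#' Every animal is an independent realization of the labeling experiment:
#' a Poisson labeled cohort drawn from the ground-truth stationary state,
#' traced through the cascade, and counted at the animal's sacrifice time.
#' Per-type proportions are computed from the realized counts, inflated by
#' the double-labeling overlap at the intermediate timepoints, and all
#' observed quantities receive multiplicative Gaussian noise at the design's
#' coefficient of variation. Per-timepoint means and sems are returned in the
#' same shape as the real measurement tables, together with the ground truth.
#'
#' @param design a \code{\link{synthetic_design}}
#' @return list with \code{observed} (an \code{\link{observed_dataset}}) and
#'   \code{truth} (ground-truth parameters and design). Uses the current R
#'   random stream.
#' @examples
#' set.seed(42)
#' d <- synthetic_design(n_animals = 2, timepoints_h = c(2, 24, 96))
#' synth <- generate_experiment(d)
#' synth$observed$counts
#' @export
generate_experiment <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  params <- design$params
  cv <- design$cv
  noisy <- function(x) pmax(0, x * (1 + cv * stats::rnorm(length(x))))
  tps <- design$timepoints_h
  n <- design$n_animals

  one_animal <- function(t) {
    founders <- sample_initial_cohort(params)
    segs <- if (nrow(founders)) simulate_cascade(founders, params) else
      data.frame(comp = character(), class = character(), id = integer(),
                 entry = numeric(), exit = numeric())
    cls <- count_alive(segs, t, by = "class",
                       levels = c("NSC", "ANP", "NB", "GC", "ASTRO", "APOP"))
    cnt <- stats::setNames(cls$count, cls$group)
    total <- cnt[["TOTAL"]]
    window <- sum(segs$comp == "ANP_NB" & segs$entry <= t & segs$exit > t)
    props <- if (total > 0) cnt / total else cnt * 0
    p_window <- if (total > 0) window / total else 0
    if (t %in% design$adjust_times_h) {
      props[["ANP"]] <- props[["ANP"]] + design$overlap * p_window
      props[["NB"]] <- props[["NB"]] + design$overlap * p_window
    }
    c(total = noisy(total), apop = noisy(cnt[["APOP"]]),
      nsc = min(1, noisy(props[["NSC"]])),
      anp = min(1, noisy(props[["ANP"]])),
      nb = min(1, noisy(props[["NB"]])),
      gc = min(1, noisy(props[["GC"]])))
  }

  counts <- list(); props <- list()
  for (t in tps) {
    obs <- vapply(seq_len(n), function(j) one_animal(t), numeric(6))
    mu <- rowMeans(obs)
    sem <- apply(obs, 1L, stats::sd) / sqrt(n)
    if (n == 1L) sem[] <- 0
    counts[[length(counts) + 1L]] <- data.frame(
      time_h = t, n = n,
      total_mean = mu[["total"]], total_sem = sem[["total"]],
      apop_mean = mu[["apop"]], apop_sem = sem[["apop"]])
    props[[length(props) + 1L]] <- data.frame(
      time_h = t, n_nscanp = n,
      nsc = mu[["nsc"]], nsc_sem = sem[["nsc"]],
      anp = mu[["anp"]], anp_sem = sem[["anp"]],
      n_nbgc = n,
      nb = mu[["nb"]], nb_sem = sem[["nb"]],
      gc = mu[["gc"]], gc_sem = sem[["gc"]])
  }
  observed <- observed_dataset(do.call(rbind, counts), do.call(rbind, props))
  list(observed = observed,
       truth = list(params = params, design = design))
}
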