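test_that("a noiseless single-animal design returns one realization exactly", {
  set.seed(81)
  d <- synthetic_design(
    params = update_parameters(cascade_parameters(),
                               list(influx_anp = 40, influx_nsc = 2)),
    timepoints_h = c(2, 48), n_animals = 1, cv = 0, overlap = 0)
  synth <- generate_experiment(d)
  cc <- synth$observed$counts
  expect_equal(cc$total_mean, round(cc$total_mean))   # integer counts
  expect_equal(cc$total_sem, c(0, 0))
  pp <- synth$observed$proportions
  # proportions from realized counts are consistent by construction
  expect_true(all(abs(pp$nsc + pp$anp + pp$nb + pp$gc +
                        cc$apop_mean / pmax(cc$total_mean, 1) - 1) < 0.3))
})

test_that("overlap inflation makes intermediate proportions over-complete", {
  set.seed(82)
  d <- synthetic_design(
    params = update_parameters(cascade_parameters(),
                               list(influx_anp = 150, influx_nsc = 7)),
    timepoints_h = c(24, 48), n_animals = 2, cv = 0, overlap = 0.5,
    adjust_times_h = c(24, 48))
  synth <- generate_experiment(d)
  pp <- synth$observed$proportions
  cc <- synth$observed$counts
  total_prop <- pp$nsc + pp$anp + pp$nb + pp$gc +
    cc$apop_mean / cc$total_mean
  # ASTRO occupancy is excluded from the marker panel, so the inflated sum
  # must exceed 1 by roughly twice the overlap times the window occupancy
  expect_true(any(total_prop > 1))
  prep <- prepare_dataset(synth$observed, adjust_times_h = c(24, 48))
  expect_true(any(prep$adjusted$adjusted))
})

test_that("re-proportioning removes symmetric overlap inflation exactly", {
  # with cv = 0 and one animal the equal-split correction recovers the
  # uninflated ANP proportion up to half the (unmeasured) astrocyte share
  set.seed(83)
  p <- update_parameters(cascade_parameters(),
                         list(influx_anp = 120, influx_nsc = 6))
  founders <- sample_initial_cohort(p)
  segs <- simulate_cascade(founders, p)
  t <- 48
  cls <- count_alive(segs, t)
  cnt <- setNames(cls$count, cls$group)
  total <- cnt[["TOTAL"]]
  w <- sum(segs$comp == "ANP_NB" & segs$entry <= t & segs$exit > t) / total
  truth_anp <- cnt[["ANP"]] / total
  truth_nb <- cnt[["NB"]] / total
  astro <- cnt[["ASTRO"]] / total
  omega <- 0.4
  infl <- reproportion(truth_anp + omega * w, truth_nb + omega * w,
                       (cnt[["NSC"]] + cnt[["GC"]] + cnt[["APOP"]]) / total)
  expect_equal(infl$p_anp, truth_anp + astro / 2, tolerance = 1e-10)
  expect_equal(infl$p_nb, truth_nb + astro / 2, tolerance = 1e-10)
})

test_that("generated sems shrink with the animal count roughly as 1/sqrt(n)", {
  set.seed(84)
  base <- update_parameters(cascade_parameters(),
                            list(influx_anp = 60, influx_nsc = 3))
  sem_of <- function(n, reps = 12) {
    s <- replicate(reps, {
      d <- synthetic_design(params = base, timepoints_h = 24,
                            n_animals = n, cv = 0.2, overlap = 0)
      generate_experiment(d)$observed$counts$total_sem
    })
    mean(s)
  }
  s2 <- sem_of(2); s8 <- sem_of(8)
  expect_lt(s8, s2)
  expect_equal(s8 / s2, sqrt(2 / 8), tolerance = 0.5)
})

test_that("the generated tables feed the preparation pipeline end to end", {
  set.seed(85)
  d <- synthetic_design(
    params = update_parameters(cascade_parameters(),
                               list(influx_anp = 100, influx_nsc = 5)),
    timepoints_h = c(2, 24, 96, 360), n_animals = 3)
  synth <- generate_experiment(d)
  prep <- prepare_dataset(synth$observed, adjust_times_h = c(24, 96))
  expect_s3_class(prep, "adjusted_dataset")
  expect_true(all(c("TOTAL", "ANP", "NB") %in% prep$measurements$class))
  expect_true(all(prep$measurements$mean > 0))
})
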