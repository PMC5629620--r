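test_that("an empty cohort yields all-zero curves with a warning", {
  p <- update_parameters(cascade_parameters(),
                         list(influx_anp = 0, influx_nsc = 0))
  expect_warning(
    curve <- simulate_labeling_curves(p, timepoints = c(0, 24),
                                      n_replicates = 2),
    "empty")
  expect_true(all(curve$mean == 0))
})

test_that("the total count at t = 0 equals the cohort size exactly", {
  set.seed(41)
  p <- cascade_parameters(influx_anp = 20, influx_nsc = 1)
  founders <- sample_initial_cohort(p)
  segs <- simulate_cascade(founders, p)
  cnt <- count_alive(segs, 0)
  expect_equal(cnt$count[cnt$group == "TOTAL"], nrow(founders))
})

test_that("certain death at G1 sends every ANP trace to apoptotic clearance", {
  set.seed(42)
  p <- cascade_parameters(d_g1 = 1)
  tr <- simulate_cell("ANP_G1_1", p)
  expect_equal(tr$comp, c("ANP_G1_1", "APOP"))
  expect_true(all(is.finite(tr$exit)))
})

test_that("certain neuroblast death means no granule cell is ever produced", {
  set.seed(43)
  p <- cascade_parameters(d_nb = 1, influx_anp = 50, influx_nsc = 2)
  founders <- sample_initial_cohort(p)
  segs <- simulate_cascade(founders, p)
  expect_equal(sum(segs$comp == "GC"), 0)
})

test_that("without death or renewal each founder yields exactly 2^a granule cells", {
  set.seed(44)
  p <- cascade_parameters(min_div_anp = 2, max_div_anp = 4, p_anp = 0,
                          d_g1 = 0, d_s = 0, d_g2m = 0, d_anp = 0, d_nb = 0)
  founders <- data.frame(comp = "ANP_G1_1", entry = 0, dur = NA_real_,
                         id = 1:200)
  segs <- simulate_cascade(founders, p)
  gc <- segs[segs$comp == "GC", ]
  expect_equal(nrow(gc), 200 * 2^2)
  expect_equal(as.integer(table(gc$id)), rep(4L, 200))
  # all lineages terminate: far beyond the transient, only absorbing remain
  late <- max(segs$exit[is.finite(segs$exit)]) + 1
  alive <- count_alive(segs, late)
  expect_equal(sum(alive$count[!alive$group %in% c("GC", "ASTRO", "TOTAL")]), 0)
})

test_that("realized progeny counts follow the progeny pmf", {
  set.seed(45)
  p <- cascade_parameters(min_div_anp = 1, max_div_anp = 4, p_anp = 0.3,
                          d_g1 = 0, d_s = 0, d_g2m = 0, d_anp = 0)
  n <- 20000
  founders <- data.frame(comp = "ANP_G1_1", entry = 0, dur = NA_real_, id = 1:n)
  segs <- simulate_cascade(founders, p)
  # with no death every terminal daughter passes through the ANP-NB stage
  progeny <- table(factor(table(segs$id[segs$comp == "ANP_NB"]),
                          levels = c(2, 4, 8, 16)))
  pmf <- progeny_distribution(1, 4, 0.3)
  chi <- suppressWarnings(chisq.test(as.numeric(progeny), p = pmf$prob))
  expect_gt(chi$p.value, 0.01)
})

test_that("the granule-cell curve is non-decreasing", {
  set.seed(46)
  p <- cascade_parameters(influx_anp = 100, influx_nsc = 5, d_nb = 0.5)
  curve <- simulate_labeling_curves(p, timepoints = seq(0, 768, by = 48),
                                    n_replicates = 2)
  gc <- curve$mean[curve$group == "GC"]
  expect_true(all(diff(gc) >= 0))
  astro <- curve$mean[curve$group == "ASTRO"]
  expect_true(all(diff(astro) >= 0))
})

test_that("seeded runs are bit-reproducible", {
  p <- cascade_parameters(influx_anp = 30, influx_nsc = 2)
  run <- function() {
    set.seed(47)
    simulate_labeling_curves(p, timepoints = c(2, 24, 96), n_replicates = 3)
  }
  expect_identical(run(), run())
})

test_that("the total equals the sum of the class counts at every timepoint", {
  set.seed(48)
  p <- cascade_parameters(influx_anp = 50, influx_nsc = 3)
  curve <- simulate_labeling_curves(p, timepoints = c(2, 48, 360),
                                    n_replicates = 2)
  for (t in unique(curve$time_h)) {
    sub <- curve[curve$time_h == t, ]
    expect_equal(sub$mean[sub$group == "TOTAL"],
                 sum(sub$mean[sub$group != "TOTAL"]))
  }
})

test_that("start-of-S residual mode draws full fresh S-phase times", {
  set.seed(49)
  p <- cascade_parameters(influx_anp = 200, influx_nsc = 5)
  fresh <- sample_initial_cohort(p, residual_mode = "start")
  expect_true(all(fresh$dur >= p$t_s_anp$shift | startsWith(fresh$comp, "NSC")))
  # stationary-age residuals are shorter on average than full transits
  stat <- sample_initial_cohort(p, residual_mode = "stationary")
  anp_s <- startsWith(stat$comp, "ANP_S")
  expect_lt(mean(stat$dur[anp_s]), sg_mean(p$t_s_anp))
  expect_equal(mean(stat$dur[anp_s]), sg_residual_mean(p$t_s_anp),
               tolerance = 0.1)
})
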