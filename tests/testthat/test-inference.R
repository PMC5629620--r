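test_that("the variance-weighted objective behaves as a chi-square distance", {
  meas <- data.frame(time_h = c(2, 24), class = c("TOTAL", "NB"),
                     mean = c(10, 5), sem = c(2, 0))
  perfect <- data.frame(time_h = c(2, 24), group = c("TOTAL", "NB"),
                        mean = c(10, 5))
  expect_equal(objective(meas, perfect), 0)
  one <- data.frame(time_h = 2, class = "TOTAL", mean = 10, sem = 2)
  sim <- data.frame(time_h = 2, group = "TOTAL", mean = 12)
  expect_equal(objective(one, sim), 1)              # (2)^2 / 4
  # zero sem is floored, not divided by
  z <- data.frame(time_h = 24, class = "NB", mean = 5, sem = 0)
  expect_equal(objective(z, data.frame(time_h = 24, group = "NB", mean = 7)), 4)
  expect_error(objective(meas, sim), "lacks")
})

test_that("genome encoding round-trips within half a grid step", {
  fx <- load_fixtures()
  searched <- c("d_g1", "d_s", "d_g2m", "d_anp", "d_nb", "p_anp",
                "min_div_anp", "max_div_anp", "t_nb_mean", "t_apop_mean")
  sp <- search_space(fx$ranges, searched, bits = 8)
  flat <- params_to_list(fx$params)
  bits <- encode_genome(flat, sp)
  expect_equal(length(bits), sp$n_bits)
  dec <- decode_genome(bits, sp)
  for (nm in searched) {
    spec <- sp$specs[[which(vapply(sp$specs, `[[`, "", "name") == nm)]]
    halfstep <- if (length(spec$grid) > 1) max(diff(spec$grid)) / 2 else 0
    expect_lte(abs(dec[[nm]] - flat[[nm]]), halfstep + 1e-12)
    # value-level fixed point: decoded values re-encode to themselves
    expect_equal(decode_genome(encode_genome(dec, sp), sp)[[nm]], dec[[nm]])
  }
  # enumerated parameters decode onto their value set exactly
  expect_true(dec$min_div_anp %in% 1:3)
  expect_true(dec$max_div_anp %in% 2:8)
})

test_that("every bit string decodes to in-range parameters", {
  fx <- load_fixtures()
  sp <- search_space(fx$ranges, c("d_nb", "max_div_anp"), bits = 8)
  set.seed(61)
  for (i in 1:200) {
    dec <- decode_genome(runif(sp$n_bits) < 0.5, sp)
    expect_gte(dec$d_nb, 0); expect_lte(dec$d_nb, 0.99)
    expect_true(dec$max_div_anp %in% 2:8)
  }
  # a one-bit binary range gives the two endpoints
  rg <- data.frame(param = "x", kind = "range", lo = 0, hi = 1, values = NA)
  sp1 <- search_space(rg, "x", bits = 1)
  expect_equal(sp1$specs[[1]]$grid, c(0, 1))
  expect_error(encode_genome(list(d_nb = 1.2, max_div_anp = 4), sp),
               "outside its search range")
})

test_that("scale calibration recovers exact multiples and zero data", {
  unit <- data.frame(time_h = rep(c(2, 24), each = 2),
                     group = rep(c("TOTAL", "NSC"), 2),
                     anp_unit = c(8, 0, 5, 0), nsc_unit = c(1, 0.5, 0.8, 0.2))
  k <- 3.5; m <- 1.25
  meas <- data.frame(time_h = unit$time_h, class = unit$group,
                     mean = k * unit$anp_unit + m * unit$nsc_unit, sem = 1)
  sc <- neurocascade:::calibrate_from_unit(unit, meas)
  expect_equal(unname(sc), c(k, m), tolerance = 1e-10)
  meas0 <- transform(meas, mean = 0)
  expect_equal(unname(neurocascade:::calibrate_from_unit(unit, meas0)),
               c(0, 0), tolerance = 1e-10)
  # an identically-zero component with non-zero matching data is degenerate
  unit_bad <- transform(unit, anp_unit = 0, nsc_unit = 0)
  expect_error(neurocascade:::calibrate_from_unit(unit_bad, meas),
               "degenerate scale")
})

test_that("stationary calibration reproduces the early total within 2 sem", {
  fx <- load_fixtures()
  meas <- fixture_measurements()
  cal <- calibrate_influx(fx$params, meas, method = "stationary")
  set.seed(62)
  curve <- simulate_labeling_curves(cal$params, timepoints = 2,
                                    n_replicates = 10)
  tot2h <- curve$mean[curve$group == "TOTAL"]
  expect_lt(abs(tot2h - 2690), 2 * 320)
})

test_that("a small genetic-algorithm run is deterministic and monotone", {
  fx <- load_fixtures()
  meas <- fixture_measurements()
  base <- update_parameters(fx$params,
                            list(influx_anp = 20, influx_nsc = 1))
  sp <- search_space(fx$ranges, c("d_anp", "d_nb"), bits = 4)
  cfg <- ga_config(population = 8, generations = 4, n_sim_replicates = 1,
                   elitism = 1, seed = 7)
  # extreme genomes at this tiny budget can trip the negative-scale clamp
  fit1 <- suppressWarnings(run_ga(base, meas, sp, cfg))
  fit2 <- suppressWarnings(run_ga(base, meas, sp, cfg))
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$best_values, fit2$best_values)
  # with elitism the best-so-far objective never increases
  expect_true(all(diff(fit1$history) <= 0))
  expect_true(is.finite(fit1$objective))
  expect_gte(fit1$best_params$d_nb, 0)
  expect_lte(fit1$best_params$d_nb, 0.99)
})
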