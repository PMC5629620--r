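test_that("grid convolution matches a brute-force Stieltjes sum", {
  set.seed(31)
  f <- runif(41)
  sg <- shifted_gamma(2, 1.5, 0.5)
  ts <- seq(0, 8, by = 0.2)
  cdf <- sg_cdf(sg, ts)
  got <- conv_ls(f, cdf)
  ref <- numeric(41)
  for (n in 2:41) {
    s <- 0
    for (j in 2:n)
      s <- s + 0.5 * (f[n - j + 2] + f[n - j + 1]) * (cdf[j] - cdf[j - 1])
    ref[n] <- s
  }
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("a childless compartment decays as its survival function", {
  sg <- shifted_gamma(2, 3, 1)
  m <- matrix(0, 1, 1, dimnames = list("A", "A"))
  sol <- solve_expectation_matrix(m, horizon = 20, step = 0.05,
                                  durations = list(A = sg))
  expect_equal(sol$M[, 1, 1], 1 - sg_cdf(sg, sol$times))
})

test_that("the expectation matrix starts at the identity", {
  p <- toy_params()
  tm <- build_transition_matrix(p, include_nsc = FALSE)
  sol <- solve_expectation_matrix(tm, horizon = 5, step = 0.5)
  expect_equal(sol$M[1, , ], diag(length(sol$labels)))
  expect_true(all(sol$M >= -1e-12))
  expect_true(all(is.finite(sol$M)))
})

test_that("a two-stage chain reproduces the survival convolution", {
  sgA <- shifted_gamma(2, 3, 1)
  sgB <- shifted_gamma(1.5, 4, 0.5)
  q <- 0.7
  m <- matrix(c(0, q, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  sol <- solve_expectation_matrix(m, horizon = 40, step = 0.02,
                                  durations = list(A = sgA, B = sgB))
  for (t in c(5, 10, 25)) {
    tau <- seq(0, t, by = 0.001)
    ref <- q * sum((1 - sg_cdf(sgB, t - tau[-1] + 0.0005)) *
                     diff(sg_cdf(sgA, tau)))
    expect_equal(sol$M[match(t, sol$times), 1, 2], ref, tolerance = 1e-4)
  }
})

test_that("halving the grid step leaves the solution essentially unchanged", {
  p <- toy_params()
  tm <- build_transition_matrix(p, include_nsc = FALSE)
  coarse <- solve_expectation_matrix(tm, horizon = 60, step = 0.2)
  fine <- solve_expectation_matrix(tm, horizon = 60, step = 0.1)
  shared <- match(coarse$times, fine$times)
  expect_lt(max(abs(coarse$M - fine$M[shared, , ])), 2e-3)
})

test_that("stationary state obeys Little's law and hand-expanded chains", {
  # single stage under influx lambda: pi = lambda E[T]
  sg <- shifted_gamma(3, 4, 2)
  pi1 <- neurocascade:::stationary_from_matrix(
    matrix(0, 1, 1, dimnames = list("A", "A")), sg_mean(sg), 5, "A")
  expect_equal(unname(pi1), 5 * sg_mean(sg))
  # chain A -> B with survival q: pi_B = lambda q E[T_B]
  q <- 0.35
  m <- matrix(c(0, q, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  pi2 <- neurocascade:::stationary_from_matrix(m, c(10, 20), 2, "A")
  expect_equal(unname(pi2), c(2 * 10, 2 * q * 20))
})

test_that("matrix-inverse stationary state matches the truncated series", {
  p <- cascade_parameters()
  mt <- transient_submatrix(build_transition_matrix(p))
  ET <- vapply(attr(mt, "durations"), sg_mean, numeric(1))
  inv_row <- solve(diag(nrow(mt)) - unclass(mt))["ANP_G1_1", ]
  series <- diag(nrow(mt))
  dimnames(series) <- dimnames(mt)
  acc <- series
  repeat {
    series <- series %*% unclass(mt)
    if (max(abs(series)) < 1e-10) break
    acc <- acc + series
  }
  expect_equal(inv_row, acc["ANP_G1_1", ], tolerance = 1e-9)
  pi <- stationary_distribution(p, ancestor = "anp")
  expect_equal(as.numeric(pi), unname(p$influx_anp * inv_row * ET),
               tolerance = 1e-9)
})

test_that("the stationary state is exactly linear in the influx intensities", {
  p <- cascade_parameters(influx_anp = 3, influx_nsc = 0.5)
  p2 <- update_parameters(p, list(influx_anp = 6, influx_nsc = 1))
  expect_equal(2 * as.numeric(stationary_distribution(p)),
               as.numeric(stationary_distribution(p2)))
})

test_that("the labeled initial state is the S-phase restriction of pi", {
  p <- cascade_parameters()
  pi <- stationary_distribution(p)
  lab <- labeled_initial_state(pi)
  expect_true(all(grepl("_S_", names(lab))))
  comp <- attr(pi, "compartments")
  expect_equal(sum(lab), sum(pi[comp$phase == "S"]))
  # zero influx: nothing is labeled
  p0 <- update_parameters(p, list(influx_anp = 0, influx_nsc = 0))
  expect_equal(sum(labeled_initial_state(stationary_distribution(p0))), 0)
})

test_that("calibrated influxes put the labeled NSC share near the observed one", {
  fx <- load_fixtures()
  meas <- fixture_measurements()
  cal <- calibrate_influx(fx$params, meas, method = "stationary")
  lab <- labeled_initial_state(stationary_distribution(cal$params))
  share <- sum(lab[grep("^NSC", names(lab))]) / sum(lab)
  expect_gt(share, 0.05)
  expect_lt(share, 0.20)
})
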