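test_that("re-proportioning reproduces the published day-1 adjustment exactly", {
  r <- reproportion(0.6014, 0.5194, 0.0568 + 0.002 + 40 / 5392,
                    sem_anp = 0.0259, sem_nb = 0.0725)
  expect_equal(round(100 * r$p_anp, 2), 50.79)
  expect_equal(round(100 * r$p_nb, 2), 42.59)
  expect_true(r$adjusted)
  # equal split removes the same amount from both classes
  expect_equal(0.6014 - r$p_anp, 0.5194 - r$p_nb)
})

test_that("alpha = 1 leaves the ANP proportion untouched", {
  r <- reproportion(0.5, 0.6, 0.05, alpha = 1)
  expect_equal(r$p_anp, 0.5)
  expect_equal(r$p_nb, 0.95 - 0.5)
})

test_that("adjusted proportions always sum to the target joint proportion", {
  set.seed(51)
  for (i in 1:100) {
    other <- runif(1, 0, 0.5)
    a <- runif(1, 0.1, 1); b <- runif(1, 0.1, 1)
    al <- runif(1)
    r <- reproportion(a, b, other, alpha = al)
    if (r$adjusted) expect_equal(r$p_anp + r$p_nb, 1 - other)
  }
})

test_that("consistent inputs pass through unchanged", {
  r0 <- reproportion(0.4, 0.5, 0.1)          # excess exactly zero
  expect_equal(r0$p_anp, 0.4)
  expect_equal(r0$p_nb, 0.5)
  r1 <- reproportion(0.3, 0.4, 0.1)          # under-complete: no double labeling
  expect_false(r1$adjusted)
  expect_equal(r1$p_anp, 0.3)
  expect_match(r1$note, "unchanged")
  expect_error(reproportion(0.5, 0.5, 1), "no room")
})

test_that("count transformation reproduces the published day-1 estimates", {
  est <- counts_from_proportions(5392, 557,
                                 c(0.0568, 0.50789, 0.42589),
                                 c(0.0057, 0.0323, 0.0395))
  expect_equal(est$mean, c(306, 2738, 2296), tolerance = 1 / 306,
               ignore_attr = TRUE)
  expect_lt(max(abs(est$mean - c(306.3, 2738.5, 2296.4))), 0.3)
  # sems reproduce within 15%
  expect_true(all(abs(est$sem / c(46, 334, 297) - 1) < 0.15))
})

test_that("count transformation is degenerate-case exact and bilinear", {
  e <- counts_from_proportions(1000, 50, 1, 0)
  expect_equal(e$mean, 1000)
  expect_equal(e$sem, 50)
  # the mean is bilinear in total and proportion
  e1 <- counts_from_proportions(800, 10, 0.3, 0.01)
  e2 <- counts_from_proportions(1600, 10, 0.3, 0.01)
  e3 <- counts_from_proportions(800, 10, 0.6, 0.01)
  expect_equal(e2$mean, 2 * e1$mean)
  expect_equal(e3$mean, 2 * e1$mean)
  # the variance formula is non-negative on the whole valid domain:
  # V = S_P^2 (Y^2 + S_Y^2 - Y) + P^2 S_Y^2 + Y P (1 - P) term-wise >= 0
  set.seed(52)
  for (i in 1:100) {
    y <- runif(1, 1, 5000); ys <- runif(1, 0, 800)
    pv <- runif(1); ps <- runif(1, 0, 0.2)
    expect_gte(counts_from_proportions(y, ys, pv, ps)$sem, 0)
  }
})

test_that("the full preparation pipeline reproduces the published tables", {
  fx <- load_fixtures()
  prep <- prepare_dataset(fx$observed)
  # exactly the 40 non-zero measurements enter the objective
  expect_equal(nrow(prep$measurements), 40L)
  adj <- prep$adjusted
  d1 <- adj[adj$time_h == 24, ]
  expect_equal(round(100 * d1$anp, 2), 50.79)
  expect_equal(round(100 * d1$nb, 2), 42.59)
  # day 2 carries a known ~0.2 percentage-point discrepancy in the source
  d2 <- adj[adj$time_h == 48, ]
  expect_equal(100 * d2$anp, 30.29, tolerance = 1 / 30.29)
  expect_equal(100 * d2$nb, 64.41, tolerance = 1 / 64.41)
  expect_lt(abs(100 * d2$anp - 30.10), 0.02)
  # day 4 reproduces to a hundredth of a percentage point
  d4 <- adj[adj$time_h == 96, ]
  expect_lt(abs(100 * d4$anp - 10.35), 0.05)
  expect_lt(abs(100 * d4$nb - 85.05), 0.05)
  # per-type day-1 count estimates
  m <- prep$measurements
  pick <- function(cls, t) m$mean[m$class == cls & m$time_h == t]
  expect_equal(pick("NSC", 24), 306, tolerance = 1 / 306)
  expect_equal(pick("ANP", 24), 2738, tolerance = 1 / 2738)
  expect_equal(pick("NB", 24), 2296, tolerance = 1 / 2296)
  expect_equal(pick("GC", 768), 735, tolerance = 1 / 735)
  expect_equal(pick("NB", 360), 1162, tolerance = 1 / 1162)
})

test_that("re-proportioning in the pipeline is idempotent", {
  fx <- load_fixtures()
  prep1 <- prepare_dataset(fx$observed)
  # feed the adjusted proportions back through: excess is now <= 0
  obs2 <- fx$observed
  a <- prep1$adjusted
  for (col in c("nsc", "nsc_sem", "anp", "anp_sem", "nb", "nb_sem",
                "gc", "gc_sem"))
    obs2$proportions[[col]] <- a[[col]][match(obs2$proportions$time_h,
                                              a$time_h)]
  prep2 <- prepare_dataset(obs2)
  expect_equal(prep2$adjusted$anp, prep1$adjusted$anp, tolerance = 1e-10)
  expect_equal(prep2$adjusted$nb, prep1$adjusted$nb, tolerance = 1e-10)
})
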