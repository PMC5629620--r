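# shared builders for small test models

# minimal one-division cascade with every fate reachable; fast to simulate
toy_params <- function(...) {
  cascade_parameters(
    min_div_anp = 1, max_div_anp = 1,
    d_g1 = 0.2, d_s = 0.1, d_g2m = 0.1, d_anp = 0.4, d_nb = 0.8,
    t_nb = c(40, 2, 5), t_anp_apop = c(10, 3, 1),
    ...)
}

# random valid parameter draw (death rates and division law)
random_params <- function() {
  a <- sample(1:3, 1)
  b <- a + sample(0:3, 1)
  cascade_parameters(
    min_div_anp = a, max_div_anp = b, p_anp = stats::runif(1),
    d_g1 = stats::runif(1, 0, 0.9), d_s = stats::runif(1, 0, 0.9),
    d_g2m = stats::runif(1, 0, 0.9), d_anp = stats::runif(1, 0, 0.9),
    d_nb = stats::runif(1, 0.05, 0.99),
    min_div_nsc = 1, max_div_nsc = sample(2:4, 1),
    p_nsc = stats::runif(1))
}

# observed dataset + measurement table from the packaged study
fixture_measurements <- function() {
  prepare_dataset(load_fixtures()$observed)$measurements
}
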