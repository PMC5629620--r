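#' Variance-weighted least-squares objective
#'
#' Goodness of fit between the experimental measurements and a simulated (or
#' expected) labeling curve: \eqn{\sum_i (E_i - S_i)^2 / \sigma_i^2}, summed
#' over every measurement row, with \eqn{\sigma_i^2} the squared sem floored
#' at \code{sigma_floor} so that zero-sem observations cannot dominate.
#'
#' @param measurements data.frame \code{time_h}, \code{class}, \code{mean},
#'   \code{sem} (e.g. \code{prepare_dataset(...)$measurements})
#' @param curve data.frame with \code{time_h}, \code{group}, \code{mean}
#'   (a \code{\link{simulate_labeling_curves}} result or any curve in that
#'   shape)
#' @param sigma_floor lower bound on the variance weight
#' @return single non-negative number
#' @export
objective <- function(measurements, curve, sigma_floor = 1) {
  joined <- merge(measurements, curve, by.x = c("time_h", "class"),
                  by.y = c("time_h", "group"), suffixes = c("_obs", "_sim"))
  if (nrow(joined) < nrow(measurements)) {
    miss <- measurements[!paste(measurements$time_h, measurements$class) %in%
                           paste(joined$time_h, joined$class), ]
    stop("simulated curve lacks ", nrow(miss), " observed point(s): ",
         paste(sprintf("%s@%gh", miss$class, miss$time_h), collapse = ", "))
  }
  sigma2 <- pmax(joined$sem^2, sigma_floor)
  sum((joined$mean_obs - joined$mean_sim)^2 / sigma2)
}

# --- per-stream unit curves -------------------------------------------------

# simulate labeling curves split by founder stream (newborn-ANP lineage vs
# labeled-NSC lineage), averaged over replicates, normalized to unit influx
simulate_unit_curves <- function(params, timepoints, n_replicates = 5,
                                 residual_mode = "stationary") {
  stopifnot(params$influx_anp > 0, params$influx_nsc > 0)
  comp <- compartment_table(params)
  lv <- sort(unique(comp$class))
  acc <- list(anp = 0, nsc = 0)
  for (r in seq_len(n_replicates)) {
    founders <- sample_initial_cohort(params, residual_mode)
    nsc_founder <- startsWith(founders$comp, "NSC")
    segs <- if (nrow(founders)) simulate_cascade(founders, params) else
      data.frame(comp = character(), class = character(), id = integer(),
                 entry = numeric(), exit = numeric())
    nsc_ids <- founders$id[nsc_founder]
    for (st in c("anp", "nsc")) {
      sel <- if (st == "nsc") segs$id %in% nsc_ids else !(segs$id %in% nsc_ids)
      cnt <- count_alive(segs[sel, , drop = FALSE], timepoints,
                         by = "class", levels = lv)
      acc[[st]] <- acc[[st]] + cnt$count
    }
  }
  grid <- count_alive(data.frame(comp = character(), class = character(),
                                 id = integer(), entry = numeric(),
                                 exit = numeric()),
                      timepoints, by = "class", levels = lv)[, 1:2]
  grid$anp_unit <- acc$anp / n_replicates / params$influx_anp
  grid$nsc_unit <- acc$nsc / n_replicates / params$influx_nsc
  grid
}

# weighted least-squares scale factors of the two unit component curves
calibrate_from_unit <- function(unit, measurements, sigma_floor = 1) {
  joined <- merge(measurements, unit, by.x = c("time_h", "class"),
                  by.y = c("time_h", "group"))
  w <- 1 / pmax(joined$sem^2, sigma_floor)
  a <- joined$anp_unit; nn <- joined$nsc_unit; e <- joined$mean
  saa <- sum(w * a * a); snn <- sum(w * nn * nn); san <- sum(w * a * nn)
  sea <- sum(w * e * a); sen <- sum(w * e * nn)
  if ((saa == 0 && any(e != 0 & nn == 0)) ||
      (snn == 0 && any(e != 0 & a == 0)))
    stop("degenerate scale: a unit-influx curve is identically zero where ",
         "observations are non-zero")
  det <- saa * snn - san^2
  if (abs(det) < 1e-12 * max(saa * snn, 1)) {
    # components collinear or one absent; fall back to marginal scales
    lambda <- if (saa > 0) sea / saa else 0
    mu <- if (snn > 0) sen / snn else 0
  } else {
    sol <- solve(matrix(c(saa, san, san, snn), 2L), c(sea, sen))
    lambda <- sol[1L]; mu <- sol[2L]
  }
  if (lambda < 0 || mu < 0) {
    warning("negative calibrated influx clamped at zero")
    lambda <- max(lambda, 0); mu <- max(mu, 0)
  }
  c(lambda = lambda, mu = mu)
}

#' Calibrate the influx intensities against observed labeling data
#'
#' The expected labeling curves are linear in the two Poisson intensities:
#' the newborn-ANP arrival rate \eqn{\lambda} scales the curve seeded by the
#' stationary ANP-lineage S-phase population, and the NSC-activation rate
#' \eqn{\mu} scales the curve seeded by labeled NSCs (including the labeled
#' ANPs they emit after the pulse). Both rates are therefore available in
#' closed form by weighted least squares of the observations on the two
#' unit-influx component curves:
#' \eqn{(\hat\lambda, \hat\mu) = \arg\min \sum_i (E_i - \lambda a_i -
#' \mu n_i)^2 / \sigma_i^2}. The NSC-class measurements identify \eqn{\mu},
#' the remaining classes mostly \eqn{\lambda}.
#'
#' \code{method = "stationary"} is the fast deterministic variant: it scales
#' each stream so the stationary labeled S-phase populations match the
#' earliest (2 h) ANP and NSC observations.
#'
#' @param params a \code{\link{cascade_parameters}} object; its influx values
#'   act as the reference scale for the unit-curve simulation
#' @param measurements observed measurement table (see \code{\link{objective}})
#' @param method \code{"curves"} (weighted least squares on simulated unit
#'   curves) or \code{"stationary"} (match the 2 h composition)
#' @param n_replicates simulation replicates for \code{method = "curves"}
#' @param sigma_floor variance floor, as in \code{\link{objective}}
#' @return list with \code{influx_anp} (\eqn{\hat\lambda}), \code{influx_nsc}
#'   (\eqn{\hat\mu}), \code{params} (updated parameter set), and
#'   \code{anps_per_episode_implied} (\eqn{\hat\lambda/\hat\mu}, the
#'   data-implied number of ANPs produced per activation episode)
#' @export
calibrate_influx <- function(params, measurements,
                             method = c("curves", "stationary"),
                             n_replicates = 5, sigma_floor = 1) {
  method <- match.arg(method)
  if (method == "stationary") {
    t0 <- min(measurements$time_h)
    e_anp <- measurements$mean[measurements$time_h == t0 &
                                 measurements$class == "ANP"]
    e_nsc <- measurements$mean[measurements$time_h == t0 &
                                 measurements$class == "NSC"]
    if (!length(e_anp) || !length(e_nsc))
      stop("stationary calibration needs ANP and NSC measurements at the ",
           "earliest timepoint")
    lab_a <- labeled_initial_state(stationary_distribution(params, "anp"))
    lab_n <- labeled_initial_state(stationary_distribution(params, "nsc"))
    unit_a <- sum(lab_a) / params$influx_anp
    unit_n <- sum(lab_n[grep("^NSC", names(lab_n))]) / params$influx_nsc
    if (unit_a <= 0 || unit_n <= 0)
      stop("degenerate scale: a unit-influx labeled population is zero")
    lambda <- e_anp / unit_a
    mu <- e_nsc / unit_n
  } else {
    unit <- simulate_unit_curves(params, sort(unique(measurements$time_h)),
                                 n_replicates = n_replicates)
    sc <- calibrate_from_unit(unit, measurements, sigma_floor)
    lambda <- sc[["lambda"]]; mu <- sc[["mu"]]
  }
  list(influx_anp = lambda, influx_nsc = mu,
       params = update_parameters(params,
                                  list(influx_anp = lambda, influx_nsc = mu)),
       anps_per_episode_implied = if (mu > 0) lambda / mu else NA_real_)
}

# --- binary encoding over the search ranges ---------------------------------

#' Build a genetic-algorithm search space
#'
#' Maps each searched parameter to a bit field: enumerated integer parameters
#' use their value set (with just enough bits), continuous parameters an
#' evenly spaced grid of \code{2^bits} values across their range.
#'
#' @param ranges data.frame of parameter ranges (\code{load_fixtures()$ranges})
#' @param names flat parameter names to search (subset of \code{ranges$param})
#' @param bits bits per continuous parameter
#' @return An object of class \code{search_space}.
#' @export
search_space <- function(ranges, names, bits = 8L) {
  stopifnot(bits >= 1L)
  missing <- setdiff(names, ranges$param)
  if (length(missing))
    stop("no range defined for parameter(s): ", paste(missing, collapse = ", "))
  specs <- lapply(names, function(nm) {
    row <- ranges[ranges$param == nm, ][1L, ]
    if (row$kind == "set") {
      grid <- as.numeric(strsplit(row$values, ";")[[1L]])
      nb <- max(1L, as.integer(ceiling(log2(length(grid)))))
    } else {
      grid <- seq(row$lo, row$hi, length.out = 2^bits)
      nb <- as.integer(bits)
    }
    list(name = nm, grid = grid, bits = nb,
         lo = min(grid), hi = max(grid))
  })
  structure(list(specs = specs,
                 n_bits = sum(vapply(specs, `[[`, integer(1), "bits"))),
            class = "search_space")
}

int_to_bits <- function(idx, nb) as.logical(bitwAnd(idx, 2^(seq_len(nb) - 1L)) > 0)
bits_to_int <- function(bits) sum(2^(seq_along(bits) - 1L) * bits)

#' Encode parameter values as a bit vector / decode a bit vector
#'
#' \code{encode_genome} snaps each value to the nearest grid point of its bit
#' field (erroring when a value lies outside its search range);
#' \code{decode_genome} inverts the mapping, clamping enumerated indices to
#' the value set so that every bit string decodes to in-range parameters.
#'
#' @param values named list/vector of flat parameter values
#' @param space a \code{\link{search_space}}
#' @rdname genome
#' @export
encode_genome <- function(values, space) {
  values <- as.list(values)
  out <- logical(0)
  for (sp in space$specs) {
    v <- values[[sp$name]]
    if (is.null(v)) stop("missing value for searched parameter ", sp$name)
    tolr <- 1e-8 * max(1, abs(sp$hi))
    if (v < sp$lo - tolr || v > sp$hi + tolr)
      stop("parameter ", sp$name, " = ", v, " outside its search range [",
           sp$lo, ", ", sp$hi, "]")
    idx <- which.min(abs(sp$grid - v)) - 1L
    out <- c(out, int_to_bits(idx, sp$bits))
  }
  out
}

#' @param bits logical vector of length \code{space$n_bits}
#' @rdname genome
#' @export
decode_genome <- function(bits, space) {
  stopifnot(length(bits) == space$n_bits)
  pos <- 0L
  out <- list()
  for (sp in space$specs) {
    idx <- bits_to_int(bits[pos + seq_len(sp$bits)])
    idx <- min(idx, length(sp$grid) - 1L)
    out[[sp$name]] <- sp$grid[idx + 1L]
    pos <- pos + sp$bits
  }
  out
}

# --- genetic algorithm ------------------------------------------------------

#' Genetic-algorithm configuration
#'
#' Defaults follow common practice for a ~19-parameter search: moderate
#' population, tournament selection, uniform crossover, light per-bit
#' mutation, and a small elite carried over unchanged. Each genome's
#' objective averages a few simulation replicates under a seed derived from
#' the genome itself, making the (stochastic) objective deterministic per
#' genome and the whole search reproducible.
#'
#' @param population population size (>= 2)
#' @param generations number of generations
#' @param bits bits per continuous parameter
#' @param p_crossover probability of uniform crossover per pairing
#' @param p_mutation per-bit mutation probability
#' @param tournament tournament size for selection
#' @param elitism number of best individuals copied unchanged
#' @param n_sim_replicates simulation replicates per objective evaluation
#' @param seed master seed of the search
#' @export
ga_config <- function(population = 100L, generations = 200L, bits = 8L,
                      p_crossover = 0.7, p_mutation = 0.01, tournament = 3L,
                      elitism = 2L, n_sim_replicates = 5L, seed = 1L) {
  stopifnot(population >= 2L, generations >= 1L, bits >= 1L,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1,
            tournament >= 1L, elitism >= 0L, n_sim_replicates >= 1L)
  list(population = as.integer(population),
       generations = as.integer(generations), bits = as.integer(bits),
       p_crossover = p_crossover, p_mutation = p_mutation,
       tournament = as.integer(tournament), elitism = as.integer(elitism),
       n_sim_replicates = as.integer(n_sim_replicates),
       seed = as.integer(seed))
}

# objective of one genome: decode, rebuild parameters, simulate unit curves
# under a genome-derived seed, calibrate the influx scale, score
evaluate_genome <- function(bits, space, base_params, measurements, config) {
  vals <- decode_genome(bits, space)
  params <- try(update_parameters(base_params, vals), silent = TRUE)
  if (inherits(params, "try-error")) return(Inf)   # e.g. mean <= min duration
  seed_g <- (config$seed + genome_hash(bits)) %% 2147483629L
  with_preserved_seed(seed_g, {
    unit <- try(simulate_unit_curves(params,
                                     sort(unique(measurements$time_h)),
                                     n_replicates = config$n_sim_replicates),
                silent = TRUE)
    if (inherits(unit, "try-error")) return(Inf)
    sc <- try(calibrate_from_unit(unit, measurements), silent = TRUE)
    if (inherits(sc, "try-error")) return(Inf)
    curve <- data.frame(time_h = unit$time_h, group = unit$group,
                        mean = unit$anp_unit * sc[["lambda"]] +
                          unit$nsc_unit * sc[["mu"]])
    objective(measurements, curve)
  })
}

#' Genetic-algorithm parameter search
#'
#' Evolves a population of bit-string genomes over the search space,
#' minimizing the variance-weighted least-squares objective of the simulated
#' labeling curves against the measurements. Selection is by tournament,
#' recombination by uniform crossover, variation by per-bit mutation;
#' elitism preserves the best genomes so the best-so-far objective is
#' non-increasing. Fully deterministic for a fixed configuration seed.
#'
#' @param base_params parameters supplying everything not searched
#' @param measurements observed measurement table (see \code{\link{objective}})
#' @param space a \code{\link{search_space}} over the searched parameters
#' @param config a \code{\link{ga_config}}
#' @param verbose print per-generation progress
#' @return An object of class \code{fit_result}: list with \code{best_params},
#'   \code{best_values} (searched parameters only), \code{objective},
#'   \code{history} (best-so-far per generation), \code{influx} (calibrated
#'   intensities for the best genome), \code{evaluations}.
#' @export
run_ga <- function(base_params, measurements, space, config = ga_config(),
                   verbose = FALSE) {
  nb <- space$n_bits
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  fitness <- function(bits) {
    key <- paste(as.integer(bits), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_eval <<- n_eval + 1L
    val <- evaluate_genome(bits, space, base_params, measurements, config)
    cache[[key]] <- val
    val
  }

  with_preserved_seed(config$seed, {
    pop <- matrix(stats::runif(config$population * nb) < 0.5,
                  config$population, nb)
    fit <- apply(pop, 1L, fitness)
    best_bits <- pop[which.min(fit), ]
    best_fit <- min(fit)
    history <- numeric(config$generations)
    for (gen in seq_len(config$generations)) {
      ord <- order(fit)
      newpop <- matrix(FALSE, config$population, nb)
      n_elite <- min(config$elitism, config$population)
      if (n_elite > 0)
        newpop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], , drop = FALSE]
      tourn <- function() {
        cand <- sample.int(config$population, config$tournament, replace = TRUE)
        cand[which.min(fit[cand])]
      }
      for (i in seq.int(n_elite + 1L, config$population)) {
        p1 <- pop[tourn(), ]; p2 <- pop[tourn(), ]
        child <- if (stats::runif(1) < config$p_crossover) {
          mask <- stats::runif(nb) < 0.5
          ifelse(mask, p1, p2)
        } else p1
        flip <- stats::runif(nb) < config$p_mutation
        child[flip] <- !child[flip]
        newpop[i, ] <- child
      }
      pop <- newpop
      fit <- apply(pop, 1L, fitness)
      if (min(fit) < best_fit) {
        best_fit <- min(fit)
        best_bits <- pop[which.min(fit), ]
      }
      history[gen] <- best_fit
      if (verbose)
        message(sprintf("generation %d: best objective %.4g", gen, best_fit))
    }
    best_values <- decode_genome(best_bits, space)
    best_params <- update_parameters(base_params, best_values)
    seed_g <- (config$seed + genome_hash(best_bits)) %% 2147483629L
    cal <- with_preserved_seed(seed_g,
      calibrate_influx(best_params, measurements, method = "curves",
                       n_replicates = config$n_sim_replicates))
    structure(list(best_params = cal$params, best_values = best_values,
                   objective = best_fit, history = history,
                   influx = c(anp = cal$influx_anp, nsc = cal$influx_nsc),
                   evaluations = n_eval),
              class = "fit_result")
  })
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("GA fit: objective %.4g after %d evaluations\n",
              x$objective, x$evaluations))
  cat("best searched values:\n")
  print(unlist(x$best_values))
  invisible(x)
}
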