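#' Event-based simulation of labeled-cell fates
#'
#' Traces every founder cell (and all of its descendants) through the
#' cascade: a cell occupies each stage for a shifted-gamma random time, may
#' die at the end of the stage (entering the apoptotic compartment for a
#' random clearance time), divides into two daughters at the end of G2M, and
#' terminates as a granule cell, an astrocyte, or a cleared apoptotic cell.
#' Renewal is a clone-level decision: each ANP founder carries a division
#' budget \eqn{N} drawn from the division-number law, so the realized progeny
#' count is exactly \eqn{2^N} (absent death) as the progeny distribution
#' states, while per-cell expected progeny still match the transition
#' matrix. Death-versus-differentiation at the end of the budget is decided
#' per daughter. NSCs divide asymmetrically, emitting one newborn ANP per
#' division while continuing their own program. Because every transition
#' moves forward in the compartment order, the simulation processes one
#' compartment at a time with fully vectorized draws.
#'
#' @param founders data.frame with columns \code{comp} (compartment name),
#'   \code{entry} (hours) and optionally \code{dur} (pre-drawn residual
#'   duration, NA = draw a fresh transit time) and \code{id} (founder id,
#'   propagated to descendants)
#' @param params a \code{\link{cascade_parameters}} object
#' @param include_in model the immature-neuron compartment
#' @return data.frame of occupancy segments: \code{comp}, \code{class},
#'   \code{id}, \code{entry}, \code{exit} (\code{Inf} for absorbing
#'   compartments). Uses the current R random stream.
#' @export
simulate_cascade <- function(founders, params, include_in = params$include_in) {
  comp <- compartment_table(params, include_nsc = TRUE,
                            include_in = include_in, include_absorbing = TRUE)
  durs <- stats::setNames(vector("list", nrow(comp)), comp$name)
  for (i in seq_len(nrow(comp)))
    if (!is.na(comp$duration[i])) durs[[i]] <- params[[comp$duration[i]]]

  q_entry <- stats::setNames(vector("list", nrow(comp)), comp$name)
  q_dur <- q_entry
  q_id <- q_entry
  q_nd <- q_entry    # allowed division count of the ANP clone (NA = undrawn)
  push <- function(name, entry, id, dur = NULL, nd = NULL) {
    if (!length(entry)) return(invisible(NULL))
    if (is.null(dur)) dur <- rep(NA_real_, length(entry))
    if (is.null(nd)) nd <- rep(NA_real_, length(entry))
    q_entry[[name]] <<- c(q_entry[[name]], entry)
    q_dur[[name]] <<- c(q_dur[[name]], dur)
    q_id[[name]] <<- c(q_id[[name]], id)
    q_nd[[name]] <<- c(q_nd[[name]], nd)
    invisible(NULL)
  }
  # division count of a clone first seen cycling in generation `gen`: the
  # geometric renewal law is memoryless, so conditioning on having reached
  # `gen` just raises the minimum
  draw_ndiv <- function(n, gen) {
    amin <- max(an, gen)
    if (amin >= bn) return(rep(bn, n))
    pmf <- progeny_distribution(amin, bn, pa)
    sample(pmf$divisions, n, replace = TRUE, prob = pmf$prob)
  }

  if (!nrow(founders)) {
    return(data.frame(comp = character(), class = character(),
                      id = integer(), entry = numeric(), exit = numeric()))
  }
  if (is.null(founders$dur)) founders$dur <- NA_real_
  if (is.null(founders$id)) founders$id <- seq_len(nrow(founders))
  bad <- setdiff(unique(founders$comp), comp$name)
  if (length(bad))
    stop("unknown founder compartment(s): ", paste(bad, collapse = ", "))
  for (cn in unique(founders$comp)) {
    sel <- founders$comp == cn
    push(cn, founders$entry[sel], founders$id[sel], founders$dur[sel])
  }

  an <- params$min_div_anp; bn <- params$max_div_anp; pa <- params$p_anp
  an_n <- params$min_div_nsc; bn_n <- params$max_div_nsc; pn <- params$p_nsc
  segs <- vector("list", nrow(comp))

  for (i in seq_len(nrow(comp))) {
    name <- comp$name[i]
    entry <- q_entry[[name]]
    n <- length(entry)
    if (!n) next
    id <- q_id[[name]]
    if (comp$phase[i] == "absorbing") {
      segs[[i]] <- data.frame(comp = name, class = comp$class[i], id = id,
                              entry = entry, exit = Inf)
      next
    }
    dur <- q_dur[[name]]
    miss <- is.na(dur)
    if (any(miss)) dur[miss] <- sg_sample(durs[[name]], sum(miss))
    exit <- entry + dur
    segs[[i]] <- data.frame(comp = name, class = comp$class[i], id = id,
                            entry = entry, exit = exit)

    lin <- comp$lineage[i]; phase <- comp$phase[i]; g <- comp$gen[i]
    if (lin == "NSC") {
      if (phase == "G1") {
        push(sprintf("NSC_S_%d", g), exit, id)
      } else if (phase == "S") {
        push(sprintf("NSC_G2M_%d", g), exit, id)
      } else {                           # G2M: divide asymmetrically
        push("ANP_G1_1", exit, id)       # one newborn ANP per division
        renew <- if (g < an_n) 1 else if (g < bn_n) pn else 0
        go_on <- stats::runif(n) < renew
        push(sprintf("NSC_G1_%d", g + 1L), exit[go_on], id[go_on])
        push("ASTRO", exit[!go_on], id[!go_on])
      }
    } else if (lin == "ANP" && phase %in% c("G1", "S")) {
      nd <- q_nd[[name]]
      d <- if (phase == "G1") params$d_g1 else params$d_s
      die <- stats::runif(n) < d
      nxt <- if (phase == "G1") sprintf("ANP_S_%d", g) else sprintf("ANP_G2M_%d", g)
      push("APOP", exit[die], id[die])
      push(nxt, exit[!die], id[!die], nd = nd[!die])
    } else if (lin == "ANP" && phase == "G2M") {
      nd <- q_nd[[name]]
      undrawn <- is.na(nd)
      if (any(undrawn)) nd[undrawn] <- draw_ndiv(sum(undrawn), g)
      die <- stats::runif(n) < params$d_g2m
      push("APOP", exit[die], id[die])
      # two daughters per surviving mother; the clone's division budget
      # decides renewal, each daughter's death-vs-differentiation fate is its own
      dx <- rep(exit[!die], each = 2L)
      did <- rep(id[!die], each = 2L)
      dnd <- rep(nd[!die], each = 2L)
      if (length(dx)) {
        cont <- g < dnd
        push(sprintf("ANP_G1_%d", g + 1L), dx[cont], did[cont], nd = dnd[cont])
        stopd <- !cont
        die2 <- stats::runif(length(dx)) < params$d_anp
        push("ANP_APOP", dx[stopd & die2], did[stopd & die2])
        push("ANP_NB", dx[stopd & !die2], did[stopd & !die2])
      }
    } else if (name == "ANP_NB") {
      push("NB", exit, id)
    } else if (name == "ANP_APOP") {
      push("APOP", exit, id)
    } else if (name == "NB") {
      die <- stats::runif(n) < params$d_nb
      push("APOP", exit[die], id[die])
      push(if (include_in) "IN" else "GC", exit[!die], id[!die])
    } else if (name == "IN") {
      die <- stats::runif(n) < params$d_in
      push("APOP", exit[die], id[die])
      push("GC", exit[!die], id[!die])
    }
    # APOP: occupancy recorded above; cells vanish at clearance
  }
  out <- do.call(rbind, segs[!vapply(segs, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Trace a single labeled cell
#'
#' Convenience wrapper around \code{\link{simulate_cascade}} for one founder:
#' returns the event trace (compartment, entry, exit) of the cell and all of
#' its descendants, ordered by entry time.
#'
#' @param comp founder compartment name (e.g. \code{"ANP_G1_1"})
#' @param params a \code{\link{cascade_parameters}} object
#' @param entry entry time (hours)
#' @param dur optional pre-drawn duration of the first stage
#' @export
simulate_cell <- function(comp, params, entry = 0, dur = NA_real_) {
  tr <- simulate_cascade(
    data.frame(comp = comp, entry = entry, dur = dur, id = 1L), params)
  tr[order(tr$entry, tr$comp), c("comp", "class", "entry", "exit")]
}

#' Count alive cells at given timepoints
#'
#' @param segments output of \code{\link{simulate_cascade}}
#' @param timepoints times (hours) at which to count
#' @param by \code{"class"} (observable classes, plus a TOTAL row summing
#'   them) or \code{"compartment"}
#' @param levels optional complete set of groups to report (zero-filled when
#'   absent from the segments)
#' @return data.frame \code{time_h}, \code{group}, \code{count}
#' @export
count_alive <- function(segments, timepoints, by = c("class", "compartment"),
                        levels = NULL) {
  by <- match.arg(by)
  key <- if (by == "class") segments$class else segments$comp
  groups <- if (is.null(levels)) sort(unique(key)) else levels
  if (!length(groups))
    return(data.frame(time_h = numeric(), group = character(),
                      count = numeric()))
  out <- lapply(timepoints, function(t) {
    alive <- segments$entry <= t & segments$exit > t
    tab <- table(factor(key[alive], levels = groups))
    data.frame(time_h = t, group = groups, count = as.numeric(tab))
  })
  out <- do.call(rbind, out)
  if (by == "class") {
    tot <- stats::aggregate(count ~ time_h, out, sum)
    tot$group <- "TOTAL"
    out <- rbind(out, tot[, c("time_h", "group", "count")])
    out <- out[order(out$time_h, out$group), ]
  }
  rownames(out) <- NULL
  out
}

#' Sample the BrdU-labeled founder cohort
#'
#' Draws the cells labeled by the pulse at \eqn{t = 0}: per S-phase
#' compartment a Poisson count with mean given by the stationary labeled
#' state, each cell carrying a remaining S-phase time drawn either from the
#' stationary-age residual distribution (default: cells are caught at a
#' uniform random point of their S phase) or as a fresh full S-phase draw
#' (\code{"start"}: labeling assumed to catch cells at S entry).
#'
#' @param params a \code{\link{cascade_parameters}} object
#' @param residual_mode \code{"stationary"} or \code{"start"}
#' @return founders data.frame for \code{\link{simulate_cascade}}
#' @export
sample_initial_cohort <- function(params, residual_mode = c("stationary", "start")) {
  residual_mode <- match.arg(residual_mode)
  pi <- stationary_distribution(params, ancestor = "combined")
  labeled <- labeled_initial_state(pi)
  comp <- attr(pi, "compartments")
  founders <- list()
  for (cn in names(labeled)) {
    k <- stats::rpois(1L, labeled[[cn]])
    if (!k) next
    dname <- comp$duration[comp$name == cn]
    sgd <- params[[dname]]
    dur <- if (residual_mode == "stationary") sg_sample_residual(sgd, k)
           else sg_sample(sgd, k)
    founders[[cn]] <- data.frame(comp = cn, entry = 0, dur = dur)
  }
  if (!length(founders))
    return(data.frame(comp = character(), entry = numeric(),
                      dur = numeric(), id = integer()))
  out <- do.call(rbind, founders)
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Simulate BrdU pulse-chase labeling curves
#'
#' Repeats the pulse-chase experiment in silico: draws a labeled founder
#' cohort from the stationary state, traces every lineage, and counts
#' BrdU+ cells per observable class at each timepoint; classes are NSC, ANP
#' (cycling phases plus both non-proliferating transition stages), NB, the
#' optional IN, GC, ASTRO, APOP (cells awaiting clearance) and their TOTAL.
#' Replicates are averaged and the between-replicate standard error reported.
#'
#' @param params a \code{\link{cascade_parameters}} object (influx intensities
#'   set the cohort scale; see \code{\link{calibrate_influx}})
#' @param timepoints observation times (hours)
#' @param n_replicates number of independent repetitions
#' @param residual_mode see \code{\link{sample_initial_cohort}}
#' @param by \code{"class"} or \code{"compartment"} resolution
#' @return data.frame of class \code{labeling_curve}: \code{time_h},
#'   \code{group}, \code{mean}, \code{se}; attribute \code{replicates}.
#' @examples
#' set.seed(1)
#' p <- cascade_parameters(influx_anp = 5, influx_nsc = 0.2)
#' simulate_labeling_curves(p, timepoints = c(0, 24, 96), n_replicates = 2)
#' @export
simulate_labeling_curves <- function(params, timepoints, n_replicates = 10,
                                     residual_mode = c("stationary", "start"),
                                     by = c("class", "compartment")) {
  residual_mode <- match.arg(residual_mode)
  by <- match.arg(by)
  stopifnot(n_replicates >= 1, all(timepoints >= 0), !is.unsorted(timepoints))
  comp <- compartment_table(params)
  lv <- if (by == "class") sort(unique(comp$class)) else comp$name
  reps <- vector("list", n_replicates)
  empty <- TRUE
  for (r in seq_len(n_replicates)) {
    founders <- sample_initial_cohort(params, residual_mode)
    if (nrow(founders)) {
      empty <- FALSE
      segs <- simulate_cascade(founders, params)
    } else {
      segs <- data.frame(comp = character(), class = character(),
                         id = integer(), entry = numeric(), exit = numeric())
    }
    cnt <- count_alive(segs, timepoints, by = by, levels = lv)
    reps[[r]] <- cnt$count
  }
  if (empty) warning("labeled cohort was empty in every replicate; curves are all zero")
  grid <- count_alive(data.frame(comp = character(), class = character(),
                                 id = integer(), entry = numeric(),
                                 exit = numeric()),
                      timepoints, by = by, levels = lv)[, c("time_h", "group")]
  vals <- matrix(unlist(reps), nrow = nrow(grid))
  grid$mean <- rowMeans(vals)
  grid$se <- if (n_replicates > 1) apply(vals, 1L, stats::sd) / sqrt(n_replicates)
             else rep(NA_real_, nrow(grid))
  rownames(grid) <- NULL
  structure(grid, replicates = n_replicates,
            class = c("labeling_curve", "data.frame"))
}

#' Time-averaged compartment occupancy under constant influx
#'
#' Simulates the cascade fed by Poisson arrival streams and returns the
#' time-average number of cells per transient compartment over a long
#' window, the Monte-Carlo counterpart of
#' \code{\link{stationary_distribution}}. Each of \code{n_runs} runs is an
#' independent realization (arrivals start at time 0, averaging after the
#' warm-up), so the standard error across runs is free of the long-range
#' autocorrelation that within-run batching would miss.
#'
#' @param params a \code{\link{cascade_parameters}} object; arrival rates are
#'   \code{influx_anp} (newborn ANPs) and \code{influx_nsc} (NSC activations)
#' @param window length of the averaging window per run (hours)
#' @param burn_in warm-up time before averaging starts (hours); should exceed
#'   the longest lineage transit so the process forgets the empty start
#' @param n_runs independent realizations
#' @param stream \code{"combined"}, \code{"anp"} or \code{"nsc"}
#' @return data.frame \code{comp}, \code{mean}, \code{se}
#' @export
simulate_occupancy <- function(params, window = 2000, burn_in = 800,
                               n_runs = 8L,
                               stream = c("combined", "anp", "nsc")) {
  stream <- match.arg(stream)
  stopifnot(n_runs >= 2L)
  horizon <- burn_in + window
  comp <- compartment_table(params)
  comp <- comp[comp$phase != "absorbing", ]
  one_run <- function() {
    founders <- list()
    if (stream %in% c("combined", "anp") && params$influx_anp > 0) {
      k <- stats::rpois(1L, params$influx_anp * horizon)
      founders$anp <- data.frame(comp = "ANP_G1_1",
                                 entry = stats::runif(k, 0, horizon))
    }
    if (stream %in% c("combined", "nsc") && params$influx_nsc > 0) {
      k <- stats::rpois(1L, params$influx_nsc * horizon)
      founders$nsc <- data.frame(comp = "NSC_G1_1",
                                 entry = stats::runif(k, 0, horizon))
    }
    founders <- do.call(rbind, founders)
    if (is.null(founders) || !nrow(founders))
      stop("no arrivals: both influx intensities are zero")
    founders$dur <- NA_real_
    founders$id <- seq_len(nrow(founders))
    segs <- simulate_cascade(founders, params)
    ov <- pmax(0, pmin(segs$exit, horizon) - pmax(segs$entry, burn_in))
    keep <- ov > 0
    tot <- tapply(ov[keep], factor(segs$comp[keep], levels = comp$name), sum)
    tot[is.na(tot)] <- 0
    tot / window
  }
  occ <- vapply(seq_len(n_runs), function(r) one_run(), numeric(nrow(comp)))
  data.frame(comp = comp$name,
             mean = rowMeans(occ),
             se = apply(occ, 1L, stats::sd) / sqrt(n_runs))
}
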