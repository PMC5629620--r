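# md5 digests of the packaged fixtures, frozen at packaging time
.fixture_md5 <- c(
  "brdu_cell_counts.csv"      = "3acebd456975d10abd699ba9b1003466",
  "brdu_cell_proportions.csv" = "b48c34d4b1f3d700580fbb701af45083",
  "parameter_ranges.csv"      = "84eb5c9046dff095939d8668d106a97c",
  "bestfit_parameters.yaml"   = "7d2b8efab4b037d307d55c06e9c218b5"
)

fixture_path <- function(file, check = TRUE) {
  path <- system.file("extdata", file, package = "neurocascade", mustWork = TRUE)
  if (check) {
    got <- unname(tools::md5sum(path))
    if (got != .fixture_md5[[file]])
      stop("checksum error: packaged fixture '", file,
           "' is corrupted (md5 ", got, ", expected ", .fixture_md5[[file]], ")")
  }
  path
}

#' Load the packaged pulse-chase dataset and best-fit parameters
#'
#' Returns the measurement tables of the bundled BrdU pulse-and-chase study
#' in 1-month-old mice (total and apoptotic BrdU+ counts at 12 timepoints;
#' per-type proportions), the best-fit cascade parameter set, and the
#' parameter search ranges. Fixture files are verified against frozen md5
#' checksums.
#'
#' @return list with \code{observed} (an \code{\link{observed_dataset}}),
#'   \code{params} (a \code{\link{cascade_parameters}} object) and
#'   \code{ranges} (a data.frame of search ranges)
#' @examples
#' fx <- load_fixtures()
#' fx$observed$counts[1, ]
#' @export
load_fixtures <- function() {
  cc <- utils::read.csv(fixture_path("brdu_cell_counts.csv"))
  pp <- utils::read.csv(fixture_path("brdu_cell_proportions.csv"))
  prop <- data.frame(
    time_h = pp$time_h,
    n_nscanp = pp$n_nscanp,
    nsc = pp$nsc_pct / 100, nsc_sem = pp$nsc_sem_pct / 100,
    anp = pp$anp_pct / 100, anp_sem = pp$anp_sem_pct / 100,
    n_nbgc = pp$n_nbgc,
    nb = pp$nb_pct / 100, nb_sem = pp$nb_sem_pct / 100,
    gc = pp$gc_pct / 100, gc_sem = pp$gc_sem_pct / 100)
  observed <- observed_dataset(cc, prop)
  params <- read_parameters(fixture_path("bestfit_parameters.yaml"))
  ranges <- utils::read.csv(fixture_path("parameter_ranges.csv"),
                            stringsAsFactors = FALSE)
  list(observed = observed, params = params, ranges = ranges)
}
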