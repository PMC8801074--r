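#' Run the default synthetic lot benchmark end to end
#'
#' Generates the study-sized panel (7 Low-risk + 4 High-risk lots, 3 wells
#' per lot, imaging every 6 h from 12 h to 138 h), simulates the time-lapse
#' cell populations and CFSE co-culture readouts, derives the two teacher
#' signals (risk labels via \code{\link{potencyFromCFSE}}, per-well growth
#' rates via \code{\link{growthRatesFromCells}}) and assembles both profile
#' sets: FOV pseudo-samples (4 per well, 132 classification samples) and
#' whole wells (33 regression samples).
#'
#' @param seed Master seed for the whole benchmark.
#' @param n_low,n_high Panel composition.
#' @param n_wells Wells per lot.
#' @param n0_cells Cells per well at 12 h.
#' @param well_cv Per-well seeding noise CV.
#' @param n_events CFSE events per co-culture well.
#' @param fov_min_cells QC threshold for FOV pseudo-sample frames (default
#'   50 = a quarter of the 200-cell whole-image minimum).
#' @param well_min_cells QC threshold for whole-well frames (default 200).
#' @param keep_cells Keep the (large) per-cell table in the result.
#' @return List: \code{panel}, \code{potency}, \code{growth},
#'   \code{profiles_fov}, \code{profiles_well}, \code{risk_labels} (named by
#'   lot, assay-derived), and optionally \code{cells}.
#' @examples
#' \donttest{
#' bench <- runBenchmark(seed = 1)
#' benchmarkAccuracy(bench)
#' }
#' @export
runBenchmark <- function(seed = 1, n_low = 7, n_high = 4, n_wells = 3,
                         n0_cells = 500, well_cv = 0.03, n_events = 10000,
                         fov_min_cells = 50, well_min_cells = 200,
                         keep_cells = FALSE) {
  panel <- generateLotPanel(n_low, n_high, seed = seed)
  cells <- simulateTimecourse(panel, n_wells = n_wells, n0_cells = n0_cells,
                              well_cv = well_cv, seed = seed)
  cells <- splitFOVs(cells)
  sum_fov <- aggregateFrames(cells, by = c("lot", "well", "fov", "time_h"),
                             min_cells = fov_min_cells)
  sum_well <- aggregateFrames(cells, by = c("lot", "well", "time_h"),
                              min_cells = well_min_cells)
  profiles_fov <- assembleProfiles(sum_fov, panel@schedule)
  profiles_well <- assembleProfiles(sum_well, panel@schedule)
  cfse <- simulateCFSEPanel(panel, n_wells = n_wells, n_events = n_events,
                            seed = seed)
  potency <- potencyFromCFSE(cfse)
  growth <- growthRatesFromCells(cells, panel@schedule)
  out <- list(
    panel = panel,
    potency = potency,
    growth = growth,
    profiles_fov = profiles_fov,
    profiles_well = profiles_well,
    risk_labels = setNames(potency$risk_class, potency$lot))
  if (keep_cells) out$cells <- cells
  out
}

#' Leave-lot-out classification accuracy on a benchmark
#'
#' Builds the classification design matrix (FOV pseudo-samples, assay-derived
#' risk labels coded 1 = Low-risk) for the requested parameter mode and time
#' window and returns the pooled leave-lot-out accuracy.
#'
#' @param bench Result of \code{\link{runBenchmark}}.
#' @param method,mode,window_end_h Model cell to evaluate (defaults: kNN,
#'   only-SD heterogeneity parameters, 96 h window = first 4 days).
#' @param hyper,seed Passed to \code{\link{runLeaveLotOut}}.
#' @return The pooled accuracy (numeric scalar); the full
#'   \code{\link{CVReport}} is attached as attribute \code{"report"}.
#' @export
benchmarkAccuracy <- function(bench, method = "kNN", mode = "only_SD",
                              window_end_h = 96, hyper = list(), seed = 1) {
  pm <- windowProfile(subsetParameters(bench$profiles_fov, mode),
                      window_end_h)
  y <- riskToLabel(bench$risk_labels)
  names(y) <- names(bench$risk_labels)
  dm <- buildDesignMatrix(pm, y, "classification")
  rep <- runLeaveLotOut(dm, method, hyper, seed, mode, window_end_h)
  structure(unname(rep@metrics["accuracy"]), report = rep)
}

#' Leave-lot-out growth-rate RMSE on a benchmark
#'
#' Wells are the regression samples; the target is the image-derived count
#' at 138 h divided by the count at 12 h.
#'
#' @inheritParams benchmarkAccuracy
#' @export
benchmarkGrowthRMSE <- function(bench, method = "LASSO", mode = "only_SD",
                                window_end_h = 96, hyper = list(),
                                seed = 1) {
  pm <- windowProfile(subsetParameters(bench$profiles_well, mode),
                      window_end_h)
  y <- setNames(bench$growth$growth_rate,
                paste(bench$growth$lot, bench$growth$well, sep = ":"))
  dm <- buildDesignMatrix(pm, y, "regression")
  rep <- runLeaveLotOut(dm, method, hyper, seed, mode, window_end_h)
  structure(unname(rep@metrics["rmse"]), report = rep)
}

#' Fold-spread of measured growth rates across a benchmark panel
#'
#' Ratio of the largest to the smallest lot-mean growth rate (each lot's
#' rate averaged over its replicate wells).
#'
#' @param bench Result of \code{\link{runBenchmark}}.
#' @return The max/min fold spread.
#' @export
growthSpread <- function(bench) {
  g <- bench$growth[, .(g = mean(growth_rate)), by = lot]
  max(g$g) / min(g$g)
}
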