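#' T-cell proliferation score from a CFSE distribution
#'
#' CFSE is halved at each division, so proliferated T cells accumulate in a
#' low-fluorescence peak. The score is the ratio of the proliferated (low)
#' population to the unproliferated (high) population: higher scores mean
#' weaker T-cell proliferation inhibitory potency of the co-cultured MSC lot.
#'
#' With \code{threshold = "auto"} the low/high gate is placed at the minimum
#' of a Gaussian kernel density estimate between the two highest modes. If
#' the density is unimodal, a 2-component Gaussian mixture is fitted on the
#' log scale and the midpoint of its means is used -- unless the fitted means
#' are closer than 0.5 log10 units, in which case the sample is treated as a
#' single unproliferated population and the gate is set 4 SD below its mean
#' (so a sample with no proliferated cells scores ~0). A numeric
#' \code{threshold} fixes the gate instead.
#'
#' @param intensities Numeric vector of log10 fluorescence events (>= 100),
#'   or a data.frame with an \code{intensity} column.
#' @param threshold \code{"auto"} or a fixed numeric gate.
#' @return A list: \code{score} (below/above ratio; \code{Inf} with
#'   \code{flag = "no_unproliferated"} if nothing lies above the gate),
#'   \code{prolif_fraction} (fraction below the gate), \code{threshold}, and
#'   \code{flag} (\code{"bimodal"}, \code{"mixture_fallback"} or
#'   \code{"unimodal"}).
#' @examples
#' x <- c(rnorm(800, 3, 0.15), rnorm(200, 1.8, 0.25))
#' tcellScore(x)$score # ~ 0.25
#' @export
tcellScore <- function(intensities, threshold = "auto") {
  x <- if (is.data.frame(intensities)) intensities$intensity else intensities
  if (length(x) < 100)
    stop("need >= 100 CFSE events (score unstable below this)")
  flag <- "fixed"
  if (identical(threshold, "auto")) {
    den <- density(x, n = 512)
    yy <- den$y
    locmax <- which(diff(sign(diff(yy))) == -2) + 1L
    # a genuine second mode must sit at least half a log10 decade away (a
    # CFSE halving is ~0.3) and rise above 0.2% of the main peak, otherwise
    # shoulder wiggles or tail noise would masquerade as a population
    prim <- locmax[which.max(yy[locmax])]
    far <- locmax[abs(den$x[locmax] - den$x[prim]) >= 0.5 &
                    yy[locmax] >= 0.002 * yy[prim]]
    sec <- if (length(far)) far[which.max(yy[far])] else integer()
    if (length(sec)) {
      lo <- min(prim, sec); hi <- max(prim, sec)
      thr <- den$x[lo + which.min(yy[lo:hi]) - 1L]
      flag <- "bimodal"
    } else {
      fit <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
      mu <- fit$parameters$mean
      if (abs(diff(mu)) >= 0.5) {
        thr <- mean(mu)
        flag <- "mixture_fallback"
      } else {
        thr <- mean(x) - 4 * sd(x)
        flag <- "unimodal"
      }
    }
  } else {
    thr <- threshold
  }
  n_below <- sum(x < thr)
  n_above <- length(x) - n_below
  score <- if (n_above == 0) Inf else n_below / n_above
  if (n_above == 0) flag <- "no_unproliferated"
  list(score = score, prolif_fraction = n_below / length(x),
       threshold = thr, flag = flag)
}

#' Classify a lot's risk from replicate CFSE readouts
#'
#' A lot is \code{"High"} risk (lacking, fully or partly, T-cell
#' proliferation inhibitory potency) when the mean proliferated fraction of
#' its replicate co-culture wells exceeds \code{frac_cutoff}; \code{"Low"}
#' otherwise. The 5\% default cutoff operationalises the judgement that
#' separates partially-failing ("risky anomaly") lots from potent ones; it is
#' configurable.
#'
#' @param prolif_fractions Proliferated fractions of the (nominally 3)
#'   replicate wells.
#' @param frac_cutoff Cutoff on the mean fraction (default 0.05).
#' @return \code{"Low"} or \code{"High"}.
#' @export
labelRisk <- function(prolif_fractions, frac_cutoff = 0.05) {
  if (length(prolif_fractions) != 3)
    warning("expected 3 replicate wells, got ", length(prolif_fractions),
            "; proceeding with available replicates")
  if (!length(prolif_fractions)) stop("no replicate fractions given")
  if (mean(prolif_fractions) > frac_cutoff) "High" else "Low"
}

#' Fold-change growth rate from image-derived cell counts
#'
#' The growth rate is the number of cells counted at 138 h after seeding
#' divided by the number counted at 12 h.
#'
#' @param count_12h,count_138h Cell counts at the first and last scheduled
#'   frame; \code{count_12h} must be >= 1.
#' @return Fold change (dimensionless), vectorised.
#' @examples
#' growthRate(500, 2900) # 5.8
#' @export
growthRate <- function(count_12h, count_138h) {
  if (any(count_12h < 1)) stop("count_12h must be >= 1 (growth undefined)")
  count_138h / count_12h
}

#' Per-well growth rates from a per-cell table
#'
#' Counts cells in the first and last scheduled frame of every (lot, well)
#' and applies \code{\link{growthRate}}.
#'
#' @param cells Per-cell table (see \code{\link{simulateTimecourse}}).
#' @param schedule The imaging schedule (first/last times are used).
#' @return data.table with \code{lot}, \code{well}, \code{count_first},
#'   \code{count_last}, \code{growth_rate}.
#' @export
growthRatesFromCells <- function(cells, schedule = scheduleTimes()) {
  dt <- data.table::as.data.table(cells)
  t0 <- min(schedule); t1 <- max(schedule)
  cnt <- dt[time_h %in% c(t0, t1), .N, by = .(lot, well, time_h)]
  wide <- data.table::dcast(cnt, lot + well ~ time_h, value.var = "N",
                            fill = 0L)
  data.table::setnames(wide, as.character(c(t0, t1)),
                       c("count_first", "count_last"))
  wide[, growth_rate := growthRate(count_first, count_last)]
  wide[]
}

#' Potency record per lot from CFSE readouts
#'
#' Scores every replicate well with \code{\link{tcellScore}} and labels each
#' lot via \code{\link{labelRisk}} -- the classification teacher signal of the
#' prediction pipeline.
#'
#' @param cfse Event table from \code{\link{simulateCFSEPanel}} (columns
#'   \code{lot}, \code{well}, \code{intensity}) or a list of such tables.
#' @param threshold Passed to \code{\link{tcellScore}}.
#' @param frac_cutoff Passed to \code{\link{labelRisk}}.
#' @return data.table with one row per lot: mean \code{tcell_score},
#'   \code{risk_class}, and the per-replicate scores/fractions in list
#'   columns \code{replicate_scores}, \code{replicate_fractions}.
#' @export
potencyFromCFSE <- function(cfse, threshold = "auto", frac_cutoff = 0.05) {
  dt <- data.table::as.data.table(cfse)
  per_well <- dt[, {
    r <- tcellScore(intensity, threshold)
    list(score = r$score, prolif_fraction = r$prolif_fraction,
         threshold_used = r$threshold, flag = r$flag)
  }, by = .(lot, well)]
  per_well[, .(
    tcell_score = mean(score),
    risk_class = labelRisk(prolif_fraction, frac_cutoff),
    replicate_scores = list(score),
    replicate_fractions = list(prolif_fraction)
  ), by = lot]
}
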