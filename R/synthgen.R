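#' @importFrom stats rnorm rlnorm runif rgamma qnorm pnorm approx sd density
#'   prcomp setNames quantile
#' @importFrom data.table data.table rbindlist setDF setDT :=
NULL

# ---- calibration constants (class-level generative truth) --------------------

# Fold-change growth presets. The overlap between the fastest Low-risk and the
# slowest High-risk lots is deliberate: growth alone must not classify risk.
.LOW_GROWTH_PRESET <- c(1.5, 2.2, 2.8, 3.4, 4.2, 5.6, 6.1)
.HIGH_GROWTH_PRESET <- c(6.6, 7.2, 8.1, 9.0)

# CFSE mixture on the log10 fluorescence scale: unproliferated (high) peak and
# proliferated (dye-diluted, low) peak.
.CFSE_HI <- c(mean = 3.0, sd = 0.15)
.CFSE_LO <- c(mean = 1.8, sd = 0.25)

# Top-quartile mean area (um^2) the calibrated lognormal must reach at 78 h:
# 7000 for Low-risk lots, 6000 for High-risk lots (86%).
.TOPQ_78H <- c(Low = 7000, High = 6000)
.TOPQ_12H <- c(Low = 3500, High = 3000)

# Growth-coupling ramp: area scale is modulated by (1 - beta(t) * (G - Gbar)),
# with beta growing linearly from 0 at 12 h to .BETA_MAX at 138 h. Slower
# lots spread more; the coupling accumulates over the time course.
.BETA_MAX <- 0.08

.classSigmaTraj <- function(times, risk_class) {
  r <- .ramp01(times, 12, 84)
  if (risk_class == "Low") 0.45 + 0.20 * r else 0.35 + 0.10 * r
}

.classTopqTraj <- function(times, risk_class) {
  r <- .ramp01(times, 12, 78)
  .TOPQ_12H[[risk_class]] +
    (.TOPQ_78H[[risk_class]] - .TOPQ_12H[[risk_class]]) * r
}

.betaTraj <- function(times) .BETA_MAX * (times - 12) / 126

#' Imaging schedule
#'
#' Scheduled imaging times in hours after seeding. The default (12 h to 138 h
#' every 6 h) yields 22 time points.
#'
#' @param start_h First imaging time (hours after seeding).
#' @param end_h Last imaging time.
#' @param interval_h Imaging interval; must divide \code{end_h - start_h}.
#' @return Numeric vector of imaging times.
#' @examples
#' length(scheduleTimes()) # 22
#' @export
scheduleTimes <- function(start_h = 12, end_h = 138, interval_h = 6) {
  if (end_h < start_h) stop("end_h must be >= start_h")
  .assertPositive(interval_h, "interval_h")
  if (abs((end_h - start_h) %% interval_h) > 1e-9)
    stop("(end_h - start_h) must be divisible by interval_h")
  seq(start_h, end_h, by = interval_h)
}

#' Calibrate a lognormal location to a target top-quartile mean
#'
#' For a lognormal(mu, sigma) cell-area distribution, the mean of the top 25%
#' of cells has the closed form
#' \deqn{E[X \mid X > q_{0.75}] = e^{\mu + \sigma^2/2}\,
#'   \Phi(\sigma - z_{0.75}) / 0.25,}
#' with \eqn{z_{0.75} = \Phi^{-1}(0.75) \approx 0.6745}. This inverts that
#' identity: it returns the \code{mu} for which the top-quartile mean equals
#' \code{target_topq_mean} at the given \code{sigma}. As \code{sigma}
#' approaches 0 the result approaches \code{log(target_topq_mean)}.
#'
#' @param target_topq_mean Target mean area of the top 25% of cells (um^2).
#' @param sigma Log-scale standard deviation (> 0).
#' @return Log-area location \code{mu} (vectorised over the inputs).
#' @examples
#' mu <- calibrateAreaMu(7000, 0.65)
#' exp(mu + 0.65^2 / 2) * pnorm(0.65 - qnorm(0.75)) / 0.25 # 7000
#' @export
calibrateAreaMu <- function(target_topq_mean, sigma) {
  .assertPositive(target_topq_mean, "target_topq_mean")
  .assertPositive(sigma, "sigma")
  z <- qnorm(0.75)
  log(target_topq_mean * 0.25 / pnorm(sigma - z)) - sigma^2 / 2
}

#' Generate a synthetic panel of MSC lots
#'
#' Creates the latent ground truth for \code{n_low} Low-risk and \code{n_high}
#' High-risk lots. Growth rates are taken from fixed class presets
#' (Low: 1.5--6.1, High: 6.6--9.0 fold over 12--138 h; the default panel spans
#' a 6.0-fold spread and the class ranges deliberately overlap so growth alone
#' cannot classify). Log-area scale trajectories rise from 0.45 to 0.65
#' (Low) and 0.35 to 0.45 (High) between 12 h and 84 h; log-area locations are
#' calibrated per time point so the class-level top-quartile mean area reaches
#' 7000 (Low) / 6000 (High) um^2 at 78 h, with a lot-level modulation
#' \eqn{1 - \beta(t)(G - \bar G_{class})} that couples area scale to the lot's
#' growth rate \eqn{G} increasingly over time. CFSE proliferated fractions are
#' drawn per lot: Low-risk U(0.01, 0.05); High-risk lots alternate between
#' "risky anomalies" U(0.15, 0.30) (partial loss of potency) and "clear
#' anomalies" U(0.55, 0.80), so the default 4 High-risk lots hold two of
#' each.
#'
#' @param n_low,n_high Number of Low-/High-risk lots (the default panel is
#'   7 + 4).
#' @param seed Master seed; every lot draws from its own substream, so adding
#'   lots never perturbs existing ones.
#' @param schedule Imaging times, see \code{\link{scheduleTimes}}.
#' @param class_shape_delta Optional class-dependent shape-noise effect passed
#'   through to \code{\link{simulateTimecourse}} via the panel metadata;
#'   0 (default) keeps non-area shape noise class-independent.
#' @return A \code{\link{LotPanel}}.
#' @examples
#' panel <- generateLotPanel(7, 4, seed = 1)
#' panel
#' @export
generateLotPanel <- function(n_low = 7, n_high = 4, seed = 1,
                             schedule = scheduleTimes(),
                             class_shape_delta = 0) {
  .assertCount(n_low, "n_low"); .assertCount(n_high, "n_high")
  if (n_low + n_high < 1) stop("need at least one lot")
  n <- n_low + n_high
  risk <- c(rep("Low", n_low), rep("High", n_high))
  growth <- c(rep_len(.LOW_GROWTH_PRESET, n_low),
              rep_len(.HIGH_GROWTH_PRESET, n_high))
  # among High-risk lots, alternate partial ("risky") and clear anomalies:
  # the default 4 High-risk lots come out 2 risky + 2 clear. Position-based,
  # so adding lots never changes the designation of existing ones.
  clear <- rep(FALSE, n)
  if (n_high > 0)
    clear[n_low + which(seq_len(n_high) %% 2 == 0)] <- TRUE
  origin <- ifelse(risk == "High" & !clear, "ADSC", "BMSC")

  gbar <- c(Low = mean(.LOW_GROWTH_PRESET), High = mean(.HIGH_GROWTH_PRESET))
  nT <- length(schedule)
  beta <- .betaTraj(schedule)
  areaMu <- matrix(NA_real_, n, nT)
  areaSigma <- matrix(NA_real_, n, nT)
  frac <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(.substreamSeed(seed, i, 0L))
    frac[i] <- if (risk[i] == "Low") runif(1, 0.01, 0.05)
      else if (clear[i]) runif(1, 0.55, 0.80) else runif(1, 0.15, 0.30)
    jitter <- exp(rnorm(1, 0, 0.01))
    sig <- .classSigmaTraj(schedule, risk[i])
    target <- .classTopqTraj(schedule, risk[i]) *
      (1 - beta * (growth[i] - gbar[[risk[i]]])) * jitter
    areaMu[i, ] <- calibrateAreaMu(target, sig)
    areaSigma[i, ] <- sig
  }
  lots <- DataFrame(
    lot_id = sprintf("lot%02d", seq_len(n)),
    origin = origin,
    risk_class = risk,
    growth_rate_true = growth,
    cfse_prolif_frac = frac
  )
  new("LotPanel", lots = lots, areaMu = areaMu, areaSigma = areaSigma,
      schedule = schedule, seed = as.integer(seed))
}

#' @rdname LotPanel-accessors
#' @name LotPanel-accessors
#' @title Accessors for LotPanel ground truth
#' @param panel A \code{\link{LotPanel}}.
#' @return \code{lotIds}: character vector; \code{riskClass}: named character
#'   vector; \code{growthRateTrue}, \code{cfseProlifFrac}: named numeric
#'   vectors; \code{panelSchedule}: numeric imaging times; \code{areaMu},
#'   \code{areaSigma}: lots x time matrices.
#' @export
lotIds <- function(panel) panel@lots$lot_id

#' @rdname LotPanel-accessors
#' @export
riskClass <- function(panel)
  setNames(panel@lots$risk_class, panel@lots$lot_id)

#' @rdname LotPanel-accessors
#' @export
growthRateTrue <- function(panel)
  setNames(panel@lots$growth_rate_true, panel@lots$lot_id)

#' @rdname LotPanel-accessors
#' @export
cfseProlifFrac <- function(panel)
  setNames(panel@lots$cfse_prolif_frac, panel@lots$lot_id)

#' @rdname LotPanel-accessors
#' @export
panelSchedule <- function(panel) panel@schedule

#' @rdname LotPanel-accessors
#' @export
areaMu <- function(panel) panel@areaMu

#' @rdname LotPanel-accessors
#' @export
areaSigma <- function(panel) panel@areaSigma

#' The 16 per-cell morphological descriptors
#'
#' Canonical descriptor order shared by the generator (descriptor tables) and
#' the image-based morphometry (\code{\link{computeDescriptors}}).
#'
#' @return Character vector of 16 descriptor names.
#' @export
descriptorNames <- function() {
  c("area", "perimeter", "shape_factor", "eq_diameter", "major_axis",
    "minor_axis", "aspect_ratio", "eccentricity", "convex_area", "solidity",
    "extent", "compactness", "feret_max", "feret_min", "boundary_roughness",
    "radius_ratio")
}

# Draw the 15 non-area descriptors from areas plus shape noise. By default the
# shape noise is class-independent, so between-class signal lives only in the
# area-distribution dynamics; class_shape_delta < 0 narrows High-risk shape
# noise to add an explicit class-dependent shape channel.
.sampleDescriptors <- function(area, risk_class = "Low",
                               class_shape_delta = 0) {
  n <- length(area)
  scale_ar <- 0.35 * (1 + if (risk_class == "High") class_shape_delta else 0)
  r <- 1 + rgamma(n, shape = 2, scale = scale_ar)
  major <- 2 * sqrt(area * r / pi)
  minor <- 2 * sqrt(area / (pi * r))
  ecc <- sqrt(1 - 1 / r^2)
  rho <- pmax(1.04 * exp(rnorm(n, 0, 0.04)), 1.001)
  a <- major / 2; b <- minor / 2
  per <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b))) * rho
  sol <- 1 / (1 + 0.005 + abs(rnorm(n, 0, 0.02)))
  data.table(
    area = area,
    perimeter = per,
    shape_factor = 4 * pi * area / per^2,
    eq_diameter = 2 * sqrt(area / pi),
    major_axis = major,
    minor_axis = minor,
    aspect_ratio = r,
    eccentricity = ecc,
    convex_area = area / sol,
    solidity = sol,
    extent = pmin(1, (pi / 4) * exp(rnorm(n, -0.05, 0.06))),
    compactness = per^2 / area,
    feret_max = major * (1 + abs(rnorm(n, 0, 0.01))),
    feret_min = minor / (1 + abs(rnorm(n, 0, 0.01))),
    boundary_roughness = rho * (1 + abs(rnorm(n, 0, 0.01))),
    radius_ratio = r * exp(abs(rnorm(n, 0, 0.05)))
  )
}

#' Simulate the time-lapse cell populations of a panel
#'
#' For every lot and well, the cell count at time \code{t} follows
#' \code{round(n0_cells * G^((t - 12) / 126) * eps_well)} where \code{G} is the
#' lot's true fold change over 12--138 h and \code{eps_well} is a per-well
#' lognormal factor with coefficient of variation \code{well_cv}. Per frame,
#' single-cell areas are drawn lognormal from the lot's calibrated
#' (mu, sigma) trajectory and the remaining 15 descriptors are derived from
#' area plus shape noise. Cells get uniform positions in the well so quadrant
#' FOV pseudo-samples can be split off later.
#'
#' @param panel A \code{\link{LotPanel}}.
#' @param n_wells Wells per lot (default 3 replicate wells).
#' @param n0_cells Expected cells per well at 12 h (default 500).
#' @param well_cv Coefficient of variation of the per-well seeding factor
#'   (default 0.03; 0 disables well noise).
#' @param well_um Side length of the square well footprint in micrometres.
#' @param seed Master seed; defaults to the panel's own seed. Each
#'   (lot, well) pair uses its own substream.
#' @param lots Optional subset of lot ids to simulate.
#' @param class_shape_delta Class-dependent shape-noise effect: 0 (default)
#'   keeps the non-area shape noise identical across classes; negative
#'   values narrow the High-risk aspect-ratio noise.
#' @return A \code{data.table} of per-cell records with columns \code{lot},
#'   \code{well}, \code{time_h}, \code{cell_id}, \code{x_um}, \code{y_um} and
#'   the 16 descriptors of \code{\link{descriptorNames}}; the well footprint
#'   is attached as attribute \code{well_um}.
#' @examples
#' panel <- generateLotPanel(1, 0, seed = 1)
#' cells <- simulateTimecourse(panel, n_wells = 1, n0_cells = 100)
#' nrow(unique(cells[, c("well", "time_h")])) # 22 frames
#' @export
simulateTimecourse <- function(panel, n_wells = 3, n0_cells = 500,
                               well_cv = 0.03, well_um = 2000,
                               seed = panel@seed, lots = lotIds(panel),
                               class_shape_delta = 0) {
  .assertCount(n_wells, "n_wells", min = 1L)
  .assertCount(n0_cells, "n0_cells", min = 1L)
  if (well_cv < 0) stop("well_cv must be >= 0")
  times <- panel@schedule
  if (!length(times)) stop("empty schedule")
  idx <- match(lots, lotIds(panel))
  if (anyNA(idx)) stop("unknown lot id(s)")
  s2 <- log(1 + well_cv^2)
  out <- vector("list", length(idx) * n_wells)
  k <- 0L
  for (i in idx) {
    G <- panel@lots$growth_rate_true[i]
    risk <- panel@lots$risk_class[i]
    mu <- panel@areaMu[i, ]; sig <- panel@areaSigma[i, ]
    for (w in seq_len(n_wells)) {
      set.seed(.substreamSeed(seed, i, w))
      eps <- if (well_cv > 0) rlnorm(1, -s2 / 2, sqrt(s2)) else 1
      counts <- pmax(0L, as.integer(round(
        n0_cells * G^((times - 12) / 126) * eps)))
      ntot <- sum(counts)
      tvec <- rep(times, counts)
      areas <- rlnorm(ntot, rep(mu, counts), rep(sig, counts))
      d <- .sampleDescriptors(areas, risk, class_shape_delta)
      d[, `:=`(
        lot = panel@lots$lot_id[i],
        well = sprintf("w%d", w),
        time_h = tvec,
        cell_id = sequence(counts),
        x_um = runif(ntot, 0, well_um),
        y_um = runif(ntot, 0, well_um)
      )]
      k <- k + 1L
      out[[k]] <- d
    }
  }
  res <- rbindlist(out)
  data.table::setcolorder(res, c("lot", "well", "time_h", "cell_id",
                                 "x_um", "y_um", descriptorNames()))
  data.table::setattr(res, "well_um", well_um)
  res[]
}

#' Simulate a CFSE dilution readout for one co-culture well
#'
#' Event intensities are drawn on the log10 fluorescence scale from the
#' two-component Gaussian mixture
#' \eqn{(1-\pi)\,N(3.0, 0.15^2) + \pi\,N(1.8, 0.25^2)}, where \eqn{\pi} is the
#' lot's true proliferated fraction: the high peak is the unproliferated
#' T-cell population, the low peak the dye-diluted proliferated one.
#'
#' @param panel A \code{\link{LotPanel}}.
#' @param lot Lot id.
#' @param well Replicate well index (default 1).
#' @param n_events Number of events (>= 100; the downstream score is unstable
#'   below that).
#' @param seed Master seed (defaults to the panel's).
#' @return A \code{data.frame} with columns \code{lot}, \code{well} and
#'   \code{intensity} (log10 fluorescence).
#' @examples
#' panel <- generateLotPanel(1, 0, seed = 1)
#' cf <- simulateCFSE(panel, "lot01", n_events = 1000)
#' @export
simulateCFSE <- function(panel, lot, well = 1, n_events = 10000,
                         seed = panel@seed) {
  if (n_events < 100)
    stop("n_events must be >= 100 (score unstable below this)")
  i <- match(lot, lotIds(panel))
  if (is.na(i)) stop("unknown lot id: ", lot)
  set.seed(.substreamSeed(seed, i, 900L + well))
  p <- panel@lots$cfse_prolif_frac[i]
  lo <- runif(n_events) < p
  x <- ifelse(lo, rnorm(n_events, .CFSE_LO[["mean"]], .CFSE_LO[["sd"]]),
              rnorm(n_events, .CFSE_HI[["mean"]], .CFSE_HI[["sd"]]))
  data.frame(lot = lot, well = sprintf("w%d", well), intensity = x)
}

#' Simulate CFSE readouts for all lots and replicate wells
#'
#' @inheritParams simulateCFSE
#' @param n_wells Replicate co-culture wells per lot (default 3).
#' @return A \code{data.table} of events across all lots/wells.
#' @export
simulateCFSEPanel <- function(panel, n_wells = 3, n_events = 10000,
                              seed = panel@seed) {
  rbindlist(lapply(lotIds(panel), function(l)
    rbindlist(lapply(seq_len(n_wells), function(w)
      simulateCFSE(panel, l, w, n_events, seed)))))
}
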