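#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' LotPanel: latent ground truth for a panel of MSC lots
#'
#' A \code{LotPanel} holds the generating truth for a synthetic panel of MSC
#' lots: the risk class of each lot (does it retain T-cell proliferation
#' inhibitory potency or not), its true fold-change growth rate over the
#' 12--138 h culture, the per-time-point log-area location/scale trajectories
#' that drive the single-cell area distributions, and the fraction of
#' proliferated T cells its co-culture CFSE readout encodes.
#'
#' @slot lots A \link[S4Vectors]{DataFrame} with one row per lot and columns
#'   \code{lot_id}, \code{origin} (\code{"BMSC"} or \code{"ADSC"}),
#'   \code{risk_class} (\code{"Low"} or \code{"High"}),
#'   \code{growth_rate_true} (fold change over 12 to 138 h) and
#'   \code{cfse_prolif_frac} (fraction in [0,1]).
#' @slot areaMu Numeric matrix, lots x time points: log-area location
#'   (log um^2) per scheduled time point.
#' @slot areaSigma Numeric matrix, lots x time points: log-area scale (> 0).
#' @slot schedule Numeric vector of imaging times in hours after seeding.
#' @slot seed Integer master seed the panel was generated from.
#'
#' @seealso \code{\link{generateLotPanel}}
#' @export
setClass("LotPanel",
  representation(
    lots = "DataFrame",
    areaMu = "matrix",
    areaSigma = "matrix",
    schedule = "numeric",
    seed = "integer"
  )
)

setValidity("LotPanel", function(object) {
  msg <- character()
  lt <- object@lots
  need <- c("lot_id", "origin", "risk_class", "growth_rate_true",
            "cfse_prolif_frac")
  if (!all(need %in% colnames(lt)))
    msg <- c(msg, paste("lots must have columns:", paste(need, collapse = ", ")))
  else {
    if (any(lt$growth_rate_true <= 0))
      msg <- c(msg, "growth_rate_true must be > 0")
    if (any(lt$cfse_prolif_frac < 0 | lt$cfse_prolif_frac > 1))
      msg <- c(msg, "cfse_prolif_frac must lie in [0, 1]")
    if (!all(lt$risk_class %in% c("Low", "High")))
      msg <- c(msg, "risk_class must be 'Low' or 'High'")
  }
  nT <- length(object@schedule)
  if (nrow(object@areaMu) != nrow(lt) || ncol(object@areaMu) != nT)
    msg <- c(msg, "areaMu must be lots x time points")
  if (nrow(object@areaSigma) != nrow(lt) || ncol(object@areaSigma) != nT)
    msg <- c(msg, "areaSigma must be lots x time points")
  if (any(object@areaSigma <= 0))
    msg <- c(msg, "areaSigma entries must be > 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn LotPanel Number of lots in the panel.
#' @param x A \code{LotPanel}.
#' @export
setMethod("length", "LotPanel", function(x) nrow(x@lots))

setMethod("show", "LotPanel", function(object) {
  lt <- object@lots
  cat("LotPanel with", nrow(lt), "lots (",
      sum(lt$risk_class == "Low"), "Low-risk /",
      sum(lt$risk_class == "High"), "High-risk )\n")
  cat("  schedule:", length(object@schedule), "time points,",
      min(object@schedule), "-", max(object@schedule), "h\n")
  cat("  growth rates:", paste(format(round(lt$growth_rate_true, 2)),
                               collapse = ", "), "\n")
})

#' SyntheticImage: a rendered well image with ground truth
#'
#' Phase-contrast-like rendering of one synthetic frame, together with the
#' exact per-cell label mask it was rendered from.
#'
#' @slot pixels Numeric matrix in [0, 1], the grayscale image.
#' @slot truthMask Integer matrix of the same size; 0 = background, cells
#'   labelled 1..K contiguously.
#' @slot pixelSizeUm Physical pixel size in micrometres.
#' @slot placedCells A \link[S4Vectors]{DataFrame} of placed cells
#'   (centroid, prescribed area in um^2, aspect ratio, orientation) plus a
#'   \code{dropped} attribute-free count column is kept in
#'   \code{metadata}-like slot \code{nDropped}.
#' @slot nDropped Integer: cells that could not be placed without overlap.
#' @export
setClass("SyntheticImage",
  representation(
    pixels = "matrix",
    truthMask = "matrix",
    pixelSizeUm = "numeric",
    placedCells = "DataFrame",
    nDropped = "integer"
  )
)

setValidity("SyntheticImage", function(object) {
  msg <- character()
  if (!identical(dim(object@pixels), dim(object@truthMask)))
    msg <- c(msg, "pixels and truthMask must share dimensions")
  labs <- sort(unique(as.integer(object@truthMask)))
  labs <- labs[labs != 0L]
  if (length(labs) && !identical(labs, seq_len(max(labs))))
    msg <- c(msg, "truthMask labels must be contiguous 1..K")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticImage", function(object) {
  cat("SyntheticImage", paste(dim(object@pixels), collapse = " x "),
      "px @", object@pixelSizeUm, "um/px;",
      max(object@truthMask), "cells placed,",
      object@nDropped, "dropped\n")
})

#' LabelMask: a segmentation result
#'
#' Integer label image (0 = background, 8-connected regions) with its pixel
#' calibration; returned by \code{\link{segmentCells}} and consumed by
#' \code{\link{computeDescriptors}}.
#'
#' @slot labels Integer matrix of region labels.
#' @slot pixelSizeUm Micrometres per pixel.
#' @export
setClass("LabelMask",
  representation(labels = "matrix", pixelSizeUm = "numeric")
)

setValidity("LabelMask", function(object) {
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    "pixelSizeUm must be a single positive number" else TRUE
})

setMethod("show", "LabelMask", function(object) {
  cat("LabelMask", paste(dim(object@labels), collapse = " x "), "px,",
      max(object@labels), "regions @", object@pixelSizeUm, "um/px\n")
})

#' MorphProfileSet: time-course morphological profiles
#'
#' A \code{MorphProfileSet} extends
#' \link[SummarizedExperiment]{SummarizedExperiment}. Rows are profile
#' features (descriptor x statistic x time point), columns are samples
#' (lot / well / optional FOV pseudo-sample). The \code{"profile"} assay
#' holds the aggregate values; the \code{"imputed"} assay marks entries
#' filled by temporal interpolation. \code{rowData} carries
#' \code{parameter}, \code{stat} (\code{"mean"} or \code{"sd"}) and
#' \code{time_h}; \code{colData} carries sample identity and any teacher
#' signals attached downstream. \code{metadata(x)$parameter_mode} is one of
#' \code{"mean+SD"}, \code{"without_SD"}, \code{"only_SD"}.
#'
#' @seealso \code{\link{assembleProfiles}}, \code{\link{subsetParameters}},
#'   \code{\link{windowProfile}}
#' @export
setClass("MorphProfileSet", contains = "SummarizedExperiment")

setValidity("MorphProfileSet", function(object) {
  msg <- character()
  if (!"profile" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'profile' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("parameter", "stat", "time_h") %in% colnames(rd)))
    msg <- c(msg, "rowData must have parameter, stat, time_h")
  mode <- metadata(object)$parameter_mode
  if (is.null(mode) || !mode %in% c("mean+SD", "without_SD", "only_SD"))
    msg <- c(msg, "metadata parameter_mode must be mean+SD / without_SD / only_SD")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MorphProfileSet", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cat("MorphProfileSet:", length(unique(rd$parameter)), "parameters x",
      length(unique(paste(rd$stat))), "stats x",
      length(unique(rd$time_h)), "time points;",
      ncol(object), "samples; mode =", metadata(object)$parameter_mode, "\n")
  callNextMethod()
})

#' CVReport: one leave-lot-out cross-validation result
#'
#' Pooled held-out predictions and metrics for one (learner, parameter mode,
#' time window) cell of the model sweep.
#'
#' @slot method \code{"kNN"}, \code{"LASSO"} or \code{"RF"}.
#' @slot task \code{"classification"} or \code{"regression"}.
#' @slot parameterMode Parameter subset the design matrix used.
#' @slot windowEndH Last imaging time (h) included in the features.
#' @slot predictions A \link[S4Vectors]{DataFrame} with one row per sample:
#'   \code{sample_id}, \code{lot}, \code{truth}, \code{pred}, \code{fold}.
#' @slot metrics Named numeric vector: accuracy/precision/specificity for
#'   classification, rmse for regression.
#' @slot confusion Classification confusion matrix (2 x 2) or a 0 x 0 matrix.
#' @slot lassoFolds List of per-fold named coefficient vectors (LASSO only).
#' @slot hyper Named list of hyperparameters actually used.
#' @export
setClass("CVReport",
  representation(
    method = "character",
    task = "character",
    parameterMode = "character",
    windowEndH = "numeric",
    predictions = "DataFrame",
    metrics = "numeric",
    confusion = "matrix",
    lassoFolds = "list",
    hyper = "list"
  )
)

setMethod("show", "CVReport", function(object) {
  cat("CVReport:", object@method, "/", object@parameterMode, "/ window",
      object@windowEndH, "h (", object@task, ")\n")
  cat("  folds:", length(unique(object@predictions$fold)),
      " samples:", nrow(object@predictions), "\n")
  m <- object@metrics
  cat("  ", paste(sprintf("%s = %.4g", names(m), m), collapse = ", "), "\n")
})
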