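#' Aggregate one frame's cells into the 32 mean/SD parameters
#'
#' Each image (frame) is summarised by the mean and the sample standard
#' deviation (n - 1 denominator) of the 16 morphological descriptors: 32
#' aggregate parameters in total. Frames with fewer than \code{min_cells}
#' cells are flagged (not dropped); an empty frame yields an all-missing
#' summary with the flag set.
#'
#' @param cells data.frame of per-cell records holding the 16 descriptor
#'   columns (\code{\link{descriptorNames}}); may be empty.
#' @param min_cells QC threshold on the number of cells per image
#'   (default 200, the minimum the profiling design assumes per full image).
#' @return A one-row \code{data.frame}: \code{n_cells}, \code{qc_flag}, then
#'   \code{mean_<descriptor>} and \code{sd_<descriptor>} columns.
#' @examples
#' f <- data.frame(matrix(1000, 300, 16, dimnames = list(NULL, descriptorNames())))
#' aggregateFrame(f)$mean_area # 1000
#' @export
aggregateFrame <- function(cells, min_cells = 200) {
  dn <- descriptorNames()
  n <- nrow(cells)
  if (n == 0) {
    vals <- rep(NA_real_, 32)
  } else {
    m <- vapply(dn, function(d) mean(cells[[d]]), numeric(1))
    s <- vapply(dn, function(d) sd(cells[[d]]), numeric(1))
    vals <- c(m, s)
  }
  out <- data.frame(n_cells = n, qc_flag = n < min_cells)
  out[paste0("mean_", dn)] <- vals[seq_len(16)]
  out[paste0("sd_", dn)] <- vals[16 + seq_len(16)]
  out
}

#' Aggregate a per-cell table into frame summaries, grouped
#'
#' Grouped version of \code{\link{aggregateFrame}} over a full per-cell table
#' (as produced by \code{\link{simulateTimecourse}} or read from descriptor
#' CSVs).
#'
#' @param cells A data.frame/data.table of per-cell records.
#' @param by Grouping columns defining one frame (default lot, well, time_h;
#'   add \code{"fov"} after \code{\link{splitFOVs}}).
#' @param min_cells QC threshold per frame.
#' @return data.table of frame summaries, one row per group.
#' @export
aggregateFrames <- function(cells, by = c("lot", "well", "time_h"),
                            min_cells = 200) {
  dt <- data.table::as.data.table(cells)
  dn <- descriptorNames()
  ms <- dt[, c(list(n_cells = .N),
               setNames(lapply(.SD, mean), paste0("mean_", dn)),
               setNames(lapply(.SD, sd), paste0("sd_", dn))),
           by = by, .SDcols = dn]
  ms[, qc_flag := n_cells < min_cells]
  data.table::setcolorder(ms, c(by, "n_cells", "qc_flag"))
  ms[]
}

#' Split a well into 2 x 2 FOV pseudo-samples
#'
#' Partitions each frame's cells into four spatial quadrants of the well
#' footprint. Each pseudo-sample inherits the well's teacher signals; the
#' quadrant boundaries are fixed, so assignment is consistent across time.
#' Pseudo-samples are used for potency classification only -- growth-rate
#' modelling treats the whole well as one sample.
#'
#' @param cells Per-cell table with \code{x_um}, \code{y_um} positions (and a
#'   \code{well_um} attribute, or pass \code{well_um}).
#' @param well_um Side length of the well footprint (um).
#' @return The table with an added \code{fov} column (\code{"f1"}..\code{"f4"}).
#' @export
splitFOVs <- function(cells, well_um = attr(cells, "well_um")) {
  dt <- data.table::as.data.table(cells)
  if (is.null(well_um)) well_um <- max(dt$x_um, dt$y_um)
  if (!all(c("x_um", "y_um") %in% names(dt)))
    stop("cells must carry x_um / y_um positions")
  qx <- dt$x_um >= well_um / 2
  qy <- dt$y_um >= well_um / 2
  dt[, fov := sprintf("f%d", 1L + qx + 2L * qy)]
  data.table::setattr(dt, "well_um", well_um)
  dt[]
}

#' Assemble time-course morphological profiles
#'
#' Builds a \code{\link{MorphProfileSet}} (32 parameters x schedule time
#' points per sample) from frame summaries. Missing or all-NA frames are
#' filled by linear interpolation along time (nearest neighbour at the
#' edges) and recorded in the \code{"imputed"} assay. Samples whose missing
#' or QC-flagged frames exceed \code{max_missing_frac} of the schedule are
#' rejected: dropped with a warning and listed in
#' \code{metadata(x)$rejected}.
#'
#' @param summaries Frame summaries from \code{\link{aggregateFrames}}; the
#'   sample identity is \code{lot:well} or \code{lot:well:fov} when a
#'   \code{fov} column is present.
#' @param schedule Imaging schedule the profiles are keyed to.
#' @param max_missing_frac Rejection threshold (default 0.2).
#' @return A \code{\link{MorphProfileSet}} in \code{"mean+SD"} mode.
#' @export
assembleProfiles <- function(summaries, schedule = scheduleTimes(),
                             max_missing_frac = 0.2) {
  dt <- data.table::as.data.table(summaries)
  idcols <- intersect(c("lot", "well", "fov"), names(dt))
  dt[, sample_id := do.call(paste, c(.SD, sep = ":")), .SDcols = idcols]
  if (!all(dt$time_h %in% schedule))
    stop("summaries contain time points outside the schedule")
  dn <- descriptorNames()
  valcols <- c(paste0("mean_", dn), paste0("sd_", dn))
  # complete (sample, time) grid; absent frames become NA rows
  ids <- unique(dt[, c("sample_id", idcols), with = FALSE])
  grid <- data.table::CJ(sample_id = ids$sample_id, time_h = schedule,
                         unique = TRUE)
  full <- merge(grid, dt, by = c("sample_id", "time_h"), all.x = TRUE)
  full[, missing_frame := is.na(n_cells) |
         rowSums(is.na(.SD)) == length(valcols), .SDcols = valcols]
  full[, flagged := !is.na(qc_flag) & qc_flag]
  bad <- full[, .(frac = mean(missing_frame | flagged)), by = sample_id]
  rejected <- bad$sample_id[bad$frac > max_missing_frac]
  if (length(rejected)) {
    warning(sprintf(
      "rejecting %d sample(s) with > %.0f%% missing/flagged frames: %s",
      length(rejected), 100 * max_missing_frac,
      paste(rejected, collapse = ", ")))
    full <- full[!sample_id %in% rejected]
    ids <- ids[!sample_id %in% rejected]
  }
  if (!nrow(full)) stop("no samples left after rejection")
  long <- data.table::melt(
    full[, c("sample_id", "time_h", "missing_frame", valcols), with = FALSE],
    id.vars = c("sample_id", "time_h", "missing_frame"),
    variable.name = "param", value.name = "value",
    variable.factor = FALSE)
  data.table::setorder(long, sample_id, param, time_h)
  long[, imputed := is.na(value)]
  long[, value := {
    v <- value
    if (anyNA(v) && any(!is.na(v))) {
      ok <- !is.na(v)
      v[!ok] <- approx(time_h[ok], v[ok], xout = time_h[!ok],
                       rule = 2)$y
    }
    v
  }, by = .(sample_id, param)]
  if (anyNA(long$value))
    stop("sample with no usable values for a parameter; cannot impute")
  stat <- ifelse(startsWith(long$param, "mean_"), "mean", "sd")
  parameter <- sub("^(mean|sd)_", "", long$param)
  long[, feature := paste0(param, "_t", time_h)]
  # deterministic row order: stat (mean first), descriptor order, time
  feat <- data.table::data.table(
    feature = long$feature, stat = stat, parameter = parameter,
    time_h = long$time_h)
  feat <- unique(feat)
  feat[, pord := match(parameter, dn)]
  feat <- feat[order(match(stat, c("mean", "sd")), pord, time_h)]
  prof <- data.table::dcast(long, feature ~ sample_id, value.var = "value")
  impu <- data.table::dcast(long, feature ~ sample_id, value.var = "imputed")
  ord <- match(feat$feature, prof$feature)
  m <- as.matrix(prof[ord, -1, with = FALSE])
  im <- as.matrix(impu[ord, -1, with = FALSE])
  rownames(m) <- rownames(im) <- feat$feature
  scol <- match(ids$sample_id, colnames(m))
  m <- m[, scol, drop = FALSE]; im <- im[, scol, drop = FALSE]
  cd <- S4Vectors::DataFrame(ids)
  rownames(cd) <- ids$sample_id
  ncmat <- data.table::dcast(full, time_h ~ sample_id, value.var = "n_cells")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(profile = m, imputed = im),
    rowData = S4Vectors::DataFrame(parameter = feat$parameter,
                                   stat = feat$stat, time_h = feat$time_h),
    colData = cd)
  metadata(se)$parameter_mode <- "mean+SD"
  metadata(se)$schedule <- schedule
  metadata(se)$n_cells <- ncmat
  metadata(se)$rejected <- as.character(rejected)
  new("MorphProfileSet", se)
}

#' Subset a profile to a parameter mode
#'
#' The three parameter usages compared throughout: \code{"mean+SD"} (all 32
#' parameters), \code{"without_SD"} (the 16 mean-related, majority
#' information) and \code{"only_SD"} (the 16 SD-related, population
#' diversity information).
#'
#' @param x A \code{\link{MorphProfileSet}} in \code{"mean+SD"} mode.
#' @param mode One of \code{"mean+SD"}, \code{"without_SD"}, \code{"only_SD"}.
#' @return The subsetted \code{MorphProfileSet} with its mode updated.
#' @export
subsetParameters <- function(x, mode = c("mean+SD", "without_SD", "only_SD")) {
  mode <- match.arg(mode)
  if (metadata(x)$parameter_mode != "mean+SD")
    stop("profile is already subset to ", metadata(x)$parameter_mode)
  if (mode == "mean+SD") return(x)
  keep <- SummarizedExperiment::rowData(x)$stat ==
    if (mode == "only_SD") "sd" else "mean"
  out <- x[keep, ]
  metadata(out)$parameter_mode <- mode
  out
}

#' Truncate a profile's time window
#'
#' Keeps feature columns with imaging time at most \code{end_h} -- used to ask
#' how early in culture the potencies become predictable.
#'
#' @param x A \code{\link{MorphProfileSet}}.
#' @param end_h Last included imaging time (hours).
#' @return The windowed \code{MorphProfileSet}.
#' @export
windowProfile <- function(x, end_h) {
  sched <- metadata(x)$schedule
  if (end_h < min(sched)) stop("end_h is before the first scheduled frame")
  out <- x[SummarizedExperiment::rowData(x)$time_h <= end_h, ]
  metadata(out)$schedule <- sched[sched <= end_h]
  out
}
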