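#' Read and write the standard plain-text artefacts
#'
#' The pipeline's tables travel as CSV: per-cell descriptor tables (so
#' imaging can be bypassed entirely), tidy long-format profiles, CFSE event
#' lists and per-lot potency records; panel ground truth travels as JSON and
#' images/masks as 16-bit grayscale TIFF.
#'
#' @param cells,file,panel,x,cfse Objects/paths as per the individual
#'   functions.
#' @name io
NULL

#' @rdname io
#' @export
writeCellTable <- function(cells, file) {
  data.table::fwrite(data.table::as.data.table(cells), file)
  invisible(file)
}

#' @rdname io
#' @export
readCellTable <- function(file) {
  dt <- data.table::fread(file)
  miss <- setdiff(c("lot", "well", "time_h", descriptorNames()), names(dt))
  if (length(miss))
    stop("cell table misses columns: ", paste(miss, collapse = ", "))
  dt
}

#' @rdname io
#' @export
writeCFSETable <- function(cfse, file) {
  data.table::fwrite(data.table::as.data.table(cfse), file)
  invisible(file)
}

#' @rdname io
#' @export
readCFSETable <- function(file) {
  dt <- data.table::fread(file)
  if (!"intensity" %in% names(dt)) stop("CFSE table needs 'intensity'")
  dt
}

#' @rdname io
#' @export
writePanelJSON <- function(panel, file) {
  obj <- list(
    seed = panel@seed,
    schedule = panel@schedule,
    lots = as.data.frame(panel@lots),
    area_mu = panel@areaMu,
    area_sigma = panel@areaSigma)
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname io
#' @export
readPanelJSON <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  new("LotPanel",
      lots = DataFrame(obj$lots),
      areaMu = as.matrix(obj$area_mu),
      areaSigma = as.matrix(obj$area_sigma),
      schedule = as.numeric(obj$schedule),
      seed = as.integer(obj$seed))
}

#' Write a profile set as tidy long-format CSV
#'
#' @param x A \code{\link{MorphProfileSet}}.
#' @param file Output path; columns sample_id, parameter, stat, time_h,
#'   value, imputed.
#' @export
writeProfileCSV <- function(x, file) {
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  m <- SummarizedExperiment::assay(x, "profile")
  im <- SummarizedExperiment::assay(x, "imputed")
  long <- data.table::data.table(
    sample_id = rep(colnames(m), each = nrow(m)),
    parameter = rep(rd$parameter, ncol(m)),
    stat = rep(rd$stat, ncol(m)),
    time_h = rep(rd$time_h, ncol(m)),
    value = as.vector(m),
    imputed = as.vector(im))
  data.table::fwrite(long, file)
  invisible(file)
}

#' Write a rendered image and its truth mask as 16-bit TIFF
#'
#' @param img A \code{\link{SyntheticImage}}.
#' @param file_image,file_mask Output paths; the mask stores label/65535 so
#'   integer labels survive the 16-bit round trip.
#' @export
writeImageTIFF <- function(img, file_image, file_mask = NULL) {
  EBImage::writeImage(EBImage::Image(img@pixels), file_image,
                      type = "tiff", bits.per.sample = 16L)
  if (!is.null(file_mask))
    EBImage::writeImage(EBImage::Image(img@truthMask / 65535), file_mask,
                        type = "tiff", bits.per.sample = 16L)
  invisible(file_image)
}

#' Read a 16-bit label mask written by \code{\link{writeImageTIFF}}
#'
#' @param file Path to the mask TIFF.
#' @param pixel_size_um Pixel calibration to attach.
#' @return A \code{\link{LabelMask}}.
#' @export
readMaskTIFF <- function(file, pixel_size_um) {
  m <- as.matrix(EBImage::imageData(EBImage::readImage(file)))
  lab <- matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  new("LabelMask", labels = lab, pixelSizeUm = pixel_size_um)
}
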