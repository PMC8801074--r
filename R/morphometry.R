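#' Segment cells in a grayscale image
#'
#' A documented, open replacement for proprietary time-lapse segmentation
#' recipes: (1) background estimation by a large-sigma Gaussian blur and
#' subtraction (cells are darker than the background; the bright halo is
#' excluded by the sign), (2) Otsu threshold on the background-subtracted
#' signal, (3) hole filling, (4) splitting of touching cells by watershed on
#' the distance transform, (5) removal of regions below \code{min_area_um2}.
#' The procedure is fully deterministic given its inputs.
#'
#' @param image Numeric matrix (grayscale) or \code{EBImage::Image}.
#' @param pixel_size_um Micrometres per pixel.
#' @param min_area_um2 Minimum region area kept, in um^2 (default 200).
#' @param bg_sigma Sigma (px) of the background-estimation blur.
#' @param ws_tolerance Watershed tolerance (object-merging threshold on the
#'   distance transform).
#' @return A \code{\link{LabelMask}}; an all-constant image yields an empty
#'   mask (0 regions), not an error.
#' @seealso \code{\link{computeDescriptors}}, \code{\link{renderImage}}
#' @export
segmentCells <- function(image, pixel_size_um, min_area_um2 = 200,
                         bg_sigma = 20, ws_tolerance = 1) {
  .assertPositive(pixel_size_um, "pixel_size_um")
  if (min_area_um2 < 0) stop("min_area_um2 must be >= 0")
  img <- as.matrix(if (is(image, "Image")) EBImage::imageData(image) else image)
  if (any(!is.finite(img))) stop("image must be finite-valued")
  empty <- function() new("LabelMask",
                          labels = matrix(0L, nrow(img), ncol(img)),
                          pixelSizeUm = pixel_size_um)
  if (diff(range(img)) == 0) return(empty())
  bg <- EBImage::gblur(EBImage::Image(img), sigma = bg_sigma)
  resid <- as.matrix(EBImage::imageData(bg)) - img
  signal <- pmax(resid, 0)
  rng <- max(signal)
  if (rng == 0) return(empty())
  signal <- signal / rng
  thr <- EBImage::otsu(EBImage::Image(signal), range = c(0, 1))
  # a field with no cells has an Otsu threshold inside the noise: require
  # the threshold to clear the background noise level (robust MAD estimate)
  if (thr * rng < 3 * stats::mad(resid)) return(empty())
  bw <- EBImage::fillHull(EBImage::Image(signal > thr))
  min_area_px <- min_area_um2 / pixel_size_um^2
  dm <- EBImage::distmap(bw)
  ext <- max(1, round(sqrt(max(min_area_px, 1)) / 2))
  ws <- EBImage::watershed(dm, tolerance = ws_tolerance, ext = ext)
  lab <- as.matrix(EBImage::imageData(ws))
  storage.mode(lab) <- "integer"
  # min-area filter + contiguous relabel
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area_px)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  new("LabelMask", labels = lab, pixelSizeUm = pixel_size_um)
}

# 2x2 symmetric eigenvalues, descending
.eig2 <- function(mxx, myy, mxy) {
  tr <- mxx + myy
  d <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  c(tr / 2 + d, tr / 2 - d)
}

# polygon area (shoelace) and perimeter for closed polygon given vertex matrix
.polyAreaPerim <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  area <- abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
  perim <- sum(sqrt(rowSums((p[j, , drop = FALSE] - p)^2)))
  c(area, perim)
}

# minimal width over hull edge directions (rotating calipers on a convex hull)
.minWidth <- function(h) {
  n <- nrow(h)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  w <- rep(NA_real_, n)
  for (e in seq_len(n)) {
    v <- h[j[e], ] - h[e, ]
    L <- sqrt(sum(v^2))
    if (L == 0) next
    nrm <- c(-v[2], v[1]) / L
    d <- (h[, 1] - h[e, 1]) * nrm[1] + (h[, 2] - h[e, 2]) * nrm[2]
    w[e] <- max(abs(d))
  }
  min(w, na.rm = TRUE)
}

#' Compute the 16 morphological descriptors per cell region
#'
#' One record per labelled region, with lengths in micrometres via the mask's
#' pixel size. Conventions (fixed and documented; they shift shape factors by
#' a few percent between alternatives): perimeter is the weighted boundary
#' step chain through boundary pixel centers (straight step = 1, diagonal =
#' sqrt(2)); axes come from second central moments of the pixel centers (plus
#' the 1/12 per-pixel variance), with major/minor = 4 sqrt(eigenvalue), which
#' is exact for a continuous ellipse; the convex hull is taken over boundary
#' pixel corners; Feret diameters are taken over hull vertices (max pairwise
#' distance and rotating-calipers minimal width). Pixel coordinates are
#' 0-based, row-major, origin top-left. A 1-pixel region gets perimeter
#' \code{4 * pixel_size} by convention; shape_factor is clamped at 1.2.
#'
#' Descriptors: area, perimeter, shape_factor (4 pi A / P^2), eq_diameter,
#' major_axis, minor_axis, aspect_ratio, eccentricity, convex_area, solidity,
#' extent (area / bounding box), compactness (P^2 / A), feret_max, feret_min,
#' boundary_roughness (P / convex perimeter), radius_ratio (max/min
#' centroid-to-boundary distance).
#'
#' @param mask A \code{\link{LabelMask}} (or an integer label matrix plus
#'   \code{pixel_size_um}).
#' @param pixel_size_um Used only when \code{mask} is a bare matrix.
#' @return A \code{data.frame} with \code{cell_id} and the 16 descriptors of
#'   \code{\link{descriptorNames}}.
#' @export
computeDescriptors <- function(mask, pixel_size_um = NULL) {
  if (is(mask, "LabelMask")) {
    lab <- mask@labels; ps <- mask@pixelSizeUm
  } else {
    lab <- mask
    storage.mode(lab) <- "integer"
    if (is.null(pixel_size_um))
      stop("pixel_size_um required when mask is a bare matrix")
    ps <- pixel_size_um
  }
  K <- max(lab)
  if (K == 0L)
    return(cbind(data.frame(cell_id = integer()),
                 as.data.frame(matrix(numeric(), 0, 16,
                   dimnames = list(NULL, descriptorNames())))))
  contours <- EBImage::ocontour(EBImage::Image(lab))
  # ocontour names objects by label
  recs <- vector("list", K)
  for (k in seq_len(K)) {
    pix <- which(lab == k, arr.ind = TRUE)
    n <- nrow(pix)
    x <- pix[, 1] - 1; y <- pix[, 2] - 1   # 0-based
    cx <- mean(x); cy <- mean(y)
    mxx <- mean((x - cx)^2) + 1 / 12
    myy <- mean((y - cy)^2) + 1 / 12
    mxy <- mean((x - cx) * (y - cy))
    ev <- .eig2(mxx, myy, mxy)
    major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(max(ev[2], 1e-12))
    oc <- contours[[as.character(k)]]
    if (is.null(oc)) oc <- contours[[k]]
    if (is.null(oc) || nrow(oc) < 2) {
      perim_px <- 4
      bpts <- cbind(x, y)
    } else {
      jn <- c(2:nrow(oc), 1)
      st <- abs(oc[jn, , drop = FALSE] - oc)
      steps <- pmax(st[, 1], st[, 2]) + (sqrt(2) - 1) * pmin(st[, 1], st[, 2])
      perim_px <- sum(steps)
      if (perim_px == 0) perim_px <- 4
      bpts <- oc
    }
    # convex hull over boundary pixel corners
    corners <- rbind(cbind(bpts[, 1] - 0.5, bpts[, 2] - 0.5),
                     cbind(bpts[, 1] + 0.5, bpts[, 2] - 0.5),
                     cbind(bpts[, 1] - 0.5, bpts[, 2] + 0.5),
                     cbind(bpts[, 1] + 0.5, bpts[, 2] + 0.5))
    h <- corners[grDevices::chull(corners), , drop = FALSE]
    ap <- if (nrow(h) >= 3) .polyAreaPerim(h) else c(n, perim_px)
    conv_area_px <- max(ap[1], n)   # hull cannot undercut the region
    conv_perim_px <- max(ap[2], 1e-9)
    dmax <- if (nrow(h) >= 2) sqrt(max(stats::dist(h))^2) else 1
    fmax <- if (nrow(h) >= 2) max(stats::dist(h)) else 1
    fmin <- if (nrow(h) >= 3) .minWidth(h) else 1
    bd <- sqrt((bpts[, 1] - cx)^2 + (bpts[, 2] - cy)^2)
    rr <- if (n == 1L) 1 else max(bd) / max(min(bd), 0.5)
    area_um <- n * ps^2
    per_um <- perim_px * ps
    sf <- min(4 * pi * area_um / per_um^2, 1.2)
    bbox <- (diff(range(x)) + 1) * (diff(range(y)) + 1)
    recs[[k]] <- data.frame(
      cell_id = k,
      area = area_um,
      perimeter = per_um,
      shape_factor = sf,
      eq_diameter = 2 * sqrt(area_um / pi),
      major_axis = major * ps,
      minor_axis = minor * ps,
      aspect_ratio = major / minor,
      eccentricity = sqrt(max(0, 1 - (minor / major)^2)),
      convex_area = conv_area_px * ps^2,
      solidity = n / conv_area_px,
      extent = n / bbox,
      compactness = per_um^2 / area_um,
      feret_max = fmax * ps,
      feret_min = max(fmin, 1) * ps,
      boundary_roughness = perim_px / conv_perim_px,
      radius_ratio = rr
    )
  }
  do.call(rbind, recs)
}

#' Per-region intersection-over-union between two label masks
#'
#' For each region of \code{truth}, finds the best-overlapping region of
#' \code{seg} and reports the IoU -- used to validate segmentation against
#' rendered ground truth.
#'
#' @param truth,seg Integer label matrices (or \code{\link{LabelMask}}s) of
#'   identical size.
#' @return \code{data.frame} with \code{truth_label}, \code{seg_label},
#'   \code{iou}.
#' @export
maskIoU <- function(truth, seg) {
  tl <- if (is(truth, "LabelMask")) truth@labels else truth
  sl <- if (is(seg, "LabelMask")) seg@labels else seg
  stopifnot(identical(dim(tl), dim(sl)))
  K <- max(tl)
  out <- data.frame(truth_label = seq_len(K), seg_label = NA_integer_,
                    iou = 0)
  ssz <- tabulate(sl[sl > 0L], nbins = max(sl, 1))
  for (k in seq_len(K)) {
    idx <- tl == k
    nk <- sum(idx)
    ov <- table(sl[idx])
    ov <- ov[names(ov) != "0"]
    if (!length(ov)) next
    best <- which.max(ov)
    j <- as.integer(names(ov)[best])
    inter <- as.integer(ov[best])
    out$seg_label[k] <- j
    out$iou[k] <- inter / (nk + ssz[j] - inter)
  }
  out
}
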