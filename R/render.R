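#' Render a synthetic phase-contrast-like frame with ground truth
#'
#' Places each cell of one frame as a smoothed, randomly perturbed ellipse of
#' the prescribed area and aspect ratio, with a darker interior and a thin
#' brighter halo on a mid-grey background plus additive Gaussian noise --
#' a stand-in for phase-contrast optics, not a physical model. Placement is
#' overlap-free by rejection sampling; cells that cannot be placed within the
#' retry cap are counted in \code{nDropped} (never dropped silently: a
#' warning reports the number).
#'
#' @param cells A data.frame of the frame's cells with at least an
#'   \code{area} column (um^2); \code{aspect_ratio} is used when present.
#' @param image_px Canvas side length in pixels.
#' @param pixel_size_um Micrometres per pixel.
#' @param noise_sd Additive Gaussian background noise SD (image in [0, 1]).
#' @param seed RNG seed for placement and perturbation.
#' @param retry_cap Placement attempts per cell before it is dropped.
#' @return A \code{\link{SyntheticImage}}.
#' @examples
#' cells <- data.frame(area = rep(2000, 5), aspect_ratio = 1.5)
#' img <- renderImage(cells, image_px = 256, pixel_size_um = 2, seed = 1)
#' max(img@truthMask) # 5
#' @export
renderImage <- function(cells, image_px = 512, pixel_size_um = 2,
                        noise_sd = 0.01, seed = 1, retry_cap = 200) {
  .assertCount(image_px, "image_px", min = 16L)
  .assertPositive(pixel_size_um, "pixel_size_um")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  n <- nrow(cells)
  mask <- matrix(0L, image_px, image_px)
  guard <- matrix(FALSE, image_px, image_px) # occupied + 1 px margin
  base <- matrix(0.5, image_px, image_px)
  placed <- list()
  dropped <- 0L
  if (n > 0) {
    ord <- order(-cells$area) # place big cells first
    lab <- 0L
    for (ci in ord) {
      A_px <- cells$area[ci] / pixel_size_um^2
      r <- if ("aspect_ratio" %in% names(cells)) cells$aspect_ratio[ci] else 1.4
      a <- sqrt(A_px * r / pi); b <- sqrt(A_px / (pi * r))
      theta <- runif(1, 0, pi)
      # low-order Fourier boundary perturbation, zero-mean, small amplitude
      ck <- rnorm(3, 0, 0.02); ph <- runif(3, 0, 2 * pi)
      half <- ceiling(a * 1.15) + 2L
      sz <- 2L * half + 1L
      if (sz >= image_px - 2L) { dropped <- dropped + 1L; next }
      off <- seq(-half, half)
      u0 <- matrix(off, sz, sz)            # local x (cols of patch vary rows?)
      v0 <- matrix(off, sz, sz, byrow = TRUE)
      ur <- u0 * cos(theta) + v0 * sin(theta)
      vr <- -u0 * sin(theta) + v0 * cos(theta)
      rho <- sqrt((ur / a)^2 + (vr / b)^2)
      phi <- atan2(vr / b, ur / a)
      lim <- 1 + ck[1] * cos(2 * phi + ph[1]) + ck[2] * cos(3 * phi + ph[2]) +
        ck[3] * cos(4 * phi + ph[3])
      patch <- rho <= lim
      if (!any(patch)) patch[half + 1L, half + 1L] <- TRUE
      ok <- FALSE
      for (try in seq_len(retry_cap)) {
        cx <- sample.int(image_px - sz - 2L, 1L) + half + 1L
        cy <- sample.int(image_px - sz - 2L, 1L) + half + 1L
        rows <- (cx - half):(cx + half); cols <- (cy - half):(cy + half)
        if (!any(guard[rows, cols] & patch)) { ok <- TRUE; break }
      }
      if (!ok) { dropped <- dropped + 1L; next }
      lab <- lab + 1L
      sub <- mask[rows, cols]; sub[patch] <- lab; mask[rows, cols] <- sub
      # guard = placed pixels dilated by 1 (3x3, separable row then col pass)
      g1 <- patch
      g1[-1, ] <- g1[-1, ] | patch[-sz, ]
      g1[-sz, ] <- g1[-sz, ] | patch[-1, ]
      g <- g1
      g[, -1] <- g[, -1] | g1[, -sz]
      g[, -sz] <- g[, -sz] | g1[, -1]
      guard[rows, cols] <- guard[rows, cols] | g
      placed[[lab]] <- data.frame(
        centroid_x = cy, centroid_y = cx, area_um2 = cells$area[ci],
        aspect_ratio = r, orientation = theta)
    }
  }
  if (dropped > 0)
    warning(sprintf("renderImage: %d of %d cells could not be placed", dropped, n))
  interior <- mask > 0L
  # thin halo: 2-px dilation ring around the cells
  halo <- interior
  nr <- nrow(halo); nc <- ncol(halo)
  for (it in 1:2) {
    h1 <- halo
    h1[-1, ] <- h1[-1, ] | halo[-nr, ]
    h1[-nr, ] <- h1[-nr, ] | halo[-1, ]
    h2 <- h1
    h2[, -1] <- h2[, -1] | h1[, -nc]
    h2[, -nc] <- h2[, -nc] | h1[, -1]
    halo <- h2
  }
  ring <- halo & !interior
  base[interior] <- base[interior] - 0.30
  base[ring] <- base[ring] + 0.15
  img <- EBImage::gblur(EBImage::Image(base), sigma = 0.5)
  px <- as.matrix(EBImage::imageData(img)) + rnorm(length(base), 0, noise_sd)
  px <- matrix(pmin(pmax(px, 0), 1), nrow(base), ncol(base))
  pc <- if (length(placed)) do.call(rbind, placed) else
    data.frame(centroid_x = numeric(), centroid_y = numeric(),
               area_um2 = numeric(), aspect_ratio = numeric(),
               orientation = numeric())
  new("SyntheticImage", pixels = px, truthMask = mask,
      pixelSizeUm = pixel_size_um, placedCells = DataFrame(pc),
      nDropped = dropped)
}
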