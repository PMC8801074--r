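#' PCA map of morphological profiles
#'
#' Centers (and by default z-scores) the flattened profiles and computes a
#' principal component map of the samples. Component signs are fixed by
#' making each component's largest-magnitude loading positive, so the map is
#' fully deterministic.
#'
#' @param x A \code{\link{MorphProfileSet}} or a samples x features matrix.
#' @param standardize Z-score features before the SVD (default TRUE);
#'   zero-variance features are centered and left unscaled.
#' @return List: \code{scores} (samples x components), \code{loadings},
#'   \code{explained} (variance fractions; they sum to 1).
#' @export
pcaMap <- function(x, standardize = TRUE) {
  X <- if (is(x, "MorphProfileSet"))
    t(SummarizedExperiment::assay(x, "profile")) else as.matrix(x)
  if (nrow(X) < 2) stop("need at least 2 samples for PCA")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (standardize) {
    sdv <- apply(X, 2, sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    Xc <- sweep(Xc, 2, sdv, "/")
  }
  sv <- svd(Xc)
  ncomp <- sum(sv$d > max(sv$d) * 1e-12)
  d <- sv$d[seq_len(ncomp)]
  U <- sv$u[, seq_len(ncomp), drop = FALSE]
  V <- sv$v[, seq_len(ncomp), drop = FALSE]
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(ncomp)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  scores <- sweep(U, 2, d, "*")
  rownames(scores) <- rownames(X)
  colnames(scores) <- colnames(V) <- paste0("PC", seq_len(ncomp))
  rownames(V) <- colnames(X)
  list(scores = scores, loadings = V, explained = d^2 / sum(sv$d^2))
}

#' Average-linkage clustering with correlation distance
#'
#' Hierarchical clustering of samples with distance 1 - r (Pearson
#' correlation over the flattened profile entries) and UPGMA (average)
#' linkage -- the unsupervised view in which replicate wells of a lot should
#' sit far closer together than different lots.
#'
#' @param x A \code{\link{MorphProfileSet}} or samples x features matrix.
#' @return List: \code{hclust} (the tree), \code{dist} (the 1 - r
#'   distances).
#' @export
hclusterProfiles <- function(x) {
  X <- if (is(x, "MorphProfileSet"))
    t(SummarizedExperiment::assay(x, "profile")) else as.matrix(x)
  if (nrow(X) < 2) stop("need at least 2 samples to cluster")
  sds <- apply(X, 1, sd)
  if (any(sds == 0))
    stop("constant profile(s), correlation undefined: ",
         paste(rownames(X)[sds == 0], collapse = ", "))
  d <- as.dist(1 - cor(t(X)))
  list(hclust = stats::hclust(d, method = "average"), dist = d)
}

#' Export a clustering tree as Newick
#'
#' @param cl Result of \code{\link{hclusterProfiles}} (or an hclust object).
#' @param file Path to write; the Newick string is also returned invisibly.
#' @export
exportNewick <- function(cl, file) {
  hc <- if (is.list(cl) && !is.null(cl$hclust)) cl$hclust else cl
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = file)
}

#' Group t-test on per-well SD parameters
#'
#' Two-sample pooled-variance Student's t-test comparing a per-image SD
#' parameter (population heterogeneity) between Low-risk and High-risk wells
#' at selected imaging times, as in the area-SD comparison at 12, 36 and
#' 78 h.
#'
#' @param summaries Frame summaries (\code{\link{aggregateFrames}}).
#' @param risk Named character vector of lot risk classes
#'   (\code{\link{riskClass}} or assay-derived).
#' @param parameter Descriptor whose SD is tested (default \code{"area"}).
#' @param times Imaging times (h) to test.
#' @return data.frame: time_h, mean_low, mean_high, t, p (two-sided).
#' @export
sdGroupTest <- function(summaries, risk, parameter = "area",
                        times = c(12, 36, 78)) {
  dt <- data.table::as.data.table(summaries)
  col <- paste0("sd_", parameter)
  if (!col %in% names(dt)) stop("unknown parameter: ", parameter)
  out <- lapply(times, function(tt) {
    sub <- dt[time_h == tt]
    g <- risk[sub$lot]
    lo <- sub[[col]][g == "Low"]; hi <- sub[[col]][g == "High"]
    if (length(lo) < 2 || length(hi) < 2)
      stop("need >= 2 wells per group at time ", tt)
    tst <- stats::t.test(lo, hi, var.equal = TRUE)
    data.frame(time_h = tt, mean_low = mean(lo), mean_high = mean(hi),
               t = unname(tst$statistic), p = tst$p.value)
  })
  do.call(rbind, out)
}

#' Plot a PCA map colored by lot
#'
#' @param pca Result of \code{\link{pcaMap}}.
#' @param lot Lot id per sample (colors the dots; replicate wells share a
#'   color).
#' @param risk Optional risk class per sample (sets the plotting symbol).
#' @param comps Two components to plot.
#' @export
plotPcaMap <- function(pca, lot, risk = NULL, comps = c(1, 2)) {
  sc <- pca$scores[, comps, drop = FALSE]
  lots <- unique(lot)
  cols <- grDevices::rainbow(length(lots))[match(lot, lots)]
  pch <- if (is.null(risk)) 19 else ifelse(risk == "High", 17, 19)
  plot(sc[, 1], sc[, 2], col = cols, pch = pch,
       xlab = sprintf("PC%d (%.1f%%)", comps[1],
                      100 * pca$explained[comps[1]]),
       ylab = sprintf("PC%d (%.1f%%)", comps[2],
                      100 * pca$explained[comps[2]]))
  legend("topright", legend = lots, col = grDevices::rainbow(length(lots)),
         pch = 19, cex = 0.6, ncol = 2)
  invisible(NULL)
}
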