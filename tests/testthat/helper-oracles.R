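# Independent brute-force oracles used to cross-check the implementation.

# exhaustive kNN: all-pairs distances, majority vote, distance ties broken by
# smaller training-row index (computed with plain loops, no shared code)
bf_knn <- function(Xtr, ytr, Xte, k) {
  pred <- numeric(nrow(Xte))
  for (i in seq_len(nrow(Xte))) {
    d <- numeric(nrow(Xtr))
    for (j in seq_len(nrow(Xtr)))
      d[j] <- sqrt(sum((Xte[i, ] - Xtr[j, ])^2))
    nn <- order(d, seq_along(d))[seq_len(k)]
    pred[i] <- as.numeric(sum(ytr[nn] == 1) > sum(ytr[nn] == 0))
  }
  pred
}

# brute-force UPGMA on a distance matrix: merge the closest pair, heights =
# average inter-cluster distance
bf_upgma <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  for (m in seq_len(n - 1)) {
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      dd <- mean(D[clusters[[a]], clusters[[b]]])
      if (dd < bd) { bd <- dd; best <- c(a, b) }
    }
    heights[m] <- bd
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# two-pass sample SD
bf_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# rasterize an ellipse (a, b semi-axes in px, rotation th) on an n x n grid
rasterize_ellipse <- function(a, b, th = 0, n = 2 * ceiling(a) + 21) {
  c0 <- (n + 1) / 2
  ii <- matrix(seq_len(n), n, n)
  jj <- matrix(seq_len(n), n, n, byrow = TRUE)
  u <- (ii - c0) * cos(th) + (jj - c0) * sin(th)
  v <- -(ii - c0) * sin(th) + (jj - c0) * cos(th)
  m <- matrix(0L, n, n)
  m[(u / a)^2 + (v / b)^2 <= 1] <- 1L
  m
}

# draw a CFSE mixture sample directly (independent of simulateCFSE)
draw_cfse <- function(n, p, seed) {
  set.seed(seed)
  lo <- runif(n) < p
  ifelse(lo, rnorm(n, 1.8, 0.25), rnorm(n, 3.0, 0.15))
}

# a tiny linearly separable classification design matrix
make_separable_dm <- function(n_per_lot = 4, n_lots = 6, seed = 1) {
  set.seed(seed)
  lot <- rep(sprintf("L%d", seq_len(n_lots)), each = n_per_lot)
  y <- rep(rep(c(0, 1), length.out = n_lots), each = n_per_lot)
  X <- cbind(y * 10 + rnorm(length(y), 0, 0.1),
             matrix(rnorm(length(y) * 5), ncol = 5))
  rownames(X) <- sprintf("s%02d", seq_along(y))
  colnames(X) <- sprintf("f%d", 1:6)
  new("DesignMatrix", X = X, lot = lot, y = y, task = "classification")
}
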