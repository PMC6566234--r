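# Shared fixtures and independent oracles for the test suite.

# a single-sample scan: one analysis tube (left) + one water tube (right)
twoTubeSpec <- function(signal = 100, seed = 1L, noiseSigma = 2,
                        appliedAffine = NULL, appliedWarp = NULL,
                        gridShape = c(64L, 64L, 64L)) {
  tubes <- list(
    tubeSpec(c(-12, 0, 0), radius = 6, length = 40, signal = signal,
             role = "test"),
    tubeSpec(c(14, 0, 0), radius = 5, length = 40, signal = 60,
             role = "water"))
  sp <- phantomSpec(tubes, gridShape = gridShape, spacing = c(1, 1, 1),
                    backgroundLevel = 0, noiseSigma = noiseSigma,
                    seed = seed, appliedAffine = appliedAffine)
  sp@appliedWarp <- appliedWarp
  sp
}

# smooth ground-truth warp bending the tube: cross-section x/y shifts that
# vary along z (recoverable structure; a cylinder's azimuthal component is
# not determined by any shape- or homogeneous-intensity metric)
bendWarp <- function(ampX = 1.5, ampY = -1.0) {
  ng <- c(4L, 4L, 7L)
  cf <- array(0, c(ng, 3))
  zs <- seq_len(ng[3])
  cf[, , , 1] <- rep(ampX * sin(zs / 2), each = ng[1] * ng[2])
  cf[, , , 2] <- rep(ampY * cos(zs / 2.5), each = ng[1] * ng[2])
  bsplineField(cf, origin = c(-36, -36, -45), spacing = c(18, 18, 15))
}

# physical centers of TRUE voxels, for TRE evaluation
maskPoints <- function(voi) voxrefl:::.maskPhysical(voi@mask, voi)

# ---- independent oracles ------------------------------------------------

# brute-force Otsu: exhaustive search over all histogram cuts
otsuOracle <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  lo <- min(v); hi <- max(v)
  bin <- pmin(floor((v - lo) / (hi - lo) * nbins) + 1L, nbins)
  h <- tabulate(bin, nbins)
  best <- -Inf; bestK <- NA
  for (k in 1:(nbins - 1)) {
    w0 <- sum(h[1:k]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:k] * (1:k)) / w0
    m1 <- sum(h[(k + 1):nbins] * ((k + 1):nbins)) / w1
    sb <- w0 * w1 * (m0 - m1)^2
    if (sb > best) { best <- sb; bestK <- k }
  }
  lo + bestK * (hi - lo) / nbins
}

# breadth-first flood fill, 26-connected, values within [low, high]
floodFillOracle <- function(values, seed, low, high) {
  d <- dim(values)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  mask <- array(FALSE, d)
  mask[seed[1], seed[2], seed[3]] <- TRUE
  front <- matrix(seed, nrow = 1)
  while (nrow(front) > 0) {
    nxt <- NULL
    for (r in seq_len(nrow(front))) {
      nb <- sweep(off, 2, front[r, ], "+")
      keep <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
        nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
      nb <- nb[keep, , drop = FALSE]
      for (q in seq_len(nrow(nb))) {
        i <- nb[q, 1]; j <- nb[q, 2]; k <- nb[q, 3]
        if (!mask[i, j, k] && !is.na(values[i, j, k]) &&
            values[i, j, k] >= low && values[i, j, k] <= high) {
          mask[i, j, k] <- TRUE
          nxt <- rbind(nxt, c(i, j, k))
        }
      }
    }
    front <- if (is.null(nxt)) matrix(0, 0, 3) else nxt
  }
  mask
}

# all-pairs Euclidean distance from every mask voxel to the boundary set
# (mask voxels face-adjacent to background; grid border counts as outside)
distanceOracle <- function(mask, spacing) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  isb <- logical(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    nb <- rbind(p + c(1, 0, 0), p - c(1, 0, 0), p + c(0, 1, 0),
                p - c(0, 1, 0), p + c(0, 0, 1), p - c(0, 0, 1))
    isb[r] <- any(apply(nb, 1, function(q)
      any(q < 1) || any(q > d) || !mask[q[1], q[2], q[3]]))
  }
  bpts <- sweep(idx[isb, , drop = FALSE], 2, c(1, 1, 1)) %*% diag(spacing)
  mpts <- sweep(idx, 2, c(1, 1, 1)) %*% diag(spacing)
  out <- array(NA_real_, d)
  out[mask] <- apply(mpts, 1, function(p)
    sqrt(min(colSums((t(bpts) - p)^2))))
  out
}

# explicit double-loop joint-histogram MI (hard binning convention:
# bin = floor((x - min) / (max - min) * bins) + 1, clamped)
miOracle <- function(x, y, bins) {
  bx <- function(v) {
    r <- range(v)
    pmin(pmax(floor((v - r[1]) / (r[2] - r[1]) * bins) + 1L, 1L), bins)
  }
  ia <- bx(x); ib <- bx(y)
  h <- matrix(0, bins, bins)
  for (q in seq_along(ia)) h[ia[q], ib[q]] <- h[ia[q], ib[q]] + 1
  p <- h / sum(h)
  mi <- 0
  for (a in 1:bins) for (b in 1:bins) {
    if (p[a, b] > 0)
      mi <- mi + p[a, b] * log(p[a, b] / (sum(p[a, ]) * sum(p[, b])))
  }
  mi
}
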