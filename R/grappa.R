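# GRAPPA calibration and reconstruction for regular 2D (ky, kz)
# undersampling of 3D Cartesian multi-channel k-space.
#
# Kernel geometry: for each missing-line offset within the R_y x R_z
# undersampling cell, the target sample of every channel is predicted
# from 2 acquired source positions per undersampled dimension times 3
# readout positions, across all channels (2 x 2 x 3 x nCoils sources).
# Weights are fit by Tikhonov-regularised least squares on a fully
# sampled central calibration block.

# source offset grids for a target offset (oy, oz) within the cell
.grappaSources <- function(oy, oz, Ry, Rz) {
  dy <- if (Ry > 1L) c(-oy, Ry - oy) else 0L
  dz <- if (Rz > 1L) c(-oz, Rz - oz) else 0L
  dx <- -1:1
  as.matrix(expand.grid(dx = dx, dy = dy, dz = dz))
}

#' Calibrate GRAPPA weights
#'
#' Fits, for every missing-line offset of the undersampling cell, the
#' complex weights predicting each channel's target sample from the
#' neighbouring acquired samples of all channels, using every valid
#' position of a fully sampled calibration block.  The normal equations
#' are regularised with \code{lambda * mean(diag(A^H A))}.
#'
#' @param calib Complex 4D array (nx, ny, nz, nCoils) of fully sampled
#'   calibration k-space.
#' @param R Length-2 undersampling factors (Ry, Rz).
#' @param lambda Relative Tikhonov regularisation.
#' @return A \code{grappaWeights} list: per target offset, a weight
#'   matrix (nSources*nCoils x nCoils), plus the geometry.
#' @export
grappaCalibrate <- function(calib, R, lambda = 1e-4) {
  stopifnot(length(dim(calib)) == 4L)
  R <- as.integer(R)
  d <- dim(calib)
  nc <- d[4]
  offs <- expand.grid(oy = 0:(R[1] - 1L), oz = 0:(R[2] - 1L))
  offs <- offs[!(offs$oy == 0 & offs$oz == 0), , drop = FALSE]
  weights <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    src <- .grappaSources(offs$oy[i], offs$oz[i], R[1], R[2])
    # valid target positions: whole kernel inside the block
    lo <- 1L - pmin(0L, apply(src, 2, min))
    hi <- d[1:3] - pmax(0L, apply(src, 2, max))
    if (any(hi < lo))
      stop("calibration block smaller than the kernel span")
    xr <- lo[1]:hi[1]; yr <- lo[2]:hi[2]; zr <- lo[3]:hi[3]
    tgt <- as.matrix(expand.grid(x = xr, y = yr, z = zr))
    A <- matrix(0i, nrow(tgt), nrow(src) * nc)
    col <- 0L
    for (c in seq_len(nc)) for (s in seq_len(nrow(src))) {
      col <- col + 1L
      A[, col] <- calib[cbind(tgt[, 1] + src[s, 1], tgt[, 2] + src[s, 2],
                              tgt[, 3] + src[s, 3], c)]
    }
    B <- matrix(0i, nrow(tgt), nc)
    for (c in seq_len(nc))
      B[, c] <- calib[cbind(tgt, c)]
    if (nrow(A) < ncol(A))
      stop("underdetermined GRAPPA fit: enlarge the calibration block")
    AHA <- Conj(t(A)) %*% A
    reg <- lambda * mean(Re(diag(AHA)))
    W <- solve(AHA + diag(reg, ncol(A)), Conj(t(A)) %*% B)
    weights[[i]] <- W
  }
  structure(list(weights = weights, offsets = offs, R = R, nCoils = nc),
            class = "grappaWeights")
}

#' Reconstruct GRAPPA-undersampled k-space
#'
#' Synthesises the missing (ky, kz) lines of a regularly undersampled
#' multi-channel k-space from calibrated weights; acquired lines are
#' preserved exactly.
#'
#' @param kspace Complex 4D array (nx, ny, nz, nCoils) with zeros at
#'   unacquired positions.
#' @param w Weights from [grappaCalibrate()].
#' @param acquired Logical matrix (ny x nz), TRUE where lines were
#'   acquired.  Missing positions outside any complete source
#'   neighbourhood fall back to the nearest valid base line.
#' @return Complex 4D array with missing lines filled.
#' @export
grappaReconstruct <- function(kspace, w, acquired) {
  stopifnot(inherits(w, "grappaWeights"), length(dim(kspace)) == 4L)
  d <- dim(kspace)
  if (w$nCoils != d[4]) stop("channel count does not match the weights")
  if (!all(dim(acquired) == d[2:3]))
    stop("acquired mask does not match the k-space grid")
  R <- w$R
  out <- kspace
  nc <- d[4]
  # stride grid is anchored on the k-space centre line, which is always
  # acquired
  anchorY <- floor(d[2] / 2) + 1L
  anchorZ <- floor(d[3] / 2) + 1L
  for (i in seq_len(nrow(w$offsets))) {
    oy <- w$offsets$oy[i]; oz <- w$offsets$oz[i]
    src <- .grappaSources(oy, oz, R[1], R[2])
    W <- w$weights[[i]]
    miss <- which(!acquired, arr.ind = TRUE)
    # targets whose offset from the previous stride line matches (oy, oz)
    sel <- ((miss[, 1] - anchorY) %% R[1] == oy %% R[1]) &
           ((miss[, 2] - anchorZ) %% R[2] == oz %% R[2])
    miss <- miss[sel, , drop = FALSE]
    if (!nrow(miss)) next
    for (m in seq_len(nrow(miss))) {
      y <- miss[m, 1]; z <- miss[m, 2]
      ys <- pmin(pmax(y + src[, 2], 1L), d[2])
      zs <- pmin(pmax(z + src[, 3], 1L), d[3])
      xs <- src[, 1]
      S <- matrix(0i, d[1], nrow(src) * nc)
      col <- 0L
      for (c in seq_len(nc)) for (s in seq_len(nrow(src))) {
        col <- col + 1L
        xr <- pmin(pmax(seq_len(d[1]) + xs[s], 1L), d[1])
        S[, col] <- kspace[cbind(xr, ys[s], zs[s], c)]
      }
      fill <- S %*% W
      for (c in seq_len(nc)) out[, y, z, c] <- fill[, c]
    }
  }
  out
}
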