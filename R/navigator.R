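# Fat-navigator simulation and motion estimation.
#
# The binomial fat excitation is modelled as imaging the fat-only signal
# (fat_fraction * PD): brain compartments contribute nothing to a
# navigator.  Each navigator sees the object under its shot's pose,
# downsampled to the low-resolution navigator grid; the optional k-space
# path applies GRAPPA undersampling with zero-filled partial Fourier and
# reconstructs with calibrated weights, matching how the real navigators
# are acquired and reconstructed.

#' Simulate a fat-navigator series
#'
#' @param ph A [Phantom-class] with a fat shell.
#' @param coils A [CoilSet-class] on the phantom grid (used by the
#'   k-space path).
#' @param trace A [MotionTrace-class], one pose per navigator.
#' @param factor Downsampling factor from phantom grid to navigator grid
#'   (navigator voxel = \code{factor * voxelSize(ph)}).
#' @param grappa Length-2 GRAPPA factors on the navigator PE dimensions.
#' @param pf Length-2 partial-Fourier fractions (zero-filled).
#' @param calib Calibration lines per PE dimension for the GRAPPA fit
#'   (acquired once, at the reference pose, as a prescan).
#' @param kspacePath If TRUE, simulate the undersampled multi-channel
#'   k-space and reconstruct with GRAPPA + zero-filling (adds the
#'   residual aliasing and ringing of a real navigator, which are locked
#'   to the scanner frame and limit rotational precision); if FALSE
#'   (default), return the ideal band-limited fat images.
#' @return A [NavSeries-class].
#' @export
simulateFatNavs <- function(ph, coils, trace, factor = 2L,
                            grappa = c(2L, 2L), pf = c(3 / 4, 3 / 4),
                            calib = 12L, kspacePath = FALSE) {
  fat <- ph@maps$fat * ph@maps$PD
  if (!any(fat > 0))
    stop("phantom has no fat shell: navigators would be empty")
  n <- dim(fat)
  vox <- ph@voxelSize
  navVox <- vox * factor
  ns <- nShots(trace)
  nnav <- as.integer(n / factor)
  navPlan <- list(matrix = nnav, grappa = as.integer(grappa),
                  pf = as.numeric(pf), calib = as.integer(calib),
                  factor = as.integer(factor))
  if (kspacePath) {
    coilsNav <- lapply(coils@maps, function(m)
      downsampleVolume(m, navVox, vox))
    maskY <- partialFourierMask(nnav[2], pf[1]) &
      grappaPattern(nnav[2], grappa[1], calib)
    maskZ <- partialFourierMask(nnav[3], pf[2]) &
      grappaPattern(nnav[3], grappa[2], calib)
    acq <- outer(maskY, maskZ)
    pfMask <- outer(as.logical(partialFourierMask(nnav[2], pf[1])),
                    as.logical(partialFourierMask(nnav[3], pf[2])))
    wrap2 <- .wrapIndex(nnav[2], nnav[2])
    wrap3 <- .wrapIndex(nnav[3], nnav[3])
    # masks are over centred indices; bring them into storage order
    acqS <- acq; acqS[wrap2, wrap3] <- acq
    pfS <- pfMask; pfS[wrap2, wrap3] <- pfMask
    # a real head has a smooth B0-induced phase; a strictly real object
    # would let the zero-filling ringing fold through zero under the
    # magnitude, which real navigators do not show
    phase <- .withSeed(ph@seed + 2L, exp(1i * (pi / 3) * .smoothField(n[1])))
    fatC <- fat * phase
    navK <- function(pose) {
      moved <- resampleVolume(fatC, pose, vox)
      obj <- downsampleVolume(moved, navVox, vox)
      K <- array(0i, c(nnav, length(coilsNav)))
      for (c in seq_along(coilsNav))
        K[, , , c] <- fft(obj * coilsNav[[c]])
      K
    }
    Kref <- navK(getPose(trace, 1L))
    # centred calibration block, gathered from storage order
    cy <- .wrapIndex(calib, nnav[2])
    cz <- .wrapIndex(calib, nnav[3])
    cx <- .wrapIndex(min(3L * max(grappa), nnav[1]), nnav[1])
    w <- grappaCalibrate(Kref[cx, cy, cz, , drop = FALSE], grappa)
    zeroLines <- function(K, keep) {
      d <- dim(K)
      dim(K) <- c(d[1], d[2] * d[3], d[4])
      K[, !keep, ] <- 0i
      dim(K) <- d
      K
    }
    vols <- vector("list", ns)
    for (s in seq_len(ns)) {
      K <- navK(getPose(trace, s))
      K <- zeroLines(K, as.vector(acqS))
      K <- grappaReconstruct(K, w, acqS)
      K <- zeroLines(K, as.vector(pfS))
      ch <- lapply(seq_len(dim(K)[4]), function(c)
        fft(K[, , , c], inverse = TRUE) / prod(nnav))
      vols[[s]] <- rssCombine(ch)
    }
  } else {
    # ideal image path: band-limited fat image, clamped at zero (a
    # magnitude image cannot be negative, and folding the ringing
    # through zero would be an artefact of the zero-phase object)
    vols <- lapply(seq_len(ns), function(s) {
      moved <- resampleVolume(fat, getPose(trace, s), vox)
      pmax(downsampleVolume(moved, navVox, vox), 0)
    })
  }
  new("NavSeries", volumes = vols, voxelSize = navVox, plan = navPlan)
}

# isotropic Gaussian smoothing in the Fourier domain (FWHM in voxels)
.gaussSmooth <- function(v, fwhmVox) {
  if (fwhmVox <= 0) return(v)
  d <- dim(v)
  s <- fwhmVox / (2 * sqrt(2 * log(2)))
  f1 <- function(n) {
    k <- 0:(n - 1)
    k[k > n / 2] <- k[k > n / 2] - n
    exp(-2 * pi^2 * s^2 * (k / n)^2)
  }
  filt <- outer(outer(f1(d[1]), f1(d[2])), f1(d[3]))
  Re(fft(fft(v + 0i) * filt, inverse = TRUE)) / prod(d)
}

# 2x box-average pyramid level (dimensions need not be even)
.pyrDown <- function(v) {
  d <- dim(v)
  d2 <- pmax(1L, d %/% 2L)
  out <- array(0, d2)
  cnt <- array(0, d2)
  ix <- pmin((seq_len(d[1]) - 1L) %/% 2L + 1L, d2[1])
  iy <- pmin((seq_len(d[2]) - 1L) %/% 2L + 1L, d2[2])
  iz <- pmin((seq_len(d[3]) - 1L) %/% 2L + 1L, d2[3])
  for (k in seq_len(d[3])) {
    sl <- rowsum(v[, , k], ix)
    sl <- t(rowsum(t(sl), iy))
    out[, , iz[k]] <- out[, , iz[k]] + sl
    cnt[, , iz[k]] <- cnt[, , iz[k]] + tcrossprod(tabulate(ix, d2[1]),
                                                  tabulate(iy, d2[2]))
  }
  out / cnt
}

# derivative of .rotmat with respect to one angle (degrees)
.rotmatDeriv <- function(rDeg, which) {
  a <- rDeg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  dRx <- matrix(c(0, 0, 0, 0, -sx, cx, 0, -cx, -sx), 3, 3)
  dRy <- matrix(c(-sy, 0, -cy, 0, 0, 0, cy, 0, -sy), 3, 3)
  dRz <- matrix(c(-sz, cz, 0, -cz, -sz, 0, 0, 0, 0), 3, 3)
  D <- switch(which, dRx %*% Ry %*% Rz, Rx %*% dRy %*% Rz,
              Rx %*% Ry %*% dRz)
  D * pi / 180
}

# Rigid registration of mov onto ref under the pose model
# pred(y) = ref(R^T (y - t)): multi-resolution Levenberg-Marquardt on the
# mean-squared difference with trilinear interpolation; the Jacobian uses
# the analytic chain rule through the resampled image gradient.
.registerRigid <- function(ref, mov, vox, levels = 3L, maxIter = 100L,
                           tolPar = 1e-3, init = NULL) {
  pyrR <- list(ref); pyrM <- list(mov); voxes <- vox
  for (l in seq_len(levels - 1L)) {
    if (min(dim(pyrR[[l]])) <= 8L) break
    pyrR[[l + 1L]] <- .pyrDown(pyrR[[l]])
    pyrM[[l + 1L]] <- .pyrDown(pyrM[[l]])
    voxes[l + 1L] <- voxes[l] * 2
  }
  p <- if (is.null(init)) numeric(6) else poseParams(init)
  # centre-of-mass translation initialisation at the coarsest level
  com <- function(v, vx) {
    w <- pmax(v, 0); s <- sum(w)
    if (s == 0) return(c(NA, NA, NA))
    d <- dim(v)
    c(sum(w * .axisCoords(d[1], vx)) / s,
      sum(w * rep(rep(.axisCoords(d[2], vx), each = d[1]), d[3])) / s,
      sum(w * rep(.axisCoords(d[3], vx), each = d[1] * d[2])) / s)
  }
  L <- length(pyrR)
  if (is.null(init)) {
    dcom <- com(pyrM[[L]], voxes[L]) - com(pyrR[[L]], voxes[L])
    if (all(is.finite(dcom))) p[1:3] <- dcom
  }
  converged <- FALSE
  for (l in seq(L, 1L)) {
    r0 <- pyrR[[l]]; m0 <- as.vector(pyrM[[l]]); vx <- voxes[l]
    scale0 <- sum(m0^2)
    if (scale0 == 0) return(list(pose = NULL, failed = TRUE))
    d <- dim(r0)
    Y <- cbind(rep(.axisCoords(d[1], vx), d[2] * d[3]),
               rep(rep(.axisCoords(d[2], vx), each = d[1]), d[3]),
               rep(.axisCoords(d[3], vx), each = d[1] * d[2]))
    # image gradient of the reference (central differences, mm^-1)
    shift1 <- function(a, k, by) {
      out <- array(0, dim(a))
      n <- dim(a)[k]
      i1 <- seq_len(n - abs(by))
      src <- if (by > 0) i1 + by else i1
      dst <- if (by > 0) i1 else i1 - by
      ix <- list(seq_len(dim(a)[1]), seq_len(dim(a)[2]),
                 seq_len(dim(a)[3]))
      ixs <- ix; ixs[[k]] <- src
      ixd <- ix; ixd[[k]] <- dst
      out[ixd[[1]], ixd[[2]], ixd[[3]]] <- a[ixs[[1]], ixs[[2]], ixs[[3]]]
      out
    }
    grad <- lapply(1:3, function(k)
      (shift1(r0, k, 1L) - shift1(r0, k, -1L)) / (2 * vx))
    srcIdx <- function(src) {
      idx <- src
      for (k in 1:3) idx[, k] <- src[, k] / vx + floor(d[k] / 2)
      idx
    }
    evalAt <- function(q) {
      R <- .rotmat(q[4:6])
      src <- sweep(Y, 2, q[1:3]) %*% R       # row-wise R^T (y - t)
      idx <- srcIdx(src)
      list(pred = .trilinear3(r0, d, idx), idx = idx, R = R)
    }
    cost <- function(q) sum((evalAt(q)$pred - m0)^2)
    cur <- cost(p)
    mu <- NA_real_   # Levenberg-Marquardt damping
    for (it in seq_len(maxIter)) {
      ev <- evalAt(p)
      r <- ev$pred - m0
      G <- cbind(.trilinear3(grad[[1]], d, ev$idx),
                 .trilinear3(grad[[2]], d, ev$idx),
                 .trilinear3(grad[[3]], d, ev$idx))
      J <- matrix(0, length(r), 6L)
      GR <- G %*% t(ev$R)                     # rows (R g)
      J[, 1:3] <- -GR
      Yt <- sweep(Y, 2, p[1:3])
      for (k in 1:3)
        J[, 3L + k] <- rowSums((G %*% t(.rotmatDeriv(p[4:6], k))) * Yt)
      g <- crossprod(J, r)
      H <- crossprod(J)
      if (is.na(mu)) mu <- 1e-6 * max(diag(H))
      done <- FALSE
      for (tries in 1:10) {
        step <- tryCatch(-solve(H + diag(mu, 6L), g),
                         error = function(e) NULL)
        if (is.null(step)) { mu <- mu * 10; next }
        pn <- p + as.vector(step)
        cn <- cost(pn)
        if (cn < cur) {
          p <- pn; cur <- cn
          mu <- mu * 0.3
          if (max(abs(step)) < tolPar) done <- TRUE
          break
        }
        mu <- mu * 10
        if (tries == 10L) done <- TRUE
      }
      if (done) { converged <- l == 1L; break }
    }
  }
  failed <- !is.finite(cur) || cur > 0.9 * scale0
  list(pose = pose(p[1], p[2], p[3], p[4], p[5], p[6]), failed = failed,
       converged = converged, mse = cur / length(m0))
}

#' Estimate the motion trace from a navigator series
#'
#' Registers every navigator volume to the reference volume with a
#' multi-resolution (3-level) Gauss-Newton minimisation of the
#' mean-squared intensity difference under the 6-DOF rigid model with
#' trilinear resampling.  The pose of the reference is the identity;
#' registration failures (degenerate overlap) are flagged as \code{NA}
#' rows.
#'
#' @param navs A [NavSeries-class] with at least two volumes (a
#'   single-volume series returns the identity).
#' @param reference Index of the reference volume.
#' @param levels Pyramid levels.
#' @param maxIter Iteration cap per level.
#' @param tolPar Convergence threshold on the parameter update
#'   (mm / degrees).
#' @param smoothFwhm Gaussian smoothing (FWHM in navigator voxels)
#'   applied to all volumes before registration; stabilises the metric
#'   when the fat layer is only one or two navigator voxels thick.
#' @param upsample Sinc (Fourier zero-padding) upsampling factor applied
#'   before registration.  Navigator volumes are band-limited by their
#'   acquisition, so trilinear interpolation on a finer grid is far more
#'   accurate; the default 2 makes sub-voxel pose recovery reliable.
#' @return A [MotionTrace-class], one pose per navigator.
#' @export
estimateMotion <- function(navs, reference = 1L, levels = 3L,
                           maxIter = 100L, tolPar = 1e-3,
                           smoothFwhm = 1.5, upsample = 2L) {
  ns <- nShots(navs)
  ref <- navs@volumes[[reference]]
  vox <- navs@voxelSize
  prep <- function(v) {
    v <- .gaussSmooth(v, smoothFwhm)
    if (upsample > 1L) v <- upsampleVolume(v, vox / upsample, vox)
    v
  }
  refS <- prep(ref)
  voxReg <- vox / max(1L, upsample)
  par <- matrix(NA_real_, ns, 6L,
                dimnames = list(NULL, .PARAM_NAMES))
  for (i in seq_len(ns)) {
    if (i == reference || identical(navs@volumes[[i]], ref)) {
      par[i, ] <- 0
      next
    }
    fit <- .registerRigid(refS, prep(navs@volumes[[i]]), voxReg,
                          levels = levels, maxIter = maxIter,
                          tolPar = tolPar)
    if (!fit$failed) par[i, ] <- poseParams(fit$pose)
  }
  motionTrace(par)
}
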