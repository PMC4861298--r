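# Forward model: motion-corrupted multi-channel k-space.
#
# For a shot acquired while the head sits at pose (R, t), the measured
# sample at Cartesian frequency k is
#     s(k) = exp(-2 pi i k . t) * F(R^T k)
# where F is the spectrum of the static coil-weighted object (Fourier
# rotation and shift theorem).  Motion is piecewise-constant per shot.

# frequency coordinates (cycles per sample) of one shot's lines
.shotCoords <- function(lines, n) {
  nx <- n[1]
  kx <- .axisCoords(nx, 1)
  L <- nrow(lines)
  cbind(rep(kx, L) / nx,
        rep(lines[, 1], each = nx) / n[2],
        rep(lines[, 2], each = nx) / n[3])
}

#' Simulate motion-corrupted multi-channel k-space
#'
#' Evaluates each shot's Cartesian lines through the type-2 NUFFT at
#' rotated coordinates with the translation phase, per receive channel,
#' optionally adding complex Gaussian noise.  Coil sensitivities stay
#' fixed in the scanner frame; the object is weighted by each coil map
#' before the motion is applied (the small-motion approximation the
#' retrospective correction itself relies on).
#'
#' @param channels List of complex coil-weighted object volumes (see
#'   [coilWeighted()]), all on the same isotropic grid.
#' @param trace A [MotionTrace-class] with one pose per shot.
#' @param plan An [AcquisitionPlan-class] whose PE grid matches the
#'   volume dimensions 2 and 3.
#' @param voxelSize Isotropic voxel size in mm.
#' @param noiseSd Standard deviation of i.i.d. complex Gaussian noise
#'   added per sample (0 for noiseless).
#' @param seed Seed for the noise.
#' @param tol NUFFT accuracy.
#' @return A [ShotSet-class].
#' @export
corruptKSpace <- function(channels, trace, plan, voxelSize = 1,
                          noiseSd = 0, seed = NULL, tol = 1e-7) {
  stopifnot(is.list(channels), length(channels) >= 1L)
  n <- dim(channels[[1L]])
  if (!all(n[2:3] == plan@mat[2:3]) || n[1] != plan@mat[1])
    stop("plan matrix does not match the volume grid")
  shotLines <- assignShots(plan)
  ns <- length(shotLines)
  if (nShots(trace) != ns)
    stop("trace has ", nShots(trace), " poses for ", ns, " shots")
  nc <- length(channels)
  kbplan <- .kbPlan(n, tol)
  # per-shot rotated coordinates and translation phases, shared by coils
  coords <- vector("list", ns)
  phases <- vector("list", ns)
  for (s in seq_len(ns)) {
    xi <- .shotCoords(shotLines[[s]], n)
    p <- poseParams(trace, s)
    if (any(is.na(p)))
      stop("corruptKSpace requires a complete trace (shot ", s, ")")
    R <- .rotmat(p[4:6])
    coords[[s]] <- xi %*% R                 # row-wise R^T k
    tvox <- p[1:3] / voxelSize
    phases[[s]] <- exp(-2i * pi * drop(xi %*% tvox))
  }
  shots <- lapply(seq_len(ns), function(s) {
    list(lines = shotLines[[s]],
         data = matrix(0i, nrow(coords[[s]]), nc))
  })
  for (c in seq_len(nc)) {
    U <- .nufftSpectrum(channels[[c]], kbplan)
    for (s in seq_len(ns)) {
      v <- .nufftInterp(U, coords[[s]], kbplan) * phases[[s]]
      shots[[s]]$data[, c] <- v
    }
  }
  if (noiseSd > 0) {
    shots <- .withSeed(seed, {
      lapply(shots, function(sh) {
        m <- length(sh$data)
        sh$data <- sh$data + complex(real = rnorm(m, 0, noiseSd),
                                     imaginary = rnorm(m, 0, noiseSd))
        sh
      })
    })
  }
  new("ShotSet", shots = shots, n = as.integer(n),
      voxelSize = voxelSize, plan = plan)
}

#' Zero-filled Cartesian reference reconstruction
#'
#' Places every shot's samples directly on the Cartesian grid and applies
#' the inverse FFT per channel -- the reconstruction one obtains when the
#' motion is ignored.  Used both as the uncorrected image and as an
#' independent oracle for the no-motion case.
#'
#' @param shots A [ShotSet-class].
#' @return List of complex volumes, one per channel.
#' @export
cartesianRecon <- function(shots) {
  n <- shots@n
  nc <- ncol(shots@shots[[1L]]$data)
  pos <- lapply(1:3, function(d) .wrapIndex(n[d], n[d]))
  out <- vector("list", nc)
  grid0 <- array(0i, n)
  for (c in seq_len(nc)) {
    K <- grid0
    for (sh in shots@shots) {
      iy <- (sh$lines[, 1] %% n[2]) + 1L
      iz <- (sh$lines[, 2] %% n[3]) + 1L
      dat <- matrix(sh$data[, c], n[1])  # readout fastest
      for (l in seq_len(nrow(sh$lines)))
        K[pos[[1]], iy[l], iz[l]] <- dat[, l]
    }
    v <- fft(K, inverse = TRUE) / prod(n)
    out[[c]] <- v[pos[[1]], pos[[2]], pos[[3]]]
  }
  out
}
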