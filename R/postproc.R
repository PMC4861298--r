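# Post-processing: bias-field correction, co-register-and-average,
# Fourier-domain resampling, PSF / scan-economics analysis and image
# metrics.

# --- discrete cosine transforms (orthonormal DCT-II / DCT-III) ---------

# DCT-II of every column (Makhoul's FFT reordering)
.dctCols <- function(X) {
  n <- nrow(X)
  if (n == 1L) return(X)
  idx <- c(seq(1L, n, 2L), rev(seq(2L, n, 2L)))
  V <- mvfft(X[idx, , drop = FALSE] + 0i)
  ph <- 2 * exp(-1i * pi * (0:(n - 1)) / (2 * n))
  Y <- Re(V * ph)
  Y[1, ] <- Y[1, ] / (2 * sqrt(n))
  Y[-1, ] <- Y[-1, ] / sqrt(2 * n)
  Y
}

.idctCols <- function(Y) {
  n <- nrow(Y)
  if (n == 1L) return(Y)
  y <- Y
  y[1, ] <- Y[1, ] * 2 * sqrt(n)
  y[-1, ] <- Y[-1, ] * sqrt(2 * n)
  yk <- rbind(y, matrix(0, 1, ncol(y)))    # y_n = 0
  k <- 0:(n - 1)
  V <- exp(1i * pi * k / (2 * n)) *
    (yk[k + 1L, , drop = FALSE] - 1i * yk[n + 1L - k, , drop = FALSE]) / 2
  v <- Re(mvfft(V, inverse = TRUE)) / n
  X <- matrix(0, n, ncol(Y))
  idx <- c(seq(1L, n, 2L), rev(seq(2L, n, 2L)))
  X[idx, ] <- v
  X
}

# apply a column transform along each dimension of a 3D array
.tensorTransform <- function(a, f) {
  d <- dim(a)
  m <- f(matrix(a, d[1], d[2] * d[3]))
  a <- array(m, d)
  a <- aperm(a, c(2, 1, 3))
  m <- f(matrix(a, d[2], d[1] * d[3]))
  a <- aperm(array(m, d[c(2, 1, 3)]), c(2, 1, 3))
  a <- aperm(a, c(3, 2, 1))
  m <- f(matrix(a, d[3], d[2] * d[1]))
  aperm(array(m, d[c(3, 2, 1)]), c(3, 2, 1))
}

.dct3 <- function(a) .tensorTransform(a, .dctCols)
.idct3 <- function(a) .tensorTransform(a, .idctCols)

# --- penalized least-squares smoother (cosine basis, GCV) --------------

# Laplacian eigenvalue field of the DCT basis
.lambdaField <- function(d) {
  l <- lapply(d, function(n) -2 + 2 * cos((seq_len(n) - 1) * pi / n))
  outer(outer(l[[1]], l[[2]], "+"), l[[3]], "+")
}

# weighted smooth fit: diffusion-type penalized least squares in the
# cosine basis, smoothing parameter s chosen by generalized
# cross-validation (optionally bounded below) unless given
.smoothFit <- function(y, w, s = NULL, sMin = 1e-6, maxIter = 20L,
                       tol = 1e-5) {
  d <- dim(y)
  N <- prod(d)
  lam2 <- .lambdaField(d)^2
  nof <- sum(w)
  z <- y
  z[!w] <- mean(y[w])
  gcv <- function(logs, A) {
    gam <- 1 / (1 + 10^logs * lam2)
    zz <- .idct3(gam * A)
    rss <- sum((y[w] - zz[w])^2)
    trH <- sum(gam)
    rss / nof / (1 - trH / N)^2
  }
  sOpt <- s
  wk <- w * 1                     # working weights (robust iterations)
  for (rob in 1:3) {
    for (it in seq_len(maxIter)) {
      A <- .dct3(wk * (y - z) + z)
      if (is.null(s) && (it <= 3L) && rob == 1L)
        sOpt <- 10^optimize(gcv, c(log10(sMin), 8), A = A)$minimum
      gam <- 1 / (1 + sOpt * lam2)
      zNew <- .idct3(gam * A)
      rel <- sqrt(sum((zNew - z)^2) / max(sum(z^2), 1e-300))
      z <- zNew
      if (rel < tol) break
    }
    # bisquare reweighting of the foreground: tissue structure that the
    # smooth field cannot (and should not) follow is downweighted
    r <- (y - z)[w]
    sc <- 1.4826 * median(abs(r - median(r)))
    if (sc <= 0) break
    u <- (r - median(r)) / (4.685 * sc)
    bw <- numeric(length(u))
    ok <- abs(u) < 1
    bw[ok] <- (1 - u[ok]^2)^2
    wk[w] <- bw
  }
  structure(z, s = sOpt)
}

#' Bias-field correction by smooth-fit division
#'
#' Fits a smooth 3D multiplicative field to the voxels above a manually
#' chosen threshold (penalized least squares on a cosine basis in the
#' log domain, smoothing strength chosen by generalized cross-validation
#' unless supplied), extrapolates it smoothly elsewhere, and divides the
#' whole volume by it.  The mean intensity over the above-threshold
#' region is preserved.  Because unconstrained cross-validation would
#' happily model the anatomy itself, the GCV search is bounded below so
#' the fitted field cannot vary on scales finer than \code{fieldScale}
#' times the field of view -- receive-coil bias varies on the scale of
#' the coil geometry, i.e. the whole head.
#'
#' @param vol Numeric 3D array.
#' @param threshold Foreground threshold (must be below \code{max(vol)}).
#' @param s Optional fixed smoothing parameter (overrides GCV).
#' @param fieldScale Minimum wavelength of the fitted field as a
#'   fraction of the field of view (default 1).
#' @return Corrected volume; attributes \code{field} (the divided-out
#'   smooth field, normalised to unit mean over the foreground) and
#'   \code{s} (the smoothing parameter used).
#' @export
biasCorrect <- function(vol, threshold, s = NULL, fieldScale = 1) {
  stopifnot(length(dim(vol)) == 3L)
  if (threshold >= max(vol))
    stop("threshold must be below the volume maximum")
  w <- vol > threshold
  # smoothness bound: half-power at fieldScale^-1 cycles per FOV
  ic <- 2 / fieldScale
  lamC <- 2 - 2 * cos(pi * ic / min(dim(vol)))
  sMin <- 1 / lamC^2
  y <- vol
  y[w] <- log(vol[w])
  y[!w] <- mean(y[w])
  fit <- exp(.smoothFit(y, w, s = s, sMin = sMin))
  field <- fit / mean(fit[w])
  field[field < 0.05] <- 0.05   # guard against division blow-up outside
  out <- vol / field
  out <- out * mean(vol[w]) / mean(out[w])
  attr(out, "field") <- as.vector(field)
  dim(attr(out, "field")) <- dim(vol)
  attr(out, "s") <- attr(fit, "s")
  out
}

# --- Fourier-domain resampling -----------------------------------------

# per-axis band filter over the centred indices of the new grid; the
# unpaired Nyquist line of an even-sized band is always excluded so that
# cropping followed by zero-padding is an exact projection
.bandFilter <- function(m, n, edge) {
  k <- abs(.axisCoords(m, 1))
  if (m >= n) return(rep(1, m))
  lim <- m / 2
  if (edge == "hard") return(as.numeric(k < lim))
  tw <- max(1, round(0.08 * m))
  f <- rep(1, m)
  t <- k > (lim - tw)
  f[t] <- 0.5 * (1 + cos(pi * (k[t] - (lim - tw)) / tw))
  f[k >= lim] <- 0
  f
}

#' Fourier-domain downsampling and upsampling
#'
#' \code{downsampleVolume} crops the spectrum to the band of the coarser
#' grid (with a raised-cosine edge by default to suppress ringing;
#' \code{edge = "hard"} gives the pure band-limiting projection) and
#' returns the volume on the coarser grid; retained-band amplitudes are
#' preserved.  \code{upsampleVolume} zero-pads the spectrum to a finer
#' grid.  This mimics acquiring the scan at the coarser resolution, as
#' opposed to box-averaging.
#'
#' @param vol Numeric or complex 3D array.
#' @param target,source Target and source voxel sizes in mm
#'   (\code{target >= source} for downsampling; scalar or length-3).
#' @param edge \code{"raised-cosine"} or \code{"hard"}.
#' @return Resampled array.
#' @export
downsampleVolume <- function(vol, target, source = 1,
                             edge = c("raised-cosine", "hard")) {
  edge <- match.arg(edge)
  d <- dim(vol)
  stopifnot(length(d) == 3L)
  if (length(target) == 1L) target <- rep(target, 3L)
  if (length(source) == 1L) source <- rep(source, 3L)
  if (any(target < source - 1e-9))
    stop("target voxel size must not be finer than the source")
  m <- pmax(1L, as.integer(round(d * source / target)))
  if (all(m == d)) return(vol)
  K <- fft(vol + 0i)
  sel <- lapply(1:3, function(dd) {
    kc <- as.integer(.axisCoords(m[dd], 1))
    (kc %% d[dd]) + 1L   # storage position on the OLD grid
  })
  Kc <- K[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
  filt <- outer(outer(.bandFilter(m[1], d[1], edge),
                      .bandFilter(m[2], d[2], edge)),
                .bandFilter(m[3], d[3], edge))
  Kc <- Kc * filt
  # back to wrapped storage order on the new grid
  Kn <- array(0i, m)
  pos <- lapply(1:3, function(dd) .wrapIndex(m[dd], m[dd]))
  Kn[pos[[1]], pos[[2]], pos[[3]]] <- Kc
  out <- fft(Kn, inverse = TRUE) / prod(d)
  if (is.complex(vol)) out else Re(out)
}

#' @rdname downsampleVolume
#' @export
upsampleVolume <- function(vol, target, source = 1) {
  d <- dim(vol)
  if (length(target) == 1L) target <- rep(target, 3L)
  if (length(source) == 1L) source <- rep(source, 3L)
  if (any(target > source + 1e-9))
    stop("target voxel size must not be coarser than the source")
  m <- as.integer(round(d * source / target))
  if (all(m == d)) return(vol)
  K <- fft(vol + 0i)
  Kn <- array(0i, m)
  src <- lapply(1:3, function(dd) {
    kc <- as.integer(.axisCoords(d[dd], 1))
    (kc %% d[dd]) + 1L
  })
  dst <- lapply(1:3, function(dd) {
    kc <- as.integer(.axisCoords(d[dd], 1))
    (kc %% m[dd]) + 1L
  })
  Kn[dst[[1]], dst[[2]], dst[[3]]] <- K[src[[1]], src[[2]], src[[3]]]
  # split the unpaired Nyquist plane of even source axes symmetrically
  for (dd in 1:3) {
    if (d[dd] %% 2L == 0L && m[dd] > d[dd]) {
      iN <- ((-d[dd] %/% 2L) %% m[dd]) + 1L
      iP <- ((d[dd] %/% 2L) %% m[dd]) + 1L
      ix <- list(seq_len(m[1]), seq_len(m[2]), seq_len(m[3]))
      ixN <- ix; ixN[[dd]] <- iN
      ixP <- ix; ixP[[dd]] <- iP
      half <- Kn[ixN[[1]], ixN[[2]], ixN[[3]], drop = FALSE] / 2
      Kn[ixN[[1]], ixN[[2]], ixN[[3]]] <- half
      Kn[ixP[[1]], ixP[[2]], ixP[[3]]] <- half
    }
  }
  out <- fft(Kn, inverse = TRUE) / prod(d)
  if (is.complex(vol)) out else Re(out)
}

#' Rigidly co-register volumes and average
#'
#' Registers every volume to the first (full-resolution rigid
#' registration, reusing the navigator registration engine), resamples
#' trilinearly into the first volume's frame and returns the arithmetic
#' mean.
#'
#' @param vols List of >= 2 numeric 3D arrays on one grid.
#' @param voxelSize Voxel size in mm.
#' @param levels Registration pyramid levels.
#' @return Mean volume; attribute \code{trace} carries the estimated
#'   [MotionTrace-class] (identity for the first volume), and failed
#'   registrations propagate as an error.
#' @export
coregisterAverage <- function(vols, voxelSize = 1, levels = 3L) {
  stopifnot(is.list(vols), length(vols) >= 2L)
  d <- dim(vols[[1L]])
  if (!all(vapply(vols, function(v) identical(dim(v), d), TRUE)))
    stop("volumes differ in shape")
  par <- matrix(0, length(vols), 6L, dimnames = list(NULL, .PARAM_NAMES))
  acc <- vols[[1L]]
  for (i in seq_along(vols)[-1L]) {
    if (identical(vols[[i]], vols[[1L]])) {
      acc <- acc + vols[[i]]
      next
    }
    fit <- .registerRigid(vols[[1L]], vols[[i]], voxelSize,
                          levels = levels)
    if (fit$failed) stop("registration failed for volume ", i)
    par[i, ] <- poseParams(fit$pose)
    acc <- acc + resampleVolume(vols[[i]], invertPose(fit$pose),
                                voxelSize)
  }
  out <- acc / length(vols)
  attr(out, "trace") <- motionTrace(par)
  out
}

# --- PSF and scan economics --------------------------------------------

# interpolated full width at half maximum of a densely sampled profile
.fwhmOf <- function(y, dx) {
  pk <- which.max(y)
  h <- y[pk] / 2
  i <- pk
  while (i > 1L && y[i] > h) i <- i - 1L
  if (y[i] > h) return(NA_real_)
  xl <- i + (h - y[i]) / (y[i + 1L] - y[i])
  i <- pk
  while (i < length(y) && y[i] > h) i <- i + 1L
  if (y[i] > h) return(NA_real_)
  xr <- (i - 1L) + (h - y[i - 1L]) / (y[i] - y[i - 1L])
  (xr - xl) * dx
}

#' Point-spread function of a zero-filled partial-Fourier window
#'
#' Builds the centred 1D k-space window of \code{n} lines with an
#' asymmetric partial-Fourier mask (missing lines zero-filled), evaluates
#' the complex PSF by a zero-padded inverse DFT, and measures the full
#' width at half maximum of the PSF magnitude by linear interpolation of
#' the half-maximum crossings.
#'
#' @param n Number of k-space lines (>= 32).
#' @param fraction Partial-Fourier fraction in (0.5, 1].
#' @param pad Zero-padding factor of the evaluation (>= 64 recommended).
#' @param weights Optional amplitude weighting per acquired line (e.g.
#'   an exponential train-decay filter), over the centred line indices.
#' @return Object of class \code{psfProfile}: list with \code{x} (voxel
#'   units), \code{profile} (complex), \code{fwhm} (voxels), \code{n},
#'   \code{fraction}, \code{pad}.
#' @seealso [psfBroadening()], [effectiveResolution()]
#' @export
psfProfile <- function(n = 512L, fraction = 3 / 4, pad = 64L,
                       weights = NULL) {
  stopifnot(n >= 32L, pad >= 1L)
  mask <- partialFourierMask(n, fraction)
  amp <- as.numeric(mask)
  if (!is.null(weights)) {
    stopifnot(length(weights) == n)
    amp <- amp * weights
  }
  N <- n * pad
  k <- attr(mask, "k")
  w <- complex(real = rep(0, N))
  w[(k %% N) + 1L] <- amp
  psf <- fft(w, inverse = TRUE)
  half <- N %/% 2L
  psf <- c(psf[(half + 1L):N], psf[1:half])   # peak to the centre
  x <- (seq_len(N) - 1 - half) / pad
  structure(list(x = x, profile = psf,
                 fwhm = .fwhmOf(Mod(psf), 1 / pad),
                 n = n, fraction = fraction, pad = pad),
            class = "psfProfile")
}

#' @export
print.psfProfile <- function(x, ...) {
  cat(sprintf(
    "psfProfile: n = %d, fraction = %.3f, |PSF| FWHM = %.4f voxels\n",
    x$n, x$fraction, x$fwhm))
  invisible(x)
}

#' FWHM broadening factor of zero-filled partial Fourier
#'
#' Ratio of the magnitude-PSF FWHM at the given partial-Fourier fraction
#' to the fully sampled FWHM (which is the 1.2067-voxel width of the
#' Dirichlet kernel magnitude).
#'
#' @inheritParams psfProfile
#' @return Dimensionless broadening factor (>= 1).
#' @export
psfBroadening <- function(fraction, n = 512L, pad = 64L) {
  psfProfile(n, fraction, pad)$fwhm / psfProfile(n, 1, pad)$fwhm
}

#' Effective resolution under zero-filled partial Fourier
#'
#' Nominal resolution multiplied by the measured magnitude-PSF FWHM
#' broadening factor, reported to the nearest 10 micrometres.
#'
#' @param nominal Nominal resolution in micrometres.
#' @param fraction Partial-Fourier fraction.
#' @param n,pad PSF evaluation parameters.
#' @return Effective resolution in micrometres (multiple of 10).
#' @export
effectiveResolution <- function(nominal, fraction, n = 512L, pad = 64L) {
  round(nominal * psfBroadening(fraction, n, pad) / 10) * 10
}

#' Voxel-volume and SNR-matched scan-time ratios
#'
#' Comparing resolutions a and b (micrometres): the voxel-volume ratio is
#' \code{(a/b)^3}, and under SNR proportional to voxel volume times the
#' square root of scan time, maintaining SNR at the finer resolution
#' requires the square of that factor in scan time.
#'
#' @param resA,resB Voxel edge lengths in micrometres (a coarser, b
#'   finer, though any pair is accepted).
#' @return List with \code{volumeRatio} and \code{timeRatio}.
#' @examples
#' voxelEconomics(500, 350)  # ~2.9-fold volume, ~8.5-fold time
#' @export
voxelEconomics <- function(resA, resB) {
  stopifnot(resA > 0, resB > 0)
  v <- (resA / resB)^3
  list(volumeRatio = v, timeRatio = v^2)
}

#' Normalised root-mean-square error
#'
#' \code{sqrt(mean(|x - ref|^2) / mean(|ref|^2))} with the first argument
#' as the reference, optionally over a mask.  Zero when the volumes are
#' equal; one when \code{x} is zero.
#'
#' @param ref Reference array.
#' @param x Test array of the same shape.
#' @param mask Optional logical array restricting the comparison.
#' @return Scalar NRMSE.
#' @export
nrmse <- function(ref, x, mask = NULL) {
  stopifnot(identical(dim(ref), dim(x)))
  if (!is.null(mask)) {
    ref <- ref[mask]
    x <- x[mask]
  }
  sqrt(sum(Mod(x - ref)^2) / sum(Mod(ref)^2))
}
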