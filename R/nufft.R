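# 3D non-uniform FFT by Kaiser-Bessel gridding with 2x oversampling.
#
# Frequencies are expressed in cycles per sample (xi = k / n for a
# Cartesian integer index k), so the Nyquist box is |xi| <= 1/2 per axis.
# Image voxels carry centred integer coordinates x in [-n/2, n/2); the
# type-2 transform evaluates
#     s_j = sum_x f(x) exp(-2 pi i  xi_j . x)
# and the (unscaled) type-1 transform is its exact adjoint.  Because the
# image support is integer-valued, frequencies are periodic with period 1,
# which is why rotated coordinates slightly outside the Nyquist box may be
# wrapped without approximation.
#
# Kernel width follows the requested tolerance (about one digit per unit
# of width at 2x oversampling); the shape parameter beta uses the
# standard minimum-aliasing design for sigma = 2.

.kbPlan <- function(dims, tol = 1e-7) {
  dims <- as.integer(dims)
  w <- max(4, min(16, ceiling(log10(1 / tol)) + 3))
  beta <- pi * sqrt(w^2 * 0.5625 - 0.8)
  G <- 2L * dims
  ntab <- 32768L
  tt <- seq(0, 1, length.out = ntab)   # |t| / (w/2)
  table <- besselI(beta * sqrt(pmax(0, 1 - tt^2)), 0)
  apod <- lapply(seq_along(dims), function(d) {
    nu <- .axisCoords(dims[d], 1) / G[d]
    g <- beta^2 - (pi * w * nu)^2
    w * sinh(sqrt(g)) / sqrt(g)
  })
  list(dims = dims, G = G, w = w, table = table, apod = apod)
}

# storage index (1-based) of centred coordinate xc on a wrapped grid of
# size G
.wrapIndex <- function(n, G) {
  xc <- as.integer(.axisCoords(n, 1))
  (xc %% G) + 1L
}

.deapodize <- function(vol, plan) {
  a <- plan$apod
  vol / outer(outer(a[[1]], a[[2]]), a[[3]])[, , , drop = TRUE]
}

# oversampled, deapodized spectrum of an image; reusable across coord sets
.nufftSpectrum <- function(image, plan) {
  d <- plan$dims
  g <- .deapodize(image + 0i, plan)
  U <- array(0i, plan$G)
  U[.wrapIndex(d[1], plan$G[1]), .wrapIndex(d[2], plan$G[2]),
    .wrapIndex(d[3], plan$G[3])] <- g
  fft(U)
}

.nufftInterp <- function(spectrum, coords, plan) {
  p <- sweep(coords, 2, plan$G, "*")
  .kbInterp3(spectrum, p, plan$G, plan$w, plan$table)
}

#' Non-uniform discrete Fourier transforms (type 2 and type 1)
#'
#' \code{nufftSample} evaluates the Fourier sum of a 3D image at arbitrary
#' frequencies (uniform to non-uniform, "type 2"):
#' \deqn{s_j = \sum_x f(x)\, e^{-2\pi i\, \xi_j \cdot x}}
#' with voxel coordinates \eqn{x} centred on the volume centre.
#' \code{nufftAdjoint} maps samples back to a volume ("type 1"), scaled by
#' \code{1/prod(n)} so that full Cartesian sampling reproduces the inverse
#' FFT; no density compensation is applied.  Up to that documented scale
#' factor the two transforms are exact adjoints of one another.
#'
#' @param image Complex or numeric 3D array.
#' @param samples Complex vector of k-space samples.
#' @param coords Numeric matrix (one row per sample) of frequencies in
#'   cycles per sample, i.e. a Cartesian integer index k corresponds to
#'   \code{k / n} on that axis.  Coordinates must lie within the Nyquist
#'   box \code{[-0.5, 0.5]} per axis unless \code{wrap = TRUE} (used for
#'   rotated Cartesian coordinates, for which wrapping is exact on an
#'   integer voxel grid).
#' @param n Output grid size (length-3 integer) for the adjoint.
#' @param tol Requested relative accuracy of the gridding approximation.
#' @param wrap Allow coordinates outside the Nyquist box (wrapped
#'   periodically).
#' @return \code{nufftSample}: complex vector of samples;
#'   \code{nufftAdjoint}: complex 3D array.
#' @examples
#' img <- array(0i, c(8, 8, 8)); img[5, 5, 5] <- 1  # centre voxel
#' k <- matrix(runif(30, -0.5, 0.5), 10, 3)
#' s <- nufftSample(img, k)      # all ones: constant spectrum
#' @export
nufftSample <- function(image, coords, tol = 1e-7, wrap = FALSE) {
  coords <- .checkCoords(coords, wrap)
  plan <- .kbPlan(dim(image), tol)
  .nufftInterp(.nufftSpectrum(image, plan), coords, plan)
}

#' @rdname nufftSample
#' @export
nufftAdjoint <- function(samples, coords, n, tol = 1e-7, wrap = FALSE) {
  coords <- .checkCoords(coords, wrap)
  n <- as.integer(n)
  stopifnot(length(n) == 3L, length(samples) == nrow(coords))
  plan <- .kbPlan(n, tol)
  p <- sweep(coords, 2, plan$G, "*")
  U <- .kbSpread3(p, as.complex(samples), plan$G, plan$w, plan$table)
  A <- fft(U, inverse = TRUE)
  out <- A[.wrapIndex(n[1], plan$G[1]), .wrapIndex(n[2], plan$G[2]),
           .wrapIndex(n[3], plan$G[3])]
  .deapodize(out, plan) / prod(n)
}

.checkCoords <- function(coords, wrap) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must have three columns")
  if (!wrap && any(abs(coords) > 0.5 + 1e-12))
    stop("coordinates outside the Nyquist box (|xi| > 1/2)")
  coords
}
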