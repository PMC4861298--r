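test_that("bias correction leaves flat volumes untouched", {
  fl <- array(5, rep(16L, 3))
  out <- biasCorrect(fl, 1)
  expect_lt(max(abs(out / 5 - 1)), 1e-6)
  expect_error(biasCorrect(fl, 5), "threshold")
})

test_that("bias correction removes a smooth multiplicative field", {
  n <- 32L
  ph <- makePhantom(n, seed = 1, voxelSize = 2, variation = 0)
  img <- Mod(contrastImage(ph, "PD"))
  u <- (seq_len(n) - 1 - floor(n / 2)) / (n / 2)
  field <- 1 + 0.4 * outer(outer(sin(pi * u / 2), cos(pi * u / 3), "+"),
                           u * 0.5, "+") / 2
  v <- img * field
  corr <- biasCorrect(v, 0.2)
  wm <- ph@maps$T1 > 1100 & ph@maps$T1 < 1300 & ph@maps$fat == 0
  cov <- function(x) sd(x[wm]) / mean(x[wm])
  expect_gt(cov(v) / cov(corr), 5)
  # mean intensity over the foreground is preserved
  fg <- v > 0.2
  expect_equal(mean(corr[fg]), mean(v[fg]), tolerance = 1e-12)
})

test_that("bias correction is near-idempotent on well-modelled data", {
  n <- 32L
  spec <- data.frame(name = "blob", a = 0.7, b = 0.75, c = 0.65,
                     cx = 0, cy = 0, cz = 0, PD = 1, T1 = 1500,
                     T2 = 80, T2star = 50, fat = 0)
  ph <- makePhantom(n, seed = 1, spec = spec, voxelSize = 2,
                    variation = 0)
  img <- Mod(contrastImage(ph, "PD"))
  u <- (seq_len(n) - 1 - floor(n / 2)) / (n / 2)
  field <- 1 + 0.4 * outer(outer(sin(pi * u / 2), cos(pi * u / 3), "+"),
                           u * 0.5, "+") / 2
  v <- img * field
  c1 <- biasCorrect(v, 0.2, fieldScale = 0.5)
  c2 <- biasCorrect(c1, 0.2, fieldScale = 0.5)
  expect_lt(nrmse(c1, c2), 0.01)
})

test_that("Fourier downsampling preserves the retained band", {
  v <- smoothVolume()
  expect_identical(downsampleVolume(v, 2, 2), v)
  expect_error(downsampleVolume(v, 1, 2), "target voxel")
  # a pure low-frequency sinusoid survives with its amplitude
  n <- 48L
  x <- seq_len(n) - 1
  s <- array(sin(2 * pi * 3 * x / n), rep(n, 3))
  out <- downsampleVolume(s, 2, 1)
  expect_equal(max(abs(out)), 1, tolerance = 0.01)
  # white noise keeps exactly the band fraction of its variance
  set.seed(61)
  wn <- array(rnorm(n^3), rep(n, 3))
  wd <- downsampleVolume(wn, 2, 1, edge = "hard")
  m <- n / 2
  bandFraction <- ((m - 1) / n)^3    # even-band Nyquist line excluded
  expect_equal(var(as.vector(wd)) / var(as.vector(wn)), bandFraction,
               tolerance = 0.1 * bandFraction)
})

test_that("down- then upsampling is a spectral projection", {
  set.seed(62)
  wn <- array(rnorm(40^3), rep(40L, 3))
  P <- function(v) upsampleVolume(downsampleVolume(v, 2, 1,
                                                   edge = "hard"), 1, 2)
  p1 <- P(wn)
  expect_lt(max(abs(P(p1) - p1)), 1e-9)
})

test_that("co-register-and-average aligns and denoises", {
  v <- smoothVolume()
  # identical inputs pass through untouched
  same <- coregisterAverage(list(v, v), 2)
  expect_equal(unclass(same), v, ignore_attr = TRUE, tolerance = 1e-12)
  # a one-voxel shift is recovered to a fifth of a voxel
  sh <- resampleVolume(v, pose(tx = 2), 2)
  avg <- coregisterAverage(list(v, sh), 2)
  tr <- attr(avg, "trace")
  expect_lt(abs(poseParams(tr, 2)["tx_mm"] - 2), 0.4)
  expect_lt(max(abs(poseParams(tr, 2)[-1])), 0.4)
  # N noisy copies: background noise shrinks as 1/sqrt(N).  An
  # anatomy-like volume pins all six pose parameters (a symmetric blob
  # would leave rotations free to overfit the noise), and the noise is
  # small enough that registration stays essentially exact.
  set.seed(63)
  N <- 4L
  anat <- Mod(contrastImage(smallPhantom(), "PD"))
  noisy <- lapply(seq_len(N), function(i)
    anat + array(rnorm(length(anat), 0, 0.005), dim(anat)))
  avgN <- coregisterAverage(noisy, 2)
  # interior background: face voxels can be zeroed as out-of-field
  bg <- anat < 1e-4
  bg[c(1, 32), , ] <- FALSE; bg[, c(1, 32), ] <- FALSE
  bg[, , c(1, 32)] <- FALSE
  sdIn <- sd(noisy[[1]][bg] - anat[bg])
  sdOut <- sd(avgN[bg] - anat[bg])
  expect_equal(sdOut, sdIn / sqrt(N), tolerance = 0.1)
})

test_that("the fully sampled PSF is the Dirichlet kernel", {
  p <- psfProfile(512, 1)
  # dense-evaluation oracle: |sinc| falls to half at 0.6034 voxels
  expect_equal(p$fwhm, 1.2067, tolerance = 1e-3)
  expect_equal(which.max(Mod(p$profile)),
               which.min(abs(p$x)))          # peak at the centre
})

test_that("partial-Fourier FWHM broadening is monotone in the fraction", {
  r <- vapply(c(0.6, 0.75, 0.9, 1), psfBroadening, 0, n = 256L)
  expect_true(all(diff(r) <= 1e-9))
  expect_equal(r[4], 1, tolerance = 1e-9)
  expect_true(all(r >= 1))
})

test_that("the PSF FWHM has converged at the default zero-padding", {
  f64 <- psfProfile(256, 3 / 4, pad = 64)$fwhm
  f128 <- psfProfile(256, 3 / 4, pad = 128)$fwhm
  expect_lt(abs(f64 - f128) / f128, 1e-3)
})

test_that("an amplitude-weighted window broadens the PSF", {
  n <- 256L
  k <- attr(partialFourierMask(n, 1), "k")
  wts <- exp(-abs(k) / (n / 4))   # train-decay style filter
  pw <- psfProfile(n, 1, weights = wts)
  expect_gt(pw$fwhm, psfProfile(n, 1)$fwhm)
})

test_that("voxel economics follow volume and SNR scaling", {
  e <- voxelEconomics(700, 350)
  expect_equal(e$volumeRatio, 8)
  expect_equal(e$timeRatio, 64)
  eq <- voxelEconomics(350, 350)
  expect_equal(eq$volumeRatio, 1)
  expect_equal(eq$timeRatio, 1)
})

test_that("NRMSE has its defining algebra", {
  v <- smoothVolume()
  expect_equal(nrmse(v, v), 0)
  expect_equal(nrmse(v, array(0, dim(v))), 1)
  expect_equal(nrmse(3 * v, 3 * (v * 0.9)), nrmse(v, v * 0.9),
               tolerance = 1e-12)
  m <- v > 0.5
  expect_equal(nrmse(v, v * 1.1, mask = m),
               sqrt(sum((0.1 * v[m])^2) / sum(v[m]^2)))
})
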