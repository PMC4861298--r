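# Shared fixtures, built once per test run and memoised.

.cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .cache))
    assign(name, builder(), envir = .cache)
  get(name, envir = .cache)
}

smallPhantom <- function() fixture("ph32", function()
  makePhantom(32, seed = 1, voxelSize = 2))

smallCoils <- function() fixture("coils32", function()
  makeCoils(32, 4L, seed = 2))

bigPhantom <- function() fixture("ph64", function()
  makePhantom(64, seed = 1, voxelSize = 1))

bigCoils <- function() fixture("coils64", function()
  makeCoils(64, 8L, seed = 2))

# a smooth positive test volume (sum of Gaussian blobs)
smoothVolume <- function(n = 32L) fixture(paste0("smooth", n), function() {
  u <- (seq_len(n) - 1 - floor(n / 2)) / (n / 2)
  g <- function(cx, cy, cz, s)
    outer(outer(exp(-(u - cx)^2 / s), exp(-(u - cy)^2 / s)),
          exp(-(u - cz)^2 / s))
  g(0, 0, 0, 0.25) + 0.6 * g(0.3, -0.2, 0.1, 0.1)
})

# multi-channel full k-space of the coil-weighted small phantom
smallKspace <- function() fixture("ksp32", function() {
  obj <- contrastImage(smallPhantom(), "PD")
  maps <- smallCoils()@maps
  K <- array(0i, c(dim(obj), length(maps)))
  for (c in seq_along(maps)) K[, , , c] <- fft(obj * maps[[c]])
  K
})

# 8-coil k-space at 32^3 for GRAPPA accuracy checks
grappaKspace <- function() fixture("ksp32x8", function() {
  obj <- contrastImage(smallPhantom(), "PD")
  maps <- makeCoils(32, 8L, seed = 2)@maps
  K <- array(0i, c(dim(obj), length(maps)))
  for (c in seq_along(maps)) K[, , , c] <- fft(obj * maps[[c]])
  K
})

# storage-order positions of centred indices (test-side mirror of the
# package convention)
wrapPos <- function(m, n = m) {
  kc <- as.integer(seq_len(m) - 1 - floor(m / 2))
  (kc %% n) + 1L
}

# centred k-space block extraction in storage order
centredBlock <- function(K, nx, ny, nz) {
  d <- dim(K)
  K[wrapPos(nx, d[1]), wrapPos(ny, d[2]), wrapPos(nz, d[3]), , drop = FALSE]
}

# zero unacquired (ky, kz) lines of a 4D k-space, mask in storage order
zeroMissing <- function(K, acq) {
  d <- dim(K)
  dim(K) <- c(d[1], d[2] * d[3], d[4])
  K[, !as.vector(acq), ] <- 0i
  dim(K) <- d
  K
}

# acquired-line mask (storage order) from centred-index masks
storageMask <- function(maskY, maskZ) {
  acq <- outer(as.logical(maskY), as.logical(maskZ))
  out <- acq
  out[wrapPos(length(maskY)), wrapPos(length(maskZ))] <- acq
  out
}

rssFromK <- function(K) {
  n <- prod(dim(K)[1:3])
  rssCombine(lapply(seq_len(dim(K)[4]), function(c)
    fft(K[, , , c], inverse = TRUE) / n))
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(abs(y)), tol)
}

# 32^3 / 4-coil / 3/4-partial-Fourier motion simulation shared by the
# correction tests
mocoSim <- function() fixture("mocoSim32", function() {
  ph <- smallPhantom()
  coils <- smallCoils()
  obj <- contrastImage(ph, "GRE-T2star", te = 15.6)
  channels <- coilWeighted(obj, coils)
  plan <- acquisitionPlan("custom", mat = rep(32L, 3L),
                          pf = c(3 / 4, 3 / 4), outerPe = 2L, trMs = 27)
  ns <- length(assignShots(plan))
  trace <- makeMotionTrace(ns, seed = 5, driftMm = 3, driftDeg = 3)
  tr0 <- motionTrace(matrix(0, ns, 6))
  still <- corruptKSpace(channels, tr0, plan, voxelSize = 2)
  moved <- corruptKSpace(channels, trace, plan, voxelSize = 2)
  list(ph = ph, coils = coils, channels = channels, plan = plan,
       ns = ns, trace = trace, tr0 = tr0, still = still, moved = moved,
       ref = rssCombine(cartesianRecon(still)))
})

# 20 seeded random poses, |t| <= 3 mm, |r| <= 3 deg, with the estimated
# trace from ideal navigators
poseRecovery <- function() fixture("poseRecovery", function() {
  ph <- bigPhantom()
  set.seed(42)
  par <- rbind(0, cbind(matrix(runif(57, -3, 3), 19),
                        matrix(runif(57, -3, 3), 19)))
  trace <- motionTrace(par)
  navs <- simulateFatNavs(ph, bigCoils(), trace)
  est <- estimateMotion(navs)
  list(truth = par, est = est@params)
})
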