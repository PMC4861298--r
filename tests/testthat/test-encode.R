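smallPlan <- function(pf = c(1, 1))
  acquisitionPlan("custom", mat = rep(32L, 3L), pf = pf, outerPe = 2L,
                  trMs = 27)

test_that("an identity trace reproduces the Cartesian FFT samples", {
  obj <- contrastImage(smallPhantom(), "PD")
  channels <- coilWeighted(obj, smallCoils())
  plan <- smallPlan()
  ns <- length(assignShots(plan))
  shots <- corruptKSpace(channels, motionTrace(matrix(0, ns, 6)), plan,
                         voxelSize = 2)
  expect_equal(nShots(shots), ns)
  # sample-count invariant: lines * nx per channel
  expect_true(all(vapply(shots@shots, function(s)
    nrow(s$data) == 32L * nrow(s$lines), TRUE)))
  # oracle: direct FFT of channel 1
  K <- fft(channels[[1]][wrapPos(32), wrapPos(32), wrapPos(32)])
  got <- shots@shots[[5]]
  oracle <- vapply(seq_len(nrow(got$lines)), function(l) {
    kx <- (attr(partialFourierMask(32, 1), "k") %% 32) + 1
    K[cbind(kx, (got$lines[l, 1] %% 32) + 1, (got$lines[l, 2] %% 32) + 1)]
  }, complex(32))
  expect_lt(max(Mod(got$data[, 1] - as.vector(oracle))) /
              max(Mod(oracle)), 1e-6)
})

test_that("pure translation obeys the Fourier shift theorem exactly", {
  obj <- contrastImage(smallPhantom(), "PD")
  channels <- coilWeighted(obj, smallCoils())
  plan <- smallPlan()
  ns <- length(assignShots(plan))
  tr0 <- motionTrace(matrix(0, ns, 6))
  t <- c(1.3, -0.7, 2.1)   # mm
  trT <- motionTrace(matrix(rep(c(t, 0, 0, 0), each = ns), ns))
  still <- corruptKSpace(channels, tr0, plan, voxelSize = 2)
  moved <- corruptKSpace(channels, trT, plan, voxelSize = 2)
  for (s in c(1L, 16L)) {
    xi <- fatnav:::.shotCoords(moved@shots[[s]]$lines, rep(32L, 3))
    phase <- exp(-2i * pi * drop(xi %*% (t / 2)))   # voxel size 2 mm
    oracle <- still@shots[[s]]$data * phase
    expect_lt(max(Mod(moved@shots[[s]]$data - oracle)) /
                max(Mod(oracle)), 1e-9)
  }
})

test_that("a 90-degree rotation samples the permuted image", {
  # odd grid so the rotation is an exact permutation
  n <- 17L
  set.seed(41)
  vol <- array(rnorm(n^3), rep(n, 3L)) + 0i
  plan <- acquisitionPlan("custom", mat = rep(n, 3L), pf = c(1, 1),
                          outerPe = 2L, trMs = 1)
  ns <- length(assignShots(plan))
  trR <- motionTrace(matrix(rep(c(0, 0, 0, 0, 0, 90), each = ns), ns))
  shots <- corruptKSpace(list(vol), trR, plan, voxelSize = 1)
  perm <- aperm(vol[, n:1, ], c(2, 1, 3))
  shotsP <- corruptKSpace(list(perm),
                          motionTrace(matrix(0, ns, 6)), plan,
                          voxelSize = 1)
  a <- do.call(rbind, lapply(shots@shots, function(s) s$data))
  b <- do.call(rbind, lapply(shotsP@shots, function(s) s$data))
  expect_lt(max(Mod(a - b)) / max(Mod(b)), 1e-5)
})

test_that("the forward model is linear in the object", {
  n <- 16L
  set.seed(42)
  f <- array(rnorm(n^3), rep(n, 3)) + 0i
  g <- array(rnorm(n^3), rep(n, 3)) + 0i
  plan <- acquisitionPlan("custom", mat = rep(n, 3L), pf = c(3 / 4, 1),
                          outerPe = 2L, trMs = 1)
  ns <- length(assignShots(plan))
  tr <- makeMotionTrace(ns, seed = 5, driftMm = 2, driftDeg = 2)
  sf <- corruptKSpace(list(f), tr, plan)
  sg <- corruptKSpace(list(g), tr, plan)
  sfg <- corruptKSpace(list(2 * f + 3i * g), tr, plan)
  for (s in c(1L, ns)) {
    want <- 2 * sf@shots[[s]]$data + 3i * sg@shots[[s]]$data
    expect_lt(max(Mod(sfg@shots[[s]]$data - want)) / max(Mod(want)),
              1e-9)
  }
})

test_that("noise is seeded and reproducible", {
  obj <- contrastImage(smallPhantom(), "PD")
  channels <- coilWeighted(obj, smallCoils())
  plan <- smallPlan()
  ns <- length(assignShots(plan))
  tr <- motionTrace(matrix(0, ns, 6))
  a <- corruptKSpace(channels, tr, plan, voxelSize = 2, noiseSd = 0.1,
                     seed = 7)
  b <- corruptKSpace(channels, tr, plan, voxelSize = 2, noiseSd = 0.1,
                     seed = 7)
  c <- corruptKSpace(channels, tr, plan, voxelSize = 2, noiseSd = 0.1,
                     seed = 8)
  expect_identical(a@shots[[1]]$data, b@shots[[1]]$data)
  expect_false(identical(a@shots[[1]]$data, c@shots[[1]]$data))
})

test_that("trace length must match the shot count", {
  obj <- contrastImage(smallPhantom(), "PD")
  channels <- coilWeighted(obj, smallCoils())
  expect_error(corruptKSpace(channels, motionTrace(matrix(0, 3, 6)),
                             smallPlan(), voxelSize = 2), "poses")
})
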