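test_that("partial-Fourier masks cover the centre and drop negative edges", {
  expect_true(all(partialFourierMask(64, 1)))
  m <- partialFourierMask(128, 3 / 4)
  k <- attr(m, "k")
  expect_equal(sum(m), 96)
  expect_true(m[k == 0])
  expect_true(all(m[k >= 0]))
  # n = 8: complement is exactly the two most-negative indices
  m8 <- partialFourierMask(8, 3 / 4)
  k8 <- attr(m8, "k")
  expect_equal(sum(m8), 6)
  expect_identical(sort(k8[!m8]), c(-4L, -3L))
  expect_error(partialFourierMask(64, 0.5), "fraction")
  expect_error(partialFourierMask(64, 1.2), "fraction")
})

test_that("GRAPPA patterns keep the stride and the calibration block", {
  expect_true(all(grappaPattern(64, 1)))
  g <- grappaPattern(128, 4, calib = 24)
  k <- attr(g, "k")
  stride <- sum(k %% 4 == 0)
  inCalib <- k >= -12 & k < 12
  extra <- sum(inCalib & (k %% 4 != 0))
  expect_equal(sum(g), stride + extra)   # enumeration oracle
  expect_true(g[k == 0])
  expect_error(grappaPattern(16, 2, calib = 32), "calibration")
  # centre line acquired for a spread of factors
  for (R in c(2, 3, 4)) expect_true(grappaPattern(60, R)[
    attr(grappaPattern(60, R), "k") == 0])
})

test_that("shot assignment reproduces the protocol loop structures", {
  gre <- assignShots(grePlan())
  expect_length(gre, 333)             # 3/4 of 444 outer steps
  expect_true(all(vapply(gre, nrow, 1L) == 240))  # 3/4 of 320 inner
  mp <- assignShots(mp2ragePlan())
  expect_length(mp, 312)              # 3/4 of 416 inversion cycles
  # turbo factor equal to all acquired lines puts everything in one shot
  plan <- acquisitionPlan("tse", mat = c(16L, 8L, 8L), pf = c(1, 1),
                          trMs = 1000, turbo = 64L)
  expect_length(assignShots(plan), 1)
  expect_error(assignShots(acquisitionPlan("tse", mat = c(16L, 8L, 8L),
                                           pf = c(1, 1), trMs = 1,
                                           turbo = 65L)), "train length")
})

test_that("every shot list covers exactly the masked lines", {
  for (plan in list(grePlan(), mp2ragePlan(),
                    acquisitionPlan("tse", mat = c(32L, 24L, 16L),
                                    pf = c(3 / 4, 3 / 4), trMs = 1,
                                    turbo = 36L))) {
    shots <- assignShots(plan)
    lines <- do.call(rbind, shots)
    expect_false(any(duplicated(lines)))   # each line in exactly one shot
    pfY <- partialFourierMask(plan@mat[2], plan@pf[1])
    pfZ <- partialFourierMask(plan@mat[3], plan@pf[2])
    kY <- attr(pfY, "k"); kZ <- attr(pfZ, "k")
    mY <- pfY & grappaPattern(plan@mat[2], plan@grappa[1])
    mZ <- pfZ & grappaPattern(plan@mat[3], plan@grappa[2])
    want <- expand.grid(ky = kY[mY], kz = kZ[mZ])
    got <- as.data.frame(lines)
    expect_setequal(paste(got$ky, got$kz), paste(want$ky, want$kz))
  }
})

test_that("scan times reproduce the printed protocol durations", {
  gre <- scanTime(grePlan())
  expect_equal(scanTime(grePlan(), withNav = FALSE)$minutes, 36)
  expect_equal(gre$minutes, 42)
  expect_equal(round(gre$cadence, 1), 7.6)
  expect_equal(gre$host, 333 * 240 * 0.027)
  mp <- scanTime(mp2ragePlan())
  expect_equal(mp$host, 312 * 6)
  expect_equal(mp$minutes, 31)   # navigators sit in the dead time
  # additivity: navigator time is exactly shots x duration for GRE
  expect_equal(gre$total - gre$navigators - gre$calibration, gre$host)
})

test_that("acquired fraction gives the partial-Fourier scan-time saving", {
  expect_equal(acquiredFraction(grePlan()), 0.5625)
  full <- acquisitionPlan("gre", mat = c(512L, 444L, 320L), pf = c(1, 1),
                          outerPe = 1L, trMs = 27)
  expect_equal(acquiredFraction(full), 1)
  oneDim <- acquisitionPlan("gre", mat = c(512L, 444L, 320L),
                            pf = c(3 / 4, 1), outerPe = 1L, trMs = 27)
  expect_equal(acquiredFraction(oneDim), 0.75, tolerance = 1e-3)
  # time ratio equals the acquired fraction for the GRE host
  expect_equal(scanTime(grePlan(), withNav = FALSE)$host /
                 scanTime(full, withNav = FALSE)$host,
               0.5625, tolerance = 1e-3)
})

test_that("plan configurations round-trip through JSON", {
  f <- tempfile(fileext = ".json")
  writePlanConfig(mp2ragePlan(), f)
  p2 <- readPlanConfig(f)
  expect_identical(p2@mat, mp2ragePlan()@mat)
  expect_equal(p2@pf, mp2ragePlan()@pf)
  expect_identical(p2@grappa, mp2ragePlan()@grappa)
  expect_equal(p2@invPeriodMs, 6000)
  expect_equal(scanTime(p2)$minutes, scanTime(mp2ragePlan())$minutes)
})
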