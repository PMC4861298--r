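navTracePar <- function() {
  par <- matrix(0, 6, 6)
  par[2, ] <- c(3, 0, 0, 0, 0, 0)
  par[3, ] <- c(0, -2, 1, 0, 0, 0)
  par[4, ] <- c(0, 0, 0, 2, 0, 0)
  par[5, ] <- c(0, 0, 0, 0, -2, 2)
  par[6, ] <- c(1, 1, -1, 1, 1, -1)
  par
}

navSeriesFixture <- function() fixture("navs64", function()
  simulateFatNavs(bigPhantom(), bigCoils(), motionTrace(navTracePar())))

test_that("identity traces give identical fat-only navigators", {
  ph <- bigPhantom()
  navs <- simulateFatNavs(ph, bigCoils(), motionTrace(matrix(0, 3, 6)))
  expect_identical(navs@volumes[[1]], navs@volumes[[2]])
  expect_identical(navs@volumes[[1]], navs@volumes[[3]])
  expect_equal(voxelSize(navs), 2 * ph@voxelSize)
})

test_that("navigators carry fat contrast only", {
  ph <- bigPhantom()
  navs <- simulateFatNavs(ph, bigCoils(), motionTrace(matrix(0, 1, 6)))
  nav <- navs@volumes[[1]]
  brainOnly <- ph@maps$PD * (ph@maps$fat == 0)
  brainNav <- downsampleVolume(brainOnly, 2, 1)
  # region-wise: inside the brain the navigator is near-empty
  core <- downsampleVolume((ph@maps$fat == 0) * (ph@maps$PD > 0) * 1,
                           2, 1) > 0.9
  expect_lt(mean(nav[core]), 0.05 * max(nav))
  expect_lt(abs(cor(as.vector(nav[core]), as.vector(brainNav[core]))),
            0.5)
  # the strong form: changing every brain compartment leaves the
  # navigators bit-identical, because only fat is excited
  spec2 <- ph@spec
  brainRows <- spec2$fat == 0
  spec2$PD[brainRows] <- spec2$PD[brainRows] * 0.37
  ph2 <- makePhantom(64, seed = ph@seed, spec = spec2, voxelSize = 1)
  navs2 <- simulateFatNavs(ph2, bigCoils(), motionTrace(matrix(0, 1, 6)))
  expect_identical(navs2@volumes[[1]], nav)
  expect_error(simulateFatNavs(makePhantom(32, spec = data.frame(
    name = "b", a = 0.5, b = 0.5, c = 0.5, cx = 0, cy = 0, cz = 0,
    PD = 1, T1 = 1000, T2 = 80, T2star = 50, fat = 0)),
    bigCoils(), motionTrace(matrix(0, 1, 6))), "fat")
})

test_that("a known translation moves the navigator centre of mass", {
  navs <- navSeriesFixture()
  com <- function(v) {
    d <- dim(v); s <- sum(v)
    vapply(1:3, function(k) {
      ax <- (seq_len(d[k]) - 1 - floor(d[k] / 2)) * 2  # 2 mm nav voxels
      w <- apply(v, k, sum)
      sum(w * ax) / s
    }, 0)
  }
  shift <- com(navs@volumes[[2]]) - com(navs@volumes[[1]])
  expect_lt(max(abs(shift - c(3, 0, 0))), 1)  # half a nav voxel
})

test_that("single-axis poses are recovered to a tenth of a voxel", {
  navs <- navSeriesFixture()
  est <- estimateMotion(navs)
  err <- est@params - navTracePar()
  expect_lt(max(abs(err[2:3, 1:3])), 0.2)   # 2-3 mm translations
  expect_lt(max(abs(err[4:5, 4:6])), 0.2)   # 2-degree rotations
  expect_lt(max(abs(err[6, ])), 0.3)        # combined pose
  expect_equal(unname(est@params[1, ]), numeric(6))
})

test_that("re-referencing a trace is pose composition", {
  navs <- navSeriesFixture()
  est1 <- estimateMotion(navs, reference = 1L)
  est3 <- estimateMotion(navs, reference = 3L)
  p3 <- getPose(est1, 3L)
  for (i in c(2L, 4L, 6L)) {
    want <- composePoses(getPose(est1, i), invertPose(p3))
    got <- getPose(est3, i)
    expect_lt(max(abs(poseParams(got) - poseParams(want))), 0.15)
  }
})

test_that("a series of identical volumes registers to the identity", {
  ph <- bigPhantom()
  navs <- simulateFatNavs(ph, bigCoils(), motionTrace(matrix(0, 4, 6)))
  est <- estimateMotion(navs)
  expect_lt(max(abs(est@params)), 1e-3)
})

test_that("pose recovery over random poses meets the precision target", {
  r <- poseRecovery()
  err <- r$est - r$truth
  expect_lt(median(abs(err[-1, 1:3])), 0.2)
  expect_lt(median(abs(err[-1, 4:6])), 0.2)
})

test_that("non-overlapping navigators are flagged, not fabricated", {
  ph <- bigPhantom()
  navs <- simulateFatNavs(ph, bigCoils(), motionTrace(matrix(0, 2, 6)))
  navs@volumes[[2]] <- array(0, dim(navs@volumes[[1]]))
  est <- estimateMotion(navs)
  expect_true(all(is.na(est@params[2, ])))
})
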