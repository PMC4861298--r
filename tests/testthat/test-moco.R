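test_that("zero-motion correction equals the zero-filled FFT recon", {
  s <- mocoSim()
  img <- rssCombine(correctShots(s$still, s$tr0))
  expect_lt(nrmse(s$ref, img), 1e-5)
})

test_that("translation-only correction is exact in k-space", {
  s <- mocoSim()
  t <- c(1.7, -0.4, 0.9)
  trT <- motionTrace(matrix(rep(c(t, 0, 0, 0), each = s$ns), s$ns))
  moved <- corruptKSpace(s$channels, trT, s$plan, voxelSize = 2)
  # undo the phase ramp shot by shot: must match the still data to
  # floating tolerance
  for (i in c(1L, 10L, s$ns)) {
    xi <- fatnav:::.shotCoords(moved@shots[[i]]$lines, rep(32L, 3))
    corr <- moved@shots[[i]]$data *
      exp(+2i * pi * drop(xi %*% (t / 2)))
    ref <- s$still@shots[[i]]$data
    expect_lt(max(Mod(corr - ref)) / max(Mod(ref)), 1e-9)
  }
  # and through the full pipeline the image is restored
  img <- rssCombine(correctShots(moved, trT))
  expect_lt(nrmse(s$ref, img), 1e-6)
})

test_that("correction with the true trace recovers most of the loss", {
  s <- mocoSim()
  unc <- nrmse(s$ref, rssCombine(cartesianRecon(s$moved)))
  corr <- nrmse(s$ref, rssCombine(correctShots(s$moved, s$trace)))
  expect_gt(unc, 0.1)          # the motion really hurts
  expect_lt(corr, unc / 3)     # and the correction really helps
})

test_that("correction error grows gracefully with rotation angle", {
  s <- mocoSim()
  errAt <- function(deg) {
    tr <- motionTrace(matrix(rep(c(0, 0, 0, deg, 0, 0), each = s$ns),
                             s$ns))
    mv <- corruptKSpace(s$channels, tr, s$plan, voxelSize = 2)
    nrmse(s$ref, rssCombine(correctShots(mv, tr)))
  }
  e <- vapply(c(0, 0.5, 2), errAt, 0)
  expect_lt(e[1], 1e-5)
  expect_true(all(diff(e) >= -1e-6))   # non-decreasing in angle
  expect_lt(e[3], 0.05)                # still small at 2 degrees
})

test_that("correct is linear in the measured samples", {
  s <- mocoSim()
  a <- s$moved
  b <- s$moved
  for (i in seq_len(s$ns)) b@shots[[i]]$data <- 2i * b@shots[[i]]$data
  va <- correctShots(a, s$trace)
  vb <- correctShots(b, s$trace)
  expect_lt(max(Mod(vb[[1]] - 2i * va[[1]])) / max(Mod(va[[1]])), 1e-9)
})

test_that("a slightly perturbed trace degrades gracefully", {
  s <- mocoSim()
  unc <- nrmse(s$ref, rssCombine(cartesianRecon(s$moved)))
  exact <- nrmse(s$ref, rssCombine(correctShots(s$moved, s$trace)))
  set.seed(6)
  pert <- s$trace@params +
    cbind(matrix(runif(3 * s$ns, -0.1, 0.1), s$ns),
          matrix(runif(3 * s$ns, -0.1, 0.1), s$ns))
  rough <- nrmse(s$ref, rssCombine(correctShots(s$moved,
                                                motionTrace(pert))))
  gain <- unc - exact
  expect_lt(rough - exact, 0.5 * gain)
})

test_that("missing poses follow the configured policy", {
  s <- mocoSim()
  par <- s$trace@params
  par[3, ] <- NA
  tr <- motionTrace(par)
  near <- rssCombine(correctShots(s$moved, tr, missingPose = "nearest"))
  drop <- rssCombine(correctShots(s$moved, tr, missingPose = "drop"))
  exact <- rssCombine(correctShots(s$moved, s$trace))
  expect_lt(nrmse(s$ref, near), nrmse(s$ref,
            rssCombine(cartesianRecon(s$moved))))
  expect_false(identical(near, drop))
  # one mildly wrong pose barely moves the result
  expect_lt(abs(nrmse(s$ref, near) - nrmse(s$ref, exact)), 0.05)
})

test_that("RSS combination has the expected algebra", {
  v <- smoothVolume()
  expect_equal(rssCombine(list(v + 0i)), abs(v))
  expect_equal(rssCombine(list(v, v)), sqrt(2) * abs(v),
               tolerance = 1e-12)
  w <- smoothVolume() * 0.3
  expect_identical(rssCombine(list(v, w)), rssCombine(list(w, v)))
  expect_error(rssCombine(list(v, array(0, c(2, 2, 2)))), "shape")
})

test_that("the estimated-trace pipeline improves the image", {
  s <- mocoSim()
  navs <- simulateFatNavs(s$ph, s$coils, s$trace)
  res <- correctWithEstimatedTrace(s$moved, navs, truth = s$trace,
                                   referenceImage = s$ref)
  expect_lt(res$nrmse["corrected"], res$nrmse["uncorrected"])
  expect_equal(nrow(res$report), s$ns)
  errT <- abs(as.matrix(res$report[, c("err_tx_mm", "err_ty_mm",
                                       "err_tz_mm")]))
  errR <- abs(as.matrix(res$report[, c("err_rx_deg", "err_ry_deg",
                                       "err_rz_deg")]))
  expect_lt(median(errT), 0.3)
  expect_lt(median(errR), 0.3)
  # no-op safety: motion-free shots are not harmed by the pipeline
  navs0 <- simulateFatNavs(s$ph, s$coils, s$tr0)
  res0 <- correctWithEstimatedTrace(s$still, navs0,
                                    referenceImage = s$ref)
  expect_lt(abs(res0$nrmse["corrected"] - res0$nrmse["uncorrected"]),
            0.01)
})
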