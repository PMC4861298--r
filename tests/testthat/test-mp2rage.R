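test_that("parameter invariants are enforced", {
  expect_s4_class(mp2rageParams(), "MP2RAGEParams")
  expect_error(mp2rageParams(ti1 = 3000), "ti1 < ti2")
  expect_error(mp2rageParams(eta = 1.2), "efficiency")
  # trains must fit inside the cycle
  expect_error(mp2rageParams(ti1 = 500, nEcho = 166), "first train")
  expect_error(mp2rageParams(ti2 = 5600, trCycle = 6000), "second train")
})

test_that("the cycle map reaches a true periodic steady state", {
  p <- mp2rageParams()
  for (t1 in c(400, 1200, 3500)) {
    s1 <- mp2rageSignals(t1, p, method = "closed")
    s2 <- mp2rageSignals(t1, p, method = "iterate")
    expect_equal(s1$S1, s2$S1, tolerance = 1e-7)
    expect_equal(s1$S2, s2$S2, tolerance = 1e-7)
  }
  # zero flip angles give zero signal
  p0 <- mp2rageParams(alpha1 = 0, alpha2 = 0)
  s0 <- mp2rageSignals(1500, p0)
  expect_equal(s0$S1, 0)
  expect_equal(s0$S2, 0)
})

test_that("n = 1, eta = 1 reduces to single-pulse inversion recovery", {
  # closed-form oracle: with one pulse per train the magnetisation at
  # the first readout is the classic inversion-recovery curve of the
  # steady-state cycle, and S1 flips sign at its null point
  p <- mp2rageParams(nEcho = 1L, eta = 1, esp = 7.8)
  cosA <- function(a) cos(a * pi / 180)
  oracle <- function(T1) {
    # propagate the affine cycle by hand: inversion at t=0, pulse 1 at
    # ti1, pulse 2 at ti2, cycle ends at trCycle (echo spacing
    # relaxation follows each pulse, matching the recursion's layout)
    E <- function(t) exp(-t / T1)
    half <- p@esp / 2
    step <- function(mz, t) 1 + (mz - 1) * E(t)
    f <- function(mz0) {
      mz <- -mz0                       # perfect inversion
      mz <- step(mz, p@ti1 - half)
      mzE1 <- mz
      mz <- step(mz * cosA(p@alpha1), p@esp)
      mz <- step(mz, (p@ti2 - half) - (p@ti1 + half))
      mzE2 <- mz
      mz <- step(mz * cosA(p@alpha2), p@esp)
      mz <- step(mz, p@trCycle - (p@ti2 + half))
      list(mz = mz, e1 = mzE1, e2 = mzE2)
    }
    # affine fixed point via two evaluations (the inversion sign is
    # already inside the cycle map)
    a <- f(1)$mz - f(0)$mz
    b <- f(0)$mz
    mzStar <- b / (1 - a)
    st <- f(mzStar)
    c(sin(p@alpha1 * pi / 180) * st$e1, sin(p@alpha2 * pi / 180) * st$e2)
  }
  for (T1 in c(300, 800, 1154, 2000, 4000)) {
    s <- mp2rageSignals(T1, p)
    o <- oracle(T1)
    expect_equal(c(s$S1, s$S2), o, tolerance = 1e-9)
  }
  # sign flip of S1 across the null of TI1 (about T1 = TI1 / ln 2 for
  # a long cycle)
  sShort <- mp2rageSignals(600, p)$S1
  sLong <- mp2rageSignals(3000, p)$S1
  expect_gt(sShort, 0)
  expect_lt(sLong, 0)
})

test_that("UNI is bounded, scale-invariant and handles zeros", {
  expect_equal(uniCombine(1 + 0i, 1 + 0i), 0.5)
  expect_equal(uniCombine(2, -2), -0.5)
  expect_equal(uniCombine(0, 0), 0)
  set.seed(51)
  s1 <- complex(real = rnorm(1e5), imaginary = rnorm(1e5))
  s2 <- complex(real = rnorm(1e5), imaginary = rnorm(1e5))
  u <- uniCombine(s1, s2)
  expect_true(all(abs(u) <= 0.5 + 1e-15))
  for (c in c(2, -0.3, 1i, 3 - 2i))
    expect_equal(uniCombine(c * s1[1:100], c * s2[1:100]), u[1:100],
                 tolerance = 1e-12)
})

test_that("the lookup table is monotone and self-inverting", {
  p <- mp2rageParams()
  tab <- suppressWarnings(buildLookup(p))
  expect_true(all(diff(tab$UNI) < 0))   # strictly decreasing in T1
  # round trip within the grid resolution
  for (T1 in c(700, 1500, 3000)) {
    s <- mp2rageSignals(T1, p)
    u <- uniCombine(s$S1, s$S2)
    expect_lt(abs(t1Map(u, tab) - T1), 2)
  }
  # eta sensitivity: small efficiency changes deform the curve smoothly
  tabLo <- suppressWarnings(buildLookup(mp2rageParams(eta = 0.94)))
  tabHi <- suppressWarnings(buildLookup(mp2rageParams(eta = 0.98)))
  common <- seq(800, 3000, by = 50)
  uni <- function(tb) approx(tb$T1, tb$UNI, xout = common)$y
  expect_lt(max(abs(uni(tabLo) - uni(tabHi))), 0.05)
  expect_true(all(diff(uni(tabLo)) < 0) && all(diff(uni(tabHi)) < 0))
})

test_that("T1 mapping inverts the phantom's UNI image", {
  ph <- smallPhantom()
  p <- mp2rageParams()
  sim <- simulateMP2RAGE(ph, p)
  expect_true(all(abs(sim$UNI) <= 0.5 + 1e-12))
  tab <- suppressWarnings(buildLookup(p))
  t1 <- t1Map(sim$UNI, tab)
  sup <- ph@maps$PD > 0
  expect_lt(median(abs(t1[sup] - ph@maps$T1[sup])), 5)
  # constant input, constant output
  const <- t1Map(array(0.1, c(4, 4, 4)), tab)
  expect_equal(max(const) - min(const), 0)
  # boundary UNI clamps to the short-T1 end and is counted
  edge <- t1Map(c(0.5, 0), tab)
  expect_equal(attr(edge, "clamped"), 1)
  expect_equal(edge[1], min(tab$T1))
  expect_error(t1Map(0.1, tab[0, ]), "empty")
})
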