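# MP2RAGE signal model, UNI combination and lookup-table T1 mapping.
#
# The longitudinal magnetisation is propagated through one cycle --
# inversion (Mz -> -eta Mz), relaxation to the first train, n small-angle
# pulses with echo-spacing relaxation, relaxation to the second train,
# n pulses, relaxation to the cycle end -- and solved for the periodic
# steady state.  Every stage is affine in Mz, so the cycle map is
# Mz -> a Mz + b and its fixed point b / (1 - a) is exact; fixed-point
# iteration is kept as a cross-check.  The inversion times refer to the
# train centres (k-space centre of a linearly ordered train).

#' Construct MP2RAGE parameters
#'
#' @param ti1,ti2 Inversion times (ms) of the first and second train
#'   centre.
#' @param alpha1,alpha2 Flip angles (degrees).
#' @param esp Echo spacing (ms).
#' @param nEcho Echoes per train; the default 166 follows from a
#'   442-line PE dimension at 3/4 partial Fourier with 2x GRAPPA
#'   (442 * 3/4 / 2 = 166 lines per train).
#' @param trCycle Time between inversion pulses (ms).
#' @param eta Inversion efficiency in (0, 1].
#' @return An [MP2RAGEParams-class].
#' @export
mp2rageParams <- function(ti1 = 800, ti2 = 2700, alpha1 = 5, alpha2 = 7,
                          esp = 7.8, nEcho = 166L, trCycle = 6000,
                          eta = 0.96) {
  new("MP2RAGEParams", ti1 = ti1, ti2 = ti2, alpha1 = alpha1,
      alpha2 = alpha2, esp = esp, nEcho = as.integer(nEcho),
      trCycle = trCycle, eta = eta)
}

# affine propagation helpers: state is c(a, b) meaning Mz = a Mz0 + b
.relax <- function(ab, t, T1) {
  e <- exp(-t / T1)
  c(ab[1] * e, ab[2] * e + (1 - e))
}
.pulse <- function(ab, cosA) c(ab[1] * cosA, ab[2] * cosA)

#' Steady-state MP2RAGE signal pair
#'
#' Returns the signed signals of the two readout trains,
#' \code{S_i = sin(alpha_i) * Mz} at the central echo of each train, at
#' the periodic steady state of the cycle.
#'
#' @param t1 Longitudinal relaxation time(s) in ms (vectorised).
#' @param p An [MP2RAGEParams-class].
#' @param method \code{"closed"} (affine fixed point, default) or
#'   \code{"iterate"} (fixed-point iteration to |dMz| < 1e-9; errors
#'   after 1e4 cycles without convergence).
#' @return List with vectors \code{S1} and \code{S2}.
#' @export
mp2rageSignals <- function(t1, p, method = c("closed", "iterate")) {
  method <- match.arg(method)
  stopifnot(all(t1 > 0))
  n <- p@nEcho
  cos1 <- cos(p@alpha1 * pi / 180)
  cos2 <- cos(p@alpha2 * pi / 180)
  half <- n * p@esp / 2
  tA <- p@ti1 - half                 # inversion -> first train start
  tB <- (p@ti2 - half) - (p@ti1 + half)  # gap between trains
  tC <- p@trCycle - (p@ti2 + half)   # second train end -> next inversion
  kc <- ceiling(n / 2)               # central echo (pulse index)
  S1 <- numeric(length(t1)); S2 <- numeric(length(t1))
  for (i in seq_along(t1)) {
    T1 <- t1[i]
    # propagate the affine map through one cycle, recording the
    # coefficients at the two central echoes
    ab <- c(-p@eta, 0)               # inversion
    ab <- .relax(ab, tA, T1)
    abE1 <- NULL; abE2 <- NULL
    for (e in seq_len(n)) {
      if (e == kc) abE1 <- ab
      ab <- .relax(.pulse(ab, cos1), p@esp, T1)
    }
    ab <- .relax(ab, tB, T1)
    for (e in seq_len(n)) {
      if (e == kc) abE2 <- ab
      ab <- .relax(.pulse(ab, cos2), p@esp, T1)
    }
    ab <- .relax(ab, tC, T1)
    if (method == "closed") {
      mz0 <- ab[2] / (1 - ab[1])
    } else {
      mz0 <- 1
      for (it in seq_len(1e4)) {
        nxt <- ab[1] * mz0 + ab[2]
        if (abs(nxt - mz0) < 1e-9) { mz0 <- nxt; break }
        mz0 <- nxt
        if (it == 1e4) stop("MP2RAGE cycle did not reach steady state")
      }
    }
    S1[i] <- sin(p@alpha1 * pi / 180) * (abE1[1] * mz0 + abE1[2])
    S2[i] <- sin(p@alpha2 * pi / 180) * (abE2[1] * mz0 + abE2[2])
  }
  list(S1 = S1, S2 = S2)
}

#' UNI combination of the two MP2RAGE signals
#'
#' \code{Re(Conj(S1) * S2) / (|S1|^2 + |S2|^2)}, bounded in
#' \[-0.5, 0.5\] and invariant to global intensity scaling (the
#' bias-field-free property); defined as 0 where both signals vanish.
#'
#' @param s1,s2 Complex or signed real signal volumes/vectors.
#' @return Numeric UNI values in \[-0.5, 0.5\].
#' @export
uniCombine <- function(s1, s2) {
  num <- Re(Conj(s1) * s2)
  den <- Mod(s1)^2 + Mod(s2)^2
  out <- num
  out[] <- 0
  nz <- den > 0
  out[nz] <- num[nz] / den[nz]
  out
}

#' Build the UNI -> T1 lookup table
#'
#' Evaluates the steady-state UNI over a T1 grid and restricts the table
#' to its largest strictly monotonic branch (with the protocol defaults
#' UNI is strictly decreasing in T1 over the whole physiological range;
#' a warning is emitted if the range had to be trimmed).
#'
#' @param p An [MP2RAGEParams-class].
#' @param t1Grid Sorted T1 grid in ms.
#' @return Data frame with columns \code{T1} and \code{UNI}, strictly
#'   monotonic in \code{UNI}.
#' @export
buildLookup <- function(p, t1Grid = seq(100, 5000, by = 1)) {
  stopifnot(!is.unsorted(t1Grid))
  s <- mp2rageSignals(t1Grid, p)
  uni <- uniCombine(s$S1, s$S2)
  d <- diff(uni)
  sgn <- sign(d)
  # longest run of constant nonzero slope sign
  runs <- rle(sgn)
  if (all(runs$values == 0)) stop("UNI is constant over the grid")
  best <- which.max(ifelse(runs$values != 0, runs$lengths, 0))
  hi <- cumsum(runs$lengths)[best]
  lo <- hi - runs$lengths[best] + 1L
  idx <- lo:(hi + 1L)
  if (length(idx) < length(t1Grid))
    warning(sprintf(
      "UNI(T1) is monotonic only on [%g, %g] ms; table restricted",
      t1Grid[idx[1]], t1Grid[idx[length(idx)]]))
  data.frame(T1 = t1Grid[idx], UNI = uni[idx])
}

#' Convert a UNI volume to a quantitative T1 map
#'
#' Linear interpolation in a monotone lookup table; UNI values outside
#' the table are clamped to the branch ends and counted.
#'
#' @param uni Numeric array or vector of UNI values.
#' @param table Lookup table from [buildLookup()].
#' @return Array of T1 values (ms) with attribute \code{clamped}: the
#'   number of out-of-range inputs.
#' @export
t1Map <- function(uni, table) {
  if (!nrow(table)) stop("empty lookup table")
  u <- table$UNI
  t1 <- table$T1
  if (u[1] > u[length(u)]) { u <- rev(u); t1 <- rev(t1) }
  x <- as.vector(uni)
  clamped <- sum(x < u[1] | x > u[length(u)])
  x <- pmin(pmax(x, u[1]), u[length(u)])
  out <- stats::approx(u, t1, xout = x, ties = "ordered")$y
  res <- uni
  res[] <- out
  attr(res, "clamped") <- clamped
  res
}

#' Simulate MP2RAGE volumes of a phantom
#'
#' Computes the two train signals per voxel from the phantom T1 map
#' (interpolating a dense signal table), weighted by proton density, and
#' the corresponding UNI volume.
#'
#' @param ph A [Phantom-class].
#' @param p An [MP2RAGEParams-class].
#' @return List with complex volumes \code{S1}, \code{S2} and the
#'   numeric \code{UNI} volume.
#' @export
simulateMP2RAGE <- function(ph, p = mp2rageParams()) {
  t1 <- ph@maps$T1
  pd <- ph@maps$PD
  sup <- pd > 0
  grid <- seq(max(50, min(t1[sup]) * 0.9), max(t1[sup]) * 1.1,
              length.out = 512)
  s <- mp2rageSignals(grid, p)
  S1 <- array(0, dim(t1)); S2 <- array(0, dim(t1))
  S1[sup] <- stats::approx(grid, s$S1, xout = t1[sup])$y * pd[sup]
  S2[sup] <- stats::approx(grid, s$S2, xout = t1[sup])$y * pd[sup]
  list(S1 = S1 + 0i, S2 = S2 + 0i, UNI = uniCombine(S1, S2))
}
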