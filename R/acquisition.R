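# Sampling masks, shot ordering and scan-time accounting.
#
# Phase-encode line indices are centred integers (k = 0 is the k-space
# centre, stored at array position floor(n/2) + 1).  Partial Fourier
# leaves out the extreme negative frequencies; the GRAPPA stride is
# applied within the partial-Fourier-acquired region.

#' Asymmetric partial-Fourier mask
#'
#' Contiguous coverage of \code{round(fraction * n)} lines containing the
#' k-space centre and the whole positive half; the unacquired lines are
#' the most-negative frequencies.
#'
#' @param n Number of lines.
#' @param fraction Acquired fraction, in (0.5, 1].
#' @return Logical vector of length \code{n} over centred indices
#'   (attribute \code{k} carries the centred index of each element).
#' @examples
#' sum(partialFourierMask(128, 3/4))  # 96 acquired lines
#' @export
partialFourierMask <- function(n, fraction) {
  if (fraction <= 0.5 || fraction > 1)
    stop("partial-Fourier fraction must lie in (0.5, 1]")
  k <- as.integer(.axisCoords(n, 1))
  nacq <- round(fraction * n)
  mask <- k >= min(k) + (n - nacq)
  structure(mask, k = k)
}

#' Regular GRAPPA undersampling pattern
#'
#' Every R-th line (anchored on the k-space centre) plus a fully sampled
#' central calibration block.
#'
#' @param n Number of lines.
#' @param R Undersampling factor (>= 1).
#' @param calib Calibration lines (0 for none; must not exceed \code{n}).
#' @return Logical vector over centred indices, as in
#'   [partialFourierMask()].
#' @export
grappaPattern <- function(n, R, calib = 0L) {
  stopifnot(R >= 1L)
  if (calib > n) stop("calibration block larger than the line count")
  k <- as.integer(.axisCoords(n, 1))
  mask <- k %% as.integer(R) == 0L
  if (calib > 0L)
    mask <- mask | (k >= -floor(calib / 2) & k < ceiling(calib / 2))
  structure(mask, k = k)
}

#' Construct an acquisition plan
#'
#' @param protocol Label: \code{"mp2rage"}, \code{"tse"}, \code{"gre"} or
#'   \code{"custom"}.  The label selects the shot-assignment and timing
#'   rules, see [assignShots()] and [scanTime()].
#' @param mat Matrix size (nx, ny, nz); dimension 1 is the readout.
#' @param pf Partial-Fourier fraction for each PE dimension (length 2).
#' @param grappa GRAPPA factor for each PE dimension (length 2).
#' @param outerPe Which PE dimension (1 = ny, 2 = nz) carries the outer
#'   loop (one navigator per completed outer step).
#' @param trMs,espMs,turbo,invPeriodMs,navMs,calibS Timing constants: see
#'   [AcquisitionPlan-class].
#' @return An [AcquisitionPlan-class].
#' @export
acquisitionPlan <- function(protocol = "custom", mat, pf = c(1, 1),
                            grappa = c(1L, 1L), outerPe = 2L,
                            trMs = NA_real_, espMs = NA_real_,
                            turbo = NA_integer_, invPeriodMs = NA_real_,
                            navMs = 0, calibS = 0) {
  new("AcquisitionPlan", protocol = protocol, mat = as.integer(mat),
      peDims = c(2L, 3L), pf = as.numeric(pf),
      grappa = as.integer(grappa), outerPe = as.integer(outerPe),
      trMs = as.numeric(trMs), espMs = as.numeric(espMs),
      turbo = as.integer(turbo), invPeriodMs = as.numeric(invPeriodMs),
      navMs = as.numeric(navMs), calibS = as.numeric(calibS))
}

#' Protocol presets
#'
#' Acquisition plans carrying the printed parameters of the three host
#' protocols: 350 um GRE (matrix 512x444x320, TR 27 ms, 3/4 partial
#' Fourier in both PE dimensions, a navigator after each partition loop),
#' 350 um MP2RAGE (552x442x416, 6000 ms inversion period, 2x GRAPPA on the
#' first PE dimension, one navigator per inversion cycle) and 380 um TSE
#' (512x320x448, turbo factor 166, 2700 ms per train).  The navigator
#' duration (1152 ms) and its 2.3 s calibration prescan are stored
#' constants of the navigator protocol.
#'
#' @return An [AcquisitionPlan-class].
#' @export
grePlan <- function() {
  acquisitionPlan("gre", mat = c(512L, 444L, 320L), pf = c(3 / 4, 3 / 4),
                  outerPe = 1L, trMs = 27, navMs = 1152, calibS = 2.3)
}

#' @rdname grePlan
#' @export
mp2ragePlan <- function() {
  acquisitionPlan("mp2rage", mat = c(552L, 442L, 416L), pf = c(3 / 4, 3 / 4),
                  grappa = c(2L, 1L), outerPe = 2L, espMs = 7.8,
                  invPeriodMs = 6000, navMs = 1152, calibS = 2.3)
}

#' @rdname grePlan
#' @export
tsePlan <- function() {
  acquisitionPlan("tse", mat = c(512L, 320L, 448L), pf = c(3 / 4, 3 / 4),
                  outerPe = 2L, trMs = 2700, espMs = 997 / 166,
                  turbo = 166L, navMs = 1152, calibS = 2.3)
}

# combined PF + GRAPPA masks for the two PE dims (list of logical vectors)
.peMasks <- function(plan) {
  lapply(1:2, function(d) {
    n <- plan@mat[plan@peDims[d]]
    m <- partialFourierMask(n, plan@pf[d]) & grappaPattern(n, plan@grappa[d])
    structure(m, k = as.integer(.axisCoords(n, 1)))
  })
}

#' Assign acquired lines to shots
#'
#' Builds the ordered shot list of a plan.  MP2RAGE and GRE produce one
#' shot per outer-PE step holding that step's acquired inner-PE lines
#' (for MP2RAGE the two readout trains of an inversion cycle share one
#' shot, since one navigator follows each cycle); TSE chops the linearly
#' ordered acquired lines into consecutive trains of \code{turbo} lines.
#' Ordering is linear ascending over the outer dimension and within a
#' shot.
#'
#' @param plan An [AcquisitionPlan-class].
#' @return List with one integer matrix per shot (columns \code{ky},
#'   \code{kz}: centred line indices).
#' @examples
#' length(assignShots(grePlan()))  # 333 partition loops
#' @export
assignShots <- function(plan) {
  masks <- .peMasks(plan)
  ky <- attr(masks[[1]], "k")[masks[[1]]]
  kz <- attr(masks[[2]], "k")[masks[[2]]]
  outerIsZ <- plan@outerPe == 2L
  outerK <- if (outerIsZ) kz else ky
  innerK <- if (outerIsZ) ky else kz
  if (plan@protocol %in% c("mp2rage", "gre", "custom")) {
    lapply(outerK, function(o) {
      if (outerIsZ) cbind(ky = innerK, kz = rep(o, length(innerK)))
      else cbind(ky = rep(o, length(innerK)), kz = innerK)
    })
  } else if (plan@protocol == "tse") {
    lines <- do.call(rbind, lapply(outerK, function(o) {
      if (outerIsZ) cbind(ky = innerK, kz = rep(o, length(innerK)))
      else cbind(ky = rep(o, length(innerK)), kz = innerK)
    }))
    tf <- plan@turbo
    if (is.na(tf) || tf < 1L) stop("TSE plan requires a turbo factor")
    if (tf > nrow(lines))
      stop("train length exceeds the number of acquired lines")
    idx <- split(seq_len(nrow(lines)), (seq_len(nrow(lines)) - 1) %/% tf)
    lapply(idx, function(i) lines[i, , drop = FALSE])
  } else stop("unknown protocol ", plan@protocol)
}

#' Fraction of the full Cartesian PE grid acquired
#'
#' @param plan An [AcquisitionPlan-class].
#' @return Acquired PE lines divided by \code{ny * nz}.
#' @examples
#' acquiredFraction(grePlan())  # (3/4)^2 = 0.5625
#' @export
acquiredFraction <- function(plan) {
  masks <- .peMasks(plan)
  mean(masks[[1]]) * mean(masks[[2]])
}

#' Scan-time accounting
#'
#' Total scan time and its breakdown into host sequence, navigators and
#' calibration prescan.  Host time is (acquired lines x TR) for GRE,
#' (shots x inversion period) for MP2RAGE and (shots x TR-per-train) for
#' TSE; every shot is followed by one navigator.  For MP2RAGE and TSE
#' the navigator fits into the sequence dead time (after the second
#' readout train / after the echo train) and adds no scan time; for GRE
#' (and custom plans) each navigator extends the scan by its duration.
#'
#' @param plan An [AcquisitionPlan-class].
#' @param withNav Include navigator and calibration time.
#' @return List with elements \code{host}, \code{navigators},
#'   \code{calibration}, \code{total} (seconds), \code{minutes} (total
#'   rounded half-up to whole minutes), \code{nShots} and
#'   \code{cadence} (seconds from one navigator to the next).
#' @examples
#' scanTime(grePlan())$minutes        # 42 with navigators
#' scanTime(grePlan(), withNav = FALSE)$minutes  # 36
#' @export
scanTime <- function(plan, withNav = TRUE) {
  shots <- assignShots(plan)
  ns <- length(shots)
  nLines <- sum(vapply(shots, nrow, 1L))
  host <- switch(plan@protocol,
    gre = nLines * plan@trMs / 1000,
    mp2rage = ns * plan@invPeriodMs / 1000,
    tse = ns * plan@trMs / 1000,
    custom = {
      if (is.na(plan@trMs)) stop("custom plan requires trMs")
      nLines * plan@trMs / 1000
    })
  if (is.na(host)) stop("missing timing constants for ", plan@protocol)
  absorbed <- plan@protocol %in% c("mp2rage", "tse")
  nav <- if (withNav && !absorbed) ns * plan@navMs / 1000 else 0
  calib <- if (withNav) plan@calibS else 0
  total <- host + nav + calib
  list(host = host, navigators = nav, calibration = calib, total = total,
       minutes = floor(total / 60 + 0.5), nShots = ns,
       cadence = host / ns + plan@navMs / 1000)
}

#' Read and write plan configuration files
#'
#' Plans serialise to JSON with keys \code{protocol, matrix, pe_dims, pf,
#' grappa, outer_pe, tr_ms, esp_ms, turbo, inv_period_ms, nav_ms,
#' calib_s}.
#'
#' @param plan An [AcquisitionPlan-class].
#' @param path File path.
#' @return \code{readPlanConfig} returns an [AcquisitionPlan-class];
#'   \code{writePlanConfig} returns \code{path} invisibly.
#' @export
writePlanConfig <- function(plan, path) {
  x <- list(protocol = plan@protocol, matrix = plan@mat,
            pe_dims = plan@peDims, pf = plan@pf, grappa = plan@grappa,
            outer_pe = plan@outerPe, tr_ms = plan@trMs,
            esp_ms = plan@espMs, turbo = plan@turbo,
            inv_period_ms = plan@invPeriodMs, nav_ms = plan@navMs,
            calib_s = plan@calibS)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname writePlanConfig
#' @export
readPlanConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("protocol", "matrix", "pf")
  if (!all(need %in% names(x)))
    stop("plan config must define ", paste(need, collapse = ", "))
  num <- function(v, default = NA_real_)
    if (is.null(v) || all(is.na(v))) default else as.numeric(v)
  acquisitionPlan(protocol = x$protocol, mat = x$matrix, pf = x$pf,
                  grappa = if (is.null(x$grappa)) c(1L, 1L) else x$grappa,
                  outerPe = if (is.null(x$outer_pe)) 2L else x$outer_pe,
                  trMs = num(x$tr_ms), espMs = num(x$esp_ms),
                  turbo = if (is.null(x$turbo) || all(is.na(x$turbo)))
                    NA_integer_ else as.integer(x$turbo),
                  invPeriodMs = num(x$inv_period_ms),
                  navMs = num(x$nav_ms, 0), calibS = num(x$calib_s, 0))
}
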