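#' @import methods
#' @importFrom stats optimize rnorm runif median sd fft mvfft nextn
#' @importFrom utils read.delim write.table head tail
#' @useDynLib fatnav, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.PARAM_NAMES <- c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg")

#' Rigid-body pose
#'
#' A 6-DOF rigid transform of the head relative to the scanner frame:
#' three translations in mm and three rotations in degrees.  Rotations are
#' right-handed intrinsic rotations applied in the order x, then y, then z,
#' about the volume centre.
#'
#' @slot params Named numeric vector of length 6
#'   (\code{tx_mm, ty_mm, tz_mm, rx_deg, ry_deg, rz_deg}).
#' @seealso [pose()], [poseMatrix()], [composePoses()], [invertPose()]
#' @export
setClass("Pose", representation(params = "numeric"),
         prototype(params = structure(numeric(6), names = .PARAM_NAMES)))

setValidity("Pose", function(object) {
  p <- object@params
  if (length(p) != 6L) return("params must have length 6")
  if (!all(is.finite(p))) return("pose parameters must be finite")
  TRUE
})

#' Per-shot motion trace
#'
#' Ordered rigid-body poses, one per shot (navigator interval).  Motion is
#' modelled as piecewise-constant over a shot.
#'
#' @slot params Numeric matrix, one row per shot, columns
#'   \code{tx_mm, ty_mm, tz_mm, rx_deg, ry_deg, rz_deg}. Rows of \code{NA}
#'   mark shots whose pose estimation failed.
#' @slot shot Integer vector of shot indices (1-based).
#' @seealso [motionTrace()], [makeMotionTrace()], [estimateMotion()]
#' @export
setClass("MotionTrace",
         representation(params = "matrix", shot = "integer"))

setValidity("MotionTrace", function(object) {
  if (ncol(object@params) != 6L) return("params must have 6 columns")
  if (nrow(object@params) != length(object@shot))
    return("one shot index per pose is required")
  if (!identical(colnames(object@params), .PARAM_NAMES))
    return(sprintf("params columns must be %s",
                   paste(.PARAM_NAMES, collapse = ", ")))
  TRUE
})

#' Digital phantom with co-registered parameter maps
#'
#' A brain-like numerical phantom on an isotropic grid: proton density,
#' relaxation times and a fat-fraction map whose support (the scalp-fat
#' shell) is disjoint from the brain compartments.  The fat shell is the
#' signal source for the fat-excitation navigators and moves rigidly with
#' the brain.
#'
#' @slot maps Named list of 3D arrays: \code{PD} (arbitrary units, >= 0),
#'   \code{T1}, \code{T2}, \code{T2star} (ms), and \code{fat} (fat fraction
#'   in \[0, 1\]).
#' @slot voxelSize Isotropic voxel size in mm.
#' @slot spec The compartment table used to build the phantom.
#' @slot seed Integer seed the phantom was generated from.
#' @seealso [makePhantom()], [contrastImage()]
#' @export
setClass("Phantom",
         representation(maps = "list", voxelSize = "numeric",
                        spec = "data.frame", seed = "integer"))

setValidity("Phantom", function(object) {
  need <- c("PD", "T1", "T2", "T2star", "fat")
  if (!all(need %in% names(object@maps)))
    return(sprintf("maps must contain %s", paste(need, collapse = ", ")))
  d <- dim(object@maps$PD)
  if (length(d) != 3L) return("maps must be 3D arrays")
  if (!all(vapply(object@maps, function(m) identical(dim(m), d), TRUE)))
    return("all maps must share the same grid")
  if (any(object@maps$PD < 0)) return("PD must be non-negative")
  f <- object@maps$fat
  if (any(f < 0 | f > 1)) return("fat fraction must lie in [0, 1]")
  sup <- object@maps$PD > 0
  if (any(object@maps$T1[sup] <= 0) || any(object@maps$T2[sup] <= 0) ||
      any(object@maps$T2star[sup] <= 0))
    return("relaxation times must be positive wherever PD > 0")
  TRUE
})

#' Coil sensitivity set
#'
#' Smooth complex receive sensitivities on the phantom grid, one map per
#' channel, normalised so the root-sum-of-squares is one over the object.
#'
#' @slot maps List of complex 3D arrays, one per coil.
#' @seealso [makeCoils()], [coilWeighted()]
#' @export
setClass("CoilSet", representation(maps = "list"))

setValidity("CoilSet", function(object) {
  if (length(object@maps) < 1L) return("at least one coil is required")
  d <- dim(object@maps[[1L]])
  if (!all(vapply(object@maps, function(m) identical(dim(m), d), TRUE)))
    return("all coil maps must share the same grid")
  TRUE
})

#' Multi-shot Cartesian acquisition plan
#'
#' Sampling masks, shot ordering and timing constants for one protocol.
#' Phase-encode masks combine an asymmetric partial-Fourier window with a
#' GRAPPA stride applied inside the acquired region.
#'
#' @slot protocol One of \code{"mp2rage"}, \code{"tse"}, \code{"gre"},
#'   \code{"custom"}.
#' @slot mat Matrix size (nx, ny, nz); the first dimension is the readout.
#' @slot peDims Indices of the two phase-encode dimensions (2 and 3).
#' @slot pf Partial-Fourier fraction per PE dimension (in (0.5, 1\]).
#' @slot grappa GRAPPA undersampling factor per PE dimension.
#' @slot outerPe Which PE dimension (1 or 2, indexing \code{peDims}) hosts
#'   the outer loop; one navigator follows each completed outer step.
#' @slot trMs Repetition time in ms (per line for GRE, per train for TSE).
#' @slot espMs Echo spacing in ms.
#' @slot turbo Echoes per train (TSE turbo factor; lines per shot).
#' @slot invPeriodMs Time between inversion pulses in ms (MP2RAGE only).
#' @slot navMs Navigator duration in ms (a stored constant of the
#'   navigator protocol, not derived from its matrix).
#' @slot calibS Calibration prescan duration in seconds.
#' @seealso [acquisitionPlan()], [grePlan()], [mp2ragePlan()], [tsePlan()],
#'   [assignShots()], [scanTime()]
#' @export
setClass("AcquisitionPlan",
         representation(protocol = "character", mat = "integer",
                        peDims = "integer", pf = "numeric",
                        grappa = "integer", outerPe = "integer",
                        trMs = "numeric", espMs = "numeric",
                        turbo = "integer", invPeriodMs = "numeric",
                        navMs = "numeric", calibS = "numeric"))

setValidity("AcquisitionPlan", function(object) {
  if (length(object@mat) != 3L || any(object@mat < 1L))
    return("matrix size must be three positive integers")
  if (any(object@pf <= 0.5) || any(object@pf > 1))
    return("partial-Fourier fractions must lie in (0.5, 1]")
  if (any(object@grappa < 1L)) return("GRAPPA factors must be >= 1")
  if (!object@outerPe %in% c(1L, 2L)) return("outerPe must be 1 or 2")
  TRUE
})

#' Multi-channel k-space shots
#'
#' The measured (or simulated) multi-channel complex k-space of a
#' multi-shot acquisition: for each shot, the Cartesian phase-encode line
#' indices and the complex samples for every readout point and channel.
#'
#' @slot shots List with one entry per shot, each a list with elements
#'   \code{lines} (integer matrix of centred (ky, kz) indices, one row per
#'   line) and \code{data} (complex matrix, \code{nx * nrow(lines)} rows by
#'   \code{nCoils} columns; readout index varies fastest).
#' @slot n Image grid size (nx, ny, nz).
#' @slot voxelSize Isotropic voxel size in mm.
#' @slot plan The [AcquisitionPlan-class] the shots follow.
#' @seealso [corruptKSpace()], [correctShots()], [writeShots()]
#' @export
setClass("ShotSet",
         representation(shots = "list", n = "integer",
                        voxelSize = "numeric", plan = "AcquisitionPlan"))

setValidity("ShotSet", function(object) {
  nx <- object@n[1L]
  nc <- if (length(object@shots)) ncol(object@shots[[1L]]$data) else 0L
  for (s in object@shots) {
    if (!is.matrix(s$lines) || ncol(s$lines) != 2L)
      return("each shot needs an L x 2 line-index matrix")
    if (nrow(s$data) != nx * nrow(s$lines))
      return("sample count must equal lines * nx per channel")
    if (ncol(s$data) != nc)
      return("all shots must have the same channel count")
  }
  TRUE
})

#' Navigator volume series
#'
#' One low-resolution fat-only magnitude volume per shot, all on a common
#' grid and intensity scale, plus the navigator sampling plan.
#'
#' @slot volumes List of 3D arrays (magnitude), one per shot.
#' @slot voxelSize Navigator voxel size in mm.
#' @slot plan List describing the navigator sampling (matrix, GRAPPA
#'   factors, partial-Fourier fractions, calibration lines).
#' @seealso [simulateFatNavs()], [estimateMotion()]
#' @export
setClass("NavSeries",
         representation(volumes = "list", voxelSize = "numeric",
                        plan = "list"))

setValidity("NavSeries", function(object) {
  if (length(object@volumes) < 1L) return("at least one volume is required")
  d <- dim(object@volumes[[1L]])
  if (!all(vapply(object@volumes, function(v) identical(dim(v), d), TRUE)))
    return("all navigator volumes must share one grid")
  TRUE
})

#' MP2RAGE sequence parameters
#'
#' Timing and flip-angle parameters of the two-readout-train MP2RAGE
#' cycle.  Defaults follow a 7T protocol: inversion times 800/2700 ms,
#' flip angles 5/7 degrees, echo spacing 7.8 ms, 166 echoes per train,
#' 6000 ms between inversions, inversion efficiency 0.96.
#'
#' @slot ti1,ti2 Inversion times of the two readout-train centres (ms).
#' @slot alpha1,alpha2 Excitation flip angles of the trains (degrees).
#' @slot esp Echo spacing within a train (ms).
#' @slot nEcho Echoes per readout train.
#' @slot trCycle Time between consecutive inversion pulses (ms).
#' @slot eta Inversion efficiency in (0, 1].
#' @seealso [mp2rageParams()], [mp2rageSignals()], [buildLookup()]
#' @export
setClass("MP2RAGEParams",
         representation(ti1 = "numeric", ti2 = "numeric",
                        alpha1 = "numeric", alpha2 = "numeric",
                        esp = "numeric", nEcho = "integer",
                        trCycle = "numeric", eta = "numeric"))

setValidity("MP2RAGEParams", function(object) {
  if (!(object@ti1 < object@ti2 && object@ti2 < object@trCycle))
    return("need ti1 < ti2 < trCycle")
  if (object@eta <= 0 || object@eta > 1)
    return("inversion efficiency must lie in (0, 1]")
  half <- object@nEcho * object@esp / 2
  if (object@ti1 - half <= 0)
    return("first train does not fit before ti1")
  if (object@ti2 + half >= object@trCycle)
    return("second train does not fit inside the cycle")
  TRUE
})
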