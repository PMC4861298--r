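#' Number of shots
#' @param x A [MotionTrace-class], [ShotSet-class] or [NavSeries-class].
#' @return Integer shot count.
#' @export
setGeneric("nShots", function(x) standardGeneric("nShots"))

#' @rdname nShots
#' @export
setMethod("nShots", "MotionTrace", function(x) nrow(x@params))

#' @rdname nShots
#' @export
setMethod("nShots", "ShotSet", function(x) length(x@shots))

#' @rdname nShots
#' @export
setMethod("nShots", "NavSeries", function(x) length(x@volumes))

#' Voxel size accessor
#' @param x An object carrying an isotropic voxel size.
#' @return Voxel size in mm.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "Phantom", function(x) x@voxelSize)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "ShotSet", function(x) x@voxelSize)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "NavSeries", function(x) x@voxelSize)

#' Pose parameter accessor
#' @param x A [Pose-class] or [MotionTrace-class].
#' @param i For a trace, the shot number.
#' @return Named numeric vector of the six rigid parameters.
#' @export
setGeneric("poseParams", function(x, i) standardGeneric("poseParams"))

#' @rdname poseParams
#' @export
setMethod("poseParams", "Pose", function(x, i) x@params)

#' @rdname poseParams
#' @export
setMethod("poseParams", "MotionTrace", function(x, i) {
  structure(x@params[i, ], names = .PARAM_NAMES)
})

#' Extract one pose from a trace
#' @param x A [MotionTrace-class].
#' @param i Shot number.
#' @return A [Pose-class].
#' @export
setGeneric("getPose", function(x, i) standardGeneric("getPose"))

#' @rdname getPose
#' @export
setMethod("getPose", "MotionTrace", function(x, i) {
  new("Pose", params = structure(x@params[i, ], names = .PARAM_NAMES))
})

setMethod("show", "Pose", function(object) {
  p <- object@params
  cat(sprintf("Pose: t = (%.3f, %.3f, %.3f) mm, r = (%.3f, %.3f, %.3f) deg\n",
              p[1], p[2], p[3], p[4], p[5], p[6]))
})

setMethod("show", "MotionTrace", function(object) {
  n <- nShots(object)
  mx <- if (n) apply(abs(object@params), 2, max, na.rm = TRUE) else numeric(6)
  cat(sprintf("MotionTrace: %d shots, max |t| = %.2f mm, max |r| = %.2f deg\n",
              n, max(mx[1:3]), max(mx[4:6])))
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@maps$PD)
  cat(sprintf(
    "Phantom: %dx%dx%d grid @ %.2f mm, %d compartments, seed %d\n",
    d[1], d[2], d[3], object@voxelSize, nrow(object@spec), object@seed))
})

setMethod("show", "CoilSet", function(object) {
  d <- dim(object@maps[[1]])
  cat(sprintf("CoilSet: %d coils on a %dx%dx%d grid\n",
              length(object@maps), d[1], d[2], d[3]))
})

setMethod("show", "AcquisitionPlan", function(object) {
  cat(sprintf(
    "AcquisitionPlan <%s>: matrix %s, PF %s, GRAPPA %s, outer PE dim %d\n",
    object@protocol, paste(object@mat, collapse = "x"),
    paste(format(object@pf), collapse = "/"),
    paste(object@grappa, collapse = "x"), object@peDims[object@outerPe]))
})

setMethod("show", "ShotSet", function(object) {
  nc <- if (nShots(object)) ncol(object@shots[[1]]$data) else 0L
  cat(sprintf("ShotSet: %d shots, %d channels, grid %s @ %.2f mm\n",
              nShots(object), nc, paste(object@n, collapse = "x"),
              object@voxelSize))
})

setMethod("show", "NavSeries", function(object) {
  d <- dim(object@volumes[[1]])
  cat(sprintf("NavSeries: %d volumes on a %dx%dx%d grid @ %.2f mm\n",
              nShots(object), d[1], d[2], d[3], object@voxelSize))
})

setMethod("show", "MP2RAGEParams", function(object) {
  cat(sprintf(
    paste0("MP2RAGEParams: TI %g/%g ms, alpha %g/%g deg, esp %g ms, ",
           "%d echoes, cycle %g ms, eta %.2f\n"),
    object@ti1, object@ti2, object@alpha1, object@alpha2, object@esp,
    object@nEcho, object@trCycle, object@eta))
})
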