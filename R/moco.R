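# Retrospective rigid-body k-space correction.
#
# Each shot's samples are phase-corrected for the translation, their
# coordinates are rotated back (k' = R^T k), and all shots are
# accumulated per channel into a single adjoint NUFFT reconstruction on
# the target grid.  Assuming small motion, no density compensation is
# applied; gaps and overlaps left in k-space by rotations are accepted.
# All shots are corrected into the frame of the trace's reference pose
# (the pose of the reference shot is the identity), so the corrected
# image sits in the reference head position.

#' Correct multi-channel k-space for per-shot rigid motion
#'
#' @param shots A [ShotSet-class].
#' @param trace A [MotionTrace-class] with one pose per shot; rows of
#'   \code{NA} mark shots without a usable pose.
#' @param missingPose Policy for shots without a pose: use the
#'   \code{"nearest"} shot's pose in time (default) or \code{"drop"} the
#'   shot.
#' @param tol NUFFT accuracy.
#' @return List of complex corrected volumes, one per channel.
#' @seealso [rssCombine()], [correctWithEstimatedTrace()]
#' @export
correctShots <- function(shots, trace, missingPose = c("nearest", "drop"),
                         tol = 1e-7) {
  missingPose <- match.arg(missingPose)
  ns <- nShots(shots)
  if (nShots(trace) != ns)
    stop("trace has ", nShots(trace), " poses for ", ns, " shots")
  n <- shots@n
  nc <- ncol(shots@shots[[1L]]$data)
  par <- trace@params
  bad <- apply(is.na(par), 1L, any)
  if (all(bad)) stop("no usable pose in the trace")
  keep <- !bad
  if (any(bad)) {
    if (missingPose == "nearest") {
      ok <- which(!bad)
      for (s in which(bad))
        par[s, ] <- par[ok[which.min(abs(ok - s))], ]
      keep <- rep(TRUE, ns)
    }
  }
  coordsL <- vector("list", ns)
  weightsL <- vector("list", ns)
  for (s in which(keep)) {
    xi <- .shotCoords(shots@shots[[s]]$lines, n)
    R <- .rotmat(par[s, 4:6])
    coordsL[[s]] <- xi %*% R
    tvox <- par[s, 1:3] / shots@voxelSize
    weightsL[[s]] <- exp(+2i * pi * drop(xi %*% tvox))
  }
  use <- which(keep)
  coords <- do.call(rbind, coordsL[use])
  out <- vector("list", nc)
  for (c in seq_len(nc)) {
    vals <- unlist(lapply(use, function(s)
      shots@shots[[s]]$data[, c] * weightsL[[s]]), use.names = FALSE)
    out[[c]] <- nufftAdjoint(vals, coords, n, tol = tol, wrap = TRUE)
  }
  out
}

#' Root-sum-of-squares channel combination
#'
#' @param channels List of complex (or numeric) volumes on one grid.
#' @return Numeric magnitude volume \code{sqrt(sum_i |c_i|^2)}.
#' @export
rssCombine <- function(channels) {
  stopifnot(is.list(channels), length(channels) >= 1L)
  d <- dim(channels[[1L]])
  if (!all(vapply(channels, function(x) identical(dim(x), d), TRUE)))
    stop("channel volumes differ in shape")
  sqrt(Reduce(`+`, lapply(channels, function(x) Mod(x)^2)))
}

#' End-to-end correction with a navigator-estimated trace
#'
#' Estimates the motion trace from a navigator series
#' ([estimateMotion()]), applies the k-space correction
#' ([correctShots()]) and combines channels ([rssCombine()]).
#'
#' @param shots A [ShotSet-class].
#' @param navs A [NavSeries-class] aligned with the shots (one volume per
#'   shot).
#' @param reference Reference navigator index (its pose is the identity).
#' @param truth Optional ground-truth [MotionTrace-class]; if given, the
#'   report carries per-shot pose errors.
#' @param referenceImage Optional motion-free magnitude volume; if given,
#'   the report carries corrected and uncorrected NRMSE against it.
#' @param tol NUFFT accuracy.
#' @return List with elements \code{volume} (corrected magnitude),
#'   \code{trace} (estimated [MotionTrace-class]) and \code{report}
#'   (data frame with one row per shot: applied pose, failure flag, and
#'   pose errors when \code{truth} is given), plus \code{nrmse} (named
#'   vector, when \code{referenceImage} is given).
#' @export
correctWithEstimatedTrace <- function(shots, navs, reference = 1L,
                                      truth = NULL, referenceImage = NULL,
                                      tol = 1e-7) {
  if (nShots(navs) != nShots(shots))
    stop("navigator series and shots disagree in shot count")
  est <- estimateMotion(navs, reference = reference)
  vols <- correctShots(shots, est, tol = tol)
  img <- rssCombine(vols)
  rep <- data.frame(shot = seq_len(nShots(shots)), est@params,
                    failed = apply(is.na(est@params), 1L, any),
                    check.names = FALSE)
  if (!is.null(truth)) {
    err <- est@params - truth@params
    colnames(err) <- paste0("err_", .PARAM_NAMES)
    rep <- cbind(rep, err)
  }
  out <- list(volume = img, trace = est, report = rep)
  if (!is.null(referenceImage)) {
    unc <- rssCombine(cartesianRecon(shots))
    out$nrmse <- c(corrected = nrmse(referenceImage, img),
                   uncorrected = nrmse(referenceImage, unc))
  }
  out
}
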