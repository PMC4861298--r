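# Rigid-body transforms and their action on volumes.
#
# Convention (fixed here, documented in the vignette): right-handed
# intrinsic rotations applied in the order x, then y, then z, about the
# volume centre; the rotation matrix is Rx %*% Ry %*% Rz acting on column
# vectors in mm.  A pose maps the reference object into the observed
# position: y = R (x - c) + c + t.

#' Construct a rigid-body pose
#'
#' @param tx,ty,tz Translations in mm.
#' @param rx,ry,rz Rotations in degrees (right-handed, intrinsic x-y-z
#'   order, about the volume centre).
#' @return A [Pose-class].
#' @examples
#' pose(tx = 1.5, rz = 2)
#' @export
pose <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0) {
  new("Pose", params = structure(as.numeric(c(tx, ty, tz, rx, ry, rz)),
                                 names = .PARAM_NAMES))
}

#' @rdname pose
#' @export
identityPose <- function() pose()

.rotmat <- function(rDeg) {
  a <- rDeg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

.anglesFromRot <- function(R) {
  # inverse of .rotmat: R = Rx Ry Rz, so R[1,3] = sin(ry)
  sy <- max(-1, min(1, R[1, 3]))
  ry <- asin(sy)
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(-R[2, 3], R[3, 3])
    rz <- atan2(-R[1, 2], R[1, 1])
  } else {
    # gimbal lock: fold everything into rx
    rx <- atan2(R[3, 2], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

#' Homogeneous matrix of a pose
#'
#' Returns the 4x4 homogeneous rigid matrix (mm) of a pose, with the
#' rotation applied about \code{center}.
#'
#' @param p A [Pose-class].
#' @param center Rotation centre in mm (3-vector).
#' @return 4x4 numeric matrix mapping reference coordinates to moved
#'   coordinates, \code{y = R (x - center) + center + t}.
#' @export
poseMatrix <- function(p, center = c(0, 0, 0)) {
  stopifnot(is(p, "Pose"))
  q <- p@params
  R <- .rotmat(q[4:6])
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- q[1:3] + center - R %*% center
  M
}

.poseFromMatrix <- function(M) {
  r <- .anglesFromRot(M[1:3, 1:3])
  pose(M[1, 4], M[2, 4], M[3, 4], r[1], r[2], r[3])
}

#' Compose and invert poses
#'
#' \code{composePoses(a, b)} is the pose whose matrix equals
#' \code{poseMatrix(a) \%*\% poseMatrix(b)} (apply \code{b} first);
#' \code{invertPose(p)} is the pose with the inverse matrix.
#'
#' @param a,b,p [Pose-class] objects.
#' @return A [Pose-class].
#' @export
composePoses <- function(a, b) {
  .poseFromMatrix(poseMatrix(a) %*% poseMatrix(b))
}

#' @rdname composePoses
#' @export
invertPose <- function(p) {
  M <- poseMatrix(p)
  R <- t(M[1:3, 1:3])
  Mi <- diag(4)
  Mi[1:3, 1:3] <- R
  Mi[1:3, 4] <- -R %*% M[1:3, 4]
  .poseFromMatrix(Mi)
}

# centred physical coordinates (mm) of a grid axis
.axisCoords <- function(n, vox) (seq_len(n) - 1 - floor(n / 2)) * vox

#' Resample a volume under a rigid pose
#'
#' Trilinearly resamples \code{vol} so that the returned volume shows the
#' object moved by \code{p} (rotation about the volume centre, then
#' translation).  Out-of-field voxels are zero.
#'
#' @param vol 3D numeric or complex array.
#' @param p A [Pose-class].
#' @param voxelSize Voxel size in mm; a scalar for isotropic grids or a
#'   length-3 vector.  Non-isotropic grids require the explicit triple.
#' @param interpolation Only \code{"trilinear"} is supported.
#' @return Array of the same dimension as \code{vol}.
#' @export
resampleVolume <- function(vol, p, voxelSize = 1,
                           interpolation = c("trilinear")) {
  interpolation <- match.arg(interpolation)
  d <- dim(vol)
  stopifnot(length(d) == 3L)
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  if (length(voxelSize) != 3L)
    stop("voxelSize must be a scalar or a length-3 vector")
  q <- p@params
  if (all(q == 0)) return(vol)
  M <- poseMatrix(invertPose(p))
  cx <- .axisCoords(d[1], voxelSize[1])
  cy <- .axisCoords(d[2], voxelSize[2])
  cz <- .axisCoords(d[3], voxelSize[3])
  gx <- rep(cx, times = d[2] * d[3])
  gy <- rep(rep(cy, each = d[1]), times = d[3])
  gz <- rep(cz, each = d[1] * d[2])
  src <- cbind(gx, gy, gz) %*% t(M[1:3, 1:3])
  src <- sweep(src, 2, M[1:3, 4], "+")
  # mm -> 0-based voxel index
  for (k in 1:3)
    src[, k] <- src[, k] / voxelSize[k] + floor(d[k] / 2)
  if (is.complex(vol)) {
    out <- complex(real = .trilinear3(Re(vol), dim(vol), src),
                   imaginary = .trilinear3(Im(vol), dim(vol), src))
  } else {
    out <- .trilinear3(vol, dim(vol), src)
  }
  array(out, d)
}

#' Construct a motion trace from a parameter matrix
#'
#' @param params Numeric matrix or data frame with one row per shot and
#'   columns \code{tx_mm, ty_mm, tz_mm, rx_deg, ry_deg, rz_deg} (extra
#'   columns are ignored; unnamed 6-column input is accepted in that
#'   order).
#' @param shot Optional shot indices (default \code{1:nrow}).
#' @return A [MotionTrace-class].
#' @export
motionTrace <- function(params, shot = NULL) {
  params <- as.matrix(as.data.frame(params))
  if (!is.null(colnames(params)) && all(.PARAM_NAMES %in% colnames(params)))
    params <- params[, .PARAM_NAMES, drop = FALSE]
  if (ncol(params) != 6L)
    stop("params must have six columns (tx, ty, tz, rx, ry, rz)")
  colnames(params) <- .PARAM_NAMES
  if (is.null(shot)) shot <- seq_len(nrow(params))
  new("MotionTrace", params = params, shot = as.integer(shot))
}

#' Generate a smooth drift-plus-jerk motion trace
#'
#' Emulates the motion pattern typical of long structural scans: a slow
#' smooth drift accumulating to roughly the requested amplitude, plus a
#' small number of sudden jerks (step changes) at random shots.
#'
#' @param nShots Number of shots.
#' @param seed Integer seed; the trace is a pure function of its
#'   arguments.
#' @param driftMm,driftDeg Approximate end-of-scan drift amplitude per
#'   axis (mm / degrees).
#' @param nJerks Number of step changes.
#' @param jerkMm,jerkDeg Step amplitude per axis.
#' @return A [MotionTrace-class] whose first pose is the identity.
#' @export
makeMotionTrace <- function(nShots, seed = 1L, driftMm = 3, driftDeg = 3,
                            nJerks = 1L, jerkMm = 1, jerkDeg = 1) {
  stopifnot(nShots >= 1L)
  .withSeed(seed, {
    ramp <- (seq_len(nShots) - 1) / max(1L, nShots - 1L)
    ramp <- ramp^1.5  # slow start, as drifts tend to accumulate late
    dirT <- runif(3, -1, 1); dirR <- runif(3, -1, 1)
    par <- cbind(outer(ramp, dirT * driftMm), outer(ramp, dirR * driftDeg))
    if (nJerks > 0L && nShots > 2L) {
      at <- sample(2:nShots, min(nJerks, nShots - 1L))
      for (j in at) {
        step <- c(runif(3, -1, 1) * jerkMm, runif(3, -1, 1) * jerkDeg)
        par[j:nShots, ] <- sweep(par[j:nShots, , drop = FALSE], 2, step, "+")
      }
    }
    par <- sweep(par, 2, par[1L, ])  # first shot is the reference
    motionTrace(par)
  })
}

#' Read and write motion traces as TSV
#'
#' The on-disk format is tab-separated with columns \code{shot_index},
#' \code{tx_mm}, \code{ty_mm}, \code{tz_mm}, \code{rx_deg}, \code{ry_deg},
#' \code{rz_deg}.
#'
#' @param trace A [MotionTrace-class].
#' @param path File path.
#' @return \code{readTrace} returns a [MotionTrace-class];
#'   \code{writeTrace} returns \code{path} invisibly.
#' @export
writeTrace <- function(trace, path) {
  df <- data.frame(shot_index = trace@shot, trace@params,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  need <- c("shot_index", .PARAM_NAMES)
  if (!all(need %in% names(df)))
    stop("trace file must have columns ", paste(need, collapse = ", "))
  motionTrace(df[, .PARAM_NAMES], shot = df$shot_index)
}

# evaluate expr under a temporary RNG state
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
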