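# Volume, trace and shot-container I/O.
#
# Volumes travel as NIfTI with the voxel size in the header and the
# scanner-frame origin at the volume centre; voxel indexing is 0-based at
# this boundary (centred coordinates internally).  Shots are stored in a
# single-file container mirroring the layout /shots/<i>/{data,lines},
# /plan (JSON string), /trace (TSV string).

#' Read and write volumes as NIfTI
#'
#' @param vol Numeric 3D array (complex volumes are written as magnitude
#'   unless \code{what = "complex"}, which stores real and imaginary
#'   parts as a 4D pair).
#' @param path File path (\code{.nii} or \code{.nii.gz}).
#' @param voxelSize Isotropic voxel size in mm.
#' @param what For complex input: \code{"magnitude"} or \code{"complex"}.
#' @return \code{readVolume} returns the array with attribute
#'   \code{voxelSize}; \code{writeVolume} returns \code{path} invisibly.
#' @export
writeVolume <- function(vol, path, voxelSize = 1,
                        what = c("magnitude", "complex")) {
  what <- match.arg(what)
  if (is.complex(vol)) {
    vol <- if (what == "complex") {
      array(c(Re(vol), Im(vol)), c(dim(vol), 2L))
    } else Mod(vol)
  }
  img <- RNifti::asNifti(unclass(vol))
  RNifti::pixdim(img) <- rep(voxelSize, length(dim(vol)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 2L) {
    arr <- array(complex(real = arr[, , , 1L], imaginary = arr[, , , 2L]),
                 d[1:3])
  }
  attr(arr, "voxelSize") <- RNifti::pixdim(img)[1L]
  arr
}

#' Write a phantom as a multi-volume NIfTI set
#'
#' One NIfTI per parameter map (\code{<prefix>_PD.nii.gz} etc.) plus a
#' JSON sidecar carrying the compartment table, voxel size and seed.
#'
#' @param ph A [Phantom-class].
#' @param prefix Output path prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
writePhantom <- function(ph, prefix) {
  paths <- character(0)
  for (m in names(ph@maps)) {
    p <- paste0(prefix, "_", m, ".nii.gz")
    writeVolume(ph@maps[[m]], p, ph@voxelSize)
    paths <- c(paths, p)
  }
  side <- paste0(prefix, ".json")
  jsonlite::write_json(list(voxel_size_mm = ph@voxelSize, seed = ph@seed,
                            compartments = ph@spec),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, side))
}

#' Write a navigator series as 4D NIfTI
#'
#' @param navs A [NavSeries-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeNavSeries <- function(navs, path) {
  d <- dim(navs@volumes[[1L]])
  arr <- array(unlist(navs@volumes, use.names = FALSE),
               c(d, length(navs@volumes)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(navs@voxelSize, 3L), 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write a shot container
#'
#' Serialises a [ShotSet-class] (with an optional motion trace) to a
#' single file laid out as \code{shots/<i>/data}, \code{shots/<i>/lines},
#' \code{plan} (JSON string) and \code{trace} (TSV string).
#'
#' @param shots A [ShotSet-class].
#' @param path File path.
#' @param trace Optional [MotionTrace-class] stored alongside.
#' @return \code{readShots} returns a list with elements \code{shots}
#'   ([ShotSet-class]) and \code{trace} ([MotionTrace-class] or NULL);
#'   \code{writeShots} returns \code{path} invisibly.
#' @export
writeShots <- function(shots, path, trace = NULL) {
  planPath <- tempfile(fileext = ".json")
  on.exit(unlink(planPath))
  writePlanConfig(shots@plan, planPath)
  planJson <- paste(readLines(planPath), collapse = "\n")
  traceTsv <- NULL
  if (!is.null(trace)) {
    tracePath <- tempfile(fileext = ".tsv")
    writeTrace(trace, tracePath)
    traceTsv <- paste(readLines(tracePath), collapse = "\n")
    unlink(tracePath)
  }
  container <- list(
    format = "fatnav-shots-v1",
    n = shots@n, voxel_size_mm = shots@voxelSize,
    shots = lapply(shots@shots, function(s)
      list(data = s$data, lines = s$lines)),
    plan = planJson, trace = traceTsv)
  saveRDS(container, path)
  invisible(path)
}

#' @rdname writeShots
#' @export
readShots <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "fatnav-shots-v1"))
    stop("not a fatnav shot container")
  planPath <- tempfile(fileext = ".json")
  writeLines(x$plan, planPath)
  plan <- readPlanConfig(planPath)
  unlink(planPath)
  trace <- NULL
  if (!is.null(x$trace)) {
    tracePath <- tempfile(fileext = ".tsv")
    writeLines(x$trace, tracePath)
    trace <- readTrace(tracePath)
    unlink(tracePath)
  }
  shots <- new("ShotSet",
               shots = lapply(x$shots, function(s)
                 list(lines = s$lines, data = s$data)),
               n = as.integer(x$n), voxelSize = x$voxel_size_mm,
               plan = plan)
  list(shots = shots, trace = trace)
}
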