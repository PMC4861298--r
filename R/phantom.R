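# Seeded brain-like digital phantoms.
#
# Compartments are nested ellipsoids painted in table order (later rows
# overwrite earlier ones), with a scalp-fat shell separated from the brain
# by a signal-free skull gap.  The fat shell gives the fat-excitation
# navigators an object that moves rigidly with the brain, which is what
# the correction method relies on.

#' Default phantom compartment table
#'
#' Semi-axes and centres are expressed as fractions of the half
#' field-of-view.  Relaxation times are 7T-like fixture values (WM T1
#' 1200 ms, GM 2000 ms, CSF 4000 ms), not measured claims.  The row with
#' \code{fat = 1} (and \code{NA} semi-axes) becomes the scalp shell,
#' whose radii are resolved at build time just outside the outermost
#' brain compartment.
#'
#' @return A data frame with columns \code{name, a, b, c, cx, cy, cz, PD,
#'   T1, T2, T2star, fat}.
#' @export
defaultCompartments <- function() {
  data.frame(
    name = c("GM", "WM", "ventricle", "fat_shell"),
    a = c(0.70, 0.50, 0.14, NA),
    b = c(0.78, 0.58, 0.20, NA),
    c = c(0.68, 0.48, 0.13, NA),
    cx = c(0, 0, 0, 0), cy = c(0, 0, 0, 0), cz = c(0, 0, 0, 0),
    PD = c(0.85, 0.70, 1.00, 0.90),
    T1 = c(2000, 1200, 4000, 400),
    T2 = c(80, 60, 1500, 120),
    T2star = c(50, 40, 500, 35),
    fat = c(0, 0, 0, 1),
    stringsAsFactors = FALSE)
}

# squared normalized ellipsoid radius field
.ellipsoidField <- function(n, a, b, c, ctr) {
  u <- .axisCoords(n, 1) / (n / 2)
  x2 <- ((u - ctr[1]) / a)^2
  y2 <- ((u - ctr[2]) / b)^2
  z2 <- ((u - ctr[3]) / c)^2
  outer(outer(x2, y2, "+"), z2, "+")
}

# smooth seeded random field in [-1, 1], built from a handful of low
# spatial frequencies
.smoothField <- function(n, kmax = 2L) {
  ks <- -kmax:kmax
  f <- array(0, rep(n, 3L))
  u <- .axisCoords(n, 1) / n
  for (kx in ks) for (ky in ks) for (kz in ks) {
    if (kx == 0 && ky == 0 && kz == 0) next
    amp <- rnorm(1) / (kx^2 + ky^2 + kz^2)
    ph <- runif(1, 0, 2 * pi)
    f <- f + amp * outer(outer(cos(2 * pi * kx * u + ph),
                               cos(2 * pi * ky * u), "*"),
                         cos(2 * pi * kz * u), "*")
  }
  f / max(abs(f))
}

#' Build a digital phantom
#'
#' Paints ellipsoidal compartments from \code{spec} onto an isotropic
#' \code{n^3} grid and adds a scalp-fat shell (about 2.5 voxels thick,
#' with smooth seeded thickness and intensity modulation so rotations are
#' observable in the navigators) outside a 1-voxel skull gap around the
#' outermost brain compartment.  Optionally modulates PD and T1 within
#' compartments by a smooth seeded random field.
#'
#' @param n Grid size per axis (>= 16).
#' @param seed Integer seed; output is a pure function of the arguments.
#' @param spec Compartment table, see [defaultCompartments()].  Rows are
#'   painted in order; a row named \code{fat_shell} (with \code{NA}
#'   semi-axes) becomes the scalp shell.
#' @param voxelSize Isotropic voxel size in mm.
#' @param variation Relative amplitude of smooth within-compartment
#'   variation of PD and T1 (0 disables it).
#' @return A [Phantom-class].
#' @examples
#' ph <- makePhantom(32, seed = 1)
#' @export
makePhantom <- function(n, seed = 1L, spec = defaultCompartments(),
                        voxelSize = 64 / n, variation = 0.05) {
  stopifnot(n >= 16L)
  n <- as.integer(n)
  maps <- list(PD = array(0, rep(n, 3L)), T1 = array(0, rep(n, 3L)),
               T2 = array(0, rep(n, 3L)), T2star = array(0, rep(n, 3L)),
               fat = array(0, rep(n, 3L)))
  shellRow <- which(!is.na(spec$fat) & spec$fat > 0 & is.na(spec$a))
  body <- spec[setdiff(seq_len(nrow(spec)), shellRow), , drop = FALSE]
  brainMask <- array(FALSE, rep(n, 3L))
  for (i in seq_len(nrow(body))) {
    r <- body[i, ]
    inside <- .ellipsoidField(n, r$a, r$b, r$c, c(r$cx, r$cy, r$cz)) <= 1
    for (m in c("PD", "T1", "T2", "T2star"))
      maps[[m]][inside] <- r[[m]]
    maps$fat[inside] <- r$fat
    if (r$fat == 0) brainMask <- brainMask | inside
  }
  shellTex <- NULL
  if (length(shellRow)) {
    # scalp-fat layer outside a 1-voxel skull gap around the outermost
    # brain compartment.  Real scalp fat is several mm thick and
    # irregular; an angularly uniform shell would make head rotations
    # almost invisible to the fat navigators, so both the thickness
    # (2.5 +/- 1.5 voxels) and the intensity of the layer carry a
    # smooth seeded modulation.
    outer_r <- c(body$a[1], body$b[1], body$c[1])
    vstep <- 2 / n   # one voxel in half-FOV units
    r <- spec[shellRow[1L], ]
    rho <- sqrt(.ellipsoidField(n, outer_r[1] + vstep, outer_r[2] + vstep,
                                outer_r[3] + vstep, c(0, 0, 0)))
    .withSeed(seed + 1L, {
      bump <- .smoothField(n, kmax = 3L)
      shellTex <- .smoothField(n, kmax = 3L)
    })
    thick <- (2.5 + 1.5 * bump) * vstep / mean(outer_r)
    shell <- rho > 1 & rho <= 1 + thick & !brainMask
    maps$PD[shell] <- r$PD * (1 + 0.3 * shellTex[shell])
    maps$T1[shell] <- r$T1
    maps$T2[shell] <- r$T2
    maps$T2star[shell] <- r$T2star
    maps$fat[shell] <- r$fat
  }
  if (any(maps$PD < 0))
    stop("compartment spec leaves negative proton density")
  if (variation > 0) {
    .withSeed(seed, {
      mod <- 1 + variation * .smoothField(n)
      sup <- maps$PD > 0
      maps$PD[sup] <- maps$PD[sup] * mod[sup]
      maps$T1[sup] <- maps$T1[sup] * mod[sup]
    })
  }
  new("Phantom", maps = maps, voxelSize = voxelSize, spec = spec,
      seed = as.integer(seed))
}

#' Smooth complex coil sensitivity maps
#'
#' Places Gaussian sensitivity lobes on a ring around the object (with a
#' small seeded jitter of centre and width, and a gentle linear phase per
#' coil) and normalises the set so the root-sum-of-squares is exactly one
#' everywhere.
#'
#' @param n Grid size per axis.
#' @param nCoils Number of channels (>= 1); one channel yields constant
#'   unit sensitivity.
#' @param seed Integer seed.
#' @return A [CoilSet-class].
#' @export
makeCoils <- function(n, nCoils = 8L, seed = 1L) {
  stopifnot(nCoils >= 1L)
  n <- as.integer(n)
  if (nCoils == 1L)
    return(new("CoilSet", maps = list(array(1 + 0i, rep(n, 3L)))))
  .withSeed(seed, {
    u <- .axisCoords(n, 1) / (n / 2)
    gx <- rep(u, times = n * n)
    gy <- rep(rep(u, each = n), times = n)
    gz <- rep(u, each = n * n)
    maps <- vector("list", nCoils)
    for (c in seq_len(nCoils)) {
      ang <- 2 * pi * (c - 1) / nCoils + rnorm(1, 0, 0.05)
      ctr <- c(1.15 * cos(ang), 1.15 * sin(ang),
               0.4 * (c %% 2) - 0.2 + rnorm(1, 0, 0.05))
      sig <- 0.85 * (1 + rnorm(1, 0, 0.05))
      d2 <- (gx - ctr[1])^2 + (gy - ctr[2])^2 + (gz - ctr[3])^2
      mag <- exp(-d2 / (2 * sig^2))
      ph <- 2 * pi * (0.08 * (gx * cos(ang) + gy * sin(ang))) +
        runif(1, 0, 2 * pi)
      maps[[c]] <- array(mag * exp(1i * ph), rep(n, 3L))
    }
    rss <- sqrt(Reduce(`+`, lapply(maps, function(m) Mod(m)^2)))
    maps <- lapply(maps, function(m) m / rss)
    new("CoilSet", maps = maps)
  })
}

#' Static contrast-weighted image of a phantom
#'
#' Voxelwise signal weighting with zero phase: GRE uses
#' \code{PD * exp(-TE / T2*)}, TSE uses \code{PD * exp(-TE / T2)}, and
#' \code{"PD"} returns the proton-density map.  MP2RAGE contrast is
#' handled by [simulateMP2RAGE()].
#'
#' @param ph A [Phantom-class].
#' @param model One of \code{"GRE-T2star"}, \code{"TSE-T2"}, \code{"PD"}.
#' @param te Echo time in ms (required for the weighted models).
#' @return Complex 3D array.
#' @export
contrastImage <- function(ph, model = c("GRE-T2star", "TSE-T2", "PD"),
                          te = NULL) {
  model <- match.arg(model)
  pd <- ph@maps$PD
  if (model == "PD") return(pd + 0i)
  if (is.null(te)) stop("model ", model, " requires an echo time")
  tmap <- switch(model, "GRE-T2star" = ph@maps$T2star, "TSE-T2" = ph@maps$T2)
  w <- array(0, dim(pd))
  sup <- pd > 0
  w[sup] <- pd[sup] * exp(-te / tmap[sup])
  w + 0i
}

#' Coil-weighted copies of an object
#'
#' Multiplies an object volume by each coil sensitivity.  Sensitivities
#' are fixed to the scanner frame; weighting the object before applying
#' motion is the standard small-motion approximation of retrospective
#' correction.
#'
#' @param image Complex or numeric 3D array.
#' @param coils A [CoilSet-class] on the same grid.
#' @return List of complex volumes, one per coil.
#' @export
coilWeighted <- function(image, coils) {
  stopifnot(is(coils, "CoilSet"),
            identical(dim(image), dim(coils@maps[[1L]])))
  lapply(coils@maps, function(m) (image + 0i) * m)
}
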