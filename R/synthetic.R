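## Seeded generators for every input the analysis stages consume. Each
## generator returns its data together with the planted ground truth, so
## recovery can be tested end to end without external downloads.

#' Synthetic equilibrium angle trajectory
#'
#' Discrete Ornstein-Uhlenbeck (AR(1)) process emulating an angle
#' observable from an equilibrating trajectory: the mean relaxes from 0 to
#' `mean` over the burn-in, after which the series is stationary Gaussian
#' with standard deviation `sd` and autocorrelation time `autocorrTime`.
#' The defaults mirror the ATP-state twist observable (10.3 +/- 2.1
#' degrees, 200 frames of 0.2 ns in the stationary window).
#'
#' @param mean stationary mean, degrees.
#' @param sd stationary standard deviation, degrees (0 gives the
#'   deterministic relaxation).
#' @param nFrames stationary frames after burn-in.
#' @param frameDt frame spacing, ns.
#' @param autocorrTime OU autocorrelation time, ns.
#' @param burnIn burn-in duration, ns.
#' @param seed RNG seed.
#' @param name observable name for the series.
#' @return list with `series` (an [AngleSeries-class]) and `truth`
#'   (`mean`, `sd`, `tEquilibrium`).
#' @export
genAngleSeries <- function(mean = 10.3, sd = 2.1, nFrames = 200L,
                           frameDt = 0.2, autocorrTime = 2, burnIn = 60,
                           seed = 1L, name = "theta3") {
  set.seed(seed)
  nBurn <- ceiling(burnIn / frameDt)
  nTot <- nBurn + nFrames
  t <- seq_len(nTot) * frameDt
  ## mean path: exponential approach completing (3 time constants) at burnIn
  muPath <- if (burnIn > 0) mean * (1 - exp(-3 * t / burnIn)) else rep(mean, nTot)
  phi <- exp(-frameDt / autocorrTime)
  x <- numeric(nTot)
  innov <- sd * sqrt(1 - phi^2)
  prev <- 0; prevMu <- 0
  for (i in seq_len(nTot)) {
    x[i] <- muPath[i] + phi * (prev - prevMu) + innov * rnorm(1L)
    prev <- x[i]; prevMu <- muPath[i]
  }
  list(series = angleSeries(x, times = t, name = name),
       truth = list(mean = mean, sd = sd, tEquilibrium = burnIn))
}

## Fixed template subunit: four well-separated subdomain blobs of 25
## deterministic points each (golden-spiral shells of protein-like extent),
## deliberately asymmetric so superpositions are unambiguous.
.templateSubunit <- function(subunit = "minus") {
  centers <- rbind(IA = c(-1.4, -1.0, -1.2), IB = c(-1.2, 1.1, 1.3),
                   IIA = c(1.3, -1.1, 1.0), IIB = c(1.5, 1.2, -1.1))
  doms <- rownames(centers)
  shell <- .spherePoints(25L)
  atoms <- do.call(rbind, lapply(seq_along(doms), function(k) {
    radiiOut <- 0.3 + 0.5 * ((seq_len(25L) * (k + 2L)) %% 7L) / 6
    xyz <- sweep(shell * radiiOut, 2, centers[k, ], `+`)
    data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], radius = 0.17,
               subunit = subunit, subdomain = doms[k],
               resid = (k - 1L) * 25L + 9L + 0:24)
  }))
  atoms
}

#' Synthetic rigid subunit pair with planted bend and twist
#'
#' Duplicates a fixed template subunit, rotates the copy by the planted
#' Euler angles (composed per [composeBendTwist()] in the bottom subunit's
#' body frame), shifts it by the axial rise along the filament axis and
#' adds isotropic positional noise. Ground truth for Euler-angle recovery
#' via [subunitTriad()] and [eulerBendTwist()].
#'
#' @param theta1,theta2,theta3 planted Euler angles, degrees.
#' @param noise isotropic positional noise SD, nm.
#' @param rise axial rise between subunits, nm.
#' @param seed RNG seed.
#' @return list with `frame` (the rotated pair), `reference` (the
#'   unrotated pair), `refTriad` (body frame of both reference subunits)
#'   and `truth` (planted angles).
#' @export
genRigidPair <- function(theta1 = 0, theta2 = 0, theta3 = 10, noise = 0,
                         rise = 5, seed = 1L) {
  set.seed(seed)
  bot <- .templateSubunit("minus")
  topRef <- .templateSubunit("plus")
  topRef$z <- topRef$z + rise
  D <- referenceTriad(comMinus = c(0, 0, 0), comPlus = c(0, 0, rise),
                      membraneNormal = c(0, 1, 0))
  Rbody <- composeBendTwist(theta1, theta2, theta3)
  Rworld <- D %*% Rbody %*% t(D)
  xyz <- as.matrix(topRef[, c("x", "y", "z")])
  pivot <- colMeans(as.matrix(bot[, c("x", "y", "z")]))
  top <- topRef
  rot <- sweep(sweep(xyz, 2, pivot) %*% t(Rworld), 2, pivot, `+`)
  top$x <- rot[, 1]; top$y <- rot[, 2]; top$z <- rot[, 3]
  if (noise > 0) {
    jit <- function(df) {
      m <- as.matrix(df[, c("x", "y", "z")]) +
        matrix(rnorm(3L * nrow(df), sd = noise), ncol = 3L)
      df$x <- m[, 1]; df$y <- m[, 2]; df$z <- m[, 3]
      df
    }
    bot <- jit(bot); top <- jit(top)
  }
  list(frame = structureFrame(rbind(bot, top)),
       reference = structureFrame(rbind(.templateSubunit("minus"), {
         tr <- .templateSubunit("plus"); tr$z <- tr$z + rise; tr
       })),
       refTriad = D,
       truth = list(theta1 = theta1, theta2 = theta2, theta3 = theta3))
}

#' Synthetic membrane leaflet point cloud of known curvature
#'
#' Square lattice of phosphate-like points on a cylinder of radius
#' `1 / curvature` (a plane at curvature 0), with optional isotropic
#' jitter. The cylinder bends toward the returned `proteinSide` point, so
#' [membraneCurvature()] recovers `+curvature`.
#'
#' @param curvature planted curvature, nm^-1 (0 = flat).
#' @param extent patch edge length, nm.
#' @param spacing lattice spacing, nm.
#' @param noise isotropic positional noise SD, nm.
#' @param seed RNG seed.
#' @return list with `points` (n x 3 matrix, nm), `proteinSide` and
#'   `truth`.
#' @export
genMembraneCloud <- function(curvature = 2.5e-3, extent = 60, spacing = 2,
                             noise = 0, seed = 1L) {
  set.seed(seed)
  g <- seq(-extent / 2, extent / 2, by = spacing)
  pts <- as.matrix(expand.grid(x = g, s = g))
  if (curvature == 0) {
    xyz <- cbind(pts[, 1], pts[, 2], 0)
    side <- c(0, 0, 10)
  } else {
    r <- 1 / curvature
    phi <- pts[, 2] / r
    xyz <- cbind(pts[, 1], r * sin(phi), r * (1 - cos(phi)))
    side <- c(0, 0, r)
  }
  if (noise > 0)
    xyz <- xyz + matrix(rnorm(length(xyz), sd = noise), ncol = 3L)
  colnames(xyz) <- c("x", "y", "z")
  list(points = xyz, proteinSide = side, truth = list(curvature = curvature))
}

#' Synthetic flattened-surface image with planted filament bands
#'
#' Renders anti-aliased bright bands of given length, pitch angle and
#' intensity at random positions, blurs them with a Gaussian point-spread
#' function and adds Poisson shot noise on top of Gaussian read noise.
#'
#' @param filaments `data.frame` with columns `length` (um), `pitch`
#'   (degrees from the long cell axis) and `intensity` (relative).
#' @param imageSize image edge, pixels.
#' @param pixelSize pixel size, um.
#' @param psfSigma Gaussian PSF sigma, um.
#' @param bandWidth filament band width, um.
#' @param noiseLevel Gaussian read-noise SD (relative intensity).
#' @param photonScale photons per unit intensity for the Poisson stage.
#' @param seed RNG seed.
#' @param cellID identifier for the image.
#' @return list with `image` (a [SurfaceImage-class]) and `truth` (planted
#'   filament table with realized centers).
#' @export
genSurfaceImage <- function(filaments, imageSize = 256L, pixelSize = 0.032,
                            psfSigma = 0.05, bandWidth = 0.06,
                            noiseLevel = 0.005, photonScale = 2e4,
                            seed = 1L, cellID = "synthetic") {
  set.seed(seed)
  n <- if (is.null(filaments) || !nrow(filaments)) 0L else nrow(filaments)
  canvas <- matrix(0, imageSize, imageSize)
  truth <- NULL
  sigmaPx <- psfSigma / pixelSize
  for (k in seq_len(n)) {
    ## pad the rendered extent by the axial half-max erosion of the blur,
    ## so the planted length is the length the segmentation convention
    ## (binary second-moment major axis) reports
    Lpx <- filaments$length[k] / pixelSize + 0.8 * sigmaPx
    wpx <- bandWidth / pixelSize
    ang <- .deg2rad(filaments$pitch[k])
    dir <- c(cos(ang), sin(ang))
    margin <- Lpx / 2 + 3 * psfSigma / pixelSize + 2
    cx <- runif(1, 1 + margin, imageSize - margin)
    cy <- runif(1, 1 + margin, imageSize - margin)
    p1 <- c(cx, cy) - Lpx / 2 * dir
    p2 <- c(cx, cy) + Lpx / 2 * dir
    rows <- floor(min(p1[1], p2[1]) - wpx - 2):ceiling(max(p1[1], p2[1]) + wpx + 2)
    cols <- floor(min(p1[2], p2[2]) - wpx - 2):ceiling(max(p1[2], p2[2]) + wpx + 2)
    rows <- rows[rows >= 1 & rows <= imageSize]
    cols <- cols[cols >= 1 & cols <= imageSize]
    for (i in rows) {
      ## elliptical band footprint: axial coordinate t, transverse d.
      ## The ellipse is the shape whose second-moment major axis equals the
      ## planted length exactly, matching how patch length is measured.
      tax <- (i - cx) * dir[1] + (cols - cy) * dir[2]
      dperp <- -(i - cx) * dir[2] + (cols - cy) * dir[1]
      wEff <- max(wpx, 1)
      rad <- (2 * tax / Lpx)^2 + (2 * dperp / wEff)^2
      ## anti-alias with the local signed distance to the ellipse boundary
      gradMag <- sqrt((8 * tax / Lpx^2)^2 + (8 * dperp / wEff^2)^2)
      sdist <- (1 - rad) / pmax(gradMag, 1e-6)
      cov <- pmin(1, pmax(0, 0.5 + sdist))
      canvas[i, cols] <- canvas[i, cols] + filaments$intensity[k] * cov
    }
    truth <- rbind(truth, data.frame(length = filaments$length[k],
                                     pitch = filaments$pitch[k],
                                     intensity = filaments$intensity[k],
                                     cx = cx * pixelSize, cy = cy * pixelSize))
  }
  if (n > 0L && sigmaPx > 0) {
    half <- ceiling(3 * sigmaPx)
    g <- dnorm(-half:half, sd = sigmaPx)
    kern <- outer(g, g); kern <- kern / sum(kern)
    canvas <- EBImage::imageData(EBImage::filter2(EBImage::Image(canvas), kern))
  }
  shot <- matrix(rpois(length(canvas), pmax(canvas, 0) * photonScale),
                 nrow(canvas)) / photonScale
  img <- shot + matrix(rnorm(length(canvas), sd = noiseLevel), nrow(canvas))
  img <- pmax(img, 0)
  list(image = surfaceImage(img, pixelSize = pixelSize, cellID = cellID),
       truth = truth)
}

#' End-to-end synthetic mutant panel
#'
#' For each planted per-step twist angle, derives the model-predicted
#' limit length (analytical flat-membrane curve, capped at `lengthCap` to
#' reflect the finite cell size when growth is energetically unbounded)
#' and the model-predicted pitch angle (interior minimum on a cylinder of
#' radius `pitchRadius`), then renders surface images whose filament
#' lengths are drawn log-normally with their 99th percentile at the
#' predicted limit length and whose pitch angles scatter around the
#' predicted pitch. The full ground truth travels with the panel.
#'
#' The default strains span the range where the model is informative under
#' the default constants: below ~8.45 degrees per step growth is
#' energetically unbounded (lengths sit at `lengthCap`), and strains
#' predicting limit lengths below ~200 nm produce patches smaller than the
#' 0.02 um^2 area filter, which the segmentation would discard wholesale.
#'
#' @param twistMeansDeg per-strain intrinsic twist angles, degrees per
#'   monomer step.
#' @param baseParams base [FilamentParams-class]; each strain overrides
#'   `omega0`.
#' @param nFilaments filaments rendered per strain.
#' @param filamentsPerImage bands per rendered image.
#' @param lengthCap cap on the predicted limit length, nm.
#' @param pitchRadius cylinder radius for the pitch prediction, nm (0.8-um
#'   cell width).
#' @param pitchSD per-filament pitch scatter, degrees.
#' @param lengthSdLog log-normal sigma of the length distribution.
#' @param seed base RNG seed.
#' @return list of per-strain lists with `twist`, `params`,
#'   `predictedLimitLength` (nm), `predictedPitch`/`predictedDeviation`
#'   (degrees), `images` (list of [SurfaceImage-class]) and `truth` (per
#'   filament).
#' @export
genMutantPanel <- function(twistMeansDeg = c(2, 5.5, 7.5, 8.5, 8.7),
                           baseParams = filamentParams(),
                           nFilaments = 300L, filamentsPerImage = 6L,
                           lengthCap = 1000, pitchRadius = 400,
                           pitchSD = 5, lengthSdLog = 0.08, seed = 1L) {
  if (length(twistMeansDeg) < 2L)
    warning("panel with a single strain: downstream correlations are undefined")
  lapply(seq_along(twistMeansDeg), function(si) {
    tw <- twistMeansDeg[si]
    p <- filamentParams(C = baseParams@C, K = baseParams@K, V = baseParams@V,
                        k0 = baseParams@k0, omega0 = twistRate(tw),
                        mu0 = baseParams@mu0, r = baseParams@r)
    prof <- energyLengthCurve(p, LMax = lengthCap * 1.5)
    Lstar <- limitLength(prof, p@mu0)
    Lpred <- min(Lstar, lengthCap)
    pCyl <- filamentParams(C = p@C, K = p@K, V = p@V, k0 = p@k0,
                           omega0 = p@omega0, mu0 = p@mu0, r = pitchRadius)
    pitchPred <- interiorPitch(pCyl)
    foldedPitch <- .foldPitch(pitchPred[["pitch"]])
    set.seed(seed + 1000L * si)
    lenUm <- stats::rlnorm(nFilaments,
                           meanlog = log(Lpred / 1000) - qnorm(0.99) * lengthSdLog,
                           sdlog = lengthSdLog)
    pitches <- .foldPitch(rnorm(nFilaments, foldedPitch, pitchSD))
    nImg <- ceiling(nFilaments / filamentsPerImage)
    images <- vector("list", nImg)
    for (im in seq_len(nImg)) {
      sel <- ((im - 1L) * filamentsPerImage + 1L):min(im * filamentsPerImage,
                                                      nFilaments)
      images[[im]] <- genSurfaceImage(
        data.frame(length = lenUm[sel], pitch = pitches[sel], intensity = 1),
        seed = seed + 1000L * si + im,
        cellID = sprintf("strain%d_img%d", si, im))$image
    }
    list(twist = tw, params = p,
         predictedLimitLength = as.numeric(Lpred),
         predictedPitch = pitchPred[["pitch"]],
         predictedDeviation = pitchPred[["deviation"]],
         images = images,
         truth = data.frame(length = lenUm, pitch = pitches))
  })
}
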