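#' Create a labelled structure frame
#'
#' @param atoms `data.frame` with columns `x`, `y`, `z` (nm), `radius`
#'   (nm), `subunit`, `subdomain` (one of IA, IB, IIA, IIB, none) and
#'   `resid`. A `mass` column is optional and enables mass-weighted
#'   centroids.
#' @param time frame time, ns.
#' @return a validated [StructureFrame-class].
#' @export
structureFrame <- function(atoms, time = 0) {
  new("StructureFrame", atoms = as.data.frame(atoms), time = time)
}

.vecAngle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  .rad2deg(acos(pmin(1, pmax(-1, cosang))))
}

#' Subdomain centers of mass of one subunit
#'
#' Centroids of the atoms labelled IA, IB, IIA and IIB for the requested
#' subunit; atoms labelled `none` (e.g. the residue 1-8 amphipathic helix)
#' are excluded. Unweighted by default; with `massWeighted = TRUE` the
#' `mass` column of the atom table is used.
#'
#' @param frame a [StructureFrame-class].
#' @param subunit subunit label.
#' @param massWeighted use mass-weighted centroids.
#' @return a 4 x 3 matrix with rows `IA`, `IB`, `IIA`, `IIB`.
#' @export
subdomainCenters <- function(frame, subunit, massWeighted = FALSE) {
  stopifnot(is(frame, "StructureFrame"))
  at <- frame@atoms[frame@atoms$subunit == subunit, , drop = FALSE]
  if (!nrow(at)) stop("no atoms for subunit '", subunit, "'")
  doms <- c("IA", "IB", "IIA", "IIB")
  out <- matrix(NA_real_, 4L, 3L, dimnames = list(doms, c("x", "y", "z")))
  for (d in doms) {
    sel <- at[at$subdomain == d, , drop = FALSE]
    if (!nrow(sel)) stop("subunit '", subunit, "' is missing subdomain ", d)
    w <- if (massWeighted) {
      if (is.null(sel$mass)) stop("massWeighted = TRUE requires a 'mass' column")
      sel$mass
    } else rep(1, nrow(sel))
    out[d, ] <- c(sum(w * sel$x), sum(w * sel$y), sum(w * sel$z)) / sum(w)
  }
  out
}

#' Opening angle of the actin fold
#'
#' Mean of the two inter-subdomain angles that open when the nucleotide
#' cleft opens: the angle at vertex IIA between IIB and IA, and the angle
#' at vertex IA between IB and IIA.
#'
#' @param centers 4 x 3 matrix as returned by [subdomainCenters()].
#' @return angle in degrees.
#' @export
openingAngle <- function(centers) {
  stopifnot(all(c("IA", "IB", "IIA", "IIB") %in% rownames(centers)))
  a1 <- .vecAngle(centers["IIB", ] - centers["IIA", ],
                  centers["IA", ] - centers["IIA", ])
  a2 <- .vecAngle(centers["IB", ] - centers["IA", ],
                  centers["IIA", ] - centers["IA", ])
  (a1 + a2) / 2
}

#' Dihedral angle of the actin fold
#'
#' Angle between the normal of the plane through IA, IB, IIA and the normal
#' of the plane through IIB, IIA, IA, reported in `[0, 180]` degrees with
#' coplanar centers mapping to 0.
#'
#' @inheritParams openingAngle
#' @return angle in degrees.
#' @export
dihedralAngle <- function(centers) {
  stopifnot(all(c("IA", "IB", "IIA", "IIB") %in% rownames(centers)))
  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  n1 <- cross3(centers["IB", ] - centers["IA", ],
               centers["IIA", ] - centers["IA", ])
  n2 <- cross3(centers["IIA", ] - centers["IIB", ],
               centers["IA", ] - centers["IIB", ])
  .vecAngle(n1, n2)
}

#' Least-squares rotation between two point sets (Kabsch)
#'
#' Rotation part of the rigid superposition mapping `from` onto `to`
#' (both n x 3, matched rows), proper (det = +1).
#'
#' @param from,to n x 3 coordinate matrices.
#' @return 3 x 3 rotation matrix `R` with `to ~ R %*% from` after
#'   centering.
#' @export
kabschRotation <- function(from, to) {
  stopifnot(nrow(from) == nrow(to), ncol(from) == 3L, ncol(to) == 3L)
  A <- sweep(as.matrix(from), 2, colMeans(from))
  B <- sweep(as.matrix(to), 2, colMeans(to))
  s <- svd(crossprod(A, B))
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

#' Construct the reference body frame of a subunit (or subunit pair)
#'
#' The filament-frame axes: `d3` points along the filament (from the
#' bottom- to the top-neighbor center of mass), `d2` is the component of
#' the membrane normal perpendicular to `d3`, and `d1 = d3 x d2`. The
#' frame is orthonormal and right-handed.
#'
#' @param comMinus,comPlus centers of mass (length-3) of the bottom and top
#'   units defining the filament direction.
#' @param membraneNormal direction perpendicular to the membrane plane
#'   (pointing away from the membrane).
#' @return 3 x 3 matrix with columns `d1`, `d2`, `d3`.
#' @export
referenceTriad <- function(comMinus, comPlus, membraneNormal = c(0, 0, 1)) {
  d3 <- comPlus - comMinus
  d3 <- d3 / sqrt(sum(d3^2))
  d2 <- membraneNormal - sum(membraneNormal * d3) * d3
  n2 <- sqrt(sum(d2^2))
  if (n2 < 1e-8) stop("membraneNormal is parallel to the filament axis")
  d2 <- d2 / n2
  d1 <- c(d3[2] * d2[3] - d3[3] * d2[2],
          d3[3] * d2[1] - d3[1] * d2[3],
          d3[1] * d2[2] - d3[2] * d2[1])
  cbind(d1 = d1, d2 = d2, d3 = d3)
}

#' Body frame of a subunit in a trajectory frame
#'
#' Superposes the reference copy of the subunit onto its coordinates in
#' `frame` (rotation part of the least-squares rigid fit) and carries the
#' reference triad along: the returned triad is `R %*% referenceTriad`
#' where `R` is the Kabsch rotation. Atom correspondence is by `resid`
#' within the subunit.
#'
#' @param frame a [StructureFrame-class].
#' @param subunit subunit label.
#' @param reference the reference [StructureFrame-class] (e.g. the crystal
#'   structure) in which `refTriad` was defined.
#' @param refTriad 3 x 3 reference triad (columns d1, d2, d3), e.g. from
#'   [referenceTriad()].
#' @return list with `triad` (3 x 3, columns d1-d3) and `origin` (subunit
#'   centroid in `frame`).
#' @export
subunitTriad <- function(frame, subunit, reference, refTriad) {
  stopifnot(is(frame, "StructureFrame"), is(reference, "StructureFrame"))
  cur <- frame@atoms[frame@atoms$subunit == subunit, , drop = FALSE]
  ref <- reference@atoms[reference@atoms$subunit == subunit, , drop = FALSE]
  if (!nrow(cur) || !nrow(ref)) stop("no atoms for subunit '", subunit, "'")
  cur <- cur[order(cur$resid), ]
  ref <- ref[order(ref$resid), ]
  if (!identical(cur$resid, ref$resid))
    stop("frame and reference atoms do not match for subunit '", subunit, "'")
  R <- kabschRotation(ref[, c("x", "y", "z")], cur[, c("x", "y", "z")])
  triad <- R %*% refTriad
  colnames(triad) <- c("d1", "d2", "d3")
  list(triad = triad, origin = colMeans(cur[, c("x", "y", "z")]))
}

## Rotation about one body axis (axis index in the d-basis), angle radians.
.axisRot <- function(axis, ang) {
  c2 <- cos(ang); s2 <- sin(ang)
  switch(axis,
         matrix(c(1, 0, 0, 0, c2, s2, 0, -s2, c2), 3, 3),   # d1
         matrix(c(c2, 0, -s2, 0, 1, 0, s2, 0, c2), 3, 3),   # d2
         matrix(c(c2, s2, 0, -s2, c2, 0, 0, 0, 1), 3, 3))   # d3
}

#' Compose a bend/twist rotation from Euler angles
#'
#' Builds `R = R_d1(theta1) %*% R_d2(theta2) %*% R_d3(theta3)` in the body
#' frame: the twist about the filament axis `d3` is applied first, then the
#' in-plane bend about `d2`, then the bend toward the membrane about `d1`.
#' This is the documented convention that [eulerBendTwist()] inverts.
#'
#' @param theta1,theta2,theta3 Euler angles, degrees.
#' @return 3 x 3 rotation matrix (body-frame coordinates).
#' @export
composeBendTwist <- function(theta1, theta2, theta3) {
  .axisRot(1L, .deg2rad(theta1)) %*% .axisRot(2L, .deg2rad(theta2)) %*%
    .axisRot(3L, .deg2rad(theta3))
}

#' Euler bend and twist angles between two subunit frames
#'
#' Expresses the rotation carrying the bottom (minus) triad onto the top
#' (plus) triad in the bottom body frame and decomposes it as
#' `R = R_d1(theta1) R_d2(theta2) R_d3(theta3)` (see
#' [composeBendTwist()]). `theta3` is the twist about the filament axis
#' (positive = left-handed with the package's generators), `theta2` the
#' bend parallel to the membrane plane, `theta1` the bend toward the
#' membrane. Supplying the crystal-structure decomposition as `refRelative`
#' zeroes the angles there, so the crystal pair reports `(0, 0, 0)`.
#'
#' @param triadMinus,triadPlus 3 x 3 triads (columns d1-d3) of the bottom
#'   and top units, e.g. from [subunitTriad()].
#' @param refRelative optional 3 x 3 relative rotation of the reference
#'   (crystal) pair to subtract; default identity.
#' @return named numeric `theta1`, `theta2`, `theta3` in degrees. A warning
#'   is raised near the gimbal singularity (`|theta2|` within 10 degrees of
#'   90).
#' @export
eulerBendTwist <- function(triadMinus, triadPlus, refRelative = diag(3)) {
  Rrel <- t(triadMinus) %*% triadPlus
  R <- t(refRelative) %*% Rrel
  th2 <- asin(pmin(1, pmax(-1, R[1, 3])))
  if (abs(.rad2deg(th2)) > 80)
    warning("theta2 within 10 degrees of the gimbal singularity; angles unreliable")
  th1 <- atan2(-R[2, 3], R[3, 3])
  th3 <- atan2(-R[1, 2], R[1, 1])
  c(theta1 = .rad2deg(th1), theta2 = .rad2deg(th2), theta3 = .rad2deg(th3))
}

#' Solvent-accessible surface area (rolling probe)
#'
#' Shrake-Rupley style numerical SASA: each atom's sphere is extended by
#' the probe radius and covered with a deterministic golden-spiral point
#' set; points falling inside any neighboring extended sphere are
#' inaccessible. The default probe radius 0.14 nm is the standard water
#' radius.
#'
#' @param xyz n x 3 atom coordinates, nm.
#' @param radii atom van der Waals radii, nm (recycled).
#' @param probe probe radius, nm.
#' @param nPoints sphere sample points per atom.
#' @return total accessible area, nm^2, with per-atom areas as attribute
#'   `"perAtom"`.
#' @export
sasa <- function(xyz, radii, probe = 0.14, nPoints = 960L) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, nPoints >= 12L)
  radii <- rep_len(radii, nrow(xyz))
  ## exactly coincident identical atoms are one atom, not mutual occluders
  dup <- duplicated(cbind(xyz, radii))
  xyz <- xyz[!dup, , drop = FALSE]
  radii <- radii[!dup]
  n <- nrow(xyz)
  ext <- radii + probe
  S <- .spherePoints(nPoints)
  per <- numeric(n)
  for (i in seq_len(n)) {
    P <- sweep(S * ext[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, nPoints)
    for (j in seq_len(n)) {
      if (j == i) next
      dd <- sum((xyz[i, ] - xyz[j, ])^2)
      if (dd >= (ext[i] + ext[j])^2) next
      dj2 <- (P[, 1] - xyz[j, 1])^2 + (P[, 2] - xyz[j, 2])^2 +
        (P[, 3] - xyz[j, 3])^2
      acc <- acc & (dj2 >= ext[j]^2)
      if (!any(acc)) break
    }
    per[i] <- 4 * pi * ext[i]^2 * sum(acc) / nPoints
  }
  out <- sum(per)
  attr(out, "perAtom") <- per
  out
}

## Deterministic golden-spiral points on the unit sphere.
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Buried surface area between two molecules
#'
#' `(A1 + A2 - A12) / 2`: half the solvent-accessible area lost when the
#' two molecules are in contact, the standard interface-size proxy. Small
#' negative values arising from point-sampling noise are clipped to zero
#' with a warning.
#'
#' @param xyzA,xyzB coordinate matrices (n x 3, nm) of the two molecules.
#' @param radiiA,radiiB van der Waals radii, nm.
#' @param probe probe radius, nm.
#' @param nPoints sphere sample points per atom.
#' @return buried area, nm^2.
#' @export
buriedSASA <- function(xyzA, radiiA, xyzB, radiiB, probe = 0.14,
                       nPoints = 960L) {
  a1 <- as.numeric(sasa(xyzA, radiiA, probe, nPoints))
  a2 <- as.numeric(sasa(xyzB, radiiB, probe, nPoints))
  a12 <- as.numeric(sasa(rbind(as.matrix(xyzA), as.matrix(xyzB)),
                         c(rep_len(radiiA, nrow(as.matrix(xyzA))),
                           rep_len(radiiB, nrow(as.matrix(xyzB)))),
                         probe, nPoints))
  out <- (a1 + a2 - a12) / 2
  if (out < 0) {
    if (out < -1e-6 * max(a1, a2))
      warning(sprintf("buried SASA slightly negative (%.3g nm^2); clipping to 0", out))
    out <- 0
  }
  out
}

#' Curvature of a membrane patch from leaflet atom positions
#'
#' Fits a second-order polynomial surface
#' `z = a x^2 + b x y + c y^2 + d x + e y + f` to the point cloud in its
#' principal-axes frame (normal = direction of least variance) and returns
#' the principal curvature of largest magnitude at the center of the fitted
#' surface. The sign convention is set by `proteinSide`: positive curvature
#' means the membrane bends toward the protein.
#'
#' @param points n x 3 matrix of leaflet atom positions, nm.
#' @param proteinSide optional length-3 reference point on the protein side
#'   of the membrane, used to orient the surface normal. Without it the
#'   sign of the result is arbitrary up to normal orientation.
#' @return signed curvature, nm^-1.
#' @export
membraneCurvature <- function(points, proteinSide = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, nrow(points) >= 6L)
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  eg <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  normal <- eg$vectors[, 3L]
  if (!is.null(proteinSide) && sum((proteinSide - ctr) * normal) < 0)
    normal <- -normal
  u <- eg$vectors[, 1L]
  v <- normal[c(2, 3, 1)] * u[c(3, 1, 2)] - normal[c(3, 1, 2)] * u[c(2, 3, 1)]
  ## local frame (u, v, normal): z along the oriented normal
  x <- as.numeric(X %*% u); y <- as.numeric(X %*% v)
  z <- as.numeric(X %*% normal)
  fit <- lm(z ~ I(x^2) + I(x * y) + I(y^2) + x + y)
  cf <- coef(fit)
  a <- cf[["I(x^2)"]]; b <- cf[["I(x * y)"]]; cc <- cf[["I(y^2)"]]
  d <- cf[["x"]]; e <- cf[["y"]]
  w <- sqrt(1 + d^2 + e^2)
  II <- matrix(c(2 * a, b, b, 2 * cc), 2, 2) / w
  I1 <- matrix(c(1 + d^2, d * e, d * e, 1 + e^2), 2, 2)
  kap <- eigen(solve(I1, II), only.values = TRUE)$values
  kap <- Re(kap)
  kap[which.max(abs(kap))]
}
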