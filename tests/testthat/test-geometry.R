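## small helpers for constructing rotations independently of the package
rotAxis <- function(axis, deg) {
  a <- deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * cos(a) + sin(a) * ux + (1 - cos(a)) * tcrossprod(u)
}

squareCenters <- function() {
  rbind(IA = c(0, 0, 0), IB = c(0, 1, 0), IIA = c(1, 0, 0), IIB = c(1, 1, 0))
}

test_that("subdomain centers reduce to atom positions and midpoints in degenerate cases", {
  one <- data.frame(x = c(0, 1, 2, 3), y = 0, z = 0, radius = 0.17,
                    subunit = "A", subdomain = c("IA", "IB", "IIA", "IIB"),
                    resid = 9:12)
  fr <- structureFrame(one)
  expect_equal(unname(subdomainCenters(fr, "A")[, "x"]), c(0, 1, 2, 3))

  two <- do.call(rbind, lapply(1:4, function(k)
    data.frame(x = k + c(-0.5, 0.5), y = c(2, -2), z = 0, radius = 0.17,
               subunit = "A", subdomain = c("IA", "IB", "IIA", "IIB")[k],
               resid = 2 * k + 8:9)))
  ctr <- subdomainCenters(structureFrame(two), "A")
  expect_equal(unname(ctr[, "x"]), 1:4 + 0)
  expect_equal(unname(ctr[, "y"]), rep(0, 4))
})

test_that("subdomain centers equal an independent centroid computation and respect mass weighting", {
  set.seed(101)
  at <- data.frame(x = rnorm(40), y = rnorm(40), z = rnorm(40), radius = 0.17,
                   subunit = "A",
                   subdomain = rep(c("IA", "IB", "IIA", "IIB"), each = 10),
                   resid = 1:40 + 8, mass = runif(40, 1, 16))
  fr <- structureFrame(at)
  ctr <- subdomainCenters(fr, "A")
  for (d in rownames(ctr)) {
    sub <- at[at$subdomain == d, ]
    expect_equal(unname(ctr[d, ]), c(mean(sub$x), mean(sub$y), mean(sub$z)))
  }
  ctrM <- subdomainCenters(fr, "A", massWeighted = TRUE)
  sub <- at[at$subdomain == "IB", ]
  expect_equal(unname(ctrM["IB", 1]), sum(sub$mass * sub$x) / sum(sub$mass))
  ## amphipathic-helix atoms (label none) never contribute
  at2 <- rbind(at, data.frame(x = 100, y = 100, z = 100, radius = 0.17,
                              subunit = "A", subdomain = "none", resid = 1,
                              mass = 10))
  expect_equal(subdomainCenters(structureFrame(at2), "A"), ctr)
  at3 <- at[at$subdomain != "IIB", ]
  expect_error(subdomainCenters(structureFrame(at3), "A"), "IIB")
})

test_that("opening angle: right angles, collinear degeneracies, and the explicit dot-product formula", {
  expect_equal(openingAngle(squareCenters()), 90)
  lin <- rbind(IA = c(0, 0, 0), IB = c(-1, 0, 0), IIA = c(1, 0, 0),
               IIB = c(2, 0, 0))
  ## at IIA: angle(IIB-IIA, IA-IIA) = 180; at IA: angle(IB-IA, IIA-IA) = 180
  expect_equal(openingAngle(lin), 180)
  set.seed(7)
  for (i in 1:5) {
    ctr <- squareCenters() + matrix(rnorm(12, sd = 0.3), 4, 3)
    ang <- function(u, v) 180 / pi *
      acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
    expected <- (ang(ctr["IIB", ] - ctr["IIA", ], ctr["IA", ] - ctr["IIA", ]) +
                   ang(ctr["IB", ] - ctr["IA", ], ctr["IIA", ] - ctr["IA", ])) / 2
    expect_equal(openingAngle(ctr), expected)
  }
})

test_that("dihedral angle: zero when coplanar, recovers a planted fold about the IIA-IA axis", {
  expect_equal(dihedralAngle(squareCenters()), 0, tolerance = 1e-12)
  for (alpha in c(5, 20, 45)) {
    ctr <- squareCenters()
    ## fold IIB out of plane about the IA-IIA (x) axis
    R <- rotAxis(c(1, 0, 0), alpha)
    ctr["IIB", ] <- as.numeric(R %*% ctr["IIB", ])
    expect_equal(dihedralAngle(ctr), alpha, tolerance = 1e-9)
  }
})

test_that("angle observables are invariant to global rigid-body motion", {
  set.seed(11)
  ctr <- squareCenters() + matrix(rnorm(12, sd = 0.2), 4, 3)
  R <- rotAxis(c(1, 2, 3), 33)
  moved <- t(R %*% t(ctr)) + matrix(rep(c(5, -2, 7), each = 4), 4, 3)
  rownames(moved) <- rownames(ctr)
  expect_equal(openingAngle(moved), openingAngle(ctr), tolerance = 1e-9)
  expect_equal(dihedralAngle(moved), dihedralAngle(ctr), tolerance = 1e-9)
})

test_that("subunit triads follow planted rotations and ignore translations", {
  pair <- genRigidPair(0, 0, 0, seed = 1)
  ref <- pair$reference
  D <- pair$refTriad
  same <- subunitTriad(ref, "minus", ref, D)
  expect_equal(same$triad, D, tolerance = 1e-10)

  R <- rotAxis(c(0.3, -1, 0.5), 25)
  at <- ref@atoms
  rot <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at$x <- rot[, 1]; at$y <- rot[, 2]; at$z <- rot[, 3]
  tri <- subunitTriad(structureFrame(at), "minus", ref, D)
  expect_equal(tri$triad, R %*% D, tolerance = 1e-8)

  at2 <- ref@atoms
  at2$x <- at2$x + 4; at2$y <- at2$y - 3
  tr2 <- subunitTriad(structureFrame(at2), "minus", ref, D)
  expect_equal(tr2$triad, D, tolerance = 1e-10)
  expect_equal(as.numeric(tr2$origin - same$origin), c(4, -3, 0),
               tolerance = 1e-10)
})

test_that("Euler decomposition recovers planted bend and twist angles", {
  D <- referenceTriad(c(0, 0, 0), c(0, 0, 5), c(0, 1, 0))
  ## orthonormality of the constructed triad
  expect_equal(crossprod(D), diag(3), tolerance = 1e-12, ignore_attr = TRUE)

  expect_equal(unname(eulerBendTwist(D, D)), c(0, 0, 0))

  ## pure twist about d3
  Rw <- D %*% composeBendTwist(0, 0, 10) %*% t(D)
  ang <- eulerBendTwist(D, Rw %*% D)
  expect_equal(unname(ang), c(0, 0, 10), tolerance = 1e-6)

  ## composite planted rotations recovered under the documented order
  set.seed(13)
  for (i in 1:10) {
    tgt <- runif(3, -20, 20)
    Rw <- D %*% composeBendTwist(tgt[1], tgt[2], tgt[3]) %*% t(D)
    got <- eulerBendTwist(D, Rw %*% D)
    expect_equal(unname(got), tgt, tolerance = 1e-6)
  }

  ## order effects are below 0.5 degrees at small angles: composing in the
  ## reversed order still recovers within 0.5 degrees
  Rrev <- D %*% (composeBendTwist(0, 0, 3) %*% composeBendTwist(5, 0, 0)) %*% t(D)
  got <- eulerBendTwist(D, Rrev %*% D)
  expect_equal(unname(got), c(5, 0, 3), tolerance = 0.5 / 5)

  ## crystal-reference subtraction zeroes the reference pair
  refRel <- composeBendTwist(2, -1, 4)
  expect_equal(unname(eulerBendTwist(D, D %*% refRel, refRelative = refRel)),
               c(0, 0, 0), tolerance = 1e-9)

  expect_warning(eulerBendTwist(D, D %*% composeBendTwist(0, 85, 0)),
                 "gimbal")
})

test_that("planted pair rotations survive the full triad pipeline, with and without noise", {
  pair <- genRigidPair(0, 0, 10, seed = 3)
  triMinus <- subunitTriad(pair$frame, "minus", pair$reference, pair$refTriad)
  triPlus <- subunitTriad(pair$frame, "plus", pair$reference, pair$refTriad)
  ang <- eulerBendTwist(triMinus$triad, triPlus$triad)
  expect_equal(unname(ang), c(0, 0, 10), tolerance = 1e-6)

  pairN <- genRigidPair(4, -2, 8, noise = 0.05, seed = 5)
  triM <- subunitTriad(pairN$frame, "minus", pairN$reference, pairN$refTriad)
  triP <- subunitTriad(pairN$frame, "plus", pairN$reference, pairN$refTriad)
  angN <- eulerBendTwist(triM$triad, triP$triad)
  expect_equal(unname(angN), c(4, -2, 8), tolerance = 0.5 / 8)
})

test_that("spherical SASA values match closed forms", {
  a1 <- sasa(matrix(c(0, 0, 0), 1), radii = 0.2)
  expect_equal(as.numeric(a1), 4 * pi * 0.34^2, tolerance = 0.01)

  ## exactly duplicated atoms count once
  a2 <- sasa(rbind(c(0, 0, 0), c(0, 0, 0)), radii = 0.2)
  expect_equal(as.numeric(a2), as.numeric(a1))

  ## two overlapping spheres: spherical-cap closed form
  R <- 0.34; d <- 0.4
  a3 <- sasa(rbind(c(0, 0, 0), c(d, 0, 0)), radii = 0.2)
  expect_equal(as.numeric(a3), 2 * (4 * pi * R^2 - 2 * pi * R * (R - d / 2)),
               tolerance = 0.02)
})

test_that("adding a neighbor never increases any atom's accessible area", {
  set.seed(17)
  xyz <- matrix(rnorm(30, sd = 0.4), 10, 3)
  before <- attr(sasa(xyz, 0.17), "perAtom")
  after <- attr(sasa(rbind(xyz, c(0.1, 0, 0)), 0.17), "perAtom")[1:10]
  expect_true(all(after <= before + 1e-12))
})

test_that("buried SASA: zero when separated, symmetric, and consistent with the cap formula", {
  A <- matrix(c(0, 0, 0), 1); B <- matrix(c(50, 0, 0), 1)
  expect_identical(buriedSASA(A, 0.2, B, 0.2), 0)

  B2 <- matrix(c(0.4, 0, 0), 1)
  ab <- buriedSASA(A, 0.2, B2, 0.2)
  ba <- buriedSASA(B2, 0.2, A, 0.2)
  expect_identical(ab, ba)
  R <- 0.34
  expect_equal(ab, 2 * pi * R * (R - 0.4 / 2), tolerance = 0.02)
})

test_that("membrane curvature: plane gives zero, planted cylinders are recovered, sign follows the protein side", {
  flat <- genMembraneCloud(curvature = 0, seed = 1)
  expect_lt(abs(membraneCurvature(flat$points, flat$proteinSide)), 1e-10)

  cyl <- genMembraneCloud(curvature = 2.5e-3, seed = 2)
  k <- membraneCurvature(cyl$points, cyl$proteinSide)
  expect_equal(k, 2.5e-3, tolerance = 0.05)

  ## flipping the reference side flips the sign
  kFlip <- membraneCurvature(cyl$points, -cyl$proteinSide)
  expect_equal(kFlip, -k, tolerance = 1e-9)

  noisy <- genMembraneCloud(curvature = 2.5e-3, noise = 0.2, seed = 3)
  kN <- membraneCurvature(noisy$points, noisy$proteinSide)
  expect_equal(kN, 2.5e-3, tolerance = 0.10)
})
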