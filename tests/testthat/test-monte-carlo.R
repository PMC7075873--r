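quickCfg <- function(...) mcConfig(maxSteps = 2e5, replicates = 2L, ...)

test_that("minimizer reaches the known global minimum when no term is frustrated", {
  p <- filamentParams(k0 = 0, omega0 = 0, V = 4)
  res <- metropolisMinimize(p, L = 100, quickCfg(seed = 5))
  expect_lt(res@energy, 1e-6)
  expect_lt(max(abs(twistProfile(res@finalState))), 0.02)
  ## theta is a neutral direction here; it should not have wandered far
  expect_lt(abs(mean(tiltProfile(res@finalState)) - pi / 2), 0.2)
})

test_that("runs are bit-identical for a fixed seed and energy matches the final state exactly", {
  p <- filamentParams(r = 400)
  a <- metropolisMinimize(p, L = 150, quickCfg(seed = 42))
  b <- metropolisMinimize(p, L = 150, quickCfg(seed = 42))
  expect_identical(a@energy, b@energy)
  expect_identical(tiltProfile(a@finalState), tiltProfile(b@finalState))
  expect_identical(a@energyTrace, b@energyTrace)
  expect_identical(a@energy, hamiltonianEnergy(a@finalState, a@params))
  c2 <- metropolisMinimize(p, L = 150, quickCfg(seed = 43))
  expect_false(identical(a@energy, c2@energy))
})

test_that("energy trace has a non-increasing running minimum and sane acceptance", {
  p <- filamentParams(r = 400)
  res <- metropolisMinimize(p, L = 200, quickCfg(seed = 2))
  expect_true(all(diff(cummin(res@energyTrace)) <= 0))
  expect_gt(res@acceptedFraction, 0.15)
  expect_lt(res@acceptedFraction, 0.9)
})

test_that("higher temperature leaves the Metropolis phase at higher energy", {
  p <- filamentParams(r = 400)
  cold <- metropolisMinimize(p, 150, mcConfig(maxSteps = 1e5, temperature = 1, seed = 3, polish = FALSE))
  hot <- metropolisMinimize(p, 150, mcConfig(maxSteps = 1e5, temperature = 50, seed = 3, polish = FALSE))
  expect_gt(tail(hot@energyTrace, 1), tail(cold@energyTrace, 1))
})

test_that("near-flat Monte Carlo energies agree with the analytical solution within 5 percent", {
  p <- filamentParams(r = 10000)
  pFlat <- filamentParams()
  prof <- energyLengthCurve(pFlat, LMax = 450)
  for (L in c(40, 120, 250, 400)) {
    res <- metropolisMinimize(p, L, quickCfg(seed = 7 + L))
    eA <- approx(prof@L, prof@E, xout = L)$y
    expect_equal(res@energy, eA, tolerance = 0.05)
    ## the MC minimum cannot undercut the continuum minimum by more than
    ## discretization tolerance
    expect_gt(res@energy, eA * 0.95)
  }
})

test_that("replicated energy-length curves have small replicate scatter and record it", {
  p <- filamentParams(r = 400)
  cfg <- mcConfig(maxSteps = 2e5, replicates = 3L, seed = 21)
  prof <- energyLengthCurveMC(p, LGrid = seq(100, 300, by = 50), cfg)
  expect_s4_class(prof, "EnergyProfile")
  expect_identical(prof@source, "mc")
  expect_true(all(prof@sd / prof@E < 0.05))
  expect_true(all(diff(prof@E) > 0))
})

test_that("smaller membrane radius lowers the free energy at fixed length", {
  cfg <- quickCfg(seed = 31)
  Es <- vapply(c(200, 400, 10000), function(r)
    metropolisMinimize(filamentParams(r = r), L = 200, cfg, seed = 31)@energy, 0)
  expect_true(all(diff(Es) > 0))  # E(r=200) < E(r=400) < E(r=10000)
})

test_that("limit length on a near-flat cylinder matches the flat analytical value within 10 percent", {
  p <- filamentParams(r = 10000)
  cfg <- mcConfig(maxSteps = 3e5, replicates = 2L, seed = 11)
  LsMC <- limitLengthMC(p, cfg, LMax = 300, LStep = 25)
  LsAn <- limitLength(energyLengthCurve(filamentParams(), LMax = 400), 2)
  expect_equal(as.numeric(LsMC), as.numeric(LsAn), tolerance = 0.10)
})

test_that("growth is unbounded on a sufficiently narrow cylinder", {
  ## at r = 60 nm the geometric twist relief keeps dE/dL below mu0
  p <- filamentParams(r = 60)
  cfg <- mcConfig(maxSteps = 3e5, replicates = 2L, seed = 13)
  expect_true(is.infinite(limitLengthMC(p, cfg, LMax = 600, LStep = 60)))
})

test_that("larger intrinsic twist shortens the limit length (3-point sweep)", {
  cfg <- mcConfig(maxSteps = 3e5, replicates = 2L, seed = 17)
  Ls <- vapply(c(9.5, 10.3, 12), function(tw)
    as.numeric(limitLengthMC(filamentParams(omega0 = twistRate(tw), r = 10000),
                             cfg, LMax = 400, LStep = 25)), 0)
  expect_true(all(diff(Ls) < 0))
})

test_that("pitch angle responds to twist and curvature as the energy balance dictates", {
  cfg <- quickCfg()
  ## no intrinsic twist: nothing drives tilt away from circumferential
  res0 <- metropolisMinimize(filamentParams(omega0 = 0, k0 = 0, r = 400),
                             L = 300, cfg, seed = 23)
  expect_lt(pitchAngleSummary(res0)[["deviation"]], 8)

  ## larger twist: orientation deviates more from 90 degrees
  devs <- vapply(c(4.5, 10.3), function(tw) pitchAngleSummary(
    metropolisMinimize(filamentParams(omega0 = twistRate(tw), r = 400),
                       L = 300, cfg, seed = 29))[["deviation"]], 0)
  expect_gt(devs[2], devs[1])

  ## larger intrinsic curvature pulls the pitch back toward 90 degrees
  devK <- vapply(c(2.3e-3, 2.3e-2), function(k0) pitchAngleSummary(
    metropolisMinimize(filamentParams(k0 = k0, r = 400), L = 300, cfg,
                       seed = 37))[["deviation"]], 0)
  expect_lt(devK[2], devK[1])
})

test_that("C moves the pitch but not the limit length; K and V move the limit length but not the pitch", {
  cfg <- quickCfg()
  pitchOf <- function(p) pitchAngleSummary(
    metropolisMinimize(filamentParams(C = p@C, K = p@K, V = p@V, k0 = p@k0,
                                      omega0 = p@omega0, mu0 = p@mu0, r = 400),
                       L = 300, cfg, seed = 41))[["pitch"]]
  LsOf <- function(p) as.numeric(limitLength(energyLengthCurve(p, LMax = 600), p@mu0))
  base <- filamentParams()

  pC <- filamentParams(C = 4 * base@C)
  expect_gt(abs(pitchOf(pC) - pitchOf(base)), 2)       # pitch responds to C
  expect_equal(LsOf(pC), LsOf(base), tolerance = 0.05) # limit length does not

  pK <- filamentParams(K = 1.5 * base@K)
  pV <- filamentParams(V = 1.5 * base@V)
  expect_gt(abs(LsOf(pK) - LsOf(base)) / LsOf(base), 0.10)
  expect_gt(abs(LsOf(pV) - LsOf(base)) / LsOf(base), 0.10)
  expect_lt(abs(pitchOf(pK) - pitchOf(base)), 3)
  expect_lt(abs(pitchOf(pV) - pitchOf(base)), 3)
})

test_that("non-convergence is reported, not hidden", {
  p <- filamentParams(r = 400)
  res <- metropolisMinimize(p, L = 300,
                            mcConfig(maxSteps = 2e4, convergenceWindow = 2e4,
                                     seed = 3, polish = FALSE))
  expect_false(res@converged)
})
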