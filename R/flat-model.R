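## Analytical flat-membrane solution. Minimizing the flat Hamiltonian over
## psi(s) with free ends gives a first integral
##   psi'(s)^2 = omega0^2 + (2V/K) (sin^2(psi/2) - sin^2(psiM/2)),
## with boundary conditions psi(+-L/2) = +-psiM (antisymmetric about s = 0)
## and psi'(+-L/2) = omega0. Changing variables from s to psi turns length
## and energy into quadratures over psi that the functions below evaluate
## adaptively; this is the normative path. The equivalent incomplete
## elliptic-integral closed form is kept as an internal cross-check only,
## because its second argument is convention-sensitive.

.psiRate <- function(psi, psiM, params) {
  sqrt(params@omega0^2 +
         2 * params@V / params@K * (sin(psi / 2)^2 - sin(psiM / 2)^2))
}

#' Largest admissible boundary twist amplitude on a flat membrane
#'
#' The boundary twist amplitude `psiM` of a finite filament is limited by
#' the twist boundary-layer scale `lm = sqrt(K / 2V) * omega0`: for
#' `sin(psiM / 2) -> min(lm, 1)` the interior twist rate vanishes and the
#' filament length diverges (the filament develops a fully untwisted, bound
#' interior with twisted end layers).
#'
#' @param params a [FilamentParams-class] with `V > 0`, `omega0 > 0`.
#' @return the supremum of admissible `psiM`, radians.
#' @export
psiMBound <- function(params) {
  stopifnot(is(params, "FilamentParams"))
  if (params@V <= 0 || params@omega0 <= 0)
    stop("psiMBound requires V > 0 and omega0 > 0")
  lm <- sqrt(params@K / (2 * params@V)) * params@omega0
  2 * asin(min(1, lm))
}

#' Filament length and energy at a given boundary twist amplitude
#'
#' On a flat membrane the energy-minimizing twist profile of a filament is
#' parameterized by its boundary twist amplitude `psiM`: the filament
#' untwists in its interior to gain binding energy and confines twist to
#' boundary layers of scale `sqrt(K / 2V)`. `flatTwistLength` returns the
#' length of the filament whose optimal profile reaches `+-psiM` at its
#' ends; `flatTwistEnergy` returns the corresponding total energy,
#' including the rest-curvature term `e0 * L` and the residual binding
#' penalty `V sin^2(psiM/2) * L`.
#'
#' Only the `n = 0` branch (no full 360-degree twist walls) is validated;
#' `n > 0` is accepted for completeness.
#'
#' @param psiM boundary twist amplitude, radians; must lie in
#'   `[0, psiMBound(params))`.
#' @param params a [FilamentParams-class] with `V > 0`, `omega0 > 0`.
#' @param n number of full twist repeats (default 0).
#' @return length in nm (`flatTwistLength`) or total energy in kBT
#'   (`flatTwistEnergy`).
#' @examples
#' p <- filamentParams()
#' flatTwistLength(1, p)
#' flatTwistEnergy(1, p)
#' @export
flatTwistLength <- function(psiM, params, n = 0) {
  stopifnot(is(params, "FilamentParams"), psiM >= 0, n >= 0)
  if (psiM == 0 && n == 0) return(0)
  bound <- psiMBound(params)
  if (psiM >= bound)
    stop(sprintf(paste0("psiM = %.6g is at or beyond the singular bound %.6g;",
                        " the filament length diverges there"), psiM, bound))
  main <- if (psiM > 0)
    2 * integrate(function(p) 1 / .psiRate(p, psiM, params), 0, psiM,
                  rel.tol = 1e-10, subdivisions = 500L)$value
  else 0
  if (n > 0)
    main <- main + integrate(function(p) 1 / .psiRate(p, psiM, params),
                             psiM, psiM + 2 * n * pi, rel.tol = 1e-10,
                             subdivisions = 500L)$value
  main
}

#' @rdname flatTwistLength
#' @export
flatTwistEnergy <- function(psiM, params, n = 0) {
  stopifnot(is(params, "FilamentParams"), psiM >= 0, n >= 0)
  L <- flatTwistLength(psiM, params, n)
  elastic <- if (psiM > 0)
    2 * integrate(function(p) .psiRate(p, psiM, params), 0, psiM,
                  rel.tol = 1e-10, subdivisions = 500L)$value
  else 0
  if (n > 0)
    elastic <- elastic + integrate(function(p) .psiRate(p, psiM, params),
                                   psiM, psiM + 2 * n * pi, rel.tol = 1e-10,
                                   subdivisions = 500L)$value
  params@K * elastic - 2 * params@K * params@omega0 * (psiM + n * pi) +
    params@V * sin(psiM / 2)^2 * L + e0(params) * L
}

## Closed-form route via incomplete elliptic integrals, parameter (m)
## convention; used only to cross-validate the quadrature path.
.flatTwistLengthElliptic <- function(psiM, params, n = 0) {
  lm2 <- params@K / (2 * params@V) * params@omega0^2
  denom <- 2 * lm2 + cos(psiM) - 1
  m <- -2 / denom
  ellF <- function(phi) integrate(function(t) 1 / sqrt(1 - m * sin(t)^2),
                                  0, phi, rel.tol = 1e-12)$value
  pre <- 4 * sqrt(2) / params@omega0 * sqrt(lm2 / denom)
  pre * ellF(psiM / 2) + if (n > 0) 2 * n * pre * ellF(pi / 2) else 0
}

#' Analytical energy-length curve on a flat membrane
#'
#' Sweeps the boundary twist amplitude over `(0, psiMBound(params))`,
#' evaluates length and energy by quadrature, resamples onto a strictly
#' increasing length grid and differentiates with centered differences on a
#' monotone spline fit. With `omega0 = 0` there is no twist frustration and
#' the curve is exactly linear with slope `e0`.
#'
#' @param params a [FilamentParams-class]; the membrane is treated as flat
#'   regardless of `params@r`.
#' @param LMax largest length on the grid, nm.
#' @param nGrid number of points of the resampled length grid.
#' @param nPsi number of boundary-amplitude samples of the parametric sweep.
#' @return an [EnergyProfile-class] with `source = "analytical"`.
#' @examples
#' prof <- energyLengthCurve(filamentParams(), LMax = 500)
#' limitLength(prof, 2)
#' @export
energyLengthCurve <- function(params, LMax = 2000, nGrid = 400, nPsi = 600) {
  stopifnot(is(params, "FilamentParams"), LMax > 0)
  Lgrid <- seq(LMax / nGrid, LMax, length.out = nGrid)
  if (params@omega0 == 0 || params@V == 0) {
    ## no twist frustration (omega0 = 0: psi stays 0) or no binding
    ## (V = 0: psi follows omega0 freely); either way E is exactly e0 * L
    slope <- e0(params)
    return(new("EnergyProfile", L = Lgrid, E = slope * Lgrid,
               dEdL = rep(slope, nGrid), psiM = rep(0, nGrid),
               sd = rep(NA_real_, nGrid), source = "analytical"))
  }
  bound <- psiMBound(params)
  ## concentrate samples near the singular bound, where L grows fastest
  frac <- 1 - exp(seq(log(1), log(1e-7), length.out = nPsi))
  psis <- bound * frac[frac > 0 & frac < 1]
  L <- vapply(psis, flatTwistLength, 0, params = params)
  keep <- L <= LMax * 1.05
  if (sum(keep) < 10L)
    keep <- seq_along(L) <= max(10L, sum(keep))
  psis <- psis[keep]; L <- L[keep]
  E <- vapply(psis, flatTwistEnergy, 0, params = params)
  o <- order(L)
  L <- L[o]; E <- E[o]; psis <- psis[o]
  mono <- c(TRUE, diff(L) > 0)
  if (!all(mono)) {
    message(sprintf("L(psiM) not strictly monotone; restricting to the monotone branch (%d of %d points)",
                    sum(mono), length(mono)))
    L <- L[mono]; E <- E[mono]; psis <- psis[mono]
  }
  Lgrid <- Lgrid[Lgrid >= min(L) & Lgrid <= max(L)]
  Efun <- splinefun(L, E, method = "monoH.FC")
  psiFun <- approxfun(L, psis, rule = 2)
  Eg <- Efun(Lgrid)
  h <- diff(Lgrid[1:2])
  dEdL <- (Efun(Lgrid + h / 2) - Efun(Lgrid - h / 2)) / h
  new("EnergyProfile", L = Lgrid, E = Eg, dEdL = dEdL, psiM = psiFun(Lgrid),
      sd = rep(NA_real_, length(Lgrid)), source = "analytical")
}

#' @rdname limitLength
#' @export
setMethod("limitLength", "EnergyProfile", function(profile, mu0) {
  d <- profile@dEdL - mu0
  if (all(is.na(d))) stop("profile has no dEdL values")
  up <- which(d[-1] >= 0 & d[-length(d)] < 0) + 1L
  hits <- if (d[1] >= 0) c(1L, up) else up
  if (!length(hits)) {
    res <- Inf
    attr(res, "crossings") <- 0L
    return(res)
  }
  if (length(hits) > 1L)
    message(sprintf("multiple dE/dL = mu0 crossings (near L = %s nm); returning the first",
                    paste(signif(profile@L[hits], 4), collapse = ", ")))
  i <- hits[1L]
  res <- if (i == 1L) profile@L[1L]
  else profile@L[i - 1L] + (profile@L[i] - profile@L[i - 1L]) *
    (-d[i - 1L]) / (d[i] - d[i - 1L])
  attr(res, "crossings") <- length(hits)
  res
})
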