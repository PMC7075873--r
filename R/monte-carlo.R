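#' Create a Metropolis minimizer configuration
#'
#' Defaults follow the study conditions: up to 1e7 steps, convergence
#' declared when the minimized (best-visited) energy improves by less than
#' 1 percent over the previous 1e4 steps, 20 independent replicates per
#' parameter set, temperature 1 kBT, segments of 5 nm (the monomer rise).
#'
#' @param maxSteps maximum Metropolis steps.
#' @param convergenceWindow steps per convergence check.
#' @param convergenceTol relative energy-fluctuation tolerance.
#' @param proposalAmplitude initial proposal half-width, radians.
#' @param replicates independent replicates.
#' @param seed base seed (replicate `k` runs with `seed + k`).
#' @param temperature Metropolis temperature, kBT.
#' @param segmentLength discretization segment length, nm.
#' @param polish run the deterministic quench after the Metropolis phase.
#' @return a validated [MCConfig-class].
#' @export
mcConfig <- function(maxSteps = 1e7, convergenceWindow = 1e4,
                     convergenceTol = 0.01, proposalAmplitude = 0.3,
                     replicates = 20L, seed = 1L, temperature = 1,
                     segmentLength = 5, polish = TRUE) {
  new("MCConfig", maxSteps = maxSteps, convergenceWindow = convergenceWindow,
      convergenceTol = convergenceTol, proposalAmplitude = proposalAmplitude,
      replicates = as.integer(replicates), seed = as.integer(seed),
      temperature = temperature, segmentLength = segmentLength,
      polish = polish)
}

.invr <- function(params) if (is.finite(params@r)) 1 / params@r else 0

## Deterministic quench: bounded BFGS on the discretized Hamiltonian with
## analytic gradients, theta constrained to [0, pi].
.quenchState <- function(theta, psi, ds, params) {
  n <- length(theta)
  invr <- .invr(params)
  fn <- function(x) .energyCpp(x[1:n], x[(n + 1):(2 * n)], ds, params@C,
                               params@K, params@V, params@k0, params@omega0,
                               invr)
  gr <- function(x) .energyGradCpp(x[1:n], x[(n + 1):(2 * n)], ds, params@C,
                                   params@K, params@V, params@k0,
                                   params@omega0, invr)
  fit <- optim(c(theta, psi), fn, gr, method = "L-BFGS-B",
               lower = c(rep(0, n), rep(-Inf, n)),
               upper = c(rep(pi, n), rep(Inf, n)),
               control = list(maxit = 500L, factr = 1e4))
  list(theta = fit$par[1:n], psi = fit$par[(n + 1):(2 * n)])
}

#' Metropolis minimization of a filament on a cylinder
#'
#' Minimizes the discretized Hamiltonian of a filament of length `L` on a
#' membrane cylinder of radius `params@r` (or a flat membrane when `r` is
#' infinite). Starting from the untwisted circumferential configuration
#' (`theta = 90` degrees, `psi = 0`), each Metropolis step perturbs one
#' randomly chosen node angle and accepts uphill moves with probability
#' `exp(-dE / kBT)`. The best-visited configuration is tracked and, when
#' `config@polish` is `TRUE`, refined by a deterministic quench (bounded
#' BFGS with analytic gradients) so the reported energy is a true local
#' minimum rather than a thermal average. Runs are bit-reproducible from
#' `seed`.
#'
#' @param params a [FilamentParams-class].
#' @param L filament length, nm.
#' @param config an [MCConfig-class]; `config@replicates` is ignored here
#'   (single run; see [energyLengthCurveMC()] for replicated sweeps).
#' @param seed seed for this run; defaults to `config@seed`.
#' @return an [MCResult-class]; `converged` is `FALSE` (never an error)
#'   when the fluctuation criterion was not met within `maxSteps`.
#' @examples
#' p <- filamentParams(r = 400)
#' res <- metropolisMinimize(p, L = 100, mcConfig(maxSteps = 2e5, seed = 7))
#' pitchAngleSummary(res)
#' @export
metropolisMinimize <- function(params, L, config = mcConfig(), seed = config@seed) {
  stopifnot(is(params, "FilamentParams"), is(config, "MCConfig"), L > 0)
  validObject(config)
  nSeg <- max(2L, round(L / config@segmentLength))
  ds <- L / nSeg
  n <- nSeg + 1L
  theta0 <- rep(pi / 2, n)
  psi0 <- rep(0, n)
  traceEvery <- max(1L, as.integer(config@convergenceWindow / 10))
  set.seed(seed)
  run <- .metropolisCpp(theta0, psi0, ds, params@C, params@K, params@V,
                        params@k0, params@omega0, .invr(params),
                        config@maxSteps, config@convergenceWindow,
                        config@convergenceTol, config@proposalAmplitude,
                        config@temperature, traceEvery)
  th <- run$theta; ps <- run$psi
  if (config@polish) {
    q <- .quenchState(th, ps, ds, params)
    th <- pmin(pi, pmax(0, q$theta)); ps <- q$psi
  }
  state <- filamentState(th, ps, segmentLength = ds)
  new("MCResult", finalState = state, params = params,
      energy = hamiltonianEnergy(state, params),
      energyTrace = run$trace, converged = run$converged,
      acceptedFraction = run$acceptedFraction, seed = as.integer(seed))
}

#' Monte Carlo energy-length curve
#'
#' Runs `config@replicates` independent Metropolis minimizations (seeds
#' `config@seed + 1, + 2, ...`, advanced across lengths) at every length of
#' `LGrid` and assembles the replicate-mean energies into an
#' [EnergyProfile-class] with centered-difference `dEdL` and the replicate
#' standard deviation. Non-converged replicates are excluded with a
#' message; if all replicates at some length fail to converge, an error is
#' raised.
#'
#' @param params a [FilamentParams-class].
#' @param LGrid strictly increasing filament lengths, nm.
#' @param config an [MCConfig-class].
#' @return an [EnergyProfile-class] with `source = "mc"`.
#' @export
energyLengthCurveMC <- function(params, LGrid, config = mcConfig()) {
  stopifnot(is(params, "FilamentParams"), length(LGrid) >= 2L,
            all(diff(LGrid) > 0))
  nRep <- config@replicates
  Emean <- Esd <- numeric(length(LGrid))
  seedCounter <- config@seed
  for (i in seq_along(LGrid)) {
    Es <- conv <- rep(NA_real_, nRep)
    for (k in seq_len(nRep)) {
      seedCounter <- seedCounter + 1L
      res <- metropolisMinimize(params, LGrid[i], config, seed = seedCounter)
      Es[k] <- res@energy
      conv[k] <- res@converged
    }
    if (!any(conv == 1)) {
      stop(sprintf("no replicate converged at L = %g nm", LGrid[i]))
    }
    if (any(conv == 0))
      message(sprintf("excluding %d non-converged replicate(s) at L = %g nm",
                      sum(conv == 0), LGrid[i]))
    Es <- Es[conv == 1]
    Emean[i] <- mean(Es)
    Esd[i] <- if (length(Es) > 1L) sd(Es) else 0
  }
  dEdL <- rep(NA_real_, length(LGrid))
  idx <- 2:(length(LGrid) - 1L)
  dEdL[idx] <- (Emean[idx + 1L] - Emean[idx - 1L]) / (LGrid[idx + 1L] - LGrid[idx - 1L])
  dEdL[1L] <- (Emean[2L] - Emean[1L]) / (LGrid[2L] - LGrid[1L])
  dEdL[length(LGrid)] <- (Emean[length(LGrid)] - Emean[length(LGrid) - 1L]) /
    (LGrid[length(LGrid)] - LGrid[length(LGrid) - 1L])
  new("EnergyProfile", L = LGrid, E = Emean, dEdL = dEdL,
      psiM = rep(NA_real_, length(LGrid)), sd = Esd, source = "mc")
}

#' Monte Carlo limit length
#'
#' Convenience wrapper: builds the Monte Carlo energy-length curve on a
#' uniform grid up to `LMax` and locates the `dE/dL = mu0` crossing with
#' [limitLength()]. `Inf` means unbounded growth up to `LMax`.
#'
#' @param params a [FilamentParams-class]; `params@mu0` is the threshold.
#' @param config an [MCConfig-class].
#' @param LMax largest length probed, nm.
#' @param LStep grid spacing, nm.
#' @return limit length in nm, or `Inf` (see [limitLength()]).
#' @export
limitLengthMC <- function(params, config = mcConfig(), LMax = 1000, LStep = 50) {
  prof <- energyLengthCurveMC(params, seq(LStep, LMax, by = LStep), config)
  limitLength(prof, params@mu0)
}

#' Mean pitch angle of a minimized filament
#'
#' Length-weighted mean of the tilt angle over segment midpoints, reported
#' in degrees together with its deviation from the circumferential
#' orientation (90 degrees).
#'
#' @param result an [MCResult-class] (or a [FilamentState-class]).
#' @return named numeric: `pitch` (degrees in `[0, 180]`) and `deviation`
#'   (`|pitch - 90|`).
#' @export
pitchAngleSummary <- function(result) {
  state <- if (is(result, "MCResult")) result@finalState else result
  stopifnot(is(state, "FilamentState"))
  th <- state@theta
  mid <- (th[-1] + th[-length(th)]) / 2  # equal-length segments
  pitch <- .rad2deg(mean(mid))
  c(pitch = pitch, deviation = abs(pitch - 90))
}

#' Interior pitch angle of a long membrane-bound filament
#'
#' For a filament much longer than its twist boundary layers, the interior
#' is uniformly bound (`psi = 0`) and tilted at the angle that balances the
#' normal-curvature frustration against the geometric twist relief of the
#' cylinder. This function minimizes that interior energy density over the
#' tilt angle and returns the resulting pitch; it is the boundary-layer-free
#' deterministic counterpart of [pitchAngleSummary()] on a Monte Carlo
#' result.
#'
#' @param params a [FilamentParams-class] with finite `r`.
#' @return named numeric as in [pitchAngleSummary()].
#' @export
interiorPitch <- function(params) {
  stopifnot(is(params, "FilamentParams"))
  if (!is.finite(params@r)) return(c(pitch = 90, deviation = 0))
  invr <- 1 / params@r
  dens <- function(th)
    0.5 * (params@C * (sin(th)^2 * invr - params@k0)^2 +
             params@K * (sin(2 * th) * invr / 2 + params@omega0)^2)
  ## the density can have two local minima (tilt toward vs. away from the
  ## twist-relieving direction): grid-scan first, then refine
  grid <- seq(0, pi, length.out = 721L)
  best <- grid[which.min(vapply(grid, dens, 0))]
  fit <- optimize(dens, interval = c(max(0, best - 0.02), min(pi, best + 0.02)))
  pitch <- .rad2deg(fit$minimum)
  c(pitch = pitch, deviation = abs(pitch - 90))
}
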