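#' Create a discretized filament state
#'
#' Angles are given at the `N + 1` boundary nodes of `N` segments of equal
#' length, so a state of total length `L` has `N = L / segmentLength`
#' segments. `psi` must be unwrapped (continuous across nodes).
#'
#' @param theta node tilt angles vs. the cylinder centerline, radians in
#'   `[0, pi]`.
#' @param psi node twist angles, radians (unwrapped).
#' @param segmentLength segment length, nm (default 5, the monomer rise).
#' @return a validated [FilamentState-class].
#' @examples
#' st <- filamentState(theta = rep(pi / 2, 21), psi = rep(0, 21))
#' filamentLength(st) # 100 nm
#' @export
filamentState <- function(theta, psi, segmentLength = 5) {
  new("FilamentState", segmentLength = segmentLength,
      theta = as.numeric(theta), psi = as.numeric(psi))
}

#' Elastic plus binding energy of a filament configuration
#'
#' Evaluates the discretized Hamiltonian of a chiral filament bound to the
#' inner surface of a rigid cylinder of radius `r`:
#' \deqn{E = \tfrac12 \sum_i \Delta s \Big[
#'   C\big(\sin^2\bar\theta_i / r - k_0\big)^2
#'   + C (\Delta\theta_i/\Delta s)^2
#'   + K\big(\Delta\psi_i/\Delta s - \sin 2\bar\theta_i/(2r) - \omega_0\big)^2
#'   + 2V \sin^2(\bar\psi_i/2) \Big]}
#' where the sum runs over the `N` segments, bars denote averages of the two
#' bounding nodes, and differences are between them. The four terms are the
#' normal-curvature frustration (the cylinder imposes curvature
#' \eqn{\sin^2\theta / r} against the preferred `k0`), tilt bending, twist
#' frustration (geometric torsion \eqn{\sin 2\theta/(2r)} plus elastic twist
#' against the preferred `omega0`), and the membrane binding potential,
#' which is fully recovered only at `psi = 0` (single binding face). On a
#' flat membrane (`r = Inf`) the two `1/r` terms drop out.
#'
#' @param state a [FilamentState-class].
#' @param params a [FilamentParams-class] (`r` is taken from it).
#' @return total energy in kBT.
#' @examples
#' p <- filamentParams(k0 = 0, omega0 = 0, V = 0)
#' st <- filamentState(rep(pi / 2, 11), rep(0, 11))
#' hamiltonianEnergy(st, p) # 0: straight, untwisted, no frustration
#' @export
hamiltonianEnergy <- function(state, params) {
  stopifnot(is(state, "FilamentState"), is(params, "FilamentParams"))
  validObject(state)
  if (state@segmentLength <= 0) stop("zero or negative segment length")
  th <- state@theta; ps <- state@psi
  if (!all(is.finite(th)) || !all(is.finite(ps)))
    stop("invalid state: non-finite angles")
  ds <- state@segmentLength
  invr <- if (is.finite(params@r)) 1 / params@r else 0
  thbar <- (th[-1] + th[-length(th)]) / 2
  psbar <- (ps[-1] + ps[-length(ps)]) / 2
  dth <- diff(th)
  dps <- diff(ps)
  dens <- params@C * (sin(thbar)^2 * invr - params@k0)^2 +
    params@C * (dth / ds)^2 +
    params@K * (dps / ds - sin(2 * thbar) * invr / 2 - params@omega0)^2 +
    2 * params@V * sin(psbar / 2)^2
  0.5 * sum(ds * dens)
}
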