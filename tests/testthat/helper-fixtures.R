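## Shared fixtures: wild-type parameters, smooth analytic filament states,
## and an independent brute-force minimizer of the flat discretized
## Hamiltonian used as the oracle for the analytical solution.

wtParams <- function(...) filamentParams(...)

## Smooth analytic state: theta(s) = pi/2 + a sin(2 pi s / L),
## psi(s) = b sin(pi s / L) + c s, sampled on N segments. Returns the state
## plus closures for the continuous profile and its exact derivatives.
smoothState <- function(L = 100, N = 400, a = 0.3, b = 0.4, c = 0.02,
                        segLen = L / N) {
  s <- seq(0, L, length.out = N + 1L)
  theta <- pi / 2 + a * sin(2 * pi * s / L)
  psi <- b * sin(pi * s / L) + c * s
  list(state = filamentState(theta, psi, segmentLength = segLen),
       theta = function(s) pi / 2 + a * sin(2 * pi * s / L),
       dtheta = function(s) a * 2 * pi / L * cos(2 * pi * s / L),
       psi = function(s) b * sin(pi * s / L) + c * s,
       dpsi = function(s) b * pi / L * cos(pi * s / L) + c,
       L = L)
}

## Continuum energy of the chiral-filament Hamiltonian by fine trapezoid
## quadrature, independent of the package's discretization.
quadratureEnergy <- function(sm, params, nQuad = 4000L) {
  s <- seq(0, sm$L, length.out = nQuad + 1L)
  invr <- if (is.finite(params@r)) 1 / params@r else 0
  th <- sm$theta(s); ps <- sm$psi(s)
  dens <- params@C * (sin(th)^2 * invr - params@k0)^2 +
    params@C * sm$dtheta(s)^2 +
    params@K * (sm$dpsi(s) - sin(2 * th) * invr / 2 - params@omega0)^2 +
    2 * params@V * sin(ps / 2)^2
  0.5 * sum((dens[-1] + dens[-length(dens)]) / 2 * diff(s))
}

## Independent brute-force minimum of the flat-membrane energy at length L:
## discretizes psi on N nodes and minimizes with BFGS from a linear ramp.
## Written without reference to the package's Hamiltonian code.
bruteForceFlatMin <- function(L, params, N = 200L) {
  ds <- L / N
  K <- params@K; V <- params@V; w0 <- params@omega0
  en <- function(psi) {
    dpsi <- diff(psi) / ds
    psb <- (psi[-1] + psi[-length(psi)]) / 2
    0.5 * sum(ds * (K * (dpsi - w0)^2 + 2 * V * sin(psb / 2)^2))
  }
  gr <- function(psi) {
    n <- length(psi)
    dpsi <- diff(psi) / ds
    psb <- (psi[-1] + psi[-n]) / 2
    g <- numeric(n)
    junc <- -K * (dpsi - w0)          # d/dpsi_i of 0.5*ds*K*(dpsi)^2 terms
    bind <- 0.5 * ds * V * sin(psb / 2) * cos(psb / 2)
    g[-n] <- g[-n] + junc + bind
    g[-1] <- g[-1] - junc + bind
    g
  }
  ## start inside the no-winding (n = 0) basin: the model excludes full
  ## 360-degree twist walls, so the ramp amplitude is capped below pi
  amp <- min(w0 * L / 4, 0.9 * pi)
  psi0 <- seq(-1, 1, length.out = N + 1L) * amp
  fit <- optim(psi0, en, gr, method = "BFGS",
               control = list(maxit = 2000L, reltol = 1e-12))
  fit$value + e0(params) * L
}

## Data with an exact prescribed Pearson correlation against x = 1..n.
exactCorData <- function(r, n = 5L) {
  x <- seq_len(n)
  xs <- (x - mean(x)) / sd(x)
  v <- resid(lm(rnorm(n) ~ x))
  v <- v / sd(v)
  lambda <- sqrt(1 / r^2 - 1)
  y <- sign(r) * xs + lambda * v
  list(x = x, y = y)
}
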