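#' Create an angle time series
#'
#' @param values angle values, degrees.
#' @param times frame times, ns; defaults to 0.2-ns spacing.
#' @param name observable name (`opening`, `dihedral`, `theta1`, `theta2`
#'   or `theta3`).
#' @return a validated [AngleSeries-class].
#' @export
angleSeries <- function(values, times = seq_along(values) * 0.2,
                        name = "theta3") {
  new("AngleSeries", name = name, times = as.numeric(times),
      values = as.numeric(values))
}

#' Gaussian fit of the equilibrium window of an angle series
#'
#' Restricts the series to its last `windowNs` nanoseconds (the part of a
#' trajectory treated as equilibrated), histograms the values with
#' `binWidth`-degree bins and fits a Gaussian to the histogram by nonlinear
#' least squares. When the fit is degenerate (too few occupied bins, zero
#' spread, or a failed fit) the sample mean and standard deviation are
#' used instead and the result is flagged.
#'
#' @param series an [AngleSeries-class].
#' @param windowNs length of the trailing window, ns.
#' @param binWidth histogram bin width, degrees.
#' @return a [GaussianFit-class].
#' @export
equilibriumWindowFit <- function(series, windowNs = 40, binWidth = 0.5) {
  stopifnot(is(series, "AngleSeries"))
  tEnd <- max(series@times)
  keep <- series@times > tEnd - windowNs  # half-open: 200 frames per 40 ns at 0.2 ns
  x <- series@values[keep]
  n <- length(x)
  if (n < 2L) stop("equilibrium window contains fewer than 2 frames")
  if (n < 20L)
    warning(sprintf("only %d frames in the window; fit is unreliable", n))
  win <- c(tEnd - windowNs, tEnd)
  m0 <- mean(x); s0 <- sd(x)
  degenerate <- TRUE
  mu <- m0; sg <- s0
  if (is.finite(s0) && s0 > 1e-8) {
    breaks <- seq(floor(min(x) / binWidth) * binWidth - binWidth,
                  ceiling(max(x) / binWidth) * binWidth + binWidth,
                  by = binWidth)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    occupied <- sum(h$counts > 0)
    if (occupied >= 5L) {
      df <- data.frame(mid = h$mids, count = h$counts)
      fit <- tryCatch(
        minpack.lm::nlsLM(count ~ A * exp(-(mid - mu)^2 / (2 * sg^2)),
                          data = df,
                          start = list(A = max(df$count), mu = m0, sg = s0),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        cf <- coef(fit)
        if (is.finite(cf[["sg"]]) && abs(cf[["sg"]]) > 1e-8) {
          mu <- cf[["mu"]]; sg <- abs(cf[["sg"]]); degenerate <- FALSE
        }
      }
    }
  } else sg <- max(s0, 0)
  new("GaussianFit", mean = mu, sd = sg, window = win, nFrames = as.integer(n),
      degenerate = degenerate)
}

#' Torsional modulus from twist-angle fluctuations
#'
#' Equipartition estimate `K = kBT * deltaL / sigma^2` for a harmonic
#' torsional spring sampled at the monomer step: a twist-angle standard
#' deviation of 1.88 degrees per 5-nm step gives `K ~ 4.6e3` kBT nm.
#' If the series was sampled at a different step length, rescale the
#' variance first (independent steps: variance proportional to length).
#'
#' @param sigmaDeg standard deviation of the twist angle per monomer step,
#'   degrees.
#' @param deltaL monomer rise, nm.
#' @return torsional modulus, kBT nm.
#' @examples
#' torsionalModulus(1.88) # ~4.6e3
#' @export
torsionalModulus <- function(sigmaDeg, deltaL = 5) {
  stopifnot(sigmaDeg > 0)
  deltaL / .deg2rad(sigmaDeg)^2
}

#' Bending modulus from the two bending-angle fluctuations
#'
#' Applies the [torsionalModulus()] equipartition formula to the two
#' bending directions and averages; warns when the two single-direction
#' moduli differ by more than 5 percent of their mean (in that regime a
#' single isotropic modulus is a poor summary).
#'
#' @param sigma1Deg,sigma2Deg standard deviations of the two bending
#'   angles per monomer step, degrees.
#' @param deltaL monomer rise, nm.
#' @return bending modulus, kBT nm, with components as attribute `"C12"`.
#' @export
bendingModulus <- function(sigma1Deg, sigma2Deg, deltaL = 5) {
  C1 <- torsionalModulus(sigma1Deg, deltaL)
  C2 <- torsionalModulus(sigma2Deg, deltaL)
  C <- (C1 + C2) / 2
  if (abs(C1 - C2) / C > 0.05)
    warning(sprintf("directional bending moduli differ by %.1f%% of their mean",
                    100 * abs(C1 - C2) / C))
  out <- C
  attr(out, "C12") <- c(C1 = C1, C2 = C2)
  out
}

#' Intrinsic curvature and twist rates from mean inter-subunit angles
#'
#' Converts equilibrium mean Euler angles per monomer step into continuum
#' rates: `omega0 = theta3 / deltaL` (twist) and
#' `k0 = sqrt(theta1^2 + theta2^2) / deltaL` (curvature magnitude), angles
#' in radians internally.
#'
#' @param meanTheta1Deg,meanTheta2Deg,meanTheta3Deg mean bending and twist
#'   angles per monomer step, degrees.
#' @param deltaL monomer rise, nm.
#' @return named numeric `k0`, `omega0` in rad/nm.
#' @export
intrinsicRates <- function(meanTheta1Deg, meanTheta2Deg, meanTheta3Deg,
                           deltaL = 5) {
  c(k0 = sqrt(.deg2rad(meanTheta1Deg)^2 + .deg2rad(meanTheta2Deg)^2) / deltaL,
    omega0 = .deg2rad(meanTheta3Deg) / deltaL)
}

#' Membrane binding potential per unit length
#'
#' Converts a per-monomer membrane binding energy into the continuum
#' line density used by the filament model: `V = n * E / deltaL` for `n`
#' protofilaments contacting the membrane (10 kBT per monomer and two
#' protofilaments give 4 kBT/nm).
#'
#' @param EMonomer binding energy per monomer, kBT.
#' @param deltaL monomer rise, nm.
#' @param nProtofilaments protofilaments in the filament.
#' @return binding potential, kBT/nm.
#' @export
bindingPotentialPerLength <- function(EMonomer, deltaL = 5,
                                      nProtofilaments = 2) {
  stopifnot(EMonomer >= 0, deltaL > 0)
  nProtofilaments * EMonomer / deltaL
}

#' Polymerization energy per unit length
#'
#' `mu0 = n * deltaG / deltaL` for `n` protofilaments: the free energy
#' released per monomer added (5 kBT, actin-like kinetics) maps to
#' 2 kBT/nm for a double protofilament. Use [deltaGFromKc()] to convert an
#' equilibrium constant (off/on rate ratio) into `deltaG`.
#'
#' @param deltaGMonomer polymerization free energy per monomer, kBT.
#' @param deltaL monomer rise, nm.
#' @param nProtofilaments protofilaments in the filament.
#' @return polymerization energy density, kBT/nm.
#' @export
polymerizationDensity <- function(deltaGMonomer, deltaL = 5,
                                  nProtofilaments = 2) {
  stopifnot(deltaL > 0)
  nProtofilaments * deltaGMonomer / deltaL
}

#' @rdname polymerizationDensity
#' @param Kc equilibrium constant (ratio of off and on rates).
#' @return `deltaGFromKc`: free energy in kBT (`-ln Kc`).
#' @export
deltaGFromKc <- function(Kc) {
  stopifnot(Kc > 0)
  -log(Kc)
}

#' Pearson correlation with a Student t p-value
#'
#' Pearson's r with the two-tailed p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, the
#' standard test for a correlation across a small strain panel.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return named numeric `r`, `p`, `n`.
#' @export
pearsonWithP <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: constant input")
  r <- cor(x, y)
  n <- length(x)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  c(r = r, p = p, n = n)
}
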