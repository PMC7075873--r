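## Central S4 containers. All energies are in units of kBT, lengths in nm,
## angles in radians inside model code and degrees at user-facing interfaces.

#' Physical constants of the coarse-grained filament model
#'
#' Bundles the elastic and binding constants of a membrane-bound chiral
#' filament: bending modulus `C` and torsional modulus `K` (kBT nm),
#' membrane binding potential per unit length `V` (kBT/nm), intrinsic
#' curvature `k0` and intrinsic twist rate `omega0` (rad/nm, positive =
#' left-handed), polymerization energy per unit length `mu0` (kBT/nm) and
#' the membrane cylinder radius `r` (nm; `Inf` means a flat membrane).
#'
#' The rest energy density `e0 = C k0^2 / 2` is always derived from `C` and
#' `k0` via [e0()] and never stored, so it cannot drift out of sync.
#'
#' @slot C bending modulus, kBT nm.
#' @slot K torsional modulus, kBT nm.
#' @slot V membrane binding potential per unit length, kBT/nm.
#' @slot k0 intrinsic curvature, rad/nm.
#' @slot omega0 intrinsic twist rate, rad/nm.
#' @slot mu0 polymerization energy per unit length, kBT/nm.
#' @slot r membrane cylinder radius, nm (`Inf` = flat).
#' @seealso [filamentParams()]
#' @exportClass FilamentParams
setClass("FilamentParams",
  representation(C = "numeric", K = "numeric", V = "numeric",
                 k0 = "numeric", omega0 = "numeric", mu0 = "numeric",
                 r = "numeric"),
  prototype(C = 4.6e3, K = 4.6e3, V = 4, k0 = 2.3e-3,
            omega0 = (10.3 * pi / 180) / 5, mu0 = 2, r = Inf))

setValidity("FilamentParams", function(object) {
  msg <- character()
  for (s in c("C", "K", "V", "k0", "omega0", "mu0", "r")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v)) msg <- c(msg, sprintf("'%s' must be a single non-missing number", s))
  }
  if (length(msg)) return(msg)
  if (object@C < 0 || object@K < 0 || object@V < 0 || object@mu0 < 0)
    msg <- c(msg, "C, K, V and mu0 must be non-negative")
  if (object@r <= 0)
    msg <- c(msg, "r must be positive (use Inf for a flat membrane)")
  if (length(msg)) msg else TRUE
})

#' Discretized filament configuration
#'
#' Tilt and twist profile of a filament of length `L = N * segmentLength`,
#' discretized into `N` segments whose boundary nodes carry the local tilt
#' angle `theta` (vs. the cylinder centerline, radians in `[0, pi]`) and the
#' unwrapped twist angle `psi` (radians, continuous: adjacent nodes never
#' jump by more than pi).
#'
#' @slot segmentLength segment length, nm.
#' @slot theta node tilt angles, radians; length `N + 1`.
#' @slot psi node twist angles, radians; length `N + 1`.
#' @seealso [filamentState()], [hamiltonianEnergy()]
#' @exportClass FilamentState
setClass("FilamentState",
  representation(segmentLength = "numeric", theta = "numeric", psi = "numeric"))

setValidity("FilamentState", function(object) {
  msg <- character()
  if (length(object@segmentLength) != 1L || !is.finite(object@segmentLength) ||
      object@segmentLength <= 0)
    msg <- c(msg, "segmentLength must be a single positive number")
  if (length(object@theta) != length(object@psi))
    msg <- c(msg, "theta and psi must have the same length")
  if (length(object@theta) < 3L)
    msg <- c(msg, "state needs at least 2 segments (3 nodes)")
  if (!all(is.finite(object@theta)) || !all(is.finite(object@psi)))
    msg <- c(msg, "angles must be finite")
  else {
    if (any(object@theta < -1e-9 | object@theta > pi + 1e-9))
      msg <- c(msg, "theta must lie in [0, pi]")
    if (length(object@psi) > 1L && any(abs(diff(object@psi)) > pi + 1e-9))
      msg <- c(msg, "psi must be unwrapped (no jumps larger than pi between nodes)")
  }
  if (length(msg)) msg else TRUE
})

#' Energy-length profile of a filament
#'
#' Total minimized energy `E(L)` on a strictly increasing length grid,
#' together with the numerical derivative `dEdL` and, for the analytical
#' flat-membrane branch, the boundary twist amplitude `psiM` at each length.
#' Monte Carlo profiles additionally carry the replicate standard deviation.
#'
#' @slot L length grid, nm (strictly increasing).
#' @slot E total energy, kBT.
#' @slot dEdL numerical derivative, kBT/nm.
#' @slot psiM boundary twist amplitude, radians (`NA` for Monte Carlo
#'   profiles).
#' @slot sd replicate standard deviation of `E`, kBT (`NA` for analytical
#'   profiles).
#' @slot source `"analytical"` or `"mc"`.
#' @seealso [energyLengthCurve()], [energyLengthCurveMC()], [limitLength()]
#' @exportClass EnergyProfile
setClass("EnergyProfile",
  representation(L = "numeric", E = "numeric", dEdL = "numeric",
                 psiM = "numeric", sd = "numeric", source = "character"))

setValidity("EnergyProfile", function(object) {
  msg <- character()
  n <- length(object@L)
  if (length(object@E) != n || length(object@dEdL) != n ||
      length(object@psiM) != n || length(object@sd) != n)
    msg <- c(msg, "L, E, dEdL, psiM and sd must have equal lengths")
  if (n > 1L && any(diff(object@L) <= 0))
    msg <- c(msg, "L must be strictly increasing")
  if (!all(is.finite(object@E)))
    msg <- c(msg, "E must be finite everywhere")
  if (length(msg)) msg else TRUE
})

#' Time series of a named angle observable
#'
#' A per-frame angle measurement from a trajectory: the subdomain opening or
#' dihedral angle of one subunit, or one of the inter-subunit Euler angles
#' theta1 (bending toward the membrane), theta2 (bending toward the paired
#' protofilament) or theta3 (twist, positive = left-handed).
#'
#' @slot name one of `"opening"`, `"dihedral"`, `"theta1"`, `"theta2"`,
#'   `"theta3"`.
#' @slot times frame times, ns (non-decreasing).
#' @slot values angle values, degrees.
#' @seealso [angleSeries()], [equilibriumWindowFit()], [genAngleSeries()]
#' @exportClass AngleSeries
setClass("AngleSeries",
  representation(name = "character", times = "numeric", values = "numeric"))

setValidity("AngleSeries", function(object) {
  msg <- character()
  ok <- c("opening", "dihedral", "theta1", "theta2", "theta3")
  if (length(object@name) != 1L || !object@name %in% ok)
    msg <- c(msg, paste0("name must be one of: ", paste(ok, collapse = ", ")))
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have equal lengths")
  if (length(object@times) > 1L && any(diff(object@times) < 0))
    msg <- c(msg, "times must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Labelled atom coordinates for one trajectory frame
#'
#' Atom positions (nm) with van der Waals radii and subunit/subdomain
#' labels. Subdomain labels follow the actin fold (`IA`, `IB`, `IIA`,
#' `IIB`); atoms outside the four subdomains (e.g. the N-terminal
#' amphipathic helix, residues 1-8) carry the label `"none"` and are
#' excluded from subdomain centroids.
#'
#' @slot atoms `data.frame` with columns `x`, `y`, `z` (nm), `radius` (nm),
#'   `subunit` (character), `subdomain` (character) and `resid` (integer).
#' @slot time frame time, ns.
#' @seealso [structureFrame()], [subdomainCenters()], [subunitTriad()]
#' @exportClass StructureFrame
setClass("StructureFrame",
  representation(atoms = "data.frame", time = "numeric"))

setValidity("StructureFrame", function(object) {
  msg <- character()
  need <- c("x", "y", "z", "radius", "subunit", "subdomain", "resid")
  miss <- setdiff(need, names(object@atoms))
  if (length(miss))
    msg <- c(msg, paste0("atoms is missing column(s): ", paste(miss, collapse = ", ")))
  else {
    ok <- c("IA", "IB", "IIA", "IIB", "none")
    if (!all(object@atoms$subdomain %in% ok))
      msg <- c(msg, "subdomain labels must be IA, IB, IIA, IIB or none")
    if (!all(is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
      msg <- c(msg, "coordinates must be finite")
  }
  if (length(object@time) != 1L) msg <- c(msg, "time must be a single number")
  if (length(msg)) msg else TRUE
})

#' Per-patch measurements from a flattened cell surface
#'
#' One row per segmented fluorescent patch: area (um^2), major-axis length
#' (um, the filament-length proxy) and pitch angle (degrees in `[0, 90]`,
#' the angle between the patch major axis and the long cell axis; 90 means
#' circumferential).
#'
#' @slot patches `data.frame` with columns `area`, `length`, `pitch`, `cx`,
#'   `cy`, `cellID`.
#' @slot minArea area filter applied during segmentation, um^2.
#' @seealso [segmentPatches()], [lengthDistribution()], [pitchDistribution()]
#' @exportClass PatchTable
setClass("PatchTable",
  representation(patches = "data.frame", minArea = "numeric"))

setValidity("PatchTable", function(object) {
  msg <- character()
  need <- c("area", "length", "pitch", "cx", "cy", "cellID")
  miss <- setdiff(need, names(object@patches))
  if (length(miss))
    msg <- c(msg, paste0("patches is missing column(s): ", paste(miss, collapse = ", ")))
  else if (nrow(object@patches)) {
    if (any(object@patches$pitch < -1e-9 | object@patches$pitch > 90 + 1e-9))
      msg <- c(msg, "pitch must lie in [0, 90] degrees")
    if (any(object@patches$area < object@minArea - 1e-12))
      msg <- c(msg, "all patch areas must be at least minArea")
  }
  if (length(msg)) msg else TRUE
})

#' Single-channel image of a flattened cell surface
#'
#' @slot intensity matrix of non-negative intensities; rows index the long
#'   cell axis, columns the circumferential axis.
#' @slot pixelSize pixel size, um.
#' @slot cellID identifier.
#' @seealso [surfaceImage()], [segmentPatches()], [genSurfaceImage()]
#' @exportClass SurfaceImage
setClass("SurfaceImage",
  representation(intensity = "matrix", pixelSize = "numeric",
                 cellID = "character"))

setValidity("SurfaceImage", function(object) {
  msg <- character()
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (!all(is.finite(object@intensity)) || any(object@intensity < 0))
    msg <- c(msg, "intensity must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' Settings for the Metropolis minimizer
#'
#' @slot maxSteps maximum Metropolis steps.
#' @slot convergenceWindow steps over which energy fluctuations are judged.
#' @slot convergenceTol relative energy fluctuation below which the run is
#'   declared converged.
#' @slot proposalAmplitude initial half-width of the uniform angle proposal,
#'   radians (auto-tuned during burn-in to 30-50 percent acceptance).
#' @slot replicates independent replicate runs per parameter set.
#' @slot seed base seed; replicate `k` uses `seed + k`.
#' @slot temperature Metropolis temperature, kBT.
#' @slot segmentLength discretization segment length, nm.
#' @slot polish logical; run a deterministic quench (bounded BFGS on the
#'   discretized Hamiltonian) from the best-visited state after the
#'   Metropolis phase.
#' @seealso [mcConfig()], [metropolisMinimize()]
#' @exportClass MCConfig
setClass("MCConfig",
  representation(maxSteps = "numeric", convergenceWindow = "numeric",
                 convergenceTol = "numeric", proposalAmplitude = "numeric",
                 replicates = "integer", seed = "integer",
                 temperature = "numeric", segmentLength = "numeric",
                 polish = "logical"),
  prototype(maxSteps = 1e7, convergenceWindow = 1e4, convergenceTol = 0.01,
            proposalAmplitude = 0.3, replicates = 20L, seed = 1L,
            temperature = 1, segmentLength = 5, polish = TRUE))

setValidity("MCConfig", function(object) {
  msg <- character()
  if (object@maxSteps < object@convergenceWindow)
    msg <- c(msg, "maxSteps must be at least convergenceWindow")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (object@convergenceTol <= 0) msg <- c(msg, "convergenceTol must be > 0")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
  if (object@segmentLength <= 0) msg <- c(msg, "segmentLength must be > 0")
  if (length(msg)) msg else TRUE
})

#' Result of one Metropolis minimization run
#'
#' @slot finalState the minimized [FilamentState-class].
#' @slot params the [FilamentParams-class] used.
#' @slot energy energy of `finalState`, kBT; always recomputed with
#'   [hamiltonianEnergy()] so it matches the state exactly.
#' @slot energyTrace energy sampled along the Metropolis phase, kBT.
#' @slot converged logical; the stated fluctuation criterion was met.
#' @slot acceptedFraction fraction of accepted proposals.
#' @slot seed seed used for this run.
#' @seealso [metropolisMinimize()], [pitchAngleSummary()]
#' @exportClass MCResult
setClass("MCResult",
  representation(finalState = "FilamentState", params = "FilamentParams",
                 energy = "numeric", energyTrace = "numeric",
                 converged = "logical", acceptedFraction = "numeric",
                 seed = "integer"))

#' Gaussian fit of an equilibrium angle window
#'
#' @slot mean fitted mean, degrees.
#' @slot sd fitted standard deviation, degrees.
#' @slot window `(t_start, t_end)` of the fitted window, ns.
#' @slot nFrames number of frames in the window.
#' @slot degenerate logical; TRUE when the histogram fit failed and the
#'   sample moments were used instead.
#' @seealso [equilibriumWindowFit()]
#' @exportClass GaussianFit
setClass("GaussianFit",
  representation(mean = "numeric", sd = "numeric", window = "numeric",
                 nFrames = "integer", degenerate = "logical"))

setValidity("GaussianFit", function(object) {
  msg <- character()
  if (object@sd < 0) msg <- c(msg, "sd must be non-negative")
  if (length(object@window) != 2L) msg <- c(msg, "window must be length 2")
  if (length(msg)) msg else TRUE
})
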