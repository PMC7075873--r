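#' @name accessors
#' @title Accessors for MreBTwist objects
#' @param object an MreBTwist S4 object.
#' @param x an MreBTwist S4 object.
#' @description Slot accessors: `filamentLength()` returns the total length
#'   in nm, `tiltProfile()`/`twistProfile()` the node angle vectors in
#'   radians, `patchData()` the per-patch `data.frame`, `angleValues()` and
#'   `angleTimes()` the series content, `e0()` the derived rest energy
#'   density `C*k0^2/2`.
NULL

#' @rdname accessors
#' @export
setGeneric("filamentLength", function(object) standardGeneric("filamentLength"))

#' @rdname accessors
#' @export
setGeneric("tiltProfile", function(object) standardGeneric("tiltProfile"))

#' @rdname accessors
#' @export
setGeneric("twistProfile", function(object) standardGeneric("twistProfile"))

#' @rdname accessors
#' @export
setGeneric("e0", function(object) standardGeneric("e0"))

#' @rdname accessors
#' @export
setGeneric("patchData", function(object) standardGeneric("patchData"))

#' @rdname accessors
#' @export
setGeneric("angleValues", function(object) standardGeneric("angleValues"))

#' @rdname accessors
#' @export
setGeneric("angleTimes", function(object) standardGeneric("angleTimes"))

#' Locate the limit length on an energy-length profile
#'
#' The limit length is the smallest length at which the marginal energy cost
#' of extension, `dE/dL`, reaches the polymerization energy density `mu0`:
#' beyond it, adding subunits costs more elastic and binding energy than
#' polymerization releases. Returns `Inf` when `dE/dL` stays below `mu0`
#' over the whole profile (growth unbounded up to the profile's maximum
#' length).
#'
#' @param profile an [EnergyProfile-class].
#' @param mu0 polymerization energy per unit length, kBT/nm.
#' @return the limit length in nm, or `Inf` when unbounded; the number of
#'   `dE/dL = mu0` crossings found is attached as attribute `"crossings"`.
#' @export
setGeneric("limitLength", function(profile, mu0) standardGeneric("limitLength"))

#' @rdname accessors
#' @export
setMethod("filamentLength", "FilamentState", function(object)
  (length(object@theta) - 1L) * object@segmentLength)

#' @rdname accessors
#' @export
setMethod("tiltProfile", "FilamentState", function(object) object@theta)

#' @rdname accessors
#' @export
setMethod("twistProfile", "FilamentState", function(object) object@psi)

#' @rdname accessors
#' @export
setMethod("e0", "FilamentParams", function(object) object@C * object@k0^2 / 2)

#' @rdname accessors
#' @export
setMethod("patchData", "PatchTable", function(object) object@patches)

#' @rdname accessors
#' @export
setMethod("angleValues", "AngleSeries", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("angleTimes", "AngleSeries", function(object) object@times)

setMethod("show", "FilamentParams", function(object) {
  cat("FilamentParams (kBT, nm, rad)\n")
  cat(sprintf("  C = %.4g kBT nm, K = %.4g kBT nm, V = %.4g kBT/nm\n",
              object@C, object@K, object@V))
  cat(sprintf("  k0 = %.4g rad/nm, omega0 = %.4g rad/nm (%.2f deg / 5 nm)\n",
              object@k0, object@omega0, .rad2deg(object@omega0) * 5))
  cat(sprintf("  mu0 = %.4g kBT/nm, r = %s nm, e0 = %.4g kBT/nm\n",
              object@mu0, if (is.finite(object@r)) format(object@r) else "Inf (flat)",
              e0(object)))
})

setMethod("show", "FilamentState", function(object) {
  n <- length(object@theta) - 1L
  cat(sprintf("FilamentState: %d segments x %.3g nm (L = %.4g nm)\n",
              n, object@segmentLength, filamentLength(object)))
  cat(sprintf("  tilt  theta: %.2f..%.2f deg\n",
              .rad2deg(min(object@theta)), .rad2deg(max(object@theta))))
  cat(sprintf("  twist psi:   %.2f..%.2f deg\n",
              .rad2deg(min(object@psi)), .rad2deg(max(object@psi))))
})

setMethod("show", "EnergyProfile", function(object) {
  cat(sprintf("EnergyProfile (%s): %d points, L in [%.3g, %.4g] nm\n",
              object@source, length(object@L), min(object@L), max(object@L)))
  cat(sprintf("  E in [%.4g, %.4g] kBT; dE/dL up to %.4g kBT/nm\n",
              min(object@E), max(object@E), max(object@dEdL, na.rm = TRUE)))
})

setMethod("show", "AngleSeries", function(object) {
  cat(sprintf("AngleSeries '%s': %d frames over %.4g ns, mean %.3g deg (sd %.3g)\n",
              object@name, length(object@values),
              if (length(object@times)) diff(range(object@times)) else 0,
              mean(object@values), sd(object@values)))
})

setMethod("show", "StructureFrame", function(object) {
  cat(sprintf("StructureFrame at t = %.4g ns: %d atoms, subunits: %s\n",
              object@time, nrow(object@atoms),
              paste(unique(object@atoms$subunit), collapse = ", ")))
})

setMethod("show", "PatchTable", function(object) {
  cat(sprintf("PatchTable: %d patches (area filter %.3g um^2)\n",
              nrow(object@patches), object@minArea))
  if (nrow(object@patches))
    cat(sprintf("  length: median %.3g um; pitch: median %.3g deg\n",
                median(object@patches$length), median(object@patches$pitch)))
})

setMethod("show", "MCResult", function(object) {
  cat(sprintf("MCResult: E = %.5g kBT, converged = %s, acceptance = %.2f, seed = %d\n",
              object@energy, object@converged, object@acceptedFraction,
              object@seed))
  cat(sprintf("  L = %.4g nm, mean pitch = %.2f deg\n",
              filamentLength(object@finalState),
              pitchAngleSummary(object)["pitch"]))
})

setMethod("show", "GaussianFit", function(object) {
  cat(sprintf("GaussianFit: mean %.3f deg, sd %.3f deg (n = %d frames%s)\n",
              object@mean, object@sd, object@nFrames,
              if (object@degenerate) ", degenerate: moment fallback" else ""))
})
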