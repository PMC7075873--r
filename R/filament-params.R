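#' Create a coarse-grained filament parameter set
#'
#' The defaults are the wild-type MreB double-protofilament constants
#' estimated from equilibrium molecular-dynamics fluctuations: torsional
#' modulus `K = 4.6e3` kBT nm (from twist-angle fluctuations of ~1.88 deg
#' per 5-nm monomer step), membrane binding `V = 4` kBT/nm (10 kBT per
#' monomer, two protofilaments), intrinsic curvature `k0 = 2.3e-3` rad/nm,
#' polymerization density `mu0 = 2` kBT/nm (5 kBT per monomer), and
#' intrinsic twist `omega0` corresponding to 10.3 degrees of left-handed
#' twist per 5-nm monomer rise. The bending modulus `C` defaults to the
#' magnitude of `K`; the limit length is insensitive to it because its only
#' flat-membrane contribution, `e0 = C k0^2/2 ~ 0.012` kBT/nm, is tiny
#' compared to the twist frustration density.
#'
#' @param C bending modulus, kBT nm.
#' @param K torsional modulus, kBT nm.
#' @param V membrane binding potential per unit length, kBT/nm.
#' @param k0 intrinsic curvature, rad/nm.
#' @param omega0 intrinsic twist rate, rad/nm (positive = left-handed).
#' @param mu0 polymerization energy per unit length, kBT/nm.
#' @param r membrane cylinder radius, nm; `Inf` for a flat membrane.
#' @return a validated [FilamentParams-class].
#' @examples
#' p <- filamentParams()
#' e0(p)                                  # C k0^2 / 2
#' filamentParams(omega0 = twistRate(4.2)) # ADP-like twist state
#' @export
filamentParams <- function(C = 4.6e3, K = 4.6e3, V = 4, k0 = 2.3e-3,
                           omega0 = twistRate(10.3), mu0 = 2, r = Inf) {
  ## Class must be matched by name: a slot named 'C' would otherwise be
  ## partially matched to new()'s 'Class' formal
  new(Class = "FilamentParams", C = C, K = K, V = V, k0 = k0,
      omega0 = omega0, mu0 = mu0, r = r)
}

#' Convert a per-step twist angle to an intrinsic twist rate
#'
#' @param twistDeg twist angle per monomer step, degrees.
#' @param deltaL monomer rise along the filament, nm.
#' @return twist rate in rad/nm.
#' @examples
#' twistRate(10.3) # ~0.036 rad/nm
#' @export
twistRate <- function(twistDeg, deltaL = 5) .deg2rad(twistDeg) / deltaL

#' Read and write filament parameter files
#'
#' Flat `key = value` text files (`#` starts a comment); keys match the
#' [FilamentParams-class] slot names. `r` may be the string `Inf` for a
#' flat membrane. Unknown keys raise an error.
#'
#' @param path file path.
#' @param params a [FilamentParams-class].
#' @return `readFilamentParams` returns a [FilamentParams-class];
#'   `writeFilamentParams` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".params")
#' writeFilamentParams(filamentParams(), f)
#' readFilamentParams(f)
#' @export
readFilamentParams <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed parameter line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2L))))
  known <- c("C", "K", "V", "k0", "omega0", "mu0", "r")
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  if (anyNA(vals))
    stop("non-numeric parameter value(s) for: ",
         paste(keys[is.na(vals)], collapse = ", "))
  args <- as.list(setNames(vals, keys))
  do.call(filamentParams, args)
}

#' @rdname readFilamentParams
#' @export
writeFilamentParams <- function(params, path) {
  stopifnot(is(params, "FilamentParams"))
  units <- c(C = "kBT nm", K = "kBT nm", V = "kBT/nm", k0 = "rad/nm",
             omega0 = "rad/nm", mu0 = "kBT/nm", r = "nm (Inf = flat)")
  lines <- vapply(names(units), function(k)
    sprintf("%s = %.10g  # %s", k, slot(params, k), units[[k]]), "")
  writeLines(lines, path)
  invisible(path)
}
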