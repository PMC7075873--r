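## Trajectory and table I/O. PDB parsing goes through bio3d; coordinates
## are converted from Angstrom to nm on the way in.

.vdwRadiiNm <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180,
                 P = 0.180)

#' Read a multi-model PDB trajectory into structure frames
#'
#' Each PDB MODEL becomes one [StructureFrame-class]; chains map to
#' subunits and a residue-range map assigns subdomain labels. Residues not
#' covered by the map (e.g. the amphipathic helix, residues 1-8) are
#' labelled `none`. Coordinates are converted to nm and van der Waals
#' radii assigned per element (Bondi values; unknown elements fall back to
#' carbon).
#'
#' @param path PDB file (single- or multi-model).
#' @param subdomainMap `data.frame` with columns `subdomain`, `start`,
#'   `end` (residue numbers, inclusive), or a YAML file readable by
#'   [readSubdomainMap()].
#' @param frameDt time between models, ns.
#' @return list of [StructureFrame-class] objects.
#' @export
readTrajectoryPDB <- function(path, subdomainMap, frameDt = 0.2) {
  if (is.character(subdomainMap)) subdomainMap <- readSubdomainMap(subdomainMap)
  stopifnot(all(c("subdomain", "start", "end") %in% names(subdomainMap)))
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  elem <- ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                 substr(trimws(at$elety), 1L, 1L), trimws(at$elesy))
  radius <- unname(.vdwRadiiNm[toupper(elem)])
  radius[is.na(radius)] <- .vdwRadiiNm[["C"]]
  subdomain <- rep("none", nrow(at))
  for (i in seq_len(nrow(subdomainMap)))
    subdomain[at$resno >= subdomainMap$start[i] &
                at$resno <= subdomainMap$end[i]] <-
      subdomainMap$subdomain[i]
  nFrames <- nrow(pdb$xyz)
  lapply(seq_len(nFrames), function(f) {
    m <- matrix(pdb$xyz[f, ], ncol = 3L, byrow = TRUE) / 10
    structureFrame(data.frame(x = m[, 1], y = m[, 2], z = m[, 3],
                              radius = radius, subunit = at$chain,
                              subdomain = subdomain, resid = at$resno),
                   time = (f - 1L) * frameDt)
  })
}

#' Read a subdomain residue-range map from YAML
#'
#' Expected layout: one key per subdomain, each holding a list of
#' `[start, end]` residue ranges, e.g. `IA: [[9, 32], [64, 80]]`.
#'
#' @param path YAML file.
#' @return `data.frame` with columns `subdomain`, `start`, `end`.
#' @export
readSubdomainMap <- function(path) {
  y <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(names(y), function(d) {
    ranges <- y[[d]]
    if (!is.list(ranges)) ranges <- list(ranges)
    do.call(rbind, lapply(ranges, function(r)
      data.frame(subdomain = d, start = r[[1]], end = r[[2]])))
  }))
  ok <- c("IA", "IB", "IIA", "IIB")
  if (!all(out$subdomain %in% ok))
    stop("subdomain map keys must be among: ", paste(ok, collapse = ", "))
  out
}

#' Read and write angle series as tab-separated tables
#'
#' Two columns: `time_ns` and `value_deg`.
#'
#' @param series an [AngleSeries-class].
#' @param path file path.
#' @param name observable name when reading.
#' @return `readAngleSeries` returns an [AngleSeries-class].
#' @export
writeAngleSeries <- function(series, path) {
  stopifnot(is(series, "AngleSeries"))
  write.table(data.frame(time_ns = series@times, value_deg = series@values),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAngleSeries
#' @export
readAngleSeries <- function(path, name = "theta3") {
  df <- read.table(path, header = TRUE, sep = "\t")
  angleSeries(df$value_deg, times = df$time_ns, name = name)
}

#' Write an energy-length profile as a tab-separated table
#'
#' Columns: `L_nm`, `E_kBT`, `dEdL_kBT_per_nm`, `psi_m_deg`, `sd_kBT`.
#'
#' @param profile an [EnergyProfile-class].
#' @param path file path.
#' @export
writeEnergyProfile <- function(profile, path) {
  stopifnot(is(profile, "EnergyProfile"))
  write.table(data.frame(L_nm = profile@L, E_kBT = profile@E,
                         dEdL_kBT_per_nm = profile@dEdL,
                         psi_m_deg = .rad2deg(profile@psiM),
                         sd_kBT = profile@sd),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
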