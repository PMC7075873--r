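#' Create a surface image
#'
#' @param intensity numeric matrix of non-negative intensities; rows run
#'   along the long cell axis, columns along the circumference.
#' @param pixelSize pixel size, um.
#' @param cellID identifier.
#' @return a validated [SurfaceImage-class].
#' @export
surfaceImage <- function(intensity, pixelSize = 0.032, cellID = "cell1") {
  new("SurfaceImage", intensity = as.matrix(intensity),
      pixelSize = pixelSize, cellID = cellID)
}

#' Read and write surface images as TIFF
#'
#' Thin wrappers over [EBImage::readImage()]/[EBImage::writeImage()] for
#' single-channel float TIFFs; the pixel size travels in a caller-supplied
#' argument because TIFF calibration tags are not portable.
#'
#' @param path file path.
#' @param img a [SurfaceImage-class].
#' @param pixelSize pixel size, um.
#' @param cellID identifier.
#' @return `readSurfaceImage` returns a [SurfaceImage-class].
#' @export
readSurfaceImage <- function(path, pixelSize = 0.032, cellID = basename(path)) {
  dat <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(dat)) > 2L) dat <- dat[, , 1L]
  surfaceImage(dat, pixelSize = pixelSize, cellID = cellID)
}

#' @rdname readSurfaceImage
#' @export
writeSurfaceImage <- function(img, path) {
  stopifnot(is(img, "SurfaceImage"))
  mx <- max(img@intensity)
  EBImage::writeImage(EBImage::Image(img@intensity / max(mx, 1e-12)), path,
                      type = "tiff", bits.per.sample = 16L)
  invisible(path)
}

## Second-moment ellipse of a pixel set (regionprops conventions):
## major-axis length 2*sqrt(2)*sqrt(uxx + uyy + sqrt((uxx-uyy)^2 + 4 uxy^2))
## and orientation of the major axis relative to the row (long cell) axis.
.regionEllipse <- function(rows, cols) {
  cx <- mean(rows); cy <- mean(cols)
  dx <- rows - cx; dy <- cols - cy
  uxx <- mean(dx^2) + 1 / 12  # +1/12: second moment of a unit pixel
  uyy <- mean(dy^2) + 1 / 12
  uxy <- mean(dx * dy)
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  major <- 2 * sqrt(2) * sqrt(uxx + uyy + common)
  orient <- 0.5 * atan2(2 * uxy, uxx - uyy)
  c(cx = cx, cy = cy, major = major, orient = orient)
}

.foldPitch <- function(deg) {
  p <- deg %% 180
  ifelse(p > 90, 180 - p, p)
}

#' Segment fluorescent patches on a flattened cell surface
#'
#' Normalizes the image to `[0, 1]`, binarizes it at a fixed global
#' threshold (default 0.5 of the normalized range, the classical default
#' of global bi-level conversion; `method = "otsu"` is offered as an
#' alternative), labels connected components with 8-connectivity, discards
#' components smaller than `minArea` (default 0.02 um^2, the structured
#' illumination resolution limit) and summarizes each remaining component
#' by its second-moment ellipse: the major-axis length is the filament
#' length proxy and the major-axis orientation, folded into `[0, 90]`
#' degrees relative to the long cell axis, is the pitch angle.
#'
#' @param img a [SurfaceImage-class].
#' @param thresholdLevel fixed threshold on the normalized intensity.
#' @param minArea minimum patch area, um^2.
#' @param method `"fixed"` or `"otsu"`.
#' @return a [PatchTable-class] (empty for a blank image).
#' @export
segmentPatches <- function(img, thresholdLevel = 0.5, minArea = 0.02,
                           method = c("fixed", "otsu")) {
  stopifnot(is(img, "SurfaceImage"))
  method <- match.arg(method)
  I <- img@intensity
  rng <- range(I)
  empty <- new("PatchTable",
               patches = data.frame(area = numeric(), length = numeric(),
                                    pitch = numeric(), cx = numeric(),
                                    cy = numeric(), cellID = character()),
               minArea = minArea)
  if (all(I == 0)) return(empty)
  if (diff(rng) <= 0) stop("constant non-zero image cannot be normalized")
  In <- (I - rng[1]) / diff(rng)
  level <- if (method == "otsu") EBImage::otsu(EBImage::Image(In)) else thresholdLevel
  mask <- In > level
  if (!any(mask)) return(empty)
  lab <- .label8Cpp(mask)
  px <- img@pixelSize
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  keepIDs <- as.integer(names(which(table(labs) * px^2 >= minArea)))
  if (!length(keepIDs)) return(empty)
  rowsplit <- split(seq_len(nrow(idx)), labs)
  recs <- lapply(as.character(keepIDs), function(id) {
    sel <- rowsplit[[id]]
    ell <- .regionEllipse(idx[sel, 1L], idx[sel, 2L])
    data.frame(area = length(sel) * px^2,
               length = ell[["major"]] * px,
               pitch = .foldPitch(.rad2deg(ell[["orient"]])),
               cx = ell[["cx"]] * px, cy = ell[["cy"]] * px,
               cellID = img@cellID)
  })
  new("PatchTable", patches = do.call(rbind, recs), minArea = minArea)
}

.poolPatches <- function(tables) {
  if (is(tables, "PatchTable")) tables <- list(tables)
  stopifnot(all(vapply(tables, is, TRUE, "PatchTable")))
  do.call(rbind, lapply(tables, patchData))
}

#' Pooled filament-length distribution and limit-length proxy
#'
#' Pools the major-axis lengths of one or more patch tables and returns
#' the empirical CDF together with the 99th percentile, the observational
#' proxy for the filament limit length. With fewer than 100 patches the
#' percentile is refused (`NA` with a warning) because the tail is not
#' resolved.
#'
#' @param tables a [PatchTable-class] or a list of them.
#' @param prob tail probability of the reported percentile.
#' @return list with `cdf` (an [stats::ecdf()]), `n`, and `percentile`
#'   (um).
#' @export
lengthDistribution <- function(tables, prob = 0.99) {
  len <- .poolPatches(tables)$length
  n <- length(len)
  pct <- if (n < 100L) {
    warning(sprintf("only %d patches; refusing the %.0fth percentile", n,
                    100 * prob))
    NA_real_
  } else unname(quantile(len, prob, type = 7))
  list(cdf = stats::ecdf(len), n = n, percentile = pct)
}

#' Pooled pitch-angle distribution
#'
#' @param tables a [PatchTable-class] or a list of them.
#' @return list with `cdf`, `n`, `mean` and `sem` (degrees).
#' @export
pitchDistribution <- function(tables) {
  p <- .poolPatches(tables)$pitch
  n <- length(p)
  list(cdf = stats::ecdf(p), n = n, mean = mean(p),
       sem = if (n > 1L) sd(p) / sqrt(n) else 0)
}

#' Correlation of a patch summary with intrinsic twist across strains
#'
#' Pearson correlation (with Student t p-value) between the per-strain
#' intrinsic twist angles and any per-strain patch summary (99th-percentile
#' length, mean pitch deviation, ...).
#'
#' @param twistDeg per-strain twist angles, degrees.
#' @param summary per-strain summary values (same length).
#' @return named numeric `r`, `p`, `n` from [pearsonWithP()].
#' @export
mutantPanelCorrelation <- function(twistDeg, summary) {
  pearsonWithP(twistDeg, summary)
}
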