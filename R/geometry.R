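#' Scan geometry of an OCT volume
#'
#' Describes the raster and physical extent of a macular volume scan: lateral
#' and axial pixel counts per B-scan, number of B-scans, physical scan width
#' and depth, and the spacing between consecutive B-scans.
#'
#' The default corresponds to a Spectralis-style 20 x 20 degree horizontal
#' line-scan protocol: 25 B-scans of 512 x 496 pixels, 5.3 mm scan length,
#' 1.9 mm scan depth, 221 um B-scan spacing.
#'
#' Conventions used throughout the package: lateral pixel `i` (1-based) sits
#' at lateral position `(i - 1) * lateral_scale(geometry)` um; axial depth is
#' measured in pixels downward from the image top (row 1 = vitreous side).
#'
#' @param width_px lateral samples per B-scan.
#' @param depth_px axial samples per B-scan.
#' @param n_bscans number of B-scans in the volume.
#' @param width_um lateral extent of a B-scan in micrometers.
#' @param depth_um axial extent of a B-scan in micrometers.
#' @param bscan_spacing_um physical spacing between consecutive B-scans (um).
#' @return An object of class `scan_geometry`.
#' @examples
#' g <- scan_geometry()
#' lateral_scale(g)  # ~10.35 um per pixel
#' axial_scale(g)    # ~3.83 um per pixel
#' @export
scan_geometry <- function(width_px = 512L, depth_px = 496L, n_bscans = 25L,
                          width_um = 5300, depth_um = 1900,
                          bscan_spacing_um = 221) {
  g <- list(width_px = as.integer(width_px), depth_px = as.integer(depth_px),
            n_bscans = as.integer(n_bscans), width_um = width_um,
            depth_um = depth_um, bscan_spacing_um = bscan_spacing_um)
  for (f in names(g)) {
    if (length(g[[f]]) != 1L || !is.finite(g[[f]]) || g[[f]] <= 0)
      stop("scan_geometry field '", f, "' must be a single positive number")
  }
  structure(g, class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "scan_geometry: %d B-scans of %d x %d px; %g x %g um, spacing %g um\n",
    x$n_bscans, x$width_px, x$depth_px, x$width_um, x$depth_um,
    x$bscan_spacing_um))
  invisible(x)
}

#' @rdname scan_geometry
#' @param geometry a `scan_geometry` object.
#' @export
lateral_scale <- function(geometry) geometry$width_um / geometry$width_px

#' @rdname scan_geometry
#' @export
axial_scale <- function(geometry) geometry$depth_um / geometry$depth_px

#' Resolve the nasal direction on the lateral axis
#'
#' Fundus laterality: under the default convention `"nasal_positive_od"`,
#' nasal is the direction of increasing lateral pixel for right eyes (OD) and
#' decreasing lateral pixel for left eyes (OS). Returns +1 or -1, the sign to
#' apply to a nasal offset in micrometers.
#'
#' @param side `"OD"` or `"OS"`.
#' @param convention laterality convention flag; only `"nasal_positive_od"`
#'   is currently defined (its mirror is obtained by swapping eye sides).
#' @return +1 if nasal offsets point toward increasing lateral coordinate,
#'   -1 otherwise.
#' @export
nasal_direction <- function(side, convention = "nasal_positive_od") {
  side <- match.arg(side, c("OD", "OS"))
  convention <- match.arg(convention, "nasal_positive_od")
  if (side == "OD") 1 else -1
}
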