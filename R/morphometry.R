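# Nulla-anchored choroidal landmark grid, measured on the single B-scan that
# contains the nulla: nine axial thicknesses at 500-um lateral steps out to
# +/- 2000 um (T5 at the nulla), the eight inter-landmark cross-sectional
# areas, and the umbo sub-analysis at +/- 100 um (TUn/TUt, AUn/AUt).

# Interpolate a boundary depth profile (axial px) at a lateral position (um).
# Boundary node i sits at lateral position (i - 1) * lateral_scale.
interp_boundary <- function(profile, x_um, geometry) {
  xs <- (seq_along(profile) - 1) * lateral_scale(geometry)
  if (any(x_um < xs[1] - 1e-9) || any(x_um > xs[length(xs)] + 1e-9))
    stop("lateral position ", paste(signif(x_um[x_um < xs[1] | x_um > xs[length(xs)]], 6),
                                    collapse = ", "),
         " um outside the scanned extent [0, ", signif(xs[length(xs)], 6), "] um")
  stats::approx(xs, profile, xout = x_um)$y
}

#' Axial choroidal thickness at a lateral position
#'
#' Thickness of the segmented choroid band, measured strictly along the axial
#' direction: the difference between the outer and inner choroid boundary
#' depths at lateral position `x_um`, both linearly interpolated between
#' adjacent lateral pixels, converted to micrometers by the axial scale.
#'
#' @param boundaries a [extract_boundaries()] result (or any list of `ilm`,
#'   `choroid_inner`, `choroid_outer` depth matrices in axial pixels).
#' @param bscan 1-based B-scan index.
#' @param x_um lateral position(s) in micrometers from the left edge.
#' @param geometry the volume's [scan_geometry()].
#' @return thickness in micrometers (vectorized over `x_um`).
#' @export
thickness_at <- function(boundaries, bscan, x_um, geometry) {
  inner <- interp_boundary(boundaries$choroid_inner[bscan, ], x_um, geometry)
  outer <- interp_boundary(boundaries$choroid_outer[bscan, ], x_um, geometry)
  (outer - inner) * axial_scale(geometry)
}

#' Choroidal cross-sectional area between two lateral positions
#'
#' Integral of [thickness_at()] over `[x1_um, x2_um]` by the trapezoid rule
#' over every lateral pixel node inside the interval plus the fractional end
#' segments. Because the boundaries are piecewise linear between pixel nodes,
#' this integral is exact for the interpolated thickness profile.
#'
#' @inheritParams thickness_at
#' @param x1_um,x2_um interval bounds in micrometers, `x1_um < x2_um`.
#' @return area in square micrometers.
#' @export
area_between <- function(boundaries, bscan, x1_um, x2_um, geometry) {
  if (!(x1_um < x2_um)) stop("area_between: need x1_um < x2_um")
  ls <- lateral_scale(geometry)
  # interior nodes strictly inside the interval
  i1 <- ceiling(x1_um / ls + 1e-12)
  i2 <- floor(x2_um / ls - 1e-12)
  xs <- c(x1_um, if (i2 >= i1) (i1:i2) * ls, x2_um)
  th <- thickness_at(boundaries, bscan, xs, geometry)
  sum(diff(xs) * (th[-length(th)] + th[-1]) / 2)
}

#' Measure the nine thickness landmarks around the nulla
#'
#' T5 is the thickness at the nulla; T4..T1 step nasally and T6..T9
#' temporally outward in 500-um increments, out to +/- 2000 um. Nasal/temporal
#' directions are resolved from the eye side via [nasal_direction()].
#'
#' @inheritParams thickness_at
#' @param nulla_x_um lateral position of the nulla in micrometers.
#' @param side `"OD"` or `"OS"`.
#' @param spacing_um landmark spacing (um).
#' @return named numeric vector `T1..T9` (micrometers).
#' @export
measure_landmarks <- function(boundaries, bscan, nulla_x_um, side, geometry,
                              spacing_um = 500) {
  dir <- nasal_direction(side)
  xs <- nulla_x_um + dir * landmark_nasal_offsets_um() / 500 * spacing_um
  th <- vapply(seq_along(xs), function(i) {
    tryCatch(thickness_at(boundaries, bscan, xs[i], geometry),
             error = function(e) stop("landmark T", i, ": ", conditionMessage(e)))
  }, numeric(1))
  stats::setNames(th, paste0("T", 1:9))
}

#' Run the full per-eye measurement pipeline
#'
#' Extracts boundary curves from the masks, smooths the ILM surface, locates
#' the nulla, and measures the landmark grid on the B-scan containing the
#' nulla (nearest integer B-scan for a fractional nulla coordinate, ties
#' resolved toward the volume center): thicknesses T1-T9 and areas A1-A8
#' (17 grid parameters), plus the umbo sub-analysis TUn/TUt at +/- 100 um and
#' AUn/AUt over the adjoining 100-um spans. Areas are ordered A1 (between T1
#' and T2, nasal-most) through A8 (between T8 and T9), so A4 and A5 flank the
#' nulla.
#'
#' @param volume an `oct_volume` (for geometry, side and covariates).
#' @param masks compartment mask stack for the volume.
#' @param window ILM smoothing window, see [smooth_ilm()].
#' @param umbo_um umbo sub-analysis offset (um).
#' @return one-row `data.frame` of class `eye_measurement`: covariates,
#'   quality, nulla coordinates (`nulla_bscan`, `nulla_x_um`, `nulla_n_tied`)
#'   and the 21 measures `T1..T9, A1..A8, TUn, TUt, AUn, AUt`.
#' @export
measure_eye <- function(volume, masks, window = c(3L, 31L), umbo_um = 100) {
  g <- volume$geometry
  bd <- withCallingHandlers(
    extract_boundaries(masks),
    error = function(e) stop("eye ", volume$eye_id, ": ", conditionMessage(e)))
  surf <- smooth_ilm(bd$ilm, window = window)
  np <- find_nulla(surf)
  ctr <- (g$n_bscans + 1) / 2
  fr <- np$bscan - floor(np$bscan)
  b <- if (abs(fr - 0.5) < 1e-12) {
    # half-integer nulla B-scan: resolve toward the volume center
    if (np$bscan > ctr) floor(np$bscan) else ceiling(np$bscan)
  } else round(np$bscan)
  b <- as.integer(min(max(b, 1L), g$n_bscans))
  x0 <- (np$lateral - 1) * lateral_scale(g)
  dir <- nasal_direction(volume$side)

  tt <- measure_landmarks(bd, b, x0, volume$side, g)
  x_land <- x0 + dir * landmark_nasal_offsets_um()  # T1..T9 positions
  aa <- vapply(1:8, function(j) {
    area_between(bd, b, min(x_land[j], x_land[j + 1]),
                 max(x_land[j], x_land[j + 1]), g)
  }, numeric(1))
  tun <- thickness_at(bd, b, x0 + dir * umbo_um, g)
  tut <- thickness_at(bd, b, x0 - dir * umbo_um, g)
  aun <- area_between(bd, b, min(x0, x0 + dir * umbo_um),
                      max(x0, x0 + dir * umbo_um), g)
  aut <- area_between(bd, b, min(x0, x0 - dir * umbo_um),
                      max(x0, x0 - dir * umbo_um), g)

  out <- data.frame(eye_id = volume$eye_id, side = volume$side,
                    sex = volume$sex, origin = volume$origin,
                    quality = volume$quality, nulla_bscan = np$bscan,
                    nulla_x_um = x0, nulla_n_tied = np$n_tied,
                    stringsAsFactors = FALSE)
  out[paste0("T", 1:9)] <- as.list(tt)
  out[paste0("A", 1:8)] <- as.list(aa)
  out$TUn <- tun; out$TUt <- tut; out$AUn <- aun; out$AUt <- aut
  class(out) <- c("eye_measurement", class(out))
  out
}

#' Measure every included eye of a cohort
#'
#' Applies the scan-quality inclusion filter, runs [measure_eye()] on each
#' included eye, and binds the per-eye rows into one measurement table.
#' Per-eye failures are reported as warnings and the run continues; excluded
#' or failed eyes are listed in the `excluded` attribute.
#'
#' @param eyes list of [generate_eye()]-style results (`volume` + `masks`).
#' @param quality_threshold minimum scan quality for inclusion.
#' @inheritParams measure_eye
#' @return `data.frame` with one row per measured eye.
#' @export
measure_cohort <- function(eyes, quality_threshold = 25L, window = c(3L, 31L)) {
  qf <- quality_filter(eyes, quality_threshold)
  excluded <- vapply(qf$excluded, function(e) e$volume$eye_id, character(1))
  rows <- list()
  for (e in qf$included) {
    r <- tryCatch(measure_eye(e$volume, e$masks, window = window),
                  error = function(err) {
                    warning("skipping ", e$volume$eye_id, ": ",
                            conditionMessage(err), call. = FALSE)
                    NULL
                  })
    if (!is.null(r)) rows[[length(rows) + 1L]] <- r
  }
  if (!length(rows)) stop("measure_cohort: no eye could be measured")
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  out
}
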