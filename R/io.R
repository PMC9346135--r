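# Volume IO and boundary extraction. B-scans and masks are written as 8-bit
# grayscale PNG; masks carry the compartment codes directly as pixel values
# (0 background/sclera, 1 vitreous, 2 retina, 3 choroid), which round-trips
# exactly through 8-bit PNG.

MASK_LABELS <- c(background = 0L, vitreous = 1L, retina = 2L, choroid = 3L)

#' Write a synthetic eye to a dataset directory
#'
#' Writes one grayscale PNG per B-scan (`bscan_000.png`, ...), one label-mask
#' PNG per B-scan (`mask_000.png`, ...), and a `metadata.json` with the
#' covariates, quality score and scan geometry. When the ground truth is
#' supplied it is stored as `truth.json`.
#'
#' @param eye a [generate_eye()] result (or any list with `volume`, `masks`,
#'   optionally `truth`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_volume <- function(eye, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vol <- eye$volume
  if (is.null(vol$bscans))
    stop("write_volume: volume has no intensity B-scans (generate with intensity = TRUE)")
  for (b in seq_along(vol$bscans)) {
    png::writePNG(vol$bscans[[b]], file.path(dir, sprintf("bscan_%03d.png", b - 1L)))
    png::writePNG(eye$masks[[b]] / 255, file.path(dir, sprintf("mask_%03d.png", b - 1L)))
  }
  meta <- list(eye_id = vol$eye_id, side = vol$side, sex = vol$sex,
               origin = vol$origin, quality = vol$quality,
               geometry = unclass(vol$geometry))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(eye$truth))
    jsonlite::write_json(
      list(pit_bscan = eye$truth$pit_bscan, pit_x_um = eye$truth$pit_x_um,
           true_measurements = as.list(eye$truth$true_measurements)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an OCT volume and its compartment masks from a directory
#'
#' Expects equally sized `bscan_*.png` / `mask_*.png` pairs and a
#' `metadata.json` as written by [write_volume()]. Masks must contain only
#' the labels 0 (background/sclera), 1 (vitreous), 2 (retina), 3 (choroid).
#'
#' @param dir dataset directory for one eye.
#' @return list with `volume` (class `oct_volume`) and `masks`.
#' @export
read_volume <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path)) stop("read_volume: missing metadata.json in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  g <- do.call(scan_geometry, meta$geometry)
  bfiles <- sort(list.files(dir, "^bscan_\\d+\\.png$", full.names = TRUE))
  if (!length(bfiles)) stop("read_volume: no B-scan images in ", dir)
  bscans <- vector("list", length(bfiles))
  masks <- vector("list", length(bfiles))
  for (i in seq_along(bfiles)) {
    mfile <- file.path(dir, sub("^bscan_", "mask_", basename(bfiles[i])))
    if (!file.exists(mfile))
      stop("read_volume: missing mask for ", basename(bfiles[i]))
    img <- png::readPNG(bfiles[i])
    msk <- round(png::readPNG(mfile) * 255)
    if (length(dim(img)) != 2L || length(dim(msk)) != 2L)
      stop("read_volume: ", basename(bfiles[i]), " is not a grayscale image")
    if (!all(dim(img) == dim(msk)))
      stop("read_volume: size mismatch between ", basename(bfiles[i]),
           " and ", basename(mfile))
    bad <- setdiff(unique(as.vector(msk)), MASK_LABELS)
    if (length(bad))
      stop("read_volume: unknown label value ", paste(bad, collapse = ", "),
           " in ", basename(mfile))
    bscans[[i]] <- img
    masks[[i]] <- matrix(as.integer(msk), nrow = nrow(msk))
  }
  if (length(bscans) != g$n_bscans)
    stop("read_volume: found ", length(bscans), " B-scans, geometry expects ",
         g$n_bscans)
  volume <- structure(list(bscans = bscans, geometry = g,
                           quality = as.integer(meta$quality),
                           eye_id = meta$eye_id, side = meta$side,
                           sex = meta$sex, origin = meta$origin),
                      class = "oct_volume")
  list(volume = volume, masks = masks)
}

#' Extract layer-boundary curves from compartment masks
#'
#' For every A-scan column of every mask, requires exactly one contiguous run
#' per compartment in the fixed vertical order vitreous, retina, choroid,
#' background (vitreous may be absent at the top), and returns the three
#' boundary depth profiles in axial pixels from the image top, half-open:
#' `ilm` = depth of the first retina pixel (the vitreous/retina border),
#' `choroid_inner` = depth of the first choroid pixel, `choroid_outer` = depth
#' one past the last choroid pixel, so `choroid_outer - choroid_inner` equals
#' the column's choroid pixel count. Columns without retina or choroid, or
#' with a compartment split into multiple runs, are hard errors: the measured
#' landmark span must be fully covered.
#'
#' @param masks list of `depth_px x width_px` integer label matrices.
#' @return object of class `boundary_curves`: list of three
#'   `n_bscans x width_px` matrices `ilm`, `choroid_inner`, `choroid_outer`
#'   (units: axial pixels, depth increasing downward).
#' @export
extract_boundaries <- function(masks) {
  n <- length(masks)
  if (!n) stop("extract_boundaries: empty mask stack")
  wpx <- ncol(masks[[1]])
  ilm <- inner <- outer <- matrix(NA_real_, n, wpx)
  # rank of each label in the required top-to-bottom order
  rank_of <- c(4L, 1L, 2L, 3L)  # indexed by label + 1: bg=4, vit=1, ret=2, cho=3
  for (b in seq_len(n)) {
    m <- masks[[b]]
    bad <- setdiff(unique(as.vector(m)), MASK_LABELS)
    if (length(bad))
      stop("extract_boundaries: unknown label ", paste(bad, collapse = ", "),
           " in B-scan ", b)
    r <- matrix(rank_of[m + 1L], nrow = nrow(m))
    viol <- which(colSums(diff(r) < 0) > 0)
    if (length(viol))
      stop("extract_boundaries: compartment split into multiple runs or out ",
           "of order in B-scan ", b, ", column ", viol[1])
    n_vit <- colSums(m == 1L)
    n_ret <- colSums(m == 2L)
    n_cho <- colSums(m == 3L)
    if (any(n_ret == 0L))
      stop("extract_boundaries: no retina pixels in B-scan ", b, ", column ",
           which(n_ret == 0L)[1])
    if (any(n_cho == 0L))
      stop("extract_boundaries: no choroid pixels in B-scan ", b, ", column ",
           which(n_cho == 0L)[1])
    ilm[b, ] <- n_vit
    inner[b, ] <- n_vit + n_ret
    outer[b, ] <- n_vit + n_ret + n_cho
  }
  structure(list(ilm = ilm, choroid_inner = inner, choroid_outer = outer),
            class = "boundary_curves")
}

#' Partition volumes by scan quality
#'
#' Applies the manufacturer-score inclusion rule: a volume is included when
#' its quality score is at least `threshold` (boundary inclusive).
#'
#' @param volumes list of `oct_volume` objects (or of [generate_eye()] results,
#'   whose `$volume` is then used for the score).
#' @param threshold minimum quality score for inclusion.
#' @return list with `included` and `excluded`, a disjoint exhaustive
#'   partition of the input.
#' @export
quality_filter <- function(volumes, threshold = 25L) {
  q <- vapply(volumes, function(v) {
    if (!is.null(v$volume)) v <- v$volume
    if (is.null(v$quality)) stop("quality_filter: volume without quality score")
    as.numeric(v$quality)
  }, numeric(1))
  list(included = volumes[q >= threshold], excluded = volumes[q < threshold])
}
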