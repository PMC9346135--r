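# Synthetic OCT-segmentation generator. Emulates a macular volume scan with a
# foveal pit in the ILM and a choroid band whose thickness is piecewise linear
# through nine landmark targets, so every landmark measurement has an exact
# closed-form truth.

# Nasal offsets (um) of the nine thickness landmarks: T1 = 2000 um nasal,
# T5 = nulla, T9 = 2000 um temporal.
landmark_nasal_offsets_um <- function() (5 - 1:9) * 500

#' Parametric ground truth for one synthetic eye
#'
#' Defines the internal limiting membrane (ILM) as a smooth surface with an
#' inverted-Gaussian foveal pit, a constant-thickness retina, and a choroid
#' whose thickness is piecewise linear through nine per-landmark targets
#' (constant beyond +/- 2000 um of the pit center). All 21 landmark values
#' (T1-T9, A1-A8, TUn/TUt, AUn/AUt) follow in closed form.
#'
#' @param geometry a [scan_geometry()].
#' @param pit_bscan 1-based index of the B-scan through the pit center.
#' @param pit_x_um lateral position (um) of the pit center.
#' @param pit_depth_um depth of the foveal pit below the surrounding ILM (um).
#'   Set to 0 with `plateau_halfwidth_um > 0` unsupported; use
#'   `plateau_halfwidth_um` together with a positive depth for a flat-bottomed
#'   pit (tie-handling tests).
#' @param pit_sigma_x_um,pit_sigma_b_um Gaussian pit widths (um) along the
#'   lateral axis and across B-scans.
#' @param ilm_base_um ILM depth (um from image top) away from the pit.
#' @param retina_um retinal thickness (um), constant across the scan.
#' @param landmark_thickness_um numeric length 9: true choroidal thickness at
#'   T1..T9 (T1 nasal-most, T5 at the pit center, T9 temporal-most).
#' @param side `"OD"` or `"OS"`; OS eyes are lateral mirror images of the OD
#'   layout under the default laterality convention.
#' @param plateau_halfwidth_um if > 0, the pit bottom is flattened to its
#'   deepest value within this lateral half-width (produces exact depth ties).
#' @return An object of class `eye_truth` with fields `pit_bscan`, `pit_x_um`,
#'   `landmarks`, `true_measurements` (named length-21 vector), the profile
#'   parameters, and closures `ilm_um(bscan, x_um)` / `choroid_um(x_um)`.
#' @export
eye_truth <- function(geometry,
                      pit_bscan = (geometry$n_bscans + 1L) %/% 2L,
                      pit_x_um = geometry$width_um / 2,
                      pit_depth_um = 120,
                      pit_sigma_x_um = 350,
                      pit_sigma_b_um = 500,
                      ilm_base_um = 550,
                      retina_um = 190,
                      landmark_thickness_um = rep(193, 9),
                      side = c("OD", "OS"),
                      plateau_halfwidth_um = 0) {
  side <- match.arg(side)
  stopifnot(length(landmark_thickness_um) == 9, all(landmark_thickness_um > 0),
            pit_depth_um >= 0, pit_sigma_x_um > 0, pit_sigma_b_um > 0,
            retina_um > 0)
  dir <- nasal_direction(side)
  offs <- landmark_nasal_offsets_um()
  # landmark lateral positions, ordered by lateral coordinate
  x_landmark <- pit_x_um + dir * offs
  ord <- order(x_landmark)

  ilm_um <- function(bscan, x_um) {
    db <- (bscan - pit_bscan) * geometry$bscan_spacing_um
    dx <- x_um - pit_x_um
    if (plateau_halfwidth_um > 0) dx <- pmax(abs(dx) - plateau_halfwidth_um, 0)
    ilm_base_um + pit_depth_um *
      exp(-(dx^2 / (2 * pit_sigma_x_um^2) + db^2 / (2 * pit_sigma_b_um^2)))
  }
  choroid_um <- function(x_um) {
    stats::approx(x_landmark[ord], landmark_thickness_um[ord], xout = x_um,
                  rule = 2)$y
  }

  tt <- unname(landmark_thickness_um)
  a <- 250 * (tt[1:8] + tt[2:9])           # 500-um trapezoids on a linear profile
  tun <- tt[5] + (tt[4] - tt[5]) * 100 / 500
  tut <- tt[5] + (tt[6] - tt[5]) * 100 / 500
  meas <- c(stats::setNames(tt, paste0("T", 1:9)),
            stats::setNames(a, paste0("A", 1:8)),
            TUn = tun, TUt = tut,
            AUn = 50 * (tt[5] + tun), AUt = 50 * (tt[5] + tut))

  structure(list(pit_bscan = pit_bscan, pit_x_um = pit_x_um,
                 pit_depth_um = pit_depth_um, pit_sigma_x_um = pit_sigma_x_um,
                 pit_sigma_b_um = pit_sigma_b_um, ilm_base_um = ilm_base_um,
                 retina_um = retina_um,
                 landmarks = stats::setNames(tt, paste0("T", 1:9)),
                 true_measurements = meas, side = side,
                 plateau_halfwidth_um = plateau_halfwidth_um,
                 ilm_um = ilm_um, choroid_um = choroid_um),
            class = "eye_truth")
}

#' Parametric layer boundaries of a synthetic eye, in micrometers
#'
#' Evaluates the truth's ILM, inner choroid and outer choroid boundary depths
#' on the full (B-scan x lateral pixel) grid, before rasterization.
#'
#' @param truth an [eye_truth()].
#' @param geometry the matching [scan_geometry()].
#' @return list of three `n_bscans x width_px` matrices (um from image top):
#'   `ilm`, `choroid_inner`, `choroid_outer`.
#' @export
truth_boundaries_um <- function(truth, geometry) {
  x <- (seq_len(geometry$width_px) - 1) * lateral_scale(geometry)
  ilm <- t(vapply(seq_len(geometry$n_bscans),
                  function(b) truth$ilm_um(b, x),
                  numeric(geometry$width_px)))
  cho <- truth$choroid_um(x)
  inner <- ilm + truth$retina_um
  outer <- sweep(inner, 2, cho, `+`)
  list(ilm = ilm, choroid_inner = inner, choroid_outer = outer)
}

#' Generate one synthetic eye: OCT volume, masks and ground truth
#'
#' Rasterizes the parametric truth onto the scan grid: each A-scan column is a
#' vertically ordered run of vitreous, retina, choroid and background/sclera
#' pixels (labels 1, 2, 3, 0). Boundary depths are rounded to the nearest
#' axial pixel, so rasterized boundaries differ from the parametric profiles
#' by at most half a pixel and measured thicknesses by at most one pixel.
#' Intensity B-scans (optional) carry per-compartment base reflectivity with
#' multiplicative speckle-like noise; masks stay noise-free.
#'
#' @param geometry a [scan_geometry()].
#' @param truth an [eye_truth()]; its profiles must fit inside the scan depth.
#' @param seed integer seed for the speckle noise (masks are deterministic).
#' @param intensity logical; render intensity B-scans (`TRUE`) or only masks.
#' @param quality manufacturer-style integer scan-quality score to attach.
#' @param eye_id,sex,origin covariates attached to the volume.
#' @param noise_sd standard deviation of the log-normal speckle multiplier.
#' @return list with `volume` (class `oct_volume`), `masks` (list of
#'   `depth_px x width_px` integer matrices) and `truth`.
#' @export
generate_eye <- function(geometry, truth = eye_truth(geometry), seed = 1L,
                         intensity = TRUE, quality = 30L, eye_id = "eye001",
                         sex = "male", origin = "Mauritius",
                         noise_sd = 0.25) {
  bd <- truth_boundaries_um(truth, geometry)
  if (max(bd$choroid_outer) >= geometry$depth_um)
    stop("geometry overflow: layer profiles exceed the scan depth (",
         round(max(bd$choroid_outer), 1), " um >= ", geometry$depth_um, " um)")
  s <- axial_scale(geometry)
  dpx <- geometry$depth_px
  wpx <- geometry$width_px
  rows <- rep(seq_len(dpx), times = wpx)  # column-major row index vector

  masks <- vector("list", geometry$n_bscans)
  bscans <- if (intensity) vector("list", geometry$n_bscans) else NULL
  if (intensity) set.seed(as.integer(seed))
  base_int <- c(`0` = 0.20, `1` = 0.08, `2` = 0.55, `3` = 0.70)  # bg,vit,ret,cho
  for (b in seq_len(geometry$n_bscans)) {
    ilm_px <- round(bd$ilm[b, ] / s)
    inner_px <- round(bd$choroid_inner[b, ] / s)
    outer_px <- round(bd$choroid_outer[b, ] / s)
    code <- (rows > rep(ilm_px, each = dpx)) +
            (rows > rep(inner_px, each = dpx)) +
            (rows > rep(outer_px, each = dpx))
    lab <- c(1L, 2L, 3L, 0L)[code + 1L]
    m <- matrix(lab, nrow = dpx, ncol = wpx)
    masks[[b]] <- m
    if (intensity) {
      img <- base_int[as.character(m)] *
        exp(stats::rnorm(length(m), 0, noise_sd) - noise_sd^2 / 2)
      bscans[[b]] <- matrix(pmin(pmax(img, 0), 1), nrow = dpx, ncol = wpx)
    }
  }
  volume <- structure(list(bscans = bscans, geometry = geometry,
                           quality = as.integer(quality), eye_id = eye_id,
                           side = truth$side, sex = sex, origin = origin),
                      class = "oct_volume")
  list(volume = volume, masks = masks, truth = truth)
}

#' @export
print.oct_volume <- function(x, ...) {
  cat(sprintf("oct_volume %s (%s, %s, %s): %d B-scans, quality %d%s\n",
              x$eye_id, x$side, x$sex, x$origin, x$geometry$n_bscans,
              x$quality,
              if (is.null(x$bscans)) " [masks-only]" else ""))
  invisible(x)
}

#' Population model for synthetic cohorts
#'
#' Per-landmark thickness distributions and covariate frequencies from which
#' [generate_cohort()] draws eyes. The `"paper_cohort"` preset encodes the
#' reference cohort: overall nulla choroidal thickness 192.83 um with a
#' coefficient of variation of 7.8% (sd 15.04 um) at every landmark, sex
#' frequencies (female 0.393), origin frequencies (Mauritius 0.5321,
#' Asia 0.4251, unknown 0.0428) and near-balanced eye sides.
#'
#' Per-eye landmark thicknesses are drawn as `mean + shared eye effect +
#' landmark residual`, with `eye_effect_share` of the variance carried by the
#' shared effect; marginal per-landmark mean and sd are exact, and adjacent
#' landmarks correlate at about the share value.
#'
#' @param n_eyes number of eyes to draw.
#' @param preset `NULL` or `"paper_cohort"`.
#' @param t_mean_um,t_sd_um numeric length 9 (or 1, recycled): per-landmark
#'   thickness mean and sd in um.
#' @param eye_effect_share fraction of thickness variance shared across the
#'   nine landmarks of one eye (0..1).
#' @param sex_freq,origin_freq,side_freq named probability vectors; must sum
#'   to 1.
#' @param quality_range,quality_mode support and mode of the integer scan
#'   quality score (triangular-ish discretized normal around the mode).
#' @param seed integer RNG seed.
#' @return object of class `population_model`.
#' @export
population_model <- function(n_eyes, preset = NULL,
                             t_mean_um = rep(192.83, 9),
                             t_sd_um = rep(15.04, 9),
                             eye_effect_share = 0.7,
                             sex_freq = c(female = 0.393, male = 0.607),
                             origin_freq = c(Mauritius = 0.5321, Asia = 0.4251,
                                             unknown = 0.0428),
                             side_freq = c(OD = 0.5027, OS = 0.4973),
                             quality_range = c(15L, 40L), quality_mode = 31,
                             seed = 1L) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "paper_cohort")
    # defaults above ARE the paper_cohort preset; keep explicit for clarity
    t_mean_um <- rep(192.83, 9)
    t_sd_um <- rep(192.83 * 0.078, 9)
  }
  if (length(n_eyes) != 1L || n_eyes <= 0) stop("n_eyes must be positive")
  t_mean_um <- rep_len(t_mean_um, 9)
  t_sd_um <- rep_len(t_sd_um, 9)
  stopifnot(all(t_sd_um >= 0), eye_effect_share >= 0, eye_effect_share <= 1)
  for (fr in list(sex_freq, origin_freq, side_freq))
    if (abs(sum(fr) - 1) > 1e-8) stop("covariate frequencies must sum to 1")
  structure(list(n_eyes = as.integer(n_eyes), t_mean_um = t_mean_um,
                 t_sd_um = t_sd_um, eye_effect_share = eye_effect_share,
                 sex_freq = sex_freq, origin_freq = origin_freq,
                 side_freq = side_freq, quality_range = as.integer(quality_range),
                 quality_mode = quality_mode, seed = as.integer(seed)),
            class = "population_model")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-eye landmark thickness truths, covariates and scan quality from a
#' [population_model()], and (optionally) rasterizes each eye into masks and
#' intensity B-scans. All population-level randomness is drawn before any
#' rasterization, so the truth table is identical whether or not
#' `rasterize = TRUE`.
#'
#' @param model a [population_model()].
#' @param geometry a [scan_geometry()].
#' @param rasterize render masks (and optionally images) for each eye.
#' @param intensity render intensity B-scans too (slower; masks suffice for
#'   the measurement pipeline).
#' @return list with `truth_table` (one row per eye: covariates, quality and
#'   the 21 true landmark values) and, when `rasterize = TRUE`, `eyes`, a list
#'   of [generate_eye()] results aligned with the table rows.
#' @export
generate_cohort <- function(model, geometry = scan_geometry(),
                            rasterize = TRUE, intensity = FALSE) {
  drawn <- draw_cohort(model, geometry)
  out <- list(truth_table = drawn$truth_table, model = model,
              geometry = geometry)
  if (rasterize) {
    out$eyes <- lapply(seq_len(model$n_eyes), function(i)
      rasterize_cohort_eye(drawn, i, geometry, intensity))
  }
  out
}

# All population-level randomness for a cohort, drawn before any
# rasterization so the truth table does not depend on whether masks are
# rendered. Internal.
draw_cohort <- function(model, geometry) {
  set.seed(model$seed)
  n <- model$n_eyes
  share <- model$eye_effect_share
  eye_sd <- sqrt(share) * model$t_sd_um    # length 9; shared effect scaled per landmark
  res_sd <- sqrt(1 - share) * model$t_sd_um

  z_eye <- stats::rnorm(n)
  tmat <- t(vapply(seq_len(n), function(i) {
    model$t_mean_um + z_eye[i] * eye_sd + stats::rnorm(9, 0, res_sd)
  }, numeric(9)))
  colnames(tmat) <- paste0("T", 1:9)

  sex <- sample(names(model$sex_freq), n, TRUE, prob = model$sex_freq)
  origin <- sample(names(model$origin_freq), n, TRUE, prob = model$origin_freq)
  side <- sample(names(model$side_freq), n, TRUE, prob = model$side_freq)
  qsup <- seq(model$quality_range[1], model$quality_range[2])
  quality <- sample(qsup, n, TRUE,
                    prob = stats::dnorm(qsup, model$quality_mode, 4.5))
  ctr_b <- (geometry$n_bscans + 1L) %/% 2L
  pit_bscan <- ctr_b + sample(-2:2, n, TRUE)
  pit_x <- geometry$width_um / 2 + stats::runif(n, -200, 200)
  pit_depth <- pmax(stats::rnorm(n, 120, 10), 60)
  eye_seeds <- sample.int(.Machine$integer.max, n)

  truths <- lapply(seq_len(n), function(i) {
    eye_truth(geometry, pit_bscan = pit_bscan[i], pit_x_um = pit_x[i],
              pit_depth_um = pit_depth[i], landmark_thickness_um = tmat[i, ],
              side = side[i])
  })
  truth_table <- data.frame(
    eye_id = sprintf("eye%04d", seq_len(n)), side = side, sex = sex,
    origin = origin, quality = quality,
    do.call(rbind, lapply(truths, function(tr) t(tr$true_measurements))),
    stringsAsFactors = FALSE)

  list(truth_table = truth_table, truths = truths, eye_seeds = eye_seeds)
}

# Rasterize eye i of a drawn cohort. Internal.
rasterize_cohort_eye <- function(drawn, i, geometry, intensity = FALSE) {
  tt <- drawn$truth_table
  generate_eye(geometry, drawn$truths[[i]], seed = drawn$eye_seeds[i],
               intensity = intensity, quality = tt$quality[i],
               eye_id = tt$eye_id[i], sex = tt$sex[i], origin = tt$origin[i])
}

#' Simulate and measure a cohort eye-by-eye
#'
#' Streaming variant of `generate_cohort(rasterize = TRUE)` followed by
#' [measure_cohort()]: each eye is rasterized, pushed through the full
#' measurement pipeline and discarded before the next one is generated, so
#' memory use stays at a single volume regardless of cohort size. The drawn
#' truth table is identical to [generate_cohort()]'s for the same model and
#' geometry.
#'
#' @inheritParams generate_cohort
#' @inheritParams measure_cohort
#' @return list with `measurements` (one row per included, measurable eye)
#'   and `truth_table` (all eyes).
#' @export
simulate_and_measure <- function(model, geometry = scan_geometry(),
                                 quality_threshold = 25L,
                                 window = c(3L, 31L)) {
  drawn <- draw_cohort(model, geometry)
  rows <- list()
  for (i in seq_len(model$n_eyes)) {
    if (drawn$truth_table$quality[i] < quality_threshold) next
    eye <- rasterize_cohort_eye(drawn, i, geometry, intensity = FALSE)
    r <- tryCatch(measure_eye(eye$volume, eye$masks, window = window),
                  error = function(err) {
                    warning("skipping ", eye$volume$eye_id, ": ",
                            conditionMessage(err), call. = FALSE)
                    NULL
                  })
    if (!is.null(r)) rows[[length(rows) + 1L]] <- r
  }
  if (!length(rows)) stop("simulate_and_measure: no eye could be measured")
  list(measurements = do.call(rbind, rows), truth_table = drawn$truth_table)
}

#' Ground-truth split arithmetic
#'
#' Converts an eye-level train/validation/test split into B-scan counts, as
#' used when assembling a segmentation ground truth (e.g. 44 eyes of 25
#' B-scans split 27/9/8 gives 675/225/200 B-scans).
#'
#' @param n_eyes total eyes in the ground truth.
#' @param bscans_per_eye B-scans contributed per eye.
#' @param split_eyes integer length 3: eyes in (train, validation, test);
#'   must sum to `n_eyes`.
#' @return named integer vector of B-scan counts (train, validation, test).
#' @export
split_ground_truth <- function(n_eyes, bscans_per_eye, split_eyes) {
  if (length(split_eyes) != 3L || sum(split_eyes) != n_eyes)
    stop("split_eyes must have length 3 and sum to n_eyes (",
         sum(split_eyes), " != ", n_eyes, ")")
  stats::setNames(as.integer(split_eyes * bscans_per_eye),
                  c("train", "validation", "test"))
}

#' Augment B-scans by mirroring and random rotation
#'
#' Training-set style augmentation: each input B-scan contributes itself, its
#' mirror image about the vertical axis, and a copy rotated by an angle drawn
#' uniformly from `rotation_range_deg` (bilinear interpolation, original frame
#' retained), tripling the set size.
#'
#' @param bscans nonempty list of numeric matrices (`depth x width`, values in
#'   `[0, 1]`).
#' @param rotation_range_deg numeric length 2: rotation angle range in degrees.
#' @param seed integer seed for the rotation angles.
#' @return list of `3 * length(bscans)` matrices: originals, then mirrored,
#'   then rotated copies, with `rotation_deg` attribute on the rotated block.
#' @export
augment_bscans <- function(bscans, rotation_range_deg = c(-8, 8), seed = 1L) {
  if (!length(bscans)) stop("augment_bscans: empty input")
  set.seed(as.integer(seed))
  angles <- stats::runif(length(bscans), rotation_range_deg[1],
                         rotation_range_deg[2])
  mirrored <- lapply(bscans, function(m) m[, ncol(m):1, drop = FALSE])
  rotated <- mapply(function(m, a) {
    r <- EBImage::rotate(m, a, output.dim = dim(m), bg.col = 0)
    matrix(as.numeric(r), nrow = nrow(m))
  }, bscans, angles, SIMPLIFY = FALSE)
  attr(rotated, "rotation_deg") <- angles
  c(bscans, mirrored, rotated)
}
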