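test_that("thickness converts choroid pixel count by the axial scale", {
  g <- scan_geometry()  # 1900/496 um per axial pixel
  bd <- analytic_boundaries(g, function(x) rep(380, length(x)),
                            function(x) rep(50 * axial_scale(g), length(x)),
                            n_bscans = 1L)
  expect_equal(thickness_at(bd, 1, 1000, g), 50 * 1900 / 496)
  # constant boundaries: identical thickness at any fractional position
  xs <- c(0, 123.4, 2650, 5287.9)
  expect_equal(thickness_at(bd, 1, xs, g), rep(50 * 1900 / 496, 4))
  expect_error(thickness_at(bd, 1, 6000, g), "outside the scanned extent")
})

test_that("linear boundary ramps interpolate exactly between pixels", {
  g <- small_geometry(1L)
  ls <- lateral_scale(g)
  # thickness grows linearly along the scan: at the midpoint between two
  # pixel nodes the thickness is the mean of the node thicknesses
  bd <- analytic_boundaries(g, function(x) rep(100, length(x)),
                            function(x) 150 + 0.01 * x, n_bscans = 1L)
  t10 <- thickness_at(bd, 1, 10 * ls, g)
  t11 <- thickness_at(bd, 1, 11 * ls, g)
  expect_equal(thickness_at(bd, 1, 10.5 * ls, g), (t10 + t11) / 2)
})

test_that("constant 193-um choroid yields the rectangular landmark values", {
  g <- small_geometry(1L)
  bd <- analytic_boundaries(g, function(x) rep(100, length(x)),
                            function(x) rep(193, length(x)), n_bscans = 1L)
  tt <- measure_landmarks(bd, 1, 2650, "OD", g)
  expect_equal(unname(tt), rep(193, 9))
  expect_equal(area_between(bd, 1, 2150, 2650, g), 96500)
  expect_equal(area_between(bd, 1, 2650, 2750, g), 19300)
})

test_that("areas match a dense-quadrature oracle on a smooth profile", {
  g <- small_geometry(1L)
  thick_fun <- function(x) 180 + 30 * sin(x / 700) + 10 * cos(x / 311)
  bd <- analytic_boundaries(g, function(x) rep(100, length(x)), thick_fun,
                            n_bscans = 1L)
  for (iv in list(c(650, 4650), c(2650, 2750), c(1000, 1500))) {
    xs <- seq(iv[1], iv[2], length.out = 1001)
    th <- thickness_at(bd, 1, xs, g)
    oracle <- sum(diff(xs) * (th[-1001] + th[-1]) / 2)
    expect_equal(area_between(bd, 1, iv[1], iv[2], g), oracle,
                 tolerance = 0.005)
  }
  expect_error(area_between(bd, 1, 2000, 1500, g), "x1_um < x2_um")
})

test_that("the eight areas partition the full +/- 2000 um span", {
  g <- small_geometry()
  eye <- small_eye(g, thickness = c(150, 170, 200, 210, 193, 180, 205, 220, 160))
  m <- measure_eye(eye$volume, eye$masks, window = c(3L, 9L))
  bd <- extract_boundaries(eye$masks)
  b <- round(m$nulla_bscan)
  total <- area_between(bd, b, m$nulla_x_um - 2000, m$nulla_x_um + 2000, g)
  expect_equal(sum(unlist(m[paste0("A", 1:8)])), total, tolerance = 1e-6)
})

test_that("measure_eye emits 17 grid parameters plus the 5-member nulla sub-analysis", {
  eye <- small_eye(small_geometry())
  m <- measure_eye(eye$volume, eye$masks, window = c(3L, 9L))
  grid_params <- c(paste0("T", 1:9), paste0("A", 1:8))
  sub_analysis <- c("T5", "TUn", "TUt", "AUn", "AUt")
  expect_true(all(grid_params %in% names(m)))
  expect_length(grid_params, 17)
  expect_length(sub_analysis, 5)
  expect_true(all(unlist(m[grid_params]) > 0))
})

test_that("the full pipeline recovers generator truth within stated tolerances", {
  g <- small_geometry()
  for (seed in 1:3) {
    set.seed(seed * 100)
    th <- runif(9, 160, 230)
    eye <- small_eye(g, thickness = th, seed = seed)
    m <- measure_eye(eye$volume, eye$masks, window = c(3L, 9L))
    truth <- eye$truth$true_measurements
    tol_t <- 2 * axial_scale(g)
    expect_lt(max(abs(unlist(m[paste0("T", 1:9)]) - truth[paste0("T", 1:9)])),
              tol_t)
    a_meas <- unlist(m[c(paste0("A", 1:8), "AUn", "AUt")])
    a_true <- truth[c(paste0("A", 1:8), "AUn", "AUt")]
    expect_lt(max(abs(a_meas / a_true - 1)), 0.02)
    expect_lt(max(abs(unlist(m[c("TUn", "TUt")]) - truth[c("TUn", "TUt")])),
              tol_t)
  }
})

test_that("OD/OS mirroring swaps nasal and temporal blocks with identical values", {
  g <- small_geometry()
  th <- c(150, 170, 200, 210, 193, 180, 205, 220, 160)
  tr_od <- eye_truth(g, landmark_thickness_um = th, side = "OD")
  eye_od <- generate_eye(g, tr_od, intensity = FALSE)
  # mirror the volume laterally and relabel it OS
  masks_os <- lapply(eye_od$masks, function(m) m[, ncol(m):1])
  vol_os <- eye_od$volume
  vol_os$side <- "OS"
  m_od <- measure_eye(eye_od$volume, eye_od$masks, window = c(3L, 9L))
  m_os <- measure_eye(vol_os, masks_os, window = c(3L, 9L))
  for (v in c(paste0("T", 1:9), paste0("A", 1:8), "TUn", "TUt", "AUn", "AUt"))
    expect_equal(m_os[[v]], m_od[[v]], tolerance = 1e-8)
  expect_equal(m_os$nulla_x_um, g$width_um - lateral_scale(g) - m_od$nulla_x_um,
               tolerance = 1e-8)
  # truth for an OS eye generated directly also swaps blockwise
  tr_os <- eye_truth(g, landmark_thickness_um = th, side = "OS")
  expect_equal(tr_os$true_measurements, tr_od$true_measurements)
})

test_that("thicknesses and areas scale with the axial and lateral pixel sizes", {
  base <- small_geometry(1L)
  thick_fun <- function(x) 180 + 20 * sin(x / 500)
  mk <- function(g) analytic_boundaries(g, function(x) rep(100, length(x)),
                                        thick_fun, n_bscans = 1L)
  # doubling the axial extent doubles thickness and area
  g2 <- scan_geometry(base$width_px, base$depth_px, 1L, base$width_um,
                      2 * base$depth_um, base$bscan_spacing_um)
  bd1 <- mk(base)
  bd2 <- bd1
  bd2$choroid_outer <- bd2$choroid_inner +
    (bd1$choroid_outer - bd1$choroid_inner)  # same pixel curves, new scale
  expect_equal(thickness_at(bd2, 1, 2000, g2),
               2 * thickness_at(bd1, 1, 2000, base))
  expect_equal(area_between(bd2, 1, 1000, 1500, g2),
               2 * area_between(bd1, 1, 1000, 1500, base))
  # doubling the lateral extent doubles areas but not thickness (constant profile)
  gl <- scan_geometry(base$width_px, base$depth_px, 1L, 2 * base$width_um,
                      base$depth_um, base$bscan_spacing_um)
  bdc <- analytic_boundaries(base, function(x) rep(100, length(x)),
                             function(x) rep(193, length(x)), n_bscans = 1L)
  expect_equal(thickness_at(bdc, 1, 2000, gl), thickness_at(bdc, 1, 2000, base))
  expect_equal(area_between(bdc, 1, 1000, 2000, gl),
               area_between(bdc, 1, 1000, 2000, base))  # same um interval
})

test_that("landmarks falling outside the scan are reported by name", {
  g <- small_geometry(1L)
  bd <- analytic_boundaries(g, function(x) rep(100, length(x)),
                            function(x) rep(193, length(x)), n_bscans = 1L)
  expect_error(measure_landmarks(bd, 1, 500, "OD", g), "landmark T")
})
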