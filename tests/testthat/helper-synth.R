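# Shared fixtures: a reduced scan geometry that keeps the physical extents of
# the default protocol (so all +/- 2000 um landmarks stay in range) at a
# fraction of the raster size, plus independent brute-force oracles.

small_geometry <- function(n_bscans = 7L) {
  scan_geometry(width_px = 128L, depth_px = 200L, n_bscans = n_bscans,
                width_um = 5300, depth_um = 1900, bscan_spacing_um = 221)
}

small_eye <- function(geometry = small_geometry(), thickness = rep(193, 9),
                      side = "OD", seed = 1L, intensity = FALSE, ...) {
  tr <- eye_truth(geometry, landmark_thickness_um = thickness, side = side, ...)
  generate_eye(geometry, tr, seed = seed, intensity = intensity)
}

# Boundary curves with exactly known fractional-pixel depths (bypasses
# rasterization for arithmetic-exact morphometry checks).
analytic_boundaries <- function(geometry, inner_fun, thickness_fun,
                                n_bscans = geometry$n_bscans) {
  x <- (seq_len(geometry$width_px) - 1) * lateral_scale(geometry)
  inner <- t(vapply(seq_len(n_bscans), function(b) inner_fun(x),
                    numeric(geometry$width_px)))
  thick_px <- t(vapply(seq_len(n_bscans),
                       function(b) thickness_fun(x) / axial_scale(geometry),
                       numeric(geometry$width_px)))
  structure(list(ilm = inner - 50, choroid_inner = inner,
                 choroid_outer = inner + thick_px),
            class = "boundary_curves")
}

# Nested-loop windowed mean: the independent oracle for smooth_ilm.
brute_box_mean <- function(mat, w) {
  h <- (w - 1) %/% 2
  out <- mat
  for (r in seq_len(nrow(mat))) for (c in seq_len(ncol(mat))) {
    rs <- max(1, r - h[1]):min(nrow(mat), r + h[1])
    cs <- max(1, c - h[2]):min(ncol(mat), c + h[2])
    out[r, c] <- mean(mat[rs, cs])
  }
  out
}

# Exhaustive scan + centroid: the independent oracle for find_nulla.
brute_nulla <- function(depth, tol = 1e-9) {
  best <- max(depth)
  idx <- which(depth >= best - tol, arr.ind = TRUE)
  list(bscan = mean(idx[, 1]), lateral = mean(idx[, 2]), depth = best,
       n_tied = nrow(idx))
}

# Type-II sums of squares by explicit nested least squares: SS(A | B) is the
# residual-SS drop from adding A to the model already containing B.
type2_oracle <- function(d, response, f1 = "sex", f2 = "origin") {
  rss <- function(terms) {
    sum(stats::resid(stats::lm(stats::reformulate(terms, response), d))^2)
  }
  full <- stats::lm(stats::reformulate(c(f1, f2), response), d)
  rss_full <- sum(stats::resid(full)^2)
  df_res <- stats::df.residual(full)
  df1 <- length(unique(d[[f1]])) - 1L
  df2 <- length(unique(d[[f2]])) - 1L
  ss1 <- rss(f2) - rss_full
  ss2 <- rss(f1) - rss_full
  f_stat <- c(ss1 / df1, ss2 / df2) / (rss_full / df_res)
  list(sumsq = c(ss1, ss2), df = c(df1, df2), statistic = f_stat,
       p.value = stats::pf(f_stat, c(df1, df2), df_res, lower.tail = FALSE),
       rss = rss_full, df_res = df_res)
}

# Random covariate table with a response unrelated to the factors.
null_effect_table <- function(n, sd = 15) {
  data.frame(sex = sample(c("male", "female"), n, TRUE, prob = c(0.6, 0.4)),
             origin = sample(c("Mauritius", "Asia"), n, TRUE, prob = c(0.55, 0.45)),
             side = sample(c("OD", "OS"), n, TRUE),
             T5 = stats::rnorm(n, 193, sd))
}

binom99 <- function(p0, n) stats::qbinom(c(0.005, 0.995), n, p0) / n
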