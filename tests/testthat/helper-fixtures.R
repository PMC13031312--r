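# Shared fixtures: small scenes keep unit tests fast; acceptance sweeps use
# the full-size default scene.

small_scene <- function(plant_radius = 8, ...) {
  scene_spec(image_size = c(240L, 320L), row_spacing = 60,
             plant_radius = plant_radius, ...)
}

small_params <- function(...) {
  row_detection_params(row_spacing = 60, min_cluster_support = 150,
                       x_margin_frac = 0.1, ...)
}

# horizontal filled bands of given half-thickness at the given y centers
band_mask <- function(h, w, centers, half = 5) {
  m <- matrix(0L, h, w)
  for (c in centers) {
    ys <- max(1, round(c - half)):min(h, round(c + half))
    m[ys, ] <- 1L
  }
  m
}

# pixel cluster along a line y = intercept + slope * x with vertical thickness
line_cluster <- function(xs, slope, intercept, half = 3) {
  px <- py <- integer(0)
  for (x in xs) {
    yc <- round(intercept + slope * x)
    py <- c(py, (yc - half):(yc + half))
    px <- c(px, rep(x, 2 * half + 1))
  }
  cl <- list(y_center = stats::median(py), y_extent = range(py),
             n_pixels = length(py), x = px, y = py,
             slope = NA_real_, intercept = NA_real_, index_from_middle = 0L)
  cl
}

# growth schedule spanning emergence -> closure -> senescence for a
# row_spacing-60 scene (radius 29 closes the canopy)
season_schedule <- function() {
  dates <- seq(10, 130, by = 10)
  data.frame(date = dates,
             plant_radius = pmin(29, 3 + 0.45 * dates),
             greenness = ifelse(dates < 100, 1, pmax(0, 1 - 0.04 * (dates - 100))))
}
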