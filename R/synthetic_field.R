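#' Scene specification for the synthetic plot renderer
#'
#' Describes one nadir view of a row-sown plot: soil background, `n_rows`
#' horizontal plant rows rendered as jittered disks, an optional rigid
#' rotation (emulating camera misalignment relative to the plot axis),
#' emergence gaps and off-row weed blobs. All stochastic elements are driven
#' by `seed`, so a spec renders to identical bytes on repeated calls.
#'
#' @param image_size integer `c(height, width)` in pixels.
#' @param n_rows number of plant rows (>= 0).
#' @param row_spacing centre-to-centre row distance in pixels; must exceed
#'   `2 * plant_radius` so rows are geometrically separable.
#' @param rotation scene rotation in degrees, in (-15, 15).
#' @param plant_radius plant disk radius in pixels.
#' @param plant_step along-row distance between plant positions (pixels);
#'   default `1.6 * plant_radius` gives overlapping disks, i.e. a near
#'   continuous row interrupted only by emergence gaps.
#' @param emergence_gap_rate probability that a plant position stays empty.
#' @param weed_rate expected number of weed blobs per image (Poisson).
#' @param soil_color,plant_color RGB triples on the 0-255 scale.
#' @param senesced_color RGB triple the plant colour fades to as greenness
#'   drops below 1 (senescence).
#' @param greenness scalar in \[0, 1\]: 1 = fully green canopy, 0 = fully
#'   senesced (plants no longer count as green in the ground truth).
#' @param color_noise_sd per-pixel Gaussian noise SD added to every channel.
#' @param x_margin_frac horizontal inset of the ground-truth plot boundary as
#'   a fraction of image width (keeps the boundary inside rendered content
#'   under rotation).
#' @param seed integer RNG seed.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(360L, 480L), n_rows = 3, row_spacing = 80,
                       rotation = 0, plant_radius = 10, plant_step = NULL,
                       emergence_gap_rate = 0.1, weed_rate = 1,
                       soil_color = c(110, 85, 60), plant_color = c(60, 140, 55),
                       senesced_color = c(150, 115, 60), greenness = 1,
                       color_noise_sd = 5, x_margin_frac = 0.1, seed = 1L) {
  stopifnot(length(image_size) == 2, all(image_size >= 32))
  if (n_rows < 0) stop("n_rows must be >= 0")
  if (row_spacing <= 2 * plant_radius)
    stop("row_spacing must exceed 2 * plant_radius")
  if (abs(rotation) >= 15) stop("rotation must lie in (-15, 15) degrees")
  if (emergence_gap_rate < 0 || emergence_gap_rate > 1)
    stop("emergence_gap_rate must be in [0, 1]")
  if (weed_rate < 0) stop("weed_rate must be >= 0")
  if (greenness < 0 || greenness > 1) stop("greenness must be in [0, 1]")
  if (is.null(plant_step)) plant_step <- 1.6 * plant_radius
  h <- image_size[1]
  if (n_rows > 0 && (n_rows - 1) * row_spacing + 2 * plant_radius >= h)
    stop(sprintf("rows overflow image: %d rows at spacing %g px need > %g px height",
                 n_rows, row_spacing, (n_rows - 1) * row_spacing + 2 * plant_radius))
  structure(list(image_size = as.integer(image_size), n_rows = as.integer(n_rows),
                 row_spacing = row_spacing, rotation = rotation,
                 plant_radius = plant_radius, plant_step = plant_step,
                 emergence_gap_rate = emergence_gap_rate, weed_rate = weed_rate,
                 soil_color = soil_color, plant_color = plant_color,
                 senesced_color = senesced_color, greenness = greenness,
                 color_noise_sd = color_noise_sd, x_margin_frac = x_margin_frac,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' @keywords internal
raster_disks <- function(h, w, cx, cy, r) {
  m <- matrix(FALSE, h, w)
  for (i in seq_along(cx)) {
    x0 <- max(1L, ceiling(cx[i] - r[i])); x1 <- min(w, floor(cx[i] + r[i]))
    y0 <- max(1L, ceiling(cy[i] - r[i])); y1 <- min(h, floor(cy[i] + r[i]))
    if (x0 > x1 || y0 > y1) next
    ys <- y0:y1; xs <- x0:x1
    d2 <- outer((ys - cy[i])^2, (xs - cx[i])^2, "+")
    m[ys, xs] <- m[ys, xs] | (d2 <= r[i]^2)
  }
  m
}

#' @keywords internal
rotate_points <- function(x, y, cx, cy, angle_deg) {
  th <- deg2rad(angle_deg)
  dx <- x - cx; dy <- y - cy
  list(x = cx + cos(th) * dx - sin(th) * dy,
       y = cy + sin(th) * dx + cos(th) * dy)
}

#' Render one synthetic plot image with exact ground truth
#'
#' Plants are filled disks jittered along horizontal row lines, the whole
#' layout rotated rigidly about the image centre; weeds are smaller disks
#' placed between rows (never counted as rows in the ground truth, but green
#' and therefore part of the true canopy cover). The ground-truth plot
#' boundary spans the outer row centrelines expanded by half a row spacing on
#' each side, with a horizontal inset of `x_margin_frac`; `true_cc` is the
#' exact count of green pixels whose back-rotated position falls inside that
#' rectangle, divided by the rectangle's pixel area.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (height x width x 3 array, 0-255) and `truth`
#'   (list: `row_centers` at the image centre x, `true_rotation`,
#'   `plot_boundary`, `true_cc`, `green_mask`, `n_green_in_boundary`).
#' @export
render_plot_image <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  withr::with_seed(spec$seed, {
    row_centers0 <- if (spec$n_rows > 0)
      cy + (seq_len(spec$n_rows) - (spec$n_rows + 1) / 2) * spec$row_spacing
    else numeric(0)

    px <- py <- numeric(0)
    for (rc in row_centers0) {
      xs <- seq(-0.25 * w, 1.25 * w, by = spec$plant_step)
      keep <- stats::runif(length(xs)) >= spec$emergence_gap_rate
      xs <- xs[keep] + stats::rnorm(sum(keep), 0, spec$plant_step / 6)
      ys <- rc + stats::rnorm(length(xs), 0, spec$plant_radius / 4)
      px <- c(px, xs); py <- c(py, ys)
    }
    rp <- rotate_points(px, py, cx, cy, spec$rotation)
    plant_mask <- raster_disks(h, w, rp$x, rp$y,
                               rep(spec$plant_radius, length(rp$x)))

    n_weeds <- stats::rpois(1, spec$weed_rate)
    weed_mask <- matrix(FALSE, h, w)
    if (n_weeds > 0 && spec$n_rows >= 1) {
      gap_lo <- if (spec$n_rows >= 2) row_centers0[-spec$n_rows] else row_centers0 - spec$row_spacing
      gi <- sample.int(length(gap_lo), n_weeds, replace = TRUE)
      wy <- gap_lo[gi] + spec$row_spacing * stats::runif(n_weeds, 0.38, 0.62)
      wx <- stats::runif(n_weeds, 0.05 * w, 0.95 * w)
      wr <- spec$plant_radius * stats::runif(n_weeds, 0.4, 0.75)
      rw <- rotate_points(wx, wy, cx, cy, spec$rotation)
      weed_mask <- raster_disks(h, w, rw$x, rw$y, wr)
    }

    veg_mask <- plant_mask | weed_mask
    g <- spec$greenness
    veg_color <- g * spec$plant_color + (1 - g) * spec$senesced_color
    is_green <- is_green_color(veg_color)
    green_mask <- if (is_green) veg_mask else matrix(FALSE, h, w)

    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      base <- matrix(spec$soil_color[ch], h, w)
      base[veg_mask] <- veg_color[ch]
      img[, , ch] <- clamp(base + stats::rnorm(h * w, 0, spec$color_noise_sd), 0, 255)
    }
  })

  xm <- round(w * spec$x_margin_frac)
  if (spec$n_rows >= 1) {
    y_top <- round(min(row_centers0) - spec$row_spacing / 2)
    y_bottom <- round(max(row_centers0) + spec$row_spacing / 2)
  } else {
    y_top <- 1L; y_bottom <- h
  }
  boundary <- plot_geometry(y_top = max(1L, y_top), y_bottom = min(h, y_bottom),
                            x_left = max(1L, 1L + xm), x_right = min(w, w - xm),
                            rotation_applied = spec$rotation, provenance = "truth")

  gpix <- which(green_mask, arr.ind = TRUE)
  if (nrow(gpix)) {
    th <- deg2rad(spec$rotation)
    dx <- gpix[, 2] - cx; dy <- gpix[, 1] - cy
    ux <- cx + cos(th) * dx + sin(th) * dy
    uy <- cy - sin(th) * dx + cos(th) * dy
    inside <- uy >= boundary$y_top - 0.5 & uy < boundary$y_bottom + 0.5 &
      ux >= boundary$x_left - 0.5 & ux < boundary$x_right + 0.5
    n_in <- sum(inside)
  } else n_in <- 0L
  area <- (boundary$y_bottom - boundary$y_top + 1) *
    (boundary$x_right - boundary$x_left + 1)

  th <- deg2rad(spec$rotation)
  rc_at_center <- cy + (row_centers0 - cy) * cos(th)

  list(image = img,
       truth = list(row_centers = sort(rc_at_center),
                    true_rotation = spec$rotation,
                    plot_boundary = boundary,
                    true_cc = n_in / area,
                    n_green_in_boundary = as.integer(n_in),
                    green_mask = green_mask))
}

#' Render a season of images following a growth schedule
#'
#' Replays one plot through the season: the plant layout is held fixed (same
#' seed) while `plant_radius` and `greenness` follow the schedule, emulating
#' emergence, canopy closure and senescence. Later dates with a closed canopy
#' make rows indistinguishable and exercise boundary propagation downstream.
#'
#' @param spec a [scene_spec()] used as the base scene.
#' @param schedule data.frame with columns `date`, `plant_radius`,
#'   `greenness`; dates strictly increasing.
#' @return list of per-date entries: `date`, `image`, `truth`.
#' @export
render_season <- function(spec, schedule) {
  stopifnot(inherits(spec, "scene_spec"), is.data.frame(schedule))
  need <- c("date", "plant_radius", "greenness")
  if (!all(need %in% names(schedule))) stop("schedule needs columns: ",
                                            paste(need, collapse = ", "))
  if (nrow(schedule) == 0) stop("schedule must be non-empty")
  if (any(diff(as.numeric(schedule$date)) <= 0))
    stop("schedule dates must be strictly increasing")
  lapply(seq_len(nrow(schedule)), function(i) {
    # radius/greenness vary over the schedule; layout (seed, step, spacing)
    # stays fixed so the plot is the same physical plot on every date. A
    # schedule radius may legitimately approach row_spacing / 2 (closed
    # canopy), so the scene_spec() separability check is not re-applied.
    s <- spec
    s$plant_radius <- schedule$plant_radius[i]
    s$greenness <- schedule$greenness[i]
    r <- render_plot_image(s)
    list(date = schedule$date[i], image = r$image, truth = r$truth)
  })
}

#' Double-logistic canopy-cover curve
#'
#' `plateau / (1 + exp(-k_growth (t - t_closure))) / (1 + exp(k_sen (t - t_sen)))`:
#' a sigmoidal rise to `plateau` around the closure midpoint followed by a
#' sigmoidal decline around the senescence midpoint, the canonical shape of a
#' seasonal CC trajectory.
#'
#' @param t numeric time (days).
#' @param plateau maximum CC in (0, 1].
#' @param t_closure growth midpoint (day).
#' @param k_growth growth rate (1/day).
#' @param t_sen senescence midpoint (day), > t_closure.
#' @param k_sen senescence rate (1/day).
#' @export
double_logistic <- function(t, plateau = 0.95, t_closure = 35, k_growth = 0.25,
                            t_sen = 110, k_sen = 0.2) {
  stopifnot(plateau > 0, plateau <= 1, t_sen > t_closure)
  plateau / (1 + exp(-k_growth * (t - t_closure))) /
    (1 + exp(k_sen * (t - t_sen)))
}

#' Trial simulation specification
#'
#' Statistical structure of a randomized complete block trial with a known
#' genotype variance, a smooth spatial field trend and i.i.d. residual noise,
#' sampled longitudinally along per-genotype double-logistic CC curves.
#' Genotypic variation is an additive per-genotype shift `a_i ~ N(0, sigma2_g)`
#' so the entry-mean heritability has the closed form
#' `H2 = sigma2_g / (sigma2_g + sigma2_e / r)`.
#'
#' @param n_genotypes,n_replicates trial dimensions.
#' @param grid `c(rows, columns)` of the field; must hold
#'   `n_genotypes * n_replicates` plots.
#' @param sigma2_g,sigma2_e genotypic and residual variances (trait units squared).
#' @param spatial_amplitude amplitude of the smooth (sinusoidal, zero-mean)
#'   row-by-column field trend, in trait units.
#' @param curve named list of base double-logistic parameters
#'   (`plateau`, `t_closure`, `k_growth`, `t_sen`, `k_sen`).
#' @param dates sampling days.
#' @param clip clip simulated values to \[0, 1\] (CC scale). Disable for
#'   variance-component studies on an unbounded trait scale.
#' @param seed integer RNG seed.
#' @export
trial_sim_spec <- function(n_genotypes = 20, n_replicates = 3, grid = c(10, 6),
                           sigma2_g = 0.01, sigma2_e = 0.0025,
                           spatial_amplitude = 0.05,
                           curve = list(plateau = 0.95, t_closure = 35,
                                        k_growth = 0.25, t_sen = 110, k_sen = 0.2),
                           dates = seq(20, 130, by = 7), clip = TRUE, seed = 1L) {
  stopifnot(n_genotypes >= 1, n_replicates >= 1, length(grid) == 2)
  if (sigma2_g < 0 || sigma2_e < 0) stop("variances must be >= 0")
  if (curve$plateau <= 0 || curve$plateau > 1) stop("plateau must be in (0, 1]")
  if (curve$t_sen <= curve$t_closure) stop("t_sen must exceed t_closure")
  if (prod(grid) < n_genotypes * n_replicates)
    stop(sprintf("grid too small: %d cells < %d plots",
                 prod(grid), n_genotypes * n_replicates))
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_replicates = as.integer(n_replicates),
                 grid = as.integer(grid), sigma2_g = sigma2_g,
                 sigma2_e = sigma2_e, spatial_amplitude = spatial_amplitude,
                 curve = curve, dates = dates, clip = isTRUE(clip),
                 seed = as.integer(seed)),
            class = "trial_sim_spec")
}

#' Simulate a randomized complete block field trial
#'
#' Blocks are contiguous column bands; genotypes are randomized within each
#' block. Plot values at each sampling date are
#' `curve(t) + a_i + trend(col, row) + e`, with the spatial trend centred to
#' zero mean over the used plots, optionally clipped to \[0, 1\].
#'
#' @param spec a [trial_sim_spec()].
#' @return list: `design` (plot_uid, genotype, replicate, row, range,
#'   is_border), `cc` (long table plot_uid, date, value) and `truth`
#'   (genotype effects, per-plot trend, curve parameters).
#' @export
simulate_trial <- function(spec) {
  stopifnot(inherits(spec, "trial_sim_spec"))
  g <- spec$n_genotypes; r <- spec$n_replicates
  nr <- spec$grid[1]; nc <- spec$grid[2]
  withr::with_seed(spec$seed, {
    # blocks are contiguous column-major chunks of the field, as even as the
    # grid allows; each must hold one full genotype set
    cells <- expand.grid(row = seq_len(nr), range = seq_len(nc))
    cells <- cells[order(cells$range, cells$row), ]
    cells$block <- ceiling(seq_len(nrow(cells)) * r / nrow(cells))
    design <- do.call(rbind, lapply(seq_len(r), function(b) {
      bc <- cells[cells$block == b, ]
      if (nrow(bc) < g) stop("grid too small for a complete block")
      bc <- bc[seq_len(g), ]
      bc$genotype <- sprintf("G%03d", sample.int(g))
      bc$replicate <- b
      bc
    }))
    design$plot_uid <- sprintf("P%04d", seq_len(nrow(design)))
    design$is_border <- FALSE
    design <- design[, c("plot_uid", "genotype", "replicate", "row", "range",
                         "is_border")]
    rownames(design) <- NULL

    a <- stats::rnorm(g, 0, sqrt(spec$sigma2_g))
    names(a) <- sprintf("G%03d", seq_len(g))

    # smooth low-frequency fertility gradient: half a cycle across each field
    # dimension, the scale of trend a spatial model is expected to absorb
    trend_raw <- spec$spatial_amplitude *
      sin(pi * design$range / nc) * cos(pi * design$row / (2 * nr))
    trend <- trend_raw - mean(trend_raw)

    cc <- do.call(rbind, lapply(spec$dates, function(t) {
      mu <- do.call(double_logistic, c(list(t = t), spec$curve))
      val <- mu + a[design$genotype] + trend +
        stats::rnorm(nrow(design), 0, sqrt(spec$sigma2_e))
      if (spec$clip) val <- clamp(val, 0, 1)
      data.frame(plot_uid = design$plot_uid, date = t, value = val)
    }))
    rownames(cc) <- NULL
  })
  list(design = design, cc = cc,
       truth = list(genotype_effects = a,
                    trend = stats::setNames(trend, design$plot_uid),
                    curve = spec$curve))
}

#' Simulate hourly weather for a season
#'
#' Diurnal and seasonal temperature cycles, daylight-only shortwave radiation
#' with day-to-day cloudiness, PPFR derived from radiation by the standard
#' linear factor, humidity anti-correlated with temperature, intermittent
#' precipitation and log-normal wind speed.
#'
#' @param start,end `Date` (or coercible) season bounds, `start <= end`.
#' @param seed integer RNG seed.
#' @return data.frame with hourly `timestamp`, `temperature` (deg C),
#'   `radiation` (MJ m-2 h-1), `ppfr`, `humidity` (%), `precipitation` (mm),
#'   `windspeed` (m s-1).
#' @export
simulate_weather <- function(start, end, seed = 1L) {
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("reversed date range: end precedes start")
  ts <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
            as.POSIXct(paste(end, "23:00:00"), tz = "UTC"), by = "hour")
  withr::with_seed(seed, {
    hour <- as.integer(format(ts, "%H"))
    doy <- as.integer(format(ts, "%j"))
    day_id <- as.integer(as.Date(ts)) - as.integer(start) + 1L
    n_days <- max(day_id)
    cloud <- stats::runif(n_days, 0.3, 1)[day_id]
    temp <- 12 + 8 * sin(2 * pi * (doy - 110) / 365) +
      6 * sin(2 * pi * (hour - 9) / 24) + stats::rnorm(length(ts), 0, 1)
    elev <- sin(pi * (hour - 6) / 12)
    elev[hour < 6 | hour > 18] <- 0
    radiation <- pmax(0, elev) * 3 * cloud
    humidity <- clamp(95 - 2.2 * (temp - 8) + stats::rnorm(length(ts), 0, 5), 25, 100)
    wet_day <- (stats::runif(n_days) < 0.3)[day_id]
    precipitation <- ifelse(wet_day & stats::runif(length(ts)) < 0.2,
                            stats::rexp(length(ts), 1), 0)
    windspeed <- stats::rlnorm(length(ts), log(2), 0.4)
  })
  data.frame(timestamp = ts, temperature = temp, radiation = radiation,
             ppfr = radiation_to_ppfr(radiation), humidity = humidity,
             precipitation = precipitation, windspeed = windspeed)
}
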