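#' Row-detection parameters
#'
#' Controls the 1-D density clustering of green-pixel y-coordinates, the row
#' count limits, and boundary/propagation behaviour.
#'
#' @param row_spacing approximate centre-to-centre row distance in pixels.
#' @param min_rows minimum number of rows expected in the plot; fewer
#'   supportable clusters signals a closed canopy (or an empty plot) and
#'   detection returns no rows.
#' @param max_rows maximum number of rows visible in the image (plot rows
#'   plus neighbouring plots' edge rows).
#' @param density_bandwidth KDE bandwidth in pixels; default `row_spacing / 4`.
#' @param min_cluster_support minimum green-pixel support per retained row.
#' @param valley_frac adjacent density peaks are merged when the valley
#'   between them stays above this fraction of the smaller peak; collapses
#'   closed-canopy plateaus.
#' @param spacing_dev_max detection is rejected (empty result, triggering
#'   boundary propagation) when the fitted row spacing deviates from
#'   `row_spacing` by more than this fraction.
#' @param expand_half_spacing expand the multi-row plot boundary by half a
#'   row spacing beyond the outer-row centrelines (default); `FALSE` gives
#'   the strict centreline reading.
#' @param x_margin_frac horizontal boundary inset as a fraction of width.
#' @param single_row treat the whole green-pixel mass as one cluster (used
#'   for dense nine-row plots whose rows cannot be separated).
#' @param iqr_multiplier half-height of the single-row boundary in IQRs of
#'   the cluster's y-distribution.
#' @export
row_detection_params <- function(row_spacing, min_rows = 3, max_rows = 5,
                                 density_bandwidth = row_spacing / 4,
                                 min_cluster_support = 300,
                                 valley_frac = 0.85, spacing_dev_max = 0.5,
                                 expand_half_spacing = TRUE, x_margin_frac = 0,
                                 single_row = FALSE, iqr_multiplier = 1.5) {
  if (row_spacing <= 0) stop("row_spacing must be > 0")
  if (min_rows < 1 || max_rows < min_rows)
    stop("need 0 < min_rows <= max_rows")
  structure(list(row_spacing = row_spacing, min_rows = as.integer(min_rows),
                 max_rows = as.integer(max_rows),
                 density_bandwidth = density_bandwidth,
                 min_cluster_support = min_cluster_support,
                 valley_frac = valley_frac, spacing_dev_max = spacing_dev_max,
                 expand_half_spacing = isTRUE(expand_half_spacing),
                 x_margin_frac = x_margin_frac, single_row = isTRUE(single_row),
                 iqr_multiplier = iqr_multiplier),
            class = "row_detection_params")
}

#' @keywords internal
new_row_cluster <- function(xs, ys) {
  list(y_center = stats::median(ys), y_extent = range(ys),
       n_pixels = length(ys), x = xs, y = ys,
       slope = NA_real_, intercept = NA_real_,
       index_from_middle = NA_integer_)
}

#' Detect crop rows from the vertical green-pixel distribution
#'
#' Rows appear as horizontal bands in an aligned nadir view, so their
#' y-coordinates form well-separated modes regardless of gaps along x caused
#' by incomplete emergence. A Gaussian KDE of the green-pixel y-coordinates
#' is scanned for peaks at minimum separation `row_spacing / 2`; pixels are
#' assigned to the nearest peak. Clusters are dropped when their support is
#' below `min_cluster_support` or their y-extent spans two or more row
#' spacings (merged rows); if more than `max_rows` clusters remain, the ones
#' nearest the image centre are kept. An empty result (all-soil mask, merged
#' closed-canopy plateau, fewer than `min_rows` supportable clusters, or a
#' fitted spacing deviating more than `spacing_dev_max` from the nominal one)
#' signals that row-based extraction is not possible on this date.
#'
#' @param mask a `segmentation_mask` or 0/1 matrix.
#' @param params a [row_detection_params()].
#' @return list of row clusters (possibly empty), sorted by `y_center`.
#' @export
detect_rows <- function(mask, params) {
  stopifnot(inherits(params, "row_detection_params"))
  m <- if (inherits(mask, "segmentation_mask")) mask$mask else mask
  h <- nrow(m)
  pix <- which(m != 0, arr.ind = TRUE)
  if (!nrow(pix)) return(list())
  ys <- pix[, 1]; xs <- pix[, 2]

  if (params$single_row) {
    if (length(ys) < params$min_cluster_support) return(list())
    cl <- new_row_cluster(xs, ys)
    cl$index_from_middle <- 0L
    return(list(cl))
  }

  d <- stats::density(ys, bw = params$density_bandwidth, from = 1, to = h,
                      n = max(512, h))
  peaks <- find_density_peaks(d$x, d$y, min_sep = params$row_spacing / 2,
                              valley_frac = params$valley_frac)
  if (!length(peaks)) return(list())

  assign_idx <- apply(abs(outer(ys, peaks, "-")), 1, which.min)
  clusters <- lapply(seq_along(peaks), function(k) {
    sel <- assign_idx == k
    if (!any(sel)) return(NULL)
    new_row_cluster(xs[sel], ys[sel])
  })
  clusters <- Filter(Negate(is.null), clusters)
  clusters <- Filter(function(cl) cl$n_pixels >= params$min_cluster_support,
                     clusters)
  clusters <- Filter(function(cl)
    diff(cl$y_extent) < 2 * params$row_spacing, clusters)
  if (length(clusters) < params$min_rows) return(list())

  clusters <- clusters[order(vapply(clusters, `[[`, 0, "y_center"))]
  if (length(clusters) > params$max_rows) {
    center_y <- (h + 1) / 2
    dist <- vapply(clusters, function(cl) abs(cl$y_center - center_y), 0)
    keep <- order(dist, vapply(clusters, `[[`, 0, "y_center"))[seq_len(params$max_rows)]
    clusters <- clusters[sort(keep)]
  }

  if (length(clusters) >= 2) {
    sp <- stats::median(diff(vapply(clusters, `[[`, 0, "y_center")))
    if (abs(sp - params$row_spacing) > params$spacing_dev_max * params$row_spacing)
      return(list())
  }
  clusters
}

#' Number clusters outward from the middle row
#'
#' The cluster whose centre is nearest the image centre becomes the middle
#' row (index 0); the others are numbered -1, -2 upward and +1, +2 downward.
#' When more than `max_rows` clusters are supplied, those farthest from the
#' middle are dropped. Ties (two clusters equidistant from the centre) go to
#' the lower y, deterministically.
#'
#' @param clusters list of row clusters from [detect_rows()].
#' @param image_center_y y-coordinate of the image centre.
#' @param max_rows maximum clusters to retain.
#' @return clusters with `index_from_middle` assigned, sorted by `y_center`.
#' @export
identify_middle_row <- function(clusters, image_center_y, max_rows = length(clusters)) {
  if (!length(clusters)) stop("no clusters to index")
  yc <- vapply(clusters, `[[`, 0, "y_center")
  clusters <- clusters[order(yc)]
  yc <- sort(yc)
  dist <- abs(yc - image_center_y)
  mid <- order(dist, yc)[1]
  for (i in seq_along(clusters))
    clusters[[i]]$index_from_middle <- as.integer(i - mid)
  if (length(clusters) > max_rows) {
    idx <- vapply(clusters, `[[`, 0L, "index_from_middle")
    keep <- order(abs(idx), yc)[seq_len(max_rows)]
    clusters <- clusters[sort(keep)]
  }
  clusters
}

#' Fit a robust line through each row cluster
#'
#' The cluster's pixels are first reduced to one median y per image column
#' (which also neutralises emergence gaps), then a line `y ~ x` is fitted with
#' Theil-Sen (default; deterministic, resistant to well over 20% outlying
#' columns from weed contamination) or Huber M-estimation via [MASS::rlm()].
#'
#' @param clusters list of row clusters carrying member pixels.
#' @param method `"theilsen"` or `"huber"`.
#' @return clusters with `slope` and `intercept` filled in.
#' @export
fit_row_lines <- function(clusters, method = c("theilsen", "huber")) {
  method <- match.arg(method)
  lapply(clusters, function(cl) {
    med_y <- tapply(cl$y, cl$x, stats::median)
    ux <- as.numeric(names(med_y))
    my <- as.numeric(med_y)
    if (length(ux) < 2) {
      warning("degenerate cluster: single x column; slope set to 0")
      cl$slope <- 0
      cl$intercept <- stats::median(cl$y)
      return(cl)
    }
    fit <- if (method == "theilsen") {
      theil_sen(ux, my)
    } else {
      f <- suppressWarnings(MASS::rlm(my ~ ux, maxit = 50))
      list(slope = unname(stats::coef(f)[2]), intercept = unname(stats::coef(f)[1]))
    }
    cl$slope <- fit$slope
    cl$intercept <- fit$intercept
    cl
  })
}

#' @keywords internal
aggregate_slope <- function(clusters, aggregate = "weighted_mean") {
  slopes <- vapply(clusters, `[[`, 0, "slope")
  n_pix <- vapply(clusters, `[[`, 0, "n_pixels")
  if (aggregate == "weighted_median") weighted_median(slopes, n_pix)
  else sum(slopes * n_pix) / sum(n_pix)
}

#' Rotate the mask so that rows are horizontal and parallel
#'
#' One rigid rotation corrects both camera misalignment and perspective
#' shear: the angle is `atan` of the support-weighted mean of the fitted
#' per-row slopes (weighted median available; the per-row fits are already
#' robust, so averaging across rows buys precision without losing
#' resistance), applied about the midpoint of the middle row. Because
#' nearest-peak pixel assignment slightly truncates a slanted row's extreme
#' y-values, a single pass attenuates the angle by a few percent; the
#' correction is therefore refined iteratively, each iteration rotating the
#' *original* mask by the accumulated angle (no compounded resampling) and
#' re-estimating the residual slope on the aligned mask, until the residual
#' is below `tol_deg` or `max_iter` passes. Rows are re-detected and
#' re-fitted on the final aligned mask so downstream boundary derivation
#' sees aligned clusters.
#'
#' @param mask a `segmentation_mask` or 0/1 matrix.
#' @param clusters fitted clusters from [fit_row_lines()] (with
#'   `index_from_middle` assigned; see [identify_middle_row()]).
#' @param params a [row_detection_params()].
#' @param aggregate `"weighted_mean"` (default) or `"weighted_median"`.
#' @param max_iter refinement passes (>= 1).
#' @param tol_deg stop when the residual aligned slope is below this angle.
#' @return list: `mask` (aligned, dimensions preserved, zero-filled),
#'   `rotation_deg` (the total correction removed), `pivot` `c(y, x)`, and
#'   `clusters` re-detected on the aligned mask.
#' @export
align_rows <- function(mask, clusters, params,
                       aggregate = c("weighted_mean", "weighted_median"),
                       max_iter = 3, tol_deg = 0.02) {
  aggregate <- match.arg(aggregate)
  if (!length(clusters)) stop("no fitted row lines to align")
  if (anyNA(vapply(clusters, `[[`, 0, "slope")))
    stop("clusters must be fitted with fit_row_lines() first")
  m <- if (inherits(mask, "segmentation_mask")) mask$mask else mask
  h <- nrow(m)

  idx <- vapply(clusters, `[[`, 0L, "index_from_middle")
  mid <- if (any(idx == 0L, na.rm = TRUE)) clusters[[which(idx == 0L)[1]]]
         else clusters[[which.min(abs(vapply(clusters, `[[`, 0, "y_center") - (h + 1) / 2))]]
  px <- stats::median(mid$x)
  py <- mid$intercept + mid$slope * px
  pivot <- c(py, px)

  theta <- rad2deg(atan(aggregate_slope(clusters, aggregate)))
  aligned <- m
  new_clusters <- list()
  for (it in seq_len(max_iter)) {
    aligned <- rotate_mask(m, -theta, center = pivot)
    new_clusters <- detect_rows(new_segmentation_mask(aligned), params)
    if (!length(new_clusters)) break
    new_clusters <- identify_middle_row(new_clusters, (h + 1) / 2,
                                        params$max_rows)
    new_clusters <- fit_row_lines(new_clusters)
    resid <- rad2deg(atan(aggregate_slope(new_clusters, aggregate)))
    if (abs(resid) < tol_deg || it == max_iter) break
    theta <- theta + resid
  }
  if (!length(new_clusters)) {
    # borderline scene: keep the input clusters, shifted into the aligned frame
    new_clusters <- lapply(clusters, function(cl) {
      cl$y_center <- py + (cl$intercept + cl$slope * px - py) * cos(deg2rad(theta))
      cl$slope <- 0
      cl
    })
  }
  list(mask = aligned, rotation_deg = theta, pivot = pivot,
       clusters = new_clusters)
}

#' Plot geometry record
#'
#' Rectangular plot region in (aligned) image coordinates, with the rotation
#' that was applied and the provenance of the boundary.
#'
#' @param y_top,y_bottom,x_left,x_right integer pixel bounds (inclusive).
#' @param rotation_applied degrees removed by alignment.
#' @param provenance one of `"detected"`, `"propagated"`, `"single_row_iqr"`,
#'   `"truth"`.
#' @param pivot rotation pivot `c(y, x)` (optional).
#' @export
plot_geometry <- function(y_top, y_bottom, x_left, x_right,
                          rotation_applied = 0,
                          provenance = c("detected", "propagated",
                                         "single_row_iqr", "truth"),
                          pivot = NULL) {
  provenance <- match.arg(provenance)
  if (y_top >= y_bottom || x_left >= x_right)
    stop("degenerate plot geometry: bounds must enclose a positive area")
  structure(list(y_top = as.integer(round(y_top)),
                 y_bottom = as.integer(round(y_bottom)),
                 x_left = as.integer(round(x_left)),
                 x_right = as.integer(round(x_right)),
                 rotation_applied = rotation_applied,
                 provenance = provenance, pivot = pivot),
            class = "plot_geometry")
}

#' Derive the plot boundary from aligned row clusters
#'
#' With more than one row, the upper and lower plot bounds are the median y
#' of the topmost and bottommost retained rows, by default expanded by half a
#' row spacing on each side so each outer row contributes fully
#' (`expand_half_spacing = FALSE` gives the strict outer-centreline reading).
#' With a single cluster (the dense nine-row case) the bounds are the cluster
#' centre plus/minus `iqr_multiplier` times the IQR of its y-distribution and
#' the provenance is `single_row_iqr`. X bounds default to the full image
#' width, inset by `x_margin_frac`.
#'
#' @param clusters indexed clusters (see [identify_middle_row()]).
#' @param params a [row_detection_params()].
#' @param mask_dim `c(height, width)` of the mask.
#' @param rotation_applied degrees recorded on the geometry.
#' @param pivot optional rotation pivot recorded on the geometry.
#' @return a [plot_geometry()].
#' @export
derive_plot_boundary <- function(clusters, params, mask_dim,
                                 rotation_applied = 0, pivot = NULL) {
  if (!length(clusters)) stop("no clusters: cannot derive a plot boundary")
  h <- mask_dim[1]; w <- mask_dim[2]
  yc <- vapply(clusters, `[[`, 0, "y_center")
  if (length(clusters) >= 2) {
    y_top <- min(yc); y_bottom <- max(yc)
    if (params$expand_half_spacing) {
      y_top <- y_top - params$row_spacing / 2
      y_bottom <- y_bottom + params$row_spacing / 2
    }
    prov <- "detected"
  } else {
    cl <- clusters[[1]]
    iqr <- diff(stats::quantile(cl$y, c(0.25, 0.75), names = FALSE))
    y_top <- cl$y_center - params$iqr_multiplier * iqr
    y_bottom <- cl$y_center + params$iqr_multiplier * iqr
    prov <- "single_row_iqr"
  }
  xm <- round(w * params$x_margin_frac)
  plot_geometry(y_top = max(1, round(y_top)), y_bottom = min(h, round(y_bottom)),
                x_left = max(1, 1 + xm), x_right = min(w, w - xm),
                rotation_applied = rotation_applied, provenance = prov,
                pivot = pivot)
}

#' Estimate a plot boundary from earlier detections
#'
#' Once the canopy closes, rows and plot edges can no longer be told apart in
#' the image, so the boundary is carried over from earlier in the season: the
#' per-coordinate median over all `detected` geometries dated before the
#' query date (falling back to all detected geometries if none are earlier).
#'
#' @param history list of entries, each `list(date = , geometry = )`.
#' @param query_date date needing a boundary.
#' @return a [plot_geometry()] with provenance `"propagated"`.
#' @export
propagate_boundary <- function(history, query_date) {
  det <- Filter(function(e) inherits(e$geometry, "plot_geometry") &&
                  e$geometry$provenance == "detected", history)
  if (!length(det))
    stop("cannot propagate: no successfully detected plot boundary in this ",
         "plot's history; extract at least one pre-closure date first")
  earlier <- Filter(function(e) as.numeric(e$date) < as.numeric(query_date), det)
  use <- if (length(earlier)) earlier else det
  med <- function(f) stats::median(vapply(use, function(e) as.numeric(e$geometry[[f]]), 0))
  pivots <- lapply(use, function(e) e$geometry$pivot)
  pivot <- if (all(!vapply(pivots, is.null, TRUE)))
    c(stats::median(vapply(pivots, `[`, 0, 1)),
      stats::median(vapply(pivots, `[`, 0, 2)))
  else NULL
  plot_geometry(y_top = med("y_top"), y_bottom = med("y_bottom"),
                x_left = med("x_left"), x_right = med("x_right"),
                rotation_applied = med("rotation_applied"),
                provenance = "propagated", pivot = pivot)
}

#' Compute canopy cover inside a plot boundary
#'
#' CC is the proportion of green pixels relative to the total number of
#' pixels in the plot rectangle (inclusive integer bounds). Geometries
#' partially outside the mask are clipped with a warning.
#'
#' @param mask a `segmentation_mask` or 0/1 matrix (aligned frame).
#' @param geometry a [plot_geometry()].
#' @param plot_uid,timestamp identifiers carried into the record.
#' @param n_rows_detected number of rows that supported the geometry.
#' @param method `"row_based"` or `"total_fraction"`.
#' @return one-row data.frame: plot_uid, timestamp, cc, n_green, n_total,
#'   n_rows_detected, method, provenance.
#' @export
compute_canopy_cover <- function(mask, geometry, plot_uid = NA_character_,
                                 timestamp = NA, n_rows_detected = NA_integer_,
                                 method = c("row_based", "total_fraction")) {
  method <- match.arg(method)
  stopifnot(inherits(geometry, "plot_geometry"))
  m <- if (inherits(mask, "segmentation_mask")) mask$mask else mask
  h <- nrow(m); w <- ncol(m)
  yt <- geometry$y_top; yb <- geometry$y_bottom
  xl <- geometry$x_left; xr <- geometry$x_right
  if (yt < 1 || yb > h || xl < 1 || xr > w) {
    warning("plot geometry extends beyond the mask; clipping to mask bounds")
    yt <- max(1L, yt); yb <- min(h, yb); xl <- max(1L, xl); xr <- min(w, xr)
  }
  if (yt >= yb || xl >= xr) stop("zero-area plot geometry after clipping")
  sub <- m[yt:yb, xl:xr, drop = FALSE]
  n_total <- length(sub)
  n_green <- sum(sub != 0)
  data.frame(plot_uid = plot_uid, timestamp = timestamp,
             cc = n_green / n_total, n_green = n_green, n_total = n_total,
             n_rows_detected = n_rows_detected, method = method,
             provenance = geometry$provenance, stringsAsFactors = FALSE)
}

#' Run the full single-image extraction: segment, cluster, align, measure
#'
#' Convenience wrapper over [detect_rows()], [identify_middle_row()],
#' [fit_row_lines()], [align_rows()], [derive_plot_boundary()] and
#' [compute_canopy_cover()]. When row detection fails (closed canopy, bare
#' soil), `status` is `"no_rows"` and the caller should fall back to
#' [propagate_boundary()].
#'
#' @param x an RGB image array or a `segmentation_mask`.
#' @param params a [row_detection_params()].
#' @param seg_params a [color_ratio_params()] (used when `x` is an image).
#' @param plot_uid,timestamp identifiers for the output record.
#' @return list: `status` ("ok"/"no_rows"), `record`, `geometry`,
#'   `rotation_deg`, `clusters`, `mask` (aligned segmentation mask).
#' @export
extract_plot_cc <- function(x, params, seg_params = color_ratio_params(),
                            plot_uid = NA_character_, timestamp = NA) {
  mask <- if (inherits(x, "segmentation_mask")) x else segment_green(x, seg_params)
  clusters <- detect_rows(mask, params)
  if (!length(clusters))
    return(list(status = "no_rows", record = NULL, geometry = NULL,
                rotation_deg = NA_real_, clusters = list(), mask = mask))
  h <- nrow(mask$mask)
  clusters <- identify_middle_row(clusters, (h + 1) / 2, params$max_rows)
  clusters <- fit_row_lines(clusters)
  al <- align_rows(mask, clusters, params)
  geometry <- derive_plot_boundary(al$clusters, params, dim(al$mask),
                                   rotation_applied = al$rotation_deg,
                                   pivot = al$pivot)
  rec <- compute_canopy_cover(al$mask, geometry, plot_uid = plot_uid,
                              timestamp = timestamp,
                              n_rows_detected = length(al$clusters),
                              method = "row_based")
  list(status = "ok", record = rec, geometry = geometry,
       rotation_deg = al$rotation_deg, clusters = al$clusters,
       mask = new_segmentation_mask(al$mask, mask$id))
}

#' Extract a whole season of canopy cover for one plot
#'
#' First pass: per-date row detection and row-based CC. Second pass: dates
#' where rows could not be distinguished (typically after canopy closure) get
#' a boundary propagated from the detected history, the mask is rotated by
#' the propagated alignment, and a total-fraction CC is computed. The two
#' record sets are merged with [merge_datasets()].
#'
#' @param masks list of `segmentation_mask` (or 0/1 matrices), one per date.
#' @param dates vector of dates parallel to `masks`.
#' @param params a [row_detection_params()].
#' @param plot_uid identifier for the records.
#' @return list: `records` (merged season table), `geometries` (per-date),
#'   `history` (detected geometries used for propagation).
#' @export
extract_season <- function(masks, dates, params, plot_uid = NA_character_) {
  stopifnot(length(masks) == length(dates))
  row_recs <- list(); tot_recs <- list()
  history <- list(); geometries <- vector("list", length(dates))
  pending <- integer(0)
  for (i in seq_along(masks)) {
    res <- extract_plot_cc(masks[[i]], params, plot_uid = plot_uid,
                           timestamp = dates[i])
    if (res$status == "ok") {
      row_recs[[length(row_recs) + 1]] <- res$record
      geometries[[i]] <- res$geometry
      history[[length(history) + 1]] <- list(date = dates[i],
                                             geometry = res$geometry)
    } else {
      pending <- c(pending, i)
    }
  }
  for (i in pending) {
    geo <- propagate_boundary(history, dates[i])
    m <- if (inherits(masks[[i]], "segmentation_mask")) masks[[i]]$mask else masks[[i]]
    aligned <- rotate_mask(m, -geo$rotation_applied,
                           center = geo$pivot %||% NULL)
    rec <- compute_canopy_cover(aligned, geo, plot_uid = plot_uid,
                                timestamp = dates[i], n_rows_detected = 0L,
                                method = "total_fraction")
    tot_recs[[length(tot_recs) + 1]] <- rec
    geometries[[i]] <- geo
  }
  merged <- merge_datasets(do.call(rbind, row_recs), do.call(rbind, tot_recs),
                           min_rows = params$min_rows)
  list(records = merged, geometries = geometries, history = history)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge row-based and total-fraction CC datasets
#'
#' One record per (plot_uid, timestamp): the row-based record wins when its
#' row count reaches `min_rows`, otherwise the total-fraction record (with
#' its propagated geometry) is used. Duplicate keys within one source are an
#' error.
#'
#' @param row_based,total_fraction data.frames of CC records (either may be
#'   NULL/empty).
#' @param min_rows minimum detected rows for the row-based record to win.
#' @return merged data.frame sorted by plot_uid, timestamp.
#' @export
merge_datasets <- function(row_based, total_fraction, min_rows = 3) {
  key <- function(d) paste(d$plot_uid, d$timestamp, sep = "\r")
  check_dups <- function(d, nm) {
    if (is.null(d) || !nrow(d)) return(invisible())
    dup <- duplicated(key(d))
    if (any(dup))
      stop(sprintf("duplicate (plot_uid, timestamp) keys in %s: %s", nm,
                   paste(unique(paste(d$plot_uid[dup], d$timestamp[dup])),
                         collapse = "; ")))
  }
  check_dups(row_based, "row_based")
  check_dups(total_fraction, "total_fraction")
  if (is.null(row_based)) row_based <- total_fraction[0, ]
  if (is.null(total_fraction)) total_fraction <- row_based[0, ]
  rb <- row_based[!is.na(row_based$n_rows_detected) &
                    row_based$n_rows_detected >= min_rows, , drop = FALSE]
  rb_demoted <- row_based[!(key(row_based) %in% key(rb)), , drop = FALSE]
  tf <- rbind(total_fraction, rb_demoted)
  tf <- tf[!(key(tf) %in% key(rb)), , drop = FALSE]
  tf <- tf[!duplicated(key(tf)), , drop = FALSE]
  out <- rbind(rb, tf)
  out[order(out$plot_uid, out$timestamp), , drop = FALSE]
}
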