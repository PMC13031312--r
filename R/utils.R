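#' @keywords internal
deg2rad <- function(x) x * pi / 180

#' @keywords internal
rad2deg <- function(x) x * 180 / pi

#' Rotate a binary mask about a point
#'
#' Rotates image content by `angle_deg` degrees using inverse nearest-neighbour
#' mapping. The coordinate convention is R-native: rows are y (increasing
#' downward), columns are x. A positive angle maps a horizontal line into a
#' line with slope `tan(angle)` (dy/dx). Pixels mapped from outside the source
#' raster are zero-filled; output dimensions equal input dimensions.
#'
#' @param mask integer/logical matrix (0/1).
#' @param angle_deg rotation in degrees.
#' @param center numeric `c(y, x)` pivot; defaults to the raster centre.
#' @return integer matrix of the same dimension.
#' @export
rotate_mask <- function(mask, angle_deg, center = NULL) {
  stopifnot(is.matrix(mask))
  h <- nrow(mask)
  w <- ncol(mask)
  if (is.null(center)) center <- c((h + 1) / 2, (w + 1) / 2)
  th <- deg2rad(angle_deg)
  out <- matrix(0L, h, w)
  if (abs(th) < 1e-12) {
    out[] <- as.integer(mask != 0)
    return(out)
  }
  cy <- center[1]
  cx <- center[2]
  yy <- rep(seq_len(h), times = w)
  xx <- rep(seq_len(w), each = h)
  dx <- xx - cx
  dy <- yy - cy
  # inverse of the forward rotation (x', y') = (cx + c*dx - s*dy, cy + s*dx + c*dy)
  sx <- round(cx + cos(th) * dx + sin(th) * dy)
  sy <- round(cy - sin(th) * dx + cos(th) * dy)
  ok <- sx >= 1 & sx <= w & sy >= 1 & sy <= h
  out[cbind(yy[ok], xx[ok])] <- as.integer(mask[cbind(sy[ok], sx[ok])] != 0)
  out
}

#' Theil-Sen line fit
#'
#' Median-of-pairwise-slopes estimator; deterministic and resistant to a large
#' fraction of outlying points. Intercept is the median of `y - slope * x`.
#'
#' @param x,y numeric vectors of equal length (>= 2 distinct x).
#' @return list with `slope` and `intercept`.
#' @export
theil_sen <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(unique(x)) < 2) {
    warning("degenerate fit: all points share one x; slope set to 0")
    return(list(slope = 0, intercept = stats::median(y)))
  }
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  keep <- upper.tri(dx) & dx != 0
  slope <- stats::median(dy[keep] / dx[keep])
  list(slope = slope, intercept = stats::median(y - slope * x))
}

#' @keywords internal
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5)[1]
  # midpoint rule at an exact 50% split, for symmetry with the unweighted median
  if (abs(cw[i] - 0.5) < 1e-12 && i < length(x)) (x[i] + x[i + 1]) / 2 else x[i]
}

#' Find peaks in a 1-D density with a minimum separation
#'
#' Local maxima are collected greedily in decreasing height order, discarding
#' candidates closer than `min_sep` to an already accepted peak. Adjacent
#' accepted peaks whose connecting valley does not dip below
#' `valley_frac * min(peak heights)` are merged (height-weighted position),
#' which collapses the plateau produced by a closed canopy into one peak.
#'
#' @param pos grid positions, increasing.
#' @param dens density values at `pos`.
#' @param min_sep minimum peak separation in `pos` units.
#' @param valley_frac valley depth criterion in (0, 1].
#' @param min_height_frac discard maxima below this fraction of the global max.
#' @return numeric vector of peak positions, sorted ascending.
#' @keywords internal
find_density_peaks <- function(pos, dens, min_sep, valley_frac = 0.85,
                               min_height_frac = 0.05) {
  n <- length(dens)
  if (n < 3 || max(dens) <= 0) return(numeric(0))
  is_max <- c(FALSE, dens[2:(n - 1)] >= dens[1:(n - 2)] &
                dens[2:(n - 1)] > dens[3:n], FALSE)
  idx <- which(is_max & dens >= min_height_frac * max(dens))
  if (!length(idx)) return(numeric(0))
  idx <- idx[order(dens[idx], decreasing = TRUE)]
  kept <- integer(0)
  for (i in idx) {
    if (!length(kept) || all(abs(pos[i] - pos[kept]) >= min_sep)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  # merge adjacent peaks without a sufficiently deep valley between them
  repeat {
    if (length(kept) < 2) break
    merged <- FALSE
    for (j in seq_len(length(kept) - 1)) {
      a <- kept[j]; b <- kept[j + 1]
      valley <- min(dens[a:b])
      if (valley > valley_frac * min(dens[a], dens[b])) {
        wa <- dens[a]; wb <- dens[b]
        newpos <- (pos[a] * wa + pos[b] * wb) / (wa + wb)
        knew <- which.min(abs(pos - newpos))
        kept <- sort(unique(c(kept[-c(j, j + 1)], knew)))
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  pos[kept]
}

#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
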