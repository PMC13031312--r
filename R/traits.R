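#' Spatially adjusted genotype means (BLUEs)
#'
#' Fits `value ~ genotype + f(range, row)` with genotype as a fixed effect
#' and `f` a tensor-product penalized-spline surface over the field column
#' (`range`) and row positions, absorbing smooth spatial trends. BLUEs are
#' the estimated genotype means at the (centred) spatial surface, with
#' standard errors from the model covariance. With the spatial term disabled
#' (or undersized data) the model reduces to ordinary least squares, so on
#' balanced data the BLUEs equal the genotype arithmetic means exactly.
#'
#' @param data data.frame with columns `plot_uid`, `genotype`, `value` and
#'   (when `spatial = TRUE`) `row`, `range`.
#' @param spatial fit the spatial smooth (default TRUE).
#' @param k marginal basis dimension of the tensor-product smooth (k x k).
#' @return object of class `blues_fit`: `blues` (genotype, estimate, se),
#'   `model`, `residuals` (named by plot_uid), `data`, `spatial`.
#' @export
fit_blues <- function(data, spatial = TRUE, k = 5) {
  need <- c("plot_uid", "genotype", "value")
  if (!all(need %in% names(data)))
    stop("data needs columns: ", paste(need, collapse = ", "))
  data <- data[!is.na(data$value), , drop = FALSE]
  data$genotype <- factor(data$genotype)
  ng <- nlevels(data$genotype)
  if (ng < 2) stop("need >= 2 genotypes")
  if (spatial && !all(c("row", "range") %in% names(data)))
    stop("spatial adjustment needs plot coordinates (columns 'row', 'range')")
  if (max(table(data$genotype)) < 2 && spatial) {
    warning("single observation per genotype: spatial term disabled")
    spatial <- FALSE
  }
  if (spatial) {
    # shrink the surface basis if the design cannot support it
    while (k > 3 && nrow(data) < ng + k * k + 5) k <- k - 1
    if (nrow(data) < ng + k * k + 5) {
      warning("too few plots for a spatial surface: spatial term disabled")
      spatial <- FALSE
    }
  }
  fit <- if (spatial) {
    mgcv::gam(value ~ genotype + te(range, row, k = c(k, k)),
              data = data, method = "REML")
  } else {
    stats::lm(value ~ genotype, data = data)
  }
  if (anyNA(stats::coef(fit)[seq_len(ng)]))
    stop("rank-deficient design: genotype confounded with field position")
  lev <- levels(data$genotype)
  p <- length(stats::coef(fit))
  L <- matrix(0, ng, p)
  L[, 1] <- 1
  for (i in seq_along(lev)[-1]) L[i, i] <- 1 # treatment contrasts; smooth centred
  est <- drop(L %*% stats::coef(fit))
  V <- stats::vcov(fit)
  se <- sqrt(rowSums((L %*% V) * L))
  res <- stats::residuals(fit)
  names(res) <- data$plot_uid
  structure(list(blues = data.frame(genotype = lev, estimate = est, se = se,
                                    stringsAsFactors = FALSE),
                 model = fit, residuals = res, data = data, spatial = spatial,
                 k = if (spatial) k else NA_integer_),
            class = "blues_fit")
}

#' @export
print.blues_fit <- function(x, ...) {
  cat(sprintf("<blues_fit> %d genotypes, %d plots, spatial smooth: %s\n",
              nrow(x$blues), nrow(x$data),
              if (x$spatial) sprintf("te(%d,%d)", x$k, x$k) else "off"))
  print(utils::head(x$blues), ...)
  invisible(x)
}

#' Remove outlier plots by the residual-SD rule and refit once
#'
#' Plots whose model residual exceeds `multiplier` times the residual
#' standard deviation in absolute value are removed and the model is refitted
#' a single time (no iteration).
#'
#' @param fit a [fit_blues()] result.
#' @param multiplier SD multiplier; default 3.
#' @return list: `removed` (plot_uids), `retained` (data subset), `fit`
#'   (refitted `blues_fit`; the original fit if nothing was removed).
#' @export
remove_outliers <- function(fit, multiplier = 3) {
  stopifnot(inherits(fit, "blues_fit"))
  res <- fit$residuals
  s <- stats::sd(res)
  out <- abs(res) > multiplier * s
  if (all(out)) stop("outlier rule removed every plot: pathological fit")
  removed <- names(res)[out]
  retained <- fit$data[!(fit$data$plot_uid %in% removed), , drop = FALSE]
  refit <- if (length(removed)) fit_blues(retained, spatial = fit$spatial,
                                          k = if (fit$spatial) fit$k else 5)
           else fit
  list(removed = removed, retained = retained, fit = refit)
}

#' Broad-sense heritability at one time point
#'
#' Genotype is treated as a random effect; variance components are estimated
#' by REML with [lme4::lmer()] and combined as the entry-mean heritability
#' `H2 = s2g / (s2g + s2e / r)` with `r` the mean replication. Estimates are
#' clamped to \[0, 1\] (REML already bounds the components at zero).
#'
#' @param data data.frame with columns `genotype`, `value` and optionally
#'   `date`.
#' @param date if given, the subset `data$date == date` is analysed.
#' @return one-row data.frame: date, H2, sigma2_g, sigma2_e, r.
#' @export
estimate_heritability <- function(data, date = NULL) {
  if (!is.null(date)) data <- data[data$date == date, , drop = FALSE]
  data <- data[!is.na(data$value), , drop = FALSE]
  tab <- table(data$genotype)
  if (length(tab) < 2 || mean(tab) < 2)
    stop("need >= 2 genotypes with >= 2 replicates on average")
  fit <- suppressMessages(lme4::lmer(value ~ (1 | genotype), data = data,
                                     REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2g <- vc$vcov[vc$grp == "genotype"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  if (s2g < 0 || s2e < 0) {
    warning("negative variance estimate clamped to 0")
    s2g <- max(0, s2g); s2e <- max(0, s2e)
  }
  r <- mean(tab)
  h2 <- if (s2g + s2e / r > 0) s2g / (s2g + s2e / r) else 0
  data.frame(date = if (is.null(date)) NA else date, H2 = clamp(h2, 0, 1),
             sigma2_g = s2g, sigma2_e = s2e, r = r)
}

#' Drop measuring dates with uninformative heritability
#'
#' Dates whose CC heritability falls below the threshold carry little
#' genotypic information (typically the latest senescence phase) and are
#' removed before growth-curve fitting.
#'
#' @param h2_table data.frame with columns `date` and `H2`.
#' @param threshold minimum H2 to retain a date; default 0.2.
#' @return the retained rows of `h2_table` (possibly empty).
#' @export
filter_low_heritability <- function(h2_table, threshold = 0.2) {
  stopifnot(all(c("date", "H2") %in% names(h2_table)))
  if (!nrow(h2_table)) stop("empty heritability table")
  h2_table[h2_table$H2 >= threshold, , drop = FALSE]
}

#' Penalized-spline growth curve of CC over time
#'
#' Fits `y = b0 + f(x) + e` with `f` a penalized regression spline of the
#' numeric date built from `k` basis functions (default 10), smoothing
#' parameter chosen by GCV (default) or REML. R-squared is reported as
#' `1 - RSS/TSS`; a constant response yields a flat fit flagged with R2 = 0.
#'
#' @param dates numeric dates (days).
#' @param values CC observations.
#' @param k basis dimension (>= 3); shrunk with a warning when there are
#'   fewer distinct dates than basis functions.
#' @param method `"GCV.Cp"` or `"REML"`.
#' @return object of class `cc_gam`: `model`, `r2`, `constant` flag,
#'   `date_range`, `k`.
#' @export
fit_gam <- function(dates, values, k = 10, method = c("GCV.Cp", "REML")) {
  method <- match.arg(method)
  ok <- !is.na(dates) & !is.na(values)
  dates <- as.numeric(dates)[ok]; values <- values[ok]
  if (length(values) < 4) stop("need >= 4 observations to fit a growth curve")
  if (k < 3) stop("k must be >= 3")
  nun <- length(unique(dates))
  if (nun <= k) {
    k_new <- max(3, nun - 1)
    warning(sprintf("only %d distinct dates: k reduced from %d to %d",
                    nun, k, k_new))
    k <- k_new
  }
  constant <- stats::sd(values) == 0
  dat <- data.frame(x = dates, y = values)
  model <- mgcv::gam(y ~ s(x, k = k), data = dat, method = method)
  rss <- sum(stats::residuals(model)^2)
  tss <- sum((values - mean(values))^2)
  r2 <- if (constant || tss == 0) 0 else 1 - rss / tss
  structure(list(model = model, r2 = r2, constant = constant,
                 date_range = range(dates), k = k),
            class = "cc_gam")
}

#' @export
predict.cc_gam <- function(object, newdates, ...) {
  as.numeric(stats::predict(object$model, newdata = data.frame(x = as.numeric(newdates))))
}

#' @export
print.cc_gam <- function(x, ...) {
  cat(sprintf("<cc_gam> k = %d over dates [%g, %g], R2 = %.3f%s\n", x$k,
              x$date_range[1], x$date_range[2], x$r2,
              if (x$constant) " (constant response)" else ""))
  invisible(x)
}

#' 50%-CC closure and senescence dates from a fitted growth curve
#'
#' The fitted curve is evaluated on a fine grid (default 0.1 day); the curve
#' maximum is located, the closure date is the first upward crossing of
#' `level` before the maximum and the senescence date is the first downward
#' crossing after it, both by linear interpolation between grid points.
#' Crossings that do not exist (curve never reaches `level`, or senescence
#' too delayed to be observed) are reported as `NA`.
#'
#' @param fit a [fit_gam()] result, or a `list(dates = , values = )` giving
#'   an already-evaluated curve (used as-is, no regridding).
#' @param level CC level to cross; default 0.5.
#' @param grid_step evaluation grid resolution in days (cc_gam input only).
#' @return list: `closure_date_50`, `senescence_date_50`, `max_date`,
#'   `max_value`, `level`.
#' @export
extract_crossing_dates <- function(fit, level = 0.5, grid_step = 0.1) {
  if (inherits(fit, "cc_gam")) {
    rng <- fit$date_range
    grid <- seq(rng[1], rng[2], by = grid_step)
    y <- predict(fit, grid)
  } else if (is.list(fit) && all(c("dates", "values") %in% names(fit))) {
    grid <- as.numeric(fit$dates)
    y <- fit$values
    if (length(grid) < 2 || is.unsorted(grid, strictly = TRUE))
      stop("curve dates must be strictly increasing")
  } else stop("fit must be a cc_gam or a list(dates, values)")
  imax <- which.max(y)
  cross_up <- function(idx) {
    for (i in idx) {
      if (y[i] < level && y[i + 1] >= level) {
        return(grid[i] + (grid[i + 1] - grid[i]) *
                 (level - y[i]) / (y[i + 1] - y[i]))
      }
    }
    NA_real_
  }
  cross_down <- function(idx) {
    for (i in idx) {
      if (y[i] >= level && y[i + 1] < level) {
        return(grid[i] + (grid[i + 1] - grid[i]) *
                 (y[i] - level) / (y[i] - y[i + 1]))
      }
    }
    NA_real_
  }
  closure <- if (imax > 1) cross_up(seq_len(imax - 1)) else NA_real_
  senescence <- if (imax < length(grid)) cross_down(imax:(length(grid) - 1)) else NA_real_
  if (y[imax] < level) closure <- senescence <- NA_real_
  list(closure_date_50 = closure, senescence_date_50 = senescence,
       max_date = grid[imax], max_value = y[imax], level = level)
}

#' Percentile of a height profile
#'
#' Plot height from a terrestrial laser-scan height profile, defined as the
#' p-th percentile with linear interpolation between order statistics
#' (quantile type 7); default p = 97.
#'
#' @param profile numeric vector of per-point heights.
#' @param p percentile in \[0, 100\].
#' @return scalar height.
#' @export
height_percentile <- function(profile, p = 97) {
  profile <- profile[!is.na(profile)]
  if (!length(profile)) stop("empty height profile")
  stats::quantile(profile, p / 100, names = FALSE, type = 7)
}

#' Pearson correlation between two per-genotype trait vectors
#'
#' Pairs with missing values are dropped; the two-sided t-test p-value and
#' the number of complete pairs are reported alongside r.
#'
#' @param x,y numeric vectors of equal length (matched by position).
#' @return list: `r`, `p_value`, `n`.
#' @export
correlate_traits <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
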