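#' Gaussian kernel density on the landscape grid
#'
#' Evaluates the 2-D Gaussian kernel density estimate of a point set at every
#' cell center of the landscape grid, with bandwidths in meters. Used to
#' delineate seasonal ranges via density isopleths. The default bandwidth is
#' Silverman's normal-reference rule per axis ([stats::bw.nrd()]).
#'
#' @param points data.frame (or matrix) with columns/cols `x`, `y` in meters.
#' @param ls a [landscape_stack()] supplying the evaluation grid.
#' @param bandwidth numeric length 1 or 2, kernel standard deviation in
#'   meters per axis; `NULL` for Silverman's rule.
#' @return matrix of densities (1/m^2) aligned with the landscape grid; cell
#'   sum times cell area is ~1 for point sets well inside the extent.
#' @export
kde2d_grid <- function(points, ls, bandwidth = NULL) {
  pts <- as.data.frame(points)
  x <- pts$x %||% pts[[1]]
  y <- pts$y %||% pts[[2]]
  n <- length(x)
  if (n < 2) stopf("need at least 2 points for a kernel density estimate")
  if (is.null(bandwidth)) bandwidth <- c(stats::bw.nrd(x), stats::bw.nrd(y))
  bandwidth <- rep(bandwidth, length.out = 2)
  if (any(bandwidth <= 0)) stopf("bandwidth must be positive")
  gx <- cell_centers_x(ls)
  gy <- cell_centers_y(ls)
  dx <- stats::dnorm(outer(gx, x, "-") / bandwidth[1]) / bandwidth[1]  # ncol x n
  dy <- stats::dnorm(outer(gy, y, "-") / bandwidth[2]) / bandwidth[2]  # nrow x n
  (dy %*% t(dx)) / n
}

#' Kernel density isopleth
#'
#' The smallest set of grid cells, accumulated in descending density order,
#' whose density mass reaches `level` times the total mass -- the standard
#' utilization-distribution isopleth used to delineate seasonal ranges
#' (default 99.9%).
#'
#' @param density density matrix from [kde2d_grid()] (non-negative, not all
#'   zero).
#' @param ls the landscape supplying grid geometry.
#' @param level isopleth level in (0, 1].
#' @return a [range_polygon()].
#' @export
isopleth <- function(density, ls, level = 0.999) {
  if (level <= 0 || level > 1) stopf("isopleth level must lie in (0, 1]")
  if (any(density < 0, na.rm = TRUE)) stopf("density must be non-negative")
  tot <- sum(density)
  if (!is.finite(tot) || tot <= 0) stopf("density is all zero")
  o <- order(density, decreasing = TRUE)
  cum <- cumsum(density[o])
  k <- which(cum >= level * tot - 1e-12)[1]
  mask <- matrix(FALSE, nrow(density), ncol(density))
  mask[o[seq_len(k)]] <- TRUE
  if (level == 1) mask <- density > 0
  range_polygon(mask, ls)
}

#' Buffer a range polygon
#'
#' Grid dilation: all cells whose center lies within Euclidean `distance` of
#' the center of any polygon cell, clipped to the landscape extent. Seasonal
#' isopleths are conventionally buffered by the mean daily movement distance
#' (~1,500 m summer, ~1,000 m winter for migratory mule deer); here the
#' distance is an explicit argument.
#'
#' @param polygon a [range_polygon()].
#' @param distance buffer distance in meters (>= 0).
#' @return a [range_polygon()] containing the input.
#' @export
buffer_polygon <- function(polygon, distance) {
  if (distance < 0) stopf("buffer distance must be non-negative")
  if (distance == 0) return(polygon)
  cs <- polygon$cell
  r <- floor(distance / cs)
  ax <- (-r):r
  disk <- outer(ax, ax, function(i, j) (i^2 + j^2) * cs^2 <= distance^2 + 1e-9)
  hit <- conv2d_fft(polygon$mask * 1, disk * 1)
  mask <- polygon$mask | (hit > 0.5)
  out <- polygon
  out$mask <- mask
  out$area <- sum(mask) * cs^2
  out
}

#' Sample available points uniformly within a polygon
#'
#' Draws `n` points uniformly over the polygon's area (uniform cell choice,
#' then uniform jitter within the cell), the availability sample of the
#' use-availability design.
#'
#' @param polygon a [range_polygon()].
#' @param n number of points (>= 1).
#' @param seed integer seed; identical seeds give identical points.
#' @return data.frame with columns `x`, `y`.
#' @export
sample_available <- function(polygon, n, seed = 1L) {
  idx <- which(polygon$mask)
  if (!length(idx)) stopf("range polygon is empty")
  if (n < 1) stopf("n must be at least 1")
  nr <- polygon$n_rows
  with_seed(seed, {
    picks <- idx[sample.int(length(idx), n, replace = TRUE)]
    rows <- ((picks - 1L) %% nr) + 1L
    cols <- ((picks - 1L) %/% nr) + 1L
    data.frame(
      x = polygon$x0 + (cols - 1L + stats::runif(n)) * polygon$cell,
      y = polygon$y0 + (nr - rows + stats::runif(n)) * polygon$cell
    )
  })
}

#' Extract covariates at points
#'
#' Nearest-cell (containing-cell) extraction of every landscape layer at the
#' given points. Aspect is emitted as the shifted trigonometric pair
#' `cos_aspect = 1 + cos(theta)` (north-south axis, 2 = due north) and
#' `sin_aspect = 1 + sin(theta)` (east-west axis), each spanning `[0, 2]` with
#' mean ~1 on varied terrain. Vegetation is returned as a factor with the
#' reference class as first level.
#'
#' @param points data.frame with columns `x`, `y` (meters); any other columns
#'   are carried through.
#' @param ls a [landscape_stack()].
#' @return `points` with covariate columns appended.
#' @export
extract_covariates <- function(points, ls) {
  pc <- point_to_cell(ls, points$x, points$y)
  idx <- (pc$col - 1L) * ls$n_rows + pc$row
  covs <- cell_covariates(ls, idx)
  if (!is.null(ls$veg_levels)) {
    covs$veg <- factor(ls$veg_levels[covs$veg], levels = ls$veg_levels)
  }
  cbind(as.data.frame(points), covs)
}

#' Thin collinear predictors
#'
#' Greedy multicollinearity reduction: while any pair of continuous columns
#' has `|Pearson r|` above the threshold, the member of the worst-offending
#' pair with the larger mean absolute correlation to all other columns is
#' dropped (ties broken by column order). The conventional wildlife-RSF
#' screen retains predictors with pairwise `|r| <= 0.65`.
#'
#' @param data data.frame of candidate continuous predictors (non-numeric
#'   columns are retained untouched and excluded from the correlations).
#' @param threshold maximum tolerated `|r|`.
#' @return list with `retained` (column names, original order), `dropped`,
#'   and `log` (data.frame of drop decisions).
#' @export
thin_collinear <- function(data, threshold = 0.65) {
  data <- as.data.frame(data)
  num <- names(data)[vapply(data, is.numeric, TRUE)]
  keep_always <- setdiff(names(data), num)
  if (length(num) < 2) stopf("need at least 2 continuous variables")
  if (nrow(data) < 3) stopf("need at least 3 rows")
  const <- num[vapply(data[num], function(z) stats::sd(z) == 0 || !is.finite(stats::sd(z)), TRUE)]
  if (length(const)) {
    warnf("constant column(s) excluded from correlation screen but retained: %s",
          paste(const, collapse = ", "))
  }
  active <- setdiff(num, const)
  log <- data.frame(dropped = character(), against = character(),
                    r = numeric(), stringsAsFactors = FALSE)
  while (length(active) >= 2) {
    cm <- abs(stats::cor(data[active]))
    diag(cm) <- 0
    worst <- max(cm)
    if (worst <= threshold) break
    ij <- which(cm == worst, arr.ind = TRUE)[1, ]
    a <- active[ij[1]]; b <- active[ij[2]]
    # keep original column order in the tie-break
    pair <- names(data)[names(data) %in% c(a, b)]
    ma <- mean(cm[pair[1], ]); mb <- mean(cm[pair[2], ])
    drop <- if (mb >= ma) pair[2] else pair[1]
    other <- setdiff(pair, drop)
    log <- rbind(log, data.frame(dropped = drop, against = other, r = worst,
                                 stringsAsFactors = FALSE))
    active <- setdiff(active, drop)
  }
  retained <- names(data)[names(data) %in% c(active, const, keep_always)]
  list(retained = retained, dropped = log$dropped, log = log)
}

#' Assemble the use-availability design
#'
#' End-to-end design construction for one season: delineate the pooled
#' population range as the `isopleth_level` kernel-density isopleth of all
#' used points, buffer it by `buffer_m`, sample available points at
#' `ratio`:1 with used points uniformly within the buffered range, extract
#' covariates at every point, and screen continuous covariates for
#' collinearity. Available rows are assigned to individuals so each
#' individual contributes equal used and available counts (this allocation
#' also defines fold membership in leave-one-individual-out
#' cross-validation).
#'
#' @param telemetry used-point data.frame from [gen_telemetry()] or
#'   [read_telemetry()] (rows with `label == "used"` are taken).
#' @param ls a [landscape_stack()].
#' @param isopleth_level kernel density isopleth level (default 0.999).
#' @param buffer_m buffer distance in meters.
#' @param ratio available:used ratio (default 1).
#' @param cor_threshold collinearity threshold for [thin_collinear()].
#' @param bandwidth KDE bandwidth (m), `NULL` for Silverman's rule.
#' @param seed seed for availability sampling.
#' @return list of class `rsf_design` with elements `data` (data.frame:
#'   `label` 1/0, `individual_id`, `season`, `x`, `y`, covariates),
#'   `polygon` (the buffered range), `retained` (continuous covariates
#'   surviving the screen), `drop_log`, and `veg_levels`.
#' @export
build_design <- function(telemetry, ls, isopleth_level = 0.999,
                         buffer_m = 1000, ratio = 1, cor_threshold = 0.65,
                         bandwidth = NULL, seed = 1L) {
  used <- telemetry[telemetry$label == "used", , drop = FALSE]
  if (!nrow(used)) stopf("telemetry contains no used rows")
  dens <- kde2d_grid(used[, c("x", "y")], ls, bandwidth = bandwidth)
  poly <- isopleth(dens, ls, level = isopleth_level)
  poly <- buffer_polygon(poly, buffer_m)

  counts <- table(used$individual_id)
  n_avail_i <- round(as.vector(counts) * ratio)
  avail <- sample_available(poly, sum(n_avail_i), seed = seed)
  avail$individual_id <- rep(names(counts), n_avail_i)
  avail$season <- used$season[1]
  avail$label <- "available"

  used_cov <- extract_covariates(used[, c("individual_id", "season", "label", "x", "y")], ls)
  avail_cov <- extract_covariates(avail[, c("individual_id", "season", "label", "x", "y")], ls)
  dat <- rbind(used_cov, avail_cov)
  dat$label <- as.integer(dat$label == "used")

  cont <- c("elev", "slope", "cos_aspect", "sin_aspect", "dist_water")
  thin <- thin_collinear(dat[cont], threshold = cor_threshold)

  structure(list(data = dat, polygon = poly, retained = thin$retained,
                 drop_log = thin$log, veg_levels = ls$veg_levels),
            class = "rsf_design")
}

#' @export
print.rsf_design <- function(x, ...) {
  n1 <- sum(x$data$label == 1); n0 <- sum(x$data$label == 0)
  cat(sprintf("<rsf_design> %d used + %d available points, %d individuals\n",
              n1, n0, length(unique(x$data$individual_id))))
  cat("  retained covariates:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$drop_log)) {
    cat("  dropped:", paste(sprintf("%s (r = %.2f vs %s)", x$drop_log$dropped,
                                    x$drop_log$r, x$drop_log$against),
                            collapse = "; "), "\n")
  }
  invisible(x)
}
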