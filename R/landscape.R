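#' Landscape configuration
#'
#' Parameters controlling the synthetic landscape generator. Defaults emulate
#' the terrain scales of a Great Basin mule-deer range: a 128 x 128 grid of
#' 100 m cells (a 12.8 km square extent), elevations spanning roughly
#' 1,650--2,900 m, smooth topography, sparse water sources biased toward
#' valley bottoms, and five vegetation communities with sagebrush as the
#' reference class.
#'
#' @param n_rows,n_cols grid dimensions (cells); must be >= 16.
#' @param cell cell size in meters (> 0).
#' @param x0,y0 coordinates of the lower-left (south-west) grid corner, meters.
#' @param elev_range numeric length 2, allowed elevation span in meters
#'   (values are clipped to it).
#' @param elev_mean,elev_sd target mean and standard deviation of the
#'   elevation field (meters); defaults echo the availability distribution
#'   of a Great Basin seasonal range (mean ~2,075 m, SD ~250 m).
#' @param elev_autocorr_m spatial autocorrelation range (Gaussian smoothing
#'   standard deviation, meters) of the elevation field.
#' @param n_water number of water source cells.
#' @param veg_autocorr_m autocorrelation range of the latent vegetation field.
#' @param n_veg_classes number of vegetation classes (>= 2); class 1 is the
#'   reference class ("sagebrush").
#' @return a list of class `landscape_config`.
#' @export
landscape_config <- function(n_rows = 128L, n_cols = 128L, cell = 100,
                             x0 = 0, y0 = 0,
                             elev_range = c(1650, 2900),
                             elev_mean = 2075, elev_sd = 250,
                             elev_autocorr_m = 1200,
                             n_water = 10L,
                             veg_autocorr_m = 800,
                             n_veg_classes = 5L) {
  if (n_rows < 16L || n_cols < 16L) stopf("grid must be at least 16 x 16 cells")
  if (cell <= 0) stopf("cell size must be positive")
  if (n_veg_classes < 2L) stopf("need at least 2 vegetation classes")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell = cell, x0 = x0, y0 = y0, elev_range = elev_range,
                 elev_mean = elev_mean, elev_sd = elev_sd,
                 elev_autocorr_m = elev_autocorr_m, n_water = as.integer(n_water),
                 veg_autocorr_m = veg_autocorr_m,
                 n_veg_classes = as.integer(n_veg_classes)),
            class = "landscape_config")
}

veg_class_names <- c("sagebrush", "pinyon_juniper", "mahogany",
                     "grassland", "desert_scrub", "aspen", "riparian",
                     "deciduous_shrub", "alpine_meadow", "introduced_grass")

#' Construct a landscape stack
#'
#' A `landscape_stack` holds aligned covariate rasters on one grid: continuous
#' layers `elev` (m), `slope` (degrees), `aspect` (radians in `[0, 2*pi)`,
#' 0 = north-facing), `dist_water` (m), and a categorical `veg` layer coded as
#' small integers with class 1 the reference class. Matrices are stored with
#' row 1 at the north edge; `x0`/`y0` give the south-west corner.
#'
#' @param layers named list of numeric matrices sharing one dimension.
#' @param cell,x0,y0 grid geometry (meters).
#' @param veg_levels character vector of vegetation class names (code i maps
#'   to `veg_levels[i]`); the first is the reference class.
#' @return object of class `landscape_stack`.
#' @export
landscape_stack <- function(layers, cell, x0 = 0, y0 = 0,
                            veg_levels = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1)
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stopf("all layers must share identical grid geometry")
  }
  if (!is.null(layers$slope) && any(layers$slope < 0, na.rm = TRUE)) {
    stopf("slope layer must be non-negative")
  }
  if (!is.null(layers$dist_water) && any(layers$dist_water < 0, na.rm = TRUE)) {
    stopf("dist_water layer must be non-negative")
  }
  if (!is.null(layers$aspect)) {
    a <- layers$aspect
    if (any(a < 0 | a >= 2 * pi, na.rm = TRUE)) stopf("aspect must lie in [0, 2*pi)")
  }
  if (!is.null(layers$veg)) {
    codes <- sort(unique(as.vector(layers$veg)))
    if (!all(codes == seq_along(codes))) {
      stopf("vegetation codes must be the contiguous set 1..k")
    }
    if (is.null(veg_levels)) veg_levels <- veg_class_names[seq_along(codes)]
    if (length(veg_levels) < max(codes)) stopf("veg_levels shorter than code range")
  }
  structure(list(layers = layers, cell = cell, x0 = x0, y0 = y0,
                 n_rows = dims[1, 1], n_cols = dims[2, 1],
                 veg_levels = veg_levels),
            class = "landscape_stack")
}

#' @export
print.landscape_stack <- function(x, ...) {
  cat(sprintf("<landscape_stack> %d x %d cells of %g m (%.1f x %.1f km)\n",
              x$n_rows, x$n_cols, x$cell,
              x$n_cols * x$cell / 1000, x$n_rows * x$cell / 1000))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  if (!is.null(x$veg_levels)) {
    cat("  vegetation classes:", paste(x$veg_levels, collapse = ", "),
        sprintf("(reference: %s)\n", x$veg_levels[1]))
  }
  invisible(x)
}

# --- grid geometry ---------------------------------------------------------

cell_centers_x <- function(ls) ls$x0 + (seq_len(ls$n_cols) - 0.5) * ls$cell
cell_centers_y <- function(ls) ls$y0 + (ls$n_rows - seq_len(ls$n_rows) + 0.5) * ls$cell

#' Map points to grid cells
#'
#' Cells use half-open intervals: a point on a cell's west or south edge
#' belongs to that cell. Points outside the extent yield an error naming the
#' offending point.
#'
#' @param ls a `landscape_stack` (or anything carrying the same geometry).
#' @param x,y point coordinates in meters.
#' @return list with integer vectors `row`, `col`.
#' @export
point_to_cell <- function(ls, x, y) {
  col <- floor((x - ls$x0) / ls$cell) + 1L
  row <- ls$n_rows - floor((y - ls$y0) / ls$cell)
  bad <- which(col < 1L | col > ls$n_cols | row < 1L | row > ls$n_rows)
  if (length(bad)) {
    stopf("point %d (x = %.1f, y = %.1f) lies outside the landscape extent",
          bad[1], x[bad[1]], y[bad[1]])
  }
  list(row = as.integer(row), col = as.integer(col))
}

# --- generation ------------------------------------------------------------

# smooth Gaussian random field on the grid, zero mean / unit sd (approx)
gaussian_field <- function(n_rows, n_cols, sd_cells) {
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  if (sd_cells > 0) z <- conv2d_fft(z, gauss_kernel(sd_cells))
  s <- stats::sd(z)
  if (s > 0) z <- (z - mean(z)) / s
  z
}

#' Generate a synthetic landscape
#'
#' Elevation is a smooth spatially autocorrelated Gaussian field rescaled to
#' the configured range; slope (degrees) and aspect (radians from north) are
#' derived from elevation by finite differences; distance to water is the
#' Euclidean distance to a set of generated water-source cells placed
#' preferentially in valley bottoms; vegetation classes are quantile bins of
#' an independent autocorrelated field.
#'
#' @param config a [landscape_config()].
#' @param seed integer seed; identical `(config, seed)` give bit-identical
#'   stacks.
#' @return a [landscape_stack()].
#' @export
gen_landscape <- function(config = landscape_config(), seed = 1L) {
  if (!inherits(config, "landscape_config")) stopf("`config` must be a landscape_config")
  with_seed(seed, {
    nr <- config$n_rows; nc <- config$n_cols; cs <- config$cell
    f <- gaussian_field(nr, nc, config$elev_autocorr_m / cs)
    elev <- config$elev_mean + f * config$elev_sd
    elev <- pmin(pmax(elev, config$elev_range[1]), config$elev_range[2])
    ta <- terrain_attributes(elev, cs)

    # water = a couple of streams (downhill-biased random walks) plus point
    # springs, all favouring low ground
    zsc <- (elev - mean(elev)) / max(stats::sd(elev), 1e-12)
    wprob <- exp(-0.75 * zsc)
    n_springs <- max(0L, config$n_water - 2L)
    widx <- sample.int(nr * nc, max(1L, n_springs), prob = as.vector(wprob))
    if (config$n_water >= 2L) {
      for (s in 1:2) {
        widx <- c(widx, stream_walk(elev, sample.int(nr * nc, 1L,
                                                     prob = as.vector(wprob))))
      }
    }
    dist_water <- distance_to_cells(nr, nc, cs, unique(widx))

    vf <- gaussian_field(nr, nc, config$veg_autocorr_m / cs)
    qs <- stats::quantile(vf, probs = seq(0, 1, length.out = config$n_veg_classes + 1))
    veg <- matrix(findInterval(vf, qs[-c(1, length(qs))]) + 1L, nr, nc)

    landscape_stack(list(elev = elev, slope = ta$slope, aspect = ta$aspect,
                         dist_water = dist_water, veg = veg),
                    cell = cs, x0 = config$x0, y0 = config$y0,
                    veg_levels = veg_class_names[seq_len(config$n_veg_classes)])
  })
}

# slope (degrees) and downhill-facing aspect (radians clockwise from north)
# by central differences, one-sided at the edges (exact for planar fields)
terrain_attributes <- function(elev, cell) {
  nr <- nrow(elev); nc <- ncol(elev)
  # d/dx: along columns (x increases with column index)
  ip <- pmin(seq_len(nc) + 1L, nc); im <- pmax(seq_len(nc) - 1L, 1L)
  dzdx <- sweep(elev[, ip, drop = FALSE] - elev[, im, drop = FALSE],
                2, (ip - im) * cell, `/`)
  # d/dy: y increases as row index decreases
  jp <- pmax(seq_len(nr) - 1L, 1L); jm <- pmin(seq_len(nr) + 1L, nr)
  dzdy <- (elev[jp, , drop = FALSE] - elev[jm, , drop = FALSE]) /
    ((jm - jp) * cell)
  grad <- sqrt(dzdx^2 + dzdy^2)
  slope <- atan(grad) * 180 / pi
  aspect <- atan2(-dzdx, -dzdy) %% (2 * pi)
  aspect[grad == 0] <- 0
  list(slope = slope, aspect = aspect)
}

# downhill-biased random walk across the grid, emulating a stream course;
# returns the visited cell indices
stream_walk <- function(elev, start, max_len = NULL) {
  nr <- nrow(elev); nc <- ncol(elev)
  if (is.null(max_len)) max_len <- nr + nc
  r <- ((start - 1L) %% nr) + 1L
  c <- ((start - 1L) %/% nr) + 1L
  path <- integer(max_len)
  for (k in seq_len(max_len)) {
    path[k] <- (c - 1L) * nr + r
    nbr_r <- r + c(-1L, 1L, 0L, 0L)
    nbr_c <- c + c(0L, 0L, -1L, 1L)
    ok <- nbr_r >= 1L & nbr_r <= nr & nbr_c >= 1L & nbr_c <= nc
    nbr_r <- nbr_r[ok]; nbr_c <- nbr_c[ok]
    z <- elev[cbind(nbr_r, nbr_c)]
    w <- exp(-(z - elev[r, c]) / max(stats::sd(elev), 1e-9))  # prefer downhill
    pick <- sample.int(length(z), 1L, prob = w)
    r <- nbr_r[pick]; c <- nbr_c[pick]
  }
  unique(path)
}

# Euclidean distance (m) from every cell center to the nearest of `idx` cells
distance_to_cells <- function(n_rows, n_cols, cell, idx) {
  rows <- ((idx - 1L) %% n_rows) + 1L
  cols <- ((idx - 1L) %/% n_rows) + 1L
  cx <- (seq_len(n_cols) - 0.5) * cell
  cy <- (n_rows - seq_len(n_rows) + 0.5) * cell
  wx <- (cols - 0.5) * cell
  wy <- (n_rows - rows + 0.5) * cell
  d2 <- matrix(Inf, n_rows, n_cols)
  dy2 <- outer(cy, wy, function(a, b) (a - b)^2)   # n_rows x n_water
  for (k in seq_along(idx)) {
    dk <- outer(dy2[, k], (cx - wx[k])^2, `+`)
    d2 <- pmin(d2, dk)
  }
  sqrt(d2)
}

# --- ASCII-grid I/O --------------------------------------------------------

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster interchange. `write_ascii_grid()` writes a single matrix
#' (row 1 = north) with the standard 6-line header; `read_ascii_grid()`
#' returns `list(values, cell, x0, y0)`. `write_landscape()` and
#' `read_landscape()` round-trip a full [landscape_stack()] as one `.asc` file
#' per layer plus a small key-value metadata file.
#'
#' @param m numeric matrix, row 1 at the north edge.
#' @param path file path.
#' @param cell,x0,y0 grid geometry in meters.
#' @param na_value NODATA sentinel written for `NA` cells.
#' @name ascii_grid
#' @export
write_ascii_grid <- function(m, path, cell, x0 = 0, y0 = 0, na_value = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(m)),
               sprintf("nrows %d", nrow(m)),
               sprintf("xllcorner %.10g", x0),
               sprintf("yllcorner %.10g", y0),
               sprintf("cellsize %.10g", cell),
               sprintf("NODATA_value %g", na_value)), con)
  mm <- m
  mm[is.na(mm)] <- na_value
  utils::write.table(format(mm, digits = 10, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  vals <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                          tolower(vapply(kv, `[`, "", 1)))
  m <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(m) <- NULL
  m[m == vals[["nodata_value"]]] <- NA
  stopifnot(nrow(m) == vals[["nrows"]], ncol(m) == vals[["ncols"]])
  list(values = m, cell = vals[["cellsize"]],
       x0 = vals[["xllcorner"]], y0 = vals[["yllcorner"]])
}

#' @rdname ascii_grid
#' @param ls a `landscape_stack`.
#' @param dir directory to hold one `.asc` per layer.
#' @export
write_landscape <- function(ls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(ls$layers)) {
    write_ascii_grid(ls$layers[[nm]], file.path(dir, paste0(nm, ".asc")),
                     cell = ls$cell, x0 = ls$x0, y0 = ls$y0)
  }
  meta <- c(paste0("veg_levels: ", paste(ls$veg_levels, collapse = ",")))
  writeLines(meta, file.path(dir, "landscape_meta.txt"))
  invisible(dir)
}

#' @rdname ascii_grid
#' @export
read_landscape <- function(dir) {
  files <- list.files(dir, pattern = "\\.asc$", full.names = TRUE)
  if (!length(files)) stopf("no .asc layers found in %s", dir)
  grids <- lapply(files, read_ascii_grid)
  layers <- lapply(grids, `[[`, "values")
  names(layers) <- sub("\\.asc$", "", basename(files))
  if (!is.null(layers$veg)) layers$veg <- matrix(as.integer(layers$veg),
                                                 nrow(layers$veg))
  meta_path <- file.path(dir, "landscape_meta.txt")
  veg_levels <- NULL
  if (file.exists(meta_path)) {
    ln <- grep("^veg_levels:", readLines(meta_path), value = TRUE)
    if (length(ln)) veg_levels <- strsplit(sub("^veg_levels:\\s*", "", ln[1]), ",")[[1]]
  }
  g <- grids[[1]]
  landscape_stack(layers, cell = g$cell, x0 = g$x0, y0 = g$y0,
                  veg_levels = veg_levels)
}
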