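#' Extract covariates at grid cells
#'
#' Internal workhorse shared by [extract_covariates()] and the generator:
#' returns the covariate row for each cell index (column-major into the layer
#' matrices), with aspect transformed to the shifted trigonometric pair
#' `cos_aspect = 1 + cos(theta)` (north-south, 2 = north-facing) and
#' `sin_aspect = 1 + sin(theta)` (east-west), each in `[0, 2]`.
#'
#' @param ls a [landscape_stack()].
#' @param idx integer vector of cell indices (column-major).
#' @return data.frame with columns `elev`, `slope`, `cos_aspect`,
#'   `sin_aspect`, `dist_water`, `veg` (integer codes).
#' @keywords internal
cell_covariates <- function(ls, idx) {
  th <- ls$layers$aspect[idx]
  data.frame(
    elev = ls$layers$elev[idx],
    slope = ls$layers$slope[idx],
    cos_aspect = 1 + cos(th),
    sin_aspect = 1 + sin(th),
    dist_water = ls$layers$dist_water[idx],
    veg = as.integer(ls$layers$veg[idx])
  )
}

#' Range polygons on the landscape grid
#'
#' A `range_polygon` is a set of grid cells (stored as a logical mask aligned
#' with the landscape grid) delineating a seasonal range, with its total area
#' in square meters.
#'
#' @param mask logical matrix on the landscape grid; must contain at least one
#'   `TRUE` cell.
#' @param ls the `landscape_stack` supplying grid geometry.
#' @return object of class `range_polygon`.
#' @export
range_polygon <- function(mask, ls) {
  mask <- mask & !is.na(mask)
  if (!any(mask)) stopf("range polygon is empty")
  if (nrow(mask) != ls$n_rows || ncol(mask) != ls$n_cols) {
    stopf("mask geometry does not match the landscape grid")
  }
  structure(list(mask = mask, cell = ls$cell, x0 = ls$x0, y0 = ls$y0,
                 n_rows = ls$n_rows, n_cols = ls$n_cols,
                 area = sum(mask) * ls$cell^2),
            class = "range_polygon")
}

#' @export
print.range_polygon <- function(x, ...) {
  cat(sprintf("<range_polygon> %d cells, %.2f km^2\n",
              sum(x$mask), x$area / 1e6))
  invisible(x)
}

full_extent_polygon <- function(ls) {
  range_polygon(matrix(TRUE, ls$n_rows, ls$n_cols), ls)
}

#' Simulate individual-level telemetry from a known selection surface
#'
#' For each individual an intercept `b_i ~ Normal(0, sigma_b^2)` is drawn and
#' `fixes_per_individual` used locations are sampled over the cells of
#' `polygon` with probability proportional to `exp(true linear predictor)`,
#' then jittered to continuous coordinates within the cell. With
#' `mode = "markov"` the fixes form a first-order movement chain: each fix is
#' drawn from the selection weights re-weighted by a Gaussian kernel around
#' the previous fix (emulating the strong temporal autocorrelation of real
#' GPS collar data); with the default `mode = "iid"` fixes are independent,
#' which keeps the sampling distribution exactly multinomial.
#'
#' Individuals use deterministic sub-streams of `seed`, so enlarging
#' `n_individuals` never perturbs the fixes of existing individuals.
#'
#' @param landscape a [landscape_stack()].
#' @param truth a [truth_surface()].
#' @param n_individuals,fixes_per_individual sampling effort; defaults emulate
#'   a multi-year GPS collar study (~50 animals, ~250 daily fixes each).
#' @param polygon a [range_polygon()]; default: the full landscape extent.
#' @param season season tag stored with the rows.
#' @param mode `"iid"` or `"markov"` (see above).
#' @param step_sd Gaussian step scale (m) for `mode = "markov"`.
#' @param seed integer seed.
#' @return data.frame of used rows with columns `individual_id`, `x`, `y`,
#'   `season`, `label` (`"used"`); per-individual intercepts in
#'   `attr(, "b_i")`.
#' @export
gen_telemetry <- function(landscape, truth, n_individuals = 50L,
                          fixes_per_individual = 250L, polygon = NULL,
                          season = "summer", mode = c("iid", "markov"),
                          step_sd = 500, seed = 1L) {
  mode <- match.arg(mode)
  if (truth$sigma_b < 0) stopf("sigma_b must be non-negative")
  if (is.null(polygon)) polygon <- full_extent_polygon(landscape)
  idx <- which(polygon$mask)
  if (!length(idx)) stopf("range polygon is empty")
  covs <- cell_covariates(landscape, idx)
  lp <- true_linear_predictor(truth, covs)
  w <- exp(lp - max(lp))
  nr <- landscape$n_rows
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  cxs <- landscape$x0 + (cols - 1L) * landscape$cell
  cys <- landscape$y0 + (nr - rows) * landscape$cell

  out <- vector("list", n_individuals)
  b_all <- numeric(n_individuals)
  ids <- sprintf("ind%03d", seq_len(n_individuals))
  for (i in seq_len(n_individuals)) {
    res <- with_seed(sub_seed(seed, i), {
      b_i <- stats::rnorm(1, 0, truth$sigma_b)
      wi <- exp(lp + b_i - max(lp + b_i))
      picks <- if (mode == "iid") {
        sample.int(length(idx), fixes_per_individual, replace = TRUE, prob = wi)
      } else {
        p <- integer(fixes_per_individual)
        p[1] <- sample.int(length(idx), 1L, prob = wi)
        for (t in seq_len(fixes_per_individual - 1L)) {
          d2 <- (cxs - cxs[p[t]])^2 + (cys - cys[p[t]])^2
          wk <- wi * exp(-d2 / (2 * step_sd^2))
          p[t + 1L] <- sample.int(length(idx), 1L, prob = wk)
        }
        p
      }
      ux <- cxs[picks] + stats::runif(fixes_per_individual) * landscape$cell
      uy <- cys[picks] + stats::runif(fixes_per_individual) * landscape$cell
      list(b_i = b_i, x = ux, y = uy)
    })
    b_all[i] <- res$b_i
    out[[i]] <- data.frame(individual_id = ids[i], x = res$x, y = res$y,
                           season = season, label = "used")
  }
  tel <- do.call(rbind, out)
  attr(tel, "b_i") <- stats::setNames(b_all, ids)
  tel
}

#' Telemetry CSV round-trip
#'
#' Fixed header `individual_id, x, y, season, label`, followed by any
#' covariate columns already extracted.
#'
#' @param tel telemetry data.frame.
#' @param path CSV path.
#' @name telemetry_io
#' @export
write_telemetry <- function(tel, path) {
  lead <- c("individual_id", "x", "y", "season", "label")
  miss <- setdiff(lead, names(tel))
  if (length(miss)) stopf("telemetry lacks column(s): %s", paste(miss, collapse = ", "))
  tel <- tel[, c(lead, setdiff(names(tel), lead)), drop = FALSE]
  utils::write.csv(tel, path, row.names = FALSE)
  invisible(path)
}

#' @rdname telemetry_io
#' @export
read_telemetry <- function(path) {
  tel <- utils::read.csv(path, stringsAsFactors = FALSE)
  lead <- c("individual_id", "x", "y", "season", "label")
  miss <- setdiff(lead, names(tel))
  if (length(miss)) stopf("telemetry file lacks column(s): %s", paste(miss, collapse = ", "))
  tel
}
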