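# background row: continuous covariates at their means, factors at the
# reference (first) level or the modal level
background_row <- function(data, background = c("mean", "mode")) {
  background <- match.arg(background)
  out <- lapply(data, function(col) {
    if (is.numeric(col)) return(mean(col))
    if (is.factor(col)) {
      lv <- if (background == "mean") levels(col)[1] else names(which.max(table(col)))
      return(factor(lv, levels = levels(col)))
    }
    col[1]
  })
  as.data.frame(out)
}

model_predict <- function(model, newdata, scale) {
  if (inherits(model, "rsf_glmm")) {
    predict(model, newdata, type = if (scale == "link") "link" else "response")
  } else if (inherits(model, "rsf_forest")) {
    p <- predict(model, newdata)
    if (scale == "link") stats::qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6)) else p
  } else if (is.function(model)) {
    model(newdata)
  } else {
    stopf("unsupported model class: %s", paste(class(model), collapse = "/"))
  }
}

focal_grid_values <- function(col, n_bins) {
  if (is.factor(col)) return(factor(levels(col), levels = levels(col)))
  r <- range(col)
  if (diff(r) == 0) return(r[1])
  edges <- seq(r[1], r[2], length.out = n_bins + 1L)
  (edges[-1] + edges[-length(edges)]) / 2
}

#' Partial dependence of a fitted RSF
#'
#' Model predictions over a grid of one or two focal covariates, holding all
#' other predictors constant at their means (categorical predictors at the
#' reference class, or the modal class). Continuous focal variables are
#' discretized into `n_bins` equal-width bins over their observed range and
#' evaluated at the bin midpoints; a categorical focal variable contributes
#' one bin per level.
#'
#' @param model an `rsf_glmm`, `rsf_forest`, or a function mapping a
#'   covariate data.frame to predictions.
#' @param data covariate data.frame defining the observed ranges and the
#'   background values.
#' @param vars one or two focal covariate names.
#' @param n_bins bins per focal variable (the interaction index uses 10).
#' @param scale `"response"` (probability) or `"link"` (logit).
#' @param background `"mean"` (reference class for factors) or `"mode"`.
#' @return object of class `rsf_pd`: `grid` (data.frame of focal values plus
#'   column `pd`), `vars`, `scale`, `background` (the row used).
#' @export
partial_dependence <- function(model, data, vars, n_bins = 10L,
                               scale = c("response", "link"),
                               background = c("mean", "mode")) {
  scale <- match.arg(scale)
  data <- as.data.frame(data)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stopf("focal variable(s) not in data: %s", paste(miss, collapse = ", "))
  if (!length(vars) %in% 1:2) stopf("supply one or two focal variables")
  bg <- background_row(data, match.arg(background))
  vals <- lapply(vars, function(v) focal_grid_values(data[[v]], n_bins))
  names(vals) <- vars
  grid <- expand.grid(vals, KEEP.OUT.ATTRS = FALSE)
  nd <- bg[rep(1L, nrow(grid)), , drop = FALSE]
  for (v in vars) nd[[v]] <- grid[[v]]
  grid$pd <- model_predict(model, nd, scale)
  if (any(!is.finite(grid$pd))) stopf("non-finite partial-dependence predictions")
  structure(list(grid = grid, vars = vars, scale = scale, background = bg),
            class = "rsf_pd")
}

#' @export
print.rsf_pd <- function(x, ...) {
  cat(sprintf("<rsf_pd> %s on the %s scale (%d grid points)\n",
              paste(x$vars, collapse = " x "), x$scale, nrow(x$grid)))
  invisible(x)
}

#' Bivariate interaction-strength index
#'
#' The three-step index of interaction strength for a pair of predictors:
#' (1) predict the model over the 10 x 10 grid of bin-midpoint combinations
#' of the pair (other predictors at means); (2) fit to those 100 predictions
#' an additive two-factor linear model with one free parameter per bin of
#' each variable (20 parameters under sum-to-zero identification) -- the best
#' additive-but-unconstrained reconstruction of the bivariate surface; (3)
#' report the root mean squared error of that reconstruction. Additive
#' surfaces score exactly 0; the index grows with the part of the bivariate
#' structure no additive function can express. For a logistic model the grid
#' is evaluated on the link scale so that a no-interaction fit scores 0 by
#' construction.
#'
#' @inheritParams partial_dependence
#' @param pair character length 2.
#' @param n_bins bins per variable (default 10, the standard grid).
#' @param scale prediction scale; defaults to `"link"` for an `rsf_glmm` and
#'   `"response"` otherwise.
#' @return object of class `rsf_interaction`: `pair`, `rmse`, `pd` (the
#'   grid), `residuals` (10 x 10 matrix).
#' @export
interaction_strength <- function(model, data, pair, n_bins = 10L, scale = NULL) {
  stopifnot(length(pair) == 2L)
  if (is.null(scale)) scale <- if (inherits(model, "rsf_glmm")) "link" else "response"
  pd <- partial_dependence(model, data, pair, n_bins = n_bins, scale = scale)
  g <- pd$grid
  f1 <- factor(g[[pair[1]]], levels = unique(g[[pair[1]]]))
  f2 <- factor(g[[pair[2]]], levels = unique(g[[pair[2]]]))
  fit <- stats::lm(g$pd ~ f1 + f2,
                   contrasts = list(f1 = "contr.sum", f2 = "contr.sum"))
  res <- stats::residuals(fit)
  structure(list(pair = pair, rmse = sqrt(mean(res^2)), pd = pd,
                 residuals = matrix(res, nlevels(f1), nlevels(f2))),
            class = "rsf_interaction")
}

#' @export
print.rsf_interaction <- function(x, ...) {
  cat(sprintf("<rsf_interaction> %s x %s: RMSE = %.4g\n",
              x$pair[1], x$pair[2], x$rmse))
  invisible(x)
}

#' Rank candidate interactions by strength
#'
#' [interaction_strength()] for every candidate pair, sorted descending by
#' RMSE. Pairs with RMSE below `negligible` are flagged as consistent with
#' an additive surface.
#'
#' @inheritParams interaction_strength
#' @param pairs list of character pairs; default: all pairs of continuous
#'   predictors in `data`.
#' @param negligible RMSE below which a pair is flagged additive.
#' @return data.frame: `var1`, `var2`, `rmse`, `rank`, `negligible`.
#' @export
rank_interactions <- function(model, data, pairs = NULL, n_bins = 10L,
                              scale = NULL, negligible = 1e-6) {
  if (is.null(pairs)) {
    cont <- names(data)[vapply(data, is.numeric, TRUE)]
    if (length(cont) < 2L) stopf("need at least 2 continuous predictors")
    pairs <- utils::combn(cont, 2, simplify = FALSE)
  }
  if (length(pairs) < 1L) stopf("no candidate pairs")
  rmse <- vapply(pairs, function(p) {
    interaction_strength(model, data, p, n_bins = n_bins, scale = scale)$rmse
  }, 0)
  out <- data.frame(var1 = vapply(pairs, `[`, "", 1),
                    var2 = vapply(pairs, `[`, "", 2),
                    rmse = rmse)
  out <- out[order(-out$rmse), ]
  out$rank <- seq_len(nrow(out))
  out$negligible <- out$rmse < negligible
  rownames(out) <- NULL
  out
}

# full covariate data.frame for every landscape cell (column-major order)
landscape_covariates <- function(ls) {
  covs <- cell_covariates(ls, seq_len(ls$n_rows * ls$n_cols))
  if (!is.null(ls$veg_levels)) {
    covs$veg <- factor(ls$veg_levels[covs$veg], levels = ls$veg_levels)
  }
  covs
}

#' Project a fitted RSF across the landscape
#'
#' Evaluates the model at every grid cell's covariate vector, producing a
#' suitability raster of predicted selection propensity; cells outside the
#' range polygon (if given) are masked to `NA`.
#'
#' @param model an `rsf_glmm` or `rsf_forest` (or prediction function).
#' @param ls a [landscape_stack()].
#' @param polygon optional [range_polygon()] mask.
#' @param scale prediction scale (probability by default; the logistic model
#'   is evaluated at an individual intercept of 0).
#' @return object of class `suitability_raster`: `values` (matrix aligned
#'   with the grid), geometry fields, `model_tag`.
#' @export
project_map <- function(model, ls, polygon = NULL, scale = "response") {
  covs <- landscape_covariates(ls)
  p <- model_predict(model, covs, scale)
  m <- matrix(p, ls$n_rows, ls$n_cols)
  if (!is.null(polygon)) m[!polygon$mask] <- NA
  structure(list(values = m, cell = ls$cell, x0 = ls$x0, y0 = ls$y0,
                 model_tag = class(model)[1]),
            class = "suitability_raster")
}

#' @export
print.suitability_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<suitability_raster> %d x %d (%s): range %.3f..%.3f, %d masked cells\n",
              nrow(x$values), ncol(x$values), x$model_tag,
              min(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

rescale01 <- function(m) {
  r <- range(m, na.rm = TRUE)
  if (diff(r) == 0) return(m * 0)
  (m - r[1]) / diff(r)
}

#' Difference map between two suitability rasters
#'
#' Pixel-by-pixel `a - b` after min-max rescaling each raster to `[0, 1]`
#' (relative selection propensity), so the two model classes are compared on
#' a common scale; positive cells are deemed more suitable by model `a`
#' (conventionally the forest). `NA` (masked) cells propagate.
#'
#' @param a,b `suitability_raster`s on identical grids.
#' @param rescale min-max rescale each raster first (default TRUE).
#' @return a `suitability_raster` of differences in `[-1, 1]`.
#' @export
difference_map <- function(a, b, rescale = TRUE) {
  if (!identical(dim(a$values), dim(b$values)) || a$cell != b$cell ||
      a$x0 != b$x0 || a$y0 != b$y0) {
    stopf("raster geometries do not match")
  }
  va <- if (rescale) rescale01(a$values) else a$values
  vb <- if (rescale) rescale01(b$values) else b$values
  structure(list(values = va - vb, cell = a$cell, x0 = a$x0, y0 = a$y0,
                 model_tag = sprintf("%s - %s", a$model_tag, b$model_tag)),
            class = "suitability_raster")
}

#' True partial-dependence curve of a simulation truth
#'
#' The known selection surface evaluated on the same grid convention as
#' [partial_dependence()] (focal bin midpoints, other covariates at their
#' means, vegetation at the reference class), on the logit scale. This is
#' the curve model-recovered partial dependence is compared against in
#' simulation studies.
#'
#' @param truth a [truth_surface()].
#' @param data covariate data.frame defining ranges and background means.
#' @param var focal covariate name.
#' @param n_bins grid resolution.
#' @return data.frame with the focal values and column `lp` (true logit).
#' @export
truth_partial_dependence <- function(truth, data, var, n_bins = 10L) {
  pd <- partial_dependence(
    function(nd) true_linear_predictor(truth, nd),
    data, var, n_bins = n_bins, scale = "link")
  out <- pd$grid
  names(out)[names(out) == "pd"] <- "lp"
  out
}
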