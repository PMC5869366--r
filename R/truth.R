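#' True selection surfaces for simulation
#'
#' A `truth_surface` encodes a known resource-selection surface on the logit
#' scale: an intercept, additive functional terms per covariate (linear,
#' humped, or threshold), pairwise product interactions, categorical
#' vegetation-class effects, and a between-individual random-intercept
#' standard deviation `sigma_b`. It is deterministic given its parameters and
#' evaluable at any complete covariate vector, which is what makes every
#' downstream stage of the pipeline testable against known truth.
#'
#' Term constructors:
#' * `term_linear(var, coef, center, scale)`: `coef * (x - center) / scale`.
#' * `term_hump(var, coef, optimum, width)`: Gaussian hump
#'   `coef * exp(-(x - optimum)^2 / (2 * width^2))`, maximal at `optimum`.
#' * `term_threshold(var, coef, breakpoint, width)`: logistic plateau
#'   `coef * plogis((breakpoint - x) / width)`; approximately `coef` well
#'   below the breakpoint, decaying to 0 beyond it over a scale of `width`.
#'
#' @param intercept baseline logit.
#' @param terms list of term objects from the constructors above.
#' @param interactions list of `interaction_term()` objects.
#' @param class_effects named numeric vector of vegetation-class effects
#'   (logit units); the reference class should be 0 or absent.
#' @param sigma_b standard deviation (>= 0) of the per-individual intercept.
#' @return object of class `truth_surface`.
#' @export
truth_surface <- function(intercept = 0, terms = list(), interactions = list(),
                          class_effects = NULL, sigma_b = 0) {
  if (sigma_b < 0) stopf("sigma_b must be non-negative")
  structure(list(intercept = intercept, terms = terms,
                 interactions = interactions, class_effects = class_effects,
                 sigma_b = sigma_b),
            class = "truth_surface")
}

#' @rdname truth_surface
#' @param var covariate name.
#' @param coef term coefficient (logit units).
#' @param center,scale standardization of a linear term.
#' @export
term_linear <- function(var, coef, center = 0, scale = 1) {
  list(var = var, type = "linear", coef = coef, center = center, scale = scale)
}

#' @rdname truth_surface
#' @param optimum covariate value at which the humped response peaks.
#' @param width Gaussian width of the hump (same units as the covariate).
#' @export
term_hump <- function(var, coef, optimum, width) {
  list(var = var, type = "hump", coef = coef, optimum = optimum, width = width)
}

#' @rdname truth_surface
#' @param breakpoint covariate value at which the plateau gives way.
#' @export
term_threshold <- function(var, coef, breakpoint, width) {
  list(var = var, type = "threshold", coef = coef, breakpoint = breakpoint,
       width = width)
}

#' @rdname truth_surface
#' @param vars character length 2, the interacting covariates.
#' @param centers,scales standardization applied to each covariate before the
#'   product is taken (defaults: raw product).
#' @param bounded squash each standardized covariate through `tanh` before
#'   the product, bounding the interaction surface (keeps extreme covariate
#'   combinations from dominating the logit).
#' @export
interaction_term <- function(vars, coef, centers = c(0, 0), scales = c(1, 1),
                             bounded = FALSE) {
  stopifnot(length(vars) == 2)
  list(vars = vars, coef = coef, centers = centers, scales = scales,
       bounded = bounded)
}

eval_term <- function(tm, x) {
  switch(tm$type,
    linear = tm$coef * (x - tm$center) / tm$scale,
    hump = tm$coef * exp(-(x - tm$optimum)^2 / (2 * tm$width^2)),
    threshold = tm$coef * stats::plogis((tm$breakpoint - x) / tm$width),
    stopf("unknown term type '%s'", tm$type))
}

#' Evaluate the true linear predictor
#'
#' Returns `intercept + sum(main-effect terms) + sum(interactions) +
#' class effect + b_i` at each row of `covariates`.
#'
#' @param truth a [truth_surface()].
#' @param covariates a data.frame (or named list) holding every covariate the
#'   truth's terms reference; vegetation may be supplied as column `veg`
#'   (integer codes or class names) when `class_effects` are present.
#' @param b_i individual intercept(s), recycled across rows.
#' @return numeric vector of logits.
#' @export
true_linear_predictor <- function(truth, covariates, b_i = 0) {
  covariates <- as.data.frame(covariates)
  need <- unique(c(vapply(truth$terms, `[[`, "", "var"),
                   unlist(lapply(truth$interactions, `[[`, "vars"))))
  miss <- setdiff(need, names(covariates))
  if (length(miss)) stopf("missing covariate(s): %s", paste(miss, collapse = ", "))
  lp <- rep(truth$intercept, nrow(covariates))
  for (tm in truth$terms) lp <- lp + eval_term(tm, covariates[[tm$var]])
  for (it in truth$interactions) {
    a <- (covariates[[it$vars[1]]] - it$centers[1]) / it$scales[1]
    b <- (covariates[[it$vars[2]]] - it$centers[2]) / it$scales[2]
    if (isTRUE(it$bounded)) { a <- tanh(a); b <- tanh(b) }
    lp <- lp + it$coef * a * b
  }
  if (!is.null(truth$class_effects)) {
    if (is.null(covariates$veg)) stopf("missing covariate(s): veg")
    v <- covariates$veg
    eff <- if (is.numeric(v)) {
      # integer codes index the effect vector; unnamed reference = 0
      ce <- truth$class_effects
      out <- ce[v]
      out[is.na(out)] <- 0
      unname(out)
    } else {
      unname(ifelse(is.na(truth$class_effects[as.character(v)]), 0,
                    truth$class_effects[as.character(v)]))
    }
    lp <- lp + eff
  }
  lp + b_i
}

#' Default true selection surface
#'
#' The study conditions used throughout the package's simulations: a humped
#' elevation response (optimum 2,075 m, width 150 m, coefficient 2), a humped
#' slope response (optimum 18 degrees, width 10, coefficient 1), a strong
#' threshold response to distance from water (plateau of 2 logits within
#' ~1 km, decaying over ~150 m), a weak linear north-south aspect effect, a
#' slope-by-elevation product interaction on standardized scales
#' (coefficient 0.75), vegetation-class effects with sagebrush as reference,
#' and `sigma_b = 0.5` between-individual heterogeneity.
#'
#' @param sigma_b override the random-intercept SD.
#' @return a [truth_surface()].
#' @export
default_truth <- function(sigma_b = 0.5) {
  truth_surface(
    intercept = 0,
    terms = list(
      term_hump("elev", coef = 2, optimum = 2075, width = 150),
      term_hump("slope", coef = 1, optimum = 18, width = 10),
      term_threshold("dist_water", coef = 2, breakpoint = 1000, width = 150),
      term_linear("cos_aspect", coef = 0.3, center = 1, scale = 0.7)
    ),
    interactions = list(
      interaction_term(c("slope", "elev"), coef = 0.75,
                       centers = c(12, 2075), scales = c(5, 250),
                       bounded = TRUE)
    ),
    class_effects = c(sagebrush = 0, pinyon_juniper = -1, mahogany = 0.5,
                      grassland = -0.5, desert_scrub = 0.3),
    sigma_b = sigma_b
  )
}
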