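#' Fixed-effects logistic regression by IRLS
#'
#' Maximum-likelihood logistic regression fitted by iteratively reweighted
#' least squares, run to a score (gradient) norm below `tol` or `max_iter`
#' iterations. This is the fixed-effects core of the classical RSF; the mixed
#' fit reduces to it when the random-intercept variance is zero.
#'
#' @param X numeric design matrix (including any intercept column), full
#'   column rank.
#' @param y 0/1 response.
#' @param tol convergence tolerance on the max absolute score.
#' @param max_iter iteration cap.
#' @return list of class `rsf_logit`: `coef`, `se`, `loglik`, `iter`,
#'   `converged`, `separation` (complete-separation flag, reported with a
#'   warning rather than an error).
#' @export
fit_logistic <- function(X, y, tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!all(y %in% c(0, 1))) stopf("y must be 0/1")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient; aliased column(s): %s",
          paste(aliased, collapse = ", "))
  }
  beta <- rep(0, ncol(X))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(X, y - mu))
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta <- drop(solve(crossprod(X, w * X), crossprod(X, w * z)))
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  separation <- all(abs(y - mu) < 1e-6)
  if (separation) warnf("complete separation detected; coefficients are unstable")
  w <- pmax(mu * (1 - mu), 1e-10)
  se <- sqrt(diag(solve(crossprod(X, w * X))))
  ll <- sum(ifelse(y == 1, stats::plogis(eta, log.p = TRUE),
                   stats::plogis(-eta, log.p = TRUE)))
  structure(list(coef = stats::setNames(beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 loglik = ll, iter = it, converged = converged,
                 separation = separation),
            class = "rsf_logit")
}

#' Small-sample-corrected AIC
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n - k - 1)`; requires `n > k + 1`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters (fixed effects plus one variance
#'   parameter for a mixed fit).
#' @param n number of observations.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stopf("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Mixed-effects logistic regression with a per-individual random intercept
#'
#' Fits `logit P(y = 1) = X beta + b[group]`, `b ~ Normal(0, sigma_b^2)`, by
#' Laplace-approximated maximum likelihood (single quadrature point) via
#' [lme4::glmer()]. At the `sigma_b = 0` boundary the fit coincides with the
#' fixed-effects IRLS fit and is flagged. A single group makes the intercept
#' and random effect confounded, so the fixed-effects fit is returned with
#' `sigma_b = NA` and a warning.
#'
#' @param X numeric design matrix including the intercept column.
#' @param y 0/1 response.
#' @param groups grouping factor (individual ids).
#' @return object of class `rsf_glmm`: `coef`, `se`, `sigma_b`, `loglik`
#'   (Laplace), `k` (fixed effects + 1 variance parameter), `n`, `aicc`,
#'   `converged`, `boundary`, `fit_engine`.
#' @export
fit_mixed_logistic <- function(X, y, groups) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  groups <- factor(groups)
  n <- length(y)
  if (nlevels(groups) < 2L) {
    warnf("single group: random intercept non-identifiable; returning the fixed-effects fit")
    fx <- fit_logistic(X, y)
    k <- ncol(X) + 1L
    return(structure(list(coef = fx$coef, se = fx$se, sigma_b = NA_real_,
                          loglik = fx$loglik, k = k, n = n,
                          aicc = aicc(fx$loglik, k, n),
                          converged = fx$converged, boundary = TRUE,
                          fit_engine = "irls"),
                     class = "rsf_glmm"))
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient; aliased column(s): %s",
          paste(aliased, collapse = ", "))
  }
  dat <- as.data.frame(X)
  nm <- paste0("V", seq_len(ncol(X)))
  names(dat) <- nm
  dat$.y <- y
  dat$.g <- groups
  fml <- stats::as.formula(paste(".y ~ 0 +", paste(nm, collapse = " + "),
                                 "+ (1 | .g)"))
  converged <- TRUE
  fit <- withCallingHandlers(
    suppressMessages(lme4::glmer(fml, data = dat, family = stats::binomial(),
                                 nAGQ = 1L,
                                 control = lme4::glmerControl(calc.derivs = FALSE))),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- lme4::fixef(fit)
  names(beta) <- colnames(X)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  names(se) <- colnames(X)
  sigma_b <- sqrt(lme4::VarCorr(fit)$.g[1, 1])
  k <- ncol(X) + 1L
  ll <- as.numeric(stats::logLik(fit))
  structure(list(coef = beta, se = se, sigma_b = sigma_b, loglik = ll,
                 k = k, n = n, aicc = aicc(ll, k, n),
                 converged = converged, boundary = sigma_b < 1e-4,
                 fit_engine = "glmer"),
            class = "rsf_glmm")
}

#' @export
print.rsf_glmm <- function(x, ...) {
  cat(sprintf("<rsf_glmm> %d fixed effects + random intercept (sigma_b = %.3f)\n",
              length(x$coef), x$sigma_b))
  cat(sprintf("  loglik %.2f, k = %d, n = %d, AICc = %.2f%s\n", x$loglik, x$k,
              x$n, x$aicc, if (!x$converged) " [convergence warning]" else ""))
  print(round(cbind(estimate = x$coef, se = x$se), 4))
  invisible(x)
}

# --- term specification and model matrices ---------------------------------

# A term spec captures how a design data.frame maps to a numeric model
# matrix: standardized continuous mains, one-hot vegetation against the
# reference class, and products of standardized mains as interactions.
term_spec <- function(data, mains, interactions = list(), veg_levels = NULL) {
  has_veg <- "veg" %in% mains
  cont <- setdiff(mains, "veg")
  for (v in cont) if (!is.numeric(data[[v]])) stopf("main term '%s' is not numeric", v)
  bad <- Filter(function(p) !all(p %in% cont), interactions)
  if (length(bad)) {
    stopf("non-hierarchical model: interaction (%s) lacks its parent main effects",
          paste(bad[[1]], collapse = " x "))
  }
  centers <- vapply(cont, function(v) mean(data[[v]]), 0)
  scales <- vapply(cont, function(v) {
    s <- stats::sd(data[[v]]); if (!is.finite(s) || s == 0) 1 else s
  }, 0)
  if (has_veg && is.null(veg_levels)) {
    veg_levels <- if (is.factor(data$veg)) levels(data$veg) else sort(unique(data$veg))
  }
  list(cont = cont, has_veg = has_veg, interactions = interactions,
       centers = centers, scales = scales, veg_levels = veg_levels)
}

make_model_matrix <- function(data, spec) {
  n <- nrow(data)
  cols <- list("(Intercept)" = rep(1, n))
  for (v in spec$cont) {
    cols[[v]] <- (data[[v]] - spec$centers[[v]]) / spec$scales[[v]]
  }
  if (spec$has_veg) {
    v <- data$veg
    if (is.numeric(v)) v <- spec$veg_levels[v]
    v <- as.character(v)
    unseen <- setdiff(unique(v), spec$veg_levels)
    if (length(unseen)) {
      warnf("unseen vegetation class(es) collapsed to reference: %s",
            paste(unseen, collapse = ", "))
      v[v %in% unseen] <- spec$veg_levels[1]
    }
    for (lv in spec$veg_levels[-1]) {
      cols[[paste0("veg_", lv)]] <- as.numeric(v == lv)
    }
  }
  for (p in spec$interactions) {
    cols[[paste(p, collapse = ":")]] <- cols[[p[1]]] * cols[[p[2]]]
  }
  do.call(cbind, cols)
}

#' Fit the classical RSF to a use-availability design
#'
#' High-level wrapper around [fit_mixed_logistic()]: builds the model matrix
#' (continuous mains standardized to mean 0 / SD 1, vegetation one-hot
#' against the reference class, interactions as products of standardized
#' mains) and fits the random-intercept logistic model grouped by individual.
#'
#' @param design an `rsf_design` from [build_design()], or a data.frame with
#'   columns `label`, `individual_id` and the covariates.
#' @param mains character vector of main-effect terms (continuous covariate
#'   names, plus `"veg"` for the vegetation block).
#' @param interactions list of character pairs of continuous mains.
#' @return an `rsf_glmm` augmented with the term `spec` for prediction.
#' @export
fit_rsf_glmm <- function(design, mains, interactions = list()) {
  dat <- if (inherits(design, "rsf_design")) design$data else design
  spec <- term_spec(dat, mains, interactions)
  X <- make_model_matrix(dat, spec)
  fit <- fit_mixed_logistic(X, dat$label, dat$individual_id)
  fit$spec <- spec
  fit$terms <- c(setdiff(mains, "veg"), if (spec$has_veg) "veg",
                 vapply(interactions, paste, "", collapse = ":"))
  fit
}

#' Predict selection propensity from a fitted RSF GLMM
#'
#' Population-level prediction (individual intercept at 0): the fixed-effects
#' linear predictor, through the inverse logit for `type = "response"`.
#'
#' @param object an `rsf_glmm` fitted by [fit_rsf_glmm()].
#' @param newdata data.frame of covariates.
#' @param type `"response"` (probability) or `"link"` (logit).
#' @param ... unused.
#' @export
predict.rsf_glmm <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(object$spec)) stopf("model lacks a term spec; fit with fit_rsf_glmm()")
  X <- make_model_matrix(newdata, object$spec)
  eta <- drop(X %*% object$coef[colnames(X)])
  if (type == "link") eta else stats::plogis(eta)
}

# --- model selection -------------------------------------------------------

#' AICc all-subsets model selection
#'
#' Fits every hierarchical submodel (an interaction is admitted only when
#' both parent mains are present; vegetation enters or leaves as a block) of
#' the candidate term sets via [fit_rsf_glmm()], including the
#' intercept-only model, and tabulates AICc, delta-AICc and Akaike weights.
#'
#' @inheritParams fit_rsf_glmm
#' @param mains candidate main effects; `interactions` candidate pairs.
#' @param progress print a dot per model.
#' @return list of class `rsf_model_table`: `table` (sorted data.frame with
#'   `model`, `k`, `loglik`, `AICc`, `delta`, `weight`), `fits` (parallel
#'   list), `term_sets`.
#' @export
all_subsets <- function(design, mains, interactions = list(), progress = FALSE) {
  if (length(mains) + length(interactions) > 20L) {
    stopf("more than 20 candidate terms; refusing the combinatorial explosion")
  }
  cont <- setdiff(mains, "veg")
  bad <- Filter(function(p) !all(p %in% cont), interactions)
  if (length(bad)) stopf("interaction (%s) has no candidate parent mains",
                         paste(bad[[1]], collapse = " x "))
  main_sets <- unlist(lapply(0:length(mains), function(k) {
    utils::combn(mains, k, simplify = FALSE)
  }), recursive = FALSE)
  models <- list()
  for (ms in main_sets) {
    ok_int <- Filter(function(p) all(p %in% ms), interactions)
    int_sets <- unlist(lapply(0:length(ok_int), function(k) {
      utils::combn(ok_int, k, simplify = FALSE)
    }), recursive = FALSE)
    for (is_ in int_sets) models[[length(models) + 1L]] <- list(mains = ms, ints = is_)
  }
  fits <- vector("list", length(models))
  rows <- vector("list", length(models))
  for (i in seq_along(models)) {
    m <- models[[i]]
    fits[[i]] <- fit_rsf_glmm(design, m$mains, m$ints)
    lab <- paste(c(m$mains, vapply(m$ints, paste, "", collapse = ":")),
                 collapse = " + ")
    if (lab == "") lab <- "(intercept only)"
    rows[[i]] <- data.frame(model = lab, k = fits[[i]]$k,
                            loglik = fits[[i]]$loglik, AICc = fits[[i]]$aicc,
                            stringsAsFactors = FALSE)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  tab <- do.call(rbind, rows)
  o <- order(tab$AICc)
  tab <- tab[o, , drop = FALSE]
  fits <- fits[o]
  models <- models[o]
  tab$delta <- tab$AICc - tab$AICc[1]
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, term_sets = models),
            class = "rsf_model_table")
}

#' @export
print.rsf_model_table <- function(x, n = 10L, ...) {
  cat(sprintf("<rsf_model_table> %d candidate models\n", nrow(x$table)))
  print(utils::head(transform(x$table, loglik = round(loglik, 2),
                              AICc = round(AICc, 2), delta = round(delta, 2),
                              weight = round(weight, 3)), n))
  invisible(x)
}

model_terms <- function(m) {
  c(m$mains, vapply(m$ints, paste, "", collapse = ":"))
}

#' Screen the confidence set for uninformative parameters
#'
#' Among models within `delta` AICc units of the best, a term present in a
#' larger model but absent from a nested submodel that the larger model fails
#' to beat by 2 AICc units is flagged uninformative, and the nested model is
#' preferred. Returns the best surviving model.
#'
#' @param ms an `rsf_model_table` from [all_subsets()].
#' @param delta width of the confidence window (AICc units).
#' @return list: `fit` (the selected `rsf_glmm`), `terms`, `pruned`
#'   (data.frame log of flagged terms), `index` (row in the model table).
#' @export
prune_uninformative <- function(ms, delta = 2.0) {
  tab <- ms$table
  win <- which(tab$delta <= delta)
  pruned <- data.frame(term = character(), larger = character(),
                       nested = character(), dAICc = numeric(),
                       stringsAsFactors = FALSE)
  flagged <- logical(length(win))
  for (a in seq_along(win)) {
    ta <- model_terms(ms$term_sets[[win[a]]])
    for (b in seq_along(win)) {
      if (a == b) next
      tb <- model_terms(ms$term_sets[[win[b]]])
      # b nested strictly inside a
      if (length(tb) < length(ta) && all(tb %in% ta)) {
        dA <- tab$AICc[win[a]] - tab$AICc[win[b]]
        if (dA > -2) {
          extra <- setdiff(ta, tb)
          flagged[a] <- TRUE
          pruned <- rbind(pruned, data.frame(
            term = paste(extra, collapse = ", "),
            larger = tab$model[win[a]], nested = tab$model[win[b]],
            dAICc = dA, stringsAsFactors = FALSE))
        }
      }
    }
  }
  keep <- win[!flagged]
  if (!length(keep)) keep <- win  # every window model flagged: fall back to best
  best <- keep[which.min(tab$AICc[keep])]
  list(fit = ms$fits[[best]], terms = model_terms(ms$term_sets[[best]]),
       pruned = unique(pruned), index = best)
}

#' Standardized regression coefficients
#'
#' Per-SD effect sizes used as the classical importance index: each
#' continuous coefficient expressed per sample standard deviation of its
#' covariate (the scale plotted in importance comparisons), alongside the
#' raw per-unit coefficient. Categorical (vegetation) and interaction terms
#' are reported unchanged and flagged.
#'
#' @param fit an `rsf_glmm` from [fit_rsf_glmm()].
#' @param data the design data the fit was built from.
#' @return data.frame: `term`, `estimate_std`, `estimate_raw`, `se_std`,
#'   `kind`.
#' @export
standardized_coefficients <- function(fit, data) {
  if (is.null(fit$spec)) stopf("model lacks a term spec; fit with fit_rsf_glmm()")
  dat <- if (inherits(data, "rsf_design")) data$data else data
  out <- list()
  for (nm in names(fit$coef)) {
    if (nm == "(Intercept)") next
    if (nm %in% fit$spec$cont) {
      sdx <- stats::sd(dat[[nm]])
      # model matrix used (x - c)/s, so per-SD coef rescales by sd/s
      f <- sdx / fit$spec$scales[[nm]]
      out[[nm]] <- data.frame(term = nm, estimate_std = fit$coef[[nm]] * f,
                              estimate_raw = fit$coef[[nm]] / fit$spec$scales[[nm]],
                              se_std = fit$se[[nm]] * f, kind = "continuous")
    } else if (startsWith(nm, "veg_")) {
      out[[nm]] <- data.frame(term = nm, estimate_std = fit$coef[[nm]],
                              estimate_raw = fit$coef[[nm]],
                              se_std = fit$se[[nm]], kind = "categorical")
    } else {
      out[[nm]] <- data.frame(term = nm, estimate_std = fit$coef[[nm]],
                              estimate_raw = fit$coef[[nm]],
                              se_std = fit$se[[nm]], kind = "interaction")
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
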