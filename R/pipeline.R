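#' Configuration for a full pipeline run
#'
#' Bundles every stage's parameters into one serializable object. The
#' defaults are the package's reference study conditions: a 12.8 km
#' synthetic landscape, 50 individuals with 250 fixes each, the
#' [default_truth()] selection surface (humped elevation, water threshold,
#' slope-by-elevation interaction, `sigma_b = 0.5`), a 99.9% isopleth with a
#' 1,000 m buffer and 1:1 availability, an `|r| <= 0.65` collinearity
#' screen, the GLMM candidate set (retained continuous mains + vegetation +
#' the three topographic pairwise interactions), and a 500-tree forest with
#' 3% subsamples and `mtry = 3`.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param landscape a [landscape_config()].
#' @param truth a [truth_surface()].
#' @param n_individuals,fixes_per_individual,season telemetry effort.
#' @param isopleth_level,buffer_m,ratio,cor_threshold design parameters.
#' @param glmm_interactions candidate interaction pairs for the GLMM.
#' @param all_subsets run AICc all-subsets selection + uninformative-term
#'   screen (slow) instead of fitting the full candidate model.
#' @param ntree,fraction,mtry,alpha,min_node forest hyperparameters.
#' @param do_cv run leave-one-individual-out cross-validation.
#' @param cv_ntree forest size during cross-validation (refits once per
#'   fold, so a reduced forest keeps runs tractable).
#' @param out_dir write artifacts there (`NULL` = in-memory only).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       landscape = landscape_config(),
                       truth = default_truth(),
                       n_individuals = 50L, fixes_per_individual = 250L,
                       season = "summer",
                       isopleth_level = 0.999, buffer_m = 1000,
                       ratio = 1, cor_threshold = 0.65,
                       glmm_interactions = list(c("slope", "elev"),
                                                c("slope", "dist_water"),
                                                c("elev", "dist_water")),
                       all_subsets = FALSE,
                       ntree = 500L, fraction = 0.03, mtry = 3L,
                       alpha = 1, min_node = 20L,
                       do_cv = TRUE, cv_ntree = 100L,
                       out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full dual-framework pipeline
#'
#' Executes simulate -> design -> fit GLMM -> fit forest -> interpret ->
#' cross-validate as one reproducible run. Each stage is timed; its warnings
#' are collected into the manifest rather than only printed; any stage error
#' aborts with the stage name. When `config$out_dir` is set, every tabular
#' artifact is written as CSV and every raster as an ASCII grid, and the
#' manifest records file checksums.
#'
#' @param config a [run_config()].
#' @return list of class `rsf_run` with the stage outputs (`landscape`,
#'   `telemetry`, `design`, `glmm`, `forest`, `importance`, `coefficients`,
#'   `interactions_rf`, `interactions_glmm`, `pd`, `maps`, `cv`) and
#'   `manifest` (stages, wall times, seeds, warnings, files).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  res <- list()
  manifest <- list(seed = config$seed, stages = list(), warnings = list(),
                   files = data.frame(file = character(), md5 = character()))
  stage <- function(name, expr) {
    ws <- character()
    t0 <- proc.time()[["elapsed"]]
    out <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
      }),
      warning = function(w) {
        ws <<- c(ws, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    manifest$stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    if (length(ws)) manifest$warnings[[name]] <<- ws
    out
  }

  res$landscape <- stage("simulate_landscape",
    gen_landscape(config$landscape, seed = sub_seed(config$seed, 1L)))
  res$telemetry <- stage("simulate_telemetry",
    gen_telemetry(res$landscape, config$truth,
                  n_individuals = config$n_individuals,
                  fixes_per_individual = config$fixes_per_individual,
                  season = config$season, seed = sub_seed(config$seed, 2L)))
  res$design <- stage("design",
    build_design(res$telemetry, res$landscape,
                 isopleth_level = config$isopleth_level,
                 buffer_m = config$buffer_m, ratio = config$ratio,
                 cor_threshold = config$cor_threshold,
                 seed = sub_seed(config$seed, 3L)))

  mains <- c(res$design$retained, "veg")
  ints <- Filter(function(p) all(p %in% res$design$retained),
                 config$glmm_interactions)
  res$glmm <- stage("fit_glmm", {
    if (config$all_subsets) {
      ms <- all_subsets(res$design, mains, ints)
      pr <- prune_uninformative(ms)
      fit <- pr$fit
      attr(fit, "model_table") <- ms$table
      attr(fit, "pruned") <- pr$pruned
      fit
    } else {
      fit_rsf_glmm(res$design, mains, ints)
    }
  })
  res$forest <- stage("fit_forest",
    fit_rsf_forest(res$design, ntree = config$ntree,
                   fraction = config$fraction, mtry = config$mtry,
                   alpha = config$alpha, min_node = config$min_node,
                   seed = sub_seed(config$seed, 4L)))

  res$importance <- stage("importance",
    permutation_importance(res$forest, seed = sub_seed(config$seed, 5L)))
  res$coefficients <- stage("std_coefficients",
    standardized_coefficients(res$glmm, res$design))
  cont <- res$design$retained
  res$interactions_rf <- stage("interactions_rf",
    rank_interactions(res$forest, res$design$data[c(cont, "veg")],
                      pairs = utils::combn(cont, 2, simplify = FALSE)))
  res$interactions_glmm <- stage("interactions_glmm",
    rank_interactions(res$glmm, res$design$data[c(cont, "veg")],
                      pairs = utils::combn(cont, 2, simplify = FALSE)))
  res$pd <- stage("partial_dependence", {
    out <- list()
    for (v in cont) {
      out[[v]] <- list(
        forest = partial_dependence(res$forest, res$design$data[c(cont, "veg")],
                                    v, n_bins = 20L),
        glmm = partial_dependence(res$glmm, res$design$data[c(cont, "veg")],
                                  v, n_bins = 20L))
    }
    out
  })
  res$maps <- stage("project_maps", {
    rf_map <- project_map(res$forest, res$landscape, res$design$polygon)
    glmm_map <- project_map(res$glmm, res$landscape, res$design$polygon)
    list(rf = rf_map, glmm = glmm_map,
         difference = difference_map(rf_map, glmm_map))
  })

  if (isTRUE(config$do_cv)) {
    res$cv <- stage("cross_validate", {
      glmm_fitter <- function(d, s) fit_rsf_glmm(d, mains, ints)
      rf_fitter <- function(d, s) {
        fit_forest(d[c(cont, "veg")], d$label, ntree = config$cv_ntree,
                   fraction = config$fraction, mtry = config$mtry,
                   alpha = config$alpha, min_node = config$min_node, seed = s)
      }
      cross_validate(rf_fitter, glmm_fitter, res$design$data,
                     seed = sub_seed(config$seed, 6L))
    })
  }

  if (!is.null(config$out_dir)) {
    manifest$files <- stage("write_artifacts", write_run(res, config$out_dir))
  }
  res$manifest <- manifest
  class(res) <- "rsf_run"
  res
}

write_run <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wcsv <- function(obj, name) {
    p <- file.path(dir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  write_telemetry(res$telemetry, file.path(dir, "telemetry.csv"))
  paths <- c(paths, file.path(dir, "telemetry.csv"))
  wcsv(res$design$data, "design.csv")
  if (nrow(res$design$drop_log)) wcsv(res$design$drop_log, "collinearity_drops.csv")
  wcsv(res$importance, "importance_rf.csv")
  wcsv(res$coefficients, "coefficients_glmm.csv")
  wcsv(res$interactions_rf, "interactions_rf.csv")
  wcsv(res$interactions_glmm, "interactions_glmm.csv")
  for (v in names(res$pd)) {
    wcsv(res$pd[[v]]$forest$grid, sprintf("pd_%s_rf.csv", v))
    wcsv(res$pd[[v]]$glmm$grid, sprintf("pd_%s_glmm.csv", v))
  }
  for (nm in names(res$maps)) {
    p <- file.path(dir, sprintf("map_%s.asc", nm))
    write_ascii_grid(res$maps[[nm]]$values, p, cell = res$maps[[nm]]$cell,
                     x0 = res$maps[[nm]]$x0, y0 = res$maps[[nm]]$y0)
    paths <- c(paths, p)
  }
  if (!is.null(res$cv)) {
    wcsv(res$cv$fold_auc, "cv_fold_auc.csv")
    wcsv(data.frame(auc_rf = res$cv$auc_a, auc_glmm = res$cv$auc_b,
                    D = res$cv$D, p = res$cv$p), "cv_summary.csv")
  }
  data.frame(file = basename(paths), md5 = unname(tools::md5sum(paths)),
             row.names = NULL)
}

#' @export
print.rsf_run <- function(x, ...) {
  cat("<rsf_run>\n  stages (s):",
      paste(sprintf("%s=%.2f", names(x$manifest$stages),
                    unlist(x$manifest$stages)), collapse = ", "), "\n")
  if (!is.null(x$cv)) {
    cat(sprintf("  CV: AUC RF = %.3f vs GLMM = %.3f (DeLong D = %.2f, p = %.3g)\n",
                x$cv$auc_a, x$cv$auc_b, x$cv$D, x$cv$p))
  }
  nw <- length(unlist(x$manifest$warnings))
  if (nw) cat(sprintf("  %d warning(s) collected in manifest\n", nw))
  invisible(x)
}

#' Side-by-side comparison report
#'
#' Pairs the two frameworks' headline outputs: forest permutation importance
#' against GLMM standardized coefficients, the interaction-strength ranking
#' under each model, and the cross-validated AUC comparison.
#'
#' @param run an `rsf_run` from [run_all()].
#' @return list of class `rsf_report`: `importance` (merged table),
#'   `interactions`, `auc` (or `NULL` without CV).
#' @export
compare_report <- function(run) {
  if (is.null(run$importance) || is.null(run$coefficients)) {
    stopf("run lacks a fitted model comparison")
  }
  imp <- run$importance
  coefs <- run$coefficients
  cont <- coefs[coefs$kind == "continuous", c("term", "estimate_std")]
  tab <- merge(data.frame(variable = imp$variable, rf_importance = imp$importance),
               data.frame(variable = cont$term, glmm_std_coef = cont$estimate_std),
               by = "variable", all.x = TRUE)
  tab <- tab[order(-tab$rf_importance), ]
  rownames(tab) <- NULL
  ints <- merge(run$interactions_rf[, c("var1", "var2", "rmse", "rank")],
                run$interactions_glmm[, c("var1", "var2", "rmse", "rank")],
                by = c("var1", "var2"), suffixes = c("_rf", "_glmm"))
  ints <- ints[order(ints$rank_rf), ]
  rownames(ints) <- NULL
  auc <- if (!is.null(run$cv)) {
    data.frame(model = c("random_forest", "glmm"),
               auc = c(run$cv$auc_a, run$cv$auc_b),
               D = run$cv$D, p = run$cv$p)
  }
  structure(list(importance = tab, interactions = ints, auc = auc),
            class = "rsf_report")
}

#' @export
print.rsf_report <- function(x, ...) {
  cat("Variable importance (forest) vs standardized coefficients (GLMM):\n")
  print(transform(x$importance, rf_importance = signif(rf_importance, 3),
                  glmm_std_coef = signif(glmm_std_coef, 3)))
  cat("\nInteraction-strength ranking (RMSE of additive reconstruction):\n")
  print(transform(x$interactions, rmse_rf = signif(rmse_rf, 3),
                  rmse_glmm = signif(rmse_glmm, 3)))
  if (!is.null(x$auc)) {
    cat("\nLeave-one-individual-out AUC:\n")
    print(transform(x$auc, auc = round(auc, 3), D = round(D, 3),
                    p = signif(p, 3)))
  }
  invisible(x)
}
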