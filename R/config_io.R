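#' Read and write run configurations
#'
#' A [run_config()] round-trips through a single YAML key-value file: the
#' landscape block, the truth surface (terms, interactions, class effects),
#' and every scalar stage parameter. `read_run_config()` rebuilds the object
#' through the constructors, so a written-then-read configuration is
#' equivalent to the original.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @name config_io
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  truth <- config$truth
  obj <- list(
    seed = config$seed,
    landscape = unclass(config$landscape),
    truth = list(
      intercept = truth$intercept,
      sigma_b = truth$sigma_b,
      terms = lapply(truth$terms, function(t) t[!vapply(t, is.null, TRUE)]),
      interactions = lapply(truth$interactions, function(it) {
        list(vars = it$vars, coef = it$coef, centers = it$centers,
             scales = it$scales, bounded = isTRUE(it$bounded))
      }),
      class_effects = as.list(truth$class_effects)
    ),
    telemetry = list(n_individuals = config$n_individuals,
                     fixes_per_individual = config$fixes_per_individual,
                     season = config$season),
    design = list(isopleth_level = config$isopleth_level,
                  buffer_m = config$buffer_m, ratio = config$ratio,
                  cor_threshold = config$cor_threshold),
    glmm = list(interactions = lapply(config$glmm_interactions, as.list),
                all_subsets = config$all_subsets),
    forest = list(ntree = config$ntree, fraction = config$fraction,
                  mtry = config$mtry, alpha = config$alpha,
                  min_node = config$min_node),
    cv = list(do_cv = config$do_cv, cv_ntree = config$cv_ntree),
    out_dir = config$out_dir
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname config_io
#' @export
read_run_config <- function(path) {
  o <- yaml::read_yaml(path)
  lc <- do.call(landscape_config, lapply(o$landscape, function(x) {
    if (is.list(x)) unlist(x) else x
  }))
  terms <- lapply(o$truth$terms, function(t) {
    switch(t$type,
      linear = term_linear(t$var, t$coef, t$center, t$scale),
      hump = term_hump(t$var, t$coef, t$optimum, t$width),
      threshold = term_threshold(t$var, t$coef, t$breakpoint, t$width),
      stopf("unknown truth term type '%s'", t$type))
  })
  ints <- lapply(o$truth$interactions, function(it) {
    interaction_term(unlist(it$vars), it$coef, unlist(it$centers),
                     unlist(it$scales), bounded = isTRUE(it$bounded))
  })
  truth <- truth_surface(intercept = o$truth$intercept, terms = terms,
                         interactions = ints,
                         class_effects = unlist(o$truth$class_effects),
                         sigma_b = o$truth$sigma_b)
  run_config(seed = o$seed, landscape = lc, truth = truth,
             n_individuals = o$telemetry$n_individuals,
             fixes_per_individual = o$telemetry$fixes_per_individual,
             season = o$telemetry$season,
             isopleth_level = o$design$isopleth_level,
             buffer_m = o$design$buffer_m, ratio = o$design$ratio,
             cor_threshold = o$design$cor_threshold,
             glmm_interactions = lapply(o$glmm$interactions, unlist),
             all_subsets = o$glmm$all_subsets,
             ntree = o$forest$ntree, fraction = o$forest$fraction,
             mtry = o$forest$mtry, alpha = o$forest$alpha,
             min_node = o$forest$min_node,
             do_cv = o$cv$do_cv, cv_ntree = o$cv$cv_ntree,
             out_dir = o$out_dir)
}
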