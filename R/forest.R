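#' Permutation association test for a split candidate
#'
#' The node-level test of the conditional-inference framework: a linear
#' statistic `T = sum(g(x) * y)` with `g` the identity for a continuous
#' predictor and the one-hot level indicators for a factor, standardized by
#' its permutation mean and variance. The default p-value uses the asymptotic
#' reference distribution (normal for continuous, chi-square with
#' `k - 1` degrees of freedom for a k-level factor); `n_perm` switches to an
#' exact Monte-Carlo permutation p-value.
#'
#' @param x predictor values at the node (numeric, or factor/integer codes).
#' @param y 0/1 response at the node; needs both classes for a nontrivial
#'   p-value.
#' @param n_perm number of Monte-Carlo permutations, or `NULL` for the
#'   asymptotic approximation.
#' @return p-value in (0, 1]; constant `x` gives exactly 1.
#' @export
node_association_test <- function(x, y, n_perm = NULL) {
  if (length(unique(y)) < 2L) return(1)
  if (is.factor(x)) return(cat_assoc_p(as.integer(x), y, n_perm = n_perm))
  if (is.numeric(x)) {
    stat_obs <- cont_assoc_stat(x, y)
    if (is.na(stat_obs)) return(1)
    if (is.null(n_perm)) return(2 * stats::pnorm(-abs(stat_obs)))
    perm <- replicate(n_perm, cont_assoc_stat(x, sample(y)))
    return((1 + sum(abs(perm) >= abs(stat_obs) - 1e-12)) / (n_perm + 1))
  }
  stopf("x must be numeric or factor")
}

# standardized linear statistic for a continuous predictor
cont_assoc_stat <- function(x, y) {
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  T <- sum(x * y)
  E <- sum(x) * mean(y)
  V <- sxx * syy / (n - 1)
  (T - E) / sqrt(V)
}

# chi-square statistic and p for a categorical predictor (2 x k table)
cat_assoc_p <- function(code, y, n_perm = NULL) {
  tab <- table(factor(code), factor(y, levels = c(0, 1)))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  k <- nrow(tab)
  if (k < 2L) return(1)
  stat <- function(tb) {
    E <- outer(rowSums(tb), colSums(tb)) / sum(tb)
    sum((tb - E)^2 / pmax(E, 1e-12))
  }
  obs <- stat(tab)
  if (is.null(n_perm)) return(stats::pchisq(obs, df = k - 1, lower.tail = FALSE))
  perm <- replicate(n_perm, {
    tb <- table(factor(code), factor(sample(y), levels = c(0, 1)))
    tb <- tb[rowSums(tb) > 0, , drop = FALSE]
    stat(tb)
  })
  (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
}

# --- tree growing ----------------------------------------------------------

# Internal predictor container: continuous matrix + integer-coded factors.
split_predictors <- function(x) {
  is_fac <- vapply(x, is.factor, TRUE)
  list(
    cont = if (any(!is_fac)) as.matrix(as.data.frame(lapply(x[!is_fac], as.numeric))) else NULL,
    cat = lapply(x[is_fac], as.integer),
    cat_levels = lapply(x[is_fac], levels),
    names = names(x), is_fac = is_fac,
    cont_idx = stats::setNames(cumsum(!is_fac), names(x)),
    cat_idx = stats::setNames(cumsum(is_fac), names(x))
  )
}

#' Grow one conditional-inference tree
#'
#' Recursive binary partitioning with permutation-test split selection: at
#' each node, `mtry` candidate predictors are drawn, their association
#' p-values computed, and the node becomes a leaf when the smallest
#' Bonferroni-adjusted p-value exceeds `alpha` or the node is too small.
#' Otherwise the minimum-p predictor is split at the point (continuous) or
#' binary level subset (categorical, exhaustive up to 10 levels) maximizing
#' the standardized two-sample statistic, subject to both children holding at
#' least `minbucket` rows.
#'
#' @param pred predictor container from `split_predictors()` (internal) or a
#'   data.frame of predictors.
#' @param y 0/1 response aligned with the predictors.
#' @param rows integer row indices forming the node sample.
#' @param mtry number of candidate predictors per split.
#' @param alpha significance threshold on the Bonferroni-adjusted p-value.
#' @param min_node do not attempt to split nodes smaller than this.
#' @param minbucket minimum child size.
#' @return a flat tree record (list of parallel node vectors) with leaf
#'   used-fractions; primarily consumed by [fit_forest()].
#' @export
grow_tree <- function(pred, y, rows, mtry = 3L, alpha = 0.05,
                      min_node = 20L, minbucket = 7L) {
  if (is.data.frame(pred)) pred <- split_predictors(pred)
  p <- length(pred$names)
  mtry <- min(mtry, p)
  nodes <- new.env(parent = emptyenv())
  nodes$var <- integer(0); nodes$split <- numeric(0)
  nodes$goleft <- list(); nodes$left <- integer(0); nodes$right <- integer(0)
  nodes$frac <- numeric(0); nodes$n <- integer(0); nodes$pval <- numeric(0)

  new_node <- function() {
    id <- length(nodes$var) + 1L
    nodes$var[id] <- NA_integer_; nodes$split[id] <- NA_real_
    nodes$goleft[[id]] <- NA; nodes$left[id] <- NA_integer_
    nodes$right[id] <- NA_integer_; nodes$frac[id] <- NA_real_
    nodes$n[id] <- NA_integer_; nodes$pval[id] <- NA_real_
    id
  }

  build <- function(rows) {
    id <- new_node()
    yr <- y[rows]
    n <- length(rows)
    nodes$n[id] <- n
    nodes$frac[id] <- mean(yr)
    if (n < min_node || all(yr == yr[1])) return(id)

    cand <- sample.int(p, mtry)
    pv <- rep(1, mtry)
    for (j in seq_along(cand)) {
      v <- cand[j]
      if (pred$is_fac[v]) {
        code <- pred$cat[[pred$cat_idx[v]]][rows]
        pv[j] <- cat_assoc_p(code, yr)
      } else {
        z <- cont_assoc_stat(pred$cont[rows, pred$cont_idx[v]], yr)
        pv[j] <- if (is.na(z)) 1 else 2 * stats::pnorm(-abs(z))
      }
    }
    best <- which.min(pv)
    p_adj <- min(1, pv[best] * mtry)
    nodes$pval[id] <- p_adj
    if (p_adj > alpha) return(id)

    v <- cand[best]
    syy <- sum((yr - mean(yr))^2)
    if (!pred$is_fac[v]) {
      x <- pred$cont[rows, pred$cont_idx[v]]
      o <- order(x)
      xs <- x[o]; ys <- yr[o]
      cum <- cumsum(ys)
      nl <- seq_len(n - 1L)
      valid <- (xs[-n] < xs[-1]) & nl >= minbucket & (n - nl) >= minbucket
      if (!any(valid)) return(id)
      Tl <- cum[nl]
      El <- nl * mean(yr)
      Vl <- nl * (n - nl) / n * syy / (n - 1)
      z2 <- ifelse(valid, (Tl - El)^2 / pmax(Vl, 1e-300), -Inf)
      cut <- which.max(z2)
      nodes$var[id] <- v
      nodes$split[id] <- (xs[cut] + xs[cut + 1L]) / 2
      go <- x <= nodes$split[id]
    } else {
      ci <- pred$cat_idx[v]
      code <- pred$cat[[ci]][rows]
      nlev_all <- length(pred$cat_levels[[ci]])
      cnt <- tabulate(code, nbins = nlev_all)
      sums <- vapply(seq_len(nlev_all), function(l) sum(yr[code == l]), 0)
      present <- which(cnt > 0)
      k <- length(present)
      if (k < 2L || k > 10L) return(id)
      # all binary partitions of present levels (fix first level on the left
      # to halve the enumeration; drop the trivial all-left partition)
      M <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), k - 1L)))
      M <- cbind(TRUE, M)
      M <- M[rowSums(M) < k, , drop = FALSE]
      nlv <- drop(M %*% cnt[present])
      Tv <- drop(M %*% sums[present])
      valid <- nlv >= minbucket & (n - nlv) >= minbucket
      if (!any(valid)) return(id)
      Vv <- nlv * (n - nlv) / n * syy / (n - 1)
      z2 <- ifelse(valid, (Tv - nlv * mean(yr))^2 / pmax(Vv, 1e-300), -Inf)
      bests <- which.max(z2)
      goleft <- rep(NA, nlev_all)
      goleft[present] <- M[bests, ]
      # unseen levels follow the majority of node rows (majority-direction)
      maj <- nlv[bests] >= n / 2
      goleft[is.na(goleft)] <- maj
      nodes$var[id] <- v
      nodes$goleft[[id]] <- goleft
      go <- goleft[code]
    }
    nodes$left[id] <- build(rows[go])
    nodes$right[id] <- build(rows[!go])
    id
  }

  root <- build(rows)
  structure(list(var = nodes$var, split = nodes$split, goleft = nodes$goleft,
                 left = nodes$left, right = nodes$right, frac = nodes$frac,
                 n = nodes$n, pval = nodes$pval, root = root),
            class = "ci_tree")
}

# route rows through a tree; returns leaf used-fractions
route_tree <- function(tree, pred, rows) {
  out <- numeric(length(rows))
  stack <- list(list(node = tree$root, pos = seq_along(rows)))
  warn_unseen <- FALSE
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top$node; pos <- top$pos
    if (!length(pos)) next
    v <- tree$var[nd]
    if (is.na(v)) {
      out[pos] <- tree$frac[nd]
      next
    }
    if (pred$is_fac[v]) {
      gl <- tree$goleft[[nd]]
      code <- pred$cat[[pred$cat_idx[v]]][rows[pos]]
      bad <- is.na(code) | code < 1L | code > length(gl)
      go <- logical(length(pos))
      go[!bad] <- gl[code[!bad]]
      if (any(bad)) {
        warn_unseen <- TRUE
        go[bad] <- mean(gl) >= 0.5  # majority-direction for unknown codes
      }
    } else {
      go <- pred$cont[rows[pos], pred$cont_idx[v]] <= tree$split[nd]
    }
    stack[[length(stack) + 1L]] <- list(node = tree$left[nd], pos = pos[go])
    stack[[length(stack) + 1L]] <- list(node = tree$right[nd], pos = pos[!go])
  }
  if (warn_unseen) warnf("unseen category routed by majority-direction rule")
  out
}

#' Fit a conditional-inference random forest
#'
#' An ensemble of [grow_tree()] trees, each grown on an independent random
#' subsample of the rows drawn without replacement at `fraction` of the data
#' (the conditional-inference convention), with `mtry` candidate predictors
#' per split. The defaults suit large GPS-collar datasets: 500 trees, 3%
#' subsamples (small fractions are appropriate when consecutive fixes are
#' strongly temporally autocorrelated), and `mtry = 3` of ~5 predictors.
#' Rows outside a tree's subsample are its out-of-bag (OOB) set, the basis
#' for honest error and permutation importance.
#'
#' Following the convention of conditional-inference *forests* (as opposed to
#' single trees), the default grows unstopped trees (`alpha = 1`): splitting
#' continues while nodes hold at least `min_node` rows, and the ensemble
#' averaging supplies the regularization. Set `alpha` below 1 to recover
#' significance-stopped trees.
#'
#' @param x data.frame of predictors (numeric and factor columns).
#' @param y 0/1 response (1 = used).
#' @param ntree number of trees.
#' @param fraction subsample fraction per tree.
#' @param mtry candidate predictors per split.
#' @param alpha,min_node,minbucket stopping rule, see [grow_tree()].
#' @param seed integer seed; identical seeds give identical forests.
#' @return object of class `rsf_forest`: `trees`, `inbag` (list of row
#'   indices per tree), the predictor container, `y`, and the
#'   hyperparameters.
#' @export
fit_forest <- function(x, y, ntree = 500L, fraction = 0.03, mtry = 3L,
                       alpha = 1, min_node = 20L, minbucket = 7L,
                       seed = 1L) {
  x <- as.data.frame(x)
  n <- nrow(x)
  m <- max(2L, floor(fraction * n))
  if (m > n) stopf("subsample larger than the data")
  if (m < min_node) stopf("subsample of %d rows is below min_node = %d", m, min_node)
  pred <- split_predictors(x)
  with_seed(seed, {
    trees <- vector("list", ntree)
    inbag <- vector("list", ntree)
    for (t in seq_len(ntree)) {
      rows <- sample.int(n, m)
      inbag[[t]] <- rows
      trees[[t]] <- grow_tree(pred, y, rows, mtry = mtry, alpha = alpha,
                              min_node = min_node, minbucket = minbucket)
    }
    structure(list(trees = trees, inbag = inbag, pred = pred, y = y, n = n,
                   hyper = list(ntree = ntree, fraction = fraction,
                                mtry = mtry, alpha = alpha,
                                min_node = min_node, minbucket = minbucket,
                                seed = seed)),
              class = "rsf_forest")
  })
}

#' @export
print.rsf_forest <- function(x, ...) {
  sizes <- vapply(x$trees, function(t) sum(is.na(t$var)), 0L)
  cat(sprintf("<rsf_forest> %d conditional-inference trees on %d rows\n",
              length(x$trees), x$n))
  cat(sprintf("  subsample %.3g, mtry %d, alpha %.3g, min_node %d; mean leaves/tree %.1f\n",
              x$hyper$fraction, x$hyper$mtry, x$hyper$alpha, x$hyper$min_node,
              mean(sizes)))
  invisible(x)
}

#' Predict selection propensity from a forest
#'
#' Mean over trees of the leaf used-fractions; with `oob = TRUE` (training
#' rows only) each row is averaged only over trees whose subsample excluded
#' it.
#'
#' @param object an `rsf_forest`.
#' @param newdata data.frame of predictors; `NULL` for the training rows.
#' @param oob average only out-of-bag trees per row (requires
#'   `newdata = NULL`).
#' @param ... unused.
#' @return numeric vector of propensities in `[0, 1]` (`NaN` for a row that
#'   is in-bag in every tree under `oob = TRUE`).
#' @export
predict.rsf_forest <- function(object, newdata = NULL, oob = FALSE, ...) {
  if (oob && !is.null(newdata)) stopf("oob predictions apply to the training rows")
  pred <- if (is.null(newdata)) object$pred else {
    nd <- as.data.frame(newdata)[object$pred$names]
    for (v in object$pred$names[object$pred$is_fac]) {
      lv <- object$pred$cat_levels[[object$pred$cat_idx[v]]]
      conv <- factor(nd[[v]], levels = lv)
      bad <- is.na(conv) & !is.na(nd[[v]])
      if (any(bad)) {
        warnf("unseen %s level(s) %s routed by majority-direction rule", v,
              paste(unique(as.character(nd[[v]])[bad]), collapse = ", "))
      }
      nd[[v]] <- conv
    }
    split_predictors(nd)
  }
  n <- if (is.null(newdata)) object$n else nrow(newdata)
  rows <- seq_len(n)
  acc <- numeric(n)
  cnt <- numeric(n)
  for (t in seq_along(object$trees)) {
    use <- if (oob) setdiff(rows, object$inbag[[t]]) else rows
    if (!length(use)) next
    acc[use] <- acc[use] + suppressWarnings(route_tree(object$trees[[t]], pred, use))
    cnt[use] <- cnt[use] + 1
  }
  acc / cnt
}

#' Out-of-bag permutation importance
#'
#' For every predictor: the mean increase, over trees (and `n_reps` random
#' permutations), of each tree's out-of-bag prediction error when that
#' predictor's values are scrambled among the tree's OOB rows --
#' information destroyed by permutation, including information expressed only
#' through interactions. Error is misclassification at 0.5 by default, or
#' the Brier score.
#'
#' @param forest an `rsf_forest`.
#' @param n_reps permutations per tree.
#' @param metric `"misclass"` or `"brier"`.
#' @param seed integer seed for the permutations.
#' @return data.frame of class `rsf_importance`, sorted descending:
#'   `variable`, `importance`, `se` (over trees).
#' @export
permutation_importance <- function(forest, n_reps = 1L,
                                   metric = c("misclass", "brier"),
                                   seed = 1L) {
  metric <- match.arg(metric)
  err <- function(p, y) {
    if (metric == "misclass") mean((p > 0.5) != y) else mean((p - y)^2)
  }
  pred <- forest$pred
  y <- forest$y
  p_vars <- pred$names
  ntree <- length(forest$trees)
  with_seed(seed, {
    delta <- array(NA_real_, c(ntree, length(p_vars)))
    for (t in seq_len(ntree)) {
      oob <- setdiff(seq_len(forest$n), forest$inbag[[t]])
      if (length(oob) < 2L) next
      base <- err(route_tree(forest$trees[[t]], pred, oob), y[oob])
      used_vars <- unique(forest$trees[[t]]$var)
      used_vars <- used_vars[!is.na(used_vars)]
      for (v in seq_along(p_vars)) {
        if (!(v %in% used_vars)) { delta[t, v] <- 0; next }
        dd <- 0
        for (r in seq_len(n_reps)) {
          perm <- sample(oob)
          pp <- permuted_pred(pred, v, oob, perm)
          dd <- dd + err(route_tree(forest$trees[[t]], pp, oob), y[oob]) - base
        }
        delta[t, v] <- dd / n_reps
      }
    }
    imp <- colMeans(delta, na.rm = TRUE)
    se <- apply(delta, 2, function(z) stats::sd(z, na.rm = TRUE) / sqrt(sum(!is.na(z))))
    out <- data.frame(variable = p_vars, importance = imp, se = se)
    out <- out[order(-out$importance), ]
    rownames(out) <- NULL
    class(out) <- c("rsf_importance", "data.frame")
    out
  })
}

# predictor container with variable v's values replaced, at rows `at`, by
# the values at rows `from` (a permutation of `at`)
permuted_pred <- function(pred, v, at, from) {
  if (pred$is_fac[v]) {
    ci <- pred$cat_idx[v]
    pred$cat[[ci]][at] <- pred$cat[[ci]][from]
  } else {
    cj <- pred$cont_idx[v]
    pred$cont[at, cj] <- pred$cont[from, cj]
  }
  pred
}

#' Fit the forest RSF to a use-availability design
#'
#' Convenience wrapper selecting the retained continuous covariates plus the
#' vegetation class from an `rsf_design` and calling [fit_forest()].
#'
#' @param design an `rsf_design` from [build_design()].
#' @param predictors predictor names; default: the design's retained
#'   continuous covariates plus `veg`.
#' @param ... passed to [fit_forest()].
#' @export
fit_rsf_forest <- function(design, predictors = NULL, ...) {
  dat <- design$data
  if (is.null(predictors)) {
    predictors <- c(design$retained, if ("veg" %in% names(dat)) "veg")
  }
  fit_forest(dat[predictors], dat$label, ...)
}
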