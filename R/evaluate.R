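#' Area under the ROC curve
#'
#' AUC computed as the Mann-Whitney probability that a random positive
#' (used) score exceeds a random negative (available) score, with ties
#' counted one half -- via midranks, so it is exact including ties.
#'
#' @param scores numeric scores (higher = more likely used).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (any(!labels %in% c(0, 1))) stopf("labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  if (any(!is.finite(scores))) stopf("scores must be finite")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong test for two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two score vectors over the same
#' labelled observations. Per-observation placement values are computed for
#' each model (for a positive: the fraction of negatives it outscores, ties
#' half; for a negative: the fraction of positives scoring below it); the
#' 2 x 2 covariance of the paired AUCs follows from the placement
#' covariances, and `D = (AUC_A - AUC_B) / sqrt(var_A + var_B - 2 cov)` is
#' referred to the standard normal (two-sided).
#'
#' @param scores_a,scores_b score vectors from the two models, over the same
#'   observations.
#' @param labels shared 0/1 labels.
#' @return list: `auc_a`, `auc_b`, `D` (z statistic), `p` (two-sided),
#'   `var_diff`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    stopf("scores and labels must share length")
  }
  pos <- labels == 1; neg <- labels == 0
  n1 <- sum(pos); n0 <- sum(neg)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  placements <- function(s) {
    # midrank formulation of the placement values (O(n log n)):
    # V10_i = fraction of negatives outscored by positive i (ties half),
    # V01_j analogous for negatives; avoids the n1 x n0 comparison matrix.
    r_all <- rank(s, ties.method = "average")
    r_pos <- rank(s[pos], ties.method = "average")
    r_neg <- rank(s[neg], ties.method = "average")
    v10 <- (r_all[pos] - r_pos) / n0
    v01 <- 1 - (r_all[neg] - r_neg) / n1
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  # note v01 stored as 1 - colMeans so that cov signs line up with AUC
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d_auc <- pa$auc - pb$auc
  if (v <= 0) {
    if (abs(d_auc) < 1e-12) return(list(auc_a = pa$auc, auc_b = pb$auc,
                                        D = 0, p = 1, var_diff = v))
    stopf("degenerate scores: zero variance of the AUC difference")
  }
  D <- d_auc / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, D = D, p = 2 * stats::pnorm(-abs(D)),
       var_diff = v)
}

#' Leave-one-individual-out folds
#'
#' One fold per individual, containing all of that individual's rows (its
#' used fixes plus its allocated share of available points), treating the
#' animal -- not the fix -- as the independent validation unit. Individuals
#' with no used rows are excluded with a warning. Folds partition the rows.
#'
#' @param data design data.frame with columns `individual_id` and `label`.
#' @return named list of integer row-index vectors, one per individual.
#' @export
loio_folds <- function(data) {
  ids <- unique(data$individual_id)
  used_counts <- table(data$individual_id[data$label == 1])
  empty <- setdiff(ids, names(used_counts)[used_counts > 0])
  if (length(empty)) {
    warnf("excluding individual(s) with no used rows: %s",
          paste(empty, collapse = ", "))
    ids <- setdiff(ids, empty)
  }
  if (length(ids) < 2L) stopf("need at least 2 individuals with used rows")
  folds <- lapply(ids, function(id) which(data$individual_id == id))
  stats::setNames(folds, ids)
}

#' Leave-one-individual-out cross-validation of two RSF frameworks
#'
#' For each fold, both models are refitted on the remaining individuals and
#' scored on the held-out rows; all out-of-fold scores are pooled, the AUC of
#' each framework computed, and the two correlated AUCs compared with the
#' DeLong test. Vegetation classes absent from a fold's training data are
#' collapsed to the reference class for scoring (with a warning).
#'
#' @param fitter_a,fitter_b functions `(data, seed) -> model`, where the
#'   model is accepted by `predict(model, newdata)` (an `rsf_glmm` or
#'   `rsf_forest`); they must be deterministic given `seed`.
#' @param data design data.frame (`label`, `individual_id`, covariates).
#' @param folds from [loio_folds()]; default computes them.
#' @param seed base seed; each fold's fitters receive a deterministic
#'   sub-seed.
#' @param progress print a dot per fold.
#' @return object of class `cv_comparison`: `folds`, pooled `scores_a`,
#'   `scores_b`, `labels`, `auc_a`, `auc_b`, `D`, `p`, and the per-fold AUC
#'   table `fold_auc`.
#' @export
cross_validate <- function(fitter_a, fitter_b, data, folds = NULL, seed = 1L,
                           progress = FALSE) {
  if (is.null(folds)) folds <- loio_folds(data)
  n <- nrow(data)
  sa <- rep(NA_real_, n); sb <- rep(NA_real_, n)
  fold_auc <- data.frame(fold = names(folds), n = NA_integer_,
                         auc_a = NA_real_, auc_b = NA_real_)
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- data[-test, , drop = FALSE]
    heldout <- data[test, , drop = FALSE]
    if (is.factor(train$veg)) {
      seen <- unique(as.character(train$veg))
      missing_lv <- setdiff(levels(train$veg), seen)
      if (length(missing_lv)) {
        warnf("fold %s: vegetation class(es) %s absent from training; collapsed to reference",
              names(folds)[f], paste(missing_lv, collapse = ", "))
        ref <- levels(train$veg)[1]
        relvl <- function(v) {
          v <- as.character(v)
          v[v %in% missing_lv] <- ref
          factor(v, levels = setdiff(levels(data$veg), missing_lv))
        }
        train$veg <- relvl(train$veg)
        heldout$veg <- relvl(heldout$veg)
      }
    }
    ma <- fitter_a(train, sub_seed(seed, f))
    mb <- fitter_b(train, sub_seed(seed, 1000L + f))
    sa[test] <- model_predict(ma, heldout, "response")
    sb[test] <- model_predict(mb, heldout, "response")
    yl <- heldout$label
    fold_auc$n[f] <- length(test)
    if (length(unique(yl)) == 2L) {
      fold_auc$auc_a[f] <- roc_auc(sa[test], yl)
      fold_auc$auc_b[f] <- roc_auc(sb[test], yl)
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  keep <- !is.na(sa)
  dl <- delong_test(sa[keep], sb[keep], data$label[keep])
  structure(list(folds = folds, scores_a = sa[keep], scores_b = sb[keep],
                 labels = data$label[keep], auc_a = dl$auc_a,
                 auc_b = dl$auc_b, D = dl$D, p = dl$p, fold_auc = fold_auc),
            class = "cv_comparison")
}

#' @export
print.cv_comparison <- function(x, ...) {
  cat(sprintf("<cv_comparison> %d leave-one-individual-out folds, %d pooled scores\n",
              length(x$folds), length(x$labels)))
  cat(sprintf("  AUC A = %.3f, AUC B = %.3f; DeLong D = %.3f, p = %.3g\n",
              x$auc_a, x$auc_b, x$D, x$p))
  invisible(x)
}
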