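test_that("IRLS logistic matches closed forms and the glm oracle", {
  # intercept-only MLE is the empirical log odds
  set.seed(1)
  y <- stats::rbinom(400, 1, 0.3)
  f <- fit_logistic(matrix(1, 400, 1), y)
  expect_equal(unname(f$coef), log(mean(y) / (1 - mean(y))), tolerance = 1e-8)

  # 2x2 table: coefficient is the log odds ratio
  X <- cbind(i = 1, B = rep(c(0, 1), each = 40))
  y2 <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  f2 <- fit_logistic(X, y2)
  expect_equal(unname(f2$coef["B"]), log((10 * 10) / (30 * 30)), tolerance = 1e-8)

  # ten random fixtures against the independent reference fit
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 300
    Xr <- cbind(1, matrix(stats::rnorm(n * 3), n))
    colnames(Xr) <- c("int", "a", "b", "c")
    yr <- stats::rbinom(n, 1, stats::plogis(Xr %*% c(-0.2, 0.7, -0.4, 0.1)))
    mine <- fit_logistic(Xr, yr)
    ref <- stats::glm.fit(Xr, yr, family = stats::binomial())
    expect_equal(unname(mine$coef), unname(ref$coefficients), tolerance = 1e-6)
    expect_equal(mine$loglik, -ref$deviance / 2, tolerance = 1e-8)
  }
})

test_that("IRLS flags separation and names aliased columns", {
  x <- c(-(5:1), 1:5)
  X <- cbind(int = 1, x = x)
  expect_warning(fs <- fit_logistic(X, as.integer(x > 0)), "separation")
  expect_true(fs$separation)

  Xa <- cbind(int = 1, a = x, twice_a = 2 * x)
  expect_error(fit_logistic(Xa, as.integer(x > 0)), "twice_a")
})

test_that("AICc follows its definition and limits", {
  expect_equal(aicc(-100, 3, 1000), 206 + 2 * 3 * 4 / 996)
  expect_lt(abs(aicc(-50, 5, 1e8) - (-2 * -50 + 2 * 5)), 1e-3)  # AIC limit
  expect_equal(aicc(-70, 0, 50), 140)
  expect_error(aicc(-10, 5, 6), "n must exceed")
})

test_that("mixed fit recovers the random-intercept SD", {
  sim <- function(sigma_b, seed, groups = 50L, per = 200L) {
    set.seed(seed)
    g <- rep(seq_len(groups), each = per)
    b <- stats::rnorm(groups, 0, sigma_b)
    X <- cbind(1, stats::rnorm(groups * per))
    colnames(X) <- c("int", "x")
    y <- stats::rbinom(groups * per, 1, stats::plogis(0.3 + 0.8 * X[, 2] + b[g]))
    fit_mixed_logistic(X, y, g)
  }
  # truth sigma_b = 1: estimates concentrate around 1
  hits <- vapply(1:5, function(s) {
    est <- sim(1, seed = s)$sigma_b
    est >= 0.7 && est <= 1.3
  }, TRUE)
  expect_gte(mean(hits), 0.8)

  # truth sigma_b = 0: boundary estimates
  est0 <- vapply(1:5, function(s) sim(0, seed = 50 + s, groups = 50L, per = 100L)$sigma_b, 0)
  expect_gte(mean(est0 < 0.1), 0.8)
})

test_that("mixed fit with shuffled groups matches the fixed-effects fit", {
  set.seed(9)
  n <- 2000
  X <- cbind(int = 1, x = stats::rnorm(n))
  y <- stats::rbinom(n, 1, stats::plogis(0.2 + 0.6 * X[, 2]))
  g <- sample(rep(1:20, each = n / 20))  # no group structure
  fm <- fit_mixed_logistic(X, y, g)
  ff <- fit_logistic(X, y)
  expect_true(all(abs(fm$coef - ff$coef) < 2 * ff$se))
})

test_that("single group degenerates to the fixed-effects fit, flagged", {
  set.seed(2)
  X <- cbind(int = 1, x = stats::rnorm(200))
  y <- stats::rbinom(200, 1, stats::plogis(X[, 2]))
  expect_warning(fm <- fit_mixed_logistic(X, y, rep(1, 200)), "non-identifiable")
  ff <- fit_logistic(X, y)
  expect_equal(fm$coef, ff$coef)
  expect_true(is.na(fm$sigma_b))
  expect_true(fm$boundary)
})

test_that("adding a term never decreases the maximized log-likelihood", {
  des <- small_design()
  f1 <- fit_rsf_glmm(des, c("elev"))
  f2 <- fit_rsf_glmm(des, c("elev", "slope"))
  f3 <- fit_rsf_glmm(des, c("elev", "slope"), list(c("slope", "elev")))
  expect_gte(f2$loglik, f1$loglik - 1e-4)
  expect_gte(f3$loglik, f2$loglik - 1e-4)
})

test_that("all_subsets enumerates hierarchical models only", {
  des <- small_design()
  ms <- all_subsets(des, c("elev", "slope"))
  expect_equal(nrow(ms$table), 4)  # 2^2 subsets incl. intercept-only
  expect_equal(ms$table$delta[1], 0)
  expect_equal(sum(ms$table$weight), 1)
  expect_false(is.unsorted(ms$table$AICc))

  ms2 <- all_subsets(des, c("elev", "slope", "dist_water"),
                     list(c("elev", "slope")))
  # 2^3 = 8 main subsets, plus the interaction admitted in the two subsets
  # containing both parents ({elev,slope} and {elev,slope,dist_water}) -> 10
  expect_equal(nrow(ms2$table), 10)

  expect_error(all_subsets(des, c("elev"), list(c("elev", "slope"))),
               "parent")
  expect_error(all_subsets(des, paste0("v", 1:21)), "20 candidate")
})

test_that("model selection recovers the generating term set", {
  recover_once <- function(seed) {
    set.seed(seed)
    n <- 5000
    d <- data.frame(A = stats::rnorm(n), B = stats::rnorm(n),
                    C = stats::rnorm(n),
                    individual_id = sample(rep(1:25, each = n / 25)))
    b <- stats::rnorm(25, 0, 0.3)
    d$label <- stats::rbinom(n, 1, stats::plogis(0.6 * d$A - 0.5 * d$B +
                                                   b[d$individual_id]))
    ms <- all_subsets(d, c("A", "B", "C"))
    ms$table$model[1]
  }
  top <- vapply(1:10, recover_once, "")
  expect_gte(mean(top == "A + B"), 0.8)
})

test_that("uninformative-parameter screen prefers the nested model", {
  # synthetic model table: top model M, M + noise at delta 1.2
  fake <- structure(list(
    table = data.frame(model = c("A + B", "A + B + C", "A"),
                       k = c(3, 4, 2), loglik = c(-100, -100.4, -110),
                       AICc = c(206, 207.2, 224),
                       delta = c(0, 1.2, 18)),
    fits = list("fitAB", "fitABC", "fitA"),
    term_sets = list(list(mains = c("A", "B"), ints = list()),
                     list(mains = c("A", "B", "C"), ints = list()),
                     list(mains = "A", ints = list()))),
    class = "rsf_model_table")
  pr <- prune_uninformative(fake)
  expect_identical(pr$fit, "fitAB")
  expect_true(any(grepl("C", pr$pruned$term)))

  # single model in the window: unchanged
  fake1 <- fake
  fake1$table$AICc <- c(206, 215, 224)
  fake1$table$delta <- c(0, 9, 18)
  pr1 <- prune_uninformative(fake1)
  expect_identical(pr1$fit, "fitAB")
  expect_equal(nrow(pr1$pruned), 0)

  # two non-nested models in the window: no pruning, best AICc wins
  fake2 <- structure(list(
    table = data.frame(model = c("A", "B"), k = c(2, 2),
                       loglik = c(-100, -100.5), AICc = c(204, 205),
                       delta = c(0, 1)),
    fits = list("fitA", "fitB"),
    term_sets = list(list(mains = "A", ints = list()),
                     list(mains = "B", ints = list()))),
    class = "rsf_model_table")
  pr2 <- prune_uninformative(fake2)
  expect_identical(pr2$fit, "fitA")
  expect_equal(nrow(pr2$pruned), 0)
})

test_that("standardized coefficients are scale invariant", {
  des <- small_design()
  d <- des$data
  f_m <- fit_rsf_glmm(d, c("dist_water"))
  d_km <- d
  d_km$dist_water <- d_km$dist_water / 1000
  f_km <- fit_rsf_glmm(d_km, c("dist_water"))
  s_m <- standardized_coefficients(f_m, d)
  s_km <- standardized_coefficients(f_km, d_km)
  expect_equal(s_m$estimate_std, s_km$estimate_std, tolerance = 1e-6)
  expect_equal(s_m$estimate_raw, s_km$estimate_raw * 1e-3, tolerance = 1e-9)

  # a covariate pre-scaled to SD 1 has standardized == raw
  d$z <- as.numeric(scale(d$elev))
  fz <- fit_rsf_glmm(d, c("z"))
  sz <- standardized_coefficients(fz, d)
  expect_equal(sz$estimate_std, sz$estimate_raw, tolerance = 1e-6)
})
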