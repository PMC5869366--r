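test_that("terrain derivation: constant field has zero slope, planar ramp exact", {
  flat <- matrix(1234, 32, 32)
  ta <- rsfcompare:::terrain_attributes(flat, 30)
  expect_true(all(ta$slope == 0))

  # plane rising eastward at 45 degrees: dz/dx = 1 everywhere
  ramp <- outer(rep(1, 32), (1:32) * 30)
  ta <- rsfcompare:::terrain_attributes(ramp, 30)
  expect_equal(max(abs(ta$slope - 45)), 0, tolerance = 1e-10)
  # downhill faces west (3*pi/2 from north)
  expect_equal(unique(as.vector(round(ta$aspect, 10))), round(3 * pi / 2, 10))

  # plane rising northward: row index decreasing = y increasing
  ramp_n <- outer(rev(seq_len(32)) * 30, rep(1, 32))
  ta <- rsfcompare:::terrain_attributes(ramp_n, 30)
  expect_equal(max(abs(ta$slope - 45)), 0, tolerance = 1e-10)
  expect_equal(unique(as.vector(round(ta$aspect, 10))), round(pi, 10))  # faces south
})

test_that("gen_landscape honors invariants and is deterministic", {
  cfg <- landscape_config(n_rows = 32L, n_cols = 48L, cell = 100, n_water = 3L)
  ls1 <- gen_landscape(cfg, seed = 41L)
  ls2 <- gen_landscape(cfg, seed = 41L)
  expect_identical(ls1, ls2)
  expect_false(identical(ls1, gen_landscape(cfg, seed = 42L)))

  expect_true(all(ls1$layers$slope >= 0))
  expect_true(all(ls1$layers$dist_water >= 0))
  expect_true(all(ls1$layers$aspect >= 0 & ls1$layers$aspect < 2 * pi))
  codes <- sort(unique(as.vector(ls1$layers$veg)))
  expect_identical(codes, seq_along(codes))  # contiguous, includes reference
  expect_identical(dim(ls1$layers$elev), c(32L, 48L))

  expect_error(landscape_config(n_rows = 8L), "16")
  expect_error(landscape_config(cell = 0), "positive")
})

test_that("default landscape emulates the reported covariate magnitudes", {
  ls <- gen_landscape(seed = 1L)
  e <- ls$layers$elev
  expect_gt(mean(e), 1900); expect_lt(mean(e), 2300)
  expect_lt(min(e), 1750); expect_gt(max(e), 2400)
  expect_true(all(e >= 1650 & e <= 2900))
  expect_gt(max(ls$layers$dist_water), 2000)  # kilometers-scale water gradient
})

test_that("true_linear_predictor follows its closed forms", {
  zero <- truth_surface()
  covs <- data.frame(elev = 2000, slope = 10, dist_water = 500)
  expect_equal(true_linear_predictor(zero, covs), 0)

  hump <- truth_surface(terms = list(term_hump("elev", 2, 2075, 150)))
  ee <- seq(1650, 2900, by = 5)
  lp <- true_linear_predictor(hump, data.frame(elev = ee))
  expect_equal(ee[which.max(lp)], 2075)
  expect_equal(max(lp), 2)

  inter <- truth_surface(interactions = list(
    interaction_term(c("slope", "elev"), coef = 0.5)))
  expect_equal(true_linear_predictor(inter, data.frame(slope = 2, elev = 3)), 3)

  expect_error(true_linear_predictor(hump, data.frame(slope = 1)),
               "missing covariate")
})

test_that("threshold term plateaus below the breakpoint and decays beyond", {
  th <- truth_surface(terms = list(term_threshold("dist_water", 2, 1000, 150)))
  lp <- true_linear_predictor(th, data.frame(dist_water = c(0, 500, 1000, 2000, 5000)))
  expect_gt(lp[1], 1.99)
  expect_equal(lp[3], 1)           # half effect exactly at the breakpoint
  expect_lt(lp[5], 0.01)
  expect_true(all(diff(lp) < 0))
})

test_that("telemetry sampling matches known multinomial weights", {
  # 3-cell toy polygon with selection weights 1:2:7
  n <- 16L
  elev <- matrix(0, n, n)
  elev[1, 1:3] <- log(c(1, 2, 7))
  ls <- landscape_stack(list(elev = elev, slope = matrix(0, n, n),
                             aspect = matrix(0, n, n),
                             dist_water = matrix(0, n, n),
                             veg = matrix(1L, n, n)), cell = 10)
  mask <- matrix(FALSE, n, n); mask[1, 1:3] <- TRUE
  poly <- range_polygon(mask, ls)
  truth <- truth_surface(terms = list(term_linear("elev", 1)))
  tel <- gen_telemetry(ls, truth, n_individuals = 1L,
                       fixes_per_individual = 50000L, polygon = poly,
                       seed = 9L)
  cells <- point_to_cell(ls, tel$x, tel$y)
  freq <- tabulate(cells$col, nbins = 3) / nrow(tel)
  p <- c(0.1, 0.2, 0.7)
  se <- sqrt(p * (1 - p) / 50000)
  expect_true(all(abs(freq - p) <= 3 * se))
})

test_that("all-zero truth yields uniform usage over the polygon", {
  n <- 16L
  ls <- constant_landscape(n = n, cell = 10)
  mask <- matrix(FALSE, n, n); mask[1:2, 1:5] <- TRUE
  poly <- range_polygon(mask, ls)
  tel <- gen_telemetry(ls, truth_surface(), n_individuals = 1L,
                       fixes_per_individual = 10000L, polygon = poly, seed = 2L)
  cells <- point_to_cell(ls, tel$x, tel$y)
  idx <- (cells$col - 1L) * n + cells$row
  counts <- table(factor(idx, levels = which(mask)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("positive elevation effect tilts usage uphill", {
  ls <- small_landscape()
  truth <- truth_surface(terms = list(term_linear("elev", 3, 2075, 250)))
  tel <- gen_telemetry(ls, truth, n_individuals = 2L,
                       fixes_per_individual = 500L, seed = 4L)
  cells <- point_to_cell(ls, tel$x, tel$y)
  used_elev <- ls$layers$elev[(cells$col - 1L) * ls$n_rows + cells$row]
  expect_gt(mean(used_elev), mean(ls$layers$elev))
})

test_that("per-individual streams are stable when individuals are added", {
  ls <- small_landscape()
  t5 <- gen_telemetry(ls, default_truth(), n_individuals = 5L,
                      fixes_per_individual = 20L, seed = 3L)
  t7 <- gen_telemetry(ls, default_truth(), n_individuals = 7L,
                      fixes_per_individual = 20L, seed = 3L)
  expect_equal(t5, t7[seq_len(nrow(t5)), ], ignore_attr = TRUE)
  t5b <- gen_telemetry(ls, default_truth(), n_individuals = 5L,
                       fixes_per_individual = 20L, seed = 3L)
  expect_identical(t5, t5b)
})

test_that("individual intercepts add between-individual predictor variance", {
  ls <- small_landscape()
  per_ind_mean_lp <- function(sigma_b, seed) {
    truth <- default_truth(sigma_b = sigma_b)
    tel <- gen_telemetry(ls, truth, n_individuals = 50L,
                         fixes_per_individual = 40L, seed = seed)
    b <- attr(tel, "b_i")
    cells <- point_to_cell(ls, tel$x, tel$y)
    covs <- rsfcompare:::cell_covariates(ls, (cells$col - 1L) * ls$n_rows + cells$row)
    lp <- true_linear_predictor(truth, covs, b_i = b[tel$individual_id])
    tapply(lp, tel$individual_id, mean)
  }
  v2 <- stats::var(per_ind_mean_lp(2, seed = 6L))
  v0 <- stats::var(per_ind_mean_lp(0, seed = 6L))
  expect_gt(v2, v0 + 1)  # sigma_b^2 = 4 dwarfs the sampling variance
})

test_that("markov movement mode stays in the polygon and is deterministic", {
  ls <- small_landscape()
  mask <- matrix(FALSE, ls$n_rows, ls$n_cols); mask[10:40, 10:40] <- TRUE
  poly <- range_polygon(mask, ls)
  t1 <- gen_telemetry(ls, default_truth(), n_individuals = 2L,
                      fixes_per_individual = 50L, polygon = poly,
                      mode = "markov", step_sd = 300, seed = 8L)
  t2 <- gen_telemetry(ls, default_truth(), n_individuals = 2L,
                      fixes_per_individual = 50L, polygon = poly,
                      mode = "markov", step_sd = 300, seed = 8L)
  expect_identical(t1, t2)
  cells <- point_to_cell(ls, t1$x, t1$y)
  expect_true(all(mask[cbind(cells$row, cells$col)]))
  # consecutive steps are spatially concentrated relative to iid draws
  iid <- gen_telemetry(ls, default_truth(), n_individuals = 2L,
                       fixes_per_individual = 50L, polygon = poly, seed = 8L)
  step_len <- function(tt) {
    d <- split(tt, tt$individual_id)
    mean(unlist(lapply(d, function(z) sqrt(diff(z$x)^2 + diff(z$y)^2))))
  }
  expect_lt(step_len(t1), step_len(iid))
})

test_that("telemetry CSV round-trips with the fixed header", {
  ls <- small_landscape()
  tel <- gen_telemetry(ls, default_truth(), n_individuals = 2L,
                       fixes_per_individual = 10L, seed = 1L)
  p <- withr::local_tempfile(fileext = ".csv")
  write_telemetry(tel, p)
  back <- read_telemetry(p)
  expect_identical(names(back)[1:5], c("individual_id", "x", "y", "season", "label"))
  expect_equal(back$x, tel$x)
  expect_error(write_telemetry(tel[, -1], p), "lacks column")
})

test_that("ascii grid and landscape IO round-trip", {
  ls <- small_landscape()
  dir <- withr::local_tempdir()
  write_landscape(ls, dir)
  back <- read_landscape(dir)
  expect_equal(back$layers$elev, ls$layers$elev, tolerance = 1e-6)
  expect_identical(back$layers$veg, ls$layers$veg)
  expect_identical(back$veg_levels, ls$veg_levels)
  expect_equal(back$cell, ls$cell)
  g <- read_ascii_grid(file.path(dir, "slope.asc"))
  expect_equal(g$values, ls$layers$slope, tolerance = 1e-6)
})
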