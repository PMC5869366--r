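test_that("kernel density peaks at the data and integrates to one", {
  ls <- constant_landscape(n = 32L, cell = 10)
  # single point (plus a far twin to satisfy n >= 2): max density at its cell
  pts <- data.frame(x = c(155, 155), y = c(155, 155))
  d <- kde2d_grid(pts, ls, bandwidth = 20)
  pc <- point_to_cell(ls, 155, 155)
  expect_equal(which(d == max(d), arr.ind = TRUE)[1, ],
               c(row = pc$row, col = pc$col))
  expect_true(all(d >= 0))
  expect_equal(sum(d) * 10^2, 1, tolerance = 0.01)

  # two well-separated identical clusters: equal modal densities
  pts2 <- data.frame(x = c(80, 80, 240, 240), y = c(80, 80, 240, 240))
  d2 <- kde2d_grid(pts2, ls, bandwidth = 15)
  m1 <- d2[point_to_cell(ls, 80, 80)$row, point_to_cell(ls, 80, 80)$col]
  m2 <- d2[point_to_cell(ls, 240, 240)$row, point_to_cell(ls, 240, 240)$col]
  expect_equal(m1, m2, tolerance = 1e-6)
  expect_error(kde2d_grid(pts, ls, bandwidth = 0), "positive")
  expect_error(kde2d_grid(pts[1, ], ls), "at least 2")
})

test_that("Silverman-rule density approximates the standard normal", {
  set.seed(1)
  pts <- data.frame(x = stats::rnorm(1000), y = stats::rnorm(1000))
  grid <- landscape_stack(list(elev = matrix(0, 64, 64)), cell = 0.25,
                          x0 = -8, y0 = -8)
  d <- kde2d_grid(pts, grid)
  pc <- point_to_cell(grid, 0, 0)
  expect_equal(d[pc$row, pc$col], 1 / (2 * pi), tolerance = 0.2)
})

test_that("isopleth accumulates the smallest mass-covering cell set", {
  ls <- constant_landscape(n = 16L, cell = 10)
  # uniform density on 100 cells: the 99.9% isopleth needs all 100
  dens <- matrix(0, 16, 16); dens[1:10, 1:10] <- 1
  poly <- isopleth(dens, ls, level = 0.999)
  expect_equal(sum(poly$mask), 100)
  # level 1 keeps exactly the positive cells
  expect_equal(sum(isopleth(dens, ls, level = 1)$mask), 100)

  # nestedness and tight mass bound on a unimodal density
  set.seed(3)
  pts <- data.frame(x = stats::runif(200, 40, 120), y = stats::runif(200, 40, 120))
  dens <- kde2d_grid(pts, ls, bandwidth = 15)
  p50 <- isopleth(dens, ls, level = 0.5)
  p999 <- isopleth(dens, ls, level = 0.999)
  expect_true(all(p999$mask[p50$mask]))
  mass <- function(p) sum(dens[p$mask]) / sum(dens)
  expect_gte(mass(p999), 0.999)
  # removing the lowest-density retained cell breaks the bound
  inside <- which(p999$mask)
  drop <- inside[which.min(dens[inside])]
  m2 <- p999$mask; m2[drop] <- FALSE
  expect_lt(sum(dens[m2]) / sum(dens), 0.999)

  expect_error(isopleth(dens, ls, level = 0), "\\(0, 1\\]")
  expect_error(isopleth(dens * 0, ls), "all zero")
})

test_that("buffering dilates by Euclidean distance, clipped to the extent", {
  ls <- constant_landscape(n = 80L, cell = 30)
  mask <- matrix(FALSE, 80, 80); mask[40, 40] <- TRUE
  poly <- range_polygon(mask, ls)
  expect_identical(buffer_polygon(poly, 0), poly)

  buf <- buffer_polygon(poly, 1000)
  expect_true(all(buf$mask[poly$mask]))  # input contained
  # area of a 1 km disk on a 30 m grid, within 5%
  expect_equal(buf$area, pi * 1000^2, tolerance = 0.05)

  # agreement with a brute-force distance oracle
  rc <- as.matrix(expand.grid(seq_len(80), seq_len(80)))
  d <- sqrt(((rc[, 1] - 40) * 30)^2 + ((rc[, 2] - 40) * 30)^2)
  oracle <- matrix(d <= 1000 + 1e-9, 80, 80)
  expect_identical(buf$mask, oracle)

  # iterated buffering matches the single larger buffer up to one cell
  # diagonal of grid discretization slack
  b2 <- buffer_polygon(buffer_polygon(poly, 400), 600)
  slack <- 30 * sqrt(2)
  inner <- matrix(d <= 1000 - slack, 80, 80)
  outer_ <- matrix(d <= 1000 + slack, 80, 80)
  expect_true(all(b2$mask[inner]))
  expect_true(all(outer_[b2$mask]))
  expect_error(buffer_polygon(poly, -1), "non-negative")
})

test_that("available points are uniform within the polygon and seeded", {
  ls <- constant_landscape(n = 40L, cell = 10)
  one <- matrix(FALSE, 40, 40); one[5, 7] <- TRUE
  p1 <- sample_available(range_polygon(one, ls), 50, seed = 2L)
  cc <- point_to_cell(ls, p1$x, p1$y)
  expect_true(all(cc$row == 5L & cc$col == 7L))

  sq <- matrix(FALSE, 40, 40); sq[1:20, 1:20] <- TRUE
  pts <- sample_available(range_polygon(sq, ls), 100000, seed = 3L)
  qx <- pts$x > 100; qy <- pts$y > 300
  counts <- table(qx, qy)
  se <- sqrt(100000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 25000) <= 3 * se))
  expect_identical(pts, sample_available(range_polygon(sq, ls), 100000, seed = 3L))
})

test_that("covariate extraction applies the shifted aspect transform", {
  ls <- constant_landscape(n = 16L, cell = 10, aspect = 0)
  out <- extract_covariates(data.frame(x = 55, y = 55), ls)
  expect_equal(out$cos_aspect, 2)  # due north
  expect_equal(out$sin_aspect, 1)
  ls_s <- constant_landscape(n = 16L, cell = 10, aspect = pi)
  out_s <- extract_covariates(data.frame(x = 55, y = 55), ls_s)
  expect_equal(out_s$cos_aspect, 0)
  expect_s3_class(out$veg, "factor")
  expect_identical(as.character(out$veg), "sagebrush")

  # exact cell-center lookup
  ls2 <- small_landscape()
  r <- 10L; c <- 20L
  x <- ls2$x0 + (c - 0.5) * ls2$cell
  y <- ls2$y0 + (ls2$n_rows - r + 0.5) * ls2$cell
  out2 <- extract_covariates(data.frame(x = x, y = y), ls2)
  expect_equal(out2$elev, ls2$layers$elev[r, c])
  expect_equal(out2$dist_water, ls2$layers$dist_water[r, c])

  expect_error(extract_covariates(data.frame(x = -5, y = 55), ls),
               "outside the landscape extent")
})

test_that("collinearity thinning drops the worse member of offending pairs", {
  set.seed(2)
  A <- stats::rnorm(1000)
  X <- data.frame(A = A, B = A + stats::rnorm(1000, 0, 0.01),
                  C = stats::rnorm(1000))
  th <- thin_collinear(X)
  expect_length(th$dropped, 1)
  expect_true(th$dropped %in% c("A", "B"))
  expect_true("C" %in% th$retained)

  # two perfect copies: exactly one survives
  Y <- data.frame(a = A, b = A)
  expect_equal(length(thin_collinear(Y)$retained), 1)

  # independent columns all survive
  Z <- as.data.frame(matrix(stats::rnorm(3000), ncol = 3))
  expect_equal(length(thin_collinear(Z)$retained), 3)

  # idempotence on the retained set
  again <- thin_collinear(X[th$retained])
  expect_identical(again$retained, th$retained)
  expect_equal(nrow(again$log), 0)

  # constant column: warned, excluded from screen, retained
  W <- data.frame(a = A, b = A + stats::rnorm(1000, 0, 0.01), k = rep(1, 1000))
  expect_warning(thw <- thin_collinear(W), "constant")
  expect_true("k" %in% thw$retained)

  expect_error(thin_collinear(X[1, ]), "3 rows")
  expect_error(thin_collinear(X["A"]), "2 continuous")
})

test_that("assembled design is exactly 1:1 used:available per individual", {
  des <- small_design()
  d <- des$data
  expect_equal(sum(d$label == 1), sum(d$label == 0))
  tab <- table(d$individual_id, d$label)
  expect_true(all(tab[, "1"] == tab[, "0"]))
  expect_false(anyNA(d))
  # no retained continuous pair above the threshold
  cm <- abs(stats::cor(d[des$retained]))
  diag(cm) <- 0
  expect_lte(max(cm), 0.65)
  # one-hot veg sums to <= 1 per row by construction of the model matrix
  spec <- rsfcompare:::term_spec(d, c("elev", "veg"))
  X <- rsfcompare:::make_model_matrix(d, spec)
  veg_cols <- grep("^veg_", colnames(X))
  expect_true(all(rowSums(X[, veg_cols]) <= 1))
})
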