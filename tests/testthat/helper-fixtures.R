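# shared small fixtures, built once per test run

small_landscape <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- gen_landscape(landscape_config(n_rows = 64L, n_cols = 64L,
                                              cell = 100, n_water = 4L),
                             seed = 7L)
    }
    memo
  }
})

# a small but realistic design: 10 individuals x 60 fixes under the default
# truth on the small landscape
small_design <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      ls <- small_landscape()
      tel <- gen_telemetry(ls, default_truth(), n_individuals = 10L,
                           fixes_per_individual = 60L, seed = 3L)
      memo <<- build_design(tel, ls, buffer_m = 500, seed = 11L)
    }
    memo
  }
})

# landscape with hand-set layers on a uniform grid, for exact extraction tests
constant_landscape <- function(n = 16L, cell = 10, elev = 100, slope = 5,
                               aspect = 0, dist = 50, veg_code = 1L) {
  landscape_stack(list(elev = matrix(elev, n, n),
                       slope = matrix(slope, n, n),
                       aspect = matrix(aspect, n, n),
                       dist_water = matrix(dist, n, n),
                       veg = matrix(veg_code, n, n)),
                  cell = cell, veg_levels = c("sagebrush", "pinyon_juniper"))
}

expect_deterministic <- function(expr1, expr2) {
  expect_identical(expr1, expr2)
}
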