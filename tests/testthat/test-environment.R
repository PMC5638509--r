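test_that("synthetic fields span the thermal band and repel at borders", {
  spec <- grid_spec(50, 20)
  env <- synth_environment(spec, t_pref = c(16, 18), seed = 1,
                           mode = "gradient")
  interior <- env$sst[interior_mask(env)]
  expect_lt(min(interior), 16)
  expect_gt(max(interior), 18)
  # border frame is hotter than anything inside, so the taxis response
  # points inward there
  border <- env$sst[!interior_mask(env)]
  expect_true(all(border > max(interior)))
  # gyre currents carry both eastward and westward flow
  gyre <- synth_environment(spec, seed = 1, mode = "gyre")
  expect_lt(min(gyre$u), 0)
  expect_gt(max(gyre$u), 0)
  # uniform mode is the degenerate comfortable field
  uni <- synth_environment(spec, mode = "uniform")
  expect_true(all(uni$sst[interior_mask(uni)] == 17))
  expect_true(all(uni$u == 0) && all(uni$v == 0))
})

test_that("field synthesis is deterministic given the seed", {
  spec <- grid_spec(30, 12)
  e1 <- synth_environment(spec, seed = 99, mode = "gyre")
  e2 <- synth_environment(spec, seed = 99, mode = "gyre")
  expect_identical(e1, e2)
  e3 <- synth_environment(spec, seed = 100, mode = "gyre")
  expect_false(identical(e1$sst, e3$sst))
})

test_that("environment files round-trip in both formats", {
  env <- synth_environment(grid_spec(15, 8), seed = 3, mode = "gyre")
  json <- withr::local_tempfile(fileext = ".json")
  write_environment(env, json, format = "json")
  back <- read_environment(json, format = "json")
  expect_equal(back$sst, env$sst)
  expect_equal(back$u, env$u)
  expect_equal(back$v, env$v)
  expect_equal(back$spec, env$spec)
  pre <- file.path(withr::local_tempdir(), "env")
  write_environment(env, pre, format = "csv")
  back2 <- read_environment(pre, format = "csv")
  expect_equal(back2$sst, env$sst, tolerance = 1e-12)
  expect_equal(back2$u, env$u, tolerance = 1e-12)
})

test_that("malformed environment files are rejected", {
  env <- synth_environment(grid_spec(10, 6), seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  # shape mismatch: claim transposed dimensions
  obj <- jsonlite::read_json({
    write_environment(env, f); f
  }, simplifyVector = TRUE)
  obj$nx <- 6; obj$ny <- 10
  jsonlite::write_json(obj, f, digits = NA, auto_unbox = TRUE)
  expect_error(read_environment(f), "shape")
  # NaN in the interior
  env2 <- env
  env2$sst[5, 3] <- NaN
  write_environment(env2, f)
  expect_error(read_environment(f), "non-finite")
  # missing layer
  obj <- jsonlite::read_json({
    write_environment(env, f); f
  }, simplifyVector = TRUE)
  obj$u <- NULL
  jsonlite::write_json(obj, f, digits = NA, auto_unbox = TRUE)
  expect_error(read_environment(f), "layer")
})

test_that("grid construction rejects non-positive dimensions", {
  expect_error(grid_spec(0, 10), "positive")
  expect_error(grid_spec(10, -1), "positive")
})

test_that("current sampling uses the floor sector convention", {
  env <- flat_env(10, 5)
  env$u[3, 2] <- 0.25   # sector (2, 1) zero-based
  env$v[3, 2] <- -0.1
  expect_equal(sample_current(env, c(2.5, 1.5)), c(0.25, -0.1))
  expect_equal(sample_current(env, c(5.5, 3.5)), c(0, 0))
  # a position exactly on a sector boundary belongs to the floor sector
  expect_equal(sample_current(env, c(2.0, 1.0)), c(0.25, -0.1))
  expect_equal(sample_current(env, c(3.0, 1.5)), c(0, 0))
  # the domain's upper edge is clamped into the last sector
  env$u[10, 5] <- 9
  expect_equal(sample_current(env, c(10, 5))[1], 9)
  expect_error(sample_current(env, c(-0.1, 1)), "outside")
})

test_that("thermal discomfort r(T) matches its closed form", {
  expect_equal(temp_response(15, c(16, 18)), -1)
  expect_equal(temp_response(19, c(16, 18)), -1)
  expect_equal(temp_response(c(16, 17, 18), c(16, 18)), c(0, 0, 0))
  # never positive, continuous at the band edges
  temps <- seq(10, 24, by = 0.01)
  r <- temp_response(temps, c(16, 18))
  expect_true(all(r <= 0))
  expect_lt(abs(temp_response(16 - 1e-9, c(16, 18))), 1e-15)
  expect_lt(abs(temp_response(18 + 1e-9, c(16, 18))), 1e-15)
})

test_that("taxis response is zero on the comfort plateau and points down-gradient", {
  env <- flat_env(20, 10)
  expect_equal(temp_gradient_response(env, c(10, 5)), c(0, 0))
  # 1-D linear field T(x) = x: at T = 20 > T2 the response points toward
  # decreasing x (sign of -2 (T - T2) dT/dx)
  spec <- grid_spec(40, 8)
  env2 <- synth_environment(spec, mode = "uniform", border_band = 0)
  env2$sst <- matrix(seq_len(40) - 0.5, 40, 8)
  g <- temp_gradient_response(env2, c(20.5, 4))  # T about 20
  expect_lt(g[1], 0)
  expect_equal(g[2], 0)
  expect_equal(sqrt(sum(g^2)), 1)
  # below the band the response points toward increasing temperature
  g2 <- temp_gradient_response(env2, c(10.5, 4))  # T about 10 < T1
  expect_gt(g2[1], 0)
})

test_that("fish in the border band receive an inward-pointing response", {
  env <- synth_environment(grid_spec(30, 12), seed = 5, mode = "gradient")
  # left edge: response must have positive x-component
  g <- temp_gradient_response(env, c(0.5, 6))
  expect_gt(g[1], 0)
  g <- temp_gradient_response(env, c(29.5, 6))
  expect_lt(g[1], 0)
  g <- temp_gradient_response(env, c(15, 0.5))
  expect_gt(g[2], 0)
  g <- temp_gradient_response(env, c(15, 11.5))
  expect_lt(g[2], 0)
})
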