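test_that("zone radii and movement weights enforce their invariants", {
  expect_error(zone_radii(0.2, 0.1, 0.1), "radii")
  expect_error(zone_radii(0, 0.1, 0.1), "radii")
  expect_error(movement_weights(0.9, 0.2), "sum to 1")
  expect_error(movement_weights(-0.1, 1.1), "sum to 1")
  w <- movement_weights()
  expect_equal(w$alpha + w$beta, 1)
})

test_that("neighbor sets follow the zonal geometry", {
  radii <- zone_radii(0.02, 0.10, 0.10)
  # isolated fish: empty repulsion/attraction, orientation holds only itself
  pop <- make_pop(x = 5, y = 5)
  ns <- neighbor_sets(pop, 1, radii)
  expect_identical(ns$NR, integer(0))
  expect_identical(ns$NO, 1L)
  expect_identical(ns$NA_, integer(0))
  # two fish 0.05 apart: in each other's orientation zone; the attraction
  # annulus is empty because r_o = r_a
  pop <- make_pop(x = c(5, 5.05), y = c(5, 5))
  ns <- neighbor_sets(pop, 1, radii)
  expect_identical(ns$NO, c(1L, 2L))
  expect_identical(ns$NA_, integer(0))
  # widening r_a opens the attraction annulus
  ns <- neighbor_sets(make_pop(x = c(5, 5.15), y = c(5, 5)), 1,
                      zone_radii(0.02, 0.10, 0.20))
  expect_identical(ns$NA_, 2L)
  # eggs neither perceive nor are perceived
  pop <- make_pop(x = c(5, 5.05), y = c(5, 5), age = c(400L, 50L))
  ns <- neighbor_sets(pop, 1, radii)
  expect_identical(ns$NO, 1L)
})

test_that("accelerated neighbor search equals the all-pairs oracle", {
  radii <- zone_radii(0.02, 0.10, 0.15)
  set.seed(42)
  for (case in 1:12) {
    n <- 200
    # clustered configurations stress the cell boundaries
    x <- runif(n, 0, 4) + rep(runif(5, 0, 3), each = 40) * (case %% 2)
    y <- runif(n, 0, 2)
    eligible <- rep(TRUE, n)
    eligible[sample(n, 20)] <- FALSE
    for (k in sample(which(eligible), 8)) {
      fast <- mpaschool:::neighbor_sets_cpp(x, y, eligible, k,
                                            radii$r_r, radii$r_o, radii$r_a)
      slow <- brute_neighbor_sets(x, y, eligible, k,
                                  radii$r_r, radii$r_o, radii$r_a)
      expect_identical(fast$NR, slow$NR)
      expect_identical(fast$NO, slow$NO)
      expect_identical(fast$NA_, slow$NA_)
    }
  }
})

test_that("speed updates average over the orientation set", {
  radii <- zone_radii()
  # isolated fish keeps its speed (self-mean)
  pop <- make_pop(x = 5, y = 5, speed = 0.45)
  expect_equal(update_speed(pop, 1, radii), 0.45)
  # neighbors at 0.42 and 0.50 with self at 0.46: mean is 0.46
  pop <- make_pop(x = c(5, 5.05, 4.95), y = 5, speed = c(0.46, 0.42, 0.50))
  expect_equal(update_speed(pop, 1, radii), 0.46)
  # speed consensus is a fixed point
  pop <- make_pop(x = c(5, 5.03, 5.06), y = 5, speed = 0.44)
  expect_equal(update_speed(pop, 2, radii), 0.44)
})

test_that("social direction combines repulsion, alignment and attraction", {
  radii <- zone_radii()
  # isolated fish: direction is its own heading
  pop <- make_pop(x = 5, y = 5, heading = pi / 3)
  expect_equal(social_direction(pop, 1, radii), c(cos(pi / 3), sin(pi / 3)))
  # a repulsion neighbor due east with self heading north:
  # d = ((-1, 0) + (0, 1)) / 2
  pop <- make_pop(x = c(5, 5.01), y = 5, heading = c(pi / 2, pi / 2))
  expect_equal(social_direction(pop, 1, radii), c(-0.5, 0.5))
  # symmetric attraction neighbors cancel across the symmetry axis
  radii_wide <- zone_radii(0.02, 0.10, 0.30)
  pop <- make_pop(x = c(5, 5.2, 5.2), y = c(5, 5.15, 4.85), heading = 0)
  d <- social_direction(pop, 1, radii_wide)
  expect_equal(d[2], 0)
  expect_gt(d[1], 0)
})

test_that("headings stay unit-norm through the combined step", {
  env <- flat_env()
  w <- movement_weights()
  set.seed(7)
  pop <- make_pop(x = runif(20, 2, 18), y = runif(20, 2, 8),
                  heading = runif(20, 0, 2 * pi))
  for (k in 1:5) {
    st <- combined_step(pop, k, env, w)
    expect_equal(sqrt(sum(c(cos(st$heading), sin(st$heading))^2)), 1)
  }
})

test_that("combined step reduces to straight-line motion when isolated", {
  env <- flat_env()
  pop <- make_pop(x = 5, y = 5, heading = 0, speed = 0.5)
  st <- combined_step(pop, 1, env, movement_weights(), dt = 0.2,
                      use_sst = FALSE)
  expect_equal(st$q, c(5 + 0.2 * 0.5, 5))
  expect_equal(st$speed, 0.5)
})

test_that("with alpha = 0 the step follows the temperature gradient", {
  spec <- grid_spec(40, 8)
  env <- synth_environment(spec, mode = "uniform", border_band = 0)
  env$sst <- matrix(seq_len(40) - 0.5, 40, 8)  # linear, T(20.5) = 20 > T2
  pop <- make_pop(x = 20.5, y = 4, heading = pi / 2, speed = 0.5)
  st <- combined_step(pop, 1, env, movement_weights(alpha = 0, beta = 1),
                      dt = 0.2, use_sst = TRUE)
  expect_lt(st$q[1], 20.5)   # moved down-gradient (toward cooler water)
  expect_equal(st$q[2], 4)
})

test_that("zero-speed fish are advected by the current term alone", {
  env <- flat_env()
  env$u[] <- 0.1
  env$v[] <- -0.05
  pop <- make_pop(x = 5, y = 5, heading = 0, speed = 0)
  st <- combined_step(pop, 1, env, movement_weights(), dt = 0.2,
                      use_sst = FALSE, use_currents = TRUE)
  expect_equal(st$q, c(5 + 0.2 * 0.1, 5 - 0.2 * 0.05))
})

test_that("border reflection mirrors positions and flips headings", {
  spec <- grid_spec(100, 40)
  rb <- reflect_border(c(-0.3, 5), spec, heading_vec = c(-1, 0))
  expect_equal(rb$q, c(0.3, 5))
  expect_equal(rb$heading_vec, c(1, 0))
  # interior point unchanged
  rb <- reflect_border(c(50, 20), spec, heading_vec = c(0, 1))
  expect_equal(rb$q, c(50, 20))
  expect_equal(rb$heading_vec, c(0, 1))
  # double reflection in both coordinates
  rb <- reflect_border(c(100.2, 40.1), spec)
  expect_equal(rb$q, c(99.8, 39.9))
  # absurd displacements flag a unit bug
  expect_error(reflect_border(c(500, 5), spec), "units")
})

test_that("diffusive displacement satisfies the 4Dt law", {
  # 10,000 walkers, 100 days at dt = 0.2, far from any border
  D <- 0.0069
  n <- 10000
  spec <- grid_spec(200, 200)
  env <- synth_environment(spec, mode = "uniform", border_band = 0)
  x0 <- rep(100, n); y0 <- rep(100, n)
  st <- list(x = x0, y = y0)
  set.seed(1)
  heading <- runif(n, 0, 2 * pi)
  for (step in 1:500) {
    st <- mpaschool:::move_substep_cpp(
      st$x, st$y, heading, rep(0.45, n), rep(500L, n), rep(0.45, n),
      rep(0.05, n), spec$nx, spec$ny, env$u, env$v, env$u, env$v,
      social = FALSE, use_sst = FALSE, use_currents = FALSE,
      rr = 0.02, ro = 0.1, ra = 0.1, alpha = 1, beta = 0,
      diff_coef = D, dt = 0.2)
  }
  msd <- mean((st$x - x0)^2 + (st$y - y0)^2)
  expect_equal(msd, 4 * D * 100, tolerance = 0.05)

  # the plain-R step obeys the same law over a single long step
  pop <- make_pop(x = rep(100, n), y = rep(100, n))
  set.seed(2)
  pop2 <- diffusive_step(pop, spec, D = D, dt = 100)
  msd_r <- mean((pop2$x - 100)^2 + (pop2$y - 100)^2)
  expect_equal(msd_r, 4 * D * 100, tolerance = 0.05)

  # D = 0 keeps every fish in place
  pop3 <- diffusive_step(pop[1:10, ], spec, D = 0, dt = 0.2)
  expect_equal(pop3$x, pop$x[1:10])
})

test_that("one engine sub-step matches the single-fish reference operations", {
  spec <- grid_spec(40, 8)
  env <- synth_environment(spec, mode = "uniform", border_band = 0)
  env$sst <- matrix(seq_len(40) - 0.5, 40, 8)
  env$u[] <- 0.03; env$v[] <- -0.02
  grad <- mpaschool:::temp_gradient_field(env)
  set.seed(11)
  n <- 40
  pop <- make_pop(x = runif(n, 5, 35), y = runif(n, 1, 7),
                  heading = runif(n, 0, 2 * pi),
                  speed = runif(n, 0.42, 0.50))
  w <- movement_weights()
  st <- mpaschool:::move_substep_cpp(
    pop$x, pop$y, pop$heading, pop$speed, pop$age, pop$speed,
    rep(0.05, n), spec$nx, spec$ny, env$u, env$v, grad$gx, grad$gy,
    social = TRUE, use_sst = TRUE, use_currents = TRUE,
    rr = 0.02, ro = 0.1, ra = 0.1, alpha = w$alpha, beta = w$beta,
    diff_coef = 0, dt = 0.2)
  for (k in c(1, 5, 12, 33)) {
    ref <- combined_step(pop, k, env, w, dt = 0.2,
                         use_sst = TRUE, use_currents = TRUE)
    expect_equal(c(st$x[k], st$y[k]), ref$q, tolerance = 1e-12)
    expect_equal(st$speed[k], ref$speed, tolerance = 1e-12)
  }
})

test_that("aligned schools are a fixed point of the interaction rules", {
  # all fish mutually inside orientation zones, equal speed, same heading
  pop <- make_pop(x = 5 + c(0, 0.04, 0.08), y = 5, heading = pi / 4,
                  speed = 0.45)
  radii <- zone_radii()
  env <- flat_env()
  for (k in 1:3) {
    expect_equal(update_speed(pop, k, radii), 0.45)
    d <- social_direction(pop, k, radii)
    expect_equal(d / sqrt(sum(d^2)), c(cos(pi / 4), sin(pi / 4)))
  }
})
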