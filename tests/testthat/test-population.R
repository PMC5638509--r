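test_that("logistic recruitment has the Gordon-Schaefer shape", {
  expect_equal(expected_recruits(0, 1.2, 30000), 0)
  expect_equal(expected_recruits(30000, 1.2, 30000), 0)
  # maximum K*r/4 at K/2
  expect_equal(expected_recruits(15000, 1.2, 30000), 9000)
  # floored at zero above K
  expect_equal(expected_recruits(40000, 1.2, 30000), 0)
  expect_error(expected_recruits(100, 1.2, K = 0), "positive")
})

test_that("egg survival is the clamped target/standing ratio", {
  expect_equal(egg_daily_survival(9000, 300000), 0.03)
  expect_equal(egg_daily_survival(9000, 5000), 1)    # clamp at 1
  expect_equal(egg_daily_survival(0, 1000), 0)
  expect_equal(egg_daily_survival(9000, 0), 1)       # vacuous case
  # always a probability
  set.seed(1)
  for (i in 1:50) {
    s <- egg_daily_survival(runif(1, 0, 1e4), round(runif(1, 0, 1e5)))
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("natural mortality applies class-specific daily hazards", {
  params <- demography_params()
  # no mortality at zero rates and full egg survival
  p0 <- demography_params(z_young = 0, z_old = 0)
  pop <- make_pop(x = runif(100, 1, 9), y = runif(100, 1, 9),
                  age = rep(c(400L, 2000L), 50))
  set.seed(3)
  out <- apply_natural_mortality(pop, p0, s_prob = 1)
  expect_true(all(out$alive))
  # binomial expectation: 10,000 two-year-olds at Z = 7e-4
  big <- make_pop(x = rep(5, 10000), y = 5, age = 730L)
  set.seed(4)
  out <- apply_natural_mortality(big, params, s_prob = 1)
  expect_equal(sum(out$alive), 10000 * (1 - 7e-4), tolerance = 0.003)
  # deadly egg hazard wipes the cohort in one day
  eggs <- make_pop(x = rep(5, 200), y = 5, age = 10L)
  set.seed(5)
  out <- apply_natural_mortality(eggs, params, s_prob = 0)
  expect_equal(sum(out$alive), 0)
  # old fish die at the higher rate
  old <- make_pop(x = rep(5, 10000), y = 5, age = 6L * 365L)
  set.seed(6)
  out <- apply_natural_mortality(old, params, s_prob = 1)
  expect_equal(sum(out$alive), 10000 * (1 - 3e-3), tolerance = 0.01)
})

test_that("spawning releases fecundity eggs at the parent's position", {
  # spawn_mu far from the scheduled day 250 so the parental redraw is
  # unambiguous
  params <- demography_params(spawn_mu = 100)
  pop <- make_pop(x = c(3, 7), y = c(2, 8), age = c(400L, 400L),
                  repro_day = c(250L, 100L))
  pop$adult_speed <- pop$speed; pop$natal_speed <- pop$speed
  set.seed(1)
  out <- spawn(pop, params, today = 250L)
  expect_equal(nrow(out), 2 + 10)
  eggs <- out[-(1:2), ]
  expect_true(all(eggs$x == 3 & eggs$y == 2))
  expect_true(all(eggs$age == 0L))
  expect_true(all(eggs$speed >= 0 & eggs$speed <= 0.1))
  expect_true(all(eggs$repro_day >= 1 & eggs$repro_day <= 365))
  expect_true(all(eggs$natal_speed == eggs$speed))
  # the parent redraws its reproduction day for the next cycle
  expect_false(out$repro_day[1] == 250L)
  # a juvenile scheduled today releases nothing
  juv <- make_pop(x = 5, y = 5, age = 300L, repro_day = 250L)
  expect_equal(nrow(spawn(juv, params, today = 250L)), 1)
  # nobody scheduled: unchanged
  expect_identical(spawn(pop, params, today = 17L), pop)
})

test_that("the annual census refreshes the recruitment target", {
  params <- demography_params(K = 200, r = 1.2)
  pop <- make_pop(x = runif(100, 1, 9), y = runif(100, 1, 9), age = 400L)
  cen <- annual_census(pop, params)
  expect_equal(cen$N_t, 100)
  expect_equal(cen$rec_target, 1.2 * 100 * (1 - 100 / 200))  # K/2: max K*r/4
  expect_equal(cen$rec_target, 200 * 1.2 / 4)
  # zero adults and K adults both give a zero target
  expect_equal(annual_census(make_pop(x = 5, y = 5, age = 100L),
                             params)$rec_target, 0)
  popK <- make_pop(x = runif(200, 1, 9), y = runif(200, 1, 9), age = 400L)
  expect_equal(annual_census(popK, params)$rec_target, 0)
})

test_that("stage boundaries follow age in days", {
  expect_equal(stage_of(c(0L, 182L, 183L, 364L, 365L, 4000L)),
               c("egg_larva", "egg_larva", "juvenile", "juvenile",
                 "adult", "adult"))
})

test_that("unfished stock equilibrates at or below carrying capacity", {
  # desk-scale unfished run: after burn-in the adult count fluctuates
  # around a level that never exceeds K by more than recruitment noise
  cfg <- sim_config(scenario = "a", grid = grid_spec(30L, 12L),
                    n_fish = 600L, demography = demography_params(K = 700),
                    fleet = fleet_params(n_boats = 50, F_annual = 0,
                                         q_scale = 1),
                    schedule = sim_schedule(total_years = 12L,
                                            fishing_start = 12L,
                                            mpa_start = 12L))
  rec <- run_simulation(cfg, seed = 21)
  late <- tail(rec$annual$adults, 6)
  expect_true(all(late <= 700 * 1.05))
  expect_true(all(late > 0.3 * 700))
  # egg cohorts are thinned toward the logistic target, so the standing
  # count stays bounded by target + one day's spawn
  expect_true(all(rec$annual$eggs <= 700 * 1.2 / 4 + 700 * 10))
})
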