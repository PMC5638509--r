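#' Simulation schedule
#'
#' Years are 365 days; the run starts on January 1st. Fishing is inactive
#' for the first `fishing_start` years (burn-in), then the whole grid is
#' fished until the MPA activates after `mpa_start` years; the run ends
#' after `total_years`. Movement advances in sub-steps of `dt` days (five
#' per day at the default 0.2), demographic and fleet events happen once
#' per day.
#'
#' @param total_years Total simulated years (default 70).
#' @param fishing_start Years of unfished burn-in (default 20).
#' @param mpa_start Year after which the MPA is in force (default 30).
#' @param dt Movement sub-step (days, default 0.2; must divide 1 evenly).
#' @return A `sim_schedule` object.
#' @export
sim_schedule <- function(total_years = 70L, fishing_start = 20L,
                         mpa_start = 30L, dt = 0.2) {
  total_years <- as.integer(total_years)
  fishing_start <- as.integer(fishing_start)
  mpa_start <- as.integer(mpa_start)
  if (!(0 <= fishing_start && fishing_start <= mpa_start &&
        mpa_start <= total_years))
    stop("schedule must satisfy 0 <= fishing_start <= mpa_start <= total_years",
         call. = FALSE)
  n_sub <- round(1 / dt)
  if (abs(n_sub * dt - 1) > 1e-9)
    stop("dt must divide one day evenly", call. = FALSE)
  structure(list(total_years = total_years, fishing_start = fishing_start,
                 mpa_start = mpa_start, dt = dt, n_substeps = as.integer(n_sub)),
            class = "sim_schedule")
}

#' No-take area mask (east-west strip)
#'
#' Closes `round(fraction * nx * ny)` sectors as an east-west strip centered
#' on the domain's mid-latitude: whole rows spanning the full x-range, plus
#' one centered partial row when the target sector count is not a whole
#' number of rows.
#'
#' @param spec A [grid_spec()].
#' @param fraction Closed share of the total area, in `[0, 1]`.
#' @return Logical nx x ny matrix, `TRUE` on closed sectors.
#' @export
mpa_mask <- function(spec, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  nx <- spec$nx; ny <- spec$ny
  n_closed <- round(fraction * nx * ny)
  m <- matrix(FALSE, nx, ny)
  if (n_closed == 0) return(m)
  full_rows <- n_closed %/% nx
  rem <- n_closed %% nx
  row0 <- floor((ny - full_rows) / 2)      # strip rows row0+1 .. row0+full_rows
  if (full_rows > 0) m[, (row0 + 1):(row0 + full_rows)] <- TRUE
  if (rem > 0) {
    part_row <- if (row0 + full_rows < ny) row0 + full_rows + 1L else row0
    col0 <- floor((nx - rem) / 2)
    m[(col0 + 1):(col0 + rem), part_row] <- TRUE
  }
  m
}

# Scenario switches along the complexity ladder:
# a = diffusion, b = schooling, c = schooling + SST taxis,
# d = schooling + SST taxis + current transport.
scenario_flags <- function(scenario) {
  scenario <- match.arg(scenario, c("a", "b", "c", "d"))
  list(scenario = scenario,
       social = scenario != "a",
       sst = scenario %in% c("c", "d"),
       currents = scenario == "d")
}

#' Full run configuration
#'
#' Bundles everything a run needs: the movement scenario, grid, environment,
#' demographic, movement and fleet parameters, schedule and MPA size.
#' Defaults reproduce the calibrated full-scale configuration (100 x 40
#' grid, ~25,000 fish, 70 years); see [scaled_config()] for the desk-scale
#' version used in tests and sweeps.
#'
#' Scenario switches are derived from `scenario`: the social term is off in
#' (a); the temperature weight only applies in (c) and (d) (in (b) the
#' effective weights are alpha = 1, beta = 0); currents only act in (d).
#'
#' @param scenario One of `"a"` (diffusion), `"b"` (schooling),
#'   `"c"` (schooling + SST), `"d"` (schooling + SST + currents).
#' @param grid A [grid_spec()].
#' @param n_fish Initial population size (default 25,000).
#' @param demography A [demography_params()].
#' @param radii A [zone_radii()].
#' @param weights A [movement_weights()].
#' @param diffusion Diffusion coefficient for scenario (a)
#'   (default 0.0069).
#' @param adult_speed Range `c(lo, hi)` of adult cruise speeds,
#'   sector/day (default `c(0.42, 0.50)`).
#' @param egg_speed Range of natal speeds (default `c(0, 0.1)`).
#' @param egg_decay_days Days over which the natal drift decays to zero
#'   (default 183, the whole egg/larva stage, so a cohort genuinely
#'   spreads away from its spawning point -- a few sectors on average --
#'   before recruiting into schools).
#' @param t_pref Thermal preference band (default `c(16, 18)` degrees C).
#' @param fleet A [fleet_params()].
#' @param schedule A [sim_schedule()].
#' @param mpa_fraction Closed share of the area (default 0).
#' @param env An `environment_grid`, or `NULL` to synthesize one with
#'   [synth_environment()] (`env_mode`, `env_seed`); the environment is
#'   static and shared across replicates.
#' @param env_mode,env_seed Passed to [synth_environment()] when `env` is
#'   `NULL`.
#' @return A `sim_config` object.
#' @export
sim_config <- function(scenario = "d", grid = grid_spec(),
                       n_fish = 25000L, demography = demography_params(),
                       radii = zone_radii(), weights = movement_weights(),
                       diffusion = 0.0069,
                       adult_speed = c(0.42, 0.50), egg_speed = c(0, 0.1),
                       egg_decay_days = 183L, t_pref = c(16, 18),
                       fleet = fleet_params(), schedule = sim_schedule(),
                       mpa_fraction = 0, env = NULL,
                       env_mode = "gyre", env_seed = 42L) {
  flags <- scenario_flags(scenario)
  problems <- character()
  if (n_fish < 1) problems <- c(problems, "n_fish must be >= 1")
  if (diffusion < 0) problems <- c(problems, "diffusion must be >= 0")
  if (mpa_fraction < 0 || mpa_fraction > 1)
    problems <- c(problems, "mpa_fraction must be in [0, 1]")
  if (adult_speed[1] > adult_speed[2] || adult_speed[1] < 0)
    problems <- c(problems, "adult_speed range invalid")
  if (mpa_fraction >= 1 && fleet$F_annual > 0 &&
      schedule$fishing_start < schedule$total_years)
    problems <- c(problems, "cannot fish a fully closed domain")
  if (length(problems))
    stop(paste("invalid configuration:", paste(problems, collapse = "; ")),
         call. = FALSE)
  structure(list(scenario = flags$scenario, flags = flags, grid = grid,
                 n_fish = as.integer(n_fish), demography = demography,
                 radii = radii, weights = weights, diffusion = diffusion,
                 adult_speed = adult_speed, egg_speed = egg_speed,
                 egg_decay_days = as.integer(egg_decay_days),
                 t_pref = t_pref, fleet = fleet, schedule = schedule,
                 mpa_fraction = mpa_fraction, env = env,
                 env_mode = env_mode, env_seed = as.integer(env_seed)),
            class = "sim_config")
}

#' Desk-scale configuration
#'
#' A factor-10 reduction of the full-scale setup (2,500 fish, K = 3,000,
#' 500 boats, 50 x 20 grid, 35 years with fishing from year 10 and the MPA
#' from year 15) used for tests and desk-scale experiments. Rates, radii,
#' speeds and the thermal band are unchanged.
#'
#' @param scenario Movement scenario (see [sim_config()]).
#' @param mpa_fraction Closed share of the area.
#' @param ... Further overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
scaled_config <- function(scenario = "d", mpa_fraction = 0, ...) {
  sim_config(scenario = scenario, grid = grid_spec(50L, 20L),
             n_fish = 2500L,
             demography = demography_params(K = 3000),
             fleet = fleet_params(n_boats = 500),
             schedule = sim_schedule(total_years = 35L, fishing_start = 10L,
                                     mpa_start = 15L),
             mpa_fraction = mpa_fraction, ...)
}

#' Initial population state
#'
#' Draws the initial fish: positions uniform over the domain, headings
#' U(0, 360) degrees, speeds U(0.42, 0.50) sector/day, ages U(1, 3) years
#' and reproduction days round(N(250, 20)). Uses the current RNG state.
#'
#' @param config A [sim_config()].
#' @return Data frame with one row per fish: `x`, `y`, `heading`, `speed`,
#'   `age`, `alive`, `repro_day`, `adult_speed`, `natal_speed`.
#' @export
initialize_population <- function(config) {
  n <- config$n_fish
  g <- config$grid
  sp <- stats::runif(n, config$adult_speed[1], config$adult_speed[2])
  data.frame(
    x = stats::runif(n, 0, g$nx), y = stats::runif(n, 0, g$ny),
    heading = stats::runif(n, 0, 2 * pi), speed = sp,
    age = as.integer(round(stats::runif(n, 365, 3 * 365))),
    alive = TRUE,
    repro_day = draw_repro_day(n, config$demography),
    adult_speed = sp, natal_speed = sp)
}

# Environment attached to a config, synthesizing the default if absent.
config_env <- function(config) {
  if (!is.null(config$env)) return(config$env)
  synth_environment(config$grid, t_pref = config$t_pref,
                    seed = config$env_seed, mode = config$env_mode)
}

#' Run one simulation
#'
#' Executes the full daily event loop in compiled code. Each simulated day:
#' (1) ages advance and stages transition; (2) natural mortality, with the
#' density-dependent egg hazard; (3) spawning; (4) five movement sub-steps
#' under the active scenario; (5) if fishing is active, fleet reallocation
#' and fishing mortality. An annual census on January 1st refreshes the
#' logistic recruitment target. The run is a pure function of
#' `(config, seed)`.
#'
#' Because the no-take area has no effect before `mpa_start` (and fishing
#' none before `fishing_start`), runs that differ only in those respects
#' share an identical prefix. `stop_after_year` returns a checkpoint (full
#' fish state plus RNG state) that `resume` continues from; a resumed run
#' is bit-identical to the corresponding uninterrupted run, so sweeps can
#' compute the shared prefix once per replicate.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param daily_record Keep per-day landings and adult counts (default
#'   `FALSE`; annual records are always kept; a resumed run only records
#'   days after the checkpoint).
#' @param verbose Print a progress line per simulated year.
#' @param stop_after_year Stop after this simulated year and attach a
#'   `checkpoint` element to the result.
#' @param resume A checkpoint from a previous `stop_after_year` run of a
#'   configuration with an identical prefix.
#' @return An `mpa_run` object: list with `annual` (data frame: `year`,
#'   `adults` (census), `rec_target`, `juveniles`, `eggs`, `density`
#'   (juveniles + adults at year end), `landings`, `realized_F` (summed
#'   daily population-mean fishing hazard)), `mean_F` (abundance-weighted
#'   annualized fishing hazard per fish-day over all fished days),
#'   `extinction_year` (`NA` if the stock never died out), `diagnostics`
#'   (max boat-conservation deviation, landings from closed sectors),
#'   `config`, `seed`, and optionally `daily`.
#' @export
run_simulation <- function(config, seed = 1L, daily_record = FALSE,
                           verbose = FALSE, stop_after_year = NULL,
                           resume = NULL) {
  stopifnot(inherits(config, "sim_config"))
  env <- config_env(config)
  if (!all(c(env$spec$nx, env$spec$ny) == c(config$grid$nx, config$grid$ny)))
    stop("environment grid does not match the configured grid", call. = FALSE)
  grad <- temp_gradient_field(env, config$t_pref)
  mask <- mpa_mask(config$grid, config$mpa_fraction)
  if (is.null(resume)) {
    set.seed(as.integer(seed))
    pop <- initialize_population(config)
    start_year <- 1L
  } else {
    assign(".Random.seed", resume$rng, envir = globalenv())
    pop <- as.data.frame(resume$state)
    start_year <- resume$year + 1L
    if (start_year > config$schedule$total_years)
      stop("checkpoint lies beyond the configured run length", call. = FALSE)
  }
  run_until <- if (is.null(stop_after_year)) config$schedule$total_years
               else as.integer(stop_after_year)
  stopifnot(run_until >= start_year,
            run_until <= config$schedule$total_years)
  want_state <- !is.null(stop_after_year)
  q_scale <- config$fleet$q_scale
  if (is.na(q_scale)) q_scale <- 0  # unfished unless calibrated
  dem <- config$demography
  res <- sim_run_cpp(
    x0 = pop$x, y0 = pop$y, heading0 = pop$heading, speed0 = pop$speed,
    age0 = pop$age, repro_day0 = pop$repro_day,
    adult_speed0 = pop$adult_speed, natal_speed0 = pop$natal_speed,
    nx = config$grid$nx, ny = config$grid$ny,
    u = env$u, v = env$v, gx = grad$gx, gy = grad$gy,
    social = config$flags$social, use_sst = config$flags$sst,
    use_currents = config$flags$currents,
    rr = config$radii$r_r, ro = config$radii$r_o, ra = config$radii$r_a,
    alpha = if (config$flags$sst) config$weights$alpha else 1,
    beta = if (config$flags$sst) config$weights$beta else 0,
    diff_coef = config$diffusion, dt = config$schedule$dt,
    n_substeps = config$schedule$n_substeps,
    adult_speed_lo = config$adult_speed[1],
    adult_speed_hi = config$adult_speed[2],
    egg_speed_lo = config$egg_speed[1], egg_speed_hi = config$egg_speed[2],
    egg_decay_days = config$egg_decay_days,
    z_young = dem$z_young, z_old = dem$z_old, fecundity = dem$fecundity,
    juvenile_age = dem$juvenile_age, maturity_age = dem$maturity_age,
    spawn_mu = dem$spawn_mu, spawn_sd = dem$spawn_sd, K = dem$K,
    r_growth = dem$r,
    n_boats = config$fleet$n_boats, c_aggr = config$fleet$c,
    F_annual = config$fleet$F_annual, q_scale = q_scale,
    total_years = run_until,
    fishing_start = config$schedule$fishing_start,
    mpa_start = config$schedule$mpa_start,
    mpa_closed = mask, daily_record = daily_record, verbose = verbose,
    start_year = start_year, return_state = want_state)
  annual <- data.frame(year = seq_len(run_until),
                       adults = res$adults_census,
                       rec_target = res$rec_target,
                       juveniles = res$juveniles_end,
                       eggs = res$eggs_end,
                       density = res$juveniles_end + res$adults_end,
                       adults_end = res$adults_end,
                       landings = res$landings,
                       realized_F = res$realized_F)
  if (!is.null(resume) && start_year > 1L)
    annual[seq_len(start_year - 1L), ] <- resume$annual
  out <- list(annual = annual,
              mean_F = res$mean_F,
              extinction_year = if (res$extinction_year > 0)
                res$extinction_year else NA_integer_,
              diagnostics = list(max_boat_dev = res$max_boat_dev,
                                 closed_landings = res$closed_landings,
                                 timers = res$timers),
              config = config, seed = as.integer(seed))
  if (daily_record)
    out$daily <- data.frame(day = seq_along(res$daily_landings),
                            landings = res$daily_landings,
                            adults = res$daily_adults)
  if (want_state)
    out$checkpoint <- list(state = res$state, rng = get(".Random.seed",
                                                        envir = globalenv()),
                           year = run_until, annual = annual)
  class(out) <- "mpa_run"
  out
}

#' @export
print.mpa_run <- function(x, ...) {
  a <- x$annual
  cat(sprintf("<mpa_run> scenario %s, MPA %.0f%%, %d years, seed %d\n",
              x$config$scenario, 100 * x$config$mpa_fraction,
              nrow(a), x$seed))
  cat(sprintf("  final density %d (juv+adult), last-year landings %d\n",
              a$density[nrow(a)], a$landings[nrow(a)]))
  if (!is.na(x$extinction_year))
    cat(sprintf("  stock extinct in year %d\n", x$extinction_year))
  invisible(x)
}
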