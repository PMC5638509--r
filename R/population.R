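#' Demographic parameters
#'
#' Life-history parameters of the simulated stock (anchovy-like): two
#' age-banded daily natural mortality rates, annual spawning normally
#' distributed around day 250 (early September), fixed per-capita fecundity,
#' and a Gordon-Schaefer (logistic) production model with carrying capacity
#' `K` and intrinsic rate of increase `r` that anchors density-dependent
#' egg survival.
#'
#' @param z_young Daily natural mortality, post-larval fish under 5 y
#'   (default 7e-4 / d).
#' @param z_old Daily natural mortality, 5 y and older (default 3e-3 / d).
#' @param fecundity Eggs per adult per spawning event (default 10).
#' @param juvenile_age Egg/larva to juvenile boundary (days, default 183).
#' @param maturity_age Juvenile to adult boundary (days, default 365).
#' @param spawn_mu,spawn_sd Mean and SD (days) of the reproduction-day
#'   distribution (defaults 250 and 20).
#' @param K Carrying capacity, adults (default 30,000).
#' @param r Intrinsic rate of increase (default 1.2 / y).
#' @return A `demography_params` object.
#' @export
demography_params <- function(z_young = 7e-4, z_old = 3e-3, fecundity = 10L,
                              juvenile_age = 183L, maturity_age = 365L,
                              spawn_mu = 250, spawn_sd = 20,
                              K = 30000, r = 1.2) {
  stopifnot(z_young >= 0, z_old >= 0, fecundity >= 1, spawn_sd > 0, r >= 0)
  if (K <= 0) stop("carrying capacity K must be positive", call. = FALSE)
  structure(list(z_young = z_young, z_old = z_old,
                 fecundity = as.integer(fecundity),
                 juvenile_age = as.integer(juvenile_age),
                 maturity_age = as.integer(maturity_age),
                 spawn_mu = spawn_mu, spawn_sd = spawn_sd, K = K, r = r),
            class = "demography_params")
}

#' Expected recruits from the logistic production model
#'
#' `Rec = r * N * (1 - N/K)`, floored at zero when the stock exceeds `K`.
#' The maximum, `K * r / 4` at `N = K/2`, is the maximum sustainable yield
#' of the Gordon-Schaefer model.
#'
#' @param N_t Adult count at the annual census.
#' @param r Intrinsic rate of increase (per year).
#' @param K Carrying capacity (adults).
#' @return Expected number of recruits for the coming year.
#' @export
expected_recruits <- function(N_t, r, K) {
  if (K <= 0) stop("carrying capacity K must be positive", call. = FALSE)
  stopifnot(N_t >= 0)
  max(0, r * N_t * (1 - N_t / K))
}

#' Daily egg/larva survival probability
#'
#' `S = Rec_target / Neggs`, clamped to `[0, 1]`; defined as 1 when no eggs
#' are present. Recomputed every day from the standing egg count, this
#' hazard thins each spawning cohort toward the logistic recruitment target
#' and then lets the survivors through (S -> 1 once the cohort is at or
#' below the target).
#'
#' @param rec_target Expected recruits from [expected_recruits()].
#' @param n_eggs Standing egg/larva count on the current day.
#' @return Daily survival probability in `[0, 1]`.
#' @export
egg_daily_survival <- function(rec_target, n_eggs) {
  stopifnot(rec_target >= 0, n_eggs >= 0)
  if (n_eggs == 0) return(1)
  min(1, max(0, rec_target / n_eggs))
}

#' Apply one day of natural mortality
#'
#' Each fish dies independently with its class probability: eggs/larvae
#' with `1 - s_prob` (the density-dependent hazard; no additive background
#' rate), post-larval fish under 5 years with `z_young`, older fish with
#' `z_old`.
#'
#' @param pop Population data frame with `age` (days) and `alive`.
#' @param params A [demography_params()].
#' @param s_prob Current daily egg survival probability.
#' @return `pop` with `alive` updated.
#' @export
apply_natural_mortality <- function(pop, params, s_prob) {
  alive <- which(pop$alive)
  if (!length(alive)) return(pop)
  age <- pop$age[alive]
  p_die <- ifelse(age < params$juvenile_age, 1 - s_prob,
                  ifelse(age < 5 * 365, params$z_young, params$z_old))
  dead <- stats::runif(length(alive)) < p_die
  pop$alive[alive[dead]] <- FALSE
  pop
}

#' Spawn eggs for adults scheduled today
#'
#' Every alive adult (age >= maturity) whose assigned reproduction day
#' equals `today` releases `fecundity` eggs at its own position; the parent
#' then redraws its reproduction day for the next annual cycle. Each egg
#' starts at age 0 with a random heading, natal speed U(0, 0.1) sector/day,
#' a personal adult cruise speed drawn U(0.42, 0.50), and its own
#' reproduction day drawn from round(N(spawn_mu, spawn_sd)).
#'
#' @param pop Population data frame with columns `x`, `y`, `heading`,
#'   `speed`, `age`, `alive`, `repro_day`.
#' @param params A [demography_params()].
#' @param today Day of year (1..365).
#' @return `pop` with new egg rows appended (and parents' `repro_day`
#'   redrawn).
#' @export
spawn <- function(pop, params, today) {
  spawners <- which(pop$alive & pop$age >= params$maturity_age &
                      pop$repro_day == today)
  if (!length(spawners)) return(pop)
  n_eggs <- length(spawners) * params$fecundity
  parent <- rep(spawners, each = params$fecundity)
  eggs <- data.frame(
    x = pop$x[parent], y = pop$y[parent],
    heading = stats::runif(n_eggs, 0, 2 * pi),
    speed = stats::runif(n_eggs, 0, 0.1),
    age = 0L, alive = TRUE,
    repro_day = draw_repro_day(n_eggs, params))
  # engine-state extras, when present
  for (col in setdiff(names(pop), names(eggs))) {
    eggs[[col]] <- switch(col,
      adult_speed = stats::runif(n_eggs, 0.42, 0.50),
      natal_speed = eggs$speed,
      NA)
  }
  pop$repro_day[spawners] <- draw_repro_day(length(spawners), params)
  rbind(pop, eggs[names(pop)])
}

# Reproduction day-of-year: rounded normal draw, clamped into 1..365.
draw_repro_day <- function(n, params) {
  pmin(365L, pmax(1L, as.integer(round(
    stats::rnorm(n, params$spawn_mu, params$spawn_sd)))))
}

#' Annual census and recruitment target
#'
#' Counts alive adults and refreshes the logistic recruitment target for
#' the coming year. Run on January 1st of each simulated year.
#'
#' @param pop Population data frame with `age` and `alive`.
#' @param params A [demography_params()].
#' @return List with `N_t` (adult count) and `rec_target`.
#' @export
annual_census <- function(pop, params) {
  N_t <- sum(pop$alive & pop$age >= params$maturity_age)
  list(N_t = N_t, rec_target = expected_recruits(N_t, params$r, params$K))
}
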