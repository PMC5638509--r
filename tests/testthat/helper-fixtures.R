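# Small in-code fixtures shared across test files.

# Population data frame in the layout the R-level operations expect.
make_pop <- function(x, y, heading = 0, speed = 0.45, age = 400L,
                     alive = TRUE, repro_day = 250L) {
  n <- length(x)
  data.frame(x = x, y = y,
             heading = rep_len(heading, n), speed = rep_len(speed, n),
             age = as.integer(rep_len(age, n)),
             alive = rep_len(alive, n),
             repro_day = as.integer(rep_len(repro_day, n)))
}

# Uniform-temperature environment (zero currents, comfortable everywhere).
flat_env <- function(nx = 20, ny = 10, t_pref = c(16, 18)) {
  synth_environment(grid_spec(nx, ny), t_pref = t_pref, mode = "uniform")
}

# Brute-force all-pairs neighbor sets: the O(n^2) oracle.
brute_neighbor_sets <- function(x, y, eligible, k, rr, ro, ra) {
  idx <- setdiff(which(eligible), k)
  d <- sqrt((x[idx] - x[k])^2 + (y[idx] - y[k])^2)
  list(NR = sort(idx[d <= rr]),
       NO = sort(c(k, idx[d > rr & d <= ro])),
       NA_ = sort(idx[d > ro & d <= ra]))
}

# Tiny run configuration for fast engine tests (3 years, small grid).
tiny_config <- function(scenario = "b", n_fish = 150L, years = 3L,
                        fishing_start = 1L, mpa_start = 2L, ...) {
  sim_config(scenario = scenario, grid = grid_spec(20L, 10L),
             n_fish = n_fish,
             demography = demography_params(K = 200),
             fleet = fleet_params(n_boats = 50, q_scale = 1),
             schedule = sim_schedule(total_years = years,
                                     fishing_start = fishing_start,
                                     mpa_start = mpa_start),
             ...)
}
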