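#' Interaction zone radii
#'
#' Concentric zones around each fish: repulsion (head away, collision
#' avoidance), orientation (align speed and direction) and attraction (head
#' toward neighbors, cohesion). Defaults follow the calibrated parameter set
#' (r_r = 0.02, r_o = r_a = 0.10 sector); note that r_o = r_a makes the
#' attraction annulus empty, so cohesion is inactive at defaults unless
#' `r_a` is increased.
#'
#' @param r_r,r_o,r_a Repulsion, orientation and attraction radii (sectors);
#'   must satisfy `0 < r_r <= r_o <= r_a`.
#' @return A `zone_radii` object.
#' @export
zone_radii <- function(r_r = 0.02, r_o = 0.10, r_a = 0.10) {
  if (!(r_r > 0 && r_r <= r_o && r_o <= r_a))
    stop("zone radii must satisfy 0 < r_r <= r_o <= r_a", call. = FALSE)
  structure(list(r_r = r_r, r_o = r_o, r_a = r_a), class = "zone_radii")
}

#' Movement weights (neighbors vs temperature)
#'
#' `alpha` weights the social direction, `beta` the temperature-taxis
#' direction; they must sum to one.
#'
#' @param alpha Neighbor weight (default 0.995).
#' @param beta Temperature weight (default 0.005).
#' @return A `movement_weights` object.
#' @export
movement_weights <- function(alpha = 0.995, beta = 0.005) {
  if (alpha < 0 || beta < 0 || abs(alpha + beta - 1) > 1e-12)
    stop("movement weights must be non-negative and sum to 1", call. = FALSE)
  structure(list(alpha = alpha, beta = beta), class = "movement_weights")
}

#' Life stage from age in days
#'
#' Egg/larva below `juvenile_age` (183 d), juvenile from there to
#' `maturity_age` (365 d), adult from `maturity_age` on.
#'
#' @param age_days Integer age(s) in days.
#' @param juvenile_age,maturity_age Stage boundaries (days).
#' @return Character vector in `c("egg_larva", "juvenile", "adult")`.
#' @export
stage_of <- function(age_days, juvenile_age = 183L, maturity_age = 365L) {
  ifelse(age_days < juvenile_age, "egg_larva",
         ifelse(age_days < maturity_age, "juvenile", "adult"))
}

# Social participants: alive juveniles and adults.
social_eligible <- function(pop) {
  pop$alive & stage_of(pop$age) != "egg_larva"
}

#' Interaction neighbor sets of one fish
#'
#' Plain all-pairs reference implementation. `NR` holds fish within the
#' repulsion radius, `NO` those in the orientation annulus plus the focal
#' fish itself (self-inclusion keeps the speed average defined for isolated
#' fish and lets them persist their heading), `NA` those in the half-open
#' attraction annulus `(r_o, r_a]`. Only alive juveniles and adults take
#' part; eggs/larvae neither perceive nor are perceived.
#'
#' @param pop Population data frame with columns `x`, `y`, `heading`
#'   (radians), `speed`, `age` (days), `alive`.
#' @param k Index of the focal fish (must be alive and post-larval).
#' @param radii A [zone_radii()].
#' @return List with integer index vectors `NR`, `NO`, `NA_` (row indices
#'   into `pop`).
#' @export
neighbor_sets <- function(pop, k, radii) {
  k <- as.integer(k)
  stopifnot(pop$alive[k])
  elig <- which(social_eligible(pop))
  elig <- elig[elig != k]
  d <- sqrt((pop$x[elig] - pop$x[k])^2 + (pop$y[elig] - pop$y[k])^2)
  list(NR = elig[d <= radii$r_r],
       NO = sort(c(k, elig[d > radii$r_r & d <= radii$r_o])),
       NA_ = elig[d > radii$r_o & d <= radii$r_a])
}

#' Speed update: orientation-zone consensus
#'
#' The new speed of fish `k` is the arithmetic mean of the current speeds
#' over its orientation set (which includes `k` itself).
#'
#' @inheritParams neighbor_sets
#' @return New speed (sector/day).
#' @export
update_speed <- function(pop, k, radii) {
  ns <- neighbor_sets(pop, k, radii)
  mean(pop$speed[ns$NO])
}

#' Social direction of one fish
#'
#' Average of unit vectors pointing away from repulsion neighbors, along the
#' headings of orientation neighbors (self included), and toward attraction
#' neighbors, divided by the total neighbor count. A coincident repulsion
#' neighbor (zero distance) contributes a random unit vector, since the
#' normalization is undefined there.
#'
#' @inheritParams neighbor_sets
#' @return Direction vector `c(dx, dy)` (not normalized).
#' @export
social_direction <- function(pop, k, radii) {
  ns <- neighbor_sets(pop, k, radii)
  n_tot <- length(ns$NR) + length(ns$NO) + length(ns$NA_)
  acc <- c(0, 0)
  for (r in ns$NR) {
    dv <- c(pop$x[k] - pop$x[r], pop$y[k] - pop$y[r])
    nrm <- sqrt(sum(dv^2))
    if (nrm == 0) {
      th <- stats::runif(1, 0, 2 * pi)
      dv <- c(cos(th), sin(th)); nrm <- 1
    }
    acc <- acc + dv / nrm
  }
  for (o in ns$NO) acc <- acc + c(cos(pop$heading[o]), sin(pop$heading[o]))
  for (a in ns$NA_) {
    dv <- c(pop$x[a] - pop$x[k], pop$y[a] - pop$y[k])
    acc <- acc + dv / sqrt(sum(dv^2))
  }
  acc / n_tot
}

#' One schooling movement sub-step for a single fish
#'
#' Combines the normalized social direction with the temperature-taxis
#' response as `D = alpha * d/|d| + beta * g`, renormalizes, and advances
#' the position by `dt * v_new` along `D`, optionally adding the current
#' displacement `dt * C(q)`. If the combined direction norm falls below
#' `tol` the previous heading is kept. The result is reflected back into
#' the domain.
#'
#' @inheritParams neighbor_sets
#' @param env An `environment_grid`.
#' @param weights A [movement_weights()].
#' @param t_pref Thermal preference band `c(T1, T2)`.
#' @param dt Sub-step length (days), default 0.2.
#' @param use_sst,use_currents Scenario switches: temperature taxis
#'   (scenarios c, d) and current transport (scenario d).
#' @param tol Direction-norm tolerance.
#' @return List with `q` (new position), `heading` (radians), `speed`.
#' @export
combined_step <- function(pop, k, env, weights, radii = zone_radii(),
                          t_pref = c(16, 18), dt = 0.2,
                          use_sst = TRUE, use_currents = FALSE, tol = 1e-12) {
  v_new <- update_speed(pop, k, radii)
  d <- social_direction(pop, k, radii)
  nd <- sqrt(sum(d^2))
  dhat <- if (nd > tol) d / nd else c(cos(pop$heading[k]), sin(pop$heading[k]))
  g <- if (use_sst) temp_gradient_response(env, c(pop$x[k], pop$y[k]), t_pref)
       else c(0, 0)
  D <- weights$alpha * dhat + weights$beta * g
  nD <- sqrt(sum(D^2))
  Dhat <- if (nD > tol) D / nD else c(cos(pop$heading[k]), sin(pop$heading[k]))
  q <- c(pop$x[k], pop$y[k]) + dt * v_new * Dhat
  if (use_currents) q <- q + dt * sample_current(env, c(pop$x[k], pop$y[k]))
  rb <- reflect_border(q, env$spec, heading_vec = Dhat)
  list(q = rb$q, heading = atan2(rb$heading_vec[2], rb$heading_vec[1]),
       speed = v_new)
}

#' Diffusive movement sub-step (random-walk scenario)
#'
#' Gaussian displacement with per-axis variance `2 * D * dt`, so the
#' ensemble mean-squared displacement grows as `4 D t` (planar diffusion).
#' All fish move; borders reflect.
#'
#' @param pop Population data frame (see [neighbor_sets()]).
#' @param spec A [grid_spec()].
#' @param D Diffusion coefficient (default 0.0069; Table-1 nominal value).
#' @param dt Sub-step length (days).
#' @return `pop` with updated `x`, `y`.
#' @export
diffusive_step <- function(pop, spec, D = 0.0069, dt = 0.2) {
  n <- nrow(pop)
  sd <- sqrt(2 * D * dt)
  x <- pop$x + stats::rnorm(n, 0, sd)
  y <- pop$y + stats::rnorm(n, 0, sd)
  for (i in seq_len(n)) {
    rb <- reflect_border(c(x[i], y[i]), spec)
    x[i] <- rb$q[1]; y[i] <- rb$q[2]
  }
  pop$x <- x; pop$y <- y
  pop
}

#' Mirror-reflect a position into the domain
#'
#' Out-of-domain coordinates are reflected about the violated wall
#' (repelling borders, no emigration); the heading component normal to that
#' wall is flipped. A displacement exceeding the domain width signals a
#' unit/timestep bug and raises an error.
#'
#' @param q_raw Position `c(x, y)`, possibly outside the domain.
#' @param spec A [grid_spec()].
#' @param heading_vec Optional unit heading `c(ux, uy)` to reflect along
#'   with the position.
#' @return List with `q` inside the domain and `heading_vec`.
#' @export
reflect_border <- function(q_raw, spec, heading_vec = c(1, 0)) {
  if (abs(q_raw[1] - spec$nx / 2) > 1.5 * spec$nx ||
      abs(q_raw[2] - spec$ny / 2) > 1.5 * spec$ny)
    stop("displacement exceeds domain width; check units/timestep", call. = FALSE)
  refl1 <- function(z, L, u) {
    if (z < 0) { z <- -z; u <- -u }
    if (z > L) { z <- 2 * L - z; u <- -u }
    c(z, u)
  }
  rx <- refl1(q_raw[1], spec$nx, heading_vec[1])
  ry <- refl1(q_raw[2], spec$ny, heading_vec[2])
  list(q = c(rx[1], ry[1]), heading_vec = c(rx[2], ry[2]))
}
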