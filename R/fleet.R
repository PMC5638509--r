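#' Fishing fleet parameters
#'
#' A fixed fleet of boats reallocated daily across sectors in proportion to
#' adult density outside the MPA (gravity-style allocation with aggregation
#' parameter `c`), converted into a per-fish daily capture probability via
#' the catchability scalar `q_scale` calibrated to the target annual
#' fishing mortality.
#'
#' @param n_boats Number of boats (default 5,000).
#' @param c Aggregation parameter, integer 1-5 (default 3): larger values
#'   concentrate effort more strongly on density hotspots.
#' @param F_annual Target mean annual fishing mortality (default 1.27 / y).
#' @param q_scale Catchability scaling factor; `NA` until calibrated with
#'   [calibrate_catchability()].
#' @return A `fleet_params` object.
#' @export
fleet_params <- function(n_boats = 5000, c = 3L, F_annual = 1.27,
                         q_scale = NA_real_) {
  stopifnot(n_boats > 0, F_annual >= 0)
  if (!(c %in% 1:5)) stop("aggregation parameter c must be in 1..5", call. = FALSE)
  if (!is.na(q_scale) && q_scale <= 0)
    stop("q_scale must be positive", call. = FALSE)
  structure(list(n_boats = n_boats, c = as.integer(c), F_annual = F_annual,
                 q_scale = q_scale), class = "fleet_params")
}

#' Relative fishing effort per sector
#'
#' On open sectors `B' = exp(-c * (1 - N/M))` where `N` is the sector's
#' adult count and `M` the maximum adult count over open sectors; closed
#' (MPA) sectors get zero. When no open sector holds any fish the formula's
#' own limit is uniform effort `exp(-c)` over the open area.
#'
#' @param adult_counts nx x ny matrix of adult counts per sector.
#' @param mpa_mask Logical nx x ny matrix, `TRUE` on closed sectors.
#' @param c Aggregation parameter.
#' @return nx x ny matrix of relative effort.
#' @export
relative_effort <- function(adult_counts, mpa_mask, c = 3L) {
  stopifnot(all(dim(adult_counts) == dim(mpa_mask)), all(adult_counts >= 0))
  if (all(mpa_mask))
    stop("no open sectors: cannot allocate fishing effort", call. = FALSE)
  M <- max(adult_counts[!mpa_mask])
  rel <- if (M > 0) exp(-c * (1 - adult_counts / M))
         else matrix(exp(-c), nrow(adult_counts), ncol(adult_counts))
  rel[mpa_mask] <- 0
  rel
}

#' Allocate the fleet across sectors
#'
#' `B = n_boats * B' / sum(B')`. Boats are kept fractional (effort
#' density): only the product boats x catchability matters.
#'
#' @param rel Relative effort matrix from [relative_effort()].
#' @param n_boats Fleet size.
#' @return Matrix of boat counts summing to `n_boats`.
#' @export
allocate_boats <- function(rel, n_boats = 5000) {
  s <- sum(rel)
  if (s <= 0) stop("total relative effort is zero", call. = FALSE)
  n_boats * rel / s
}

#' Daily per-fish capture probability
#'
#' Local hazard `h = (F_annual / 365) * boats * q_scale`, converted to a
#' probability `1 - exp(-h)`: homogeneous within a sector, heterogeneous
#' between sectors.
#'
#' @param boats Boat counts (scalar or matrix).
#' @param params A [fleet_params()] with calibrated `q_scale`.
#' @return Capture probability, same shape as `boats`.
#' @export
capture_probability <- function(boats, params) {
  if (any(boats < 0)) stop("negative boat counts", call. = FALSE)
  q <- params$q_scale
  if (is.na(q)) stop("q_scale has not been calibrated", call. = FALSE)
  1 - exp(-(params$F_annual / 365) * boats * q)
}

#' Apply one day of fishing mortality
#'
#' Each alive adult in an open sector dies independently with its sector's
#' capture probability; juveniles, eggs and fish inside the MPA are never
#' caught.
#'
#' @param pop Population data frame with `x`, `y`, `age`, `alive`.
#' @param p_capture nx x ny matrix of per-fish daily capture probabilities
#'   (zero on closed sectors).
#' @param spec A [grid_spec()].
#' @param maturity_age Adult age boundary (days).
#' @return List with updated `pop` and `landings` (number caught).
#' @export
apply_fishing <- function(pop, p_capture, spec, maturity_age = 365L) {
  adults <- which(pop$alive & pop$age >= maturity_age)
  if (!length(adults)) return(list(pop = pop, landings = 0L))
  s <- sector_of(cbind(pop$x[adults], pop$y[adults]), spec)
  p <- p_capture[cbind(s[, "ix"], s[, "iy"])]
  caught <- stats::runif(length(adults)) < p
  pop$alive[adults[caught]] <- FALSE
  list(pop = pop, landings = sum(caught))
}

#' Calibrate the catchability scalar to the target fishing mortality
#'
#' Adjusts `q_scale` by fixed-point iteration until the realized mean
#' annual fishing mortality of a no-MPA run matches `F_annual` within
#' `tol` relative error. The realized mortality is the abundance-weighted
#' mean daily hazard per fish-day over all fished days of the run,
#' annualized -- the "average over space and time" -- computed from the
#' expectation `sum(n_ij * h_ij)`, so binomial catch noise does not enter.
#' Weighting by abundance keeps the measure smooth in `q_scale`: unweighted
#' year-means explode when the stock is nearly gone and boats concentrate
#' on the survivors (that overshoot is the intended overfishing regime,
#' not a calibration error).
#'
#' @param config A [sim_config()]; its `mpa_fraction` is forced to 0.
#' @param seed Integer seed for the calibration runs.
#' @param tol Relative tolerance on the realized F (default 0.02).
#' @param max_iter Iteration cap (default 10).
#' @return List with `q_scale`, `realized_F`, `iterations`, `history`
#'   (data frame of iterates).
#' @export
calibrate_catchability <- function(config, seed = 1L, tol = 0.02,
                                   max_iter = 10L) {
  config$mpa_fraction <- 0
  F_target <- config$fleet$F_annual
  if (F_target == 0)
    return(list(q_scale = 1, realized_F = 0, iterations = 0L,
                history = data.frame()))
  # well-mixed starting point: mean boats/sector * q = 1 -> hazard F/365
  open_sectors <- config$grid$nx * config$grid$ny
  q <- open_sectors / config$fleet$n_boats
  hist <- data.frame(iter = integer(), q_scale = numeric(),
                     realized_F = numeric())
  # the unfished burn-in does not depend on q: compute it once
  ckpt <- NULL
  if (config$schedule$fishing_start >= 1) {
    pre <- config
    pre$fleet$q_scale <- 1
    ckpt <- run_simulation(pre, seed = seed,
                           stop_after_year =
                             config$schedule$fishing_start)$checkpoint
  }
  for (it in seq_len(max_iter)) {
    config$fleet$q_scale <- q
    rec <- run_simulation(config, seed = seed, resume = ckpt)
    F_real <- rec$mean_F
    hist <- rbind(hist, data.frame(iter = it, q_scale = q,
                                   realized_F = F_real))
    if (!is.finite(F_real) || F_real <= 0)
      stop("calibration failed: no realized fishing mortality (is the stock extinct before fishing?)",
           call. = FALSE)
    if (abs(F_real - F_target) / F_target < tol)
      return(list(q_scale = q, realized_F = F_real, iterations = it,
                  history = hist))
    q <- q * F_target / F_real  # realized F is monotone, near-linear in q
  }
  stop(sprintf(
    "catchability calibration did not converge in %d iterations (last realized F = %.3f, target %.3f)",
    max_iter, hist$realized_F[nrow(hist)], F_target), call. = FALSE)
}
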