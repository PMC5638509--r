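#' Grid geometry for the simulated ocean
#'
#' The fishing ground is a rectangle of `nx` by `ny` unit sectors. The sector
#' side is the unit of length throughout the package, so all speeds are in
#' sector/day. Continuous fish positions live in `[0, nx] x [0, ny]`; the
#' sector containing a position is found by flooring each coordinate
#' (half-open sector intervals, upper domain boundary assigned to the last
#' sector).
#'
#' @param nx,ny Number of sectors in x and y (default 100 x 40).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(nx = 100L, ny = 40L) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx <= 0L || ny <= 0L)
    stop("grid dimensions must be positive integers", call. = FALSE)
  structure(list(nx = nx, ny = ny), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d sectors\n", x$nx, x$ny))
  invisible(x)
}

#' Sector index of a continuous position
#'
#' Floor convention with the upper boundary clamped into the last sector.
#' Returns 1-based matrix indices (column `ix`, `iy`).
#'
#' @param q Numeric vector `c(x, y)` or a two-column matrix of positions.
#' @param spec A [grid_spec()].
#' @return Integer matrix with columns `ix`, `iy` in `1..nx`, `1..ny`.
#' @export
sector_of <- function(q, spec) {
  q <- matrix(as.numeric(q), ncol = 2)
  if (any(q[, 1] < 0 | q[, 1] > spec$nx | q[, 2] < 0 | q[, 2] > spec$ny))
    stop("position outside the domain", call. = FALSE)
  ix <- pmin(as.integer(floor(q[, 1])), spec$nx - 1L) + 1L
  iy <- pmin(as.integer(floor(q[, 2])), spec$ny - 1L) + 1L
  cbind(ix = ix, iy = iy)
}

#' Synthesize a gridded environment (SST and currents)
#'
#' Generates sea-surface temperature and surface-current fields with the
#' statistical structure the simulator needs: smooth spatial SST gradients
#' spanning values below, inside and above the thermal preference band
#' `t_pref`, a one-sector frame of extreme (repulsive) border temperatures,
#' and, in `gyre` mode, a smooth recirculating current field whose zonal
#' component takes both signs (eastward and westward flow).
#'
#' Modes:
#' \describe{
#'   \item{`uniform`}{every interior sector at the band midpoint, zero
#'     currents (degenerate field for testing).}
#'   \item{`gradient`}{meridional SST gradient plus smooth seeded
#'     perturbations; zero currents.}
#'   \item{`gyre`}{the `gradient` SST plus a single-gyre current field
#'     derived from a sinusoidal streamfunction (peak speed
#'     `current_max` sector/day).}
#' }
#'
#' @param spec A [grid_spec()].
#' @param t_pref Thermal preference band `c(T1, T2)` in degrees C
#'   (default `c(16, 18)`).
#' @param seed Integer seed controlling the smooth SST perturbations;
#'   the same seed always yields bit-identical fields.
#' @param mode One of `"gradient"`, `"gyre"`, `"uniform"`.
#' @param border_band Width (sectors) of the extreme-temperature frame.
#' @param border_offset Temperature added to the interior maximum on the
#'   border frame; large enough that the taxis response always points
#'   inward there.
#' @param current_max Peak current speed (sector/day) in `gyre` mode.
#' @return An `environment_grid`: list with `spec`, `sst` (nx x ny matrix,
#'   degrees C), `u`, `v` (nx x ny matrices, sector/day), `border_band`.
#' @export
synth_environment <- function(spec, t_pref = c(16, 18), seed = 1L,
                              mode = c("gradient", "gyre", "uniform"),
                              border_band = 1L, border_offset = 100,
                              current_max = 0.1) {
  mode <- match.arg(mode)
  stopifnot(length(t_pref) == 2, t_pref[1] < t_pref[2])
  nx <- spec$nx; ny <- spec$ny
  mid <- mean(t_pref)
  half <- diff(t_pref) / 2
  xs <- (seq_len(nx) - 0.5) / nx   # sector centers, normalized
  ys <- (seq_len(ny) - 0.5) / ny

  if (mode == "uniform") {
    sst <- matrix(mid, nx, ny)
    u <- v <- matrix(0, nx, ny)
  } else {
    # predominantly zonal (cross-shore) gradient, as over an eastern-
    # boundary upwelling system: cold inshore water on one side, warm
    # offshore water on the other, so the comfort band is a meridional
    # corridor; smooth seeded bumps keep isotherms from being straight
    base <- mid + 3.5 * half * cos(pi * xs)
    sst <- matrix(base, nx, ny, byrow = FALSE)
    pert <- withr::with_seed(as.integer(seed), {
      amp <- stats::runif(4, 0.2, 0.5) * half
      kx <- sample(1:3, 4, replace = TRUE)
      ky <- sample(1:3, 4, replace = TRUE)
      ph <- stats::runif(4, 0, 2 * pi)
      p <- matrix(0, nx, ny)
      for (m in 1:4)
        p <- p + amp[m] * outer(sin(2 * pi * kx[m] * xs + ph[m]),
                                cos(2 * pi * ky[m] * ys + ph[m]))
      p
    })
    sst <- sst + pert
    if (mode == "gyre") {
      # streamfunction psi = A sin(pi x/nx) sin(pi y/ny); u = dpsi/dy, v = -dpsi/dx
      A <- current_max * ny / pi
      u <- A * (pi / ny) * outer(sin(pi * xs), cos(pi * ys))
      v <- -A * (pi / nx) * outer(cos(pi * xs), sin(pi * ys))
    } else {
      u <- v <- matrix(0, nx, ny)
    }
  }

  env <- structure(list(spec = spec, sst = sst, u = u, v = v,
                        border_band = as.integer(border_band)),
                   class = "environment_grid")
  apply_border_band(env, border_offset)
}

# Set the border frame to interior max + offset so grad r points inward there.
apply_border_band <- function(env, border_offset = 100) {
  b <- env$border_band
  if (b <= 0L) return(env)
  nx <- env$spec$nx; ny <- env$spec$ny
  interior_max <- max(env$sst[(b + 1):(nx - b), (b + 1):(ny - b)])
  extreme <- interior_max + border_offset
  frame <- matrix(FALSE, nx, ny)
  frame[c(seq_len(b), nx - seq_len(b) + 1L), ] <- TRUE
  frame[, c(seq_len(b), ny - seq_len(b) + 1L)] <- TRUE
  env$sst[frame] <- extreme
  env
}

#' Interior (non-border) sector mask of an environment
#' @param env An `environment_grid`.
#' @return Logical nx x ny matrix, `TRUE` on interior sectors.
#' @export
interior_mask <- function(env) {
  nx <- env$spec$nx; ny <- env$spec$ny; b <- env$border_band
  m <- matrix(FALSE, nx, ny)
  m[(b + 1):(nx - b), (b + 1):(ny - b)] <- TRUE
  m
}

#' @export
print.environment_grid <- function(x, ...) {
  int <- x$sst[interior_mask(x)]
  cat(sprintf("<environment_grid> %d x %d; interior SST %.2f-%.2f C; max |current| %.3f sector/d\n",
              x$spec$nx, x$spec$ny, min(int), max(int),
              max(sqrt(x$u^2 + x$v^2))))
  invisible(x)
}

#' Write / read a gridded environment
#'
#' `format = "json"` writes one self-describing container holding the grid
#' dimensions, the border-band width and the three layers (`sst`, `u`, `v`)
#' row-by-row. `format = "csv"` writes a plain-text fallback: `<path>` is
#' used as a prefix and `_sst.csv`, `_u.csv`, `_v.csv`, `_meta.json` files
#' are produced, each layer stored as an nx x ny table (rows = x sectors).
#'
#' @param env An `environment_grid`.
#' @param path Output file (json) or prefix (csv).
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly (writer); an `environment_grid` (reader).
#' @export
write_environment <- function(env, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(nx = env$spec$nx, ny = env$spec$ny,
                border_band = env$border_band,
                sst = env$sst, u = env$u, v = env$v)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                         matrix = "rowmajor")
  } else {
    meta <- list(nx = env$spec$nx, ny = env$spec$ny,
                 border_band = env$border_band, layers = c("sst", "u", "v"))
    jsonlite::write_json(meta, paste0(path, "_meta.json"), auto_unbox = TRUE)
    for (layer in c("sst", "u", "v"))
      utils::write.table(env[[layer]], paste0(path, "_", layer, ".csv"),
                         sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_environment
#' @export
read_environment <- function(path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    nx <- as.integer(obj$nx); ny <- as.integer(obj$ny)
    layers <- lapply(obj[c("sst", "u", "v")], function(m) {
      if (is.null(m) || !is.matrix(m))
        stop("environment file is missing a layer", call. = FALSE)
      m
    })
  } else {
    meta <- jsonlite::read_json(paste0(path, "_meta.json"), simplifyVector = TRUE)
    nx <- as.integer(meta$nx); ny <- as.integer(meta$ny)
    layers <- lapply(c("sst", "u", "v"), function(layer) {
      f <- paste0(path, "_", layer, ".csv")
      if (!file.exists(f)) stop("environment file is missing a layer", call. = FALSE)
      as.matrix(utils::read.table(f, sep = ",", header = FALSE))
    })
    names(layers) <- c("sst", "u", "v")
    bb <- meta$border_band
    obj <- list(border_band = bb)
  }
  for (m in layers)
    if (!all(dim(m) == c(nx, ny)))
      stop(sprintf("layer shape %d x %d does not match grid %d x %d",
                   nrow(m), ncol(m), nx, ny), call. = FALSE)
  env <- structure(list(spec = grid_spec(nx, ny), sst = layers$sst,
                        u = layers$u, v = layers$v,
                        border_band = as.integer(obj$border_band)),
                   class = "environment_grid")
  dimnames(env$sst) <- dimnames(env$u) <- dimnames(env$v) <- NULL
  if (any(!is.finite(env$sst[interior_mask(env)])) ||
      any(!is.finite(env$u)) || any(!is.finite(env$v)))
    stop("non-finite values in interior environment layers", call. = FALSE)
  env
}

#' Sample the current vector at a continuous position
#'
#' Nearest-sector lookup (floor convention): the current is the per-sector
#' value of the sector containing `q`. Units sector/day.
#'
#' @param env An `environment_grid`.
#' @param q Position `c(x, y)`.
#' @return Numeric `c(u, v)`.
#' @export
sample_current <- function(env, q) {
  s <- sector_of(q, env$spec)
  c(env$u[s[1, "ix"], s[1, "iy"]], env$v[s[1, "ix"], s[1, "iy"]])
}

#' Sample the temperature at a continuous position
#' @inheritParams sample_current
#' @return Temperature (degrees C) of the sector containing `q`.
#' @export
sample_sst <- function(env, q) {
  s <- sector_of(q, env$spec)
  env$sst[s[1, "ix"], s[1, "iy"]]
}

#' Thermal discomfort function r(T)
#'
#' Zero inside the preference band, and a downward quadratic penalty
#' outside: `-(T - T1)^2` below the band, `-(T - T2)^2` above. Continuous
#' at both band edges and always <= 0. Fish climb the gradient of r, i.e.
#' move toward comfortable temperatures.
#'
#' @param temp Temperature(s), degrees C.
#' @param t_pref Preference band `c(T1, T2)`.
#' @return Numeric vector, same length as `temp`.
#' @export
temp_response <- function(temp, t_pref = c(16, 18)) {
  ifelse(temp < t_pref[1], -(temp - t_pref[1])^2,
         ifelse(temp > t_pref[2], -(temp - t_pref[2])^2, 0))
}

# Per-sector normalized gradient of r(T): central differences in the
# interior, one-sided at the grid edges; cells where |grad| < tol get the
# zero vector. Returns list(gx, gy) of nx x ny matrices.
temp_gradient_field <- function(env, t_pref = c(16, 18), tol = 1e-12) {
  r <- temp_response(env$sst, t_pref)
  nx <- env$spec$nx; ny <- env$spec$ny
  gx <- matrix(0, nx, ny); gy <- matrix(0, nx, ny)
  if (nx >= 2) {
    gx[1, ] <- r[2, ] - r[1, ]
    gx[nx, ] <- r[nx, ] - r[nx - 1, ]
    if (nx >= 3) gx[2:(nx - 1), ] <- (r[3:nx, ] - r[1:(nx - 2), ]) / 2
  }
  if (ny >= 2) {
    gy[, 1] <- r[, 2] - r[, 1]
    gy[, ny] <- r[, ny] - r[, ny - 1]
    if (ny >= 3) gy[, 2:(ny - 1)] <- (r[, 3:ny] - r[, 1:(ny - 2)]) / 2
  }
  nrm <- sqrt(gx^2 + gy^2)
  keep <- nrm > tol
  gx[keep] <- gx[keep] / nrm[keep]; gx[!keep] <- 0
  gy[keep] <- gy[keep] / nrm[keep]; gy[!keep] <- 0
  list(gx = gx, gy = gy)
}

#' Temperature-taxis response at a position
#'
#' The normalized spatial gradient of the discomfort function [temp_response()]
#' evaluated at the sector containing `q` (central finite differences on the
#' grid, one-sided at edges). Returns the zero vector where the gradient
#' norm is below `tol`, in particular anywhere on the comfort plateau
#' `T1 <= T <= T2`.
#'
#' @inheritParams sample_current
#' @param t_pref Preference band `c(T1, T2)`.
#' @param tol Gradient-norm tolerance below which the response is zero.
#' @return Unit vector `c(gx, gy)` or `c(0, 0)`.
#' @export
temp_gradient_response <- function(env, q, t_pref = c(16, 18), tol = 1e-12) {
  g <- temp_gradient_field(env, t_pref, tol)
  s <- sector_of(q, env$spec)
  c(g$gx[s[1, "ix"], s[1, "iy"]], g$gy[s[1, "ix"], s[1, "iy"]])
}
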