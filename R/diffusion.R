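#' @useDynLib rspaquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Unit conventions, fixed package-wide: lengths in micrometres, time in
# seconds, concentration in nanomolar, amounts in femtomoles.
# 1 nM = 1e-24 mol / um^3, 1 fmol = 1e-15 mol, hence
# C[nM] = amount[fmol] * 1e9 / V[um^3].
.NM_PER_FMOL_UM3 <- 1e9

#' Configuration for the axisymmetric diffusion simulation
#'
#' Describes one simulation of an instantaneous release of PGE2 from a
#' single cell sitting at the bottom of a culture dish. The medium above
#' the dish is modelled as an axisymmetric cylinder (coordinates `r`, `z`)
#' with a reflecting bottom and symmetry axis and an open (zero
#' concentration) far field at `r_max` and `z_max`.
#'
#' @param D diffusion constant (um^2/s). Default 500, the rounded value for
#'   fluorescein, a molecule of similar weight to PGE2.
#' @param r_max,z_max radial and axial domain size (um). Defaults 1500 and
#'   1000 um keep the open boundaries invisible over a few minutes for
#'   releases up to about 1 fmol; results for larger releases or longer
#'   times depend on them, so they are explicit configuration.
#' @param dr,dz grid spacings (um); must divide `r_max`/`z_max`.
#' @param dt time step (s). `NULL` (default) derives 0.4 times the explicit
#'   stability bound `0.5 / (D * (1/dr^2 + 1/dz^2))`; a supplied value
#'   exceeding the bound is rejected.
#' @param t_end simulated duration (s).
#' @param Q released amount (fmol).
#' @param source_extent radius (um) of the initial hemispherical deposit at
#'   the origin; `0` (default) deposits the whole amount into the single
#'   grid cell at `(r = 0, z = 0)`.
#' @param C_thresh contour concentration (nM) used when extracting
#'   threshold radii. Default 1.35, the PGE2 concentration matched to a 20
#'   percent FRET ratio increase of the reporter.
#' @return An object of class `diffusion_config` (a validated list).
#' @seealso [solve_diffusion()], [contour_trace()], [build_calibration()]
#' @export
#' @examples
#' cfg <- diffusion_config(Q = 0.25, t_end = 60)
#' cfg$dt
diffusion_config <- function(D = 500, r_max = 1500, z_max = 1000,
                             dr = 5, dz = 5, dt = NULL, t_end = 120,
                             Q = 0.25, source_extent = 0, C_thresh = 1.35) {
  num1 <- function(x, nm, strict = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        (strict && x <= 0) || (!strict && x < 0))
      stop(sprintf("'%s' must be a %s finite number", nm,
                   if (strict) "positive" else "non-negative"), call. = FALSE)
    as.numeric(x)
  }
  D <- num1(D, "D"); r_max <- num1(r_max, "r_max"); z_max <- num1(z_max, "z_max")
  dr <- num1(dr, "dr"); dz <- num1(dz, "dz"); t_end <- num1(t_end, "t_end")
  Q <- num1(Q, "Q", strict = FALSE)
  source_extent <- num1(source_extent, "source_extent", strict = FALSE)
  C_thresh <- num1(C_thresh, "C_thresh")
  if (abs(r_max / dr - round(r_max / dr)) > 1e-8 ||
      abs(z_max / dz - round(z_max / dz)) > 1e-8)
    stop("'r_max'/'dr' and 'z_max'/'dz' must be integral", call. = FALSE)
  bound <- 0.5 / (D * (1 / dr^2 + 1 / dz^2))
  if (is.null(dt)) {
    dt <- 0.4 * bound
  } else {
    dt <- num1(dt, "dt")
    if (dt > bound * (1 + 1e-12))
      stop(sprintf(
        "unstable time step: dt = %g exceeds the explicit stability bound %g s",
        dt, bound), call. = FALSE)
  }
  structure(list(D = D, r_max = r_max, z_max = z_max, dr = dr, dz = dz,
                 dt = dt, t_end = t_end, Q = Q,
                 source_extent = source_extent, C_thresh = C_thresh),
            class = "diffusion_config")
}

#' @export
print.diffusion_config <- function(x, ...) {
  cat("Axisymmetric diffusion configuration\n")
  cat(sprintf("  D = %g um^2/s, domain r <= %g um, z <= %g um\n",
              x$D, x$r_max, x$z_max))
  cat(sprintf("  grid dr = %g, dz = %g um; dt = %.5g s; t_end = %g s\n",
              x$dr, x$dz, x$dt, x$t_end))
  cat(sprintf("  release Q = %g fmol (source extent %g um); contour %g nM\n",
              x$Q, x$source_extent, x$C_thresh))
  invisible(x)
}

# node quadrature weights of the finite-volume grid: the axis node is a disc
# of radius dr/2, reflecting faces carry half cells, open-boundary nodes are
# held at zero so their weight is irrelevant.
.node_volumes <- function(nr, nz, dr, dz) {
  r <- (seq_len(nr) - 1) * dr
  a <- 2 * pi * r * dr
  a[1] <- pi * (dr / 2)^2
  h <- rep(dz, nz)
  h[1] <- dz / 2
  outer(a, h)
}

.initial_field <- function(cfg) {
  nr <- as.integer(round(cfg$r_max / cfg$dr)) + 1L
  nz <- as.integer(round(cfg$z_max / cfg$dz)) + 1L
  C0 <- matrix(0, nr, nz)
  vol <- .node_volumes(nr, nz, cfg$dr, cfg$dz)
  if (cfg$source_extent <= 0) {
    C0[1, 1] <- cfg$Q * .NM_PER_FMOL_UM3 / vol[1, 1]
  } else {
    r <- (seq_len(nr) - 1) * cfg$dr
    z <- (seq_len(nz) - 1) * cfg$dz
    inside <- outer(r^2, z^2, `+`) <= cfg$source_extent^2
    inside[nr, ] <- FALSE; inside[, nz] <- FALSE
    if (!any(inside)) inside[1, 1] <- TRUE
    C0[inside] <- cfg$Q * .NM_PER_FMOL_UM3 / sum(vol[inside])
  }
  C0
}

#' Solve the axisymmetric diffusion equation for a point release
#'
#' Integrates `dC/dt = D (d2C/dr2 + (1/r) dC/dr + d2C/dz2)` with a
#' reflecting dish bottom (`dC/dz = 0` at `z = 0`), a reflecting symmetry
#' axis (`dC/dr = 0` at `r = 0`, with the `1/r` term replaced by its
#' symmetric limit), zero concentration at `z = z_max` and `r = r_max`, and
#' an initial condition of total amount `Q` deposited at the origin. The
#' explicit scheme is run at the configured `dt` and snapshots are returned
#' at the requested output times.
#'
#' @param config a [diffusion_config()].
#' @param output_times times (s) at which to return the field; rounded to
#'   the nearest time step. Default `config$t_end`.
#' @return An object of class `concentration_fields`: a list of
#'   `concentration_field` objects (fields `values` (nM, r-by-z), `t`,
#'   `dr`, `dz`), with the configuration attached as an attribute.
#' @export
#' @examples
#' cfg <- diffusion_config(r_max = 600, z_max = 400, dr = 10, dz = 10,
#'                         Q = 0.25, t_end = 30)
#' fld <- solve_diffusion(cfg, output_times = 30)[[1]]
#' total_amount(fld)  # close to 0.25 fmol
solve_diffusion <- function(config, output_times = config$t_end) {
  stopifnot(inherits(config, "diffusion_config"))
  output_times <- sort(unique(as.numeric(output_times)))
  if (any(output_times < 0) || any(output_times > config$t_end + 1e-9))
    stop("output times must lie in [0, t_end]", call. = FALSE)
  steps <- as.integer(round(output_times / config$dt))
  res <- .ftcs_run(.initial_field(config), config$D, config$dr, config$dz,
                   config$dt, max(steps), steps, 0L)
  fields <- mapply(function(m, s) {
    structure(list(values = m, t = s * config$dt,
                   dr = config$dr, dz = config$dz),
              class = "concentration_field")
  }, res$snapshots, steps, SIMPLIFY = FALSE)
  structure(fields, class = "concentration_fields", config = config)
}

#' Total amount of substance in a simulated field
#'
#' Discrete volume integral of the concentration over the cylindrical
#' domain, using the finite-volume node weights of the solver (the axis
#' node is a disc of radius `dr/2`; the reflecting faces at `z = 0` carry
#' half cells). By construction the scheme conserves this integral exactly
#' up to the flux lost through the open boundaries, so the result never
#' exceeds the released amount.
#'
#' @param field a `concentration_field`.
#' @return Amount in fmol.
#' @export
total_amount <- function(field) {
  stopifnot(inherits(field, "concentration_field"))
  vol <- .node_volumes(nrow(field$values), ncol(field$values),
                       field$dr, field$dz)
  sum(field$values * vol) / .NM_PER_FMOL_UM3
}

#' Closed-form half-space solution for an instantaneous point release
#'
#' Green's function of the diffusion equation for an instantaneous point
#' source on a reflecting plane: the free-space Gaussian doubled by the
#' image source,
#' `C(r, z, t) = 2 Q / (4 pi D t)^(3/2) * exp(-(r^2 + z^2) / (4 D t))`.
#' Serves as the independent oracle for the finite-difference solver while
#' the open boundaries are out of reach.
#'
#' @param Q released amount (fmol).
#' @param D diffusion constant (um^2/s).
#' @param r,z cylindrical coordinates (um); vectorized.
#' @param t time since release (s), strictly positive.
#' @return Concentration in nM.
#' @export
#' @examples
#' analytic_halfspace(0.25, 500, r = 110, z = 0, t = 30)  # about 5 nM
analytic_halfspace <- function(Q, D = 500, r, z = 0, t) {
  if (any(t <= 0)) stop("'t' must be strictly positive", call. = FALSE)
  if (any(Q < 0) || any(D <= 0)) stop("'Q' must be >= 0 and 'D' > 0", call. = FALSE)
  2 * Q * .NM_PER_FMOL_UM3 / (4 * pi * D * t)^1.5 *
    exp(-(r^2 + z^2) / (4 * D * t))
}

#' Radius of the threshold concentration contour at the dish bottom
#'
#' Outermost radius at `z = 0` where the concentration is at or above
#' `C_thresh`, linearly interpolated between grid nodes. Returns 0 when the
#' field is nowhere above threshold, and the domain radius when the whole
#' bottom row is above it.
#'
#' @param field a `concentration_field`.
#' @param C_thresh contour concentration (nM).
#' @return Radius in um.
#' @export
contour_radius <- function(field, C_thresh) {
  stopifnot(inherits(field, "concentration_field"))
  if (!is.numeric(C_thresh) || length(C_thresh) != 1L || C_thresh <= 0)
    stop("'C_thresh' must be a positive number", call. = FALSE)
  .contour_radius_row(field$values[, 1], field$dr, C_thresh)
}

.contour_radius_row <- function(v, dr, thresh) {
  idx <- which(v >= thresh)
  if (length(idx) == 0L) return(0)
  i <- max(idx)
  if (i == length(v)) return((i - 1) * dr)
  (i - 1) * dr + dr * (v[i] - thresh) / (v[i] - v[i + 1])
}

#' Threshold-contour radius across time
#'
#' Runs the solver and records the radius of the `C_thresh` contour at the
#' dish bottom at a regular sampling interval. The radius is 0 before the
#' concentration first reaches the threshold and again after the field has
#' everywhere decayed below it.
#'
#' @param config a [diffusion_config()]; `config$C_thresh` sets the contour.
#' @param sample_interval sampling interval (s), default 1 s. 60 s mimics a
#'   1-min imaging cadence.
#' @return A data frame with columns `time` (s) and `radius` (um), of class
#'   `contour_trace`.
#' @export
contour_trace <- function(config, sample_interval = 1) {
  stopifnot(inherits(config, "diffusion_config"))
  if (sample_interval <= 0) stop("'sample_interval' must be positive", call. = FALSE)
  every <- max(1L, as.integer(round(sample_interval / config$dt)))
  n_steps <- as.integer(round(config$t_end / config$dt))
  res <- .ftcs_run(.initial_field(config), config$D, config$dr, config$dz,
                   config$dt, n_steps, integer(0), every)
  radius <- apply(res$bottom, 1L, .contour_radius_row,
                  dr = config$dr, thresh = config$C_thresh)
  # drop the release instant itself: at t = 0 the whole deposit sits in the
  # source cell, which is above any threshold for any Q and carries no
  # information about the observable spread
  keep <- res$bottom_times > 0
  res$bottom_times <- res$bottom_times[keep]
  radius <- radius[keep]
  structure(data.frame(time = res$bottom_times, radius = radius),
            class = c("contour_trace", "data.frame"), config = config)
}

#' Maximum threshold-contour radius over the observation
#'
#' The maximum over time of [contour_trace()]; with the default 1-s
#' sampling this approximates the continuous maximum. This is the quantity
#' the amount-to-radius calibration tabulates.
#'
#' @inheritParams contour_trace
#' @return Maximum contour radius (um); 0 when the release never brings the
#'   field above `C_thresh`.
#' @export
max_contour_radius <- function(config, sample_interval = 1) {
  max(contour_trace(config, sample_interval)$radius)
}

#' Build the amount-to-radius calibration curve
#'
#' Runs one diffusion simulation per released amount and records the
#' maximum radius of the threshold contour during the observation window.
#' The resulting monotone curve converts an observed maximum event radius
#' back into the amount discharged (see [radius_to_amount()]).
#'
#' @param config_base a [diffusion_config()]; its `Q` is replaced by each
#'   entry of `amounts`.
#' @param amounts strictly increasing released amounts (fmol), at least two.
#' @param sample_interval sampling interval (s) of the radius search.
#' @return An object of class `rspa_calibration`: a data frame with columns
#'   `amount_fmol` and `max_radius_um`, the configuration attached.
#' @export
#' @examples
#' \donttest{
#' cfg <- diffusion_config(t_end = 60)
#' cal <- build_calibration(cfg, amounts = c(0.1, 0.2, 0.4))
#' }
build_calibration <- function(config_base, amounts, sample_interval = 1) {
  stopifnot(inherits(config_base, "diffusion_config"))
  amounts <- as.numeric(amounts)
  if (length(amounts) < 2L || any(diff(amounts) <= 0) || any(amounts <= 0))
    stop("'amounts' must be >= 2 strictly increasing positive values",
         call. = FALSE)
  radii <- vapply(amounts, function(q) {
    cfg <- config_base
    cfg$Q <- q
    max_contour_radius(cfg, sample_interval)
  }, numeric(1))
  if (any(diff(radii) < 0))
    stop("calibration radii are not monotone in the released amount; ",
         "this indicates insufficient numerical resolution (refine the ",
         "grid or the sampling interval)", call. = FALSE)
  structure(data.frame(amount_fmol = amounts, max_radius_um = radii),
            class = c("rspa_calibration", "data.frame"),
            config = config_base)
}

#' @export
print.rspa_calibration <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "Amount-to-radius calibration (%d amounts, D = %g um^2/s, C* = %g nM)\n",
    nrow(x), cfg$D, cfg$C_thresh))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.rspa_calibration <- function(x, ...) {
  graphics::plot(x$amount_fmol, x$max_radius_um, log = "xy", type = "b",
                 xlab = "released amount (fmol)",
                 ylab = "maximum contour radius (um)", ...)
  invisible(x)
}

#' Write / read a calibration curve as CSV
#'
#' @param x an `rspa_calibration`.
#' @param path file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns an `rspa_calibration` (without the originating configuration).
#' @export
write_calibration <- function(x, path) {
  stopifnot(inherits(x, "rspa_calibration"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("amount_fmol", "max_radius_um") %in% names(df)))
    stop("calibration CSV needs columns 'amount_fmol' and 'max_radius_um'",
         call. = FALSE)
  if (any(diff(df$amount_fmol) <= 0))
    stop("calibration amounts must be strictly increasing", call. = FALSE)
  structure(df[c("amount_fmol", "max_radius_um")],
            class = c("rspa_calibration", "data.frame"))
}
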