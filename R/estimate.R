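#' Convert an observed maximum event radius into a released amount
#'
#' Monotone piecewise-linear interpolation of the simulated calibration
#' curve, inverted from radius to amount. A radius below the smallest
#' calibrated radius is reported as amount 0 with a `below_calibration`
#' flag (the smallest calibrated amount is then an upper bound); a radius
#' above the largest calibrated radius is refused rather than
#' extrapolated and reported as NA with an `above_calibration` flag.
#'
#' @param radius observed maximum radii (um), vectorized, >= 0.
#' @param curve an `rspa_calibration` (see [build_calibration()],
#'   [read_calibration()]); its radii must be non-decreasing.
#' @return A data frame with columns `radius_um`, `amount_fmol`, `flag`
#'   (`"ok"`, `"below_calibration"`, `"above_calibration"`).
#' @export
radius_to_amount <- function(radius, curve) {
  if (!is.data.frame(curve) ||
      !all(c("amount_fmol", "max_radius_um") %in% names(curve)))
    stop("'curve' must be a calibration with 'amount_fmol' and 'max_radius_um'",
         call. = FALSE)
  if (any(diff(curve$amount_fmol) <= 0) || any(diff(curve$max_radius_um) < 0))
    stop("calibration curve must be monotone (amounts strictly increasing, ",
         "radii non-decreasing)", call. = FALSE)
  radius <- as.numeric(radius)
  if (any(radius < 0)) stop("'radius' must be >= 0", call. = FALSE)
  # keep the first node of any flat (duplicated-radius) run so the inverse
  # map stays single-valued and conservative (smallest amount)
  keep <- !duplicated(curve$max_radius_um)
  x <- curve$max_radius_um[keep]
  y <- curve$amount_fmol[keep]
  amount <- rep(NA_real_, length(radius))
  flag <- rep("ok", length(radius))
  below <- radius < min(x)
  above <- radius > max(x)
  flag[below] <- "below_calibration"
  flag[above] <- "above_calibration"
  amount[below] <- 0
  inside <- !below & !above
  if (any(inside)) {
    if (length(x) < 2L)
      stop("calibration has fewer than two distinct radii", call. = FALSE)
    amount[inside] <- stats::approx(x, y, xout = radius[inside],
                                    ties = "ordered")$y
  }
  data.frame(radius_um = radius, amount_fmol = amount, flag = flag)
}

#' Number of cells inside a PKA-activated disc
#'
#' `pi * radius^2 / cell_area`, optionally rounded to a number of
#' significant figures for reporting (e.g. "about 1000 cells").
#'
#' @param radius disc radius (um), vectorized, >= 0.
#' @param cell_area area of a single cell (um^2), default 200.
#' @param sig_figs optional significant figures for rounding.
#' @return Cell counts (numeric).
#' @export
#' @examples
#' cells_covered(250)                 # 981.7...
#' cells_covered(250, sig_figs = 1)   # 1000
cells_covered <- function(radius, cell_area = 200, sig_figs = NULL) {
  if (any(radius < 0)) stop("'radius' must be >= 0", call. = FALSE)
  if (cell_area <= 0) stop("'cell_area' must be positive", call. = FALSE)
  n <- pi * radius^2 / cell_area
  if (!is.null(sig_figs)) n <- signif(n, sig_figs)
  n
}

#' Bulk-assay amount per cell
#'
#' Divides a total released amount (in moles, as reported by an ELISA of
#' the pooled medium) by the number of cells, returning femtomoles per
#' cell.
#'
#' @param total_amount_mol total released amount (mol).
#' @param n_cells number of cells (> 0).
#' @return fmol per cell.
#' @export
#' @examples
#' per_cell_amount(300e-12, 1e6)  # 300 pmol over 1e6 cells -> 0.3 fmol/cell
per_cell_amount <- function(total_amount_mol, n_cells) {
  if (any(n_cells <= 0)) stop("'n_cells' must be positive", call. = FALSE)
  if (any(total_amount_mol < 0))
    stop("'total_amount_mol' must be >= 0", call. = FALSE)
  total_amount_mol * 1e15 / n_cells
}

#' Estimate discharged amounts for a set of tracked events
#'
#' Applies [radius_to_amount()] to every event's maximum radius and
#' summarises the result, including the number of cells a disc of the
#' mean maximum radius covers.
#'
#' @param stats an `rspa_event_stats` (from [event_statistics()]) or an
#'   `rspa_events` data frame.
#' @param curve an `rspa_calibration`.
#' @param cell_area single-cell area (um^2) for the coverage count.
#' @return An object of class `rspa_estimate`: list with `events` (per
#'   event: radius, amount, flag) and `summary` (n events, mean amount
#'   over unflagged events, mean diameter, cells covered at the mean
#'   radius).
#' @export
estimate_amounts <- function(stats, curve, cell_area = 200) {
  if (inherits(stats, "rspa_events") ||
      (is.data.frame(stats) && "radius_um" %in% names(stats)))
    stats <- event_statistics(stats)
  stopifnot(inherits(stats, "rspa_event_stats"))
  per <- stats$events
  est <- radius_to_amount(per$max_radius_um, curve)
  events <- cbind(per[c("event_id", "birth_frame", "max_radius_um",
                        "diameter_um")],
                  est[c("amount_fmol", "flag")])
  ok <- events$flag == "ok"
  summary <- data.frame(
    n_events = nrow(events),
    n_quantified = sum(ok),
    mean_amount_fmol = if (any(ok)) mean(events$amount_fmol[ok]) else NA_real_,
    mean_diameter_um = if (nrow(events)) mean(events$diameter_um) else NA_real_,
    cells_covered = if (nrow(events))
      cells_covered(mean(events$max_radius_um), cell_area) else NA_real_)
  structure(list(events = events, summary = summary),
            class = "rspa_estimate")
}

#' @export
print.rspa_estimate <- function(x, ...) {
  s <- x$summary
  if (s$n_events == 0L) {
    cat("No events to estimate\n")
    return(invisible(x))
  }
  cat(sprintf(
    "%d event(s), %d quantified; mean amount %.3g fmol; mean diameter %.1f um; about %.3g cells covered\n",
    s$n_events, s$n_quantified, s$mean_amount_fmol, s$mean_diameter_um,
    s$cells_covered))
  invisible(x)
}
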