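#' Ratio stack container
#'
#' A time-lapse of FRET ratio images (fold-change units) with the spatial
#' and temporal metadata every downstream step needs. Image frames are
#' `H x W` matrices indexed `[y, x]`; pixel centres map to physical
#' coordinates `x_um = (col - 0.5) * pixel_size`, y likewise, with the
#' origin at the top-left corner.
#'
#' @param values array of dimension `c(H, W, T)`; values must be positive
#'   (NA marks masked pixels).
#' @param pixel_size pixel edge (um).
#' @param frame_interval time between frames (s).
#' @return An object of class `ratio_stack`.
#' @export
ratio_stack <- function(values, pixel_size, frame_interval) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (any(values <= 0, na.rm = TRUE))
    stop("ratio values must be positive", call. = FALSE)
  if (!is.numeric(pixel_size) || pixel_size <= 0 ||
      !is.numeric(frame_interval) || frame_interval <= 0)
    stop("'pixel_size' and 'frame_interval' must be positive", call. = FALSE)
  structure(list(values = values, pixel_size = as.numeric(pixel_size),
                 frame_interval = as.numeric(frame_interval)),
            class = "ratio_stack")
}

#' @export
print.ratio_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "ratio_stack: %d frames of %d x %d px (%.3g um/px, %.3g s/frame)\n",
    d[3], d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Detection parameters for radial PKA activation events
#'
#' @param binarize_fold threshold on the normalized ratio (fold change
#'   over the pixel's temporal minimum). Default 1.20, i.e. a 20 percent
#'   FRET ratio increase.
#' @param open_radius,close_radius structuring-element radii (um) for the
#'   morphological opening and closing that refine the binary mask. `NA`
#'   (default) uses 3 pixels at the stack's pixel size.
#' @param min_radius detection limit (um): regions whose equivalent circle
#'   radius falls below it are discarded. Default 33 um.
#' @param link_distance maximum distance (um) between centres in
#'   successive frames for two regions to count as the same event.
#'   Default 100 um.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(binarize_fold = 1.20, open_radius = NA,
                             close_radius = NA, min_radius = 33,
                             link_distance = 100) {
  if (binarize_fold <= 1) stop("'binarize_fold' must exceed 1", call. = FALSE)
  if (min_radius < 0) stop("'min_radius' must be >= 0", call. = FALSE)
  if (link_distance <= 0) stop("'link_distance' must be positive", call. = FALSE)
  for (r in list(open_radius, close_radius))
    if (!is.na(r) && r < 0) stop("morphology radii must be >= 0", call. = FALSE)
  structure(list(binarize_fold = binarize_fold, open_radius = open_radius,
                 close_radius = close_radius, min_radius = min_radius,
                 link_distance = link_distance),
            class = "detection_config")
}

.smooth_frame <- function(m, method, sigma_px) {
  switch(method,
         none = m,
         median = .median3x3(m),
         gaussian = {
           brush <- EBImage::makeBrush(2L * ceiling(2 * sigma_px) + 1L,
                                       shape = "Gaussian", sigma = sigma_px)
           EBImage::filter2(m, brush)
         },
         stop("unknown smoothing method: ", method, call. = FALSE))
}

#' Build a background-corrected ratio stack from raw channels
#'
#' Subtracts the background from both channels, applies a small noise
#' reduction filter to each frame (3x3 median by default), and forms the
#' per-pixel acceptor/donor ratio. Pixels whose background-corrected donor
#' (or acceptor) is not positive are masked with NA; a frame that is
#' entirely masked is an error.
#'
#' @param donor,acceptor raw intensity stacks, arrays `c(H, W, T)` (or
#'   matrices for a single frame) of equal dimension.
#' @param background scalar offset or an `H x W` matrix, subtracted from
#'   both channels. Must lie below the signal.
#' @param pixel_size,frame_interval stack metadata (um, s).
#' @param smooth noise-reduction filter: `"median"` (3x3, default),
#'   `"gaussian"`, or `"none"`.
#' @param sigma Gaussian sigma in pixels (only for `smooth = "gaussian"`).
#' @return A [ratio_stack()].
#' @export
preprocess <- function(donor, acceptor, background = 0, pixel_size,
                       frame_interval, smooth = c("median", "gaussian", "none"),
                       sigma = 1) {
  smooth <- match.arg(smooth)
  if (is.matrix(donor)) donor <- array(donor, c(dim(donor), 1L))
  if (is.matrix(acceptor)) acceptor <- array(acceptor, c(dim(acceptor), 1L))
  if (!identical(dim(donor), dim(acceptor)))
    stop("donor and acceptor stacks must have identical dimensions",
         call. = FALSE)
  nt <- dim(donor)[3]
  out <- array(NA_real_, dim(donor))
  n_masked <- 0L
  for (k in seq_len(nt)) {
    d <- donor[, , k] - background
    a <- acceptor[, , k] - background
    d <- .smooth_frame(d, smooth, sigma)
    a <- .smooth_frame(a, smooth, sigma)
    bad <- !(d > 0 & a > 0)
    n_masked <- n_masked + sum(bad)
    if (all(bad))
      stop(sprintf(
        "frame %d is entirely masked after background subtraction", k),
        call. = FALSE)
    r <- a / d
    r[bad] <- NA_real_
    out[, , k] <- r
  }
  if (n_masked > 0L)
    warning(sprintf(
      "%d pixel(s) had non-positive background-corrected intensity and were masked",
      n_masked), call. = FALSE)
  ratio_stack(out, pixel_size, frame_interval)
}

#' Normalize a ratio stack by its temporal minimum projection
#'
#' Divides every pixel trace by its own minimum over time, so each pixel's
#' minimum over the movie becomes exactly 1 and values are fold changes
#' over the pixel's quietest moment. This is the normalization applied
#' before binarizing radial PKA activation events.
#'
#' @param stack a [ratio_stack()] with at least 2 frames.
#' @return A normalized [ratio_stack()].
#' @export
normalize_by_min_projection <- function(stack) {
  stopifnot(inherits(stack, "ratio_stack"))
  if (dim(stack$values)[3] < 2L)
    stop("need at least 2 frames to form a minimum projection", call. = FALSE)
  mp <- apply(stack$values, c(1, 2), min, na.rm = TRUE)
  mp[!is.finite(mp)] <- NA_real_
  out <- sweep(stack$values, c(1, 2), mp, `/`)
  ratio_stack(out, stack$pixel_size, stack$frame_interval)
}

.brush_radius_px <- function(radius_um, pixel_size) {
  if (is.na(radius_um)) return(3L)
  as.integer(round(radius_um / pixel_size))
}

.disc_brush <- function(radius_px) {
  EBImage::makeBrush(2L * max(radius_px, 0L) + 1L, shape = "disc")
}

#' Segment radial PKA activation areas in one normalized frame
#'
#' Binarizes a normalized ratio frame at `binarize_fold`, refines the mask
#' by morphological opening then closing with disc structuring elements,
#' labels 8-connected components, and measures each region's centroid and
#' equivalent circle radius `sqrt(area / pi)`. Regions below the
#' `min_radius` detection limit are discarded.
#'
#' @param frame an `H x W` normalized ratio matrix (NA treated as below
#'   threshold).
#' @param cfg a [detection_config()].
#' @param pixel_size pixel edge (um).
#' @return A data frame with one row per region: `x_um`, `y_um`,
#'   `radius_um`, `area_px`.
#' @export
segment_frame <- function(frame, cfg, pixel_size) {
  stopifnot(is.matrix(frame), inherits(cfg, "detection_config"))
  mask <- !is.na(frame) & frame >= cfg$binarize_fold
  r_open <- .brush_radius_px(cfg$open_radius, pixel_size)
  r_close <- .brush_radius_px(cfg$close_radius, pixel_size)
  if (any(mask) && r_open > 0L)
    mask <- EBImage::opening(mask, .disc_brush(r_open)) > 0
  if (any(mask) && r_close > 0L)
    mask <- EBImage::closing(mask, .disc_brush(r_close)) > 0
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      radius_um = numeric(0), area_px = numeric(0))
  if (!any(mask)) return(empty)
  lab <- .label8(mask)
  ids <- seq_len(max(lab))
  area <- tabulate(lab[lab > 0], nbins = max(lab))
  row_idx <- row(lab)[lab > 0]; col_idx <- col(lab)[lab > 0]
  labv <- lab[lab > 0]
  cy <- vapply(split(row_idx, labv), mean, numeric(1))
  cx <- vapply(split(col_idx, labv), mean, numeric(1))
  out <- data.frame(x_um = (cx - 0.5) * pixel_size,
                    y_um = (cy - 0.5) * pixel_size,
                    radius_um = sqrt(area[ids] * pixel_size^2 / pi),
                    area_px = area[ids])
  out <- out[out$radius_um >= cfg$min_radius, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Link per-frame regions into events across successive frames
#'
#' Greedy nearest-neighbour association: regions in successive frames
#' whose centres lie within `link_distance` are the same event, closest
#' pairs claimed first (ties broken by the lower existing event id), each
#' event and each region matched at most once per frame. Unmatched
#' regions start new events. An event interrupted for even one frame ends;
#' a reappearance starts a new event (the successive-frame rule taken
#' literally).
#'
#' @param regions a list of per-frame region data frames (as produced by
#'   [segment_frame()]), ordered by frame, or a single data frame with a
#'   `frame` column.
#' @param cfg a [detection_config()].
#' @param frame_interval time between frames (s), used to stamp `t_s`.
#' @return An object of class `rspa_events`: a data frame with columns
#'   `event_id`, `frame`, `t_s`, `x_um`, `y_um`, `radius_um`.
#' @export
track_events <- function(regions, cfg, frame_interval = 1) {
  stopifnot(inherits(cfg, "detection_config"))
  if (is.data.frame(regions)) {
    stopifnot("frame" %in% names(regions))
    frames <- sort(unique(regions$frame))
    regions <- lapply(frames, function(f)
      regions[regions$frame == f, c("x_um", "y_um", "radius_um"),
              drop = FALSE])
  } else {
    frames <- seq_along(regions)
  }
  rows <- list()
  next_id <- 1L
  prev <- NULL   # data.frame: event_id, x_um, y_um (of previous frame)
  prev_frame <- -Inf
  for (k in seq_along(regions)) {
    reg <- regions[[k]]
    f <- frames[k]
    assigned <- rep(NA_integer_, nrow(reg))
    if (!is.null(prev) && nrow(reg) > 0L && f == prev_frame + 1L) {
      d <- outer(prev$x_um, reg$x_um, `-`)^2 + outer(prev$y_um, reg$y_um, `-`)^2
      d <- sqrt(d)
      cand <- which(d <= cfg$link_distance, arr.ind = TRUE)
      if (nrow(cand) > 0L) {
        ord <- order(d[cand], prev$event_id[cand[, 1]])
        cand <- cand[ord, , drop = FALSE]
        used_prev <- logical(nrow(prev)); used_reg <- logical(nrow(reg))
        for (m in seq_len(nrow(cand))) {
          i <- cand[m, 1]; j <- cand[m, 2]
          if (used_prev[i] || used_reg[j]) next
          used_prev[i] <- TRUE; used_reg[j] <- TRUE
          assigned[j] <- prev$event_id[i]
        }
      }
    }
    if (nrow(reg) > 0L) {
      for (j in which(is.na(assigned))) {
        assigned[j] <- next_id
        next_id <- next_id + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = assigned, frame = f, t_s = (f - 1) * frame_interval,
        x_um = reg$x_um, y_um = reg$y_um, radius_um = reg$radius_um)
      prev <- data.frame(event_id = assigned, x_um = reg$x_um,
                         y_um = reg$y_um)
      prev_frame <- f
    } else {
      prev <- NULL
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = integer(0), frame = integer(0), t_s = numeric(0),
               x_um = numeric(0), y_um = numeric(0), radius_um = numeric(0))
  out <- out[order(out$event_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("rspa_events", "data.frame"))
}

#' Detect and track radial PKA activation events in a ratio stack
#'
#' Convenience wrapper: normalizes the stack by its temporal minimum
#' projection, segments every frame, and links regions into events.
#'
#' @param stack a [ratio_stack()] (raw ratios; normalization is applied
#'   here). Pass `normalized = TRUE` if the stack is already normalized.
#' @param cfg a [detection_config()].
#' @param normalized set to `TRUE` to skip the minimum-projection
#'   normalization.
#' @return An `rspa_events` data frame (see [track_events()]).
#' @export
detect_events <- function(stack, cfg = detection_config(),
                          normalized = FALSE) {
  stopifnot(inherits(stack, "ratio_stack"))
  if (!normalized) stack <- normalize_by_min_projection(stack)
  nt <- dim(stack$values)[3]
  regions <- lapply(seq_len(nt), function(k)
    segment_frame(stack$values[, , k], cfg, stack$pixel_size))
  track_events(regions, cfg, frame_interval = stack$frame_interval)
}

#' Per-event maxima and summary statistics
#'
#' Collapses tracked events to their maximum radius (the quantity the
#' calibration converts into an amount), reports diameters, and tabulates
#' a histogram of maximum radii.
#'
#' @param events an `rspa_events` data frame from [track_events()].
#' @param bin_width histogram bin width (um).
#' @return An object of class `rspa_event_stats`: list with `events` (one
#'   row per event: `event_id`, `birth_frame`, `n_frames`,
#'   `max_radius_um`, `diameter_um`), `summary` (count, mean/median radius
#'   and diameter), and `histogram` (bin edges and counts). All elements
#'   are empty (not an error) when no events were detected.
#' @export
event_statistics <- function(events, bin_width = 25) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0L) {
    return(structure(list(
      events = data.frame(event_id = integer(0), birth_frame = integer(0),
                          n_frames = integer(0), max_radius_um = numeric(0),
                          diameter_um = numeric(0)),
      summary = data.frame(n_events = 0L, mean_radius_um = NA_real_,
                           median_radius_um = NA_real_,
                           mean_diameter_um = NA_real_,
                           median_diameter_um = NA_real_),
      histogram = data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                             count = integer(0))),
      class = "rspa_event_stats"))
  }
  sp <- split(events, events$event_id)
  per <- data.frame(
    event_id = as.integer(names(sp)),
    birth_frame = vapply(sp, function(d) min(d$frame), numeric(1)),
    n_frames = vapply(sp, nrow, integer(1)),
    max_radius_um = vapply(sp, function(d) max(d$radius_um), numeric(1)))
  per <- per[order(per$event_id), , drop = FALSE]
  rownames(per) <- NULL
  per$diameter_um <- 2 * per$max_radius_um
  breaks <- seq(0, (max(per$max_radius_um) %/% bin_width + 1) * bin_width,
                by = bin_width)
  h <- graphics::hist(per$max_radius_um, breaks = breaks, plot = FALSE)
  structure(list(
    events = per,
    summary = data.frame(
      n_events = nrow(per),
      mean_radius_um = mean(per$max_radius_um),
      median_radius_um = stats::median(per$max_radius_um),
      mean_diameter_um = mean(per$diameter_um),
      median_diameter_um = stats::median(per$diameter_um)),
    histogram = data.frame(bin_lo = utils::head(h$breaks, -1),
                           bin_hi = utils::tail(h$breaks, -1),
                           count = h$counts)),
    class = "rspa_event_stats")
}

#' @export
print.rspa_event_stats <- function(x, ...) {
  s <- x$summary
  if (s$n_events == 0L) {
    cat("No radial PKA activation events detected\n")
    return(invisible(x))
  }
  cat(sprintf(
    "%d event(s); mean max radius %.1f um (mean diameter %.1f um, median %.1f um)\n",
    s$n_events, s$mean_radius_um, s$mean_diameter_um, s$median_diameter_um))
  invisible(x)
}
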