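#' Configuration of a synthetic reporter-field scene
#'
#' Describes a ground-truthed two-channel time-lapse emulating a field of
#' FRET reporter cells around one or more PGE2-releasing cells. The
#' concentration at the dish bottom follows the closed-form half-space
#' solution for each instantaneous release (deliberately independent of
#' the grid solver, so the generator can validate the estimator), the
#' ratio follows the Hill response of the reporter with an optional
#' first-order lag, and the two channels split the ratio as
#' `donor = baseline_donor / sqrt(R)`, `acceptor = baseline_acceptor *
#' sqrt(R)` so that acceptor/donor equals `R` in expectation, with
#' multiplicative Gaussian camera noise and a constant background offset
#' on top. A uniform flow velocity translates each released bolus,
#' reproducing the comet-like smear seen when the medium moves.
#'
#' @param field_size side (um) of the square field of view.
#' @param pixel_size pixel edge (um).
#' @param frame_interval time between frames (s).
#' @param n_frames number of frames.
#' @param events data frame with one release per row: `x_um`, `y_um`,
#'   `t_release_s`, `amount_fmol`. Must lie inside the field and the
#'   recorded interval.
#' @param hill reporter response parameters: list with `R_min`, `R_max`,
#'   `EC50` (nM), `n`.
#' @param D diffusion constant (um^2/s).
#' @param reporter_tau first-order reporter response time (s); 0 renders
#'   the instantaneous Hill response.
#' @param baseline_donor,baseline_acceptor channel baselines (counts).
#' @param noise_sd_frac per-channel multiplicative Gaussian noise sd as a
#'   fraction of the signal.
#' @param background constant camera offset (counts) added to both
#'   channels.
#' @param flow_velocity uniform advection (um/s, length-2 `c(vx, vy)`).
#' @param truth_fold fold threshold defining the ground-truth contour
#'   radius recorded for each event (default 1.20).
#' @param seed integer seed fixing all randomness of the render.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(field_size = 1200, pixel_size = 2.6,
                         frame_interval = 5, n_frames = 40,
                         events = data.frame(x_um = 600, y_um = 600,
                                             t_release_s = 20,
                                             amount_fmol = 0.25),
                         hill = list(R_min = 1, R_max = 1.35,
                                     EC50 = 1, n = 1),
                         D = 500, reporter_tau = 30,
                         baseline_donor = 1000, baseline_acceptor = 1000,
                         noise_sd_frac = 0.01, background = 100,
                         flow_velocity = c(0, 0), truth_fold = 1.20,
                         seed = 1L) {
  stopifnot(field_size > 0, pixel_size > 0, frame_interval > 0,
            n_frames >= 1, D > 0, reporter_tau >= 0,
            baseline_donor > 0, baseline_acceptor > 0,
            noise_sd_frac >= 0, background >= 0,
            length(flow_velocity) == 2L, truth_fold > 1)
  stopifnot(is.data.frame(events),
            all(c("x_um", "y_um", "t_release_s", "amount_fmol") %in%
                  names(events)))
  t_end <- (n_frames - 1) * frame_interval
  if (nrow(events) > 0) {
    if (any(events$amount_fmol <= 0))
      stop("event amounts must be positive", call. = FALSE)
    if (any(events$x_um < 0 | events$x_um > field_size |
            events$y_um < 0 | events$y_um > field_size))
      stop("event positions must lie inside the field", call. = FALSE)
    if (any(events$t_release_s < 0 | events$t_release_s >= t_end))
      stop("event release times must fall within the recorded interval",
           call. = FALSE)
  }
  for (p in c("R_min", "R_max", "EC50", "n"))
    if (is.null(hill[[p]])) stop("hill needs ", p, call. = FALSE)
  if (hill$R_max <= hill$R_min || hill$R_min <= 0)
    stop("hill must satisfy R_max > R_min > 0", call. = FALSE)
  structure(list(field_size = field_size, pixel_size = pixel_size,
                 frame_interval = frame_interval, n_frames = as.integer(n_frames),
                 events = events, hill = hill, D = D,
                 reporter_tau = reporter_tau,
                 baseline_donor = baseline_donor,
                 baseline_acceptor = baseline_acceptor,
                 noise_sd_frac = noise_sd_frac, background = background,
                 flow_velocity = as.numeric(flow_velocity),
                 truth_fold = truth_fold, seed = as.integer(seed)),
            class = "scene_config")
}

.hill_forward <- function(C, h) {
  out <- rep(h$R_min, length(C))
  pos <- C > 0
  out[pos] <- h$R_min + (h$R_max - h$R_min) *
    C[pos]^h$n / (C[pos]^h$n + h$EC50^h$n)
  out
}

#' Closed-form maximum threshold-contour radius of one release
#'
#' For an instantaneous release of `Q` fmol into a half space, the radius
#' of the `C_star` contour at the bottom peaks at
#' `t* = (2 Q / (C_star e^(3/2)))^(2/3) / (4 pi D)` with
#' `r_max = sqrt(6 D t*)`. When the observation ends before `t*`, the
#' radius at the end of the window is returned instead.
#'
#' @param Q released amount (fmol).
#' @param C_star contour concentration (nM).
#' @param D diffusion constant (um^2/s).
#' @param t_obs observation window after the release (s), `Inf` for the
#'   unconstrained maximum.
#' @return Radius (um); 0 when the release never reaches `C_star`.
#' @export
analytic_max_radius <- function(Q, C_star, D = 500, t_obs = Inf) {
  stopifnot(Q >= 0, C_star > 0, D > 0)
  if (Q == 0) return(0)
  t_star <- (2 * Q * 1e9 / (C_star * exp(1.5)))^(2 / 3) / (4 * pi * D)
  t_use <- pmin(t_star, t_obs)
  arg <- 4 * D * t_use *
    log(2 * Q * 1e9 / ((4 * pi * D * t_use)^1.5 * C_star))
  if (arg <= 0) return(0)
  sqrt(arg)
}

#' Render a synthetic two-channel scene with ground truth
#'
#' @param cfg a [scene_config()].
#' @return An object of class `rspa_scene`: list with `donor` and
#'   `acceptor` stacks (arrays `c(H, W, T)`), `truth` (per event: amount,
#'   release frame, true maximum threshold-contour radius at the
#'   configured `truth_fold`), and the configuration.
#' @export
#' @examples
#' sc <- render_scene(scene_config(field_size = 300, pixel_size = 5,
#'                                 n_frames = 8, frame_interval = 5,
#'                                 events = data.frame(x_um = 150, y_um = 150,
#'                                                     t_release_s = 5,
#'                                                     amount_fmol = 0.05)))
#' dim(sc$donor)
render_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  npx <- as.integer(round(cfg$field_size / cfg$pixel_size))
  xs <- (seq_len(npx) - 0.5) * cfg$pixel_size   # column centres
  ys <- (seq_len(npx) - 0.5) * cfg$pixel_size   # row centres
  times <- (seq_len(cfg$n_frames) - 1) * cfg$frame_interval
  h <- cfg$hill

  set.seed(cfg$seed)
  donor <- array(NA_real_, c(npx, npx, cfg$n_frames))
  acceptor <- array(NA_real_, c(npx, npx, cfg$n_frames))
  R_lag <- matrix(h$R_min, npx, npx)
  alpha <- if (cfg$reporter_tau > 0)
    1 - exp(-cfg$frame_interval / cfg$reporter_tau) else 1

  for (k in seq_len(cfg$n_frames)) {
    C <- matrix(0, npx, npx)
    if (nrow(cfg$events) > 0) {
      for (e in seq_len(nrow(cfg$events))) {
        dt_e <- times[k] - cfg$events$t_release_s[e]
        if (dt_e <= 0) next
        cx <- cfg$events$x_um[e] + cfg$flow_velocity[1] * dt_e
        cy <- cfg$events$y_um[e] + cfg$flow_velocity[2] * dt_e
        d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
        C <- C + 2 * cfg$events$amount_fmol[e] * 1e9 /
          (4 * pi * cfg$D * dt_e)^1.5 * exp(-d2 / (4 * cfg$D * dt_e))
      }
    }
    R_inst <- matrix(.hill_forward(as.vector(C), h), npx, npx)
    R_lag <- R_lag + alpha * (R_inst - R_lag)
    donor[, , k] <- cfg$baseline_donor / sqrt(R_lag) *
      (1 + stats::rnorm(npx * npx, 0, cfg$noise_sd_frac)) + cfg$background
    acceptor[, , k] <- cfg$baseline_acceptor * sqrt(R_lag) *
      (1 + stats::rnorm(npx * npx, 0, cfg$noise_sd_frac)) + cfg$background
  }

  C_star <- threshold_to_concentration(h, cfg$truth_fold)
  truth <- if (nrow(cfg$events) > 0) {
    data.frame(
      event = seq_len(nrow(cfg$events)),
      amount_fmol = cfg$events$amount_fmol,
      release_frame = vapply(cfg$events$t_release_s, function(t0)
        min(which(times > t0)), integer(1)),
      true_max_radius_um = vapply(seq_len(nrow(cfg$events)), function(e)
        analytic_max_radius(cfg$events$amount_fmol[e], C_star, cfg$D,
                            t_obs = max(times) - cfg$events$t_release_s[e]),
        numeric(1)))
  } else {
    data.frame(event = integer(0), amount_fmol = numeric(0),
               release_frame = integer(0), true_max_radius_um = numeric(0))
  }
  structure(list(donor = donor, acceptor = acceptor, truth = truth,
                 config = cfg),
            class = "rspa_scene")
}

#' @export
print.rspa_scene <- function(x, ...) {
  d <- dim(x$donor)
  cat(sprintf(
    "Synthetic scene: %d frames of %d x %d px, %d event(s), seed %d\n",
    d[3], d[1], d[2], nrow(x$truth), x$config$seed))
  invisible(x)
}

#' Reproducible batch of single-event validation scenes
#'
#' Builds `n_scenes` scene configurations with one central release each,
#' amounts log-spaced across `amount_range`, per-scene noise seeds derived
#' from `seed`. The scenes are rendered lazily through [render_scene()]
#' (so large batches need not be held in memory at once); the manifest
#' links each scene to its ground truth.
#'
#' These validation scenes render the instantaneous reporter response
#' (`reporter_tau = 0`): the batch benchmarks the detection-estimation
#' chain itself, while the bias introduced by slow reporter kinetics is a
#' property of the reporter, quantified separately.
#'
#' @param n_scenes number of scenes (>= 1).
#' @param amount_range range (fmol) spanned log-uniformly.
#' @param seed integer master seed.
#' @param ... overrides passed to [scene_config()] (e.g. `noise_sd_frac`).
#' @return An object of class `rspa_scene_suite`: list with `configs` (one
#'   [scene_config()] per scene) and `manifest` (scene, seed, amount,
#'   true maximum contour radius).
#' @export
scene_suite <- function(n_scenes, amount_range = c(0.05, 1), seed = 1L, ...) {
  stopifnot(n_scenes >= 1, length(amount_range) == 2L,
            all(amount_range > 0), amount_range[2] > amount_range[1])
  amounts <- exp(seq(log(amount_range[1]), log(amount_range[2]),
                     length.out = n_scenes))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_scenes)
  dots <- list(...)
  if (!"reporter_tau" %in% names(dots)) dots$reporter_tau <- 0
  configs <- lapply(seq_len(n_scenes), function(i)
    do.call(scene_config, c(
      list(events = data.frame(x_um = 600, y_um = 600, t_release_s = 20,
                               amount_fmol = amounts[i]),
           seed = seeds[i]),
      dots)))
  C_star <- vapply(configs, function(cf)
    threshold_to_concentration(cf$hill, cf$truth_fold), numeric(1))
  manifest <- data.frame(
    scene = seq_len(n_scenes), seed = seeds, amount_fmol = amounts,
    true_max_radius_um = vapply(seq_len(n_scenes), function(i) {
      cf <- configs[[i]]
      analytic_max_radius(amounts[i], C_star[i], cf$D,
                          t_obs = (cf$n_frames - 1) * cf$frame_interval -
                            cf$events$t_release_s[1])
    }, numeric(1)))
  structure(list(configs = configs, manifest = manifest),
            class = "rspa_scene_suite")
}

#' End-to-end amount recovery over a scene batch
#'
#' Renders each scene of a [scene_suite()], runs detection and tracking,
#' keeps the event nearest the known release site, converts its maximum
#' radius into an amount with the supplied calibration, and reports the
#' relative error against the manifest truth. Scenes are processed one at
#' a time and discarded.
#'
#' @param suite an `rspa_scene_suite`.
#' @param curve an `rspa_calibration` whose contour concentration matches
#'   the detection threshold (see [threshold_to_concentration()]).
#' @param cfg a [detection_config()].
#' @return A data frame with one row per scene: `scene`, `amount_fmol`,
#'   `detected` (logical), `max_radius_um`, `estimate_fmol`, `rel_error`.
#' @export
recover_amounts <- function(suite, curve, cfg = detection_config()) {
  stopifnot(inherits(suite, "rspa_scene_suite"))
  res <- lapply(seq_along(suite$configs), function(i) {
    sc_cfg <- suite$configs[[i]]
    sc <- render_scene(sc_cfg)
    stack <- preprocess(sc$donor, sc$acceptor,
                        background = sc_cfg$background,
                        pixel_size = sc_cfg$pixel_size,
                        frame_interval = sc_cfg$frame_interval)
    ev <- detect_events(stack, cfg)
    truth_q <- suite$manifest$amount_fmol[i]
    if (nrow(ev) == 0L)
      return(data.frame(scene = i, amount_fmol = truth_q, detected = FALSE,
                        max_radius_um = NA_real_, estimate_fmol = NA_real_,
                        rel_error = NA_real_))
    per <- event_statistics(ev)$events
    # nearest detected event to the known release site
    first <- ev[!duplicated(ev$event_id), ]
    d <- sqrt((first$x_um - sc_cfg$events$x_um[1])^2 +
                (first$y_um - sc_cfg$events$y_um[1])^2)
    id <- first$event_id[which.min(d)]
    rmax <- per$max_radius_um[per$event_id == id]
    est <- radius_to_amount(rmax, curve)$amount_fmol
    data.frame(scene = i, amount_fmol = truth_q, detected = TRUE,
               max_radius_um = rmax, estimate_fmol = est,
               rel_error = abs(est - truth_q) / truth_q)
  })
  do.call(rbind, res)
}
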