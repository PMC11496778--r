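# Small, fast configurations used across test files. Coarse grids keep unit
# tests quick; the acceptance tests exercise the full default geometry.

coarse_config <- function(...) {
  args <- list(...)
  defaults <- list(r_max = 600, z_max = 400, dr = 10, dz = 10,
                   Q = 0.25, t_end = 30)
  do.call(diffusion_config, utils::modifyList(defaults, args))
}

# analytic field evaluated on the solver's grid
analytic_field_matrix <- function(Q, D, t, r_max, z_max, dr, dz) {
  r <- seq(0, r_max, by = dr)
  z <- seq(0, z_max, by = dz)
  outer(r, z, function(R, Z) analytic_halfspace(Q, D, R, Z, t))
}

# paint a disc of the given fold change onto a baseline frame
paint_disc <- function(npx, pixel_size, cx_um, cy_um, radius_um,
                       fold = 1.3, baseline = 1.0) {
  xs <- (seq_len(npx) - 0.5) * pixel_size
  m <- matrix(baseline, npx, npx)
  d2 <- outer((xs - cy_um)^2, (xs - cx_um)^2, `+`)
  m[d2 <= radius_um^2] <- baseline * fold
  m
}

# region table shorthand for tracking tests
regions_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(x_um = r[1], y_um = r[2], radius_um = r[3])))
}

small_scene_config <- function(...) {
  args <- list(...)
  merged <- list(
    field_size = 600, pixel_size = 4, frame_interval = 5, n_frames = 12,
    events = data.frame(x_um = 300, y_um = 300, t_release_s = 10,
                        amount_fmol = 0.1),
    reporter_tau = 0, noise_sd_frac = 0, seed = 1L)
  for (nm in names(args)) merged[[nm]] <- args[[nm]]
  do.call(scene_config, merged)
}
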