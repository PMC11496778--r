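test_that("configuration validation rejects bad geometry and unstable steps", {
  expect_error(diffusion_config(D = -1), "positive")
  expect_error(diffusion_config(dr = 7), "integral")
  bound <- 0.5 / (500 * (1 / 25 + 1 / 25))
  expect_error(diffusion_config(dt = 2 * bound), "unstable")
  cfg <- diffusion_config()
  expect_equal(cfg$dt, 0.4 * bound)
  expect_equal(cfg$C_thresh, 1.35)
  expect_equal(cfg$D, 500)
})

test_that("zero release yields identically zero fields", {
  cfg <- coarse_config(Q = 0, t_end = 5)
  flds <- solve_diffusion(cfg, output_times = c(1, 5))
  for (f in flds) expect_true(all(f$values == 0))
})

test_that("closed-form half-space solution has the expected values", {
  # direct evaluation: 2Q/(4 pi D t)^(3/2) * exp(-(r^2+z^2)/(4Dt)), in nM
  expected <- 2 * 0.25 * 1e9 / (4 * pi * 500 * 30)^1.5 * exp(-110^2 / (4 * 500 * 30))
  expect_equal(analytic_halfspace(0.25, 500, r = 110, z = 0, t = 30), expected)
  expect_equal(round(expected, 1), 5.0)
  # isotropy: swapping r and z leaves the value unchanged
  expect_equal(analytic_halfspace(0.1, 500, r = 80, z = 30, t = 12),
               analytic_halfspace(0.1, 500, r = 30, z = 80, t = 12))
  # decays to zero far away
  expect_equal(analytic_halfspace(0.25, 500, r = 1e6, z = 0, t = 30), 0)
  expect_error(analytic_halfspace(0.25, 500, r = 1, z = 0, t = 0), "positive")
})

test_that("solver agrees with the analytic Green function away from boundaries", {
  # time and cutoff chosen so the compared region stays well inside this
  # small 10 um test domain; the acceptance suite covers the full default
  # geometry at the 0.01 nM cutoff
  cfg <- coarse_config(t_end = 10)
  f <- solve_diffusion(cfg, output_times = 10)[[1]]
  ana <- analytic_field_matrix(0.25, 500, 10, 600, 400, 10, 10)
  sel <- ana > 0.05
  expect_lt(max(abs(f$values[sel] - ana[sel]) / ana[sel]), 0.05)
  expect_true(all(f$values >= 0))
})

test_that("the discrete volume integral conserves the released amount", {
  cfg <- coarse_config(t_end = 10)
  flds <- solve_diffusion(cfg, output_times = c(2, 10))
  for (f in flds) {
    expect_lte(total_amount(f), cfg$Q * (1 + 1e-9))
    expect_equal(total_amount(f), cfg$Q, tolerance = 0.01)
  }
})

test_that("contour radius handles empty, saturated and analytic fields", {
  zero <- structure(list(values = matrix(0, 61, 41), t = 1, dr = 10, dz = 10),
                    class = "concentration_field")
  expect_equal(contour_radius(zero, 1.35), 0)
  sat <- structure(list(values = matrix(10, 61, 41), t = 1, dr = 10, dz = 10),
                   class = "concentration_field")
  expect_equal(contour_radius(sat, 1.35), 600)
  ana <- structure(list(values = analytic_field_matrix(0.25, 500, 30,
                                                       600, 400, 5, 5),
                        t = 30, dr = 5, dz = 5),
                   class = "concentration_field")
  # closed form: r = sqrt(4 D t log(C(0)/C*))
  expected <- sqrt(4 * 500 * 30 *
                     log(analytic_halfspace(0.25, 500, 0, 0, 30) / 1.35))
  expect_equal(contour_radius(ana, 1.35), expected, tolerance = 0.005)
  expect_equal(round(expected / 100), 3)  # about 300 um
})

test_that("maximum contour radius is zero for undetectable releases and grows with Q", {
  cfg <- coarse_config(Q = 1e-4, t_end = 10)
  expect_equal(max_contour_radius(cfg), 0)
  r1 <- max_contour_radius(coarse_config(Q = 0.05, t_end = 30))
  r2 <- max_contour_radius(coarse_config(Q = 0.10, t_end = 30))
  expect_gt(r1, 0)
  expect_gt(r2, r1)
})

test_that("contour trace rises from and returns to zero", {
  cfg <- coarse_config(Q = 0.02, t_end = 60)
  tr <- contour_trace(cfg)
  expect_s3_class(tr, "contour_trace")
  expect_gt(tr$time[1], 0)             # sampling starts after the release
  expect_equal(tr$radius[nrow(tr)], 0) # after decay below C*
  expect_gt(max(tr$radius), 0)
  expect_true(all(tr$radius >= 0 & tr$radius <= cfg$r_max))
})

test_that("calibration is monotone and follows the one-third power law", {
  cfg <- coarse_config(t_end = 40, C_thresh = 1.35)
  amounts <- c(0.05, 0.1, 0.2, 0.4)
  cal <- build_calibration(cfg, amounts)
  expect_true(all(diff(cal$max_radius_um) > 0))
  slope <- stats::coef(stats::lm(log(max_radius_um) ~ log(amount_fmol),
                                 data = as.data.frame(cal)))[[2]]
  expect_equal(slope, 1 / 3, tolerance = 0.05)
  expect_error(build_calibration(cfg, 0.25), "increasing")
  expect_error(build_calibration(cfg, c(0.4, 0.2)), "increasing")
})

test_that("grid refinement changes the maximum contour radius by little", {
  base <- diffusion_config(r_max = 600, z_max = 400, dr = 10, dz = 10,
                           Q = 0.1, t_end = 30)
  fine <- diffusion_config(r_max = 600, z_max = 400, dr = 5, dz = 5,
                           Q = 0.1, t_end = 30)
  r_base <- max_contour_radius(base)
  r_fine <- max_contour_radius(fine)
  expect_equal(r_base, r_fine, tolerance = 0.02)
})

test_that("calibration CSV round-trips", {
  cfg <- coarse_config(t_end = 30)
  cal <- build_calibration(cfg, c(0.1, 0.2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(back$amount_fmol, cal$amount_fmol)
  expect_equal(back$max_radius_um, cal$max_radius_um)
})
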