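hill_ratio <- function(C, R_min = 1, R_max = 1.35, EC50 = 1, n = 1)
  R_min + (R_max - R_min) * ifelse(C > 0, C^n / (C^n + EC50^n), 0)

dose_table <- function(ratios, conc = 10^seq(-2, 2, length.out = 8))
  data.frame(concentration_nM = conc, ratio = ratios)

test_that("noiseless synthetic dose-response is recovered to machine precision", {
  conc <- 10^seq(-2, 2, length.out = 8)
  fit <- fit_hill(dose_table(hill_ratio(conc)))
  expect_false(fit$flagged)
  expect_equal(coef(fit), c(R_min = 1, R_max = 1.35, EC50 = 1, n = 1),
               tolerance = 1e-6)
  fit2 <- fit_hill(dose_table(hill_ratio(conc, 1.1, 2.2, 5.7, 1.8)))
  expect_equal(coef(fit2), c(R_min = 1.1, R_max = 2.2, EC50 = 5.7, n = 1.8),
               tolerance = 1e-6)
})

test_that("fitting is equivariant under ratio rescaling", {
  conc <- 10^seq(-2, 2, length.out = 8)
  f1 <- fit_hill(dose_table(hill_ratio(conc)))
  f3 <- fit_hill(dose_table(3 * hill_ratio(conc)))
  expect_equal(f3$R_min, 3 * f1$R_min, tolerance = 1e-6)
  expect_equal(f3$R_max, 3 * f1$R_max, tolerance = 1e-6)
  expect_equal(f3$EC50, f1$EC50, tolerance = 1e-6)
  expect_equal(f3$n, f1$n, tolerance = 1e-6)
})

test_that("EC50 is recovered under response noise across Monte-Carlo replicates", {
  # 5% multiplicative noise on the activation response above baseline,
  # three replicate titrations per dose as in the bath-application assay
  conc <- 10^seq(-2, 2, length.out = 8)
  theta <- conc / (conc + 1)
  set.seed(7)
  errs <- replicate(100, {
    tab <- do.call(rbind, lapply(1:3, function(rep)
      data.frame(concentration_nM = conc, replicate = rep,
                 ratio = 1 + 0.35 * theta * (1 + stats::rnorm(8, 0, 0.05)))))
    abs(fit_hill(tab)$EC50 - 1)
  })
  expect_lt(stats::median(errs), 0.1)
})

test_that("degenerate tables are flagged, invalid ones rejected", {
  conc <- 10^seq(-2, 2, length.out = 8)
  fit <- fit_hill(dose_table(rep(1.1, 8)))
  expect_true(fit$flagged)
  expect_error(fit_hill(dose_table(rep(-1, 8))), "ratios")
  expect_error(fit_hill(data.frame(concentration_nM = c(0, 1, 2),
                                   ratio = c(1, 1.1, 1.2))),
               "4 distinct")
})

test_that("threshold inversion is the inverse of the forward model", {
  fit <- list(R_min = 1, R_max = 1.35, EC50 = 1, n = 1)
  # 20% increase -> (0.20 / 0.15) * EC50 = 4/3 nM
  expect_equal(threshold_to_concentration(fit, 1.20), 4 / 3)
  # midpoint threshold recovers EC50 by definition
  fold_mid <- (fit$R_min + fit$R_max) / 2 / fit$R_min
  expect_equal(threshold_to_concentration(fit, fold_mid), fit$EC50)
  # identity on concentrations, through the forward model, incl. n != 1
  fit2 <- list(R_min = 0.8, R_max = 2.1, EC50 = 3.2, n = 1.7)
  for (C in c(0.1, 1, 3.2, 20)) {
    fold <- hill_ratio(C, fit2$R_min, fit2$R_max, fit2$EC50, fit2$n) / fit2$R_min
    expect_equal(threshold_to_concentration(fit2, fold), C)
  }
  # fold -> 1+ gives a vanishing threshold concentration
  expect_lt(threshold_to_concentration(fit, 1 + 1e-9), 1e-8)
  # unreachable thresholds are rejected
  expect_error(threshold_to_concentration(fit, 1.4), "unreachable")
  expect_error(threshold_to_concentration(fit, 0.9), "> 1")
})

test_that("window-averaged field ratio averages intensities before dividing", {
  a <- array(300, c(4, 4, 6))
  d <- array(200, c(4, 4, 6))
  expect_equal(mean_ratio_window(a, d, frame_interval = 60,
                                 t_window = c(0, 300)), 1.5)
  # single-frame window picks that frame
  a[, , 3] <- 500
  expect_equal(mean_ratio_window(a, d, 60, c(120, 120)), 2.5)
  # empty window is an error
  expect_error(mean_ratio_window(a, d, 60, c(7, 8)), "no frames")
  # plateau of a rendered scene is recovered
  sc <- render_scene(small_scene_config(
    events = data.frame(x_um = 300, y_um = 300, t_release_s = 10,
                        amount_fmol = 0.3),
    noise_sd_frac = 0.005, n_frames = 12))
  r <- mean_ratio_window(sc$acceptor - 100, sc$donor - 100,
                         frame_interval = 5, t_window = c(15, 35))
  expect_gt(r, 1.0)
  expect_lt(r, 1.35)
})
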