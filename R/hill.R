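#' Fit a four-parameter Hill dose-response model
#'
#' Fits `R(C) = R_min + (R_max - R_min) * C^n / (C^n + EC50^n)` to a
#' biosensor titration table by least squares, as used to calibrate the
#' FRET ratio of the PKA reporter against bath-applied PGE2. Replicates
#' are weighted equally. The optimiser is started from a fixed grid of
#' EC50 values (log-spaced over the tested positive concentrations) and
#' Hill coefficients (0.5, 1, 2, 4), so the fit is deterministic.
#'
#' The fit is flagged (not failed) when no start converges, when the
#' fitted EC50 falls outside the tested concentration range, or when the
#' fitted amplitude is indistinguishable from the residual noise (no
#' sigmoid, e.g. constant ratios).
#'
#' @param table a data frame with columns `concentration_nM` (>= 0,
#'   nanomolar) and `ratio` (> 0); an optional `replicate` column is
#'   carried through but not used for weighting. At least 4 distinct
#'   positive concentrations are required.
#' @return An object of class `hill_fit` with components `R_min`, `R_max`,
#'   `EC50` (nM), `n`, `rss`, `rms` (residual root mean square), `flagged`,
#'   `flag_reasons`, and the data used.
#' @seealso [threshold_to_concentration()], [predict.hill_fit()]
#' @export
#' @examples
#' conc <- 10^seq(-2, 2, length.out = 8)
#' tab <- data.frame(concentration_nM = conc,
#'                   ratio = 1 + 0.35 * conc / (conc + 1))
#' fit_hill(tab)
fit_hill <- function(table) {
  if (!is.data.frame(table) ||
      !all(c("concentration_nM", "ratio") %in% names(table)))
    stop("'table' must have columns 'concentration_nM' and 'ratio'",
         call. = FALSE)
  conc <- as.numeric(table$concentration_nM)
  ratio <- as.numeric(table$ratio)
  ok <- is.finite(conc) & is.finite(ratio)
  conc <- conc[ok]; ratio <- ratio[ok]
  if (any(conc < 0) || any(ratio <= 0))
    stop("concentrations must be >= 0 and ratios > 0", call. = FALSE)
  pos <- sort(unique(conc[conc > 0]))
  if (length(pos) < 4L)
    stop("need at least 4 distinct positive concentrations", call. = FALSE)

  hill <- function(p, C) p[1] + (p[2] - p[1]) * ifelse(
    C > 0, C^p[4] / (C^p[4] + p[3]^p[4]), 0)
  r_lo <- min(ratio); r_hi <- max(ratio)
  ec_grid <- exp(seq(log(min(pos)), log(max(pos)), length.out = 7))
  best <- NULL
  for (ec in ec_grid) for (nn in c(0.5, 1, 2, 4)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        ratio ~ Rmin + (Rmax - Rmin) * ifelse(conc > 0,
          conc^n / (conc^n + EC50^n), 0),
        data = data.frame(conc = conc, ratio = ratio),
        start = list(Rmin = r_lo, Rmax = r_hi, EC50 = ec, n = nn),
        lower = c(Rmin = 1e-12, Rmax = 1e-12, EC50 = 1e-12, n = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(coef = stats::coef(fit), rss = rss)
  }

  flags <- character(0)
  if (is.null(best)) {
    flags <- "no start converged"
    best <- list(coef = c(Rmin = r_lo, Rmax = r_hi, EC50 = stats::median(pos),
                          n = 1), rss = sum((ratio - mean(ratio))^2))
  }
  cf <- best$coef
  rms <- sqrt(best$rss / length(ratio))
  if (cf[["EC50"]] < min(pos) || cf[["EC50"]] > max(pos))
    flags <- c(flags, "EC50 outside the tested concentration range")
  amp <- cf[["Rmax"]] - cf[["Rmin"]]
  if (amp <= max(4 * rms, 1e-6 * mean(ratio)))
    flags <- c(flags, "no resolvable sigmoid amplitude")
  structure(list(R_min = unname(cf[["Rmin"]]), R_max = unname(cf[["Rmax"]]),
                 EC50 = unname(cf[["EC50"]]), n = unname(cf[["n"]]),
                 rss = best$rss, rms = rms,
                 flagged = length(flags) > 0L, flag_reasons = flags,
                 data = data.frame(concentration_nM = conc, ratio = ratio)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill dose-response fit\n")
  cat(sprintf("  R_min = %.4g, R_max = %.4g, EC50 = %.4g nM, n = %.3g\n",
              x$R_min, x$R_max, x$EC50, x$n))
  cat(sprintf("  residual RMS = %.3g over %d points\n",
              x$rms, nrow(x$data)))
  if (x$flagged)
    cat("  FLAGGED:", paste(x$flag_reasons, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(R_min = object$R_min, R_max = object$R_max,
    EC50 = object$EC50, n = object$n)
}

#' Predicted ratio at given concentrations
#'
#' Forward Hill model of a [fit_hill()] result.
#'
#' @param object a `hill_fit`.
#' @param concentration_nM concentrations (nM), vectorized.
#' @param ... unused.
#' @return Predicted ratios.
#' @export
predict.hill_fit <- function(object, concentration_nM, ...) {
  C <- as.numeric(concentration_nM)
  out <- rep(object$R_min, length(C))
  pos <- C > 0
  out[pos] <- object$R_min + (object$R_max - object$R_min) *
    C[pos]^object$n / (C[pos]^object$n + object$EC50^object$n)
  out
}

#' Convert a fractional ratio-increase threshold to a concentration
#'
#' Inverts the Hill model at the ratio `R_thr = fold_increase * R_min`:
#' `C* = EC50 * ((R_thr - R_min) / (R_max - R_thr))^(1/n)`. This maps the
#' detection pipeline's fold-change threshold (e.g. a 20 percent FRET
#' ratio increase, `fold_increase = 1.20`) onto the iso-concentration
#' contour the diffusion calibration must trace. The threshold is defined
#' as a fold change over the baseline ratio, not as a fraction of the
#' dynamic range, matching the normalized-ratio units of the detector.
#'
#' @param fit a `hill_fit` (or any list with `R_min`, `R_max`, `EC50`, `n`).
#' @param fold_increase ratio threshold as a fold change over baseline,
#'   > 1; `fold_increase * R_min` must stay below `R_max`.
#' @return Threshold concentration (nM).
#' @export
#' @examples
#' fit <- list(R_min = 1, R_max = 1.35, EC50 = 1, n = 1)
#' threshold_to_concentration(fit, 1.20)  # 4/3 nM
threshold_to_concentration <- function(fit, fold_increase = 1.20) {
  p <- fit[c("R_min", "R_max", "EC50", "n")]
  if (any(vapply(p, is.null, logical(1))))
    stop("'fit' must carry R_min, R_max, EC50 and n", call. = FALSE)
  if (!is.numeric(fold_increase) || length(fold_increase) != 1L ||
      fold_increase <= 1)
    stop("'fold_increase' must be a single number > 1", call. = FALSE)
  R_thr <- fold_increase * p$R_min
  if (R_thr >= p$R_max)
    stop(sprintf(
      "threshold ratio %.4g is at or above the plateau R_max = %.4g; ",
      R_thr, p$R_max), "the threshold is unreachable", call. = FALSE)
  p$EC50 * ((R_thr - p$R_min) / (p$R_max - R_thr))^(1 / p$n)
}

#' Field-averaged ratio over a time window
#'
#' Mean mKate2/mKO-kappa ratio of a whole field of view over a time
#' window, computed as the ratio of the window-averaged channel means
#' (intensities are averaged first, then the ratio is taken), as done when
#' titrating reporter sensitivity at a plateau (e.g. 20 to 30 min after
#' agonist addition).
#'
#' @param acceptor,donor intensity stacks, arrays of dimension
#'   `c(H, W, T)` (or matrices for a single frame).
#' @param frame_interval time between frames (s).
#' @param t_window numeric length-2 interval `c(t0, t1)` in seconds; frame
#'   k covers time `(k - 1) * frame_interval`.
#' @return The window-averaged acceptor/donor ratio (dimensionless).
#' @export
mean_ratio_window <- function(acceptor, donor, frame_interval, t_window) {
  if (is.matrix(acceptor)) acceptor <- array(acceptor, c(dim(acceptor), 1L))
  if (is.matrix(donor)) donor <- array(donor, c(dim(donor), 1L))
  stopifnot(identical(dim(acceptor), dim(donor)), length(t_window) == 2L)
  nt <- dim(acceptor)[3]
  t_frames <- (seq_len(nt) - 1) * frame_interval
  keep <- t_frames >= t_window[1] & t_frames <= t_window[2]
  if (!any(keep))
    stop("time window contains no frames", call. = FALSE)
  mean(acceptor[, , keep, drop = FALSE]) / mean(donor[, , keep, drop = FALSE])
}
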