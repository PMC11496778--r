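.check_keys <- function(x, allowed, where) {
  if (is.null(x)) return(invisible(NULL))
  if (!is.list(x)) stop(sprintf("section '%s' must be a mapping", where),
                        call. = FALSE)
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(sprintf("unknown key(s) in '%s': %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  invisible(NULL)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes an equivalent nested list) describing one
#' end-to-end run: where the images come from (files or a synthetic scene
#' directive), the pixel/frame metadata, and the detection, dose-response,
#' diffusion-calibration and estimation parameters. Unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' Sections (all optional unless noted):
#' \describe{
#'   \item{input}{`donor`, `acceptor` (per-channel TIFF paths) or
#'     `interleaved` + `channels`, and `background` (offset counts); or
#'     `synth: TRUE` to render the scene in `scene`.}
#'   \item{metadata}{`pixel_size_um`, `frame_interval_s` — required for
#'     file input, never guessed.}
#'   \item{scene}{arguments of [scene_config()] (used when
#'     `input$synth`).}
#'   \item{detection}{arguments of [detection_config()].}
#'   \item{dose}{`R_min`, `R_max`, `EC50`, `n` (reporter Hill parameters)
#'     or `table_csv` to fit from a titration table; `fold_increase`
#'     (default 1.20).}
#'   \item{diffusion}{arguments of [diffusion_config()] except `Q` and
#'     `C_thresh`; plus `sample_interval`.}
#'   \item{calibration}{`amounts` (fmol grid) and/or `csv` (cache path:
#'     read when present, otherwise built and written).}
#'   \item{estimate}{`cell_area_um2` (default 200).}
#' }
#'
#' @param x path to a YAML file, or a nested list.
#' @return A validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) {
    if (!file.exists(x)) .io_error("config file '%s' does not exist", x)
    yaml::read_yaml(x)
  } else x
  if (!is.list(cfg)) stop("configuration must be a mapping", call. = FALSE)
  .check_keys(cfg, c("input", "metadata", "scene", "detection", "dose",
                     "diffusion", "calibration", "estimate"), "top level")
  .check_keys(cfg$input, c("donor", "acceptor", "interleaved", "channels",
                           "background", "synth"), "input")
  .check_keys(cfg$metadata, c("pixel_size_um", "frame_interval_s"),
              "metadata")
  .check_keys(cfg$scene,
              names(formals(scene_config)), "scene")
  .check_keys(cfg$detection,
              names(formals(detection_config)), "detection")
  .check_keys(cfg$dose, c("R_min", "R_max", "EC50", "n", "table_csv",
                          "fold_increase"), "dose")
  .check_keys(cfg$diffusion,
              c(setdiff(names(formals(diffusion_config)),
                        c("Q", "C_thresh")), "sample_interval"),
              "diffusion")
  .check_keys(cfg$calibration, c("amounts", "csv"), "calibration")
  .check_keys(cfg$estimate, c("cell_area_um2"), "estimate")
  synth <- isTRUE(cfg$input$synth)
  if (!synth) {
    has_files <- !is.null(cfg$input$donor) && !is.null(cfg$input$acceptor) ||
      !is.null(cfg$input$interleaved)
    if (!has_files)
      stop("input must name donor/acceptor TIFFs, an interleaved TIFF, ",
           "or set synth: true", call. = FALSE)
    if (is.null(cfg$metadata$pixel_size_um) ||
        is.null(cfg$metadata$frame_interval_s))
      stop("metadata must provide 'pixel_size_um' and 'frame_interval_s' ",
           "for file input; they are never guessed", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

.pipeline_hill <- function(dose) {
  if (!is.null(dose$table_csv)) {
    tab <- utils::read.csv(dose$table_csv)
    fit <- fit_hill(tab)
    if (fit$flagged)
      warning("dose-response fit flagged: ",
              paste(fit$flag_reasons, collapse = "; "), call. = FALSE)
    return(fit)
  }
  h <- list(R_min = dose$R_min %||% 1, R_max = dose$R_max %||% 1.35,
            EC50 = dose$EC50 %||% 1, n = dose$n %||% 1)
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full detection-to-amount pipeline
#'
#' Acquires the two channels (from TIFF files or by rendering the
#' configured synthetic scene), forms the normalized ratio stack, detects
#' and tracks radial PKA activation events, converts the detection fold
#' threshold into a concentration through the reporter's Hill response,
#' obtains the amount-to-radius calibration (from a CSV cache when
#' present, otherwise by running the diffusion simulations), and converts
#' each event's maximum radius into a discharged amount.
#'
#' @param cfg a [pipeline_config()], a path to one, or a nested list.
#' @return A report list: `provenance` (package version, config digest,
#'   threshold concentration), `events`, `event_summary`, `estimates`,
#'   `estimate_summary`.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)

  if (isTRUE(cfg$input$synth)) {
    sc_cfg <- do.call(scene_config, c(
      list(events = do.call(data.frame, cfg$scene$events %||%
                              list(x_um = 600, y_um = 600, t_release_s = 20,
                                   amount_fmol = 0.25))),
      cfg$scene[setdiff(names(cfg$scene), "events")]))
    sc <- render_scene(sc_cfg)
    donor <- sc$donor; acceptor <- sc$acceptor
    px <- sc_cfg$pixel_size; dt <- sc_cfg$frame_interval
    bg <- sc_cfg$background
  } else {
    if (!is.null(cfg$input$interleaved)) {
      ch <- read_stack(cfg$input$interleaved,
                       channels = cfg$input$channels %||%
                         c("donor", "acceptor"))
      donor <- ch$donor; acceptor <- ch$acceptor
    } else {
      donor <- read_stack(cfg$input$donor)
      acceptor <- read_stack(cfg$input$acceptor)
    }
    if (!identical(dim(donor), dim(acceptor)))
      .io_error("donor and acceptor stacks disagree in dimensions")
    px <- cfg$metadata$pixel_size_um
    dt <- cfg$metadata$frame_interval_s
    bg <- cfg$input$background %||% 0
  }

  det_cfg <- do.call(detection_config, cfg$detection %||% list())
  stack <- preprocess(donor, acceptor, background = bg,
                      pixel_size = px, frame_interval = dt)
  events <- detect_events(stack, det_cfg)
  stats <- event_statistics(events)

  hill <- .pipeline_hill(cfg$dose %||% list())
  fold <- (cfg$dose %||% list())$fold_increase %||% det_cfg$binarize_fold
  C_star <- threshold_to_concentration(hill, fold)

  cal_csv <- (cfg$calibration %||% list())$csv
  curve <- if (!is.null(cal_csv) && file.exists(cal_csv)) {
    read_calibration(cal_csv)
  } else {
    dif <- cfg$diffusion %||% list()
    sample_interval <- dif$sample_interval %||% 1
    dif <- dif[setdiff(names(dif), "sample_interval")]
    dcfg <- do.call(diffusion_config, c(dif, list(C_thresh = C_star)))
    amounts <- (cfg$calibration %||% list())$amounts %||%
      exp(seq(log(0.02), log(2), length.out = 10))
    cv <- build_calibration(dcfg, sort(as.numeric(amounts)), sample_interval)
    if (!is.null(cal_csv)) write_calibration(cv, cal_csv)
    cv
  }

  cell_area <- (cfg$estimate %||% list())$cell_area_um2 %||% 200
  est <- if (stats$summary$n_events > 0)
    estimate_amounts(stats, curve, cell_area) else NULL

  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), cfg_file)
  digest <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)

  list(
    provenance = list(
      package = "rspaquant",
      version = as.character(utils::packageVersion("rspaquant")),
      config_md5 = digest,
      threshold_concentration_nM = C_star,
      n_frames = dim(donor)[3], pixel_size_um = px, frame_interval_s = dt),
    events = as.data.frame(events),
    event_summary = stats$summary,
    estimates = if (is.null(est)) data.frame() else est$events,
    estimate_summary = if (is.null(est)) data.frame(n_events = 0L)
      else est$summary)
}
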