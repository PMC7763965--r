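# End-to-end orchestration: frame equalization -> segmentation ->
# stabilization -> ensemble mask -> coordinate determination -> ST maps ->
# event counting, with the six method arms (manual / conventional / dnn,
# each with or without stabilization).

#' Pipeline configuration
#'
#' Collects every tunable of the counting pipeline with its default. The
#' defaults pin the reference operating point: red weight `lambda_red = 1.5`,
#' binarization thresholds 80 (conventional) and 150 (U-Net), reference
#' update period `period_p = 50` frames, and a 3x3 ST-map median filter.
#'
#' @param method segmentation arm: `"conventional"`, `"dnn"` or `"manual"`.
#' @param stabilize apply video stabilization (default TRUE).
#' @param period_p reference update period in frames.
#' @param lambda_red red-component weight of the color score.
#' @param threshold_conventional,threshold_dnn mask binarization thresholds.
#' @param equalize apply per-channel histogram equalization first.
#' @param median_kernel ST-map median filter size (odd).
#' @param sobel_axis ST-map Sobel variant (see [process_st_map()]).
#' @param thetas Radon angle grid in degrees.
#' @param neighborhood,min_fraction peak-picking parameters
#'   (see [detect_local_maxima()]).
#' @param angle_tolerance base-event angle window in degrees.
#' @param max_capillaries,min_area capillary instance selection.
#' @param roi_margin ROI margin in pixels.
#' @param channel scalar intensity channel sampled for the ST map.
#' @param seed seed for any stochastic component (U-Net initialization).
#' @return A validated list of class `wbc_config`.
#' @export
wbc_config <- function(method = c("conventional", "dnn", "manual"),
                       stabilize = TRUE, period_p = 50L, lambda_red = 1.5,
                       threshold_conventional = 80, threshold_dnn = 150,
                       equalize = TRUE, median_kernel = 3L,
                       sobel_axis = "magnitude", thetas = 0:179,
                       neighborhood = c(11L, 15L), min_fraction = 0.35,
                       angle_tolerance = 5, max_capillaries = 2L,
                       min_area = 200L, roi_margin = 2L, channel = "green",
                       seed = 1L) {
  method <- match.arg(method)
  stopifnot(period_p >= 1, median_kernel %% 2 == 1, min_fraction > 0,
            min_fraction <= 1, angle_tolerance > 0, max_capillaries >= 1,
            min_area >= 0, roi_margin >= 0)
  sp <- seg_params(lambda_red, threshold_conventional, threshold_dnn)
  structure(list(method = method, stabilize = stabilize,
                 period_p = as.integer(period_p), seg = sp,
                 equalize = equalize, median_kernel = as.integer(median_kernel),
                 sobel_axis = sobel_axis, thetas = thetas,
                 neighborhood = neighborhood, min_fraction = min_fraction,
                 angle_tolerance = angle_tolerance,
                 max_capillaries = as.integer(max_capillaries),
                 min_area = as.integer(min_area),
                 roi_margin = as.integer(roi_margin), channel = channel,
                 seed = as.integer(seed)),
            class = "wbc_config")
}

#' Arm name of a configuration, Table-style ("S-DNN", "Conventional", ...)
#' @param config a [wbc_config()].
#' @return Character arm label.
#' @export
arm_name <- function(config) {
  base <- c(conventional = "Conventional", dnn = "DNN", manual = "Manual")[config$method]
  if (config$stabilize) paste0("S-", base) else unname(base)
}

#' Count WBC events in a capillary video
#'
#' Runs the full counting pipeline on a loaded video: per-channel histogram
#' equalization; per-frame capillary segmentation (color score, U-Net, or a
#' user-supplied manual mask); label-based video stabilization with periodic
#' reference updates (optional); temporal ensemble mask; per-capillary
#' ordered coordinate determination; ST-map construction and enhancement; and
#' Radon-domain event counting with duplicate elimination.
#'
#' For the manual arm the supplied mask provides the capillary geometry while
#' translation vectors are still estimated from the color-score labels (a
#' single static mask carries no motion information).
#'
#' @param video a [video_stack()].
#' @param config a [wbc_config()].
#' @param mask manual capillary mask (matrix, [capillary_mask()], or path to
#'   an 8-bit PNG) — required for `method = "manual"`.
#' @param model trained [unet_build()] model — required for `method = "dnn"`.
#' @return An object of class `wbc_result`: per-capillary `event_sets`,
#'   `geometries`, `st_raw`, `st_processed`, the `ensemble` mask, the
#'   stabilization `trace` (or NULL), `config`, `video_info` and `skipped`
#'   (per-capillary error messages, if any).
#' @export
wbc_pipeline <- function(video, config = wbc_config(), mask = NULL,
                         model = NULL) {
  stopifnot(inherits(video, "video_stack"), inherits(config, "wbc_config"))
  if (config$method == "dnn" && is.null(model))
    stop("method 'dnn' requires a trained model", call. = FALSE)
  if (config$method == "manual" && is.null(mask))
    stop("method 'manual' requires a mask", call. = FALSE)
  eq <- if (config$equalize) equalize_frames(video) else video
  d <- dim(eq$frames[[1]])

  threshold <- switch(config$method,
                      conventional = config$seg$threshold_conventional,
                      dnn = config$seg$threshold_dnn,
                      manual = 128)
  seg_masks <- switch(config$method,
    conventional = segment_video(eq, "conventional", config$seg),
    dnn = segment_video(eq, "dnn", config$seg, model = model),
    manual = {
      if (is.character(mask)) mask <- round(png::readPNG(mask) * 255)
      if (inherits(mask, "capillary_mask")) mask <- mask$values
      if (length(dim(mask)) == 3L) mask <- mask[, , 1]
      rep(list(capillary_mask(mask, kind = if (all(mask %in% c(0, 255)))
        "binary" else "soft", method = "manual")), length(eq$frames))
    })
  reg_masks <- if (config$method == "manual")
    segment_video(eq, "conventional", config$seg) else seg_masks

  trace <- NULL
  if (config$stabilize) {
    # register on the labels, then shift frames and geometry masks alike
    st <- stabilize(eq, reg_masks, config$period_p)
    trace <- st$trace
    frames_s <- st$video
    geo_masks <- if (config$method == "manual") {
      seg_masks  # static mask already lives in reference coordinates
    } else st$masks
  } else {
    frames_s <- eq
    geo_masks <- seg_masks
  }
  ens <- ensemble_mask(geo_masks, threshold)

  instances <- extract_capillary_instances(ens, config$max_capillaries,
                                           config$min_area)
  event_sets <- list(); geometries <- list()
  st_raw <- list(); st_processed <- list(); skipped <- character(0)
  for (k in seq_along(instances)) {
    res_k <- tryCatch({
      tb <- trace_boundaries(instances[[k]])
      geom <- pair_coordinates(tb$internal, tb$external)
      geom <- build_intermediates(geom)
      geom$roi <- determine_roi(instances[[k]], config$roi_margin)
      vecs <- lapply(frames_s$frames, sample_capillary_vector,
                     geometry = geom, channel = config$channel)
      raw <- build_st_map(vecs, fps = video$fps, capillary_id = k)
      proc <- process_st_map(raw, config$median_kernel, config$sobel_axis)
      ev <- count_events(proc, thetas = config$thetas,
                         neighborhood = config$neighborhood,
                         min_fraction = config$min_fraction,
                         angle_tolerance = config$angle_tolerance,
                         fps = video$fps)
      list(geom = geom, raw = raw, proc = proc, ev = ev)
    }, error = function(e) e)
    if (inherits(res_k, "error")) {
      skipped <- c(skipped, sprintf("capillary %d: %s", k,
                                    conditionMessage(res_k)))
      warning(utils::tail(skipped, 1), call. = FALSE)
    } else {
      kk <- length(event_sets) + 1L
      event_sets[[kk]] <- res_k$ev
      geometries[[kk]] <- res_k$geom
      st_raw[[kk]] <- res_k$raw
      st_processed[[kk]] <- res_k$proc
    }
  }
  structure(list(event_sets = event_sets, geometries = geometries,
                 st_raw = st_raw, st_processed = st_processed,
                 ensemble = ens, trace = trace, config = config,
                 video_info = list(n_frames = length(video$frames),
                                   height = d[1], width = d[2],
                                   fps = video$fps, source = video$source),
                 skipped = skipped),
            class = "wbc_result")
}

#' @export
print.wbc_result <- function(x, ...) {
  counts <- vapply(x$event_sets, `[[`, 0L, "n_events")
  cat(sprintf("<wbc_result> arm %s | %d frames %dx%d @ %.4g fps\n",
              arm_name(x$config), x$video_info$n_frames, x$video_info$height,
              x$video_info$width, x$video_info$fps))
  if (length(counts) == 0) {
    cat("  no capillaries found\n")
  } else {
    for (k in seq_along(counts))
      cat(sprintf("  capillary %d: %d WBC events\n", k, counts[k]))
    cat(sprintf("  total: %d events\n", sum(counts)))
  }
  if (length(x$skipped)) cat("  skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.wbc_result <- function(object, ...) {
  print(object)
  if (!is.null(object$trace)) print(object$trace)
  for (k in seq_along(object$event_sets)) {
    cat(sprintf("-- capillary %d (n_points %d) --\n", k,
                object$geometries[[k]]$n_points))
    print(as.data.frame(object$event_sets[[k]]), row.names = FALSE)
  }
  invisible(object)
}

#' Plot a processed ST map with the reconstructed event lines
#'
#' @param x a `wbc_result`.
#' @param capillary capillary index.
#' @param which `"processed"` or `"raw"` map.
#' @param ... passed to [graphics::image()].
#' @export
plot.wbc_result <- function(x, capillary = 1L, which = "processed", ...) {
  if (length(x$st_processed) < capillary) stop("no such capillary", call. = FALSE)
  st <- if (which == "raw") x$st_raw[[capillary]] else x$st_processed[[capillary]]
  v <- st$values
  graphics::image(x = seq_len(ncol(v)) / st$fps, y = seq_len(nrow(v)),
                  z = t(v), col = grDevices::gray.colors(64, 0, 1),
                  xlab = "time [s]", ylab = "path position [px]",
                  main = sprintf("capillary %d (%s): %d events", capillary,
                                 arm_name(x$config),
                                 x$event_sets[[capillary]]$n_events), ...)
  for (e in x$event_sets[[capillary]]$events) {
    px <- e$line_pixels
    graphics::points(px[, 2] / st$fps, px[, 1], pch = ".", col = "cyan", cex = 2)
  }
  invisible(x)
}

#' Run the counting pipeline on a video path and write reports
#'
#' Thin orchestrator over [load_video()] and [wbc_pipeline()]: optionally
#' writes a JSON report (effective configuration, per-capillary counts and
#' events, stabilization summary), a per-event CSV table, diagnostic PNG
#' panels (equalized frame, ensemble mask, raw and processed ST maps with
#' reconstructed lines) and the translation-norm histogram.
#'
#' @param video_path frame directory (see [load_video()]) or a
#'   [video_stack()].
#' @param config a [wbc_config()].
#' @param out_dir output directory for reports, or NULL for no files.
#' @param mask,model forwarded to [wbc_pipeline()].
#' @param fps frames per second for directory input.
#' @return The [wbc_pipeline()] result, invisibly.
#' @export
run_pipeline <- function(video_path, config = wbc_config(), out_dir = NULL,
                         mask = NULL, model = NULL, fps = 30) {
  video <- if (inherits(video_path, "video_stack")) video_path
           else load_video(video_path, fps = fps)
  result <- wbc_pipeline(video, config, mask = mask, model = model)
  if (!is.null(out_dir)) write_report(result, out_dir)
  invisible(result)
}

#' Write the JSON/CSV/PNG report bundle of a pipeline result
#'
#' Writes `report.json` (effective configuration, per-capillary counts and
#' events, stabilization summary), `events.csv`, the ensemble-mask PNG, per
#' capillary the raw/processed ST-map PNGs, the numeric raw ST matrix as CSV
#' with a JSON axis sidecar, the sampling geometry (ROI and coordinate
#' lists) as JSON, the reconstructed-line overlay panel, and the
#' translation-norm histogram.
#'
#' @param result a `wbc_result`.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the report file paths.
#' @export
write_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  report <- list(
    arm = arm_name(cfg),
    config = list(method = cfg$method, stabilize = cfg$stabilize,
                  period_p = cfg$period_p, lambda_red = cfg$seg$lambda_red,
                  threshold_conventional = cfg$seg$threshold_conventional,
                  threshold_dnn = cfg$seg$threshold_dnn,
                  median_kernel = cfg$median_kernel,
                  min_fraction = cfg$min_fraction,
                  angle_tolerance = cfg$angle_tolerance,
                  neighborhood = cfg$neighborhood,
                  max_capillaries = cfg$max_capillaries,
                  min_area = cfg$min_area, channel = cfg$channel,
                  seed = cfg$seed),
    video = result$video_info,
    capillaries = lapply(seq_along(result$event_sets), function(k) {
      df <- as.data.frame(result$event_sets[[k]])
      list(id = k, n_events = result$event_sets[[k]]$n_events,
           n_points = result$geometries[[k]]$n_points,
           events = df[, c("theta", "z", "strength", "time_s")])
    }),
    skipped = result$skipped,
    stabilization = if (is.null(result$trace)) NULL else list(
      period_p = result$trace$period_p,
      reference_indices = result$trace$reference_indices,
      n_failed = sum(result$trace$failed),
      per_frame_vectors = unname(apply(result$trace$per_frame_vectors, 1,
                                       as.list)))
  )
  paths <- c(json = file.path(out_dir, "report.json"))
  jsonlite::write_json(report, paths["json"], auto_unbox = TRUE, digits = NA,
                       null = "null")
  # per-event CSV summary
  rows <- do.call(rbind, lapply(seq_along(result$event_sets), function(k) {
    df <- as.data.frame(result$event_sets[[k]])
    if (nrow(df)) cbind(capillary = k, df) else NULL
  }))
  paths["csv"] <- file.path(out_dir, "events.csv")
  utils::write.csv(rows %||% data.frame(), paths["csv"], row.names = FALSE)
  # PNG panels
  paths["ensemble"] <- file.path(out_dir, "ensemble_mask.png")
  png::writePNG(result$ensemble$values / 255, paths["ensemble"])
  for (k in seq_along(result$st_processed)) {
    p1 <- file.path(out_dir, sprintf("st_raw_cap%d.png", k))
    p2 <- file.path(out_dir, sprintf("st_processed_cap%d.png", k))
    png::writePNG(rescale255(result$st_raw[[k]]$values) / 255, p1)
    png::writePNG(result$st_processed[[k]]$values / 255, p2)
    paths[sprintf("st%d", k)] <- p2
    # numeric ST matrix with an axis-metadata sidecar
    pm <- file.path(out_dir, sprintf("st_raw_cap%d.csv", k))
    utils::write.table(result$st_raw[[k]]$values, pm, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(list(rows = "capillary path position (px, 1-based)",
                              cols = "frame index (1-based)",
                              fps = result$st_raw[[k]]$fps,
                              n_points = nrow(result$st_raw[[k]]$values),
                              n_frames = ncol(result$st_raw[[k]]$values)),
                         file.path(out_dir, sprintf("st_raw_cap%d.json", k)),
                         auto_unbox = TRUE, digits = NA)
    # sampling geometry for inspection and overlays
    g <- result$geometries[[k]]
    jsonlite::write_json(list(roi = g$roi, n_points = g$n_points,
                              internal_coords = g$internal_coords,
                              external_coords = g$external_coords),
                         file.path(out_dir, sprintf("geometry_cap%d.json", k)),
                         digits = NA)
    p3 <- file.path(out_dir, sprintf("st_lines_cap%d.png", k))
    grDevices::png(p3, width = 640, height = 480)
    plot(result, capillary = k)
    grDevices::dev.off()
    paths[sprintf("lines%d", k)] <- p3
  }
  if (!is.null(result$trace)) {
    p4 <- file.path(out_dir, "translation_norms.png")
    grDevices::png(p4, width = 480, height = 360)
    n2 <- sqrt(rowSums(result$trace$per_frame_vectors^2))
    graphics::hist(n2, breaks = 20, xlab = "translation L2 norm [px]",
                   main = "Per-frame translation norms")
    grDevices::dev.off()
    paths["norms"] <- p4
  }
  invisible(paths)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a pipeline JSON report against the bundled schema
#'
#' Structural check of the report written by [write_report()] against the
#' schema shipped in `inst/extdata/report-schema.json` (required fields and
#' their types).
#'
#' @param report path to a report JSON file, or the parsed list.
#' @return TRUE if valid, otherwise a character vector of problems.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(system.file("extdata", "report-schema.json",
                                            package = "capcount"))
  problems <- character(0)
  check <- function(obj, sch, path) {
    for (fld in names(sch$required)) {
      if (is.null(obj[[fld]])) {
        problems <<- c(problems, sprintf("%s: missing field '%s'", path, fld))
        next
      }
      want <- sch$required[[fld]]
      if (is.character(want) && length(want) == 1L) {
        ok <- switch(want,
                     number = is.numeric(unlist(obj[[fld]])),
                     string = is.character(unlist(obj[[fld]])),
                     boolean = is.logical(unlist(obj[[fld]])),
                     list = is.list(obj[[fld]]) || is.null(obj[[fld]]),
                     TRUE)
        if (!ok) problems <<- c(problems,
          sprintf("%s: field '%s' is not a %s", path, fld, want))
      } else if (is.list(want)) {
        check(obj[[fld]], list(required = want), paste0(path, ".", fld))
      }
    }
  }
  check(report, schema, "report")
  if (length(problems)) problems else TRUE
}
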