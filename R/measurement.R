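# Pipeline orchestration: nine-gaze inputs -> per-gaze per-eye deviation
# distances in the primary frame -> movement-percentage comparisons ->
# report serialization and overlay rendering.

#' Pipeline configuration
#'
#' @param reflex_threshold relative brightness threshold for reflex
#'   detection (fraction of in-limbus maximum; default 0.9).
#' @param reflex_floor absolute brightness floor for the no-reflex error
#'   (fraction of dynamic range; default 0.8).
#' @param circularity_threshold minor/major ratio above which an eccentric
#'   limbus fit is treated as circular (default 0.95).
#' @param sclera_limbus_ratio sclera/limbus radius ratio (adult default 2.5;
#'   exposed because the value is age-dependent).
#' @param min_component_area minimum connected-component area in pixels for
#'   eye splitting and speck removal (default 20).
#' @param comparison_spec list of ratio comparisons for
#'   [compare_excursions()]; each element is
#'   `list(label =, numerator = c(gaze =, eye =), denominator = c(gaze =, eye =))`.
#' @param anatomical_laterality if `TRUE`, report labels are mirrored so that
#'   "left"/"right" mean the subject's anatomical left/right eye instead of
#'   the image-left/image-right component (default `FALSE`).
#' @param dice_printed_variant use the non-standard DSC normalization in
#'   [segmentation_metrics()] (default `FALSE`).
#' @return named configuration list.
#' @export
strab_config <- function(reflex_threshold = 0.9, reflex_floor = 0.8,
                         circularity_threshold = 0.95,
                         sclera_limbus_ratio = 2.5, min_component_area = 20,
                         comparison_spec = NULL,
                         anatomical_laterality = FALSE,
                         dice_printed_variant = FALSE) {
  list(reflex_threshold = reflex_threshold, reflex_floor = reflex_floor,
       circularity_threshold = circularity_threshold,
       sclera_limbus_ratio = sclera_limbus_ratio,
       min_component_area = min_component_area,
       comparison_spec = comparison_spec,
       anatomical_laterality = anatomical_laterality,
       dice_printed_variant = dice_printed_variant)
}

#' Load a pipeline configuration from YAML or JSON
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return configuration list (unknown keys rejected).
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(strab_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_strab("strab_spec_error", "unknown config key(s): %s",
               paste(unknown, collapse = ", "))
  do.call(strab_config, vals)
}

#' Pixel-wise deviation distance
#'
#' Euclidean distance between a limbus center and the primary-gaze corneal
#' reflex point of the same eye, both in the primary frame.
#'
#' @param limbus_center,reflex `(x, y)` points.
#' @return distance in pixels (full precision; summaries round to 1 px).
#' @export
measure_deviation <- function(limbus_center, reflex) {
  a <- assert_point(limbus_center, "limbus_center")
  b <- assert_point(reflex, "reflex")
  sqrt(sum((a - b)^2))
}

#' Movement percentage between two excursion distances
#'
#' @param numerator_px impaired-side distance (px).
#' @param denominator_px reference distance (px); must be positive.
#' @return `100 * numerator / denominator` (full precision; reports round to
#'   1 decimal).
#' @export
movement_ratio <- function(numerator_px, denominator_px) {
  if (!is.finite(denominator_px) || denominator_px <= 0)
    stop_strab("strab_undefined_ratio", "denominator distance must be positive")
  100 * numerator_px / denominator_px
}

#' Evaluate a list of excursion comparisons on a movement report
#'
#' Supports within-eye comparisons (e.g. inward vs outward excursion of the
#' same eye, the trochlear-palsy presentation) and between-eye comparisons
#' (left vs right eye for the same direction, the abducens-palsy
#' presentation).
#'
#' @param report a `movement_report` from [run_pipeline()], or any list with
#'   a `measurements` data frame (columns `gaze`, `eye`, `distance_px`).
#' @param spec list of comparisons; each element
#'   `list(label =, numerator = c(gaze =, eye =), denominator = c(gaze =, eye =))`.
#' @return data frame with columns `label`, `numerator_px`,
#'   `denominator_px`, `percentage` (1-decimal rounding applied to
#'   `percentage`).
#' @export
compare_excursions <- function(report, spec) {
  meas <- report$measurements
  lookup <- function(ref) {
    i <- which(meas$gaze == ref[["gaze"]] & meas$eye == ref[["eye"]])
    if (length(i) != 1L)
      stop_strab("strab_spec_error", "no measurement for gaze '%s', eye '%s'",
                 ref[["gaze"]], ref[["eye"]])
    meas$distance_px[i]
  }
  rows <- lapply(spec, function(cmp) {
    num <- lookup(cmp$numerator); den <- lookup(cmp$denominator)
    data.frame(label = cmp$label, numerator_px = num, denominator_px = den,
               percentage = round(movement_ratio(num, den), 1))
  })
  do.call(rbind, rows)
}

# Resolve pipeline inputs into a named list of
# list(image=, sclera=, limbus=) per gaze, running the segmenter when masks
# are absent.
resolve_inputs <- function(inputs, segmenter) {
  if (inherits(inputs, "nine_gaze_set")) inputs <- inputs$scenes
  if (is.character(inputs) && length(inputs) == 1L)
    inputs <- read_nine_gaze_dir(inputs)
  missing_g <- setdiff(.gazes, names(inputs))
  if (length(missing_g))
    stop_strab("strab_input_error", "missing gaze input(s): %s",
               paste(missing_g, collapse = ", "))
  out <- list()
  for (g in .gazes) {
    el <- inputs[[g]]
    img <- if (!is.null(el$image)) to_gray(el$image)
    sclera <- el$sclera_mask %||% el$sclera
    limbus <- el$limbus_mask %||% el$limbus
    if (is.null(sclera) || is.null(limbus)) {
      if (is.null(segmenter) || is.null(img))
        stop_strab("strab_input_error",
                   "gaze '%s': masks absent and no segmenter/image available", g)
      if (is.null(sclera)) sclera <- segmenter(img, "sclera")
      if (is.null(limbus)) limbus <- segmenter(img, "limbus")
    }
    out[[g]] <- list(image = img, sclera = assert_mask(sclera),
                     limbus = assert_mask(limbus))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a nine-gaze input directory
#'
#' Expects `<gaze>.png` per gaze label, plus optional `<gaze>.sclera.png`
#' and `<gaze>.limbus.png` masks (as written by [write_scene_set()]).
#' @param dir directory path.
#' @return named list of per-gaze inputs for [run_pipeline()].
#' @export
read_nine_gaze_dir <- function(dir) {
  out <- list()
  for (g in .gazes) {
    imgp <- file.path(dir, paste0(g, ".png"))
    if (!file.exists(imgp))
      stop_strab("strab_input_error", "missing image for gaze '%s': %s", g, imgp)
    el <- list(image = read_image_png(imgp))
    for (m in c("sclera", "limbus")) {
      mp <- file.path(dir, paste0(g, ".", m, ".png"))
      if (file.exists(mp)) el[[m]] <- read_mask_png(mp)
    }
    out[[g]] <- el
  }
  out
}

#' Run the full strabismus measurement pipeline on a nine-gaze set
#'
#' Stages: (1) obtain sclera and limbus masks per gaze (provided, or from
#' the pluggable `segmenter`); (2) measure the primary gaze's reference line
#' from its sclera mask; (3) register the eight eccentric gazes onto the
#' primary frame; (4) model the primary limbus circles (minimum enclosing
#' circle), sclera circles (2.5 x limbus radius) and corneal reflex points;
#' (5) per registered eccentric gaze and eye, fit an ellipse to the limbus
#' component, recover its center, and measure the pixel distance to the same
#' eye's primary reflex; (6) evaluate the configured ratio comparisons.
#' Deterministic for fixed inputs and configuration.
#'
#' @param inputs a `nine_gaze_set`, a directory path (see
#'   [read_nine_gaze_dir()]), or a named list over the nine gaze labels with
#'   elements `image` and/or `sclera`/`limbus` masks.
#' @param config configuration from [strab_config()].
#' @param segmenter optional function `(image, target) -> mask` used when
#'   masks are not supplied (default [segment_threshold()] when images are
#'   present).
#' @return a `movement_report`: list with `measurements` (data frame: gaze,
#'   eye, limbus center x/y, `distance_px`), `ratios` (from
#'   [compare_excursions()], `NULL` without a comparison spec), `primary`
#'   (per-eye limbus/sclera circles and reflex points) and `transforms`
#'   (per-gaze registration transforms).
#' @export
run_pipeline <- function(inputs, config = strab_config(),
                         segmenter = segment_threshold) {
  if (inherits(inputs, "nine_gaze_set") && is.null(config$comparison_spec))
    config$comparison_spec <- attr(inputs$deviation_spec, "comparison_spec")
  inp <- resolve_inputs(inputs, segmenter)
  min_area <- config$min_component_area

  with_ctx <- function(gaze, expr) {
    tryCatch(expr, strab_error = function(e) {
      stop_strab(class(e)[1], "gaze '%s': %s", gaze, conditionMessage(e))
    })
  }

  primary <- inp$primary
  primary_line <- with_ctx("primary", scene_reference_line(primary$sclera, min_area))

  # primary-gaze eye models
  sclera_comps <- with_ctx("primary", split_eyes(primary$sclera, min_area))
  limbus_comps <- with_ctx("primary", split_eyes(primary$limbus, min_area))
  eyes <- c("left", "right")
  primary_models <- list()
  for (e in eyes) {
    limbus <- min_enclosing_circle(limbus_comps[[e]])
    sclera <- model_sclera(sclera_comps[[e]], limbus$radius,
                           config$sclera_limbus_ratio)
    reflex <- with_ctx("primary", detect_corneal_reflex(
      primary$image, limbus_comps[[e]],
      threshold_frac = config$reflex_threshold, floor = config$reflex_floor))
    primary_models[[e]] <- list(limbus = limbus, sclera = sclera, reflex = reflex)
  }

  transforms <- list(primary = similarity_transform())
  rows <- list()
  for (g in setdiff(.gazes, "primary")) {
    # solve the registration transform from the scene's own reference line;
    # geometry is fitted in the scene's native frame and mapped through the
    # transform (a similarity commutes with ellipse fitting), which avoids
    # the aliasing noise of fitting on resampled masks
    line_g <- with_ctx(g, scene_reference_line(inp[[g]]$sclera, min_area))
    tf <- with_ctx(g, solve_similarity(line_g, primary_line))
    transforms[[g]] <- tf
    lcomps <- with_ctx(g, split_eyes(inp[[g]]$limbus, min_area))
    scomps <- with_ctx(g, split_eyes(inp[[g]]$sclera, min_area))
    for (e in eyes) {
      radius <- primary_models[[e]]$limbus$radius
      fit <- with_ctx(g, transform_ellipse(fit_ellipse(lcomps[[e]]), tf))
      sclera_g <- with_ctx(g, model_sclera(scomps[[e]], radius,
                                           config$sclera_limbus_ratio))
      sclera_g <- circle(transform_points(tf, sclera_g$center), sclera_g$radius)
      ctr <- with_ctx(g, recover_limbus_center(
        fit, radius, sclera_g, config$circularity_threshold))
      dist <- measure_deviation(ctr$center, primary_models[[e]]$reflex)
      rows[[length(rows) + 1L]] <- data.frame(
        gaze = g, eye = e, x = ctr$center[1], y = ctr$center[2],
        distance_px = dist)
    }
  }
  measurements <- do.call(rbind, rows)
  rownames(measurements) <- NULL
  if (isTRUE(config$anatomical_laterality)) {
    # image-left component is the subject's anatomical right eye
    measurements$eye <- ifelse(measurements$eye == "left", "right", "left")
    primary_models <- list(left = primary_models$right,
                           right = primary_models$left)
  }

  report <- structure(list(measurements = measurements, ratios = NULL,
                           primary = primary_models, transforms = transforms,
                           config = config),
                      class = "movement_report")
  if (!is.null(config$comparison_spec))
    report$ratios <- compare_excursions(report, config$comparison_spec)
  report
}

#' @export
print.movement_report <- function(x, ...) {
  cat("<movement_report>\n")
  m <- x$measurements
  m$distance_px <- round(m$distance_px)  # summaries print integer pixels
  m$x <- round(m$x, 1); m$y <- round(m$y, 1)
  print(m, row.names = FALSE)
  if (!is.null(x$ratios)) {
    cat("\nmovement percentages:\n")
    r <- x$ratios
    r$numerator_px <- round(r$numerator_px)
    r$denominator_px <- round(r$denominator_px)
    print(r, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a movement report to JSON
#'
#' Distances are reported as integers and percentages to one decimal (the
#' presentation convention); limbus centers and transforms keep full
#' precision.
#'
#' @param report a `movement_report`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
report_to_json <- function(report, path = NULL) {
  m <- report$measurements
  obj <- list(
    measurements = lapply(seq_len(nrow(m)), function(i) list(
      gaze = m$gaze[i], eye = m$eye[i],
      limbus_center = c(m$x[i], m$y[i]),
      distance_px = round(m$distance_px[i]))),
    ratios = if (!is.null(report$ratios))
      lapply(seq_len(nrow(report$ratios)), function(i) list(
        label = report$ratios$label[i],
        numerator_px = round(report$ratios$numerator_px[i]),
        denominator_px = round(report$ratios$denominator_px[i]),
        percentage = report$ratios$percentage[i])),
    transforms = lapply(report$transforms, transform_to_list)
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Export the ratio table as CSV
#'
#' Columns mirror the clinical presentation: comparison label, the two
#' pixel distances (integer), and the percentage (1 decimal).
#' @param report a `movement_report` with a non-`NULL` ratio table.
#' @param path output CSV path.
#' @return the data frame written, invisibly.
#' @export
report_to_csv <- function(report, path) {
  if (is.null(report$ratios))
    stop_strab("strab_input_error", "report has no ratio table")
  df <- report$ratios
  df$numerator_px <- round(df$numerator_px)
  df$denominator_px <- round(df$denominator_px)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

# Overlay rendering -----------------------------------------------------

draw_circle_px <- function(img, center, radius, value) {
  n <- max(16L, ceiling(2 * pi * radius))
  th <- seq(0, 2 * pi, length.out = n + 1L)[-1L]
  xs <- round(center[1] + radius * cos(th)); ys <- round(center[2] + radius * sin(th))
  ok <- xs >= 0 & xs < ncol(img) & ys >= 0 & ys < nrow(img)
  img[cbind(ys[ok] + 1L, xs[ok] + 1L)] <- value
  img
}

draw_segment_px <- function(img, p, q, value) {
  n <- max(2L, ceiling(sqrt(sum((p - q)^2))) * 2L)
  t <- seq(0, 1, length.out = n)
  xs <- round(p[1] + t * (q[1] - p[1])); ys <- round(p[2] + t * (q[2] - p[2]))
  ok <- xs >= 0 & xs < ncol(img) & ys >= 0 & ys < nrow(img)
  img[cbind(ys[ok] + 1L, xs[ok] + 1L)] <- value
  img
}

#' Render an annotated overlay of the measurement
#'
#' Draws, per eye model: the limbus circle, the sclera circle, a cross-hair
#' at the reflex point, and (per measurement) the center-to-reflex segment.
#' Annotations are purely presentational; the drawing-call log (attribute
#' `draw_log`) records what was drawn so tests need not inspect pixels.
#'
#' @param image numeric matrix in `[0, 1]` (the primary-frame image).
#' @param eye_models named list (eye -> list(limbus, sclera, reflex)), as in
#'   a report's `primary` field.
#' @param measurements data frame of measurements in the same frame (may
#'   have zero rows).
#' @param out_path optional PNG output path.
#' @return the annotated image matrix with attribute `draw_log` (character
#'   vector of drawing calls); written to `out_path` when given.
#' @export
render_overlay <- function(image, eye_models, measurements = NULL,
                           out_path = NULL) {
  img <- to_gray(image)
  log <- character(0)
  for (e in names(eye_models)) {
    em <- eye_models[[e]]
    img <- draw_circle_px(img, em$limbus$center, em$limbus$radius, 1)
    log <- c(log, sprintf("circle:limbus:%s", e))
    if (!is.null(em$sclera)) {
      img <- draw_circle_px(img, em$sclera$center, em$sclera$radius, 1)
      log <- c(log, sprintf("circle:sclera:%s", e))
    }
    if (!is.null(em$reflex)) {
      r <- em$reflex
      img <- draw_segment_px(img, r - c(4, 0), r + c(4, 0), 1)
      img <- draw_segment_px(img, r - c(0, 4), r + c(0, 4), 1)
      log <- c(log, sprintf("crosshair:reflex:%s", e))
    }
  }
  if (!is.null(measurements) && nrow(measurements) > 0) {
    for (i in seq_len(nrow(measurements))) {
      e <- measurements$eye[i]
      if (is.null(eye_models[[e]]$reflex)) next
      img <- draw_segment_px(img, c(measurements$x[i], measurements$y[i]),
                             eye_models[[e]]$reflex, 1)
      log <- c(log, sprintf("segment:distance:%s:%s", measurements$gaze[i], e))
    }
  }
  attr(img, "draw_log") <- log
  if (!is.null(out_path)) write_image_png(img, out_path)
  img
}
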