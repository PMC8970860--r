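# Forward renderer for synthetic nine-gaze eye scenes.
#
# The rendered world is deliberately simple: each eye is a flat eyeball disk
# (the sclera) whose radius is 2.5 x the limbus radius, with the limbus disk
# displaced from the eyeball center by the gaze offset, and -- in the primary
# gaze only -- a small near-white specular blob at the corneal reflex point.
# Camera jitter between gaze frames is a similarity transform applied to the
# rendered scene.  Every scene carries exhaustive ground truth so each
# downstream stage can be validated independently.

.gazes <- c("up_left", "up", "up_right", "left", "primary", "right",
            "down_left", "down", "down_right")

.gaze_dirs <- list(
  up_left = c(-1, -1) / sqrt(2), up = c(0, -1), up_right = c(1, -1) / sqrt(2),
  left = c(-1, 0), primary = c(0, 0), right = c(1, 0),
  down_left = c(-1, 1) / sqrt(2), down = c(0, 1), down_right = c(1, 1) / sqrt(2)
)

#' The nine cardinal gaze labels
#'
#' Fixed vocabulary used throughout the package, ordered top-left to
#' bottom-right with `"primary"` (straight ahead) in the middle.
#' @return character vector of 9 labels.
#' @export
gaze_labels <- function() .gazes

#' Default rendering options for synthetic scenes
#'
#' Intensities are fractions of the dynamic range: dark background, mid-gray
#' sclera, dark limbus, near-white reflex, chosen to give a threshold
#' segmenter unambiguous targets.
#' In addition to the intensity levels, `canthus_px` controls a small nasal
#' canthus wedge appended to each visible sclera region (apex `canthus_px`
#' beyond the eyeball disk, pointing at the facial midline).  A bare disk
#' has no rotation-covariant nasal landmark -- its rasterized horizontal
#' extreme is a tall chord whose top jumps by several pixels with subpixel
#' alignment -- so without a canthus the reference line the registration
#' depends on cannot be measured stably in any frame.  Set `canthus_px = 0`
#' for pure disks.
#'
#' @param ... overrides for `background`, `sclera`, `limbus`, `reflex`,
#'   `reflex_radius`, `canthus_px`, `noise_sd`.
#' @return named list of render options.
#' @export
render_options <- function(...) {
  opts <- list(background = 0.1, sclera = 0.75, limbus = 0.35,
               reflex = 0.98, reflex_radius = 2, canthus_px = 2, noise_sd = 0)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(opts))
  if (length(unknown))
    stop_strab("strab_spec_error", "unknown render option(s): %s",
               paste(unknown, collapse = ", "))
  utils::modifyList(opts, dots)
}

#' Parameters of one synthetic eye
#'
#' @param limbus_radius_px positive limbus radius in pixels.
#' @param sclera_center `(x, y)` eyeball center in pixel coordinates.
#' @param gaze_offset `(x, y)` displacement of the limbus center from the
#'   eyeball center; its norm must not exceed `(ratio - 1) * limbus_radius_px`
#'   so the limbus disk stays inside the eyeball disk.
#' @param reflex_point optional `(x, y)` corneal reflex location (rendered
#'   only when non-`NULL`; by convention present in the primary gaze).
#' @param sclera_limbus_ratio eyeball-to-limbus radius ratio (adult default
#'   2.5).
#' @return an `eye_params` object.
#' @export
eye_params <- function(limbus_radius_px, sclera_center, gaze_offset = c(0, 0),
                       reflex_point = NULL, sclera_limbus_ratio = 2.5) {
  if (!is.numeric(limbus_radius_px) || length(limbus_radius_px) != 1L ||
      !is.finite(limbus_radius_px) || limbus_radius_px <= 0)
    stop_strab("strab_invalid_geometry", "limbus_radius_px must be positive")
  sclera_center <- assert_point(sclera_center, "sclera_center")
  gaze_offset <- assert_point(gaze_offset, "gaze_offset")
  sclera_radius <- sclera_limbus_ratio * limbus_radius_px
  if (sqrt(sum(gaze_offset^2)) > sclera_radius - limbus_radius_px + 1e-9)
    stop_strab("strab_invalid_geometry",
               "|gaze_offset| = %.2f px pushes the limbus outside the eyeball (max %.2f px)",
               sqrt(sum(gaze_offset^2)), sclera_radius - limbus_radius_px)
  if (!is.null(reflex_point)) reflex_point <- assert_point(reflex_point, "reflex_point")
  structure(list(limbus_radius_px = limbus_radius_px,
                 sclera_center = sclera_center,
                 sclera_radius_px = sclera_radius,
                 gaze_offset = gaze_offset,
                 limbus_center = sclera_center + gaze_offset,
                 reflex_point = reflex_point),
            class = "eye_params")
}

# Medial-canthus wedge: blunt-tipped trapezoid reaching canthus_px beyond
# the eyeball disk along the nasal unit direction `dir`, half-width growing
# at slope 1/2 back to the disk but never below 1.25 px.  The blunt tip
# guarantees the tip column always contains pixel centers, so the measured
# innermost point is stable to about a pixel in every frame.
canthus_wedge <- function(image_shape, eye, dir, canthus_px) {
  g <- pixel_grid(image_shape)
  ctr <- eye$sclera_center; r <- eye$sclera_radius_px
  dx <- g$x - ctr[1]; dy <- g$y - ctr[2]
  t <- dx * dir[1] + dy * dir[2]           # along the nasal axis
  perp <- abs(-dx * dir[2] + dy * dir[1])
  t >= r - canthus_px & t <= r + canthus_px &
    perp <= pmax(1.25, (r + canthus_px - t) / 2)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Render one synthetic scene (two eyes, one gaze)
#'
#' @param eyes list with `left` and `right` [eye_params()] (image-left and
#'   image-right eye).
#' @param image_shape integer `(height, width)`; default `c(512, 512)`.
#' @param options render options from [render_options()].
#' @param gaze gaze label attached to the scene.
#' @param seed optional seed for the additive pixel noise (no effect when
#'   `noise_sd = 0`, the default).
#' @param roll_deg camera roll applied to the nasal canthus direction
#'   (degrees, from +x toward +y); used when rendering a jittered frame
#'   analytically.
#' @return a `synthetic_scene`: list with `image` (numeric matrix in `[0,1]`),
#'   `sclera_mask` (visible sclera, i.e. eyeball minus limbus), `limbus_mask`
#'   (full limbus disks), `gaze`, and `truth` (the `eyes` list).
#' @export
make_eye_scene <- function(eyes, image_shape = c(512, 512),
                           options = render_options(), gaze = "primary",
                           seed = NULL, roll_deg = 0) {
  if (!all(c("left", "right") %in% names(eyes)))
    stop_strab("strab_input_error", "eyes must have components 'left' and 'right'")
  for (e in eyes[c("left", "right")])
    if (!inherits(e, "eye_params"))
      stop_strab("strab_input_error", "each eye must be an eye_params object")
  h <- image_shape[1]; w <- image_shape[2]
  for (side in c("left", "right")) {
    e <- eyes[[side]]
    if (e$sclera_center[1] - e$sclera_radius_px < 0 ||
        e$sclera_center[1] + e$sclera_radius_px > w - 1 ||
        e$sclera_center[2] - e$sclera_radius_px < 0 ||
        e$sclera_center[2] + e$sclera_radius_px > h - 1)
      stop_strab("strab_invalid_geometry", "%s eyeball disk out of image bounds", side)
  }
  sep <- sqrt(sum((eyes$left$sclera_center - eyes$right$sclera_center)^2))
  if (sep <= eyes$left$sclera_radius_px + eyes$right$sclera_radius_px)
    stop_strab("strab_invalid_geometry", "eyeball disks overlap (separation %.1f px)", sep)
  if (eyes$left$sclera_center[1] >= eyes$right$sclera_center[1])
    stop_strab("strab_invalid_geometry", "'left' eye must lie left of 'right' eye in the image")

  eye_disks <- lapply(eyes[c("left", "right")], function(e)
    disk_mask(image_shape, e$sclera_center, e$sclera_radius_px))
  limbus_disks <- lapply(eyes[c("left", "right")], function(e)
    disk_mask(image_shape, e$limbus_center, e$limbus_radius_px))
  eyeball <- eye_disks$left | eye_disks$right
  if (options$canthus_px > 0) {
    # nasal canthus wedge per eye: apex canthus_px beyond the eyeball disk,
    # pointing at the facial midline (+x for the image-left eye), rotated
    # with the camera roll
    th <- roll_deg * pi / 180
    nasal <- c(cos(th), sin(th))
    eyeball <- eyeball |
      canthus_wedge(image_shape, eyes$left, nasal, options$canthus_px) |
      canthus_wedge(image_shape, eyes$right, -nasal, options$canthus_px)
  }
  limbus <- limbus_disks$left | limbus_disks$right
  sclera <- eyeball & !limbus

  img <- matrix(options$background, h, w)
  img[sclera] <- options$sclera
  img[limbus] <- options$limbus
  for (e in eyes[c("left", "right")]) {
    if (!is.null(e$reflex_point))
      img[disk_mask(image_shape, e$reflex_point, options$reflex_radius)] <- options$reflex
  }
  if (options$noise_sd > 0) {
    img <- with_seed(seed,
      img + matrix(stats::rnorm(h * w, 0, options$noise_sd), h, w))
    img <- pmin(pmax(img, 0), 1)
  }
  structure(list(image = img, sclera_mask = sclera, limbus_mask = limbus,
                 gaze = gaze, truth = eyes[c("left", "right")]),
            class = "synthetic_scene")
}

#' Equal-excursion deviation specification
#'
#' The baseline (healthy) stated world: in every eccentric gaze both eyes
#' move by `excursion_px` along the gaze direction (diagonals normalized to
#' the same excursion magnitude); the primary gaze has zero offset.
#'
#' @param excursion_px gaze excursion magnitude in pixels (default 30 at the
#'   512-px scene scale).
#' @return named list over the nine gaze labels; each entry has `left` and
#'   `right` `(x, y)` offsets.
#' @export
gaze_deviation_spec <- function(excursion_px = 30) {
  spec <- lapply(.gaze_dirs, function(d) {
    off <- d * excursion_px
    list(left = off, right = off)
  })
  structure(spec, class = "deviation_spec")
}

#' Cranial-nerve-palsy deviation presets
#'
#' Scales the excursion of the affected eye(s)/direction(s) relative to the
#' baseline equal-excursion world:
#' \describe{
#'   \item{`CN4_bilateral`}{trochlear palsy in both eyes: the downward-inward
#'     excursion of each eye (gaze `down_right` for the image-left eye,
#'     `down_left` for the image-right eye) is scaled by `ratio`
#'     (default 0.9).}
#'   \item{`CN6_left`}{abducens palsy of the image-left eye: its outward
#'     (leftward) excursion component is scaled by `ratio` (default 0.3);
#'     inward excursion stays matched to the other eye.}
#' }
#' The returned spec carries a `comparison_spec` attribute with the ratio
#' comparisons that quantify the deficit (within-eye for CN4, between-eye for
#' CN6), usable directly as `config$comparison_spec` in [run_pipeline()].
#'
#' @param name preset name, `"CN4_bilateral"` or `"CN6_left"`.
#' @param excursion_px healthy excursion magnitude in pixels.
#' @param ratio impaired/normal excursion ratio in `(0, 1]`; preset default
#'   0.9 for CN4, 0.3 for CN6.
#' @return a `deviation_spec` (see [gaze_deviation_spec()]) with attributes
#'   `comparison_spec` and `ratio`.
#' @export
simulate_palsy_preset <- function(name, excursion_px = 30, ratio = NULL) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("CN4_bilateral", "CN6_left"))
    stop_strab("strab_spec_error", "unknown palsy preset: %s",
               paste(as.character(name), collapse = ", "))
  spec <- gaze_deviation_spec(excursion_px)
  if (name == "CN4_bilateral") {
    if (is.null(ratio)) ratio <- 0.9
    spec$down_right$left <- spec$down_right$left * ratio
    spec$down_left$right <- spec$down_left$right * ratio
    comparison <- list(
      list(label = "left_eye_down_inward_vs_outward",
           numerator = c(gaze = "down_right", eye = "left"),
           denominator = c(gaze = "down_left", eye = "left")),
      list(label = "right_eye_down_inward_vs_outward",
           numerator = c(gaze = "down_left", eye = "right"),
           denominator = c(gaze = "down_right", eye = "right")))
  } else {
    if (is.null(ratio)) ratio <- 0.3
    for (g in c("left", "up_left", "down_left"))
      spec[[g]]$left[1] <- spec[[g]]$left[1] * ratio
    comparison <- list(
      list(label = "outwards_left_vs_right",
           numerator = c(gaze = "left", eye = "left"),
           denominator = c(gaze = "right", eye = "right")),
      list(label = "inwards_left_vs_right",
           numerator = c(gaze = "right", eye = "left"),
           denominator = c(gaze = "left", eye = "right")))
  }
  if (ratio <= 0 || ratio > 1)
    stop_strab("strab_spec_error", "ratio must be in (0, 1]")
  structure(spec, comparison_spec = comparison, ratio = ratio, preset = name,
            class = "deviation_spec")
}

#' Default two-eye subject at the 512-px scene scale
#'
#' Eyeballs on the horizontal midline, symmetric about the vertical facial
#' midline at the image center.
#' @param image_shape integer `(height, width)`.
#' @param limbus_radius_px limbus radius in pixels (default 24; eyeball
#'   radius is 2.5 x that).
#' @param eye_half_separation_px distance from facial midline to each eyeball
#'   center (default 110).
#' @return list with `left` and `right` baseline [eye_params()].
#' @export
default_subject <- function(image_shape = c(512, 512), limbus_radius_px = 24,
                            eye_half_separation_px = 110) {
  cx <- (image_shape[2] - 1) / 2
  cy <- (image_shape[1] - 1) / 2
  list(
    left = eye_params(limbus_radius_px, c(cx - eye_half_separation_px, cy)),
    right = eye_params(limbus_radius_px, c(cx + eye_half_separation_px, cy))
  )
}

#' Sample a random camera-jitter transform
#'
#' Defaults model hand-held/tripod photography of a seated subject between
#' shots of one sitting: up to +/-10 percent distance change (scale),
#' +/-10 degrees of camera roll, and +/-20 px translation at the 512-px
#' scene scale.
#'
#' @param image_shape `(height, width)`; the pivot is the image center.
#' @param scale_range,rotation_range,translation_range uniform sampling
#'   ranges (scale factor, degrees, px).
#' @return a [similarity_transform()].
#' @export
sample_jitter <- function(image_shape, scale_range = c(0.9, 1.1),
                          rotation_range = c(-10, 10),
                          translation_range = c(-20, 20)) {
  similarity_transform(
    scale = stats::runif(1, scale_range[1], scale_range[2]),
    rotation_deg = stats::runif(1, rotation_range[1], rotation_range[2]),
    translation = stats::runif(2, translation_range[1], translation_range[2]),
    pivot = c((image_shape[2] - 1) / 2, (image_shape[1] - 1) / 2)
  )
}

#' Render a full nine-gaze scene set with ground truth
#'
#' The primary-gaze scene carries a reflex blob per eye at the primary limbus
#' center; each non-primary scene is rendered in the primary camera frame and
#' then warped by its per-gaze camera jitter (bilinear for the image,
#' nearest-neighbor for the masks).  Ground truth records the true limbus
#' centers in the primary frame and the jitter transforms.
#'
#' @param subject baseline eyes from [default_subject()] (gaze offsets and
#'   reflex points are ignored; geometry comes from `deviation_spec`).
#' @param deviation_spec per-gaze per-eye offsets from
#'   [gaze_deviation_spec()] or [simulate_palsy_preset()].
#' @param jitter_spec `"random"` (default; per-gaze similarity jitter from
#'   [sample_jitter()] with ranges `jitter_ranges`), `"identity"`, or a named
#'   list of [similarity_transform()]s for the non-primary gazes.
#' @param jitter_ranges optional list overriding [sample_jitter()] ranges
#'   (`scale_range`, `rotation_range`, `translation_range`).
#' @param seed seed for the jitter sampling (and render noise, if enabled).
#' @param image_shape integer `(height, width)`.
#' @param options render options from [render_options()].
#' @return a `nine_gaze_set`: list with `scenes` (named list of 9
#'   `synthetic_scene`s), `truth` (per-gaze per-eye `eye_params` in the
#'   primary frame, `jitter` transforms, `image_shape`), and the
#'   `deviation_spec` used.
#' @export
make_nine_gaze_set <- function(subject = default_subject(),
                               deviation_spec = gaze_deviation_spec(),
                               jitter_spec = "random", seed = NULL,
                               image_shape = c(512, 512),
                               options = render_options(),
                               jitter_ranges = list()) {
  missing_g <- setdiff(.gazes, names(deviation_spec))
  if (length(missing_g))
    stop_strab("strab_spec_error", "deviation_spec missing gaze label(s): %s",
               paste(missing_g, collapse = ", "))

  jitter <- with_seed(seed, {
    if (identical(jitter_spec, "identity")) {
      stats::setNames(lapply(.gazes, function(g) similarity_transform()), .gazes)
    } else if (identical(jitter_spec, "random")) {
      j <- lapply(.gazes, function(g) {
        if (g == "primary") similarity_transform()
        else do.call(sample_jitter, c(list(image_shape), jitter_ranges))
      })
      stats::setNames(j, .gazes)
    } else {
      j <- stats::setNames(lapply(.gazes, function(g) similarity_transform()), .gazes)
      for (g in names(jitter_spec)) {
        if (!g %in% .gazes)
          stop_strab("strab_spec_error", "unknown gaze label in jitter_spec: %s", g)
        if (g != "primary") j[[g]] <- jitter_spec[[g]]
      }
      j
    }
  })

  gaze_eyes <- list()
  for (g in .gazes) {
    dev <- deviation_spec[[g]]
    gaze_eyes[[g]] <- list(
      left = eye_params(subject$left$limbus_radius_px, subject$left$sclera_center,
                        gaze_offset = dev$left,
                        reflex_point = if (g == "primary")
                          subject$left$sclera_center + dev$left),
      right = eye_params(subject$right$limbus_radius_px, subject$right$sclera_center,
                         gaze_offset = dev$right,
                         reflex_point = if (g == "primary")
                           subject$right$sclera_center + dev$right))
  }

  # Jittered frames are rendered analytically from the transformed geometry
  # (a jittered camera re-images the continuous scene; warping the primary
  # raster would resample away subpixel structure such as the canthus apex).
  scenes <- list()
  for (g in .gazes) {
    J <- jitter[[g]]
    if (transform_is_identity(J)) {
      sc <- make_eye_scene(gaze_eyes[[g]], image_shape, options, gaze = g,
                           seed = seed)
    } else {
      af <- transform_affine(J)
      eyes_j <- lapply(gaze_eyes[[g]], function(e) eye_params(
        limbus_radius_px = J$scale * e$limbus_radius_px,
        sclera_center = transform_points(J, e$sclera_center),
        gaze_offset = as.numeric(af$A %*% e$gaze_offset),
        reflex_point = if (!is.null(e$reflex_point))
          transform_points(J, e$reflex_point)))
      sc <- make_eye_scene(eyes_j, image_shape, options, gaze = g,
                           seed = seed, roll_deg = J$rotation_deg)
    }
    sc$truth <- gaze_eyes[[g]]
    sc$truth$jitter <- J
    scenes[[g]] <- sc
  }

  structure(list(
    scenes = scenes,
    truth = list(eyes = gaze_eyes, jitter = jitter, image_shape = image_shape),
    deviation_spec = deviation_spec
  ), class = "nine_gaze_set")
}

#' Write a nine-gaze set to disk
#'
#' Emits `<gaze>.png` (8-bit grayscale image), `<gaze>.sclera.png` and
#' `<gaze>.limbus.png` mask PNGs, plus a `ground_truth.json` sidecar with the
#' true geometry and jitter transforms.
#'
#' @param set a `nine_gaze_set` from [make_nine_gaze_set()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene_set <- function(set, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (g in names(set$scenes)) {
    sc <- set$scenes[[g]]
    write_image_png(sc$image, file.path(dir, paste0(g, ".png")))
    write_mask_png(sc$sclera_mask, file.path(dir, paste0(g, ".sclera.png")))
    write_mask_png(sc$limbus_mask, file.path(dir, paste0(g, ".limbus.png")))
  }
  truth <- lapply(names(set$truth$eyes), function(g) {
    ge <- set$truth$eyes[[g]]
    list(gaze = g,
         left = list(limbus_center = as.numeric(ge$left$limbus_center),
                     limbus_radius_px = ge$left$limbus_radius_px,
                     sclera_center = as.numeric(ge$left$sclera_center),
                     reflex_point = if (!is.null(ge$left$reflex_point))
                       as.numeric(ge$left$reflex_point)),
         right = list(limbus_center = as.numeric(ge$right$limbus_center),
                      limbus_radius_px = ge$right$limbus_radius_px,
                      sclera_center = as.numeric(ge$right$sclera_center),
                      reflex_point = if (!is.null(ge$right$reflex_point))
                        as.numeric(ge$right$reflex_point)),
         jitter = transform_to_list(set$truth$jitter[[g]]))
  })
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
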