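# Segmenter contract, reference threshold segmenter, mask resizing, and
# confusion-matrix evaluation metrics.
#
# The measurement pipeline is agnostic to segmenter provenance: any function
# (image, target) -> BinaryMask can be plugged in (e.g. a trained network's
# predictions loaded from PNG).  The reference implementation below is an
# intensity-band threshold segmenter matched to the synthetic renderer.

#' Threshold segmenter for synthetic scenes
#'
#' Marks pixels whose intensity falls in the target's configured band, then
#' removes connected specks smaller than `min_area` (8-connectivity).  Bands
#' default to the synthetic renderer's intensity levels: sclera 0.75, limbus
#' 0.35, against background 0.1 and reflex 0.98.
#'
#' @param image numeric matrix in `[0, 1]` (RGB arrays are converted to
#'   luminance).
#' @param target `"sclera"` or `"limbus"`.
#' @param bands named list of `c(lo, hi)` intensity bands per target.
#' @param min_area specks below this pixel count are removed (default 20).
#' @param fill named logical per target: fill enclosed holes in the
#'   thresholded mask.  On by default for the limbus, whose specular reflex
#'   falls outside the intensity band but is anatomically part of the
#'   region (a trained segmenter would include it); off for the sclera,
#'   whose central "hole" is the limbus itself.
#' @return logical mask (possibly empty; downstream operations raise on
#'   empty input).
#' @export
segment_threshold <- function(image, target,
                              bands = list(sclera = c(0.55, 0.90),
                                           limbus = c(0.20, 0.50)),
                              min_area = 20,
                              fill = c(sclera = FALSE, limbus = TRUE)) {
  if (!is.character(target) || length(target) != 1L || !target %in% names(bands))
    stop_strab("strab_spec_error", "unknown segmentation target: %s",
               paste(as.character(target), collapse = ", "))
  img <- to_gray(image)
  band <- bands[[target]]
  mask <- img >= band[1] & img <= band[2]
  if (isTRUE(fill[[target]])) mask <- fill_holes(mask)
  remove_specks(mask, min_area)
}

# Fill background regions not connected to the image border.
fill_holes <- function(mask) {
  if (!any(mask) || all(mask)) return(mask)
  bg <- label_components(!mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  mask | !(bg %in% setdiff(border, 0L)) & bg > 0L
}

remove_specks <- function(mask, min_area) {
  if (!any(mask) || min_area <= 1) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Resize a binary mask by nearest-neighbor resampling
#'
#' Used to move masks between the 512 x 512 model space and the raw image
#' size; the result stays binary and large components keep their centroid
#' (relative to image size) within a pixel over a round trip.
#'
#' @param mask logical matrix.
#' @param out_shape integer `(height, width)` of the result.
#' @return logical matrix of shape `out_shape`.
#' @export
resize_mask <- function(mask, out_shape) {
  mask <- assert_mask(mask)
  ho <- out_shape[1]; wo <- out_shape[2]
  if (length(out_shape) != 2L || any(!is.finite(out_shape)) || ho < 1 || wo < 1)
    stop_strab("strab_spec_error", "out_shape must be two positive integers")
  hi <- nrow(mask); wi <- ncol(mask)
  if (ho == hi && wo == wi) return(mask)
  # map each output pixel center to the nearest input pixel
  ri <- pmin(hi, pmax(1L, as.integer(floor((seq_len(ho) - 0.5) * hi / ho) + 1L)))
  ci <- pmin(wi, pmax(1L, as.integer(floor((seq_len(wo) - 0.5) * wi / wo) + 1L)))
  mask[ri, ci, drop = FALSE]
}

#' Pixel-wise confusion counts between predicted and ground-truth masks
#'
#' @param pred,truth logical masks of equal shape.
#' @return a `confusion_counts` list with integer fields `TP`, `TN`, `FP`,
#'   `FN` summing to the number of compared pixels.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- assert_mask(pred, "pred"); truth <- assert_mask(truth, "truth")
  if (!identical(dim(pred), dim(truth)))
    stop_strab("strab_input_error", "pred (%d x %d) and truth (%d x %d) shapes differ",
               nrow(pred), ncol(pred), nrow(truth), ncol(truth))
  structure(list(
    TP = sum(pred & truth), TN = sum(!pred & !truth),
    FP = sum(pred & !truth), FN = sum(!pred & truth)
  ), class = "confusion_counts")
}

#' Segmentation evaluation metrics from confusion counts
#'
#' Computes, in percent:
#' accuracy = 100 (TP+TN)/N, sensitivity = 100 TP/(TP+FN),
#' specificity = 100 TN/(FP+TN), and the Dice similarity coefficient
#' DSC = 100 * 2TP/(2TP + FP + FN).  Any ratio with a zero denominator is
#' reported as `NA` (never 0).
#'
#' `dice_printed_variant = TRUE` switches DSC to 100 * 2TP/(TP+TN+FP+FN),
#' a non-standard normalization kept only for auditability; it is not the
#' Dice coefficient and is off by default.
#'
#' @param counts a `confusion_counts` object (or list with TP/TN/FP/FN).
#' @param dice_printed_variant use the non-standard total-pixel
#'   normalization for DSC (default `FALSE`).
#' @return list with `accuracy_pct`, `sensitivity_pct`, `specificity_pct`,
#'   `dsc_pct`, each in `[0, 100]` or `NA`.
#' @export
segmentation_metrics <- function(counts, dice_printed_variant = FALSE) {
  for (f in c("TP", "TN", "FP", "FN"))
    if (is.null(counts[[f]]) || counts[[f]] < 0)
      stop_strab("strab_input_error", "counts must have non-negative %s", f)
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total == 0)
    stop_strab("strab_input_error", "confusion counts are all zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  dsc <- if (dice_printed_variant) ratio(2 * TP, total)
         else ratio(2 * TP, 2 * TP + FP + FN)
  list(accuracy_pct = ratio(TP + TN, total),
       sensitivity_pct = ratio(TP, TP + FN),
       specificity_pct = ratio(TN, FP + TN),
       dsc_pct = dsc)
}

#' Split a two-eye mask into image-left and image-right components
#'
#' Keeps the two largest connected components at or above `min_area`; the
#' component with the smaller centroid x is the image-left eye.
#'
#' @param mask logical mask expected to contain both eyes.
#' @param min_area minimum component area in pixels (default 20).
#' @return list with logical masks `left` and `right` (same shape as input).
#' @export
split_eyes <- function(mask, min_area = 20) {
  mask <- assert_mask(mask)
  lab <- label_components(mask)
  k <- max(lab)
  if (k > 0) {
    sizes <- tabulate(lab[lab > 0L], nbins = k)
    qual <- which(sizes >= min_area)
  } else qual <- integer(0)
  if (length(qual) < 2L)
    stop_strab("strab_degenerate_mask",
               "expected two eye components >= %d px, found %d", min_area, length(qual))
  top2 <- qual[order(-sizes[qual])][1:2]
  cx <- vapply(top2, function(lbl) mask_centroid(lab == lbl)[["x"]], numeric(1))
  top2 <- top2[order(cx)]
  list(left = lab == top2[1], right = lab == top2[2])
}

#' Write segmentation metrics for several targets as CSV
#'
#' Columns `(target, accuracy, sensitivity, specificity, dsc)`, percentages
#' rounded to 2 decimals.
#'
#' @param metrics named list (target -> [segmentation_metrics()] result).
#' @param path output CSV path.
#' @return the data frame written, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  df <- do.call(rbind, lapply(names(metrics), function(tg) {
    m <- metrics[[tg]]
    data.frame(target = tg,
               accuracy = round(m$accuracy_pct, 2),
               sensitivity = round(m$sensitivity_pct, 2),
               specificity = round(m$specificity_pct, 2),
               dsc = round(m$dsc_pct, 2))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
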