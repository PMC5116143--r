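#' Detection parameters
#'
#' The three tunable inputs of the counting algorithm plus plumbing options.
#' `bw_threshold` is the grayscale cut-off in \[0, 255\] below which a pixel is
#' treated as egg (eggs are dark on a light substrate). `min_box_area` and
#' `max_box_area` bracket, in pixels, the bounding-box area a single egg may
#' occupy: smaller objects are rejected as noise, larger ones are flagged as
#' possible clusters. Defaults are 80 / 800 / 1400, the values the method was
#' calibrated with for microscope images of eggs on sandpaper.
#'
#' @param bw_threshold integer in \[0, 255\]; foreground is intensity strictly
#'   below this value.
#' @param min_box_area,max_box_area bounding-box area bounds in pixels,
#'   `0 < min < max`.
#' @param connectivity 4 or 8; with 8 (the default) diagonally touching eggs
#'   merge into one flagged component.
#' @param mode `"micro"` (per-object counting, the precise mode),
#'   `"macro"` (whole-strip histogram estimation), or `"raft"` (each
#'   large-enough component counts as one, for floating egg rafts).
#' @return an `detection_params` object (named list).
#' @examples
#' detection_params()
#' detection_params(bw_threshold = 100, mode = "macro")
#' @export
detection_params <- function(bw_threshold = 80, min_box_area = 800,
                          max_box_area = 1400, connectivity = 8,
                          mode = c("micro", "macro", "raft")) {
  mode <- match.arg(mode)
  bw_threshold <- check_scalar_int(bw_threshold, "bw_threshold", 0, 255)
  min_box_area <- check_scalar_int(min_box_area, "min_box_area", 1)
  max_box_area <- check_scalar_int(max_box_area, "max_box_area", 1)
  if (min_box_area >= max_box_area) {
    stop_ovocount("min_box_area must be smaller than max_box_area",
                  "ovocount_parameter_error")
  }
  if (!connectivity %in% c(4, 8)) {
    stop_ovocount("connectivity must be 4 or 8", "ovocount_parameter_error")
  }
  structure(list(bw_threshold = bw_threshold, min_box_area = min_box_area,
                 max_box_area = max_box_area,
                 connectivity = as.integer(connectivity), mode = mode),
            class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat(sprintf("<detection_params> threshold %d, box area [%d, %d], %d-connectivity, mode %s\n",
              x$bw_threshold, x$min_box_area, x$max_box_area, x$connectivity,
              x$mode))
  invisible(x)
}

#' Binarize a grayscale image
#'
#' Foreground (egg candidate) is every pixel with intensity strictly below the
#' threshold; eggs are dark on a light background. A threshold of 0 therefore
#' yields an empty mask.
#'
#' @param image a [gray_image].
#' @param bw_threshold integer in \[0, 255\].
#' @return logical matrix of the same shape, `TRUE` = foreground.
#' @examples
#' img <- gray_image(matrix(c(10L, 200L), 1, 2), "demo")
#' binarize(img, 80)
#' @export
binarize <- function(image, bw_threshold) {
  stopifnot(is_gray_image(image))
  bw_threshold <- check_scalar_int(bw_threshold, "bw_threshold", 0, 255)
  mask <- unclass(image) < bw_threshold
  dim(mask) <- dim(image)
  mask
}

#' Label connected foreground components
#'
#' Partitions the foreground of a binary mask into maximal connected
#' components under 4- or 8-connectivity. Components are returned in
#' deterministic scan order of their bounding-box top-left corner
#' (top-to-bottom, then left-to-right), so object ids are reproducible.
#'
#' @param mask logical matrix (`TRUE` = foreground).
#' @param connectivity 4 or 8.
#' @return a data frame with one row per component: `top`, `left`, `bottom`,
#'   `right` (0-based half-open bounding box), `box_area`, `pixel_area`, and a
#'   list-column `pixels` of linear indices into the mask.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!connectivity %in% c(4, 8)) {
    stop_ovocount("connectivity must be 4 or 8", "ovocount_parameter_error")
  }
  lab <- .cc_label(mask, as.integer(connectivity))
  n <- max(lab)
  if (n == 0L) {
    return(data.frame(top = integer(), left = integer(), bottom = integer(),
                      right = integer(), box_area = integer(),
                      pixel_area = integer(),
                      pixels = I(list()), stringsAsFactors = FALSE))
  }
  idx <- which(lab > 0L)
  comp <- lab[idx]
  rows <- (idx - 1L) %% nrow(mask)        # 0-based
  cols <- (idx - 1L) %/% nrow(mask)
  top <- tapply(rows, comp, min)
  bottom <- tapply(rows, comp, max) + 1L
  left <- tapply(cols, comp, min)
  right <- tapply(cols, comp, max) + 1L
  pixel_area <- tabulate(comp, nbins = n)
  pixels <- split(idx, comp)
  ord <- order(top, left)
  data.frame(top = as.integer(top[ord]), left = as.integer(left[ord]),
             bottom = as.integer(bottom[ord]), right = as.integer(right[ord]),
             box_area = as.integer((bottom - top) * (right - left))[ord],
             pixel_area = pixel_area[ord],
             pixels = I(unname(pixels[ord])), stringsAsFactors = FALSE)
}

#' Classify components by bounding-box area
#'
#' Implements the box-area filter: a component whose bounding-box area is
#' below `min_box_area` is rejected as noise; within
#' \[`min_box_area`, `max_box_area`\] it is a confidently detected single egg;
#' above `max_box_area` it is flagged as uncertain (likely several eggs merged
#' into one object). Confident objects get `estimated_count` 1, rejected 0;
#' uncertain objects are left at `NA` for [estimate_cluster()]. In raft mode
#' there is no upper bound: everything at or above `min_box_area` counts as
#' exactly one raft.
#'
#' @param components data frame from [label_components()].
#' @param params an [detection_params].
#' @return the data frame with `object_id`, `status` and `estimated_count`
#'   columns added.
#' @export
classify_objects <- function(components, params) {
  stopifnot(inherits(params, "detection_params"))
  n <- nrow(components)
  status <- rep("confident", n)
  status[components$box_area < params$min_box_area] <- "rejected"
  if (params$mode != "raft") {
    status[components$box_area > params$max_box_area] <- "uncertain"
  }
  est <- rep(NA_integer_, n)
  est[status == "confident"] <- 1L
  est[status == "rejected"] <- 0L
  components$object_id <- seq_len(n)
  components$status <- status
  components$estimated_count <- est
  components[, c("object_id", "top", "left", "bottom", "right", "box_area",
                 "pixel_area", "status", "estimated_count", "pixels")]
}

#' Per-image single-egg reference area
#'
#' The pixel area one egg is assumed to occupy in this particular image, used
#' to convert a merged cluster's pixel area into an egg count. It is the
#' median pixel area of the confidently detected single eggs, so magnification
#' differences between images self-calibrate. When an image has no confident
#' object the fallback is 0.7 x the midpoint of the box-area band, rounded —
#' roughly the fill fraction of a rotated ellipse in its bounding box.
#'
#' @param objects classified object table ([classify_objects()]).
#' @param params an [detection_params].
#' @return reference area in pixels (positive scalar).
#' @examples
#' reference_egg_area(data.frame(status = "confident", pixel_area = 950),
#'                    detection_params())
#' @export
reference_egg_area <- function(objects, params) {
  stopifnot(inherits(params, "detection_params"))
  conf <- objects$pixel_area[objects$status == "confident"]
  if (length(conf) == 0L) {
    return(round_half_up(0.7 * (params$min_box_area + params$max_box_area) / 2))
  }
  round_half_up(stats::median(conf))
}

#' Estimate the egg content of a merged cluster
#'
#' Eggs laid touching each other merge into a single connected object. Its egg
#' count is estimated as the component's pixel area divided by the single-egg
#' reference area, rounded half up, floored at 1 — the total-area over
#' average-area ratio. Very large blobs may estimate many eggs; they remain
#' flagged for human review.
#'
#' @param pixel_area foreground pixel count of the flagged component.
#' @param reference_area positive single-egg reference area
#'   ([reference_egg_area()]).
#' @return estimated egg count (integer >= 1).
#' @examples
#' estimate_cluster(2600, 1000)  # 2.6 -> 3
#' @export
estimate_cluster <- function(pixel_area, reference_area) {
  if (length(reference_area) != 1L || !is.numeric(reference_area) ||
      is.na(reference_area) || reference_area <= 0) {
    stop_ovocount("reference_area must be a positive number",
                  "ovocount_parameter_error")
  }
  pmax(1L, round_half_up(pixel_area / reference_area))
}

new_count_result <- function(image, params, objects, reference_area) {
  objects$pixels <- NULL
  total <- sum(objects$estimated_count)
  structure(list(image_id = source_id(image), params = params,
                 objects = objects,
                 n_confident = sum(objects$status == "confident"),
                 n_uncertain = sum(objects$status == "uncertain"),
                 n_rejected = sum(objects$status == "rejected"),
                 reference_area = reference_area,
                 total_estimate = as.integer(total),
                 image_shape = c(nrow(image), ncol(image))),
            class = "egg_count_result")
}

#' @export
print.egg_count_result <- function(x, ...) {
  cat(sprintf("<egg_count_result> %s: %d eggs estimated (%d confident, %d uncertain, %d rejected objects; reference area %d px)\n",
              x$image_id, x$total_estimate, x$n_confident, x$n_uncertain,
              x$n_rejected, x$reference_area))
  invisible(x)
}

#' Count eggs in a grayscale image
#'
#' The full automatic pipeline: binarize at the BW threshold, label connected
#' components, classify by bounding-box area, derive the per-image single-egg
#' reference, and estimate the egg content of every flagged cluster from its
#' pixel-area ratio. Deterministic for fixed inputs. With `mode = "raft"` the
#' raft rule is applied instead (see [count_rafts()]).
#'
#' @param image a [gray_image].
#' @param params an [detection_params]; defaults are the published 80 / 800 /
#'   1400.
#' @return an `egg_count_result`: per-object table (`object_id`, bounding box,
#'   `box_area`, `pixel_area`, `status`, `estimated_count`), the single-egg
#'   `reference_area`, and `total_estimate` = sum of estimated counts.
#' @examples
#' blank <- gray_image(matrix(255L, 50, 50), "blank")
#' count_eggs(blank)$total_estimate  # 0
#' @export
count_eggs <- function(image, params = detection_params()) {
  stopifnot(is_gray_image(image), inherits(params, "detection_params"))
  if (params$mode == "raft") return(count_rafts(image, params))
  mask <- binarize(image, params$bw_threshold)
  comp <- label_components(mask, params$connectivity)
  obj <- classify_objects(comp, params)
  ref <- reference_egg_area(obj, params)
  unc <- obj$status == "uncertain"
  if (any(unc)) {
    obj$estimated_count[unc] <- estimate_cluster(obj$pixel_area[unc], ref)
  }
  new_count_result(image, params, obj, ref)
}

#' Count floating egg rafts
#'
#' Culex mosquitoes deposit eggs in floating rafts that cannot be separated
#' into individual eggs by thresholding; each raft is counted as one unit.
#' Identical to [count_eggs()] except that no cluster splitting occurs: every
#' component with bounding-box area at or above `min_box_area` counts as
#' exactly 1 regardless of `max_box_area`, and smaller ones are rejected.
#'
#' @param image a [gray_image].
#' @param params an [detection_params] with `mode = "raft"`.
#' @return an `egg_count_result` whose total is the number of rafts.
#' @export
count_rafts <- function(image, params = detection_params(mode = "raft")) {
  stopifnot(is_gray_image(image), inherits(params, "detection_params"))
  if (params$mode != "raft") {
    stop_ovocount("count_rafts requires params with mode = 'raft'",
                  "ovocount_parameter_error")
  }
  mask <- binarize(image, params$bw_threshold)
  comp <- label_components(mask, params$connectivity)
  obj <- classify_objects(comp, params)
  ref <- reference_egg_area(obj, params)
  new_count_result(image, params, obj, ref)
}

#' Histogram-based whole-strip estimate
#'
#' The fast estimation mode for whole-strip camera images: no per-object
#' labeling, just the total foreground pixel count at the BW threshold divided
#' by the single-egg reference area, rounded half up. Suited to "macro" images
#' where individual eggs are not resolved well enough for box classification.
#'
#' @param image a [gray_image].
#' @param params an [detection_params] (only `bw_threshold` is used).
#' @param reference_area positive single-egg reference area in pixels; derive
#'   it from a counted image via [reference_egg_area()] or supply a known
#'   value for the imaging setup.
#' @return estimated egg count (integer >= 0).
#' @examples
#' blank <- gray_image(matrix(255L, 20, 20), "blank")
#' estimate_by_histogram(blank, detection_params(), reference_area = 900)  # 0
#' @export
estimate_by_histogram <- function(image, params = detection_params(),
                                  reference_area) {
  stopifnot(is_gray_image(image), inherits(params, "detection_params"))
  if (length(reference_area) != 1L || !is.numeric(reference_area) ||
      is.na(reference_area) || reference_area <= 0) {
    stop_ovocount("reference_area must be a positive number",
                  "ovocount_parameter_error")
  }
  fg <- sum(binarize(image, params$bw_threshold))
  round_half_up(fg / reference_area)
}

#' Write detection results as CSV tables
#'
#' Batch output contract: one row per object in the object table, one row per
#' image in the summary table.
#'
#' @param results list of `egg_count_result` objects.
#' @param objects_path,summary_path output CSV paths (either may be `NULL` to
#'   skip).
#' @return invisibly, a list with the two data frames.
#' @export
write_results_csv <- function(results, objects_path = NULL,
                              summary_path = NULL) {
  obj <- do.call(rbind, lapply(results, function(r) {
    if (nrow(r$objects) == 0L) return(NULL)
    cbind(data.frame(image_id = r$image_id, stringsAsFactors = FALSE),
          r$objects[, c("object_id", "top", "left", "bottom", "right",
                        "box_area", "pixel_area", "status", "estimated_count")])
  }))
  if (is.null(obj)) {
    obj <- data.frame(image_id = character(), object_id = integer(),
                      top = integer(), left = integer(), bottom = integer(),
                      right = integer(), box_area = integer(),
                      pixel_area = integer(), status = character(),
                      estimated_count = integer(), stringsAsFactors = FALSE)
  }
  summ <- do.call(rbind, lapply(results, function(r) {
    data.frame(image_id = r$image_id, n_confident = r$n_confident,
               n_uncertain = r$n_uncertain, n_rejected = r$n_rejected,
               reference_area = r$reference_area,
               total_estimate = r$total_estimate, stringsAsFactors = FALSE)
  }))
  if (!is.null(objects_path)) {
    utils::write.csv(obj, objects_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(summary_path)) {
    utils::write.csv(summ, summary_path, row.names = FALSE, quote = FALSE)
  }
  invisible(list(objects = obj, summary = summ))
}
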