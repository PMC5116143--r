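#' Export detections for human review
#'
#' The first half of the semi-automatic workflow: the flagged (uncertain) and
#' rejected objects of a detection result are written to a CSV that a reviewer
#' opens in any spreadsheet, fills in the `corrected_count` column where the
#' automatic estimate is wrong, and feeds back through
#' [apply_corrections()]. The header is fixed:
#' `image_id,object_id,status,auto_count,corrected_count,note`.
#'
#' @param result an `egg_count_result`.
#' @param path output CSV path.
#' @param flagged_only if `TRUE` (default), export only uncertain and rejected
#'   objects — the ones a reviewer needs to look at; `FALSE` exports all.
#' @return invisibly, the exported data frame.
#' @export
export_review <- function(result, path, flagged_only = TRUE) {
  stopifnot(inherits(result, "egg_count_result"))
  obj <- result$objects
  if (flagged_only) obj <- obj[obj$status != "confident", , drop = FALSE]
  tab <- data.frame(image_id = rep(result$image_id, nrow(obj)),
                    object_id = obj$object_id,
                    status = obj$status,
                    auto_count = obj$estimated_count,
                    corrected_count = rep(NA_integer_, nrow(obj)),
                    note = rep("", nrow(obj)),
                    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_ovocount(sprintf("cannot write review CSV to %s: %s", path,
                          conditionMessage(ok)), "ovocount_io_error")
  }
  invisible(tab)
}

#' Read a review CSV
#'
#' @param path a CSV written by [export_review()], possibly with
#'   `corrected_count` values filled in by a reviewer.
#' @return data frame of review records.
#' @export
read_review <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(image_id = "character",
                                        corrected_count = "integer",
                                        note = "character"))
  needed <- c("image_id", "object_id", "status", "auto_count",
              "corrected_count", "note")
  if (!all(needed %in% names(tab))) {
    stop_ovocount(sprintf("review CSV %s is missing columns: %s", path,
                          paste(setdiff(needed, names(tab)), collapse = ", ")),
                  "ovocount_format_error")
  }
  if (anyDuplicated(tab[, c("image_id", "object_id")])) {
    stop_ovocount(sprintf("review CSV %s has duplicate (image_id, object_id) rows",
                          path), "ovocount_format_error")
  }
  tab
}

#' Fold reviewer corrections back into a detection result
#'
#' Each record with a non-empty `corrected_count` overrides the automatic
#' estimate of the matching object; the original status is kept for audit and
#' a `corrected` flag records where the human intervened. Works in both
#' directions: a flagged merge can be corrected upward and a rejected faint
#' egg rescued, or an artefact zeroed out. The total is recomputed; the input
#' result is not modified. Applying the same corrections twice is idempotent.
#'
#' @param result an `egg_count_result`.
#' @param records review records ([read_review()] / [export_review()]) for
#'   this image; records for other images are ignored.
#' @return a new `egg_count_result` with corrections applied.
#' @examples
#' img <- gray_image(matrix(255L, 60, 60), "blank")
#' res <- count_eggs(img)
#' identical(apply_corrections(res, data.frame())$total_estimate,
#'           res$total_estimate)
#' @export
apply_corrections <- function(result, records) {
  stopifnot(inherits(result, "egg_count_result"))
  out <- result
  if (!"corrected" %in% names(out$objects)) {
    out$objects$corrected <- rep(FALSE, nrow(out$objects))
  }
  if (NROW(records) == 0L) return(out)
  rec <- records[records$image_id == result$image_id &
                   !is.na(records$corrected_count), , drop = FALSE]
  if (nrow(rec) == 0L) {
    out$total_estimate <- as.integer(sum(out$objects$estimated_count))
    return(out)
  }
  if (any(rec$corrected_count < 0)) {
    stop_ovocount("corrected_count must be >= 0", "ovocount_validation_error")
  }
  unknown <- setdiff(rec$object_id, out$objects$object_id)
  if (length(unknown)) {
    stop_ovocount(sprintf("corrections refer to unknown object ids in %s: %s",
                          result$image_id, paste(unknown, collapse = ", ")),
                  "ovocount_consistency_error")
  }
  pos <- match(rec$object_id, out$objects$object_id)
  out$objects$estimated_count[pos] <- as.integer(rec$corrected_count)
  out$objects$corrected[pos] <- TRUE
  out$total_estimate <- as.integer(sum(out$objects$estimated_count))
  out
}

#' Ground-truth corrections for flagged objects of a synthetic strip
#'
#' Plays the role of a perfect reviewer on generator output: for every flagged
#' (uncertain or rejected) object of a detection result, the corrected count
#' is the number of true egg centres belonging to that connected component.
#' The mask is re-derived from the image with the result's own parameters and
#' each centre assigned to the component containing its pixel (falling back to
#' bounding-box containment for a centre that is not foreground). Used to
#' exercise the semi-automatic workflow at scale without a human.
#'
#' @param result an `egg_count_result` for a generated strip.
#' @param truth the matching [generate_strip()] ground truth.
#' @param image the [gray_image] the result was computed from.
#' @return review records ready for [apply_corrections()].
#' @export
truth_corrections <- function(result, truth, image) {
  stopifnot(inherits(result, "egg_count_result"),
            inherits(truth, "strip_truth"), is_gray_image(image))
  obj <- result$objects
  flag_ids <- obj$object_id[obj$status != "confident"]
  if (length(flag_ids) == 0L) {
    return(data.frame(image_id = character(), object_id = integer(),
                      status = character(), auto_count = integer(),
                      corrected_count = integer(), note = character(),
                      stringsAsFactors = FALSE))
  }
  # reproduce the component partition the result was built from
  mask <- binarize(image, result$params$bw_threshold)
  comp <- label_components(mask, result$params$connectivity)
  centers <- truth$egg_centers
  # centre (row, col) are 0-based; linear index into the mask matrix
  lin <- (centers$col) * nrow(mask) + centers$row + 1L
  center_comp <- rep(NA_integer_, nrow(centers))
  for (k in seq_len(nrow(comp))) {
    center_comp[lin %in% comp$pixels[[k]]] <- k
  }
  # rare fallback: a centre whose pixel happens to be background
  for (i in which(is.na(center_comp))) {
    hit <- which(centers$row[i] >= obj$top & centers$row[i] < obj$bottom &
                   centers$col[i] >= obj$left & centers$col[i] < obj$right)
    if (length(hit)) center_comp[i] <- hit[1L]
  }
  flag <- obj[obj$object_id %in% flag_ids, , drop = FALSE]
  corrected <- vapply(flag$object_id, function(id) {
    sum(center_comp == id, na.rm = TRUE)
  }, integer(1))
  data.frame(image_id = rep(result$image_id, nrow(flag)),
             object_id = flag$object_id, status = flag$status,
             auto_count = flag$estimated_count,
             corrected_count = corrected,
             note = rep("ground truth", nrow(flag)),
             stringsAsFactors = FALSE)
}
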