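#' Recipe for a synthetic oviposition-strip image
#'
#' Describes a light, noisy sandpaper-like background bearing dark ellipsoidal
#' eggs at a controllable density and degree of clustering, with exact ground
#' truth. Defaults emulate a microscope snapshot of eggs on sandpaper: egg
#' axes (46 x 24 px, 8% jitter) are sized so a single egg's bounding box falls
#' inside the default \[800, 1400\] px classification band at typical
#' orientations, and the intensity model (background 200 +- 10, eggs 30 +- 10)
#' leaves the default threshold 80 cleanly between the two populations.
#'
#' @param height,width image shape in pixels.
#' @param n_eggs number of eggs to place (>= 0).
#' @param egg_major_axis,egg_minor_axis mean full axis lengths in pixels
#'   (>= 2).
#' @param axis_jitter relative jitter: each egg's axes are scaled by
#'   independent uniform factors in \[1 - jitter, 1 + jitter\].
#' @param bg_mean,bg_sd per-pixel Gaussian background intensity.
#' @param egg_mean,egg_sd per-pixel Gaussian egg intensity; the spec requires
#'   `egg_mean + 2 egg_sd < bg_mean - 2 bg_sd` (dark-on-light separability).
#' @param cluster_fraction share of eggs laid touching a neighbour, in
#'   \[0, 1\]; clustered eggs are placed in touching groups of 2-4.
#' @param min_gap minimum pixel gap between non-cluster eggs (and between
#'   groups), so isolated eggs never merge.
#' @param seed RNG seed making the strip fully reproducible.
#' @param label image id; defaults to `strip_seed<seed>`.
#' @return a `strip_spec` list.
#' @examples
#' strip_spec(n_eggs = 25, seed = 7)
#' @export
strip_spec <- function(height = 480, width = 1280, n_eggs = 60,
                       egg_major_axis = 46, egg_minor_axis = 24,
                       axis_jitter = 0.08, bg_mean = 200, bg_sd = 10,
                       egg_mean = 30, egg_sd = 10, cluster_fraction = 0,
                       min_gap = 6, seed = 1,
                       label = sprintf("strip_seed%d", seed)) {
  height <- check_scalar_int(height, "height", 1)
  width <- check_scalar_int(width, "width", 1)
  n_eggs <- check_scalar_int(n_eggs, "n_eggs", 0)
  seed <- check_scalar_int(seed, "seed")
  if (egg_major_axis < 2 || egg_minor_axis < 2) {
    stop_ovocount("egg axes must be at least 2 px", "ovocount_parameter_error")
  }
  if (egg_minor_axis > egg_major_axis) {
    stop_ovocount("egg_minor_axis cannot exceed egg_major_axis",
                  "ovocount_parameter_error")
  }
  if (cluster_fraction < 0 || cluster_fraction > 1) {
    stop_ovocount("cluster_fraction must lie in [0, 1]",
                  "ovocount_parameter_error")
  }
  if (egg_mean + 2 * egg_sd >= bg_mean - 2 * bg_sd) {
    stop_ovocount("egg and background intensity distributions overlap: need egg_mean + 2*egg_sd < bg_mean - 2*bg_sd",
                  "ovocount_parameter_error")
  }
  structure(list(height = height, width = width, n_eggs = n_eggs,
                 egg_major_axis = egg_major_axis,
                 egg_minor_axis = egg_minor_axis, axis_jitter = axis_jitter,
                 bg_mean = bg_mean, bg_sd = bg_sd, egg_mean = egg_mean,
                 egg_sd = egg_sd, cluster_fraction = cluster_fraction,
                 min_gap = min_gap, seed = seed, label = label),
            class = "strip_spec")
}

#' Preset strip recipes
#'
#' `micro`: a microscope-style snapshot (480 x 1280) at moderate density with
#' light clustering. `macro`: a whole-strip camera-style frame (720 x 2400)
#' with more eggs. `dense`: a crowded micro frame with heavy clustering, the
#' regime where automatic counting degrades.
#'
#' @param preset one of `"micro"`, `"macro"`, `"dense"`.
#' @param ... overrides passed to [strip_spec()].
#' @return a `strip_spec`.
#' @export
strip_preset <- function(preset = c("micro", "macro", "dense"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    micro = list(height = 480, width = 1280, n_eggs = 60,
                 cluster_fraction = 0.05),
    macro = list(height = 720, width = 2400, n_eggs = 300,
                 cluster_fraction = 0.05),
    dense = list(height = 480, width = 1280, n_eggs = 140,
                 cluster_fraction = 0.25))
  args <- utils::modifyList(base, list(...))
  do.call(strip_spec, args)
}

# Pixels (linear indices into an H x W matrix) of a filled rotated ellipse.
# (cr, cc) are 0-based centre coordinates; a, b semi-axes; theta radians.
ellipse_pixels <- function(cr, cc, a, b, theta, H, W) {
  ext <- ceiling(max(a, b))
  rr <- max(0, floor(cr - ext)):min(H - 1, ceiling(cr + ext))
  cc2 <- max(0, floor(cc - ext)):min(W - 1, ceiling(cc + ext))
  dy <- rr - cr
  dx <- rep(cc2 - cc, each = length(rr))
  dyv <- rep(dy, times = length(cc2))
  u <- (dx * cos(theta) + dyv * sin(theta)) / a
  v <- (-dx * sin(theta) + dyv * cos(theta)) / b
  inside <- u * u + v * v <= 1
  rows <- rep(rr, times = length(cc2))[inside]
  cols <- rep(cc2, each = length(rr))[inside]
  cols * H + rows + 1L
}

# split `n` clustered eggs into touching groups of 2-4
cluster_sizes <- function(n) {
  sizes <- integer(0)
  while (n > 0) {
    if (n <= 4L) {
      k <- n
    } else {
      k <- sample(2:4, 1L)
      if (n - k == 1L) k <- k + 1L      # never leave a 1-egg remainder
    }
    sizes <- c(sizes, k)
    n <- n - k
  }
  sizes
}

#' Generate a synthetic strip image with ground truth
#'
#' Builds the image described by a [strip_spec]: per-pixel Gaussian
#' background, filled rotated ellipses with per-pixel Gaussian egg intensity,
#' `round(n_eggs * (1 - cluster_fraction))` eggs placed as isolated singles at
#' least `min_gap` pixels from any neighbour, and the remainder in touching
#' groups of 2-4 whose centre separation is 0.85-0.95 of the minor axis.
#' Group geometry is resampled until the merged pixel set is one connected
#' component and its bounding box exceeds the default flagging bound, so every
#' synthetic merge is guaranteed to be flagged for review by the default
#' parameters. Placement is by rejection sampling with a bounded number of
#' attempts; generation is fully deterministic given the seed and never
#' perturbs the caller's RNG state.
#'
#' @param spec a [strip_spec].
#' @param placement_attempts rejection-sampling cap per egg/group before a
#'   capacity error is raised.
#' @return list with `image` (a [gray_image]) and `truth` (a `strip_truth`:
#'   `image_id`, `egg_centers` data frame with 0-based `row`, `col`,
#'   `orientation`, `object_index`; `object_truth` with per-object egg counts;
#'   `total_eggs`).
#' @examples
#' out <- generate_strip(strip_spec(n_eggs = 5, height = 200, width = 400,
#'                                  seed = 3))
#' out$truth$total_eggs
#' @export
generate_strip <- function(spec, placement_attempts = 10000) {
  stopifnot(inherits(spec, "strip_spec"))
  with_seed(spec$seed, {
    H <- spec$height; W <- spec$width
    a0 <- spec$egg_major_axis / 2
    b0 <- spec$egg_minor_axis / 2
    jit <- spec$axis_jitter
    gap <- spec$min_gap
    margin <- ceiling(a0 * (1 + jit)) + 1L
    if (spec$n_eggs > 0 && (H - 2 * margin < 1 || W - 2 * margin < 1)) {
      stop_ovocount("strip too small for the requested egg size (limiting parameter: height/width vs egg_major_axis)",
                    "ovocount_capacity_error")
    }
    n_single <- round_half_up(spec$n_eggs * (1 - spec$cluster_fraction))
    n_clustered <- spec$n_eggs - n_single
    if (n_clustered == 1L) {            # clusters need >= 2 members
      n_single <- spec$n_eggs
      n_clustered <- 0L
    }
    sizes <- c(rep(1L, n_single), if (n_clustered > 0) cluster_sizes(n_clustered))
    excl <- matrix(FALSE, H, W)         # occupied + min_gap halo
    egg_px <- vector("list", spec$n_eggs)
    centers <- matrix(NA_real_, spec$n_eggs, 3)  # row, col, theta
    group_of <- integer(spec$n_eggs)
    # flagging guarantee for merged groups: default max box area + margin
    flag_area <- 1.05 * detection_params()$max_box_area
    egg_i <- 0L
    for (g in seq_along(sizes)) {
      k <- sizes[g]
      placed <- FALSE
      for (attempt in seq_len(placement_attempts)) {
        cr <- stats::runif(1, margin, H - margin)
        cc <- stats::runif(1, margin, W - margin)
        th <- stats::runif(k, 0, pi)
        fa <- a0 * stats::runif(k, 1 - jit, 1 + jit)
        fb <- b0 * stats::runif(k, 1 - jit, 1 + jit)
        crs <- cr; ccs <- cc
        if (k > 1L) {
          for (m in 2:k) {
            d <- 2 * b0 * stats::runif(1, 0.85, 0.95)
            phi <- stats::runif(1, 0, 2 * pi)
            crs[m] <- crs[m - 1] + d * sin(phi)
            ccs[m] <- ccs[m - 1] + d * cos(phi)
          }
          if (any(crs < margin) || any(crs > H - margin) ||
              any(ccs < margin) || any(ccs > W - margin)) next
        }
        px <- unique(unlist(lapply(seq_len(k), function(m) {
          ellipse_pixels(crs[m], ccs[m], fa[m], fb[m], th[m], H, W)
        })))
        if (any(excl[px])) next
        if (k > 1L) {
          # the merged object must be a single component whose box is flagged
          rows0 <- (px - 1L) %% H
          cols0 <- (px - 1L) %/% H
          bbox_area <- (max(rows0) - min(rows0) + 1L) *
            (max(cols0) - min(cols0) + 1L)
          if (bbox_area <= flag_area) next
          loc <- matrix(FALSE, max(rows0) - min(rows0) + 1L,
                        max(cols0) - min(cols0) + 1L)
          loc[cbind(rows0 - min(rows0) + 1L, cols0 - min(cols0) + 1L)] <- TRUE
          if (nrow(label_components(loc, 8)) != 1L) next
        }
        # accept: record members and mark the min_gap halo
        for (m in seq_len(k)) {
          egg_i <- egg_i + 1L
          centers[egg_i, ] <- c(crs[m], ccs[m], th[m])
          group_of[egg_i] <- g
          egg_px[[egg_i]] <- ellipse_pixels(crs[m], ccs[m], fa[m], fb[m],
                                            th[m], H, W)
          excl[ellipse_pixels(crs[m], ccs[m], fa[m] + gap + 1, fb[m] + gap + 1,
                              th[m], H, W)] <- TRUE
        }
        placed <- TRUE
        break
      }
      if (!placed) {
        stop_ovocount(
          sprintf("could not place egg group %d of %d after %d attempts (limiting parameter: n_eggs x min_gap vs strip area)",
                  g, length(sizes), placement_attempts),
          "ovocount_capacity_error")
      }
    }
    img <- matrix(stats::rnorm(H * W, spec$bg_mean, spec$bg_sd), H, W)
    all_px <- unique(unlist(egg_px))
    if (length(all_px)) {
      img[all_px] <- stats::rnorm(length(all_px), spec$egg_mean, spec$egg_sd)
    }
    img <- pmin(pmax(round_half_up(img), 0L), 255L)
    dim(img) <- c(H, W)
    truth <- structure(
      list(image_id = spec$label,
           egg_centers = data.frame(
             row = floor(centers[, 1]), col = floor(centers[, 2]),
             orientation = centers[, 3],
             object_index = group_of)[seq_len(spec$n_eggs), , drop = FALSE],
           object_truth = if (spec$n_eggs > 0) {
             data.frame(object_index = seq_along(sizes), count = sizes)
           } else {
             data.frame(object_index = integer(), count = integer())
           },
           total_eggs = spec$n_eggs),
      class = "strip_truth")
    list(image = gray_image(img, source_id = spec$label), truth = truth)
  })
}

#' @export
print.strip_truth <- function(x, ...) {
  cat(sprintf("<strip_truth> %s: %d eggs in %d objects\n", x$image_id,
              x$total_eggs, nrow(x$object_truth)))
  invisible(x)
}

#' Write a batch of synthetic strips to disk
#'
#' One PNG and one ground-truth CSV (egg centres with their object index) per
#' spec, plus a manifest CSV. Re-running with identical specs reproduces
#' byte-identical files.
#'
#' @param specs list of [strip_spec] objects.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest data frame (`image`, `truth`, `seed`,
#'   `n_eggs`, `cluster_fraction`).
#' @export
generate_dataset <- function(specs, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(specs, function(sp) {
    stopifnot(inherits(sp, "strip_spec"))
    out <- generate_strip(sp)
    img_path <- file.path(out_dir, paste0(sp$label, ".png"))
    truth_path <- file.path(out_dir, paste0(sp$label, "_truth.csv"))
    write_image(out$image, img_path)
    utils::write.csv(out$truth$egg_centers, truth_path, row.names = FALSE,
                     quote = FALSE)
    data.frame(image = basename(img_path), truth = basename(truth_path),
               seed = sp$seed, n_eggs = sp$n_eggs,
               cluster_fraction = sp$cluster_fraction,
               stringsAsFactors = FALSE)
  })
  manifest <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(image = character(), truth = character(), seed = integer(),
               n_eggs = integer(), cluster_fraction = numeric(),
               stringsAsFactors = FALSE)
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a ground-truth CSV back as a `strip_truth`
#'
#' @param path a `*_truth.csv` written by [generate_dataset()].
#' @param image_id image id to attach; defaults to the file name minus the
#'   `_truth.csv` suffix.
#' @return a `strip_truth`.
#' @export
read_truth <- function(path, image_id = sub("_truth\\.csv$", "",
                                            basename(path))) {
  centers <- utils::read.csv(path, stringsAsFactors = FALSE)
  counts <- if (nrow(centers)) {
    as.data.frame(table(object_index = centers$object_index),
                  stringsAsFactors = FALSE)
  } else {
    data.frame(object_index = character(), Freq = integer())
  }
  structure(list(image_id = image_id,
                 egg_centers = centers,
                 object_truth = data.frame(
                   object_index = as.integer(counts$object_index),
                   count = as.integer(counts$Freq)),
                 total_eggs = nrow(centers)),
            class = "strip_truth")
}
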