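#' Grayscale image container
#'
#' The unit of all image processing in ovocount: an integer matrix of 8-bit
#' intensities in \[0, 255\], row-major with row 1 at the top, carrying a
#' free-text provenance label. All detection and generation functions consume
#' and produce this type.
#'
#' @param pixels integer matrix, every value in \[0, 255\].
#' @param source_id free-text provenance label (usually the file name).
#' @return an object of class `gray_image`: the integer matrix with a
#'   `source_id` attribute.
#' @examples
#' img <- gray_image(matrix(255L, 4, 4), "blank")
#' dim(img)
#' @export
gray_image <- function(pixels, source_id = "unknown") {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop_ovocount("`pixels` must be a matrix with at least one row and column",
                  "ovocount_parameter_error")
  }
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255) ||
      any(pixels != as.integer(pixels))) {
    stop_ovocount("intensities must be integers in [0, 255]",
                  "ovocount_parameter_error")
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, source_id = as.character(source_id)[1L],
            class = c("gray_image", class(matrix())))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d  source: %s  intensity range [%d, %d]\n",
              nrow(x), ncol(x), attr(x, "source_id"), min(x), max(x)))
  invisible(x)
}

#' @rdname gray_image
#' @param x object to test.
#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

source_id <- function(image) attr(image, "source_id") %||% "unknown"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rectangular region
#'
#' Half-open rectangle \[top, bottom) x \[left, right) in 0-based pixel
#' coordinates with row 0 at the top. This convention is shared by every
#' module: bounding boxes in detection results and review tables use the same
#' fields.
#'
#' @param top,left inclusive 0-based start row / column.
#' @param bottom,right exclusive end row / column.
#' @return a `rect` object (named integer vector).
#' @examples
#' rect(0, 0, 10, 20)  # full frame of a 10 x 20 image
#' @export
rect <- function(top, left, bottom, right) {
  r <- c(top = check_scalar_int(top, "top", min = 0),
         left = check_scalar_int(left, "left", min = 0),
         bottom = check_scalar_int(bottom, "bottom"),
         right = check_scalar_int(right, "right"))
  if (r[["bottom"]] <= r[["top"]] || r[["right"]] <= r[["left"]]) {
    stop_ovocount("rect must satisfy top < bottom and left < right (half-open, non-empty)",
                  "ovocount_bounds_error")
  }
  structure(r, class = "rect")
}

# ITU-R BT.601 luminance, rounded half up. `rgb` is an H x W x 3 array scaled
# to [0, 255].
luminance_601 <- function(rgb) {
  round_half_up(0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3])
}

#' Load a raster image as grayscale
#'
#' Reads PNG, TIFF, JPEG or BMP. Colour images are converted by BT.601
#' luminance 0.299 R + 0.587 G + 0.114 B, rounded half up; single-channel
#' images pass through unchanged. Any alpha channel is dropped. The result's
#' `source_id` is the file name.
#'
#' @param path path to a PNG, TIFF, JPEG or BMP file.
#' @return a [gray_image].
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(1, 4, 4), f)
#' img <- load_image(f)
#' unique(as.vector(img))  # 255
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop_ovocount(sprintf("image file does not exist: %s", path),
                  "ovocount_format_error")
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    bmp  = read_bmp(path),
    stop_ovocount(
      sprintf("unsupported image format '%s' for %s (PNG, TIFF, JPEG or BMP expected)",
              ext, path),
      "ovocount_format_error")
  )
  if (is.matrix(arr)) {
    px <- round_half_up(arr * 255)
    dim(px) <- dim(arr)
  } else if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] == 2L) {          # gray + alpha
      px <- round_half_up(arr[, , 1] * 255)
      dim(px) <- dim(arr)[1:2]
    } else {                          # RGB or RGBA
      px <- luminance_601(arr[, , 1:3, drop = FALSE] * 255)
      dim(px) <- dim(arr)[1:2]
    }
  } else {
    stop_ovocount(sprintf("cannot interpret image data in %s", path),
                  "ovocount_format_error")
  }
  gray_image(px, source_id = basename(path))
}

# Minimal BMP reader: uncompressed (BI_RGB) 8-bit paletted, 24-bit and 32-bit
# files, the variants bench cameras and MS Paint emit. Returns an array scaled
# to [0, 1] like the png/tiff/jpeg readers. Hand-written because no installed
# package reads BMP.
read_bmp <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, "raw", 2L)
  if (!identical(as.integer(magic), c(0x42L, 0x4DL))) {
    stop_ovocount(sprintf("not a BMP file: %s", path), "ovocount_format_error")
  }
  readBin(con, "raw", 8L)                               # size + reserved
  data_offset <- readBin(con, "integer", 1L, 4L, endian = "little")
  header_size <- readBin(con, "integer", 1L, 4L, endian = "little")
  if (header_size < 40L) {
    stop_ovocount(sprintf("unsupported BMP header in %s", path),
                  "ovocount_format_error")
  }
  width  <- readBin(con, "integer", 1L, 4L, endian = "little")
  height <- readBin(con, "integer", 1L, 4L, endian = "little")
  readBin(con, "integer", 1L, 2L, endian = "little")    # planes
  bpp <- readBin(con, "integer", 1L, 2L, endian = "little")
  compression <- readBin(con, "integer", 1L, 4L, endian = "little")
  if (compression != 0L || !(bpp %in% c(8L, 24L, 32L))) {
    stop_ovocount(
      sprintf("unsupported BMP variant in %s (need uncompressed 8/24/32-bit)", path),
      "ovocount_format_error")
  }
  flip <- height > 0L            # positive height = bottom-up row order
  height <- abs(height)
  palette <- NULL
  if (bpp == 8L) {
    seek(con, 14L + header_size)
    n_pal <- (data_offset - 14L - header_size) %/% 4L
    pal_raw <- readBin(con, "raw", n_pal * 4L)
    pal <- matrix(as.integer(pal_raw), nrow = 4L)       # B, G, R, reserved
    palette <- pal[3:1, , drop = FALSE]                 # -> R, G, B
  }
  seek(con, data_offset)
  bytes_pp <- bpp %/% 8L
  row_size <- ((bpp * width + 31L) %/% 32L) * 4L        # rows pad to 4 bytes
  raw <- readBin(con, "raw", row_size * height)
  rows <- matrix(as.integer(raw), nrow = row_size)[seq_len(width * bytes_pp), ,
                                                   drop = FALSE]
  ord <- if (flip) rev(seq_len(height)) else seq_len(height)
  if (bpp == 8L) {
    idx <- t(rows)[ord, , drop = FALSE] + 1L
    arr <- array(0, c(height, width, 3L))
    for (ch in 1:3) arr[, , ch] <- matrix(palette[ch, idx], height, width)
  } else {
    arr <- array(0, c(height, width, 3L))
    for (ch in 1:3) {
      # BMP stores B, G, R
      plane <- rows[seq(4L - ch, by = bytes_pp, length.out = width), ,
                    drop = FALSE]
      arr[, , ch] <- t(plane)[ord, , drop = FALSE]
    }
  }
  arr / 255
}

#' Crop a grayscale image
#'
#' Extracts the sub-image covered by `region`, the explicit stand-in for the
#' manual background trim applied to whole-strip camera photographs before
#' counting. The input image is not modified.
#'
#' @param image a [gray_image].
#' @param region a [rect] lying entirely inside the image.
#' @return a [gray_image] of shape (bottom - top) x (right - left).
#' @examples
#' img <- gray_image(matrix(0:99, 10, 10), "demo")
#' trim_image(img, rect(2, 3, 5, 7))
#' @export
trim_image <- function(image, region) {
  stopifnot(is_gray_image(image), inherits(region, "rect"))
  if (region[["bottom"]] > nrow(image) || region[["right"]] > ncol(image)) {
    stop_ovocount(
      sprintf("crop region [%d,%d)x[%d,%d) exceeds image bounds %d x %d",
              region[["top"]], region[["bottom"]], region[["left"]],
              region[["right"]], nrow(image), ncol(image)),
      "ovocount_bounds_error")
  }
  sub <- unclass(image)[(region[["top"]] + 1L):region[["bottom"]],
                        (region[["left"]] + 1L):region[["right"]], drop = FALSE]
  gray_image(sub, source_id = source_id(image))
}

# 3 x 5 bitmap digits for overlay labels, one matrix per digit 0-9.
.digit_font <- local({
  rows <- list(
    "0" = c("111", "101", "101", "101", "111"),
    "1" = c("010", "110", "010", "010", "111"),
    "2" = c("111", "001", "111", "100", "111"),
    "3" = c("111", "001", "111", "001", "111"),
    "4" = c("101", "101", "111", "001", "001"),
    "5" = c("111", "100", "111", "001", "111"),
    "6" = c("111", "100", "111", "101", "111"),
    "7" = c("111", "001", "010", "010", "010"),
    "8" = c("111", "101", "111", "101", "111"),
    "9" = c("111", "101", "111", "001", "111"))
  lapply(rows, function(r) {
    do.call(rbind, lapply(strsplit(r, ""), function(b) as.integer(b) == 1L))
  })
})

# Stamp `text` (digits only) into an H x W x 3 array at (row, col), scale 2,
# in colour `col` (length-3 in [0,1]). Silently clips at the border.
stamp_digits <- function(arr, text, row, col, colour, scale = 2L) {
  chars <- strsplit(text, "")[[1]]
  x <- col
  for (ch in chars) {
    glyph <- .digit_font[[ch]]
    if (is.null(glyph)) next
    glyph <- glyph[rep(seq_len(5), each = scale), rep(seq_len(3), each = scale)]
    rr <- row + seq_len(nrow(glyph)) - 1L
    cc <- x + seq_len(ncol(glyph)) - 1L
    keep_r <- rr >= 1L & rr <= dim(arr)[1]
    keep_c <- cc >= 1L & cc <= dim(arr)[2]
    g <- glyph[keep_r, keep_c, drop = FALSE]
    for (chn in 1:3) {
      block <- arr[rr[keep_r], cc[keep_c], chn]
      block[g] <- colour[chn]
      arr[rr[keep_r], cc[keep_c], chn] <- block
    }
    x <- x + 3L * scale + scale          # glyph width + 1 space
  }
  arr
}

# draw a 1-px rectangle outline (0-based half-open box) into an RGB array
draw_box <- function(arr, top, left, bottom, right, colour) {
  h <- dim(arr)[1]; w <- dim(arr)[2]
  r1 <- max(top + 1L, 1L); r2 <- min(bottom, h)
  c1 <- max(left + 1L, 1L); c2 <- min(right, w)
  for (chn in 1:3) {
    arr[r1, c1:c2, chn] <- colour[chn]
    arr[r2, c1:c2, chn] <- colour[chn]
    arr[r1:r2, c1, chn] <- colour[chn]
    arr[r1:r2, c2, chn] <- colour[chn]
  }
  arr
}

#' Render a detection overlay image
#'
#' Writes an RGB PNG of the grayscale input with every detected object
#' outlined: green for confident single eggs, red for flagged (uncertain)
#' objects, blue for rejected sub-threshold objects so discarded noise can be
#' audited. Uncertain boxes carry their estimated egg count as a small pixel
#' label. The input image is never modified; this is a pure render to file.
#'
#' @param image the [gray_image] the detection ran on.
#' @param result the [count_eggs()] result for that image.
#' @param path output PNG path.
#' @return `invisible(path)`.
#' @export
render_overlay <- function(image, result, path) {
  stopifnot(is_gray_image(image), inherits(result, "egg_count_result"))
  if (!identical(unname(result$image_shape), c(nrow(image), ncol(image)))) {
    stop_ovocount(
      sprintf("result was computed on a %d x %d image but a %d x %d image was given",
              result$image_shape[1], result$image_shape[2], nrow(image), ncol(image)),
      "ovocount_consistency_error")
  }
  gray <- unclass(image) / 255
  arr <- array(gray, c(nrow(image), ncol(image), 3L))
  cols <- list(confident = c(0, 0.8, 0), uncertain = c(1, 0, 0),
               rejected = c(0.2, 0.4, 1))
  obj <- result$objects
  if (nrow(obj)) {
    for (i in seq_len(nrow(obj))) {
      colour <- cols[[obj$status[i]]]
      arr <- draw_box(arr, obj$top[i], obj$left[i], obj$bottom[i], obj$right[i],
                      colour)
      if (obj$status[i] == "uncertain") {
        arr <- stamp_digits(arr, as.character(obj$estimated_count[i]),
                            row = obj$top[i] + 3L, col = obj$left[i] + 3L,
                            colour = colour)
      }
    }
  }
  ok <- tryCatch({png::writePNG(arr, path); TRUE}, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_ovocount(sprintf("cannot write overlay to %s: %s", path,
                          conditionMessage(ok)), "ovocount_io_error")
  }
  invisible(path)
}

#' Write a grayscale image to PNG
#'
#' @param image a [gray_image].
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_image <- function(image, path) {
  stopifnot(is_gray_image(image))
  png::writePNG(unclass(image) / 255, path)
  invisible(path)
}
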