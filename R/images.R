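# In-memory image conventions
#
# Grayscale images are numeric matrices (rows = y, cols = x) with values in
# [0, 255]. RGB images are numeric arrays of dimension c(height, width, 3) on
# the same scale. Pixel coordinates are 0-based with the origin at the image
# top-left and y increasing downward, matching screen conventions; a pixel
# (x, y) therefore lives at `img[y + 1, x + 1]`.

#' Convert an RGB image to grayscale
#'
#' @param img A grayscale matrix (returned unchanged) or an RGB array of
#'   dimension `c(h, w, 3)`.
#' @return A numeric matrix, the per-pixel mean of the three channels.
#' @export
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    pa_stop("pa_param_error", "expected a grayscale matrix or an h x w x 3 array")
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}

#' Replicate a grayscale image into an RGB array
#' @param mat Numeric matrix.
#' @return Array `c(nrow, ncol, 3)` with identical channels.
#' @export
gray_to_rgb <- function(mat) {
  array(rep(mat, 3), dim = c(nrow(mat), ncol(mat), 3L))
}

#' Per-pixel channel spread of an RGB image
#'
#' Population standard deviation of the three channel values of each pixel.
#' A pixel is "colored" (i.e. not a grayscale color) when this spread exceeds
#' a threshold; 10 gray levels is the default used throughout the package.
#'
#' @param img RGB array `c(h, w, 3)`.
#' @return Numeric matrix of standard deviations.
#' @export
channel_sd <- function(img) {
  if (is.matrix(img)) return(matrix(0, nrow(img), ncol(img)))
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  m <- (r + g + b) / 3
  sqrt(((r - m)^2 + (g - m)^2 + (b - m)^2) / 3)
}

#' Crop an image to a region of interest
#'
#' @param img Grayscale matrix or RGB array.
#' @param box A [roi_box()] in 0-based, half-open pixel coordinates.
#' @return The cropped image, same storage type as the input.
#' @export
crop_roi <- function(img, box) {
  stopifnot(inherits(box, "roi_box"))
  h <- dim(img)[1]; w <- dim(img)[2]
  if (box$x2 > w || box$y2 > h)
    pa_stop("pa_geometry_error", "ROI [%d,%d)x[%d,%d) exceeds image %dx%d",
            box$x1, box$x2, box$y1, box$y2, w, h)
  ys <- (box$y1 + 1):box$y2
  xs <- (box$x1 + 1):box$x2
  if (is.matrix(img)) img[ys, xs, drop = FALSE] else img[ys, xs, , drop = FALSE]
}

#' Read an image file
#'
#' Supports PNG (via the `png` package when installed) and portable anymap
#' (PGM/PPM, both ASCII and binary) through a built-in codec, so the package
#' works without any external image library.
#'
#' @param path File path; format chosen by extension (`.png`, `.pgm`, `.ppm`,
#'   `.pnm`).
#' @return Grayscale matrix or RGB array on the 0-255 scale.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      pa_stop("pa_io_error", "the 'png' package is required to read PNG files")
    img <- png::readPNG(path) * 255
    if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
    return(img)
  }
  if (ext %in% c("pgm", "ppm", "pnm")) return(read_pnm(path))
  pa_stop("pa_io_error", "unsupported image format: .%s", ext)
}

#' Write an image file
#'
#' @param img Grayscale matrix or RGB array, values in [0, 255].
#' @param path Output path; `.png` requires the `png` package, `.pgm`/`.ppm`
#'   use the built-in netpbm codec.
#' @param ascii For PNM output, write the plain-text (P2/P3) variant.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, ascii = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      pa_stop("pa_io_error", "the 'png' package is required to write PNG files")
    png::writePNG(clamp(img, 0, 255) / 255, path)
    return(invisible(path))
  }
  if (ext %in% c("pgm", "ppm", "pnm")) return(write_pnm(img, path, ascii = ascii))
  pa_stop("pa_io_error", "unsupported image format: .%s", ext)
}

#' @rdname read_image
#' @export
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    pa_stop("pa_io_error", "not a supported PNM file (magic '%s')", magic)
  tokens <- character(0)
  # header: width, height, maxval; '#' starts a comment
  read_token <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0) pa_stop("pa_io_error", "truncated PNM header")
      if (grepl("\\s", ch)) next
      if (ch == "#") {
        repeat {
          c2 <- readChar(con, 1L, useBytes = TRUE)
          if (length(c2) == 0 || c2 == "\n") break
        }
        next
      }
      tok <- ch
      repeat {
        c2 <- readChar(con, 1L, useBytes = TRUE)
        if (length(c2) == 0 || grepl("\\s", c2)) break
        tok <- paste0(tok, c2)
      }
      return(tok)
    }
  }
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P2", "P3")) {
    scan(con, what = integer(), n = n, quiet = TRUE)
  } else {
    as.integer(readBin(con, "raw", n = n))
  }
  vals <- vals * (255 / maxval)
  if (nch == 1L) {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    # PNM interleaves RGB per pixel, row-major
    arr <- array(0, dim = c(h, w, 3L))
    m <- matrix(vals, ncol = 3L, byrow = TRUE)
    for (k in 1:3) arr[, , k] <- matrix(m[, k], nrow = h, ncol = w, byrow = TRUE)
    arr
  }
}

#' @rdname write_image
#' @export
write_pnm <- function(img, path, ascii = FALSE) {
  img <- round(clamp(img, 0, 255))
  rgb <- !is.matrix(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  vals <- if (rgb) {
    as.vector(t(cbind(as.vector(t(img[, , 1])), as.vector(t(img[, , 2])),
                      as.vector(t(img[, , 3])))))
  } else {
    as.vector(t(img))
  }
  magic <- if (ascii) (if (rgb) "P3" else "P2") else (if (rgb) "P6" else "P5")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n255\n", magic, w, h), con, eos = NULL)
  if (ascii) {
    writeChar(paste(vals, collapse = "\n"), con, eos = NULL)
    writeChar("\n", con, eos = NULL)
  } else {
    writeBin(as.raw(vals), con)
  }
  invisible(path)
}
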