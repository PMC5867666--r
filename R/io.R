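# Raster I/O. Fundus photographs arrive as 8-bit colour rasters; everything
# downstream works on integer matrices in [0, 255] indexed [row, col] with
# row 1 at the top of the image.

#' Read a fundus image
#'
#' Reads an 8-bit colour raster (PNG, TIFF, or uncompressed BMP) into a
#' `fundus_rgb` object: three integer intensity planes in \[0, 255\].
#' Grayscale files are promoted to three equal planes; an alpha channel, if
#' present, is dropped. 16-bit files are rescaled to 8 bits (integer division
#' by 257) with a warning, since the pipeline assumes 8-bit data throughout.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, or `.bmp` file.
#' @return A `fundus_rgb` object: list with integer matrices `red`, `green`,
#'   `blue` (rows = image rows, top first).
#' @export
read_fundus <- function(path) {
  if (!file.exists(path)) {
    druscan_abort(sprintf("cannot read image: no such file '%s'", path),
                  "druscan_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = read_png_8bit(path),
    tif = ,
    tiff = read_tiff_8bit(path),
    bmp = read_bmp_8bit(path),
    druscan_abort(sprintf("unsupported image format '.%s' for '%s'", ext, path),
                  "druscan_io_error")
  )
  planes_to_rgb(arr)
}

read_png_8bit <- function(path) {
  x <- tryCatch(png::readPNG(path, info = TRUE),
                error = function(e) druscan_abort(
                  sprintf("cannot decode PNG '%s': %s", path, conditionMessage(e)),
                  "druscan_io_error"))
  info <- attr(x, "info")
  depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  scale_to_8bit(unclass(x), depth, path)
}

read_tiff_8bit <- function(path) {
  x <- tryCatch(tiff::readTIFF(path, info = TRUE),
                error = function(e) druscan_abort(
                  sprintf("cannot decode TIFF '%s': %s", path, conditionMessage(e)),
                  "druscan_io_error"))
  depth <- attr(x, "bits.per.sample")
  if (is.null(depth)) depth <- 8L
  scale_to_8bit(unclass(x), depth, path)
}

scale_to_8bit <- function(x, depth, path) {
  # readers return values in [0, 1]; recover the integer levels
  if (depth > 8) {
    warning(sprintf("'%s' has bit depth %d; rescaling to 8-bit (v %%/%% 257)",
                    path, depth), call. = FALSE)
    v <- as.integer(round(x * (2^depth - 1))) %/% as.integer(257)
  } else {
    v <- as.integer(round(x * 255))
  }
  array(v, dim = if (length(dim(x)) >= 2) dim(x) else c(length(x), 1))
}

# Minimal reader for uncompressed 8/24/32-bit BMP (BITMAPINFOHEADER); no
# installed package decodes BMP. Rows are stored bottom-up and padded to
# 4-byte boundaries.
read_bmp_8bit <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM") {
    druscan_abort(sprintf("cannot decode BMP '%s'", path), "druscan_io_error")
  }
  le <- function(idx) sum(as.integer(raw[idx]) * 256^(seq_along(idx) - 1))
  offset <- le(11:14)
  width <- le(19:22); height <- le(23:26)
  bpp <- le(29:30); compression <- le(31:34)
  if (compression != 0 || !bpp %in% c(8, 24, 32)) {
    druscan_abort(sprintf("unsupported BMP variant in '%s' (bpp %d, compression %d)",
                          path, bpp, compression), "druscan_io_error")
  }
  bytes_pp <- bpp / 8
  row_bytes <- ((width * bytes_pp + 3) %/% 4) * 4
  out <- array(0L, c(height, width, 3))
  for (r in seq_len(height)) {
    # BMP rows are bottom-up
    start <- offset + (r - 1) * row_bytes
    row <- as.integer(raw[(start + 1):(start + width * bytes_pp)])
    rr <- height - r + 1
    if (bpp == 8) {
      out[rr, , 1] <- out[rr, , 2] <- out[rr, , 3] <- row
    } else {
      # pixel order is B, G, R (, A)
      m <- matrix(row, nrow = bytes_pp)
      out[rr, , 1] <- m[3, ]; out[rr, , 2] <- m[2, ]; out[rr, , 3] <- m[1, ]
    }
  }
  out
}

planes_to_rgb <- function(arr) {
  d <- dim(arr)
  if (length(d) == 2) {
    g <- matrix(as.integer(arr), d[1], d[2])
    return(new_fundus_rgb(g, g, g))
  }
  nc <- d[3]
  plane <- function(i) matrix(as.integer(arr[, , i]), d[1], d[2])
  if (nc == 1) {
    g <- plane(1)
    new_fundus_rgb(g, g, g)
  } else if (nc >= 3) {
    new_fundus_rgb(plane(1), plane(2), plane(3))
  } else {
    druscan_abort(sprintf("unsupported channel count: %d", nc), "druscan_io_error")
  }
}

#' Construct a fundus RGB image from intensity planes
#'
#' @param red,green,blue Integer matrices with values in \[0, 255\], equal
#'   dimensions.
#' @return A `fundus_rgb` object.
#' @export
new_fundus_rgb <- function(red, green, blue) {
  assert_gray(red, "red"); assert_gray(green, "green"); assert_gray(blue, "blue")
  assert_same_dim(red, green, "colour planes")
  assert_same_dim(red, blue, "colour planes")
  structure(list(red = as_gray_int(red), green = as_gray_int(green),
                 blue = as_gray_int(blue)),
            class = "fundus_rgb")
}

#' @export
print.fundus_rgb <- function(x, ...) {
  cat(sprintf("<fundus_rgb> %d x %d pixels (rows x cols), 8-bit RGB\n",
              nrow(x$green), ncol(x$green)))
  invisible(x)
}

#' @export
dim.fundus_rgb <- function(x) dim(x$green)

#' Extract the green channel
#'
#' The green plane carries the highest drusen/vessel contrast in fundus
#' photography (red is dominated by illumination, blue by noise), so the
#' whole pipeline operates on it.
#'
#' @param img A `fundus_rgb` object.
#' @return Integer matrix of green intensities in \[0, 255\].
#' @export
green_channel <- function(img) {
  if (!inherits(img, "fundus_rgb")) {
    druscan_abort("`img` must be a fundus_rgb object", "druscan_invalid_parameter")
  }
  img$green
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground pixels are written as 255, background as 0, losslessly.
#'
#' @param mask Logical matrix.
#' @param path Output path (`.png`).
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  ok <- tryCatch({ png::writePNG(mask * 1.0, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) {
    druscan_abort(sprintf("cannot write mask to '%s'", path), "druscan_io_error")
  }
  invisible(path)
}

#' Read a binary mask from a raster file
#'
#' Any nonzero pixel reads as foreground; colour masks are reduced by their
#' first channel.
#'
#' @param path Path to a mask raster (PNG/TIFF/BMP).
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  img <- read_fundus(path)
  img$red > 0L
}

#' Write an 8-bit grayscale image as PNG
#'
#' Convenience for dumping intermediate pipeline images (filtered, subtract,
#' stretched) for visual inspection.
#'
#' @param gray Integer matrix in \[0, 255\].
#' @param path Output path (`.png`).
#' @export
write_gray <- function(gray, path) {
  assert_gray(gray)
  png::writePNG(gray / 255, path)
  invisible(path)
}
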