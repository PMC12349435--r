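# Raster containers and I/O.
#
# Images are H x W x 3 double arrays in [0, 1]; masks are H x W integer
# matrices (0 = background). Label rasters are written as single-channel
# 16-bit TIFF so label ids survive a round trip exactly; RGB images as 8-bit
# PNG. See the package help page for the pixel coordinate convention.

#' Round half away from zero
#'
#' Used wherever a float pixel coordinate meets an integer raster grid, so
#' that prompt rasterization is deterministic and independent of the banker's
#' rounding of [round()].
#'
#' @param x numeric vector.
#' @return integer vector.
#' @export
px_round <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

# matrix of the pixel (x, y) pairs of the nonzero entries of a mask
mask_coords <- function(mask) {
  idx <- which(mask != 0)
  r <- ((idx - 1L) %% nrow(mask)) + 1L
  c <- ((idx - 1L) %/% nrow(mask)) + 1L
  cbind(x = c - 1L, y = r - 1L)
}

#' Sorted nonzero labels present in an instance mask
#'
#' @param mask integer matrix, 0 = background.
#' @return increasing integer vector of the labels present.
#' @export
mask_labels <- function(mask) {
  u <- sort(unique(as.vector(mask)))
  as.integer(u[u != 0])
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) abort(sprintf("`%s` must be a matrix", arg))
  if (anyNA(mask)) abort(sprintf("`%s` contains NA", arg))
  if (any(mask < 0)) abort(sprintf("`%s` has negative labels", arg))
  invisible(mask)
}

assert_same_shape <- function(a, b, what = "masks") {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    abort(sprintf("shape mismatch between %s: %s vs %s",
                  what, paste(dim(a)[1:2], collapse = "x"),
                  paste(dim(b)[1:2], collapse = "x")))
  }
  invisible(TRUE)
}

#' Read / write label rasters
#'
#' Label rasters (semantic or instance masks) are stored as single-channel
#' 16-bit TIFF, 0 = background, so up to 65535 labels round-trip exactly.
#' `read_label_raster()` also accepts single-channel PNG.
#'
#' @param path file path; `.tif`/`.tiff` or `.png`.
#' @param mask integer matrix of labels in `[0, 65535]`.
#' @return `read_label_raster()` returns an integer matrix.
#' @export
read_label_raster <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read raster: %s", path))
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    "png" = png::readPNG(path),
    "tif" = ,
    "tiff" = tiff::readTIFF(path),
    abort(sprintf("unsupported raster format: .%s", ext))
  )
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] > 1L && !all(x[, , 1] == x[, , -1])) {
      abort(sprintf("multi-channel raster is not a label mask: %s", path))
    }
    x <- x[, , 1]
  }
  m <- matrix(as.integer(round(x * 65535)), nrow(x), ncol(x))
  assert_mask(m)
  m
}

#' @rdname read_label_raster
#' @export
write_label_raster <- function(mask, path) {
  assert_mask(mask)
  if (any(mask > 65535)) abort("labels above 65535 cannot be stored in 16 bits")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read / write RGB images
#'
#' 8-bit PNG, returned as an H x W x 3 double array in `[0, 1]`.
#'
#' @param path PNG file path.
#' @param image H x W x 3 array in `[0, 1]`.
#' @return `read_rgb_image()` returns the image array.
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read image: %s", path))
  x <- png::readPNG(path)
  if (length(dim(x)) != 3L || dim(x)[3] < 3L) abort("expected a colour image")
  x[, , 1:3, drop = FALSE]
}

#' @rdname read_rgb_image
#' @export
write_rgb_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

# Z[r, c] = M[r + dy, c + dx] (zero padded): the value of M at offset (dx, dy)
# from each pixel, in (x, y) = (col, row) terms.
shift_mat <- function(m, dy, dx, fill = 0L) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1L, 1L - dy):min(h, h - dy)
  cs <- max(1L, 1L - dx):min(w, w - dx)
  if (length(rs) && length(cs)) out[rs, cs] <- m[rs + dy, cs + dx]
  out
}

# integer (dx, dy) offsets with 0 < dx^2 + dy^2 <= eps^2
disc_offsets <- function(eps) {
  r <- floor(eps)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g <- g[g$dx^2 + g$dy^2 <= eps^2 & !(g$dx == 0 & g$dy == 0), ]
  as.matrix(g)
}

# run body with a deterministic RNG stream, restoring the caller's stream
with_seed <- function(seed, body) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  body
}
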