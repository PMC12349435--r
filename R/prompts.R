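# Prompt engineering: from labelled trunk instances to a five-point diamond
# prompt per tree. Each trunk gets a least-squares regression axis; the
# per-trunk angles are averaged into a row-wide mean tilt; the constrained
# axis through each trunk centroid anchors the prompt: B at the trunk
# bottom, T at the tree summit (supervised height or unsupervised
# foreground-mask scan), C midway between B and T, and lateral points R/L
# at 20% of the distance from C toward the neighbouring border.

#' Prompt-engineering configuration
#'
#' @param mode `"supervised"` (operator-supplied tree height in pixels) or
#'   `"unsupervised"` (summit from a foreground-vegetation mask).
#' @param height_px tree height h in pixels (supervised mode); scalar or one
#'   value per tree.
#' @param gap_tolerance_px allowed off-mask break, in pixels, when scanning
#'   the foreground run along the axis (unsupervised mode).
#' @param edge_policy border for boundary trees with no neighbour on one
#'   side: `"edge"` uses the image edge (x = 0 or width - 1), `"half"` the
#'   midpoint between the trunk and that edge.
#' @param shared_angle constrain every axis to the row-wide mean tilt
#'   (default); `FALSE` keeps each trunk's free fit angle.
#' @return a `prompt_config` list.
#' @export
prompt_config <- function(mode = c("supervised", "unsupervised"),
                          height_px = NULL, gap_tolerance_px = 10,
                          edge_policy = c("edge", "half"),
                          shared_angle = TRUE) {
  mode <- match.arg(mode)
  if (mode == "supervised") {
    if (is.null(height_px) || any(height_px <= 0))
      abort("supervised mode needs height_px > 0")
  }
  structure(list(mode = mode, height_px = height_px,
                 gap_tolerance_px = gap_tolerance_px,
                 edge_policy = match.arg(edge_policy),
                 shared_angle = shared_angle),
            class = "prompt_config")
}

#' Fit the free regression axis of one trunk
#'
#' Least squares of column on row (`x = a * y + b`): regressing x on y, not
#' y on x, keeps near-vertical trunks finite-sloped. The returned angle is
#' `atan(a)` in degrees from the image vertical, in `(-90, 90)`.
#'
#' @param trunk_pixels two-column matrix or data frame of pixel `(x, y)`
#'   coordinates; at least two distinct rows (y values) are required.
#' @return angle from vertical, degrees.
#' @export
fit_free_axis <- function(trunk_pixels) {
  xy <- as.matrix(trunk_pixels)
  if (nrow(xy) < 2 || length(unique(xy[, 2])) < 2)
    abort("degenerate trunk: pixels span fewer than 2 rows")
  fit <- stats::lm.fit(cbind(1, xy[, 2]), xy[, 1])
  atan(fit$coefficients[[2]]) * 180 / pi
}

#' Row-wide mean axis angle
#'
#' Plain arithmetic mean of the per-trunk angles: tilts in row images are
#' small and sign-consistent, so no circular statistics are needed.
#'
#' @param free_angles numeric vector of per-trunk angles, degrees.
#' @return mean angle, degrees.
#' @export
mean_axis_angle <- function(free_angles) {
  if (!length(free_angles)) abort("no angles to average")
  mean(free_angles)
}

#' Constrained trunk axis
#'
#' The line through the trunk centroid at the shared angle; the bottom
#' endpoint B sits on this line at the trunk's maximal pixel row.
#'
#' @param trunk_pixels pixel coordinates of one trunk (matrix of x, y).
#' @param angle_deg shared angle alpha, degrees from vertical.
#' @param centroid optional `(x, y)` anchor; defaults to the pixel mean.
#' @return a `trunk_axis` list: `anchor`, `angle_deg`, `bottom`,
#'   `free_angle_deg`.
#' @export
constrained_axis <- function(trunk_pixels, angle_deg, centroid = NULL) {
  xy <- as.matrix(trunk_pixels)
  if (!nrow(xy)) abort("empty trunk pixel set")
  if (is.null(centroid)) centroid <- c(mean(xy[, 1]), mean(xy[, 2]))
  free <- tryCatch(fit_free_axis(xy), error = function(e) NA_real_)
  a <- tan(angle_deg * pi / 180)
  y_b <- max(xy[, 2])
  bottom <- c(centroid[1] + a * (y_b - centroid[2]), y_b)
  structure(list(anchor = centroid, angle_deg = angle_deg,
                 bottom = bottom, free_angle_deg = free,
                 y_min = min(xy[, 2])),
            class = "trunk_axis")
}

# x on the axis at row y
axis_x_at <- function(axis, y) {
  axis$anchor[1] + tan(axis$angle_deg * pi / 180) * (y - axis$anchor[2])
}

#' Horizontal neighbour spans
#'
#' For each trunk, the x coordinates of the nearest trunk centroids to its
#' left and right; boundary trees take the missing side from `edge_policy`:
#' `"edge"` uses x = 0 / width - 1, `"half"` the midpoint between the
#' centroid and that edge.
#'
#' @param centroids_x trunk centroid x coordinates, sorted increasing.
#' @param image_width image width in pixels.
#' @param edge_policy `"edge"` or `"half"`.
#' @return tibble with `label`, `x_left`, `x_right` (label = rank in x order).
#' @export
horizontal_neighbors <- function(centroids_x, image_width,
                                 edge_policy = c("edge", "half")) {
  edge_policy <- match.arg(edge_policy)
  k <- length(centroids_x)
  if (k < 1) abort("need at least one centroid")
  if (is.unsorted(centroids_x)) abort("centroids_x must be sorted increasing")
  left_edge <- 0; right_edge <- image_width - 1
  xl <- c(NA, centroids_x[-k])
  xr <- c(centroids_x[-1], NA)
  if (edge_policy == "edge") {
    xl[1] <- left_edge; xr[k] <- right_edge
  } else {
    xl[1] <- (centroids_x[1] + left_edge) / 2
    xr[k] <- (centroids_x[k] + right_edge) / 2
  }
  tibble(label = seq_len(k), x_left = xl, x_right = xr)
}

#' Supervised summit
#'
#' T is B displaced `h` pixels along the axis toward decreasing y (Euclidean
#' distance along the line): `dy = -h cos(alpha)`, `dx = -h sin(alpha)`.
#' A summit above the image top is clamped to y = 0 along the line, with a
#' warning.
#'
#' @param axis a `trunk_axis`.
#' @param h tree height in pixels (> 0).
#' @return summit point `c(x, y)`.
#' @export
summit_supervised <- function(axis, h) {
  if (h <= 0) abort("height h must be > 0")
  al <- axis$angle_deg * pi / 180
  t <- c(axis$bottom[1] - h * sin(al), axis$bottom[2] - h * cos(al))
  if (t[2] < 0) {
    warn("summit above image top; clamped to y = 0 along the axis")
    t <- c(axis_x_at(axis, 0), 0)
  }
  t
}

#' Estimate a foreground-vegetation mask
#'
#' Stand-in for an external foreground-segmentation plugin: the excess-green
#' index `ExG = 2g - r - b` (channels in `[0, 1]`) thresholded by Otsu's
#' method, with the threshold floored at 0 so pixels must actually be
#' green-dominant. Any user-supplied vegetation mask can be used in its
#' place, which is the fidelity path on real imagery.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @return logical matrix, `TRUE` = vegetation.
#' @export
estimate_foreground <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    abort("estimate_foreground needs a 3-channel image")
  exg <- 2 * image[, , 2] - image[, , 1] - image[, , 3]
  if (stats::sd(exg) < 1e-9) return(exg > 0)
  scaled <- (exg + 2) / 4
  thr <- EBImage::otsu(scaled, range = c(0, 1)) * 4 - 2
  exg > max(thr, 0)
}

#' Unsupervised summit from a foreground mask
#'
#' Rasterizes the axis from B upward (decreasing y) to the image top and
#' finds the continuous run of foreground pixels starting at the first
#' foreground hit at or above B (the trunk base itself is often not
#' vegetation), tolerating off-mask gaps of up to `gap_tolerance_px` rows.
#' T is the run's topmost point.
#'
#' @param axis a `trunk_axis`.
#' @param foreground logical or 0/1 matrix matching the scene.
#' @param gap_tolerance_px allowed break in the run, pixels.
#' @return summit point `c(x, y)`; errors with "summit not found" when the
#'   axis meets no foreground (callers may fall back to supervised mode).
#' @export
summit_unsupervised <- function(axis, foreground, gap_tolerance_px = 10) {
  fg <- foreground != 0
  a <- tan(axis$angle_deg * pi / 180)
  top <- trace_line_top(fg, axis$bottom[1], axis$bottom[2], a,
                        gap_tolerance = gap_tolerance_px)
  if (is.null(top)) abort("summit not found: no foreground on the axis")
  top
}

#' Build the five-point diamond prompts for every trunk instance
#'
#' Runs the full prompt-engineering procedure: trunk centroids, horizontal
#' neighbours, per-trunk free axes and their mean angle, the constrained
#' axis per trunk, the summit (supervised height or unsupervised foreground
#' scan), and the five points per tree i:
#' \itemize{
#'   \item B: bottom endpoint of the axis at the trunk's maximal pixel row;
#'   \item T: the summit;
#'   \item C: midpoint of B and T;
#'   \item R: `(x_c + 0.2 (x_br - x_c), y_c)`;
#'   \item L: `(x_c - 0.2 (x_c - x_bl), y_c)`,
#' }
#' with `x_bl`/`x_br` the neighbouring-border x from
#' [horizontal_neighbors()]. Coordinates are emitted as floats; rounding to
#' the pixel grid happens only at consumer boundaries.
#'
#' @param trunk_instances integer instance matrix of k labelled trunks.
#' @param config a [prompt_config()].
#' @param image RGB image (unsupervised mode, unless `foreground` is given).
#' @param foreground optional vegetation mask overriding [estimate_foreground()].
#' @return a `prompt_set`: tibble with columns `tree`, `point` (B, T, C, R,
#'   L), `x`, `y`; per-tree axis metadata in `attr(, "meta")`. Trees whose
#'   summit could not be located are recorded in the metadata
#'   (`summit_ok = FALSE`) and carry no points.
#' @export
build_prompts <- function(trunk_instances, config = prompt_config(),
                          image = NULL, foreground = NULL) {
  assert_mask(trunk_instances)
  ids <- mask_labels(trunk_instances)
  k <- length(ids)
  if (k == 0L) {
    warn("no trunk instances: empty prompt set")
    return(new_prompt_set(
      tibble(tree = integer(), point = character(), x = numeric(), y = numeric()),
      tibble()))
  }
  if (config$mode == "unsupervised" && is.null(foreground)) {
    if (is.null(image)) abort("unsupervised mode needs an image or a foreground mask")
    assert_same_shape(trunk_instances, image, "trunks and image")
    foreground <- estimate_foreground(image)
  }
  if (!is.null(foreground)) assert_same_shape(trunk_instances, foreground)

  cents <- trunk_centroids(trunk_instances)
  ord <- order(cents$x)
  spans <- horizontal_neighbors(cents$x[ord], ncol(trunk_instances),
                                config$edge_policy)
  spans <- spans[match(seq_len(k), ord), ]  # back to label order

  axes <- lapply(seq_len(k), function(j) {
    xy <- mask_coords(trunk_instances == ids[j])
    list(pixels = xy, centroid = c(cents$x[j], cents$y[j]))
  })
  free <- vapply(axes, function(ax) fit_free_axis(ax$pixels), numeric(1))
  alpha <- mean_axis_angle(free)

  hs <- config$height_px
  if (!is.null(hs) && length(hs) == 1L) hs <- rep(hs, k)
  if (!is.null(hs) && length(hs) != k)
    abort("height_px must be scalar or one value per tree")

  pts <- vector("list", k)
  meta <- vector("list", k)
  for (j in seq_len(k)) {
    ang <- if (config$shared_angle) alpha else free[j]
    axis <- constrained_axis(axes[[j]]$pixels, ang, axes[[j]]$centroid)
    summit_ok <- TRUE
    t_pt <- if (config$mode == "supervised") {
      summit_supervised(axis, hs[j])
    } else {
      tryCatch(summit_unsupervised(axis, foreground, config$gap_tolerance_px),
               error = function(e) { summit_ok <<- FALSE; NULL })
    }
    b_pt <- axis$bottom
    if (summit_ok) {
      c_pt <- (b_pt + t_pt) / 2
      r_pt <- c(c_pt[1] + 0.2 * (spans$x_right[j] - c_pt[1]), c_pt[2])
      l_pt <- c(c_pt[1] - 0.2 * (c_pt[1] - spans$x_left[j]), c_pt[2])
      pts[[j]] <- tibble(tree = ids[j],
                         point = c("B", "T", "C", "R", "L"),
                         x = c(b_pt[1], t_pt[1], c_pt[1], r_pt[1], l_pt[1]),
                         y = c(b_pt[2], t_pt[2], c_pt[2], r_pt[2], l_pt[2]))
    }
    meta[[j]] <- tibble(tree = ids[j], anchor_x = axis$anchor[1],
                        anchor_y = axis$anchor[2], angle_deg = ang,
                        free_angle_deg = free[j],
                        x_left = spans$x_left[j], x_right = spans$x_right[j],
                        height_px = if (is.null(hs)) NA_real_ else hs[j],
                        mode = config$mode, summit_ok = summit_ok)
  }
  new_prompt_set(dplyr::bind_rows(pts), dplyr::bind_rows(meta))
}

new_prompt_set <- function(points, meta) {
  out <- as_tibble(points)
  attr(out, "meta") <- meta
  class(out) <- c("prompt_set", class(out))
  out
}

#' @export
print.prompt_set <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<prompt_set: %d trees, %d points>\n",
              if (nrow(meta)) nrow(meta) else 0L, nrow(x)))
  NextMethod()
}

#' Prompt JSON (rowprompt-v1) I/O
#'
#' Schema: `{"schema": "rowprompt-v1", "image": str, "trees": [{"id": int,
#' "points": {"B": [x, y], "T": ..., "C": ..., "R": ..., "L": ...},
#' "point_labels": [1, 1, 1, 1, 1]}]}`. Label 1 marks a foreground prompt
#' point, the convention of promptable segmenters; the diamond layout
#' defines no background points.
#'
#' @param prompts a `prompt_set`.
#' @param path JSON file path.
#' @param image image filename recorded in the header.
#' @return `read_prompts()` returns a `prompt_set`.
#' @export
write_prompts <- function(prompts, path, image = "") {
  split_pts <- split(as.data.frame(prompts), prompts$tree)
  trees <- lapply(split_pts, function(d) {
    pt <- lapply(c("B", "T", "C", "R", "L"), function(p)
      unname(c(d$x[d$point == p], d$y[d$point == p])))
    list(id = d$tree[1], points = setNames(pt, c("B", "T", "C", "R", "L")),
         point_labels = rep(1L, 5))
  })
  jsonlite::write_json(list(schema = "rowprompt-v1", image = image,
                            trees = unname(trees)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_prompts
#' @export
read_prompts <- function(path) {
  j <- jsonlite::read_json(path)
  if (!identical(j$schema, "rowprompt-v1"))
    abort(sprintf("unsupported prompt schema: %s", j$schema %||% "<missing>"))
  pts <- purrr::map_dfr(j$trees, function(tr) {
    purrr::map_dfr(c("B", "T", "C", "R", "L"), function(p) {
      xy <- tr$points[[p]]
      if (is.null(xy)) abort(sprintf("tree %s misses point %s", tr$id, p))
      tibble(tree = as.integer(tr$id), point = p,
             x = as.numeric(xy[[1]]), y = as.numeric(xy[[2]]))
    })
  })
  meta <- tibble(tree = purrr::map_int(j$trees, ~ as.integer(.x$id)),
                 summit_ok = TRUE)
  new_prompt_set(pts, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
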