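# Synthetic orchard-row scenes with pixel-perfect ground truth.
#
# The generator emulates the geometry that makes row phenotyping hard: a
# handful of near-vertical trunks at roughly regular spacing, tilted a few
# degrees from vertical, carrying asymmetric canopies that may intertwine
# with their neighbours, over a desaturated cluttered background. Vegetation
# is green-dominant by construction so that an excess-green foreground
# estimate works offline. Every scene comes with a semantic trunk mask,
# trunk and tree instance masks, and per-tree geometry records.

#' Scene configuration for the synthetic orchard generator
#'
#' All lengths are in pixels. `trunk_tilt_deg` and `tree_height_px` accept a
#' scalar (shared by all trees), a length-2 range (sampled per tree), or a
#' length-`n_trees` vector of exact values. Tilt is the angle from the image
#' vertical in the column-on-row regression convention: a trunk with tilt
#' `a = tan(angle)` follows `x = x_bottom + a * (y - y_bottom)`.
#'
#' `overlap_fraction` controls how much neighbouring canopies intertwine:
#' the default canopy half-width is `trunk_spacing_px * (0.7 + f) / 2`, so
#' `f = 0` leaves a gap of 0.3 spacing between crowns (well-separated trees)
#' and larger `f` makes neighbours overlap. An explicit `canopy_halfwidth_px`
#' overrides the derived value.
#'
#' @param width,height image size in pixels.
#' @param n_trees number of trees `k` (>= 0).
#' @param trunk_spacing_px mean horizontal spacing between trunk bottoms.
#' @param spacing_jitter_px uniform jitter applied to each trunk position.
#' @param trunk_tilt_deg per-tree angle from vertical, degrees; see above.
#' @param trunk_width_px trunk ribbon width; must be below the spacing.
#' @param tree_height_px per-tree height `h`: the along-axis distance from
#'   the trunk bottom to the canopy summit, the ground-truth counterpart of
#'   the supervised prompt height.
#' @param canopy_halfwidth_px optional explicit canopy half-width.
#' @param canopy_asymmetry left/right half-width imbalance in `[0, 1)`.
#' @param overlap_fraction horizontal canopy overlap between neighbours, `[0, 1)`.
#' @param vegetation_color,background_color,trunk_color RGB triplets in `[0, 1]`.
#' @param noise_sd Gaussian pixel noise amplitude.
#' @param seed integer RNG seed; identical (config, seed) pairs give
#'   bit-identical scenes.
#' @return a `scene_config` list.
#' @export
scene_config <- function(width = 640L, height = 480L, n_trees = 4L,
                         trunk_spacing_px = 140, spacing_jitter_px = 8,
                         trunk_tilt_deg = c(-10, 10), trunk_width_px = 10,
                         tree_height_px = c(280, 400),
                         canopy_halfwidth_px = NULL, canopy_asymmetry = 0.25,
                         overlap_fraction = 0.3,
                         vegetation_color = c(0.20, 0.55, 0.18),
                         background_color = c(0.50, 0.52, 0.55),
                         trunk_color = c(0.36, 0.26, 0.16),
                         noise_sd = 0.02, seed = 1L) {
  cfg <- list(width = as.integer(width), height = as.integer(height),
              n_trees = as.integer(n_trees),
              trunk_spacing_px = trunk_spacing_px,
              spacing_jitter_px = spacing_jitter_px,
              trunk_tilt_deg = trunk_tilt_deg,
              trunk_width_px = trunk_width_px,
              tree_height_px = tree_height_px,
              canopy_halfwidth_px = canopy_halfwidth_px,
              canopy_asymmetry = canopy_asymmetry,
              overlap_fraction = overlap_fraction,
              vegetation_color = vegetation_color,
              background_color = background_color,
              trunk_color = trunk_color,
              noise_sd = noise_sd, seed = as.integer(seed))
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  if (cfg$width <= 0 || cfg$height <= 0) abort("width and height must be positive")
  if (cfg$n_trees < 0) abort("n_trees must be >= 0")
  if (cfg$trunk_width_px >= cfg$trunk_spacing_px)
    abort("trunk width must be below the trunk spacing")
  if (cfg$overlap_fraction < 0 || cfg$overlap_fraction >= 1)
    abort("overlap_fraction must be in [0, 1)")
  if (cfg$canopy_asymmetry < 0 || cfg$canopy_asymmetry >= 1)
    abort("canopy_asymmetry must be in [0, 1)")
  invisible(cfg)
}

# scalar -> rep; length 2 -> uniform sample; length k -> exact values
sample_per_tree <- function(v, k, what) {
  if (length(v) == 1L) rep(v, k)
  else if (length(v) == k) v
  else if (length(v) == 2L) runif(k, min(v), max(v))
  else abort(sprintf("%s must have length 1, 2 or n_trees", what))
}

#' Generate one synthetic orchard-row scene
#'
#' @param config a [scene_config()].
#' @return a list with `image` (H x W x 3 array in `[0, 1]`) and `truth`, a
#'   `scene_truth` list holding `trunk_semantic` (binary matrix),
#'   `trunk_instances` and `tree_instances` (integer label matrices, labels
#'   `1..k` ordered left to right, each tree containing its trunk), `per_tree`
#'   (tibble: `label`, `tilt_deg`, `trunk_x`, `bottom_x`, `bottom_y`,
#'   `summit_x`, `summit_y`, `height_px`) and the `config`.
#' @export
generate_scene <- function(config) {
  validate_scene_config(config)
  with_seed(config$seed, generate_scene_impl(config))
}

generate_scene_impl <- function(cfg) {
  H <- cfg$height; W <- cfg$width; k <- cfg$n_trees

  trunk_sem <- matrix(0L, H, W)
  trunk_ins <- matrix(0L, H, W)
  tree_ins <- matrix(0L, H, W)
  own_dist <- matrix(Inf, H, W)
  per_tree <- tibble(label = integer(), tilt_deg = numeric(),
                     trunk_x = numeric(), bottom_x = numeric(),
                     bottom_y = numeric(), summit_x = numeric(),
                     summit_y = numeric(), height_px = numeric())

  if (k == 0L) {
    img <- render_background(cfg)
    truth <- new_scene_truth(trunk_sem, trunk_ins, tree_ins, per_tree, cfg)
    return(list(image = img, truth = truth))
  }

  x0 <- (W - 1 - (k - 1) * cfg$trunk_spacing_px) / 2
  if (x0 < cfg$trunk_width_px)
    abort("n_trees * trunk_spacing_px does not fit in the image width")
  xb <- x0 + (seq_len(k) - 1) * cfg$trunk_spacing_px +
    runif(k, -cfg$spacing_jitter_px, cfg$spacing_jitter_px)
  xb <- sort(xb)

  tilt <- sample_per_tree(cfg$trunk_tilt_deg, k, "trunk_tilt_deg")
  hgt <- sample_per_tree(cfg$tree_height_px, k, "tree_height_px")
  hw0 <- if (is.null(cfg$canopy_halfwidth_px))
    cfg$trunk_spacing_px * (0.7 + cfg$overlap_fraction) / 2
  else cfg$canopy_halfwidth_px
  asym <- runif(k, -cfg$canopy_asymmetry, cfg$canopy_asymmetry)

  yb <- H - 1L - 4L
  a <- tan(tilt * pi / 180)
  # cap height so the summit stays inside the frame
  hgt <- pmin(hgt, (yb - 8) / cos(tilt * pi / 180))

  axis_x <- function(i, y) xb[i] + a[i] * (y - yb)  # true trunk line, 0-based y

  blobs <- vector("list", k)
  trunk_blobs <- vector("list", k)
  rows_y <- 0:(H - 1)

  for (i in seq_len(k)) {
    y_span <- hgt[i] * cos(tilt[i] * pi / 180)     # vertical extent B -> summit
    y_s <- yb - round(y_span)                      # nominal summit row
    y_cb <- yb - round(0.30 * y_span)              # canopy bottom
    y_tt <- yb - round(0.45 * y_span)              # trunk top (inside canopy)

    # trunk ribbon around the true line
    tr <- matrix(FALSE, H, W)
    half_w <- cfg$trunk_width_px / 2
    for (y in y_tt:yb) {
      cx <- axis_x(i, y)
      cs <- max(0L, ceiling(cx - half_w)):min(W - 1L, floor(cx + half_w))
      tr[y + 1L, cs + 1L] <- TRUE
    }

    # canopy: union of half-ellipses strung along the axis, tapering upward
    cp <- matrix(FALSE, H, W)
    m <- 7L
    span0 <- y_cb - y_s
    ry <- max(3, round(0.18 * span0))
    y_top_c <- y_s + ry
    centers_y <- seq(y_top_c, y_cb, length.out = m)
    d <- if (m > 1) (y_cb - y_top_c) / (m - 1) else 0
    ry <- max(ry, ceiling(0.65 * d) + 1)
    hw_l <- hw0 * (1 - asym[i])
    hw_r <- hw0 * (1 + asym[i])
    for (j in seq_len(m)) {
      cy <- centers_y[j]
      u <- if (span0 > 0) (cy - y_top_c) / max(y_cb - y_top_c, 1) else 1
      f <- 0.45 + 0.55 * sin(pi * (0.15 + 0.85 * u))
      cx <- axis_x(i, cy) + runif(1, -0.05, 0.05) * hw0
      rxl <- max(3, hw_l * f); rxr <- max(3, hw_r * f)
      rr <- max(0L, floor(cy - ry)):min(H - 1L, ceiling(cy + ry))
      cc <- max(0L, floor(cx - rxl)):min(W - 1L, ceiling(cx + rxr))
      if (!length(rr) || !length(cc)) next
      dy2 <- ((rr - cy) / ry)^2
      dxv <- cc - cx
      rx <- ifelse(dxv >= 0, rxr, rxl)
      dx2 <- (dxv / rx)^2
      inside <- outer(dy2, dx2, `+`) <= 1
      cp[rr + 1L, cc + 1L] <- cp[rr + 1L, cc + 1L] | inside
    }

    trunk_blobs[[i]] <- tr
    blobs[[i]] <- tr | cp
  }

  # ownership: contested pixels go to the tree whose trunk axis is
  # horizontally nearer; ties to the lower label id (strict < with ascending i)
  for (i in seq_len(k)) {
    idx <- which(blobs[[i]])
    if (!length(idx)) next
    r <- ((idx - 1L) %% H)
    cxs <- axis_x(i, r)                     # axis x at each pixel's y
    dx <- abs(((idx - 1L) %/% H) - cxs)     # |x - axis_x|
    win <- dx < own_dist[idx]
    tree_ins[idx[win]] <- i
    own_dist[idx[win]] <- dx[win]
  }
  for (i in seq_len(k)) {
    idx <- which(trunk_blobs[[i]] & tree_ins == i)
    trunk_ins[idx] <- i
  }
  trunk_sem <- (trunk_ins != 0L) + 0L
  storage.mode(trunk_sem) <- "integer"

  # truth records; the summit is the top of the contiguous axis run of the
  # tree's own pixels starting at the trunk bottom
  for (i in seq_len(k)) {
    bx <- axis_x(i, yb)
    own <- tree_ins == i
    top <- trace_line_top(own, bx, yb, a[i], gap_tolerance = 3)
    if (is.null(top)) top <- c(bx, yb)   # degenerate, should not occur
    h_true <- sqrt((top[1] - bx)^2 + (top[2] - yb)^2)
    per_tree <- dplyr::bind_rows(per_tree, tibble(
      label = i, tilt_deg = tilt[i], trunk_x = xb[i],
      bottom_x = bx, bottom_y = yb,
      summit_x = top[1], summit_y = top[2], height_px = h_true))
  }

  img <- render_background(cfg)
  veg <- tree_ins != 0L & trunk_ins == 0L
  trk <- trunk_ins != 0L
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[veg] <- cfg$vegetation_color[ch] + rnorm(sum(veg), 0, cfg$noise_sd)
    pl[trk] <- cfg$trunk_color[ch] + rnorm(sum(trk), 0, cfg$noise_sd)
    img[, , ch] <- pl
  }
  img <- pmin(pmax(img, 0), 1)

  truth <- new_scene_truth(trunk_sem, trunk_ins, tree_ins, per_tree, cfg)
  list(image = img, truth = truth)
}

# follow the line x = bx + a * (y - yb) upward from (bx, yb) through `mask`,
# tolerating gaps of up to `gap_tolerance` rows; NULL when the start misses
trace_line_top <- function(mask, bx, yb, a, gap_tolerance = 3) {
  H <- nrow(mask); W <- ncol(mask)
  top <- NULL; gap <- 0L
  for (y in seq(yb, 0)) {
    x <- px_round(bx + a * (y - yb))
    on <- x >= 0 && x < W && mask[y + 1L, x + 1L]
    if (on) {
      top <- c(bx + a * (y - yb), y); gap <- 0L
    } else if (!is.null(top)) {
      gap <- gap + 1L
      if (gap > gap_tolerance) break
    }
  }
  top
}

render_background <- function(cfg) {
  H <- cfg$height; W <- cfg$width
  img <- array(0, c(H, W, 3))
  # desaturated sky-to-earth vertical gradient plus clutter noise
  t <- seq(0, 1, length.out = H)
  sky <- cfg$background_color * 1.15
  earth <- cfg$background_color * 0.75
  for (ch in 1:3) {
    col_ramp <- sky[ch] + (earth[ch] - sky[ch]) * t
    img[, , ch] <- matrix(col_ramp, H, W) +
      matrix(rnorm(H * W, 0, cfg$noise_sd), H, W)
  }
  pmin(pmax(img, 0), 1)
}

new_scene_truth <- function(trunk_semantic, trunk_instances, tree_instances,
                            per_tree, config) {
  structure(list(trunk_semantic = trunk_semantic,
                 trunk_instances = trunk_instances,
                 tree_instances = tree_instances,
                 per_tree = per_tree, config = config),
            class = "scene_truth")
}

#' Generate a reproducible batch of synthetic scenes
#'
#' Scene-level parameters are sampled within ranges under the master seed;
#' each scene then gets its own derived seed, so the batch is reproducible
#' as a whole and scene by scene. Within a scene, tree tilts share a common
#' row lean (sampled from `tilt_range`) plus a small per-tree jitter
#' (`tilt_jitter_deg`), mirroring trellis rows where the whole row leans
#' together far more than trees lean against each other.
#'
#' @param n_scenes number of scenes (>= 1).
#' @param seed master seed.
#' @param width,height image size.
#' @param n_trees_range inclusive integer range for the per-scene tree count.
#' @param spacing_range,overlap_range,height_range per-scene uniform ranges.
#' @param tilt_range range of the per-scene row lean, degrees.
#' @param tilt_jitter_deg half-width of the per-tree tilt jitter, degrees.
#' @param trunk_width_px trunk ribbon width.
#' @param ... further scalar overrides passed to [scene_config()].
#' @return list of scenes; each element is `list(image, truth)` with the
#'   sampled `scene_config` stored in `truth$config`.
#' @export
generate_batch <- function(n_scenes, seed = 1L, width = 480L, height = 360L,
                           n_trees_range = c(2L, 4L),
                           spacing_range = c(105, 130),
                           overlap_range = c(0.1, 0.5),
                           height_range = c(220, 310),
                           tilt_range = c(-8, 8), tilt_jitter_deg = 2,
                           trunk_width_px = 10, ...) {
  if (n_scenes < 1) abort("n_scenes must be >= 1")
  configs <- with_seed(seed, {
    scene_seeds <- sample.int(.Machine$integer.max, n_scenes)
    lapply(seq_len(n_scenes), function(s) {
      ks <- seq(n_trees_range[1], n_trees_range[2])
      k <- if (length(ks) == 1L) ks else sample(ks, 1)
      lean <- runif(1, tilt_range[1], tilt_range[2])
      tilts <- pmin(pmax(lean + runif(k, -tilt_jitter_deg, tilt_jitter_deg),
                         -10), 10)
      scene_config(width = width, height = height, n_trees = k,
                   trunk_spacing_px = runif(1, spacing_range[1], spacing_range[2]),
                   trunk_tilt_deg = tilts,
                   tree_height_px = sort(runif(2, height_range[1], height_range[2])),
                   overlap_fraction = runif(1, overlap_range[1], overlap_range[2]),
                   trunk_width_px = trunk_width_px,
                   seed = scene_seeds[s], ...)
    })
  })
  lapply(configs, generate_scene)
}

#' Write / read a scene directory
#'
#' Lays a scene out as `image.png` (8-bit RGB), `trunk_semantic.tif`,
#' `trunk_instances.tif`, `tree_instances.tif` (16-bit label rasters) and a
#' `truth.json` sidecar with the per-tree geometry records.
#'
#' @param scene a `list(image, truth)` from [generate_scene()].
#' @param dir output directory (created if missing).
#' @return `write_scene()` the directory, invisibly; `read_scene()` the scene.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_rgb_image(scene$image, file.path(dir, "image.png"))
  write_label_raster(scene$truth$trunk_semantic, file.path(dir, "trunk_semantic.tif"))
  write_label_raster(scene$truth$trunk_instances, file.path(dir, "trunk_instances.tif"))
  write_label_raster(scene$truth$tree_instances, file.path(dir, "tree_instances.tif"))
  sidecar <- list(per_tree = scene$truth$per_tree,
                  config = unclass(scene$truth$config))
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  img <- read_rgb_image(file.path(dir, "image.png"))
  side <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  cfg <- side$config
  cfg <- scene_config(width = cfg$width, height = cfg$height,
                      n_trees = cfg$n_trees,
                      trunk_spacing_px = cfg$trunk_spacing_px,
                      spacing_jitter_px = cfg$spacing_jitter_px,
                      trunk_tilt_deg = unlist(cfg$trunk_tilt_deg),
                      trunk_width_px = cfg$trunk_width_px,
                      tree_height_px = unlist(cfg$tree_height_px),
                      canopy_halfwidth_px = cfg$canopy_halfwidth_px,
                      canopy_asymmetry = cfg$canopy_asymmetry,
                      overlap_fraction = cfg$overlap_fraction,
                      vegetation_color = unlist(cfg$vegetation_color),
                      background_color = unlist(cfg$background_color),
                      trunk_color = unlist(cfg$trunk_color),
                      noise_sd = cfg$noise_sd, seed = cfg$seed)
  truth <- new_scene_truth(
    read_label_raster(file.path(dir, "trunk_semantic.tif")),
    read_label_raster(file.path(dir, "trunk_instances.tif")),
    read_label_raster(file.path(dir, "tree_instances.tif")),
    as_tibble(side$per_tree), cfg)
  list(image = img, truth = truth)
}
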