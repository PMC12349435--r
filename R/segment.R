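# Prompt-conditioned segmentation: the backend contract is the seam where
# foundation-model segmenters plug in. A backend takes (image, foreground
# prompt points) and returns one binary mask per call. Two offline backends
# are built in: a truth oracle (test instrument for synthetic scenes) and a
# seeded region grower (offline reference; a stand-in, not a claim about
# any pretrained model). External checkpoints attach through the same
# contract via `external_backend()`.

#' Construct a segmentation backend
#'
#' @param name identifier recorded in provenance.
#' @param fn function `(image, points, params)` returning a logical or 0/1
#'   matrix of the image's H x W shape; `points` is a matrix with columns
#'   `x`, `y` (all foreground prompts, label 1).
#' @param params list of backend parameters.
#' @param stochastic declare the backend non-deterministic.
#' @return a `segmenter` object.
#' @export
segmenter <- function(name, fn, params = list(), stochastic = FALSE) {
  stopifnot(is.character(name), is.function(fn))
  structure(list(name = name, fn = fn, params = params,
                 stochastic = stochastic),
            class = "segmenter")
}

#' Update backend parameters
#'
#' @param backend a [segmenter()].
#' @param ... named parameter overrides.
#' @return the modified backend.
#' @export
backend_params <- function(backend, ...) {
  backend$params[names(list(...))] <- list(...)
  backend
}

#' Segment one tree from its prompt points
#'
#' Clamps out-of-bounds points into the image (with a warning), calls the
#' backend, and enforces the contract: the returned mask must be a binary
#' matrix of the image's shape.
#'
#' @param image H x W x 3 array.
#' @param points matrix or data frame with columns `x`, `y` (pixels; the
#'   five diamond points in B, T, C, R, L order).
#' @param backend a [segmenter()].
#' @return logical H x W matrix.
#' @export
segment_one <- function(image, points, backend) {
  stopifnot(inherits(backend, "segmenter"))
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  h <- dim(image)[1]; w <- dim(image)[2]
  clamped <- pmin(pmax(pts, 0), matrix(rep(c(w - 1, h - 1), each = nrow(pts)),
                                       ncol = 2))
  if (any(clamped != pts)) warn("prompt points outside image bounds; clamped")
  out <- backend$fn(image, clamped, backend$params)
  if (!is.matrix(out) || !identical(dim(out), c(h, w)))
    abort(sprintf("backend '%s' violated the contract: wrong output shape",
                  backend$name))
  v <- as.vector(out)
  if (!(is.logical(v) || all(v %in% c(0, 1))))
    abort(sprintf("backend '%s' violated the contract: non-binary output",
                  backend$name))
  matrix(as.logical(out), h, w)
}

#' Ground-truth oracle backend (synthetic scenes only)
#'
#' Returns the ground-truth tree instance that receives the majority of the
#' prompt points; ties go to the instance containing C (the third point);
#' when no point hits any instance the mask is empty. A test instrument: it
#' bounds what a perfect prompt-conditioned segmenter could do with these
#' prompts.
#'
#' @param truth a `scene_truth`.
#' @return a [segmenter()].
#' @export
oracle_backend <- function(truth) {
  stopifnot(inherits(truth, "scene_truth"))
  segmenter("oracle", function(image, points, params) {
    ti <- truth$tree_instances
    labs <- apply(points, 1, function(p) {
      r <- px_round(p[2]) + 1L; c <- px_round(p[1]) + 1L
      if (r < 1 || r > nrow(ti) || c < 1 || c > ncol(ti)) 0L else ti[r, c]
    })
    hit <- labs[labs != 0L]
    if (!length(hit)) return(matrix(FALSE, nrow(ti), ncol(ti)))
    tab <- table(hit)
    best <- as.integer(names(tab)[tab == max(tab)])
    lab <- if (length(best) == 1L) best
           else if (nrow(points) >= 3L && labs[3] %in% best) labs[3]
           else min(best)
    ti == lab
  })
}

#' Seeded region-growing backend
#'
#' Offline reference segmenter: from each prompt point, flood-fills over
#' pixels whose RGB Euclidean distance to the running mean colour of the
#' grown region stays within `color_tol`, with 4- or 8-connectivity,
#' optionally confined to the vertical corridor between the tree's
#' neighbour axes; the five per-seed regions are unioned. A deliberately
#' simple stand-in for a promptable foundation model, used to exercise the
#' pipeline offline.
#'
#' @param color_tol RGB Euclidean tolerance around the running region mean.
#' @param connectivity 4 or 8.
#' @param corridor optional `c(x_min, x_max)`: columns outside are excluded.
#' @return a [segmenter()].
#' @export
region_grow_backend <- function(color_tol = 0.2, connectivity = 4L,
                                corridor = NULL) {
  segmenter("regiongrow", function(image, points, params) {
    h <- dim(image)[1]; w <- dim(image)[2]
    allowed <- matrix(TRUE, h, w)
    if (!is.null(params$corridor)) {
      cols <- 0:(w - 1)
      allowed[, cols < params$corridor[1] | cols > params$corridor[2]] <- FALSE
    }
    out <- matrix(FALSE, h, w)
    for (i in seq_len(nrow(points))) {
      out <- out | grow_region(image, points[i, , drop = FALSE],
                               params$color_tol, params$connectivity, allowed)
    }
    out
  }, params = list(color_tol = color_tol, connectivity = as.integer(connectivity),
                   corridor = corridor))
}

# flood fill with a running seed-region mean colour criterion; frontier-based
# so the cost is proportional to the grown area, not the image size
grow_region <- function(image, seed, tol, connectivity, allowed) {
  h <- dim(image)[1]; w <- dim(image)[2]
  r0 <- px_round(seed[1, 2]) + 1L; c0 <- px_round(seed[1, 1]) + 1L
  region <- matrix(FALSE, h, w)
  if (r0 < 1 || r0 > h || c0 < 1 || c0 > w || !allowed[r0, c0]) return(region)
  rch <- image[, , 1]; gch <- image[, , 2]; bch <- image[, , 3]
  i0 <- (c0 - 1L) * h + r0
  region[i0] <- TRUE
  seen <- region  # pixels already tested or taken; rejected stay rejected
  n <- 1L
  mn <- c(rch[i0], gch[i0], bch[i0])
  frontier <- i0
  repeat {
    # candidate neighbours of the current frontier
    r <- (frontier - 1L) %% h + 1L
    up <- frontier[r > 1L] - 1L
    dn <- frontier[r < h] + 1L
    lf <- frontier[frontier > h] - h
    rt <- frontier[frontier <= h * (w - 1L)] + h
    cand <- c(up, dn, lf, rt)
    if (connectivity >= 8L) {
      ul <- frontier[r > 1L & frontier > h] - 1L - h
      ur <- frontier[r > 1L & frontier <= h * (w - 1L)] - 1L + h
      dl <- frontier[r < h & frontier > h] + 1L - h
      dr <- frontier[r < h & frontier <= h * (w - 1L)] + 1L + h
      cand <- c(cand, ul, ur, dl, dr)
    }
    cand <- unique(cand)
    cand <- cand[!seen[cand] & allowed[cand]]
    if (!length(cand)) break
    seen[cand] <- TRUE
    d2 <- (rch[cand] - mn[1])^2 + (gch[cand] - mn[2])^2 + (bch[cand] - mn[3])^2
    take <- cand[d2 <= tol^2]
    if (!length(take)) break
    region[take] <- TRUE
    # running mean over the whole grown region
    m <- length(take)
    mn <- (mn * n + c(sum(rch[take]), sum(gch[take]), sum(bch[take]))) / (n + m)
    n <- n + m
    frontier <- take
  }
  region
}

#' External subprocess backend
#'
#' Protocol for attaching any model server: the command is invoked as
#' `cmd IMAGE.png PROMPTS.json OUT_DIR` and must write one binary mask
#' (`tree_<id>.png` or `.tif`, nonzero = foreground) per prompted tree into
#' `OUT_DIR`. The returned backend segments one tree per call by writing a
#' single-tree prompt file. No checkpoint is bundled; this is an optional
#' shim, not exercised by the default test suite.
#'
#' @param command path to the executable.
#' @param args extra arguments placed before the positional ones.
#' @return a [segmenter()] (declared stochastic: external models need not be
#'   deterministic).
#' @export
external_backend <- function(command, args = character()) {
  segmenter("external", function(image, points, params) {
    td <- tempfile("extseg"); dir.create(td)
    on.exit(unlink(td, recursive = TRUE))
    img_path <- file.path(td, "image.png")
    write_rgb_image(image, img_path)
    pr <- new_prompt_set(
      tibble(tree = 1L, point = c("B", "T", "C", "R", "L"),
             x = points[, 1], y = points[, 2]),
      tibble(tree = 1L, summit_ok = TRUE))
    write_prompts(pr, file.path(td, "prompts.json"), image = "image.png")
    out_dir <- file.path(td, "out"); dir.create(out_dir)
    status <- system2(params$command,
                      c(params$args, img_path, file.path(td, "prompts.json"), out_dir))
    if (status != 0) abort(sprintf("external backend exited with status %d", status))
    hits <- list.files(out_dir, pattern = "^tree_1\\.(png|tif|tiff)$",
                       full.names = TRUE)
    if (!length(hits)) abort("external backend wrote no mask for tree 1")
    read_label_raster(hits[1]) != 0
  }, params = list(command = command, args = args), stochastic = TRUE)
}

#' Assemble per-tree masks into one instance raster
#'
#' Pixels claimed by several trees go to the tree whose prompt centre C is
#' nearest (Euclidean); unique claims keep their label. Output labels are
#' the prompt tree ids. The result is invariant to the ordering of the
#' per-tree masks.
#'
#' @param mask_set named list of binary masks keyed by tree id.
#' @param prompts the `prompt_set` the masks were generated from.
#' @param keep_largest_component reduce each per-tree mask to its largest
#'   4-connected component before assembly (off by default; no
#'   post-processing is presumed).
#' @return integer instance matrix.
#' @export
assemble_instances <- function(mask_set, prompts, keep_largest_component = FALSE) {
  ids <- as.integer(names(mask_set))
  pids <- sort(unique(prompts$tree))
  if (!setequal(ids, pids))
    abort("tree ids in mask_set and prompts disagree")
  if (!length(ids)) abort("empty mask set")
  h <- nrow(mask_set[[1]]); w <- ncol(mask_set[[1]])
  centres <- dplyr::filter(as_tibble(prompts), .data$point == "C")
  out <- matrix(0L, h, w)
  best <- matrix(Inf, h, w)
  xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
  ys <- matrix(0:(h - 1), h, w)
  for (i in order(ids)) {
    m <- mask_set[[i]] != 0
    assert_same_shape(m, out)
    if (keep_largest_component) m <- largest_component(m)
    cx <- centres$x[centres$tree == ids[i]]
    cy <- centres$y[centres$tree == ids[i]]
    d <- (xs - cx)^2 + (ys - cy)^2
    win <- m & d < best
    out[win] <- ids[i]
    best[win] <- d[win]
  }
  out
}

largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask), ncol(mask))
  keep <- which.max(tabulate(lab[lab > 0L]))
  lab == keep
}
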