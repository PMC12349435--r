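# Trunk instancing: split a semantic trunk mask into individually labelled
# trunks with density-based clustering (DBSCAN) over foreground pixel
# coordinates. The raster formulation is exact DBSCAN under the Euclidean
# metric: neighbour counts come from summing disc-offset shifts of the
# foreground mask, and clusters are connected components of the within-eps
# graph over core pixels.

#' Density-clustering parameters for trunk instancing
#'
#' Trunks in row images are separated by tens to hundreds of pixels, so the
#' clustering is insensitive near these defaults; all are exposed on the CLI.
#'
#' @param eps_px neighbourhood radius in pixels (> 0).
#' @param min_pts core-point threshold, counting the pixel itself (>= 1).
#' @param min_area_px clusters below this pixel area are discarded.
#' @param subsample_stride pixel subsampling step (>= 1); labels are
#'   propagated back to full resolution by nearest-labelled-pixel assignment.
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(eps_px = 5, min_pts = 20, min_area_px = 200,
                           subsample_stride = 1L) {
  if (eps_px <= 0) abort("eps_px must be > 0")
  if (min_pts < 1) abort("min_pts must be >= 1")
  if (subsample_stride < 1) abort("subsample_stride must be >= 1")
  structure(list(eps_px = eps_px, min_pts = as.integer(min_pts),
                 min_area_px = as.integer(min_area_px),
                 subsample_stride = as.integer(subsample_stride)),
            class = "cluster_params")
}

#' Cluster a semantic trunk mask into trunk instances
#'
#' Density-based clustering of the foreground pixel coordinates (Euclidean
#' metric, radius `eps_px`, core threshold `min_pts`). A foreground pixel is
#' a core point when at least `min_pts` foreground pixels (itself included)
#' lie within `eps_px`; clusters are the transitive closure of core points
#' within `eps_px` of each other; non-core foreground pixels within `eps_px`
#' of a core point join the cluster of their nearest core neighbour (ties
#' broken by scan order of the offsets, sorted by distance then row then
#' column offset). Remaining pixels are noise. Clusters below `min_area_px`
#' are dropped and the survivors are relabelled `1..k` by increasing
#' centroid x, so labels read left to right along the row.
#'
#' @param mask binary matrix (nonzero = trunk).
#' @param params a [cluster_params()].
#' @return integer instance matrix; `k = 0` (all zero) for an empty mask.
#' @export
cluster_trunk_mask <- function(mask, params = cluster_params()) {
  assert_mask(mask)
  s <- params$subsample_stride
  fgm <- mask != 0
  if (!any(fgm)) return(matrix(0L, nrow(mask), ncol(mask)))

  work <- fgm
  if (s > 1L) {
    keep <- matrix(FALSE, nrow(mask), ncol(mask))
    keep[seq(1L, nrow(mask), by = s), seq(1L, ncol(mask), by = s)] <- TRUE
    work <- fgm & keep
    if (!any(work)) work <- fgm
  }

  lab <- dbscan_raster(work, params$eps_px, params$min_pts)
  if (s > 1L) lab <- propagate_labels(lab, fgm)

  # area filter, then relabel 1..k by increasing centroid x
  if (params$min_area_px > 1L && any(lab != 0L)) {
    area <- tabulate(lab[lab != 0L])
    drop <- which(area < params$min_area_px)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  relabel_by_centroid_x(lab)
}

# exact DBSCAN on a logical raster; returns integer labels (0 = noise)
dbscan_raster <- function(fgm, eps, min_pts) {
  H <- nrow(fgm); W <- ncol(fgm)
  offs <- disc_offsets(eps)
  fgi <- matrix(as.integer(fgm), H, W)

  cnt <- matrix(1L, H, W)  # self counts
  for (j in seq_len(nrow(offs)))
    cnt <- cnt + shift_mat(fgi, offs[j, "dy"], offs[j, "dx"])
  core <- fgm & cnt >= min_pts

  lab <- matrix(0L, H, W)
  if (!any(core)) return(lab)

  core_idx <- which(core)
  core_id <- matrix(0L, H, W)
  core_id[core_idx] <- seq_along(core_idx)

  # edges between core pixels within eps (half the offsets suffice)
  half <- offs[offs[, "dy"] > 0 | (offs[, "dy"] == 0 & offs[, "dx"] > 0), ,
               drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (j in seq_len(nrow(half))) {
    dy <- half[j, "dy"]; dx <- half[j, "dx"]
    nb <- shift_mat(core_id, dy, dx)          # id of core at offset (dx, dy)
    sel <- core & nb > 0L
    if (any(sel)) {
      from <- c(from, core_id[sel])
      to <- c(to, nb[sel])
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(core_idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_along(core_idx)]
  lab[core_idx] <- as.integer(comp)

  # border points join their nearest core neighbour's cluster
  border <- fgm & !core
  if (any(border)) {
    corelab <- lab  # border points may only attach to core points
    ord <- order(offs[, "dx"]^2 + offs[, "dy"]^2, offs[, "dy"], offs[, "dx"])
    for (j in ord) {
      dy <- offs[j, "dy"]; dx <- offs[j, "dx"]
      nb <- shift_mat(corelab, dy, dx)
      sel <- border & lab == 0L & nb > 0L
      if (any(sel)) lab[sel] <- nb[sel]
    }
  }
  lab
}

# assign labels to unlabelled foreground by iterative 8-neighbour growth
propagate_labels <- function(lab, fgm) {
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0), ]
  repeat {
    todo <- fgm & lab == 0L
    if (!any(todo)) break
    changed <- FALSE
    for (j in seq_len(nrow(offs))) {
      nb <- shift_mat(lab, offs$dy[j], offs$dx[j])
      sel <- todo & lab == 0L & nb > 0L
      if (any(sel)) { lab[sel] <- nb[sel]; changed <- TRUE }
    }
    if (!changed) break  # disconnected leftovers stay noise
  }
  lab
}

relabel_by_centroid_x <- function(lab) {
  ids <- mask_labels(lab)
  if (!length(ids)) return(matrix(0L, nrow(lab), ncol(lab)))
  cx <- vapply(ids, function(i) mean(mask_coords(lab == i)[, "x"]), numeric(1))
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (r in seq_along(ids)) out[lab == ids[order(cx)][r]] <- r
  out
}

#' Centroids of an instance mask
#'
#' Arithmetic mean of the member pixel coordinates of each label.
#'
#' @param instances integer instance matrix.
#' @return tibble with `label`, `x`, `y` in label order; zero rows for `k = 0`.
#' @export
trunk_centroids <- function(instances) {
  assert_mask(instances)
  ids <- mask_labels(instances)
  purrr::map_dfr(ids, function(i) {
    xy <- mask_coords(instances == i)
    tibble(label = i, x = mean(xy[, "x"]), y = mean(xy[, "y"]))
  })
}

#' Ingest an externally produced trunk raster
#'
#' Adapter seam for a trained trunk detector: reads a single-channel label
#' raster, preserving values. Multi-valued rasters are instance masks;
#' `{0, 1}` rasters are semantic masks. Optionally checks the shape against
#' a paired image.
#'
#' @param path single-channel PNG or TIFF.
#' @param image optional paired image whose shape must match.
#' @return integer matrix of labels.
#' @export
ingest_detection <- function(path, image = NULL) {
  m <- read_label_raster(path)
  if (!is.null(image)) assert_same_shape(m, image, "raster and image")
  m
}
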