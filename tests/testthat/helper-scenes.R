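# Shared synthetic fixtures, generated once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

# the standard 100-scene study batch used by the batch-level properties
study_batch <- function() {
  if (is.null(.fixtures$batch100))
    .fixtures$batch100 <- generate_batch(100, seed = 20240801)
  .fixtures$batch100
}

# supervised prompts (ground-truth trunk instances, true heights) over the
# study batch, computed once and shared by the batch-level property tests
study_prompts <- function() {
  if (is.null(.fixtures$prompts100)) {
    .fixtures$prompts100 <- lapply(study_batch(), function(sc) {
      build_prompts(sc$truth$trunk_instances, prompt_config(
        mode = "supervised", height_px = sc$truth$per_tree$height_px))
    })
  }
  .fixtures$prompts100
}

# small quick batch for unit-level checks
quick_batch <- function(n = 5, seed = 99, ...) {
  key <- paste0("qb_", n, "_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_batch(n, seed = seed, ...)
  .fixtures[[key]]
}

# run trunk clustering + supervised prompts (true heights) on one scene
scene_prompts_supervised <- function(sc) {
  tr <- sc$truth
  ci <- cluster_trunk_mask(tr$trunk_semantic)
  build_prompts(ci, prompt_config(mode = "supervised",
                                  height_px = tr$per_tree$height_px))
}

# the five points of one tree in B, T, C, R, L order
tree_points <- function(prompts, id) {
  p <- prompts[prompts$tree == id, ]
  p[match(c("B", "T", "C", "R", "L"), p$point), c("x", "y")]
}

# segment every prompted tree through a backend and assemble instances
segment_scene <- function(sc, prompts, backend, corridor = FALSE) {
  ids <- sort(unique(prompts$tree))
  meta <- attr(prompts, "meta")
  masks <- stats::setNames(lapply(ids, function(i) {
    be <- backend
    if (corridor) {
      sp <- meta[meta$tree == i, ]
      be <- backend_params(be, corridor = c(sp$x_left, sp$x_right))
    }
    segment_one(sc$image, tree_points(prompts, i), be)
  }), ids)
  assemble_instances(masks, prompts)
}
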