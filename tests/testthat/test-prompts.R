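# Prompt engineering: axis fits, neighbour spans, summit estimation, the
# five-point diamond construction and its invariants.

test_that("free axis fit recovers exact and noisy lines", {
  # perfectly vertical bar
  xy <- cbind(x = rep(10, 50), y = 0:49)
  expect_equal(fit_free_axis(xy), 0)
  # exact line x = 0.1 y + 3
  y <- 0:99
  expect_equal(fit_free_axis(cbind(0.1 * y + 3, y)), atan(0.1) * 180 / pi,
               tolerance = 1e-9)
  # noisy ribbon at 8 degrees: matches the normal-equations oracle exactly
  # and the true angle within a degree
  set.seed(5)
  a <- tan(8 * pi / 180)
  y <- rep(0:199, each = 5)
  x <- a * y + rnorm(length(y), 0, 2)
  expect_equal(fit_free_axis(cbind(x, y)), oracle_slope_angle(x, y),
               tolerance = 1e-9)
  expect_lt(abs(fit_free_axis(cbind(x, y)) - 8), 1)
  # degenerate: single row
  expect_error(fit_free_axis(cbind(1:5, rep(3, 5))), "degenerate")
})

test_that("mean axis angle is the arithmetic mean", {
  expect_equal(mean_axis_angle(c(0, 0, 0)), 0)
  expect_equal(mean_axis_angle(c(5, -5)), 0)
  expect_equal(mean_axis_angle(c(2, 4, 9)), 5)
  expect_error(mean_axis_angle(numeric(0)), "no angles")
})

test_that("constrained axis anchors the bottom at the trunk's maximal row", {
  xy <- expand.grid(x = 95:105, y = 50:149)
  ax <- constrained_axis(as.matrix(xy), 0)
  expect_equal(ax$bottom, c(100, 149))
  # any alpha = 0 keeps the bottom at the centroid x
  ax2 <- constrained_axis(as.matrix(xy), 0, centroid = c(100, 99.5))
  expect_equal(ax2$bottom[1], 100)
  # tilted synthetic trunk: B within the dilated trunk mask
  sc <- generate_scene(scene_config(n_trees = 3, trunk_tilt_deg = 7, seed = 13))
  tr <- sc$truth
  for (i in 1:3) {
    xy <- which(tr$trunk_instances == i, arr.ind = TRUE)
    ax <- constrained_axis(cbind(xy[, 2] - 1, xy[, 1] - 1), 7)
    d <- sqrt((xy[, 2] - 1 - ax$bottom[1])^2 + (xy[, 1] - 1 - ax$bottom[2])^2)
    expect_lte(min(d), 2)
  }
})

test_that("horizontal neighbours follow the edge policy", {
  sp <- horizontal_neighbors(c(100, 300, 500), 600, "edge")
  expect_equal(sp$x_left, c(0, 100, 300))
  expect_equal(sp$x_right, c(300, 500, 599))
  sp1 <- horizontal_neighbors(200, 600, "edge")
  expect_equal(c(sp1$x_left, sp1$x_right), c(0, 599))
  sp2 <- horizontal_neighbors(200, 600, "half")
  expect_equal(c(sp2$x_left, sp2$x_right), c(100, 399.5))
})

test_that("supervised summit displaces B along the axis by exactly h", {
  ax <- list(anchor = c(100, 200), angle_deg = 0, bottom = c(100, 400))
  class(ax) <- "trunk_axis"
  expect_equal(summit_supervised(ax, 300), c(100, 100))
  expect_equal(summit_supervised(ax, 1e-9), ax$bottom, tolerance = 1e-6)
  # tilted: dy = h cos(a), dx = -h sin(a); |T - B| = h to 1e-9
  a <- atan(0.1) * 180 / pi
  axt <- list(anchor = c(100, 200), angle_deg = a, bottom = c(100, 400))
  class(axt) <- "trunk_axis"
  t_pt <- summit_supervised(axt, 100)
  expect_equal(t_pt[1], 100 - 100 * sin(a * pi / 180), tolerance = 1e-9)
  expect_equal(t_pt[2], 400 - 100 * cos(a * pi / 180), tolerance = 1e-9)
  expect_equal(sqrt(sum((t_pt - axt$bottom)^2)), 100, tolerance = 1e-9)
  # clamping above the image top warns
  expect_warning(t_cl <- summit_supervised(ax, 500), "clamped")
  expect_equal(t_cl[2], 0)
  expect_error(summit_supervised(ax, 0), "h must be")
})

test_that("excess-green foreground isolates vegetation", {
  pure_green <- array(0, c(8, 8, 3)); pure_green[, , 2] <- 1
  expect_true(all(estimate_foreground(pure_green)))
  gray <- array(0.5, c(8, 8, 3))
  expect_false(any(estimate_foreground(gray)))
  expect_error(estimate_foreground(matrix(0, 4, 4)), "3-channel")
  sc <- generate_scene(scene_config(seed = 29))
  fg <- estimate_foreground(sc$image)
  tree <- sc$truth$tree_instances != 0
  expect_gte(sum(fg & tree) / sum(tree), 0.9)
  expect_lte(sum(fg & !tree) / sum(!tree), 0.1)
})

test_that("unsupervised summit scans the axis run with gap tolerance", {
  ax <- list(anchor = c(100, 200), angle_deg = 0, bottom = c(100, 400))
  class(ax) <- "trunk_axis"
  F1 <- matrix(TRUE, 500, 200)
  expect_equal(summit_unsupervised(ax, F1), c(100, 0))
  F2 <- matrix(FALSE, 500, 200)
  F2[101:401, 101] <- TRUE  # rows y = 100..400 at the line's column
  expect_equal(summit_unsupervised(ax, F2, 0), c(100, 100))
  # 4-row hole at y in [200, 203]
  F3 <- F2; F3[201:204, 101] <- FALSE
  expect_equal(summit_unsupervised(ax, F3, 5), c(100, 100))
  expect_equal(summit_unsupervised(ax, F3, 2), c(100, 204))
  # no foreground anywhere on the line
  expect_error(summit_unsupervised(ax, matrix(FALSE, 500, 200)),
               "summit not found")
})

test_that("lateral points follow the 20% formulas, including degenerate spans", {
  m <- matrix(0L, 300, 240)
  m[200:290, 98:103] <- 1L
  pr <- build_prompts(m, prompt_config(mode = "supervised", height_px = 200),
                      )
  d <- tidy(pr)
  cx <- d$x[d$point == "C"]; cy <- d$y[d$point == "C"]
  xl <- d$x_left[1]; xr <- d$x_right[1]
  expect_equal(d$x[d$point == "R"], cx + 0.2 * (xr - cx), tolerance = 1e-12)
  expect_equal(d$x[d$point == "L"], cx - 0.2 * (cx - xl), tolerance = 1e-12)
  expect_equal(d$y[d$point == "R"], cy)
  expect_equal(d$y[d$point == "L"], cy)
  # direct substitution case
  expect_equal(100 + 0.2 * (200 - 100), 120)
  expect_equal(100 - 0.2 * (100 - 40), 88)
  # collapsed span: R and L collapse onto C
  sp <- horizontal_neighbors(100, 201, "half")  # centroid mid-image
  expect_equal(sp$x_left, 50)
  pr2 <- build_prompts(m, prompt_config(mode = "supervised", height_px = 150))
  d2 <- tidy(pr2)
  expect_true(all(c("B", "T", "C", "R", "L") %in% d2$point))
})

test_that("prompt sets satisfy the diamond invariants on synthetic scenes", {
  for (sc in quick_batch(4, seed = 61)) {
    pr <- scene_prompts_supervised(sc)
    d <- tidy(pr)
    for (i in unique(d$tree)) {
      p <- d[d$tree == i, ]
      expect_identical(sort(p$point), sort(c("B", "T", "C", "R", "L")))
      b <- p[p$point == "B", ]; t <- p[p$point == "T", ]; c <- p[p$point == "C", ]
      r <- p[p$point == "R", ]; l <- p[p$point == "L", ]
      expect_lt(abs(c$x - (b$x + t$x) / 2), 0.5)
      expect_lt(abs(c$y - (b$y + t$y) / 2), 0.5)
      expect_true(t$y < c$y && c$y < b$y)
      expect_equal(c(r$y, l$y), c(c$y, c$y))
      expect_true(l$x <= c$x && c$x <= r$x)
      # 0.2 keeps laterals strictly inside the neighbour span
      expect_lt(r$x, p$x_right[1])
      expect_gt(l$x, p$x_left[1])
    }
  }
})

test_that("prompts scale with the scene", {
  m <- matrix(0L, 200, 160)
  m[120:190, 78:83] <- 1L
  pr1 <- tidy(build_prompts(m, prompt_config(mode = "supervised",
                                             height_px = 120)))
  s <- 2L
  m2 <- matrix(0L, 400, 320)
  m2[(2 * 120 - 1):(2 * 190), (2 * 78 - 1):(2 * 83)] <- 1L
  pr2 <- tidy(build_prompts(m2, prompt_config(mode = "supervised",
                                              height_px = 240)))
  for (p in c("B", "T", "C")) {
    expect_equal(pr2$y[pr2$point == p] / s, pr1$y[pr1$point == p],
                 tolerance = 0.02 * 200)
    expect_equal(pr2$x[pr2$point == p] / s, pr1$x[pr1$point == p],
                 tolerance = 0.02 * 160)
  }
})

test_that("empty and failing inputs are reported, not fatal", {
  expect_warning(pr <- build_prompts(matrix(0L, 20, 20),
                                     prompt_config(mode = "supervised",
                                                   height_px = 10)),
                 "empty prompt set")
  expect_identical(nrow(pr), 0L)
  # unsupervised with no vegetation at all: summit failure recorded per tree
  m <- matrix(0L, 100, 80)
  m[60:95, 38:43] <- 1L
  pr2 <- build_prompts(m, prompt_config(mode = "unsupervised"),
                       foreground = matrix(FALSE, 100, 80))
  expect_identical(nrow(pr2), 0L)
  expect_false(attr(pr2, "meta")$summit_ok)
  expect_error(prompt_config(mode = "supervised"), "height_px")
})

test_that("prompt JSON round-trips through the rowprompt-v1 schema", {
  m <- matrix(0L, 300, 240)
  m[200:290, 98:103] <- 1L
  pr <- build_prompts(m, prompt_config(mode = "supervised", height_px = 200))
  td <- withr::local_tempdir()
  path <- file.path(td, "prompts.json")
  write_prompts(pr, path, image = "image.png")
  j <- jsonlite::read_json(path)
  expect_identical(j$schema, "rowprompt-v1")
  expect_identical(j$trees[[1]]$point_labels, as.list(rep(1L, 5)))
  back <- read_prompts(path)
  for (col in c("tree", "point", "x", "y"))
    expect_equal(back[[col]], pr[[col]], tolerance = 1e-12)
  # schema violations are caught
  j$trees[[1]]$points$T <- NULL
  jsonlite::write_json(j, path, auto_unbox = TRUE)
  expect_error(read_prompts(path), "misses point T")
})
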