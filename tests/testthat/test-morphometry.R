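toy_neurite <- function() {
  # soma + straight 3-segment neurite of 10 um segments
  data.frame(id = 1:4, type = c(1L, 3L, 3L, 3L),
             x = c(0, 10, 20, 30), y = 0, z = 0,
             radius = c(5, 1, 1, 1), parent = c(-1L, 1L, 2L, 3L))
}

test_that("SWC round-trips and validation errors are specific", {
  g <- gen_morphology(synth_morph_params(seed = 21))
  path <- tempfile(fileext = ".swc")
  write_swc(g$tree, path)
  back <- read_swc(path)
  expect_equal(as.data.frame(back), as.data.frame(g$tree),
               tolerance = 1e-7)
  unlink(path)
  toy <- toy_neurite()
  p2 <- tempfile(fileext = ".swc")
  write_swc(toy, p2)
  expect_equal(nrow(read_swc(p2)), 4)
  unlink(p2)
  # cycle
  bad <- toy; bad$parent[2] <- 4L; bad$parent[1] <- 2L
  pb <- tempfile(fileext = ".swc"); write_swc(bad, pb)
  expect_error(read_swc(pb), "root|cycle")
  # duplicate ids
  dup <- toy; dup$id[4] <- 3L
  write_swc(dup, pb)
  expect_error(read_swc(pb), "duplicate")
  # orphan parent
  orph <- toy; orph$parent[4] <- 99L
  write_swc(orph, pb)
  expect_error(read_swc(pb), "orphan")
  # multiple roots
  mr <- toy; mr$parent[3] <- -1L
  write_swc(mr, pb)
  expect_error(read_swc(pb), "multi-root")
  unlink(pb)
})

test_that("toy arbors give exact tip, bifurcation and length counts", {
  m <- compute_morphometrics(toy_neurite())
  expect_equal(m$n_tips, 1)
  expect_equal(m$n_bifurcations, 0)
  expect_equal(m$total_length, 30)
  # symmetric Y: two children on one 10 um parent segment
  y <- data.frame(id = 1:4, type = c(1L, 3L, 3L, 3L),
                  x = c(0, 10, 20, 20), y = c(0, 0, 10, -10),
                  z = 0, radius = 1, parent = c(-1L, 1L, 2L, 2L))
  m2 <- compute_morphometrics(y)
  expect_equal(m2$n_tips, 2)
  expect_equal(m2$n_bifurcations, 1)
  expect_equal(m2$total_length, 10 + 2 * sqrt(100 + 100))
  # soma surface area of a single-node soma
  expect_equal(m$soma_surface_area, 4 * pi * 25)
})

test_that("metrics equal the exhaustive traversal oracle on random trees", {
  for (s in 1:20) {
    g <- gen_morphology(synth_morph_params(branch_probability = 0.4,
                                           max_depth = 7L, seed = s))
    m <- compute_morphometrics(g$tree)
    o <- morph_traversal_oracle(g$tree)
    expect_equal(m$n_tips, o$n_tips)
    expect_equal(m$n_bifurcations, o$n_bifurcations)
    expect_equal(m$total_length, o$total_length, tolerance = 1e-9)
    # generator truth agrees too
    expect_equal(m$n_tips, g$truth$n_tips)
    expect_equal(m$total_length, g$truth$total_length, tolerance = 1e-9)
  }
})

test_that("degenerate single-trunk trees have one tip and no bifurcations", {
  g <- gen_morphology(synth_morph_params(branch_probability = 0,
                                         max_depth = 1L, n_trunks = 1L,
                                         seed = 5))
  m <- compute_morphometrics(g$tree)
  expect_equal(m$n_tips, 1)
  expect_equal(m$n_bifurcations, 0)
})

line_fixture <- function(len = 1000, spacing = 0.5) {
  xx <- seq(0, len, by = spacing)
  data.frame(id = seq_along(xx), type = 3L, x = xx, y = 0, z = 0,
             radius = 0.5, parent = c(-1L, seq_len(length(xx) - 1L)))
}

plane_fixture <- function(side = 100) {
  rows <- list(data.frame(id = 1L, type = 3L, x = 0, y = 0, z = 0,
                          radius = 0.5, parent = -1L))
  id <- 2L
  for (yy in seq(0, side, by = 1)) {
    rows[[length(rows) + 1L]] <- data.frame(id = id, type = 3L, x = 0,
                                            y = yy, z = 0, radius = 0.5,
                                            parent = 1L)
    rows[[length(rows) + 1L]] <- data.frame(id = id + 1L, type = 3L,
                                            x = side, y = yy, z = 0,
                                            radius = 0.5, parent = id)
    id <- id + 2L
  }
  do.call(rbind, rows)
}

test_that("box-counting dimension scores lines ~1 and planes ~2", {
  hd_line <- hausdorff_dimension(line_fixture(), eps_min = 1, eps_max = 50)
  expect_equal(hd_line$dimension, 1, tolerance = 0.05)
  expect_gt(hd_line$r_squared, 0.99)
  hd_plane <- hausdorff_dimension(plane_fixture(), eps_min = 1, eps_max = 5)
  expect_equal(hd_plane$dimension, 2, tolerance = 0.1)
  # monotonicity: the plane scores strictly higher than the line
  expect_gt(hd_plane$dimension, hd_line$dimension)
  # degenerate input
  pt <- data.frame(id = 1L, type = 3L, x = 0, y = 0, z = 0, radius = 1,
                   parent = -1L)
  expect_error(hausdorff_dimension(pt), "degenerate")
})

test_that("metrics are invariant under rigid rotation and translation", {
  g <- gen_morphology(synth_morph_params(seed = 33))
  tree <- as.data.frame(g$tree)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(tree[, c("x", "y", "z")]) %*% R + 50
  rot <- tree
  rot[, c("x", "y", "z")] <- xyz
  m0 <- compute_morphometrics(tree)
  m1 <- compute_morphometrics(rot)
  expect_equal(m1$n_tips, m0$n_tips)
  expect_equal(m1$n_bifurcations, m0$n_bifurcations)
  expect_equal(m1$total_length, m0$total_length, tolerance = 1e-9)
  d0 <- hausdorff_dimension(tree, eps_min = 1)$dimension
  d1 <- hausdorff_dimension(rot, eps_min = 1)$dimension
  expect_equal(d1, d0, tolerance = 0.06)
  # total length must at least reach the largest bounding-box extent
  expect_gte(m0$total_length, max(m0$width, m0$height, m0$depth))
})
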