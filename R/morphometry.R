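#' Read an SWC neuron reconstruction
#'
#' SWC is the interchange format for traced neurons: seven whitespace-
#' separated fields per line (`id type x y z radius parent`), `#` comments,
#' parent `-1` marking the root. The tree is validated: unique ids, exactly
#' one root, resolvable parents, no cycles.
#'
#' @param path SWC file path.
#' @return a data frame of class `swc_tree` with columns `id`, `type`,
#'   `x`, `y`, `z` (micrometres), `radius` (micrometres), `parent`.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop(sprintf("'%s' contains no SWC records", path))
  fields <- strsplit(lines, "\\s+")
  if (any(lengths(fields) != 7L))
    stop(sprintf("malformed SWC line(s) in '%s': 7 fields required", path))
  m <- matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE)
  if (anyNA(m)) stop(sprintf("non-numeric SWC fields in '%s'", path))
  tree <- data.frame(id = as.integer(m[, 1L]), type = as.integer(m[, 2L]),
                     x = m[, 3L], y = m[, 4L], z = m[, 5L],
                     radius = m[, 6L], parent = as.integer(m[, 7L]))
  validate_swc(tree)
}

#' @keywords internal
#' @noRd
validate_swc <- function(tree) {
  if (anyDuplicated(tree$id)) stop("duplicate node ids in SWC tree")
  if (any(tree$radius < 0)) stop("negative radius in SWC tree")
  roots <- which(tree$parent == -1L)
  if (length(roots) == 0L) stop("SWC tree has no root (parent -1)")
  if (length(roots) > 1L)
    stop("multi-root SWC trees are rejected rather than silently merged")
  pidx <- match(tree$parent, tree$id)
  orphan <- tree$parent != -1L & is.na(pidx)
  if (any(orphan))
    stop(sprintf("orphan parent reference(s) for node id(s): %s",
                 paste(tree$id[orphan], collapse = ", ")))
  # cycle check: walk to the root from every node
  n <- nrow(tree)
  for (i in seq_len(n)) {
    steps <- 0L; j <- i
    while (!is.na(j) && tree$parent[j] != -1L) {
      j <- pidx[j]
      steps <- steps + 1L
      if (steps > n) stop("cycle detected in SWC tree")
    }
  }
  class(tree) <- c("swc_tree", "data.frame")
  tree
}

#' Write an SWC reconstruction
#'
#' `write_swc` then [read_swc()] returns the identical tree up to
#' whitespace.
#'
#' @param tree an `swc_tree` (see [read_swc()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  stopifnot(inherits(tree, "data.frame"))
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                   tree$id, tree$type, tree$x, tree$y, tree$z,
                   tree$radius, tree$parent)
  writeLines(c("# SWC reconstruction", lines), path)
  invisible(path)
}

# SWC structure-type codes
SWC_SOMA <- 1L
SWC_AXON <- 2L
SWC_DENDRITE <- 3L

#' Single-neuron morphometrics from an SWC tree
#'
#' Computes the per-neuron summary used to characterize dendritic-arbor
#' hypertrophy: number of dendritic tips, number of bifurcations, total
#' dendritic length, bounding-box height/width/depth, soma surface area and
#' (via [hausdorff_dimension()]) box-counting fractal dimension. Tips are
#' non-soma nodes without children; bifurcations are nodes with two or more
#' children; total length sums Euclidean parent-child segment lengths;
#' width/height/depth are the bounding-box extents along x/y/z (axis
#' assignment is a documented convention). Soma surface area is `4*pi*r^2`
#' for a single-node soma, or the lateral frustum-area sum for multi-node
#' somas.
#'
#' @param tree an `swc_tree`.
#' @param dendrites_only restrict tips/bifurcations/length to dendrite
#'   nodes (type 3); bounding box always uses all nodes.
#' @param dimension also estimate the box-counting dimension (slower).
#' @return list of class `morphometrics`: `n_tips`, `n_bifurcations`,
#'   `total_length` (um), `width`, `height`, `depth` (um),
#'   `soma_surface_area` (um^2), `hausdorff_dimension` (NA unless
#'   requested).
#' @export
compute_morphometrics <- function(tree, dendrites_only = TRUE,
                                  dimension = FALSE) {
  tree <- validate_swc(as.data.frame(tree))
  pidx <- match(tree$parent, tree$id)
  n_children <- tabulate(pidx[!is.na(pidx)], nbins = nrow(tree))
  is_soma <- tree$type == SWC_SOMA
  keep <- if (dendrites_only) tree$type == SWC_DENDRITE else !is_soma
  if (!any(keep)) warning("no dendrite nodes; neurite metrics are zero")

  tips <- sum(keep & n_children == 0L)
  bif <- sum(keep & n_children >= 2L)
  seg_ok <- keep & !is.na(pidx)
  seg_len <- sqrt((tree$x - tree$x[pidx])^2 +
                  (tree$y - tree$y[pidx])^2 +
                  (tree$z - tree$z[pidx])^2)
  total_len <- sum(seg_len[seg_ok])

  width <- diff(range(tree$x))
  height <- diff(range(tree$y))
  depth <- diff(range(tree$z))

  soma <- tree[is_soma, , drop = FALSE]
  soma_area <- if (nrow(soma) == 1L) {
    4 * pi * soma$radius^2
  } else if (nrow(soma) > 1L) {
    sp <- match(soma$parent, tree$id)
    a <- 0
    for (i in seq_len(nrow(soma))) {
      j <- sp[i]
      if (is.na(j) || tree$type[j] != SWC_SOMA) next
      h <- sqrt((soma$x[i] - tree$x[j])^2 + (soma$y[i] - tree$y[j])^2 +
                  (soma$z[i] - tree$z[j])^2)
      r1 <- soma$radius[i]; r2 <- tree$radius[j]
      a <- a + pi * (r1 + r2) * sqrt((r1 - r2)^2 + h^2)  # frustum lateral
    }
    a
  } else 0
  hd <- if (dimension) hausdorff_dimension(tree)$dimension else NA_real_
  out <- list(n_tips = tips, n_bifurcations = bif, total_length = total_len,
              width = width, height = height, depth = depth,
              soma_surface_area = soma_area, hausdorff_dimension = hd)
  class(out) <- "morphometrics"
  out
}

#' @export
print.morphometrics <- function(x, ...) {
  cat(sprintf(
    "Morphometrics: %d tips, %d bifurcations, length %.1f um, WxHxD %.1f x %.1f x %.1f um, soma %.1f um^2%s\n",
    x$n_tips, x$n_bifurcations, x$total_length, x$width, x$height, x$depth,
    x$soma_surface_area,
    if (is.na(x$hausdorff_dimension)) ""
    else sprintf(", dimension %.2f", x$hausdorff_dimension)))
  invisible(x)
}

# Resample every parent-child segment as points at <= `spacing` um
# arc-length spacing (including both endpoints).
#' @keywords internal
#' @noRd
resample_arbor <- function(tree, spacing = 0.25) {
  pidx <- match(tree$parent, tree$id)
  pts <- list(cbind(tree$x, tree$y, tree$z))
  for (i in which(!is.na(pidx))) {
    j <- pidx[i]
    d <- sqrt((tree$x[i] - tree$x[j])^2 + (tree$y[i] - tree$y[j])^2 +
                (tree$z[i] - tree$z[j])^2)
    if (d <= spacing) next
    k <- ceiling(d / spacing)
    f <- seq_len(k - 1L) / k
    pts[[length(pts) + 1L]] <- cbind(
      tree$x[j] + f * (tree$x[i] - tree$x[j]),
      tree$y[j] + f * (tree$y[i] - tree$y[j]),
      tree$z[j] + f * (tree$z[i] - tree$z[j]))
  }
  do.call(rbind, pts)
}

#' Box-counting (Hausdorff) dimension of an arbor
#'
#' Three-dimensional measure of arbor complexity: the arbor is resampled as
#' points at fine arc-length spacing, occupied axis-aligned boxes `N(eps)`
#' are counted over a geometric ladder of box sizes, and the dimension is
#' the negative slope of the least-squares line of `log N(eps)` against
#' `log eps`. A straight line scores 1, a filled planar region 2.
#'
#' @param tree an `swc_tree` with positive total length.
#' @param eps_min,eps_max smallest and largest box size, um; `eps_max`
#'   defaults to a quarter of the largest bounding-box extent.
#' @param n_ladder number of ladder points (>= 8).
#' @param spacing resampling arc-length spacing, um.
#' @return list with `dimension`, `r_squared`, and the ladder
#'   (`eps`, `n_boxes`).
#' @export
hausdorff_dimension <- function(tree, eps_min = 1, eps_max = NULL,
                                n_ladder = 10L, spacing = 0.25) {
  tree <- as.data.frame(tree)
  ext <- max(diff(range(tree$x)), diff(range(tree$y)), diff(range(tree$z)))
  if (!is.finite(ext) || ext <= 0)
    stop("degenerate arbor extent: dimension undefined")
  if (is.null(eps_max)) eps_max <- ext / 4
  if (eps_max <= eps_min)
    stop("eps_max must exceed eps_min (arbor too small for the ladder)")
  n_ladder <- max(8L, as.integer(n_ladder))
  pts <- resample_arbor(tree, spacing)
  origin <- apply(pts, 2L, min)
  eps <- exp(seq(log(eps_min), log(eps_max), length.out = n_ladder))
  n_boxes <- vapply(eps, function(e) {
    ix <- floor((pts[, 1L] - origin[1L]) / e)
    iy <- floor((pts[, 2L] - origin[2L]) / e)
    iz <- floor((pts[, 3L] - origin[3L]) / e)
    nrow(unique(cbind(ix, iy, iz)))
  }, numeric(1L))
  lx <- log(eps); ly <- log(n_boxes)
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  r2 <- if (stats::var(ly) > 0)
    stats::cor(lx, ly)^2 else NA_real_
  list(dimension = -slope, r_squared = r2, eps = eps, n_boxes = n_boxes)
}

#' Parameters for the random-tree morphology generator
#'
#' @param branch_probability probability that a growing node bifurcates
#'   (in `[0, 1]`).
#' @param segment_length_mean,segment_length_sd segment length distribution,
#'   um (`mean > 0`).
#' @param max_depth maximum branch order.
#' @param soma_radius um.
#' @param n_trunks primary neurites leaving the soma.
#' @param seed integer seed.
#' @export
synth_morph_params <- function(branch_probability = 0.3,
                               segment_length_mean = 20,
                               segment_length_sd = 5,
                               max_depth = 6L, soma_radius = 8,
                               n_trunks = 2L, seed = 1L) {
  if (branch_probability < 0 || branch_probability > 1)
    stop("branch_probability must be in [0, 1]")
  assert_scalar_num(segment_length_mean, "segment_length_mean", positive = TRUE)
  assert_scalar_num(segment_length_sd, "segment_length_sd", nonneg = TRUE)
  assert_scalar_num(soma_radius, "soma_radius", positive = TRUE)
  structure(
    list(branch_probability = branch_probability,
         segment_length_mean = segment_length_mean,
         segment_length_sd = segment_length_sd,
         max_depth = as.integer(max_depth),
         soma_radius = soma_radius, n_trunks = as.integer(n_trunks),
         seed = as.integer(seed)),
    class = "synth_morph_params")
}

#' Generate a random branched SWC tree with known ground truth
#'
#' Grows `n_trunks` dendrites from a single soma node; at each node below
#' `max_depth` the branch bifurcates with `branch_probability`, otherwise
#' continues with one child; growth stops at `max_depth`. Directions
#' perform a persistent random walk; segment lengths are truncated normal.
#' Ground-truth tips, bifurcations, total length and bounding box are
#' tracked during construction, independently of any traversal of the
#' finished tree.
#'
#' @param params a [synth_morph_params()].
#' @return list with `tree` (an `swc_tree`) and `truth` (list: `n_tips`,
#'   `n_bifurcations`, `total_length`, `width`, `height`, `depth`).
#' @export
gen_morphology <- function(params) {
  stopifnot(inherits(params, "synth_morph_params"))
  set.seed(params$seed)
  rows <- list(data.frame(id = 1L, type = SWC_SOMA, x = 0, y = 0, z = 0,
                          radius = params$soma_radius, parent = -1L))
  next_id <- 2L
  n_tips <- 0L; n_bif <- 0L; total_len <- 0
  rand_dir <- function(prev = NULL) {
    v <- stats::rnorm(3L)
    v <- v / sqrt(sum(v^2))
    if (!is.null(prev)) {
      v <- 0.7 * prev + 0.3 * v
      v <- v / sqrt(sum(v^2))
    }
    v
  }
  # stack of growth fronts: list(parent_id, pos, dir, depth)
  fronts <- lapply(seq_len(params$n_trunks), function(i)
    list(parent = 1L, pos = c(0, 0, 0), dir = rand_dir(), depth = 1L))
  while (length(fronts)) {
    f <- fronts[[1L]]; fronts <- fronts[-1L]
    len <- max(0.5, stats::rnorm(1L, params$segment_length_mean,
                                 params$segment_length_sd))
    pos <- f$pos + len * f$dir
    id <- next_id; next_id <- next_id + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      id = id, type = SWC_DENDRITE, x = pos[1L], y = pos[2L], z = pos[3L],
      radius = max(0.3, params$soma_radius / 8 / f$depth), parent = f$parent)
    total_len <- total_len + len
    if (f$depth >= params$max_depth) {
      n_tips <- n_tips + 1L
    } else if (stats::runif(1L) < params$branch_probability) {
      n_bif <- n_bif + 1L
      fronts <- c(fronts, list(
        list(parent = id, pos = pos, dir = rand_dir(f$dir), depth = f$depth + 1L),
        list(parent = id, pos = pos, dir = rand_dir(f$dir), depth = f$depth + 1L)))
    } else {
      fronts <- c(fronts, list(
        list(parent = id, pos = pos, dir = rand_dir(f$dir), depth = f$depth + 1L)))
    }
  }
  tree <- validate_swc(do.call(rbind, rows))
  truth <- list(n_tips = n_tips, n_bifurcations = n_bif,
                total_length = total_len,
                width = diff(range(tree$x)), height = diff(range(tree$y)),
                depth = diff(range(tree$z)))
  list(tree = tree, truth = truth)
}
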