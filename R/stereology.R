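#' Optical fractionator sampling design
#'
#' The design used for the IO counts: 30 um serial sections with a section
#' evaluation interval of 4, a 200 um x 200 um counting frame on a
#' 50 um x 50 um sampling grid, ~20 um counting depth and 1 um guard zones.
#' Note that a frame larger than its grid step implies an area sampling
#' fraction above 1 (overlapping frames); that is how the design is printed
#' and it is implemented as such, with a warning, since asf <= 1 is the
#' typical arrangement.
#'
#' @param section_interval every `section_interval`-th section is sampled
#'   (ssf = 1/interval).
#' @param frame_x,frame_y counting-frame side lengths, um.
#' @param grid_x,grid_y sampling-grid step, um (asf = frame area / grid
#'   area).
#' @param counting_depth optical disector depth, um.
#' @param section_thickness um (tsf = depth/thickness).
#' @param guard_zone um; `counting_depth + 2*guard_zone` must not exceed
#'   `section_thickness`.
#' @return an object of class `fractionator_design` with derived fields
#'   `ssf`, `asf`, `tsf`.
#' @export
fractionator_design <- function(section_interval = 4L,
                                frame_x = 200, frame_y = 200,
                                grid_x = 50, grid_y = 50,
                                counting_depth = 20,
                                section_thickness = 30,
                                guard_zone = 1) {
  if (section_interval < 1L) stop("section_interval must be >= 1")
  assert_scalar_num(frame_x, "frame_x", positive = TRUE)
  assert_scalar_num(frame_y, "frame_y", positive = TRUE)
  assert_scalar_num(grid_x, "grid_x", positive = TRUE)
  assert_scalar_num(grid_y, "grid_y", positive = TRUE)
  assert_scalar_num(counting_depth, "counting_depth", positive = TRUE)
  assert_scalar_num(section_thickness, "section_thickness", positive = TRUE)
  assert_scalar_num(guard_zone, "guard_zone", nonneg = TRUE)
  if (counting_depth + 2 * guard_zone > section_thickness)
    stop("counting depth plus both guard zones exceeds the section thickness")
  asf <- (frame_x * frame_y) / (grid_x * grid_y)
  if (asf > 1)
    warning("frame larger than grid step: asf > 1 (overlapping frames)")
  structure(
    list(section_interval = as.integer(section_interval),
         frame_x = frame_x, frame_y = frame_y,
         grid_x = grid_x, grid_y = grid_y,
         counting_depth = counting_depth,
         section_thickness = section_thickness,
         guard_zone = guard_zone,
         ssf = 1 / section_interval, asf = asf,
         tsf = counting_depth / section_thickness),
    class = "fractionator_design")
}

#' Optical fractionator population estimate
#'
#' `N_hat = sum(Q-) * (1/ssf) * (1/asf) * (1/tsf)`: the raw disector counts
#' scaled back by the inverse section, area and thickness sampling
#' fractions.
#'
#' @param counts either a numeric vector of per-section counts for one
#'   marker, or a `section_counts` data frame (see
#'   [gen_tissue_and_sample()]) whose `Qminus_*` columns are each
#'   estimated.
#' @param design a [fractionator_design()].
#' @return estimated total number(s); named when `counts` has multiple
#'   marker columns.
#' @export
fractionator_estimate <- function(counts, design) {
  stopifnot(inherits(design, "fractionator_design"))
  if (design$ssf <= 0 || design$asf <= 0 || design$tsf <= 0)
    stop("sampling fractions must be positive")
  scale <- (1 / design$ssf) * (1 / design$asf) * (1 / design$tsf)
  if (is.data.frame(counts)) {
    cols <- grep("^Qminus_", names(counts), value = TRUE)
    if (!length(cols)) stop("no Qminus_* columns in counts")
    out <- vapply(cols, function(cl) sum(counts[[cl]]) * scale, numeric(1L))
    names(out) <- sub("^Qminus_", "", cols)
    return(out)
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  sum(counts) * scale
}

#' Cavalieri volume estimate
#'
#' `V_hat = sum(section areas) * interval * thickness`, from the areas of
#' the systematically sampled sections.
#'
#' @param section_areas per-sampled-section region areas, um^2 (>= 0).
#' @param interval section evaluation interval.
#' @param thickness section thickness, um.
#' @return estimated volume in um^3.
#' @export
cavalieri_volume <- function(section_areas, interval, thickness) {
  if (any(section_areas < 0)) stop("section areas must be non-negative")
  assert_scalar_num(thickness, "thickness", positive = TRUE)
  if (interval < 1) stop("interval must be >= 1")
  sum(section_areas) * interval * thickness
}

#' Gundersen-Jensen coefficient of error
#'
#' Precision estimate for systematic-uniform-random-sampling counts. With
#' per-section counts `Q_i` in anatomical order, `A = sum(Q_i^2)`,
#' `B = sum(Q_i Q_{i+1})`, `C = sum(Q_i Q_{i+2})` and `noise = sum(Q_i)`,
#' the smoothness-class m = 1 variant is
#' `VarSURS = (3 (A - noise) - 4 B + C) / 240`, and
#' `CE = sqrt(noise + VarSURS) / sum(Q_i)`. The m = 0 variant divides by 12
#' instead of 240.
#'
#' @param per_section_counts ordered per-section counts (>= 3 sections).
#' @param m smoothness class, 1 (default, smooth structures) or 0.
#' @return the coefficient of error (dimensionless).
#' @export
gundersen_ce <- function(per_section_counts, m = 1L) {
  q <- as.numeric(per_section_counts)
  if (length(q) < 3L)
    stop("Gundersen CE requires at least 3 sections in anatomical order")
  if (any(q < 0)) stop("counts must be non-negative")
  total <- sum(q)
  if (total == 0) stop("CE undefined: total count is zero")
  A <- sum(q^2)
  B <- sum(q[-length(q)] * q[-1L])
  C <- sum(q[seq_len(length(q) - 2L)] * q[-(1:2)])
  denom <- if (m == 1L) 240 else 12
  var_surs <- (3 * (A - total) - 4 * B + C) / denom
  sqrt(total + var_surs) / total
}

#' Nucleator area estimate
#'
#' Profile area from `n` systematic isotropic rays from an interior
#' reference point to the profile boundary: `area = pi * mean(l_i^2)`.
#' Exact for circles centred on the reference point and unbiased over
#' isotropic ray orientations for any star-shaped profile. The source
#' measurements used the 4-ray variant.
#'
#' @param ray_lengths ray lengths, um (>= 0).
#' @return area in um^2.
#' @export
nucleator_area <- function(ray_lengths) {
  l <- as.numeric(ray_lengths)
  if (!length(l)) stop("at least one ray length required")
  if (any(l < 0)) stop("ray lengths must be non-negative")
  pi * mean(l^2)
}

#' Disector counting rule
#'
#' Counts cells by the top-of-cell rule: a cell is counted iff its top
#' (reference point) lies strictly inside the counting frame (touching the
#' left or bottom exclusion edge does not count; the right and top edges
#' are inclusion edges) and within the counting depth below the guard zone
#' (`guard < z <= guard + depth`, with `z` the depth of the cell top below
#' the section surface).
#'
#' @param cells data frame with columns `x`, `y` (um, section plane) and
#'   `z` (um, depth of the cell top below the section top surface).
#' @param frame list or vector with `x0`, `y0` (lower-left corner) and
#'   `w`, `h` (side lengths), um.
#' @param guard guard-zone depth, um.
#' @param depth counting depth, um.
#' @return the disector count Q- for this frame.
#' @export
apply_counting_rules <- function(cells, frame, guard, depth) {
  frame <- as.list(frame)
  with(cells,
       sum(x > frame$x0 & x <= frame$x0 + frame$w &
           y > frame$y0 & y <= frame$y0 + frame$h &
           z > guard & z <= guard + depth))
}

#' Parameters for the synthetic-tissue generator
#'
#' @param true_N named integer vector of true cell numbers per marker
#'   class, e.g. `c(NeuN = 1000, NeuN_Calb = 800)`; classes are nested
#'   (later classes are subsets of the first).
#' @param region_extent box extents `c(x, y, z)` in um, or semi-axes when
#'   `region_shape = "ellipsoid"`.
#' @param region_shape `"box"` or `"ellipsoid"`.
#' @param soma_area_mean,soma_area_sd soma profile area distribution, um^2.
#' @param section_thickness um.
#' @param seed integer seed.
#' @export
synth_tissue_params <- function(true_N = c(NeuN = 1000, NeuN_Calb = 800),
                                region_extent = c(600, 600, 1200),
                                region_shape = c("box", "ellipsoid"),
                                soma_area_mean = 300, soma_area_sd = 60,
                                section_thickness = 30, seed = 1L) {
  region_shape <- match.arg(region_shape)
  if (any(true_N < 0)) stop("true_N must be non-negative")
  if (is.null(names(true_N)) || any(!nzchar(names(true_N))))
    stop("true_N must be a named vector of marker classes")
  if (length(true_N) > 1L && any(diff(as.numeric(true_N)) > 0))
    stop("marker classes must be nested: counts non-increasing")
  assert_scalar_num(section_thickness, "section_thickness", positive = TRUE)
  if (length(region_extent) != 3L || any(region_extent <= 0))
    stop("region_extent must be three positive extents (um)")
  structure(
    list(true_N = true_N, region_extent = region_extent,
         region_shape = region_shape, soma_area_mean = soma_area_mean,
         soma_area_sd = soma_area_sd,
         section_thickness = section_thickness, seed = as.integer(seed)),
    class = "synth_tissue_params")
}

#' Place cells, section the region, and sample with a fractionator design
#'
#' Cells (cell tops) are placed uniformly in the region; the region is cut
#' into serial sections of the design's thickness along z; every
#' `section_interval`-th section (random start) is sampled; within each
#' sampled section, counting frames on the sampling grid (random grid
#' origin) are applied with the top-of-cell disector rule of
#' [apply_counting_rules()]. Section areas for the Cavalieri estimator are
#' the analytic region cross-section areas at the sampled planes.
#'
#' @param params a [synth_tissue_params()].
#' @param design a [fractionator_design()]; its `section_thickness` must
#'   match `params$section_thickness`.
#' @return list with `counts` (a `section_counts` data frame: `section`,
#'   one `Qminus_<marker>` column per class, `region_area`), `truth`
#'   (list: `N` per marker, `volume` in um^3).
#' @export
gen_tissue_and_sample <- function(params, design = fractionator_design()) {
  stopifnot(inherits(params, "synth_tissue_params"),
            inherits(design, "fractionator_design"))
  if (abs(design$section_thickness - params$section_thickness) > 1e-9)
    stop("design and tissue section thickness disagree")
  set.seed(params$seed)
  ext <- params$region_extent
  n_total <- as.integer(params$true_N[1L])
  if (params$region_shape == "box") {
    pos <- cbind(stats::runif(n_total, 0, ext[1L]),
                 stats::runif(n_total, 0, ext[2L]),
                 stats::runif(n_total, 0, ext[3L]))
    volume <- prod(ext)
  } else {
    # rejection sampling inside the ellipsoid with semi-axes ext/..
    semi <- ext / 2
    pos <- matrix(numeric(0), ncol = 3L)
    while (nrow(pos) < n_total) {
      cand <- cbind(stats::runif(2L * n_total, -semi[1L], semi[1L]),
                    stats::runif(2L * n_total, -semi[2L], semi[2L]),
                    stats::runif(2L * n_total, -semi[3L], semi[3L]))
      inside <- rowSums((cand / rep(semi, each = nrow(cand)))^2) <= 1
      pos <- rbind(pos, cand[inside, , drop = FALSE])
    }
    pos <- pos[seq_len(n_total), , drop = FALSE]
    pos[, 3L] <- pos[, 3L] + semi[3L]  # z in [0, ext_z]
    volume <- 4 / 3 * pi * prod(semi)
  }
  # nested marker membership: first true_N[k] placed cells carry marker k
  markers <- names(params$true_N)

  h <- design$section_thickness
  n_sections <- max(1L, floor(ext[3L] / h))
  start <- sample.int(design$section_interval, 1L)
  sampled <- seq.int(start, n_sections, by = design$section_interval)

  counts <- matrix(0L, nrow = length(sampled), ncol = length(markers),
                   dimnames = list(NULL, paste0("Qminus_", markers)))
  areas <- numeric(length(sampled))
  for (si in seq_along(sampled)) {
    s <- sampled[si]
    z_top <- (s - 1L) * h
    in_sec <- pos[, 3L] >= z_top & pos[, 3L] < z_top + h
    zg <- pos[in_sec, 3L] - z_top
    ok_z <- zg > design$guard_zone &
      zg <= design$guard_zone + design$counting_depth
    xs <- pos[in_sec, 1L][ok_z]
    ys <- pos[in_sec, 2L][ok_z]
    idx <- which(in_sec)[ok_z]
    # frames on the sampling grid with a random origin; count each cell
    # once per frame that contains it (frames may overlap when asf > 1)
    ox <- stats::runif(1L, 0, design$grid_x)
    oy <- stats::runif(1L, 0, design$grid_y)
    n_fx <- frames_covering(xs, ox, design$grid_x, design$frame_x)
    n_fy <- frames_covering(ys, oy, design$grid_y, design$frame_y)
    mult <- n_fx * n_fy
    for (k in seq_along(markers)) {
      is_k <- idx <= params$true_N[k]
      counts[si, k] <- sum(mult[is_k])
    }
    areas[si] <- if (params$region_shape == "box") ext[1L] * ext[2L] else {
      semi <- ext / 2
      zc <- z_top - semi[3L]
      if (abs(zc) >= semi[3L]) 0 else
        pi * semi[1L] * semi[2L] * (1 - (zc / semi[3L])^2)
    }
  }
  out <- data.frame(section = sampled, counts, region_area = areas)
  class(out) <- c("section_counts", "data.frame")
  list(counts = out,
       truth = list(N = params$true_N, volume = volume))
}

# number of frame origins (on an infinite grid with step `step` and offset
# `origin`) whose frame of width `w` contains coordinate x under the
# exclusion-edge rule origin < x <= origin + w
#' @keywords internal
#' @noRd
frames_covering <- function(x, origin, step, w) {
  if (!length(x)) return(integer(0))
  # frame i has left edge L = origin + i*step; x is counted iff
  # L < x <= L + w, i.e. i in [ (x-w-origin)/step, (x-origin)/step ).
  # number of integers in [a, b) is ceiling(b) - ceiling(a); when x sits
  # exactly on a left (exclusion) edge, b is an integer and that frame is
  # correctly excluded.
  a <- (x - w - origin) / step
  b <- (x - origin) / step
  pmax(0, ceiling(b) - ceiling(a))
}

#' Generate nucleator ray measurements on random elliptical profiles
#'
#' For Monte-Carlo validation of [nucleator_area()]: each profile is an
#' ellipse with random semi-axes; the reference point is placed at a random
#' interior offset; four systematic rays at a uniformly random phase
#' (theta0 + k * 90 degrees) are cast to the boundary.
#'
#' @param n number of profiles.
#' @param semi_axis_range range of semi-axis lengths, um.
#' @param offset_frac maximal reference-point offset as a fraction of each
#'   semi-axis (0 = centred).
#' @param seed integer seed.
#' @return data frame with columns `true_area` (um^2) and `l1`..`l4` (um).
#' @export
gen_nucleator_rays <- function(n, semi_axis_range = c(4, 12),
                               offset_frac = 0.5, seed = 1L) {
  set.seed(seed)
  a <- stats::runif(n, semi_axis_range[1L], semi_axis_range[2L])
  b <- stats::runif(n, semi_axis_range[1L], semi_axis_range[2L])
  # random interior reference point (uniform in the scaled disc of radius
  # offset_frac)
  r <- offset_frac * sqrt(stats::runif(n))
  phi <- stats::runif(n, 0, 2 * pi)
  px <- a * r * cos(phi)
  py <- b * r * sin(phi)
  theta0 <- stats::runif(n, 0, pi / 2)
  rays <- matrix(0, n, 4L)
  for (k in 0:3) {
    th <- theta0 + k * pi / 2
    ux <- cos(th); uy <- sin(th)
    A <- ux^2 / a^2 + uy^2 / b^2
    B <- 2 * (px * ux / a^2 + py * uy / b^2)
    C <- px^2 / a^2 + py^2 / b^2 - 1
    rays[, k + 1L] <- (-B + sqrt(B^2 - 4 * A * C)) / (2 * A)
  }
  out <- data.frame(true_area = pi * a * b, rays)
  names(out)[2:5] <- paste0("l", 1:4)
  out
}
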