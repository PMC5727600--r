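#' Region-of-interest solids for phantoms
#'
#' A phantom ROI is either an axis-aligned box or an ellipsoid, with a known
#' analytic volume (the ground truth for volume estimation). All lengths in
#' um.
#'
#' @param lengths Box edge lengths `c(lx, ly, lz)`, um.
#' @param origin Box corner (minimum coordinates), um.
#' @return A list of class `phantom_roi`.
#' @export
roi_box <- function(lengths, origin = c(0, 0, 0)) {
  stopifnot(length(lengths) == 3L, all(lengths > 0))
  structure(list(type = "box", origin = origin, lengths = lengths,
                 volume_mm3 = prod(lengths) * 1e-9),
            class = "phantom_roi")
}

#' @rdname roi_box
#' @param center Ellipsoid centre, um.
#' @param semiaxes Ellipsoid semi-axes `c(a, b, c)`, um.
#' @export
roi_ellipsoid <- function(center, semiaxes) {
  stopifnot(length(center) == 3L, length(semiaxes) == 3L, all(semiaxes > 0))
  structure(list(type = "ellipsoid", center = center, semiaxes = semiaxes,
                 volume_mm3 = 4 / 3 * pi * prod(semiaxes) * 1e-9),
            class = "phantom_roi")
}

roi_bbox3 <- function(roi) {
  if (roi$type == "box") {
    rbind(roi$origin, roi$origin + roi$lengths)
  } else {
    rbind(roi$center - roi$semiaxes, roi$center + roi$semiaxes)
  }
}

roi_contains <- function(roi, pts) {
  if (roi$type == "box") {
    lo <- roi$origin; hi <- roi$origin + roi$lengths
    pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
      pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
      pts[, 3] >= lo[3] & pts[, 3] <= hi[3]
  } else {
    u <- sweep(sweep(pts, 2, roi$center), 2, roi$semiaxes, "/")
    rowSums(u^2) <= 1
  }
}

# uniform points in the roi (rejection from the bounding box for ellipsoids)
roi_runif <- function(roi, m) {
  bb <- roi_bbox3(roi)
  draw <- function(k) {
    cbind(runif(k, bb[1, 1], bb[2, 1]),
          runif(k, bb[1, 2], bb[2, 2]),
          runif(k, bb[1, 3], bb[2, 3]))
  }
  pts <- draw(m)
  keep <- roi_contains(roi, pts)
  pts <- pts[keep, , drop = FALSE]
  while (nrow(pts) < m) {
    extra <- draw(m)
    extra <- extra[roi_contains(roi, extra), , drop = FALSE]
    pts <- rbind(pts, extra)
  }
  pts[seq_len(m), , drop = FALSE]
}

# drop proposed points closer than min_sep to an accepted point or to an
# earlier proposal; grid hashing keeps the pair search near-linear
min_sep_filter <- function(accepted, proposed, min_sep) {
  if (min_sep <= 0 || nrow(proposed) == 0L) return(rep(TRUE, nrow(proposed)))
  all_pts <- rbind(accepted, proposed)
  n_acc <- nrow(accepted)
  cell <- pmax(min_sep, 1e-9)
  key <- function(p) floor(p / cell)
  k <- key(all_pts)
  df <- data.frame(i = seq_len(nrow(all_pts)), kx = k[, 1], ky = k[, 2], kz = k[, 3])
  offs <- expand.grid(ox = -1:1, oy = -1:1, oz = -1:1)
  keep <- rep(TRUE, nrow(proposed))
  # neighbours of each proposed point via 27-cell join
  prop_idx <- n_acc + seq_len(nrow(proposed))
  lookup <- split(df$i, paste(df$kx, df$ky, df$kz))
  for (j in seq_along(prop_idx)) {
    i <- prop_idx[j]
    kx <- df$kx[i]; ky <- df$ky[i]; kz <- df$kz[i]
    neigh <- unlist(lookup[paste(rep(kx + offs$ox), rep(ky + offs$oy), rep(kz + offs$oz))],
                    use.names = FALSE)
    neigh <- neigh[!is.na(neigh) & neigh != i]
    if (!length(neigh)) next
    # only accepted points and surviving earlier proposals block j
    is_acc <- neigh <= n_acc
    earlier_ok <- logical(length(neigh))
    sel <- !is_acc & neigh < i
    earlier_ok[sel] <- keep[neigh[sel] - n_acc]
    neigh <- neigh[is_acc | earlier_ok]
    if (!length(neigh)) next
    d2 <- (all_pts[neigh, 1] - all_pts[i, 1])^2 +
      (all_pts[neigh, 2] - all_pts[i, 2])^2 +
      (all_pts[neigh, 3] - all_pts[i, 3])^2
    if (any(d2 < min_sep^2)) keep[j] <- FALSE
  }
  keep
}

#' Generate a synthetic 3D particle phantom with known truth
#'
#' Places exactly `n` spherical particles uniformly at random inside the ROI
#' (rejection sampling enforcing a minimum centre-to-centre separation) with
#' radii drawn uniformly from `radius_range`. The phantom carries its true
#' particle number and true ROI volume, the ground truth against which the
#' fractionator and Cavalieri estimators are validated.
#'
#' Defaults emulate a nigral neuron population: soma-scale radii of 5-10 um
#' and a small 2 um separation so rendered profiles do not merge in raster
#' mode.
#'
#' @param n Number of particles (>= 0).
#' @param roi A [roi_box()] or [roi_ellipsoid()]; default a 3 x 2 x 1.2 mm
#'   box.
#' @param radius_range Particle radius range `c(min, max)`, um.
#' @param min_separation Minimum centre-to-centre distance, um.
#' @param seed Optional integer seed; the phantom is deterministic per seed.
#' @param max_iter Maximum rejection rounds before a packing error.
#' @return Object of class `phantom`: list with `particles` (tibble
#'   `particle_id`, `x`, `y`, `z`, `r`), `roi`, `true_n`, `seed`.
#' @examples
#' ph <- generate_phantom(100, seed = 1)
#' ph$true_n
#' @export
generate_phantom <- function(n, roi = roi_box(c(3000, 2000, 1200)),
                             radius_range = c(5, 10), min_separation = 2,
                             seed = NULL, max_iter = 100L) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != as.integer(n)) {
    abort("`n` must be a non-negative integer.")
  }
  stopifnot(inherits(roi, "phantom_roi"))
  pts <- with_seed(seed, {
    acc <- matrix(numeric(0), 0, 3)
    iter <- 0L
    while (nrow(acc) < n) {
      iter <- iter + 1L
      if (iter > max_iter) {
        abort(sprintf("packing error: placed %d of %d particles after %d rounds.",
                      nrow(acc), n, max_iter))
      }
      m <- max(16L, ceiling((n - nrow(acc)) * 1.3))
      prop <- roi_runif(roi, m)
      prop <- prop[min_sep_filter(acc, prop, min_separation), , drop = FALSE]
      if (nrow(acc) + nrow(prop) > n) prop <- prop[seq_len(n - nrow(acc)), , drop = FALSE]
      acc <- rbind(acc, prop)
    }
    list(xyz = acc, r = runif(n, radius_range[1], radius_range[2]))
  })
  particles <- tibble::tibble(
    particle_id = seq_len(n),
    x = pts$xyz[, 1], y = pts$xyz[, 2], z = pts$xyz[, 3],
    r = pts$r
  )
  structure(list(particles = particles, roi = roi, true_n = n,
                 seed = if (!is.null(seed)) as.integer(seed) else NULL),
            class = "phantom")
}

#' Build a phantom from an explicit particle table
#'
#' Low-level constructor for deterministic phantoms (e.g. hand-placed
#' particles in validation work). All centres must lie inside the ROI.
#'
#' @param particles Data frame with columns `x`, `y`, `z`, `r` (um);
#'   `particle_id` is added when absent.
#' @param roi A [roi_box()] or [roi_ellipsoid()].
#' @return An object of class `phantom`.
#' @export
as_phantom <- function(particles, roi) {
  stopifnot(inherits(roi, "phantom_roi"))
  for (nm in c("x", "y", "z", "r")) {
    if (!nm %in% names(particles)) abort(sprintf("particles need column `%s`.", nm))
  }
  particles <- tibble::as_tibble(particles)
  if (!"particle_id" %in% names(particles)) {
    particles$particle_id <- seq_len(nrow(particles))
  }
  if (nrow(particles) &&
      !all(roi_contains(roi, cbind(particles$x, particles$y, particles$z)))) {
    abort("all particle centres must lie inside the ROI.")
  }
  structure(list(particles = particles[, c("particle_id", "x", "y", "z", "r")],
                 roi = roi, true_n = nrow(particles), seed = NULL),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d particles in a %s ROI of %.4g mm^3\n",
              x$true_n, x$roi$type, x$roi$volume_mm3))
  invisible(x)
}

# cutting-axis helpers: axis is the sectioning direction, (u, v) the in-plane
# coordinates in a fixed right-handed order
axis_cols <- function(axis) {
  switch(axis,
         x = c(a = "x", u = "y", v = "z"),
         y = c(a = "y", u = "z", v = "x"),
         z = c(a = "z", u = "x", v = "y"),
         abort("`axis` must be one of 'x', 'y', 'z'."))
}

#' Virtually section a phantom into ordered profile sections
#'
#' Cuts the phantom into parallel slabs of thickness `t` perpendicular to
#' `axis`. Section `i` occupies the half-open slab `[i*t, (i+1)*t)` along the
#' cutting coordinate (measured from a start placed one empty slab before the
#' first particle, so every particle's full profile set is contained in the
#' section range). A sphere appears in every slab its `[center - r,`
#' `center + r]` extent intersects; the profile radius is the sphere's
#' cross-section at the slab midplane (clamped to a small epsilon when the
#' midplane falls just outside the sphere). The slab containing `center + r`
#' is the particle's unique *top* section: tops sum to the true particle
#' number, the conservation law behind disector counting.
#'
#' @param phantom A [generate_phantom()] phantom.
#' @param thickness Slab thickness t, um (> 0).
#' @param axis Cutting axis: `"x"` (default), `"y"` or `"z"`.
#' @return Tibble of class `section_profiles` with columns `particle_id`,
#'   `section_index`, `x`, `y` (in-plane coordinates, um), `r`, `is_top`.
#'   Attributes: `thickness`, `axis`, `a_start` (cutting coordinate of
#'   section 0), `n_sections`, `roi`, `true_n`.
#' @examples
#' ph <- generate_phantom(50, seed = 2)
#' secs <- virtual_sectioning(ph, 5)
#' sum(secs$is_top) == ph$true_n
#' @export
virtual_sectioning <- function(phantom, thickness, axis = "x") {
  stopifnot(inherits(phantom, "phantom"))
  if (!is.numeric(thickness) || length(thickness) != 1L || thickness <= 0) {
    abort("`thickness` must be > 0.")
  }
  cols <- axis_cols(axis)
  p <- phantom$particles
  a <- p[[cols[["a"]]]]
  bb <- roi_bbox3(phantom$roi)
  ai <- match(cols[["a"]], c("x", "y", "z"))
  # start one empty slab before anything a profile can reach
  lo <- min(bb[1, ai], if (nrow(p)) min(a - p$r) else bb[1, ai])
  hi <- max(bb[2, ai], if (nrow(p)) max(a + p$r) else bb[2, ai])
  a_start <- (floor(lo / thickness) - 1L) * thickness
  n_sections <- as.integer(ceiling((hi - a_start) / thickness) + 1L)
  if (nrow(p) == 0L) {
    out <- tibble::tibble(particle_id = integer(0), section_index = integer(0),
                          x = numeric(0), y = numeric(0), r = numeric(0),
                          is_top = logical(0))
  } else {
    i_lo <- floor((a - p$r - a_start) / thickness)
    i_hi <- floor((a + p$r - a_start) / thickness) # the top slab
    counts <- as.integer(i_hi - i_lo + 1L)
    idx <- rep.int(seq_len(nrow(p)), counts)
    sec <- unlist(mapply(seq.int, i_lo, i_hi, SIMPLIFY = FALSE), use.names = FALSE)
    mid <- a_start + (sec + 0.5) * thickness
    da <- mid - a[idx]
    r_prof <- sqrt(pmax(p$r[idx]^2 - da^2, 1e-6^2))
    out <- tibble::tibble(
      particle_id = p$particle_id[idx],
      section_index = as.integer(sec),
      x = p[[cols[["u"]]]][idx],
      y = p[[cols[["v"]]]][idx],
      r = r_prof,
      is_top = sec == i_hi[idx]
    )
  }
  out <- out[order(out$section_index, out$particle_id), ]
  class(out) <- c("section_profiles", class(out))
  attr(out, "thickness") <- thickness
  attr(out, "axis") <- axis
  attr(out, "a_start") <- a_start
  attr(out, "n_sections") <- n_sections
  attr(out, "roi") <- phantom$roi
  attr(out, "true_n") <- phantom$true_n
  out
}

# in-plane bounding box and cross-section membership of the roi for a given
# cutting axis
roi_plane_bbox <- function(roi, axis) {
  cols <- axis_cols(axis)
  bb <- roi_bbox3(roi)
  ui <- match(cols[["u"]], c("x", "y", "z"))
  vi <- match(cols[["v"]], c("x", "y", "z"))
  c(bb[1, ui], bb[1, vi], bb[2, ui], bb[2, vi])
}

roi_cross_contains <- function(roi, axis, u, v, a_mid) {
  cols <- axis_cols(axis)
  ord <- match(c(cols[["a"]], cols[["u"]], cols[["v"]]), c("x", "y", "z"))
  pts <- matrix(0, length(u), 3)
  pts[, ord[1]] <- a_mid
  pts[, ord[2]] <- u
  pts[, ord[3]] <- v
  roi_contains(roi, pts)
}

#' Simulate a full disector/fractionator study on a phantom
#'
#' Runs the complete in-silico sampling chain on a virtually sectioned
#' phantom: a systematic uniform random sample of sections
#' ([surs_section_indices()]), disector pairs formed from each sampled
#' section and its cutting-order neighbour, a fresh systematic frame grid
#' per pair ([surs_grid()]), bidirectional disector counting with
#' particle-id matching ([disector_count()]), and Cavalieri point counting
#' (one test point per grid position, counted when it falls inside the ROI
#' cross-section of the reference section). The result feeds straight into
#' [fractionator_estimate()].
#'
#' @param phantom A [generate_phantom()] phantom.
#' @param design A [sampling_design()]; its `section_thickness` is the
#'   virtual slab thickness.
#' @param seed Optional integer seed driving the section start and all grid
#'   offsets.
#' @param axis Cutting axis passed to [virtual_sectioning()].
#' @param sections Optional precomputed [virtual_sectioning()] result (reuse
#'   across replicate designs of the same phantom).
#' @return A `count_table` tibble (one row per disector pair in cutting
#'   order: `pair_index`, `section_index`, `q_forward`, `q_reverse`, `q`,
#'   `p_points`) with attributes `design`, `seed` and `truth`
#'   (`list(true_n, true_v_mm3)`).
#' @examples
#' ph <- generate_phantom(500, roi_box(c(600, 400, 300)), seed = 3)
#' d <- sampling_design(10, 10000, 150, 150, 5)
#' ct <- simulate_study(ph, d, seed = 4)
#' sum(ct$q)
#' @export
simulate_study <- function(phantom, design, seed = NULL, axis = "x",
                           sections = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(design, "sampling_design"))
  if (is.null(sections)) {
    sections <- virtual_sectioning(phantom, design$section_thickness, axis)
  } else {
    stopifnot(inherits(sections, "section_profiles"))
    if (!isTRUE(all.equal(attr(sections, "thickness"), design$section_thickness))) {
      abort("`sections` were cut at a different thickness than the design specifies.")
    }
    axis <- attr(sections, "axis")
  }
  n_sections <- attr(sections, "n_sections")
  a_start <- attr(sections, "a_start")
  t <- design$section_thickness
  r_max <- if (nrow(sections)) max(sections$r) else 0
  bbox <- roi_plane_bbox(phantom$roi, axis)
  fd <- frame_dims(design)

  with_seed(seed, {
    sampled <- surs_section_indices(n_sections, design$ssf_period, seed = NULL)
    sampled <- sampled[sampled + 1L < n_sections] # pair partner must exist
    if (length(sampled) == 0L) {
      warn("design yields no disector pairs on this phantom.")
      return(new_count_table(
        tibble::tibble(pair_index = integer(0), section_index = integer(0),
                       q_forward = integer(0), q_reverse = integer(0),
                       q = integer(0), p_points = integer(0)),
        design = design, seed = seed,
        truth = list(true_n = phantom$true_n,
                     true_v_mm3 = phantom$roi$volume_mm3)
      ))
    }
    by_sec <- split(seq_len(nrow(sections)), sections$section_index)
    rows <- vector("list", length(sampled))
    for (k in seq_along(sampled)) {
      s <- sampled[k]
      ref <- sections[by_sec[[as.character(s)]] %||% integer(0), , drop = FALSE]
      lkp <- sections[by_sec[[as.character(s + 1L)]] %||% integer(0), , drop = FALSE]
      grid <- surs_grid(bbox, design, seed = NULL, expand = r_max + max(fd))
      counts <- disector_count(section_pair(ref, lkp), grid)
      # Cavalieri test point at each frame origin, on the reference section
      inside <- roi_cross_contains(phantom$roi, axis,
                                   grid$frames$x0, grid$frames$y0,
                                   a_mid = a_start + (s + 0.5) * t)
      rows[[k]] <- tibble::tibble(
        pair_index = k,
        section_index = s,
        q_forward = sum(counts$q_forward),
        q_reverse = sum(counts$q_reverse),
        p_points = sum(inside)
      )
    }
    out <- dplyr::bind_rows(rows)
    out$q <- out$q_forward + out$q_reverse
    out <- out[, c("pair_index", "section_index", "q_forward", "q_reverse",
                   "q", "p_points")]
    new_count_table(out, design = design, seed = seed,
                    truth = list(true_n = phantom$true_n,
                                 true_v_mm3 = phantom$roi$volume_mm3))
  })
}
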