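#' Define a stereological sampling design
#'
#' A sampling design collects every sampling constant of a physical-disector
#' fractionator study in one validated object: the section sampling period
#' (every k-th section), the area of the unbiased counting frame, the X and Y
#' steps of the frame grid, the nominal section thickness and the separation
#' between the two members of a disector pair. All lengths are in micrometres
#' and areas in square micrometres.
#'
#' The frame must fit inside one grid step (`frame_area <= step_x * step_y`)
#' so that frames never overlap and a profile can be attributed to at most one
#' frame. The frame rectangle keeps the aspect ratio of the grid step, so a
#' design with `frame_area == step_x * step_y` tiles the plane exactly
#' (area sampling fraction 1).
#'
#' @param ssf_period Integer >= 1; every `ssf_period`-th section is sampled
#'   (section sampling fraction `1/ssf_period`).
#' @param frame_area Counting-frame area a(frame), um^2.
#' @param step_x,step_y Grid step along X and Y, um.
#' @param section_thickness Nominal section thickness t, um (microtome
#'   setting).
#' @param disector_separation Distance h between the two sections of a
#'   disector pair, um. Defaults to `section_thickness` (adjacent sections).
#' @param smoothness_constant Denominator of the systematic-sampling variance
#'   formula; 240 is appropriate for this design. See [var_surs()].
#' @param seed Optional integer recorded with the design; used as the default
#'   random seed by sampling operations when they are not given one.
#'
#' @return An object of class `sampling_design` (a named list).
#' @examples
#' design <- sampling_design(
#'   ssf_period = 50, frame_area = 60000,
#'   step_x = 387.29, step_y = 387.29, section_thickness = 5
#' )
#' sampling_fractions(design)
#' @seealso [sampling_fractions()], [surs_section_indices()], [surs_grid()]
#' @export
sampling_design <- function(ssf_period, frame_area, step_x, step_y,
                            section_thickness,
                            disector_separation = section_thickness,
                            smoothness_constant = 240,
                            seed = NULL) {
  stopifnot_scalar_number(ssf_period, "ssf_period", positive = TRUE)
  if (ssf_period < 1 || ssf_period != as.integer(ssf_period)) {
    abort("invalid design: `ssf_period` must be an integer >= 1.")
  }
  stopifnot_scalar_number(frame_area, "frame_area", positive = TRUE)
  stopifnot_scalar_number(step_x, "step_x", positive = TRUE)
  stopifnot_scalar_number(step_y, "step_y", positive = TRUE)
  stopifnot_scalar_number(section_thickness, "section_thickness", positive = TRUE)
  stopifnot_scalar_number(disector_separation, "disector_separation", positive = TRUE)
  stopifnot_scalar_number(smoothness_constant, "smoothness_constant", positive = TRUE)
  if (frame_area > step_x * step_y * (1 + 1e-12)) {
    abort("invalid design: `frame_area` must not exceed step_x * step_y (frames must not overlap).")
  }
  structure(
    list(
      ssf_period = as.integer(ssf_period),
      frame_area = frame_area,
      step_x = step_x,
      step_y = step_y,
      section_thickness = section_thickness,
      disector_separation = disector_separation,
      smoothness_constant = smoothness_constant,
      seed = if (!is.null(seed)) as.integer(seed) else NULL
    ),
    class = "sampling_design"
  )
}

#' @export
print.sampling_design <- function(x, ...) {
  fr <- sampling_fractions(x)
  cat("<sampling_design>\n")
  cat(sprintf("  every %d-th section (ssf = 1/%d), t = %g um, h = %g um\n",
              x$ssf_period, x$ssf_period, x$section_thickness,
              x$disector_separation))
  cat(sprintf("  frame %g um^2 on a %g x %g um grid (asf = %.6g, 1/asf = %.6g)\n",
              x$frame_area, x$step_x, x$step_y, fr$asf, fr$inv_asf))
  invisible(x)
}

# frame rectangle dimensions implied by a design (same aspect as the step)
frame_dims <- function(design) {
  w <- sqrt(design$frame_area * design$step_x / design$step_y)
  c(width = w, height = design$frame_area / w)
}

#' Section and area sampling fractions of a design
#'
#' Computes the section sampling fraction `ssf = 1/ssf_period` and the area
#' sampling fraction `asf = frame_area / (step_x * step_y)` at full
#' precision, together with their reciprocals as conventionally reported.
#'
#' @param design A [sampling_design()].
#' @return A one-row tibble with columns `ssf`, `asf`, `inv_ssf`, `inv_asf`.
#' @examples
#' d <- sampling_design(50, 60000, 387.29, 387.29, 5)
#' sampling_fractions(d)$inv_asf # 2.49989..., prints as 2.50 at 2 decimals
#' @export
sampling_fractions <- function(design) {
  stopifnot(inherits(design, "sampling_design"))
  asf <- design$frame_area / (design$step_x * design$step_y)
  tibble::tibble(
    ssf = 1 / design$ssf_period,
    asf = asf,
    inv_ssf = design$ssf_period,
    inv_asf = 1 / asf
  )
}

#' Systematic uniform random sample of section indices
#'
#' Draws the random start of a systematic section sample uniformly from
#' `{0, ..., period - 1}` and returns every `period`-th 0-based section index
#' below `n_total`. Section `i` occupies the half-open slab
#' `[i * t, (i + 1) * t)` along the cutting axis.
#'
#' @param n_total Total number of cut sections (>= 0).
#' @param period Sampling period k (every k-th section), integer >= 1.
#' @param seed Optional integer seed; the draw is deterministic for a fixed
#'   seed and leaves the global RNG stream untouched.
#' @return Integer vector of sampled 0-based section indices, increasing.
#' @examples
#' surs_section_indices(700, 50, seed = 1) # always 14 indices
#' @export
surs_section_indices <- function(n_total, period, seed = NULL) {
  stopifnot_scalar_number(n_total, "n_total", nonneg = TRUE)
  if (!is.numeric(period) || length(period) != 1L || period < 1 ||
      period != as.integer(period)) {
    abort("invalid design: `period` must be an integer >= 1.")
  }
  start <- with_seed(seed, sample.int(period, 1L) - 1L)
  if (n_total <= start) return(integer(0))
  seq.int(from = start, to = as.integer(n_total) - 1L, by = as.integer(period))
}

#' Place a systematic counting-frame grid over a region of interest
#'
#' Generates the X-Y grid of unbiased counting frames for one section: the
#' grid offset is drawn uniformly in `[0, step)` on each axis, and every frame
#' whose rectangle intersects the (optionally expanded) bounding box is
#' emitted. Consecutive frame origins differ by exactly one step.
#'
#' @param roi_bbox Numeric length-4 vector `c(xmin, ymin, xmax, ymax)` in um.
#' @param design A [sampling_design()].
#' @param seed Optional integer seed for the random offsets.
#' @param expand Margin (um) added on every side of the bounding box before
#'   selecting frames. Use at least the largest profile radius when the grid
#'   must offer every profile its counting chance (profiles protruding from
#'   the box can be sampled by a frame lying just outside it).
#' @return An object of class `grid_placement`: a list with `offset_x`,
#'   `offset_y` and a tibble `frames` with columns `frame_id`, `x0`, `y0`,
#'   `width`, `height`.
#' @examples
#' d <- sampling_design(50, 60000, 387.29, 387.29, 5)
#' g <- surs_grid(c(0, 0, 2000, 1200), d, seed = 7)
#' nrow(g$frames)
#' @export
surs_grid <- function(roi_bbox, design, seed = NULL, expand = 0) {
  stopifnot(inherits(design, "sampling_design"))
  if (!is.numeric(roi_bbox) || length(roi_bbox) != 4L || any(!is.finite(roi_bbox))) {
    abort("`roi_bbox` must be c(xmin, ymin, xmax, ymax).")
  }
  if (roi_bbox[3] < roi_bbox[1] || roi_bbox[4] < roi_bbox[2]) {
    abort("`roi_bbox` must have xmax >= xmin and ymax >= ymin.")
  }
  off <- with_seed(seed, runif(2) * c(design$step_x, design$step_y))
  if ((roi_bbox[3] - roi_bbox[1]) * (roi_bbox[4] - roi_bbox[2]) <= 0) {
    warn("zero-area ROI bounding box: empty grid placement.")
    frames <- tibble::tibble(frame_id = integer(0), x0 = numeric(0),
                             y0 = numeric(0), width = numeric(0),
                             height = numeric(0))
    return(structure(list(offset_x = off[1], offset_y = off[2], frames = frames),
                     class = "grid_placement"))
  }
  fd <- frame_dims(design)
  xmin <- roi_bbox[1] - expand; xmax <- roi_bbox[3] + expand
  ymin <- roi_bbox[2] - expand; ymax <- roi_bbox[4] + expand
  # frame at origin o intersects [min, max] iff o <= max and o + size >= min
  ix <- seq.int(ceiling((xmin - fd["width"] - off[1]) / design$step_x),
                floor((xmax - off[1]) / design$step_x))
  iy <- seq.int(ceiling((ymin - fd["height"] - off[2]) / design$step_y),
                floor((ymax - off[2]) / design$step_y))
  grid <- expand.grid(x0 = off[1] + ix * design$step_x,
                      y0 = off[2] + iy * design$step_y)
  frames <- tibble::tibble(
    frame_id = seq_len(nrow(grid)),
    x0 = grid$x0, y0 = grid$y0,
    width = unname(fd["width"]), height = unname(fd["height"])
  )
  structure(list(offset_x = off[1], offset_y = off[2], frames = frames),
            class = "grid_placement")
}

#' @export
print.grid_placement <- function(x, ...) {
  cat(sprintf("<grid_placement> offset (%.2f, %.2f) um, %d frames\n",
              x$offset_x, x$offset_y, nrow(x$frames)))
  invisible(x)
}
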