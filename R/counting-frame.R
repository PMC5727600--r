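#' Construct an unbiased counting frame
#'
#' The unbiased counting frame is a rectangle with two *inclusion* edges (top
#' and right) and two *exclusion* edges (left and bottom) whose exclusion line
#' is extended to infinity: upward from the top-left corner along the left
#' edge, and downward from the bottom-right corner along the right edge. A
#' profile is sampled by the frame iff it intersects the closed frame (or
#' touches an inclusion edge) and does not touch the exclusion line anywhere.
#' Under an exhaustive tiling of the plane by such frames every profile is
#' sampled by exactly one frame, which is what makes the rule unbiased.
#'
#' @param x0,y0 Coordinates of the lower-left corner, um.
#' @param width,height Frame dimensions, um.
#' @return An object of class `counting_frame`.
#' @examples
#' counting_frame(0, 0, 245, 245)
#' @export
counting_frame <- function(x0, y0, width, height) {
  stopifnot_scalar_number(width, "width", positive = TRUE)
  stopifnot_scalar_number(height, "height", positive = TRUE)
  structure(list(x0 = x0, y0 = y0, width = width, height = height),
            class = "counting_frame")
}

#' @export
print.counting_frame <- function(x, ...) {
  cat(sprintf("<counting_frame> [%g, %g] x [%g, %g] um\n",
              x$x0, x$x0 + x$width, x$y0, x$y0 + x$height))
  invisible(x)
}

as_frame <- function(frame) {
  if (inherits(frame, "counting_frame")) return(frame)
  # one row of a grid_placement$frames tibble
  counting_frame(frame$x0, frame$y0, frame$width, frame$height)
}

#' Unbiased counting-frame decision for circular profiles
#'
#' Applies the counting rule of the unbiased frame to one or more circular
#' particle profiles: a profile is sampled iff it intersects the closed frame
#' rectangle (touching the top or right inclusion edge counts) and does not
#' touch the exclusion line — the left edge extended infinitely upward, the
#' bottom edge, and the right edge extended infinitely downward. "Touching"
#' means non-empty intersection of the closed disc with the line.
#'
#' Irregular profiles are handled in raster mode (label masks via
#' [profiles_from_mask()]), where each object is reduced to its centroid and
#' equivalent-area circle.
#'
#' @param profiles A data frame with columns `x`, `y` (centroid, um) and `r`
#'   (profile radius, um; 0 gives a point profile).
#' @param frame A [counting_frame()] or a one-row subset of
#'   `grid_placement$frames`.
#' @return Logical vector, one decision per profile.
#' @examples
#' f <- counting_frame(0, 0, 100, 100)
#' frame_decision(data.frame(x = 50, y = 50, r = 5), f)   # TRUE
#' frame_decision(data.frame(x = 0, y = 50, r = 5), f)    # FALSE: left edge
#' @export
frame_decision <- function(profiles, frame) {
  frame <- as_frame(frame)
  x <- profiles$x; y <- profiles$y; r <- profiles$r
  if (any(r < 0)) abort("profile radii must be >= 0.")
  x1 <- frame$x0 + frame$width
  y1 <- frame$y0 + frame$height
  # distance^2 from centre to the closed rectangle
  dx <- pmax(frame$x0 - x, 0, x - x1)
  dy <- pmax(frame$y0 - y, 0, y - y1)
  hits_frame <- dx * dx + dy * dy <= r * r
  # exclusion line: {x0} x [y0, +Inf) U [x0, x1] x {y0} U {x1} x (-Inf, y0]
  d_left <- (x - frame$x0)^2 + pmin(y - frame$y0, 0)^2
  d_bottom <- (x - pmin(pmax(x, frame$x0), x1))^2 + (y - frame$y0)^2
  d_right <- (x - x1)^2 + pmax(y - frame$y0, 0)^2
  touches_exclusion <- pmin(d_left, d_bottom, d_right) <= r * r
  hits_frame & !touches_exclusion
}
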