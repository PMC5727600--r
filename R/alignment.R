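#' Rigid transform between a lookup and a reference section
#'
#' A rotation by `theta` degrees (counter-clockwise, about a stated centre)
#' followed by a translation `(dx, dy)`. Produced automatically by
#' [align_pair()] or supplied manually via [apply_manual_override()].
#'
#' @param dx,dy Translation, in the length unit of the coordinates being
#'   transformed (um for profile coordinates, px for images).
#' @param theta Rotation, degrees counter-clockwise.
#' @param center Length-2 rotation centre (default the origin).
#' @param similarity Similarity metric value achieved (normalized
#'   cross-correlation, in \[-1, 1\]), `NA` for manual transforms.
#' @param confidence `TRUE`/`FALSE`: did the similarity pass the acceptance
#'   threshold? `NA` for manual transforms.
#' @param source `"automatic"` or `"manual"`.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(dx = 0, dy = 0, theta = 0, center = c(0, 0),
                            similarity = NA_real_, confidence = NA,
                            source = "manual") {
  vals <- c(dx, dy, theta, center)
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    abort("rigid transform parameters must be finite numbers.")
  }
  structure(list(dx = dx, dy = dy, theta = theta, center = center,
                 similarity = similarity, confidence = confidence,
                 source = match.arg(source, c("automatic", "manual"))),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> dx = %.3f, dy = %.3f, theta = %.3f deg (%s",
              x$dx, x$dy, x$theta, x$source))
  if (is.finite(x$similarity)) {
    cat(sprintf(", similarity = %.3f, confidence %s",
                x$similarity, if (isTRUE(x$confidence)) "pass" else "FAIL"))
  }
  cat(")\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param xy A two-column matrix or data frame of coordinates.
#' @param transform A [rigid_transform()].
#' @return Matrix of transformed coordinates.
#' @export
apply_transform <- function(xy, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  xy <- as.matrix(xy)
  th <- transform$theta * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- matrix(transform$center, nrow(xy), 2, byrow = TRUE)
  out <- (xy - ctr) %*% t(rot) + ctr
  out[, 1] <- out[, 1] + transform$dx
  out[, 2] <- out[, 2] + transform$dy
  out
}

#' Invert a rigid transform
#' @param transform A [rigid_transform()].
#' @return The inverse `rigid_transform` (same centre).
#' @export
invert_transform <- function(transform) {
  # forward: p' = R(p - c) + c + d; inverse in the same form has rotation
  # -theta about c and translation -R(-theta) d
  th <- -transform$theta * pi / 180
  d <- c(transform$dx, transform$dy)
  rigid_transform(
    dx = -(cos(th) * d[1] - sin(th) * d[2]),
    dy = -(sin(th) * d[1] + cos(th) * d[2]),
    theta = -transform$theta,
    center = transform$center,
    source = transform$source
  )
}

transform_profiles <- function(profiles, transform) {
  if (nrow(profiles) == 0L) return(profiles)
  xy <- apply_transform(cbind(profiles$x, profiles$y), transform)
  profiles$x <- xy[, 1]
  profiles$y <- xy[, 2]
  profiles
}

# block-mean downsample by integer factor (trailing remainder rows dropped)
downsample_image <- function(img, f) {
  if (f == 1L) return(img)
  nr <- nrow(img) %/% f
  nc <- ncol(img) %/% f
  img <- img[seq_len(nr * f), seq_len(nc * f), drop = FALSE]
  ri <- rep(seq_len(nr), each = f)
  ci <- rep(seq_len(nc), each = f)
  t(rowsum(t(rowsum(img, ri)), ci)) / (f * f)
}

#' Rotate an image about its centre (nearest-neighbour)
#'
#' Rotates a numeric matrix by `theta` degrees about the image centre using
#' nearest-neighbour resampling; pixels mapped from outside the source get
#' `fill`. In x/y terms (x = column, y = row) content moves by the rotation
#' matrix `[[cos, -sin], [sin, cos]]`. Used by [align_pair()] and to
#' synthesize ground-truth rotated section pairs.
#'
#' @param img Numeric matrix.
#' @param theta Rotation in degrees.
#' @param fill Value for unmapped output pixels (default 0).
#' @return The rotated matrix, same dimensions.
#' @export
rotate_image <- function(img, theta, fill = 0) {
  if (theta == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  th <- theta * pi / 180
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  grid_r <- matrix(seq_len(nr), nr, nc) - cr
  grid_c <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
  # inverse map: source coords for each output pixel
  sr <- round(cos(th) * grid_r - sin(th) * grid_c + cr)
  sc <- round(sin(th) * grid_r + cos(th) * grid_c + cc)
  ok <- sr >= 1 & sr <= nr & sc >= 1 & sc <= nc
  out <- matrix(fill, nr, nc)
  out[ok] <- img[cbind(sr[ok], sc[ok])]
  out
}

# normalized cross-correlation of two equal-size matrices
ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a * a) * sum(b * b))
  if (den == 0) return(NA_real_)
  sum(a * b) / den
}

# best integer (dx, dy) shift of `moving` onto `fixed` within a window;
# shift (dx, dy) means moving pixel (r, c) lands on fixed pixel (r+dy, c+dx)
best_shift <- function(fixed, moving, dxs, dys, min_overlap = 16L) {
  best <- c(score = -Inf, dx = 0, dy = 0)
  nr <- nrow(fixed); nc <- ncol(fixed)
  # scan outward from the window centre so NCC ties keep the smallest move
  dxs <- dxs[order(abs(dxs - round(mean(range(dxs)))))]
  dys <- dys[order(abs(dys - round(mean(range(dys)))))]
  for (dy in dys) {
    lo_r <- max(1L, 1L + dy); hi_r <- min(nr, nrow(moving) + dy)
    if (hi_r - lo_r < 1L) next
    r_f <- lo_r:hi_r
    r_m <- r_f - dy
    for (dx in dxs) {
      lo_c <- max(1L, 1L + dx); hi_c <- min(nc, ncol(moving) + dx)
      if (hi_c - lo_c < 1L) next
      c_f <- lo_c:hi_c
      if (length(r_f) * length(c_f) < min_overlap) next
      s <- ncc(fixed[r_f, c_f, drop = FALSE],
               moving[r_m, c_f - dx, drop = FALSE])
      if (!is.na(s) && s > best["score"]) best <- c(score = s, dx = dx, dy = dy)
    }
  }
  best
}

#' Automated rigid alignment of a reference/lookup section image pair
#'
#' Finds the rigid transform (shift and small rotation) that maximises the
#' normalized cross-correlation between the lookup and reference images,
#' using a coarse-to-fine pyramid (downsampling factors 4, 2, 1): the coarse
#' level scans the full shift window and rotation range, and each finer level
#' refines around the best candidate. This mirrors the self-similarity
#' alignment of automated disector systems; when the best similarity falls
#' below `threshold` the transform is flagged as low-confidence and the
#' pipeline should request a manual override rather than proceed silently.
#'
#' @param reference,lookup Numeric grayscale matrices at the same pixel
#'   scale.
#' @param max_shift Maximum shift searched, px; default 25% of the smaller
#'   image dimension.
#' @param max_rotation Maximum rotation searched, degrees (default 10).
#' @param threshold Minimum similarity for a confident automatic alignment
#'   (default 0.5).
#' @return A [rigid_transform()] (units px, rotation centre at the image
#'   centre) with `similarity`, `confidence` and `source = "automatic"`.
#' @examples
#' img <- matrix(0, 48, 48); img[15:25, 20:33] <- 1
#' tf <- align_pair(img, img)
#' c(tf$dx, tf$dy, tf$theta) # 0 0 0
#' @export
align_pair <- function(reference, lookup,
                       max_shift = NULL, max_rotation = 10, threshold = 0.5) {
  if (!is.matrix(reference) || !is.matrix(lookup)) {
    abort("images must be numeric matrices.")
  }
  if (sd(reference) == 0 || sd(lookup) == 0) {
    abort("no signal: empty or constant image.")
  }
  if (is.null(max_shift)) {
    max_shift <- floor(0.25 * min(dim(reference)))
  }
  # pyramid: translation-only scan at factor 4 (rotations this small barely
  # move coarse pixels), full rotation sweep at factor 2, sub-degree
  # refinement at full resolution
  levels <- c(4L, 2L, 1L)
  best_theta <- 0; best_dx <- 0; best_dy <- 0; best_sim <- -Inf
  theta_step <- c(NA, 0.5, 0.25)
  for (li in seq_along(levels)) {
    f <- levels[li]
    ref_l <- downsample_image(reference, f)
    look_l <- downsample_image(lookup, f)
    if (li == 1L) {
      thetas <- 0
      w <- ceiling(max_shift / f)
      dxs <- seq.int(-w, w); dys <- seq.int(-w, w)
    } else if (li == 2L) {
      thetas <- seq(-max_rotation, max_rotation, by = theta_step[li])
      cdx <- best_dx * 2; cdy <- best_dy * 2
      dxs <- seq.int(cdx - 6L, cdx + 6L)
      dys <- seq.int(cdy - 6L, cdy + 6L)
    } else {
      thetas <- seq(best_theta - 2 * theta_step[li], best_theta + 2 * theta_step[li],
                    by = theta_step[li])
      thetas <- thetas[abs(thetas) <= max_rotation + 1e-9]
      cdx <- best_dx * 2; cdy <- best_dy * 2
      dxs <- seq.int(cdx - 3L, cdx + 3L)
      dys <- seq.int(cdy - 3L, cdy + 3L)
    }
    # try angles smallest-magnitude first: sub-pixel rotations can leave a
    # resampled image unchanged, and ties must then keep the least rotation
    thetas <- thetas[order(abs(thetas))]
    lvl_best <- c(score = -Inf, dx = 0, dy = 0, theta = 0)
    for (th in thetas) {
      rot <- rotate_image(look_l, th)
      bs <- best_shift(ref_l, rot, dxs, dys)
      if (bs["score"] > lvl_best["score"]) {
        lvl_best <- c(bs, theta = th)
      }
    }
    best_dx <- lvl_best[["dx"]]; best_dy <- lvl_best[["dy"]]
    best_theta <- lvl_best[["theta"]]; best_sim <- lvl_best[["score"]]
  }
  conf <- is.finite(best_sim) && best_sim >= threshold
  if (!conf) {
    warn(sprintf("alignment confidence failure (similarity %.3f < %.2f): manual override advised.",
                 best_sim, threshold))
  }
  rigid_transform(
    dx = best_dx, dy = best_dy, theta = best_theta,
    center = c((ncol(reference) + 1) / 2, (nrow(reference) + 1) / 2),
    similarity = best_sim, confidence = conf, source = "automatic"
  )
}

#' Replace a pair's alignment with a manual transform
#'
#' The manual-override path for pairs whose automatic alignment failed its
#' confidence check: the supplied transform replaces the pair's transform,
#' its source is recorded as manual, and the override is written to the
#' pair's audit log together with the operator tag.
#'
#' @param pair A [section_pair()].
#' @param transform A finite [rigid_transform()].
#' @param operator Operator tag recorded in the audit log.
#' @return The pair with the manual transform installed; the audit log is in
#'   `attr(pair, "audit")`.
#' @export
apply_manual_override <- function(pair, transform, operator = "operator") {
  stopifnot(inherits(pair, "section_pair"))
  if (!inherits(transform, "rigid_transform")) {
    abort("`transform` must be a rigid_transform.")
  }
  vals <- c(transform$dx, transform$dy, transform$theta)
  if (any(!is.finite(vals))) abort("manual transform parameters must be finite.")
  transform$source <- "manual"
  pair$transform <- transform
  entry <- sprintf("manual override by %s: dx=%.4g dy=%.4g theta=%.4g deg",
                   operator, transform$dx, transform$dy, transform$theta)
  attr(pair, "audit") <- c(attr(pair, "audit"), entry)
  message(entry)
  pair
}
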