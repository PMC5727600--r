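#' Read a grayscale section image (PNG or TIFF)
#'
#' Reads a raster section image into a numeric matrix, averaging colour
#' channels when present. Orientation follows the reading package: rows are
#' image rows from the top.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix.
#' @export
read_section_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE)) abort("package `png` is required.")
      png::readPNG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) abort("package `tiff` is required.")
      tiff::readTIFF(path)
    },
    abort(sprintf("unsupported image format `.%s` (use PNG or TIFF).", ext))
  )
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}

#' Rasterize circular profiles into a label mask
#'
#' Renders the profiles of one section into an integer label image: pixel
#' value = particle id of the covering profile (later-drawn profiles win on
#' overlap), background 0. Used to exercise raster-mode counting and the
#' image alignment on synthetic sections with known truth.
#'
#' @param profiles Data frame with columns `x`, `y`, `r` (um) and optionally
#'   `particle_id`.
#' @param bbox `c(xmin, ymin, xmax, ymax)` extent rendered, um.
#' @param pixel_size Pixel edge, um/px.
#' @return Integer matrix (rows = y from `ymin` upward, cols = x).
#' @export
render_section_mask <- function(profiles, bbox, pixel_size = 2) {
  nr <- max(1L, ceiling((bbox[4] - bbox[2]) / pixel_size))
  nc <- max(1L, ceiling((bbox[3] - bbox[1]) / pixel_size))
  mask <- matrix(0L, nr, nc)
  if (nrow(profiles) == 0L) return(mask)
  ids <- if ("particle_id" %in% names(profiles)) profiles$particle_id else seq_len(nrow(profiles))
  px <- bbox[1] + (seq_len(nc) - 0.5) * pixel_size
  py <- bbox[2] + (seq_len(nr) - 0.5) * pixel_size
  for (i in seq_len(nrow(profiles))) {
    ci <- which(abs(px - profiles$x[i]) <= profiles$r[i])
    ri <- which(abs(py - profiles$y[i]) <= profiles$r[i])
    if (!length(ci) || !length(ri)) next
    sub_d2 <- outer((py[ri] - profiles$y[i])^2, (px[ci] - profiles$x[i])^2, "+")
    hit <- sub_d2 <= profiles$r[i]^2
    mask[ri, ci][hit] <- as.integer(ids[i])
  }
  mask
}

#' Extract circular profiles from an integer label mask
#'
#' Raster-mode ingestion: each distinct positive label in the mask is one
#' object; its centroid and equivalent-area circle radius are returned in
#' physical units, ready for [disector_count()]. Masks are expected to carry
#' one label per connected object (background 0).
#'
#' @param mask Integer matrix, background 0.
#' @param pixel_size Pixel edge, um/px.
#' @param origin `c(x, y)` of the pixel-grid origin, um.
#' @return Tibble with `particle_id`, `x`, `y`, `r` (um).
#' @export
profiles_from_mask <- function(mask, pixel_size = 2, origin = c(0, 0)) {
  labs <- sort(unique(mask[mask > 0]))
  if (!length(labs)) {
    return(tibble::tibble(particle_id = integer(0), x = numeric(0),
                          y = numeric(0), r = numeric(0)))
  }
  out <- lapply(labs, function(l) {
    idx <- which(mask == l, arr.ind = TRUE)
    npx <- nrow(idx)
    tibble::tibble(
      particle_id = as.integer(l),
      x = origin[1] + (mean(idx[, 2]) - 0.5) * pixel_size,
      y = origin[2] + (mean(idx[, 1]) - 0.5) * pixel_size,
      r = sqrt(npx / pi) * pixel_size
    )
  })
  dplyr::bind_rows(out)
}
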