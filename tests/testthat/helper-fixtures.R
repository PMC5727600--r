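# Worked-example per-pair count series (13 nonempty pairs, total 158)
table2_q <- c(9, 30, 23, 12, 14, 6, 11, 15, 15, 14, 7, 2, 0)

# The published study design: every 50th section, 60,000 um^2 frame on a
# 387.29 um square grid, 5 um sections
paper_design <- function() {
  sampling_design(
    ssf_period = 50, frame_area = 60000,
    step_x = 387.29, step_y = 387.29,
    section_thickness = 5
  )
}

# binary section image built from random disc profiles (for alignment tests)
make_section_image <- function(seed, size = 256, n = 40) {
  set.seed(seed)
  prof <- data.frame(
    x = runif(n, 20, size - 20), y = runif(n, 20, size - 20),
    r = runif(n, 4, 9)
  )
  (render_section_mask(prof, c(0, 0, size, size), pixel_size = 1) > 0) * 1
}

# integer-pixel translation with zero fill
shift_image <- function(img, dx, dy, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dy
  cs <- seq_len(nc) - dx
  ok_r <- rs >= 1 & rs <= nr
  ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- img[rs[ok_r], cs[ok_c]]
  out
}

# independent permutation enumerator (recursive insertion; used as the
# exhaustive oracle against the package's own enumeration)
oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}
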