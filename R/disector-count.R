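#' Construct a physical disector section pair
#'
#' A section pair holds the particle profiles seen on two adjacent sections:
#' the *reference* section and the *lookup* section. A rigid transform (from
#' [align_pair()] or [apply_manual_override()]) maps lookup coordinates into
#' the reference frame; `NULL` means the sections are already co-registered.
#'
#' @param reference,lookup Data frames of profiles with columns `x`, `y`, `r`
#'   (um), optionally `particle_id` and `section_index`.
#' @param transform Optional [rigid_transform()] applied to the lookup
#'   profiles before matching and counting.
#' @param roi Optional ROI polygon or bounding box (informational).
#' @return An object of class `section_pair`.
#' @export
section_pair <- function(reference, lookup, transform = NULL, roi = NULL) {
  for (nm in c("x", "y", "r")) {
    if (!nm %in% names(reference) || !nm %in% names(lookup)) {
      abort(sprintf("profiles need column `%s`.", nm))
    }
  }
  if (!is.null(transform) && !inherits(transform, "rigid_transform")) {
    abort("`transform` must be a rigid_transform or NULL.")
  }
  ri <- reference$section_index; li <- lookup$section_index
  if (length(ri) && length(li) &&
      abs(ri[1] - li[1]) != 1 && !(length(unique(c(ri, li))) == 1)) {
    warn("reference and lookup section indices are not adjacent in cutting order.")
  }
  structure(list(reference = tibble::as_tibble(reference),
                 lookup = tibble::as_tibble(lookup),
                 transform = transform, roi = roi),
            class = "section_pair")
}

#' @export
print.section_pair <- function(x, ...) {
  cat(sprintf("<section_pair> %d reference / %d lookup profiles, alignment: %s\n",
              nrow(x$reference), nrow(x$lookup),
              if (is.null(x$transform)) "none (co-registered)" else x$transform$source))
  invisible(x)
}

# Match profiles of `from` to profiles of `to`; returns logical: does each
# `from` profile have a partner in `to`? By particle_id when both sides carry
# complete ids; otherwise one-to-one greedy nearest-centroid within r_match,
# ties broken by smallest distance then lowest row index.
match_profiles <- function(from, to, r_match) {
  if (nrow(from) == 0L) return(logical(0))
  has_id <- function(df) "particle_id" %in% names(df) && !anyNA(df$particle_id)
  if (has_id(from) && has_id(to)) {
    return(from$particle_id %in% to$particle_id)
  }
  if (nrow(to) == 0L) return(rep(FALSE, nrow(from)))
  d <- sqrt(outer(from$x, to$x, "-")^2 + outer(from$y, to$y, "-")^2)
  cand <- which(d <= r_match, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(rep(FALSE, nrow(from)))
  ord <- order(d[cand], cand[, 1L], cand[, 2L])
  cand <- cand[ord, , drop = FALSE]
  matched_from <- rep(FALSE, nrow(from))
  used_to <- rep(FALSE, nrow(to))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (!matched_from[i] && !used_to[j]) {
      matched_from[i] <- TRUE
      used_to[j] <- TRUE
    }
  }
  matched_from
}

# q counting events among `profiles` (already reduced to unmatched ones),
# attributed to the first frame whose decision samples them
count_in_frames <- function(profiles, frames) {
  q <- integer(nrow(frames))
  if (nrow(profiles) == 0L || nrow(frames) == 0L) return(q)
  taken <- rep(FALSE, nrow(profiles))
  for (k in seq_len(nrow(frames))) {
    dec <- frame_decision(profiles, frames[k, ]) & !taken
    q[k] <- sum(dec)
    taken <- taken | dec
  }
  q
}

#' Bidirectional physical disector count over a frame grid
#'
#' Applies the physical disector decision to an aligned section pair: a
#' particle produces a *forward* counting event when its profile appears in
#' the reference section but has no matching profile in the lookup section,
#' and a *reverse* event with the roles swapped (the two sections of a pair
#' can be compared both ways, which is why the fractionator estimate is later
#' divided by two). Each counting event must additionally be sampled by one
#' of the unbiased counting frames; a profile is attributed to at most one
#' frame.
#'
#' @param pair A [section_pair()]. Its `transform`, when present, is applied
#'   to the lookup profiles before matching. Supplying raw data frames
#'   without a common coordinate system is an error.
#' @param frames A [surs_grid()] placement, its `frames` tibble, or a single
#'   [counting_frame()].
#' @param r_match Centroid-match tolerance (um) used when particle ids are
#'   not available; defaults to the mean profile radius of the pair (half the
#'   mean profile diameter).
#' @return A tibble with one row per frame: `frame_id`, `q_forward`,
#'   `q_reverse`.
#' @examples
#' ref <- data.frame(particle_id = 1:2, x = c(30, 60), y = c(40, 40), r = 5)
#' lkp <- data.frame(particle_id = 2:3, x = c(60, 80), y = c(40, 50), r = 5)
#' f <- counting_frame(0, 0, 100, 100)
#' disector_count(section_pair(ref, lkp), f) # forward 1, reverse 1
#' @export
disector_count <- function(pair, frames, r_match = NULL) {
  if (!inherits(pair, "section_pair")) {
    abort("alignment missing: build a section_pair() (with its transform) first.")
  }
  if (inherits(frames, "grid_placement")) frames <- frames$frames
  if (inherits(frames, "counting_frame")) {
    frames <- tibble::tibble(frame_id = 1L, x0 = frames$x0, y0 = frames$y0,
                             width = frames$width, height = frames$height)
  }
  ref <- pair$reference
  lkp <- pair$lookup
  if (!is.null(pair$transform)) {
    lkp <- transform_profiles(lkp, pair$transform)
  }
  if (is.null(r_match)) {
    rr <- c(ref$r, lkp$r)
    r_match <- if (length(rr)) mean(rr) else 0
  }
  fwd_unmatched <- ref[!match_profiles(ref, lkp, r_match), , drop = FALSE]
  rev_unmatched <- lkp[!match_profiles(lkp, ref, r_match), , drop = FALSE]
  tibble::tibble(
    frame_id = frames$frame_id,
    q_forward = count_in_frames(fwd_unmatched, frames),
    q_reverse = count_in_frames(rev_unmatched, frames)
  )
}

#' Aggregate per-frame disector counts into a count table
#'
#' Collapses per-frame forward/reverse counting events to one row per
#' disector pair, preserving cutting order (required later by the
#' systematic-sampling variance of [var_surs()]). The bidirectional per-pair
#' count is `q = q_forward + q_reverse`.
#'
#' @param per_frame A data frame with columns `pair_index`, `q_forward`,
#'   `q_reverse` (one row per frame, or already per pair) and optionally
#'   `p_points` and identifier columns `animal_id`, `region`, `side`.
#' @return A `count_table` tibble: one row per pair in cutting order with
#'   columns `pair_index`, `q_forward`, `q_reverse`, `q`, and `p_points` when
#'   present. `sum(q)` is the study total Q^-.
#' @examples
#' tally_counts(data.frame(pair_index = c(1, 1, 2),
#'                         q_forward = c(1, 2, 0), q_reverse = c(0, 1, 3)))
#' @export
tally_counts <- function(per_frame) {
  need <- c("pair_index", "q_forward", "q_reverse")
  if (!all(need %in% names(per_frame))) {
    abort("`per_frame` needs columns pair_index, q_forward, q_reverse.")
  }
  keys <- intersect(c("animal_id", "region", "side", "pair_index"), names(per_frame))
  out <- per_frame |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      q_forward = sum(.data$q_forward),
      q_reverse = sum(.data$q_reverse),
      p_points = if ("p_points" %in% names(per_frame)) sum(.data$p_points) else 0L,
      .groups = "drop"
    ) |>
    dplyr::mutate(q = .data$q_forward + .data$q_reverse) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
  new_count_table(out)
}

new_count_table <- function(df, design = NULL, truth = NULL, seed = NULL) {
  out <- tibble::as_tibble(df)
  class(out) <- c("count_table", class(out))
  if (!is.null(design)) attr(out, "design") <- design
  if (!is.null(truth)) attr(out, "truth") <- truth
  if (!is.null(seed)) attr(out, "seed") <- seed
  out
}
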