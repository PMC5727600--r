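#' Fractionator number and Cavalieri volume estimates from a count table
#'
#' Turns a per-pair count table into the study-level estimates: the
#' bidirectional fractionator number estimate N, the point-counting volume
#' estimate V and the predicted coefficient of error of N (via
#' [precision_summary()]). When the table carries identifier columns
#' (`animal_id`, `region`, `side`) each group is estimated separately.
#'
#' Pipeline computations use the full-precision area sampling fraction of
#' the design; pass `inv_asf` explicitly (e.g. a printed 2-decimal value)
#' only to reproduce published tables.
#'
#' @param count_table A `count_table` tibble ([tally_counts()],
#'   [simulate_study()] or [read_count_table()]), with per-pair columns `q`
#'   (or `q_forward`/`q_reverse`) and optionally `p_points`, in cutting
#'   order.
#' @param design A [sampling_design()]; defaults to the table's `design`
#'   attribute.
#' @param inv_asf,inv_ssf Optional overrides of the design's reciprocal
#'   sampling fractions.
#' @param bidirectional Were pairs counted both ways (default `TRUE`)?
#' @param thickness Section thickness for the volume estimate, um; defaults
#'   to the design's `section_thickness` (use the block-calculated mean
#'   thickness when available).
#' @return An object of class `stereo_estimate`; see [tidy.stereo_estimate()]
#'   for the per-group table and [glance.stereo_estimate()] for a one-row
#'   summary. Reported columns follow the display conventions (`n` rounded
#'   half away from zero, `v_mm3` and `ce` at full precision alongside).
#' @examples
#' ct <- tally_counts(data.frame(pair_index = 1:3, q_forward = c(3, 5, 2),
#'                               q_reverse = c(2, 4, 1)))
#' d <- sampling_design(50, 60000, 387.29, 387.29, 5)
#' tidy(fractionator_estimate(ct, d))
#' @export
fractionator_estimate <- function(count_table, design = NULL,
                                  inv_asf = NULL, inv_ssf = NULL,
                                  bidirectional = TRUE, thickness = NULL) {
  design <- design %||% attr(count_table, "design")
  if (is.null(design)) abort("no sampling design supplied or attached to the table.")
  fr <- sampling_fractions(design)
  inv_asf <- inv_asf %||% fr$inv_asf
  inv_ssf <- inv_ssf %||% fr$inv_ssf
  thickness <- thickness %||% design$section_thickness
  if (!"q" %in% names(count_table)) {
    count_table$q <- count_table$q_forward + count_table$q_reverse
  }
  if (!"p_points" %in% names(count_table)) count_table$p_points <- 0L
  keys <- intersect(c("animal_id", "region", "side"), names(count_table))
  groups <- if (length(keys)) {
    dplyr::group_split(dplyr::group_by(count_table, dplyr::across(dplyr::all_of(keys))))
  } else {
    list(count_table)
  }
  est <- purrr::map_dfr(groups, function(g) {
    g <- dplyr::arrange(g, .data$pair_index)
    q <- g$q
    sum_q <- sum(q)
    prec <- if (sum_q > 0) precision_summary(q, design$smoothness_constant) else NULL
    n_raw <- estimate_total_number(sum_q, inv_ssf, inv_asf, bidirectional)
    v_raw <- estimate_volume(sum(g$p_points), design$step_x, design$step_y,
                             thickness, inv_ssf)
    dplyr::bind_cols(
      g[1, keys, drop = FALSE],
      tibble::tibble(
        n_pairs = nrow(g),
        sum_q = sum_q,
        sum_p = sum(g$p_points),
        n_raw = n_raw,
        n = round_half_away(n_raw),
        v_raw_mm3 = v_raw,
        v_mm3 = round(v_raw, 2),
        var_surs_raw = if (is.null(prec)) NA_real_ else prec$var_surs_raw,
        var_surs = if (is.null(prec)) NA_real_ else prec$var_surs,
        ce = if (is.null(prec)) NA_real_ else prec$ce,
        q_list = list(q)
      )
    )
  })
  structure(
    list(estimates = est, design = design,
         inv_asf = inv_asf, inv_ssf = inv_ssf,
         bidirectional = bidirectional, thickness = thickness,
         count_table = count_table),
    class = "stereo_estimate"
  )
}

#' @export
print.stereo_estimate <- function(x, ...) {
  cat("<stereo_estimate>\n")
  show <- dplyr::select(x$estimates, -dplyr::any_of(c("q_list", "n_raw", "v_raw_mm3",
                                                      "var_surs_raw")))
  print(show)
  invisible(x)
}

#' Tidy a stereological estimate
#'
#' @param x A [fractionator_estimate()] result.
#' @param ... Unused.
#' @return A tibble with one row per estimated group: total counts, the
#'   rounded and unrounded number estimate, the volume estimate and the
#'   predicted CE.
#' @method tidy stereo_estimate
#' @export
tidy.stereo_estimate <- function(x, ...) {
  dplyr::select(x$estimates, -dplyr::any_of("q_list"))
}

#' One-row summary of a stereological estimate
#'
#' @param x A [fractionator_estimate()] result.
#' @param ... Unused.
#' @return A one-row tibble: number of groups, total counting events, the
#'   group mean CE ([mean_ce()]) and the sampling fractions used.
#' @method glance stereo_estimate
#' @export
glance.stereo_estimate <- function(x, ...) {
  ces <- x$estimates$ce
  tibble::tibble(
    n_groups = nrow(x$estimates),
    total_q = sum(x$estimates$sum_q),
    total_p = sum(x$estimates$sum_p),
    mean_ce = if (all(is.na(ces))) NA_real_ else mean_ce(ces[!is.na(ces)]),
    inv_ssf = x$inv_ssf,
    inv_asf = x$inv_asf,
    bidirectional = x$bidirectional
  )
}
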