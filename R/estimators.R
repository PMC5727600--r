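#' Fractionator estimate of total particle number
#'
#' The fractionator principle estimates the total particle number from the
#' counting events collected in a known fraction of the tissue:
#' \deqn{N = \frac{1}{ssf} \cdot \frac{1}{asf} \cdot \Sigma Q^-}
#' When the disector pairs are compared both ways (bidirectional counting,
#' the default for the physical disector) every particle gets two counting
#' chances and the result is divided by two.
#'
#' The returned value is kept at full precision; report it with
#' [round_half_away()] (the Table-style convention rounds N to the nearest
#' integer, ties away from zero).
#'
#' @param sum_q Total number of disector counting events Q^- (>= 0).
#' @param inv_ssf Reciprocal section sampling fraction (e.g. 50 for every
#'   50th section).
#' @param inv_asf Reciprocal area sampling fraction. Use the full-precision
#'   value from [sampling_fractions()] in pipelines; pass a printed 2-decimal
#'   value only when reproducing a published table.
#' @param bidirectional Were the pairs counted both ways? Default `TRUE`.
#' @return The estimated total number, unrounded.
#' @examples
#' round_half_away(estimate_total_number(159, 50, 2.50)) # 9938
#' @export
estimate_total_number <- function(sum_q, inv_ssf, inv_asf, bidirectional = TRUE) {
  stopifnot_scalar_number(sum_q, "sum_q", nonneg = TRUE)
  stopifnot_scalar_number(inv_ssf, "inv_ssf", positive = TRUE)
  stopifnot_scalar_number(inv_asf, "inv_asf", positive = TRUE)
  n <- inv_ssf * inv_asf * sum_q
  if (bidirectional) n <- n / 2
  n
}

#' Cavalieri point-counting estimate of regional volume
#'
#' Each grid position carries one test point representing an area
#' `step_x * step_y`; with systematic sections of thickness `t` sampled at
#' fraction `1/inv_ssf`, the regional volume is
#' \deqn{V = \Sigma P \cdot step_x \cdot step_y \cdot t \cdot \frac{1}{ssf}}
#' converted from um^3 to mm^3. Report at 2 decimals; the returned value is
#' unrounded.
#'
#' @param sum_p Total test points hitting the region (>= 0).
#' @param step_x,step_y Grid steps, um.
#' @param t Section thickness, um (> 0); use the block-calculated mean
#'   thickness from [mean_section_thickness()] when available.
#' @param inv_ssf Reciprocal section sampling fraction.
#' @return Estimated volume in mm^3, unrounded.
#' @examples
#' round(estimate_volume(181, 387.29, 387.29, 5, 50), 2) # 6.79
#' @export
estimate_volume <- function(sum_p, step_x, step_y, t, inv_ssf) {
  stopifnot_scalar_number(sum_p, "sum_p", nonneg = TRUE)
  stopifnot_scalar_number(step_x, "step_x", positive = TRUE)
  stopifnot_scalar_number(step_y, "step_y", positive = TRUE)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0) {
    abort("section thickness `t` must be > 0.")
  }
  stopifnot_scalar_number(inv_ssf, "inv_ssf", positive = TRUE)
  sum_p * step_x * step_y * t * inv_ssf * 1e-9
}

#' Caliper record for a sectioned block
#'
#' Stores the block caliper measurements taken before and after sectioning,
#' the number of sections cut, and the wet (formalin) and paraffin block
#' weights used for the shrinkage index.
#'
#' @param block_height_before,block_height_after Block heights, mm; before
#'   must be >= after.
#' @param sections_cut_total Total number of sections cut (sampled and
#'   discarded), > 0.
#' @param formalin_weight,paraffin_weight Block weights, g (optional, needed
#'   only for [shrinkage_index()]).
#' @return An object of class `caliper_record`.
#' @export
caliper_record <- function(block_height_before, block_height_after,
                           sections_cut_total,
                           formalin_weight = NA_real_,
                           paraffin_weight = NA_real_) {
  stopifnot_scalar_number(block_height_before, "block_height_before", nonneg = TRUE)
  stopifnot_scalar_number(block_height_after, "block_height_after", nonneg = TRUE)
  if (block_height_before < block_height_after) {
    abort("measurement order error: block height before sectioning must be >= after.")
  }
  stopifnot_scalar_number(sections_cut_total, "sections_cut_total", positive = TRUE)
  structure(list(block_height_before = block_height_before,
                 block_height_after = block_height_after,
                 sections_cut_total = as.integer(sections_cut_total),
                 formalin_weight = formalin_weight,
                 paraffin_weight = paraffin_weight),
            class = "caliper_record")
}

#' Mean section thickness from block caliper measurements
#'
#' The calculated mean section thickness is the difference between the block
#' caliper measurements taken before and after sectioning, divided by the
#' total number of cut sections (sampled and discarded).
#'
#' @param caliper A [caliper_record()].
#' @return Mean section thickness t in um.
#' @examples
#' mean_section_thickness(caliper_record(10.0, 6.5, 700)) # 5 um
#' @export
mean_section_thickness <- function(caliper) {
  stopifnot(inherits(caliper, "caliper_record"))
  t_um <- (caliper$block_height_before - caliper$block_height_after) * 1000 /
    caliper$sections_cut_total
  if (t_um == 0) warn("degenerate thickness: caliper difference is zero.")
  t_um
}

#' Shrinkage index upon paraffin embedding
#'
#' The relative weight loss between the wet (formalin) block and the
#' paraffin-infiltrated block, used as an index of tissue shrinkage:
#' `(formalin - paraffin) / formalin`.
#'
#' @param caliper A [caliper_record()] with both weights recorded.
#' @return Shrinkage fraction; negative values (paraffin heavier than
#'   formalin) are returned with a warning.
#' @export
shrinkage_index <- function(caliper) {
  stopifnot(inherits(caliper, "caliper_record"))
  f <- caliper$formalin_weight; p <- caliper$paraffin_weight
  if (!is.finite(f) || f <= 0) abort("formalin weight must be a positive number.")
  if (!is.finite(p)) abort("paraffin weight must be recorded.")
  idx <- (f - p) / f
  if (idx < 0) warn("negative shrinkage index: paraffin weight exceeds formalin weight.")
  idx
}

#' Group summary of paired (ipsi- vs contralateral) number estimates
#'
#' Summarises per-animal estimates for the lesioned (ipsilateral) and intact
#' (contralateral) sides and reports the percent reduction under both
#' conventions: the per-animal paired ratio averaged over animals (default
#' convention for a within-animal lesion design), and the ratio of group
#' means. Animals with a zero contralateral estimate are excluded from the
#' paired convention with a warning.
#'
#' @param estimates Data frame with columns `n_ipsi` and `n_contra`, one row
#'   per animal.
#' @return A one-row tibble: `n`, `mean_ipsi`, `sem_ipsi`, `mean_contra`,
#'   `sem_contra`, `pct_reduction_paired` (mean over animals of
#'   `100 * (1 - n_ipsi/n_contra)`), `pct_reduction_of_means`
#'   (`100 * (1 - mean_ipsi/mean_contra)`).
#' @examples
#' group_summary(data.frame(n_ipsi = c(40, 60), n_contra = c(100, 100)))
#' @export
group_summary <- function(estimates) {
  if (!all(c("n_ipsi", "n_contra") %in% names(estimates))) {
    abort("`estimates` needs columns n_ipsi and n_contra.")
  }
  if (nrow(estimates) < 1L) abort("need at least one animal per side.")
  sem <- function(v) if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
  ok <- estimates$n_contra != 0
  if (any(!ok)) {
    warn(sprintf("%d animal(s) with zero contralateral estimate excluded from the paired reduction.",
                 sum(!ok)))
  }
  paired <- estimates[ok, , drop = FALSE]
  tibble::tibble(
    n = nrow(estimates),
    mean_ipsi = mean(estimates$n_ipsi),
    sem_ipsi = sem(estimates$n_ipsi),
    mean_contra = mean(estimates$n_contra),
    sem_contra = sem(estimates$n_contra),
    pct_reduction_paired =
      if (nrow(paired)) 100 * mean(1 - paired$n_ipsi / paired$n_contra) else NA_real_,
    pct_reduction_of_means = 100 * (1 - mean_ipsi / mean_contra)
  )
}

# Spearman rho on mid-ranks (ties averaged)
spearman_rho <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

#' Spearman rank correlation with a permutation p-value
#'
#' Computes Spearman's rho on mid-ranks (tied observations receive their
#' average rank) and a two-sided p-value under the permutation null: exact
#' enumeration of all `n!` pairings for `n <= 8`, otherwise a seeded Monte
#' Carlo permutation test.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param n_perm Number of random permutations when `n > 8` (default 10000).
#' @param seed Optional integer seed for the Monte Carlo permutations.
#' @return A one-row tibble: `rho`, `p_value`, `n`, `method` ("exact" or
#'   "permutation"). A constant input vector gives `rho = NA` with a warning
#'   (rank correlation undefined).
#' @examples
#' rank_correlation(1:5, c(2, 1, 4, 3, 5))
#' @export
rank_correlation <- function(x, y, n_perm = 10000, seed = NULL) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 3L) abort("need at least 3 paired observations.")
  if (anyNA(x) || anyNA(y)) abort("missing values are not supported.")
  rho <- spearman_rho(x, y)
  if (is.na(rho)) {
    warn("constant input vector: Spearman rho undefined.")
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n,
                          method = "undefined"))
  }
  ry <- rank(y, ties.method = "average")
  if (n <= 8L) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1L, function(p) spearman_rho(x, ry[p]))
    p_value <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    rhos <- with_seed(seed, vapply(
      seq_len(n_perm),
      function(i) spearman_rho(x, ry[sample.int(n)]),
      numeric(1)
    ))
    p_value <- (1 + sum(abs(rhos) >= abs(rho) - 1e-12)) / (n_perm + 1)
    method <- "permutation"
  }
  tibble::tibble(rho = rho, p_value = p_value, n = n, method = method)
}
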