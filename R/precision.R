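#' SURS product sums A, B, C of an ordered count series
#'
#' For per-pair disector counts `q_1, ..., q_m` taken in cutting order, the
#' systematic-sampling error prediction uses three product sums:
#' `A = sum(q_i^2)`, `B = sum(q_i * q_(i+1))`, `C = sum(q_i * q_(i+2))`.
#' The B and C sums simply have one and two fewer terms than A.
#'
#' @param q_list Ordered numeric vector of per-pair counts (cutting order),
#'   length >= 1.
#' @return Named numeric vector `c(A = , B = , C = )`.
#' @examples
#' surs_products(c(9, 30, 23, 12, 14, 6, 11, 15, 15, 14, 7, 2, 0))
#' # A = 2706, B = 2266, C = 1713
#' @export
surs_products <- function(q_list) {
  if (length(q_list) == 0L) abort("empty series: need at least one count.")
  if (anyNA(q_list)) abort("counts must not be missing.")
  m <- length(q_list)
  c(
    A = sum(q_list^2),
    B = if (m >= 2L) sum(q_list[-m] * q_list[-1L]) else 0,
    C = if (m >= 3L) sum(q_list[1:(m - 2L)] * q_list[3:m]) else 0
  )
}

#' Systematic sampling variance Var_SURS
#'
#' The between-section variance component of a systematic uniform random
#' sample, predicted from the product sums of [surs_products()]:
#' \deqn{Var_{SURS} = \frac{3(A - noise) - 4B + C}{240}}
#' where, for number estimates, the noise (nugget) term equals the total
#' count. The constant 240 reflects the smoothness class of this
#' stereological design and is configurable. Short or flat series can yield
#' a negative raw value; it is clamped to zero (with a warning) because a
#' variance prediction cannot be negative, and both values are returned.
#'
#' @param q_list Ordered per-pair counts in cutting order.
#' @param noise Nugget variance; defaults to `sum(q_list)` (number
#'   estimates).
#' @param constant Smoothness constant (default 240), > 0.
#' @return A list with `raw` (possibly negative), `value` (clamped at 0) and
#'   `clamped` (logical).
#' @examples
#' var_surs(c(9, 30, 23, 12, 14, 6, 11, 15, 15, 14, 7, 2, 0))$value # 1.22...
#' @export
var_surs <- function(q_list, noise = sum(q_list), constant = 240) {
  prods <- surs_products(q_list)
  stopifnot_scalar_number(noise, "noise", nonneg = TRUE)
  if (!is.numeric(constant) || length(constant) != 1L || constant <= 0) {
    abort("`constant` must be > 0.")
  }
  raw <- (3 * (prods[["A"]] - noise) - 4 * prods[["B"]] + prods[["C"]]) / constant
  clamped <- raw < 0
  if (clamped) {
    warn(sprintf("negative raw Var_SURS (%.4g) clamped to 0.", raw))
  }
  list(raw = raw, value = max(raw, 0), clamped = clamped)
}

#' Coefficient of error of a fractionator number estimate
#'
#' Combines the counting noise and the systematic-sampling variance into the
#' predicted coefficient of error of the number estimate:
#' \deqn{CE = \frac{\sqrt{noise + Var_{SURS}}}{\Sigma Q^-}}
#' With a flat series whose Var_SURS clamps to zero this reduces to the
#' Poisson-like `1 / sqrt(sum Q)`. Report at 2 decimals; the returned value
#' is full precision.
#'
#' @inheritParams var_surs
#' @return The CE as a fraction (full precision).
#' @examples
#' ce_number(c(9, 30, 23, 12, 14, 6, 11, 15, 15, 14, 7, 2, 0)) # 0.0799
#' @export
ce_number <- function(q_list, constant = 240) {
  total <- sum(q_list)
  if (length(q_list) == 0L) abort("empty series: need at least one count.")
  if (total <= 0) abort("undefined CE: total count is zero.")
  vs <- var_surs(q_list, noise = total, constant = constant)
  sqrt(total + vs$value) / total
}

#' Mean coefficient of error of a group
#'
#' The group-level CE is the root mean square of the individual CEs:
#' `sqrt(sum(CE_i^2) / n)`.
#'
#' @param ce_list Non-empty numeric vector of CEs, each >= 0.
#' @return The group mean CE.
#' @examples
#' mean_ce(c(0.03, 0.04)) # 0.0354
#' @export
mean_ce <- function(ce_list) {
  if (length(ce_list) == 0L) abort("empty CE list.")
  if (any(!is.finite(ce_list)) || any(ce_list < 0)) {
    abort("CEs must be finite and >= 0.")
  }
  sqrt(sum(ce_list^2) / length(ce_list))
}

#' Decompose observed group variance into sampling and biological parts
#'
#' The observed coefficient of variation of a group of estimates,
#' `CV_obs = SD/mean`, is the sum in quadrature of the biological variation
#' and the stereological sampling error:
#' `CV_obs^2 = CV_biol^2 + mean_CE^2`. The sampling design is considered
#' acceptable when its contribution `mean_CE^2 / CV_obs^2` is below 50% of
#' the total variance. When `mean_CE > CV_obs` (sampling noise alone exceeds
#' the observed spread) `CV_biol` is set to 0 and flagged.
#'
#' @param estimates Numeric vector of per-animal estimates (length >= 2).
#' @param ces Matching vector of per-animal CEs.
#' @return One-row tibble: `n`, `mean`, `sem`, `cv_obs`, `mean_ce`,
#'   `cv_biol`, `ce_variance_fraction`, `acceptable` (fraction < 0.5),
#'   `negative_cv_biol` flag.
#' @examples
#' variance_decomposition(c(9000, 10000, 11000), c(0.05, 0.05, 0.05))
#' @export
variance_decomposition <- function(estimates, ces) {
  if (length(estimates) != length(ces)) abort("`estimates` and `ces` must match.")
  if (length(estimates) < 2L) abort("need at least 2 animals.")
  m <- mean(estimates)
  if (m == 0) abort("undefined CV: mean estimate is zero.")
  cv_obs <- sd(estimates) / m
  mce <- mean_ce(ces)
  negflag <- mce > cv_obs
  cv_biol <- sqrt(max(cv_obs^2 - mce^2, 0))
  tibble::tibble(
    n = length(estimates),
    mean = m,
    sem = sd(estimates) / sqrt(length(estimates)),
    cv_obs = cv_obs,
    mean_ce = mce,
    cv_biol = cv_biol,
    ce_variance_fraction = mce^2 / cv_obs^2,
    acceptable = ce_variance_fraction < 0.5,
    negative_cv_biol = negflag
  )
}

#' One-row precision summary of a count series
#'
#' Convenience wrapper running the whole error-prediction chain on one
#' ordered count series: noise, the A/B/C product sums, raw and clamped
#' Var_SURS and the CE.
#'
#' @inheritParams var_surs
#' @return One-row tibble: `n_pairs`, `noise`, `A`, `B`, `C`,
#'   `var_surs_raw`, `var_surs`, `ce`.
#' @examples
#' precision_summary(c(9, 30, 23, 12, 14, 6, 11, 15, 15, 14, 7, 2, 0))
#' @export
precision_summary <- function(q_list, constant = 240) {
  prods <- surs_products(q_list)
  total <- sum(q_list)
  vs <- var_surs(q_list, noise = total, constant = constant)
  tibble::tibble(
    n_pairs = length(q_list),
    noise = total,
    A = prods[["A"]], B = prods[["B"]], C = prods[["C"]],
    var_surs_raw = vs$raw,
    var_surs = vs$value,
    ce = if (total > 0) sqrt(total + vs$value) / total else NA_real_
  )
}
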