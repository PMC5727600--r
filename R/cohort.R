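#' Simulate a unilateral-lesion cohort with known effect size
#'
#' Generates per-animal true and estimated neuron numbers for the intact
#' (contralateral) and lesioned (ipsilateral) side of a unilateral lesion
#' model, plus drug-induced rotation scores linked to the fractional loss.
#' Contralateral numbers are lognormal around `baseline_n` with
#' between-animal coefficient of variation `between_animal_cv`; the
#' ipsilateral number is `n_contra * (1 - effect_size)` times a mean-one
#' lognormal lesion-noise factor, so the expected per-animal fractional loss
#' equals `effect_size` exactly. Estimated numbers add mean-zero sampling
#' noise at a stereological CE of `estimate_ce`. Amphetamine rotations
#' increase linearly with fractional loss plus noise (the strong behavioural
#' readout); apomorphine rotations use a quarter of the slope (the weak
#' readout, uninformative for restricted lesions).
#'
#' @param n_animals Number of animals (default 26).
#' @param effect_size Mean fractional ipsilateral loss, in \[0, 1\]
#'   (default 0.55, a partial lesion; 0.85 emulates a full lesion).
#' @param between_animal_cv CV of the contralateral baseline across animals
#'   (default 0.25).
#' @param lesion_cv CV of the per-animal lesion-noise factor (default 0.4).
#' @param baseline_n Mean contralateral number (default 10000).
#' @param rotation_link_slope Rotations per unit fractional loss
#'   (default 500 net turns per 15 min).
#' @param rotation_noise_sd SD of the additive rotation noise (default 100).
#' @param estimate_ce Stereological CE applied as estimation noise
#'   (default 0.08).
#' @param seed Optional integer seed.
#' @return A tibble of class `lesion_cohort`: `animal_id`, `n_contra_true`,
#'   `n_ipsi_true`, `n_contra`, `n_ipsi`, `fractional_loss`,
#'   `rotations_amphetamine`, `rotations_apomorphine`.
#' @examples
#' coh <- generate_lesion_cohort(seed = 1)
#' mean(1 - coh$n_ipsi_true / coh$n_contra_true)
#' @export
generate_lesion_cohort <- function(n_animals = 26, effect_size = 0.55,
                                   between_animal_cv = 0.25, lesion_cv = 0.4,
                                   baseline_n = 10000,
                                   rotation_link_slope = 500,
                                   rotation_noise_sd = 100,
                                   estimate_ce = 0.08,
                                   seed = NULL) {
  if (!is.numeric(effect_size) || effect_size < 0 || effect_size > 1) {
    abort("`effect_size` must lie in [0, 1].")
  }
  for (nm in c("between_animal_cv", "lesion_cv")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      abort(sprintf("`%s` must be a finite non-negative CV.", nm))
    }
  }
  with_seed(seed, {
    sd_b <- sqrt(log(1 + between_animal_cv^2))
    sd_l <- sqrt(log(1 + lesion_cv^2))
    n_contra <- baseline_n * exp(rnorm(n_animals, -sd_b^2 / 2, sd_b))
    lesion_factor <- exp(rnorm(n_animals, -sd_l^2 / 2, sd_l))
    n_ipsi <- n_contra * (1 - effect_size) * lesion_factor
    loss <- 1 - n_ipsi / n_contra
    est <- function(v) pmax(0, round(v * (1 + estimate_ce * rnorm(n_animals))))
    out <- tibble::tibble(
      animal_id = seq_len(n_animals),
      n_contra_true = round(n_contra),
      n_ipsi_true = round(n_ipsi),
      n_contra = est(n_contra),
      n_ipsi = est(n_ipsi),
      fractional_loss = loss,
      rotations_amphetamine =
        pmax(0, round(rotation_link_slope * loss +
                        rnorm(n_animals, 0, rotation_noise_sd))),
      rotations_apomorphine =
        pmax(0, round(rotation_link_slope / 4 * loss +
                        rnorm(n_animals, 0, rotation_noise_sd)))
    )
    class(out) <- c("lesion_cohort", class(out))
    attr(out, "effect_size") <- effect_size
    attr(out, "seed") <- if (!is.null(seed)) as.integer(seed) else NULL
    out
  })
}
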