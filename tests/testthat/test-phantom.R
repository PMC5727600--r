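test_that("phantom generation is deterministic and respects its invariants", {
  ph <- generate_phantom(300, roi_box(c(600, 400, 300)), seed = 5)
  ph2 <- generate_phantom(300, roi_box(c(600, 400, 300)), seed = 5)
  expect_identical(ph$particles, ph2$particles)
  expect_equal(ph$true_n, 300)
  expect_true(all(ph$particles$x >= 0 & ph$particles$x <= 600))
  expect_true(all(ph$particles$z >= 0 & ph$particles$z <= 300))
  # minimum centre-to-centre separation holds
  d <- as.matrix(dist(ph$particles[, c("x", "y", "z")]))
  expect_gte(min(d[upper.tri(d)]), 2)

  empty <- generate_phantom(0, seed = 1)
  expect_equal(nrow(empty$particles), 0)

  expect_error(
    generate_phantom(100, roi_box(c(30, 30, 30)), min_separation = 25,
                     seed = 1, max_iter = 5),
    "packing"
  )
})

test_that("particles are uniform across octants of the ROI", {
  lens <- c(3000, 2000, 1200)
  totals <- rep(0, 8)
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    ph <- generate_phantom(10000, roi_box(lens), min_separation = 0, seed = s)
    oct <- 1 + (ph$particles$x > lens[1] / 2) +
      2 * (ph$particles$y > lens[2] / 2) +
      4 * (ph$particles$z > lens[3] / 2)
    totals <- totals + tabulate(oct, 8)
  }
  expected <- 10000 * n_seeds / 8
  expect_true(all(abs(totals / expected - 1) < 0.02))
})

test_that("virtual sectioning conserves particle tops and section geometry", {
  ph <- generate_phantom(400, roi_box(c(800, 500, 400)), seed = 8)
  for (t in c(3, 5, 10)) {
    secs <- virtual_sectioning(ph, t)
    expect_equal(sum(secs$is_top), ph$true_n) # each particle tops exactly once
    expect_true(all(secs$section_index >= 0 &
                      secs$section_index < attr(secs, "n_sections")))
  }

  # a 6 um sphere cut at 5 um appears in 3 or 4 consecutive sections
  # depending on centre phase
  mk <- function(cz) {
    as_phantom(data.frame(x = 50, y = 50, z = cz, r = 6),
               roi_box(c(100, 100, 100)))
  }
  spans <- vapply(seq(40, 45, by = 0.25), function(cz) {
    secs <- virtual_sectioning(mk(cz), 5, axis = "z")
    expect_equal(diff(range(secs$section_index)) + 1L, nrow(secs))
    nrow(secs)
  }, numeric(1))
  expect_true(all(spans %in% c(3, 4)))
  expect_true(any(spans == 3) && any(spans == 4))
})

test_that("profile radii follow the sphere cross-section at the slab midplane", {
  # centre placed exactly on a slab midplane: the equatorial profile radius
  # equals the sphere radius, neighbours follow sqrt(r^2 - dz^2)
  t <- 5
  ph <- as_phantom(data.frame(x = 50, y = 50, z = 42.5, r = 8),
                   roi_box(c(100, 100, 100)))
  secs <- virtual_sectioning(ph, t, axis = "z")
  a_start <- attr(secs, "a_start")
  mids <- a_start + (secs$section_index + 0.5) * t
  expected <- sqrt(pmax(8^2 - (mids - 42.5)^2, 1e-12))
  expect_equal(secs$r, expected, tolerance = 1e-9)
  expect_equal(max(secs$r), 8)
})

test_that("a census design (ssf = asf = 1) recovers the truth", {
  ph <- generate_phantom(250, roi_box(c(600, 400, 300)), seed = 11)
  d <- sampling_design(1, 50 * 50, 50, 50, 5)
  ct <- suppressWarnings(simulate_study(ph, d, seed = 3))
  est <- tidy(suppressWarnings(fractionator_estimate(ct)))
  expect_equal(est$n, 250) # exact
  expect_lt(abs(est$v_raw_mm3 / ph$roi$volume_mm3 - 1), 0.01)
})

test_that("a fractionator design is unbiased on a particle phantom", {
  ph <- generate_phantom(2000, roi_box(c(1500, 1000, 600)), seed = 4)
  d <- sampling_design(25, 60000, 387.29, 387.29, 5)
  secs <- virtual_sectioning(ph, 5)
  reps <- vapply(1:30, function(s) {
    ct <- suppressWarnings(simulate_study(ph, d, seed = s, sections = secs))
    e <- tidy(suppressWarnings(fractionator_estimate(ct)))
    c(e$n_raw, e$v_raw_mm3)
  }, numeric(2))
  se_n <- sd(reps[1, ]) / sqrt(ncol(reps))
  se_v <- sd(reps[2, ]) / sqrt(ncol(reps))
  expect_lt(abs(mean(reps[1, ]) - 2000), 3 * se_n)
  expect_lt(abs(mean(reps[2, ]) - ph$roi$volume_mm3), 3 * se_v)
})

test_that("simulation and raster ingestion agree on a section's profiles", {
  ph <- generate_phantom(40, roi_box(c(400, 300, 200)), seed = 6)
  secs <- virtual_sectioning(ph, 5)
  s <- secs[secs$section_index == secs$section_index[which.max(
    tabulate(secs$section_index + 1L))], ]
  mask <- render_section_mask(s, c(0, 0, 300, 200), pixel_size = 0.5)
  got <- profiles_from_mask(mask, pixel_size = 0.5)
  expect_equal(nrow(got), nrow(s))
  got <- got[order(got$particle_id), ]
  s <- s[order(s$particle_id), ]
  expect_equal(got$x, s$x, tolerance = 1)
  expect_equal(got$y, s$y, tolerance = 1)
  expect_equal(got$r, s$r, tolerance = 1)
})

test_that("lesion cohorts carry the designed effect size and behaviour link", {
  # no lesion: ipsilateral/contralateral ratio centred on 1
  none <- generate_lesion_cohort(n_animals = 200, effect_size = 0, seed = 2)
  expect_lt(abs(mean(none$n_ipsi_true / none$n_contra_true) - 1), 0.1)

  # partial lesion: rotations anti-correlate with the ipsilateral count
  neg <- vapply(1:200, function(s) {
    coh <- generate_lesion_cohort(n_animals = 26, effect_size = 0.55, seed = s)
    rank_correlation(coh$n_ipsi, coh$rotations_amphetamine,
                     n_perm = 10, seed = s)$rho < 0
  }, logical(1))
  expect_gte(mean(neg), 0.95)

  # full lesion: recovered group reduction close to the designed 85%
  red <- vapply(1:200, function(s) {
    coh <- generate_lesion_cohort(n_animals = 26, effect_size = 0.85, seed = s)
    group_summary(data.frame(n_ipsi = coh$n_ipsi,
                             n_contra = coh$n_contra))$pct_reduction_paired
  }, numeric(1))
  expect_lt(abs(mean(red) - 85), 3)

  expect_error(generate_lesion_cohort(effect_size = 1.2), "effect_size")
  expect_error(generate_lesion_cohort(between_animal_cv = -1), "CV")

  coh <- generate_lesion_cohort(seed = 7)
  expect_identical(coh, generate_lesion_cohort(seed = 7))
  expect_true(all(coh$n_ipsi >= 0 & coh$rotations_amphetamine >= 0))
})
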