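test_that("identical images align at the identity with similarity 1", {
  img <- make_section_image(1, size = 128)
  tf <- align_pair(img, img)
  expect_equal(c(tf$dx, tf$dy, tf$theta), c(0, 0, 0))
  expect_equal(tf$similarity, 1, tolerance = 1e-12)
  expect_true(tf$confidence)
  expect_identical(tf$source, "automatic")
})

test_that("a known integer shift is recovered to the pixel", {
  ref <- make_section_image(2, size = 128)
  look <- shift_image(ref, -12, 7) # lookup displaced by (-12, +7)
  tf <- align_pair(ref, look, max_shift = 20)
  expect_equal(tf$dx, 12)
  expect_equal(tf$dy, -7)
  expect_equal(tf$theta, 0)
  expect_gt(tf$similarity, 0.8)
})

test_that("independent noise images fail the confidence check", {
  set.seed(5)
  a <- matrix(runif(64 * 64), 64)
  b <- matrix(runif(64 * 64), 64)
  expect_warning(tf <- align_pair(a, b, max_shift = 10), "confidence")
  expect_false(tf$confidence)
})

test_that("empty or constant images raise a no-signal error", {
  flat <- matrix(0, 64, 64)
  img <- make_section_image(3, size = 64)
  expect_error(align_pair(flat, img), "no signal")
  expect_error(align_pair(img, flat), "no signal")
})

test_that("a transform composed with its inverse is the identity", {
  set.seed(9)
  pts <- cbind(runif(50, -200, 200), runif(50, -200, 200))
  for (i in 1:10) {
    tf <- rigid_transform(dx = runif(1, -30, 30), dy = runif(1, -30, 30),
                          theta = runif(1, -45, 45), center = runif(2, -50, 50))
    back <- apply_transform(apply_transform(pts, tf), invert_transform(tf))
    expect_equal(back, pts, tolerance = 1e-9)
  }
})

test_that("manual override replaces the transform and is audited", {
  ref <- data.frame(particle_id = 1:3, x = c(20, 50, 80), y = c(30, 60, 20), r = 4)
  lkp <- ref[1:2, ]
  pair <- section_pair(ref, lkp)
  ident <- rigid_transform(0, 0, 0)
  expect_message(pair2 <- apply_manual_override(pair, ident, operator = "kf"),
                 "manual override by kf")
  expect_identical(pair2$transform$source, "manual")
  expect_match(attr(pair2, "audit"), "kf")
  f <- counting_frame(0, 0, 100, 100)
  expect_equal(disector_count(pair2, f), disector_count(pair, f))
  bad <- ident
  bad$dx <- NaN
  expect_error(apply_manual_override(pair, bad), "finite")
})

test_that("manual and automatic alignment give the same counts", {
  # lookup profiles displaced by a known shift; recovering it automatically
  # from rendered masks or supplying it manually must count identically
  set.seed(21)
  ref <- data.frame(particle_id = 1:20, x = runif(20, 30, 220),
                    y = runif(20, 30, 220), r = 6)
  keep <- sample(20, 12)
  true_shift <- c(-9, 13)
  lkp <- ref[keep, ]
  lkp$x <- lkp$x - true_shift[1]
  lkp$y <- lkp$y - true_shift[2]

  ref_img <- (render_section_mask(ref, c(0, 0, 256, 256), 1) > 0) * 1
  lkp_img <- (render_section_mask(lkp, c(0, 0, 256, 256), 1) > 0) * 1
  auto <- align_pair(ref_img, lkp_img, max_shift = 20)
  expect_equal(c(auto$dx, auto$dy), true_shift)

  d <- sampling_design(1, 64 * 64, 64, 64, 5)
  g <- surs_grid(c(0, 0, 256, 256), d, seed = 2, expand = 80)
  auto_tf <- rigid_transform(auto$dx, auto$dy, auto$theta, source = "manual")
  manual_tf <- rigid_transform(true_shift[1], true_shift[2], 0)
  q_auto <- disector_count(section_pair(ref, lkp, transform = auto_tf), g)
  pair_manual <- suppressMessages(
    apply_manual_override(section_pair(ref, lkp), manual_tf)
  )
  q_manual <- disector_count(pair_manual, g)
  expect_equal(q_auto, q_manual)
  # and both match the co-registered ground truth
  q_truth <- disector_count(section_pair(ref, ref[keep, ]), g)
  expect_equal(sum(q_manual$q_forward) + sum(q_manual$q_reverse),
               sum(q_truth$q_forward) + sum(q_truth$q_reverse))
})
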