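test_that("frame decision follows the inclusion/exclusion rule", {
  f <- counting_frame(0, 0, 100, 100)
  dec <- function(x, y, r) frame_decision(data.frame(x = x, y = y, r = r), f)

  expect_true(dec(50, 50, 5))     # strictly inside, touching nothing
  expect_false(dec(0, 50, 5))     # touching the left exclusion edge
  expect_false(dec(50, 0, 5))     # touching the bottom exclusion edge
  expect_true(dec(50, 100, 5))    # touching the top inclusion edge
  expect_true(dec(100, 50, 5))    # touching the right inclusion edge
  expect_false(dec(300, 300, 5))  # entirely outside frame and extensions
  # infinite extensions: above the top-left corner, below the bottom-right
  expect_false(dec(0, 150, 5))
  expect_false(dec(98, -2, 5))
  # profile overlapping the frame through the top but touching the upward
  # left extension is excluded
  expect_false(dec(2, 101, 5))
})

test_that("an exhaustive frame tiling counts every disc exactly once", {
  set.seed(77)
  d <- sampling_design(1, 100 * 100, 100, 100, 5)
  prof <- data.frame(x = runif(300, 0, 700), y = runif(300, 0, 500),
                     r = runif(300, 0, 20))
  g <- surs_grid(c(0, 0, 700, 500), d, seed = 5, expand = 130)
  times_counted <- rep(0, nrow(prof))
  for (k in seq_len(nrow(g$frames))) {
    times_counted <- times_counted + frame_decision(prof, g$frames[k, ])
  }
  expect_true(all(times_counted == 1))
})

test_that("disector counting applies the reference/lookup rule both ways", {
  f <- counting_frame(0, 0, 100, 100)
  p <- function(ids, xs, ys) {
    data.frame(particle_id = ids, x = xs, y = ys, r = rep(4, length(ids)))
  }

  same <- section_pair(p(1:3, c(20, 50, 70), c(30, 50, 60)),
                       p(1:3, c(20, 50, 70), c(30, 50, 60)))
  res <- disector_count(same, f)
  expect_equal(sum(res$q_forward) + sum(res$q_reverse), 0)

  one <- section_pair(p(1, 50, 50), p(integer(0), numeric(0), numeric(0)))
  res <- disector_count(one, f)
  expect_equal(c(sum(res$q_forward), sum(res$q_reverse)), c(1, 0))

  # reference {P1, P2}, lookup {P2, P3}: forward counts P1, reverse counts P3
  pair <- section_pair(p(1:2, c(30, 60), c(40, 40)), p(2:3, c(60, 80), c(40, 55)))
  res <- disector_count(pair, f)
  expect_equal(c(sum(res$q_forward), sum(res$q_reverse)), c(1, 1))

  # symmetry: swapping reference and lookup swaps the directions
  swapped <- disector_count(section_pair(p(2:3, c(60, 80), c(40, 55)),
                                         p(1:2, c(30, 60), c(40, 40))), f)
  expect_equal(sum(swapped$q_forward), sum(res$q_reverse))
  expect_equal(sum(swapped$q_reverse), sum(res$q_forward))
})

test_that("centroid matching is used when particle ids are unavailable", {
  f <- counting_frame(0, 0, 100, 100)
  ref <- data.frame(x = c(30, 60), y = c(40, 40), r = 4)
  lkp <- data.frame(x = c(31, 90), y = c(40.5, 80), r = 4)
  res <- disector_count(section_pair(ref, lkp), f, r_match = 4)
  # ref(30,40) matches lkp(31,40.5); ref(60,40) and lkp(90,80) are unmatched
  expect_equal(c(sum(res$q_forward), sum(res$q_reverse)), c(1, 1))
})

test_that("total Q is invariant under a common rigid motion of both sections", {
  set.seed(12)
  d <- sampling_design(1, 80 * 80, 80, 80, 5)
  ref <- data.frame(particle_id = 1:25, x = runif(25, 0, 400),
                    y = runif(25, 0, 300), r = 5)
  keep <- sample(25, 15)
  lkp <- ref[keep, ]
  total_q <- function(ref, lkp) {
    bb <- c(min(ref$x, lkp$x), min(ref$y, lkp$y),
            max(ref$x, lkp$x), max(ref$y, lkp$y))
    g <- surs_grid(bb, d, seed = 3, expand = 100)
    res <- disector_count(section_pair(ref, lkp), g)
    sum(res$q_forward) + sum(res$q_reverse)
  }
  tf <- rigid_transform(dx = 37.5, dy = -12.25, theta = 23, center = c(200, 150))
  move <- function(df) {
    xy <- apply_transform(cbind(df$x, df$y), tf)
    df$x <- xy[, 1]; df$y <- xy[, 2]
    df
  }
  expect_equal(total_q(ref, lkp), total_q(move(ref), move(lkp)))
})

test_that("tally_counts aggregates frames to pairs and preserves order", {
  # bidirectional per-pair totals of the worked example sum to 158
  per_pair <- data.frame(pair_index = seq_along(table2_q),
                         q_forward = table2_q, q_reverse = 0)
  ct <- tally_counts(per_pair)
  expect_s3_class(ct, "count_table")
  expect_equal(sum(ct$q), 158)
  expect_equal(ct$pair_index, seq_along(table2_q))

  empty <- tally_counts(data.frame(pair_index = integer(0),
                                   q_forward = integer(0),
                                   q_reverse = integer(0)))
  expect_equal(sum(empty$q), 0)

  single <- tally_counts(data.frame(pair_index = 1, q_forward = 3, q_reverse = 2))
  expect_equal(single$q, 5)
})
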