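test_that("fractionator number estimates reproduce the worked examples", {
  # bidirectional counts with the printed design constants 1/ssf = 50,
  # 1/asf = 2.50
  expect_equal(round_half_away(estimate_total_number(159, 50, 2.50)), 9938)
  expect_equal(round_half_away(estimate_total_number(180, 50, 2.50)), 11250)
  expect_equal(round_half_away(estimate_total_number(172, 50, 2.50)), 10750)
  expect_equal(estimate_total_number(0, 50, 2.50), 0)
  # unidirectional counting skips the division by two
  expect_equal(estimate_total_number(100, 10, 2, bidirectional = FALSE), 2000)
  expect_error(estimate_total_number(-1, 50, 2.5), ">= 0")
})

test_that("the number estimate is linear in the total count", {
  for (q in c(1, 17, 158, 1000)) {
    expect_equal(estimate_total_number(2 * q, 50, 2.49989),
                 2 * estimate_total_number(q, 50, 2.49989))
  }
})

test_that("point-counting volume estimates reproduce the worked examples", {
  expect_equal(round(estimate_volume(181, 387.29, 387.29, 5, 50), 2), 6.79)
  expect_equal(round(estimate_volume(147, 387.29, 387.29, 5, 50), 2), 5.51)
  expect_equal(estimate_volume(0, 387.29, 387.29, 5, 50), 0)
  expect_error(estimate_volume(10, 387.29, 387.29, 0, 50), "> 0")
  # unit round trip: V in mm^3 equals the um^3 product scaled by 1e-9
  expect_equal(estimate_volume(7, 100, 200, 5, 10),
               7 * 100 * 200 * 5 * 10 / 1e9)
})

test_that("mean section thickness comes from the caliper difference", {
  expect_equal(mean_section_thickness(caliper_record(10.0, 6.5, 700)), 5)
  expect_equal(round(mean_section_thickness(caliper_record(10.0, 6.4975, 700)), 4),
               5.0036)
  expect_warning(t0 <- mean_section_thickness(caliper_record(8, 8, 700)),
                 "degenerate")
  expect_equal(t0, 0)
  expect_error(caliper_record(6.0, 6.5, 700), "measurement order")
})

test_that("shrinkage index is the relative weight loss", {
  expect_equal(shrinkage_index(caliper_record(10, 6, 700, 2.0, 2.0)), 0)
  expect_equal(shrinkage_index(caliper_record(10, 6, 700, 2.0, 1.5)), 0.25)
  expect_warning(s <- shrinkage_index(caliper_record(10, 6, 700, 2.0, 2.2)),
                 "negative")
  expect_lt(s, 0)
  expect_error(shrinkage_index(caliper_record(10, 6, 700, 0, 1)), "positive")
})

test_that("group summaries report both percent-reduction conventions", {
  one <- group_summary(data.frame(n_ipsi = 45, n_contra = 100))
  expect_equal(one$pct_reduction_paired, 55)
  expect_equal(one$pct_reduction_of_means, 55)

  same <- group_summary(data.frame(n_ipsi = c(80, 90), n_contra = c(80, 90)))
  expect_equal(same$pct_reduction_paired, 0)

  two <- group_summary(data.frame(n_ipsi = c(40, 60), n_contra = c(100, 100)))
  expect_equal(two$pct_reduction_paired, 50)
  expect_equal(two$pct_reduction_of_means, 50)

  expect_warning(
    zero <- group_summary(data.frame(n_ipsi = c(40, 60), n_contra = c(100, 0))),
    "zero contralateral"
  )
  expect_equal(zero$pct_reduction_paired, 60)
})

test_that("Spearman rho matches the base-R mid-rank computation", {
  expect_equal(rank_correlation(1:6, (1:6)^2)$rho, 1)
  expect_equal(rank_correlation(1:6, -(1:6))$rho, -1)
  set.seed(31)
  for (i in 1:20) {
    x <- sample(0:5, 9, replace = TRUE) # ties likely
    y <- sample(0:5, 9, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(rank_correlation(x, y, n_perm = 10, seed = 1)$rho,
                 cor(x, y, method = "spearman"))
  }
})

test_that("the exact permutation p-value equals an exhaustive oracle", {
  x <- c(3, 1, 4, 1, 5)
  y <- c(2, 7, 1, 8, 2)
  res <- rank_correlation(x, y)
  expect_identical(res$method, "exact")

  # independent enumeration with its own rank-covariance formula
  rx <- rank(x); ry <- rank(y)
  rho_of <- function(a, b) {
    a <- a - mean(a); b <- b - mean(b)
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  rhos <- vapply(oracle_perms(seq_along(y)), function(p) rho_of(rx, ry[p]),
                 numeric(1))
  expect_equal(res$rho, rho_of(rx, ry), tolerance = 1e-12)
  expect_equal(res$p_value, mean(abs(rhos) >= abs(res$rho) - 1e-12),
               tolerance = 1e-12)
})

test_that("degenerate correlation inputs are flagged", {
  expect_warning(res <- rank_correlation(c(1, 1, 1, 1), c(1, 2, 3, 4)),
                 "constant")
  expect_true(is.na(res$rho))
  expect_error(rank_correlation(1:3, 1:4), "equal length")
  expect_error(rank_correlation(1:2, 2:1), "at least 3")
})
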