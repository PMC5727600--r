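test_that("SURS product sums reproduce the worked example", {
  prods <- surs_products(table2_q)
  expect_equal(unname(prods), c(2706, 2266, 1713))
  expect_equal(unname(surs_products(rep(0, 6))), c(0, 0, 0))
  expect_equal(unname(surs_products(c(1, 1, 1, 1))), c(4, 3, 2))
  expect_error(surs_products(numeric(0)), "empty")
})

test_that("product sums equal a brute-force double loop", {
  brute <- function(q) {
    m <- length(q)
    A <- 0; B <- 0; C <- 0
    for (i in seq_len(m)) {
      A <- A + q[i] * q[i]
      if (i + 1 <= m) B <- B + q[i] * q[i + 1]
      if (i + 2 <= m) C <- C + q[i] * q[i + 2]
    }
    c(A = A, B = B, C = C)
  }
  set.seed(99)
  for (i in 1:30) {
    q <- sample(0:100, sample(1:50, 1), replace = TRUE)
    expect_equal(surs_products(q), brute(q))
  }
})

test_that("Var_SURS reproduces the worked example and clamps at zero", {
  vs <- var_surs(table2_q)
  expect_equal(round(vs$value, 2), 1.22)
  expect_equal(vs$raw, (3 * (2706 - 158) - 4 * 2266 + 1713) / 240)
  expect_false(vs$clamped)

  expect_equal(var_surs(rep(0, 5), noise = 0)$value, 0)

  expect_warning(flat <- var_surs(c(1, 1, 1, 1)), "clamped")
  expect_equal(flat$raw, (3 * (4 - 4) - 4 * 3 + 2) / 240) # -0.0417
  expect_equal(flat$value, 0)
  expect_true(flat$clamped)

  expect_error(var_surs(table2_q, constant = 0), "constant")
})

test_that("CE combines noise and Var_SURS as in the worked example", {
  expect_equal(round(ce_number(table2_q), 2), 0.08)
  # flat series with clamped Var_SURS and total 100: CE = 1/sqrt(100)
  flat100 <- rep(5, 20)
  expect_warning(ce <- ce_number(flat100), "clamped")
  expect_equal(ce, 0.10)
  expect_error(ce_number(rep(0, 4)), "undefined CE")

  # composition oracle: CE recomposed by hand from its parts
  q <- rep(1, 158)
  expect_warning(ce <- ce_number(q))
  prods <- surs_products(q)
  raw <- (3 * (prods[["A"]] - sum(q)) - 4 * prods[["B"]] + prods[["C"]]) / 240
  expect_equal(ce, sqrt(sum(q) + max(raw, 0)) / sum(q), tolerance = 1e-12)
})

test_that("CE strictly decreases when counts are scaled up in shape", {
  set.seed(7)
  for (i in 1:10) {
    q <- sample(1:40, 12, replace = TRUE)
    ce1 <- suppressWarnings(ce_number(q))
    for (k in c(2L, 5L)) {
      expect_lt(suppressWarnings(ce_number(k * q)), ce1)
    }
  }
})

test_that("group mean CE is the root mean square", {
  expect_equal(mean_ce(c(0.08, 0.08)), 0.08)
  expect_equal(mean_ce(0.05), 0.05)
  expect_equal(round(mean_ce(c(0.03, 0.04)), 4), 0.0354)
  expect_error(mean_ce(numeric(0)), "empty")
})

test_that("variance decomposition applies the 50%-of-variance rule", {
  # estimates with CV_obs = 0.10 and mean CE = 0.05
  est <- c(90, 100, 110)
  est <- est * 0.10 / (sd(est) / mean(est)) # exact CV 0.10
  res <- variance_decomposition(est, rep(0.05, 3))
  expect_equal(res$cv_obs, 0.10)
  expect_equal(round(res$cv_biol, 4), 0.0866)
  expect_equal(res$ce_variance_fraction, 0.25)
  expect_true(res$acceptable)

  res2 <- variance_decomposition(est, rep(res$cv_obs, 3))
  expect_equal(res2$cv_biol, 0)
  expect_equal(res2$ce_variance_fraction, 1)
  expect_false(res2$acceptable)

  res3 <- variance_decomposition(est, rep(0.5, 3))
  expect_equal(res3$cv_biol, 0)
  expect_true(res3$negative_cv_biol)

  expect_error(variance_decomposition(c(0, 0), c(0.1, 0.1)), "undefined CV")
})

test_that("precision_summary runs the whole chain consistently", {
  ps <- precision_summary(table2_q)
  expect_equal(ps$noise, 158)
  expect_equal(c(ps$A, ps$B, ps$C), c(2706, 2266, 1713))
  expect_equal(round(ps$var_surs, 2), 1.22)
  expect_equal(round(ps$ce, 2), 0.08)
  expect_equal(ps$ce, sqrt(ps$noise + ps$var_surs) / ps$noise, tolerance = 1e-12)
})
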