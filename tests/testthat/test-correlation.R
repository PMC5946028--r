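test_that("rank correlation handles monotone, reversed, tied and constant input", {
  r <- cor_spearman(c(1, 2, 3), c(10, 20, 30))
  expect_equal(r$coefficient, 1)
  expect_equal(r$p_two_sided, 0)
  expect_equal(cor_spearman(c(1, 2, 3), c(30, 20, 10))$coefficient, -1)

  # midrank tie handling equals Pearson of brute-force midranks
  x <- c(1, 1, 2, 3); y <- c(2, 1, 4, 4)
  expect_equal(cor_spearman(x, y)$coefficient,
               brute_pearson(brute_midrank(x), brute_midrank(y)))

  const <- cor_spearman(c(2, 2, 2), c(1, 5, 9))
  expect_true(is.na(const$coefficient))
  expect_equal(const$flag, "constant_input")

  # invariance under strictly monotone transforms, including with ties
  set.seed(21)
  for (i in 1:10) {
    a <- sample(0:5, 15, replace = TRUE)
    b <- rnorm(15)
    r0 <- cor_spearman(a, b)$coefficient
    expect_equal(cor_spearman(exp(a), b)$coefficient, r0)
    expect_equal(cor_spearman(a, b^3)$coefficient, r0)
  }
})

test_that("Pearson matches the textbook formula and is symmetric", {
  x <- 1:10
  expect_equal(cor_pearson(x, 2 * x + 1)$coefficient, 1)
  expect_equal(cor_pearson(x, 2 * x + 1)$p_two_sided, 0)

  # constructed zero-covariance sample
  x0 <- c(-2, -1, 0, 1, 2)
  y0 <- c(4, 1, 0, 1, 4)
  expect_equal(cor_pearson(x0, y0)$coefficient, 0)

  set.seed(22)
  for (i in 1:10) {
    a <- rnorm(20); b <- rnorm(20)
    ra <- cor_pearson(a, b)
    expect_equal(ra$coefficient, brute_pearson(a, b))
    rb <- cor_pearson(b, a)
    expect_equal(rb$coefficient, ra$coefficient)
    expect_equal(rb$p_two_sided, ra$p_two_sided)
    expect_true(abs(ra$coefficient) <= 1)
    expect_true(ra$p_two_sided >= 0 && ra$p_two_sided <= 1)
    rs <- cor_spearman(a, b)
    expect_equal(cor_spearman(b, a)$coefficient, rs$coefficient)
  }
})

test_that("weighted Pearson reduces to unweighted and replicates integer weights", {
  set.seed(23)
  x <- rnorm(30); y <- x + rnorm(30)
  rw <- cor_weighted_pearson(x, y, rep(2.5, 30))
  expect_equal(rw$coefficient, cor_pearson(x, y)$coefficient,
               tolerance = 1e-12)

  for (i in 1:5) {
    a <- rnorm(25); b <- rnorm(25)
    w <- sample(0:6, 25, replace = TRUE); w[1] <- max(w, 1)
    keep <- w > 0
    rep_x <- rep(a[keep], w[keep]); rep_y <- rep(b[keep], w[keep])
    expect_equal(cor_weighted_pearson(a, b, w)$coefficient,
                 brute_pearson(rep_x, rep_y), tolerance = 1e-12)
    expect_equal(cor_weighted_pearson(a, b, w)$n, sum(w))
  }

  # weight concentrated on an exactly linear subset drives r to 1
  x2 <- c(1, 2, 3, 4, 10, -3)
  y2 <- c(2, 4, 6, 8, 1, 7)
  w2 <- c(1, 1, 1, 1, 1e-9, 1e-9)
  expect_gt(cor_weighted_pearson(x2, y2, w2)$coefficient, 0.999)

  expect_error(cor_weighted_pearson(x2, y2, c(-1, 1, 1, 1, 1, 1)), "negative")
  one_pt <- cor_weighted_pearson(x2, y2, c(1, 0, 0, 0, 0, 0))
  expect_true(is.na(one_pt$coefficient))
  expect_equal(one_pt$flag, "degenerate_weights")

  # normalized weights keep the coefficient, change the effective n
  rn <- cor_weighted_pearson(x2, y2, c(5, 5, 5, 5, 5, 5),
                             normalize_weights = TRUE)
  expect_equal(rn$n, 6)
})

test_that("attenuation correction divides by the geometric mean reliability", {
  expect_equal(attenuation_correct(0.45, 0.9, 0.9)$corrected, 0.5)
  expect_equal(attenuation_correct(c(0.2, 0.4), 1, 1)$corrected, 0.3)
  oor <- attenuation_correct(0.9, 0.5, 0.5)
  expect_equal(oor$corrected, 1.8)  # reported as-is, not clipped
  expect_equal(oor$flag, "out_of_range")
  expect_error(attenuation_correct(0.4, 0, 0.9), "non-positive")
})

test_that("attenuation correction recovers a simulated latent correlation", {
  corrected <- raw <- numeric(20)
  for (s in 1:20) {
    st <- simulate_reliability_study(500, rho = 0.6, reliability = 0.85,
                                     seed = 1000 + s)
    rc <- replicate_correction(st$x[, 1], st$x[, 2], st$y[, 1], st$y[, 2],
                               method = "pearson")
    raw[s] <- rc$corrected$raw_mean
    corrected[s] <- rc$corrected$corrected
  }
  expect_equal(mean(raw), 0.6 * 0.85, tolerance = 0.05)  # depressed raw
  expect_lt(abs(mean(corrected) - 0.6), 0.05)            # recovered latent
})

test_that("Mann-Whitney U matches brute-force pair counting", {
  sep <- mann_whitney_u(c(5, 6), c(1, 2))
  expect_equal(unname(sep$u_statistic), 4)  # n1*n2, complete separation
  tie <- mann_whitney_u(c(3, 3), c(3, 3))
  expect_equal(unname(tie$u_statistic), 2)  # n1*n2/2, all ties
  expect_equal(tie$p_two_sided, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "empty")

  set.seed(24)
  for (i in 1:20) {
    a <- sample(0:10, sample(2:40, 1), replace = TRUE)
    b <- sample(0:10, sample(2:40, 1), replace = TRUE)
    got <- mann_whitney_u(a, b)
    expect_equal(unname(got$u_statistic), brute_u(a, b))
    expect_true(got$u_statistic >= 0 &&
                  got$u_statistic <= length(a) * length(b))
    expect_true(got$p_two_sided >= 0 && got$p_two_sided <= 1)
    expect_equal(got$mean_a, mean(a))
    expect_equal(got$sem_a, sd(a) / sqrt(length(a)))
  }
})
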