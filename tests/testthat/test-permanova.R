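test_that("univariate balanced pseudo-F equals the classical ANOVA F", {
  withr::with_seed(21, {
    for (i in 1:5) {
      d <- tibble::tibble(g = rep(letters[1:3], each = 4), y = rnorm(12))
      f_cls <- anova(stats::lm(y ~ g, data = d))$`F value`[1]
      fit <- permanova(d, y, ~g, permutations = 99, seed = 1)
      expect_equal(tidy(fit)$pseudo_f, f_cls, tolerance = 1e-10)
    }
  })
})

test_that("a constant response is guarded: F = 0, p = 1", {
  d <- tibble::tibble(g = rep(c("a", "b"), each = 3), y = 5)
  fit <- permanova(d, y, ~g)
  expect_equal(tidy(fit)$pseudo_f, 0)
  expect_equal(tidy(fit)$p_perm, 1)
  expect_equal(tidy(fit)$p_mc, 1)
})

test_that("small two-group designs are enumerated with the right distinct count", {
  withr::with_seed(3, {
    d <- tibble::tibble(g = rep(c("a", "b"), each = 3), y = rnorm(6))
  })
  fit <- permanova(d, y, ~g)
  tt <- tidy(fit)
  expect_equal(tt$unique_permutations, 10) # C(6,3)/2 distinct relabelings
  expect_equal(tt$method, "enumerated")
  # enumeration is bit-exact reproducible (no randomness involved)
  expect_identical(tt$p_perm, tidy(permanova(d, y, ~g))$p_perm)
  # 3 + 4 groups give 35 distinct relabelings
  withr::with_seed(4, {
    d2 <- tibble::tibble(g = rep(c("a", "b"), c(3, 4)), y = rnorm(7))
  })
  expect_equal(tidy(permanova(d2, y, ~g))$unique_permutations, 35)
})

test_that("sampled permutation p-values are reproducible under a seed", {
  withr::with_seed(5, {
    d <- tibble::tibble(g = rep(letters[1:3], each = 6), y = rnorm(18),
      z = rnorm(18))
  })
  p1 <- tidy(permanova(d, c(y, z), ~g, permutations = 199, seed = 42))$p_perm
  p2 <- tidy(permanova(d, c(y, z), ~g, permutations = 199, seed = 42))$p_perm
  expect_identical(p1, p2)
})

test_that("raw-response and distance-matrix routes agree (Gower identity)", {
  withr::with_seed(6, {
    d <- tibble::tibble(
      a = rep(c("x", "y"), each = 6),
      b = rep(rep(c("u", "v"), each = 3), 2),
      r1 = rnorm(12), r2 = rnorm(12), r3 = rnorm(12)
    )
  })
  f1 <- permanova(d, c(r1, r2, r3), ~ a * b, permutations = 49, seed = 1)
  f2 <- permanova(d, formula = ~ a * b, permutations = 49, seed = 1,
    distance = dist(d[, c("r1", "r2", "r3")]))
  expect_equal(tidy(f1)$pseudo_f, tidy(f2)$pseudo_f, tolerance = 1e-10)
  expect_equal(tidy(f1)$ss, tidy(f2)$ss, tolerance = 1e-10)

  # and both agree with the direct cross-product partition of the response
  y <- as.matrix(d[, c("r1", "r2", "r3")])
  contr <- list(a = stats::contr.sum, b = stats::contr.sum)
  dd <- as.data.frame(d)
  dd$a <- factor(dd$a); dd$b <- factor(dd$b)
  x <- stats::model.matrix(~ a * b, dd, contrasts.arg = contr)
  part <- spongeflux:::ss_partition_response(y, x, attr(x, "assign"), 1:3)
  expect_equal(part$ss, tidy(f1)$ss, tolerance = 1e-10)
})

test_that("one-factor multivariate pseudo-F matches an independent implementation", {
  skip_if_not_installed("vegan")
  withr::with_seed(8, {
    d <- tibble::tibble(g = rep(letters[1:3], each = 5),
      y1 = rnorm(15), y2 = rnorm(15), y3 = rnorm(15))
  })
  ours <- tidy(permanova(d, c(y1, y2, y3), ~g, permutations = 49, seed = 1))
  ref <- vegan::adonis2(d[, c("y1", "y2", "y3")] ~ g, data = d,
    permutations = 9, method = "euclidean")
  expect_equal(ours$pseudo_f, ref$F[1], tolerance = 1e-10)
  expect_equal(ours$ss, ref$SumOfSqs[1], tolerance = 1e-10)
})

test_that("a single-level factor raises a structured design error", {
  d <- tibble::tibble(g = "a", y = rnorm(4))
  expect_error(permanova(d, y, ~g), class = "spongeflux_error_design")
})

test_that("pairwise t equals the pooled-variance two-sample t", {
  withr::with_seed(9, {
    d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 5), y = rnorm(15))
  })
  pw <- pairwise_permanova(d, y, "g", permutations = 99, seed = 1)
  for (i in seq_len(nrow(pw))) {
    sub <- d[d$g %in% c(pw$level_1[i], pw$level_2[i]), ]
    t_ref <- stats::t.test(y ~ g, data = sub, var.equal = TRUE)$statistic
    expect_equal(pw$t[i], abs(unname(t_ref)), tolerance = 1e-8)
  }
  # scale invariance of the statistic
  d2 <- dplyr::mutate(d, y = 1000 * y)
  pw2 <- pairwise_permanova(d2, y, "g", permutations = 99, seed = 1)
  expect_equal(pw2$t, pw$t, tolerance = 1e-8)
  # identical groups: t = 0, p_mc = 1
  d3 <- tibble::tibble(g = rep(c("a", "b"), each = 3), y = rep(1:3, 2))
  pw3 <- pairwise_permanova(d3, y, "g")
  expect_equal(pw3$t, 0)
  expect_equal(pw3$p_mc, 1)
})

test_that("pairs with a single observation per level are skipped with a warning", {
  d <- tibble::tibble(g = rep(c("a", "b", "c"), c(1, 3, 3)), y = rnorm(7))
  ws <- testthat::capture_warnings(pw <- pairwise_permanova(d, y, "g"))
  expect_length(ws, 2) # both pairs involving the singleton level
  expect_match(ws, "Skipping", all = TRUE)
  expect_equal(nrow(pw), 1) # only b vs c survives
})

test_that("Welch's t matches its closed form and handles degeneracy", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 4, 6, 9)
  got <- welch_t(x, y)
  # independent closed-form evaluation
  se2 <- stats::var(x) / 4 + stats::var(y) / 4
  t_ref <- (mean(x) - mean(y)) / sqrt(se2)
  df_ref <- se2^2 / ((stats::var(x) / 4)^2 / 3 + (stats::var(y) / 4)^2 / 3)
  expect_equal(got$t, t_ref, tolerance = 1e-10)
  expect_equal(got$df, df_ref, tolerance = 1e-10)
  expect_equal(got$p_value, 2 * stats::pt(-abs(t_ref), df_ref),
    tolerance = 1e-10)
  # x == y: t = 0, p = 1
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  # equal variances and equal n: Satterthwaite df -> 2n - 2
  withr::with_seed(10, {
    a <- rnorm(20); b <- a + 0.5 # identical spread
  })
  expect_equal(welch_t(a, b)$df, 38, tolerance = 1e-6)
  # constant equal samples are guarded
  const <- welch_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(const$p_value, 1)
  expect_error(welch_t(1, c(1, 2)), class = "spongeflux_error_design")
})
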