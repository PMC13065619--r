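test_that("the two-food worked examples reproduce exactly", {
  # orthogonal foods: the fat composition is matched exactly
  fit1 <- fit_diet(toy_fat(), vertex_foods(), step = 0.01)
  expect_equal(fit1$diet, c(food1 = 0.38, food2 = 0.62))
  expect_equal(fit1$bmd, 0)
  # overlapping foods, fat outside their span: all weight on food 2
  fit2 <- fit_diet(toy_fat(), overlap_foods(), step = 0.01)
  expect_equal(fit2$diet, c(food1 = 0, food2 = 1))
  expect_equal(fit2$bmd, 44)
  expect_equal(summed_abs_deviation(c("16:0" = 60, "18:1" = 40), toy_fat()), 44)
})

test_that("predict_fat_signature mixes, calibrates and rescales correctly", {
  M <- vertex_foods()
  expect_equal(predict_fat_signature(c(food1 = 0.38, food2 = 0.62), M),
               c("16:0" = 38, "18:1" = 62))
  # 100% of one food returns that food's signature
  expect_equal(predict_fat_signature(c(food1 = 1, food2 = 0), M),
               c("16:0" = 100, "18:1" = 0))
  # doubling one coefficient (before rescaling) raises that acid's share
  # and lowers every other share
  M3 <- toy_sources()
  p <- c(a = 0.5, b = 0.3, c = 0.2)
  base <- predict_fat_signature(p, M3, total = 100)
  cc <- c("16:0" = 2, "18:1" = 1, "18:2" = 1)
  boosted <- predict_fat_signature(p, M3, cc = cc, total = 100)
  expect_gt(boosted["16:0"], base["16:0"])
  expect_lt(boosted["18:1"], base["18:1"])
  expect_lt(boosted["18:2"], base["18:2"])
  expect_error(predict_fat_signature(c(nope = 1), M), "unknown source")
  expect_error(predict_fat_signature(p, M3, cc = c("16:0" = 1, "18:1" = 1)),
               "missing")
})

test_that("summed_abs_deviation is symmetric, zero at equality, strict on subsets", {
  a <- c("16:0" = 10, "18:1" = 30)
  b <- c("16:0" = 14, "18:1" = 22)
  expect_equal(summed_abs_deviation(a, b), 12)
  expect_equal(summed_abs_deviation(b, a), 12)
  expect_equal(summed_abs_deviation(a, a), 0)
  expect_error(summed_abs_deviation(a, c("16:0" = 10, "18:2" = 30)),
               "different fatty-acid subsets")
})

test_that("pearson_r_squared matches the textbook covariance formula", {
  obs <- c("16:0" = 10, "18:1" = 30, "18:2" = 25)
  expect_equal(pearson_r_squared(2 * obs, obs), 1)
  # predictor whose centered vector is orthogonal to centered obs
  x <- c(-1, -3, 4)  # sum(x) = 0 and x . obs = 0
  pred <- as_signature(stats::setNames(50 + x, names(obs)))
  expect_equal(pearson_r_squared(pred, obs), 0, tolerance = 1e-12)
  set.seed(5)
  for (i in 1:10) {
    p <- as_signature(stats::setNames(runif(3, 1, 100), names(obs)))
    o <- as_signature(stats::setNames(runif(3, 1, 100), names(obs)))
    r2_manual <- (sum((p - mean(p)) * (o - mean(o))))^2 /
      (sum((p - mean(p))^2) * sum((o - mean(o))^2))
    r2 <- pearson_r_squared(p, o)
    expect_equal(r2, r2_manual, tolerance = 1e-12)
    expect_true(r2 >= 0 && r2 <= 1)
  }
  expect_error(pearson_r_squared(c("16:0" = 1, "18:1" = 1, "18:2" = 1), obs),
               "constant")
  expect_error(pearson_r_squared(c("16:0" = 1, "18:1" = 2),
                                 c("16:0" = 2, "18:1" = 1)), "at least 3")
})

test_that("no enumerated grid diet beats the returned minimum", {
  set.seed(11)
  for (i in 1:5) {
    inst <- random_lad_instance(k = 3, m = 6)
    fit <- fit_diet(inst$obs, inst$M, step = 0.05, rescale = FALSE,
                    profile = FALSE)
    devs <- enumerate_grid_deviations(inst$M, inst$obs, nsteps = 20)
    expect_equal(fit$bmd, min(devs), tolerance = 1e-9)
  }
})

test_that("halving the grid step never increases the best deviation", {
  set.seed(21)
  for (i in 1:5) {
    inst <- random_lad_instance(k = sample(2:4, 1), m = 8)
    b1 <- fit_diet(inst$obs, inst$M, step = 0.04, rescale = FALSE,
                   profile = FALSE)$bmd
    b2 <- fit_diet(inst$obs, inst$M, step = 0.02, rescale = FALSE,
                   profile = FALSE)$bmd
    b3 <- fit_diet(inst$obs, inst$M, step = 0.01, rescale = FALSE,
                   profile = FALSE)$bmd
    expect_lte(b2, b1 + 1e-9)
    expect_lte(b3, b2 + 1e-9)
  }
})

test_that("exact grid mixtures are recovered, with and without calibration", {
  set.seed(31)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    inst <- random_lad_instance(k = k, m = 8)
    p_true <- as.numeric(rmultinom(1, 100, rep(1, k))) / 100
    names(p_true) <- colnames(inst$M)
    cc <- stats::setNames(exp(rnorm(8, 0, 0.3)), rownames(inst$M))
    obs <- predict_fat_signature(p_true, inst$M, cc = cc)
    fit <- fit_diet(obs, inst$M, cc = cc, step = 0.01, profile = FALSE)
    expect_equal(fit$diet, p_true, tolerance = 1e-9)
    expect_lt(fit$bmd, 1e-9)
  }
})

test_that("relabeling sources permutes fitted proportions identically", {
  set.seed(41)
  inst <- random_lad_instance(k = 3, m = 8)
  fit <- fit_diet(inst$obs, inst$M, step = 0.02, rescale = FALSE,
                  profile = FALSE)
  perm <- c(3, 1, 2)
  Mp <- inst$M[, perm]
  fit_p <- fit_diet(inst$obs, Mp, step = 0.02, rescale = FALSE,
                    profile = FALSE)
  expect_equal(fit_p$diet[colnames(inst$M)], fit$diet)
  expect_equal(fit_p$bmd, fit$bmd)
})

test_that("ties break toward the lexicographically smallest diet vector", {
  # two identical sources: every split of the optimum is a tie; the
  # smallest vector puts all weight on the later source
  M <- cbind(a = c("16:0" = 50, "18:1" = 50), b = c("16:0" = 50, "18:1" = 50))
  fit <- fit_diet(c("16:0" = 50, "18:1" = 50), M, step = 0.1, profile = FALSE)
  expect_equal(fit$diet, c(a = 0, b = 1))
  expect_equal(fit$n_ties, 11)
})

test_that("uniqueness profiles flag degenerate but not well-posed fits", {
  # V-shaped profile with a unique minimum at 0.38
  u <- uniqueness_profile(toy_fat(), vertex_foods(), step = 0.01)
  p1 <- u$profiles[u$profiles$source == "food1", ]
  expect_equal(p1$proportion[which.min(p1$min_dev)], 0.38)
  expect_false(any(u$non_unique))
  # interchangeable sources are flagged along their exchange direction
  M <- cbind(a = c("16:0" = 60, "18:1" = 30, "18:2" = 10),
             b = c("16:0" = 60, "18:1" = 30, "18:2" = 10),
             c = c("16:0" = 10, "18:1" = 30, "18:2" = 60))
  obs <- predict_fat_signature(c(a = 0.3, b = 0.3, c = 0.4), M)
  u2 <- uniqueness_profile(obs, M, step = 0.01)
  expect_true(u2$non_unique[["a"]])
  expect_true(u2$non_unique[["b"]])
  expect_false(u2$non_unique[["c"]])
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_diet(toy_fat(), vertex_foods(), step = 0.03), "divide 1")
  expect_error(fit_diet(toy_fat(), vertex_foods(), step = 0), "in \\(0, 1\\]")
  expect_error(fit_diet(toy_fat(), vertex_foods()[, 1, drop = FALSE]),
               "at least 2 sources")
  expect_error(fit_diet(c("16:0" = 38, "18:2" = 62), vertex_foods()),
               "same fatty acids")
})
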