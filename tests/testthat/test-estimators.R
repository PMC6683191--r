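test_that("Wald ratios divide through and flag zero exposure effects", {
  inp <- mr_input(bx = c(1, 0.5), sx = c(0.1, 0.1),
                  by = c(0.3, 0.1), sy = c(0.1, 0.05))
  r <- ratio_estimates(inp)
  expect_equal(r$ratio, c(0.3, 0.2))
  expect_equal(r$se, c(0.1, 0.1))

  # joint sign flip of bx and by leaves the ratio unchanged
  inp2 <- mr_input(bx = -inp$bx, sx = inp$sx, by = -inp$by, sy = inp$sy)
  expect_equal(ratio_estimates(inp2)$ratio, r$ratio)

  bad <- mr_input(bx = c(1, 0), sx = c(0.1, 0.1),
                  by = c(0.3, 0.1), sy = c(0.1, 0.05),
                  variant_ids = c("ok", "degenerate"))
  expect_error(ratio_estimates(bad), "degenerate")
})

test_that("IVW recovers exact fits and matches the weighted-least-squares oracle", {
  # exact proportionality: slope recovered, Q = 0
  bx <- c(0.1, 0.2, 0.3)
  inp <- mr_input(bx, rep(0.01, 3), by = 0.2 * bx, sy = c(0.05, 0.02, 0.04))
  fit <- mr_ivw(inp)
  expect_equal(fit$slope, 0.2)
  expect_equal(fit$q_statistic, 0, tolerance = 1e-24)

  # flat exposure effects: slope is the weighted mean of by
  inp2 <- mr_input(c(1, 1, 1), rep(0.01, 3), c(0.1, 0.2, 0.3), rep(0.1, 3))
  fit2 <- mr_ivw(inp2)
  o <- oracle_ivw(inp2$bx, inp2$by, inp2$sy)
  expect_equal(fit2$slope, 0.2)
  expect_equal(fit2$slope, o$slope, tolerance = 1e-12)
  expect_equal(fit2$slope_se, o$se, tolerance = 1e-12)
  expect_equal(fit2$q_statistic, o$q, tolerance = 1e-12)

  # sign equivariance: negating bx negates the slope only
  inp3 <- random_mr_input(8, seed = 3)
  f <- mr_ivw(inp3)
  f_neg <- mr_ivw(mr_input(-inp3$bx, inp3$sx, inp3$by, inp3$sy))
  expect_equal(f_neg$slope, -f$slope)
  expect_equal(f_neg$slope_se, f$slope_se)
  expect_equal(f_neg$q_statistic, f$q_statistic)

  # scale equivariance: bx, sx scaled by c divides the slope by c
  c_ <- 3.7
  f_sc <- mr_ivw(mr_input(c_ * inp3$bx, c_ * inp3$sx, inp3$by, inp3$sy))
  expect_equal(f_sc$slope, f$slope / c_, tolerance = 1e-12)

  expect_error(mr_ivw(mr_input(1, 0.1, 0.1, 0.1)), "at least 2")
})

test_that("Egger recovers exact affine fits and matches the oracle", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  inp <- mr_input(bx, rep(0.01, 4), by = 0.05 + 0.3 * bx,
                  sy = c(0.05, 0.02, 0.04, 0.03))
  fit <- mr_egger(inp)
  expect_equal(fit$slope, 0.3, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.05, tolerance = 1e-10)
  expect_equal(fit$q_statistic, 0, tolerance = 1e-20)

  # proportional data: intercept is zero
  inp2 <- mr_input(bx, rep(0.01, 4), by = 0.4 * bx, sy = rep(0.03, 4))
  expect_equal(mr_egger(inp2)$intercept, 0, tolerance = 1e-12)

  # random input matches the lm() oracle after orientation
  inp3 <- random_mr_input(6, seed = 11)
  fit3 <- mr_egger(inp3)
  o <- oracle_egger(inp3$bx, inp3$by, inp3$sy)
  expect_equal(fit3$slope, o$slope, tolerance = 1e-12)
  expect_equal(fit3$intercept, o$intercept, tolerance = 1e-12)
  expect_equal(fit3$slope_se, o$slope_se, tolerance = 1e-12)
  expect_equal(fit3$intercept_se, o$intercept_se, tolerance = 1e-12)

  # negating all outcome effects negates slope and intercept
  fit_neg <- mr_egger(mr_input(inp3$bx, inp3$sx, -inp3$by, inp3$sy))
  expect_equal(fit_neg$slope, -fit3$slope)
  expect_equal(fit_neg$intercept, -fit3$intercept)

  expect_error(mr_egger(mr_input(1:2, c(.1, .1), c(.1, .2), c(.1, .1))),
               "at least 3")
})

test_that("weighted median interpolates the crossing and stays in the ratio range", {
  # equal weights, ratios (0.1, 0.2, 0.9): crossing lands on the middle ratio
  inp <- mr_input(bx = c(1, 1, 1), sx = rep(0.01, 3),
                  by = c(0.1, 0.2, 0.9), sy = rep(0.1, 3))
  expect_equal(mr_weighted_median(inp, n_boot = 0)$slope, 0.2)

  # constant ratios are returned whatever the weights
  inp2 <- mr_input(bx = c(0.5, 1, 2), sx = rep(0.01, 3),
                   by = 0.3 * c(0.5, 1, 2), sy = c(0.1, 0.03, 0.07))
  expect_equal(mr_weighted_median(inp2, n_boot = 0)$slope, 0.3)

  # unequal weights on 5 ratios match the independently coded crossing scan
  set.seed(21)
  bx <- runif(5, 0.1, 0.5)
  by <- rnorm(5, 0.2 * bx, 0.05)
  sy <- runif(5, 0.02, 0.2)
  inp3 <- mr_input(bx, rep(0.01, 5), by, sy)
  rat <- by / bx
  w <- (abs(bx) / sy)^2
  expect_equal(mr_weighted_median(inp3, n_boot = 0)$slope,
               oracle_weighted_median(rat, w), tolerance = 1e-12)

  # estimate always lies within [min ratio, max ratio]
  for (seed in 31:40) {
    inp4 <- random_mr_input(7, seed = seed)
    est <- mr_weighted_median(inp4, n_boot = 0)$slope
    r <- inp4$by / inp4$bx
    expect_gte(est, min(r))
    expect_lte(est, max(r))
  }
})

test_that("weighted-median bootstrap is deterministic in the seed", {
  inp <- random_mr_input(10, seed = 5)
  a <- mr_weighted_median(inp, n_boot = 200, seed = 99)
  b <- mr_weighted_median(inp, n_boot = 200, seed = 99)
  expect_identical(a, b)
  c_ <- mr_weighted_median(inp, n_boot = 200, seed = 100)
  expect_false(identical(a$slope_se, c_$slope_se))
  # the caller's RNG stream is not consumed
  set.seed(1); x1 <- rnorm(1)
  set.seed(1); invisible(mr_weighted_median(inp, n_boot = 50, seed = 3))
  expect_identical(rnorm(1), x1)
})

test_that("pleiotropy flagging isolates a planted outlier", {
  # 9 conforming SNPs on the line by = 0.2 bx, one outlier 10 outcome SEs off
  set.seed(13)
  bx <- runif(10, 0.1, 0.5)
  sy <- rep(0.02, 10)
  by <- 0.2 * bx
  by[4] <- by[4] + 10 * sy[4]
  inp <- mr_input(bx, rep(0.005, 10), by, sy,
                  variant_ids = sprintf("v%d", 1:10))
  flagged <- flag_pleiotropic(inp)
  expect_identical(flagged, "v4")

  # hand-derived check of the same rule: Q_j against chi-square(1)
  slope_all <- sum(bx * by / sy^2) / sum(bx^2 / sy^2)
  q_j <- (by - slope_all * bx)^2 / sy^2
  p_j <- pchisq(q_j, 1, lower.tail = FALSE)
  expect_identical(which(p_j < 0.05 / 10), 4L)

  # proportional data flags nothing
  inp_clean <- mr_input(bx, rep(0.005, 10), 0.2 * bx, sy)
  expect_length(flag_pleiotropic(inp_clean), 0)
})

test_that("exclusion IVW equals IVW on the conforming complement", {
  set.seed(13)
  bx <- runif(10, 0.1, 0.5)
  sy <- rep(0.02, 10)
  by <- 0.2 * bx
  by[4] <- by[4] + 10 * sy[4]
  inp <- mr_input(bx, rep(0.005, 10), by, sy,
                  variant_ids = sprintf("v%d", 1:10))
  fit <- mr_ivw_excluding_pleiotropic(inp)
  expect_identical(fit$excluded_ids, "v4")
  sub <- mr_input(bx[-4], rep(0.005, 9), by[-4], sy[-4])
  expect_equal(fit$slope, mr_ivw(sub)$slope)
  expect_equal(fit$slope, 0.2, tolerance = 1e-12)

  # with no flags the result equals plain IVW
  inp_clean <- random_mr_input(8, seed = 17)
  excl <- mr_ivw_excluding_pleiotropic(inp_clean)
  plain <- mr_ivw(inp_clean)
  expect_length(excl$excluded_ids, 0)
  expect_equal(excl$slope, plain$slope)
  expect_equal(excl$slope_se, plain$slope_se)
})

test_that("mr_fit bundles the four analyses with standard accessors", {
  inp <- random_mr_input(12, seed = 23)
  fit <- mr_fit(inp, n_boot = 100, seed = 4)
  expect_s3_class(fit, "mr_fit")
  expect_named(fit$results, c("ivw", "ivw_excl", "median", "egger"))
  expect_equal(unname(coef(fit)["ivw"]), mr_ivw(inp)$slope)
  ci <- confint(fit)
  expect_equal(dim(ci), c(4L, 2L))
  expect_true(all(ci[, 1] < ci[, 2]))
  # CI agrees with slope +- 1.96 SE
  expect_equal(ci["ivw", 2] - ci["ivw", 1],
               2 * qnorm(0.975) * fit$results$ivw$slope_se)
  res <- residuals(fit)
  expect_length(res, 12)
  expect_equal(unname(res), inp$by - coef(fit)["ivw"] * inp$bx,
               ignore_attr = TRUE)
  s <- summary(fit)
  expect_s3_class(s, "summary.mr_fit")
  expect_equal(nrow(s$table), 4L)
  expect_output(print(fit), "Inverse-variance weighted")
  expect_output(print(s), "Egger intercept")
  # plot draws without error
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("slope p-values are consistent with the two-sided normal route", {
  for (seed in 41:45) {
    inp <- random_mr_input(9, seed = seed)
    for (fit in list(mr_ivw(inp), mr_egger(inp))) {
      expect_equal(fit$slope_p, 2 * pnorm(-abs(fit$slope / fit$slope_se)))
    }
  }
})

test_that("Egger intercept test is calibrated under no pleiotropy", {
  # data generated with zero intercept: rejection near nominal 0.05
  n_rep <- 400
  set.seed(97)
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    J <- 30
    bx_true <- abs(rnorm(J, 0, 0.1)) + 0.02
    sy <- runif(J, 0.01, 0.03)
    inp <- mr_input(bx_true + rnorm(J, 0, 0.005), rep(0.005, J),
                    rnorm(J, 0.2 * bx_true, sy), sy)
    rej[r] <- mr_egger(inp)$intercept_p < 0.05
  }
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})
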