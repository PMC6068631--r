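test_that("absolute errors are symmetric absolute differences", {
  truth <- data.frame(object_id = c("A", "B"), dim_x = c(100, 50),
                      dim_y = c(80, 50), dim_z = c(150, 120))
  meas <- data.frame(object_id = c("A", "B"), dim_x = c(98, 52),
                     dim_y = c(80, 50), dim_z = c(152, 118))
  errs <- abs_errors(meas, truth)
  expect_equal(errs$abs_error_mm[errs$dimension == "x"], c(2, 2))
  expect_equal(errs$abs_error_mm[errs$dimension == "y"], c(0, 0))
  expect_equal(errs$abs_error_mm[errs$dimension == "z"], c(2, 2))
  # grouping columns ride along
  meas$pou <- c(278, 278)
  expect_true("pou" %in% names(abs_errors(meas, truth)))
  meas$object_id[1] <- "missing"
  expect_error(abs_errors(meas, truth), "missing")
})

test_that("power fit recovers exact and noisy generating laws", {
  pous <- design_pou_grid()$pou_int
  fit <- fit_power(pous, 200 * pous^-0.6)
  expect_equal(fit$a, 200, tolerance = 1e-9)
  expect_equal(fit$b, -0.6, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # constant errors: slope zero, coefficient the geometric mean
  flat <- fit_power(pous, rep(4, length(pous)))
  expect_equal(flat$b, 0, tolerance = 1e-12)
  expect_equal(flat$a, 4, tolerance = 1e-12)
  # scale invariance: errors scaled by c scale a by c, leave b and R^2
  noisy <- make_error_dataset(200, -0.6, 0.2, pous, seed = 5)
  f1 <- fit_power(noisy$pou, noisy$abs_error_mm)
  f2 <- fit_power(noisy$pou, 3 * noisy$abs_error_mm)
  expect_equal(f2$a, 3 * f1$a)
  expect_equal(f2$b, f1$b)
  expect_equal(f2$r_squared, f1$r_squared)
  # zero errors are floored, not fatal
  withfloor <- fit_power(pous, c(0, 200 * pous[-1]^-0.6))
  expect_equal(withfloor$n_floored, 1L)
  expect_error(fit_power(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_power(c(-1, 2, 3), c(1, 2, 3)), "positive")
})

test_that("agreement statistics match the normal-equations oracle", {
  x <- c(100, 150, 200, 250, 300)
  y <- c(104, 149, 205, 248, 307)
  ag <- agreement_stats(y, x)
  want <- oracle_ols(x, y)
  expect_equal(ag$slope, want$slope)
  expect_equal(ag$intercept, want$intercept)
  expect_equal(ag$r_squared, want$r_squared)
  expect_equal(ag$rmse_mm, sqrt(mean((y - x)^2)))
  # identical vectors and pure offsets
  same <- agreement_stats(x, x)
  expect_equal(same$slope, 1); expect_equal(same$intercept, 0)
  expect_equal(same$r_squared, 1); expect_equal(same$rmse_mm, 0)
  off <- agreement_stats(x + 5, x)
  expect_equal(off$slope, 1); expect_equal(off$rmse_mm, 5)
  expect_equal(off$r_squared, 1)
  # R^2 equals the squared Pearson correlation
  expect_equal(ag$r_squared, cor(x, y)^2)
  expect_error(agreement_stats(c(1, 2, 3), c(5, 5, 5)), "zero variance")
})

test_that("one-way ANOVA matches direct summation and the t-test link", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8))
  an <- one_way_anova(groups)
  want <- oracle_anova(groups)
  expect_equal(an$ss_between, want$ss_between)
  expect_equal(an$ss_within, want$ss_within)
  expect_equal(an$f_value, want$f)
  expect_equal(an$ms_between, an$ss_between / an$df_between)
  # total decomposition
  tot <- sum((unlist(groups) - mean(unlist(groups)))^2)
  expect_equal(an$ss_between + an$ss_within, tot, tolerance = 1e-9)
  # two identical groups: F = 0, p = 1
  same <- one_way_anova(list(x = c(1, 2, 3), y = c(1, 2, 3)))
  expect_equal(same$f_value, 0)
  expect_equal(same$p_value, 1)
  # two groups: F equals the squared pooled two-sample t statistic
  set.seed(31)
  g1 <- rnorm(8); g2 <- rnorm(10, 1)
  an2 <- one_way_anova(list(g1 = g1, g2 = g2))
  tt <- stats::t.test(g1, g2, var.equal = TRUE)
  expect_equal(an2$f_value, unname(tt$statistic)^2)
  expect_equal(an2$p_value, tt$p.value)
  # pairwise table mirrors the pooled-variance t tests
  expect_equal(nrow(an$pairwise), 3L)
  expect_true(all(an$pairwise$p >= 0 & an$pairwise$p <= 1))
  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "at least two")
})

test_that("error summaries are order-invariant grouped moments", {
  rec <- data.frame(shape = c("O1", "O1", "O2"),
                    dimension = c("x", "x", "x"),
                    abs_error_mm = c(4, 6, 3))
  s <- summarize_errors(rec)
  expect_equal(s$mean_mm[s$shape == "O1"], 5)
  expect_equal(s$sd_mm[s$shape == "O1"], sqrt(2), tolerance = 1e-12)
  expect_equal(s$sd_mm[s$shape == "O2"], 0)
  expect_true(s$single_obs[s$shape == "O2"])
  perm <- summarize_errors(rec[c(3, 1, 2), ])
  expect_equal(perm, s)
})

test_that("power-law parameter recovery meets the 5% simulation bound", {
  pous <- design_pou_grid()$pou_int
  fits <- vapply(1:500, function(i) {
    d <- make_error_dataset(200, -0.6, 0.1, pous, seed = i)
    f <- fit_power(d$pou, d$abs_error_mm)
    c(f$a, f$b)
  }, numeric(2))
  expect_lt(abs(mean(fits[1, ]) - 200) / 200, 0.05)
  expect_lt(abs(mean(fits[2, ]) - (-0.6)) / 0.6, 0.05)
})

test_that("the full synthetic evaluation reproduces the headline findings", {
  ev <- run_full_evaluation(pou_values = c(17, 56, 168, 556),
                            n_replicates = 2, density = 0.4, seed = 2)
  # errors in x and y rise as POU falls: fitted exponents negative
  expect_lt(ev$power_fits$x$b, 0)
  expect_lt(ev$power_fits$y$b, 0)
  # height errors stay below planimetric errors
  sm <- ev$summary
  for (sh in unique(sm$shape)) {
    z <- sm$mean_mm[sm$shape == sh & sm$dimension == "z"]
    expect_lt(z, sm$mean_mm[sm$shape == sh & sm$dimension == "x"])
    expect_lt(z, sm$mean_mm[sm$shape == sh & sm$dimension == "y"])
  }
  # determinism: identical config and seed, identical records
  ev2 <- run_full_evaluation(pou_values = c(17, 56, 168, 556),
                             n_replicates = 2, density = 0.4, seed = 2)
  expect_identical(ev$errors, ev2$errors)
})
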