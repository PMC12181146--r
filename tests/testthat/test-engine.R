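test_that("noise-free interaction data are recovered to machine precision", {
  d <- make_fit_data(n = 300, noise_sd = 0)
  f <- fit_interaction(d$y, d$g, d$age, d$covars)
  expect_equal(f$beta_int, 0.003, tolerance = 1e-12)
  expect_equal(f$beta_g, 0.5, tolerance = 1e-10)
  expect_equal(f$beta_age, 0.02, tolerance = 1e-12)

  fm <- fit_marginal(2 * d$g + d$age, d$g, d$age, d$covars)
  expect_equal(fm$beta_g, 2, tolerance = 1e-12)
})

test_that("degenerate designs raise informative errors", {
  d <- make_fit_data(n = 100)
  expect_error(fit_interaction(d$y, rep(0, 100), d$age, d$covars),
               "monomorphic")
  covars_bad <- cbind(d$covars, dup = d$covars[, "pc1"])
  expect_error(fit_interaction(d$y, d$g, d$age, covars_bad),
               "collinearity|rank")
})

test_that("coefficients match a brute-force normal-equation solve", {
  d <- make_fit_data(n = 500, seed = 77)
  X <- cbind(d$covars, g = d$g, age = d$age, g_age = d$g * d$age)
  oracle <- brute_force_ols(X, d$y)
  f <- fit_interaction(d$y, d$g, d$age, d$covars)
  expect_equal(f$beta_int, unname(oracle$beta["g_age"]), tolerance = 1e-10)
  expect_equal(f$se_int, unname(oracle$se["g_age"]), tolerance = 1e-10)
  expect_equal(f$p_int, unname(oracle$p["g_age"]), tolerance = 1e-10)
  expect_equal(f$df, oracle$df)
})

test_that("interaction inference is invariant to centring age", {
  d <- make_fit_data(n = 400, seed = 5)
  f0 <- fit_interaction(d$y, d$g, d$age, d$covars)
  for (c0 in c(0, 58)) {
    fc <- fit_interaction(d$y, d$g, d$age - c0, d$covars)
    expect_equal(fc$beta_int, f0$beta_int, tolerance = 1e-9)
    expect_equal(fc$se_int, f0$se_int, tolerance = 1e-9)
    expect_equal(fc$p_int, f0$p_int, tolerance = 1e-9)
  }
})

test_that("duplicating every row keeps betas and shrinks SEs by sqrt(2)", {
  d <- make_fit_data(n = 300, seed = 10)
  f1 <- fit_marginal(d$y, d$g, d$age, d$covars)
  idx <- rep(seq_along(d$y), 2)
  f2 <- fit_marginal(d$y[idx], d$g[idx], d$age[idx],
                     d$covars[idx, , drop = FALSE])
  expect_equal(f2$beta_g, f1$beta_g, tolerance = 1e-10)
  # exact ratio: sqrt((n - p) / (2n - p)) from the duplicated design
  p <- ncol(d$covars) + 2
  n <- length(d$y)
  expect_equal(f2$se_g / f1$se_g, sqrt((n - p) / (2 * n - p)),
               tolerance = 1e-10)
})

test_that("marginal p-values are uniform under the null", {
  set.seed(123)
  n <- 150
  age <- runif(n, 40, 70)
  covars <- cbind(`(Intercept)` = 1, sex = rbinom(n, 1, 0.5))
  pvals <- replicate(2000, {
    g <- rbinom(n, 2, 0.3)
    y <- 0.02 * age + rnorm(n)
    fit_marginal(y, g, age, covars)$p_g_marginal
  })
  ks <- ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.015)
})

test_that("robust SEs equal the sandwich HC0 estimator", {
  skip_if_not_installed("sandwich")
  d <- make_fit_data(n = 400, seed = 2)
  f <- fit_interaction(d$y, d$g, d$age, d$covars, se_type = "robust")
  dat <- data.frame(y = d$y, g = d$g, age = d$age,
                    sex = d$covars[, "sex"],
                    d$covars[, paste0("pc", 1:10)])
  lf <- lm(y ~ g + age + g:age + sex + pc1 + pc2 + pc3 + pc4 + pc5 +
             pc6 + pc7 + pc8 + pc9 + pc10, data = dat)
  vc <- sandwich::vcovHC(lf, type = "HC0")
  expect_equal(f$se_int, sqrt(vc["g:age", "g:age"]), tolerance = 1e-9)
  expect_equal(f$se_g, sqrt(vc["g", "g"]), tolerance = 1e-9)
})

test_that("missing dosages are mean-imputed by default and droppable", {
  d <- make_fit_data(n = 300, seed = 4)
  g <- d$g
  g[1:30] <- NA
  f_imp <- fit_interaction(d$y, g, d$age, d$covars)
  expect_equal(f_imp$n, 300)
  f_drop <- fit_interaction(d$y, g, d$age, d$covars, na_action = "drop")
  expect_equal(f_drop$n, 270)
  g_manual <- g
  g_manual[is.na(g)] <- mean(g, na.rm = TRUE)
  f_manual <- fit_interaction(d$y, g_manual, d$age, d$covars)
  expect_equal(f_imp$beta_int, f_manual$beta_int, tolerance = 1e-12)
})

test_that("the streaming fast path reproduces per-variant fits exactly", {
  for (seed in c(1, 2, 3)) {
    d <- make_fit_data(n = 300, seed = seed)
    set.seed(seed + 100)
    G <- matrix(rbinom(40 * 300, 2, 0.25), nrow = 40,
                dimnames = list(sprintf("v%02d", 1:40), NULL))
    G[3, ] <- 0   # monomorphic row must be flagged, not fatal
    sb <- scan_block(d$y, G, d$age, d$covars, model = "both")
    expect_match(sb$flag[3], "monomorphic")
    for (j in c(1, 2, 4, 20, 40)) {
      fi <- fit_interaction(d$y, G[j, ], d$age, d$covars)
      fm <- fit_marginal(d$y, G[j, ], d$age, d$covars)
      expect_equal(sb$beta_int[j], fi$beta_int, tolerance = 1e-10)
      expect_equal(sb$se_int[j], fi$se_int, tolerance = 1e-10)
      expect_equal(sb$p_int[j], fi$p_int, tolerance = 1e-10)
      expect_equal(sb$p_marginal[j], fm$p_g_marginal, tolerance = 1e-10)
    }
    # row-order invariance of the samples
    perm <- sample(300)
    sb2 <- scan_block(d$y[perm], G[, perm], d$age[perm],
                      d$covars[perm, , drop = FALSE], model = "both")
    expect_equal(sb2$beta_int, sb$beta_int, tolerance = 1e-9)
  }
})
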