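# shared fixture builders; everything is generated in code at test time

# minimal raw phenotype table with explicit values, no simulator involved
make_raw_pheno <- function(n = 20, seed = 1) {
  set.seed(seed)
  ph <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    age = runif(n, 40, 70),
    sex = sample(c("male", "female"), n, replace = TRUE),
    apob = rnorm(n, 1.03, 0.24),
    ldl = rnorm(n, 3.57, 0.86),
    tg = exp(rnorm(n, 0.4, 0.5)),
    sbp = rnorm(n, 138, 18),
    bmi = rnorm(n, 27, 4.7),
    statin = rbinom(n, 1, 0.2),
    bp_med = rbinom(n, 1, 0.2),
    stringsAsFactors = FALSE)
  for (k in 1:10) ph[[paste0("pc", k)]] <- rnorm(n)
  ph
}

# covariates + a dosage and a trait with known generative coefficients
make_fit_data <- function(n = 500, seed = 1, maf = 0.3,
                          beta_g = 0.5, beta_age = 0.02, beta_int = 0.003,
                          noise_sd = 1) {
  set.seed(seed)
  ph <- make_raw_pheno(n, seed)
  g <- rbinom(n, 2, maf)
  y <- 1 + beta_g * g + beta_age * ph$age + beta_int * g * ph$age +
    rnorm(n, 0, noise_sd)
  list(y = y, g = g, age = ph$age, pheno = ph,
       covars = covariate_matrix(ph))
}

# independent OLS oracle: brute-force solve of the normal equations
brute_force_ols <- function(X, y) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  p <- 2 * pt(abs(b / se), df, lower.tail = FALSE)
  list(beta = drop(b), se = se, p = drop(p), df = df)
}

quick_cohort <- function(n = 2000, m = 10, seed = 7, ...) {
  spec <- simulation_spec(n_individuals = n,
                          variants = variant_panel(m, maf = 0.3),
                          seed = seed, ...)
  simulate_cohort(spec)
}
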