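# cohort with one causal variant and configurable effects on sbp
strata_cohort <- function(n = 30000, beta_g = 8, beta_int = -0.1,
                          seed = 41, noise = NULL) {
  tp <- default_trait_params()
  if (!is.null(noise)) tp$sbp$noise_sd <- noise
  spec <- simulation_spec(
    n, variants = list(variant_spec("v1", maf = 0.3,
                                    beta_g = c(sbp = beta_g),
                                    beta_gxage = c(sbp = beta_int))),
    trait_params = tp, seed = seed)
  coh <- simulate_cohort(spec)
  pheno <- preprocess_phenotypes(coh$phenotypes)
  idx <- match(pheno$sample_id, coh$genotypes$sample_id)
  list(pheno = pheno, g = coh$genotypes$dosage[1, idx])
}

test_that("additive truth yields a 2:1 homozygote/heterozygote contrast", {
  d <- strata_cohort(beta_g = 8, beta_int = 0, noise = 0.5)
  st <- stratified_fit(d$pheno, d$g, "sbp")
  for (b in unique(st$bin)) {
    het <- st$beta[st$bin == b & st$contrast == "het"]
    hom <- st$beta[st$bin == b & st$contrast == "hom"]
    expect_equal(hom / het, 2, tolerance = 0.02)
  }
  expect_true(all(st$ci_lo <= st$beta & st$beta <= st$ci_hi))
})

test_that("a negative age interaction attenuates contrasts across bins", {
  d <- strata_cohort(beta_g = 8, beta_int = -0.1)
  st <- stratified_fit(d$pheno, d$g, "sbp")
  for (cn in c("het", "hom")) {
    est <- st$beta[st$contrast == cn]
    expect_true(all(diff(est) < 0))   # 40-49 > 50-59 > 60-70
  }
  # additive coding shows the same attenuation
  sa <- stratified_fit(d$pheno, d$g, "sbp", coding = "additive")
  expect_true(all(diff(sa$beta) < 0))
})

test_that("sex-stratified estimates match all-sample ones without sex effects", {
  tp <- default_trait_params()
  tp$sbp$sex_effect <- 0
  spec <- simulation_spec(
    20000, variants = list(variant_spec("v1", maf = 0.3,
                                        beta_g = c(sbp = 8))),
    trait_params = tp, seed = 43)
  coh <- simulate_cohort(spec)
  pheno <- preprocess_phenotypes(coh$phenotypes)
  g <- coh$genotypes$dosage[1, match(pheno$sample_id,
                                     coh$genotypes$sample_id)]
  all_s <- stratified_fit(pheno, g, "sbp", sex_scope = "all")
  wom <- stratified_fit(pheno, g, "sbp", sex_scope = "women")
  for (i in seq_len(nrow(all_s))) {
    se <- sqrt(all_s$se[i]^2 + wom$se[i]^2)
    expect_lt(abs(all_s$beta[i] - wom$beta[i]), 4 * se)
  }
})

test_that("fold-changes exponentiate log-scale betas and reference is 1", {
  d <- strata_cohort(seed = 47)
  # fit tg (log scale after preprocessing) to get fold-change columns
  st <- stratified_fit(d$pheno, d$g, "tg")
  expect_true(all(c("fold_change", "fold_lo", "fold_hi") %in% names(st)))
  expect_equal(st$fold_change, exp(st$beta))
  expect_equal(exp(0), 1)  # reference category: zero beta, fold-change 1
  # sbp is not log scale: no fold-change columns
  st2 <- stratified_fit(d$pheno, d$g, "sbp")
  expect_false("fold_change" %in% names(st2))
})

test_that("genotype frequency tables sum to 100% and follow HWE shape", {
  g <- c(0, 0, 1, 2)
  tab <- genotype_frequencies(g, age = c(45, 45, 45, 45),
                              age_bins = data.frame(label = "40-49",
                                                    lo = 40, hi = 50))
  expect_equal(c(tab$pct_ref, tab$pct_het, tab$pct_hom), c(50, 25, 25))

  spec <- simulation_spec(100000,
                          variants = variant_panel(1, maf = 0.017),
                          seed = 53)
  coh <- simulate_cohort(spec)
  tab2 <- genotype_frequencies(coh$genotypes$dosage[1, ],
                               coh$phenotypes$age)
  sums <- tab2$pct_ref + tab2$pct_het + tab2$pct_hom
  expect_true(all(abs(sums - 100) < 0.02))
  # HWE reference-homozygote share at maf 0.017 is (1 - p)^2 = 96.6%
  expect_equal(tab2$pct_ref, rep((1 - 0.017)^2 * 100, 3), tolerance = 0.005)

  fmt <- format_genotype_frequencies(tab2)
  expect_match(fmt$pct_ref[1], "^\\d+\\.\\d{2}%$")
})

test_that("empty genotype categories are reported unavailable, not fatal", {
  set.seed(3)
  n <- 400
  ph <- make_raw_pheno(n, seed = 3)
  ph$age <- runif(n, 40, 70)
  g <- rbinom(n, 1, 0.2)          # no effect-allele homozygotes at all
  st <- stratified_fit(ph, g, "sbp")
  expect_true(all(is.na(st$beta[st$contrast == "hom"])))
  expect_true(all(!is.na(st$beta[st$contrast == "het"])))
})

test_that("per-sex interaction fits agree when the truth is shared", {
  cover <- replicate(100, NA)
  for (r in 1:100) {
    set.seed(500 + r)
    n <- 600
    age <- runif(n, 40, 70)
    sex <- sample(c("female", "male"), n, TRUE)
    g <- rbinom(n, 2, 0.3)
    y <- 0.1 * g + 0.02 * age + 0.003 * g * age + rnorm(n)
    ph <- data.frame(sample_id = as.character(1:n), age = age, sex = sex)
    for (k in 1:10) ph[[paste0("pc", k)]] <- rnorm(n)
    ph$y <- y
    fits <- interaction_by_sex(ph, g, "y")
    diff <- fits$women$beta_int - fits$men$beta_int
    cover[r] <- abs(diff) <= 2 * sqrt(fits$women$se_int^2 +
                                        fits$men$se_int^2)
  }
  expect_gte(mean(cover), 0.93)
})

test_that("an all-female table cannot provide a male fit", {
  ph <- make_raw_pheno(50)
  ph$sex <- "female"
  g <- rbinom(50, 2, 0.3)
  expect_error(interaction_by_sex(ph, g, "sbp"), "empty stratum")
})

test_that("an interaction confined to men yields smaller p-values in men", {
  men_wins <- logical(30)
  for (r in 1:30) {
    set.seed(900 + r)
    n <- 1200
    age <- runif(n, 40, 70)
    sex <- rep(c("female", "male"), length.out = n)
    male <- as.numeric(sex == "male")
    g <- rbinom(n, 2, 0.3)
    y <- 0.1 * g + 0.02 * age + 0.02 * g * age * male + rnorm(n)
    ph <- data.frame(sample_id = as.character(1:n), age = age, sex = sex)
    for (k in 1:10) ph[[paste0("pc", k)]] <- rnorm(n)
    ph$y <- y
    fits <- interaction_by_sex(ph, g, "y")
    men_wins[r] <- fits$men$p_int < fits$women$p_int
  }
  expect_gt(mean(men_wins), 0.5)
})
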