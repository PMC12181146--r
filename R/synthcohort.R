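#' Specify a simulated variant
#'
#' Describes one biallelic variant of the synthetic cohort: its position,
#' alleles, effect-allele frequency, and its true per-trait genetic main
#' effect and SNP-by-age interaction effect. Effects are on the analysis
#' scale of each trait (log scale for TG), per copy of the effect allele;
#' interaction effects are per allele per year of age.
#'
#' @param id Variant identifier (e.g. an rsID-like string).
#' @param chrom Chromosome label.
#' @param pos 1-based position (>= 1).
#' @param effect_allele,non_effect_allele Single-character allele codes; the
#'   dosage counts copies of `effect_allele`.
#' @param maf Effect-allele frequency in (0, 0.5]. A monomorphic variant
#'   (`maf = 0`) is rejected.
#' @param beta_g Named numeric vector of per-allele main effects by trait
#'   (trait units per allele). Traits not named have effect 0.
#' @param beta_gxage Named numeric vector of interaction effects by trait
#'   (trait units per allele per year).
#' @return A `variant_spec` list.
#' @export
variant_spec <- function(id, chrom = "1", pos = 1L,
                         effect_allele = "A", non_effect_allele = "G",
                         maf = 0.1, beta_g = numeric(0),
                         beta_gxage = numeric(0)) {
  if (!is.numeric(maf) || length(maf) != 1 || is.na(maf) ||
      maf <= 0 || maf > 0.5) {
    stop("invalid variant spec: maf must lie in (0, 0.5], got ", maf,
         call. = FALSE)
  }
  if (pos < 1) stop("invalid variant spec: pos must be >= 1", call. = FALSE)
  if (nchar(effect_allele) != 1 || nchar(non_effect_allele) != 1) {
    stop("alleles must be single characters", call. = FALSE)
  }
  structure(list(id = as.character(id), chrom = as.character(chrom),
                 pos = as.integer(pos),
                 effect_allele = effect_allele,
                 non_effect_allele = non_effect_allele,
                 maf = maf, beta_g = beta_g, beta_gxage = beta_gxage),
            class = "variant_spec")
}

# the five cardiometabolic risk factors analysed throughout
sim_traits <- c("apob", "ldl", "tg", "sbp", "bmi")

# Default generative parameters, calibrated to a middle-aged biobank cohort:
# trait levels and dispersions of the magnitude seen in population studies of
# ApoB (g/L), LDL-C (mmol/L), TG (mmol/L, generated on the natural-log
# scale), SBP (mmHg) and BMI (kg/m^2), with modest positive age trends and a
# male/female offset. Intercepts are at age 0 on the model scale.
default_trait_params <- function() {
  list(
    # intercept (age 0), per-year age slope, additive male effect, noise SD,
    # all on the analysis scale (log for tg)
    apob = list(intercept = 0.90, age_slope = 0.0022, sex_effect = 0.010,
                noise_sd = 0.23),
    ldl  = list(intercept = 3.25, age_slope = 0.0055, sex_effect = 0.05,
                noise_sd = 0.84),
    tg   = list(intercept = 0.05, age_slope = 0.0060, sex_effect = 0.25,
                noise_sd = 0.50),
    sbp  = list(intercept = 93.0, age_slope = 0.80,   sex_effect = 3.0,
                noise_sd = 16.5),
    bmi  = list(intercept = 25.6, age_slope = 0.030,  sex_effect = 0.4,
                noise_sd = 4.7)
  )
}

# Logistic medication-assignment model: probabilities rise with age and with
# the untreated trait value, reproducing the steep age gradient in treatment
# prevalence of middle-aged cohorts (statins roughly 4% -> 28%,
# antihypertensives roughly 6% -> 32% from the youngest to the oldest decade)
# without copying any cohort's exact joint distribution.
default_medication_model <- function() {
  list(
    statin = list(intercept = -2.2, age_slope = 0.125, trait_slope = 0.30,
                  trait = "ldl", trait_center = 3.6, age_center = 55,
                  ldl_multiplier = 0.7),
    bp_med = list(intercept = -1.9, age_slope = 0.115, trait_slope = 0.045,
                  trait = "sbp", trait_center = 138, age_center = 55,
                  sbp_reduction = 10)
  )
}

#' Specify a synthetic biobank cohort
#'
#' Bundles everything the generator needs: sample size, age range, sex
#' composition, the variant panel with true effects, optional LD blocks,
#' trait generative parameters, the medication model, missingness and the
#' age-centering constant of the genetic effects.
#'
#' The generative model for each trait is
#' \deqn{y = b_0 + b_{age} \cdot age + b_{sex} \cdot male +
#'   \sum_v (\beta_{G,v} + \beta_{G\times age,v}(age - c)) g_v +
#'   \sum_k \gamma_k PC_k + \epsilon}
#' with TG generated on the natural-log scale and exponentiated to mmol/L.
#' Statin users' measured LDL-C is the untreated value times the statin
#' multiplier; antihypertensive users' measured SBP is the untreated value
#' minus the additive reduction. Missingness is applied last.
#'
#' @param n_individuals Cohort size (> 0).
#' @param age_range Numeric length-2, low/high in years, within (0, 120).
#'   Ages are drawn uniformly on the range (default 40-70).
#' @param sex_fraction_female Proportion of women in (0, 1).
#' @param variants List of [variant_spec()] objects.
#' @param ld_blocks List of `list(from =, to =, rho =)` entries giving
#'   variant index ranges correlated through a first-order Gaussian-copula
#'   chain with parameter `rho` in `[0, 1)`. Blocks may not overlap.
#' @param trait_params Per-trait intercept/age slope/sex effect/noise SD; see
#'   `default_trait_params()` for the calibrated defaults.
#' @param medication_model Logistic assignment model plus treatment effects
#'   (statin multiplicative on measured LDL-C, antihypertensive additive on
#'   measured SBP).
#' @param pc_effects Optional trait-by-PC effect matrix (5 traits x 10 PCs);
#'   defaults to zero. PCs themselves are standard-normal columns.
#' @param missingness Named per-trait missingness probabilities.
#' @param age_center Centering constant c of the genetic effects (default 0,
#'   i.e. effects defined at age 0); `"mean"` centres at the realised cohort
#'   mean age. Recorded in the truth table so recovery tests are well posed.
#' @param dosage_noise If `TRUE`, adds beta-distributed jitter to hard calls
#'   to emulate imputed dosages (values stay in `[0, 2]`).
#' @param seed Mandatory integer seed; all randomness derives from it.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_individuals,
                            age_range = c(40, 70),
                            sex_fraction_female = 0.542,
                            variants = list(),
                            ld_blocks = list(),
                            trait_params = default_trait_params(),
                            medication_model = default_medication_model(),
                            pc_effects = NULL,
                            missingness = NULL,
                            age_center = 0,
                            dosage_noise = FALSE,
                            seed = NULL) {
  if (is.null(seed)) {
    stop("a seed is required for simulation; none was given", call. = FALSE)
  }
  if (!is.numeric(n_individuals) || n_individuals < 1) {
    stop("n_individuals must be positive", call. = FALSE)
  }
  if (length(age_range) != 2 || age_range[1] >= age_range[2] ||
      age_range[1] <= 0 || age_range[2] >= 120) {
    stop("age_range must be an increasing pair within (0, 120)",
         call. = FALSE)
  }
  if (sex_fraction_female < 0 || sex_fraction_female > 1) {
    stop("sex_fraction_female must be in [0, 1]", call. = FALSE)
  }
  for (v in variants) {
    if (!inherits(v, "variant_spec")) {
      stop("variants must be variant_spec objects", call. = FALSE)
    }
  }
  ld_blocks <- lapply(ld_blocks, function(b) {
    if (is.null(b$rho) || b$rho < 0 || b$rho >= 1) {
      stop("invalid spec: LD rho must be in [0, 1)", call. = FALSE)
    }
    if (b$from > b$to || b$from < 1 || b$to > length(variants)) {
      stop("invalid spec: LD block range out of bounds", call. = FALSE)
    }
    b
  })
  if (length(ld_blocks) > 1) {
    idx <- unlist(lapply(ld_blocks, function(b) seq(b$from, b$to)))
    if (anyDuplicated(idx)) {
      stop("invalid spec: overlapping LD blocks", call. = FALSE)
    }
  }
  if (is.null(missingness)) {
    missingness <- stats::setNames(rep(0, length(sim_traits)), sim_traits)
  }
  if (any(missingness < 0 | missingness > 1)) {
    stop("missingness probabilities must be in [0, 1]", call. = FALSE)
  }
  if (is.null(pc_effects)) {
    pc_effects <- matrix(0, nrow = length(sim_traits), ncol = 10,
                         dimnames = list(sim_traits, paste0("pc", 1:10)))
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 age_range = age_range,
                 sex_fraction_female = sex_fraction_female,
                 variants = variants, ld_blocks = ld_blocks,
                 trait_params = trait_params,
                 medication_model = medication_model,
                 pc_effects = pc_effects,
                 missingness = missingness,
                 age_center = age_center,
                 dosage_noise = dosage_noise,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Build a panel of independent variants with uniform properties
#'
#' Convenience constructor for test and simulation panels: `m` variants at
#' the given MAFs with optional effects on one trait.
#'
#' @param m Number of variants.
#' @param maf Single MAF or vector of length `m`.
#' @param trait Trait carrying the effects (default none).
#' @param beta_g,beta_gxage Effect sizes recycled to length `m`.
#' @param chrom Chromosome label for all variants.
#' @param prefix Variant-id prefix; keep prefixes distinct when combining
#'   several panels.
#' @return List of [variant_spec()] objects.
#' @export
variant_panel <- function(m, maf = 0.2, trait = NULL,
                          beta_g = 0, beta_gxage = 0, chrom = "1",
                          prefix = "var") {
  maf <- rep_len(maf, m)
  beta_g <- rep_len(beta_g, m)
  beta_gxage <- rep_len(beta_gxage, m)
  lapply(seq_len(m), function(j) {
    bg <- if (is.null(trait)) numeric(0) else stats::setNames(beta_g[j], trait)
    bi <- if (is.null(trait)) numeric(0) else {
      stats::setNames(beta_gxage[j], trait)
    }
    variant_spec(id = sprintf("%s%04d", prefix, j), chrom = chrom,
                 pos = j * 1000L, maf = maf[j],
                 beta_g = bg, beta_gxage = bi)
  })
}

#' Simulate Hardy-Weinberg genotypes with optional LD blocks
#'
#' Draws hard-call dosages in `{0, 1, 2}` per variant from Hardy-Weinberg
#' proportions \eqn{(1-p)^2, 2p(1-p), p^2} at effect-allele frequency p.
#' Within an LD block, the two haplotypes of each individual follow
#' independent first-order Gaussian-copula chains: each latent variable
#' correlates `rho` with its predecessor, and an allele is the indicator of
#' the latent falling below the MAF quantile, so marginal frequencies (and
#' hence HWE) are preserved exactly while adjacent-variant dosage
#' correlation rises with `rho`.
#'
#' @param spec A [simulation_spec()].
#' @return A `genotype_block`: list with `dosage` (variants x individuals
#'   matrix), `variants` (metadata data frame with id, chrom, pos, alleles,
#'   maf) and `sample_id`.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_individuals
  m <- length(spec$variants)
  if (m == 0) stop("spec contains no variants", call. = FALSE)
  set.seed(spec$seed)
  maf <- vapply(spec$variants, function(v) v$maf, numeric(1))

  # latent N(0,1) draws for the two haplotypes of each individual
  z1 <- matrix(stats::rnorm(m * n), nrow = m)
  z2 <- matrix(stats::rnorm(m * n), nrow = m)
  for (b in spec$ld_blocks) {
    idx <- seq(b$from, b$to)
    rho <- b$rho
    if (length(idx) > 1 && rho > 0) {
      w <- sqrt(1 - rho^2)
      for (j in idx[-1]) {
        z1[j, ] <- rho * z1[j - 1, ] + w * z1[j, ]
        z2[j, ] <- rho * z2[j - 1, ] + w * z2[j, ]
      }
    }
  }
  thr <- stats::qnorm(maf)
  dosage <- (z1 < thr) + (z2 < thr)
  storage.mode(dosage) <- "double"

  if (isTRUE(spec$dosage_noise)) {
    # beta-distributed jitter toward the interval interior mimics the
    # shrinkage of imputed dosages; hard calls remain the modal value
    eps <- matrix(stats::rbeta(m * n, 1, 19), nrow = m)
    dosage <- dosage + ifelse(dosage < 1, eps, ifelse(dosage > 1, -eps,
                              eps * sample(c(-1, 1), m * n, TRUE)))
    dosage <- pmin(pmax(dosage, 0), 2)
  }

  meta <- data.frame(
    id = vapply(spec$variants, `[[`, character(1), "id"),
    chrom = vapply(spec$variants, `[[`, character(1), "chrom"),
    pos = vapply(spec$variants, `[[`, integer(1), "pos"),
    non_effect_allele = vapply(spec$variants, `[[`, character(1),
                               "non_effect_allele"),
    effect_allele = vapply(spec$variants, `[[`, character(1),
                           "effect_allele"),
    maf = maf, stringsAsFactors = FALSE
  )
  sample_id <- sprintf("S%06d", seq_len(n))
  rownames(dosage) <- meta$id
  colnames(dosage) <- sample_id
  structure(list(dosage = dosage, variants = meta, sample_id = sample_id),
            class = "genotype_block")
}

#' Simulate phenotypes, covariates and medication masking
#'
#' Generates the five cardiometabolic traits under the linear SNP-by-age
#' model described in [simulation_spec()], applies the medication masking
#' (statins multiply measured LDL-C, antihypertensives subtract from
#' measured SBP), then missingness, and returns both the measured phenotype
#' table and a truth table of the generative effects.
#'
#' @param genotypes A `genotype_block` from [simulate_genotypes()].
#' @param spec The same [simulation_spec()].
#' @return List with `phenotypes` (data frame: sample_id, age, sex, the five
#'   traits on their measured scales, statin/bp_med flags, pc1..pc10) and
#'   `truth` (data frame: variant_id, trait, beta_g, beta_gxage, age_center).
#' @export
simulate_phenotypes <- function(genotypes, spec) {
  stopifnot(inherits(spec, "simulation_spec"),
            inherits(genotypes, "genotype_block"))
  n <- spec$n_individuals
  if (ncol(genotypes$dosage) != n) {
    stop("dimension error: genotype columns (", ncol(genotypes$dosage),
         ") != spec n_individuals (", n, ")", call. = FALSE)
  }
  # phenotype stream is seeded independently of the genotype stream so the
  # same genotypes can carry replicate phenotype draws
  set.seed(spec$seed + 1L)
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  sex <- ifelse(stats::runif(n) < spec$sex_fraction_female,
                "female", "male")
  male <- as.numeric(sex == "male")
  pcs <- matrix(stats::rnorm(n * 10), nrow = n,
                dimnames = list(NULL, paste0("pc", 1:10)))

  cc <- if (identical(spec$age_center, "mean")) mean(age) else spec$age_center
  G <- genotypes$dosage                     # m x n
  m <- nrow(G)

  bg <- sapply(sim_traits, function(tr) {
    vapply(spec$variants, function(v) {
      if (tr %in% names(v$beta_g)) v$beta_g[[tr]] else 0
    }, numeric(1))
  })                                         # m x 5
  bi <- sapply(sim_traits, function(tr) {
    vapply(spec$variants, function(v) {
      if (tr %in% names(v$beta_gxage)) v$beta_gxage[[tr]] else 0
    }, numeric(1))
  })
  bg <- matrix(bg, nrow = m); bi <- matrix(bi, nrow = m)

  pheno <- data.frame(sample_id = genotypes$sample_id, age = age, sex = sex,
                      stringsAsFactors = FALSE)
  genet <- crossprod(G, bg) +                       # n x 5: sum beta_g * g
    crossprod(G, bi) * (age - cc)                   # + sum beta_int*(age-c)*g
  for (k in seq_along(sim_traits)) {
    tr <- sim_traits[k]
    p <- spec$trait_params[[tr]]
    y <- p$intercept + p$age_slope * age + p$sex_effect * male +
      genet[, k] + as.vector(pcs %*% spec$pc_effects[tr, ]) +
      stats::rnorm(n, 0, p$noise_sd)
    pheno[[tr]] <- if (tr == "tg") exp(y) else y    # tg generated on log scale
  }

  med <- spec$medication_model
  st <- med$statin
  p_statin <- stats::plogis(st$intercept + st$age_slope * (age - st$age_center) +
                              st$trait_slope * (pheno[[st$trait]] - st$trait_center))
  bp <- med$bp_med
  p_bp <- stats::plogis(bp$intercept + bp$age_slope * (age - bp$age_center) +
                          bp$trait_slope * (pheno[[bp$trait]] - bp$trait_center))
  pheno$statin <- as.integer(stats::runif(n) < p_statin)
  pheno$bp_med <- as.integer(stats::runif(n) < p_bp)
  # medication masks the measurement of the treated trait
  pheno$ldl <- ifelse(pheno$statin == 1,
                      pheno$ldl * st$ldl_multiplier, pheno$ldl)
  pheno$sbp <- ifelse(pheno$bp_med == 1,
                      pheno$sbp - bp$sbp_reduction, pheno$sbp)

  for (k in 1:10) pheno[[paste0("pc", k)]] <- pcs[, k]

  for (tr in sim_traits) {
    pr <- spec$missingness[[tr]]
    if (!is.null(pr) && pr > 0) {
      pheno[[tr]][stats::runif(n) < pr] <- NA_real_
    }
  }

  # one row per variant-trait pair, variant-major
  truth <- data.frame(
    variant_id = rep(genotypes$variants$id, each = length(sim_traits)),
    trait = rep(sim_traits, times = m),
    beta_g = as.vector(t(bg)),
    beta_gxage = as.vector(t(bi)),
    age_center = cc, stringsAsFactors = FALSE)

  list(phenotypes = pheno, truth = truth)
}

#' Simulate a complete cohort in one call
#'
#' @param spec A [simulation_spec()].
#' @return List with `genotypes`, `phenotypes` and `truth`.
#' @export
simulate_cohort <- function(spec) {
  g <- simulate_genotypes(spec)
  ph <- simulate_phenotypes(g, spec)
  list(genotypes = g, phenotypes = ph$phenotypes, truth = ph$truth)
}

#' Write a simulated cohort to disk
#'
#' Writes the genotypes as VCF v4.2 (GT and DS fields), the phenotype /
#' covariate table and the truth table as tab-separated text.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param prefix Output path prefix; files `<prefix>.vcf`,
#'   `<prefix>_pheno.tsv`, `<prefix>_truth.tsv` are produced.
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, prefix) {
  vcf <- paste0(prefix, ".vcf")
  write_vcf(cohort$genotypes, vcf)
  ph <- paste0(prefix, "_pheno.tsv")
  write_pheno(cohort$phenotypes, ph)
  tr <- paste0(prefix, "_truth.tsv")
  utils::write.table(cohort$truth, tr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(vcf = vcf, pheno = ph, truth = tr))
}
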