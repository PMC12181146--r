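#!/usr/bin/env Rscript
# Stage 1 — build the synthetic study cohort.
#
# A biobank-style cohort of 8,000 unrelated adults aged 40-70 (54.2% women)
# with 150 variants: two LD blocks (copula rho 0.8 and 0.9) plus unlinked
# background variants, and four causal variants with known architecture:
#   - apob_hit:  strong SNP-by-age interaction on ApoB (the GWIS discovery)
#   - tg_hit:    strong marginal TG effect whose age interaction is too weak
#                for genome-wide discovery (the look-up-stage catch)
#   - sbp_mild:  SBP main effect attenuating with age
#   - bmi_null:  main effect only, a negative control for the scan
# Medication masking is on: statin use lowers measured LDL-C
# multiplicatively, antihypertensive use lowers measured SBP additively.

suppressPackageStartupMessages(library(snpage))

out_dir <- "results/cohort"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260101 %% 100000

variants <- c(
  variant_panel(30, maf = 0.25, chrom = "1", prefix = "blkA_"),
  variant_panel(30, maf = 0.15, chrom = "2", prefix = "blkB_"),
  variant_panel(86, maf = 0.3, chrom = "3", prefix = "bg_"),
  list(
    variant_spec("apob_hit", chrom = "4", pos = 1e6, maf = 0.30,
                 beta_g = c(apob = 0.05), beta_gxage = c(apob = 0.004)),
    variant_spec("tg_hit", chrom = "4", pos = 2e6, maf = 0.25,
                 beta_g = c(tg = 0.30), beta_gxage = c(tg = -0.003)),
    variant_spec("sbp_mild", chrom = "4", pos = 3e6, maf = 0.35,
                 beta_g = c(sbp = 2.5), beta_gxage = c(sbp = -0.05)),
    variant_spec("bmi_null", chrom = "4", pos = 4e6, maf = 0.20,
                 beta_g = c(bmi = 0.5))))

spec <- simulation_spec(
  n_individuals = 8000,
  variants = variants,
  ld_blocks = list(list(from = 1, to = 30, rho = 0.8),
                   list(from = 31, to = 60, rho = 0.9)),
  missingness = c(apob = 0.01, ldl = 0.01, tg = 0.01, sbp = 0.005,
                  bmi = 0.005),
  seed = seed)

cohort <- simulate_cohort(spec)
paths <- write_cohort(cohort, file.path(out_dir, "cohort"))

cat(sprintf("Simulated %d individuals x %d variants (seed %d)\n",
            ncol(cohort$genotypes$dosage), nrow(cohort$genotypes$dosage),
            seed))
cat(sprintf("Statin use: %.1f%%; antihypertensive use: %.1f%%\n",
            100 * mean(cohort$phenotypes$statin),
            100 * mean(cohort$phenotypes$bp_med)))
cat("Wrote:", paste(paths, collapse = ", "), "\n")
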