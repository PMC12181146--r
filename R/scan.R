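#' Scan configuration
#'
#' @param maf_min Variants with minor allele frequency strictly below this
#'   are removed (default 0.001); a variant at exactly the boundary is kept.
#' @param model Which model(s) to fit: `"both"`, `"interaction"` or
#'   `"marginal"`.
#' @param se_type `"model"` or `"robust"` standard errors.
#' @param block_size Variants per streamed block.
#' @param alpha Genome-wide significance level before the trait correction
#'   (default 5e-8).
#' @param n_traits Number of risk factors sharing the Bonferroni budget
#'   (default 5, giving a per-trait threshold of 1e-8).
#' @param na_action Missing-dosage policy, see [fit_interaction()].
#' @return A `scan_config` list.
#' @export
scan_config <- function(maf_min = 0.001,
                        model = c("both", "interaction", "marginal"),
                        se_type = c("model", "robust"),
                        block_size = 512L,
                        alpha = 5e-8, n_traits = 5,
                        na_action = c("mean_impute", "drop")) {
  model <- match.arg(model)
  se_type <- match.arg(se_type)
  na_action <- match.arg(na_action)
  if (maf_min < 0 || maf_min >= 0.5) {
    stop("maf_min must be in [0, 0.5)", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(maf_min = maf_min, model = model, se_type = se_type,
                 block_size = as.integer(block_size), alpha = alpha,
                 n_traits = n_traits, na_action = na_action),
            class = "scan_config")
}

#' Per-trait genome-wide significance threshold
#'
#' Bonferroni division of the genome-wide level across the analysed traits:
#' `alpha / n_traits` (e.g. 5e-8 over five risk factors gives 1e-8).
#'
#' @param alpha Genome-wide level in (0, 1).
#' @param n_traits Number of traits (>= 1).
#' @return The per-trait threshold.
#' @export
genomewide_threshold <- function(alpha = 5e-8, n_traits = 5) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (n_traits < 1) stop("n_traits must be >= 1", call. = FALSE)
  alpha / n_traits
}

#' Effect-allele frequency of dosage rows
#' @param G Dosage matrix, variants in rows.
#' @return Numeric vector of EAFs (mean dosage / 2, missing dropped).
#' @export
eaf <- function(G) rowMeans(G, na.rm = TRUE) / 2

#' Filter a genotype block on minor allele frequency
#'
#' MAF is computed on the analysis sample (the columns of the block as
#' given, i.e. after phenotype exclusions). A variant whose MAF is exactly
#' `maf_min` is kept: only frequencies strictly below the bound are removed.
#'
#' @param block A `genotype_block`.
#' @param maf_min Removal bound (default 0.001).
#' @return List with `kept` (filtered block) and `removed` (ids).
#' @export
maf_filter <- function(block, maf_min = 0.001) {
  f <- eaf(block$dosage)
  maf <- pmin(f, 1 - f)
  drop <- maf < maf_min
  kept <- block
  kept$dosage <- block$dosage[!drop, , drop = FALSE]
  kept$variants <- block$variants[!drop, , drop = FALSE]
  rownames(kept$variants) <- NULL
  list(kept = kept, removed = block$variants$id[drop])
}

#' Run the interaction / marginal scan over a cohort
#'
#' For each requested trait and each variant passing the MAF filter, fits
#' the SNP-by-age interaction model and/or the marginal model and emits one
#' summary-statistics row. Samples are reconciled between the genotype
#' block and the phenotype table by `sample_id` (intersection used); MAF is
#' computed on that analysis sample. Rows are ordered by (chrom, pos, id)
#' and carry a significance flag against the per-trait Bonferroni
#' threshold.
#'
#' @param genotypes A `genotype_block`.
#' @param phenotypes Preprocessed phenotype table.
#' @param cfg A [scan_config()].
#' @param traits Traits to scan (default the five risk factors).
#' @return Data frame of scan rows: variant metadata, `EAF`, `MAF`, `N`,
#'   `trait`, betas/SEs/p-values, `sig_int` flag, `flag`.
#' @export
run_scan <- function(genotypes, phenotypes, cfg = scan_config(),
                     traits = sim_traits) {
  common <- intersect(genotypes$sample_id, phenotypes$sample_id)
  if (length(common) == 0) {
    stop("alignment error: no overlapping samples between genotypes and ",
         "phenotypes", call. = FALSE)
  }
  gi <- match(common, genotypes$sample_id)
  pi <- match(common, phenotypes$sample_id)
  G <- genotypes$dosage[, gi, drop = FALSE]
  ph <- phenotypes[pi, , drop = FALSE]

  blk <- genotypes
  blk$dosage <- G
  blk$sample_id <- common
  flt <- maf_filter(blk, cfg$maf_min)
  blk <- flt$kept
  if (length(flt$removed) > 0) {
    message(length(flt$removed), " variant(s) removed by MAF filter")
  }
  m <- nrow(blk$dosage)
  if (m == 0) return(empty_scan_rows())

  covars <- covariate_matrix(ph)
  thr <- genomewide_threshold(cfg$alpha, cfg$n_traits)
  f <- eaf(blk$dosage)

  out <- vector("list", length(traits))
  for (k in seq_along(traits)) {
    tr <- traits[k]
    res <- scan_block(ph[[tr]], blk$dosage, ph$age, covars,
                      model = cfg$model, se_type = cfg$se_type,
                      na_action = cfg$na_action)
    rows <- cbind(blk$variants[, c("id", "chrom", "pos",
                                   "non_effect_allele", "effect_allele")],
                  data.frame(eaf = f, maf = pmin(f, 1 - f),
                             trait = tr, stringsAsFactors = FALSE),
                  res[, setdiff(names(res), "variant_id")])
    rows$sig_int <- !is.na(rows$p_int) & rows$p_int < thr
    out[[k]] <- rows
  }
  out <- do.call(rbind, out)
  out <- out[order(out$trait, out$chrom, out$pos, out$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold_int") <- thr
  attr(out, "config") <- cfg
  out
}

empty_scan_rows <- function() {
  data.frame(id = character(0), chrom = character(0), pos = integer(0),
             non_effect_allele = character(0), effect_allele = character(0),
             eaf = numeric(0), maf = numeric(0), trait = character(0),
             n = integer(0), beta_g = numeric(0), se_g = numeric(0),
             beta_age = numeric(0), se_age = numeric(0),
             beta_int = numeric(0), se_int = numeric(0),
             p_int = numeric(0), p_marginal = numeric(0),
             flag = character(0), sig_int = logical(0),
             stringsAsFactors = FALSE)
}
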