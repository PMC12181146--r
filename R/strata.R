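#' Age- and sex-stratified genotype effects for one variant
#'
#' Within each age group (and sex scope), fits an OLS of the trait on the
#' coded genotype, adjusting for sex (omitted when sex-stratified) and the
#' ten principal components — age itself is not a covariate inside a
#' stratum. Genotype coding is either additive (per effect allele) or
#' categorical: indicator contrasts for heterozygotes and effect-allele
#' homozygotes against the non-effect homozygote reference. For a
#' log-transformed trait the fold-change `exp(beta)` and its CI are added,
#' interpretable as the multiplicative effect on the raw scale.
#'
#' Fractional dosages are rounded to the nearest hard call (ties at .5 go
#' up); the number of entries changed by rounding is reported in the
#' `n_rounded` attribute.
#'
#' @param phenotypes Preprocessed phenotype table.
#' @param dosage Named or sample-aligned dosage vector for the variant.
#' @param trait Trait column to analyse.
#' @param age_bins Age-group table, see [default_age_bins()].
#' @param coding `"genotype"` (two contrasts vs. the reference homozygote)
#'   or `"additive"` (per allele).
#' @param sex_scope `"all"`, `"women"` or `"men"`.
#' @param conf_level Wald CI level (default 0.95, normal quantile).
#' @param log_scale Is the trait on a natural-log scale (default: yes for
#'   `tg` when the table's `tg_scale` attribute says so)?
#' @return Data frame, one row per bin x contrast: `bin`, `sex_scope`,
#'   `contrast`, `n`, `beta`, `se`, `ci_lo`, `ci_hi`, and
#'   `fold_change`/`fold_lo`/`fold_hi` for log-scale traits.
#' @export
stratified_fit <- function(phenotypes, dosage, trait,
                           age_bins = default_age_bins(),
                           coding = c("genotype", "additive"),
                           sex_scope = c("all", "women", "men"),
                           conf_level = 0.95,
                           log_scale = NULL) {
  coding <- match.arg(coding)
  sex_scope <- match.arg(sex_scope)
  if (is.null(log_scale)) {
    log_scale <- trait == "tg" && identical(attr(phenotypes, "tg_scale"),
                                            "log")
  }
  g <- as.numeric(dosage)
  hard <- round(g)
  n_rounded <- sum(hard != g, na.rm = TRUE)
  if (coding == "genotype") g <- hard

  keep_sex <- switch(sex_scope,
                     all = rep(TRUE, nrow(phenotypes)),
                     women = phenotypes$sex == "female",
                     men = phenotypes$sex == "male")
  if (!any(keep_sex, na.rm = TRUE)) {
    stop("empty stratum: no ", sex_scope, " in the dataset", call. = FALSE)
  }
  bins <- assign_age_bins(phenotypes$age, age_bins)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  out <- list()
  for (b in age_bins$label) {
    idx <- which(keep_sex & !is.na(bins) & bins == b)
    ph <- phenotypes[idx, , drop = FALSE]
    gg <- g[idx]
    W <- covariate_matrix(ph, include_sex = sex_scope == "all")
    y <- ph[[trait]]
    ok <- !is.na(y) & !is.na(gg) & stats::complete.cases(W)
    y <- y[ok]; gg <- gg[ok]; W <- W[ok, , drop = FALSE]

    contrasts <- if (coding == "additive") {
      list(additive = gg)
    } else {
      list(het = as.numeric(gg == 1), hom = as.numeric(gg == 2))
    }
    # a genotype category absent from the stratum leaves its contrast
    # unavailable (NA); the remaining contrasts are still estimated
    present <- vapply(contrasts, function(x) sum(x, na.rm = TRUE) > 0,
                      logical(1))
    fit <- NULL
    if (any(present)) {
      Xg <- do.call(cbind, contrasts[present])
      if (length(y) > ncol(W) + ncol(Xg)) {
        fit <- tryCatch(ols_wald(cbind(W, Xg), y), error = function(e) NULL)
      }
    }
    for (cn in names(contrasts)) {
      est <- if (!is.null(fit) && cn %in% names(fit$beta)) {
        c(fit$beta[cn], fit$se[cn])
      } else {
        c(NA_real_, NA_real_)
      }
      row <- data.frame(bin = b, sex_scope = sex_scope, contrast = cn,
                        n = length(y), beta = unname(est[1]),
                        se = unname(est[2]),
                        ci_lo = unname(est[1] - z * est[2]),
                        ci_hi = unname(est[1] + z * est[2]),
                        stringsAsFactors = FALSE)
      if (log_scale) {
        row$fold_change <- exp(row$beta)
        row$fold_lo <- exp(row$ci_lo)
        row$fold_hi <- exp(row$ci_hi)
      }
      out[[length(out) + 1]] <- row
    }
  }
  out <- do.call(rbind, out)
  attr(out, "n_rounded") <- n_rounded
  if (n_rounded > 0) {
    message(n_rounded, " dosage value(s) rounded to hard calls")
  }
  out
}

#' Genotype frequency table by age group
#'
#' Percentage of each hard-call genotype category within each age bin, the
#' descriptive check that genotype distributions are stable across age
#' groups (survivorship would distort them).
#'
#' @param dosage Hard-call dosage vector.
#' @param age Age vector aligned to `dosage`.
#' @param age_bins Bin table, see [default_age_bins()].
#' @return Data frame: `bin`, `n`, `pct_ref` (0 copies), `pct_het` (1),
#'   `pct_hom` (2 copies of the effect allele).
#' @export
genotype_frequencies <- function(dosage, age, age_bins = default_age_bins()) {
  hard <- round(as.numeric(dosage))
  bins <- assign_age_bins(age, age_bins)
  rows <- lapply(age_bins$label, function(b) {
    idx <- which(!is.na(bins) & bins == b & !is.na(hard))
    n <- length(idx)
    pct <- if (n > 0) {
      100 * c(sum(hard[idx] == 0), sum(hard[idx] == 1),
              sum(hard[idx] == 2)) / n
    } else {
      rep(NA_real_, 3)
    }
    data.frame(bin = b, n = n, pct_ref = pct[1], pct_het = pct[2],
               pct_hom = pct[3], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Render genotype frequencies with two decimals
#' @param freq Output of [genotype_frequencies()].
#' @return The same table with percentage columns formatted as strings.
#' @export
format_genotype_frequencies <- function(freq) {
  for (cn in c("pct_ref", "pct_het", "pct_hom")) {
    freq[[cn]] <- sprintf("%.2f%%", freq[[cn]])
  }
  freq
}

#' SNP-by-age interaction fitted separately in women and men
#'
#' Runs [fit_interaction()] on each sex subset with the sex column dropped
#' from the covariates.
#'
#' @param phenotypes Preprocessed phenotype table.
#' @param dosage Dosage vector aligned to the table.
#' @param trait Trait column.
#' @param se_type Passed to [fit_interaction()].
#' @return List with `women` and `men` `fit_result`s.
#' @export
interaction_by_sex <- function(phenotypes, dosage, trait,
                               se_type = c("model", "robust")) {
  se_type <- match.arg(se_type)
  one <- function(which_sex) {
    idx <- which(phenotypes$sex == which_sex)
    if (length(idx) == 0) {
      stop("empty stratum: no ", which_sex, " samples", call. = FALSE)
    }
    ph <- phenotypes[idx, , drop = FALSE]
    fit_interaction(ph[[trait]], as.numeric(dosage)[idx], ph$age,
                    covariate_matrix(ph, include_sex = FALSE),
                    se_type = se_type)
  }
  list(women = one("female"), men = one("male"))
}

#' Forest-style plot of stratified genotype effects
#'
#' One panel per contrast, point estimate and CI per age bin; fold-change
#' scale for log traits.
#'
#' @param strata Output of [stratified_fit()].
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_stratified <- function(strata, title = "Age-stratified genotype effects") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  use_fold <- "fold_change" %in% names(strata)
  df <- strata
  if (use_fold) {
    df$est <- df$fold_change; df$lo <- df$fold_lo; df$hi <- df$fold_hi
    ref <- 1
  } else {
    df$est <- df$beta; df$lo <- df$ci_lo; df$hi <- df$ci_hi
    ref <- 0
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$est, y = .data$bin)) +
    ggplot2::geom_vline(xintercept = ref, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo,
                                          xmax = .data$hi)) +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::labs(title = title, y = "Age group",
                  x = if (use_fold) "Fold-change (95% CI)" else
                    "Effect (95% CI)") +
    ggplot2::theme_minimal()
}
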