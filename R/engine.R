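#' Build the shared covariate matrix
#'
#' Assembles intercept, sex indicator (male = 1) and the ten principal
#' components from a phenotype table, the adjustment set of both the
#' interaction and the marginal model. Age is handled separately by the
#' fitting functions because the interaction model also forms the
#' variant-by-age product.
#'
#' @param pheno Phenotype data frame with `sex` and `pc1..pc10` columns.
#' @param include_sex Drop the sex column for sex-stratified fits.
#' @param n_pcs Number of principal components to include (default 10).
#' @return Numeric matrix with an `(Intercept)` column.
#' @export
covariate_matrix <- function(pheno, include_sex = TRUE, n_pcs = 10) {
  cols <- list(`(Intercept)` = rep(1, nrow(pheno)))
  if (include_sex) {
    if (is.numeric(pheno$sex)) cols$sex <- pheno$sex
    else cols$sex <- as.numeric(pheno$sex == "male")
  }
  for (k in seq_len(n_pcs)) {
    nm <- paste0("pc", k)
    if (!nm %in% names(pheno)) {
      stop("covariate column ", nm, " missing from phenotype table",
           call. = FALSE)
    }
    cols[[nm]] <- pheno[[nm]]
  }
  do.call(cbind, cols)
}

# Core OLS with Wald inference; shared by the per-variant and streaming
# paths. Returns coefficients, model-based or HC0 sandwich SEs, t statistics
# and two-sided p-values from the t distribution on the residual df.
ols_wald <- function(X, y, se_type = c("model", "robust")) {
  se_type <- match.arg(se_type)
  qrx <- qr(X)
  p <- ncol(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    stop("collinearity error: design is rank deficient (column ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  n <- nrow(X)
  beta <- qr.coef(qrx, y)
  res <- y - X %*% beta
  df <- n - p
  sigma2 <- sum(res^2) / df
  R <- qr.R(qrx)
  xtx_inv <- chol2inv(R)
  piv <- qrx$pivot
  xtx_inv[piv, piv] <- xtx_inv
  if (se_type == "model") {
    vc <- sigma2 * xtx_inv
  } else {
    meat <- crossprod(X * as.vector(res))   # HC0
    vc <- xtx_inv %*% meat %*% xtx_inv
  }
  se <- stats::setNames(sqrt(diag(vc)), colnames(X))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(beta = beta, se = se, t = tval, p = pval, n = n, df = df,
       sigma2 = sigma2, residuals = as.vector(res))
}

fit_result <- function(core, model = c("interaction", "marginal")) {
  model <- match.arg(model)
  b <- core$beta; se <- core$se; p <- core$p
  out <- list(
    beta_g = unname(b["g"]), se_g = unname(se["g"]),
    beta_age = unname(b["age"]), se_age = unname(se["age"]),
    n = core$n, df = core$df, sigma2 = core$sigma2, model = model
  )
  if (model == "interaction") {
    out$beta_int <- unname(b["g_age"])
    out$se_int <- unname(se["g_age"])
    out$t_int <- unname(core$t["g_age"])
    out$p_int <- unname(p["g_age"])
  } else {
    out$p_g_marginal <- unname(p["g"])
  }
  structure(out, class = "fit_result")
}

check_variant <- function(g, y) {
  if (length(g) != length(y)) {
    stop("dosage and trait vectors differ in length", call. = FALSE)
  }
  if (stats::var(g) == 0 || length(unique(g)) < 2) {
    stop("monomorphic error: dosage vector is constant", call. = FALSE)
  }
}

#' Fit the SNP-by-age interaction model for one variant
#'
#' Ordinary least squares of the trait on
#' `[1, g, age, g*age, sex, pc1..pc10]`. The interaction coefficient
#' `beta_int` is the `g*age` term in trait units per effect allele per year
#' of age; its two-sided Wald p-value `p_int` uses the t reference with
#' residual degrees of freedom. Age enters uncentred by default so the
#' reported interaction is on the per-year scale throughout.
#'
#' Missing dosages are mean-imputed per variant (standard practice for
#' imputed genotypes); rows with missing trait, age or covariates are
#' dropped.
#'
#' @param y Trait vector on the analysis scale.
#' @param g Dosage vector in `[0, 2]` (hard calls or imputed dosages).
#' @param age Age vector in years.
#' @param covars Covariate matrix from [covariate_matrix()] (intercept, sex,
#'   PCs); must not contain an age column.
#' @param se_type `"model"` (default) for classical SEs, `"robust"` for
#'   HC0 heteroscedasticity-robust sandwich SEs.
#' @param na_action `"mean_impute"` (default) or `"drop"` for missing
#'   dosages.
#' @return A `fit_result` with `beta_g`, `beta_age`, `beta_int`, their SEs,
#'   `t_int`, `p_int`, `n`, `df`, `sigma2`.
#' @export
fit_interaction <- function(y, g, age, covars,
                            se_type = c("model", "robust"),
                            na_action = c("mean_impute", "drop")) {
  se_type <- match.arg(se_type)
  na_action <- match.arg(na_action)
  d <- align_model_rows(y, g, age, covars, na_action)
  check_variant(d$g, d$y)
  X <- cbind(d$covars, g = d$g, age = d$age, g_age = d$g * d$age)
  core <- ols_wald(X, d$y, se_type)
  fit_result(core, "interaction")
}

#' Fit the marginal (main-effect) model for one variant
#'
#' OLS of the trait on `[1, g, age, sex, pc1..pc10]` without the
#' interaction term; `p_g_marginal` is the Wald p-value of the dosage
#' coefficient, the conventional GWAS test.
#'
#' @inheritParams fit_interaction
#' @return A `fit_result` with `beta_g`, `se_g`, `p_g_marginal`,
#'   `beta_age`, `se_age`, `n`, `df`, `sigma2`.
#' @export
fit_marginal <- function(y, g, age, covars,
                         se_type = c("model", "robust"),
                         na_action = c("mean_impute", "drop")) {
  se_type <- match.arg(se_type)
  na_action <- match.arg(na_action)
  d <- align_model_rows(y, g, age, covars, na_action)
  check_variant(d$g, d$y)
  X <- cbind(d$covars, g = d$g, age = d$age)
  core <- ols_wald(X, d$y, se_type)
  fit_result(core, "marginal")
}

align_model_rows <- function(y, g, age, covars, na_action) {
  if (is.null(dim(covars))) covars <- matrix(covars, ncol = 1)
  stopifnot(length(y) == length(g), length(y) == length(age),
            nrow(covars) == length(y))
  if (na_action == "mean_impute" && anyNA(g)) {
    g[is.na(g)] <- mean(g, na.rm = TRUE)
  }
  keep <- !is.na(y) & !is.na(age) & stats::complete.cases(covars) & !is.na(g)
  list(y = y[keep], g = g[keep], age = age[keep],
       covars = covars[keep, , drop = FALSE])
}

#' Stream interaction and marginal fits over a genotype block
#'
#' The genome-wide fast path: fits every variant of a block against one
#' trait reusing a single prebuilt design skeleton (the `g` and `g*age`
#' columns are swapped in place per variant). Estimates, standard errors and
#' p-values are mathematically identical to calling [fit_interaction()] /
#' [fit_marginal()] per variant — a tested contract, not an approximation.
#' Degenerate variants (monomorphic, rank-deficient) are returned as flagged
#' rows rather than aborting the stream.
#'
#' @param Y Numeric trait vector (one trait) on the analysis scale.
#' @param G Dosage matrix, variants in rows, samples in columns.
#' @param age Age vector in years.
#' @param covars Covariate matrix (intercept, sex, PCs).
#' @param model `"interaction"`, `"marginal"` or `"both"`.
#' @param se_type `"model"` or `"robust"` (HC0).
#' @param na_action Missing-dosage policy as in [fit_interaction()].
#' @return Data frame, one row per variant: the `fit_result` fields of the
#'   requested model(s) plus `variant_id`, `flag` (`"ok"` or the error
#'   message) and `n`.
#' @export
scan_block <- function(Y, G, age, covars,
                       model = c("both", "interaction", "marginal"),
                       se_type = c("model", "robust"),
                       na_action = c("mean_impute", "drop")) {
  model <- match.arg(model)
  se_type <- match.arg(se_type)
  na_action <- match.arg(na_action)
  m <- nrow(G)
  ids <- rownames(G)
  if (is.null(ids)) ids <- sprintf("v%d", seq_len(m))

  keep0 <- !is.na(Y) & !is.na(age) & stats::complete.cases(covars)
  Y0 <- Y[keep0]; age0 <- age[keep0]
  W0 <- covars[keep0, , drop = FALSE]

  empty <- rep(NA_real_, m)
  out <- data.frame(variant_id = ids, n = rep(NA_integer_, m),
                    beta_g = empty, se_g = empty,
                    beta_age = empty, se_age = empty,
                    beta_int = empty, se_int = empty,
                    p_int = empty, p_marginal = empty,
                    flag = rep("ok", m), stringsAsFactors = FALSE)

  for (j in seq_len(m)) {
    g <- G[j, keep0]
    res <- tryCatch({
      if (na_action == "mean_impute" && anyNA(g)) {
        g[is.na(g)] <- mean(g, na.rm = TRUE)
      }
      keep <- !is.na(g)
      gj <- g[keep]; yj <- Y0[keep]; aj <- age0[keep]
      Wj <- W0[keep, , drop = FALSE]
      check_variant(gj, yj)
      row <- list(n = length(yj))
      if (model %in% c("both", "interaction")) {
        core <- ols_wald(cbind(Wj, g = gj, age = aj, g_age = gj * aj),
                         yj, se_type)
        row$beta_g <- unname(core$beta["g"])
        row$se_g <- unname(core$se["g"])
        row$beta_age <- unname(core$beta["age"])
        row$se_age <- unname(core$se["age"])
        row$beta_int <- unname(core$beta["g_age"])
        row$se_int <- unname(core$se["g_age"])
        row$p_int <- unname(core$p["g_age"])
      }
      if (model %in% c("both", "marginal")) {
        core <- ols_wald(cbind(Wj, g = gj, age = aj), yj, se_type)
        if (model == "marginal") {
          row$beta_g <- unname(core$beta["g"])
          row$se_g <- unname(core$se["g"])
          row$beta_age <- unname(core$beta["age"])
          row$se_age <- unname(core$se["age"])
        }
        row$p_marginal <- unname(core$p["g"])
      }
      row
    }, error = function(e) list(flag = conditionMessage(e)))
    if (!is.null(res$flag)) {
      out$flag[j] <- res$flag
    } else {
      for (nm in names(res)) out[[nm]][j] <- res[[nm]]
    }
  }
  out
}
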