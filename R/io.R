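#' Write a genotype block as VCF v4.2
#'
#' Emits one record per variant with GT (rounded hard call) and DS (dosage)
#' fields, REF = non-effect allele, ALT = effect allele, so the
#' effect-counted allele is the ALT dosage throughout.
#'
#' @param block A `genotype_block`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(block, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=snpage",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage of ALT allele">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", block$sample_id), collapse = "\t")), con)
  gt_of <- c("0/0", "0/1", "1/1")
  v <- block$variants
  for (j in seq_len(nrow(v))) {
    ds <- block$dosage[j, ]
    hard <- pmin(pmax(round(ds), 0), 2)
    cells <- paste0(gt_of[hard + 1], ":", format_num(ds))
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j],
                       v$non_effect_allele[j], v$effect_allele[j],
                       ".", "PASS", ".", "GT:DS", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

format_num <- function(x) {
  out <- formatC(x, digits = 12, format = "g")
  gsub(" ", "", out)
}

#' Read genotypes from VCF or a dosage TSV
#'
#' VCF records need GT or DS; DS is preferred when both are present.
#' Multi-allelic records are skipped with a warning. The dosage-TSV dialect
#' is the transpose-free matrix the package writes: columns `id`, `chrom`,
#' `pos`, `non_effect_allele`, `effect_allele` followed by one column per
#' sample.
#'
#' @param path Input file.
#' @param format `"vcf"` or `"dosage-tsv"` (guessed from the extension by
#'   default).
#' @return A `genotype_block`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage-tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage-tsv"
  }
  if (format == "vcf") read_vcf_block(path) else read_dosage_tsv(path)
}

read_vcf_block <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
  }
  keep <- !multi
  samples <- colnames(vcf@gt)[-1]
  fmt <- vcf@gt[, 1]
  has_ds <- grepl("(^|:)DS(:|$)", fmt)

  n <- length(samples)
  m <- sum(keep)
  dosage <- matrix(NA_real_, nrow = m, ncol = n)
  rows <- which(keep)
  for (r in seq_along(rows)) {
    i <- rows[r]
    keys <- strsplit(fmt[i], ":", fixed = TRUE)[[1]]
    cells <- strsplit(vcf@gt[i, -1], ":", fixed = TRUE)
    if (has_ds[i]) {
      k <- match("DS", keys)
      dosage[r, ] <- as.numeric(vapply(cells, `[`, character(1), k))
    } else {
      k <- match("GT", keys)
      if (is.na(k)) stop("record without GT or DS at line ", i, call. = FALSE)
      gt <- vapply(cells, `[`, character(1), k)
      dosage[r, ] <- vapply(strsplit(gt, "[/|]"), function(a) {
        if (any(a == ".")) NA_real_ else sum(a == "1")
      }, numeric(1))
    }
  }
  meta <- data.frame(id = fix$ID[keep], chrom = fix$CHROM[keep],
                     pos = as.integer(fix$POS[keep]),
                     non_effect_allele = fix$REF[keep],
                     effect_allele = fix$ALT[keep],
                     stringsAsFactors = FALSE)
  meta$maf <- pmin(rowMeans(dosage, na.rm = TRUE) / 2,
                   1 - rowMeans(dosage, na.rm = TRUE) / 2)
  rownames(dosage) <- meta$id
  colnames(dosage) <- samples
  structure(list(dosage = dosage, variants = meta, sample_id = samples),
            class = "genotype_block")
}

#' Write a genotype block as a dosage TSV
#' @param block A `genotype_block`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dosage_tsv <- function(block, path) {
  df <- cbind(block$variants[, c("id", "chrom", "pos", "non_effect_allele",
                                 "effect_allele")],
              as.data.frame(block$dosage, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("id", "chrom", "pos", "non_effect_allele", "effect_allele")
  if (!all(meta_cols %in% names(df))) {
    stop("dosage TSV missing columns: ",
         paste(setdiff(meta_cols, names(df)), collapse = ", "),
         call. = FALSE)
  }
  samples <- setdiff(names(df), meta_cols)
  dosage <- as.matrix(df[, samples, drop = FALSE])
  rownames(dosage) <- df$id
  meta <- df[, meta_cols]
  meta$chrom <- as.character(meta$chrom)
  f <- rowMeans(dosage, na.rm = TRUE) / 2
  meta$maf <- pmin(f, 1 - f)
  structure(list(dosage = dosage, variants = meta, sample_id = samples),
            class = "genotype_block")
}

#' Write / read the phenotype TSV
#'
#' Columns: sample_id, age, sex, apob, ldl, tg, sbp, bmi, statin, bp_med,
#' pc1..pc10; missing values as NA.
#'
#' @param table Phenotype data frame.
#' @param path File path.
#' @return `write_pheno`: invisibly `path`; `read_pheno`: the data frame.
#' @export
write_pheno <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pheno
#' @export
read_pheno <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

results_columns <- c("SNPID", "CHR", "POS", "Non_Effect_Allele",
                     "Effect_Allele", "N", "EAF", "Beta_G", "SE_G",
                     "Beta_Age", "SE_Age", "Beta_GxAge", "SE_GxAge",
                     "P_Int", "P_Marginal")

#' Write scan rows as a summary-statistics TSV
#'
#' One file per trait, fixed column order (`SNPID CHR POS Non_Effect_Allele
#' Effect_Allele N EAF Beta_G SE_G Beta_Age SE_Age Beta_GxAge SE_GxAge P_Int
#' P_Marginal`); `#`-prefixed header lines record the configuration and
#' seed. Round-trips through [read_results()] to 12 significant digits.
#'
#' @param rows Scan rows (one trait).
#' @param path Output path.
#' @param header Named list written as `# key: value` comment lines.
#' @return Invisibly, `path`.
#' @export
write_results <- function(rows, path, header = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(header)) {
    writeLines(paste0("# ", nm, ": ", header[[nm]]), con)
  }
  df <- data.frame(SNPID = rows$id, CHR = rows$chrom, POS = rows$pos,
                   Non_Effect_Allele = rows$non_effect_allele,
                   Effect_Allele = rows$effect_allele,
                   N = rows$n, EAF = format_num(rows$eaf),
                   Beta_G = format_num(rows$beta_g),
                   SE_G = format_num(rows$se_g),
                   Beta_Age = format_num(rows$beta_age),
                   SE_Age = format_num(rows$se_age),
                   Beta_GxAge = format_num(rows$beta_int),
                   SE_GxAge = format_num(rows$se_int),
                   P_Int = format_num(rows$p_int),
                   P_Marginal = format_num(rows$p_marginal),
                   stringsAsFactors = FALSE)
  writeLines(paste(results_columns, collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a summary-statistics TSV written by [write_results()]
#' @param path Input path.
#' @return Scan-row data frame (internal column names).
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(results_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("schema mismatch: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data.frame(id = as.character(df$SNPID), chrom = as.character(df$CHR),
             pos = df$POS,
             non_effect_allele = df$Non_Effect_Allele,
             effect_allele = df$Effect_Allele,
             n = df$N, eaf = df$EAF, maf = pmin(df$EAF, 1 - df$EAF),
             beta_g = df$Beta_G, se_g = df$SE_G,
             beta_age = df$Beta_Age, se_age = df$SE_Age,
             beta_int = df$Beta_GxAge, se_int = df$SE_GxAge,
             p_int = df$P_Int, p_marginal = df$P_Marginal,
             stringsAsFactors = FALSE)
}
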