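#' Full analysis configuration
#'
#' Aggregates the constants of every stage: preprocessing, scan, clumping,
#' look-up, gene mapping, age bins and the seed. Serialized into the run
#' manifest of [run_pipeline()] so outputs are self-describing.
#'
#' @param prep A [prep_config()].
#' @param scan A [scan_config()].
#' @param r2_max Clumping LD bound (default 0.1).
#' @param lookup_alpha Family-wise level of the look-up stage (default
#'   0.05).
#' @param gene_max_dist Positional gene-mapping distance in bp (default
#'   10000).
#' @param age_bins Age-group table (default 40-49 / 50-59 / 60-70).
#' @param traits Traits to scan.
#' @param seed Mandatory integer seed for any stochastic stage.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(prep = prep_config(), scan = scan_config(),
                            r2_max = 0.1, lookup_alpha = 0.05,
                            gene_max_dist = 10000,
                            age_bins = default_age_bins(),
                            traits = sim_traits, seed = NULL) {
  if (is.null(seed)) {
    stop("a seed is required in the analysis configuration", call. = FALSE)
  }
  if (r2_max <= 0 || r2_max > 1) stop("r2_max must be in (0, 1]",
                                      call. = FALSE)
  structure(list(prep = prep, scan = scan, r2_max = r2_max,
                 lookup_alpha = lookup_alpha, gene_max_dist = gene_max_dist,
                 age_bins = age_bins, traits = traits,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Recognised keys mirror the [analysis_config()], [prep_config()] and
#' [scan_config()] arguments (flat, e.g. `maf_min`, `statin_ldl_divisor`,
#' `r2_max`, `seed`).
#'
#' @param path YAML file.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(fn, keys) {
    args <- y[intersect(keys, names(y))]
    do.call(fn, args)
  }
  prep <- pick(prep_config, c("statin_ldl_divisor", "bp_med_sbp_addition",
                              "winsor_k", "tg_log",
                              "winsorize_after_correction",
                              "complete_case_traits"))
  scan <- pick(scan_config, c("maf_min", "model", "se_type", "block_size",
                              "alpha", "n_traits", "na_action"))
  args <- list(prep = prep, scan = scan)
  for (k in c("r2_max", "lookup_alpha", "gene_max_dist", "traits", "seed")) {
    if (k %in% names(y)) args[[k]] <- y[[k]]
  }
  do.call(analysis_config, args)
}

config_hash <- function(cfg) {
  # order-stable serialisation; any field change changes the hash
  s <- paste(utils::capture.output(utils::str(cfg, digits.d = 15)),
             collapse = "\n")
  sum(utf8ToInt(gsub("\\s+", " ", s)) *
        (seq_len(nchar(gsub("\\s+", " ", s))) %% 97 + 1)) %% 2^31
}

#' Run the whole analysis on a cohort
#'
#' Composes every stage on an in-memory cohort: phenotype preprocessing,
#' the interaction + marginal scan, per-trait Bonferroni flagging, greedy
#' LD clumping of genome-wide significant interaction hits, positional gene
#' mapping (when gene intervals are supplied), the two-stage look-up of
#' marginal leads, and age-stratified estimation for each interaction lead.
#' Writes per-trait summary-statistics TSVs, a leads TSV, a look-up TSV,
#' stratified-estimate TSVs, a plain-text report and a JSON manifest
#' (config hash, seed, stage counts) under `out_dir`.
#'
#' @param genotypes A `genotype_block` (e.g. from [simulate_genotypes()] or
#'   [read_genotypes()]).
#' @param phenotypes Raw phenotype table.
#' @param config An [analysis_config()].
#' @param out_dir Output directory (created if needed).
#' @param genes Optional gene-interval data frame for positional mapping.
#' @return Invisibly, a list with `scan_rows`, `gwis_leads`, `lookup`,
#'   `strata`, `manifest`.
#' @export
run_pipeline <- function(genotypes, phenotypes, config, out_dir,
                         genes = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "preprocess"
  res <- tryCatch({
    pheno <- preprocess_phenotypes(phenotypes, config$prep)

    stage <- "scan"
    rows <- run_scan(genotypes, pheno, config$scan, config$traits)
    thr <- attr(rows, "threshold_int")
    hdr <- list(tool = "snpage", seed = config$seed,
                se_type = config$scan$se_type,
                maf_min = config$scan$maf_min,
                threshold_interaction = format_num(thr))
    for (tr in config$traits) {
      write_results(rows[rows$trait == tr, , drop = FALSE],
                    file.path(out_dir, paste0("scan_", tr, ".tsv")), hdr)
    }

    stage <- "clump"
    ld <- ld_matrix(genotypes)
    gwis_leads <- list()
    marginal_leads <- list()
    for (tr in config$traits) {
      sub <- rows[rows$trait == tr, , drop = FALSE]
      gwis_leads[[tr]] <- clump(sub, ld, config$r2_max, p_max = thr,
                                stat = "interaction")
      marginal_leads[[tr]] <- clump(sub, ld, config$r2_max, p_max = 5e-8,
                                    stat = "marginal")
    }
    if (!is.null(genes)) {
      stage <- "map_genes"
      gwis_leads <- lapply(gwis_leads, map_genes, genes = genes,
                           max_dist = config$gene_max_dist)
    }
    lead_df <- leads_table(gwis_leads)
    utils::write.table(lead_df, file.path(out_dir, "gwis_leads.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "lookup"
    lk <- lookup_interactions(marginal_leads, rows, config$lookup_alpha)
    lk_out <- lk
    for (cn in c("threshold", "beta_int", "se_int", "p_int")) {
      lk_out[[cn]] <- format_num(lk_out[[cn]])
    }
    utils::write.table(lk_out, file.path(out_dir, "lookup.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "stratify"
    strata <- list()
    for (tr in names(gwis_leads)) {
      for (l in gwis_leads[[tr]]) {
        id <- l$row$id
        common <- intersect(genotypes$sample_id, pheno$sample_id)
        d <- genotypes$dosage[id, match(common, genotypes$sample_id)]
        ph <- pheno[match(common, pheno$sample_id), , drop = FALSE]
        attr(ph, "tg_scale") <- attr(pheno, "tg_scale")
        st <- stratified_fit(ph, d, tr, config$age_bins)
        st <- cbind(data.frame(id = id, trait = tr,
                               stringsAsFactors = FALSE), st)
        strata[[length(strata) + 1]] <- st
      }
    }
    strata <- if (length(strata) > 0) {
      do.call(rbind, strata)
    } else {
      data.frame()
    }
    st_out <- strata
    for (cn in intersect(c("beta", "se", "ci_lo", "ci_hi", "fold_change",
                           "fold_lo", "fold_hi"), names(st_out))) {
      st_out[[cn]] <- format_num(st_out[[cn]])
    }
    utils::write.table(st_out, file.path(out_dir, "stratified.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "report"
    manifest <- list(
      package = "snpage",
      package_version = as.character(utils::packageVersion("snpage")),
      seed = config$seed,
      config_hash = config_hash(config),
      threshold_interaction = thr,
      n_samples_scanned = if (nrow(rows) > 0) max(rows$n, na.rm = TRUE) else 0,
      n_variants_scanned = length(unique(rows$id)),
      n_gwis_leads = as.list(vapply(gwis_leads, length, integer(1))),
      n_marginal_leads = as.list(vapply(marginal_leads, length,
                                        integer(1))),
      n_lookup_significant = sum(lk$significant)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(report_text(gwis_leads, lk, thr),
               file.path(out_dir, "report.txt"))
    list(scan_rows = rows, gwis_leads = gwis_leads,
         marginal_leads = marginal_leads, lookup = lk, strata = strata,
         manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

leads_table <- function(gwis_leads) {
  out <- list()
  for (tr in names(gwis_leads)) {
    for (l in gwis_leads[[tr]]) {
      r <- l$row
      out[[length(out) + 1]] <- data.frame(
        trait = tr, id = r$id, chrom = r$chrom, pos = r$pos,
        eaf = format_num(r$eaf), n = r$n,
        beta_int = format_num(r$beta_int), se_int = format_num(r$se_int),
        p_int = format_num(r$p_int),
        n_members = length(l$members),
        genes = if (is.null(l$genes) || nrow(l$genes) == 0) {
          ""
        } else {
          paste(l$genes$gene, collapse = ";")
        },
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(trait = character(0), id = character(0),
                      chrom = character(0), pos = integer(0),
                      eaf = character(0), n = integer(0),
                      beta_int = character(0), se_int = character(0),
                      p_int = character(0), n_members = integer(0),
                      genes = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

report_text <- function(gwis_leads, lookup, thr) {
  lines <- c("SNP-by-age interaction scan report",
             sprintf("Per-trait genome-wide interaction threshold: %s",
                     format_num(thr)), "")
  for (tr in names(gwis_leads)) {
    leads <- gwis_leads[[tr]]
    lines <- c(lines, sprintf("%s: %d genome-wide significant lead(s)",
                              tr, length(leads)))
    for (l in leads) {
      g <- if (is.null(l$genes) || nrow(l$genes) == 0) {
        ""
      } else {
        paste0(" [", paste(l$genes$gene, collapse = ", "), "]")
      }
      lines <- c(lines, sprintf(
        "  %s chr%s:%d beta_int=%s p_int=%s (%d clumped)%s",
        l$row$id, l$row$chrom, l$row$pos, format_num(l$row$beta_int),
        format_num(l$row$p_int), length(l$members), g))
    }
  }
  sig <- lookup[lookup$significant, , drop = FALSE]
  lines <- c(lines, "",
             sprintf("Look-up stage: %d significant interaction(s) among %d tested marginal lead(s)",
                     nrow(sig), nrow(lookup)))
  for (i in seq_len(nrow(sig))) {
    lines <- c(lines, sprintf("  %s (%s) p_int=%s < %s",
                              sig$id[i], sig$trait[i],
                              format_num(sig$p_int[i]),
                              format_num(sig$threshold[i])))
  }
  lines
}
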