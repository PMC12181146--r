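#!/usr/bin/env Rscript
# Stage 4 — lead-variant selection and the two-stage look-up.
#
# GWIS leads: greedy LD clumping (in-sample dosage r^2, bound 0.1) of
# rows with interaction p < 1e-8, then positional gene mapping within
# 10 kb against a small synthetic gene annotation. Look-up: clump the
# marginal GWAS at 5e-8 per trait, then test each marginal lead's
# interaction term at 0.05 / (number of that trait's leads).

suppressPackageStartupMessages(library(snpage))

genotypes <- read_genotypes("results/cohort/cohort.vcf")
rows <- do.call(rbind, lapply(risk_factor_traits(), function(tr) {
  r <- read_results(file.path("results/scan", paste0("scan_", tr, ".tsv")))
  r$trait <- tr
  r
}))
ld <- ld_matrix(genotypes)
thr <- genomewide_threshold(5e-8, 5)

# synthetic gene annotation around the causal positions (BED, 0-based)
dir.create("results/leads", showWarnings = FALSE, recursive = TRUE)
bed <- "results/leads/genes_synthetic.bed"
writeLines(c("4\t994999\t1005000\tGENE_A",
             "4\t1994999\t2005000\tGENE_T",
             "4\t2989999\t2994999\tGENE_S"), bed)
genes <- read_bed_genes(bed)

gwis_leads <- list()
marginal_leads <- list()
for (tr in risk_factor_traits()) {
  sub <- rows[rows$trait == tr, ]
  gwis_leads[[tr]] <- map_genes(
    clump(sub, ld, r2_max = 0.1, p_max = thr, stat = "interaction"),
    genes, max_dist = 10000)
  marginal_leads[[tr]] <- clump(sub, ld, r2_max = 0.1, p_max = 5e-8,
                                stat = "marginal")
}

lookup <- lookup_interactions(marginal_leads, rows, alpha = 0.05)
utils::write.table(lookup, "results/leads/lookup.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(snpage:::leads_table(gwis_leads),
                   "results/leads/gwis_leads.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

for (tr in risk_factor_traits()) {
  for (l in gwis_leads[[tr]]) {
    g <- if (nrow(l$genes)) paste(l$genes$gene, collapse = ",") else "-"
    cat(sprintf("GWIS lead  %-9s (%s) beta_int=%.4g p=%.3g genes=%s\n",
                l$row$id, tr, l$row$beta_int, l$p, g))
  }
  n <- length(marginal_leads[[tr]])
  if (n > 0) {
    cat(sprintf("Marginal leads for %s: %d (look-up threshold %.4g)\n",
                tr, n, 0.05 / n))
  }
}
sig <- lookup[lookup$significant, ]
cat(sprintf("\nLook-up: %d of %d marginal leads interact with age:\n",
            nrow(sig), nrow(lookup)))
if (nrow(sig)) {
  print(sig[, c("trait", "id", "n_leads", "threshold", "beta_int",
                "p_int")], digits = 3, row.names = FALSE)
}
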