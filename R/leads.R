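#' Pairwise LD matrix from dosages
#'
#' Squared Pearson correlation between the dosage vectors of every variant
#' pair, the in-sample LD estimate used for clumping. A precomputed matrix
#' (e.g. from an external reference panel) can be passed to [clump()]
#' instead.
#'
#' @param G Dosage matrix, variants in rows, or a `genotype_block`.
#' @return Symmetric matrix of r-squared values with unit diagonal,
#'   dimnames set to variant ids.
#' @export
ld_matrix <- function(G) {
  if (inherits(G, "genotype_block")) G <- G$dosage
  r <- suppressWarnings(stats::cor(t(G)))
  r[is.na(r)] <- 0
  diag(r) <- 1
  r^2
}

#' Greedy LD clumping of scan rows
#'
#' Selects independent lead variants: rows are sorted by ascending p-value
#' (ties broken by larger absolute effect, then chromosome/position), the
#' best remaining row becomes a lead, and every remaining row in LD with it
#' (r-squared at or above `r2_max`) joins its clump. Only rows with
#' `p < p_max` may seed a clump. All retained leads therefore have pairwise
#' r-squared strictly below `r2_max`.
#'
#' @param rows Scan rows for one trait (data frame with `id` and the chosen
#'   p-value column).
#' @param ld Square r-squared matrix with variant ids as dimnames (see
#'   [ld_matrix()]). Variants absent from it are treated as independent,
#'   with a warning.
#' @param r2_max LD bound (default 0.1).
#' @param p_max Only rows below this p seed clumps (default 1: every row is
#'   eligible; the genome-wide and look-up callers pass their own
#'   thresholds).
#' @param stat `"interaction"` (clump on `p_int`, effect `beta_int`) or
#'   `"marginal"` (`p_marginal`, `beta_g`).
#' @return List of `lead_variant` entries: `row` (the representative scan
#'   row), `members` (ids clumped away), `p`, `genes` (filled by
#'   [map_genes()]).
#' @export
clump <- function(rows, ld, r2_max = 0.1, p_max = 1,
                  stat = c("interaction", "marginal")) {
  stat <- match.arg(stat)
  pcol <- if (stat == "interaction") "p_int" else "p_marginal"
  bcol <- if (stat == "interaction") "beta_int" else "beta_g"
  stopifnot(pcol %in% names(rows))
  rows <- rows[!is.na(rows[[pcol]]), , drop = FALSE]
  if (nrow(rows) == 0) return(list())

  missing_ld <- setdiff(rows$id, rownames(ld))
  if (length(missing_ld) > 0) {
    warning(length(missing_ld), " variant(s) absent from the LD source; ",
            "treated as independent: ",
            paste(utils::head(missing_ld, 5), collapse = ", "))
  }

  ord <- order(rows[[pcol]], -abs(rows[[bcol]]), rows$chrom, rows$pos)
  rows <- rows[ord, , drop = FALSE]

  r2_of <- function(a, b) {
    if (a %in% rownames(ld) && b %in% colnames(ld)) ld[a, b] else 0
  }

  leads <- list()
  remaining <- seq_len(nrow(rows))
  while (length(remaining) > 0) {
    i <- remaining[1]
    if (rows[[pcol]][i] >= p_max) break  # sorted: no further seeds possible
    lead_id <- rows$id[i]
    rest <- remaining[-1]
    in_clump <- vapply(rest, function(j) {
      r2_of(lead_id, rows$id[j]) >= r2_max
    }, logical(1))
    leads[[length(leads) + 1]] <- structure(
      list(row = rows[i, , drop = FALSE],
           members = rows$id[rest[in_clump]],
           p = rows[[pcol]][i], genes = NULL),
      class = "lead_variant")
    remaining <- rest[!in_clump]
  }
  leads
}

#' Maximum pairwise LD among leads
#'
#' Diagnostic invariant of a clumping result: the largest r-squared between
#' any two retained leads (must be below the clumping bound).
#'
#' @param leads [clump()] output.
#' @param ld The LD matrix used.
#' @return Single r-squared value (0 if fewer than two leads).
#' @export
max_lead_r2 <- function(leads, ld) {
  ids <- vapply(leads, function(l) l$row$id, character(1))
  ids <- intersect(ids, rownames(ld))
  if (length(ids) < 2) return(0)
  sub <- ld[ids, ids]
  diag(sub) <- 0
  max(sub)
}

#' Read gene intervals from BED
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention (`start + 1`, `end`).
#'
#' @param path BED file (chrom, start, end, name).
#' @return Data frame with `gene`, `chrom`, `start`, `end` (1-based,
#'   inclusive).
#' @export
read_bed_genes <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name"))
  data.frame(gene = bed$name, chrom = as.character(bed$chrom),
             start = bed$start + 1L, end = bed$end,
             stringsAsFactors = FALSE)
}

#' Positionally map leads to genes
#'
#' Annotates each lead with every gene whose interval lies within
#' `max_dist` base pairs of the variant position on the same chromosome
#' (distance 0 inside the interval; the boundary at exactly `max_dist` is
#' inclusive).
#'
#' @param leads [clump()] output.
#' @param genes Gene interval data frame (`gene`, `chrom`, `start`, `end`,
#'   1-based inclusive), e.g. from [read_bed_genes()].
#' @param max_dist Maximum variant-to-gene distance in bp (default 10000).
#' @return The leads, each with `genes` set to a data frame of `gene` and
#'   `distance`.
#' @export
map_genes <- function(leads, genes, max_dist = 10000) {
  lapply(leads, function(l) {
    chrom <- l$row$chrom
    pos <- l$row$pos
    cand <- genes[genes$chrom == chrom, , drop = FALSE]
    if (nrow(cand) == 0) {
      l$genes <- data.frame(gene = character(0), distance = numeric(0))
      return(l)
    }
    d <- ifelse(pos >= cand$start & pos <= cand$end, 0,
                pmin(abs(pos - cand$start), abs(pos - cand$end)))
    hit <- d <= max_dist
    l$genes <- data.frame(gene = cand$gene[hit], distance = d[hit],
                          stringsAsFactors = FALSE)
    l
  })
}

#' Two-stage look-up of age interactions among marginal GWAS hits
#'
#' Strict genome-wide interaction testing can miss weak age interactions,
#' so the look-up stage starts from the conventional GWAS instead: take the
#' independent lead variants with genome-wide significant marginal effects
#' for each trait, and test their interaction terms at a Bonferroni level of
#' `alpha` divided by the number of that trait's marginal leads (e.g.
#' 0.05/145 for a trait with 145 leads).
#'
#' @param marginal_leads Named list (by trait) of [clump()] outputs built on
#'   marginal p-values.
#' @param gwis_rows Scan rows containing interaction results for the same
#'   variants (any trait mix; matched on `id` + `trait`).
#' @param alpha Family-wise level distributed over each trait's leads
#'   (default 0.05).
#' @return Data frame, one row per tested lead: `trait`, `id`, `n_leads`,
#'   `threshold`, `beta_int`, `se_int`, `p_int`, `significant`.
#' @export
lookup_interactions <- function(marginal_leads, gwis_rows, alpha = 0.05) {
  out <- list()
  for (tr in names(marginal_leads)) {
    leads <- marginal_leads[[tr]]
    n_leads <- length(leads)
    if (n_leads == 0) next
    thr <- alpha / n_leads
    sub <- gwis_rows[gwis_rows$trait == tr, , drop = FALSE]
    for (l in leads) {
      hit <- sub[sub$id == l$row$id, , drop = FALSE]
      if (nrow(hit) == 0) next
      out[[length(out) + 1]] <- data.frame(
        trait = tr, id = l$row$id, chrom = hit$chrom[1], pos = hit$pos[1],
        n_leads = n_leads, threshold = thr,
        beta_int = hit$beta_int[1], se_int = hit$se_int[1],
        p_int = hit$p_int[1],
        significant = !is.na(hit$p_int[1]) && hit$p_int[1] < thr,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(trait = character(0), id = character(0),
                      chrom = character(0), pos = integer(0),
                      n_leads = integer(0), threshold = numeric(0),
                      beta_int = numeric(0), se_int = numeric(0),
                      p_int = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
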