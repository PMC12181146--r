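fake_rows <- function(ids, p, beta = 1, chrom = "1", pos = seq_along(ids)) {
  data.frame(id = ids, chrom = chrom, pos = pos, p_int = p,
             beta_int = rep_len(beta, length(ids)),
             stringsAsFactors = FALSE)
}

# brute-force clumping verifier: checks every pairwise constraint of a
# clumping result rather than re-running the greedy algorithm
verify_clumping <- function(leads, rows, ld, r2_max, p_max, pcol) {
  lead_ids <- vapply(leads, function(l) l$row$id, character(1))
  # leads mutually below the LD bound
  if (length(lead_ids) > 1) {
    sub <- ld[lead_ids, lead_ids]
    diag(sub) <- 0
    if (max(sub) >= r2_max) return("leads in LD")
  }
  # no variant assigned to two clumps
  assigned <- c(lead_ids, unlist(lapply(leads, `[[`, "members")))
  if (anyDuplicated(assigned)) return("double assignment")
  # every significant row is a lead or a member
  sig <- rows$id[rows[[pcol]] < p_max]
  if (!all(sig %in% assigned)) return("significant row unassigned")
  # members sit in LD with their representative, whose p is no larger
  for (l in leads) {
    for (mid in l$members) {
      if (ld[l$row$id, mid] < r2_max) return("member not in LD with lead")
      if (rows[[pcol]][rows$id == mid] < l$p) return("member beats lead")
    }
  }
  "ok"
}
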