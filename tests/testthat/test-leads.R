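test_that("clumping handles the degenerate one- and two-variant cases", {
  ld1 <- matrix(1, 1, 1, dimnames = list("a", "a"))
  leads <- clump(fake_rows("a", 1e-10), ld1, p_max = 1e-8)
  expect_length(leads, 1)
  expect_equal(leads[[1]]$row$id, "a")

  ld2 <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  leads2 <- clump(fake_rows(c("a", "b"), c(1e-9, 1e-10)), ld2,
                  p_max = 1e-8)
  expect_length(leads2, 1)
  expect_equal(leads2[[1]]$row$id, "b")       # the smaller p leads
  expect_equal(leads2[[1]]$members, "a")
})

test_that("greedy clumping satisfies the exhaustive pairwise oracle", {
  for (seed in c(101, 202, 303)) {
    spec <- simulation_spec(
      5000, variants = variant_panel(200, maf = 0.3),
      ld_blocks = list(list(from = 1, to = 200, rho = 0.9)),
      seed = seed)
    g <- simulate_genotypes(spec)
    ld <- ld_matrix(g)
    set.seed(seed)
    rows <- fake_rows(g$variants$id, p = runif(200, 0, 2e-8),
                      beta = rnorm(200), pos = g$variants$pos)
    leads <- clump(rows, ld, r2_max = 0.1, p_max = 1e-8)
    expect_identical(verify_clumping(leads, rows, ld, 0.1, 1e-8, "p_int"),
                     "ok")
    expect_lt(max_lead_r2(leads, ld), 0.1)

    # row-order invariance
    perm <- sample(nrow(rows))
    leads2 <- clump(rows[perm, ], ld, r2_max = 0.1, p_max = 1e-8)
    expect_identical(vapply(leads2, function(l) l$row$id, character(1)),
                     vapply(leads, function(l) l$row$id, character(1)))
  }
})

test_that("variants missing from the LD source are treated as independent", {
  ld <- matrix(1, 1, 1, dimnames = list("a", "a"))
  rows <- fake_rows(c("a", "zz"), c(1e-10, 1e-9))
  expect_warning(leads <- clump(rows, ld, p_max = 1e-8), "absent")
  expect_length(leads, 2)
})

test_that("positional gene mapping respects the inclusive distance bound", {
  genes <- data.frame(gene = c("G1", "G2"), chrom = c("1", "1"),
                      start = c(1000, 50000), end = c(2000, 60000),
                      stringsAsFactors = FALSE)
  mk_lead <- function(pos) {
    structure(list(row = data.frame(id = "v", chrom = "1", pos = pos,
                                    stringsAsFactors = FALSE),
                   members = character(0), p = 1e-9, genes = NULL),
              class = "lead_variant")
  }
  inside <- map_genes(list(mk_lead(1500)), genes)[[1]]$genes
  expect_equal(inside$gene, "G1")
  expect_equal(inside$distance, 0)

  at_bound <- map_genes(list(mk_lead(12000)), genes)[[1]]$genes
  expect_equal(at_bound$gene, "G1")       # 10,000 bp away: inclusive
  expect_equal(at_bound$distance, 10000)

  beyond <- map_genes(list(mk_lead(12001)), genes)[[1]]$genes
  expect_equal(nrow(beyond), 0)           # 10,001 bp: out of range
})

test_that("BED gene intervals convert to 1-based inclusive coordinates", {
  bed <- tempfile(fileext = ".bed")
  writeLines("1\t999\t2000\tG1", bed)
  g <- read_bed_genes(bed)
  expect_equal(g$start, 1000)
  expect_equal(g$end, 2000)
})

test_that("look-up thresholds divide alpha by each trait's lead count", {
  mk_leads <- function(ids) {
    lapply(ids, function(id) {
      structure(list(row = data.frame(id = id, chrom = "1", pos = 1,
                                      stringsAsFactors = FALSE),
                     members = character(0), p = 1e-9, genes = NULL),
                class = "lead_variant")
    })
  }
  gwis <- data.frame(id = c(sprintf("a%03d", 1:145), "b1"),
                     trait = c(rep("apob", 145), "tg"),
                     chrom = "1", pos = 1,
                     beta_int = 0.001, se_int = 0.0002,
                     p_int = c(1e-5, rep(0.5, 144), 0.03),
                     stringsAsFactors = FALSE)
  rep145 <- lookup_interactions(
    list(apob = mk_leads(sprintf("a%03d", 1:145)), tg = mk_leads("b1")),
    gwis)
  expect_equal(unique(rep145$threshold[rep145$trait == "apob"]), 0.05 / 145)
  expect_equal(rep145$threshold[rep145$trait == "tg"], 0.05)  # single lead
  expect_true(rep145$significant[rep145$id == "a001"])   # 1e-5 < 0.05/145
  expect_false(any(rep145$significant[rep145$id != "a001" &
                                        rep145$trait == "apob"]))
  expect_true(rep145$significant[rep145$trait == "tg"])  # 0.03 < 0.05
  # thresholds decrease in the number of leads
  expect_lt(rep145$threshold[1], rep145$threshold[rep145$trait == "tg"])
})

test_that("high-powered look-up recovers exactly the true interacting leads", {
  causal <- c(1, 7, 13)
  beta_int <- rep(0, 20)
  beta_int[causal] <- 0.004   # sized for near-certain Bonferroni detection
  spec <- simulation_spec(
    20000,
    variants = variant_panel(20, maf = 0.3, trait = "apob",
                             beta_g = 0.15, beta_gxage = beta_int),
    seed = 99)
  coh <- simulate_cohort(spec)
  pheno <- preprocess_phenotypes(coh$phenotypes)
  rows <- run_scan(coh$genotypes, pheno, scan_config(), traits = "apob")
  ld <- ld_matrix(coh$genotypes)
  marg <- clump(rows, ld, r2_max = 0.1, p_max = 5e-8, stat = "marginal")
  expect_length(marg, 20)   # independent variants, all strongly marginal
  rep <- lookup_interactions(list(apob = marg), rows)
  sig <- rep$id[rep$significant]
  expect_true(all(sprintf("var%04d", causal) %in% sig))
  expect_lte(length(setdiff(sig, sprintf("var%04d", causal))), 1)
})
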