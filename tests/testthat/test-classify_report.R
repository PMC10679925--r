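cand_row <- function(model = "oligogene", carrier_parent = "mother",
                     func_class = "exonic", exonic_func = "missense",
                     splice_distance = NA_real_, gene = "GENEX",
                     af1 = NA_real_, af2 = NA_real_, votes = 0L, ...) {
  data.frame(model = model, carrier_parent = carrier_parent,
             func_class = func_class, exonic_func = exonic_func,
             splice_distance = splice_distance, gene = gene,
             af_g1000_all = af1, af_gnomad_all = af2,
             votes_of4 = votes, ..., stringsAsFactors = FALSE)
}

test_that("panel intersection tags candidates and keeps off-panel rows", {
  panel <- cvid_panel()
  cand <- rbind(cand_row(gene = "LRBA"), cand_row(gene = "MYB"),
                cand_row(gene = "TAP1"))
  tagged <- intersect_panel(cand, panel)
  expect_equal(tagged$panel_tag, c("CVID_OMIM", "off_panel", "PID"))
  expect_equal(nrow(tagged), 3)
  empty <- intersect_panel(cand[0, ], panel)
  expect_equal(nrow(empty), 0)
  expect_true("panel_tag" %in% names(empty))
})

test_that("evidence codes trigger per the documented mapping", {
  # stopgain, de novo, absent everywhere -> PVS1 + PS2 + PM2
  ev <- assign_evidence(cand_row(model = "de_novo", carrier_parent = "none",
                                 exonic_func = "stopgain"))
  expect_true(all(unlist(ev[c("PVS1", "PS2", "PM2")])))
  expect_false(any(unlist(ev[c("PM3", "PP1", "PP2", "PP3", "PP4", "BP4",
                               "BS1", "BA1")])))

  # canonical splice +1, de novo, absent -> same trio of codes
  ev2 <- assign_evidence(cand_row(model = "de_novo", carrier_parent = "none",
                                  func_class = "splicing",
                                  exonic_func = "unknown",
                                  splice_distance = 1))
  expect_true(all(unlist(ev2[c("PVS1", "PS2", "PM2")])))

  # missense het, AF present below 0.01, 3/4 vote -> PP3 only
  ev3 <- assign_evidence(cand_row(af1 = 0.0005, votes = 3L))
  expect_true(ev3$PP3)
  expect_false(any(unlist(ev3[setdiff(names(ev3), "PP3")])))

  # trio-confirmed X-linked recessive in a constrained gene
  ev4 <- assign_evidence(cand_row(model = "x_linked_recessive",
                                  carrier_parent = "mother",
                                  gene = "CD40LG", votes = 4L))
  expect_true(all(unlist(ev4[c("PM2", "PM3", "PP2", "PP3")])))

  # sporadic homozygote gets no PM3 (no trans confirmation)
  ev5 <- assign_evidence(cand_row(model = "sporadic_only",
                                  carrier_parent = "none", votes = 4L))
  expect_false(ev5$PM3)

  # frequency-based benign codes
  ev6 <- assign_evidence(cand_row(af1 = 0.02))
  expect_true(ev6$BS1); expect_false(ev6$BA1)
  ev7 <- assign_evidence(cand_row(af1 = 0.3))
  expect_true(ev7$BA1)
})

test_that("ACMG combination reproduces the published fixture classes", {
  cl <- classify_candidates(cvid_candidates())
  key <- paste(cl$gene, cl$change)
  expect_equal(cl$acmg_class[key == "GATA2 p.R348X"], "Pathogenic")
  expect_equal(cl$acmg_class[key == "PIK3R1 c.336+1G>A"], "Pathogenic")
  expect_equal(cl$acmg_class[key == "CD40LG p.H125P"], "Likely Pathogenic")
  others <- cl$acmg_class[!key %in% c("GATA2 p.R348X", "PIK3R1 c.336+1G>A",
                                      "CD40LG p.H125P")]
  expect_true(all(others == "VUS"))
  # engine classes match the published column everywhere
  expect_identical(cl$acmg_class, cl$acmg_published)
})

test_that("combine_acmg is total over the full evidence space and pure", {
  codes <- c("PVS1", "PS2", "PM2", "PM3", "PP1", "PP2", "PP3", "PP4",
             "BP4", "BS1", "BA1")
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(codes)))
  names(grid) <- codes
  classes <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    res <- combine_acmg(grid[i, ])
    classes[i] <- as.character(res)
    expect_true(classes[i] %in% c("Pathogenic", "Likely Pathogenic", "VUS",
                                  "Likely Benign", "Benign"))
    expect_type(attr(res, "conflict"), "logical")
  }
  # purity: re-evaluation gives identical classes
  idx <- sample(nrow(grid), 64)
  again <- vapply(idx, function(i) as.character(combine_acmg(grid[i, ])),
                  character(1))
  expect_identical(again, classes[idx])
  expect_equal(as.character(combine_acmg(grid[1, ])), "VUS")  # no evidence
  # contradictory evidence collapses to VUS with the conflict flag
  conflict <- combine_acmg(stats::setNames(
    as.list(codes %in% c("PVS1", "PS2", "PM2", "BA1")), codes))
  expect_equal(as.character(conflict), "VUS")
  expect_true(attr(conflict, "conflict"))
})

test_that("de novo evidence strength is configurable", {
  profile <- stats::setNames(as.list(c("PS2", "PM2", "PP3") %in%
                                       c("PS2", "PM2", "PP3")), c("PS2", "PM2", "PP3"))
  # moderate (default): assumed de novo missense with PM2+PP3 stays VUS
  expect_equal(as.character(combine_acmg(profile)), "VUS")
  # strong: 1 PS + 1 PM reaches Likely Pathogenic
  expect_equal(as.character(combine_acmg(profile,
                                         acmg_config(denovo_strength = "strong"))),
               "Likely Pathogenic")
})

test_that("hypergeometric enrichment matches the combinatorial oracle to 1e-12", {
  set.seed(19)
  for (rep in 1:30) {
    N <- sample(10:50, 1)
    universe <- paste0("G", seq_len(N))
    n_q <- sample(1:min(8, N), 1)
    K <- sample(1:min(10, N), 1)
    query <- sample(universe, n_q)
    sets <- list(S = sample(universe, K))
    res <- enrich(query, sets, universe = N)
    k <- length(intersect(query, sets$S))
    expect_equal(res$overlap, k)
    expect_equal(res$p, oracle_hyper_p(k, K, N, n_q), tolerance = 1e-12)
  }
  # closed-form corner: 6-gene query entirely inside a 6-gene set
  res <- enrich(paste0("G", 1:6), list(S = paste0("G", 1:6)),
                universe = 20000)
  expect_equal(res$p, 1 / choose(20000, 6), tolerance = 1e-12)
  # disjoint set -> p = 1, reported not dropped
  res0 <- enrich(c("A", "B"), list(S = c("X", "Y")), universe = 100)
  expect_equal(res0$p, 1)
  expect_equal(res0$overlap, 0)
  # BH adjustment and ascending order
  multi <- enrich(paste0("G", 1:6),
                  list(S1 = paste0("G", 1:6), S2 = paste0("G", 90:95)),
                  universe = 100)
  expect_equal(multi$p_adj, stats::p.adjust(multi$p, "BH"))
  expect_true(!is.unsorted(multi$p))
})

test_that("cohort summary deduplicates loci and aggregates phenotypes", {
  cand <- cvid_candidates()
  s <- summarize_cohort(cand, cvid_phenotypes())
  expect_equal(s$n_rows, 34)
  expect_equal(s$n_genes, 28)
  expect_equal(s$n_loci, 32)
  # dedup correctness: loci + duplicate rows = total rows
  expect_equal(s$n_loci + (s$n_rows - s$n_loci), s$n_rows)
  expect_equal(sum(s$loci$n_patients), s$n_rows)
  r84t <- s$loci[s$loci$change == "p.R84T", ]
  expect_equal(r84t$n_patients, 2)
  expect_equal(r84t$pct_patients, 12.5)
  expect_equal(s$n_patients_multi_locus, 11)
  ctd <- s$phenotype_groups
  expect_equal(ctd$n[ctd$group == "connective_tissue"], 10)
  expect_equal(ctd$pct[ctd$group == "connective_tissue"], 62.5)
  sle <- s$phenotype[s$phenotype$category == "SLE", ]
  expect_equal(sle$pct, 37.5)
  # empty candidate set
  s0 <- summarize_cohort(cand[0, ], n_patients = 16)
  expect_equal(s0$n_loci, 0)
  expect_equal(s0$n_genes, 0)
  expect_equal(s0$n_patients_multi_locus, 0)
})
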