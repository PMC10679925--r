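ped3 <- trio_ped("F1", child_sex = "female")
SAMPLES <- c("F1_FA", "F1_MO", "F1_PB")

# single-site helper: ac by sample
site_vs <- function(fa, mo, pb, ..., dp = 30, ploidy = c(2, 2, 2)) {
  v <- make_vs(1, ..., samples = SAMPLES, ac = 1, dp = dp)
  v$ac[1, ] <- as.integer(c(fa, mo, pb))
  v$ploidy[1, ] <- as.integer(ploidy)
  v
}

test_that("trio model calls de novo only with well-covered hom-ref parents", {
  v <- site_vs(0, 0, 1)
  call <- call_trio_model(v, 1, "F1_PB", ped3)
  expect_equal(call$model, "de_novo")
  expect_equal(call$carrier_parent, "none")

  # low parental depth blocks the de novo call
  v_low <- site_vs(0, 0, 1, dp = c(3, 30, 30))
  call_low <- call_trio_model(v_low, 1, "F1_PB", ped3)
  expect_false(identical(call_low$model, "de_novo"))

  # parent missing: de novo not callable
  duo <- make_ped("F2", c("F2_MO", "F2_PB"),
                  father_id = c(NA, NA), mother_id = c(NA, "F2_MO"),
                  sex = c("female", "female"), affected = c(FALSE, TRUE))
  v_duo <- make_vs(1, samples = c("F2_MO", "F2_PB"), ac = c(0, 1))
  call_duo <- call_trio_model(v_duo, 1, "F2_PB", duo)
  expect_equal(call_duo$model, "inherited_het")
  expect_equal(call_duo$flags, "incomplete_trio")
})

test_that("recessive and inherited-het calls record the transmitting parent", {
  expect_equal(call_trio_model(site_vs(1, 1, 2), 1, "F1_PB", ped3)$model,
               "hom_recessive")
  expect_equal(call_trio_model(site_vs(1, 1, 2), 1, "F1_PB", ped3)$carrier_parent,
               "both")
  c_f <- call_trio_model(site_vs(1, 0, 1), 1, "F1_PB", ped3)
  expect_equal(c_f$model, "inherited_het")
  expect_equal(c_f$carrier_parent, "father")
  c_m <- call_trio_model(site_vs(0, 1, 1), 1, "F1_PB", ped3)
  expect_equal(c_m$carrier_parent, "mother")
  # non-carrying proband yields no call
  expect_null(call_trio_model(site_vs(1, 1, 0), 1, "F1_PB", ped3))
})

test_that("hom-alt child with a confirmed hom-ref parent is flagged, never recessive", {
  call <- call_trio_model(site_vs(0, 1, 2), 1, "F1_PB", ped3)
  expect_equal(call$model, "possible_denovo_or_error")
  expect_equal(call$flags, "mendelian_inconsistent")
})

test_that("male X hemizygous alt with carrier mother is X-linked recessive", {
  pedm <- trio_ped("F1", child_sex = "male")
  v <- site_vs(0, 1, 1, chrom = "X", ploidy = c(1, 2, 1))
  call <- call_trio_model(v, 1, "F1_PB", pedm)
  expect_equal(call$model, "x_linked_recessive")
  expect_equal(call$carrier_parent, "mother")
  expect_equal(zygosity_display(v$ac[1, "F1_PB"], v$ploidy[1, "F1_PB"]),
               "hom")                       # hemizygous displayed as hom
  # hom-ref mother instead: de novo on the male X
  v_dn <- site_vs(0, 0, 1, chrom = "X", ploidy = c(1, 2, 1))
  expect_equal(call_trio_model(v_dn, 1, "F1_PB", pedm)$model, "de_novo")
})

test_that("no variant is called both de novo and inherited for one proband", {
  set.seed(5)
  for (rep in 1:20) {
    fa <- sample(0:2, 1); mo <- sample(0:2, 1); pb <- sample(1:2, 1)
    call <- call_trio_model(site_vs(fa, mo, pb), 1, "F1_PB", ped3)
    if (is.null(call)) next
    if (call$model == "de_novo") {
      expect_true(fa == 0 && mo == 0)
    }
    if (call$model == "inherited_het") {
      expect_false(fa == 0 && mo == 0)
    }
  }
})

test_that("compound-het pairing equals brute-force trans enumeration", {
  # 2 paternal + 2 maternal hets in one gene -> 4 trans pairs
  n <- 4
  v <- make_vs(n, gene = "GENE1", samples = SAMPLES, ac = 1)
  v$ac[, "F1_FA"] <- c(1L, 1L, 0L, 0L)
  v$ac[, "F1_MO"] <- c(0L, 0L, 1L, 1L)
  pairs <- call_compound_het(v, 1:4, "F1_PB", ped3)
  expect_equal(nrow(pairs), 4)
  expect_true(all(pairs$phase == "trans"))

  # randomized genes with <= 10 variants against an explicit double loop
  set.seed(31)
  for (rep in 1:10) {
    k <- sample(2:10, 1)
    v <- make_vs(k, gene = "GENEX", samples = SAMPLES, ac = 1)
    v$ac[, "F1_FA"] <- sample(0:1, k, replace = TRUE)
    v$ac[, "F1_MO"] <- sample(0:1, k, replace = TRUE)
    v$ac[, "F1_PB"] <- sample(0:1, k, replace = TRUE)
    got <- call_compound_het(v, 1:k, "F1_PB", ped3)
    got_trans <- got[got$phase == "trans", c("variant_a", "variant_b")]
    # oracle: proband-het variants with opposite single-parent origin
    pb_het <- v$ac[, "F1_PB"] == 1
    orig <- ifelse(v$ac[, "F1_FA"] >= 1 & v$ac[, "F1_MO"] == 0, "f",
            ifelse(v$ac[, "F1_MO"] >= 1 & v$ac[, "F1_FA"] == 0, "m",
            ifelse(v$ac[, "F1_FA"] >= 1 & v$ac[, "F1_MO"] >= 1, "b", "d")))
    want <- list()
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (b <= a || !pb_het[a] || !pb_het[b]) next
      # with hom-ref unphasable parents the pair would be de novo, not listed
      if (orig[a] == "d" && v$ac[a, "F1_FA"] == 0 && v$ac[a, "F1_MO"] == 0) next
      if (sort(c(orig[a], orig[b]))[1] == "f" &&
          sort(c(orig[a], orig[b]))[2] == "m") {
        want[[length(want) + 1]] <- sort(v$variants$variant_id[c(a, b)])
      }
    }
    got_keys <- apply(got_trans, 1, function(r) paste(sort(r), collapse = "|"))
    want_keys <- vapply(want, paste, character(1), collapse = "|")
    expect_setequal(unname(got_keys), unname(want_keys))
  }
})

test_that("cis and unphasable configurations are separated", {
  v <- make_vs(2, gene = "GENE1", samples = SAMPLES, ac = 1)
  v$ac[, "F1_FA"] <- c(1L, 1L); v$ac[, "F1_MO"] <- c(0L, 0L)
  expect_equal(nrow(call_compound_het(v, 1:2, "F1_PB", ped3)), 0)  # cis
  v$ac[, "F1_MO"] <- c(1L, 0L)   # first variant carried by both parents
  pairs <- call_compound_het(v, 1:2, "F1_PB", ped3)
  expect_equal(pairs$phase, "possible_cis")
})

test_that("sporadic rule requires case-exclusive presence", {
  samples <- c("S1", paste0("C", 1:26))
  v <- make_vs(1, samples = samples, ac = 0)
  v$ac[1, "S1"] <- 1L
  call <- call_sporadic(v, 1, "S1", paste0("C", 1:26))
  expect_equal(call$model, "sporadic_only")
  expect_equal(call$flags, "")

  v$ac[1, "C7"] <- 1L
  expect_null(call_sporadic(v, 1, "S1", paste0("C", 1:26)))

  v$ac[1, "C7"] <- NA_integer_
  call_na <- call_sporadic(v, 1, "S1", paste0("C", 1:26))
  expect_equal(call_na$model, "sporadic_only")
  expect_equal(call_na$flags, "control_missing")
})

test_that("oligogenic profiles need >= 2 genes from unaffected parents or de novo", {
  calls <- rbind(
    data.frame(proband = "F1_PB", variant_id = "1:100:C:T", gene = "NCF2",
               model = "inherited_het", carrier_parent = "mother",
               flags = "", partner_variant = NA, stringsAsFactors = FALSE),
    data.frame(proband = "F1_PB", variant_id = "1:200:C:T", gene = "TCIRG1",
               model = "inherited_het", carrier_parent = "father",
               flags = "", partner_variant = NA, stringsAsFactors = FALSE),
    data.frame(proband = "F1_PB", variant_id = "1:300:C:T", gene = "TIRAP",
               model = "inherited_het", carrier_parent = "mother",
               flags = "", partner_variant = NA, stringsAsFactors = FALSE))
  prof <- build_oligogenic_profile(calls, ped3)
  expect_equal(nrow(prof$loci), 3)
  expect_true(all(prof$loci$model == "oligogene"))

  expect_null(build_oligogenic_profile(calls[1, ], ped3))   # single locus
  # 3 inherited + 2 de novo loci -> 5-locus profile, de novo labels kept
  calls5 <- rbind(calls,
    data.frame(proband = "F1_PB", variant_id = c("1:400:C:T", "1:500:C:T"),
               gene = c("GATA2", "STAT5B"), model = "de_novo",
               carrier_parent = "none", flags = "", partner_variant = NA,
               stringsAsFactors = FALSE))
  prof5 <- build_oligogenic_profile(calls5, ped3)
  expect_equal(nrow(prof5$loci), 5)
  expect_equal(sum(prof5$loci$model == "de_novo"), 2)

  # an affected carrier parent disqualifies the inherited variant
  ped_aff <- ped3; ped_aff$affected[ped_aff$sample_id == "F1_MO"] <- TRUE
  prof_aff <- build_oligogenic_profile(calls, ped_aff)
  expect_null(prof_aff)   # only the paternal locus remains -> 1 gene
})
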