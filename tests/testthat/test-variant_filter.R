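t_def <- filter_thresholds()

test_that("site QC applies strict bounds on depth, MQ and QUAL", {
  vs <- make_vs(3, qual = c(21, 21, 50), mq = c(31, 31, 30),
                dp = c(4, 5, 30))
  d <- lapply(1:3, function(i) site_qc(vs, i, "P1", t_def))
  expect_false(d[[1]]$passed)                 # depth exactly at bound
  expect_equal(d[[1]]$reason, "low_depth")
  expect_true(d[[2]]$passed)                  # depth 5 > 4
  expect_false(d[[3]]$passed)                 # MQ exactly at bound
  expect_equal(d[[3]]$reason, "low_mq")

  vs_na <- make_vs(1, dp = NA_real_)
  expect_equal(site_qc(vs_na, 1, "P1", t_def)$reason, "missing_dp")
})

test_that("region filter keeps exons and splice sites within the 10 bp window", {
  vs <- make_vs(4,
                func_class = c("exonic", "splicing", "splicing", "other"),
                splice_distance = c(NA, 1, 10, NA))
  expect_true(region_filter(vs, 1, t_def)$passed)
  expect_true(region_filter(vs, 2, t_def)$passed)   # canonical +1
  expect_true(region_filter(vs, 3, t_def)$passed)   # +10, inclusive window
  expect_false(region_filter(vs, 4, t_def)$passed)
  vs11 <- make_vs(1, func_class = "splicing", splice_distance = 11)
  expect_false(region_filter(vs11, 1, t_def)$passed)
})

test_that("synonymous variants are discarded unless dbscSNV rescues them", {
  vs <- make_vs(3, exonic_func = c("synonymous", "synonymous", "missense"),
                dbscsnv_ada = c(NA, 0.95, NA))
  expect_false(synonymous_filter(vs, 1, t_def)$passed)
  expect_true(synonymous_filter(vs, 2, t_def)$passed)
  d3 <- synonymous_filter(vs, 3, t_def)
  expect_true(d3$passed)
  expect_equal(d3$reason, "not_applicable")
})

test_that("small non-frameshift indels in repeats are discarded", {
  vs <- make_vs(3,
                ref = c("GACT", "GACT", "GACTA"),
                alt = c("G", "G", "G"),
                in_repeat = c(TRUE, FALSE, TRUE))
  expect_false(repeat_indel_filter(vs, 1, t_def)$passed)  # 3 bp in repeat
  expect_true(repeat_indel_filter(vs, 2, t_def)$passed)   # outside repeat
  expect_true(repeat_indel_filter(vs, 3, t_def)$passed)   # 4 bp = frameshift
})

test_that("frequency filter is strict and treats absent as rare", {
  vs <- make_vs(3,
                af_g1000_all = c(NA, 0.0071885, 0.01),
                af_gnomad_all = c(NA, 0.00199517, NA))
  expect_true(frequency_filter(vs, 1, t_def)$passed)
  expect_true(frequency_filter(vs, 2, t_def)$passed)
  d3 <- frequency_filter(vs, 3, t_def)
  expect_false(d3$passed)                                 # 0.01 not < 0.01
  expect_match(d3$reason, "common_g1000_all")
})

test_that("deleteriousness vote maps predictor codes as documented", {
  # rows: 4/4 unanimous; 0 supporting; SIFT+PolyPhen+CADD = 3/4;
  # two-supporter row (vote 2 of 4 available)
  vs <- make_vs(4,
                sift = c("D", "T", "D", "T"),
                polyphen_hvar = c("D", "B", "P", "B"),
                polyphen_hdiv = c("D", "B", "P", "B"),
                mutation_taster = c("D", "N", "N", "D"),
                cadd = c(31, 5, 23, 20.6))
  votes <- predictor_votes(vs$variants, t_def)
  expect_equal(votes$votes_of4, c(4, 0, 3, 2))
  expect_equal(votes$n_available, c(4, 4, 4, 4))
  d <- lapply(1:4, function(i) deleteriousness_filter(vs, i, t_def))
  expect_true(d[[1]]$passed)
  expect_false(d[[2]]$passed)
  expect_true(d[[3]]$passed)
  expect_true(d[[4]]$passed)        # half of available under default rule
  # strict majority-of-4 rule rejects the 2/4 row
  t_strict <- filter_thresholds(vote_rule = "majority4")
  expect_false(deleteriousness_filter(vs, 4, t_strict)$passed)
  expect_true(deleteriousness_filter(vs, 3, t_strict)$passed)
})

test_that("no-prediction missense fails but LoF and splicing bypass the vote", {
  vs <- make_vs(3,
                func_class = c("exonic", "exonic", "splicing"),
                exonic_func = c("missense", "stopgain", "unknown"))
  d <- lapply(1:3, function(i) deleteriousness_filter(vs, i, t_def))
  expect_false(d[[1]]$passed)
  expect_equal(d[[1]]$reason, "no_predictions")
  expect_true(d[[2]]$passed)
  expect_equal(d[[2]]$reason, "lof_bypass")
  expect_true(d[[3]]$passed)
  expect_equal(d[[3]]$reason, "splicing_bypass")
})

test_that("cascade agrees with the straight-line oracle on 1000 random variants", {
  vs <- random_variants(1000, seed = 42)
  got <- cascade_pass(vs, "P1", t_def)
  want <- oracle_cascade_pass(vs, "P1", t_def)
  expect_identical(got, want)
  # also under the strict vote rule
  t2 <- filter_thresholds(vote_rule = "majority4")
  expect_identical(cascade_pass(vs, "P1", t2),
                   oracle_cascade_pass(vs, "P1", t2))
})

test_that("short-circuiting changes traces but never outcomes", {
  vs <- random_variants(200, seed = 7)
  tr_sc <- run_cascade(vs, "P1", t_def, short_circuit = TRUE)
  tr_full <- run_cascade(vs, "P1", t_def, short_circuit = FALSE)
  expect_identical(tr_sc$final, tr_full$final)
  # full trace has every stage for every variant
  expect_equal(nrow(tr_full$trace), 200 * 6)
  expect_true(nrow(tr_sc$trace) <= nrow(tr_full$trace))
  # final pass equals the conjunction of independently evaluated stages
  full_pass <- tapply(tr_full$trace$passed, tr_full$trace$variant_id, all)
  expect_identical(as.vector(full_pass[tr_full$final$variant_id]),
                   tr_full$final$pass)
  # a common synonymous SNV stops at the synonymous stage
  vs_syn <- make_vs(1, exonic_func = "synonymous")
  tr <- run_cascade(vs_syn, "P1", t_def)
  expect_equal(tr$final$fail_stage, "synonymous")
  expect_false("frequency" %in% tr$trace$stage)
})

test_that("tightening thresholds never adds passing variants", {
  vs <- random_variants(600, seed = 99)
  base <- cascade_pass(vs, "P1", t_def)
  lower_af <- cascade_pass(vs, "P1", filter_thresholds(max_af = 0.001))
  expect_true(all(!lower_af | base))       # lower_af subset of base
  higher_cadd <- cascade_pass(
    vs, "P1", filter_thresholds(cadd_deleterious_cutoff = 25))
  expect_true(all(!higher_cadd | base))
})

test_that("trace export writes one row per variant and stage", {
  vs <- make_vs(2)
  tr <- run_cascade(vs, "P1", t_def, short_circuit = FALSE)
  path <- tempfile(fileext = ".tsv")
  export_trace_tsv(tr, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 12)
  expect_setequal(names(back),
                  c("variant_id", "stage", "passed", "reason", "observed"))
})
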