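# In-code builders for small fixtures; no data files needed.

.vs_defaults <- list(
  chrom = "1", ref = "C", alt = "T", qual = 60, mq = 50,
  func_class = "exonic", exonic_func = "missense",
  splice_distance = NA_real_, dbscsnv_ada = NA_real_, dbscsnv_rf = NA_real_,
  in_repeat = FALSE, sift = NA_character_, polyphen_hvar = NA_character_,
  polyphen_hdiv = NA_character_, mutation_taster = NA_character_,
  cadd = NA_real_, gerp = NA_real_,
  af_g1000_all = NA_real_, af_esp6500_all = NA_real_,
  af_gnomad_all = NA_real_, af_gnomad_eas = NA_real_
)

# Build a variant_set of n rows; any variant column or genotype matrix
# can be overridden (scalars are recycled).
make_vs <- function(n = 1, ..., samples = "P1", ac = 1, ploidy = 2, dp = 30) {
  over <- list(...)
  v <- data.frame(pos = seq_len(n) * 100L)
  if ("pos" %in% names(over)) v$pos <- rep(over$pos, length.out = n)
  for (nm in names(.vs_defaults)) {
    x <- if (nm %in% names(over)) over[[nm]] else .vs_defaults[[nm]]
    v[[nm]] <- rep(x, length.out = n)
  }
  v$gene <- rep(if ("gene" %in% names(over)) over$gene
                else paste0("G", seq_len(n)), length.out = n)
  m <- function(x, cast = identity) {
    matrix(cast(rep(x, length.out = n * length(samples))), n,
           length(samples), dimnames = list(NULL, samples))
  }
  variant_set(v, m(ac, as.integer), m(ploidy, as.integer), m(dp, as.numeric))
}

# pedigree object without touching disk
make_ped <- function(family_id, sample_id, father_id = NA, mother_id = NA,
                     sex = "female", affected = FALSE) {
  df <- data.frame(family_id = family_id, sample_id = sample_id,
                   father_id = father_id, mother_id = mother_id,
                   sex = sex, affected = affected,
                   stringsAsFactors = FALSE)
  class(df) <- c("pedigree", "data.frame")
  df
}

trio_ped <- function(fam = "F1", child_sex = "male", extra = NULL) {
  ped <- make_ped(
    family_id = fam,
    sample_id = paste0(fam, c("_FA", "_MO", "_PB")),
    father_id = c(NA, NA, paste0(fam, "_FA")),
    mother_id = c(NA, NA, paste0(fam, "_MO")),
    sex = c("male", "female", child_sex),
    affected = c(FALSE, FALSE, TRUE))
  if (!is.null(extra)) ped <- rbind(ped, extra)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Randomized variants that exercise every cascade stage, including
# boundary values sitting exactly on the thresholds.
random_variants <- function(n, seed) {
  set.seed(seed)
  pick <- function(...) sample(c(...), n, replace = TRUE)
  af_draw <- function() {
    x <- pick(NA_real_, 0, 0.0005, 0.009, 0.01, 0.02, 0.3)
    x
  }
  make_vs(
    n,
    samples = "P1",
    chrom = pick("1", "2", "X"),
    ref = pick("A", "C", "ACGT", "ACG"),
    alt = pick("G", "T", "GT", "GATTACA"),
    qual = pick(10, 20, 21, 60),
    mq = pick(25, 30, 31, 55),
    func_class = pick("exonic", "splicing", "other"),
    exonic_func = pick("missense", "synonymous", "stopgain", "frameshift",
                       "nonframeshift", "unknown"),
    splice_distance = pick(NA_real_, 1, 2, 10, 11, 28),
    dbscsnv_ada = pick(NA_real_, 0.1, 0.6, 0.95),
    dbscsnv_rf = pick(NA_real_, 0.2, 0.7),
    in_repeat = pick(TRUE, FALSE),
    sift = pick(NA_character_, "D", "T"),
    polyphen_hvar = pick(NA_character_, "D", "P", "B"),
    polyphen_hdiv = pick(NA_character_, "D", "P", "B"),
    mutation_taster = pick(NA_character_, "D", "A", "N", "P"),
    cadd = pick(NA_real_, 5, 9.99, 10, 20, 35),
    af_g1000_all = af_draw(),
    af_esp6500_all = af_draw(),
    af_gnomad_all = af_draw(),
    af_gnomad_eas = af_draw(),
    ac = sample(0:2, n, replace = TRUE),
    dp = pick(2, 4, 5, 30)
  )
}

# Straight-line, independent re-statement of the filtering rules, used
# as the oracle for cascade equivalence. Deliberately written as plain
# per-variant conditionals, not via the package's stage machinery.
oracle_cascade_pass <- function(vs, sample, t = filter_thresholds()) {
  v <- vs$variants
  vapply(seq_len(nrow(v)), function(i) {
    dp <- vs$dp[i, sample]
    if (is.na(dp) || dp <= t$min_depth) return(FALSE)
    if (is.na(v$mq[i]) || v$mq[i] <= t$min_mq) return(FALSE)
    if (is.na(v$qual[i]) || v$qual[i] <= t$min_qual) return(FALSE)
    fc <- v$func_class[i]
    if (is.na(fc)) return(FALSE)
    if (fc == "exonic") {
      # ok
    } else if (fc == "splicing") {
      sd <- v$splice_distance[i]
      if (!is.na(sd) && sd > t$splice_window_bp) return(FALSE)
    } else {
      return(FALSE)
    }
    ef <- v$exonic_func[i]
    if (!is.na(ef) && ef == "synonymous") {
      ada <- v$dbscsnv_ada[i]; rf <- v$dbscsnv_rf[i]
      rescue <- (!is.na(ada) && ada >= t$dbscsnv_splice_cutoff) ||
        (!is.na(rf) && rf >= t$dbscsnv_splice_cutoff)
      if (!rescue) return(FALSE)
    }
    d <- abs(nchar(v$ref[i]) - nchar(v$alt[i]))
    if (d > 0 && d %% 3 == 0 && d < t$indel_repeat_max_len &&
        isTRUE(v$in_repeat[i])) {
      return(FALSE)
    }
    for (col in c("af_g1000_all", "af_esp6500_all", "af_gnomad_all",
                  "af_gnomad_eas")) {
      af <- v[[col]][i]
      if (!is.na(af) && af >= t$max_af) return(FALSE)
    }
    if (fc == "splicing" ||
        (!is.na(ef) && ef %in% c("stopgain", "stoploss", "frameshift"))) {
      return(TRUE)
    }
    s <- !is.na(v$sift[i]) && v$sift[i] == "D"
    pp <- (!is.na(v$polyphen_hvar[i]) && v$polyphen_hvar[i] %in% c("D", "P")) ||
      (!is.na(v$polyphen_hdiv[i]) && v$polyphen_hdiv[i] %in% c("D", "P"))
    mt <- !is.na(v$mutation_taster[i]) &&
      v$mutation_taster[i] %in% c("D", "A")
    cd <- !is.na(v$cadd[i]) && v$cadd[i] >= t$cadd_deleterious_cutoff
    support <- s + pp + mt + cd
    avail <- (!is.na(v$sift[i])) +
      (!is.na(v$polyphen_hvar[i]) || !is.na(v$polyphen_hdiv[i])) +
      (!is.na(v$mutation_taster[i])) + (!is.na(v$cadd[i]))
    if (avail == 0) return(FALSE)
    if (t$vote_rule == "majority4") support >= 3
    else 2 * support >= avail
  }, logical(1))
}

# exact hypergeometric upper tail by direct combinatorial summation
oracle_hyper_p <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
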