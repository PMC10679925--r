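.cascade_stages <- c("site_qc", "region", "synonymous", "repeat_indel",
                     "frequency", "deleteriousness")

#' Deleteriousness votes for variants
#'
#' Four voters: SIFT, PolyPhen2 (HVAR and HDIV merged into one vote,
#' supporting if either sub-score is D or P), MutationTaster and CADD.
#' Supporting codes: SIFT `D`; PolyPhen `D`/`P`; MutationTaster `D`/`A`;
#' CADD at or above the configured cutoff. An absent voter never
#' supports; `votes_of4` counts supporters out of the fixed four while
#' `n_available` counts voters with any data.
#'
#' @param variants The `variants` data.frame of a [variant_set()] (or
#'   any data.frame with `sift`, `polyphen_hvar`, `polyphen_hdiv`,
#'   `mutation_taster`, `cadd` columns).
#' @param thresholds A [filter_thresholds()].
#' @return data.frame with per-voter logicals (`sift_vote`, `pph_vote`,
#'   `mt_vote`, `cadd_vote`), `votes_of4` and `n_available`.
#' @export
predictor_votes <- function(variants, thresholds = filter_thresholds()) {
  sift_vote <- !is.na(variants$sift) & variants$sift == "D"
  pph_any <- !is.na(variants$polyphen_hvar) | !is.na(variants$polyphen_hdiv)
  pph_vote <- (!is.na(variants$polyphen_hvar) &
                 variants$polyphen_hvar %in% c("D", "P")) |
              (!is.na(variants$polyphen_hdiv) &
                 variants$polyphen_hdiv %in% c("D", "P"))
  mt_vote <- !is.na(variants$mutation_taster) &
    variants$mutation_taster %in% c("D", "A")
  cadd_vote <- !is.na(variants$cadd) &
    variants$cadd >= thresholds$cadd_deleterious_cutoff
  data.frame(
    sift_vote = sift_vote, pph_vote = pph_vote,
    mt_vote = mt_vote, cadd_vote = cadd_vote,
    votes_of4 = sift_vote + pph_vote + mt_vote + cadd_vote,
    n_available = (!is.na(variants$sift)) + pph_any +
      (!is.na(variants$mutation_taster)) + (!is.na(variants$cadd))
  )
}

# --- vectorized stage evaluators: list(passed, reason, observed) ----------

.stage_site_qc <- function(vs, sample, t) {
  dp <- vs$dp[, sample]
  qual <- vs$variants$qual
  mq <- vs$variants$mq
  passed <- !is.na(dp) & dp > t$min_depth &
    !is.na(mq) & mq > t$min_mq &
    !is.na(qual) & qual > t$min_qual
  reason <- rep("ok", length(passed))
  reason[!is.na(qual) & qual <= t$min_qual] <- "low_qual"
  reason[!is.na(mq) & mq <= t$min_mq] <- "low_mq"
  reason[!is.na(dp) & dp <= t$min_depth] <- "low_depth"
  reason[is.na(qual)] <- "missing_qual"
  reason[is.na(mq)] <- "missing_mq"
  reason[is.na(dp)] <- "missing_dp"
  reason[passed] <- "ok"
  list(passed = passed, reason = reason,
       observed = sprintf("dp=%s;mq=%s;qual=%s", dp, mq, qual))
}

.stage_region <- function(vs, t) {
  fc <- vs$variants$func_class
  sd <- vs$variants$splice_distance
  in_window <- fc == "splicing" & (is.na(sd) | sd <= t$splice_window_bp)
  passed <- !is.na(fc) & (fc == "exonic" | in_window)
  reason <- rep("ok", length(passed))
  reason[!passed] <- "non_exonic"
  reason[!is.na(fc) & fc == "splicing" & !passed] <- "splice_too_far"
  reason[is.na(fc)] <- "unannotated"
  list(passed = passed, reason = reason,
       observed = sprintf("func=%s;splice_dist=%s", fc, sd))
}

.stage_synonymous <- function(vs, t) {
  ef <- vs$variants$exonic_func
  ada <- vs$variants$dbscsnv_ada
  rf <- vs$variants$dbscsnv_rf
  syn <- !is.na(ef) & ef == "synonymous"
  splice_impact <- (!is.na(ada) & ada >= t$dbscsnv_splice_cutoff) |
    (!is.na(rf) & rf >= t$dbscsnv_splice_cutoff)
  passed <- !syn | splice_impact
  reason <- rep("not_applicable", length(passed))
  reason[syn & passed] <- "dbscsnv_rescue"
  reason[syn & !passed] <- "synonymous"
  list(passed = passed, reason = reason,
       observed = sprintf("exonic_func=%s;dbscsnv=%s,%s", ef, ada, rf))
}

.stage_repeat_indel <- function(vs, t) {
  d <- abs(nchar(vs$variants$ref) - nchar(vs$variants$alt))
  rep_ <- !is.na(vs$variants$in_repeat) & vs$variants$in_repeat
  fail <- d > 0 & d %% 3 == 0 & d < t$indel_repeat_max_len & rep_
  reason <- rep("not_applicable", length(d))
  reason[d > 0] <- "ok"
  reason[fail] <- "nonframeshift_in_repeat"
  list(passed = !fail, reason = reason,
       observed = sprintf("indel_len=%d;in_repeat=%s", d, rep_))
}

.stage_frequency <- function(vs, t) {
  cols <- af_columns(vs)
  af <- as.matrix(vs$variants[cols])
  common <- !is.na(af) & af >= t$max_af
  passed <- rowSums(common) == 0
  reason <- rep("rare_or_absent", length(passed))
  if (any(!passed)) {
    first_db <- apply(common[!passed, , drop = FALSE], 1,
                      function(r) sub("^af_", "", cols[which(r)[1]]))
    reason[!passed] <- paste0("common_", first_db)
  }
  obs <- apply(af, 1, function(r) paste(ifelse(is.na(r), ".", r), collapse = "|"))
  list(passed = passed, reason = reason, observed = obs)
}

.stage_deleteriousness <- function(vs, t) {
  v <- vs$variants
  votes <- predictor_votes(v, t)
  splicing <- !is.na(v$func_class) & v$func_class == "splicing"
  lof <- !is.na(v$exonic_func) &
    v$exonic_func %in% c("stopgain", "stoploss", "frameshift")
  no_pred <- votes$n_available == 0
  vote_pass <- switch(t$vote_rule,
    half_available = votes$n_available >= 1 &
      2 * votes$votes_of4 >= votes$n_available,
    majority4 = votes$votes_of4 >= 3
  )
  passed <- splicing | lof | (!no_pred & vote_pass)
  reason <- rep("vote_fail", length(passed))
  reason[!no_pred & vote_pass] <- "vote_pass"
  reason[no_pred & !splicing & !lof] <- "no_predictions"
  reason[lof] <- "lof_bypass"
  reason[splicing] <- "splicing_bypass"
  list(passed = passed, reason = reason,
       observed = sprintf("votes=%d/4;available=%d", votes$votes_of4,
                          votes$n_available))
}

.eval_stage <- function(stage, vs, sample, t) {
  switch(stage,
    site_qc = .stage_site_qc(vs, sample, t),
    region = .stage_region(vs, t),
    synonymous = .stage_synonymous(vs, t),
    repeat_indel = .stage_repeat_indel(vs, t),
    frequency = .stage_frequency(vs, t),
    deleteriousness = .stage_deleteriousness(vs, t)
  )
}

.decision_df <- function(vs, stage, res, i = NULL) {
  idx <- if (is.null(i)) seq_len(nrow(vs$variants)) else i
  data.frame(
    variant_id = vs$variants$variant_id[idx],
    stage = stage,
    passed = res$passed[if (is.null(i)) idx else 1L][seq_along(idx)],
    reason = res$reason[if (is.null(i)) idx else 1L][seq_along(idx)],
    observed = res$observed[if (is.null(i)) idx else 1L][seq_along(idx)],
    stringsAsFactors = FALSE
  )
}

#' Individual filter stages
#'
#' Each stage takes a variant set, a variant index and thresholds and
#' returns a one-row decision data.frame (`variant_id`, `stage`,
#' `passed`, `reason`, `observed`).
#'
#' `site_qc`: per-sample depth, site RMS mapping quality and variant
#' quality, all strict `>` bounds. `region_filter`: exonic, or splicing
#' within the (inclusive) splice window. `synonymous_filter`:
#' synonymous SNVs are discarded unless a dbscSNV score reaches the
#' cutoff. `repeat_indel_filter`: non-frameshift indels shorter than
#' the length bound inside repeat regions are discarded.
#' `frequency_filter`: every configured database frequency must be
#' absent or strictly below `max_af`. `deleteriousness_filter`: the
#' predictor vote (see [predictor_votes()]); splicing and
#' loss-of-function variants, which the missense predictors cannot
#' score, bypass the vote.
#'
#' @param vs A [variant_set()].
#' @param i Variant row index.
#' @param sample Sample id (site_qc only).
#' @param thresholds A [filter_thresholds()].
#' @return One-row decision data.frame.
#' @export
site_qc <- function(vs, i, sample, thresholds = filter_thresholds()) {
  sub <- subset_variants(vs, i)
  .decision_df(sub, "site_qc", .stage_site_qc(sub, sample, thresholds))
}

#' @rdname site_qc
#' @export
region_filter <- function(vs, i, thresholds = filter_thresholds()) {
  sub <- subset_variants(vs, i)
  .decision_df(sub, "region", .stage_region(sub, thresholds))
}

#' @rdname site_qc
#' @export
synonymous_filter <- function(vs, i, thresholds = filter_thresholds()) {
  sub <- subset_variants(vs, i)
  .decision_df(sub, "synonymous", .stage_synonymous(sub, thresholds))
}

#' @rdname site_qc
#' @export
repeat_indel_filter <- function(vs, i, thresholds = filter_thresholds()) {
  sub <- subset_variants(vs, i)
  .decision_df(sub, "repeat_indel", .stage_repeat_indel(sub, thresholds))
}

#' @rdname site_qc
#' @export
frequency_filter <- function(vs, i, thresholds = filter_thresholds()) {
  sub <- subset_variants(vs, i)
  .decision_df(sub, "frequency", .stage_frequency(sub, thresholds))
}

#' @rdname site_qc
#' @export
deleteriousness_filter <- function(vs, i, thresholds = filter_thresholds()) {
  sub <- subset_variants(vs, i)
  .decision_df(sub, "deleteriousness", .stage_deleteriousness(sub, thresholds))
}

#' Run the full filter cascade for one sample
#'
#' Applies the six stages in fixed order (site QC, region, synonymous,
#' repeat-indel, frequency, deleteriousness) and records a per-variant
#' audit trail. With `short_circuit = TRUE` (default) the trace stops at
#' the first failing stage; the final verdict is identical either way,
#' because every stage is evaluated independently of the others.
#'
#' @param vs A [variant_set()].
#' @param sample Sample id whose depth drives site QC.
#' @param thresholds A [filter_thresholds()].
#' @param short_circuit Stop tracing a variant at its first failure?
#' @return Object of class `filter_trace`: list with `trace` (long
#'   decision data.frame) and `final` (`variant_id`, `pass`,
#'   `fail_stage`).
#' @export
run_cascade <- function(vs, sample, thresholds = filter_thresholds(),
                        short_circuit = TRUE) {
  n <- nrow(vs$variants)
  results <- lapply(.cascade_stages, .eval_stage, vs = vs, sample = sample,
                    t = thresholds)
  names(results) <- .cascade_stages
  pass_mat <- vapply(results, `[[`, logical(n), "passed")
  if (n == 1) pass_mat <- matrix(pass_mat, nrow = 1,
                                 dimnames = list(NULL, .cascade_stages))
  pass <- rowSums(!pass_mat) == 0
  first_fail <- apply(pass_mat, 1, function(r) {
    w <- which(!r)
    if (length(w)) w[1] else NA_integer_
  })

  keep <- if (short_circuit) {
    lapply(seq_along(.cascade_stages), function(s) {
      is.na(first_fail) | first_fail >= s
    })
  } else {
    rep(list(rep(TRUE, n)), length(.cascade_stages))
  }
  trace <- do.call(rbind, lapply(seq_along(.cascade_stages), function(s) {
    idx <- which(keep[[s]])
    data.frame(
      variant_id = vs$variants$variant_id[idx],
      stage = rep(.cascade_stages[s], length(idx)),
      passed = results[[s]]$passed[idx],
      reason = results[[s]]$reason[idx],
      observed = results[[s]]$observed[idx],
      stringsAsFactors = FALSE
    )
  }))
  trace <- trace[order(match(trace$variant_id, vs$variants$variant_id),
                       match(trace$stage, .cascade_stages)), ]
  rownames(trace) <- NULL
  final <- data.frame(
    variant_id = vs$variants$variant_id,
    pass = pass,
    fail_stage = ifelse(is.na(first_fail), NA_character_,
                        .cascade_stages[first_fail]),
    stringsAsFactors = FALSE
  )
  structure(list(trace = trace, final = final, sample = sample),
            class = "filter_trace")
}

#' @export
print.filter_trace <- function(x, ...) {
  cat("filter_trace for sample", x$sample, "-",
      sum(x$final$pass), "of", nrow(x$final), "variants pass\n")
  invisible(x)
}

#' Convenience: logical pass vector for one sample
#' @inheritParams run_cascade
#' @return Logical vector along the variants of `vs`.
#' @export
cascade_pass <- function(vs, sample, thresholds = filter_thresholds()) {
  run_cascade(vs, sample, thresholds)$final$pass
}

#' Per-site QC summary across samples
#'
#' Site-level complement to the per-sample QC: a site passes when its
#' QUAL and MQ bounds hold and at least `min_samples` samples exceed the
#' depth bound.
#'
#' @param vs A [variant_set()].
#' @param thresholds A [filter_thresholds()].
#' @param min_samples Minimum number of samples passing the depth bound.
#' @return data.frame with `variant_id`, `n_samples_dp_ok`, `pass`.
#' @export
site_qc_summary <- function(vs, thresholds = filter_thresholds(),
                            min_samples = 1L) {
  dp_ok <- rowSums(!is.na(vs$dp) & vs$dp > thresholds$min_depth)
  qual <- vs$variants$qual; mq <- vs$variants$mq
  data.frame(
    variant_id = vs$variants$variant_id,
    n_samples_dp_ok = dp_ok,
    pass = !is.na(qual) & qual > thresholds$min_qual &
      !is.na(mq) & mq > thresholds$min_mq & dp_ok >= min_samples
  )
}

#' Export a filter trace as TSV (one row per variant x stage)
#' @param trace A `filter_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_trace_tsv <- function(trace, path) {
  utils::write.table(trace$trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
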