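#' Prioritize candidate variants across a cohort
#'
#' Runs the full screen for every affected sample: filter cascade,
#' then -- per family structure -- de novo / recessive / X-linked
#' calling, compound-heterozygote detection by parental origin, the
#' case-exclusive sporadic rule, and oligogenic aggregation of
#' heterozygous variants inherited from unaffected parents. Variants
#' qualifying under several models are reported once under the most
#' specific one (monogenic model > compound het > oligogenic).
#'
#' @param vs A [variant_set()].
#' @param ped A [read_ped()] pedigree.
#' @param thresholds A [filter_thresholds()].
#' @param panel Optional [read_panel()] gene panel for tagging.
#' @param acmg An [acmg_config()]; set `classify = FALSE` to skip
#'   classification.
#' @param classify Assign ACMG evidence and classes?
#' @return Candidate data.frame (one row per proband x variant, plus
#'   paired rows for compound heterozygotes). Mendelian-inconsistent
#'   observations (`possible_denovo_or_error`) are excluded from the
#'   candidates and attached as the `"inconsistent"` attribute.
#' @export
prioritize_cohort <- function(vs, ped, thresholds = filter_thresholds(),
                              panel = NULL, acmg = acmg_config(),
                              classify = TRUE) {
  stopifnot(inherits(vs, "variant_set"), inherits(ped, "pedigree"))
  probands <- intersect(affected_ids(ped), vs$samples)
  controls <- unaffected_ids(ped)
  all_calls <- list()
  inconsistent <- list()

  for (p in probands) {
    pass <- cascade_pass(vs, p, thresholds)
    idx <- which(pass & !is.na(vs$ac[, p]) & vs$ac[, p] >= 1)
    if (length(idx) == 0) next

    if (is_sporadic(ped, p)) {
      calls <- do.call(rbind, lapply(idx, function(i) {
        call_sporadic(vs, i, p, controls)
      }))
      if (!is.null(calls)) all_calls[[p]] <- calls
      next
    }

    raw <- do.call(rbind, lapply(idx, function(i) {
      call_trio_model(vs, i, p, ped, thresholds)
    }))
    if (is.null(raw)) next
    inconsistent[[p]] <- raw[raw$model == "possible_denovo_or_error", ,
                             drop = FALSE]
    direct <- raw[raw$model %in% c("de_novo", "hom_recessive",
                                   "x_linked_recessive"), , drop = FALSE]

    # compound heterozygotes, gene by gene
    ch_rows <- list()
    het_idx <- idx[!is.na(vs$ac[idx, p]) & vs$ac[idx, p] == 1 &
                     vs$ploidy[idx, p] == 2]
    for (g in unique(vs$variants$gene[het_idx])) {
      if (is.na(g)) next
      gi <- het_idx[vs$variants$gene[het_idx] %in% g]
      if (length(gi) < 2) next
      pairs <- call_compound_het(vs, gi, p, ped)
      pairs <- pairs[pairs$phase == "trans", , drop = FALSE]
      if (nrow(pairs) == 0) next
      for (r in seq_len(nrow(pairs))) {
        ch_rows[[length(ch_rows) + 1]] <- data.frame(
          proband = p,
          variant_id = c(pairs$variant_a[r], pairs$variant_b[r]),
          gene = g, model = "compound_het",
          carrier_parent = c(pairs$origin_a[r], pairs$origin_b[r]),
          flags = "", phase = "trans",
          partner_variant = c(pairs$variant_b[r], pairs$variant_a[r]),
          stringsAsFactors = FALSE)
      }
    }
    ch <- if (length(ch_rows)) do.call(rbind, ch_rows) else NULL

    olig_input <- raw[raw$model %in% c("inherited_het", "de_novo"), ,
                      drop = FALSE]
    prof <- build_oligogenic_profile(olig_input, ped)
    olig <- if (!is.null(prof)) {
      prof$loci[prof$loci$model == "oligogene", , drop = FALSE]
    } else NULL

    calls <- direct
    calls$phase <- rep(NA_character_, nrow(calls))
    calls <- calls[, c(names(raw), "phase")]
    add <- function(base, new) {
      if (is.null(new) || nrow(new) == 0) return(base)
      if (!("phase" %in% names(new))) new$phase <- NA_character_
      new <- new[!(new$variant_id %in% base$variant_id), , drop = FALSE]
      rbind(base, new[names(base)])
    }
    calls <- add(calls, ch)
    calls <- add(calls, olig)
    if (nrow(calls)) all_calls[[p]] <- calls
  }

  calls <- if (length(all_calls)) {
    cols <- c("proband", "variant_id", "gene", "model", "carrier_parent",
              "flags", "partner_variant", "phase")
    do.call(rbind, lapply(all_calls, function(d) {
      if (!("phase" %in% names(d))) d$phase <- NA_character_
      d[cols]
    }))
  } else {
    data.frame(proband = character(0), variant_id = character(0),
               gene = character(0), model = character(0),
               carrier_parent = character(0), flags = character(0),
               partner_variant = character(0), phase = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(calls) <- NULL

  # annotate with variant-level columns
  vi <- match(calls$variant_id, vs$variants$variant_id)
  votes <- predictor_votes(vs$variants, thresholds)
  ann_cols <- intersect(
    c("chrom", "pos", "ref", "alt", "func_class", "exonic_func",
      "splice_distance", "sift", "polyphen_hvar", "polyphen_hdiv",
      "mutation_taster", "cadd", "gerp", af_columns(vs)),
    names(vs$variants))
  out <- cbind(calls, vs$variants[vi, ann_cols, drop = FALSE])
  out$votes_of4 <- votes$votes_of4[vi]
  out$n_predictors_available <- votes$n_available[vi]
  out$zygosity <- zygosity_display(
    vs$ac[cbind(vi, match(calls$proband, vs$samples))],
    vs$ploidy[cbind(vi, match(calls$proband, vs$samples))])
  out$family <- ped$family_id[match(out$proband, ped$sample_id)]
  out$change <- out$variant_id
  rownames(out) <- NULL

  if (!is.null(panel)) out <- intersect_panel(out, panel)
  if (classify && nrow(out)) out <- classify_candidates(out, acmg)
  inc <- if (length(inconsistent)) do.call(rbind, inconsistent) else NULL
  attr(out, "inconsistent") <- inc
  out
}

#' Spike-in recovery against a simulator truth table
#'
#' @param candidates Output of [prioritize_cohort()].
#' @param truth Truth table from [spike_causal()].
#' @return List with per-model and overall recall and the unmatched
#'   truth rows.
#' @export
spike_recall <- function(candidates, truth) {
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(candidates$proband == truth$proband[i] &
          candidates$variant_id == truth$variant_id[i] &
          candidates$model == truth$model[i])
  }, logical(1))
  by_model <- tapply(hit, truth$model, mean)
  list(recall = mean(hit),
       by_model = by_model,
       missed = truth[!hit, , drop = FALSE])
}
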