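.call_row <- function(proband, variant_id, gene, model,
                      carrier_parent = "none", flags = "",
                      partner_variant = NA_character_) {
  data.frame(proband = proband, variant_id = variant_id, gene = gene,
             model = model, carrier_parent = carrier_parent,
             flags = flags, partner_variant = partner_variant,
             stringsAsFactors = FALSE)
}

.gt_at <- function(vs, i, sample) {
  if (is.na(sample) || !(sample %in% vs$samples)) {
    return(list(ac = NA_integer_, ploidy = NA_integer_, dp = NA_real_,
                present = FALSE))
  }
  list(ac = vs$ac[i, sample], ploidy = vs$ploidy[i, sample],
       dp = vs$dp[i, sample], present = TRUE)
}

.observed_ref <- function(g, min_depth) {
  g$present && !is.na(g$ac) && g$ac == 0 && !is.na(g$dp) && g$dp > min_depth
}

.carries <- function(g) g$present && !is.na(g$ac) && g$ac >= 1

#' Call the inheritance model of one variant in one trio
#'
#' Evaluates, in order: de novo (proband carries the alternate allele,
#' both parents observed homozygous-reference with depth above the QC
#' bound; on the male X only the mother is informative), homozygous
#' recessive / X-linked recessive (proband homozygous or hemizygous
#' alternate with each observed parent carrying at least one copy), and
#' inherited heterozygous with the transmitting parent recorded (the
#' raw material for compound-heterozygote and oligogenic calls). An
#' autosomal homozygous proband with a parent observed
#' homozygous-reference is reported as `possible_denovo_or_error`,
#' never as recessive.
#'
#' @param vs A [variant_set()].
#' @param i Variant row index.
#' @param proband Proband sample id.
#' @param ped A [read_ped()] pedigree.
#' @param thresholds [filter_thresholds()]; the depth bound is reused
#'   for parental genotype confirmation.
#' @return One-row call data.frame, or `NULL` when the proband does not
#'   carry the allele or its genotype is missing.
#' @export
call_trio_model <- function(vs, i, proband, ped,
                            thresholds = filter_thresholds()) {
  pi <- match(proband, ped$sample_id)
  if (is.na(pi)) stop("proband not in pedigree: ", proband)
  p <- .gt_at(vs, i, proband)
  if (!p$present || is.na(p$ac) || p$ac == 0) return(NULL)

  chrom <- vs$variants$chrom[i]
  vid <- vs$variants$variant_id[i]
  gene <- vs$variants$gene[i]
  x <- is_x_chrom(chrom)
  male <- ped$sex[pi] == "male"
  father <- ped$father_id[pi]
  mother <- ped$mother_id[pi]
  f <- .gt_at(vs, i, if (is.na(father)) NA_character_ else father)
  m <- .gt_at(vs, i, if (is.na(mother)) NA_character_ else mother)
  md <- thresholds$min_depth

  hom_alt <- p$ac == 2 || (p$ac == 1 && !is.na(p$ploidy) && p$ploidy == 1)

  # --- de novo: requires observed hom-ref parents with adequate depth
  if (x && male) {
    if (m$present) {
      if (.observed_ref(m, md)) {
        return(.call_row(proband, vid, gene, "de_novo",
                         carrier_parent = "none"))
      }
    }
  } else if (f$present && m$present &&
             .observed_ref(f, md) && .observed_ref(m, md)) {
    return(.call_row(proband, vid, gene, "de_novo", carrier_parent = "none"))
  }

  # --- homozygous / hemizygous alternate
  if (hom_alt) {
    if (x && male) {
      if (.carries(m)) {
        return(.call_row(proband, vid, gene, "x_linked_recessive",
                         carrier_parent = "mother"))
      }
      return(.call_row(proband, vid, gene, "x_linked_recessive",
                       carrier_parent = "unknown",
                       flags = "parent_unconfirmed"))
    }
    f_ref <- .observed_ref(f, md); m_ref <- .observed_ref(m, md)
    if (.carries(f) && .carries(m)) {
      model <- if (x) "x_linked_recessive" else "hom_recessive"
      return(.call_row(proband, vid, gene, model, carrier_parent = "both"))
    }
    if ((f_ref && .carries(m)) || (m_ref && .carries(f)) ||
        (f_ref && m_ref)) {
      return(.call_row(proband, vid, gene, "possible_denovo_or_error",
                       carrier_parent = "unknown",
                       flags = "mendelian_inconsistent"))
    }
    model <- if (x) "x_linked_recessive" else "hom_recessive"
    return(.call_row(proband, vid, gene, model, carrier_parent = "unknown",
                     flags = "parent_unconfirmed"))
  }

  # --- inherited heterozygote (or unresolvable)
  f_c <- .carries(f); m_c <- .carries(m)
  if (f_c && m_c) {
    return(.call_row(proband, vid, gene, "inherited_het",
                     carrier_parent = "both"))
  }
  if (f_c) {
    return(.call_row(proband, vid, gene, "inherited_het",
                     carrier_parent = "father"))
  }
  if (m_c) {
    return(.call_row(proband, vid, gene, "inherited_het",
                     carrier_parent = "mother"))
  }
  flags <- if (!f$present || !m$present) "incomplete_trio"
           else "parent_unconfirmed"
  .call_row(proband, vid, gene, "inherited_het",
            carrier_parent = "unknown", flags = flags)
}

#' Parental origin class of a proband-het variant
#' @keywords internal
.het_origin <- function(vs, i, proband, ped) {
  call <- call_trio_model(vs, i, proband, ped)
  if (is.null(call)) return(NA_character_)
  if (call$model == "de_novo") return("de_novo")
  if (call$model != "inherited_het") return(NA_character_)
  call$carrier_parent
}

#' Detect compound heterozygotes within one gene
#'
#' Given the indices of proband-heterozygous variants in a single gene,
#' pairs a paternally transmitted variant with a maternally transmitted
#' one (trans configuration by parental origin). Pairs that cannot be
#' phased -- a parent carries both variants, or parental genotypes are
#' unavailable -- are reported with phase `"possible_cis"`; pairs whose
#' variants share the same single transmitting parent are in cis and
#' are not reported.
#'
#' @param vs A [variant_set()].
#' @param idx Variant row indices (same gene, proband heterozygous).
#' @param proband Proband sample id.
#' @param ped A [read_ped()] pedigree.
#' @return data.frame with `variant_a`, `variant_b`, `origin_a`,
#'   `origin_b`, `phase` (`"trans"` or `"possible_cis"`); zero rows when
#'   no pair qualifies.
#' @export
call_compound_het <- function(vs, idx, proband, ped) {
  empty <- data.frame(variant_a = character(0), variant_b = character(0),
                      origin_a = character(0), origin_b = character(0),
                      phase = character(0), stringsAsFactors = FALSE)
  if (length(idx) < 2) return(empty)
  het <- vapply(idx, function(i) {
    ac <- vs$ac[i, proband]
    !is.na(ac) && ac == 1 && vs$ploidy[i, proband] == 2
  }, logical(1))
  idx <- idx[het]
  if (length(idx) < 2) return(empty)

  origin <- vapply(idx, .het_origin, character(1),
                   vs = vs, proband = proband, ped = ped)
  vid <- vs$variants$variant_id[idx]
  out <- list()
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (b <= a) next
      oa <- origin[a]; ob <- origin[b]
      if (is.na(oa) || is.na(ob)) next
      trans <- (oa == "father" && ob == "mother") ||
               (oa == "mother" && ob == "father")
      cis <- (oa == "father" && ob == "father") ||
             (oa == "mother" && ob == "mother")
      ambiguous <- oa %in% c("both", "unknown") ||
                   ob %in% c("both", "unknown")
      if (trans) {
        out[[length(out) + 1]] <- data.frame(
          variant_a = vid[a], variant_b = vid[b],
          origin_a = oa, origin_b = ob, phase = "trans",
          stringsAsFactors = FALSE)
      } else if (!cis && ambiguous) {
        out[[length(out) + 1]] <- data.frame(
          variant_a = vid[a], variant_b = vid[b],
          origin_a = oa, origin_b = ob, phase = "possible_cis",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

#' Case-exclusive screen for sporadic samples
#'
#' A variant in a sporadic case (no sequenced relatives) is retained
#' only when the alternate allele is absent from every control sample.
#' A missing control genotype counts as "not detected" (absence of data
#' is not presence) but is flagged `control_missing`.
#'
#' @param vs A [variant_set()].
#' @param i Variant row index.
#' @param case_sample Sporadic case sample id.
#' @param control_samples Control sample ids.
#' @return One-row call data.frame (model `sporadic_only`) or `NULL`.
#' @export
call_sporadic <- function(vs, i, case_sample, control_samples) {
  ac <- vs$ac[i, case_sample]
  if (is.na(ac) || ac == 0) return(NULL)
  ctl <- vs$ac[i, intersect(control_samples, vs$samples)]
  if (any(!is.na(ctl) & ctl >= 1)) return(NULL)
  flags <- if (any(is.na(ctl))) "control_missing" else ""
  .call_row(case_sample, vs$variants$variant_id[i], vs$variants$gene[i],
            "sporadic_only", carrier_parent = "none", flags = flags)
}

#' Aggregate heterozygous candidates into an oligogenic profile
#'
#' A proband with candidate heterozygous variants in two or more
#' distinct genes -- each either de novo or inherited from an
#' unaffected parent -- forms an oligogenic profile; inherited members
#' are relabeled `oligogene`. Single-gene candidate sets yield no
#' profile.
#'
#' @param calls Call data.frame for one proband (rows with models
#'   `inherited_het` and/or `de_novo`).
#' @param ped A [read_ped()] pedigree.
#' @return List with `proband` and `loci` (the relabeled calls), or
#'   `NULL`.
#' @export
build_oligogenic_profile <- function(calls, ped) {
  if (is.null(calls) || nrow(calls) == 0) return(NULL)
  proband <- unique(calls$proband)
  stopifnot(length(proband) == 1)
  pi <- match(proband, ped$sample_id)
  father <- ped$father_id[pi]; mother <- ped$mother_id[pi]
  unaffected <- function(s) {
    !is.na(s) && s %in% ped$sample_id && !ped$affected[match(s, ped$sample_id)]
  }
  ok_parent <- vapply(calls$carrier_parent, function(cp) {
    switch(cp,
      father = unaffected(father),
      mother = unaffected(mother),
      both = unaffected(father) && unaffected(mother),
      FALSE)
  }, logical(1))
  eligible <- calls$model == "de_novo" |
    (calls$model == "inherited_het" & ok_parent)
  loci <- calls[eligible, , drop = FALSE]
  if (length(unique(loci$gene)) < 2) return(NULL)
  loci$model[loci$model == "inherited_het"] <- "oligogene"
  rownames(loci) <- NULL
  list(proband = proband, loci = loci)
}
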