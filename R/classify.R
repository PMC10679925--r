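.acmg_codes <- c("PVS1", "PS2", "PM2", "PM3", "PP1", "PP2", "PP3", "PP4",
                 "BP4", "BS1", "BA1")

#' Tag candidates against a gene panel
#'
#' Every candidate is kept; on-panel candidates receive their sub-panel
#' tag (e.g. `CVID_OMIM`, `PID`), the rest are flagged `off_panel`.
#'
#' @param candidates Candidate data.frame with a `gene` column.
#' @param panel A [read_panel()] gene panel.
#' @return `candidates` with a `panel_tag` column.
#' @export
intersect_panel <- function(candidates, panel) {
  if (nrow(candidates) == 0) {
    candidates$panel_tag <- character(0)
    return(candidates)
  }
  tag <- panel$tag[match(toupper(candidates$gene), panel$gene)]
  candidates$panel_tag <- ifelse(is.na(tag), "off_panel", tag)
  candidates
}

#' Assign ACMG evidence codes to candidates
#'
#' Implements a deliberately small, fully documented subset of the
#' evidence codes; codes requiring literature curation are out of
#' scope. Triggers:
#' \describe{
#'   \item{PVS1}{null variant: stopgain, frameshift, or splicing within
#'     2 bp of the junction.}
#'   \item{PS2}{confirmed de novo call (weighted per
#'     `acmg_config()$denovo_strength`).}
#'   \item{PM2}{absent from every configured population database.}
#'   \item{PM3}{recessive genotype confirmed in trans by parental
#'     genotypes: homozygous/X-linked recessive with observed carrier
#'     parent(s), or a trans compound-heterozygote pair.}
#'   \item{PP1}{co-segregation with disease in at least one additional
#'     affected relative (`coseg_affected` column).}
#'   \item{PP2}{missense in a configured missense-constrained gene.}
#'   \item{PP3}{at least 3 of the 4 deleteriousness voters support
#'     (`votes_of4` column; see [predictor_votes()]).}
#'   \item{PP4}{phenotype specifically matching the gene
#'     (`phenotype_match` column).}
#'   \item{BP4}{predictors available but none supporting.}
#'   \item{BS1/BA1}{any database frequency at or above the configured
#'     bounds.}
#' }
#'
#' @param candidates Candidate data.frame; requires `model`,
#'   `carrier_parent`, `func_class`, `exonic_func`, `splice_distance`,
#'   `gene`, `votes_of4` and `af_*` columns. Optional: `phase`,
#'   `coseg_affected`, `phenotype_match`, `n_predictors_available`.
#' @param acmg An [acmg_config()].
#' @return Logical data.frame, one column per implemented code.
#' @export
assign_evidence <- function(candidates, acmg = acmg_config()) {
  n <- nrow(candidates)
  col <- function(name, default) {
    if (name %in% names(candidates)) candidates[[name]] else rep(default, n)
  }
  af <- as.matrix(candidates[grep("^af_", names(candidates))])
  if (ncol(af) == 0) stop("candidates carry no af_* columns")
  af_absent <- rowSums(!is.na(af)) == 0
  af_max <- suppressWarnings(apply(af, 1, max, na.rm = TRUE))
  af_max[af_absent] <- 0

  ef <- candidates$exonic_func
  null_var <- (!is.na(ef) & ef %in% c("stopgain", "frameshift")) |
    (!is.na(candidates$func_class) & candidates$func_class == "splicing" &
       !is.na(candidates$splice_distance) & candidates$splice_distance <= 2)
  phase <- col("phase", NA_character_)
  trans_pair <- !is.na(phase) & phase == "trans" &
    candidates$model == "compound_het"
  recessive_confirmed <- (candidates$model %in%
                            c("hom_recessive", "x_linked_recessive") &
                          candidates$carrier_parent %in%
                            c("both", "mother", "father")) | trans_pair
  votes <- col("votes_of4", 0L)
  n_avail <- col("n_predictors_available", NA_integer_)

  out <- data.frame(
    PVS1 = null_var,
    PS2 = candidates$model == "de_novo",
    PM2 = af_absent,
    PM3 = recessive_confirmed,
    PP1 = col("coseg_affected", 0L) >= 1,
    PP2 = toupper(candidates$gene) %in% acmg$pp2_genes &
      !is.na(ef) & ef == "missense",
    PP3 = votes >= 3,
    PP4 = isTRUE_vec(col("phenotype_match", FALSE)),
    BP4 = !is.na(n_avail) & n_avail >= 2 & votes == 0,
    BS1 = af_max >= acmg$bs1_af,
    BA1 = af_max >= acmg$ba1_af,
    stringsAsFactors = FALSE
  )
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Combine ACMG evidence into a five-tier class
#'
#' Applies the standard combination table over very-strong, strong,
#' moderate and supporting pathogenic evidence and the benign branch
#' (BA1 standalone, strong and supporting benign). De novo evidence
#' (PS2) is weighted per `denovo_strength`: `"moderate"` (default)
#' treats it as assumed-de-novo moderate evidence, `"strong"` as full
#' strength. Contradictory pathogenic and benign evidence yields VUS
#' with the `conflict` flag.
#'
#' @param profile Logical vector or one-row data.frame with the
#'   implemented codes (see [assign_evidence()]); absent codes count
#'   FALSE.
#' @param acmg An [acmg_config()].
#' @return Character scalar: `"Pathogenic"`, `"Likely Pathogenic"`,
#'   `"VUS"`, `"Likely Benign"` or `"Benign"`, with logical attribute
#'   `"conflict"`.
#' @export
combine_acmg <- function(profile, acmg = acmg_config()) {
  p <- as.list(profile)
  g <- function(code) isTRUE(as.logical(p[[code]]))
  strong_denovo <- acmg$denovo_strength == "strong"

  n_vs <- g("PVS1")
  n_s <- as.integer(g("PS2") && strong_denovo)
  n_m <- g("PM2") + g("PM3") + as.integer(g("PS2") && !strong_denovo)
  n_p <- g("PP1") + g("PP2") + g("PP3") + g("PP4")
  n_bs <- as.integer(g("BS1"))
  n_bp <- as.integer(g("BP4"))

  pathogenic <-
    (n_vs >= 1 && (n_s >= 1 || n_m >= 2 || (n_m == 1 && n_p >= 1) ||
                     n_p >= 2)) ||
    n_s >= 2 ||
    (n_s == 1 && (n_m >= 3 || (n_m == 2 && n_p >= 2) ||
                    (n_m == 1 && n_p >= 4)))
  likely_pathogenic <-
    (n_vs >= 1 && n_m == 1) ||
    (n_s == 1 && n_m >= 1 && n_m <= 2) ||
    (n_s == 1 && n_p >= 2) ||
    n_m >= 3 ||
    (n_m == 2 && n_p >= 2) ||
    (n_m == 1 && n_p >= 4)
  benign <- g("BA1") || n_bs >= 2
  likely_benign <- (n_bs == 1 && n_bp >= 1) || n_bp >= 2

  path_side <- pathogenic || likely_pathogenic
  ben_side <- benign || likely_benign
  conflict <- path_side && ben_side
  class <- if (conflict) "VUS"
    else if (pathogenic) "Pathogenic"
    else if (likely_pathogenic) "Likely Pathogenic"
    else if (benign) "Benign"
    else if (likely_benign) "Likely Benign"
    else "VUS"
  structure(class, conflict = conflict)
}

#' Classify a candidate table
#'
#' Assigns evidence codes and the combined ACMG class to every row.
#'
#' @param candidates Candidate data.frame (see [assign_evidence()]).
#' @param acmg An [acmg_config()].
#' @return `candidates` with the evidence code columns, `acmg_class`
#'   and `acmg_conflict` appended.
#' @export
classify_candidates <- function(candidates, acmg = acmg_config()) {
  if (nrow(candidates) == 0) {
    candidates$acmg_class <- character(0)
    candidates$acmg_conflict <- logical(0)
    return(candidates)
  }
  ev <- assign_evidence(candidates, acmg)
  cls <- lapply(seq_len(nrow(ev)), function(i) combine_acmg(ev[i, ], acmg))
  candidates <- cbind(candidates, ev)
  candidates$acmg_class <- vapply(cls, as.character, character(1))
  candidates$acmg_conflict <- vapply(cls, attr, logical(1), "conflict")
  candidates
}

#' Gene-set over-representation test
#'
#' Hypergeometric upper-tail test of the overlap between a query gene
#' list and each gene set, with Benjamini-Hochberg adjustment across
#' sets. Zero-overlap sets are reported with p = 1, not dropped.
#'
#' @param query Character vector of query gene symbols.
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @param universe Either the number of genes in the background
#'   universe (default 20000 protein-coding genes) or a character
#'   vector of background symbols, in which case query and sets are
#'   intersected with it.
#' @return data.frame sorted by ascending p: `set`, `overlap`,
#'   `set_size`, `query_size`, `universe`, `p`, `p_adj`.
#' @export
enrich <- function(query, gene_sets, universe = 20000) {
  query <- unique(toupper(query))
  gene_sets <- lapply(gene_sets, function(s) unique(toupper(s)))
  if (is.character(universe)) {
    bg <- unique(toupper(universe))
    query <- intersect(query, bg)
    gene_sets <- lapply(gene_sets, intersect, bg)
    n_universe <- length(bg)
  } else {
    n_universe <- as.integer(universe)
  }
  n_query <- length(query)
  res <- lapply(names(gene_sets), function(nm) {
    set <- gene_sets[[nm]]
    k <- length(intersect(query, set))
    K <- length(set)
    p <- stats::phyper(k - 1, K, n_universe - K, n_query,
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, query_size = n_query,
               universe = n_universe, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a candidate table over the cohort
#'
#' Computes distinct-gene and distinct-locus counts (dedup key =
#' gene + change), per-locus recurrence across patients, per-patient
#' locus counts, and phenotype category percentages (one decimal).
#'
#' @param candidates Candidate data.frame with `proband`, `gene` and a
#'   `change` column (amino-acid or nucleotide change; falls back to
#'   `variant_id`).
#' @param phenotypes Optional data.frame with `patient` and `category`
#'   columns (one row per patient).
#' @param n_patients Number of patients; defaults to the number of
#'   phenotype rows, else the number of distinct probands.
#' @param groups Category grouping, see [phenotype_groups()].
#' @return List of class `cohort_summary`.
#' @export
summarize_cohort <- function(candidates, phenotypes = NULL,
                             n_patients = NULL,
                             groups = phenotype_groups()) {
  ch <- if ("change" %in% names(candidates)) candidates$change
        else candidates$variant_id
  if (is.null(n_patients)) {
    n_patients <- if (!is.null(phenotypes)) nrow(phenotypes)
                  else length(unique(candidates$proband))
  }
  pct <- function(k) round(100 * k / n_patients, 1)

  if (nrow(candidates) == 0) {
    loci <- data.frame(gene = character(0), change = character(0),
                       n_patients = integer(0), pct_patients = numeric(0))
    per_patient <- data.frame(patient = character(0), n_loci = integer(0))
    n_genes <- 0L; n_loci <- 0L; n_multi <- 0L
  } else {
    key <- paste(toupper(candidates$gene), ch, sep = "|")
    loci <- do.call(rbind, lapply(split(seq_len(nrow(candidates)), key),
      function(ix) {
        data.frame(gene = toupper(candidates$gene[ix[1]]),
                   change = ch[ix[1]],
                   n_patients = length(unique(candidates$proband[ix])),
                   stringsAsFactors = FALSE)
      }))
    loci$pct_patients <- pct(loci$n_patients)
    loci <- loci[order(-loci$n_patients, loci$gene, loci$change), ]
    rownames(loci) <- NULL
    n_genes <- length(unique(toupper(candidates$gene)))
    n_loci <- nrow(loci)
    pp <- tapply(key, candidates$proband, function(k) length(unique(k)))
    per_patient <- data.frame(patient = names(pp),
                              n_loci = as.integer(pp),
                              stringsAsFactors = FALSE)
    n_multi <- sum(per_patient$n_loci >= 2)
  }

  phen <- NULL; phen_groups <- NULL
  if (!is.null(phenotypes)) {
    tab <- table(toupper(phenotypes$category))
    phen <- data.frame(category = names(tab), n = as.integer(tab),
                       pct = pct(as.integer(tab)),
                       stringsAsFactors = FALSE)
    phen <- phen[order(-phen$n, phen$category), ]
    rownames(phen) <- NULL
    phen_groups <- do.call(rbind, lapply(names(groups), function(g) {
      k <- sum(toupper(phenotypes$category) %in% toupper(groups[[g]]))
      data.frame(group = g, n = k, pct = pct(k), stringsAsFactors = FALSE)
    }))
  }

  structure(list(
    n_rows = nrow(candidates),
    n_genes = n_genes,
    n_loci = n_loci,
    loci = loci,
    per_patient = per_patient,
    n_patients = n_patients,
    n_patients_multi_locus = n_multi,
    pct_patients_multi_locus = pct(n_multi),
    phenotype = phen,
    phenotype_groups = phen_groups
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("cohort_summary:", x$n_rows, "candidate rows;",
      x$n_genes, "genes;", x$n_loci, "loci;",
      x$n_patients_multi_locus, "of", x$n_patients,
      "patients with >= 2 loci\n")
  invisible(x)
}

#' Export a candidate table as TSV in the clinical-table column layout
#'
#' @param candidates Classified candidate data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_candidates_tsv <- function(candidates, path) {
  cols <- intersect(
    c("proband", "family", "carrier_label", "model", "carrier_parent",
      "gene", "func_class", "exonic_func", "zygosity", "change",
      "acmg_class", grep("^af_", names(candidates), value = TRUE),
      "sift", "polyphen_hvar", "polyphen_hdiv", "mutation_taster",
      "cadd", "gerp", "panel_tag", "flags"),
    names(candidates))
  utils::write.table(candidates[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
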