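#' Path to a bundled example data file
#' @param file File name under the package's `extdata`, or empty to
#'   list them.
#' @return File path.
#' @export
triovar_example <- function(file = "") {
  system.file("extdata", file, package = "triovar", mustWork = nzchar(file))
}

#' Bundled CVID cohort candidate table
#'
#' The candidate-variant table of a 16-patient CVID-with-autoimmunity
#' cohort (12 core trio families, 4 sporadic cases; 26 healthy
#' first-degree relatives as controls): 34 rows covering 28 genes and
#' 32 distinct loci, with published inheritance labels, ACMG classes,
#' population frequencies (1000 Genomes and gnomAD; absent entries mean
#' the site is unobserved in that database), predictor verdicts, CADD
#' and GERP++ scores. Chromosome assignments follow the genes' true
#' chromosomes.
#'
#' The loader normalizes the table into the candidate layout used
#' throughout the package: inheritance `model` (`sporadic_only`,
#' `oligogene`, `de_novo`, `x_linked_recessive` for the hemizygous
#' X-linked case), `carrier_parent` parsed from the carrier label,
#' `func_class`/`exonic_func`, and the deleteriousness vote tally.
#'
#' @return Candidate data.frame (one row per patient x variant).
#' @export
cvid_candidates <- function() {
  df <- utils::read.table(triovar_example("cvid_candidates.tsv"),
                          header = TRUE, sep = "\t", na.strings = ".",
                          stringsAsFactors = FALSE, comment.char = "")
  model <- c(sporadic = "sporadic_only", oligogene = "oligogene",
             de_novo = "de_novo", recessive = "recessive")[df$heredity]
  model[model == "recessive"] <-
    ifelse(df$chrom[model == "recessive"] == "X" &
             df$zygosity[model == "recessive"] == "hom",
           "x_linked_recessive", "hom_recessive")
  carrier <- rep("unknown", nrow(df))
  carrier[grepl("Dad", df$carrier_label)] <- "father"
  carrier[grepl("Mom", df$carrier_label)] <- "mother"
  carrier[model %in% c("de_novo", "sporadic_only")] <- "none"

  out <- data.frame(
    proband = df$patient,
    family = df$family,
    carrier_label = df$carrier_label,
    model = model,
    carrier_parent = carrier,
    gene = df$gene,
    chrom = df$chrom,
    func_class = ifelse(df$func == "splicing", "splicing", "exonic"),
    exonic_func = ifelse(df$func == "splicing", "unknown", df$func),
    splice_distance = df$splice_distance,
    zygosity = df$zygosity,
    change = df$change,
    acmg_published = df$acmg_published,
    af_g1000_all = df$af_g1000_all,
    af_gnomad_all = df$af_gnomad_all,
    sift = df$sift,
    polyphen_hvar = df$polyphen_hvar,
    polyphen_hdiv = df$polyphen_hdiv,
    mutation_taster = df$mutation_taster,
    cadd = df$cadd,
    dbscsnv_ada = df$dbscsnv_ada,
    dbscsnv_rf = df$dbscsnv_rf,
    gerp = df$gerp,
    phenotype_match = FALSE,
    coseg_affected = 0L,
    stringsAsFactors = FALSE)
  votes <- predictor_votes(out)
  out$votes_of4 <- votes$votes_of4
  out$n_predictors_available <- votes$n_available
  out
}

#' Bundled candidate loci as a variant set
#'
#' Deduplicates the bundled candidate table to its 32 distinct loci and
#' rebuilds them as a [variant_set()] with a single pseudo-sample
#' (`PROBAND`) carrying each variant, so the filter cascade can be run
#' over the published loci. The published table reports no raw QC
#' fields or coordinates, so nominal within-bounds values are used
#' (depth 30, QUAL 60, MQ 60, synthetic positions and alleles; the
#' splice-region duplication is rebuilt as a 19 bp insertion). All
#' other columns carry the published annotations.
#'
#' @param thresholds Unused placeholder kept for signature stability.
#' @return A [variant_set()] with one variant per distinct locus, in
#'   table order; the `change` and `proband_zygosity` columns are kept
#'   in `$variants` for reference.
#' @export
cvid_candidate_variants <- function(thresholds = NULL) {
  cand <- cvid_candidates()
  loci <- cand[!duplicated(paste(cand$gene, cand$change)), , drop = FALSE]
  n <- nrow(loci)
  ref <- rep("C", n); alt <- rep("T", n)
  dup19 <- grepl("dup", loci$change)
  ref[dup19] <- "A"
  alt[dup19] <- paste0("A", strrep("T", 19))
  variants <- data.frame(
    chrom = loci$chrom,
    pos = seq_len(n) * 1000L,
    ref = ref, alt = alt,
    qual = 60, mq = 60,
    gene = loci$gene,
    func_class = loci$func_class,
    exonic_func = loci$exonic_func,
    splice_distance = loci$splice_distance,
    dbscsnv_ada = loci$dbscsnv_ada,
    dbscsnv_rf = loci$dbscsnv_rf,
    in_repeat = FALSE,
    sift = loci$sift,
    polyphen_hvar = loci$polyphen_hvar,
    polyphen_hdiv = loci$polyphen_hdiv,
    mutation_taster = loci$mutation_taster,
    cadd = loci$cadd,
    gerp = loci$gerp,
    af_g1000_all = loci$af_g1000_all,
    af_esp6500_all = NA_real_,
    af_gnomad_all = loci$af_gnomad_all,
    af_gnomad_eas = NA_real_,
    change = loci$change,
    proband_zygosity = loci$zygosity,
    stringsAsFactors = FALSE)
  hemi <- is_x_chrom(loci$chrom) & loci$zygosity == "hom"
  ac <- matrix(ifelse(loci$zygosity == "hom" & !hemi, 2L, 1L), n, 1,
               dimnames = list(NULL, "PROBAND"))
  ploidy <- matrix(ifelse(hemi, 1L, 2L), n, 1,
                   dimnames = list(NULL, "PROBAND"))
  dp <- matrix(30, n, 1, dimnames = list(NULL, "PROBAND"))
  variant_set(variants, ac, ploidy, dp)
}

#' Bundled CVID/PID gene panel
#'
#' 13 OMIM-curated CVID genes (tag `CVID_OMIM`) plus a compact
#' primary-immunodeficiency panel (tag `PID`).
#'
#' @return A [read_panel()] gene panel.
#' @export
cvid_panel <- function() read_panel(triovar_example("cvid_panel.tsv"))

#' Bundled per-patient autoimmune phenotype table
#'
#' One row per patient with sex and the leading autoimmune category.
#' The cohort-level category counts match the published aggregates
#' (6 SLE, 2 Sjogren's, 1 UCTD, 1 EGPA, 2 inflammatory arthritis,
#' 1 each psoriatic arthritis, ITP, necrotizing lymphadenitis,
#' pancytopenia); per-patient assignments beyond the individually
#' described cases are a plausible reconstruction, so only aggregate
#' statistics should be relied on.
#'
#' @return data.frame with `patient`, `sex`, `category`.
#' @export
cvid_phenotypes <- function() {
  utils::read.table(triovar_example("cvid_phenotypes.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
}

#' Bundled immune gene sets (GMT)
#'
#' Small KEGG-style pathway sets for over-representation examples.
#'
#' @return Named list of gene vectors (see [read_gmt()]).
#' @export
cvid_gene_sets <- function() read_gmt(triovar_example("immune_sets.gmt"))
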