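#' Default annotation dialect
#'
#' INFO key names used to pull ANNOVAR-style annotations out of a VCF.
#' Key spellings vary between annotation runs, so the mapping is
#' configuration rather than code; the defaults follow common ANNOVAR
#' column names. Override individual entries or load a YAML file with
#' [read_dialect()].
#'
#' @return A list with two components: `info`, a named list mapping
#'   internal annotation slots to INFO keys, and `af`, a named character
#'   vector mapping population-database labels to the INFO keys holding
#'   their allele frequencies. The names of `af` become the `af_<name>`
#'   columns of a variant set.
#' @export
default_dialect <- function() {
  list(
    info = list(
      gene            = "Gene.refGene",
      func            = "Func.refGene",
      exonic_func     = "ExonicFunc.refGene",
      splice_distance = "SpliceDist",
      mq              = "MQ",
      sift            = "SIFT_pred",
      polyphen_hvar   = "Polyphen2_HVAR_pred",
      polyphen_hdiv   = "Polyphen2_HDIV_pred",
      mutation_taster = "MutationTaster_pred",
      cadd            = "CADD_phred",
      gerp            = "GERP_RS",
      dbscsnv_ada     = "dbscSNV_ADA_SCORE",
      dbscsnv_rf      = "dbscSNV_RF_SCORE",
      in_repeat       = "RepeatMasker"
    ),
    af = c(
      g1000_all   = "1000g2015aug_all",
      esp6500_all = "esp6500siv2_all",
      gnomad_all  = "gnomAD_genome_ALL",
      gnomad_eas  = "gnomAD_genome_EAS"
    )
  )
}

#' Read an annotation dialect from a YAML file
#'
#' Entries present in the file override the defaults; everything else is
#' kept.
#'
#' @param path Path to a YAML file with optional `info` and `af` blocks.
#' @return A dialect list as returned by [default_dialect()].
#' @export
read_dialect <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading a dialect file requires the 'yaml' package")
  }
  user <- yaml::read_yaml(path)
  d <- default_dialect()
  if (!is.null(user$info)) d$info <- utils::modifyList(d$info, user$info)
  if (!is.null(user$af)) {
    af <- unlist(user$af)
    d$af[names(af)] <- af
  }
  d
}

#' Filtering thresholds
#'
#' Bundles every tunable of the site-QC and rare/deleterious filter
#' cascade. All comparisons against `min_*`/`max_*` bounds are strict
#' (`>` / `<`); the splice window is inclusive (`<=`).
#'
#' @param min_depth Per-sample read depth must exceed this (default 4).
#' @param min_mq Site root-mean-square mapping quality must exceed this
#'   (default 30).
#' @param min_qual Variant quality score must exceed this (default 20).
#' @param max_af Every configured population allele frequency must be
#'   below this, or absent (default 0.01).
#' @param splice_window_bp Splicing variants within this many bp of a
#'   junction are kept, inclusive (default 10).
#' @param indel_repeat_max_len Non-frameshift indels shorter than this
#'   (strict) inside repeat regions are discarded (default 10).
#' @param cadd_deleterious_cutoff CADD phred score at or above which the
#'   CADD voter supports deleteriousness (default 10).
#' @param dbscsnv_splice_cutoff A synonymous variant is rescued when
#'   either dbscSNV score reaches this value (default 0.6).
#' @param vote_rule `"half_available"` (default): the variant passes the
#'   deleteriousness stage when supporting voters are at least half of
#'   the voters with data. `"majority4"`: strict more-than-half of the
#'   four fixed voters (supporting >= 3), absent voters counting
#'   against.
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_depth = 4,
                              min_mq = 30,
                              min_qual = 20,
                              max_af = 0.01,
                              splice_window_bp = 10,
                              indel_repeat_max_len = 10,
                              cadd_deleterious_cutoff = 10,
                              dbscsnv_splice_cutoff = 0.6,
                              vote_rule = c("half_available", "majority4")) {
  vote_rule <- match.arg(vote_rule)
  stopifnot(
    min_depth > 0, min_mq > 0, min_qual > 0,
    max_af > 0, splice_window_bp > 0, indel_repeat_max_len > 0,
    cadd_deleterious_cutoff > 0,
    dbscsnv_splice_cutoff > 0, dbscsnv_splice_cutoff <= 1
  )
  structure(
    list(
      min_depth = min_depth, min_mq = min_mq, min_qual = min_qual,
      max_af = max_af, splice_window_bp = splice_window_bp,
      indel_repeat_max_len = indel_repeat_max_len,
      cadd_deleterious_cutoff = cadd_deleterious_cutoff,
      dbscsnv_splice_cutoff = dbscsnv_splice_cutoff,
      vote_rule = vote_rule
    ),
    class = "filter_thresholds"
  )
}

#' ACMG engine configuration
#'
#' @param pp2_genes Genes treated as missense-constrained for PP2
#'   (missense as established disease mechanism with little benign
#'   missense variation). Default `"CD40LG"`.
#' @param denovo_strength Weight of a confirmed de novo call:
#'   `"moderate"` (default; parentage assumed, not independently
#'   confirmed) or `"strong"`.
#' @param bs1_af Allele frequency at or above which BS1 fires
#'   (default 0.01).
#' @param ba1_af Allele frequency at or above which BA1 fires
#'   (default 0.05).
#' @return An object of class `acmg_config`.
#' @export
acmg_config <- function(pp2_genes = "CD40LG",
                        denovo_strength = c("moderate", "strong"),
                        bs1_af = 0.01,
                        ba1_af = 0.05) {
  denovo_strength <- match.arg(denovo_strength)
  stopifnot(bs1_af > 0, ba1_af >= bs1_af)
  structure(
    list(
      pp2_genes = toupper(pp2_genes),
      denovo_strength = denovo_strength,
      bs1_af = bs1_af, ba1_af = ba1_af
    ),
    class = "acmg_config"
  )
}

#' Default phenotype category grouping
#'
#' Maps clinical autoimmune categories onto reporting groups; the
#' shipped default groups systemic lupus erythematosus, Sjogren's
#' syndrome, undifferentiated connective tissue disease and eosinophilic
#' granulomatosis with polyangiitis as connective-tissue disease.
#'
#' @return Named list of character vectors (group -> categories).
#' @export
phenotype_groups <- function() {
  list(connective_tissue = c("SLE", "SJOGREN", "UCTD", "EGPA"))
}
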