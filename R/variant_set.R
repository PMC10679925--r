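.karyotype <- c(as.character(1:22), "X", "Y", "MT", "M")

#' Karyotype rank of chromosome labels
#'
#' 1-22, X, Y, MT order with or without a "chr" prefix; unknown labels
#' sort last, alphabetically.
#'
#' @param chrom Character vector of chromosome labels.
#' @return Numeric rank usable with [order()].
#' @keywords internal
chrom_rank <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  r <- match(x, .karyotype)
  r[is.na(r)] <- length(.karyotype) + 1
  r + match(x, sort(unique(x))) / (length(unique(x)) + 1)
}

is_x_chrom <- function(chrom) sub("^chr", "", as.character(chrom)) == "X"

#' Construct a variant set
#'
#' The central container for normalized variants: one row per
#' (chrom, pos, ref, alt) with exactly one alternate allele
#' (multi-allelic records are split on read), an annotation bundle, and
#' aligned per-sample genotype matrices.
#'
#' @param variants data.frame with at least `chrom`, `pos`, `ref`,
#'   `alt`, `qual`, `mq` plus annotation columns (`gene`, `func_class`,
#'   `exonic_func`, `splice_distance`, `dbscsnv_ada`, `dbscsnv_rf`,
#'   `in_repeat`, predictor columns, `cadd`, `gerp`, and one
#'   `af_<database>` column per configured population database, with
#'   `NA` meaning the site is absent from that database, which is
#'   distinct from frequency 0).
#' @param ac Integer matrix (variants x samples) of alternate-allele
#'   copies; `NA` = missing genotype.
#' @param ploidy Integer matrix of call ploidy (1 = hemizygous,
#'   2 = diploid).
#' @param dp Numeric matrix of per-sample read depth.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(variants, ac, ploidy, dp) {
  stopifnot(is.data.frame(variants))
  req <- c("chrom", "pos", "ref", "alt", "qual", "mq")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variants lacks columns: ", paste(miss, collapse = ", "))
  n <- nrow(variants)
  for (m in list(ac, ploidy, dp)) {
    stopifnot(is.matrix(m), nrow(m) == n)
  }
  stopifnot(identical(colnames(ac), colnames(ploidy)),
            identical(colnames(ac), colnames(dp)))
  if (any(variants$pos < 1)) stop("positions must be >= 1")
  if (any(!nzchar(variants$ref)) || any(!nzchar(variants$alt))) {
    stop("ref and alt must be non-empty")
  }
  if (any(variants$ref == variants$alt)) stop("ref and alt must differ")
  bad <- ac[!is.na(ac)]
  if (any(bad < 0 | bad > 2)) stop("allele counts must be in 0..2")
  variants$variant_id <- variant_key(variants)
  structure(
    list(variants = variants, ac = ac, ploidy = ploidy, dp = dp,
         samples = colnames(ac)),
    class = "variant_set"
  )
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$variants), "variants x",
      length(x$samples), "samples\n")
  invisible(x)
}

#' @export
dim.variant_set <- function(x) c(nrow(x$variants), length(x$samples))

#' Names of the allele-frequency columns of a variant set
#' @param vs A `variant_set`.
#' @return Character vector of `af_*` column names.
#' @export
af_columns <- function(vs) grep("^af_", names(vs$variants), value = TRUE)

#' Reorder a variant set into deterministic genomic order
#'
#' (chromosome in karyotype order, position, ref, alt).
#'
#' @param vs A `variant_set`.
#' @return The reordered `variant_set`.
#' @export
sort_variants <- function(vs) {
  o <- order(chrom_rank(vs$variants$chrom), vs$variants$pos,
             vs$variants$ref, vs$variants$alt)
  subset_variants(vs, o)
}

#' Subset a variant set by variant index
#' @param vs A `variant_set`.
#' @param i Row indices (integer or logical).
#' @return A `variant_set` with the selected variants.
#' @export
subset_variants <- function(vs, i) {
  variant_set(vs$variants[i, , drop = FALSE],
              vs$ac[i, , drop = FALSE],
              vs$ploidy[i, , drop = FALSE],
              vs$dp[i, , drop = FALSE])
}

#' Zygosity display labels
#'
#' Hemizygous alternate calls (single-copy, e.g. male X) are displayed
#' as `"hom"`, matching clinical reporting convention.
#'
#' @param ac Alternate allele counts (0/1/2, NA missing).
#' @param ploidy Call ploidy (1 or 2).
#' @return Character vector: `"ref"`, `"het"`, `"hom"` or `NA`.
#' @export
zygosity_display <- function(ac, ploidy) {
  out <- rep(NA_character_, length(ac))
  out[!is.na(ac) & ac == 0] <- "ref"
  out[!is.na(ac) & ac == 1 & ploidy == 2] <- "het"
  out[!is.na(ac) & (ac == 2 | (ac == 1 & ploidy == 1))] <- "hom"
  out
}
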