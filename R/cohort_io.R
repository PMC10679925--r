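#' Read a multi-sample VCF into a variant set
#'
#' Reads a VCF v4.2 file with GT/DP FORMAT fields and ANNOVAR-style
#' INFO annotations named by the dialect. Multi-allelic rows are split
#' into one record per alternate allele, with genotypes re-coded against
#' that allele (a `1/2` genotype contributes one copy to each of the two
#' alternate records). Unparseable allele-frequency values (e.g. `"."`)
#' become `NA`, meaning absent from the database -- never frequency 0.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param dialect Annotation dialect; see [default_dialect()].
#' @return A [variant_set()] in file order.
#' @export
read_vcf <- function(path, dialect = default_dialect()) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0) stop("VCF contains no variant rows: ", path)
  samples <- colnames(v@gt)[-1]
  if (length(samples) == 0) stop("VCF has no sample columns: ", path)

  alt_list <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",",
                       fixed = TRUE)
  n_alt <- lengths(alt_list)
  if (any(n_alt == 0)) {
    stop("malformed VCF row (no ALT allele) at data line ",
         which(n_alt == 0)[1])
  }
  ridx <- rep(seq_along(n_alt), n_alt)        # original row per output record
  aidx <- unlist(lapply(n_alt, seq_len))      # alt index within row

  info_kv <- parse_info(fix[, "INFO"])

  # genotype matrices on original rows
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  spl <- strsplit(as.vector(gt), "[/|]")
  a1 <- vapply(spl, function(x) if (length(x) >= 1) x[1] else NA_character_,
               character(1))
  a2 <- vapply(spl, function(x) if (length(x) >= 2) x[2] else NA_character_,
               character(1))
  dim(a1) <- dim(gt); dim(a2) <- dim(gt)
  missing1 <- is.na(a1) | a1 == "."
  ploidy0 <- ifelse(is.na(a2), 1L, 2L)

  n_out <- length(ridx)
  ac <- matrix(NA_integer_, n_out, length(samples),
               dimnames = list(NULL, samples))
  ploidy <- matrix(2L, n_out, length(samples),
                   dimnames = list(NULL, samples))
  dpo <- matrix(NA_real_, n_out, length(samples),
                dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    tgt <- as.character(aidx)
    c1 <- !missing1[ridx, j] & a1[ridx, j] == tgt
    c2 <- !is.na(a2[ridx, j]) & a2[ridx, j] == tgt
    counts <- as.integer(c1) + as.integer(c2)
    counts[missing1[ridx, j]] <- NA_integer_
    ac[, j] <- counts
    ploidy[, j] <- ploidy0[ridx, j]
    dpo[, j] <- dp[ridx, j]
  }

  ikey <- function(key) {
    vals <- vapply(info_kv, function(kv) {
      if (is.null(kv[[key]])) NA_character_ else kv[[key]]
    }, character(1))
    per_alt(vals[ridx], n_alt[ridx], aidx)
  }
  num <- function(x) suppressWarnings(as.numeric(x))

  di <- dialect$info
  variants <- data.frame(
    chrom = fix[ridx, "CHROM"],
    pos = as.integer(fix[ridx, "POS"]),
    ref = fix[ridx, "REF"],
    alt = unlist(alt_list),
    qual = num(fix[ridx, "QUAL"]),
    mq = num(ikey(di$mq)),
    gene = ikey(di$gene),
    func_class = normalize_func(ikey(di$func)),
    exonic_func = normalize_exonic_func(ikey(di$exonic_func)),
    splice_distance = num(ikey(di$splice_distance)),
    dbscsnv_ada = num(ikey(di$dbscsnv_ada)),
    dbscsnv_rf = num(ikey(di$dbscsnv_rf)),
    in_repeat = info_flag(fix[ridx, "INFO"], di$in_repeat),
    sift = pred_code(ikey(di$sift), c("D", "T")),
    polyphen_hvar = pred_code(ikey(di$polyphen_hvar), c("D", "P", "B")),
    polyphen_hdiv = pred_code(ikey(di$polyphen_hdiv), c("D", "P", "B")),
    mutation_taster = pred_code(ikey(di$mutation_taster), c("D", "A", "N", "P")),
    cadd = num(ikey(di$cadd)),
    gerp = num(ikey(di$gerp)),
    stringsAsFactors = FALSE
  )
  for (db in names(dialect$af)) {
    variants[[paste0("af_", db)]] <- num(ikey(dialect$af[[db]]))
  }
  bad_af <- unlist(variants[paste0("af_", names(dialect$af))])
  bad_af <- bad_af[!is.na(bad_af)]
  if (any(bad_af < 0 | bad_af > 1)) {
    stop("allele frequencies outside [0,1] in ", path)
  }
  variant_set(variants, ac, ploidy, dpo)
}

parse_info <- function(info) {
  lapply(strsplit(ifelse(is.na(info), "", info), ";", fixed = TRUE),
         function(fields) {
           fields <- fields[nzchar(fields)]
           eq <- regexpr("=", fields, fixed = TRUE)
           keys <- ifelse(eq > 0, substr(fields, 1, eq - 1), fields)
           vals <- ifelse(eq > 0, substring(fields, eq + 1), "")
           stats::setNames(as.list(vals), keys)
         })
}

info_flag <- function(info, key) {
  grepl(paste0("(^|;)", key, "(;|=|$)"), ifelse(is.na(info), "", info))
}

# pick the alt-specific element of a comma-separated per-allele value
per_alt <- function(vals, n_alt, aidx) {
  multi <- !is.na(vals) & n_alt > 1 & grepl(",", vals, fixed = TRUE)
  out <- vals
  if (any(multi)) {
    parts <- strsplit(vals[multi], ",", fixed = TRUE)
    out[multi] <- mapply(function(p, i) {
      if (length(p) >= i) p[i] else p[1]
    }, parts, aidx[multi])
  }
  out[!is.na(out) & out == "."] <- NA_character_
  out
}

normalize_func <- function(x) {
  x <- tolower(x)
  out <- rep("other", length(x))
  out[grepl("splicing", x)] <- "splicing"
  out[!grepl("splicing", x) & grepl("exonic", x)] <- "exonic"
  out[is.na(x)] <- NA_character_
  out
}

normalize_exonic_func <- function(x) {
  lx <- tolower(x)
  out <- rep("unknown", length(x))
  out[grepl("^nonsynonymous", lx) | lx == "missense"] <- "missense"
  out[grepl("^synonymous", lx)] <- "synonymous"
  out[grepl("stopgain", lx)] <- "stopgain"
  out[grepl("stoploss", lx)] <- "stoploss"
  out[grepl("^frameshift", lx)] <- "frameshift"
  out[grepl("^nonframeshift", lx)] <- "nonframeshift"
  out[is.na(x)] <- NA_character_
  out
}

pred_code <- function(x, vocab) {
  x <- toupper(x)
  x[!is.na(x) & !(x %in% vocab)] <- NA_character_
  x
}

#' Write a variant set to a VCF v4.2 file
#'
#' Emits one row per record (records are already single-alt) with GT/DP
#' FORMAT fields and the annotation bundle as INFO keys named by the
#' dialect. Hemizygous genotypes are written haploid (`0` / `1`).
#' Absent annotation values are omitted, so a re-read restores them as
#' `NA`.
#'
#' @param vs A [variant_set()].
#' @param path Output path.
#' @param dialect Annotation dialect; see [default_dialect()].
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path, dialect = default_dialect()) {
  di <- dialect$info
  num_fmt <- function(x) sprintf("%.17g", x)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=triovar",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"RMS mapping quality\">", di$mq),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Gene symbol\">", di$gene),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Functional class\">", di$func),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Exonic consequence\">", di$exonic_func),
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"Distance to splice junction (bp)\">", di$splice_distance),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"dbscSNV ADA score\">", di$dbscsnv_ada),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"dbscSNV RF score\">", di$dbscsnv_rf),
    sprintf("##INFO=<ID=%s,Number=0,Type=Flag,Description=\"Overlaps a repeat region\">", di$in_repeat),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"SIFT verdict\">", di$sift),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"PolyPhen2 HVAR verdict\">", di$polyphen_hvar),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"PolyPhen2 HDIV verdict\">", di$polyphen_hdiv),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"MutationTaster verdict\">", di$mutation_taster),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"CADD phred score\">", di$cadd),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"GERP++ conservation\">", di$gerp),
    vapply(names(dialect$af), function(db) {
      sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s allele frequency\">",
              dialect$af[[db]], db)
    }, character(1)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vs$samples), collapse = "\t")
  )

  v <- vs$variants
  kv <- function(key, vals, fmt = identity) {
    ifelse(is.na(vals), NA_character_, paste0(key, "=", fmt(vals)))
  }
  info_parts <- cbind(
    kv(di$mq, v$mq, num_fmt),
    kv(di$gene, v$gene),
    kv(di$func, v$func_class),
    kv(di$exonic_func, v$exonic_func),
    kv(di$splice_distance, v$splice_distance, function(x) sprintf("%d", as.integer(x))),
    kv(di$dbscsnv_ada, v$dbscsnv_ada, num_fmt),
    kv(di$dbscsnv_rf, v$dbscsnv_rf, num_fmt),
    ifelse(!is.na(v$in_repeat) & v$in_repeat, di$in_repeat, NA_character_),
    kv(di$sift, v$sift),
    kv(di$polyphen_hvar, v$polyphen_hvar),
    kv(di$polyphen_hdiv, v$polyphen_hdiv),
    kv(di$mutation_taster, v$mutation_taster),
    kv(di$cadd, v$cadd, num_fmt),
    kv(di$gerp, v$gerp, num_fmt)
  )
  for (db in names(dialect$af)) {
    info_parts <- cbind(info_parts,
                        kv(dialect$af[[db]], v[[paste0("af_", db)]], num_fmt))
  }
  info <- apply(info_parts, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r)) paste(r, collapse = ";") else "."
  })

  gt_str <- matrix("", nrow(v), length(vs$samples))
  for (j in seq_along(vs$samples)) {
    a <- vs$ac[, j]; p <- vs$ploidy[, j]; d <- vs$dp[, j]
    g <- ifelse(is.na(a), ifelse(p == 1, ".", "./."),
         ifelse(p == 1, as.character(a),
         ifelse(a == 0, "0/0", ifelse(a == 1, "0/1", "1/1"))))
    ds <- ifelse(is.na(d), ".", sprintf("%d", as.integer(d)))
    gt_str[, j] <- paste(g, ds, sep = ":")
  }

  rows <- paste(v$chrom, v$pos, ".", v$ref, v$alt,
                ifelse(is.na(v$qual), ".", num_fmt(v$qual)), "PASS", info,
                "GT:DP",
                apply(gt_str, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a 6-column PED pedigree file
#'
#' Columns: family, sample, father, mother, sex (1 = male, 2 = female),
#' phenotype (2 = affected). `0` denotes a missing parent. Parent ids
#' must refer to samples of the same family, parentage must be acyclic,
#' and every family must contain at least one affected member.
#'
#' @param path Path to a PED file (whitespace-separated, no header).
#' @return A data.frame of class `pedigree` with columns `family_id`,
#'   `sample_id`, `father_id`, `mother_id` (NA when missing), `sex`
#'   (`"male"`/`"female"`) and `affected` (logical).
#' @export
read_ped <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 6) stop("PED file must have 6 columns: ", path)
  df <- df[, 1:6]
  names(df) <- c("family_id", "sample_id", "father_id", "mother_id",
                 "sex", "phenotype")
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample id in PED: ",
         df$sample_id[duplicated(df$sample_id)][1])
  }
  df$father_id[df$father_id == "0"] <- NA_character_
  df$mother_id[df$mother_id == "0"] <- NA_character_
  if (!all(df$sex %in% c("1", "2"))) stop("PED sex codes must be 1 or 2")
  df$sex <- ifelse(df$sex == "1", "male", "female")
  df$affected <- df$phenotype == "2"
  df$phenotype <- NULL

  for (p in c("father_id", "mother_id")) {
    known <- is.na(df[[p]]) | df[[p]] %in% df$sample_id
    if (!all(known)) {
      stop("unknown parent id in PED: ", df[[p]][!known][1])
    }
    fam_of_parent <- df$family_id[match(df[[p]], df$sample_id)]
    same <- is.na(df[[p]]) | fam_of_parent == df$family_id
    if (!all(same)) stop("parent from a different family in PED")
  }
  # acyclic parentage
  parent_of <- function(s) {
    i <- match(s, df$sample_id)
    stats::na.omit(c(df$father_id[i], df$mother_id[i]))
  }
  for (s in df$sample_id) {
    seen <- character(0); frontier <- s
    while (length(frontier)) {
      frontier <- unique(unlist(lapply(frontier, parent_of)))
      if (s %in% frontier) stop("cyclic parentage in PED involving ", s)
      frontier <- setdiff(frontier, seen)
      seen <- c(seen, frontier)
    }
  }
  no_aff <- tapply(df$affected, df$family_id, sum) == 0
  if (any(no_aff)) {
    stop("family without an affected member in PED: ",
         names(no_aff)[no_aff][1])
  }
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Family structure around an affected sample
#'
#' @param ped A [read_ped()] pedigree.
#' @param sample_id Sample of interest.
#' @return List with `father`, `mother` (NA when unavailable), and
#'   `type`: `"trio"`, `"duo"` or `"singleton"`. De novo calling is only
#'   possible for trios.
#' @export
family_structure <- function(ped, sample_id) {
  i <- match(sample_id, ped$sample_id)
  if (is.na(i)) stop("unknown sample: ", sample_id)
  f <- ped$father_id[i]; m <- ped$mother_id[i]
  n_par <- sum(!is.na(c(f, m)))
  list(father = f, mother = m,
       type = c("singleton", "duo", "trio")[n_par + 1])
}

#' Is a sample a sporadic case?
#'
#' A sporadic case is an affected sample with no sequenced relatives:
#' it is the only member of its family.
#'
#' @param ped A pedigree.
#' @param sample_id Sample of interest.
#' @return Logical.
#' @export
is_sporadic <- function(ped, sample_id) {
  i <- match(sample_id, ped$sample_id)
  if (is.na(i)) stop("unknown sample: ", sample_id)
  ped$affected[i] && sum(ped$family_id == ped$family_id[i]) == 1
}

#' Affected / unaffected sample ids
#' @param ped A pedigree.
#' @return Character vector of sample ids.
#' @export
affected_ids <- function(ped) ped$sample_id[ped$affected]

#' @rdname affected_ids
#' @export
unaffected_ids <- function(ped) ped$sample_id[!ped$affected]

#' Read a CNV/SV event table
#'
#' Tab-separated with header `sample chrom start end type source`;
#' coordinates are 0-based half-open. Rows with `start >= end` are
#' rejected with a warning and returned in the `"rejected"` attribute.
#'
#' @param path Path to the event table.
#' @return data.frame of class `interval_events`, sorted by
#'   (chrom, start, end).
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  req <- c("sample", "chrom", "start", "end", "type", "source")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("event table lacks columns: ",
                         paste(miss, collapse = ", "))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  bad <- is.na(df$start) | is.na(df$end) | df$start >= df$end
  rejected <- df[bad, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- "start_not_before_end"
    warning(nrow(rejected), " event row(s) rejected (start >= end)")
  }
  df <- df[!bad, , drop = FALSE]
  df <- df[order(chrom_rank(df$chrom), df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, rejected = rejected,
            class = c("interval_events", "data.frame"))
}

#' Read a gene panel
#'
#' One gene symbol per line with an optional tab-separated sub-panel tag
#' (e.g. `CVID_OMIM`, `PID`); untagged genes get `default_tag`. Symbols
#' are uppercased and deduplicated (first occurrence wins).
#'
#' @param path Path to the panel file.
#' @param default_tag Tag for untagged lines.
#' @return data.frame of class `gene_panel` with columns `gene`, `tag`.
#' @export
read_panel <- function(path, default_tag = "PID") {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty gene panel: ", path)
  parts <- strsplit(lines, "[\t ]+")
  df <- data.frame(
    gene = toupper(vapply(parts, `[`, character(1), 1)),
    tag = vapply(parts, function(p) {
      if (length(p) >= 2) toupper(p[2]) else default_tag
    }, character(1)),
    stringsAsFactors = FALSE
  )
  df <- df[!duplicated(df$gene), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_panel", "data.frame")
  df
}

#' Read a GMT gene-set file
#'
#' Standard 3+ column format: set name, description, member genes.
#' Symbols are uppercased and deduplicated per set.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors; set descriptions in the
#'   `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3
  if (any(short)) stop("GMT line with fewer than 3 fields: line ",
                       which(short)[1])
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' Read a BED file of intervals (e.g. repeat regions or exons)
#'
#' Only the first three columns are used; coordinates stay 0-based
#' half-open.
#'
#' @param path Path to the BED file.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3) stop("BED file must have at least 3 columns: ", path)
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("BED interval with start >= end")
  out
}
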