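#' Configuration of the synthetic cohort generator
#'
#' The defaults emulate the study conditions the pipeline targets: 12
#' core trio families plus 4 sporadic cases (16 affected, 26 healthy
#' first-degree relatives once trios are expanded), mean sequencing
#' depth 34x, rare-variant background with a log-uniform allele
#' frequency spectrum and four population databases that independently
#' drop to "absent" for very rare sites.
#'
#' @param n_trio_families Number of father-mother-child trios.
#' @param n_sporadic_cases Number of affected singletons.
#' @param n_sites Number of background variant sites.
#' @param n_genes Number of synthetic genes (`GENE0001`...), assigned
#'   to consecutive coordinate windows.
#' @param af_range True allele-frequency range; sites draw log-uniform
#'   within it.
#' @param p_absent_af Probability that a database reports no entry for
#'   a site (independently per database).
#' @param p_deleterious Probability of the latent deleterious state.
#' @param p_support_given_del,p_support_given_neut Probability that a
#'   predictor supports deleteriousness given the latent state.
#' @param p_predictor_absent Probability a predictor has no score.
#' @param genotyping_error_rate Per-genotype probability of replacing
#'   the true call with a random Hardy-Weinberg draw.
#' @param mean_depth Mean of the Poisson per-sample read depth.
#' @param spikes Named integer vector: number of causal variants to
#'   plant per inheritance model (`de_novo`, `hom_recessive`,
#'   `compound_het` (pairs), `x_linked_recessive`, `sporadic_only`).
#' @param seed Integer RNG seed; a fixed seed gives byte-identical
#'   output.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_trio_families = 12,
                          n_sporadic_cases = 4,
                          n_sites = 5000,
                          n_genes = 400,
                          af_range = c(1e-6, 0.5),
                          p_absent_af = 0.3,
                          p_deleterious = 0.1,
                          p_support_given_del = 0.9,
                          p_support_given_neut = 0.05,
                          p_predictor_absent = 0.1,
                          genotyping_error_rate = 0,
                          mean_depth = 34,
                          spikes = c(de_novo = 5, hom_recessive = 4,
                                     compound_het = 3,
                                     x_linked_recessive = 2,
                                     sporadic_only = 3),
                          seed = 1) {
  stopifnot(n_trio_families >= 0, n_sporadic_cases >= 0, n_sites > 0,
            n_genes > 0, all(af_range > 0), af_range[1] < af_range[2],
            p_absent_af >= 0, p_absent_af <= 1,
            genotyping_error_rate >= 0, genotyping_error_rate <= 1,
            all(spikes >= 0))
  structure(as.list(environment()), class = "cohort_config")
}

.sim_pedigree <- function(cfg) {
  rows <- list()
  n_x <- if ("x_linked_recessive" %in% names(cfg$spikes)) {
    cfg$spikes[["x_linked_recessive"]]
  } else 0
  for (k in seq_len(cfg$n_trio_families)) {
    fam <- sprintf("F%02d", k)
    fa <- paste0(fam, "_FA"); mo <- paste0(fam, "_MO")
    pb <- paste0(fam, "_PB")
    child_sex <- if (k <= n_x) "male" else {
      if (stats::runif(1) < 0.5) "male" else "female"
    }
    rows[[length(rows) + 1]] <- data.frame(
      family_id = fam,
      sample_id = c(fa, mo, pb),
      father_id = c(NA, NA, fa),
      mother_id = c(NA, NA, mo),
      sex = c("male", "female", child_sex),
      affected = c(FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE)
  }
  for (j in seq_len(cfg$n_sporadic_cases)) {
    rows[[length(rows) + 1]] <- data.frame(
      family_id = sprintf("S%02d", j),
      sample_id = sprintf("S%02d", j),
      father_id = NA_character_, mother_id = NA_character_,
      sex = if (stats::runif(1) < 0.5) "male" else "female",
      affected = TRUE, stringsAsFactors = FALSE)
  }
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Simulate the background cohort
#'
#' Draws site positions, annotations and trio genotypes: founder
#' genotypes at Hardy-Weinberg proportions from each site's true allele
#' frequency, offspring genotypes by Mendelian transmission (one allele
#' per parent; male X is hemizygous and maternally derived), optional
#' genotyping error, and database frequencies as noisy copies of the
#' true frequency that are independently absent with `p_absent_af`.
#'
#' @param cfg A [cohort_config()]. The caller is responsible for
#'   seeding ([simulate_cohort()] seeds from `cfg$seed`).
#' @return List with `vs` (a [variant_set()]) and `ped`.
#' @export
simulate_background <- function(cfg) {
  ped <- .sim_pedigree(cfg)
  n <- cfg$n_sites
  m <- nrow(ped)

  # sites in genomic order; ~1/23 of sites on X
  chroms <- c(as.character(1:22), "X")
  chrom <- sample(chroms, n, replace = TRUE)
  chrom <- chrom[order(chrom_rank(chrom))]
  pos <- unlist(lapply(split(seq_len(n), factor(chrom, levels = unique(chrom))),
                       function(ix) cumsum(sample(100:5000, length(ix),
                                                  replace = TRUE))),
                use.names = FALSE)
  sites_per_gene <- max(1L, ceiling(n / cfg$n_genes))
  gene <- sprintf("GENE%04d", (seq_len(n) - 1L) %/% sites_per_gene + 1L)

  base <- c("A", "C", "G", "T")
  ref <- sample(base, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(base, r), 1), character(1))

  func_class <- sample(c("exonic", "splicing", "other"), n, replace = TRUE,
                       prob = c(0.90, 0.05, 0.05))
  exonic_func <- rep("unknown", n)
  ex <- func_class == "exonic"
  exonic_func[ex] <- sample(c("missense", "synonymous", "stopgain",
                              "frameshift", "nonframeshift"),
                            sum(ex), replace = TRUE,
                            prob = c(0.60, 0.25, 0.05, 0.05, 0.05))
  # indel alleles for indel consequences
  fs <- which(exonic_func == "frameshift")
  alt[fs] <- paste0(ref[fs], "A")
  nf <- which(exonic_func == "nonframeshift")
  alt[nf] <- paste0(ref[nf], "AGT")
  splice_distance <- ifelse(func_class == "splicing",
                            sample(1:30, n, replace = TRUE), NA_integer_)

  af_true <- 10^stats::runif(n, log10(cfg$af_range[1]),
                             log10(cfg$af_range[2]))

  # latent deleterious state and predictor verdicts
  z <- stats::rbinom(n, 1, cfg$p_deleterious) == 1
  p_sup <- ifelse(z, cfg$p_support_given_del, cfg$p_support_given_neut)
  draw_pred <- function(sup_codes, ben_codes) {
    absent <- stats::runif(n) < cfg$p_predictor_absent
    sup <- stats::runif(n) < p_sup
    out <- ifelse(sup, sample(sup_codes, n, replace = TRUE),
                  sample(ben_codes, n, replace = TRUE))
    out[absent] <- NA_character_
    out
  }
  sift <- draw_pred("D", "T")
  pph_hvar <- draw_pred(c("D", "P"), "B")
  pph_hdiv <- draw_pred(c("D", "P"), "B")
  mt <- draw_pred(c("D", "A"), c("N", "P"))
  cadd <- ifelse(z, stats::runif(n, 15, 40), stats::runif(n, 0, 12))
  cadd[stats::runif(n) < cfg$p_predictor_absent] <- NA_real_
  gerp <- round(stats::runif(n, -5, 6), 2)
  dbscsnv_ada <- rep(NA_real_, n)
  dbscsnv_rf <- rep(NA_real_, n)
  syn <- which(exonic_func == "synonymous")
  rescue <- syn[stats::runif(length(syn)) < 0.05]
  dbscsnv_ada[rescue] <- round(stats::runif(length(rescue), 0.6, 1), 3)
  dbscsnv_rf[rescue] <- round(stats::runif(length(rescue), 0.6, 1), 3)
  in_repeat <- stats::runif(n) < 0.1

  variants <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    qual = round(stats::runif(n, 30, 100), 1),
    mq = round(stats::runif(n, 40, 60), 1),
    gene = gene, func_class = func_class, exonic_func = exonic_func,
    splice_distance = splice_distance,
    dbscsnv_ada = dbscsnv_ada, dbscsnv_rf = dbscsnv_rf,
    in_repeat = in_repeat,
    sift = sift, polyphen_hvar = pph_hvar, polyphen_hdiv = pph_hdiv,
    mutation_taster = mt, cadd = round(cadd, 2), gerp = gerp,
    stringsAsFactors = FALSE)
  for (db in c("g1000_all", "esp6500_all", "gnomad_all", "gnomad_eas")) {
    v <- signif(pmin(af_true * exp(stats::rnorm(n, 0, 0.2)), 1), 6)
    v[stats::runif(n) < cfg$p_absent_af] <- NA_real_
    variants[[paste0("af_", db)]] <- v
  }

  # genotypes
  is_x <- is_x_chrom(chrom)
  male <- ped$sex == "male"
  founder <- is.na(ped$father_id)
  ac <- matrix(0L, n, m, dimnames = list(NULL, ped$sample_id))
  ploidy <- matrix(2L, n, m, dimnames = list(NULL, ped$sample_id))
  ploidy[is_x, male] <- 1L
  for (j in which(founder)) {
    ac[, j] <- stats::rbinom(n, ifelse(is_x & male[j], 1L, 2L), af_true)
  }
  transmit <- function(parent_ac, parent_ploidy) {
    # one allele drawn from the parent's genotype
    stats::rbinom(length(parent_ac), 1, parent_ac / parent_ploidy)
  }
  for (j in which(!founder)) {
    fa <- match(ped$father_id[j], ped$sample_id)
    mo <- match(ped$mother_id[j], ped$sample_id)
    from_mo <- transmit(ac[, mo], ploidy[, mo])
    from_fa <- transmit(ac[, fa], ploidy[, fa])
    g <- from_mo + from_fa
    if (male[j]) {
      g[is_x] <- from_mo[is_x]        # male X: maternal allele only
    } else {
      g[is_x] <- from_mo[is_x] + ac[is_x, fa]  # father transmits his X
    }
    ac[, j] <- g
  }
  if (cfg$genotyping_error_rate > 0) {
    err <- matrix(stats::runif(n * m) < cfg$genotyping_error_rate, n, m)
    if (any(err)) {
      redraw <- matrix(stats::rbinom(n * m, as.vector(ploidy),
                                     rep(af_true, m)), n, m)
      ac[err] <- redraw[err]
    }
  }
  dp <- matrix(stats::rpois(n * m, cfg$mean_depth), n, m,
               dimnames = list(NULL, ped$sample_id))

  list(vs = variant_set(variants, ac, ploidy, dp), ped = ped,
       af_true = af_true)
}

#' Plant causal variants into a simulated cohort
#'
#' Overwrites selected background sites with causal genotype
#' configurations: de novo (parents homozygous reference, child
#' heterozygous), homozygous recessive (both parents carriers, child
#' homozygous), compound heterozygous (two heterozygous sites in one
#' gene, one transmitted by each parent), X-linked recessive
#' (hemizygous male child, carrier mother) and sporadic-only (present
#' in a single unrelated case). Spiked sites get annotations that pass
#' the filter cascade (all databases absent, unanimous deleteriousness
#' vote) and all other samples are set to homozygous reference.
#'
#' @param cfg A [cohort_config()].
#' @param sim Output of [simulate_background()].
#' @return `sim` with genotypes/annotations modified and a `truth`
#'   data.frame appended (`variant_id`, `model`, `family`, `proband`,
#'   `carrier_parent`, `partner_variant`).
#' @export
spike_causal <- function(cfg, sim) {
  vs <- sim$vs; ped <- sim$ped
  v <- vs$variants
  n <- nrow(v)
  trio_fams <- unique(ped$family_id[!is.na(ped$father_id)])
  sporadics <- ped$sample_id[ped$affected &
                               !(ped$family_id %in% trio_fams)]
  male_child_fams <- trio_fams[vapply(trio_fams, function(f) {
    i <- which(ped$family_id == f & !is.na(ped$father_id))
    ped$sex[i] == "male"
  }, logical(1))]

  used <- logical(n)
  autosomal_pool <- which(!is_x_chrom(v$chrom))
  x_pool <- which(is_x_chrom(v$chrom))

  force_annotation <- function(i) {
    vs$variants$func_class[i] <<- "exonic"
    vs$variants$exonic_func[i] <<- "missense"
    vs$variants$splice_distance[i] <<- NA_integer_
    vs$variants$in_repeat[i] <<- FALSE
    vs$variants$sift[i] <<- "D"
    vs$variants$polyphen_hvar[i] <<- "D"
    vs$variants$polyphen_hdiv[i] <<- "D"
    vs$variants$mutation_taster[i] <<- "D"
    vs$variants$cadd[i] <<- 35
    vs$variants$qual[i] <<- 60
    vs$variants$mq[i] <<- 55
    for (col in af_columns(vs)) vs$variants[[col]][i] <<- NA_real_
    # alleles back to a SNV so no indel stage interferes
    vs$variants$ref[i] <<- "C"; vs$variants$alt[i] <<- "T"
    vs$variants$variant_id[i] <<- paste(vs$variants$chrom[i],
                                        vs$variants$pos[i], "C", "T",
                                        sep = ":")
    vs$ac[i, ] <<- 0L
    vs$dp[i, ] <<- pmax(vs$dp[i, ], 20)
  }
  take_site <- function(pool, k = 1) {
    avail <- pool[!used[pool]]
    if (length(avail) < k) stop("not enough free sites to host spikes")
    s <- avail[seq_len(k)]
    used[s] <<- TRUE
    s
  }
  fam_members <- function(f) {
    i <- which(ped$family_id == f)
    founders <- i[is.na(ped$father_id[i])]
    list(fa = ped$sample_id[founders[ped$sex[founders] == "male"][1]],
         mo = ped$sample_id[founders[ped$sex[founders] == "female"][1]],
         pb = ped$sample_id[i[!is.na(ped$father_id[i])][1]])
  }

  truth <- list()
  push <- function(i, model, fam, pb, carrier, partner = NA_character_) {
    truth[[length(truth) + 1]] <<- data.frame(
      variant_id = vs$variants$variant_id[i], model = model,
      family = fam, proband = pb, carrier_parent = carrier,
      partner_variant = partner, stringsAsFactors = FALSE)
  }
  cyc <- function(pool, k) pool[((seq_len(k) - 1L) %% length(pool)) + 1L]

  sp <- cfg$spikes
  get_n <- function(nm) if (nm %in% names(sp)) sp[[nm]] else 0L

  k <- get_n("de_novo")
  if (k > 0) {
    if (length(trio_fams) == 0) stop("de novo spikes need trio families")
    fams <- cyc(trio_fams, k)
    for (s in seq_len(k)) {
      i <- take_site(autosomal_pool); force_annotation(i)
      fm <- fam_members(fams[s])
      vs$ac[i, fm$pb] <- 1L
      push(i, "de_novo", fams[s], fm$pb, "none")
    }
  }
  k <- get_n("hom_recessive")
  if (k > 0) {
    if (length(trio_fams) == 0) stop("recessive spikes need trio families")
    fams <- cyc(trio_fams, k)
    for (s in seq_len(k)) {
      i <- take_site(autosomal_pool); force_annotation(i)
      fm <- fam_members(fams[s])
      vs$ac[i, fm$fa] <- 1L; vs$ac[i, fm$mo] <- 1L; vs$ac[i, fm$pb] <- 2L
      push(i, "hom_recessive", fams[s], fm$pb, "both")
    }
  }
  k <- get_n("compound_het")
  if (k > 0) {
    if (length(trio_fams) == 0) stop("compound-het spikes need trio families")
    fams <- cyc(trio_fams, k)
    for (s in seq_len(k)) {
      # two free sites inside one gene
      gene_sites <- split(autosomal_pool[!used[autosomal_pool]],
                          v$gene[autosomal_pool[!used[autosomal_pool]]])
      gene_sites <- Filter(function(x) length(x) >= 2, gene_sites)
      if (length(gene_sites) == 0) stop("no gene with 2 free sites for compound-het spike")
      pair <- gene_sites[[1]][1:2]
      used[pair] <- TRUE
      fm <- fam_members(fams[s])
      force_annotation(pair[1]); force_annotation(pair[2])
      vs$ac[pair[1], fm$fa] <- 1L; vs$ac[pair[1], fm$pb] <- 1L
      vs$ac[pair[2], fm$mo] <- 1L; vs$ac[pair[2], fm$pb] <- 1L
      push(pair[1], "compound_het", fams[s], fm$pb, "father",
           vs$variants$variant_id[pair[2]])
      push(pair[2], "compound_het", fams[s], fm$pb, "mother",
           vs$variants$variant_id[pair[1]])
    }
  }
  k <- get_n("x_linked_recessive")
  if (k > 0) {
    if (length(male_child_fams) == 0) {
      stop("X-linked spikes need trio families with a male child")
    }
    fams <- cyc(male_child_fams, k)
    for (s in seq_len(k)) {
      i <- take_site(x_pool); force_annotation(i)
      fm <- fam_members(fams[s])
      vs$ac[i, fm$mo] <- 1L
      vs$ac[i, fm$pb] <- 1L   # hemizygous (ploidy 1 on male X)
      push(i, "x_linked_recessive", fams[s], fm$pb, "mother")
    }
  }
  k <- get_n("sporadic_only")
  if (k > 0) {
    if (length(sporadics) == 0) stop("sporadic spikes need singleton cases")
    cases <- cyc(sporadics, k)
    for (s in seq_len(k)) {
      i <- take_site(autosomal_pool); force_annotation(i)
      vs$ac[i, cases[s]] <- 1L
      push(i, "sporadic_only",
           ped$family_id[match(cases[s], ped$sample_id)],
           cases[s], "none")
    }
  }

  sim$vs <- vs
  sim$truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(variant_id = character(0), model = character(0),
               family = character(0), proband = character(0),
               carrier_parent = character(0),
               partner_variant = character(0), stringsAsFactors = FALSE)
  sim
}

#' Simulate a complete spiked cohort
#'
#' Seeds the RNG from `cfg$seed`, simulates the background
#' ([simulate_background()]) and plants the configured causal variants
#' ([spike_causal()]).
#'
#' @param cfg A [cohort_config()].
#' @return List with `vs`, `ped`, `truth`.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  set.seed(cfg$seed)
  spike_causal(cfg, simulate_background(cfg))
}

#' Simulate CNV/SV event tables with planted recurrent clusters
#'
#' Plants `n_recurrent` clusters shared by two or more patients with no
#' control carrier (members jittered by less than 20% of their length,
#' keeping reciprocal overlap above 0.5), `n_control_hit` clusters that
#' additionally appear in a control, and `n_single` single-patient
#' decoy events. Cluster seeds are spaced far apart so planted groups
#' never overlap each other.
#'
#' @param ped A pedigree (affected members are patients).
#' @param n_recurrent,n_control_hit,n_single Planted cluster counts.
#' @param seed Integer RNG seed.
#' @return List with `events` (an `interval_events` data.frame) and
#'   `truth` (planted group, kind, expected screen verdict).
#' @export
simulate_events <- function(ped, n_recurrent = 5, n_control_hit = 3,
                            n_single = 10, seed = 1) {
  set.seed(seed)
  patients <- affected_ids(ped)
  controls <- unaffected_ids(ped)
  stopifnot(length(patients) >= 2)
  rows <- list(); truth <- list()
  types <- c("DEL", "DUP", "INV")
  gi <- 0
  place <- function(kind, members, verdict) {
    gi <<- gi + 1
    chrom <- as.character(((gi - 1) %% 22) + 1)
    base <- 1e6 * gi
    len <- sample(5000:50000, 1)
    type <- sample(types, 1)
    src <- if (type == "INV") "SV" else sample(c("CNV", "SV"), 1)
    for (s in members) {
      shift <- sample(seq(-0.2 * len, 0.2 * len), 1)
      rows[[length(rows) + 1]] <<- data.frame(
        sample = s, chrom = chrom,
        start = as.integer(base + shift),
        end = as.integer(base + shift + len),
        type = type, source = src, stringsAsFactors = FALSE)
    }
    truth[[length(truth) + 1]] <<- data.frame(
      group = gi, kind = kind, chrom = chrom, start = base,
      end = base + len, n_members = length(members),
      expected_kept = verdict, stringsAsFactors = FALSE)
  }
  for (r in seq_len(n_recurrent)) {
    k <- sample(2:min(4, length(patients)), 1)
    place("recurrent", sample(patients, k), TRUE)
  }
  for (r in seq_len(n_control_hit)) {
    k <- sample(2:min(4, length(patients)), 1)
    place("control_hit", c(sample(patients, k), sample(controls, 1)), FALSE)
  }
  for (r in seq_len(n_single)) {
    place("single", sample(patients, 1), FALSE)
  }
  events <- do.call(rbind, rows)
  events <- events[order(chrom_rank(events$chrom), events$start,
                         events$end), ]
  rownames(events) <- NULL
  class(events) <- c("interval_events", "data.frame")
  list(events = events, truth = do.call(rbind, truth))
}

#' Write a simulated cohort to disk
#'
#' Emits `cohort.vcf` (VCF v4.2), `cohort.ped`, and `truth.tsv` under
#' `dir`.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param dialect Annotation dialect for the VCF INFO keys.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir, dialect = default_dialect()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(sim$vs, file.path(dir, "cohort.vcf"), dialect)
  write_ped(sim$ped, file.path(dir, "cohort.ped"))
  if (!is.null(sim$truth)) {
    utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Write a pedigree as a 6-column PED file
#' @param ped A pedigree data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  out <- data.frame(
    ped$family_id, ped$sample_id,
    ifelse(is.na(ped$father_id), "0", ped$father_id),
    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    ifelse(ped$sex == "male", "1", "2"),
    ifelse(ped$affected, "2", "1"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
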