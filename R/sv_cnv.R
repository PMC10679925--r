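#' Reciprocal overlap of two intervals
#'
#' Intervals are 0-based half-open. Returns the overlap as a fraction
#' of each interval's length; two events are "the same" when the
#' smaller fraction strictly exceeds 0.5 and they share chromosome,
#' event type and source.
#'
#' @param a,b Lists or one-row data.frames with `start` and `end` (and,
#'   for [same_event()], `chrom`, `type`, `source`).
#' @return Named numeric vector `c(frac_a, frac_b)`.
#' @export
reciprocal_overlap <- function(a, b) {
  ov <- max(0, min(a$end, b$end) - max(a$start, b$start))
  c(frac_a = ov / (a$end - a$start), frac_b = ov / (b$end - b$start))
}

#' @rdname reciprocal_overlap
#' @param min_fraction Strict lower bound on the reciprocal overlap.
#' @return `same_event()`: logical.
#' @export
same_event <- function(a, b, min_fraction = 0.5) {
  if (a$chrom != b$chrom || a$type != b$type || a$source != b$source) {
    return(FALSE)
  }
  min(reciprocal_overlap(a, b)) > min_fraction
}

# pairwise same-event adjacency within one (chrom, type, source) group
.adjacency <- function(start, end, min_fraction) {
  lo <- outer(start, start, pmax)
  hi <- outer(end, end, pmin)
  ov <- pmax(hi - lo, 0)
  len <- end - start
  fa <- sweep(ov, 1, len, "/")
  fb <- sweep(ov, 2, len, "/")
  adj <- pmin(fa, fb) > min_fraction
  diag(adj) <- FALSE
  adj
}

#' Cluster CNV/SV events by reciprocal overlap
#'
#' Events sharing chromosome, type and source whose reciprocal overlap
#' strictly exceeds `min_fraction` are considered the same event.
#' `"single_linkage"` (default) clusters are the connected components
#' of that pairwise relation, so a cluster may chain together pairs
#' that individually fall below the bound; `"clique"` mode instead
#' grows clusters greedily in sorted order, admitting an event only
#' when it matches every current member.
#'
#' @param events An `interval_events` data.frame (see [read_events()]).
#' @param min_fraction Strict reciprocal-overlap bound (default 0.5).
#' @param mode `"single_linkage"` or `"clique"`.
#' @return List of class `event_clusters`: `clusters` (one row per
#'   cluster: union-bound coordinates, member and sample counts) and
#'   `members` (events annotated with `cluster_id`). Ordering is
#'   deterministic regardless of input order.
#' @export
cluster_events <- function(events, min_fraction = 0.5,
                           mode = c("single_linkage", "clique")) {
  mode <- match.arg(mode)
  ev <- as.data.frame(events)
  ev <- ev[order(chrom_rank(ev$chrom), ev$type, ev$source,
                 ev$start, ev$end, ev$sample), , drop = FALSE]
  rownames(ev) <- NULL
  if (nrow(ev) == 0) {
    return(structure(list(
      clusters = data.frame(cluster_id = integer(0), chrom = character(0),
                            type = character(0), source = character(0),
                            start = integer(0), end = integer(0),
                            n_events = integer(0), samples = character(0)),
      members = cbind(ev, cluster_id = integer(0))),
      class = "event_clusters"))
  }
  grp <- paste(ev$chrom, ev$type, ev$source, sep = "\r")
  comp <- integer(nrow(ev))
  offset <- 0L
  for (g in unique(grp)) {
    sel <- which(grp == g)
    adj <- .adjacency(ev$start[sel], ev$end[sel], min_fraction)
    if (mode == "single_linkage") {
      gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      mem <- igraph::components(gr)$membership
    } else {
      mem <- integer(length(sel)); nxt <- 0L
      for (k in seq_along(sel)) {
        if (mem[k] != 0L) next
        nxt <- nxt + 1L
        mem[k] <- nxt
        for (l in seq_along(sel)) {
          if (mem[l] != 0L || l == k) next
          if (all(adj[l, mem == nxt])) mem[l] <- nxt
        }
      }
    }
    comp[sel] <- mem + offset
    offset <- offset + max(mem)
  }
  ev$cluster_id <- comp
  agg_start <- tapply(ev$start, comp, min)
  agg <- data.frame(
    cluster_id = as.integer(names(agg_start)),
    chrom = tapply(ev$chrom, comp, `[`, 1),
    type = tapply(ev$type, comp, `[`, 1),
    source = tapply(ev$source, comp, `[`, 1),
    start = as.integer(agg_start),
    end = as.integer(tapply(ev$end, comp, max)),
    n_events = as.integer(tapply(ev$sample, comp, length)),
    samples = tapply(ev$sample, comp,
                     function(s) paste(sort(unique(s)), collapse = ";")),
    stringsAsFactors = FALSE
  )
  agg <- agg[order(chrom_rank(agg$chrom), agg$start, agg$end,
                   agg$type, agg$source), , drop = FALSE]
  # renumber clusters in genomic order
  new_id <- stats::setNames(seq_len(nrow(agg)), agg$cluster_id)
  agg$cluster_id <- as.integer(new_id[as.character(agg$cluster_id)])
  ev$cluster_id <- as.integer(new_id[as.character(ev$cluster_id)])
  rownames(agg) <- NULL
  structure(list(clusters = agg, members = ev), class = "event_clusters")
}

#' @export
print.event_clusters <- function(x, ...) {
  cat("event_clusters:", nrow(x$clusters), "clusters from",
      nrow(x$members), "events\n")
  invisible(x)
}

#' Recurrence screen on event clusters
#'
#' Keeps clusters carried by at least two distinct affected samples
#' (patients) and by no unaffected sample (control). Counts are of
#' distinct samples, not events.
#'
#' @param clusters An `event_clusters` object.
#' @param ped A [read_ped()] pedigree; every member sample must appear
#'   in it.
#' @return The `clusters` data.frame with `patient_count`,
#'   `control_count` and `kept` columns appended.
#' @export
recurrence_screen <- function(clusters, ped) {
  mem <- clusters$members
  unknown <- setdiff(unique(mem$sample), ped$sample_id)
  if (length(unknown)) {
    stop("event sample(s) missing from pedigree: ",
         paste(unknown, collapse = ", "))
  }
  aff <- stats::setNames(ped$affected, ped$sample_id)
  cl <- clusters$clusters
  counts <- lapply(split(mem$sample, mem$cluster_id), unique)
  cl$patient_count <- vapply(as.character(cl$cluster_id), function(id) {
    sum(aff[counts[[id]]])
  }, numeric(1))
  cl$control_count <- vapply(as.character(cl$cluster_id), function(id) {
    sum(!aff[counts[[id]]])
  }, numeric(1))
  cl$kept <- cl$patient_count >= 2 & cl$control_count == 0
  cl
}

#' Label clusters by exon overlap
#'
#' A cluster is `"exonic"` when its representative (union-bound)
#' interval intersects any exon interval by at least 1 bp, otherwise
#' `"intronic_intergenic"`; with no exon table every cluster is
#' `"unknown"`.
#'
#' @param clusters An `event_clusters` object or its `clusters`
#'   data.frame.
#' @param exons data.frame with `chrom`, `start`, `end` (0-based
#'   half-open; see [read_bed()]), or `NULL`.
#' @return The clusters data.frame with a `region` column appended.
#' @export
annotate_exon_overlap <- function(clusters, exons = NULL) {
  cl <- if (inherits(clusters, "event_clusters")) clusters$clusters
        else clusters
  if (is.null(exons)) {
    cl$region <- rep("unknown", nrow(cl))
    return(cl)
  }
  cl$region <- vapply(seq_len(nrow(cl)), function(i) {
    sel <- exons$chrom == cl$chrom[i] &
      exons$start < cl$end[i] & exons$end > cl$start[i]
    if (any(sel)) "exonic" else "intronic_intergenic"
  }, character(1))
  cl
}
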