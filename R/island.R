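## Plasmid-mode screening and GC-deviation genomic-island detection.

#' Screen plasmids for NAT genes at a relaxed identity threshold
#'
#' Runs [translated_genome_search()] over each plasmid with the identity
#' threshold relaxed to 40\% -- the setting that retrieves the maximum
#' number of non-redundant translated-search hits in plasmid databases --
#' and reports per-plasmid hit counts, since plasmids frequently carry more
#' than one NAT gene.
#'
#' @param query protein residue string.
#' @param plasmids list of `genome_record`s, all with
#'   `replicon_class == "plasmid"`.
#' @param min_identity minimum percent identity (default 40).
#' @param max_evalue maximum E-value (default 1e-6).
#' @param ... passed to [translated_genome_search()].
#' @return `list(hits = data.frame with a `replicon` column, counts =
#'   data.frame of per-plasmid hit counts)`.
#' @export
plasmid_screen <- function(query, plasmids, min_identity = 40,
                           max_evalue = 1e-6, ...) {
  if (inherits(plasmids, "genome_record")) plasmids <- list(plasmids)
  for (p in plasmids)
    if (!identical(p$replicon_class, "plasmid"))
      stop("replicon '", p$replicon_id, "' is not a plasmid")
  hits <- lapply(plasmids, function(p) {
    h <- translated_genome_search(query, p, min_identity = min_identity,
                                  max_evalue = max_evalue, ...)
    if (nrow(h)) h$replicon <- p$replicon_id
    h
  })
  hits <- do.call(rbind, hits[vapply(hits, nrow, 0L) > 0L])
  if (is.null(hits)) {
    hits <- cbind(empty_hits(), data.frame(replicon = character()))
  }
  counts <- data.frame(
    replicon = vapply(plasmids, `[[`, character(1), "replicon_id"),
    n_hits = vapply(plasmids, function(p)
      sum(hits$replicon == p$replicon_id), integer(1)),
    stringsAsFactors = FALSE)
  list(hits = hits, counts = counts)
}

#' Sliding-window GC profile of a contig
#'
#' @param seq DNA residue string.
#' @param window window size in bases.
#' @param step step between window starts.
#' @return data.frame with `start`, `end` (0-based half-open) and `gc`.
#' @export
gc_profile <- function(seq, window = 1000L, step = 500L) {
  L <- nchar(seq)
  if (window > L) stop("window larger than contig")
  if (step > window) stop("step must not exceed window")
  is_gc <- strsplit(seq, "")[[1]] %in% c("G", "C")
  cum <- c(0L, cumsum(is_gc))
  starts <- seq.int(0L, L - window, by = step)
  data.frame(start = starts, end = starts + window,
             gc = (cum[starts + window + 1L] - cum[starts + 1L]) / window)
}

#' Detect GC-deviant genomic islands
#'
#' Chromosomal or plasmid segments of atypical base composition are a
#' recognised signature of horizontal acquisition. Windows whose GC content
#' deviates from the replicon mean by at least `z_threshold` standard
#' deviations (of the window GC distribution) are flagged; overlapping or
#' adjacent flagged windows are merged into maximal runs, each annotated as
#' a low- or high-GC island with its mean GC and peak z-score.
#'
#' @param genome a `genome_record` or DNA [seq_set()].
#' @param window,step sliding-window geometry in bases (defaults 1000/500,
#'   resolving islands of a few kb and larger).
#' @param z_threshold minimum |z| for a window to be flagged (default 2).
#' @return data.frame of island calls: `contig`, `start`, `end`, `mean_gc`,
#'   `direction` (`low`/`high`), `z`.
#' @export
detect_gc_islands <- function(genome, window = 1000L, step = 500L,
                              z_threshold = 2.0) {
  contigs <- if (inherits(genome, "genome_record")) genome$contigs else genome
  profs <- lapply(seq_len(nrow(contigs)), function(i)
    cbind(contig = contigs$id[i],
          gc_profile(contigs$seq[i], window, step)))
  prof <- do.call(rbind, profs)
  mu <- mean(prof$gc); sdev <- stats::sd(prof$gc)
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), mean_gc = numeric(),
                      direction = character(), z = numeric(),
                      stringsAsFactors = FALSE)
  if (!is.finite(sdev) || sdev == 0) return(empty)
  prof$z <- (prof$gc - mu) / sdev
  flagged <- prof[abs(prof$z) >= z_threshold, , drop = FALSE]
  if (!nrow(flagged)) return(empty)
  calls <- list()
  for (ctg in unique(flagged$contig)) {
    f <- flagged[flagged$contig == ctg, , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    run <- cumsum(c(0L, utils::head(f$start, -1L) + window < utils::tail(f$start, -1L) |
                      sign(utils::head(f$z, -1L)) != sign(utils::tail(f$z, -1L))))
    for (r in unique(run)) {
      g <- f[run == r, , drop = FALSE]
      calls[[length(calls) + 1L]] <- data.frame(
        contig = ctg, start = min(g$start), end = max(g$end),
        mean_gc = mean(g$gc),
        direction = if (g$z[1] > 0) "high" else "low",
        z = max(abs(g$z)), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, calls)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect island calls with NAT loci
#'
#' @param islands data.frame from [detect_gc_islands()].
#' @param loci list of `nat_locus` objects (or a single one).
#' @return data.frame of all (locus, island) pairs with at least one base of
#'   overlap, with the exact overlap length in bases.
#' @export
intersect_islands <- function(islands, loci) {
  if (inherits(loci, "nat_locus")) loci <- list(loci)
  rows <- list()
  for (loc in loci) {
    lstart <- min(loc$segments$start); lend <- max(loc$segments$end)
    isl <- islands[islands$contig == loc$contig, , drop = FALSE]
    if (!nrow(isl)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(lstart + 1L, lend),
      IRanges::IRanges(isl$start + 1L, isl$end))
    for (h in seq_along(ov)) {
      i <- S4Vectors::subjectHits(ov)[h]
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = loc$locus_id, contig = loc$contig,
        island_start = isl$start[i], island_end = isl$end[i],
        overlap = overlap_len(lstart, lend, isl$start[i], isl$end[i]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(locus_id = character(), contig = character(),
                      island_start = integer(), island_end = integer(),
                      overlap = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
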