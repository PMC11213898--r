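## BGC-localization bookkeeping: flank extraction with partial-ORF trimming,
## protocluster membership, and cross-cluster synteny mapping/grouping.

#' Extract the genomic context window around a NAT locus
#'
#' Prokaryotic loci are taken with 500 kb of flanking sequence per side
#' (about 1 Mb of total sequence); eukaryotic loci with 1 Mb per side. The
#' window is clipped at contig ends, and any feature crossing a window edge
#' is removed entirely, because downstream cluster predictors refuse inputs
#' that begin or end with a partial ORF.
#'
#' @param locus a `nat_locus` (or any list with `contig` and `segments`).
#' @param genome a `genome_record` or DNA [seq_set()].
#' @param features a [feature_table()] for the genome.
#' @param domain_kind `"prokaryote"` (500 kb flanks) or `"eukaryote"`
#'   (1 Mb flanks).
#' @param flank override the flank size in bases.
#' @return A `context_window`: list with `contig`, `span` (0-based
#'   half-open), `domain_kind`, `trimmed_features` (global coordinates) and
#'   `sequence` (the window sequence).
#' @export
extract_window <- function(locus, genome, features,
                           domain_kind = c("prokaryote", "eukaryote"),
                           flank = NULL) {
  domain_kind <- match.arg(domain_kind)
  flank <- as.integer(flank %||%
                        if (domain_kind == "prokaryote") 500000L else 1000000L)
  contigs <- if (inherits(genome, "genome_record")) genome$contigs else genome
  ci <- match(locus$contig, contigs$id)
  if (is.na(ci)) stop("locus contig not in genome: ", locus$contig)
  Lc <- nchar(contigs$seq[ci])
  lstart <- min(locus$segments$start)
  lend <- max(locus$segments$end)
  span <- c(max(0L, lstart - flank), min(Lc, lend + flank))

  sub <- features[features$contig == locus$contig, , drop = FALSE]
  if (!nrow(sub) ||
      !any(sub$start <= lstart & sub$end >= lend & sub$kind != "protocluster"))
    warning("locus not present in the feature table; window still produced")
  inside <- sub$start >= span[1] & sub$end <= span[2]
  trimmed <- sub[inside, , drop = FALSE]
  class(trimmed) <- class(features)

  structure(list(contig = locus$contig, span = span,
                 domain_kind = domain_kind, trimmed_features = trimmed,
                 sequence = substr(contigs$seq[ci], span[1] + 1L, span[2])),
            class = "context_window")
}

#' @export
print.context_window <- function(x, ...) {
  cat(sprintf("context_window %s:[%d,%d) (%s), %d feature(s) retained\n",
              x$contig, x$span[1], x$span[2], x$domain_kind,
              nrow(x$trimmed_features)))
  invisible(x)
}

#' Protocluster objects from a feature table
#'
#' @param features a [feature_table()] containing `protocluster` features
#'   (e.g. antiSMASH region output or [implant_cluster()] ground truth);
#'   `gene` features falling inside a protocluster span become its genes.
#' @return A list of `protocluster` objects: `cluster_id`, `contig`, `span`,
#'   `cluster_type`, `genes` (data.frame with `tag`, `start`, `end`,
#'   `strand`, `protein`).
#' @export
protoclusters_from_features <- function(features) {
  pc <- features[features$kind == "protocluster", , drop = FALSE]
  genes <- features[features$kind %in% c("gene", "CDS"), , drop = FALSE]
  lapply(seq_len(nrow(pc)), function(i) {
    q <- pc$qualifiers[[i]]
    span <- c(pc$start[i], pc$end[i])
    g <- genes[genes$contig == pc$contig[i] & genes$start >= span[1] &
                 genes$end <= span[2], , drop = FALSE]
    gq <- g$qualifiers
    structure(list(
      cluster_id = if ("cluster_id" %in% names(q)) q[["cluster_id"]]
                   else sprintf("%s_pc%02d", pc$contig[i], i),
      contig = pc$contig[i], span = span,
      cluster_type = if ("category" %in% names(q)) q[["category"]]
                     else if ("product" %in% names(q)) q[["product"]]
                     else "unknown",
      genes = data.frame(
        tag = vapply(seq_len(nrow(g)), function(j) {
          qq <- gq[[j]]
          if ("locus_tag" %in% names(qq)) qq[["locus_tag"]]
          else sprintf("g%03d", j)
        }, character(1)),
        start = g$start, end = g$end, strand = g$strand,
        protein = vapply(gq, function(qq)
          if ("translation" %in% names(qq)) qq[["translation"]]
          else NA_character_, character(1)),
        stringsAsFactors = FALSE)),
      class = "protocluster")
  })
}

#' Protocluster membership of a locus
#'
#' A locus found in the overlapping region of more than one protocluster is
#' considered part of all protoclusters sharing that region: membership is
#' any overlap of at least one base between the locus span and the
#' protocluster span.
#'
#' @param locus a `nat_locus` (or list with `contig` and `segments`).
#' @param protoclusters list of `protocluster` objects (see
#'   [protoclusters_from_features()]).
#' @return Character vector of member `cluster_id`s (possibly empty).
#' @export
assign_membership <- function(locus, protoclusters) {
  lstart <- min(locus$segments$start)
  lend <- max(locus$segments$end)
  same <- vapply(protoclusters, function(p) p$contig == locus$contig,
                 logical(1))
  if (!any(same)) return(character())
  pcs <- protoclusters[same]
  spans <- do.call(rbind, lapply(pcs, function(p) p$span))
  hit <- IRanges::overlapsAny(
    IRanges::IRanges(start = spans[, 1] + 1L, end = spans[, 2]),
    IRanges::IRanges(start = lstart + 1L, end = lend))
  vapply(pcs[hit], `[[`, character(1), "cluster_id")
}

#' Bidirectional-best-hit synteny map across gene clusters
#'
#' For each cluster pair, the member proteins are compared all-vs-all with
#' [align_proteins()]; a link is a bidirectional best hit (BBH), with
#' identity reported over the aligned span. Two clusters are 100%-conserved
#' when the BBH links form a bijection covering every gene of both clusters,
#' with identical gene order (or its full reversal) and every link at 100%
#' identity. Conservation groups are the transitive closure of this
#' relation; each group is represented by its lexicographically smallest
#' cluster id.
#'
#' @param clusters list of `protocluster` objects whose genes carry protein
#'   sequences.
#' @param scoring substitution matrix configuration.
#' @return A `synteny_map`: list with `links` (data.frame: `cluster_a`,
#'   `cluster_b`, `gene_a`, `gene_b`, `identity`), `conserved_pairs`
#'   (data.frame of 100%-conserved cluster pairs) and `groups` (data.frame:
#'   `cluster_id`, `group`, `representative`).
#' @export
map_synteny <- function(clusters, scoring = default_scoring()) {
  stopifnot(length(clusters) >= 2L)
  ids <- vapply(clusters, `[[`, character(1), "cluster_id")
  for (cl in clusters)
    if (any(is.na(cl$genes$protein)))
      stop("gene without protein sequence in cluster ", cl$cluster_id)

  links <- list(); conserved <- list()
  for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
    if (i >= j) next
    a <- clusters[[i]]$genes; b <- clusters[[j]]$genes
    idm <- matrix(0, nrow(a), nrow(b))
    scm <- matrix(-Inf, nrow(a), nrow(b))
    for (x in seq_len(nrow(a))) for (y in seq_len(nrow(b))) {
      al <- align_proteins(a$protein[x], b$protein[y], scoring = scoring)
      idm[x, y] <- al$identity
      scm[x, y] <- al$score
    }
    best_ab <- apply(scm, 1, which.max)
    best_ba <- apply(scm, 2, which.max)
    bbh <- which(best_ba[best_ab] == seq_len(nrow(a)) &
                   apply(scm, 1, max) > 0)
    if (length(bbh))
      links[[length(links) + 1L]] <- data.frame(
        cluster_a = ids[i], cluster_b = ids[j],
        gene_a = a$tag[bbh], gene_b = b$tag[best_ab[bbh]],
        identity = idm[cbind(bbh, best_ab[bbh])], stringsAsFactors = FALSE)
    full <- length(bbh) == nrow(a) && nrow(a) == nrow(b) &&
      !anyDuplicated(best_ab[bbh])
    if (full) {
      ord <- best_ab            # position of each a-gene's partner in b
      in_order <- all(ord == seq_len(nrow(b))) || all(ord == rev(seq_len(nrow(b))))
      all100 <- all(idm[cbind(seq_len(nrow(a)), best_ab)] == 100)
      if (in_order && all100)
        conserved[[length(conserved) + 1L]] <- data.frame(
          cluster_a = ids[i], cluster_b = ids[j], stringsAsFactors = FALSE)
    }
  }
  links <- if (length(links)) do.call(rbind, links) else
    data.frame(cluster_a = character(), cluster_b = character(),
               gene_a = character(), gene_b = character(),
               identity = numeric(), stringsAsFactors = FALSE)
  cons <- if (length(conserved)) do.call(rbind, conserved) else
    data.frame(cluster_a = character(), cluster_b = character(),
               stringsAsFactors = FALSE)

  g <- igraph::graph_from_data_frame(cons, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  groups <- data.frame(cluster_id = names(comp), group = unname(comp),
                       stringsAsFactors = FALSE)
  reps <- vapply(split(groups$cluster_id, groups$group),
                 function(x) sort(x)[1], character(1))
  groups$representative <- reps[as.character(groups$group)]
  groups <- groups[order(groups$cluster_id), , drop = FALSE]
  rownames(groups) <- NULL
  structure(list(links = links, conserved_pairs = cons, groups = groups),
            class = "synteny_map")
}

#' @export
print.synteny_map <- function(x, ...) {
  cat(sprintf("synteny_map: %d BBH link(s), %d conservation group(s)\n",
              nrow(x$links), length(unique(x$groups$group))))
  invisible(x)
}
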