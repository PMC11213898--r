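## NAT locus annotation: ORF reconstruction (incl. frameshift joining),
## semi-conserved motif scanning, catalytic-triad verification and
## committee-style symbol assignment.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' The four semi-conserved NAT family motifs
#'
#' Consensus strings "VPFENL", "RGGYC", "THRL" and "VDV", in their canonical
#' N- to C-terminal order. The catalytic Cys-His-Asp triad residues sit at
#' fixed positions inside the last three motifs (0-based index within the
#' motif): C at 4 in "RGGYC", H at 1 in "THRL", D at 1 in "VDV" (a Glu at
#' that position is tolerated but flagged as the known triad variant).
#'
#' @return A data.frame with columns `motif_id`, `consensus`,
#'   `catalytic_index` (NA for M1) and `catalytic_residues`.
#' @export
nat_motifs <- function() {
  data.frame(motif_id = c("M1", "M2", "M3", "M4"),
             consensus = c("VPFENL", "RGGYC", "THRL", "VDV"),
             catalytic_index = c(NA_integer_, 4L, 1L, 1L),
             catalytic_residues = c(NA_character_, "C", "H", "D|E"),
             stringsAsFactors = FALSE)
}

#' Reconstruct a (possibly frameshifted) NAT locus from search hits
#'
#' Hits from [translated_genome_search()] lying at one genomic locus (same
#' contig, same strand, spans within a few kb) are turned into a gene model:
#' the outermost hits are extended in-frame to the nearest upstream start
#' codon and the nearest downstream stop codon (stopping at a contig edge
#' sets the corresponding partial flag); same-frame hits are merged;
#' different-frame hits -- the signature of a frameshift pseudogene -- are
#' joined at the midpoint of their genomic gap, each side snapped to its own
#' codon lattice, producing a multi-segment locus. The locus protein is the
#' concatenation of the per-segment translations.
#'
#' @param hits data.frame of hits for one locus.
#' @param genome a `genome_record` or DNA [seq_set()].
#' @param locus_id identifier for the reconstructed locus.
#' @param max_upstream_scan cap (in codons) on the upstream start-codon scan.
#' @return A `nat_locus`: list with `locus_id`, `contig`, `strand`,
#'   `segments` (data.frame of forward-strand 0-based half-open `start`,
#'   `end`, `frame`, ordered 5' to 3' on the coding strand), `protein`,
#'   `partial_5p`, `partial_3p`.
#' @export
reconstruct_orf <- function(hits, genome, locus_id = "locus1",
                            max_upstream_scan = 200L) {
  if (nrow(hits) == 0L) stop("no hits to reconstruct from")
  if (length(unique(hits$contig)) != 1L || length(unique(hits$strand)) != 1L)
    stop("hits span multiple contigs or strands")
  contigs <- if (inherits(genome, "genome_record")) genome$contigs else genome
  ci <- match(hits$contig[1], contigs$id)
  if (is.na(ci)) stop("unknown contig: ", hits$contig[1])
  fwd <- contigs$seq[ci]
  Lc <- nchar(fwd)
  strand <- hits$strand[1]

  # work on the coding strand so all arithmetic reads left to right
  S <- if (strand == "+") fwd else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  cs <- if (strand == "+") hits$gstart else Lc - hits$gend
  ce <- if (strand == "+") hits$gend else Lc - hits$gstart
  o <- order(cs)
  cs <- cs[o]; ce <- ce[o]; ident <- hits$identity[o]

  # where consecutive hits overlap (an exact local aligner may extend a hit
  # a little across a frameshift), give the overlap to the hit whose
  # alignment identity is higher, snapping to the trimmed hit's codon lattice
  if (length(cs) > 1L) for (i in 2L:length(cs)) {
    if (cs[i] < ce[i - 1L]) {
      if (ident[i] >= ident[i - 1L]) {
        ce[i - 1L] <- ce[i - 1L] - 3L * as.integer(ceiling((ce[i - 1L] - cs[i]) / 3))
        if (ce[i - 1L] <= cs[i - 1L]) ce[i - 1L] <- cs[i - 1L] + 3L
      } else {
        cs[i] <- cs[i] + 3L * as.integer(ceiling((ce[i - 1L] - cs[i]) / 3))
        if (cs[i] >= ce[i]) cs[i] <- ce[i] - 3L
      }
    }
  }

  codon_at <- function(pos) substr(S, pos + 1L, pos + 3L)
  partial_5p <- FALSE; partial_3p <- FALSE

  # 5' extension of the first hit to the nearest upstream ATG
  pos <- cs[1]
  if (codon_at(pos) != "ATG") {
    cur <- pos
    for (step in seq_len(max_upstream_scan)) {
      cand <- cur - 3L
      if (cand < 0L) { partial_5p <- TRUE; break }
      cod <- codon_at(cand)
      if (cod %in% STOP_CODONS) break
      cur <- cand
      if (cod == "ATG") { cs[1] <- cand; break }
    }
  }

  # 3' extension of the last hit to the next in-frame stop
  n <- length(cs)
  e <- ce[n]
  repeat {
    if (e + 3L > Lc) { partial_3p <- TRUE; break }
    if (codon_at(e) %in% STOP_CODONS) break
    e <- e + 3L
  }
  ce[n] <- e

  # merge same-frame neighbours, join different-frame ones at the midpoint
  segs <- list(c(cs[1], ce[1]))
  if (n > 1L) for (i in 2L:n) {
    prev <- segs[[length(segs)]]
    if ((cs[i] - prev[1]) %% 3L == 0L) {
      segs[[length(segs)]] <- c(prev[1], max(prev[2], ce[i]))
    } else {
      m <- (prev[2] + cs[i]) %/% 2L
      prev[2] <- prev[2] + 3L * ((m - prev[2]) %/% 3L)
      new_start <- cs[i] - 3L * ((cs[i] - m) %/% 3L)
      if (prev[2] <= prev[1]) prev[2] <- prev[1] + 3L
      segs[[length(segs)]] <- prev
      segs[[length(segs) + 1L]] <- c(max(new_start, prev[2]), ce[i])
    }
  }

  prot <- paste(vapply(segs, function(s) {
    if (s[2] <= s[1]) return("")
    w <- s[2] - s[1]; w <- w - w %% 3L
    if (w <= 0L) return("")
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(S, s[1] + 1L, s[1] + w)),
      if.fuzzy.codon = "solve", no.init.codon = TRUE))
  }, character(1)), collapse = "")

  seg_df <- do.call(rbind, lapply(segs, function(s) {
    st <- if (strand == "+") s[1] else Lc - s[2]
    en <- if (strand == "+") s[2] else Lc - s[1]
    data.frame(start = st, end = en,
               frame = frame_of(st, en, strand, Lc))
  }))
  seg_df <- seg_df[order(if (strand == "+") seg_df$start else -seg_df$start), ,
                   drop = FALSE]
  rownames(seg_df) <- NULL

  structure(list(locus_id = locus_id, contig = hits$contig[1],
                 strand = strand, segments = seg_df, protein = prot,
                 partial_5p = partial_5p,
                 partial_3p = if (strand == "+") partial_3p else partial_3p),
            class = "nat_locus")
}

#' @export
print.nat_locus <- function(x, ...) {
  cat(sprintf("nat_locus '%s' on %s(%s): %d segment(s), %d aa%s%s\n",
              x$locus_id, x$contig, x$strand, nrow(x$segments),
              nchar(x$protein),
              if (x$partial_5p) ", 5' partial" else "",
              if (x$partial_3p) ", 3' partial" else ""))
  invisible(x)
}

#' Group search hits into candidate loci
#'
#' Hits on the same contig and strand whose genomic spans lie within
#' `max_gap` of each other are grouped; each group feeds one
#' [reconstruct_orf()] call.
#'
#' @param hits data.frame from [translated_genome_search()].
#' @param max_gap maximum genomic gap (bases) between hits of one locus.
#' @return A list of hit data.frames.
#' @export
group_hits <- function(hits, max_gap = 5000L) {
  if (nrow(hits) == 0L) return(list())
  out <- list()
  for (key in unique(paste(hits$contig, hits$strand))) {
    sub <- hits[paste(hits$contig, hits$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$gstart), , drop = FALSE]
    grp <- cumsum(c(0L, diff(sub$gstart) > max_gap +
                      (utils::head(sub$gend, -1L) - utils::head(sub$gstart, -1L))))
    for (g in unique(grp))
      out[[length(out) + 1L]] <- sub[grp == g, , drop = FALSE]
  }
  out
}

#' Scan a protein for the semi-conserved NAT motifs
#'
#' Every window of consensus length is scored against each motif with
#' BLOSUM62. A window is a candidate when its score reaches
#' `min_score_fraction` of the consensus self-score and the catalytic
#' residue (where defined) matches exactly (for the "VDV" motif, Asp or the
#' flagged Glu variant). The best-scoring combination of candidates with
#' strictly increasing, non-overlapping positions in the canonical motif
#' order is selected by dynamic programming.
#'
#' @param protein amino-acid string (>= 30 residues for a meaningful scan).
#' @param defs motif definitions, see [nat_motifs()].
#' @param min_score_fraction fraction of the consensus self-score required
#'   (default 0.6, which admits the consensi and single conservative
#'   substitutions while rejecting random windows).
#' @param scoring substitution matrix configuration.
#' @return A data.frame with one row per motif: `motif_id`, `position`
#'   (0-based start, NA if not found), `matched`, `score_fraction`,
#'   `catalytic_pos`, `catalytic_residue`.
#' @export
scan_motifs <- function(protein, defs = nat_motifs(), min_score_fraction = 0.6,
                        scoring = default_scoring()) {
  mat <- get_submat(scoring)
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  cand <- lapply(seq_len(nrow(defs)), function(i) {
    cons <- strsplit(defs$consensus[i], "")[[1]]
    w <- length(cons)
    if (n < w) return(data.frame())
    self <- sum(mat[cbind(cons, cons)])
    starts <- 0:(n - w)
    scores <- vapply(starts, function(p)
      sum(mat[cbind(cons, res[(p + 1):(p + w)])]), numeric(1))
    ok <- scores >= min_score_fraction * self
    if (!is.na(defs$catalytic_index[i])) {
      allowed <- strsplit(defs$catalytic_residues[i], "|", fixed = TRUE)[[1]]
      ok <- ok & res[starts + defs$catalytic_index[i] + 1L] %in% allowed
    }
    data.frame(position = starts[ok], score = scores[ok],
               frac = scores[ok] / self, stringsAsFactors = FALSE)
  })

  # DP over motifs: maximise (number found, total score) subject to ordered,
  # non-overlapping placement; states are deduplicated by end position
  width <- nchar(defs$consensus)
  states <- list(list(count = 0L, score = 0,
                      picks = rep(NA_integer_, nrow(defs)), end = -1L))
  for (i in seq_len(nrow(defs))) {
    nxt <- states  # option: skip motif i entirely
    ci <- cand[[i]]
    if (nrow(ci)) for (st in states) {
      for (u in which(ci$position >= st$end)) {
        picks <- st$picks; picks[i] <- u
        nxt[[length(nxt) + 1L]] <- list(count = st$count + 1L,
                                        score = st$score + ci$score[u],
                                        picks = picks,
                                        end = ci$position[u] + width[i])
      }
    }
    ends <- vapply(nxt, `[[`, 0L, "end")
    keep <- integer(0)
    for (e in unique(ends)) {
      grp <- which(ends == e)
      cnts <- vapply(nxt[grp], `[[`, 0L, "count")
      scs <- vapply(nxt[grp], `[[`, 0, "score")
      keep <- c(keep, grp[order(-cnts, -scs)[1]])
    }
    states <- nxt[sort(keep)]
  }
  counts <- vapply(states, `[[`, 0L, "count")
  scores <- vapply(states, `[[`, 0, "score")
  win <- states[[order(-counts, -scores)[1]]]

  out <- data.frame(motif_id = defs$motif_id, position = NA_integer_,
                    matched = NA_character_, score_fraction = NA_real_,
                    catalytic_pos = NA_integer_,
                    catalytic_residue = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(defs))) {
    u <- win$picks[i]
    if (is.na(u)) next
    p <- cand[[i]]$position[u]
    out$position[i] <- p
    out$matched[i] <- substr(protein, p + 1L, p + width[i])
    out$score_fraction[i] <- cand[[i]]$frac[u]
    if (!is.na(defs$catalytic_index[i])) {
      cp <- p + defs$catalytic_index[i]
      out$catalytic_pos[i] <- cp
      out$catalytic_residue[i] <- substr(protein, cp + 1L, cp + 1L)
    }
  }
  out
}

#' Catalytic-triad status from motif hits
#'
#' @param motif_hits output of [scan_motifs()].
#' @return `"canonical_CHD"` when Cys, His and Asp are all present at their
#'   catalytic positions; `"variant_CHE"` when the Asp is replaced by Glu
#'   (the known functional variant); `"incomplete"` when one or two triad
#'   residues are present; `"absent"` when none are.
#' @export
verify_triad <- function(motif_hits) {
  m2 <- motif_hits$catalytic_residue[motif_hits$motif_id == "M2"]
  m3 <- motif_hits$catalytic_residue[motif_hits$motif_id == "M3"]
  m4 <- motif_hits$catalytic_residue[motif_hits$motif_id == "M4"]
  have_c <- length(m2) && !is.na(m2) && m2 == "C"
  have_h <- length(m3) && !is.na(m3) && m3 == "H"
  have_d <- length(m4) && !is.na(m4) && m4 %in% c("D", "E")
  npres <- sum(have_c, have_h, have_d)
  if (npres == 3L) {
    if (m4 == "E") "variant_CHE" else "canonical_CHD"
  } else if (npres >= 1L) "incomplete" else "absent"
}

#' Classify loci and assign species-specific NAT gene symbols
#'
#' A locus is `non_nat` when fewer than three motifs are found, when the
#' catalytic triad is absent, or when its best reference identity/coverage
#' falls below the callable thresholds. Otherwise it is a
#' `frameshifted_pseudogene` (more than one segment), `truncated` (a partial
#' flag set), or `intact`. Within each species, callable loci are numbered
#' NAT1, NAT2, ... in descending best-reference identity (ties broken by
#' genomic coordinate); the numbering thresholds are configurable because
#' the nomenclature committee's exact bands are external to this package.
#'
#' @param loci a `nat_locus` or list of them.
#' @param references protein [seq_set()] of labelled reference sequences;
#'   a record's `desc` (falling back to its `id`) is its family label.
#' @param species optional character vector assigning each locus to a
#'   species (symbols are numbered per species); default: one species.
#' @param min_identity,min_coverage callable thresholds (defaults 25 / 75).
#' @param min_score_fraction passed to [scan_motifs()].
#' @param scoring substitution matrix configuration.
#' @return A data.frame with one row per locus: locus/contig/strand,
#'   `n_segments`, `motifs_found`, `triad_status`, `best_reference`,
#'   `best_identity`, `best_coverage`, `classification`, `assigned_symbol`.
#' @export
classify_and_name <- function(loci, references, species = NULL,
                              min_identity = 25, min_coverage = 75,
                              min_score_fraction = 0.6,
                              scoring = default_scoring()) {
  if (inherits(loci, "nat_locus")) loci <- list(loci)
  stopifnot(inherits(references, "seq_set"), nrow(references) > 0L)
  if (is.null(species)) species <- rep("sp1", length(loci))
  stopifnot(length(species) == length(loci))

  rows <- lapply(seq_along(loci), function(i) {
    loc <- loci[[i]]
    mh <- scan_motifs(loc$protein, min_score_fraction = min_score_fraction,
                      scoring = scoring)
    triad <- verify_triad(mh)
    found <- sum(!is.na(mh$position))
    als <- lapply(seq_len(nrow(references)), function(r)
      align_proteins(loc$protein, references$seq[r], scoring = scoring,
                     mode = "local", query_id = loc$locus_id,
                     subject_id = references$id[r]))
    als <- do.call(rbind, als)
    b <- which.max(als$identity)
    data.frame(locus_id = loc$locus_id, contig = loc$contig,
               strand = loc$strand, start = min(loc$segments$start),
               n_segments = nrow(loc$segments), motifs_found = found,
               triad_status = triad,
               best_reference = als$subject_id[b],
               best_identity = als$identity[b],
               best_coverage = als$coverage[b],
               partial = loci[[i]]$partial_5p || loci[[i]]$partial_3p,
               species = species[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)

  callable <- out$motifs_found >= 3L & out$triad_status != "absent" &
    out$best_identity >= min_identity & out$best_coverage >= min_coverage
  out$classification <- ifelse(!callable, "non_nat",
                        ifelse(out$n_segments > 1L, "frameshifted_pseudogene",
                        ifelse(out$partial, "truncated", "intact")))
  out$assigned_symbol <- ""
  for (sp in unique(out$species)) {
    idx <- which(out$species == sp & callable)
    if (!length(idx)) next
    o <- idx[order(-out$best_identity[idx], out$contig[idx], out$start[idx])]
    out$assigned_symbol[o] <- paste0("NAT", seq_along(o))
  }
  out$partial <- NULL
  rownames(out) <- NULL
  out
}

#' Search, reconstruct and annotate NAT loci in one genome
#'
#' Convenience pipeline: [translated_genome_search()] with each query,
#' [group_hits()], [reconstruct_orf()] per group, then
#' [classify_and_name()] against the references.
#'
#' @param genome a `genome_record` or DNA [seq_set()].
#' @param queries protein [seq_set()] of search queries (defaults to the
#'   synthetic NAT reference).
#' @param references passed to [classify_and_name()]; defaults to `queries`.
#' @param min_identity,max_evalue search thresholds.
#' @param ... passed on to [classify_and_name()].
#' @return `list(annotations = data.frame, loci = list of nat_locus)`.
#' @export
annotate_genome <- function(genome,
                            queries = seq_set("nat_ref",
                                              nat_reference_protein(),
                                              alphabet = "protein"),
                            references = queries,
                            min_identity = 25, max_evalue = 1e-6, ...) {
  hits <- do.call(rbind, lapply(seq_len(nrow(queries)), function(q)
    translated_genome_search(queries$seq[q], genome,
                             min_identity = min_identity,
                             max_evalue = max_evalue,
                             query_id = queries$id[q])))
  if (is.null(hits) || nrow(hits) == 0L)
    return(list(annotations = data.frame(), loci = list()))
  groups <- group_hits(hits)
  loci <- lapply(seq_along(groups), function(i)
    reconstruct_orf(groups[[i]], genome, locus_id = sprintf("locus%03d", i)))
  ann <- classify_and_name(loci, references, ...)
  list(annotations = ann, loci = loci)
}
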