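#' Translate a DNA sequence in all six reading frames
#'
#' Frames +1..+3 read the forward strand at offsets 0..2; frames -1..-3 read
#' the reverse complement likewise. Stop codons are rendered `*`; ambiguous
#' codons that cannot be resolved translate to `X`.
#'
#' @param dna a DNA residue string.
#' @return A named character vector of six protein strings
#'   (`+1`, `+2`, `+3`, `-1`, `-2`, `-3`).
#' @export
translate_six_frames <- function(dna) {
  d <- Biostrings::DNAString(toupper(dna))
  rc <- Biostrings::reverseComplement(d)
  one <- function(x, off) {
    n <- length(x) - off
    n <- n - n %% 3L
    if (n <= 0L) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(x, start = off + 1L, width = n),
      if.fuzzy.codon = "solve", no.init.codon = TRUE))
  }
  c("+1" = one(d, 0L), "+2" = one(d, 1L), "+3" = one(d, 2L),
    "-1" = one(rc, 0L), "-2" = one(rc, 1L), "-3" = one(rc, 2L))
}

frame_to_genomic <- function(frame, sstart, send, contig_len) {
  k <- abs(frame)
  if (frame > 0L) c(k - 1L + 3L * sstart, k - 1L + 3L * send)
  else c(contig_len - (k - 1L) - 3L * send, contig_len - (k - 1L) - 3L * sstart)
}

empty_hits <- function() {
  data.frame(query_id = character(), contig = character(), strand = character(),
             frame = integer(), score = numeric(), identity = numeric(),
             coverage = numeric(), evalue = numeric(),
             qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(),
             gstart = integer(), gend = integer(), stringsAsFactors = FALSE)
}

#' Search a genome with a protein query across all six frames
#'
#' The in-package analogue of a translated (tBLASTn-style) search: the query
#' is locally aligned against every reading frame of every contig; within a
#' frame, successive hits are recovered by masking the aligned subject span
#' and re-aligning, so several loci per frame are found. Hits below
#' `min_identity` or above `max_evalue` are dropped; surviving hits are
#' reported in forward-strand genomic coordinates, sorted by contig then
#' start. Hits are not merged across frames -- joining frameshifted
#' fragments is the annotator's job (see [reconstruct_orf()]).
#'
#' @param query protein residue string.
#' @param genome a `genome_record` or a DNA [seq_set()].
#' @param min_identity minimum percent identity (default 25).
#' @param max_evalue maximum expectation value (default 1e-6).
#' @param scoring see [default_scoring()].
#' @param query_id identifier carried into the hits.
#' @param max_hits_per_frame cap on masking iterations per frame.
#' @return A data.frame of hits: alignment columns plus `contig`, `strand`,
#'   `frame` and genomic `gstart`/`gend` (0-based half-open, forward strand).
#'   The genomic span length always equals 3x the aligned subject residues.
#' @export
translated_genome_search <- function(query, genome, min_identity = 25,
                                     max_evalue = 1e-6,
                                     scoring = default_scoring(),
                                     query_id = "query",
                                     max_hits_per_frame = 25L) {
  if (!nzchar(query)) stop("empty query")
  contigs <- if (inherits(genome, "genome_record")) genome$contigs
             else genome
  stopifnot(inherits(contigs, "seq_set"))
  db_res <- sum(vapply(contigs$seq, function(s) {
    n <- nchar(s); sum((n - 0:2) %/% 3L) * 2L
  }, numeric(1)))
  hits <- list()
  for (i in seq_len(nrow(contigs))) {
    ctg <- contigs$id[i]
    Lc <- nchar(contigs$seq[i])
    frames <- translate_six_frames(contigs$seq[i])
    for (fname in names(frames)) {
      fr <- as.integer(sub("\\+", "", fname))
      prot <- frames[[fname]]
      if (!nzchar(prot)) next
      for (iter in seq_len(max_hits_per_frame)) {
        al <- align_proteins(query, prot, scoring = scoring, mode = "local",
                             query_id = query_id, subject_id = ctg)
        if (al$score <= 0) break
        al$evalue <- evalue(al$score, nchar(query), db_res)
        if (al$evalue > max_evalue) break
        g <- frame_to_genomic(fr, al$sstart, al$send, Lc)
        if (al$identity >= min_identity) {
          hits[[length(hits) + 1L]] <- data.frame(
            query_id = query_id, contig = ctg,
            strand = if (fr > 0) "+" else "-", frame = fr,
            score = al$score, identity = al$identity,
            coverage = al$coverage, evalue = al$evalue,
            qstart = al$qstart, qend = al$qend,
            sstart = al$sstart, send = al$send,
            gstart = g[1], gend = g[2], stringsAsFactors = FALSE)
        }
        # mask the found span and look for further loci in this frame
        mask <- strrep("*", al$send - al$sstart)
        prot <- paste0(substr(prot, 1L, al$sstart), mask,
                       substr(prot, al$send + 1L, nchar(prot)))
      }
    }
  }
  if (!length(hits)) return(empty_hits())
  out <- do.call(rbind, hits)
  out <- merge_same_frame_hits(out)
  out <- out[order(out$contig, out$gstart, out$gend), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# overlapping same-frame hits are collapsed to the best-scoring one
merge_same_frame_hits <- function(hits) {
  keep <- rep(TRUE, nrow(hits))
  o <- order(-hits$score)
  for (a in o) {
    if (!keep[a]) next
    for (b in seq_len(nrow(hits))) {
      if (b == a || !keep[b]) next
      if (hits$contig[a] == hits$contig[b] &&
          hits$frame[a] == hits$frame[b] &&
          overlap_len(hits$gstart[a], hits$gend[a],
                      hits$gstart[b], hits$gend[b]) > 0L &&
          hits$score[b] <= hits$score[a])
        keep[b] <- FALSE
    }
  }
  hits[keep, , drop = FALSE]
}

#' Interrogate a local protein database with a query
#'
#' BLASTp-style ranked search of a protein collection: the query is locally
#' aligned against every database sequence, E-values are computed against
#' the total database residue count, and results are sorted by ascending
#' E-value, then descending identity, then subject identifier.
#'
#' @param query protein residue string.
#' @param db a protein [seq_set()] (non-empty).
#' @param max_evalue report hits with E-value at or below this.
#' @param scoring see [default_scoring()].
#' @param query_id identifier carried into the results.
#' @return A data.frame of alignment results (possibly zero rows).
#' @export
search_protein_db <- function(query, db, max_evalue = 10,
                              scoring = default_scoring(),
                              query_id = "query") {
  stopifnot(inherits(db, "seq_set"), nrow(db) > 0L)
  db_res <- sum(nchar(db$seq))
  rows <- lapply(seq_len(nrow(db)), function(i) {
    al <- align_proteins(query, db$seq[i], scoring = scoring, mode = "local",
                         query_id = query_id, subject_id = db$id[i])
    al$evalue <- if (al$score > 0) evalue(al$score, nchar(query), db_res)
                 else Inf
    al
  })
  out <- do.call(rbind, rows)
  out <- out[is.finite(out$evalue) & out$evalue <= max_evalue, , drop = FALSE]
  out <- out[order(out$evalue, -out$identity, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
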