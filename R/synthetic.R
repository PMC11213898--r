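## Synthetic genome generator: the stand-in for genome-database downloads.
## Every implant records exact ground-truth coordinates so downstream
## recovery can be scored without fuzzy matching.

MOCK_TAXONOMY <- data.frame(
  domain = c(rep("Bacteria", 16), rep("Archaea", 2), rep("Eukaryota", 2)),
  phylum = c(rep("Actinobacteria", 5), rep("Firmicutes", 4),
             rep("Proteobacteria", 5), "Bacteroidetes", "Cyanobacteria",
             rep("Euryarchaeota", 2), rep("Ascomycota", 2)),
  class = c(rep("Actinomycetia", 5), rep("Bacilli", 4),
            "Alphaproteobacteria", "Alphaproteobacteria",
            "Betaproteobacteria", "Gammaproteobacteria",
            "Gammaproteobacteria", "Flavobacteriia", "Cyanophyceae",
            rep("Halobacteria", 2), "Eurotiomycetes", "Sordariomycetes"),
  genus = c("Streptomyces", "Amycolatopsis", "Mycobacterium", "Salinispora",
            "Tsukamurella", "Bacillus", "Paenibacillus", "Brevibacillus",
            "Staphylococcus", "Bosea", "Rhizobium", "Cupriavidus",
            "Pantoea", "Klebsiella", "Flavobacterium", "Synechococcus",
            "Halostella", "Halogeometricum", "Aspergillus", "Fusarium"),
  species = c("coelicolor", "mediterranei", "smegmatis", "arenicola",
              "paurometabola", "cereus", "polymyxa", "brevis", "aureus",
              "vestrisii", "leguminosarum", "necator", "agglomerans",
              "pneumoniae", "aquatile", "elongatus", "salina",
              "borinquense", "flavus", "verticillioides"),
  stringsAsFactors = FALSE)

#' Synthetic reference NAT-like protein
#'
#' A fixed, synthetic 280-residue protein used as the generator's seed for
#' implanted NAT-like loci and as the default search query in synthetic mode.
#' It carries the four semi-conserved NAT family motifs in their canonical
#' order -- "VPFENL", "RGGYC", "THRL" and "VDV", housing the Cys-His-Asp
#' catalytic triad -- embedded in reproducible random filler. As in natural
#' NATs, the motif block sits in the N-terminal half, upstream of the band
#' where frameshift lesions are introduced and out of reach of 3'
#' truncations, keeping lesion and motif ground truths independent. This is
#' not a natural sequence.
#'
#' @return A single upper-case amino-acid string.
#' @export
nat_reference_protein <- function() {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  filler <- function(n, s) with_seed(s, paste(sample(aa, n, replace = TRUE),
                                              collapse = ""))
  paste0("M", filler(29, 101L),
         "VPFENL",              # M1 at 30 (0-based)
         filler(24, 102L),
         "RGGYC",               # M2 at 60; catalytic C at 64
         filler(35, 103L),
         "THRL",                # M3 at 100; catalytic H at 101
         filler(17, 104L),
         "VDV",                 # M4 at 121; catalytic D at 122
         filler(156, 105L))
}

codon_map <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Back-translate a protein into a DNA open reading frame
#'
#' Uses the standard/bacterial codon table with uniform synonymous-codon
#' choice under the given seed. The first residue must be Met (encoded ATG,
#' the start codon); a seeded stop codon is appended unless `stop = FALSE`.
#'
#' @param protein amino-acid string starting with "M".
#' @param seed integer seed for synonymous-codon choice.
#' @param stop append a stop codon?
#' @return A DNA string of length `3 * nchar(protein) (+ 3)`.
#' @export
back_translate <- function(protein, seed = 1L, stop = TRUE) {
  if (substr(protein, 1, 1) != "M") stop("protein must start with Met")
  cm <- codon_map()
  res <- strsplit(protein, "")[[1]]
  with_seed(split_seed(seed, "backtranslate"), {
    codons <- vapply(res, function(a) {
      opts <- cm[[a]]
      if (is.null(opts)) stop("residue without codon: ", a)
      opts[sample.int(length(opts), 1L)]
    }, character(1))
    codons[1] <- "ATG"
    if (stop) codons <- c(codons, cm[["*"]][sample.int(3L, 1L)])
    paste(codons, collapse = "")
  })
}

#' Generate a mock microbial replicon
#'
#' Bases are drawn i.i.d. with the requested GC fraction, split into
#' `n_contigs` contigs of (near) equal length. Taxon labels are drawn from a
#' bundled mock taxonomy. Identical seeds give byte-identical output.
#'
#' @param length total length in bases (`>= n_contigs * 1000`).
#' @param gc target GC fraction, in (0, 1); generated replicons are intended
#'   to stay within the realistic 0.25--0.75 band.
#' @param n_contigs number of contigs.
#' @param replicon_class `"chromosome"` or `"plasmid"`.
#' @param seed integer seed.
#' @param replicon_id identifier for the replicon.
#' @param topology `"linear"` or `"circular"`; circular replicons are stored
#'   linearly and no implanted feature ever spans the origin.
#' @return A `genome_record`: list with `replicon_id`, `contigs` (a DNA
#'   [seq_set()]), `taxon`, `topology`, `replicon_class`, `background_gc`,
#'   plus ground-truth manifests `implants`, `islands` and `features`
#'   accumulated by the implant functions.
#' @export
generate_genome <- function(length, gc = 0.5, n_contigs = 1L,
                            replicon_class = c("chromosome", "plasmid"),
                            seed = 1L, replicon_id = "rep1",
                            topology = c("linear", "circular")) {
  replicon_class <- match.arg(replicon_class)
  topology <- match.arg(topology)
  if (gc <= 0 || gc >= 1) stop("gc must be inside (0, 1)")
  length <- as.integer(length)
  n_contigs <- as.integer(n_contigs)
  if (length < n_contigs * 1000L)
    stop("length must allow >= 1 kb per contig")
  lens <- rep(length %/% n_contigs, n_contigs)
  lens[n_contigs] <- lens[n_contigs] + length %% n_contigs
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n_contigs), function(i) {
    with_seed(split_seed(seed, "genome", paste(replicon_id, i)),
              paste(sample(names(probs), lens[i], replace = TRUE,
                           prob = probs), collapse = ""))
  }, character(1))
  taxon_row <- with_seed(split_seed(seed, "taxon", replicon_id),
                         MOCK_TAXONOMY[sample.int(nrow(MOCK_TAXONOMY), 1L), ])
  taxon <- as.list(taxon_row)
  taxon$strain <- paste0("syn-", split_seed(seed, "strain", replicon_id) %% 10000L)
  g <- list(replicon_id = replicon_id,
            contigs = seq_set(paste0(replicon_id, "_c", seq_len(n_contigs)),
                              seqs, alphabet = "dna"),
            taxon = taxon, topology = topology,
            replicon_class = replicon_class, background_gc = gc,
            implants = list(),
            islands = data.frame(contig = character(), start = integer(),
                                 end = integer(), gc = numeric(),
                                 stringsAsFactors = FALSE),
            features = feature_table())
  class(g) <- "genome_record"
  g
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("genome_record '%s' (%s, %s): %d contig(s), %d bp, GC %.2f\n",
              x$replicon_id, x$replicon_class, x$topology,
              nrow(x$contigs), sum(nchar(x$contigs$seq)), x$background_gc))
  cat(sprintf("  taxon: %s %s %s | implants: %d | islands: %d\n",
              x$taxon$genus, x$taxon$species, x$taxon$strain,
              length(x$implants), nrow(x$islands)))
  invisible(x)
}

contig_index <- function(genome, contig) {
  if (is.numeric(contig)) return(as.integer(contig))
  i <- match(contig, genome$contigs$id)
  if (is.na(i)) stop("unknown contig: ", contig)
  i
}

occupied_intervals <- function(genome, contig_id) {
  segs <- do.call(rbind, lapply(genome$implants, function(e) {
    if (e$contig != contig_id) return(NULL)
    data.frame(start = min(e$window[1]), end = max(e$window[2]))
  }))
  isl <- genome$islands[genome$islands$contig == contig_id, c("start", "end")]
  rbind(segs, isl)
}

check_no_overlap <- function(genome, contig_id, start, end, what) {
  occ <- occupied_intervals(genome, contig_id)
  if (!is.null(occ) && nrow(occ) &&
      any(overlap_len(occ$start, occ$end, start, end) > 0L))
    stop(what, " would overlap an existing implant/island on ", contig_id)
  invisible(TRUE)
}

# reading frame of a forward-coordinate segment, in six-frame convention
frame_of <- function(start, end, strand, contig_len) {
  if (strand == "+") (start %% 3L) + 1L else -(((contig_len - end) %% 3L) + 1L)
}

overwrite_seq <- function(seq, at, replacement) {
  # at: 0-based start
  paste0(substr(seq, 1L, at), replacement,
         substr(seq, at + nchar(replacement) + 1L, nchar(seq)))
}

#' Implant a NAT-like open reading frame into a genome
#'
#' The protein is back-translated (start/stop codons included, seeded
#' synonymous-codon choice) and written over the genome at `position`
#' (replacement, so genome length never changes; lesions are absorbed inside
#' a small padding window so coordinates elsewhere stay stable). Lesions:
#' `frameshift_del1`/`frameshift_ins1` remove/insert one nucleotide at a
#' seeded internal offset, shifting the downstream reading frame by -1/+1;
#' `truncation_5p`/`truncation_3p` clip 20--40\% of the ORF at the stated end
#' and place the truncated end at the contig edge so that partiality is
#' recoverable. The returned manifest entry records exact ground-truth
#' segments, frames and the post-lesion protein product.
#'
#' @param genome a `genome_record`.
#' @param protein amino-acid string starting with "M"; for a true positive it
#'   must contain the four canonical motifs (see [nat_reference_protein()]).
#' @param position 0-based base index of the implant window start (ignored
#'   for the clipped end of truncation lesions).
#' @param strand `"+"` or `"-"`.
#' @param lesion one of `none`, `frameshift_del1`, `frameshift_ins1`,
#'   `truncation_5p`, `truncation_3p`.
#' @param seed integer seed.
#' @param contig contig id or index (default first).
#' @param locus_id identifier (auto-generated when `NULL`).
#' @param in_cluster optional protocluster id this locus belongs to.
#' @return `list(genome = updated genome_record, entry = manifest entry)`.
#' @export
implant_locus <- function(genome, protein, position, strand = "+",
                          lesion = c("none", "frameshift_del1",
                                     "frameshift_ins1", "truncation_5p",
                                     "truncation_3p"),
                          seed = 1L, contig = 1L, locus_id = NULL,
                          in_cluster = NA_character_) {
  lesion <- match.arg(lesion)
  stopifnot(inherits(genome, "genome_record"))
  ci <- contig_index(genome, contig)
  contig_id <- genome$contigs$id[ci]
  contig_seq <- genome$contigs$seq[ci]
  Lc <- nchar(contig_seq)
  L <- nchar(protein)
  if (L < 30L) stop("protein too short to implant")
  locus_id <- locus_id %||%
    sprintf("%s_nat%02d", genome$replicon_id, length(genome$implants) + 1L)
  sseed <- split_seed(seed, "implant", locus_id)
  orf <- back_translate(protein, seed = sseed)        # 3L + 3 nt incl. stop
  pad_n <- 6L
  W <- 3L * L + 3L + pad_n
  partial_5p <- FALSE; partial_3p <- FALSE
  prod_protein <- protein

  # content: coding-orientation window sequence; segs: list of
  # (off_start, off_end) coding-orientation offsets of product codons
  if (lesion == "none") {
    pad <- with_seed(sseed + 1L, paste(sample(c("A", "C", "G", "T"), pad_n,
                                              replace = TRUE), collapse = ""))
    content <- paste0(orf, pad)
    segs <- list(c(0L, 3L * L))
  } else if (lesion %in% c("frameshift_del1", "frameshift_ins1")) {
    # lesion band sits downstream of the motif block so that frameshifted
    # pseudogenes remain motif-recognisable, as the annotated ones are
    lo <- max(3L, floor(0.55 * 3 * L)); hi <- min(3L * L - 4L, floor(0.85 * 3 * L))
    d <- with_seed(sseed + 2L, sample(lo:hi, 1L))
    k <- d %/% 3L                                    # intact upstream codons
    if (lesion == "frameshift_del1") {
      mutated <- paste0(substr(orf, 1L, d), substr(orf, d + 2L, nchar(orf)))
      segs <- list(c(0L, 3L * k), c(3L * k + 2L, 3L * L - 1L))
    } else {
      ins <- with_seed(sseed + 3L, sample(c("A", "C", "G", "T"), 1L))
      mutated <- paste0(substr(orf, 1L, d), ins,
                        substr(orf, d + 1L, nchar(orf)))
      segs <- list(c(0L, 3L * k), c(3L * k + 4L, 3L * L + 1L))
    }
    fill <- W - nchar(mutated)
    pad <- with_seed(sseed + 4L, paste(sample(c("A", "C", "G", "T"), fill,
                                              replace = TRUE), collapse = ""))
    content <- paste0(mutated, pad)
    prod_protein <- paste0(substr(protein, 1L, k),
                           substr(protein, k + 2L, L))  # codon k+1 lost
  } else {
    u <- with_seed(sseed + 5L, stats::runif(1, 0.2, 0.4))
    k <- as.integer(ceiling(u * L))                    # codons clipped
    if (lesion == "truncation_5p") {
      content <- substr(orf, 3L * k + 1L, nchar(orf))  # no start, has stop
      segs <- list(c(0L, 3L * (L - k)))
      prod_protein <- substr(protein, k + 1L, L)
      partial_5p <- TRUE
      position <- if (strand == "+") 0L else Lc - nchar(content)
    } else {
      content <- substr(orf, 1L, 3L * (L - k))         # has start, no stop
      segs <- list(c(0L, 3L * (L - k)))
      prod_protein <- substr(protein, 1L, L - k)
      partial_3p <- TRUE
      position <- if (strand == "+") Lc - nchar(content) else 0L
    }
    W <- nchar(content)
  }

  position <- as.integer(position)
  if (position < 0L || position + W > Lc)
    stop("implant does not fit at the requested position")
  check_no_overlap(genome, contig_id, position, position + W, locus_id)

  written <- if (strand == "+") content else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(content)))
  genome$contigs$seq[ci] <- overwrite_seq(contig_seq, position, written)

  seg_df <- do.call(rbind, lapply(segs, function(s) {
    if (strand == "+") {
      st <- position + s[1]; en <- position + s[2]
    } else {
      st <- position + W - s[2]; en <- position + W - s[1]
    }
    data.frame(start = st, end = en,
               frame = frame_of(st, en, strand, Lc))
  }))
  # order segments 5'->3' on the coding strand
  seg_df <- seg_df[order(if (strand == "+") seg_df$start else -seg_df$start), ,
                   drop = FALSE]
  rownames(seg_df) <- NULL

  entry <- list(locus_id = locus_id, contig = contig_id, segments = seg_df,
                strand = strand, lesion = lesion, in_cluster = in_cluster,
                seed_protein_id = "nat_ref", protein = prod_protein,
                partial_5p = partial_5p, partial_3p = partial_3p,
                window = c(position, position + W))
  genome$implants[[locus_id]] <- entry
  list(genome = genome, entry = entry)
}

random_protein <- function(n, seed) {
  aa <- strsplit("ACDEFGHIKLNPQRSTVWY", "")[[1]]  # no M internally
  with_seed(seed, paste0("M", paste(sample(aa, n - 1L, replace = TRUE),
                                    collapse = "")))
}

#' Implant a BGC-like gene neighborhood around a NAT locus
#'
#' Writes `n_flank_genes` random ORFs (0.3--3 kb) plus one NAT-like ORF (at
#' ordinal `nat_position`) into the genome, non-overlapping with >= 50 bp
#' intergenic gaps, and returns a feature table containing the gene features
#' (with `locus_tag` and `translation` qualifiers) and one `protocluster`
#' feature spanning all implanted genes with qualifier
#' `category = cluster_type`. With `nat_position = n_flank_genes + 1` the NAT
#' gene is the last gene of the cluster, the layout seen in ansamycin core
#' BGCs where the amide-synthase gene closes the cluster.
#'
#' @param genome a `genome_record`.
#' @param n_flank_genes number of non-NAT genes.
#' @param cluster_type label stored in the protocluster `category` qualifier
#'   (e.g. `"T1PKS"`, `"NRPS"`, `"terpene"`).
#' @param nat_position 1-based ordinal of the NAT gene within the cluster.
#' @param seed integer seed.
#' @param contig contig id or index.
#' @param at 0-based start of the cluster (seeded when `NULL`).
#' @param extend_span extra bases added to each side of the protocluster
#'   feature span (used to construct overlapping protoclusters).
#' @param nat_protein protein implanted as the NAT gene.
#' @param nat_lesion lesion passed to [implant_locus()] for the NAT gene.
#' @param cluster_id protocluster identifier (auto when `NULL`).
#' @return `list(genome = updated genome_record, features = feature_table)`.
#' @export
implant_cluster <- function(genome, n_flank_genes, cluster_type = "T1PKS",
                            nat_position = n_flank_genes + 1L, seed = 1L,
                            contig = 1L, at = NULL, extend_span = 0L,
                            nat_protein = nat_reference_protein(),
                            nat_lesion = "none", cluster_id = NULL) {
  stopifnot(inherits(genome, "genome_record"))
  n_genes <- n_flank_genes + 1L
  stopifnot(nat_position >= 1L, nat_position <= n_genes)
  ci <- contig_index(genome, contig)
  contig_id <- genome$contigs$id[ci]
  Lc <- nchar(genome$contigs$seq[ci])
  cluster_id <- cluster_id %||%
    sprintf("%s_bgc%02d", genome$replicon_id,
            sum(genome$features$kind == "protocluster") + 1L)
  sseed <- split_seed(seed, "cluster", cluster_id)
  aa_lens <- with_seed(sseed, sample(100:1000, n_flank_genes, replace = TRUE))
  gaps <- with_seed(sseed + 1L, sample(50:200, n_genes, replace = TRUE))
  gene_lens <- integer(n_genes)
  gene_lens[nat_position] <- 3L * nchar(nat_protein) + 3L + 6L  # implant window
  gene_lens[-nat_position] <- 3L * aa_lens + 3L
  total <- sum(gene_lens) + sum(gaps[-1L])
  if (is.null(at))
    at <- with_seed(sseed + 2L, sample.int(max(1L, Lc - total - 100L), 1L)) - 1L
  if (at + total > Lc) stop("insufficient space for cluster on ", contig_id)

  pos <- at
  feats <- list()
  nat_entry <- NULL
  j <- 0L
  for (g in seq_len(n_genes)) {
    if (g > 1L) pos <- pos + gaps[g]
    if (g == nat_position) {
      res <- implant_locus(genome, nat_protein, position = pos,
                           strand = "+", lesion = nat_lesion,
                           seed = split_seed(sseed, "natgene", g),
                           contig = ci, in_cluster = cluster_id)
      genome <- res$genome
      nat_entry <- res$entry
      feats[[g]] <- data.frame(start = pos, end = pos + gene_lens[g],
                               strand = "+", tag = res$entry$locus_id,
                               translation = res$entry$protein,
                               stringsAsFactors = FALSE)
    } else {
      j <- j + 1L
      prot <- random_protein(aa_lens[j], split_seed(sseed, "flankprot", g))
      orf <- back_translate(prot, seed = split_seed(sseed, "flankorf", g))
      strand <- with_seed(split_seed(sseed, "flankstrand", g),
                          sample(c("+", "-"), 1L))
      written <- if (strand == "+") orf else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(orf)))
      check_no_overlap(genome, contig_id, pos, pos + nchar(orf),
                       paste0(cluster_id, " gene ", g))
      genome$contigs$seq[ci] <- overwrite_seq(genome$contigs$seq[ci], pos,
                                              written)
      feats[[g]] <- data.frame(start = pos, end = pos + nchar(orf),
                               strand = strand,
                               tag = sprintf("%s_g%02d", cluster_id, g),
                               translation = prot, stringsAsFactors = FALSE)
    }
    pos <- pos + gene_lens[g]
  }
  fdf <- do.call(rbind, feats)
  span <- c(max(0L, min(fdf$start) - extend_span),
            min(Lc, max(fdf$end) + extend_span))
  quals <- c(lapply(seq_len(nrow(fdf)), function(i) {
    q <- c(locus_tag = fdf$tag[i], translation = fdf$translation[i])
    if (!is.null(nat_entry) && fdf$tag[i] == nat_entry$locus_id)
      q <- c(q, gene = "NAT")
    q
  }), list(c(cluster_id = cluster_id, category = cluster_type)))
  ft <- feature_table(contig = rep(contig_id, n_genes + 1L),
                      start = c(fdf$start, span[1]),
                      end = c(fdf$end, span[2]),
                      strand = c(fdf$strand, "+"),
                      kind = c(rep("gene", n_genes), "protocluster"),
                      qualifiers = quals)
  genome$features <- feature_table(
    contig = c(genome$features$contig, ft$contig),
    start = c(genome$features$start, ft$start),
    end = c(genome$features$end, ft$end),
    strand = c(genome$features$strand, ft$strand),
    kind = c(genome$features$kind, ft$kind),
    qualifiers = c(genome$features$qualifiers, ft$qualifiers))
  list(genome = genome, features = ft)
}

#' Implant a GC-deviant island
#'
#' Resamples the interval i.i.d. at `island_gc`, emulating a horizontally
#' acquired segment of atypical composition. Ground truth is appended to the
#' genome's `islands` manifest; islands may not overlap each other or
#' existing implants.
#'
#' @param genome a `genome_record`.
#' @param start 0-based start of the island.
#' @param length island length in bases.
#' @param island_gc GC fraction of the island, in (0, 1).
#' @param seed integer seed.
#' @param contig contig id or index.
#' @return The updated `genome_record`.
#' @export
implant_gc_island <- function(genome, start, length, island_gc, seed = 1L,
                              contig = 1L) {
  stopifnot(inherits(genome, "genome_record"))
  if (island_gc <= 0 || island_gc >= 1) stop("island_gc must be inside (0, 1)")
  ci <- contig_index(genome, contig)
  contig_id <- genome$contigs$id[ci]
  Lc <- nchar(genome$contigs$seq[ci])
  start <- as.integer(start); length <- as.integer(length)
  if (start < 0L || start + length > Lc)
    stop("island out of bounds on ", contig_id)
  check_no_overlap(genome, contig_id, start, start + length, "island")
  probs <- c(A = (1 - island_gc) / 2, C = island_gc / 2,
             G = island_gc / 2, T = (1 - island_gc) / 2)
  isl <- with_seed(split_seed(seed, "island", paste(contig_id, start)),
                   paste(sample(names(probs), length, replace = TRUE,
                                prob = probs), collapse = ""))
  genome$contigs$seq[ci] <- overwrite_seq(genome$contigs$seq[ci], start, isl)
  genome$islands <- rbind(genome$islands,
                          data.frame(contig = contig_id, start = start,
                                     end = start + length, gc = island_gc,
                                     stringsAsFactors = FALSE))
  genome
}

#' Evolve a protein family from a seed sequence
#'
#' Each site substitutes independently along each branch with probability
#' \eqn{1 - \exp(-\mathrm{rate} \times \mathrm{branch\ length})}, uniformly
#' among the other 19 residues (a Jukes-Cantor-style protein model). Without
#' a guide tree, a star tree of unit branches over `n_taxa` tips is used.
#'
#' @param seed_protein the ancestral amino-acid string.
#' @param n_taxa number of tips (ignored when `guide_tree` is given).
#' @param rate expected substitutions per site per unit branch length
#'   (`>= 0`).
#' @param guide_tree optional `ape::phylo` with branch lengths; its tip
#'   labels become the sequence identifiers.
#' @param seed integer seed.
#' @return A protein [seq_set()] with the guide tree attached as attribute
#'   `"tree"`.
#' @export
evolve_family <- function(seed_protein, n_taxa = 8L, rate = 0.05,
                          guide_tree = NULL, seed = 1L) {
  stopifnot(rate >= 0, nchar(seed_protein) >= 1L)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mutate <- function(s, bl, eseed) {
    p <- 1 - exp(-rate * bl)
    if (p == 0) return(s)
    res <- strsplit(s, "")[[1]]
    with_seed(eseed, {
      hit <- stats::runif(length(res)) < p
      if (any(hit))
        res[hit] <- vapply(res[hit], function(a)
          sample(setdiff(aa, a), 1L), character(1))
    })
    paste(res, collapse = "")
  }
  if (is.null(guide_tree)) {
    if (n_taxa < 2L) stop("n_taxa must be >= 2")
    labs <- sprintf("t%02d", seq_len(n_taxa))
    seqs <- vapply(seq_len(n_taxa), function(i)
      mutate(seed_protein, 1, split_seed(seed, "evolve", labs[i])),
      character(1))
    tree <- ape::stree(n_taxa, type = "star", tip.label = labs)
    tree$edge.length <- rep(1, nrow(tree$edge))
  } else {
    tree <- guide_tree
    stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
    n_tip <- length(tree$tip.label)
    node_seq <- vector("character", n_tip + tree$Nnode)
    root <- n_tip + 1L
    node_seq[root] <- seed_protein
    # edges of a phylo object are ordered parent-before-child via reorder
    eo <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(eo$edge))) {
      par <- eo$edge[e, 1]; child <- eo$edge[e, 2]
      node_seq[child] <- mutate(node_seq[par], eo$edge.length[e],
                                split_seed(seed, "evolve", e))
    }
    labs <- tree$tip.label
    seqs <- node_seq[seq_len(n_tip)]
  }
  out <- seq_set(labs, seqs, alphabet = "protein")
  attr(out, "tree") <- tree
  out
}
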