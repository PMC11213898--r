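ref_set <- function() {
  seq_set("nat_ref", nat_reference_protein(), desc = "bacterial reference",
          alphabet = "protein")
}

test_that("a lesion-free locus reconstructs to the implanted protein exactly", {
  p <- nat_reference_protein()
  g <- generate_genome(20000, seed = 42)
  res <- implant_locus(g, p, position = 5000, strand = "+", seed = 7)
  hits <- translated_genome_search(p, res$genome)
  loc <- reconstruct_orf(hits, res$genome)
  expect_equal(nrow(loc$segments), 1L)
  expect_identical(loc$protein, p)
  expect_false(loc$partial_5p || loc$partial_3p)
  # protein length == sum of segment codon counts
  expect_equal(nchar(loc$protein),
               sum((loc$segments$end - loc$segments$start) %/% 3L))
})

test_that("frameshift loci reconstruct as two segments close to the truth", {
  p <- nat_reference_protein()
  g <- generate_genome(20000, seed = 42)
  for (lesion in c("frameshift_del1", "frameshift_ins1"))
    for (strand in c("+", "-")) {
      res <- implant_locus(g, p, position = 5000, strand = strand,
                           lesion = lesion, seed = 9)
      hits <- translated_genome_search(p, res$genome)
      loc <- reconstruct_orf(hits, res$genome)
      expect_equal(nrow(loc$segments), 2L)
      # consecutive segment frames differ
      expect_false(loc$segments$frame[1] == loc$segments$frame[2])
      expect_lte(c(adist(loc$protein, res$entry$protein)), 2)
    }
})

test_that("contig-edge truncations set partial flags", {
  p <- nat_reference_protein()
  g <- generate_genome(20000, seed = 42)
  r3 <- implant_locus(g, p, position = 0, strand = "+",
                      lesion = "truncation_3p", seed = 5)
  hits <- translated_genome_search(p, r3$genome)
  loc <- reconstruct_orf(hits, r3$genome)
  expect_true(loc$partial_3p)
  r5 <- implant_locus(g, p, position = 0, strand = "+",
                      lesion = "truncation_5p", seed = 4)
  hits5 <- translated_genome_search(p, r5$genome)
  loc5 <- reconstruct_orf(hits5, r5$genome)
  expect_true(loc5$partial_5p)
})

test_that("reconstruct_orf rejects invalid hit sets", {
  g <- generate_genome(5000, seed = 1)
  expect_error(reconstruct_orf(data.frame(), g), "no hits")
  bad <- data.frame(contig = c("a", "b"), strand = c("+", "+"),
                    gstart = c(0L, 0L), gend = c(30L, 30L),
                    identity = c(100, 100))
  expect_error(reconstruct_orf(bad, g), "multiple contigs")
})

test_that("motif scan finds constructed exact motifs at analytic positions", {
  prot <- paste0("XXX", "VPFENL", "XXX", "RGGYC", "XXX", "THRL", "XXX",
                 "VDV", "XXX")
  mh <- scan_motifs(prot)
  expect_equal(mh$position, c(3L, 12L, 20L, 27L))
  expect_equal(mh$score_fraction, rep(1, 4))
  expect_equal(mh$catalytic_pos, c(NA, 16L, 21L, 28L))
  expect_equal(mh$catalytic_residue, c(NA, "C", "H", "D"))
  expect_equal(verify_triad(mh), "canonical_CHD")
})

test_that("scrambled motif order cannot produce four compatible hits", {
  prot <- paste0("XXX", "VDV", "XXX", "RGGYC", "XXX", "THRL", "XXX",
                 "VPFENL", "XXX")
  mh <- scan_motifs(prot)
  expect_lt(sum(!is.na(mh$position)), 4L)
  # reported positions are strictly increasing
  pos <- mh$position[!is.na(mh$position)]
  expect_true(all(diff(pos) > 0))
})

test_that("a conservative substitution keeps the motif with the oracle's score", {
  prot <- paste0("XXX", "VPYENL", "XXX", "RGGYC", "XXX", "THRL", "XXX",
                 "VDV", "XXX")
  mh <- scan_motifs(prot, min_score_fraction = 0.6)
  expect_equal(mh$position[1], 3L)
  # exhaustive window-scoring oracle for M1
  mat <- blosum62_matrix()
  cons <- strsplit("VPFENL", "")[[1]]
  res <- strsplit(prot, "")[[1]]
  scores <- vapply(0:(length(res) - 6), function(p)
    sum(mat[cbind(cons, res[(p + 1):(p + 6)])]), numeric(1))
  self <- sum(mat[cbind(cons, cons)])
  expect_equal(mh$score_fraction[1], max(scores) / self)
})

test_that("triad status distinguishes canonical, variant and incomplete", {
  canonical <- paste0("XXX", "VPFENL", "X", "RGGYC", "X", "THRL", "X", "VDV")
  expect_equal(verify_triad(scan_motifs(canonical)), "canonical_CHD")
  # Glu-for-Asp variant, the known functional deviation
  variant <- sub("VDV", "VEV", canonical)
  expect_equal(verify_triad(scan_motifs(variant)), "variant_CHE")
  # catalytic Cys mutated away: M2 cannot hit
  noc <- sub("RGGYC", "RGGYA", canonical)
  expect_equal(verify_triad(scan_motifs(noc)), "incomplete")
  none <- random_protein_str(60, seed = 3)
  expect_true(verify_triad(scan_motifs(none)) %in% c("absent", "incomplete"))
})

test_that("random proteins do not pass the motif screen", {
  n_full <- 0L
  for (r in 1:25) {
    mh <- scan_motifs(random_protein_str(300, seed = 9000 + r))
    if (sum(!is.na(mh$position)) >= 3L &&
        verify_triad(mh) != "absent") n_full <- n_full + 1L
  }
  expect_equal(n_full, 0L)
})

test_that("classification and naming follow identity and lesion state", {
  p <- nat_reference_protein()
  g <- generate_genome(40000, seed = 13)
  r1 <- implant_locus(g, p, position = 5000, seed = 1)
  hits <- translated_genome_search(p, r1$genome)
  loc <- reconstruct_orf(hits, r1$genome, locus_id = "L1")
  ann <- classify_and_name(loc, ref_set())
  expect_equal(ann$classification, "intact")
  expect_equal(ann$best_identity, 100)
  expect_equal(ann$assigned_symbol, "NAT1")

  # frameshifted homologue still receives a symbol
  r2 <- implant_locus(g, p, position = 5000, lesion = "frameshift_del1",
                      seed = 2)
  h2 <- translated_genome_search(p, r2$genome)
  loc2 <- reconstruct_orf(h2, r2$genome, locus_id = "L2")
  ann2 <- classify_and_name(loc2, ref_set())
  expect_equal(ann2$classification, "frameshifted_pseudogene")
  expect_match(ann2$assigned_symbol, "^NAT")
})

test_that("paralogs are numbered by descending identity within a species", {
  p <- nat_reference_protein()
  g <- generate_genome(40000, seed = 17)
  r1 <- implant_locus(g, p, position = 25000, seed = 1)            # 100%
  div <- mutate_protein(p, 0.30, seed = 5)                          # ~70%
  r2 <- implant_locus(r1$genome, div, position = 5000, seed = 2)
  hits <- translated_genome_search(p, r2$genome, min_identity = 25)
  groups <- group_hits(hits)
  loci <- lapply(seq_along(groups), function(i)
    reconstruct_orf(groups[[i]], r2$genome, locus_id = paste0("L", i)))
  ann <- classify_and_name(loci, ref_set())
  expect_equal(nrow(ann), 2L)
  top <- ann[ann$assigned_symbol == "NAT1", ]
  second <- ann[ann$assigned_symbol == "NAT2", ]
  expect_gt(top$best_identity, second$best_identity)

  # permutation invariance: shuffling locus order never changes symbols
  ann_r <- classify_and_name(rev(loci), ref_set())
  m <- merge(ann[, c("locus_id", "assigned_symbol")],
             ann_r[, c("locus_id", "assigned_symbol")], by = "locus_id")
  expect_equal(m$assigned_symbol.x, m$assigned_symbol.y)
})

test_that("non-NAT proteins are classified non_nat with no symbol", {
  # a random protein similar to nothing, forced through the classifier
  loc <- structure(list(locus_id = "junk", contig = "c1", strand = "+",
                        segments = data.frame(start = 0L, end = 900L,
                                              frame = 1L),
                        protein = random_protein_str(300, seed = 77),
                        partial_5p = FALSE, partial_3p = FALSE),
                   class = "nat_locus")
  ann <- classify_and_name(loc, ref_set())
  expect_equal(ann$classification, "non_nat")
  expect_equal(ann$assigned_symbol, "")
})

test_that("classify_and_name requires references", {
  loc <- structure(list(locus_id = "x", contig = "c", strand = "+",
                        segments = data.frame(start = 0L, end = 90L,
                                              frame = 1L),
                        protein = nat_reference_protein(),
                        partial_5p = FALSE, partial_3p = FALSE),
                   class = "nat_locus")
  empty_refs <- seq_set(character(), character(), alphabet = "protein")
  expect_error(classify_and_name(loc, empty_refs))
})
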