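test_that("genome generation is deterministic and conserves length", {
  g1 <- generate_genome(10000, gc = 0.5, seed = 42)
  g2 <- generate_genome(10000, gc = 0.5, seed = 42)
  expect_identical(g1$contigs$seq, g2$contigs$seq)
  expect_identical(g1$taxon, g2$taxon)
  g3 <- generate_genome(10000, gc = 0.5, seed = 43)
  expect_false(identical(g1$contigs$seq, g3$contigs$seq))

  gm <- generate_genome(10001, gc = 0.5, n_contigs = 3, seed = 1)
  expect_equal(nrow(gm$contigs), 3L)
  expect_equal(sum(nchar(gm$contigs$seq)), 10001L)

  expect_error(generate_genome(10000, gc = 1.2, seed = 1), "gc")
  expect_error(generate_genome(1500, n_contigs = 2, seed = 1), "1 kb")
})

test_that("generated GC content concentrates at the requested fraction", {
  g <- generate_genome(1e6, gc = 0.7, seed = 5)
  obs <- mean(strsplit(g$contigs$seq, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(obs - 0.7), 0.01)
})

test_that("lesion-free implants back-translate and re-translate exactly", {
  p <- nat_reference_protein()
  g <- generate_genome(10000, seed = 2)
  res <- implant_locus(g, p, position = 3000, strand = "+", lesion = "none",
                       seed = 7)
  expect_equal(nrow(res$entry$segments), 1L)
  seg <- res$entry$segments
  sub <- substr(res$genome$contigs$seq[1], seg$start + 1L, seg$end)
  expect_equal(oracle_translate(sub), p)
  # conservation: genome length unchanged
  expect_equal(nchar(res$genome$contigs$seq[1]), 10000L)
})

test_that("frameshift lesions produce two frame-shifted segments", {
  p <- nat_reference_protein()
  g <- generate_genome(10000, seed = 2)
  for (lesion in c("frameshift_del1", "frameshift_ins1")) {
    res <- implant_locus(g, p, position = 3000, strand = "+", lesion = lesion,
                         seed = 11)
    segs <- res$entry$segments
    expect_equal(nrow(segs), 2L)
    expect_false(segs$frame[1] == segs$frame[2])
    # naive single-frame translation of the full lesioned region hits a
    # premature stop
    naive <- oracle_translate(substr(res$genome$contigs$seq[1],
                                     segs$start[1] + 1L, max(segs$end)))
    expect_true(grepl("\\*", naive))
    # ground-truth product: original protein minus the lesion codon
    joined <- paste0(
      oracle_translate(substr(res$genome$contigs$seq[1], segs$start[1] + 1L,
                              segs$end[1])),
      oracle_translate(substr(res$genome$contigs$seq[1], segs$start[2] + 1L,
                              segs$end[2])))
    expect_equal(joined, res$entry$protein)
    expect_equal(nchar(res$entry$protein), nchar(p) - 1L)
  }
})

test_that("truncation lesions clip at least 20% and sit at the contig edge", {
  p <- nat_reference_protein()
  g <- generate_genome(10000, seed = 2)
  r5 <- implant_locus(g, p, position = 3000, strand = "+",
                      lesion = "truncation_5p", seed = 3)
  expect_true(r5$entry$partial_5p)
  expect_false(r5$entry$partial_3p)
  expect_equal(r5$entry$segments$start[1], 0L)
  expect_lte(nchar(r5$entry$protein), 0.8 * nchar(p))

  r3 <- implant_locus(g, p, position = 3000, strand = "+",
                      lesion = "truncation_3p", seed = 3)
  expect_true(r3$entry$partial_3p)
  expect_equal(r3$entry$segments$end[1], 10000L)
  expect_lte(nchar(r3$entry$protein), 0.8 * nchar(p))
})

test_that("overlapping implants are rejected", {
  p <- nat_reference_protein()
  g <- generate_genome(10000, seed = 2)
  res <- implant_locus(g, p, position = 3000, seed = 7)
  expect_error(implant_locus(res$genome, p, position = 3200, seed = 8),
               "overlap")
})

test_that("implanted clusters have a spanning protocluster and gapped genes", {
  g <- generate_genome(60000, seed = 21)
  rc <- implant_cluster(g, n_flank_genes = 5, cluster_type = "T1PKS",
                        nat_position = 6, seed = 2, at = 5000)
  ft <- rc$features
  genes <- ft[ft$kind == "gene", ]
  pc <- ft[ft$kind == "protocluster", ]
  expect_equal(nrow(genes), 6L)
  expect_equal(nrow(pc), 1L)
  expect_equal(pc$qualifiers[[1]][["category"]], "T1PKS")
  # span covers the union of its genes
  expect_equal(pc$start, min(genes$start))
  expect_equal(pc$end, max(genes$end))
  # NAT is the last gene (amide-synthase-at-cluster-end layout)
  nat_tag <- vapply(genes$qualifiers, function(q)
    "gene" %in% names(q) && q[["gene"]] == "NAT", logical(1))
  expect_equal(which(nat_tag), 6L)
  # >= 50 bp intergenic gaps, non-overlapping
  o <- order(genes$start)
  expect_true(all(diff(genes$start[o]) > 0))
  expect_true(all(genes$start[o][-1] - genes$end[o][-6] >= 50L))
})

test_that("overlapping protocluster features can be constructed", {
  g <- generate_genome(80000, seed = 30)
  r1 <- implant_cluster(g, n_flank_genes = 2, cluster_type = "NRPS",
                        seed = 4, at = 5000, extend_span = 600L)
  span1 <- r1$features[r1$features$kind == "protocluster", ]
  r2 <- implant_cluster(r1$genome, n_flank_genes = 2, cluster_type = "terpene",
                        seed = 5, at = span1$end + 100L, extend_span = 600L,
                        cluster_id = "bgcB")
  both <- r2$genome$features[r2$genome$features$kind == "protocluster", ]
  expect_equal(nrow(both), 2L)
  expect_gt(overlap_len(both$start[1], both$end[1], both$start[2], both$end[2]),
            0L)
})

test_that("GC islands are implanted at the requested composition", {
  g <- generate_genome(100000, gc = 0.60, seed = 8)
  g <- implant_gc_island(g, 40000, 10000, 0.30, seed = 9)
  isl <- substr(g$contigs$seq[1], 40001, 50000)
  obs <- mean(strsplit(isl, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(obs - 0.30), 0.02)
  expect_equal(nrow(g$islands), 1L)

  g <- implant_gc_island(g, 70000, 5000, 0.35, seed = 10)
  expect_equal(nrow(g$islands), 2L)
  expect_error(implant_gc_island(g, 42000, 2000, 0.3, seed = 1), "overlap")
  expect_error(implant_gc_island(g, 99000, 5000, 0.3, seed = 1), "bounds")
})

test_that("family evolution is deterministic, rate-0 exact, and MC-calibrated", {
  p <- nat_reference_protein()
  f0 <- evolve_family(p, n_taxa = 4, rate = 0, seed = 1)
  expect_true(all(f0$seq == p))

  f1 <- evolve_family(p, n_taxa = 6, rate = 0.1, seed = 9)
  f2 <- evolve_family(p, n_taxa = 6, rate = 0.1, seed = 9)
  expect_identical(f1$seq, f2$seq)

  # mean pairwise p-distance vs an independent per-site Monte-Carlo oracle
  # (star tree, unit branches): two lineages differ at a site unless both
  # kept the ancestral residue or both substituted to the same residue
  rate <- 0.08
  fam <- evolve_family(p, n_taxa = 10, rate = rate, seed = 33)
  mats <- do.call(rbind, strsplit(fam$seq, ""))
  pd <- c()
  for (i in 1:(nrow(mats) - 1)) for (j in (i + 1):nrow(mats))
    pd <- c(pd, mean(mats[i, ] != mats[j, ]))
  obs <- mean(pd)

  set.seed(101)
  psub <- 1 - exp(-rate)
  reps <- replicate(4000, {
    a <- stats::runif(1) < psub; b <- stats::runif(1) < psub
    if (!a && !b) FALSE
    else if (xor(a, b)) TRUE
    else sample(19, 1) != sample(19, 1)  # both substituted: differ unless same target
  })
  expected <- mean(reps)
  expect_lt(abs(obs - expected), 0.02)
})

test_that("guide-tree evolution respects the four-point condition in expectation", {
  p <- nat_reference_protein()
  tree <- ape::read.tree(text = "((A:0.3,B:0.3):0.15,(C:0.3,D:0.3):0.15);")
  ok <- 0L
  n_rep <- 60L
  for (r in seq_len(n_rep)) {
    fam <- evolve_family(p, guide_tree = tree, rate = 1, seed = 1000L + r)
    m <- do.call(rbind, strsplit(fam$seq, ""))
    rownames(m) <- fam$id
    dd <- function(x, y) mean(m[x, ] != m[y, ])
    s_ab <- dd("A", "B") + dd("C", "D")
    s_ac <- dd("A", "C") + dd("B", "D")
    s_ad <- dd("A", "D") + dd("B", "C")
    if (s_ab < s_ac && s_ab < s_ad) ok <- ok + 1L
  }
  # AB|CD is the true split; the smallest sum should identify it almost always
  expect_gte(ok / n_rep, 0.9)
})

test_that("seed splitting is stable and order-independent", {
  expect_identical(split_seed(5, "genome", "a"), split_seed(5, "genome", "a"))
  expect_false(split_seed(5, "genome", "a") == split_seed(5, "genome", "b"))
  expect_false(split_seed(5, "genome", "a") == split_seed(5, "island", "a"))
  s <- split_seed(2^40, "x", "y")
  expect_true(s >= 0 && s < 2^31)
})
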