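## Sequence similarity networks and neighbor-joining phylogenies.

# global center-star alignment of a set against its center sequence;
# returns a character matrix (rows = sequences, columns = MSA columns)
center_star_msa <- function(proteins, scoring = default_scoring()) {
  n <- nrow(proteins)
  if (any(nchar(proteins$seq) == 0L)) stop("zero-length sequence")
  if (n == 1L)
    return(matrix(strsplit(proteins$seq, "")[[1]], nrow = 1,
                  dimnames = list(proteins$id, NULL)))
  # center = sequence maximising summed pairwise global scores
  sc <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    al <- align_proteins(proteins$seq[i], proteins$seq[j], scoring = scoring,
                         mode = "global")
    sc[i, j] <- sc[j, i] <- al$score
  }
  center <- which.max(rowSums(sc))
  cseq <- proteins$seq[center]
  m <- nchar(cseq)
  others <- setdiff(seq_len(n), center)

  pair <- lapply(others, function(i) {
    al <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(proteins$seq[i]),
      subject = Biostrings::AAString(cseq),
      substitutionMatrix = get_submat(scoring),
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
      type = "global")
    list(p = strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]],
         s = strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]])
  })

  # "once a gap, always a gap": merge by center coordinates. ins[k] = max
  # number of inserted columns after center position k (k = 0 .. m)
  ins <- rep(0L, m + 1L)
  per_ins <- lapply(pair, function(pr) {
    cnt <- rep(0L, m + 1L)
    cpos <- 0L
    for (ch in pr$s) {
      if (ch == "-") cnt[cpos + 1L] <- cnt[cpos + 1L] + 1L
      else cpos <- cpos + 1L
    }
    cnt
  })
  for (cnt in per_ins) ins <- pmax(ins, cnt)

  ncol_msa <- m + sum(ins)
  msa <- matrix("-", nrow = n, ncol = ncol_msa,
                dimnames = list(proteins$id, NULL))
  # column index in the master MSA for center position k (1-based)
  col_of <- cumsum(ins[seq_len(m)] + 1L)  # center position k -> MSA column
  msa[center, col_of] <- strsplit(cseq, "")[[1]]
  for (t in seq_along(others)) {
    pr <- pair[[t]]; cnt <- per_ins[[t]]
    row <- rep("-", ncol_msa)
    cpos <- 0L; used_ins <- 0L
    for (a in seq_along(pr$s)) {
      if (pr$s[a] == "-") {
        used_ins <- used_ins + 1L
        # insertion block after center position cpos starts right before
        # col_of[cpos + 1] (or at column 1 when cpos == 0)
        base <- if (cpos == 0L) 0L else col_of[cpos]
        row[base + used_ins] <- pr$p[a]
      } else {
        cpos <- cpos + 1L
        used_ins <- 0L
        row[col_of[cpos]] <- pr$p[a]
      }
    }
    msa[others[t], ] <- row
  }
  msa
}

pdist_from_msa <- function(msa) {
  n <- nrow(msa)
  d <- matrix(0, n, n, dimnames = list(rownames(msa), rownames(msa)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    ok <- msa[i, ] != "-" & msa[j, ] != "-"
    d[i, j] <- d[j, i] <- if (!any(ok)) 1 else
      sum(msa[i, ok] != msa[j, ok]) / sum(ok)
  }
  d
}

#' Pairwise p-distance matrix via a center-star alignment
#'
#' A multiple alignment is built by globally aligning every sequence to the
#' center sequence (the one maximising summed pairwise scores) and merging
#' columns by center coordinates ("once a gap, always a gap"). The pairwise
#' p-distance is the fraction of differing residues over shared non-gap
#' columns -- the protein-distance default of the common NJ tools.
#'
#' @param proteins a protein [seq_set()] with at least 2 sequences.
#' @param scoring substitution matrix configuration.
#' @return A symmetric numeric matrix with zero diagonal, labelled by
#'   sequence id, with the alignment attached as attribute `"msa"`.
#' @export
distance_matrix <- function(proteins, scoring = default_scoring()) {
  stopifnot(inherits(proteins, "seq_set"), nrow(proteins) >= 2L)
  msa <- center_star_msa(proteins, scoring)
  d <- pdist_from_msa(msa)
  attr(d, "msa") <- msa
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (the standard implementation in
#' \pkg{ape}); negative branch-length estimates are clamped to zero and
#' flagged via the `"clamped"` attribute. NJ is exactly consistent on
#' additive matrices: for those, leaf-to-leaf path lengths reproduce the
#' input distances.
#'
#' @param d symmetric distance matrix with labels (2 taxa give the trivial
#'   single-edge tree).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12))
    stop("distance matrix must be symmetric")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 taxa")
  if (n == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%g,%s:%g);", rownames(d)[1],
                                        d[1, 2] / 2, rownames(d)[2], d[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  clamped <- any(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

# canonical keys for the non-trivial splits of an unrooted tree
tree_splits <- function(tree) {
  labs <- sort(tree$tip.label)
  n <- length(labs)
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- sort(tree$tip.label[p])
    if (length(side) <= 1L || length(side) >= n - 1L) next
    other <- setdiff(labs, side)
    a <- paste(side, collapse = ",")
    b <- paste(other, collapse = ",")
    keys <- c(keys, if (a < b) a else b)
  }
  unique(keys)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement `n_reps` times; each
#' replicate's p-distance matrix is re-run through [nj_tree()], and each
#' internal split of the original tree is supported by the percentage of
#' replicates containing it. Deterministic under `seed`.
#'
#' @param proteins a protein [seq_set()] with at least 4 sequences.
#' @param n_reps number of bootstrap replicates (published analyses
#'   conventionally use 1000).
#' @param seed integer seed.
#' @param scoring substitution matrix configuration.
#' @return The NJ tree with supports in `node.label` (root/trivial nodes
#'   get an empty label).
#' @export
bootstrap_nj <- function(proteins, n_reps = 1000L, seed = 1L,
                         scoring = default_scoring()) {
  stopifnot(inherits(proteins, "seq_set"), nrow(proteins) >= 4L)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  # canonicalise input order so that supports depend only on the data, not
  # on row order (NJ tie-breaking is order-sensitive on tied distances)
  alpha <- attr(proteins, "alphabet")
  proteins <- proteins[order(proteins$id), , drop = FALSE]
  attr(proteins, "alphabet") <- alpha
  msa <- center_star_msa(proteins, scoring)
  tree <- nj_tree(pdist_from_msa(msa))
  orig <- tree_splits(tree)
  hits <- stats::setNames(numeric(length(orig)), orig)
  nc <- ncol(msa)
  for (r in seq_len(n_reps)) {
    cols <- with_seed(split_seed(seed, "bootstrap", r),
                      sample.int(nc, nc, replace = TRUE))
    rt <- nj_tree(pdist_from_msa(msa[, cols, drop = FALSE]))
    rs <- tree_splits(rt)
    present <- orig %in% rs
    hits[present] <- hits[present] + 1
  }
  support <- 100 * hits / n_reps
  # attach supports as internal-node labels
  labs <- rep("", tree$Nnode)
  n_tip <- length(tree$tip.label)
  full <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)  # element nd describes node n_tip + nd
  for (nd in seq_len(tree$Nnode)) {
    tips <- sort(tree$tip.label[parts[[nd]]])
    if (length(tips) <= 1L || length(tips) >= n_tip - 1L) next
    other <- setdiff(full, tips)
    a <- paste(tips, collapse = ","); b <- paste(other, collapse = ",")
    key <- if (a < b) a else b
    if (key %in% names(support)) labs[nd] <- format(round(support[[key]], 1))
  }
  tree$node.label <- labs
  tree
}

#' Build a sequence similarity network
#'
#' All-vs-all local alignment with E-values against the total residue count;
#' an edge connects two proteins when the alignment score, defined as
#' \eqn{-\log_{10} E}, is at or above the threshold. The published analyses
#' use a threshold of 29 (E-value 1e-29). Connected components are recorded
#' as node attributes.
#'
#' @param proteins a protein [seq_set()]; record descriptions of the form
#'   `"taxon=...;cluster_type=..."` populate the node attributes.
#' @param threshold minimum \eqn{-\log_{10} E} for an edge (default 29).
#' @param scoring substitution matrix configuration.
#' @return An [edge_table()] whose node table carries `taxon`,
#'   `cluster_type` and `component`.
#' @export
build_ssn <- function(proteins, threshold = 29, scoring = default_scoring()) {
  stopifnot(inherits(proteins, "seq_set"), nrow(proteins) >= 2L)
  n <- nrow(proteins)
  db_res <- sum(nchar(proteins$seq))
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    al <- align_proteins(proteins$seq[i], proteins$seq[j], scoring = scoring)
    if (al$score <= 0) next
    e <- evalue(al$score, nchar(proteins$seq[i]), db_res)
    s <- -log10(e)
    if (s >= threshold)
      rows[[length(rows) + 1L]] <- data.frame(node_a = proteins$id[i],
                                              node_b = proteins$id[j],
                                              score = s,
                                              stringsAsFactors = FALSE)
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node_a = character(), node_b = character(), score = numeric(),
               stringsAsFactors = FALSE)
  parse_attr <- function(desc, key) {
    m <- regmatches(desc, regexec(paste0(key, "=([^;]*)"), desc))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
           character(1))
  }
  nodes <- data.frame(id = proteins$id,
                      taxon = parse_attr(proteins$desc, "taxon"),
                      cluster_type = parse_attr(proteins$desc, "cluster_type"),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = nodes$id)
  comp <- igraph::components(g)$membership
  nodes$component <- unname(comp[nodes$id])
  out <- edge_table(edges, nodes)
  attr(out, "threshold") <- threshold
  out
}
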