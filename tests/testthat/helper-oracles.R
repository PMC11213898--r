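# Independent oracles used across the suite. These deliberately do not
# share code with the package implementation.

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

# Plain-R Gotoh affine-gap alignment oracle (three-state recurrence written
# out directly). Returns the optimal score only. gap of length k costs
# open + k * extend.
oracle_align_score <- function(query, subject, mode = c("local", "global"),
                               open = 11, extend = 1,
                               mat = blosum62_matrix()) {
  mode <- match.arg(mode)
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  m <- length(q); n <- length(s)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)   # ends in a match/mismatch
  X <- matrix(NEG, m + 1, n + 1)   # ends in a gap in subject (up move)
  Y <- matrix(NEG, m + 1, n + 1)   # ends in a gap in query (left move)
  M[1, 1] <- 0
  if (mode == "global") {
    for (i in 2:(m + 1)) X[i, 1] <- -(open + (i - 1) * extend)
    for (j in 2:(n + 1)) Y[1, j] <- -(open + (j - 1) * extend)
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      sub <- mat[q[i - 1], s[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sub
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
      if (mode == "local") {
        M[i, j] <- max(M[i, j], 0)
      }
    }
  }
  if (mode == "global") max(M[m + 1, n + 1], X[m + 1, n + 1], Y[m + 1, n + 1])
  else max(0, max(M), max(X), max(Y))
}

# per-codon translation oracle using the genetic code table directly
oracle_translate <- function(dna) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(dna) - nchar(dna) %% 3
  if (n <= 0) return("")
  codons <- substring(dna, seq(1, n, 3), seq(3, n, 3))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# brute-force interval overlap oracle (0-based half-open)
oracle_overlaps <- function(s1, e1, s2, e2) {
  min(e1, e2) - max(s1, s2) > 0
}

random_protein_str <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

random_dna_str <- function(n, seed, gc = 0.5) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# mutate a fraction of residues (uniform replacement) -- used to make
# diverged homologues with known expected identity
mutate_protein <- function(protein, fraction, seed) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  res <- strsplit(protein, "")[[1]]
  set.seed(seed)
  # keep the initial Met so mutants stay implantable
  idx <- sample(2:length(res), round(fraction * length(res)))
  res[idx] <- vapply(res[idx], function(a) sample(setdiff(aa, a), 1),
                     character(1))
  paste(res, collapse = "")
}
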