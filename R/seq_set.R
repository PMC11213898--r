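#' Ordered sets of named sequences
#'
#' `seq_set` is the package's container for DNA or protein sequence
#' collections: an ordered set of records, each with a unique identifier, an
#' optional free-text description, and an upper-case residue string. It is a
#' thin, validated layer over a plain data.frame so that FASTA round-trips
#' are exact; conversion to [Biostrings::XStringSet] is done internally where
#' alignment or translation is needed.
#'
#' @param id character vector of unique record identifiers (no whitespace).
#' @param seq character vector of residue strings.
#' @param desc character vector of descriptions (defaults to "").
#' @param alphabet `"dna"` or `"protein"`; `"auto"` guesses from residue
#'   content (sets consisting only of A/C/G/T/N and IUPAC ambiguity codes are
#'   taken as DNA).
#' @return An object of class `seq_set`: a data.frame with columns `id`,
#'   `desc`, `seq` and an `alphabet` attribute.
#' @examples
#' s <- seq_set(c("a", "b"), c("ACGT", "GATTACA"))
#' nchar(s$seq)
#' @export
seq_set <- function(id, seq, desc = NULL, alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  desc <- if (is.null(desc)) rep("", length(id)) else as.character(desc)
  stopifnot(length(seq) == length(id), length(desc) == length(id))
  dup <- id[duplicated(id)]
  if (length(dup) > 0L)
    stop("duplicate sequence identifier(s): ", paste(unique(dup), collapse = ", "))
  if (alphabet == "auto") alphabet <- guess_alphabet(seq)
  validate_alphabet(id, seq, alphabet)
  out <- data.frame(id = id, desc = desc, seq = seq, stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  class(out) <- c("seq_set", "data.frame")
  out
}

DNA_CHARS  <- "ACGTNRYSWKMBDHV-"
PROT_CHARS <- "ACDEFGHIKLMNPQRSTVWYXBZJU*-"

guess_alphabet <- function(seq) {
  chars <- unique(strsplit(paste(seq, collapse = ""), "")[[1]])
  if (length(chars) == 0L) return("dna")
  if (all(chars %in% strsplit("ACGTN-", "")[[1]])) "dna" else "protein"
}

validate_alphabet <- function(id, seq, alphabet) {
  legal <- if (alphabet == "dna") DNA_CHARS else PROT_CHARS
  pat <- paste0("[^", gsub("([*-])", "\\\\\\1", legal), "]")
  bad <- regexpr(pat, seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal %s residue '%s' in record '%s' at position %d",
                 alphabet, substr(seq[i], bad[i], bad[i]), id[i], bad[i]))
  }
  invisible(TRUE)
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set of %d %s sequence(s)\n", nrow(x), attr(x, "alphabet")))
  if (nrow(x) > 0L) {
    shown <- utils::head(x, 6L)
    cat(sprintf("  %-20s %6s  %s\n", shown$id, nchar(shown$seq),
                substr(shown$seq, 1L, 40L)), sep = "")
    if (nrow(x) > 6L) cat("  ...\n")
  }
  invisible(x)
}

#' Read a FASTA file into a `seq_set`
#'
#' Sequence lines are concatenated with whitespace stripped and case
#' normalised to upper. The first whitespace-delimited token of each header
#' is the identifier; the remainder is the description.
#'
#' @param path path to a FASTA file.
#' @param alphabet as in [seq_set()].
#' @return A [seq_set()].
#' @export
read_fasta <- function(path, alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(seq_set(character(), character(),
                   alphabet = if (alphabet == "auto") "dna" else alphabet))
  }
  x <- Biostrings::readBStringSet(path)
  headers <- names(x)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- gsub("\\s", "", as.character(x))
  seq_set(id, seqs, desc, alphabet = alphabet)
}

#' Write a `seq_set` to FASTA
#'
#' @param x a [seq_set()].
#' @param path output path.
#' @param width line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "seq_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    hdr <- if (nzchar(x$desc[i])) paste(x$id[i], x$desc[i]) else x$id[i]
    writeLines(paste0(">", hdr), con)
    s <- x$seq[i]
    if (nchar(s) > 0L) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}

# internal: seq_set -> AAStringSet / DNAStringSet
as_xstringset <- function(x) {
  stopifnot(inherits(x, "seq_set"))
  s <- stats::setNames(x$seq, x$id)
  if (attr(x, "alphabet") == "dna") Biostrings::DNAStringSet(s)
  else Biostrings::AAStringSet(s)
}
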