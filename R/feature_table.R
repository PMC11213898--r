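#' Genomic feature tables
#'
#' `feature_table` is the internal representation of gene/protocluster/island
#' annotations: a data.frame with 0-based half-open coordinates sorted by
#' (contig, start), plus a list-column of named-character qualifier vectors.
#' Coordinates are converted to the 1-based inclusive convention only at file
#' boundaries (GFF3, GenBank feature-table subset, TSV), and re-import
#' restores the original table.
#'
#' @param contig character vector of contig identifiers.
#' @param start,end integer vectors, 0-based half-open (`start < end`).
#' @param strand character vector, `"+"` or `"-"`.
#' @param kind feature kind: `gene`, `CDS`, `protocluster`, `island` or other.
#' @param qualifiers list of named character vectors (one per feature), or
#'   `NULL` for none.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(contig = character(), start = integer(),
                          end = integer(), strand = character(),
                          kind = character(), qualifiers = NULL) {
  n <- length(contig)
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == n, length(end) == n,
            length(strand) == n, length(kind) == n)
  if (is.null(qualifiers)) qualifiers <- rep(list(character()), n)
  stopifnot(length(qualifiers) == n)
  if (any(start >= end)) {
    i <- which(start >= end)[1L]
    stop(sprintf("feature %d has start >= end (%d >= %d)", i, start[i], end[i]))
  }
  if (any(start < 0L)) stop("negative start coordinate")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  out <- data.frame(contig = as.character(contig), start = start, end = end,
                    strand = as.character(strand), kind = as.character(kind),
                    stringsAsFactors = FALSE)
  out$qualifiers <- lapply(qualifiers, function(q) {
    q <- vapply(q, as.character, character(1))
    if (length(q) && (is.null(names(q)) || any(!nzchar(names(q)))))
      stop("qualifiers must be named")
    q
  })
  o <- order(out$contig, out$start, out$end)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table with %d feature(s) on %d contig(s)\n",
              nrow(x), length(unique(x$contig))))
  if (nrow(x)) print(utils::head(as.data.frame(x)[, 1:5], 10L))
  invisible(x)
}

qual_get <- function(ft, key) {
  vapply(ft$qualifiers, function(q) if (key %in% names(q)) q[[key]] else NA_character_,
         character(1))
}

#' Read an annotation file into a `feature_table`
#'
#' External 1-based inclusive coordinates are converted to the internal
#' 0-based half-open convention. Protocluster-typed features retain their
#' `category`/`product` qualifiers verbatim.
#'
#' @param path input file.
#' @param dialect one of `"gff3"`, `"genbank-ft"` (LOCUS/FEATURES subset of a
#'   GenBank flat file, as emitted by antiSMASH), or `"tsv"` (this package's
#'   own tabular dialect).
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, dialect = c("gff3", "genbank-ft", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(dialect,
         "gff3" = read_gff3_ft(path),
         "genbank-ft" = read_genbank_ft(path),
         "tsv" = read_tsv_ft(path))
}

#' Write a `feature_table`
#'
#' @param ft a [feature_table()].
#' @param path output file.
#' @param dialect as in [read_feature_table()].
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path, dialect = c("gff3", "genbank-ft", "tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ft, "feature_table"))
  switch(dialect,
         "gff3" = write_gff3_ft(ft, path),
         "genbank-ft" = write_genbank_ft(ft, path),
         "tsv" = write_tsv_ft(ft, path))
  invisible(path)
}

## ---- GFF3 (read via rtracklayer, the field-standard parser) ----

read_gff3_ft <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  skip <- c("source", "type", "score", "phase")
  keys <- setdiff(colnames(mc), skip)
  quals <- lapply(seq_along(gr), function(i) {
    q <- character()
    for (k in keys) {
      v <- mc[[k]][i]
      if (methods::is(v, "List") || is.list(v)) v <- unlist(v)
      v <- as.character(v)
      if (length(v) == 1L && !is.na(v)) q[[k]] <- v
      else if (length(v) > 1L) q[[k]] <- paste(v, collapse = ",")
    }
    q
  })
  st <- as.character(BiocGenerics::strand(gr))
  st[!st %in% c("+", "-")] <- "+"
  if (any(BiocGenerics::start(gr) - 1L >= BiocGenerics::end(gr)))
    stop("feature with start > end after coordinate conversion")
  feature_table(contig = as.character(GenomicRanges::seqnames(gr)),
                start = BiocGenerics::start(gr) - 1L,
                end = BiocGenerics::end(gr),
                strand = st, kind = as.character(mc$type),
                qualifiers = quals)
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  gsub("\t", "%09", x, fixed = TRUE)
}

write_gff3_ft <- function(ft, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(ft))) {
    q <- ft$qualifiers[[i]]
    attrs <- if (length(q))
      paste(paste0(gff3_escape(names(q)), "=", gff3_escape(unname(q))),
            collapse = ";")
    else "."
    writeLines(paste(ft$contig[i], "natminer", ft$kind[i],
                     ft$start[i] + 1L, ft$end[i], ".", ft$strand[i], ".",
                     attrs, sep = "\t"), con)
  }
}

## ---- GenBank feature-table subset (LOCUS/FEATURES/ORIGIN) ----
## antiSMASH region files are consumed for coordinates and qualifiers only,
## so a minimal flat-file subset is parsed; no installed package provides a
## GenBank feature parser.

read_genbank_ft <- function(path) {
  lines <- readLines(path)
  contig <- NA_character_
  recs <- list()
  in_features <- FALSE
  cur <- NULL
  flush <- function(cur, recs) { if (!is.null(cur)) recs[[length(recs) + 1L]] <- cur; recs }
  for (ln in lines) {
    if (grepl("^LOCUS\\s+", ln)) {
      contig <- strsplit(trimws(sub("^LOCUS\\s+", "", ln)), "\\s+")[[1]][1]
      in_features <- FALSE
    } else if (grepl("^FEATURES", ln)) {
      in_features <- TRUE
    } else if (grepl("^(ORIGIN|//)", ln)) {
      recs <- flush(cur, recs); cur <- NULL
      in_features <- FALSE
    } else if (in_features) {
      if (grepl("^\\s{5}\\S", ln)) {  # new feature line
        recs <- flush(cur, recs)
        parts <- strsplit(trimws(ln), "\\s+")[[1]]
        kind <- parts[1]; loc <- parts[2]
        strand <- if (grepl("^complement\\(", loc)) "-" else "+"
        loc <- gsub("complement\\(|\\)|<|>", "", loc)
        se <- as.integer(strsplit(loc, "\\.\\.")[[1]])
        cur <- list(contig = contig, start = se[1] - 1L, end = se[2],
                    strand = strand, kind = kind, qualifiers = character())
      } else if (grepl("^\\s{10,}/", ln) && !is.null(cur)) {
        kv <- sub("^\\s+/", "", ln)
        eq <- regexpr("=", kv, fixed = TRUE)
        if (eq > 0L) {
          key <- substr(kv, 1L, eq - 1L)
          val <- gsub('^"|"$', "", substr(kv, eq + 1L, nchar(kv)))
          cur$qualifiers[[key]] <- val
        } else {
          cur$qualifiers[[kv]] <- ""
        }
      }
    }
  }
  recs <- flush(cur, recs)
  if (!length(recs))
    return(feature_table())
  feature_table(contig = vapply(recs, `[[`, "", "contig"),
                start = vapply(recs, `[[`, 0L, "start"),
                end = vapply(recs, `[[`, 0L, "end"),
                strand = vapply(recs, `[[`, "", "strand"),
                kind = vapply(recs, `[[`, "", "kind"),
                qualifiers = lapply(recs, `[[`, "qualifiers"))
}

write_genbank_ft <- function(ft, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in unique(ft$contig)) {
    sub <- ft[ft$contig == ctg, , drop = FALSE]
    writeLines(sprintf("LOCUS       %s %d bp    DNA     linear", ctg,
                       max(sub$end)), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    for (i in seq_len(nrow(sub))) {
      loc <- sprintf("%d..%d", sub$start[i] + 1L, sub$end[i])
      if (sub$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-16s%s", sub$kind[i], loc), con)
      q <- sub$qualifiers[[i]]
      for (k in names(q))
        writeLines(sprintf("                     /%s=\"%s\"", k, q[[k]]), con)
    }
    writeLines("//", con)
  }
}

## ---- TSV dialect (qualifiers packed as key=value;key=value) ----

pack_quals <- function(qlist) {
  vapply(qlist, function(q) {
    if (!length(q)) return("")
    paste(paste0(names(q), "=", gff3_escape(unname(q))), collapse = ";")
  }, character(1))
}

unpack_quals <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(character())
    kv <- strsplit(s, ";", fixed = TRUE)[[1]]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    vals <- gsub("%3B", ";", gsub("%3D", "=", gsub("%2C", ",",
            gsub("%09", "\t", gsub("%26", "&", vals)))))
    vals <- gsub("%25", "%", vals)
    stats::setNames(vals, keys)
  })
}

read_tsv_ft <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  feature_table(contig = df$contig, start = as.integer(df$start) - 1L,
                end = as.integer(df$end), strand = df$strand, kind = df$kind,
                qualifiers = unpack_quals(df$qualifiers))
}

write_tsv_ft <- function(ft, path) {
  df <- data.frame(contig = ft$contig, start = ft$start + 1L, end = ft$end,
                   strand = ft$strand, kind = ft$kind,
                   qualifiers = pack_quals(ft$qualifiers),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
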