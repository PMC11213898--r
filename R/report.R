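## Survey aggregation and the bundled transcriptions of the published
## summary tables (plasmid census, fungal BGCs, plasmid BGCs, MIBiG hits).

FIXTURE_NAMES <- c("table1_fungal_bgc", "table2_plasmids", "table3_plasmid_bgc",
                   "table4_mibig", "genus_class_map")

#' Load a bundled survey fixture table
#'
#' The package ships verbatim transcriptions of the published survey
#' summary tables: `table1_fungal_bgc` (fungal NAT genes in BGCs),
#' `table2_plasmids` (per-genus plasmid census), `table3_plasmid_bgc`
#' (plasmid-borne NAT genes inside BGCs), `table4_mibig` (NAT genes in
#' experimentally characterised MIBiG clusters) and `genus_class_map`
#' (fungal genus to taxonomic class).
#'
#' @param name fixture name.
#' @return A data.frame; integer columns of the plasmid census are integer.
#' @export
load_fixture <- function(name) {
  if (!name %in% FIXTURE_NAMES)
    stop("unknown fixture '", name, "'; available: ",
         paste(FIXTURE_NAMES, collapse = ", "))
  path <- system.file("extdata", paste0(name, ".tsv"), package = "natminer")
  if (!nzchar(path)) stop("fixture file missing from installation: ", name)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (name == "table2_plasmids")
    for (col in c("n_species_strains", "n_plasmids", "n_nat_genes"))
      df[[col]] <- as.integer(df[[col]])
  df
}

#' Aggregate annotations and cluster memberships into a survey table
#'
#' Long format: one row per (locus, protocluster-membership) pair -- a locus
#' lying in the overlap of two protoclusters contributes two rows, matching
#' the membership rule -- and one row with `NA` cluster for loci outside any
#' protocluster. All survey counts are derived exactly from this table.
#'
#' @param annotations data.frame from [classify_and_name()] (needs
#'   `locus_id`, `assigned_symbol`, `classification`; a `species` column is
#'   used when present).
#' @param memberships data.frame with `locus_id`, `cluster_id`,
#'   `cluster_type` (zero rows allowed); every `locus_id` must exist in
#'   `annotations`.
#' @param taxa optional data.frame with `species` plus any taxon columns
#'   (e.g. `domain`, `phylum`, `class`, `genus`), joined by species.
#' @return A `survey_table` data.frame.
#' @export
aggregate_survey <- function(annotations, memberships = NULL, taxa = NULL) {
  if (nrow(annotations) == 0L) {
    out <- data.frame(locus_id = character(), species = character(),
                      symbol = character(), classification = character(),
                      cluster_id = character(), cluster_type = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("survey_table", "data.frame")
    return(out)
  }
  if (is.null(memberships))
    memberships <- data.frame(locus_id = character(), cluster_id = character(),
                              cluster_type = character(),
                              stringsAsFactors = FALSE)
  dangling <- setdiff(memberships$locus_id, annotations$locus_id)
  if (length(dangling))
    stop("membership references unknown locus id(s): ",
         paste(dangling, collapse = ", "))
  base <- data.frame(locus_id = annotations$locus_id,
                     species = if ("species" %in% names(annotations))
                       annotations$species else "sp1",
                     symbol = annotations$assigned_symbol,
                     classification = annotations$classification,
                     stringsAsFactors = FALSE)
  out <- merge(base, memberships[, intersect(names(memberships),
                                             c("locus_id", "cluster_id",
                                               "cluster_type"))],
               by = "locus_id", all.x = TRUE, sort = FALSE)
  if (!"cluster_id" %in% names(out)) out$cluster_id <- NA_character_
  if (!"cluster_type" %in% names(out)) out$cluster_type <- NA_character_
  if (!is.null(taxa)) out <- merge(out, taxa, by = "species", all.x = TRUE,
                                   sort = FALSE)
  out <- out[order(out$locus_id, out$cluster_id, na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("survey_table", "data.frame")
  out
}

#' Summary counts from a survey table
#'
#' @param survey a [aggregate_survey()] table.
#' @return List with `n_rows`, `n_loci`, `n_species` (distinct species with
#'   at least one locus), `n_clusters`, `loci_per_classification` and
#'   `clusters_per_type`.
#' @export
survey_counts <- function(survey) {
  uniq <- survey[!duplicated(survey$locus_id), , drop = FALSE]
  cl <- survey[!is.na(survey$cluster_id) & !duplicated(survey$cluster_id), ,
               drop = FALSE]
  list(n_rows = nrow(survey),
       n_loci = length(unique(survey$locus_id)),
       n_species = length(unique(survey$species)),
       n_clusters = length(unique(stats::na.omit(survey$cluster_id))),
       loci_per_classification = table(uniq$classification),
       clusters_per_type = table(cl$cluster_type))
}

#' Percentage of table rows falling in given groups
#'
#' Report percentages are conventionally displayed rounded to whole
#' percent; the full-precision value is returned and the rounded one is
#' attached as attribute `"display"`.
#'
#' @param table a data.frame (survey or fixture table).
#' @param group_column column to group on.
#' @param groups character vector of group values counted as "in".
#' @return Numeric percentage in `[0, 100]`.
#' @export
fraction_by_group <- function(table, group_column, groups) {
  if (!group_column %in% names(table))
    stop("no such column: ", group_column)
  if (nrow(table) == 0L) stop("empty table")
  pct <- 100 * sum(table[[group_column]] %in% groups) / nrow(table)
  attr(pct, "display") <- round(pct)
  pct
}
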