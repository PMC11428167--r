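#' Construct and validate a feature table
#'
#' A feature table is the central data container of the package: a taxa x
#' samples matrix of non-negative integer counts (OTU/ASV "gene counts"), with
#' unique taxon ids as row names and unique sample ids as column names.
#'
#' @param counts matrix-like object of non-negative integer counts with row
#'   (taxon) and column (sample) names.
#' @return An integer matrix of class \code{feature_table}.
#' @examples
#' ft <- feature_table(matrix(c(3, 5, 0, 2), 2, 2,
#'   dimnames = list(c("t1", "t2"), c("s1", "s2"))))
#' @export
feature_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  validate_feature_table(counts)
  storage.mode(counts) <- "integer"
  class(counts) <- c("feature_table", class(counts))
  counts
}

#' Validate feature-table invariants
#'
#' Checks the structural contract: non-negative integer entries, duplicate-free
#' taxon and sample ids, at least one taxon and one sample.  Errors name the
#' offending ids or cells.
#'
#' @param counts matrix to validate.
#' @return Invisibly \code{TRUE}; errors otherwise.
#' @export
validate_feature_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("feature table must be a numeric matrix")
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("feature table needs at least 1 taxon and 1 sample")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("feature table must carry taxon (row) and sample (column) names")
  dup_t <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_t))
    stop("duplicate taxon ids: ", paste(dup_t, collapse = ", "))
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    cell <- bad[1L, ]
    stop(sprintf(
      "invalid count %s at taxon '%s', sample '%s' (must be a non-negative integer)",
      format(counts[cell[1L], cell[2L]]),
      rownames(counts)[cell[1L]], colnames(counts)[cell[2L]]))
  }
  invisible(TRUE)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d taxa x %d samples, total count %.0f\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Read a feature table from tab-separated text
#'
#' Accepts either orientation: \code{"tsv_taxa_rows"} (first column taxon ids,
#' remaining columns samples) or \code{"tsv_samples_rows"} (first column sample
#' ids, remaining columns taxa).  The result is always normalized to the
#' canonical taxa x samples orientation.
#'
#' @param path path to a UTF-8 TSV file with a header row.
#' @param dialect orientation of the file.
#' @return A \code{\link{feature_table}}.
#' @export
read_feature_table <- function(path, dialect = c("tsv_taxa_rows", "tsv_samples_rows")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expected an id column plus at least one data column")
  ids <- as.character(raw[[1L]])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  rownames(m) <- ids
  if (dialect == "tsv_samples_rows") m <- t(m)
  feature_table(m)
}

#' Write a feature table as TSV (taxa rows)
#'
#' @param table a \code{\link{feature_table}}.
#' @param path output path.
#' @return Invisibly \code{path}.
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  df <- data.frame(taxon_id = rownames(table), unclass(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Fixed rank order of Silva-style lineages handled by the package.
TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family",
                    "genus", "species")

#' Build a taxonomy map from lineage strings
#'
#' Parses semicolon-separated Silva-style lineages ("d__Bacteria;
#' p__Proteobacteria; ...") into a fixed-rank table (domain through species).
#' Missing or empty trailing ranks are allowed (ragged lineages) and stored as
#' \code{NA}; \code{\link{collapse_by_rank}} buckets them per parent.
#'
#' @param taxon_id character vector of feature ids.
#' @param lineage character vector of lineage strings, same length.
#' @return A data.frame of class \code{taxonomy_map} with columns
#'   \code{taxon_id} and one column per rank.
#' @export
taxonomy_map <- function(taxon_id, lineage) {
  taxon_id <- as.character(taxon_id)
  if (anyDuplicated(taxon_id))
    stop("duplicate taxon ids in taxonomy: ",
         paste(unique(taxon_id[duplicated(taxon_id)]), collapse = ", "))
  if (length(taxon_id) != length(lineage))
    stop("taxon_id and lineage lengths differ")
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  ranks <- t(vapply(parts, function(p) {
    p <- trimws(p)
    # treat empty labels and bare rank prefixes ("g__") as unassigned
    p[p == "" | grepl("^[a-z]__$", p)] <- NA_character_
    length(p) <- length(TAXONOMY_RANKS)
    p
  }, character(length(TAXONOMY_RANKS))))
  out <- data.frame(taxon_id = taxon_id, ranks, stringsAsFactors = FALSE)
  names(out) <- c("taxon_id", TAXONOMY_RANKS)
  class(out) <- c("taxonomy_map", "data.frame")
  out
}

#' Read a taxonomy map from a two-column TSV
#'
#' @param path TSV with header and columns taxon id, lineage string.
#' @return A \code{\link{taxonomy_map}}.
#' @export
read_taxonomy <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("taxonomy file needs id and lineage columns")
  taxonomy_map(raw[[1L]], raw[[2L]])
}

lineage_string <- function(tax, upto = "species") {
  r <- match(match.arg(upto, TAXONOMY_RANKS), TAXONOMY_RANKS)
  apply(as.matrix(tax[, TAXONOMY_RANKS[seq_len(r)], drop = FALSE]), 1L,
        function(x) paste(x[!is.na(x)], collapse = ";"))
}

#' Collapse a feature table at a taxonomic rank
#'
#' Features sharing the same classification down to \code{rank} are summed into
#' a single row, so that per-sample totals are conserved exactly (integer
#' arithmetic).  Lineages unassigned at (or before) the requested rank collapse
#' into an \code{unclassified_<parent>} bucket under their deepest assigned
#' label, one bucket per parent.
#'
#' @param table a \code{\link{feature_table}}.
#' @param tax a \code{\link{taxonomy_map}} covering every taxon in \code{table}.
#' @param rank one of \code{"phylum"}, \code{"class"}, \code{"order"},
#'   \code{"family"}, \code{"genus"}.
#' @return A \code{\link{feature_table}} whose row names are lineage prefixes
#'   truncated at \code{rank}.
#' @export
collapse_by_rank <- function(table, tax, rank) {
  rank <- match.arg(rank, TAXONOMY_RANKS[2:6])
  validate_feature_table(table)
  missing <- setdiff(rownames(table), tax$taxon_id)
  if (length(missing))
    stop("taxa missing from taxonomy: ", paste(missing, collapse = ", "))
  r <- match(rank, TAXONOMY_RANKS)
  labs <- as.matrix(tax[match(rownames(table), tax$taxon_id),
                        TAXONOMY_RANKS[seq_len(r)], drop = FALSE])
  group <- apply(labs, 1L, function(x) {
    miss <- which(is.na(x))
    if (!length(miss)) return(paste(x, collapse = ";"))
    j <- miss[1L]
    parent <- if (j > 1L) x[j - 1L] else "root"
    paste(c(x[seq_len(j - 1L)], paste0("unclassified_", parent)),
          collapse = ";")
  })
  out <- rowsum(unclass(table), group = group, reorder = TRUE)
  feature_table(out)
}

#' Remove nontarget lineages (mitochondria, chloroplast, ...)
#'
#' Drops any feature whose full lineage string contains one of the blocklist
#' tokens as a fixed substring.  Matching is case-sensitive.
#'
#' @param table a \code{\link{feature_table}}.
#' @param tax a \code{\link{taxonomy_map}}.
#' @param blocklist character vector of lineage substrings to remove.
#' @return Filtered \code{\link{feature_table}}; warns if nothing survives.
#' @export
remove_nontarget <- function(table, tax,
                             blocklist = c("Mitochondria", "Chloroplast")) {
  validate_feature_table(table)
  if (!length(blocklist)) return(feature_table(unclass(table)))
  idx <- match(rownames(table), tax$taxon_id)
  if (anyNA(idx))
    stop("taxa missing from taxonomy: ",
         paste(rownames(table)[is.na(idx)], collapse = ", "))
  lin <- lineage_string(tax[idx, , drop = FALSE])
  hit <- Reduce(`|`, lapply(blocklist, function(tok) grepl(tok, lin, fixed = TRUE)))
  keep <- !hit
  if (!any(keep)) {
    warning("all taxa matched the nontarget blocklist; returning empty table")
    out <- unclass(table)[keep, , drop = FALSE]
    return(out)
  }
  feature_table(unclass(table)[keep, , drop = FALSE])
}

WATER_USES <- c("potable_conventional", "potable_reuse", "nonpotable_reuse")
LOCATIONS <- c("POC", "POU")

#' Construct and validate a sample metadata frame
#'
#' Required columns: \code{sample_id}, \code{water_use} (one of
#' potable_conventional / potable_reuse / nonpotable_reuse, NA allowed for
#' blanks), \code{location} (POC or POU, NA allowed for blanks) and
#' \code{is_blank}.  An \code{atypical} flag (systems excluded from the
#' core/discriminatory analysis, e.g. mixed-source water with limited
#' treatment) defaults to \code{FALSE}.  Any further columns are carried along
#' as covariates.
#'
#' @param df data.frame of per-sample metadata.
#' @return A data.frame of class \code{sample_frame}.
#' @export
sample_frame <- function(df) {
  need <- c("sample_id", "water_use", "location", "is_blank")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample frame missing columns: ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df$is_blank <- as.logical(df$is_blank)
  if (anyNA(df$is_blank)) stop("is_blank must be TRUE/FALSE for every sample")
  if (!"atypical" %in% names(df)) df$atypical <- FALSE
  df$atypical <- as.logical(df$atypical)
  df$water_use <- as.character(df$water_use)
  df$location <- as.character(df$location)
  real <- !df$is_blank
  bad_use <- real & (is.na(df$water_use) | !df$water_use %in% WATER_USES)
  if (any(bad_use))
    stop("non-blank samples with undefined water_use: ",
         paste(df$sample_id[bad_use], collapse = ", "))
  bad_loc <- real & (is.na(df$location) | !df$location %in% LOCATIONS)
  if (any(bad_loc))
    stop("non-blank samples with undefined location: ",
         paste(df$sample_id[bad_loc], collapse = ", "))
  class(df) <- c("sample_frame", "data.frame")
  df
}

#' Read a sample metadata frame from TSV
#'
#' @param path TSV with header; see \code{\link{sample_frame}} for columns.
#' @return A \code{sample_frame}.
#' @export
read_sample_frame <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  sample_frame(raw)
}

#' Cross-file consistency check
#'
#' Verifies that every sample in the feature table has a metadata row and
#' (when a taxonomy is supplied) every taxon has a lineage entry.
#'
#' @param table a \code{\link{feature_table}}.
#' @param frame a \code{\link{sample_frame}}.
#' @param tax optional \code{\link{taxonomy_map}}.
#' @return Invisibly \code{TRUE}; errors name the offending ids.
#' @export
validate_study <- function(table, frame, tax = NULL) {
  validate_feature_table(table)
  miss <- setdiff(colnames(table), frame$sample_id)
  if (length(miss))
    stop("samples without metadata: ", paste(miss, collapse = ", "))
  if (!is.null(tax)) {
    mt <- setdiff(rownames(table), tax$taxon_id)
    if (length(mt))
      stop("taxa without taxonomy: ", paste(mt, collapse = ", "))
  }
  invisible(TRUE)
}
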