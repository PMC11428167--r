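IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Trim amplicon sequences at a primer site
#'
#' Harmonizes V4-V5 (515f/926r) amplicon sequence variants with V4 (515f/806r)
#' features by truncating each read immediately before the 806r primer site,
#' using the two-pass strategy: pass 1 locates the primer (in read
#' orientation) with zero errors via an IUPAC-aware scan; sequences still
#' unmatched go to pass 2, a tolerant search permitting substitutions and
#' indels, accepting the best hit with at most
#' \code{floor(max_error_rate * primer_length)} errors.  A degenerate primer
#' symbol matches any base in its IUPAC set at zero cost.  When several sites
#' tie on error count, the 3'-most match wins (the primer sits at the 3' end
#' of the amplicon).  Sequences unmatched after both passes are flagged
#' \code{untrimmed} and retained unmodified.
#'
#' @param seqs a named character vector or \code{Biostrings::DNAStringSet} of
#'   ASV sequences.
#' @param primer IUPAC primer string as it appears on the read orientation.
#' @param max_error_rate maximum error rate for the tolerant pass, in
#'   [0, 0.5); default 0.2.
#' @return A list with \code{results}, a data.frame of per-sequence
#'   \code{seq_id}, \code{pass} (exact / tolerant / untrimmed),
#'   \code{cut_position} (0-based; retained prefix is \code{[0, cut_position)})
#'   and \code{errors_used}; and \code{seqs}, the trimmed
#'   \code{DNAStringSet}.
#' @export
trim_at_primer <- function(seqs, primer, max_error_rate = 0.2) {
  if (!nzchar(primer)) stop("primer must be non-empty")
  primer <- toupper(primer)
  bad <- setdiff(strsplit(primer, "")[[1L]], IUPAC_CHARS)
  if (length(bad))
    stop("non-IUPAC characters in primer: ", paste(unique(bad), collapse = ", "))
  if (max_error_rate < 0 || max_error_rate >= 0.5)
    stop("max_error_rate must lie in [0, 0.5)")
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%d", seq_along(seqs))
  pr <- Biostrings::DNAString(primer)
  max_err <- floor(max_error_rate * nchar(primer))

  n <- length(seqs)
  pass <- rep("untrimmed", n)
  cut <- Biostrings::width(seqs)
  errs <- rep(NA_integer_, n)
  trimmed <- as.character(seqs)
  for (i in seq_len(n)) {
    s <- seqs[[i]]
    hit_start <- NA_integer_
    m <- Biostrings::matchPattern(pr, s, max.mismatch = 0, fixed = FALSE)
    if (length(m)) {
      hit_start <- max(Biostrings::start(m))
      pass[i] <- "exact"
      errs[i] <- 0L
    } else if (max_err > 0L) {
      for (k in seq_len(max_err)) {
        m <- Biostrings::matchPattern(pr, s, max.mismatch = k,
                                      with.indels = TRUE, fixed = FALSE)
        if (length(m)) {
          hit_start <- max(Biostrings::start(m))
          pass[i] <- "tolerant"
          errs[i] <- k
          break
        }
      }
    }
    if (!is.na(hit_start)) {
      cut[i] <- hit_start - 1L
      trimmed[i] <- substr(trimmed[i], 1L, cut[i])
    }
  }
  results <- data.frame(seq_id = names(seqs), pass = pass,
                        cut_position = as.integer(cut),
                        errors_used = errs,
                        row.names = NULL, stringsAsFactors = FALSE)
  out <- Biostrings::DNAStringSet(trimmed)
  names(out) <- names(seqs)
  list(results = results, seqs = out)
}

#' Trim a FASTA file at a primer site
#'
#' File-level wrapper around \code{\link{trim_at_primer}}.
#'
#' @param fasta_in input FASTA path.
#' @param primer IUPAC primer string.
#' @param fasta_out output FASTA path.
#' @param max_error_rate see \code{\link{trim_at_primer}}.
#' @return The per-sequence results data.frame, invisibly carrying the output
#'   path as attribute \code{"fasta_out"}.
#' @export
trim_fasta <- function(fasta_in, primer, fasta_out, max_error_rate = 0.2) {
  seqs <- Biostrings::readDNAStringSet(fasta_in)
  res <- trim_at_primer(seqs, primer, max_error_rate)
  Biostrings::writeXStringSet(res$seqs, fasta_out)
  attr(res$results, "fasta_out") <- fasta_out
  invisible(res$results)
}

#' Merge two feature tables over disjoint sample sets
#'
#' Outer join on taxa (missing taxa zero-filled) and column concatenation of
#' samples, e.g. to combine the trimmed V4-V5 features with native V4
#' features before continuing the pipeline.
#'
#' @param table_a,table_b \code{\link{feature_table}}s with disjoint sample
#'   id sets.
#' @return The merged \code{\link{feature_table}}.
#' @export
merge_feature_sets <- function(table_a, table_b) {
  validate_feature_table(table_a)
  validate_feature_table(table_b)
  overlap <- intersect(colnames(table_a), colnames(table_b))
  if (length(overlap))
    stop("overlapping sample ids: ", paste(overlap, collapse = ", "))
  taxa <- union(rownames(table_a), rownames(table_b))
  out <- matrix(0L, length(taxa), ncol(table_a) + ncol(table_b),
                dimnames = list(taxa, c(colnames(table_a), colnames(table_b))))
  out[rownames(table_a), colnames(table_a)] <- unclass(table_a)
  out[rownames(table_b), colnames(table_b)] <- unclass(table_b)
  feature_table(out)
}
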