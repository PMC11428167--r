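#' Score taxa for blank-associated contamination (prevalence method)
#'
#' For each taxon, builds the 2 x 2 table of presence (count >= 1) versus
#' sample type (blank / true sample) and computes a one-sided p-value against
#' the alternative "more prevalent in blanks": a chi-square test with
#' continuity correction when all expected cell counts are at least 5, and
#' Fisher's exact test otherwise.  A taxon is called a contaminant when its
#' score falls below \code{threshold}.  The score depends only on the presence
#' pattern, never on abundance magnitudes.
#'
#' The one-sided alternative deliberately flags only blank-enrichment:
#' two-sided flagging would also remove genuinely rare sample-side taxa.
#'
#' @param table a \code{\link{feature_table}} that still contains the blank
#'   columns.
#' @param frame a \code{\link{sample_frame}} with \code{is_blank} set.
#' @param threshold score cutoff in (0, 1); default 0.1.
#' @return A data.frame of class \code{contaminant_calls} with columns
#'   \code{taxon_id}, \code{presence_in_blanks}, \code{presence_in_samples},
#'   \code{score}, \code{is_contaminant}.
#' @export
score_contaminants <- function(table, frame, threshold = 0.1) {
  validate_feature_table(table)
  validate_study(table, frame)
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  meta <- frame[match(colnames(table), frame$sample_id), ]
  blank <- meta$is_blank
  n_b <- sum(blank)
  n_s <- sum(!blank)
  if (n_b < 1L)
    stop("no blank samples present; skip decontamination explicitly instead")
  if (n_s < 1L) stop("no non-blank samples present")
  pres <- unclass(table) >= 1L
  in_b <- rowSums(pres[, blank, drop = FALSE])
  in_s <- rowSums(pres[, !blank, drop = FALSE])
  score <- mapply(function(a, c) {
    tab <- rbind(blank = c(a, n_b - a), sample = c(c, n_s - c))
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expd < 5)) {
      stats::fisher.test(tab, alternative = "greater")$p.value
    } else {
      # one-sided Yates-corrected chi-square on two proportions
      stats::prop.test(c(a, c), c(n_b, n_s),
                       alternative = "greater")$p.value
    }
  }, in_b, in_s)
  out <- data.frame(taxon_id = rownames(table),
                    presence_in_blanks = in_b,
                    presence_in_samples = in_s,
                    score = unname(score),
                    is_contaminant = unname(score) < threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("contaminant_calls", "data.frame")
  out
}

#' Drop contaminant taxa and blank columns
#'
#' Removes every taxon flagged by \code{\link{score_contaminants}} and drops
#' the blank columns, returning the table used for all downstream analysis.
#'
#' @param table a \code{\link{feature_table}} including blanks.
#' @param calls a \code{contaminant_calls} data.frame covering all taxa.
#' @param frame a \code{\link{sample_frame}} identifying the blanks.
#' @return A \code{\link{feature_table}} without contaminants or blanks.
#' @export
filter_contaminants <- function(table, calls, frame) {
  validate_feature_table(table)
  miss <- setdiff(rownames(table), calls$taxon_id)
  if (length(miss))
    stop("contaminant calls missing for taxa: ", paste(miss, collapse = ", "))
  flag <- calls$is_contaminant[match(rownames(table), calls$taxon_id)]
  if (all(flag))
    stop("every taxon was called a contaminant; refusing to return an empty table")
  meta <- frame[match(colnames(table), frame$sample_id), ]
  keep_s <- !meta$is_blank
  feature_table(unclass(table)[!flag, keep_s, drop = FALSE])
}
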