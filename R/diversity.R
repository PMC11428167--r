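#' Per-sample alpha diversity
#'
#' Richness (number of taxa with count >= 1), Shannon entropy
#' H = -sum p_i log p_i over present taxa, and Simpson diversity.  Shannon uses
#' the natural logarithm by default; Simpson defaults to the Gini-Simpson form
#' 1 - sum p_i^2, with the inverse form 1 / sum p_i^2 available.
#'
#' @param table a \code{\link{feature_table}}.
#' @param shannon_base base of the Shannon logarithm (default e).
#' @param simpson one of \code{"gini"} (1 - sum p^2) or \code{"inverse"}.
#' @return data.frame with columns \code{sample_id}, \code{richness},
#'   \code{shannon}, \code{simpson}.
#' @export
alpha_diversity <- function(table, shannon_base = exp(1),
                            simpson = c("gini", "inverse")) {
  simpson <- match.arg(simpson)
  validate_feature_table(table)
  tot <- colSums(table)
  if (any(tot == 0))
    stop("all-zero sample(s): ",
         paste(colnames(table)[tot == 0], collapse = ", "))
  comm <- t(unclass(table))
  data.frame(
    sample_id = colnames(table),
    richness = as.integer(colSums(unclass(table) >= 1L)),
    shannon = unname(vegan::diversity(comm, index = "shannon",
                                      base = shannon_base)),
    simpson = unname(vegan::diversity(
      comm, index = if (simpson == "gini") "simpson" else "invsimpson")),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(a, b) = sum |a_i - b_i| / sum (a_i + b_i) over taxa, for every sample
#' pair.  Returns a \code{stats::dist} object labelled with the sample ids;
#' Bray-Curtis is a semimetric (symmetric with zero diagonal, but the triangle
#' inequality is not guaranteed).
#'
#' @param table a \code{\link{feature_table}} with at least two samples and no
#'   all-zero sample.
#' @return A \code{dist} of Bray-Curtis dissimilarities in [0, 1].
#' @export
bray_curtis <- function(table) {
  validate_feature_table(table)
  if (ncol(table) < 2L) stop("need at least two samples")
  tot <- colSums(table)
  if (any(tot == 0))
    stop("all-zero sample(s): ",
         paste(colnames(table)[tot == 0], collapse = ", "))
  vegan::vegdist(t(unclass(table)), method = "bray")
}

#' Benjamini-Yekutieli adjusted Wilcoxon rank-sum tests between groups
#'
#' Runs a two-sided Wilcoxon rank-sum test for each requested group
#' comparison of a per-sample metric (e.g. richness or Shannon diversity) and
#' adjusts the p-values with the conservative Benjamini-Yekutieli correction,
#' which controls the false-discovery rate under arbitrary dependence.
#'
#' @param values numeric per-sample metric.
#' @param groups group label per sample.
#' @param comparisons list of length-2 character vectors \code{c(A, B)}.
#' @return data.frame with one row per comparison: group labels, per-side
#'   sample sizes, the rank-sum statistic, raw and BY-adjusted p-values.
#' @export
group_wilcoxon_by <- function(values, groups, comparisons) {
  groups <- as.character(groups)
  if (length(values) != length(groups))
    stop("values and groups lengths differ")
  rows <- lapply(comparisons, function(cmp) {
    stopifnot(length(cmp) == 2L)
    a <- values[groups == cmp[1L]]
    b <- values[groups == cmp[2L]]
    if (length(a) < 2L || length(b) < 2L)
      stop("comparison ", cmp[1L], " vs ", cmp[2L],
           " needs at least 2 samples per side")
    wt <- stats::wilcox.test(a, b, exact = FALSE)
    data.frame(group_a = cmp[1L], group_b = cmp[2L],
               n_a = length(a), n_b = length(b),
               statistic = unname(wt$statistic), p_raw = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BY")
  out
}
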