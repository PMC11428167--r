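#' Frequency of detection per taxon, water use and stratum
#'
#' The frequency of detection of a taxon in a water use is the fraction of
#' that use's samples in which the taxon has a nonzero count
#' (presence/absence basis, which better accounts for rare taxa than
#' abundance).  Frequencies are computed per sampling stratum: POC (point of
#' compliance), POU (point of use), and "combined" (POC and POU pooled).
#' Blanks and samples flagged atypical are always excluded.
#'
#' @param table a \code{\link{feature_table}}, typically collapsed at the
#'   analysis rank.
#' @param frame a \code{\link{sample_frame}}.
#' @param strata which strata to profile (default all three).
#' @return data.frame of class \code{detection_profiles} with columns
#'   \code{taxon}, \code{stratum}, \code{group}, \code{n} (samples in the
#'   group-stratum cell) and \code{freq} in [0, 1].
#' @export
detection_frequencies <- function(table, frame,
                                  strata = c("POC", "POU", "combined")) {
  validate_feature_table(table)
  validate_study(table, frame)
  strata <- match.arg(strata, several.ok = TRUE)
  meta <- frame[match(colnames(table), frame$sample_id), ]
  use <- !meta$is_blank & !meta$atypical
  pres <- unclass(table) >= 1L
  rows <- list()
  for (st in strata) {
    in_st <- use & (st == "combined" | (!is.na(meta$location) &
                                          meta$location == st))
    for (g in WATER_USES) {
      ix <- in_st & meta$water_use == g
      ix[is.na(ix)] <- FALSE
      if (!any(ix))
        stop("empty group-stratum cell: ", g, " / ", st)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = rownames(table), stratum = st, group = g,
        n = sum(ix),
        freq = rowMeans(pres[, ix, drop = FALSE]),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("detection_profiles", "data.frame")
  out
}

#' Flag core taxa
#'
#' A taxon is core to a water use (within a stratum) when its frequency of
#' detection strictly exceeds the threshold: detected in greater than 80% of
#' that use's samples by default.  A frequency of exactly 0.80 is not core.
#'
#' @param profiles output of \code{\link{detection_frequencies}}.
#' @param core_threshold strict lower bound on the detection frequency.
#' @return \code{profiles} with a logical \code{core} column added.
#' @export
call_core <- function(profiles, core_threshold = 0.80) {
  stopifnot(all(c("taxon", "stratum", "group", "freq") %in% names(profiles)))
  profiles$core <- profiles$freq > core_threshold
  profiles
}

#' Flag discriminatory taxa between water uses
#'
#' A taxon discriminates water use A from water use B (within a stratum) when
#' it is core to A and either (1) its frequency of detection in B is below
#' \code{low} (less than 20%), or (2) the frequency gap freq_A - freq_B
#' exceeds \code{gap} (greater than 60%).  All inequalities are strict.  Every
#' ordered pair of water uses is evaluated in every stratum, and the
#' triggering criterion ("low", "gap" or "both") is recorded.
#'
#' @param profiles output of \code{\link{call_core}} (must carry \code{core}).
#' @param low strict upper bound on the contrast-group frequency.
#' @param gap strict lower bound on the frequency-of-detection gap.
#' @return data.frame of class \code{discriminatory_calls}: \code{taxon},
#'   \code{stratum}, \code{group}, \code{contrast}, \code{freq_group},
#'   \code{freq_contrast}, \code{discriminatory}, \code{criterion}.
#' @export
call_discriminatory <- function(profiles, low = 0.20, gap = 0.60) {
  if (!"core" %in% names(profiles))
    stop("profiles must carry core flags; run call_core() first")
  rows <- list()
  for (st in unique(profiles$stratum)) {
    sub <- profiles[profiles$stratum == st, ]
    wide_f <- tapply(sub$freq, list(sub$taxon, sub$group), identity)
    wide_c <- tapply(sub$core, list(sub$taxon, sub$group), identity)
    for (a in colnames(wide_f)) for (b in setdiff(colnames(wide_f), a)) {
      fa <- wide_f[, a]; fb <- wide_f[, b]
      by_low <- fb < low
      by_gap <- (fa - fb) > gap
      disc <- wide_c[, a] & (by_low | by_gap)
      crit <- ifelse(by_low & by_gap, "both",
                     ifelse(by_low, "low", ifelse(by_gap, "gap", NA)))
      crit[!disc] <- NA
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = rownames(wide_f), stratum = st, group = a, contrast = b,
        freq_group = unname(fa), freq_contrast = unname(fb),
        discriminatory = unname(disc), criterion = unname(crit),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("discriminatory_calls", "data.frame")
  out
}

#' ANCOM-style differential abundance between potable and nonpotable waters
#'
#' Compares potable samples (conventional and reuse pooled) against nonpotable
#' reuse samples on raw counts within a stratum (POC, POU, or all samples
#' combined).  After adding a pseudocount, every pairwise log-ratio
#' log(x_i / x_j) is tested between the two groups with a two-sided Wilcoxon
#' rank-sum test; within each taxon i's family of m - 1 tests the p-values are
#' Benjamini-Yekutieli adjusted and W_i counts how many fall below
#' \code{alpha}.  Taxon i is flagged differentially abundant when
#' W_i >= w_frac * (m - 1).  The log-fold change is the difference of
#' group means of centered-log-ratio transformed abundances (natural log,
#' nonpotable minus potable), so a positive LFC indicates higher abundance in
#' nonpotable waters.
#'
#' The input is deliberately the unmodified count table for the stratum:
#' atypical samples are retained (only blanks are excluded), in contrast to
#' the detection-frequency analysis.
#'
#' @param table a \code{\link{feature_table}} with at least 3 taxa.
#' @param frame a \code{\link{sample_frame}}.
#' @param stratum \code{"combined"}, \code{"POC"} or \code{"POU"}.
#' @param alpha within-family significance level (default 0.01).
#' @param w_frac fraction of the family that must be significant (default
#'   0.7).
#' @param pseudocount added to all counts before log-ratios (default 1).
#' @return data.frame of class \code{ancom_result} with columns \code{taxon},
#'   \code{W}, \code{significant}, \code{lfc}; attributes record the stratum,
#'   group sizes and parameters.
#' @export
ancom_test <- function(table, frame, stratum = c("combined", "POC", "POU"),
                       alpha = 0.01, w_frac = 0.7, pseudocount = 1) {
  stratum <- match.arg(stratum)
  validate_feature_table(table)
  validate_study(table, frame)
  m <- nrow(table)
  if (m < 3L) stop("ANCOM needs at least 3 taxa (log-ratio family degenerate)")
  meta <- frame[match(colnames(table), frame$sample_id), ]
  keep <- !meta$is_blank &
    (stratum == "combined" | (!is.na(meta$location) & meta$location == stratum))
  keep[is.na(keep)] <- FALSE
  grp <- ifelse(meta$water_use == "nonpotable_reuse", "nonpotable", "potable")
  grp <- grp[keep]
  if (length(unique(grp)) < 2L)
    stop("both potable and nonpotable samples required in stratum ", stratum)
  L <- log(unclass(table)[, keep, drop = FALSE] + pseudocount)
  is_np <- grp == "nonpotable"

  # two-sided rank-sum p for each pairwise log-ratio (symmetric in i, j)
  P <- matrix(NA_real_, m, m)
  for (i in seq_len(m - 1L)) {
    di <- L[i, ]
    for (j in (i + 1L):m) {
      v <- di - L[j, ]
      P[i, j] <- P[j, i] <- stats::wilcox.test(
        v[is_np], v[!is_np], exact = FALSE)$p.value
    }
  }
  W <- vapply(seq_len(m), function(i) {
    fam <- stats::p.adjust(P[i, -i], method = "BY")
    sum(fam < alpha)
  }, integer(1))
  clr <- sweep(L, 2L, colMeans(L))
  lfc <- rowMeans(clr[, is_np, drop = FALSE]) -
    rowMeans(clr[, !is_np, drop = FALSE])
  out <- data.frame(taxon = rownames(table), W = W,
                    significant = W >= w_frac * (m - 1L),
                    lfc = unname(lfc),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "stratum") <- stratum
  attr(out, "n_potable") <- sum(!is_np)
  attr(out, "n_nonpotable") <- sum(is_np)
  attr(out, "alpha") <- alpha
  attr(out, "w_frac") <- w_frac
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("ancom_result", "data.frame")
  out
}

#' Consensus signature taxa across detection and abundance methods
#'
#' Names the taxa that are differentially abundant between potable and
#' nonpotable waters in all three comparisons (POC, POU, and all samples
#' combined) with an average |log-fold change| above \code{lfc_threshold}
#' (strictly), and annotates whether each is also discriminatory by frequency
#' of detection and in which strata.  Direction follows the LFC sign: positive
#' means nonpotable-enriched, negative potable-enriched.
#'
#' @param disc_calls output of \code{\link{call_discriminatory}}.
#' @param ancom_combined,ancom_poc,ancom_pou \code{\link{ancom_test}} results
#'   at the three comparisons, computed at the same rank.
#' @param lfc_threshold strict lower bound on |average LFC| (default 1.5).
#' @return data.frame of class \code{consensus_signatures}: \code{taxon}, the
#'   three LFCs, \code{average_lfc}, \code{significant_all_three},
#'   \code{consensus}, \code{direction}, \code{discriminatory_strata} (e.g.
#'   "POC and POU", "-").
#' @export
consensus_signatures <- function(disc_calls, ancom_combined, ancom_poc,
                                 ancom_pou, lfc_threshold = 1.5) {
  for (r in list(ancom_combined, ancom_poc, ancom_pou))
    if (is.null(r) || !inherits(r, "ancom_result"))
      stop("all three ANCOM comparisons (combined, POC, POU) are required")
  taxa <- ancom_combined$taxon
  if (!identical(sort(taxa), sort(ancom_poc$taxon)) ||
      !identical(sort(taxa), sort(ancom_pou$taxon)))
    stop("ANCOM comparisons cover different taxon sets")
  poc <- ancom_poc[match(taxa, ancom_poc$taxon), ]
  pou <- ancom_pou[match(taxa, ancom_pou$taxon), ]
  avg <- (ancom_combined$lfc + poc$lfc + pou$lfc) / 3
  sig3 <- ancom_combined$significant & poc$significant & pou$significant
  consensus <- sig3 & abs(avg) > lfc_threshold
  direction <- ifelse(avg > 0, "nonpotable_enriched", "potable_enriched")

  # strata where the taxon discriminates across the potable/nonpotable
  # boundary in the direction of its LFC
  disc_str <- vapply(seq_along(taxa), function(i) {
    d <- disc_calls[disc_calls$taxon == taxa[i] & disc_calls$discriminatory, ]
    if (direction[i] == "nonpotable_enriched") {
      d <- d[d$group == "nonpotable_reuse" & d$contrast != "nonpotable_reuse", ]
    } else {
      d <- d[d$group != "nonpotable_reuse" & d$contrast == "nonpotable_reuse", ]
    }
    st <- intersect(c("POC", "POU"), unique(d$stratum))
    if (!length(st)) "-" else paste(st, collapse = " and ")
  }, character(1))

  out <- data.frame(taxon = taxa,
                    lfc_combined = ancom_combined$lfc,
                    lfc_poc = poc$lfc, lfc_pou = pou$lfc,
                    average_lfc = avg,
                    significant_all_three = sig3,
                    consensus = consensus,
                    direction = direction,
                    discriminatory_strata = disc_str,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$average_lfc)), ]
  rownames(out) <- NULL
  attr(out, "lfc_threshold") <- lfc_threshold
  class(out) <- c("consensus_signatures", "data.frame")
  out
}
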