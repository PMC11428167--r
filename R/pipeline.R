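#' Build a pipeline run configuration
#'
#' Collects every tunable of the full analysis in one object: input paths (or
#' in-memory objects), the analysis rank, the classifier thresholds, the
#' permutation and ordination settings, and a single top-level seed that is
#' fanned out deterministically to the stochastic stages.  The configuration
#' is echoed into every output bundle for provenance.
#'
#' @param table,taxonomy,metadata either file paths (TSV) or in-memory
#'   objects (\code{\link{feature_table}}, \code{\link{taxonomy_map}},
#'   \code{\link{sample_frame}}).
#' @param rank taxonomic rank for collapsing (default \code{"genus"}).
#' @param core_threshold,low,gap core/discriminatory thresholds (strict
#'   inequalities; defaults 0.80, 0.20, 0.60).
#' @param lfc_threshold consensus |average LFC| cutoff (default 1.5).
#' @param alpha significance cutoff for all statistical tests (default 0.01).
#' @param decontam_threshold prevalence-method score cutoff (default 0.1);
#'   \code{NA} skips decontamination explicitly.
#' @param n_perm permutations for ANOSIM / Betadisper / PERMANOVA (default
#'   1000).
#' @param nmds_k,nmds_restarts ordination dimensions and restarts.
#' @param w_frac ANCOM family fraction (default 0.7).
#' @param pseudocount ANCOM pseudocount (default 1).
#' @param nontarget lineage substrings removed before analysis.
#' @param exclude_atypical honor the metadata \code{atypical} flag in the
#'   detection-frequency analysis (default TRUE; ANCOM always uses the
#'   unmodified sample set).
#' @param seed top-level integer seed.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(table, metadata, taxonomy = NULL,
                       rank = "genus",
                       core_threshold = 0.80, low = 0.20, gap = 0.60,
                       lfc_threshold = 1.5, alpha = 0.01,
                       decontam_threshold = 0.1,
                       n_perm = 1000, nmds_k = 3L, nmds_restarts = 10L,
                       w_frac = 0.7, pseudocount = 1,
                       nontarget = c("Mitochondria", "Chloroplast"),
                       exclude_atypical = TRUE,
                       seed = 1L) {
  stopifnot(core_threshold > 0, core_threshold < 1,
            low > 0, low < 1, gap > 0, gap < 1,
            alpha > 0, alpha < 1, lfc_threshold >= 0,
            n_perm >= 1, nmds_k >= 1, nmds_restarts >= 1,
            w_frac > 0, w_frac <= 1, pseudocount > 0)
  if (!is.na(decontam_threshold))
    stopifnot(decontam_threshold > 0, decontam_threshold < 1)
  structure(list(table = table, metadata = metadata, taxonomy = taxonomy,
                 rank = rank, core_threshold = core_threshold, low = low,
                 gap = gap, lfc_threshold = lfc_threshold, alpha = alpha,
                 decontam_threshold = decontam_threshold, n_perm = n_perm,
                 nmds_k = nmds_k, nmds_restarts = nmds_restarts,
                 w_frac = w_frac, pseudocount = pseudocount,
                 nontarget = nontarget, exclude_atypical = exclude_atypical,
                 seed = as.integer(seed)),
            class = "run_config")
}

## Fixed per-stage seed derivation from the top-level seed, so each stage can
## be reproduced standalone.
stage_seed <- function(seed, stage) {
  offsets <- c(betadisper = 101L, anosim = 211L, permanova = 307L,
               nmds = 401L)
  seed + offsets[[stage]]
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

#' Run the full signature analysis pipeline
#'
#' Orchestrates the stages in the processing order of the analysis:
#' validation, nontarget removal, blank-based decontamination, taxonomy
#' collapsing, alpha diversity with BY-adjusted Wilcoxon group tests, Bray-
#' Curtis distances, NMDS ordination, the homogeneity-gated ANOSIM per stratum
#' plus a sequential PERMANOVA, the detection-frequency core/discriminatory
#' classifier, the three ANCOM comparisons and the cross-method consensus.
#' The run is a pure function of (inputs, configuration, seed).
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir optional directory; when given, per-stage TSVs, a JSON
#'   summary and a log are written there.
#' @return A list bundle with every stage's result (invisibly when
#'   \code{out_dir} is given).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  table <- resolve_input(config$table, read_feature_table)
  frame <- resolve_input(config$metadata, read_sample_frame)
  tax <- if (!is.null(config$taxonomy))
    resolve_input(config$taxonomy, read_taxonomy) else NULL
  stage("validate", validate_study(table, frame, tax))
  say("inputs: %d taxa x %d samples (%d blanks)", nrow(table), ncol(table),
      sum(frame$is_blank))

  if (!is.null(tax) && length(config$nontarget)) {
    table <- stage("nontarget", remove_nontarget(table, tax, config$nontarget))
    say("after nontarget removal: %d taxa", nrow(table))
  }

  calls <- NULL
  if (!is.na(config$decontam_threshold) && any(frame$is_blank)) {
    calls <- stage("decontam",
                   score_contaminants(table, frame, config$decontam_threshold))
    table <- stage("decontam", filter_contaminants(table, calls, frame))
    say("decontamination: %d contaminant taxa removed, blanks dropped",
        sum(calls$is_contaminant))
  } else {
    keep <- !frame$is_blank[match(colnames(table), frame$sample_id)]
    table <- feature_table(unclass(table)[, keep, drop = FALSE])
    say("decontamination skipped; blanks dropped")
  }

  if (!is.null(tax)) {
    table <- stage("collapse", collapse_by_rank(table, tax, config$rank))
    say("collapsed at %s: %d taxa", config$rank, nrow(table))
  }
  frame_a <- frame[match(colnames(table), frame$sample_id), ]
  if (!config$exclude_atypical) frame_a$atypical <- FALSE

  alpha_tab <- stage("alpha", alpha_diversity(table))
  grp <- frame_a$water_use
  wil <- stage("alpha", group_wilcoxon_by(
    alpha_tab$shannon, grp,
    list(c("potable_conventional", "nonpotable_reuse"),
         c("potable_reuse", "nonpotable_reuse"),
         c("potable_conventional", "potable_reuse"))))

  dm <- stage("beta", bray_curtis(table))
  ord <- stage("nmds", nmds(dm, k = config$nmds_k,
                            n_restarts = config$nmds_restarts,
                            seed = stage_seed(config$seed, "nmds")))
  say("NMDS k = %d: stress = %.3f", config$nmds_k, ord$stress)

  perm <- list()
  for (st in c("POC", "POU", "combined")) {
    ix <- if (st == "combined") rep(TRUE, ncol(table)) else
      frame_a$location == st
    sub <- feature_table(unclass(table)[, ix, drop = FALSE])
    dsub <- bray_curtis(sub)
    g <- frame_a$water_use[ix]
    bd <- stage("betadisper", betadisper(
      dsub, g, config$n_perm, stage_seed(config$seed, "betadisper")))
    an <- stage("anosim", anosim(
      dsub, g, config$n_perm, stage_seed(config$seed, "anosim")))
    perm[[st]] <- gated_report(bd, an, config$alpha)
    say("%s: ANOSIM r = %.3f, p = %.4g; Betadisper p = %.4g (%s)",
        st, an$statistic, an$p_value, bd$p_value, perm[[st]]$report)
  }
  adn <- stage("permanova", permanova(
    dm, data.frame(water_use = frame_a$water_use,
                   location = frame_a$location),
    c("water_use", "location"), config$n_perm,
    stage_seed(config$seed, "permanova")))

  prof <- stage("signatures", detection_frequencies(table, frame_a))
  prof <- call_core(prof, config$core_threshold)
  disc <- call_discriminatory(prof, config$low, config$gap)
  anc <- lapply(c(combined = "combined", POC = "POC", POU = "POU"),
                function(st) stage("ancom", ancom_test(
                  table, frame_a, st, config$alpha, config$w_frac,
                  config$pseudocount)))
  cons <- stage("consensus", consensus_signatures(
    disc, anc$combined, anc$POC, anc$POU, config$lfc_threshold))
  say("signatures: %d core calls, %d discriminatory relationships, %d consensus taxa",
      sum(prof$core), sum(disc$discriminatory), sum(cons$consensus))

  bundle <- list(config = config, seed = config$seed, table = table,
                 frame = frame_a, contaminant_calls = calls,
                 alpha = alpha_tab, alpha_wilcoxon = wil,
                 distances = dm, ordination = ord,
                 gated = perm, permanova = adn,
                 profiles = prof, discriminatory = disc,
                 ancom = anc, consensus = cons, log = log)
  if (!is.null(out_dir)) {
    write_bundle(bundle, out_dir)
    return(invisible(bundle))
  }
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_feature_table(bundle$table, file.path(out_dir, "feature_table.tsv"))
  if (!is.null(bundle$contaminant_calls))
    wt(bundle$contaminant_calls, "contaminant_calls.tsv")
  wt(bundle$alpha, "alpha_diversity.tsv")
  wt(bundle$alpha_wilcoxon, "alpha_wilcoxon_by.tsv")
  wt(data.frame(sample_id = rownames(bundle$ordination$coordinates),
                bundle$ordination$coordinates), "nmds_coordinates.tsv")
  stats_df <- do.call(rbind, lapply(names(bundle$gated), function(st) {
    g <- bundle$gated[[st]]
    data.frame(stratum = st, anosim_r = g$statistic, anosim_p = g$p_value,
               betadisper_p = g$betadisper_p,
               homogeneity_ok = g$homogeneity_ok, report = g$report,
               stringsAsFactors = FALSE)
  }))
  wt(stats_df, "gated_anosim.tsv")
  wt(data.frame(term = names(bundle$permanova$r_squared),
                r_squared = unname(bundle$permanova$r_squared)),
     "permanova_r2.tsv")
  wt(bundle$profiles, "detection_profiles.tsv")
  wt(bundle$discriminatory, "discriminatory_calls.tsv")
  for (st in names(bundle$ancom))
    wt(bundle$ancom[[st]], paste0("ancom_", st, ".tsv"))
  wt(bundle$consensus, "consensus_signatures.tsv")
  summary <- list(
    seed = bundle$seed,
    config = bundle$config[setdiff(names(bundle$config),
                                   c("table", "metadata", "taxonomy"))],
    r_version = as.character(getRversion()),
    n_taxa = nrow(bundle$table), n_samples = ncol(bundle$table),
    nmds_stress = bundle$ordination$stress,
    n_consensus = sum(bundle$consensus$consensus),
    log = bundle$log)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
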