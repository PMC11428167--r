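#' Specify a synthetic water-microbiome study
#'
#' A community spec fixes every parameter of the generator: the sampling
#' design (samples per water use and location, number of blanks), the
#' presence/absence model (per-group occurrence probabilities), the abundance
#' model (per-group mean log relative abundances, Dirichlet concentration,
#' lognormal sequencing depths), and the planted structure (core taxa,
#' discriminatory taxa, differentially abundant taxa, blank-enriched
#' contaminants).  Presence and abundance are decoupled (a hurdle structure):
#' the core/discriminatory classifier operates on presence/absence while the
#' differential-abundance test operates on counts, and the generator must
#' exercise both channels independently.
#'
#' @param group_sizes 3 x 2 integer matrix of sample counts, rows
#'   \code{potable_conventional}, \code{potable_reuse}, \code{nonpotable_reuse},
#'   columns \code{POC}, \code{POU}.
#' @param occurrence n_taxa x 3 matrix of per-group presence probabilities in
#'   [0, 1]; columns named by water use.
#' @param log_abundance n_taxa x 3 matrix of mean log relative abundances per
#'   group (natural log, arbitrary offset); planted log-fold changes are
#'   encoded as column differences.
#' @param concentration Dirichlet concentration (total mass); smaller values
#'   give more overdispersed compositions.
#' @param depth_meanlog,depth_sdlog lognormal parameters of sequencing depth.
#' @param n_blanks number of negative-control samples.
#' @param blank_occurrence per-taxon presence probability in blanks (sparse
#'   background, contaminants enriched).
#' @param blank_log_abundance per-taxon mean log relative abundance in blanks.
#' @param blank_depth_meanlog lognormal meanlog of blank depths.
#' @param contaminants integer indices of planted contaminant taxa.
#' @param planted list describing planted ground truth: \code{core} (list of
#'   taxon indices per water use), \code{discriminatory} (data.frame with
#'   columns \code{taxon}, \code{group}, \code{contrast}), \code{lfc}
#'   (length-n_taxa vector of planted nonpotable-minus-potable log-fold
#'   changes).
#' @param taxon_ids,sample_prefix identifiers used in the emitted table.
#' @param seed integer seed governing all draws through one generator stream.
#' @return A validated list of class \code{community_spec}.
#' @seealso \code{\link{default_paper_like_spec}}, \code{\link{simulate_study}}
#' @export
community_spec <- function(group_sizes, occurrence, log_abundance,
                           concentration = 50,
                           depth_meanlog = log(2e4), depth_sdlog = 0.4,
                           n_blanks = 0L,
                           blank_occurrence = NULL,
                           blank_log_abundance = NULL,
                           blank_depth_meanlog = depth_meanlog - log(10),
                           contaminants = integer(0),
                           planted = list(core = list(),
                                          discriminatory = NULL,
                                          lfc = NULL),
                           taxon_ids = NULL,
                           sample_prefix = "S",
                           seed = 1L) {
  occurrence <- as.matrix(occurrence)
  log_abundance <- as.matrix(log_abundance)
  n_taxa <- nrow(occurrence)
  if (is.null(colnames(occurrence))) colnames(occurrence) <- WATER_USES
  if (is.null(colnames(log_abundance))) colnames(log_abundance) <- WATER_USES
  if (is.null(taxon_ids)) taxon_ids <- sprintf("T%03d", seq_len(n_taxa))
  if (is.null(blank_occurrence)) blank_occurrence <- rep(0.05, n_taxa)
  if (is.null(blank_log_abundance)) blank_log_abundance <- rep(0, n_taxa)
  if (is.null(planted$lfc)) planted$lfc <- rep(0, n_taxa)
  spec <- structure(list(
    group_sizes = group_sizes, n_taxa = n_taxa,
    occurrence = occurrence, log_abundance = log_abundance,
    concentration = concentration,
    depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
    n_blanks = as.integer(n_blanks),
    blank_occurrence = blank_occurrence,
    blank_log_abundance = blank_log_abundance,
    blank_depth_meanlog = blank_depth_meanlog,
    contaminants = as.integer(contaminants),
    planted = planted,
    taxon_ids = taxon_ids, sample_prefix = sample_prefix,
    seed = as.integer(seed)), class = "community_spec")
  validate_community_spec(spec)
  spec
}

#' Validate a community spec
#'
#' Checks probability ranges, positive depths and concentration, and that the
#' planted structure is self-consistent: planted core taxa must have occurrence
#' above 0.8 in their group, and planted discriminatory taxa must satisfy their
#' own occurrence criteria (below 0.2 in the contrast group, or an occurrence
#' gap above 0.6).
#'
#' @param spec a \code{community_spec}.
#' @return Invisibly \code{TRUE}; errors otherwise.
#' @export
validate_community_spec <- function(spec) {
  gs <- spec$group_sizes
  if (!is.matrix(gs) || nrow(gs) != 3L || ncol(gs) != 2L)
    stop("group_sizes must be a 3 x 2 (water use x location) matrix")
  if (any(gs < 0) || any(gs != round(gs))) stop("group_sizes must be non-negative integers")
  if (any(spec$occurrence < 0 | spec$occurrence > 1))
    stop("occurrence probabilities must lie in [0, 1]")
  if (any(spec$blank_occurrence < 0 | spec$blank_occurrence > 1))
    stop("blank occurrence probabilities must lie in [0, 1]")
  if (spec$concentration <= 0) stop("Dirichlet concentration must be positive")
  if (spec$depth_sdlog < 0) stop("depth_sdlog must be non-negative")
  if (nrow(spec$log_abundance) != spec$n_taxa ||
      ncol(spec$log_abundance) != ncol(spec$occurrence))
    stop("log_abundance must match occurrence in dimension")
  for (use in names(spec$planted$core)) {
    idx <- spec$planted$core[[use]]
    low <- idx[spec$occurrence[idx, use] <= 0.8]
    if (length(low))
      stop("planted core taxa with occurrence <= 0.8 in ", use, ": ",
           paste(spec$taxon_ids[low], collapse = ", "))
  }
  disc <- spec$planted$discriminatory
  if (!is.null(disc) && nrow(disc)) {
    for (i in seq_len(nrow(disc))) {
      a <- spec$occurrence[disc$taxon[i], disc$group[i]]
      b <- spec$occurrence[disc$taxon[i], disc$contrast[i]]
      if (a <= 0.8 || !(b < 0.2 || a - b > 0.6))
        stop("planted discriminatory taxon violates its occurrence constraints: ",
             spec$taxon_ids[disc$taxon[i]], " (", disc$group[i], " vs ",
             disc$contrast[i], ")")
    }
  }
  invisible(TRUE)
}

## One Dirichlet draw via normalized gammas.
rdirichlet1 <- function(alpha) {
  w <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(w) == 0) w[which.max(alpha)] <- 1
  w / sum(w)
}

#' Simulate a study from a community spec
#'
#' For each sample: taxon presence is drawn Bernoulli from the group's
#' occurrence probabilities; relative abundances of the present taxa are drawn
#' from a Dirichlet whose mean follows the group's log-abundance profile
#' (overdispersion set by the concentration); counts are drawn multinomially at
#' a lognormal depth, so per-sample totals equal the drawn depths exactly.
#' Blanks are drawn from a sparse background community with the planted
#' contaminants enriched.
#'
#' @param spec a \code{\link{community_spec}}.
#' @param seed optional integer overriding \code{spec$seed}.
#' @return A list with elements \code{table} (\code{\link{feature_table}}),
#'   \code{frame} (\code{\link{sample_frame}}), \code{taxonomy}
#'   (\code{\link{taxonomy_map}} assigning each taxon its own genus-level
#'   lineage), and \code{truth} (planted ground truth: core, discriminatory,
#'   differentially abundant and contaminant taxa, the occurrence matrix and
#'   per-taxon maximum between-group occurrence gaps).
#' @export
simulate_study <- function(spec, seed = spec$seed) {
  validate_community_spec(spec)
  set.seed(as.integer(seed))
  uses <- WATER_USES
  locs <- LOCATIONS
  n_real <- sum(spec$group_sizes)
  n_all <- n_real + spec$n_blanks
  counts <- matrix(0L, spec$n_taxa, n_all)
  sample_id <- character(n_all)
  water_use <- character(n_all)
  location <- character(n_all)
  is_blank <- logical(n_all)
  s <- 0L
  for (ui in seq_along(uses)) for (li in seq_along(locs)) {
    for (k in seq_len(spec$group_sizes[ui, li])) {
      s <- s + 1L
      sample_id[s] <- sprintf("%s%04d", spec$sample_prefix, s)
      water_use[s] <- uses[ui]
      location[s] <- locs[li]
      z <- stats::runif(spec$n_taxa) < spec$occurrence[, uses[ui]]
      if (!any(z)) z[which.max(spec$occurrence[, uses[ui]])] <- TRUE
      mu <- exp(spec$log_abundance[z, uses[ui]])
      alpha <- spec$concentration * mu / sum(mu)
      p <- rdirichlet1(alpha)
      depth <- max(1L, as.integer(round(stats::rlnorm(1, spec$depth_meanlog,
                                                      spec$depth_sdlog))))
      counts[z, s] <- stats::rmultinom(1L, depth, p)[, 1L]
    }
  }
  for (k in seq_len(spec$n_blanks)) {
    s <- s + 1L
    sample_id[s] <- sprintf("B%03d", k)
    water_use[s] <- NA_character_
    location[s] <- NA_character_
    is_blank[s] <- TRUE
    z <- stats::runif(spec$n_taxa) < spec$blank_occurrence
    if (!any(z)) z[which.max(spec$blank_occurrence)] <- TRUE
    mu <- exp(spec$blank_log_abundance[z])
    alpha <- spec$concentration * mu / sum(mu)
    p <- rdirichlet1(alpha)
    depth <- max(1L, as.integer(round(stats::rlnorm(1, spec$blank_depth_meanlog,
                                                    spec$depth_sdlog))))
    counts[z, s] <- stats::rmultinom(1L, depth, p)[, 1L]
  }
  rownames(counts) <- spec$taxon_ids
  colnames(counts) <- sample_id
  frame <- sample_frame(data.frame(
    sample_id = sample_id, water_use = water_use, location = location,
    is_blank = is_blank, atypical = FALSE, stringsAsFactors = FALSE))
  tax <- taxonomy_map(spec$taxon_ids, sprintf(
    "d__Bacteria;p__Phylum_%02d;c__Class;o__Order;f__Family;g__Genus_%s",
    (seq_len(spec$n_taxa) - 1L) %% 8L + 1L, spec$taxon_ids))
  gap <- apply(spec$occurrence, 1L, function(x) max(x) - min(x))
  truth <- list(
    core = spec$planted$core,
    discriminatory = spec$planted$discriminatory,
    diff_abundant = which(spec$planted$lfc != 0),
    lfc = spec$planted$lfc,
    contaminants = spec$contaminants,
    occurrence = spec$occurrence,
    occurrence_gap = gap)
  list(table = feature_table(counts), frame = frame, taxonomy = tax,
       truth = truth)
}

#' Default study-shaped community spec
#'
#' Returns a spec whose sampling design mirrors a large multi-campaign
#' drinking-water / reuse survey: 244 conventional potable, 53 potable reuse
#' and 177 nonpotable reuse samples plus 30 blanks at \code{scale = 1}, each
#' group scaled as \code{ceiling(scale * n)} and split evenly between the POC
#' and POU strata.  The planted community contains, per direction, three
#' discriminatory taxa (occurrence 0.9 in their core group vs 0.1 in the
#' contrast, planted |log-fold change| = 2 on the natural-log scale), a shared
#' high-occurrence backbone, blank-enriched contaminants, and a background of
#' taxa whose between-group occurrence gaps stay below 0.3 (false-positive
#' controls for the discriminatory classifier).
#'
#' @param scale positive scaling factor on the group sizes.
#' @param n_taxa total number of taxa (at least 20).
#' @param seed integer seed stored in the spec.
#' @return A \code{\link{community_spec}}.
#' @export
default_paper_like_spec <- function(scale = 1, n_taxa = 40L, seed = 1L) {
  stopifnot(scale > 0, n_taxa >= 20L)
  totals <- ceiling(scale * c(244L, 53L, 177L))
  poc <- ceiling(totals / 2)
  gs <- cbind(POC = poc, POU = totals - poc)
  rownames(gs) <- WATER_USES
  n_blanks <- ceiling(scale * 30L)

  idx_np <- 1:3      # discriminatory, nonpotable-enriched
  idx_pot <- 4:6     # discriminatory, potable-enriched
  idx_cont <- 7:9    # contaminants
  idx_back <- 10:13  # shared core backbone
  idx_bg <- 14:n_taxa

  set.seed(as.integer(seed))
  occ <- matrix(0, n_taxa, 3L, dimnames = list(NULL, WATER_USES))
  occ[idx_np, ] <- matrix(c(0.1, 0.1, 0.9), length(idx_np), 3L, byrow = TRUE)
  occ[idx_pot, ] <- matrix(c(0.9, 0.9, 0.1), length(idx_pot), 3L, byrow = TRUE)
  occ[idx_cont, ] <- 0.05
  occ[idx_back, ] <- 0.95
  bg_base <- stats::runif(length(idx_bg), 0.3, 0.65)
  jitter <- matrix(stats::runif(length(idx_bg) * 3L, -0.1, 0.1),
                   ncol = 3L)
  occ[idx_bg, ] <- pmin(0.99, pmax(0.01, bg_base + jitter))

  lfc <- rep(0, n_taxa)
  lfc[idx_np] <- 2
  lfc[idx_pot] <- -2
  base <- stats::rnorm(n_taxa, 0, 1)
  # planted core/discriminatory taxa sit at the community-mean abundance so
  # that presence implies detection and realized detection frequencies track
  # the occurrence probabilities (the generator's detection contract)
  base[c(idx_np, idx_pot, idx_back)] <- 0
  la <- cbind(base, base, base + lfc)
  colnames(la) <- WATER_USES

  blank_occ <- rep(0.05, n_taxa)
  blank_occ[idx_cont] <- 0.5  # 10x blank enrichment
  blank_la <- rep(0, n_taxa)
  blank_la[idx_cont] <- 1.5

  disc <- rbind(
    expand.grid(taxon = idx_np, group = "nonpotable_reuse",
                contrast = c("potable_conventional", "potable_reuse"),
                stringsAsFactors = FALSE),
    expand.grid(taxon = idx_pot, group = "potable_conventional",
                contrast = "nonpotable_reuse", stringsAsFactors = FALSE))
  planted <- list(
    core = list(nonpotable_reuse = c(idx_np, idx_back),
                potable_conventional = c(idx_pot, idx_back),
                potable_reuse = c(idx_pot, idx_back)),
    discriminatory = disc,
    lfc = lfc)
  community_spec(group_sizes = gs, occurrence = occ, log_abundance = la,
                 concentration = 50, depth_meanlog = log(2e4),
                 depth_sdlog = 0.4, n_blanks = n_blanks,
                 blank_occurrence = blank_occ,
                 blank_log_abundance = blank_la,
                 contaminants = idx_cont, planted = planted, seed = seed)
}
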