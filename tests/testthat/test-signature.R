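# small deterministic study: 2 taxa patterns across three uses and two strata
signature_fixture <- function() {
  n_per <- 10  # per use x location cell
  ids <- sprintf("s%02d", 1:(n_per * 6))
  use <- rep(c("potable_conventional", "potable_reuse", "nonpotable_reuse"),
             each = 2 * n_per)
  loc <- rep(rep(c("POC", "POU"), each = n_per), 3)
  x <- matrix(0L, 4, length(ids),
              dimnames = list(c("everywhere", "np_only", "absent", "filler"),
                              ids))
  x["everywhere", ] <- 3L
  x["np_only", use == "nonpotable_reuse"] <- 2L
  x["filler", ] <- 1L
  list(table = feature_table(x), frame = simple_frame(ids, use, loc))
}

test_that("detection frequencies hit the degenerate endpoints", {
  fx <- signature_fixture()
  prof <- detection_frequencies(fx$table, fx$frame)
  ev <- prof[prof$taxon == "everywhere", ]
  expect_true(all(ev$freq == 1))
  ab <- prof[prof$taxon == "absent", ]
  expect_true(all(ab$freq == 0))
  np <- prof[prof$taxon == "np_only", ]
  expect_true(all(np$freq[np$group == "nonpotable_reuse"] == 1))
  expect_true(all(np$freq[np$group != "nonpotable_reuse"] == 0))
  expect_equal(unique(prof$n[prof$stratum == "combined"]), 20L)
  expect_equal(unique(prof$n[prof$stratum == "POC"]), 10L)
})

test_that("frequencies ignore abundance rescaling and excluded samples", {
  fx <- signature_fixture()
  scaled <- unclass(fx$table)
  scaled[, 3] <- scaled[, 3] * 50L
  expect_equal(detection_frequencies(feature_table(scaled), fx$frame),
               detection_frequencies(fx$table, fx$frame))
  # atypical samples drop out of the denominators
  fr2 <- fx$frame
  fr2$atypical[fr2$sample_id %in% sprintf("s%02d", 1:5)] <- TRUE
  prof <- detection_frequencies(fx$table, fr2)
  expect_equal(unique(prof$n[prof$stratum == "POC" &
                               prof$group == "potable_conventional"]), 5L)
})

test_that("core calls use a strict 80% threshold", {
  prof <- data.frame(taxon = c("a", "b", "c"), stratum = "combined",
                     group = "nonpotable_reuse", n = 1000,
                     freq = c(0.80, 0.801, 0.79))
  out <- call_core(prof)
  expect_identical(out$core, c(FALSE, TRUE, FALSE))
})

test_that("discriminatory calls follow the two strict criteria exactly", {
  mk <- function(freq_a, freq_b) {
    prof <- data.frame(
      taxon = "t", stratum = "combined",
      group = c("nonpotable_reuse", "potable_conventional",
                "potable_reuse"),
      n = 100, freq = c(freq_a, freq_b, freq_b))
    d <- call_discriminatory(call_core(prof))
    d[d$group == "nonpotable_reuse" & d$contrast == "potable_conventional", ]
  }
  both <- mk(0.9, 0.1)       # freq_B < 0.2 and gap 0.8 > 0.6
  expect_true(both$discriminatory)
  expect_equal(both$criterion, "both")
  neither <- mk(0.85, 0.30)  # 0.30 >= 0.2 and gap 0.55 <= 0.6
  expect_false(neither$discriminatory)
  gap_only <- mk(0.85, 0.24) # gap 0.61 > 0.6
  expect_true(gap_only$discriminatory)
  expect_equal(gap_only$criterion, "gap")
  not_core <- mk(0.80, 0.05) # fails the strict core threshold
  expect_false(not_core$discriminatory)
})

test_that("every discriminatory taxon is core in its named group", {
  sim <- simulate_study(default_paper_like_spec(scale = 0.1, seed = 6))
  prof <- call_core(detection_frequencies(sim$table, sim$frame))
  disc <- call_discriminatory(prof)
  hit <- disc[disc$discriminatory, ]
  for (i in seq_len(nrow(hit))) {
    core <- prof$core[prof$taxon == hit$taxon[i] &
                        prof$stratum == hit$stratum[i] &
                        prof$group == hit$group[i]]
    expect_true(core)
  }
})

test_that("detection is monotone under taxonomic aggregation", {
  sim <- simulate_study(default_paper_like_spec(scale = 0.05, seed = 8))
  gen <- call_core(detection_frequencies(sim$table, sim$frame, "combined"))
  phy <- collapse_by_rank(sim$table, sim$taxonomy, "phylum")
  pf <- detection_frequencies(phy, sim$frame, "combined")
  lin <- lineage_string_for_test(sim$taxonomy)
  for (i in which(gen$core)) {
    parent <- lin[match(gen$taxon[i], sim$taxonomy$taxon_id)]
    f_phy <- pf$freq[pf$taxon == parent & pf$group == gen$group[i]]
    expect_gte(f_phy, gen$freq[i])
  }
})

test_that("planted discriminatory relationships are recovered with high pooled sensitivity", {
  found <- 0L
  total <- 0L
  fp <- 0L
  for (seed in 1:10) {
    sim <- simulate_study(default_paper_like_spec(scale = 0.25, seed = seed))
    calls <- score_contaminants(sim$table, sim$frame, 0.1)
    tab <- filter_contaminants(sim$table, calls, sim$frame)
    disc <- call_discriminatory(call_core(
      detection_frequencies(tab, sim$frame, "combined")))
    hit <- disc[disc$discriminatory, ]
    ids <- rownames(sim$table)
    planted <- sim$truth$discriminatory
    for (i in seq_len(nrow(planted))) {
      total <- total + 1L
      found <- found + any(hit$taxon == ids[planted$taxon[i]] &
                             hit$group == planted$group[i] &
                             hit$contrast == planted$contrast[i])
    }
    controls <- ids[sim$truth$occurrence_gap < 0.3]
    fp <- fp + length(intersect(hit$taxon, controls))
  }
  expect_gte(found / total, 0.9)
  expect_identical(fp, 0L)
})

test_that("ANCOM finds a planted enrichment with the right sign and W", {
  spec <- default_paper_like_spec(scale = 0.25, seed = 12)
  sim <- simulate_study(spec)
  anc <- ancom_test(sim$table, sim$frame, "combined")
  m <- nrow(sim$table)
  for (i in sim$truth$diff_abundant) {
    expect_true(anc$significant[i])
    expect_gte(anc$W[i], 0.7 * (m - 1))
    expect_equal(sign(anc$lfc[i]), sign(sim$truth$lfc[i]))
  }
})

test_that("swapping group labels negates every LFC exactly", {
  sim <- simulate_study(default_paper_like_spec(scale = 0.05, seed = 9))
  anc <- ancom_test(sim$table, sim$frame, "combined")
  swapped <- sim$frame
  swapped$water_use[sim$frame$water_use == "nonpotable_reuse"] <-
    "potable_conventional"
  swapped$water_use[sim$frame$water_use %in%
                      c("potable_conventional", "potable_reuse")] <-
    "nonpotable_reuse"
  anc2 <- ancom_test(sim$table, swapped, "combined")
  expect_equal(anc2$lfc, -anc$lfc, tolerance = 1e-12)
  expect_identical(anc2$W, anc$W)
})

test_that("ANCOM refuses degenerate inputs", {
  sim <- simulate_study(default_paper_like_spec(scale = 0.05, seed = 10))
  two <- feature_table(unclass(sim$table)[1:2, ])
  expect_error(ancom_test(two, sim$frame, "combined"), "at least 3 taxa")
})

test_that("consensus requires all three comparisons and the LFC cutoff", {
  mk_anc <- function(sig, lfc) {
    out <- data.frame(taxon = c("t1", "t2", "t3"), W = ifelse(sig, 30L, 0L),
                      significant = sig, lfc = lfc)
    class(out) <- c("ancom_result", "data.frame")
    out
  }
  disc <- data.frame(taxon = character(0), stratum = character(0),
                     group = character(0), contrast = character(0),
                     discriminatory = logical(0))
  # t1: significant everywhere, LFCs (2.0, 1.8, 1.0) -> average 1.6 > 1.5
  # t2: significant at POC and POU only -> excluded
  # t3: significant everywhere but average LFC 1.2 -> excluded
  cons <- consensus_signatures(
    disc,
    mk_anc(c(TRUE, FALSE, TRUE), c(2.0, 3.0, 1.2)),
    mk_anc(c(TRUE, TRUE, TRUE), c(1.8, 3.0, 1.2)),
    mk_anc(c(TRUE, TRUE, TRUE), c(1.0, 3.0, 1.2)),
    lfc_threshold = 1.5)
  expect_equal(cons$average_lfc[cons$taxon == "t1"], 1.6)
  expect_true(cons$consensus[cons$taxon == "t1"])
  expect_false(cons$consensus[cons$taxon == "t2"])
  expect_false(cons$significant_all_three[cons$taxon == "t2"])
  expect_false(cons$consensus[cons$taxon == "t3"])
  expect_equal(cons$direction[cons$taxon == "t1"], "nonpotable_enriched")
  expect_error(consensus_signatures(disc, mk_anc(TRUE, 1), NULL,
                                    mk_anc(TRUE, 1)),
               "all three")
})
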