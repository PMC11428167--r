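# Shared fixtures and independent oracles used across the suite.

toy_table <- function() {
  feature_table(matrix(c(3L, 5L, 0L,
                         1L, 0L, 2L),
                       nrow = 3L,
                       dimnames = list(c("t1", "t2", "t3"), c("S1", "S2"))))
}

random_table <- function(n_taxa, n_samples, seed = 1, lambda = 15) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
              dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                              sprintf("s%02d", seq_len(n_samples))))
  feature_table(m)
}

simple_frame <- function(sample_ids, water_use, location,
                         is_blank = rep(FALSE, length(sample_ids)),
                         atypical = rep(FALSE, length(sample_ids))) {
  sample_frame(data.frame(sample_id = sample_ids, water_use = water_use,
                          location = location, is_blank = is_blank,
                          atypical = atypical, stringsAsFactors = FALSE))
}

# Exhaustive two-group ANOSIM oracle: enumerates every distinct assignment of
# n1 samples to group 1 and recomputes R from first principles.
oracle_anosim <- function(dm, groups) {
  n <- attr(dm, "Size")
  lev <- unique(groups)
  stopifnot(length(lev) == 2L)
  n1 <- sum(groups == lev[1L])
  rk <- rank(as.vector(dm))
  M <- n * (n - 1) / 2
  pairs <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  r_of <- function(members1) {
    in1 <- seq_len(n) %in% members1
    within <- in1[pairs[, 1]] == in1[pairs[, 2]]
    (mean(rk[!within]) - mean(rk[within])) / (M / 2)
  }
  r_obs <- r_of(which(groups == lev[1L]))
  r_all <- apply(utils::combn(n, n1), 2L, r_of)
  list(r = r_obs, p = mean(r_all >= r_obs - 1e-12))
}

# IUPAC-aware semi-global alignment oracle: minimum edit distance of the
# primer against any substring of the read (primer aligned globally,
# substitutions and indels unit cost, degenerate symbols match at zero cost).
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

oracle_primer_edit <- function(read, primer) {
  r <- strsplit(toupper(read), "")[[1]]
  p <- strsplit(toupper(primer), "")[[1]]
  n <- length(r); m <- length(p)
  # dp[i+1, j+1] = min edits aligning primer[1..j] ending at read position i;
  # free start anywhere in the read (semi-global)
  dp <- matrix(Inf, n + 1L, m + 1L)
  dp[, 1L] <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      cost <- if (r[i - 1L] %in% IUPAC_SETS[[p[j - 1L]]]) 0 else 1
      dp[i, j] <- min(dp[i - 1L, j - 1L] + cost,  # sub/match
                      dp[i - 1L, j] + 1,          # read insertion
                      dp[i, j - 1L] + 1)          # primer deletion
    }
  }
  min(dp[, m + 1L])
}

lineage_string_for_test <- function(tax) {
  paste(tax$domain, tax$phylum, sep = ";")
}

# Hand-applied Benjamini-Yekutieli adjustment.
oracle_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  run <- rev(cummin(rev(pmin(1, m * cm * sorted / seq_len(m)))))
  adj[o] <- run
  adj
}
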