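## Shared constructor for permutation-test results.  Results carry the sample
## ids and grouping they were computed on so the homogeneity gate can verify
## that two results refer to the same comparison.
perm_test_result <- function(method, statistic, p_value, n_permutations,
                             sample_ids, groups, extra = list()) {
  structure(c(list(method = method, statistic = statistic, p_value = p_value,
                   n_permutations = n_permutations, sample_ids = sample_ids,
                   groups = groups, homogeneity_ok = NA), extra),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (%s permutations)\n",
              x$method, x$statistic, x$p_value,
              if (isTRUE(x$exhaustive)) "exhaustive" else x$n_permutations))
  if (!is.null(x$r_squared)) {
    cat("R2 by term:\n")
    print(round(x$r_squared, 4))
  }
  if (!is.na(x$homogeneity_ok))
    cat("homogeneity gate:", if (x$homogeneity_ok) "passed" else
      "FAILED - heterogeneous dispersions, interpret conservatively", "\n")
  invisible(x)
}

check_dist_groups <- function(dm, groups, min_size = 2L) {
  if (!inherits(dm, "dist")) stop("dm must be a stats::dist object")
  n <- attr(dm, "Size")
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups length must match the distance matrix")
  if (anyNA(groups)) stop("groups must be defined for every sample")
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  small <- names(sizes)[sizes < min_size]
  if (length(small))
    stop("group(s) with fewer than ", min_size, " members: ",
         paste(small, collapse = ", "))
  groups
}

## ANOSIM R for a rank vector and a within-pair indicator.
anosim_r <- function(rk, within, M) {
  (mean(rk[!within]) - mean(rk[within])) / (M / 2)
}

pair_within <- function(groups) {
  g <- as.integer(factor(groups))
  d <- stats::dist(g)  # 0 iff same group
  d == 0
}

#' Analysis of similarities (ANOSIM)
#'
#' Ranks all n(n-1)/2 dissimilarities and computes
#' R = (mean between-group rank - mean within-group rank) / (M/2) with
#' M = n(n-1)/2, so R lies in [-1, 1] and is invariant to any monotone
#' transform of the dissimilarities.  The p-value is obtained by permuting the
#' group labels with the +1 correction,
#' p = (1 + #\{R* >= R\}) / (1 + n_perm); with \code{exhaustive = TRUE} (two
#' groups only) every distinct relabelling is enumerated instead and p is the
#' exact proportion of relabellings with R* >= R.
#'
#' @param dm a \code{dist} of dissimilarities.
#' @param groups group label per sample; every group needs >= 2 members.
#' @param n_perm number of random permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param exhaustive enumerate all relabellings (two-group designs).
#' @return A \code{perm_test_result} with the R statistic.
#' @export
anosim <- function(dm, groups, n_perm = 1000, seed = 1L, exhaustive = FALSE) {
  groups <- check_dist_groups(dm, groups)
  n <- attr(dm, "Size")
  M <- n * (n - 1) / 2
  rk <- rank(as.vector(dm))
  within <- pair_within(groups)
  r_obs <- anosim_r(rk, within, M)

  if (exhaustive) {
    lev <- unique(groups)
    if (length(lev) != 2L)
      stop("exhaustive enumeration implemented for two groups only")
    n1 <- sum(groups == lev[1L])
    combos <- utils::combn(n, n1)
    r_all <- apply(combos, 2L, function(ix) {
      g <- rep(lev[2L], n)
      g[ix] <- lev[1L]
      anosim_r(rk, pair_within(g), M)
    })
    p <- mean(r_all >= r_obs - 1e-12)
    res <- perm_test_result("ANOSIM", r_obs, p, ncol(combos),
                            attr(dm, "Labels"), groups,
                            list(exhaustive = TRUE, permuted = r_all))
    return(res)
  }
  set.seed(as.integer(seed))
  r_perm <- vapply(seq_len(n_perm), function(i) {
    g <- sample(groups)
    anosim_r(rk, pair_within(g), M)
  }, numeric(1))
  p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_perm)
  perm_test_result("ANOSIM", r_obs, p, n_perm, attr(dm, "Labels"), groups,
                   list(exhaustive = FALSE))
}

## Principal coordinates of a dissimilarity matrix, keeping real and
## imaginary axes separately (negative eigenvalues arise because Bray-Curtis
## is a semimetric).
pcoa_axes <- function(dm) {
  d <- as.matrix(dm)
  n <- nrow(d)
  A <- -0.5 * d^2
  # two sequential sweeps give the full double-centering (I-11'/n)A(I-11'/n)
  G <- sweep(A, 1L, rowMeans(A))
  G <- sweep(G, 2L, colMeans(G))
  eg <- eigen(G, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-8
  pos <- eg$values > tol
  neg <- eg$values < -tol
  list(
    real = eg$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(eg$values[pos]), sum(pos)),
    imag = eg$vectors[, neg, drop = FALSE] %*%
      diag(sqrt(-eg$values[neg]), sum(neg)))
}

dispersion_to_centroids <- function(ax, groups) {
  zsq <- numeric(length(groups))
  for (g in unique(groups)) {
    ix <- groups == g
    cr <- colMeans(ax$real[ix, , drop = FALSE])
    dr2 <- rowSums(sweep(ax$real[ix, , drop = FALSE], 2L, cr)^2)
    di2 <- 0
    if (ncol(ax$imag)) {
      ci <- colMeans(ax$imag[ix, , drop = FALSE])
      di2 <- rowSums(sweep(ax$imag[ix, , drop = FALSE], 2L, ci)^2)
    }
    zsq[ix] <- dr2 - di2
  }
  sqrt(pmax(0, zsq))
}

anova_f <- function(z, groups) {
  n <- length(z)
  g <- length(unique(groups))
  gm <- tapply(z, groups, mean)
  ssb <- sum(tapply(z, groups, length) * (gm - mean(z))^2)
  ssw <- sum((z - gm[groups])^2)
  (ssb / (g - 1)) / (ssw / (n - g))
}

#' Multivariate homogeneity of group dispersions (Betadisper)
#'
#' Embeds the dissimilarities by principal coordinates analysis, measures each
#' sample's distance to its group centroid separately in the real
#' (positive-eigenvalue) and imaginary (negative-eigenvalue) subspaces,
#' combines them as sqrt(max(0, d_real^2 - d_imag^2)), and tests equality of
#' mean dispersion across groups with a one-way ANOVA F whose p-value is
#' obtained by permuting the least-squares residuals of the dispersion model.
#' Used as the homogeneity gate that must pass before location tests (ANOSIM,
#' PERMANOVA) are reported.
#'
#' @inheritParams anosim
#' @return A \code{perm_test_result} with the F statistic and per-sample
#'   dispersions in \code{$dispersions}.
#' @export
betadisper <- function(dm, groups, n_perm = 1000, seed = 1L) {
  groups <- check_dist_groups(dm, groups)
  ax <- pcoa_axes(dm)
  z <- dispersion_to_centroids(ax, groups)
  f_obs <- anova_f(z, groups)
  gm <- tapply(z, groups, mean)
  res <- z - gm[groups]  # least-squares residuals of the one-way model
  set.seed(as.integer(seed))
  f_perm <- vapply(seq_len(n_perm), function(i) {
    anova_f(sample(res), groups)
  }, numeric(1))
  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
  perm_test_result("Betadisper", f_obs, p, n_perm, attr(dm, "Labels"), groups,
                   list(dispersions = stats::setNames(z, attr(dm, "Labels"))))
}

#' Sequential PERMANOVA on a distance matrix
#'
#' Partitions the total sum of squares of the Gower-centered inner-product
#' matrix G = -(1/2) C D^2 C sequentially (Type I) over the supplied model
#' terms, in the given order, via hat matrices of the cumulative design.  Each
#' term reports R^2 = SS_term / SS_total and a pseudo-F against the residual
#' of the full model, with p-values from free permutation of the samples.
#' Term R^2 plus residual R^2 sum to one.
#'
#' @param dm a \code{dist} of dissimilarities.
#' @param data data.frame of per-sample variables, rows aligned with
#'   \code{dm}.
#' @param terms character vector naming the model terms in the order they
#'   enter the model (defaults to all columns of \code{data}).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return A \code{perm_test_result}; \code{$statistic} is the first term's
#'   pseudo-F, with per-term \code{$f}, \code{$r_squared}, \code{$p_values},
#'   \code{$df} and the residual share in \code{$r_squared["Residual"]}.
#' @export
permanova <- function(dm, data, terms = colnames(data), n_perm = 1000,
                      seed = 1L) {
  if (!inherits(dm, "dist")) stop("dm must be a stats::dist object")
  n <- attr(dm, "Size")
  data <- as.data.frame(data)
  if (nrow(data) != n) stop("data rows must match the distance matrix")
  for (tm in terms) {
    if (!tm %in% names(data)) stop("term not found in data: ", tm)
    if (anyNA(data[[tm]])) stop("term has undefined values: ", tm)
  }
  d <- as.matrix(dm)
  A <- -0.5 * d^2
  G <- sweep(A, 1L, rowMeans(A))
  G <- sweep(G, 2L, colMeans(G))
  ss_total <- sum(diag(G))

  hats <- vector("list", length(terms))
  ranks <- integer(length(terms))
  prev_rank <- 1L
  for (j in seq_along(terms)) {
    X <- stats::model.matrix(
      stats::reformulate(terms[seq_len(j)]), data = data)
    qrX <- qr(X)
    if (qrX$rank <= prev_rank)
      stop("collinear or redundant term: ", terms[j])
    Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    hats[[j]] <- tcrossprod(Q)
    ranks[j] <- qrX$rank
    prev_rank <- qrX$rank
  }
  df_terms <- diff(c(1L, ranks))
  df_res <- n - ranks[length(ranks)]
  if (df_res <= 0L)
    stop("saturated design after term: ", terms[length(terms)])

  ss_fun <- function(Gp) {
    cum <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    ss <- diff(c(sum(Gp) / n, cum))  # intercept hat = J/n; tr(JG/n)=sum(G)/n
    res <- ss_total - cum[length(cum)]
    list(ss = ss, res = res,
         f = (ss / df_terms) / (res / df_res))
  }
  obs <- ss_fun(G)
  set.seed(as.integer(seed))
  exceed <- numeric(length(terms))
  for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    fp <- ss_fun(G[p, p])$f
    exceed <- exceed + (fp >= obs$f - 1e-12)
  }
  p_vals <- (1 + exceed) / (1 + n_perm)
  r2 <- c(obs$ss / ss_total, Residual = obs$res / ss_total)
  names(r2) <- c(terms, "Residual")
  perm_test_result(
    "PERMANOVA", unname(obs$f[1L]), unname(p_vals[1L]), n_perm,
    attr(dm, "Labels"), interaction(data[terms], drop = TRUE),
    list(terms = terms, f = stats::setNames(obs$f, terms),
         r_squared = r2, p_values = stats::setNames(p_vals, terms),
         df = stats::setNames(df_terms, terms), df_residual = df_res))
}

#' Gate a location test on homogeneity of dispersions
#'
#' Location tests on dissimilarities (ANOSIM, PERMANOVA) confound location and
#' dispersion differences, so the main result is only marked for reporting
#' after Betadisper confirms homogeneous within-group dispersions
#' (Betadisper p >= alpha).  A failed gate does not suppress the statistic; it
#' marks the result "heterogeneous - interpret conservatively".
#'
#' @param betadisper_result \code{perm_test_result} from
#'   \code{\link{betadisper}}.
#' @param main_result \code{perm_test_result} from \code{\link{anosim}} or
#'   \code{\link{permanova}}, computed on the identical samples and grouping.
#' @param alpha gate significance level (default 0.01).
#' @return \code{main_result} with \code{homogeneity_ok},
#'   \code{betadisper_p} and \code{report} ("report" or "heterogeneous -
#'   interpret conservatively") filled in.
#' @export
gated_report <- function(betadisper_result, main_result, alpha = 0.01) {
  if (!identical(betadisper_result$sample_ids, main_result$sample_ids))
    stop("mismatched sample sets between Betadisper and the main test")
  ok <- betadisper_result$p_value >= alpha
  main_result$homogeneity_ok <- ok
  main_result$betadisper_p <- betadisper_result$p_value
  main_result$gate_alpha <- alpha
  main_result$report <- if (ok) "report" else
    "heterogeneous - interpret conservatively"
  main_result
}
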