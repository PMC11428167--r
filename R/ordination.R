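#' Nonmetric multidimensional scaling with deterministic restarts
#'
#' Finds a k-dimensional configuration minimizing Kruskal's stress-1,
#' sqrt(sum (dhat_ij - e_ij)^2 / sum e_ij^2), where e are configuration
#' distances and dhat is the monotone (isotonic) regression of e on the
#' dissimilarity ranks.  The first restart starts from the principal
#' coordinates of the input; remaining restarts start from random
#' configurations generated from a fixed per-restart seed, so that the best
#' stress is reproducible and non-increasing in the number of restarts.
#' The iterative engine is vegan's \code{monoMDS} (global model).
#'
#' @param dm a \code{dist} of dissimilarities over n >= k + 1 samples.
#' @param k number of ordination dimensions (default 3).
#' @param n_restarts number of starting configurations (default 20).
#' @param seed integer seed; restart i uses seed + i.
#' @return A list of class \code{nmds_fit}: \code{coordinates} (n x k matrix),
#'   \code{stress} (Kruskal stress-1, in [0, 1]), \code{k},
#'   \code{n_restarts}, \code{converged}, \code{best_restart}.
#' @export
nmds <- function(dm, k = 3L, n_restarts = 20L, seed = 1L) {
  if (!inherits(dm, "dist")) stop("dm must be a stats::dist object")
  n <- attr(dm, "Size")
  if (k < 1L) stop("k must be at least 1")
  if (n < k + 1L) stop("need at least k + 1 samples")
  starts <- vector("list", n_restarts)
  pc <- stats::cmdscale(dm, k = k)
  if (ncol(pc) < k) {  # degenerate PCoA: pad with small noise
    set.seed(as.integer(seed))
    pc <- cbind(pc, matrix(stats::rnorm(n * (k - ncol(pc)), sd = 1e-4),
                           n, k - ncol(pc)))
  }
  starts[[1L]] <- pc
  for (i in seq_len(n_restarts)[-1L]) {
    set.seed(as.integer(seed) + i)
    starts[[i]] <- matrix(stats::rnorm(n * k), n, k)
  }
  best <- NULL
  best_i <- NA_integer_
  for (i in seq_len(n_restarts)) {
    fit <- vegan::monoMDS(dm, y = starts[[i]], k = k, model = "global",
                          maxit = 500, smin = 1e-6, sfgrmin = 1e-7)
    if (is.null(best) || fit$stress < best$stress) {
      best <- fit
      best_i <- i
    }
  }
  coords <- best$points
  rownames(coords) <- attr(dm, "Labels")
  structure(list(coordinates = coords, stress = best$stress, k = k,
                 n_restarts = n_restarts,
                 converged = best$icause != 1L, best_restart = best_i),
            class = "nmds_fit")
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("NMDS (k = %d): stress = %.4f after %d restart(s)%s\n",
              x$k, x$stress, x$n_restarts,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}
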