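#' Model and preprocessing hyperparameters
#'
#' Bundles every tunable of the pipeline with the published defaults:
#' fit weight \code{alpha} = 100 and sparsity weight \code{lambda} = 1e-3
#' for the factorization; \code{K} = 5 neighbors and decay 0.9 for WKNKN
#' with equal fusion weights; dominant-energy threshold \code{sigma} = 0.7
#' for the PCA features; GIP scaling constant \code{gammaPrime} = 1.
#' \code{useGraphReg} and \code{useLpq} are ablation switches that remove
#' the graph-Laplacian term and the squared L1,2 penalty respectively.
#'
#' @param alpha nonnegative weight on the fit-to-A term.
#' @param lambda nonnegative weight on the squared L1,2 penalty.
#' @param K positive integer WKNKN neighbor count.
#' @param decay WKNKN weight decay in [0, 1].
#' @param fuseWeights two nonnegative WKNKN fusion weights (microbe-side,
#'   disease-side), not both zero.
#' @param sigma dominant-energy threshold in (0, 1].
#' @param gammaPrime positive GIP bandwidth-scaling constant.
#' @param useGraphReg logical, include the graph-Laplacian regularizer.
#' @param useLpq logical, include the squared L1,2 penalty.
#' @param maxIter maximum alternating iterations per view.
#' @param tol relative objective-change convergence tolerance.
#' @return A list of class \code{"MdaParams"}.
#' @examples
#' mdaParams(alpha = 50)
#' @export
mdaParams <- function(alpha = 100, lambda = 1e-3, K = 5L, decay = 0.9,
                      fuseWeights = c(1, 1), sigma = 0.7, gammaPrime = 1,
                      useGraphReg = TRUE, useLpq = TRUE,
                      maxIter = 500L, tol = 1e-6) {
  stopifnot(alpha >= 0, lambda >= 0, K >= 1, decay >= 0, decay <= 1,
            length(fuseWeights) == 2L, all(fuseWeights >= 0),
            sum(fuseWeights) > 0, sigma > 0, sigma <= 1, gammaPrime > 0,
            maxIter >= 1, tol > 0)
  structure(list(alpha = alpha, lambda = lambda, K = as.integer(K),
                 decay = decay, fuseWeights = fuseWeights, sigma = sigma,
                 gammaPrime = gammaPrime, useGraphReg = isTRUE(useGraphReg),
                 useLpq = isTRUE(useLpq), maxIter = as.integer(maxIter),
                 tol = tol),
            class = "MdaParams")
}

#' @export
print.MdaParams <- function(x, ...) {
  cat("MdaParams:\n")
  cat(sprintf("  alpha = %g, lambda = %g, K = %d, decay = %g\n",
              x$alpha, x$lambda, x$K, x$decay))
  cat(sprintf("  sigma = %g, gammaPrime = %g, fuseWeights = (%g, %g)\n",
              x$sigma, x$gammaPrime, x$fuseWeights[1], x$fuseWeights[2]))
  cat(sprintf("  graph regularization: %s, L1,2 penalty: %s\n",
              x$useGraphReg, x$useLpq))
  cat(sprintf("  maxIter = %d, tol = %g\n", x$maxIter, x$tol))
  invisible(x)
}

# Evaluate expr with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
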