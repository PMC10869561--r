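#' Simulate a sparse low-rank microbe-disease association matrix
#'
#' Generates data with the structure the model assumes: nonnegative latent
#' factors U (m x rank) and V (n x rank) drawn as absolute Gaussians, true
#' score matrix Theta = U V', and a binary observation matrix with ones at
#' the top \code{density} fraction of Theta (then each entry flipped with
#' probability \code{noise}). Defaults emulate the scale of the curated
#' HMDAD-style catalogues this method targets: 292 microbes, 39 diseases,
#' ~4\% density, a low latent rank, no observation noise. The true score
#' matrix is returned so tests can compute oracle ranking ceilings.
#'
#' @param m,n numbers of microbes and diseases.
#' @param rank latent dimension, at most min(m, n).
#' @param density target fraction of observed 1s, in (0, 1).
#' @param noise entry flip probability, in [0, 0.5).
#' @param seed integer seed; the draw is deterministic given it.
#' @return List with \code{A} (binary \linkS4class{AssociationMatrix}) and
#'   \code{theta} (m x n true score matrix).
#' @examples
#' sim <- simulateAssociations(m = 40, n = 12, rank = 2, density = 0.08,
#'                             seed = 7)
#' mean(sim$A@.Data)
#' @export
simulateAssociations <- function(m = 292L, n = 39L, rank = 3L,
                                 density = 0.04, noise = 0, seed = 1L) {
  stopifnot(density > 0, density < 1, noise >= 0, noise < 0.5,
            rank >= 1, rank <= min(m, n))
  nPos <- round(density * m * n)
  if (nPos < 1L) stop("density yields no positive associations")
  withSeed(seed, {
    U <- matrix(abs(stats::rnorm(m * rank)), m, rank)
    V <- matrix(abs(stats::rnorm(n * rank)), n, rank)
    theta <- tcrossprod(U, V)
    A <- matrix(0, m, n)
    A[order(theta, decreasing = TRUE)[seq_len(nPos)]] <- 1
    if (noise > 0) {
      flip <- stats::runif(m * n) < noise
      A[flip] <- 1 - A[flip]
    }
    dimnames(A) <- list(sprintf("microbe%03d", seq_len(m)),
                        sprintf("disease%03d", seq_len(n)))
    dimnames(theta) <- dimnames(A)
    list(A = associationMatrix(A, stage = "binary"), theta = theta)
  })
}

#' Mask a fraction of known associations
#'
#' Uniformly samples \code{round(fraction * #positives)} of the 1-entries
#' and sets them to 0, returning the masked matrix and the held-out
#' positions. Serves the cross-validation and recovery tests.
#'
#' @param A binary-stage \linkS4class{AssociationMatrix}.
#' @param fraction fraction of positives to mask, in (0, 1).
#' @param seed integer seed.
#' @return List with \code{A} (masked \linkS4class{AssociationMatrix}) and
#'   \code{heldOut} (two-column matrix of row/col indices).
#' @export
maskPositives <- function(A, fraction, seed = 1L) {
  stopifnot(is(A, "AssociationMatrix"), fraction > 0, fraction < 1)
  pos <- which(A@.Data == 1)
  nMask <- round(fraction * length(pos))
  if (nMask >= length(pos))
    warning("masking removes every known association")
  held <- withSeed(seed, sample(pos, nMask))
  Am <- A@.Data
  Am[held] <- 0
  list(A = associationMatrix(Am, stage = "binary"),
       heldOut = arrayInd(held, dim(A@.Data),
                          dimnames(A@.Data), useNames = TRUE))
}
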