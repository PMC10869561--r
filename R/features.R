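#' Dominant-energy embedding dimension
#'
#' Smallest x such that the top-x eigenvalues of the similarity matrix carry
#' at least a fraction \code{sigma} of the total spectrum (eigenvalues sorted
#' descending; small negative eigenvalues from numerical noise are clipped to
#' zero before the ratio is formed — the GIP kernel is PSD in theory).
#'
#' @param S \linkS4class{GipKernel} (or any symmetric numeric matrix).
#' @param sigma energy fraction in (0, 1].
#' @return Integer dimension, at least 1.
#' @examples
#' A <- associationMatrix(matrix(c(1, 0, 0, 1), 2, 2,
#'   dimnames = list(c("m1", "m2"), c("d1", "d2"))))
#' energyDim(gipKernel(A, "microbe"), 0.7)
#' @export
energyDim <- function(S, sigma = 0.7) {
  stopifnot(sigma > 0, sigma <= 1)
  v <- if (is(S, "GipKernel")) S@.Data else as.matrix(S)
  if (nrow(v) != ncol(v) || max(abs(v - t(v))) > 1e-8)
    stop("similarity matrix must be symmetric")
  lam <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  lam[lam < 0] <- 0
  tot <- sum(lam)
  if (tot <= 0) stop("degenerate similarity: no positive eigenvalues")
  g <- which(cumsum(lam) / tot >= sigma - 1e-12)[1L]
  max(1L, as.integer(g))
}

#' PCA latent features of a similarity matrix
#'
#' Spectral embedding \eqn{F = U_g \sqrt{\Lambda_g}} from the top-g
#' eigenpairs of the symmetric similarity matrix, with g chosen by
#' [energyDim()]. F reproduces S in the Gram sense: \eqn{F F^T} is the best
#' rank-g PSD approximation of S. Column signs are fixed so each
#' eigenvector's largest-magnitude entry is positive, making runs
#' reproducible across LAPACK builds. Set \code{scaled = FALSE} for the
#' plain eigenvector embedding \eqn{U_g}.
#'
#' @inheritParams energyDim
#' @param scaled logical, scale eigenvectors by the square roots of their
#'   eigenvalues (default TRUE).
#' @return k x g numeric matrix with columns in descending-eigenvalue order.
#' @export
pcaFeatures <- function(S, sigma = 0.7, scaled = TRUE) {
  v <- if (is(S, "GipKernel")) S@.Data else as.matrix(S)
  if (nrow(v) != ncol(v) || max(abs(v - t(v))) > 1e-8)
    stop("similarity matrix must be symmetric")
  eg <- eigen((v + t(v)) / 2, symmetric = TRUE)
  lam <- eg$values
  lam[lam < 0] <- 0
  tot <- sum(lam)
  if (tot <= 0) stop("degenerate similarity: no positive eigenvalues")
  g <- max(1L, which(cumsum(lam) / tot >= sigma - 1e-12)[1L])
  U <- eg$vectors[, seq_len(g), drop = FALSE]
  for (j in seq_len(g)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  F2 <- if (scaled) sweep(U, 2L, sqrt(lam[seq_len(g)]), `*`) else U
  rownames(F2) <- rownames(v)
  F2
}

#' Assemble a view's multi-modal feature set
#'
#' For the microbe view the modalities are the (WKNKN-updated) association
#' matrix A (m x n) and the PCA embedding of the microbe GIP kernel
#' (m x g). For the disease view they are t(A) (n x m) and the embedding of
#' the disease kernel (n x g). Using the WKNKN-updated matrix as modality 1
#' matches the pipeline ordering (completion precedes fitting); pass a
#' binary-stage matrix for the ablated variant.
#'
#' @param A \linkS4class{AssociationMatrix} (normally WKNKN-updated).
#' @param S \linkS4class{GipKernel} for the view's own axis.
#' @param view \code{"microbe"} or \code{"disease"}.
#' @param sigma dominant-energy threshold in (0, 1].
#' @return A \linkS4class{LatentFeatureSet} with two modalities.
#' @export
buildFeatureSet <- function(A, S, view = c("microbe", "disease"),
                            sigma = 0.7) {
  view <- match.arg(view)
  stopifnot(is(A, "AssociationMatrix"), is(S, "GipKernel"), S@axis == view)
  F1 <- if (view == "microbe") A@.Data else t(A@.Data)
  if (nrow(F1) != nrow(S))
    stop("shape mismatch between association matrix and similarity kernel")
  F2 <- pcaFeatures(S, sigma)
  feats <- list(F1, F2)
  new("LatentFeatureSet", view = view, features = feats,
      dims = vapply(feats, ncol, 0L), energyThreshold = sigma)
}
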