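#' K nearest known neighbors of an entity
#'
#' Returns up to K indices of entities (other than the query) that have at
#' least one known association in the binary matrix, ordered by decreasing
#' GIP similarity to the query. Similarity ties are broken by ascending
#' entity index so the ordering is deterministic.
#'
#' @param S \linkS4class{GipKernel} over the entities of one axis.
#' @param A binary-stage \linkS4class{AssociationMatrix}.
#' @param query 1-based entity index on the kernel's axis.
#' @param K maximum number of neighbors.
#' @return Integer vector of neighbor indices (possibly empty).
#' @export
knownNeighbors <- function(S, A, query, K) {
  stopifnot(is(S, "GipKernel"), is(A, "AssociationMatrix"))
  k <- nrow(S)
  if (query < 1L || query > k) stop("query index out of range")
  deg <- if (S@axis == "microbe") rowSums(A@.Data) else colSums(A@.Data)
  cand <- setdiff(which(deg > 0), query)
  if (length(cand) == 0L) return(integer(0))
  ord <- cand[order(-S@.Data[cand, query], cand)]
  ord[seq_len(min(K, length(ord)))]
}

#' WKNKN interaction-likelihood profile for one entity
#'
#' Weighted average of the binary profiles of the query's K nearest known
#' neighbors: neighbor i (in decreasing-similarity order) gets weight
#' \eqn{w_i = \mathrm{decay}^{i-1} S(n_i, q)}, normalized by
#' \eqn{Q = \sum_i S(n_i, q)}. If all neighbor similarities are zero the
#' profile is left at zero.
#'
#' @inheritParams knownNeighbors
#' @param decay weight decay in [0, 1].
#' @return Numeric likelihood vector over the opposite axis, entries in [0, 1].
#' @export
wknknProfile <- function(S, A, query, K, decay = 0.9) {
  nb <- knownNeighbors(S, A, query, K)
  len <- if (S@axis == "microbe") ncol(A) else nrow(A)
  if (length(nb) == 0L) return(numeric(len))
  s <- S@.Data[nb, query]
  Q <- sum(s)
  if (Q == 0) return(numeric(len))
  w <- decay^(seq_along(nb) - 1L) * s
  prof <- if (S@axis == "microbe") {
    colSums(A@.Data[nb, , drop = FALSE] * w)
  } else {
    colSums(t(A@.Data[, nb, drop = FALSE]) * w)
  }
  unname(prof) / Q
}

#' WKNKN completion of the association matrix
#'
#' Replaces the zeros of the binary association matrix with interaction
#' likelihood scores fused from microbe-side and disease-side neighbor
#' profiles: the microbe-wise and disease-wise WKNKN profiles are averaged
#' with weights \code{fuseWeights} and the result is combined with the
#' original matrix by an elementwise maximum, so every curated association
#' is preserved and entries stay in [0, 1]. A single pass is performed.
#'
#' @param A binary-stage \linkS4class{AssociationMatrix}.
#' @param SM,SD \linkS4class{GipKernel} objects for microbes and diseases
#'   (computed from the same binary A).
#' @param params an [mdaParams()] list (uses \code{K}, \code{decay},
#'   \code{fuseWeights}).
#' @return The completed \linkS4class{AssociationMatrix}, stage
#'   \code{"wknkn"}.
#' @examples
#' A <- associationMatrix(matrix(c(1, 0, 1, 0, 1, 0), 3, 2,
#'   dimnames = list(paste0("m", 1:3), c("d1", "d2"))))
#' Aw <- wknknUpdate(A, gipKernel(A, "microbe"), gipKernel(A, "disease"),
#'                   mdaParams(K = 2))
#' all(Aw@.Data >= A@.Data)
#' @export
wknknUpdate <- function(A, SM, SD, params = mdaParams()) {
  stopifnot(is(A, "AssociationMatrix"), stage(A) == "binary",
            is(SM, "GipKernel"), is(SD, "GipKernel"),
            SM@axis == "microbe", SD@axis == "disease",
            nrow(SM) == nrow(A), nrow(SD) == ncol(A))
  m <- nrow(A); n <- ncol(A)
  Am <- matrix(0, m, n)
  for (q in seq_len(m))
    Am[q, ] <- wknknProfile(SM, A, q, params$K, params$decay)
  Ad <- matrix(0, m, n)
  for (q in seq_len(n))
    Ad[, q] <- wknknProfile(SD, A, q, params$K, params$decay)
  w <- params$fuseWeights
  Amd <- (w[1] * Am + w[2] * Ad) / sum(w)
  out <- pmax(A@.Data, Amd)
  out[out > 1] <- 1           # numerical guard; theory bounds entries by 1
  dimnames(out) <- dimnames(A@.Data)
  associationMatrix(out, stage = "wknkn", nDuplicates = A@nDuplicates)
}
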