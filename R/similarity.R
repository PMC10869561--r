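#' Gaussian interaction profile kernel similarity
#'
#' Computes the GIP kernel similarity over microbes (rows of the binary
#' association matrix) or diseases (columns). For entities i and j with
#' binary interaction profiles IP(i), IP(j),
#' \deqn{S(i,j) = \exp(-\gamma \|IP(i) - IP(j)\|^2)}
#' with bandwidth
#' \deqn{\gamma = \gamma' \cdot k / \sum_i \|IP(i)\|^2,}
#' i.e. the scaling constant \eqn{\gamma'} divided by the mean squared
#' profile norm over the k entities of the chosen axis. The bandwidth is
#' always computed from the original binary matrix, before any WKNKN
#' completion. Squared norms of the binary profiles are exact integer counts.
#'
#' @param A binary-stage \linkS4class{AssociationMatrix}.
#' @param axis \code{"microbe"} (rows) or \code{"disease"} (columns).
#' @param gammaPrime positive bandwidth-scaling constant, default 1.
#' @return A \linkS4class{GipKernel}.
#' @examples
#' A <- associationMatrix(matrix(c(1, 0, 0, 1), 2, 2,
#'   dimnames = list(c("m1", "m2"), c("d1", "d2"))))
#' S <- gipKernel(A, "microbe")
#' S[1, 2]  # exp(-2)
#' @export
gipKernel <- function(A, axis = c("microbe", "disease"), gammaPrime = 1) {
  axis <- match.arg(axis)
  stopifnot(is(A, "AssociationMatrix"))
  if (stage(A) != "binary")
    stop("GIP bandwidth is defined on the binary association matrix")
  if (length(gammaPrime) != 1L || !is.finite(gammaPrime) || gammaPrime <= 0)
    stop("gammaPrime must be a positive scalar")
  P <- if (axis == "microbe") A@.Data else t(A@.Data)
  sq <- rowSums(P)              # binary profiles: squared norm == row sum
  tot <- sum(sq)
  if (tot == 0) stop("degenerate profiles: association matrix is all zero")
  gamma <- gammaPrime * nrow(P) / tot
  # ||pi - pj||^2 = ||pi||^2 + ||pj||^2 - 2 <pi, pj>
  G <- tcrossprod(P)
  D2 <- outer(sq, sq, `+`) - 2 * G
  D2[D2 < 0] <- 0               # numerical guard
  S <- exp(-gamma * D2)
  S <- (S + t(S)) / 2
  dimnames(S) <- list(rownames(P), rownames(P))
  new("GipKernel", S, axis = axis, bandwidth = gamma,
      gammaPrime = gammaPrime)
}
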