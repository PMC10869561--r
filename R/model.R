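#' Graph Laplacian of a similarity matrix
#'
#' L = D - S with D the diagonal matrix of row sums of S. Row sums of L are
#' zero and L is symmetric positive semidefinite, so the quadratic form
#' tr(G' L G) penalizes score differences between similar entities.
#'
#' @param S \linkS4class{GipKernel} (or symmetric numeric matrix).
#' @return k x k numeric Laplacian matrix.
#' @examples
#' graphLaplacian(matrix(1, 3, 3))  # 3 I - 1
#' @export
graphLaplacian <- function(S) {
  v <- if (is(S, "GipKernel")) S@.Data else as.matrix(S)
  if (nrow(v) != ncol(v) || max(abs(v - t(v))) > 1e-8)
    stop("similarity matrix must be symmetric")
  diag(rowSums(v)) - v
}

# squared L1,2 norm: sum over rows of the squared row-wise L1 norm
l12sq <- function(P) sum(rowSums(abs(P))^2)

#' Per-view factorization objective
#'
#' Evaluates
#' \deqn{\sum_i \|F^{(i)} P^{(i)\top} - G\|_F^2 + \alpha \|G - A\|_F^2
#'       + \mathrm{tr}(G^\top L G) + \lambda \sum_i \|P^{(i)}\|_{1,2}^2}
#' where \eqn{\|P\|_{1,2}^2 = \sum_x (\sum_y |P_{xy}|)^2} (squared row-wise
#' L1 norms). The ablation switches in \code{params} zero the Laplacian and
#' sparsity terms respectively.
#'
#' @param G view latent interaction matrix (k x l).
#' @param P list of projection matrices, P[[i]] is l x g_i.
#' @param F_ list of feature matrices, F_[[i]] is k x g_i.
#' @param A numeric target matrix (k x l), the view-oriented association
#'   matrix.
#' @param L k x k graph Laplacian (ignored when \code{useGraphReg} is off).
#' @param params an [mdaParams()] list.
#' @return Scalar objective value.
#' @export
viewObjective <- function(G, P, F_, A, L, params = mdaParams()) {
  stopifnot(length(P) == length(F_))
  if (!all(dim(G) == dim(A))) stop("shape mismatch: G vs A")
  obj <- params$alpha * sum((G - A)^2)
  for (i in seq_along(F_)) {
    if (ncol(F_[[i]]) != ncol(P[[i]]) || nrow(P[[i]]) != ncol(G) ||
        nrow(F_[[i]]) != nrow(G))
      stop("shape mismatch in modality ", i)
    obj <- obj + sum((tcrossprod(F_[[i]], P[[i]]) - G)^2)
  }
  if (params$useGraphReg) obj <- obj + sum(G * (L %*% G))
  if (params$useLpq)
    obj <- obj + params$lambda * sum(vapply(P, l12sq, 0))
  obj
}

#' Closed-form update of the latent interaction matrix G
#'
#' Exact minimizer of the G-subproblem: solves
#' \deqn{(L + (M + \alpha) I)\, G = \alpha A + \sum_i F^{(i)} P^{(i)\top}}
#' by Cholesky factorization (the left-hand side is symmetric positive
#' definite for \eqn{\alpha > 0} since L is PSD); no explicit inverse is
#' formed. With graph regularization disabled, L drops out and the update
#' reduces to a scalar rescaling of the right-hand side.
#'
#' @inheritParams viewObjective
#' @param chol_lhs optional precomputed Cholesky factor of the left-hand
#'   side (it is constant across iterations).
#' @return The minimizing G.
#' @export
updateG <- function(F_, A, L, P, params = mdaParams(), chol_lhs = NULL) {
  M <- length(F_)
  rhs <- params$alpha * A
  for (i in seq_len(M)) rhs <- rhs + tcrossprod(F_[[i]], P[[i]])
  if (!params$useGraphReg) {
    d <- M + params$alpha
    if (d == 0) stop("singular system: alpha = 0 with no modalities")
    return(rhs / d)
  }
  if (is.null(chol_lhs)) {
    lhs <- L + diag(M + params$alpha, nrow(A))
    chol_lhs <- tryCatch(chol(lhs),
                         error = function(e) stop("singular system: ",
                                                  conditionMessage(e)))
  }
  backsolve(chol_lhs, backsolve(chol_lhs, rhs, transpose = TRUE))
}

#' Sign-split multiplicative update of a projection matrix
#'
#' One nonnegativity-preserving multiplicative step on P for modality i.
#' With \eqn{B = F^\top F + \lambda e e^\top} and \eqn{C = G^\top F}, and
#' \eqn{X^+ = (|X| + X)/2}, \eqn{X^- = (|X| - X)/2},
#' \deqn{P \leftarrow P \odot \frac{P B^- + C^+}{P B^+ + C^- + \epsilon}.}
#' The split keeps the rule valid when F contains negative entries (the PCA
#' modality does); B is PSD so each step does not increase the
#' P-subproblem objective. \eqn{\epsilon = 10^{-12}} guards zero
#' denominators. With the L1,2 penalty ablated the \eqn{\lambda e e^\top}
#' term vanishes.
#'
#' @param F_i k x g feature matrix for this modality.
#' @param G current latent interaction matrix (k x l).
#' @param P_i current l x g nonnegative projection matrix.
#' @param params an [mdaParams()] list (uses \code{lambda}, \code{useLpq}).
#' @param eps denominator guard.
#' @return Updated nonnegative projection matrix.
#' @export
updateP <- function(F_i, G, P_i, params = mdaParams(), eps = 1e-12) {
  if (any(P_i < 0)) stop("projection matrix must be nonnegative")
  B <- crossprod(F_i)
  if (params$useLpq) B <- B + params$lambda
  C <- crossprod(G, F_i)
  num <- P_i %*% pmax(-B, 0) + pmax(C, 0)
  den <- P_i %*% pmax(B, 0) + pmax(-C, 0) + eps
  P_i * num / den
}

#' Fit one view of the factorization
#'
#' Alternates the closed-form G update and the multiplicative P updates
#' from a seeded uniform-[0,1] initialization of the projection matrices
#' until the relative objective change drops below \code{tol} or
#' \code{maxIter} is reached. The objective trace is recorded after every
#' full iteration and is non-increasing. Deterministic given the seed.
#'
#' @param features \linkS4class{LatentFeatureSet} for the view.
#' @param A \linkS4class{AssociationMatrix} in its canonical m x n
#'   orientation (normally WKNKN-updated); the disease view transposes it
#'   internally.
#' @param S \linkS4class{GipKernel} for the view's axis.
#' @param params an [mdaParams()] list.
#' @param seed integer seed for the projection initialization.
#' @param init optional list of initial nonnegative projection matrices
#'   (overrides the seeded initialization).
#' @return A \linkS4class{ViewFit}.
#' @export
fitView <- function(features, A, S, params = mdaParams(), seed = 1L,
                    init = NULL) {
  stopifnot(is(features, "LatentFeatureSet"), is(A, "AssociationMatrix"),
            is(S, "GipKernel"), S@axis == features@view)
  view <- features@view
  Av <- if (view == "microbe") A@.Data else t(A@.Data)
  F_ <- features@features
  M <- length(F_)
  if (nrow(Av) != nrow(F_[[1L]]))
    stop("shape mismatch between association matrix and features")
  l <- ncol(Av)
  L <- if (params$useGraphReg) graphLaplacian(S) else
    matrix(0, nrow(Av), nrow(Av))
  P <- if (!is.null(init)) {
    lapply(init, function(p) { if (any(p < 0)) stop("negative init"); p })
  } else {
    withSeed(seed, lapply(F_, function(f)
      matrix(stats::runif(l * ncol(f)), l, ncol(f))))
  }
  chol_lhs <- if (params$useGraphReg)
    chol(L + diag(M + params$alpha, nrow(Av))) else NULL
  trace <- numeric(0)
  G <- NULL
  converged <- FALSE
  it <- 0L
  for (it in seq_len(params$maxIter)) {
    G <- updateG(F_, Av, L, P, params, chol_lhs)
    for (i in seq_len(M)) P[[i]] <- updateP(F_[[i]], G, P[[i]], params)
    obj <- viewObjective(G, P, F_, Av, L, params)
    if (!is.finite(obj))
      stop("diverged: non-finite objective at iteration ", it)
    trace <- c(trace, obj)
    if (it > 1L) {
      prev <- trace[it - 1L]
      if (abs(prev - obj) <= params$tol * max(1, abs(prev))) {
        converged <- TRUE
        break
      }
    }
  }
  dimnames(G) <- dimnames(Av)
  new("ViewFit", G = G, P = P, objectiveTrace = trace,
      converged = converged, iterations = it, view = view)
}

#' Fuse the two view fits into the final score matrix
#'
#' The disease-view latent matrix is transposed to the microbe x disease
#' orientation and averaged elementwise with the microbe-view matrix.
#'
#' @param fitM microbe-view \linkS4class{ViewFit}.
#' @param fitD disease-view \linkS4class{ViewFit}.
#' @param provenance optional list stored with the prediction.
#' @return An \linkS4class{MdaPrediction}.
#' @export
predictAssociations <- function(fitM, fitD, provenance = list()) {
  stopifnot(is(fitM, "ViewFit"), is(fitD, "ViewFit"))
  Gd <- t(fitD@G)
  if (!all(dim(fitM@G) == dim(Gd)))
    stop("shape mismatch between microbe and disease views after transpose")
  G <- (fitM@G + Gd) / 2
  new("MdaPrediction", scores = G,
      viewFits = list(microbe = fitM, disease = fitD),
      provenance = provenance)
}

#' Full prediction pipeline
#'
#' Runs the complete method on a binary association matrix: GIP kernels on
#' both axes (bandwidth from the binary matrix), single-pass WKNKN
#' completion, PCA feature extraction per view, per-view alternating
#' factorization, and fusion of the two latent matrices into the final
#' m x n score matrix. The microbe view uses \code{seed} and the disease
#' view \code{seed + 1} for their projection initializations.
#'
#' @param A binary-stage \linkS4class{AssociationMatrix}.
#' @param params an [mdaParams()] list.
#' @param seed integer seed.
#' @return An \linkS4class{MdaPrediction}.
#' @examples
#' sim <- simulateAssociations(m = 30, n = 10, rank = 2, density = 0.1,
#'                             seed = 1)
#' pred <- mdaPredict(sim$A, mdaParams(maxIter = 50), seed = 1)
#' dim(scores(pred))
#' @export
mdaPredict <- function(A, params = mdaParams(), seed = 1L) {
  stopifnot(is(A, "AssociationMatrix"), stage(A) == "binary")
  SM <- gipKernel(A, "microbe", params$gammaPrime)
  SD <- gipKernel(A, "disease", params$gammaPrime)
  Aw <- wknknUpdate(A, SM, SD, params)
  featM <- buildFeatureSet(Aw, SM, "microbe", params$sigma)
  featD <- buildFeatureSet(Aw, SD, "disease", params$sigma)
  fitM <- fitView(featM, Aw, SM, params, seed = seed)
  fitD <- fitView(featD, Aw, SD, params, seed = seed + 1L)
  predictAssociations(fitM, fitD,
                      provenance = list(params = params, seed = seed))
}

#' Degree-product baseline scores
#'
#' Naive score for each pair: (row degree) x (column degree) of the binary
#' matrix. Used as the reference ranking that any structure-aware method
#' must beat.
#'
#' @param A binary-stage \linkS4class{AssociationMatrix} (or 0/1 matrix).
#' @return m x n numeric score matrix.
#' @export
degreeBaseline <- function(A) {
  v <- if (is(A, "AssociationMatrix")) A@.Data else as.matrix(A)
  outer(rowSums(v), colSums(v))
}
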