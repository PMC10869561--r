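#' @import methods
NULL

#' AssociationMatrix: a named bipartite microbe-disease association matrix
#'
#' An m x n matrix whose rows are microbes and columns are diseases.
#' At the \code{"binary"} stage entries are 0/1 indicators of curated
#' associations; after WKNKN preprocessing (stage \code{"wknkn"}) entries are
#' interaction-likelihood scores in [0, 1] that dominate the binary entries
#' elementwise. Row and column names are the entity labels and must be unique.
#'
#' @slot .Data numeric matrix of association evidence.
#' @slot stage character, either \code{"binary"} or \code{"wknkn"}.
#' @slot nDuplicates integer, number of duplicate edges collapsed on load
#'   (0 when the object was not built from an edge list).
#'
#' @seealso [associationMatrix()], [readEdgeList()], [wknknUpdate()]
#' @exportClass AssociationMatrix
setClass("AssociationMatrix",
  contains = "matrix",
  representation(stage = "character", nDuplicates = "integer"),
  prototype(stage = "binary", nDuplicates = 0L)
)

setValidity("AssociationMatrix", function(object) {
  v <- object@.Data
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "row and column names (entity labels) are required")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate microbe labels")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate disease labels")
  }
  if (!object@stage %in% c("binary", "wknkn"))
    msg <- c(msg, "stage must be 'binary' or 'wknkn'")
  if (length(v) > 0L && is.numeric(v)) {
    if (object@stage == "binary" && !all(v %in% c(0, 1)))
      msg <- c(msg, "binary stage requires entries in {0, 1}")
    if (object@stage == "wknkn" && (any(v < 0) || any(v > 1 + 1e-12)))
      msg <- c(msg, "wknkn stage requires entries in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' GipKernel: Gaussian interaction profile kernel similarity matrix
#'
#' A k x k symmetric similarity matrix over microbes or diseases, computed
#' from binary interaction profiles with a Gaussian kernel whose bandwidth is
#' scaled by the mean squared profile norm.
#'
#' @slot .Data numeric similarity matrix, symmetric with unit diagonal.
#' @slot axis character, \code{"microbe"} or \code{"disease"}.
#' @slot bandwidth numeric, the realized kernel bandwidth gamma.
#' @slot gammaPrime numeric, the bandwidth-scaling constant gamma'.
#'
#' @seealso [gipKernel()]
#' @exportClass GipKernel
setClass("GipKernel",
  contains = "matrix",
  representation(axis = "character", bandwidth = "numeric",
                 gammaPrime = "numeric")
)

setValidity("GipKernel", function(object) {
  v <- object@.Data
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "must be square")
  else if (max(abs(v - t(v))) > 1e-12) msg <- c(msg, "must be symmetric")
  if (any(v < 0) || any(v > 1 + 1e-12)) msg <- c(msg, "entries must be in (0, 1]")
  if (!object@axis %in% c("microbe", "disease"))
    msg <- c(msg, "axis must be 'microbe' or 'disease'")
  if (length(object@bandwidth) != 1L || object@bandwidth <= 0)
    msg <- c(msg, "bandwidth must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' LatentFeatureSet: per-view multi-modal feature matrices
#'
#' Ordered list of feature matrices for one view. Feature 1 is the (WKNKN
#' updated) association matrix seen from that view; feature 2 is the PCA
#' embedding of the view's GIP similarity, with the embedding dimension
#' chosen by the dominant-energy criterion.
#'
#' @slot view character, \code{"microbe"} or \code{"disease"}.
#' @slot features list of numeric matrices, all with the same row count.
#' @slot dims integer vector of feature column counts.
#' @slot energyThreshold numeric in (0, 1], the dominant-energy fraction.
#'
#' @seealso [buildFeatureSet()], [pcaFeatures()]
#' @exportClass LatentFeatureSet
setClass("LatentFeatureSet",
  representation(view = "character", features = "list", dims = "integer",
                 energyThreshold = "numeric")
)

setValidity("LatentFeatureSet", function(object) {
  msg <- character()
  if (!object@view %in% c("microbe", "disease"))
    msg <- c(msg, "view must be 'microbe' or 'disease'")
  if (length(object@features) < 1L) msg <- c(msg, "at least one feature matrix")
  nr <- vapply(object@features, nrow, 0L)
  if (length(unique(nr)) > 1L)
    msg <- c(msg, "all feature matrices must have the same number of rows")
  if (!identical(object@dims, vapply(object@features, ncol, 0L)))
    msg <- c(msg, "dims must match feature column counts")
  if (any(object@dims < 1L)) msg <- c(msg, "feature dimensions must be >= 1")
  if (length(msg)) msg else TRUE
})

#' ViewFit: fitted state of one view's factorization
#'
#' Holds the common latent interaction matrix G, the nonnegative projection
#' matrices (one per feature modality), the objective trace of the
#' alternating solver, and convergence metadata.
#'
#' @slot G numeric matrix, the view's common latent interaction matrix.
#' @slot P list of nonnegative projection matrices.
#' @slot objectiveTrace numeric vector of objective values per iteration.
#' @slot converged logical.
#' @slot iterations integer, iterations actually run.
#' @slot view character, \code{"microbe"} or \code{"disease"}.
#'
#' @seealso [fitView()]
#' @exportClass ViewFit
setClass("ViewFit",
  representation(G = "matrix", P = "list", objectiveTrace = "numeric",
                 converged = "logical", iterations = "integer",
                 view = "character")
)

setValidity("ViewFit", function(object) {
  msg <- character()
  if (any(vapply(object@P, function(p) any(p < 0), NA)))
    msg <- c(msg, "projection matrices must be nonnegative")
  if (!all(is.finite(object@G))) msg <- c(msg, "G must be finite")
  if (length(msg)) msg else TRUE
})

#' MdaPrediction: final fused association score matrix
#'
#' The elementwise average of the microbe-view and (transposed) disease-view
#' latent interaction matrices, with fitting provenance.
#'
#' @slot scores numeric m x n matrix of association scores.
#' @slot viewFits list with elements \code{microbe} and \code{disease}
#'   (\linkS4class{ViewFit} objects).
#' @slot provenance list of hyperparameters and seeds used.
#'
#' @seealso [mdaPredict()], [predictAssociations()]
#' @exportClass MdaPrediction
setClass("MdaPrediction",
  representation(scores = "matrix", viewFits = "list", provenance = "list")
)

setValidity("MdaPrediction", function(object) {
  if (!all(is.finite(object@scores))) "scores must be finite" else TRUE
})

#' CVResult: cross-validation outcome
#'
#' @slot scheme character, \code{"loocv"} or \code{"kfold"}.
#' @slot auc numeric, pooled (LOOCV) or mean-over-repeats (k-fold) AUC.
#' @slot aucSD numeric, SD of per-repeat AUCs (k-fold; NA for LOOCV).
#' @slot perRepeatAUC numeric vector of per-repeat AUCs (k-fold).
#' @slot ranks numeric vector, midrank of each held-out positive among the
#'   candidate (unvalidated) pairs.
#' @slot roc data.frame with columns \code{fpr}, \code{tpr}.
#' @slot foldAssignments list (k-fold) mapping positives to folds per repeat.
#' @slot nCandidates integer, size of the candidate set.
#'
#' @seealso [globalLoocv()], [kfoldCv()]
#' @exportClass CVResult
setClass("CVResult",
  representation(scheme = "character", auc = "numeric", aucSD = "numeric",
                 perRepeatAUC = "numeric", ranks = "numeric",
                 roc = "data.frame", foldAssignments = "list",
                 nCandidates = "integer")
)

setValidity("CVResult", function(object) {
  msg <- character()
  if (!object@scheme %in% c("loocv", "kfold"))
    msg <- c(msg, "scheme must be 'loocv' or 'kfold'")
  if (length(object@auc) == 1L && (object@auc < 0 || object@auc > 1))
    msg <- c(msg, "auc must be in [0, 1]")
  if (length(object@ranks) &&
      (any(object@ranks < 0.5) || any(object@ranks > object@nCandidates + 1)))
    msg <- c(msg, "ranks out of range")
  if (length(msg)) msg else TRUE
})
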