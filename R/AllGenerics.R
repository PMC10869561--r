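#' Accessors for latentMDA classes
#'
#' Small accessor generics so slots are never reached into directly:
#' \code{stage()} returns the processing stage of an
#' \linkS4class{AssociationMatrix}; \code{bandwidth()} and
#' \code{gammaPrime()} the realized and requested kernel bandwidth of a
#' \linkS4class{GipKernel}; \code{scores()} the fused score matrix of an
#' \linkS4class{MdaPrediction}; \code{objectiveTrace()} the per-iteration
#' objective values of a \linkS4class{ViewFit}; \code{auc()} the AUC of a
#' \linkS4class{CVResult}.
#'
#' @param x object to access.
#' @return The slot value (see above).
#' @name accessors
#' @examples
#' A <- associationMatrix(matrix(c(1, 0, 0, 1), 2, 2,
#'   dimnames = list(c("m1", "m2"), c("d1", "d2"))))
#' stage(A)
NULL

#' @rdname accessors
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))

#' @rdname accessors
#' @export
setGeneric("bandwidth", function(x) standardGeneric("bandwidth"))

#' @rdname accessors
#' @export
setGeneric("gammaPrime", function(x) standardGeneric("gammaPrime"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))

#' @rdname accessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname accessors
#' @export
setMethod("stage", "AssociationMatrix", function(x) x@stage)

#' @rdname accessors
#' @export
setMethod("bandwidth", "GipKernel", function(x) x@bandwidth)

#' @rdname accessors
#' @export
setMethod("gammaPrime", "GipKernel", function(x) x@gammaPrime)

#' @rdname accessors
#' @export
setMethod("scores", "MdaPrediction", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("objectiveTrace", "ViewFit", function(x) x@objectiveTrace)

#' @rdname accessors
#' @export
setMethod("auc", "CVResult", function(x) x@auc)

setMethod("show", "AssociationMatrix", function(object) {
  cat(sprintf("AssociationMatrix: %d microbes x %d diseases [stage: %s]\n",
              nrow(object), ncol(object), object@stage))
  cat(sprintf("  positives: %d (density %.3f)\n",
              sum(object@.Data > 0), mean(object@.Data > 0)))
  if (object@nDuplicates > 0L)
    cat(sprintf("  duplicate edges removed on load: %d\n", object@nDuplicates))
})

setMethod("show", "GipKernel", function(object) {
  cat(sprintf("GipKernel (%s): %d x %d, gamma = %.4g (gamma' = %g)\n",
              object@axis, nrow(object), ncol(object),
              object@bandwidth, object@gammaPrime))
})

setMethod("show", "LatentFeatureSet", function(object) {
  cat(sprintf("LatentFeatureSet (%s view): %d modalities, dims [%s], sigma = %g\n",
              object@view, length(object@features),
              paste(object@dims, collapse = ", "), object@energyThreshold))
})

setMethod("show", "ViewFit", function(object) {
  tr <- object@objectiveTrace
  cat(sprintf("ViewFit (%s view): G %d x %d, %d iterations, %s\n",
              object@view, nrow(object@G), ncol(object@G), object@iterations,
              if (object@converged) "converged" else "max iterations reached"))
  if (length(tr))
    cat(sprintf("  objective: %.6g -> %.6g\n", tr[1L], tr[length(tr)]))
})

setMethod("show", "MdaPrediction", function(object) {
  cat(sprintf("MdaPrediction: %d x %d score matrix\n",
              nrow(object@scores), ncol(object@scores)))
})

setMethod("show", "CVResult", function(object) {
  if (object@scheme == "loocv") {
    cat(sprintf("CVResult (global LOOCV): AUC = %.4f over %d held-out positives\n",
                object@auc, length(object@ranks)))
  } else {
    cat(sprintf("CVResult (k-fold): AUC = %.4f +/- %.4f over %d repeats\n",
                object@auc, object@aucSD, length(object@perRepeatAUC)))
  }
})
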