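#' Accessors for weighted-HSAN objects
#'
#' @param object an object of the relevant class.
#' @param ... passed to methods.
#' @return \code{flowWeights} and \code{flowCounts} return the sparse
#'   area x hospital matrices of an [AreaFlows-class]; \code{hsaAssignment}
#'   the named area -> hospital vector of an [HsaPartition-class];
#'   \code{hsaMembers} a named list of area ids per hospital (empty HSAs are
#'   empty elements); \code{emptyHsas} the hospitals with no service area.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("flowWeights", function(object) standardGeneric("flowWeights"))
#' @rdname accessors
#' @export
setGeneric("flowCounts", function(object) standardGeneric("flowCounts"))
#' @rdname accessors
#' @export
setGeneric("hsaAssignment", function(object) standardGeneric("hsaAssignment"))
#' @rdname accessors
#' @export
setGeneric("hsaMembers", function(object) standardGeneric("hsaMembers"))
#' @rdname accessors
#' @export
setGeneric("emptyHsas", function(object) standardGeneric("emptyHsas"))

#' Posterior sample accessors
#'
#' @param object an [MmFit-class].
#' @param classification name or index of a random classification.
#' @return \code{betaSamples}: matrix of fixed-effect draws;
#'   \code{sigma2Samples}: matrix of variance-component draws;
#'   \code{uSamples}: matrix of random-effect draws for one classification;
#'   \code{devianceTrace}: numeric deviance at each stored state.
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
setGeneric("betaSamples", function(object) standardGeneric("betaSamples"))
#' @rdname fit-accessors
#' @export
setGeneric("sigma2Samples", function(object) standardGeneric("sigma2Samples"))
#' @rdname fit-accessors
#' @export
setGeneric("uSamples", function(object, classification = 1L)
  standardGeneric("uSamples"))
#' @rdname fit-accessors
#' @export
setGeneric("devianceTrace", function(object) standardGeneric("devianceTrace"))

setMethod("flowWeights", "AreaFlows", function(object) object@weights)
setMethod("flowCounts", "AreaFlows", function(object) object@counts)

setMethod("hsaAssignment", "HsaPartition", function(object) object@assignment)

setMethod("hsaMembers", "HsaPartition", function(object) {
  m <- split(names(object@assignment), object@assignment)
  out <- stats::setNames(vector("list", length(object@hospitals)), object@hospitals)
  for (h in object@hospitals) out[[h]] <- sort(if (h %in% names(m)) m[[h]] else character())
  out
})

setMethod("emptyHsas", "HsaPartition", function(object)
  setdiff(object@hospitals, unique(object@assignment)))

setMethod("betaSamples", "MmFit", function(object) object@beta)
setMethod("sigma2Samples", "MmFit", function(object) object@sigma2)
setMethod("uSamples", "MmFit", function(object, classification = 1L)
  object@u[[classification]])
setMethod("devianceTrace", "MmFit", function(object) object@deviance)

setMethod("show", "AreaFlows", function(object) {
  w <- object@weights
  cat(sprintf("AreaFlows: %d areas x %d hospitals (%d nonzero flows)\n",
              nrow(w), ncol(w), length(w@x)))
  top1 <- apply(as.matrix(w), 1L, max)
  cat(sprintf("  mean top-1 hospital share: %.1f%%\n", 100 * mean(top1)))
})

setMethod("show", "HsaPartition", function(object) {
  cat(sprintf("HsaPartition: %d areas -> %d non-empty HSAs (%d hospitals, %d empty)\n",
              length(object@assignment),
              length(unique(object@assignment)),
              length(object@hospitals),
              length(emptyHsas(object))))
})

setMethod("show", "MmDataset", function(object) {
  cat(sprintf("MmDataset: %d persons, %d fixed-effect terms\n",
              length(object@y), ncol(object@X)))
  for (nm in names(object@classifications))
    cat(sprintf("  classification '%s': %d units\n",
                nm, ncol(object@classifications[[nm]])))
})

setMethod("show", "MmFit", function(object) {
  cat(sprintf("MmFit: %d stored samples (burn-in %d, thin %d)\n",
              nrow(object@beta), object@control$burnin, object@control$thin))
  for (k in seq_len(ncol(object@sigma2)))
    cat(sprintf("  sigma2[%s]: posterior mean %.4f\n",
                colnames(object@sigma2)[k], mean(object@sigma2[, k])))
})

setMethod("show", "SimConfig", function(object) {
  p <- object@params
  cat(sprintf("SimConfig: %d areas, %d hospitals, ~%d persons/area, sigma2_u = %.3f\n",
              p$nAreas, p$nHospitals, p$personsPerArea, p$sigma2U))
})
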