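#' @import methods
#' @importFrom Matrix rowSums colSums Matrix sparseMatrix t Diagonal
#' @importClassesFrom Matrix Matrix CsparseMatrix dgCMatrix
NULL

setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' Area-level patient-flow weights
#'
#' Holds, for every residence area with at least one admission, the empirical
#' probability distribution of admissions over hospitals: the weight of
#' hospital j in area a is the fraction of area a's admissions that went to j.
#' These weights define the weighted hospital service area network
#' (weighted-HSAN). Rows are areas, columns hospitals; every row sums to 1.
#'
#' @slot weights sparse \code{dgCMatrix} (areas x hospitals) of flow fractions.
#' @slot counts sparse \code{dgCMatrix} of the underlying admission counts.
#'
#' @seealso [computeAreaWeights()], [assignHsa()], [personWeightMatrix()]
#' @export
setClass("AreaFlows", slots = c(weights = "Matrix", counts = "Matrix"))

setValidity("AreaFlows", function(object) {
  w <- object@weights
  msg <- character()
  if (is.null(rownames(w)) || is.null(colnames(w)))
    msg <- c(msg, "weights must carry area row names and hospital column names")
  if (any(w@x < 0)) msg <- c(msg, "weights must be non-negative")
  rs <- Matrix::rowSums(w)
  if (any(abs(rs - 1) > 1e-9))
    msg <- c(msg, "every area's weights must sum to 1 (within 1e-9)")
  if (!identical(dim(w), dim(object@counts)))
    msg <- c(msg, "weights and counts must have identical dimensions")
  if (length(msg)) msg else TRUE
})

#' Discrete hospital service area partition
#'
#' Assigns every area to the single hospital receiving the plurality of its
#' admissions. Hospitals that never achieve plurality have empty service
#' areas (the study system had 79 hospitals but only 72 HSAs).
#'
#' @slot assignment named character vector, area id -> hospital id.
#' @slot hospitals character vector of all hospitals in the system, including
#'   those with empty service areas.
#' @export
setClass("HsaPartition",
         slots = c(assignment = "character", hospitals = "character"))

setValidity("HsaPartition", function(object) {
  msg <- character()
  if (is.null(names(object@assignment)) || anyNA(names(object@assignment)))
    msg <- c(msg, "assignment must be named by area id")
  if (!all(object@assignment %in% object@hospitals))
    msg <- c(msg, "assigned hospitals must appear in the hospital set")
  if (anyDuplicated(names(object@assignment)))
    msg <- c(msg, "each area may be assigned only once")
  if (length(msg)) msg else TRUE
})

#' Model-ready dataset for a multilevel Poisson fit
#'
#' Bundles the person-level outcome counts, follow-up offset, fixed-effect
#' design matrix and one or more random classifications. Each classification
#' is a sparse person x unit weight matrix whose rows sum to 1; a
#' single-membership classification is the degenerate case where every row is
#' a unit vector.
#'
#' @slot y integer outcome counts, one per person.
#' @slot offset positive follow-up times (years); the model uses their log.
#' @slot X numeric fixed-effect design matrix (including the intercept).
#' @slot classifications named list of sparse \code{dgCMatrix} weight
#'   matrices, one per random classification.
#' @slot personIds character person identifiers (row order of all components).
#' @export
setClass("MmDataset",
         slots = c(y = "integer", offset = "numeric", X = "matrix",
                   classifications = "list", personIds = "character"))

setValidity("MmDataset", function(object) {
  n <- length(object@y)
  msg <- character()
  if (any(object@y < 0)) msg <- c(msg, "outcome counts must be non-negative")
  if (length(object@offset) != n || any(object@offset <= 0))
    msg <- c(msg, "offset must be positive follow-up time for every person")
  if (nrow(object@X) != n) msg <- c(msg, "design matrix row count must match y")
  if (length(object@classifications) < 1 ||
      is.null(names(object@classifications)))
    msg <- c(msg, "at least one named classification is required")
  for (nm in names(object@classifications)) {
    W <- object@classifications[[nm]]
    if (nrow(W) != n) {
      msg <- c(msg, sprintf("classification '%s' must have one row per person", nm))
      next
    }
    if (any(abs(Matrix::rowSums(W) - 1) > 1e-9))
      msg <- c(msg, sprintf("classification '%s' weight rows must sum to 1", nm))
  }
  if (length(msg)) msg else TRUE
})

#' MCMC fit of a multilevel Poisson model
#'
#' Posterior samples for the fixed effects, the random effects of every
#' classification, and the classification variances, plus the deviance trace
#' (-2 x Poisson log-likelihood at each stored state) and per-block
#' acceptance rates.
#'
#' @slot beta matrix of fixed-effect samples (iterations x terms).
#' @slot u named list of random-effect sample matrices (iterations x units).
#' @slot sigma2 matrix of variance-component samples (iterations x
#'   classifications).
#' @slot deviance numeric deviance trace.
#' @slot acceptance list of acceptance rates (betas and each u block).
#' @slot control list echoing burn-in, iterations, thinning, seed and priors.
#' @export
setClass("MmFit",
         slots = c(beta = "matrix", u = "list", sigma2 = "matrix",
                   deviance = "numeric", acceptance = "list", control = "list"))

setValidity("MmFit", function(object) {
  msg <- character()
  if (any(object@sigma2 <= 0)) msg <- c(msg, "sigma2 samples must be positive")
  if (length(object@deviance) != nrow(object@beta))
    msg <- c(msg, "deviance trace length must equal number of stored samples")
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic area-hospital system
#'
#' Parameters of the gravity-flow generator used to emulate the statistical
#' structure of a linked-cohort hospital system: areas and hospitals on a
#' unit square, flows proportional to hospital size times an exponential
#' distance decay, Poisson all-cause admissions and Poisson preventable
#' outcome counts driven by hospital-level random effects.
#'
#' @slot params named list of generator parameters; see [simConfig()].
#' @export
setClass("SimConfig", slots = c(params = "list"))

setValidity("SimConfig", function(object) {
  p <- object@params
  msg <- character()
  for (nm in c("nAreas", "nHospitals", "personsPerArea"))
    if (p[[nm]] < 1) msg <- c(msg, sprintf("%s must be >= 1", nm))
  if (p$flowConcentration <= 0) msg <- c(msg, "flowConcentration must be > 0")
  if (p$sigma2U < 0 || p$sigma2Sla < 0) msg <- c(msg, "variances must be >= 0")
  if (p$admissionRate <= 0 || p$preventableRate <= 0)
    msg <- c(msg, "admission rates must be > 0")
  if (length(msg)) msg else TRUE
})
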