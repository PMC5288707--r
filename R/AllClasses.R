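#' @useDynLib tdcnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

#' TemporalNetwork: a sequence of binary contact snapshots
#'
#' A temporal network on a fixed node set: an ordered sequence of L symmetric
#' binary adjacency matrices A(1)..A(L), each describing the contacts that
#' occurred during one time bin of width \code{delta}. Snapshot indices are
#' 1-based throughout the package. Node identifiers are arbitrary strings
#' mapped to dense matrix indices in first-appearance order.
#'
#' @slot nodes character vector of node identifiers; its order fixes the row
#'   and column order of every snapshot.
#' @slot snapshots list of L sparse symmetric 0/1 matrices
#'   (\code{Matrix::dgCMatrix}) with zero diagonal.
#' @slot delta positive snapshot width, in the time unit of the source
#'   contact list.
#' @slot tStart left edge of the first bin (only meaningful for binned data).
#'
#' @seealso [temporalNetwork()], [binEvents()], [snapshotAt()],
#'   [aggregateNetwork()]
#' @exportClass TemporalNetwork
setClass("TemporalNetwork",
  representation(
    nodes = "character",
    snapshots = "list",
    delta = "numeric",
    tStart = "numeric"
  )
)

setValidity("TemporalNetwork", function(object) {
  n <- length(object@nodes)
  if (length(object@snapshots) < 1L) return("need at least one snapshot")
  if (anyDuplicated(object@nodes)) return("duplicated node identifiers")
  if (length(object@delta) != 1L || !is.finite(object@delta) ||
      object@delta <= 0) {
    return("delta must be a single positive number")
  }
  for (t in seq_along(object@snapshots)) {
    a <- object@snapshots[[t]]
    if (!methods::is(a, "CsparseMatrix")) {
      return(sprintf("snapshot %d is not a sparse Matrix", t))
    }
    if (!all(dim(a) == c(n, n))) {
      return(sprintf("snapshot %d has wrong dimensions", t))
    }
    if (length(a@x) && !all(a@x %in% c(0, 1))) {
      return(sprintf("snapshot %d has entries outside {0,1}", t))
    }
    if (any(Matrix::diag(a) != 0)) {
      return(sprintf("snapshot %d has nonzero diagonal", t))
    }
    if (!Matrix::isSymmetric(a, check.attributes = FALSE)) {
      return(sprintf("snapshot %d is not symmetric", t))
    }
  }
  TRUE
})

#' SpreadingParams: parameters of the discrete-time SIR dynamics
#'
#' Shared by the analytic (linearized) recursion and the Monte Carlo
#' simulator: per-contact per-step infection probability \code{beta},
#' per-step recovery probability \code{mu}, a horizon in steps, and the
#' boundary convention used to resolve snapshots beyond index L
#' (\code{"periodic"}: A(L+1) = A(1); \code{"truncate"}: error).
#'
#' @slot beta infection probability in [0, 1].
#' @slot mu recovery probability in [0, 1].
#' @slot horizon positive integer number of time steps.
#' @slot boundary \code{"periodic"} or \code{"truncate"}.
#' @exportClass SpreadingParams
setClass("SpreadingParams",
  representation(
    beta = "numeric",
    mu = "numeric",
    horizon = "integer",
    boundary = "character"
  )
)

setValidity("SpreadingParams", function(object) {
  if (length(object@beta) != 1L || is.na(object@beta) ||
      object@beta < 0 || object@beta > 1) {
    return("beta must be a single value in [0, 1]")
  }
  if (length(object@mu) != 1L || is.na(object@mu) ||
      object@mu < 0 || object@mu > 1) {
    return("mu must be a single value in [0, 1]")
  }
  if (length(object@horizon) != 1L || is.na(object@horizon) ||
      object@horizon < 1L) {
    return("horizon must be a positive integer")
  }
  if (!object@boundary %in% c("periodic", "truncate")) {
    return("boundary must be 'periodic' or 'truncate'")
  }
  TRUE
})

#' AggregatedNetwork: the static integrated network
#'
#' Time-collapsed view of a [TemporalNetwork-class]: \code{counts[i, j]} is
#' the number of snapshots in which the pair was connected, and
#' \code{binary} marks pairs that were ever connected.
#'
#' @slot nodes character node identifiers (same order as the source network).
#' @slot counts symmetric nonnegative integer sparse matrix of per-pair
#'   contact-snapshot counts.
#' @slot binary symmetric 0/1 sparse matrix, nonzero exactly where
#'   \code{counts} is.
#' @exportClass AggregatedNetwork
setClass("AggregatedNetwork",
  representation(nodes = "character", counts = "ANY", binary = "ANY")
)

setValidity("AggregatedNetwork", function(object) {
  n <- length(object@nodes)
  if (!all(dim(object@counts) == c(n, n))) return("counts has wrong dimensions")
  if (!all(dim(object@binary) == c(n, n))) return("binary has wrong dimensions")
  if (any(object@counts@x < 0)) return("negative contact count")
  if (!all((object@counts > 0) == (object@binary > 0)))
    return("binary does not match the support of counts")
  TRUE
})

#' CentralityScores: per-node scores with method metadata
#'
#' A named real score vector (one entry per node, in node-index order)
#' together with the label of the method that produced it (\code{"tdc"},
#' \code{"sd"}, \code{"td"}, \code{"sc"}, \code{"tc"}, \code{"sb"},
#' \code{"tb"}, \code{"sir"}) and the parameters used.
#'
#' @slot scores named numeric vector, one finite score per node.
#' @slot method method label.
#' @slot params list of the parameters the method was run with (may include
#'   a per-seed simulation summary data.frame under \code{$simulation}).
#' @exportClass CentralityScores
setClass("CentralityScores",
  representation(scores = "numeric", method = "character", params = "list")
)

setValidity("CentralityScores", function(object) {
  if (is.null(names(object@scores))) return("scores must be named by node")
  if (anyDuplicated(names(object@scores))) return("duplicated node names")
  if (any(!is.finite(object@scores))) return("non-finite score")
  if (length(object@method) != 1L) return("method must be a single label")
  TRUE
})

#' ThresholdResult: epidemic threshold of a temporal network
#'
#' Result of solving rho(M(beta)) = 1 for the one-period infection
#' propagator M = prod_t [beta A(t) + (1 - mu) I].
#'
#' @slot betaC the epidemic threshold.
#' @slot mu recovery probability used.
#' @slot rhoAtBetaC spectral radius of M at the returned beta (close to 1
#'   when converged).
#' @slot iterations number of bisection iterations performed.
#' @slot bracket final (lo, hi) bisection interval.
#' @exportClass ThresholdResult
setClass("ThresholdResult",
  representation(
    betaC = "numeric",
    mu = "numeric",
    rhoAtBetaC = "numeric",
    iterations = "integer",
    bracket = "numeric"
  )
)

setValidity("ThresholdResult", function(object) {
  if (length(object@bracket) != 2L) return("bracket must have length 2")
  if (object@bracket[1] > object@betaC || object@betaC > object@bracket[2])
    return("betaC outside bracket")
  TRUE
})

#' ProbabilityVectors: trajectory of the linearized infection recursion
#'
#' Step-wise output of [infectionRecursion()]: the newly-infected
#' probability vectors P(1)..P(t) and their cumulative sums x(1)..x(t)
#' (which may exceed 1; the linear coupling overestimates infection
#' probabilities and the cumulative vector is read as an influence measure,
#' not a probability).
#'
#' @slot x0 initial indicator vector (1 at the seed).
#' @slot newly horizon x N matrix; row r is P(r).
#' @slot cumulative horizon x N matrix; row r is x(r).
#' @exportClass ProbabilityVectors
setClass("ProbabilityVectors",
  representation(x0 = "numeric", newly = "matrix", cumulative = "matrix")
)

setValidity("ProbabilityVectors", function(object) {
  if (any(object@newly < -1e-12)) return("negative newly-infected probability")
  if (!all(dim(object@newly) == dim(object@cumulative)))
    return("newly and cumulative dimensions differ")
  TRUE
})
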