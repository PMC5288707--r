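## Linearized SIR Markov recursion and the temporal dynamics-sensitive
## centrality (TDC).
##
## Under linear coupling (a susceptible node with m infectious neighbours is
## infected with probability m * beta), the expected infectious mass evolves
## by the step matrix H(t) = beta * A(t) + (1 - mu) * I, and the
## newly-infected probability vector at step r for a seed vector x(0) is
## P(r) = beta * A(r) * H(r-1) * ... * H(1) * x(0).  The TDC score of node i
## is the total cumulative infected probability over all nodes at the
## horizon when i is the sole seed.

#' Construct spreading parameters
#'
#' @param beta per-contact per-step infection probability in [0, 1].
#' @param mu per-step recovery probability in [0, 1].
#' @param horizon positive integer number of steps.
#' @param boundary snapshot resolution beyond L: \code{"periodic"}
#'   (A(L+1) = A(1), default) or \code{"truncate"} (error past L).
#' @return a [SpreadingParams-class].
#' @examples
#' spreadingParams(beta = 0.1, mu = 0.1, horizon = 10)
#' @export
spreadingParams <- function(beta, mu, horizon,
                            boundary = c("periodic", "truncate")) {
  boundary <- match.arg(boundary)
  methods::new("SpreadingParams", beta = as.numeric(beta), mu = as.numeric(mu),
    horizon = as.integer(horizon), boundary = boundary)
}

setMethod("show", "SpreadingParams", function(object) {
  cat(sprintf("SpreadingParams: beta = %g, mu = %g, horizon = %d (%s)\n",
    object@beta, object@mu, object@horizon, object@boundary))
})

#' One-step infectious-mass propagation matrix
#'
#' Returns H(t) = beta * A(t) + (1 - mu) * I for the snapshot resolved at
#' index t under the boundary mode of \code{params}. H(t) is symmetric with
#' diagonal 1 - mu.
#'
#' @param net a [TemporalNetwork-class].
#' @param t 1-based step index.
#' @param params a [SpreadingParams-class].
#' @return sparse symmetric matrix H(t).
#' @export
stepMatrix <- function(net, t, params) {
  a <- snapshotAt(net, t, params@boundary)
  params@beta * a + (1 - params@mu) * Matrix::Diagonal(nrow(a))
}

.seedIndex <- function(net, seed) {
  i <- match(as.character(seed), net@nodes)
  if (is.na(i)) stop("unknown seed node: ", seed)
  i
}

#' Linearized infection recursion from a single seed
#'
#' Runs the linear Markov recursion for a single initially infected node:
#' x(1) = beta * A(1) * x(0), and for r >= 1 the newly-infected vector is
#' P(r) = beta * A(r) * y(r - 1) with the infectious-mass vector
#' y(r) = H(r) * y(r - 1), y(0) = x(0). The cumulative vector
#' x(r) = P(1) + ... + P(r) may exceed 1 (linear coupling overestimates;
#' it is read as an influence measure).
#'
#' @param net a [TemporalNetwork-class].
#' @param seed node identifier of the initially infected node.
#' @param params a [SpreadingParams-class].
#' @return a [ProbabilityVectors-class] with rows P(r) and x(r),
#'   r = 1..horizon.
#' @export
infectionRecursion <- function(net, seed, params) {
  i <- .seedIndex(net, seed)
  n <- length(net@nodes)
  horizon <- params@horizon
  x0 <- numeric(n); x0[i] <- 1
  y <- x0
  newly <- matrix(0, horizon, n, dimnames = list(NULL, net@nodes))
  for (r in seq_len(horizon)) {
    a <- snapshotAt(net, r, params@boundary)
    newly[r, ] <- params@beta * as.numeric(a %*% y)
    y <- newly[r, ] + (1 - params@mu) * y
  }
  cumulative <- apply(newly, 2, cumsum)
  if (horizon == 1L) cumulative <- matrix(cumulative, 1, n,
    dimnames = list(NULL, net@nodes))
  methods::new("ProbabilityVectors", x0 = x0, newly = newly,
    cumulative = cumulative)
}

#' Temporal dynamics-sensitive centrality
#'
#' Scores every node i by S_i(t) = sum_j x_j(t), the total cumulative
#' infected probability over all nodes at the horizon under the linearized
#' SIR recursion with i as the sole seed. Two equivalent routes are
#' provided: \code{"onepass"} (default) evaluates the transposed closed form
#' S = sum_r H(1)...H(r-1) (beta A(r) V), V the all-ones vector, by a
#' Horner-style backward accumulation that keeps only one vector and one
#' sparse matrix in memory; \code{"perseed"} runs [infectionRecursion()]
#' once per node. Both use only sparse matrix-vector products; with all
#' snapshots equal the score reduces to the static dynamics-sensitive
#' centrality.
#'
#' @param net a [TemporalNetwork-class].
#' @param params a [SpreadingParams-class].
#' @param route \code{"onepass"} or \code{"perseed"}.
#' @return a [CentralityScores-class] with method \code{"tdc"}.
#' @examples
#' net <- toyFixture("chain_forward")
#' scores(tdcScores(net, spreadingParams(0.1, 0.1, 2)))
#' @export
tdcScores <- function(net, params, route = c("onepass", "perseed")) {
  route <- match.arg(route)
  n <- length(net@nodes)
  horizon <- params@horizon
  if (route == "perseed") {
    s <- vapply(net@nodes, function(v) {
      pv <- infectionRecursion(net, v, params)
      sum(pv@cumulative[horizon, ])
    }, numeric(1))
  } else {
    ones <- rep(1, n)
    acc <- numeric(n)
    for (r in rev(seq_len(horizon))) {
      a <- snapshotAt(net, r, params@boundary)
      w <- params@beta * as.numeric(a %*% ones)
      if (r == horizon) {
        acc <- w
      } else {
        acc <- w + params@beta * as.numeric(a %*% acc) + (1 - params@mu) * acc
      }
    }
    s <- acc
    names(s) <- net@nodes
  }
  methods::new("CentralityScores", scores = s, method = "tdc",
    params = list(beta = params@beta, mu = params@mu, horizon = horizon,
      boundary = params@boundary, route = route))
}

#' Min-max normalization of centrality scores
#'
#' Rescales scores to [0, 1] by (s - min) / (max - min); a constant score
#' vector maps to all zeros. Ranking is preserved, so Kendall-tau
#' comparisons are unaffected; scores are reported unnormalized by default
#' everywhere in the package and this rescaling is opt-in (used for plotting
#' several methods on a shared axis).
#'
#' @param x a [CentralityScores-class].
#' @return a [CentralityScores-class] with scores in [0, 1].
#' @export
normalizeScores <- function(x) {
  stopifnot(methods::is(x, "CentralityScores"))
  s <- x@scores
  rng <- range(s)
  s <- if (rng[2] > rng[1]) (s - rng[1]) / (rng[2] - rng[1]) else 0 * s
  methods::initialize(x, scores = s,
    params = c(x@params, list(normalized = TRUE)))
}

#' Shift normalized scores by one
#'
#' Plotting convenience: the translation S' = normal(S) + 1 places
#' normalized analytic scores and simulated mean outbreak sizes (which are
#' at least 1) on a shared axis. Ranking is unchanged.
#'
#' @param x a [CentralityScores-class] (typically normalized).
#' @return a [CentralityScores-class] with 1 added to every score.
#' @export
shiftedScores <- function(x) {
  stopifnot(methods::is(x, "CentralityScores"))
  methods::initialize(x, scores = x@scores + 1,
    params = c(x@params, list(shifted = TRUE)))
}

#' Accessors for CentralityScores
#'
#' \code{scores} returns the named score vector; \code{scoreMethod} the
#' method label.
#'
#' @param x a [CentralityScores-class].
#' @name CentralityScores-accessors
NULL

#' @rdname CentralityScores-accessors
#' @export
setMethod("scores", "CentralityScores", function(x) x@scores)

#' @rdname CentralityScores-accessors
#' @export
setMethod("scoreMethod", "CentralityScores", function(x) x@method)

setMethod("show", "CentralityScores", function(object) {
  cat(sprintf("CentralityScores (%s): %d nodes\n", object@method,
    length(object@scores)))
  top <- utils::head(sort(object@scores, decreasing = TRUE), 5L)
  cat("  top:", paste(sprintf("%s=%.4g", names(top), top), collapse = ", "),
    "\n")
})

#' @export
#' @method as.data.frame CentralityScores
as.data.frame.CentralityScores <- function(x, ...) {
  data.frame(node = names(x@scores), score = unname(x@scores),
    method = x@method, stringsAsFactors = FALSE)
}

#' Write centrality scores as TSV
#'
#' Columns \code{node}, \code{score}, \code{method}, \code{beta}, \code{mu},
#' \code{t} (the latter three empty for purely structural methods), in
#' deterministic node-index order.
#'
#' @param x a [CentralityScores-class].
#' @param path output file path.
#' @export
writeScores <- function(x, path) {
  stopifnot(methods::is(x, "CentralityScores"))
  g <- function(k) if (is.null(x@params[[k]])) NA else x@params[[k]]
  df <- data.frame(node = names(x@scores), score = unname(x@scores),
    method = x@method, beta = g("beta"), mu = g("mu"), t = g("horizon"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
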