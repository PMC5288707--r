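## Discrete-time Monte Carlo SIR on a temporal network (SI when mu = 0).
##
## Update order within step s, on snapshot A(s):
##   (1) every susceptible node with k infectious neighbours at the start of
##       the step is infected with probability 1 - (1 - beta)^k
##       (independent Bernoulli per infectious contact);
##   (2) every node infectious at the START of the step recovers with
##       probability mu (a node cannot recover in the step it was infected);
##   (3) newly infected nodes become infectious at the next step.
## This is the discrete scheme whose linearization reproduces the analytic
## recursion x(1) = beta A(1) x(0), P(2) = beta A(2) H(1) x(0) exactly.

## deterministic 32-bit substream seed from a base seed and counters,
## via a Lehmer-style mix kept below 2^31 - 1
deriveSeed <- function(base, ...) {
  s <- as.numeric(base) %% 2147483647
  for (k in c(...)) s <- (s * 48271 + as.numeric(k)) %% 2147483647
  as.integer(s)
}

#' Run one SIR realization and count ever-infected nodes
#'
#' Simulates `horizon` steps of the discrete-time SIR process from a single
#' seed node; snapshots beyond L are resolved by the boundary mode of
#' \code{params} (periodic by default). Returns the number of nodes ever
#' infected (states I or R), counting the seed.
#'
#' @param net a [TemporalNetwork-class].
#' @param seed node identifier of the initially infected node.
#' @param params a [SpreadingParams-class].
#' @param rngSeed integer seed for this realization; when \code{NULL} the
#'   current RNG stream is used.
#' @param detail when TRUE, also return the per-node ever-infected
#'   indicator and final compartment sizes.
#' @return integer ever-infected count, or (with \code{detail}) a list with
#'   \code{count}, \code{everInfected} (named logical) and \code{state}
#'   (named character, one of S/I/R).
#' @export
runSIR <- function(net, seed, params, rngSeed = NULL, detail = FALSE) {
  i0 <- .seedIndex(net, seed)
  if (!is.null(rngSeed)) set.seed(rngSeed)
  n <- length(net@nodes)
  inf <- logical(n); inf[i0] <- TRUE   # infectious
  rec <- logical(n)                    # recovered
  beta <- params@beta; mu <- params@mu
  for (s in seq_len(params@horizon)) {
    a <- snapshotAt(net, s, params@boundary)
    sus <- !(inf | rec)
    k <- as.numeric(a %*% inf)
    newInf <- sus & (stats::runif(n) < 1 - (1 - beta)^k)
    recover <- inf & (stats::runif(n) < mu)
    rec <- rec | recover
    inf <- (inf & !recover) | newInf
  }
  ever <- inf | rec
  if (!detail) return(sum(ever))
  state <- ifelse(rec, "R", ifelse(inf, "I", "S"))
  names(state) <- net@nodes
  ev <- ever; names(ev) <- net@nodes
  list(count = sum(ever), everInfected = ev, state = state)
}

#' Simulated spreading influence of every node
#'
#' For every node i, averages the ever-infected count of [runSIR()] over
#' \code{runs} independent replicates seeded at i. Each (seed node,
#' replicate) pair draws from its own deterministic substream derived from
#' \code{rngSeed}, so results are reproducible and independent of
#' evaluation order.
#'
#' @param net a [TemporalNetwork-class].
#' @param params a [SpreadingParams-class].
#' @param runs number of replicates per seed node.
#' @param rngSeed integer base seed.
#' @return a [CentralityScores-class] with method \code{"sir"}; the mean
#'   influence per node is the score and a per-seed summary data.frame
#'   (columns \code{seed}, \code{mean}, \code{sd}, \code{runs},
#'   \code{horizon}) is stored in \code{params$simulation}.
#' @export
spreadingInfluence <- function(net, params, runs, rngSeed = 1L) {
  stopifnot(runs >= 1)
  n <- length(net@nodes)
  m <- numeric(n); sdv <- numeric(n)
  for (i in seq_len(n)) {
    counts <- vapply(seq_len(runs), function(rep)
      as.numeric(runSIR(net, net@nodes[i], params,
        rngSeed = deriveSeed(rngSeed, i, rep))), numeric(1))
    m[i] <- mean(counts)
    sdv[i] <- stats::sd(counts)
  }
  names(m) <- net@nodes
  sim <- data.frame(seed = net@nodes, mean = m, sd = ifelse(is.na(sdv), 0, sdv),
    runs = runs, horizon = params@horizon, stringsAsFactors = FALSE,
    row.names = NULL)
  methods::new("CentralityScores", scores = m, method = "sir",
    params = list(beta = params@beta, mu = params@mu,
      horizon = params@horizon, boundary = params@boundary, runs = runs,
      rngSeed = rngSeed, simulation = sim))
}
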