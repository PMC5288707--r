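## Time-order randomization null model: every (pair, snapshot) contact event
## can be relocated to another snapshot of the SAME pair, provided that slot
## is empty.  Per-pair contact counts, the aggregated network (counts and
## binary), N and L are conserved exactly; only the time order is destroyed.

## window-free triplet view: data.frame(pair, i, j, step) with i < j and a
## pair index shared by all events of the same unordered pair
.pairEvents <- function(net) {
  rows <- vector("list", length(net@snapshots))
  for (t in seq_along(net@snapshots)) {
    e <- .edgeList(net@snapshots[[t]])
    if (nrow(e)) rows[[t]] <- cbind(e, step = t)
  }
  ev <- do.call(rbind, rows)
  if (is.null(ev))
    return(data.frame(pair = integer(0), i = integer(0), j = integer(0),
      step = integer(0)))
  key <- paste(ev$i, ev$j)
  ev$pair <- match(key, unique(key))
  ev[, c("pair", "i", "j", "step")]
}

.netFromPairEvents <- function(net, ev) {
  n <- length(net@nodes)
  L <- length(net@snapshots)
  snaps <- rep(list(.emptySnapshot(net@nodes)), L)
  if (nrow(ev)) {
    for (t in unique(ev$step)) {
      sel <- ev$step == t
      i <- c(ev$i[sel], ev$j[sel]); j <- c(ev$j[sel], ev$i[sel])
      snaps[[t]] <- Matrix::sparseMatrix(i = i, j = j, x = rep(1, length(i)),
        dims = c(n, n), dimnames = list(net@nodes, net@nodes))
    }
  }
  methods::new("TemporalNetwork", nodes = net@nodes, snapshots = snaps,
    delta = net@delta, tStart = net@tStart)
}

#' Randomize the time order of contact events
#'
#' Performs \code{sweeps} randomization passes. Each pass visits every
#' (pair, event) in a fresh random order, draws a candidate snapshot t2
#' uniformly from 1..L, and relocates the event from its current snapshot
#' t1 to t2 if and only if the pair has no event at t2 (t2 = t1 or an
#' occupied slot is a rejected move). The aggregated network, per-pair
#' contact counts, N and L are conserved exactly; burstiness and event
#' correlations along time are destroyed.
#'
#' @param net a [TemporalNetwork-class] with L >= 2.
#' @param rngSeed integer seed; when \code{NULL} the current RNG stream is
#'   used.
#' @param sweeps number of full passes (0 returns the network unchanged);
#'   the default 10 passes mix the per-pair event times to uniformity over
#'   feasible slots on networks of the sizes used here.
#' @param record when TRUE, return the audit log of proposed moves.
#' @return list with \code{network} (the shuffled [TemporalNetwork-class])
#'   and \code{records} (data.frame \code{u}, \code{v}, \code{from_step},
#'   \code{to_step}, \code{accepted}; empty unless \code{record = TRUE}).
#' @export
randomizeTimes <- function(net, rngSeed = NULL, sweeps = 10, record = FALSE) {
  stopifnot(methods::is(net, "TemporalNetwork"))
  L <- length(net@snapshots)
  if (L < 2L) stop("need at least 2 snapshots to randomize time order")
  if (sweeps < 0) stop("sweeps must be >= 0")
  if (!is.null(rngSeed)) set.seed(rngSeed)
  ev <- .pairEvents(net)
  emptyRec <- data.frame(u = character(0), v = character(0),
    from_step = integer(0), to_step = integer(0), accepted = logical(0))
  if (nrow(ev) == 0L || sweeps == 0L)
    return(list(network = net, records = emptyRec))
  res <- shuffle_sweeps_cpp(as.integer(ev$pair), as.integer(ev$step),
    max(ev$pair), L, as.integer(sweeps), isTRUE(record))
  ev$step <- res$step
  shuffled <- .netFromPairEvents(net, ev)
  records <- emptyRec
  if (record && length(res$rec_pair)) {
    firstOfPair <- ev[!duplicated(ev$pair), ]
    iIdx <- firstOfPair$i[res$rec_pair]
    jIdx <- firstOfPair$j[res$rec_pair]
    records <- data.frame(u = net@nodes[iIdx], v = net@nodes[jIdx],
      from_step = res$rec_from, to_step = res$rec_to,
      accepted = res$rec_accepted == 1L, stringsAsFactors = FALSE)
  }
  list(network = shuffled, records = records)
}

#' Mean TDC over an ensemble of time-shuffled networks
#'
#' Applies [randomizeTimes()] \code{nShuffles} times (independent
#' substreams derived from \code{rngSeed}) and averages the TDC score
#' vector over the shuffled networks. The per-shuffle score matrix is
#' attached for dispersion summaries.
#'
#' @param net a [TemporalNetwork-class].
#' @param params a [SpreadingParams-class]; for the time-order impact
#'   experiment the horizon is conventionally t = L.
#' @param nShuffles ensemble size.
#' @param rngSeed integer base seed.
#' @param sweeps randomization passes per shuffle.
#' @return a [CentralityScores-class] with method \code{"tdc_null"}; the
#'   nShuffles x N matrix of per-shuffle scores is in
#'   \code{params$ensemble}.
#' @export
nullEnsembleInfluence <- function(net, params, nShuffles, rngSeed = 1L,
                                  sweeps = 10) {
  stopifnot(nShuffles >= 1)
  n <- length(net@nodes)
  mat <- matrix(0, nShuffles, n, dimnames = list(NULL, net@nodes))
  for (k in seq_len(nShuffles)) {
    sh <- randomizeTimes(net, rngSeed = deriveSeed(rngSeed, 104729, k),
      sweeps = sweeps)
    mat[k, ] <- scores(tdcScores(sh$network, params))
  }
  m <- colMeans(mat)
  methods::new("CentralityScores", scores = m, method = "tdc_null",
    params = list(beta = params@beta, mu = params@mu,
      horizon = params@horizon, nShuffles = nShuffles, sweeps = sweeps,
      rngSeed = rngSeed, ensemble = mat))
}
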