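## Benchmark centralities: static degree/closeness/betweenness on the
## aggregated (static integrated) network, and their temporal counterparts
## on the time-ordered graph (one contact-edge hop per snapshot, waiting
## allowed at any node).

.aggGraph <- function(agg) {
  igraph::graph_from_adjacency_matrix(agg@binary, mode = "undirected")
}

.newScores <- function(s, nodes, method, params = list()) {
  s <- as.numeric(s)
  names(s) <- nodes
  methods::new("CentralityScores", scores = s, method = method,
    params = params)
}

#' Static degree centrality
#'
#' Number of distinct neighbours on the aggregated binary network.
#'
#' @param agg an [AggregatedNetwork-class].
#' @return a [CentralityScores-class] with method \code{"sd"}.
#' @export
staticDegree <- function(agg) {
  stopifnot(methods::is(agg, "AggregatedNetwork"))
  .newScores(Matrix::rowSums(agg@binary), agg@nodes, "sd")
}

#' Static closeness centrality
#'
#' Reciprocal of the sum of shortest-path distances to all other nodes on
#' the aggregated binary network, CC_i = 1 / sum_j d_ij. That form is
#' undefined on disconnected networks, so when the aggregate is
#' disconnected the harmonic form sum_j 1/d_ij (unreachable pairs
#' contributing 0) is used instead and a message notes the fallback.
#'
#' @param agg an [AggregatedNetwork-class].
#' @return a [CentralityScores-class] with method \code{"sc"}; the variant
#'   used is recorded in \code{params$variant}.
#' @export
staticCloseness <- function(agg) {
  stopifnot(methods::is(agg, "AggregatedNetwork"))
  n <- length(agg@nodes)
  if (n <= 1L)
    return(.newScores(numeric(n), agg@nodes, "sc",
      list(variant = "reciprocal_sum")))
  d <- igraph::distances(.aggGraph(agg))
  diag(d) <- NA
  if (any(is.infinite(d))) {
    message("aggregated network is disconnected; using harmonic closeness")
    s <- rowSums(1 / d, na.rm = TRUE)  # 1/Inf = 0 for unreachable
    return(.newScores(s, agg@nodes, "sc", list(variant = "harmonic")))
  }
  .newScores(1 / rowSums(d, na.rm = TRUE), agg@nodes, "sc",
    list(variant = "reciprocal_sum"))
}

#' Static betweenness centrality
#'
#' Sum over unordered node pairs (j, k), both distinct from i, of the
#' fraction of shortest paths between j and k that pass through i.
#'
#' @param agg an [AggregatedNetwork-class].
#' @return a [CentralityScores-class] with method \code{"sb"}.
#' @export
staticBetweenness <- function(agg) {
  stopifnot(methods::is(agg, "AggregatedNetwork"))
  s <- igraph::betweenness(.aggGraph(agg), directed = FALSE, weights = NA)
  .newScores(s, agg@nodes, "sb")
}

.checkWindow <- function(net, window) {
  L <- length(net@snapshots)
  if (length(window) != 2L || any(is.na(window)) ||
      window[1] < 1 || window[2] > L || window[1] > window[2] ||
      any(window != floor(window)))
    stop(sprintf("invalid window (%s): need 1 <= start <= end <= %d",
      paste(window, collapse = ", "), L))
  as.integer(window)
}

#' Temporal (earliest-arrival) distances from one source
#'
#' Earliest-arrival breadth-first search over the time-ordered graph: the
#' walker starts at the source before snapshot \code{window[1]}, and in each
#' snapshot s of the window may either wait or traverse one contact edge of
#' A(s). The temporal distance to j is \code{s_j - window[1] + 1} where s_j
#' is the earliest snapshot at which j can be reached; unreachable nodes get
#' \code{Inf}.
#'
#' @param net a [TemporalNetwork-class].
#' @param source source node identifier.
#' @param window integer pair (start, end), 1 <= start <= end <= L.
#' @return named numeric vector of temporal distances (0 for the source,
#'   \code{Inf} if unreachable within the window).
#' @export
temporalDistances <- function(net, source, window = c(1, numSnapshots(net))) {
  window <- .checkWindow(net, window)
  i0 <- .seedIndex(net, source)
  n <- length(net@nodes)
  arrived <- rep(Inf, n); arrived[i0] <- 0
  reach <- logical(n); reach[i0] <- TRUE
  for (s in seq(window[1], window[2])) {
    a <- net@snapshots[[s]]
    nb <- as.numeric(a %*% reach) > 0
    new <- nb & !reach
    if (any(new)) {
      arrived[new] <- s - window[1] + 1
      reach <- reach | new
    }
    if (all(reach)) break
  }
  names(arrived) <- net@nodes
  arrived
}

#' Temporal degree centrality
#'
#' Average snapshot degree over the window: TD_i = mean_t k_i(t).
#'
#' @inheritParams temporalDistances
#' @return a [CentralityScores-class] with method \code{"td"}.
#' @export
temporalDegree <- function(net, window = c(1, numSnapshots(net))) {
  window <- .checkWindow(net, window)
  ts <- seq(window[1], window[2])
  deg <- rowMeans(vapply(ts, function(t) Matrix::rowSums(net@snapshots[[t]]),
    numeric(length(net@nodes))))
  .newScores(deg, net@nodes, "td", list(window = window,
    variant = "mean_snapshot_degree"))
}

#' Temporal closeness centrality
#'
#' TC_i = sum over other nodes j of 1 / Delta_ij, with Delta_ij the
#' earliest-arrival temporal distance of [temporalDistances()]; unreachable
#' nodes contribute 0.
#'
#' @inheritParams temporalDistances
#' @return a [CentralityScores-class] with method \code{"tc"}.
#' @export
temporalCloseness <- function(net, window = c(1, numSnapshots(net))) {
  window <- .checkWindow(net, window)
  s <- vapply(net@nodes, function(v) {
    d <- temporalDistances(net, v, window)
    d <- d[names(d) != v]
    sum(1 / d[is.finite(d)])
  }, numeric(1))
  .newScores(s, net@nodes, "tc", list(window = window,
    variant = "reciprocal_earliest_arrival"))
}

## Forward path-count DP on the time-layered graph.  F[v, s] counts
## time-respecting contact sequences from (source, start-1) that place the
## walker at v after snapshot s (waits allowed); Fm[v, s] counts only those
## whose last action is a move at snapshot s.
.temporalPathCounts <- function(net, i0, window) {
  n <- length(net@nodes)
  steps <- seq(window[1], window[2])
  f <- numeric(n); f[i0] <- 1
  Fm <- matrix(0, n, length(steps))
  Fc <- matrix(0, n, length(steps))
  arrive <- rep(NA_integer_, n); arrive[i0] <- window[1] - 1L
  for (k in seq_along(steps)) {
    a <- net@snapshots[[steps[k]]]
    mv <- as.numeric(a %*% f)
    f <- f + mv
    Fm[, k] <- mv
    Fc[, k] <- f
    newly <- is.na(arrive) & f > 0
    arrive[newly] <- steps[k]
  }
  list(Fm = Fm, Fc = Fc, arrive = arrive, steps = steps)
}

#' Temporal betweenness centrality
#'
#' TB_i = sum over ordered source-target pairs (j, k) of distinct nodes
#' other than i (time-respecting routes are directional, so j -> k and
#' k -> j contribute separately) of sigma_jk(i) / sigma_jk, where
#' sigma_jk counts the earliest-arrival time-respecting contact sequences
#' from j to k within the window (one contact-edge hop per snapshot, waits
#' allowed; all sequences arriving at the earliest possible snapshot are
#' counted) and sigma_jk(i) those passing through i strictly between the
#' endpoints. Pairs with no time-respecting route contribute 0.
#'
#' Counting is done by forward/backward dynamic programming on the
#' time-layered graph. Sequences revisiting a node are counted as walks
#' (one count per arrival at i); on sparse short-window instances these
#' coincide with simple paths, and the measure is used as a ranking
#' baseline only.
#'
#' @inheritParams temporalDistances
#' @return a [CentralityScores-class] with method \code{"tb"}.
#' @export
temporalBetweenness <- function(net, window = c(1, numSnapshots(net))) {
  window <- .checkWindow(net, window)
  n <- length(net@nodes)
  tb <- numeric(n)
  for (j in seq_len(n)) {
    fw <- .temporalPathCounts(net, j, window)
    for (k in seq_len(n)) {
      if (k == j || is.na(fw$arrive[k])) next
      sK <- fw$arrive[k]
      if (sK < window[1]) next
      kIdx <- match(sK, fw$steps)
      sigma <- fw$Fm[k, kIdx]
      if (sigma == 0) next
      # backward counts B[v, s]: continuations from (v, s) to (k, sK)
      b <- numeric(n); b[k] <- 1
      through <- numeric(n)
      if (kIdx > 1L) {
        for (s in rev(seq_len(kIdx - 1L))) {
          a <- net@snapshots[[fw$steps[s + 1L]]]
          b <- b + as.numeric(a %*% b)
          b[k] <- 1  # walks end on first arrival at k
          through <- through + fw$Fm[, s] * b
        }
      }
      through[c(j, k)] <- 0
      tb <- tb + through / sigma
    }
  }
  .newScores(tb, net@nodes, "tb", list(window = window,
    variant = "earliest_arrival_walk_counts"))
}
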