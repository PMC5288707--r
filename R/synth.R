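## Synthetic temporal-network generators: temporal scale-free (independent
## Barabasi-Albert snapshots over a fixed node set), temporal Erdos-Renyi,
## and the deterministic toy fixtures used throughout the test suite.

.igraphSnapshot <- function(g, nodes, perm = NULL) {
  a <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  a <- methods::as(methods::as(methods::as(a, "dMatrix"), "generalMatrix"),
    "CsparseMatrix")
  if (!is.null(perm)) a <- a[perm, perm, drop = FALSE]
  dimnames(a) <- list(nodes, nodes)
  Matrix::drop0(sign(a))  # collapse any multi-edges to binary
}

#' Temporal scale-free network: independent BA snapshots
#'
#' Generates L mutually independent Barabasi-Albert graphs on the same
#' labeled node set of size N (each snapshot has m(N - m) edges for the
#' default linear preferential attachment with m edges per arriving node).
#' By default the node order is re-randomized in every snapshot, so the
#' hubs differ across snapshots; with \code{persistentHubs = TRUE} the same
#' attachment order is kept and hubs persist.
#'
#' @param N number of nodes (N >= 2).
#' @param L number of snapshots.
#' @param m edges attached per arriving node (integer, 1 <= m < N).
#' @param rngSeed integer seed (same seed, same network).
#' @param persistentHubs keep one attachment order across snapshots.
#' @return a [TemporalNetwork-class] with delta = 1.
#' @examples
#' net <- generateTemporalBA(N = 50, L = 5, rngSeed = 1)
#' numSnapshots(net)
#' @export
generateTemporalBA <- function(N, L, m = 1, rngSeed = NULL,
                               persistentHubs = FALSE) {
  if (m != floor(m) || m < 1 || m >= N) stop("m must be an integer in [1, N)")
  if (N < 2) stop("N must be >= 2")
  if (!is.null(rngSeed)) set.seed(rngSeed)
  nodes <- paste0("v", seq_len(N))
  snaps <- lapply(seq_len(L), function(t) {
    g <- igraph::sample_pa(N, m = m, directed = FALSE)
    perm <- if (persistentHubs) NULL else sample.int(N)
    .igraphSnapshot(g, nodes, perm)
  })
  methods::new("TemporalNetwork", nodes = nodes, snapshots = snaps,
    delta = 1, tStart = 0)
}

#' Temporal Erdos-Renyi network
#'
#' L independent G(N, p) snapshots on a fixed node set; expected edges per
#' snapshot p N (N - 1) / 2. Used as a structureless test fixture.
#'
#' @param N number of nodes.
#' @param L number of snapshots.
#' @param p per-pair edge probability in [0, 1].
#' @param rngSeed integer seed.
#' @return a [TemporalNetwork-class] with delta = 1.
#' @export
generateTemporalER <- function(N, L, p, rngSeed = NULL) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (N < 1) stop("N must be >= 1")
  if (!is.null(rngSeed)) set.seed(rngSeed)
  nodes <- paste0("v", seq_len(N))
  snaps <- lapply(seq_len(L), function(t)
    .igraphSnapshot(igraph::sample_gnp(N, p), nodes))
  methods::new("TemporalNetwork", nodes = nodes, snapshots = snaps,
    delta = 1, tStart = 0)
}

#' Deterministic toy temporal networks
#'
#' Small hand-checkable fixtures: \code{"chain_forward"} (3 nodes A, B, C;
#' snapshot 1 has edge A-B, snapshot 2 has edge B-C, so a time-respecting
#' route A to C exists), \code{"chain_reversed"} (the same two snapshots in
#' the opposite order, so C is unreachable from A), and \code{"fig1_style"}
#' (4 nodes A-D over 3 snapshots with delta = 1, a small multilayer
#' example; the edge pattern is a fixed choice of this package).
#'
#' @param name one of \code{"chain_forward"}, \code{"chain_reversed"},
#'   \code{"fig1_style"}.
#' @return a [TemporalNetwork-class].
#' @export
toyFixture <- function(name = c("chain_forward", "chain_reversed",
                                "fig1_style")) {
  name <- match.arg(name)
  edge <- function(nodes, pairs) {
    n <- length(nodes)
    if (!length(pairs)) return(.emptySnapshot(nodes))
    i <- match(vapply(pairs, `[`, "", 1L), nodes)
    j <- match(vapply(pairs, `[`, "", 2L), nodes)
    Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
      x = rep(1, 2 * length(i)), dims = c(n, n),
      dimnames = list(nodes, nodes))
  }
  if (name == "chain_forward") {
    nodes <- c("A", "B", "C")
    snaps <- list(edge(nodes, list(c("A", "B"))),
                  edge(nodes, list(c("B", "C"))))
  } else if (name == "chain_reversed") {
    nodes <- c("A", "B", "C")
    snaps <- list(edge(nodes, list(c("B", "C"))),
                  edge(nodes, list(c("A", "B"))))
  } else {
    nodes <- c("A", "B", "C", "D")
    snaps <- list(
      edge(nodes, list(c("A", "B"), c("C", "D"))),
      edge(nodes, list(c("B", "C"))),
      edge(nodes, list(c("A", "B"), c("B", "D"))))
  }
  methods::new("TemporalNetwork", nodes = nodes, snapshots = snaps,
    delta = 1, tStart = 0)
}
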