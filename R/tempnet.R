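## Temporal-network data model: construction, contact-list I/O, snapshot
## binning, static aggregation, periodic time indexing.

.asSnapshotMatrix <- function(m, n, nodes, what = "snapshot") {
  a <- methods::as(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
    "dMatrix"), "generalMatrix"), "CsparseMatrix")
  a <- Matrix::drop0(a)
  if (!all(dim(a) == c(n, n))) stop(what, " has wrong dimensions")
  dimnames(a) <- list(nodes, nodes)
  a
}

.emptySnapshot <- function(nodes) {
  n <- length(nodes)
  Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
    dims = c(n, n), dimnames = list(nodes, nodes))
}

#' Construct a temporal network from a list of snapshot adjacencies
#'
#' @param snapshots list of L square symmetric 0/1 matrices (base or
#'   \pkg{Matrix}), all of the same dimension.
#' @param nodes optional character vector of node identifiers; defaults to
#'   existing dimnames or \code{"v1".."vN"}.
#' @param delta snapshot width (time units per bin).
#' @param tStart left edge of the first bin.
#' @return a [TemporalNetwork-class] object.
#' @examples
#' a1 <- rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0))
#' a2 <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 0))
#' net <- temporalNetwork(list(a1, a2), nodes = c("A", "B", "C"))
#' numSnapshots(net)
#' @export
temporalNetwork <- function(snapshots, nodes = NULL, delta = 1, tStart = 0) {
  if (!is.list(snapshots) || length(snapshots) < 1L)
    stop("snapshots must be a non-empty list")
  n <- nrow(snapshots[[1L]])
  if (is.null(nodes)) {
    nodes <- dimnames(snapshots[[1L]])[[1L]]
    if (is.null(nodes)) nodes <- if (n > 0) paste0("v", seq_len(n)) else character(0)
  }
  nodes <- as.character(nodes)
  if (length(nodes) != n) stop("length(nodes) must match snapshot dimension")
  snaps <- lapply(seq_along(snapshots), function(t)
    .asSnapshotMatrix(snapshots[[t]], n, nodes, sprintf("snapshot %d", t)))
  methods::new("TemporalNetwork", nodes = nodes, snapshots = snaps,
    delta = as.numeric(delta), tStart = as.numeric(tStart))
}

#' Accessors for TemporalNetwork objects
#'
#' \code{numNodes} and \code{numSnapshots} return N and L; \code{nodeIds}
#' the node identifiers in index order; \code{snapshotWidth} the bin width
#' delta; \code{snapshotList} the list of sparse snapshot adjacencies.
#'
#' @param x a [TemporalNetwork-class].
#' @name TemporalNetwork-accessors
NULL

#' @rdname TemporalNetwork-accessors
#' @export
setMethod("numNodes", "TemporalNetwork", function(x) length(x@nodes))

#' @rdname TemporalNetwork-accessors
#' @export
setMethod("numSnapshots", "TemporalNetwork", function(x) length(x@snapshots))

#' @rdname TemporalNetwork-accessors
#' @export
setMethod("nodeIds", "TemporalNetwork", function(x) x@nodes)

#' @rdname TemporalNetwork-accessors
#' @export
setMethod("snapshotWidth", "TemporalNetwork", function(x) x@delta)

#' @rdname TemporalNetwork-accessors
#' @export
setMethod("snapshotList", "TemporalNetwork", function(x) x@snapshots)

setMethod("show", "TemporalNetwork", function(object) {
  ev <- sum(vapply(object@snapshots, function(a) length(a@x), numeric(1))) / 2
  cat(sprintf(
    "TemporalNetwork: %d nodes, %d snapshots (delta = %g), %d edge incidences\n",
    length(object@nodes), length(object@snapshots), object@delta, ev))
})

#' Read a timestamped contact list
#'
#' Parses a plain-text undirected contact list with one event per line,
#' whitespace- or tab-separated columns \code{u v time} (extra columns are
#' ignored) and \code{#} comments. Self-loop events are dropped with a
#' message; duplicate events are kept; events are returned in file order.
#'
#' @param path path to the contact-list file.
#' @return data.frame with character columns \code{u}, \code{v} and numeric
#'   \code{time}; zero rows for an empty file.
#' @seealso [binEvents()] to build a [TemporalNetwork-class] from the events.
#' @export
loadContactList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(!grepl("^\\s*$", lines))
  u <- character(length(keep)); v <- character(length(keep))
  tm <- numeric(length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1L]]
    if (length(f) < 3L)
      stop(sprintf("malformed contact line %d: need at least 3 fields", ln))
    ti <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(ti))
      stop(sprintf("malformed contact line %d: time '%s' is not numeric",
        ln, f[3L]))
    u[k] <- f[1L]; v[k] <- f[2L]; tm[k] <- ti
  }
  self <- u == v
  if (any(self))
    message(sprintf("dropped %d self-loop event(s)", sum(self)))
  data.frame(u = u[!self], v = v[!self], time = tm[!self],
    stringsAsFactors = FALSE)
}

#' Bin contact events into equal-width snapshots
#'
#' Assigns each event with timestamp tau to snapshot
#' \code{floor((tau - tStart) / delta) + 1}. Bins are half-open
#' \code{[start, start + delta)}, so an event exactly on an interior bin
#' boundary belongs to the later bin; an event exactly on the right boundary
#' of the last bin is clamped into the last bin. Multiple events of a pair
#' within one bin collapse to a single edge (snapshots are binary).
#'
#' @param events data.frame with columns \code{u}, \code{v}, \code{time}
#'   (as returned by [loadContactList()]).
#' @param delta positive bin width, same unit as \code{time}.
#' @param tStart left edge of the first bin (default 0).
#' @param L number of snapshots; when \code{NULL} it is derived as
#'   \code{ceiling((max(time) - tStart) / delta)}, minimum 1.
#' @param nodes optional node identifiers to include (and order first);
#'   nodes appearing in events are appended in first-appearance order.
#' @return a [TemporalNetwork-class] with L snapshots.
#' @export
binEvents <- function(events, delta, tStart = 0, L = NULL, nodes = NULL) {
  if (delta <= 0) stop("delta must be positive")
  if (nrow(events) && any(events$time < tStart))
    stop("event time earlier than tStart")
  evNodes <- as.character(rbind(events$u, events$v))  # first-appearance order
  nodes <- unique(c(as.character(nodes), evNodes))
  if (is.null(L)) {
    L <- if (nrow(events)) max(1, ceiling(max(events$time - tStart) / delta))
         else 1L
  }
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1")
  snaps <- rep(list(.emptySnapshot(nodes)), L)
  if (nrow(events)) {
    idx <- floor((events$time - tStart) / delta) + 1
    atRight <- idx == L + 1 & events$time == tStart + L * delta
    idx[atRight] <- L
    if (any(idx > L))
      stop("event time beyond the last snapshot boundary")
    iu <- match(events$u, nodes); iv <- match(events$v, nodes)
    n <- length(nodes)
    for (t in unique(idx)) {
      sel <- idx == t
      i <- c(iu[sel], iv[sel]); j <- c(iv[sel], iu[sel])
      key <- !duplicated((i - 1) * n + j)
      snaps[[t]] <- Matrix::sparseMatrix(i = i[key], j = j[key],
        x = rep(1, sum(key)), dims = c(n, n), dimnames = list(nodes, nodes))
    }
  }
  methods::new("TemporalNetwork", nodes = nodes, snapshots = snaps,
    delta = as.numeric(delta), tStart = as.numeric(tStart))
}

#' Retrieve one snapshot, with periodic or truncating time boundary
#'
#' With \code{boundary = "periodic"} the snapshot sequence is cycled,
#' A(L + 1) = A(1), so any t >= 1 resolves to A(((t - 1) mod L) + 1); with
#' \code{"truncate"} an index beyond L is an error.
#'
#' @param x a [TemporalNetwork-class].
#' @param t 1-based snapshot index (t >= 1).
#' @param boundary \code{"periodic"} (default) or \code{"truncate"}.
#' @return the sparse symmetric 0/1 adjacency of the resolved snapshot.
#' @export
setMethod("snapshotAt", "TemporalNetwork",
  function(x, t, boundary = c("periodic", "truncate")) {
    boundary <- match.arg(boundary)
    if (length(t) != 1L || is.na(t) || t < 1 || t != floor(t))
      stop("t must be a single integer >= 1")
    L <- length(x@snapshots)
    if (boundary == "truncate") {
      if (t > L) stop(sprintf("snapshot index %d out of range (L = %d)", t, L))
      return(x@snapshots[[t]])
    }
    x@snapshots[[((t - 1) %% L) + 1]]
  })

#' Aggregate a temporal network into its static integrated network
#'
#' Sums the snapshots: \code{counts[i, j]} is the number of snapshots in
#' which i and j were connected; \code{binary} marks pairs ever connected.
#'
#' @param x a [TemporalNetwork-class].
#' @return an [AggregatedNetwork-class].
#' @export
setMethod("aggregateNetwork", "TemporalNetwork", function(x) {
  counts <- Reduce(`+`, x@snapshots)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
    "generalMatrix"), "CsparseMatrix")
  binary <- Matrix::drop0(sign(counts))
  methods::new("AggregatedNetwork", nodes = x@nodes, counts = counts,
    binary = binary)
})

setMethod("show", "AggregatedNetwork", function(object) {
  cat(sprintf("AggregatedNetwork: %d nodes, %d connected pairs, %d contacts\n",
    length(object@nodes), length(object@binary@x) / 2,
    sum(object@counts@x) / 2))
})

#' Convert a temporal network back to contact events
#'
#' Emits one event per (pair, snapshot) edge incidence, timestamped at the
#' bin midpoint, so re-binning with the same delta and tStart reproduces the
#' snapshots exactly.
#'
#' @param net a [TemporalNetwork-class].
#' @return data.frame with columns \code{u}, \code{v}, \code{time}, ordered
#'   by snapshot.
#' @export
asContactEvents <- function(net) {
  stopifnot(methods::is(net, "TemporalNetwork"))
  out <- vector("list", length(net@snapshots))
  for (t in seq_along(net@snapshots)) {
    e <- .edgeList(net@snapshots[[t]])
    out[[t]] <- if (nrow(e)) data.frame(
      u = net@nodes[e$i], v = net@nodes[e$j],
      time = net@tStart + (t - 0.5) * net@delta, stringsAsFactors = FALSE)
    else NULL
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(u = character(0), v = character(0), time = numeric(0))
  res
}

## upper-triangle edge list (i < j) of one sparse snapshot
.edgeList <- function(a) {
  s <- Matrix::summary(a)
  s <- s[s$i < s$j, c("i", "j"), drop = FALSE]
  rownames(s) <- NULL
  as.data.frame(s)
}

#' Write a contact list or snapshot dump
#'
#' \code{writeContactList} writes events (or a network, converted through
#' [asContactEvents()]) as whitespace-separated \code{u v time} lines.
#' \code{writeSnapshots} writes one \code{t u v} line per edge incidence
#' with a commented header recording N, L, delta and the node order;
#' \code{readSnapshots} reconstructs the network from such a dump.
#'
#' @param x events data.frame or [TemporalNetwork-class].
#' @param path output file path.
#' @export
writeContactList <- function(x, path) {
  if (methods::is(x, "TemporalNetwork")) x <- asContactEvents(x)
  writeLines(sprintf("%s\t%s\t%.10g", x$u, x$v, x$time), path)
  invisible(path)
}

#' @rdname writeContactList
#' @param net a [TemporalNetwork-class].
#' @export
writeSnapshots <- function(net, path) {
  stopifnot(methods::is(net, "TemporalNetwork"))
  hdr <- c(
    sprintf("# N %d", length(net@nodes)),
    sprintf("# L %d", length(net@snapshots)),
    sprintf("# delta %.10g", net@delta),
    sprintf("# tstart %.10g", net@tStart),
    paste0("# nodes ", paste(net@nodes, collapse = "\t")))
  body <- character(0)
  for (t in seq_along(net@snapshots)) {
    e <- .edgeList(net@snapshots[[t]])
    if (nrow(e))
      body <- c(body, sprintf("%d\t%s\t%s", t, net@nodes[e$i], net@nodes[e$j]))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname writeContactList
#' @export
readSnapshots <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  getv <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key))]
    if (!length(ln)) stop("snapshot dump missing header field: ", key)
    sub(paste0("^# ", key, " "), "", ln[1L])
  }
  L <- as.integer(getv("L"))
  delta <- as.numeric(getv("delta"))
  tStart <- as.numeric(getv("tstart"))
  nodes <- strsplit(getv("nodes"), "\t")[[1L]]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  snaps <- rep(list(.emptySnapshot(nodes)), L)
  if (length(body)) {
    f <- do.call(rbind, strsplit(body, "[ \t]+"))
    t <- as.integer(f[, 1L])
    i <- match(f[, 2L], nodes); j <- match(f[, 3L], nodes)
    if (any(is.na(i) | is.na(j))) stop("snapshot dump names an unknown node")
    n <- length(nodes)
    for (tt in unique(t)) {
      sel <- t == tt
      ii <- c(i[sel], j[sel]); jj <- c(j[sel], i[sel])
      key <- !duplicated((ii - 1) * n + jj)
      snaps[[tt]] <- Matrix::sparseMatrix(i = ii[key], j = jj[key],
        x = rep(1, sum(key)), dims = c(n, n), dimnames = list(nodes, nodes))
    }
  }
  methods::new("TemporalNetwork", nodes = nodes, snapshots = snaps,
    delta = delta, tStart = tStart)
}
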