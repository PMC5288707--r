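# Independent oracles used to freeze expected values.  These deliberately
# use literal dense-matrix formulas and exhaustive enumeration, never the
# package's sparse one-pass/DP code paths.

denseSnap <- function(net, t) {
  L <- numSnapshots(net)
  as.matrix(snapshotList(net)[[((t - 1) %% L) + 1]])
}

# literal per-seed recursion: P(r) = beta * A(r) %*% Hleft %*% x0 with the
# left product H(r-1)...H(1) materialized as a dense matrix
oracleTdcScores <- function(net, beta, mu, horizon) {
  n <- numNodes(net)
  s <- numeric(n)
  for (i in seq_len(n)) {
    x0 <- numeric(n); x0[i] <- 1
    Hleft <- diag(n)
    x <- numeric(n)
    for (r in seq_len(horizon)) {
      Ar <- denseSnap(net, r)
      x <- x + beta * (Ar %*% Hleft %*% x0)
      Hleft <- (beta * Ar + (1 - mu) * diag(n)) %*% Hleft
    }
    s[i] <- sum(x)
  }
  names(s) <- nodeIds(net)
  s
}

# static dynamics-sensitive centrality (dense, literal):
# S = sum_{r=1}^{t} (beta A) H^{r-1} V, H = beta A + (1 - mu) I
oracleStaticDSC <- function(A, beta, mu, horizon) {
  n <- nrow(A)
  H <- beta * A + (1 - mu) * diag(n)
  Hpow <- diag(n)
  s <- numeric(n)
  V <- rep(1, n)
  for (r in seq_len(horizon)) {
    s <- s + (beta * A) %*% Hpow %*% V
    Hpow <- Hpow %*% H
  }
  as.numeric(s)
}

# dense spectral radius of the explicitly multiplied one-period propagator
oracleSpectralRadius <- function(net, beta, mu) {
  n <- numNodes(net)
  M <- diag(n)
  for (t in seq_len(numSnapshots(net))) {
    M <- (beta * denseSnap(net, t) + (1 - mu) * diag(n)) %*% M
  }
  if (n == 0) return(0)
  max(Mod(eigen(M, only.values = TRUE)$values))
}

# brute-force Kendall tau-b over all pairs, with tie corrections
oracleKendallTauB <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Exhaustive enumeration of time-respecting contact sequences from `source`
# within the window: at each snapshot the walker waits or traverses one
# edge.  Returns, for each target, the earliest arrival step, the number of
# sequences arriving then, and per-node through-counts (one count per move
# into the node) over those sequences.
oracleTemporalPaths <- function(net, source, window) {
  nodes <- nodeIds(net)
  n <- length(nodes)
  steps <- seq(window[1], window[2])
  snaps <- lapply(steps, function(t) denseSnap(net, t))
  src <- match(source, nodes)
  walks <- list()  # each: list(pos = final node, moves = index vector of move-arrival nodes)
  recurse <- function(pos, k, moves) {
    walks[[length(walks) + 1]] <<- list(pos = pos, moves = moves)
    if (k > length(steps)) return()
    a <- snaps[[k]]
    recurse(pos, k + 1, moves)                 # wait
    for (v in which(a[pos, ] > 0)) {           # move
      recurse(v, k + 1, c(moves, stats::setNames(v, k)))
    }
  }
  recurse(src, 1, integer(0))
  out <- list()
  for (tgt in seq_len(n)) {
    if (tgt == src) next
    arr <- vapply(walks, function(w) {
      hit <- which(w$moves == tgt)
      if (!length(hit)) NA_real_ else as.numeric(names(w$moves)[hit[1]])
    }, numeric(1))
    if (all(is.na(arr))) {
      out[[nodes[tgt]]] <- list(arrival = Inf, sigma = 0,
        through = numeric(n))
      next
    }
    sK <- min(arr, na.rm = TRUE)
    # sequences whose FIRST arrival at tgt is at sK, truncated there
    sel <- which(!is.na(arr) & arr == sK)
    trunc <- lapply(sel, function(wi) {
      w <- walks[[wi]]
      cut <- which(w$moves == tgt)[1]
      w$moves[seq_len(cut)]
    })
    trunc <- unique(trunc)
    through <- numeric(n)
    for (mv in trunc) {
      inter <- mv[-length(mv)]               # drop the final arrival at tgt
      inter <- inter[inter != src & inter != tgt]
      for (v in inter) through[v] <- through[v] + 1
    }
    # moves are named by their window-relative step, so sK is already the
    # temporal distance
    out[[nodes[tgt]]] <- list(arrival = sK,
      sigma = length(trunc), through = through)
  }
  out
}

# exact mean ever-infected count for the 2-step chain (seed A):
# B infected at step 1 w.p. beta; C then infected at step 2 w.p. beta
oracleChainMeanInfluence <- function(beta) {
  m <- 0
  for (b1 in 0:1) {
    pb <- if (b1 == 1) beta else 1 - beta
    for (c2 in 0:1) {
      pc <- if (b1 == 0) (if (c2 == 1) 0 else 1) else
        (if (c2 == 1) beta else 1 - beta)
      m <- m + pb * pc * (1 + b1 + c2)
    }
  }
  m
}

randomTemporalER <- function(seed, nMax = 50, lMax = 20, p = NULL) {
  set.seed(seed)
  n <- sample(3:nMax, 1)
  l <- sample(2:lMax, 1)
  if (is.null(p)) p <- stats::runif(1, 0.05, 0.3)
  generateTemporalER(n, l, p, rngSeed = seed + 7)
}
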