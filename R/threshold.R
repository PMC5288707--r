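## Epidemic threshold of a temporal network via the one-period infection
## propagator M = H(L) ... H(1), H(t) = beta * A(t) + (1 - mu) * I, under
## periodic boundary conditions A(L+1) = A(1).  The threshold beta_c is the
## infection probability at which the spectral radius rho(M) crosses 1.

#' Spectral radius of the one-period infection propagator
#'
#' Computes rho(M) for M = prod_{t=L..1} [beta A(t) + (1 - mu) I] (factors
#' applied in chronological order) by power iteration that applies the L
#' sparse factors sequentially to a vector; the dense product is never
#' formed. All factors are entrywise nonnegative, so the dominant eigenvalue
#' is real and nonnegative and equals the spectral radius. The iterate is
#' renormalized every sweep and the per-sweep growth factor is the estimate;
#' iteration stops when the estimate changes by less than \code{tol}
#' (relative) between sweeps.
#'
#' For disconnected aggregated networks rho is taken over the whole matrix
#' (the maximum across components) and a warning reports the component
#' structure.
#'
#' @param net a [TemporalNetwork-class].
#' @param beta infection probability in [0, 1].
#' @param mu recovery probability in [0, 1].
#' @param tol relative convergence tolerance on the growth-factor estimate.
#' @param maxIter maximum number of full sweeps over the L factors.
#' @param warnComponents warn when the aggregated network is disconnected.
#' @return the spectral radius, a nonnegative number.
#' @export
propagatorSpectralRadius <- function(net, beta, mu, tol = 1e-10,
                                     maxIter = 1e5, warnComponents = TRUE) {
  stopifnot(beta >= 0, beta <= 1, mu >= 0, mu <= 1)
  n <- length(net@nodes)
  if (n == 0L) return(0)
  if (warnComponents) .warnIfDisconnected(net)
  snaps <- net@snapshots
  oneMu <- 1 - mu
  applyM <- function(v) {
    for (a in snaps) v <- beta * as.numeric(a %*% v) + oneMu * v
    v
  }
  v <- rep(1, n)
  est <- NA_real_
  estPrev <- NA_real_
  for (it in seq_len(maxIter)) {
    w <- applyM(v)
    nw <- sqrt(sum(w * w))
    if (nw == 0) return(0)
    newEst <- nw / sqrt(sum(v * v))
    v <- w / nw
    if (!is.na(est) && abs(newEst - est) <= tol * max(1, abs(newEst)))
      return(newEst)
    # period-2 oscillation (reducible/imprimitive M): growth over two sweeps
    # is rho^2 and stabilizes even when single-sweep ratios alternate
    if (!is.na(estPrev) && abs(newEst - estPrev) <= tol * max(1, abs(newEst)))
      return(sqrt(newEst * est))
    estPrev <- est
    est <- newEst
  }
  stop(sprintf(
    "power iteration did not converge in %d sweeps (last estimate %.12g)",
    as.integer(maxIter), est))
}

.warnIfDisconnected <- function(net) {
  agg <- aggregateNetwork(net)
  g <- igraph::graph_from_adjacency_matrix(agg@binary, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1L)
    warning(sprintf(
      "aggregated network has %d components (sizes: %s); rho is the maximum over components",
      comp$no, paste(sort(comp$csize, decreasing = TRUE), collapse = ", ")),
      call. = FALSE)
  invisible(comp$no)
}

#' Epidemic threshold from the propagator condition rho(M) = 1
#'
#' Solves rho(M(beta)) = 1 for beta by bisection over
#' \code{[0, betaMax]}. rho is continuous and nondecreasing in beta (the
#' factors are entrywise nonnegative and entrywise monotone in beta), so
#' bisection is valid; the bracket is halved until its width is at most
#' \code{tol}.
#'
#' @param net a [TemporalNetwork-class] whose aggregated network has at
#'   least one edge.
#' @param mu recovery probability in [0, 1].
#' @param tol bisection tolerance on beta (bracket width at convergence).
#' @param betaMax upper end of the search bracket (beta is a probability,
#'   so 1 by default).
#' @param rhoTol relative tolerance passed to
#'   [propagatorSpectralRadius()].
#' @return a [ThresholdResult-class].
#' @examples
#' k2 <- temporalNetwork(rep(list(rbind(c(0, 1), c(1, 0))), 3))
#' epidemicThreshold(k2, mu = 0.1)  # beta_c = mu / lambda_max = 0.1
#' @export
epidemicThreshold <- function(net, mu, tol = 1e-6, betaMax = 1.0,
                              rhoTol = 1e-10) {
  agg <- aggregateNetwork(net)
  if (length(agg@binary@x) == 0L)
    stop("aggregated network has no edges; no epidemic threshold exists")
  .warnIfDisconnected(net)
  rho <- function(b) propagatorSpectralRadius(net, b, mu, tol = rhoTol,
    warnComponents = FALSE)
  rho0 <- rho(0)
  if (rho0 >= 1) {
    # (1 - mu)^L >= 1 only when mu = 0: any beta > 0 is supercritical
    warning("rho(M) >= 1 already at beta = 0 (mu = 0); returning beta_c = 0",
      call. = FALSE)
    return(methods::new("ThresholdResult", betaC = 0, mu = as.numeric(mu),
      rhoAtBetaC = rho0, iterations = 0L, bracket = c(0, 0)))
  }
  hi <- betaMax
  rhoHi <- rho(hi)
  if (rhoHi < 1)
    stop(sprintf(
      "no threshold in range: rho(M) = %.6g < 1 at beta = %g", rhoHi, hi))
  lo <- 0
  iter <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (rho(mid) < 1) lo <- mid else hi <- mid
    iter <- iter + 1L
  }
  betaC <- (lo + hi) / 2
  methods::new("ThresholdResult", betaC = betaC, mu = as.numeric(mu),
    rhoAtBetaC = rho(betaC), iterations = iter, bracket = c(lo, hi))
}

setMethod("show", "ThresholdResult", function(object) {
  cat(sprintf(
    "ThresholdResult: beta_c = %.6g (mu = %g, rho = %.8g, %d bisection steps)\n",
    object@betaC, object@mu, object@rhoAtBetaC, object@iterations))
})
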