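test_that("step matrix is beta*A + (1-mu)*I in all regimes", {
  net <- toyFixture("chain_forward")
  h0 <- stepMatrix(net, 1, spreadingParams(0, 0, 1))
  expect_equal(as.matrix(h0), diag(3), ignore_attr = TRUE)

  h <- as.matrix(stepMatrix(net, 1, spreadingParams(0.1, 0.1, 1)))
  expect_equal(diag(h), rep(0.9, 3), ignore_attr = TRUE)
  expect_equal(h["A", "B"], 0.1)
  expect_equal(h["B", "A"], 0.1)
  expect_equal(h["A", "C"], 0)

  h11 <- stepMatrix(net, 2, spreadingParams(1, 1, 1))
  expect_equal(as.matrix(h11), as.matrix(snapshotAt(net, 2)),
    ignore_attr = TRUE)
})

test_that("infection recursion reproduces hand-evaluated toy trajectories", {
  p <- spreadingParams(0.1, 0.1, 2)
  pv <- infectionRecursion(toyFixture("chain_forward"), "A", p)
  expect_equal(unname(pv@newly[1, ]), c(0, 0.1, 0), tolerance = 1e-14)
  expect_equal(unname(pv@newly[2, ]), c(0, 0, 0.01), tolerance = 1e-14)
  expect_equal(unname(pv@cumulative[2, ]), c(0, 0.1, 0.01), tolerance = 1e-14)

  # time-order sensitivity: reversed snapshots give P(1) = 0 and
  # P(2) = beta * (1 - mu) at B because y(1)_A = 1 - mu
  pvr <- infectionRecursion(toyFixture("chain_reversed"), "A", p)
  expect_equal(unname(pvr@newly[1, ]), c(0, 0, 0))
  expect_equal(unname(pvr@newly[2, ]), c(0, 0.09, 0), tolerance = 1e-14)

  p0 <- spreadingParams(0, 0.3, 3)
  pv0 <- infectionRecursion(toyFixture("chain_forward"), "A", p0)
  expect_true(all(pv0@newly == 0))
  expect_error(infectionRecursion(toyFixture("chain_forward"), "Z", p),
    "unknown seed")
})

test_that("tdc scores match the literal dense oracle on the toys", {
  p <- spreadingParams(0.1, 0.1, 2)
  s <- scores(tdcScores(toyFixture("chain_forward"), p))
  expect_equal(unname(s), c(0.11, 0.19, 0.09), tolerance = 1e-14)
  expect_equal(s, oracleTdcScores(toyFixture("chain_forward"), 0.1, 0.1, 2),
    tolerance = 1e-12)
  # ranking B > A > C
  expect_equal(names(sort(s, decreasing = TRUE)), c("B", "A", "C"))

  iso <- temporalNetwork(list(matrix(0, 1, 1)), nodes = "X")
  expect_equal(unname(scores(tdcScores(iso, p))), 0)
})

test_that("per-seed and one-pass routes agree on random temporal networks", {
  for (seed in 1:12) {
    net <- randomTemporalER(seed, nMax = 25, lMax = 10)
    set.seed(seed + 100)
    p <- spreadingParams(runif(1), runif(1), sample(1:15, 1))
    a <- scores(tdcScores(net, p, route = "onepass"))
    b <- scores(tdcScores(net, p, route = "perseed"))
    expect_equal(a, b, tolerance = 1e-10)
    expect_equal(a, oracleTdcScores(net, p@beta, p@mu, p@horizon),
      tolerance = 1e-10)
  }
})

test_that("with equal snapshots TDC reduces to the static DSC", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(4:20, 1)
    A <- as.matrix(Matrix::triu(
      matrix(rbinom(n * n, 1, 0.3), n, n), k = 1))
    A <- A + t(A)
    horizon <- sample(1:8, 1)
    beta <- runif(1); mu <- runif(1)
    net <- temporalNetwork(rep(list(A), horizon))
    s <- scores(tdcScores(net, spreadingParams(beta, mu, horizon)))
    expect_equal(unname(s), oracleStaticDSC(A, beta, mu, horizon),
      tolerance = 1e-10)
  }
})

test_that("cumulative influence is monotone in the horizon and zero when beta = 0", {
  net <- randomTemporalER(42, nMax = 15, lMax = 6)
  p <- spreadingParams(0.2, 0.3, 12)
  pv <- infectionRecursion(net, nodeIds(net)[1], p)
  expect_true(all(pv@newly >= 0))
  expect_true(all(diff(rowSums(pv@cumulative)) >= -1e-15))

  sz <- scores(tdcScores(net, spreadingParams(0, 0.5, 5)))
  expect_true(all(sz == 0))

  # mu has no effect when horizon = 1
  s1 <- scores(tdcScores(net, spreadingParams(0.3, 0.0, 1)))
  s2 <- scores(tdcScores(net, spreadingParams(0.3, 0.9, 1)))
  expect_equal(s1, s2)
})

test_that("linear coupling overestimates the Monte Carlo ever-infected probability", {
  net <- generateTemporalER(8, 4, 0.35, rngSeed = 5)
  p <- spreadingParams(0.4, 0.2, 4)
  seedNode <- nodeIds(net)[1]
  x <- infectionRecursion(net, seedNode, p)@cumulative[p@horizon, ]
  runs <- 3000
  ever <- matrix(0, runs, numNodes(net))
  for (k in seq_len(runs)) {
    ever[k, ] <- runSIR(net, seedNode, p, rngSeed = 5000 + k,
      detail = TRUE)$everInfected
  }
  phat <- colMeans(ever)
  se <- sqrt(phat * (1 - phat) / runs)
  others <- nodeIds(net) != seedNode
  expect_true(all(x[others] >= phat[others] - 3 * se[others]))
})

test_that("normalization rescales to [0, 1], preserves order, and shifts by one", {
  cs <- tdcnet:::.newScores(c(1, 2, 3), c("A", "B", "C"), "tdc")
  nn <- normalizeScores(cs)
  expect_equal(unname(scores(nn)), c(0, 0.5, 1))
  expect_equal(unname(scores(shiftedScores(nn))), c(1, 1.5, 2))

  const <- tdcnet:::.newScores(c(5, 5, 5), c("A", "B", "C"), "tdc")
  expect_equal(unname(scores(normalizeScores(const))), c(0, 0, 0))
  expect_equal(unname(scores(shiftedScores(normalizeScores(const)))),
    c(1, 1, 1))

  set.seed(9)
  v <- rnorm(20)
  cs2 <- tdcnet:::.newScores(v, paste0("n", 1:20), "tdc")
  n2 <- scores(normalizeScores(cs2))
  expect_true(all(n2 >= 0 & n2 <= 1))
  expect_equal(order(n2), order(v))
})

test_that("score TSV output has the documented columns in node order", {
  net <- toyFixture("chain_forward")
  sc <- tdcScores(net, spreadingParams(0.1, 0.1, 2))
  f <- withr::local_tempfile()
  writeScores(sc, f)
  df <- read.delim(f)
  expect_equal(names(df), c("node", "score", "method", "beta", "mu", "t"))
  expect_equal(df$node, c("A", "B", "C"))
  expect_equal(df$score, c(0.11, 0.19, 0.09), tolerance = 1e-12)
})
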