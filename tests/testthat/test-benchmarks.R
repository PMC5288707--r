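aggOf <- function(net) aggregateNetwork(net)

test_that("static degree counts distinct neighbours on the aggregate", {
  chain <- aggOf(toyFixture("chain_forward"))
  expect_equal(unname(scores(staticDegree(chain))), c(1, 2, 1))

  empty <- aggOf(temporalNetwork(list(matrix(0, 3, 3))))
  expect_equal(unname(scores(staticDegree(empty))), c(0, 0, 0))

  k4 <- aggOf(temporalNetwork(list(1 - diag(4))))
  expect_equal(unname(scores(staticDegree(k4))), rep(3, 4))
})

test_that("static closeness is the reciprocal distance sum, with harmonic fallback", {
  chain <- aggOf(toyFixture("chain_forward"))
  expect_equal(unname(scores(staticCloseness(chain))), c(1/3, 1/2, 1/3))

  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star[2:5, 1] <- 1
  sc <- scores(staticCloseness(aggOf(temporalNetwork(list(star)))))
  expect_equal(unname(sc[1]), 1/4)

  # two components: harmonic form sum(1/d), unreachable -> 0
  two <- matrix(0, 4, 4)
  two[1, 2] <- two[2, 1] <- 1; two[3, 4] <- two[4, 3] <- 1
  expect_message(
    sh <- scores(staticCloseness(aggOf(temporalNetwork(rep(list(two), 2))))),
    "harmonic")
  expect_equal(unname(sh), c(1, 1, 1, 1))
})

test_that("static betweenness matches igraph's pair-dependency and brute force", {
  chain <- aggOf(toyFixture("chain_forward"))
  expect_equal(unname(scores(staticBetweenness(chain))), c(0, 1, 0))

  k4 <- aggOf(temporalNetwork(list(1 - diag(4))))
  expect_equal(unname(scores(staticBetweenness(k4))), rep(0, 4))

  # bowtie: two triangles sharing a centre; the centre carries the 4
  # cross-pairs (each with a unique shortest path through it)
  bt <- matrix(0, 5, 5)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(3, 4), c(3, 5), c(4, 5))) {
    bt[e[1], e[2]] <- bt[e[2], e[1]] <- 1
  }
  sb <- scores(staticBetweenness(aggOf(temporalNetwork(list(bt)))))
  expect_equal(unname(sb), c(0, 0, 4, 0, 0))
})

test_that("temporal distances follow earliest-arrival traces on the toys", {
  chain <- toyFixture("chain_forward")
  d <- temporalDistances(chain, "A", c(1, 2))
  expect_equal(unname(d), c(0, 1, 2))

  rev <- toyFixture("chain_reversed")
  dr <- temporalDistances(rev, "A", c(1, 2))
  expect_equal(unname(dr), c(0, 2, Inf))

  # a source with no contacts in the window reaches nobody
  dc <- temporalDistances(chain, "C", c(1, 1))
  expect_equal(unname(dc), c(Inf, Inf, 0))

  expect_error(temporalDistances(chain, "A", c(2, 1)), "invalid window")
  expect_error(temporalDistances(chain, "A", c(0, 2)), "invalid window")
})

test_that("temporal distances and sigma counts match exhaustive enumeration", {
  for (seed in 1:6) {
    net <- randomTemporalER(seed + 40, nMax = 6, lMax = 4, p = 0.35)
    window <- c(1, numSnapshots(net))
    for (src in nodeIds(net)[1:2]) {
      oracle <- oracleTemporalPaths(net, src, window)
      d <- temporalDistances(net, src, window)
      for (tgt in names(oracle)) {
        expect_equal(unname(d[tgt]), oracle[[tgt]]$arrival,
          info = sprintf("seed %d %s->%s", seed, src, tgt))
      }
    }
  }
})

test_that("temporal degree averages snapshot degrees over the window", {
  chain <- toyFixture("chain_forward")
  expect_equal(unname(scores(temporalDegree(chain))), c(0.5, 1, 0.5))

  pair <- temporalNetwork(rep(list(rbind(c(0, 1), c(1, 0))), 4))
  expect_equal(unname(scores(temporalDegree(pair))), c(1, 1))
  expect_error(temporalDegree(chain, c(3, 3)), "invalid window")
})

test_that("temporal closeness sums reciprocal earliest arrivals", {
  chain <- toyFixture("chain_forward")
  tc <- scores(temporalCloseness(chain))
  expect_equal(unname(tc["A"]), 1.5)  # 1/1 + 1/2

  rev <- toyFixture("chain_reversed")
  expect_equal(unname(scores(temporalCloseness(rev))["A"]), 0.5)

  iso <- temporalNetwork(list(matrix(0, 2, 2), matrix(0, 2, 2)))
  expect_equal(unname(scores(temporalCloseness(iso))), c(0, 0))
})

test_that("temporal betweenness matches path enumeration on toys and random nets", {
  chain <- toyFixture("chain_forward")
  expect_equal(unname(scores(temporalBetweenness(chain))), c(0, 1, 0))

  # reversed toy: the time-respecting route C -> B (t=1) -> A (t=2)
  # passes through B
  rev <- toyFixture("chain_reversed")
  expect_equal(unname(scores(temporalBetweenness(rev))), c(0, 1, 0))

  # single snapshot: only 1-hop routes exist, nothing is intermediate
  single <- temporalNetwork(list(1 - diag(4)))
  expect_equal(unname(scores(temporalBetweenness(single))), rep(0, 4))

  for (seed in 1:5) {
    net <- randomTemporalER(seed + 60, nMax = 6, lMax = 4, p = 0.35)
    window <- c(1, numSnapshots(net))
    tb <- scores(temporalBetweenness(net, window))
    nodes <- nodeIds(net)
    expected <- numeric(length(nodes))
    for (src in nodes) {
      oracle <- oracleTemporalPaths(net, src, window)
      for (tgt in names(oracle)) {
        o <- oracle[[tgt]]
        if (o$sigma > 0) expected <- expected + o$through / o$sigma
      }
    }
    expect_equal(unname(tb), expected, tolerance = 1e-10,
      info = sprintf("seed %d", seed))
  }
})

test_that("temporal reachability is contained in static reachability", {
  for (seed in 1:6) {
    net <- randomTemporalER(seed + 80, nMax = 10, lMax = 5, p = 0.2)
    agg <- aggregateNetwork(net)
    g <- igraph::graph_from_adjacency_matrix(agg@binary, mode = "undirected")
    dStatic <- igraph::distances(g)
    for (src in nodeIds(net)[1:3]) {
      dTemp <- temporalDistances(net, src)
      reachableT <- names(dTemp)[is.finite(dTemp)]
      reachableS <- nodeIds(net)[is.finite(dStatic[match(src, nodeIds(net)), ])]
      expect_true(all(reachableT %in% reachableS))
    }
  }
})

test_that("with equal snapshots and a long window temporal and static closeness agree in ranking", {
  # agreement is up to ties: 1/sum(d) can tie nodes whose distance profiles
  # differ, which sum(1/d) then refines, so assert that no node pair is
  # ranked strictly oppositely by the two measures
  for (seed in 1:4) {
    set.seed(seed)
    g <- igraph::sample_gnp(10, 0.35)
    while (igraph::components(g)$no > 1) g <- igraph::sample_gnp(10, 0.35)
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    L <- 12  # >= diameter of a connected 10-node graph
    net <- temporalNetwork(rep(list(A), L))
    tc <- scores(temporalCloseness(net))
    sc <- scores(staticCloseness(aggregateNetwork(net)))
    for (i in 1:9) {
      for (j in (i + 1):10) {
        expect_gte(sign(tc[i] - tc[j]) * sign(sc[i] - sc[j]), 0)
      }
    }
  }
})

test_that("centralities are equivariant under node relabeling", {
  net <- randomTemporalER(99, nMax = 8, lMax = 4, p = 0.3)
  n <- numNodes(net)
  set.seed(1); perm <- sample.int(n)
  snapsP <- lapply(snapshotList(net), function(a) {
    m <- as.matrix(a)[perm, perm]
    dimnames(m) <- NULL
    m
  })
  netP <- temporalNetwork(snapsP, nodes = nodeIds(net)[perm])
  for (f in list(
    function(x) scores(staticDegree(aggregateNetwork(x))),
    function(x) suppressMessages(scores(staticCloseness(aggregateNetwork(x)))),
    function(x) scores(staticBetweenness(aggregateNetwork(x))),
    function(x) scores(temporalDegree(x)),
    function(x) scores(temporalCloseness(x)),
    function(x) scores(temporalBetweenness(x)))) {
    s <- f(net); sp <- f(netP)
    expect_equal(sp[nodeIds(net)], s[nodeIds(net)], tolerance = 1e-10)
  }
})
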