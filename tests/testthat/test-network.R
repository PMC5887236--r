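test_that("network edges obey the bond-change caps and carry CD weights", {
  fx <- fixtureInterhalogen()
  sts <- eqn1States()
  net <- buildNetwork(sts, fx$reactant, fx$product, fx$config)
  expect_s4_class(net, "ReactionNetwork")
  e <- networkEdges(net)
  expect_true(all(e$formed <= 2 & e$broken <= 2))
  expect_true(all(e$weight == e$formed + e$broken))
  expect_true(all(e$weight >= 1))
  ## the reactant connects to the HI + HCl + ICl intermediate with weight 4
  C <- matrix(0L, 6, 6)
  C[5, 6] <- C[6, 5] <- -1L; C[1, 2] <- C[2, 1] <- -1L
  C[1, 5] <- C[5, 1] <- 1L;  C[2, 6] <- C[6, 2] <- 1L
  I1 <- applyConversion(fx$reactant@ac, C)
  iKey <- findState(sts, chemState(fx$reactant@atoms, I1))
  hit <- e[(e$from == reactantKey(net) & e$to == iKey) |
           (e$to == reactantKey(net) & e$from == iKey), ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$weight, 4L)
})

test_that("states differing by more changes than the caps get no edge", {
  at <- atomTable(rep("C", 8))   # element-distinct enough: all like atoms
  ## A empty, B a fixed 3-edge matching: any mapping needs 3 formations
  A <- chemState(at, NULL)
  B <- chemState(at, rbind(c(1, 2), c(3, 4), c(5, 6)))
  states <- list(A, B)
  names(states) <- vapply(states, stateKey, character(1))
  net <- buildNetwork(states, A, B, enumerationConfig())
  expect_identical(nrow(networkEdges(net)), 0L)
})

test_that("catalyst rule drops edges with no catalyst-atom involvement", {
  ## Co + 2 H: the H-H bond can form with or without Co participating
  at <- atomTable(c("Co", "H", "H"), active = 1:3, catalyst = 1L)
  s0 <- chemState(at, NULL)
  s1 <- chemState(at, rbind(c(2, 3)))       # H2 formed away from Co
  s2 <- chemState(at, rbind(c(1, 2)))       # Co-H formed
  states <- list(s0, s1, s2)
  names(states) <- vapply(states, stateKey, character(1))
  net <- buildNetwork(states, s0, s1, enumerationConfig())
  e <- networkEdges(net)
  pairKey <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  present <- vapply(seq_len(nrow(e)), function(i)
    pairKey(e$from[i], e$to[i]), character(1))
  expect_false(pairKey(s0@key, s1@key) %in% present)  # no Co involvement
  expect_true(pairKey(s0@key, s2@key) %in% present)
  ## without the rule the edge reappears
  net2 <- buildNetwork(states, s0, s1, enumerationConfig(),
                       requireCatalyst = FALSE)
  e2 <- networkEdges(net2)
  present2 <- vapply(seq_len(nrow(e2)), function(i)
    pairKey(e2$from[i], e2$to[i]), character(1))
  expect_true(pairKey(s0@key, s1@key) %in% present2)
})

mkSimpleNet <- function(keys, edges) {
  at <- atomTable("H")
  states <- lapply(keys, function(k) {
    st <- chemState(at, NULL)
    st@key <- k
    st
  })
  names(states) <- keys
  edges$formed <- 1L; edges$broken <- 0L; edges$catalyst <- FALSE
  new("ReactionNetwork", states = states, edges = edges,
      reactant = keys[1], product = keys[length(keys)])
}

test_that("shortest paths through a vertex enumerate all ties", {
  ## 3-vertex chain: unique geodesic through the middle vertex
  chain <- mkSimpleNet(c("R", "M", "P"),
                       data.frame(from = c("R", "M"), to = c("M", "P"),
                                  weight = 1, stringsAsFactors = FALSE))
  ps <- shortestPathsThrough(chain, "M")
  expect_length(ps, 1L)
  expect_identical(ps[[1]], c("R", "M", "P"))
  ## diamond with two equal-length R -> M legs: both returned
  d <- mkSimpleNet(c("R", "M", "X", "P"),
                   data.frame(from = c("R", "R", "X", "M"),
                              to = c("M", "X", "M", "P"),
                              weight = c(2, 1, 1, 1),
                              stringsAsFactors = FALSE))
  ps <- shortestPathsThrough(d, "M")
  expect_setequal(vapply(ps, paste, character(1), collapse = ">"),
                  c("R>M>P", "R>X>M>P"))
  ## disconnected vertex yields an empty set
  d2 <- mkSimpleNet(c("R", "Z", "P"),
                    data.frame(from = "R", to = "P", weight = 1,
                               stringsAsFactors = FALSE))
  expect_length(shortestPathsThrough(d2, "Z"), 0L)
})

test_that("through-vertex sampling matches the exhaustive path oracle on
           random graphs", {
  set.seed(23)
  for (rep in 1:12) {
    net <- randomTestNetwork(sample(8:12, 1), p = 0.35)
    e <- networkEdges(net)
    for (v in names(networkStates(net))) {
      mine <- shortestPathsThrough(net, v)
      all <- oracleSimplePaths(e, reactantKey(net), productKey(net))
      through <- Filter(function(p) v %in% p$path, all)
      if (!length(through)) {
        expect_length(mine, 0L)
        next
      }
      L <- min(vapply(through, `[[`, numeric(1), "length"))
      best <- Filter(function(p) p$length == L, through)
      expect_setequal(
        vapply(mine, paste, character(1), collapse = ">"),
        vapply(best, function(p) paste(p$path, collapse = ">"),
               character(1)))
    }
  }
})

test_that("minimal subnetwork keeps only path edges in the R/P component", {
  set.seed(5)
  for (rep in 1:5) {
    net <- randomTestNetwork(10, p = 0.3)
    paths <- sampleNetworkPaths(net)
    sub <- extractMinimalSubnetwork(net, paths)
    e <- networkEdges(sub)
    ## every surviving edge lies on a sampled path
    onPath <- new.env(parent = emptyenv())
    for (p in paths@paths)
      for (i in seq_len(length(p) - 1L))
        assign(paste(sort(c(p[i], p[i + 1L])), collapse = "|"), TRUE, onPath)
    for (i in seq_len(nrow(e)))
      expect_true(exists(paste(sort(c(e$from[i], e$to[i])), collapse = "|"),
                         envir = onPath))
    ## connected and contains both endpoints
    expect_true(all(c(reactantKey(sub), productKey(sub)) %in%
                      names(networkStates(sub))))
    ## path lengths equal recomputed edge-weight sums
    g <- igraph::graph_from_data_frame(networkEdges(net)[, 1:3],
                                       directed = FALSE)
    for (i in seq_along(paths@paths)) {
      p <- paths@paths[[i]]
      ids <- igraph::get_edge_ids(g, as.vector(rbind(p[-length(p)], p[-1])))
      expect_equal(paths@lengths[i], sum(igraph::E(g)$weight[ids]))
    }
  }
})

test_that("top-q ranking keeps ties at the cutoff and is stable", {
  mk <- function(lens) {
    paths <- lapply(seq_along(lens), function(i)
      c("R", sprintf("m%d", i), "P"))
    reactionPathSet(paths, lens)
  }
  r <- rankPathsTopq(mk(c(6, 6, 8, 10)), 0.5)
  expect_identical(pathLengths(r), c(6, 6))
  expect_identical(r@ranks, 1:2)
  ## q = 1 keeps everything
  expect_identical(pathCount(rankPathsTopq(mk(c(3, 1, 2)), 1)), 3L)
  ## ties at the cutoff are kept even beyond ceiling(q n)
  r2 <- rankPathsTopq(mk(c(4, 4, 4, 9)), 0.25)
  expect_identical(pathCount(r2), 3L)
  ## stability: adding a longer path does not reorder kept shorter ones
  a <- rankPathsTopq(mk(c(5, 3, 7)), 1)
  b <- rankPathsTopq(mk(c(5, 3, 7, 99)), 1)
  expect_identical(a@paths, b@paths[1:3])
  expect_error(rankPathsTopq(mk(1), 0), "q must be")
})

test_that("edge frequencies count path membership with deterministic order", {
  p1 <- c("a", "b", "c")
  p2 <- c("a", "b", "d", "c")
  ps <- reactionPathSet(list(p1, p2), c(2, 3))
  r <- edgeFrequencyRanking(ps)
  expect_identical(r$count[1], 2L)                  # shared a-b edge first
  expect_identical(sort(c(r$from[1], r$to[1])), c("a", "b"))
  expect_identical(sum(r$count), 5L)                # total edge slots
  expect_error(edgeFrequencyRanking(reactionPathSet(list(), numeric(0))),
               "empty")
})

test_that("kinetic filter drops high vertices, uphill edges, then isolates", {
  mkNet <- function(energies, edges) {
    keys <- names(energies)
    at <- atomTable("H")
    states <- lapply(keys, function(k) {
      st <- chemState(at, NULL)
      st@key <- k
      st@energy <- energies[[k]]
      st
    })
    names(states) <- keys
    new("ReactionNetwork", states = states, edges = edges,
        reactant = keys[1], product = keys[length(keys)])
  }
  e3 <- data.frame(from = c("R", "M"), to = c("M", "P"), weight = 1,
                   formed = 1L, broken = 0L, catalyst = FALSE,
                   stringsAsFactors = FALSE)
  ## thresholds = Inf leave everything
  net <- mkNet(c(R = 0, M = 10, P = -5), e3)
  f <- kineticFilter(net, Inf, Inf)
  expect_identical(names(networkStates(f)), c("R", "M", "P"))
  ## pendant vertex above eTol goes, with its edge
  e4 <- rbind(e3, data.frame(from = "M", to = "X", weight = 1, formed = 1L,
                             broken = 0L, catalyst = FALSE))
  net4 <- mkNet(c(R = 0, M = 10, X = 80, P = -5), e4)
  f4 <- kineticFilter(net4, eTol = 20)
  expect_false("X" %in% names(networkStates(f4)))
  ## a 25 kcal/mol uphill edge at threshold 20: edge removed, pendant
  ## vertex isolated and dropped
  net5 <- mkNet(c(R = 0, M = 25, P = -5),
                rbind(e3, data.frame(from = "R", to = "P", weight = 2,
                                     formed = 1L, broken = 1L,
                                     catalyst = FALSE)))
  f5 <- kineticFilter(net5, eTol = Inf, endoThreshold = 20)
  expect_false("M" %in% names(networkStates(f5)))
  expect_identical(nrow(networkEdges(f5)), 1L)
  ## monotonicity: raising thresholds never removes a kept vertex/edge
  for (tol in list(c(10, 10), c(20, 20), c(40, 40))) {
    f1 <- kineticFilter(net4, tol[1], tol[2])
    f2 <- kineticFilter(net4, tol[1] + 10, tol[2] + 10)
    expect_true(all(names(networkStates(f1)) %in%
                      names(networkStates(f2))))
    expect_true(nrow(networkEdges(f1)) <= nrow(networkEdges(f2)))
  }
  ## missing energy errors with the vertex named
  net6 <- mkNet(c(R = 0, M = 10, P = -5), e3)
  net6@states[["M"]]@energy <- NULL
  expect_error(kineticFilter(net6, 10, 10), "missing energy")
})

test_that("removing an edge removes exactly the paths using it", {
  set.seed(31)
  net <- randomTestNetwork(9, p = 0.4)
  paths <- sampleNetworkPaths(net)
  e <- networkEdges(net)
  for (i in sample(nrow(e), min(4, nrow(e)))) {
    edge <- c(e$from[i], e$to[i])
    res <- removeEdgeAndPaths(net, paths, edge)
    uses <- vapply(paths@paths, function(p) {
      any(vapply(seq_len(length(p) - 1L), function(j)
        setequal(c(p[j], p[j + 1L]), edge), logical(1)))
    }, logical(1))
    expect_identical(pathCount(res$paths), sum(!uses))
    expect_identical(nrow(networkEdges(res$network)), nrow(e) - 1L)
  }
})
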