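test_that("fixed-order chemical distance counts differing bonds", {
  fx <- fixtureInterhalogen()
  expect_identical(cdFixed(fx$reactant@ac, fx$reactant@ac), 0L)
  expect_identical(cdFixed(fx$reactant@ac, fx$product@ac), 6L)
  ## one bond moved between two like pairs: one break + one form
  at <- atomTable(c("H", "H", "H", "H"))
  A <- chemState(at, rbind(c(1, 2)))@ac
  B <- chemState(at, rbind(c(3, 4)))@ac
  expect_identical(cdFixed(A, B), 2L)
  expect_error(cdFixed(A, matrix(0L, 3, 3)), "basis")
})

test_that("cdMin minimizes over element-preserving mappings", {
  at <- atomTable(c("H", "H", "H", "H"))
  A <- chemState(at, rbind(c(1, 2)))@ac
  B <- chemState(at, rbind(c(3, 4)))@ac
  r <- cdMin(A, B, at)
  expect_identical(r$cd, 0L)           # permutationally isomorphic
  expect_lt(r$cd, cdFixed(A, B))       # identity mapping overestimates
  ## the optimal mapping transports the bond
  expect_identical(sort(r$mapping[1:2]), c(3L, 4L))
  ## interhalogen reactant vs product: no mapping beats 6
  fx <- fixtureInterhalogen()
  expect_identical(cdMin(fx$reactant@ac, fx$product@ac,
                         fx$reactant@atoms)$cd, 6L)
  expect_identical(
    oraclePermCD(fx$reactant@ac, fx$product@ac, fx$reactant@atoms$symbol),
    6)
  ## element multiset mismatch is an error
  expect_error(cdMin(A, B, at, atomsB = atomTable(c("H", "H", "H", "O"))),
               "multiset")
})

test_that("cdMin equals the exhaustive-permutation oracle on random
           instances and satisfies the metric properties", {
  set.seed(11)
  randState <- function(symbols, nbond) {
    n <- length(symbols)
    ac <- matrix(0L, n, n)
    on <- sample(which(upper.tri(ac)), nbond)
    ac[on] <- 1L
    ac + t(ac)
  }
  for (rep in 1:40) {
    symbols <- sample(c("C", "H", "O"), sample(4:6, 1), replace = TRUE)
    at <- atomTable(symbols)
    n <- length(symbols)
    A <- randState(symbols, sample(1:4, 1))
    B <- randState(symbols, sample(1:4, 1))
    Cm <- randState(symbols, sample(1:4, 1))
    dAB <- cdMin(A, B, at)$cd
    expect_identical(dAB, as.integer(oraclePermCD(A, B, symbols)))
    ## symmetry, identity, triangle inequality
    expect_identical(dAB, cdMin(B, A, at)$cd)
    expect_identical(cdMin(A, A, at)$cd, 0L)
    expect_lte(cdMin(A, Cm, at)$cd, dAB + cdMin(B, Cm, at)$cd)
  }
  ## element-distinct atoms: cdMin equals cdFixed
  at <- atomTable(c("C", "N", "O", "S"))
  A <- chemState(at, rbind(c(1, 2), c(3, 4)))@ac
  B <- chemState(at, rbind(c(1, 3)))@ac
  expect_identical(cdMin(A, B, at)$cd, cdFixed(A, B))
})

test_that("ellipse filter keeps the corridor inclusively and monotonically", {
  fx <- fixtureInterhalogen()
  sts <- eqn1States()
  R <- sts[[findState(sts, fx$reactant)]]
  P <- sts[[findState(sts, fx$product)]]
  ## R and P always survive, even at delta = 0
  kept0 <- ellipseFilter(sts, R, P, 0)
  expect_true(all(c(R@key, P@key) %in% names(kept0)))
  ## the HI + HCl + ICl intermediate is inside the delta = 6 ellipse:
  ## verified against the exhaustive-permutation oracle
  C <- matrix(0L, 6, 6)
  C[5, 6] <- C[6, 5] <- -1L; C[1, 2] <- C[2, 1] <- -1L
  C[1, 5] <- C[5, 1] <- 1L;  C[2, 6] <- C[6, 2] <- 1L
  I1 <- applyConversion(fx$reactant@ac, C)
  sym <- fx$reactant@atoms$symbol
  dSum <- oraclePermCD(fx$reactant@ac, I1, sym) +
    oraclePermCD(I1, fx$product@ac, sym)
  expect_lte(dSum, 6 + 6)
  kept6 <- ellipseFilter(sts, R, P, 6)
  iKey <- findState(sts, chemState(fx$reactant@atoms, I1))
  expect_true(iKey %in% names(kept6))
  ## monotone in delta
  prev <- character(0)
  for (d in c(0, 2, 4, 6, 10)) {
    cur <- names(ellipseFilter(sts, R, P, d))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  expect_error(ellipseFilter(sts, R, P, -1), ">= 0")
})
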