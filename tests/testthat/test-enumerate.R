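cfgDefault <- enumerationConfig()

test_that("single H-H bond admits exactly one conversion (dissociation)", {
  H2 <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  cs <- enumerateConversions(H2, H2, cfgDefault)
  expect_length(cs, 1L)
  expect_identical(cs[[1]], -H2)
})

test_that("three isolated atoms give six conversions before molecularity", {
  z <- matrix(0L, 3, 3)
  ## a shared component id disables the molecularity screen
  cs <- enumerateConversions(z, z, cfgDefault, components = rep(1L, 3))
  expect_length(cs, 6L)   # 3 single formations + 3 double formations
  nForm <- vapply(cs, function(C) sum(C == 1L) / 2L, numeric(1))
  expect_identical(sort(nForm), c(1, 1, 1, 2, 2, 2))
  ## with true components, double formations touching 3 molecules drop out
  cs2 <- enumerateConversions(z, z, cfgDefault)
  expect_length(cs2, 3L)
})

test_that("conversion enumeration equals the brute-force oracle", {
  fx <- fixtureInterhalogen()
  R <- fx$reactant@ac
  asSet <- function(lst) sort(vapply(lst, function(C)
    paste(C[upper.tri(C)], collapse = ","), character(1)))
  ## at the reactant and along a dissociated intermediate
  I2 <- R; I2[5, 6] <- I2[6, 5] <- 0L
  for (I in list(R, I2)) {
    mine <- enumerateConversions(I, R, cfgDefault)
    oracle <- oracleConversions(I, R, 2L, 2L, molecularity = 2L)
    expect_identical(asSet(mine), asSet(oracle))
  }
  ## seeded random 4-atom systems, including rule interactions with R
  set.seed(42)
  for (rep in 1:10) {
    n <- 4L
    Rr <- matrix(0L, n, n)
    pairs <- which(upper.tri(Rr))
    on <- sample(pairs, sample(0:3, 1))
    Rr[on] <- 1L; Rr <- Rr + t(Rr) - diag(diag(Rr))
    storage.mode(Rr) <- "integer"
    Ir <- Rr
    off <- sample(pairs, sample(0:2, 1))
    Ir[off] <- 1L - Ir[off]
    Ir[lower.tri(Ir)] <- t(Ir)[lower.tri(Ir)]
    diag(Ir) <- 0L
    storage.mode(Ir) <- "integer"
    ## legality of Ir wrt the monotone rules is irrelevant for rule testing:
    ## both routes apply the same formation/breaking conditions
    mine <- enumerateConversions(Ir, Rr, cfgDefault)
    oracle <- oracleConversions(Ir, Rr, 2L, 2L, molecularity = 2L)
    expect_identical(asSet(mine), asSet(oracle))
  }
})

test_that("re-break prevention: a broken reactant bond never re-forms", {
  fx <- fixtureInterhalogen()
  R <- fx$reactant@ac
  I <- R; I[5, 6] <- I[6, 5] <- 0L     # H-H broken in a previous cycle
  for (C in enumerateConversions(I, R, cfgDefault)) {
    expect_identical(C[5, 6], 0L)
  }
  ## mirror rule: a bond formed during the run is never broken
  I2 <- R; I2[1, 3] <- I2[3, 1] <- 1L  # I-I formed, not a reactant bond
  for (C in enumerateConversions(I2, R, cfgDefault)) {
    expect_gte(C[1, 3], 0L)
  }
})

test_that("H2 enumerates to exactly the bonded and dissociated states", {
  h2 <- chemState(atomTable(c("H", "H"), active = 1:2), rbind(c(1, 2)))
  sts <- enumerateIntermediates(h2, enumerationConfig(ringMax = 0))
  expect_length(sts, 2L)
})

test_that("interhalogen enumeration reaches the product and matches the
           exhaustive reachability oracle", {
  fx <- fixtureInterhalogen()
  sts <- eqn1States()
  expect_false(is.na(findState(sts, fx$product)))
  expect_false(anyDuplicated(names(sts)) > 0)
  ## cycle bookkeeping: reactant at 0, everything else later
  cyc <- vapply(sts, function(s) s@cycle, integer(1))
  expect_identical(unname(cyc[fx$reactant@key]), 0L)
  expect_true(all(cyc[names(cyc) != fx$reactant@key] >= 1L))

  ## oracle: breadth-first reachability over brute-force conversions with
  ## pairwise isomorphism dedup and the same perception screens
  at <- fx$reactant@atoms
  R <- fx$reactant@ac
  screensOK <- function(ac) {
    screenRingCount(ac, 0, 0, atoms = at) &&
      screenValenceCharge(assignBondOrders(ac, totalCharge = 0L, atoms = at,
                                           localizedCharges = TRUE,
                                           allowRadicals = TRUE), 1L)
  }
  isoIn <- function(A, lst) {
    for (S in lst) if (.acIso(A, S, at$Z)) return(TRUE)
    FALSE
  }
  .acIso <- function(A, B, z) rxnpath:::.acIsomorphic(A, B, z, z)
  keepStates <- list(R); rejected <- list(); frontier <- list(R)
  while (length(frontier)) {
    nf <- list()
    for (I in frontier) {
      for (C in oracleConversions(I, R, 2L, 2L, molecularity = 2L)) {
        A <- I + C
        if (any(A < 0L | A > 1L)) next
        if (isoIn(A, keepStates) || isoIn(A, rejected)) next
        if (!screensOK(A)) { rejected[[length(rejected) + 1L]] <- A; next }
        keepStates[[length(keepStates) + 1L]] <- A
        nf[[length(nf) + 1L]] <- A
      }
    }
    frontier <- nf
  }
  expect_identical(length(sts), length(keepStates))
  ## set equality up to isomorphism
  for (s in sts) expect_true(isoIn(s@ac, keepStates))
})

test_that("enumeration with all atoms flagged active equals all-atom mode", {
  at1 <- atomTable(c("I", "Cl", "H", "H"), active = 1:4)
  at2 <- atomTable(c("I", "Cl", "H", "H"))
  bonds <- rbind(c(1, 2), c(3, 4))
  cfg <- enumerationConfig(ringMax = 0)
  s1 <- enumerateIntermediates(chemState(at1, bonds), cfg)
  s2 <- enumerateIntermediates(chemState(at2, bonds),
                               enumerationConfig(ringMax = 0,
                                                 activeMode = FALSE))
  expect_identical(sort(names(s1)), sort(names(s2)))
})
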