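test_that("bond orders and charges on reference molecules", {
  ## H2: single bond, no charges
  h2 <- chemState(atomTable(c("H", "H")), rbind(c(1, 2)))
  a <- assignBondOrders(h2)
  expect_true(a$ok)
  expect_identical(a$orders[1, 2], 1L)
  expect_identical(a$charges, c(0L, 0L))
  ## CO2 connectivity resolves to two double bonds, all neutral
  co2 <- chemState(atomTable(c("O", "C", "O")), rbind(c(1, 2), c(2, 3)))
  a <- assignBondOrders(co2)
  expect_identical(c(a$orders[1, 2], a$orders[2, 3]), c(2L, 2L))
  expect_identical(sum(abs(a$charges)), 0L)
  ## carbon with five hydrogens has no feasible valence
  ch5 <- chemState(atomTable(c("C", rep("H", 5))), cbind(1L, 2:6))
  expect_false(assignBondOrders(ch5)$ok)
  ## ethoxide carries its charge on oxygen
  eto <- chemState(atomTable(c("C", "C", "O", rep("H", 5))),
                   rbind(c(1, 2), c(2, 3), c(1, 4), c(1, 5), c(1, 6),
                         c(2, 7), c(2, 8)), charge = -1L)
  a <- assignBondOrders(eto)
  expect_true(a$ok)
  expect_identical(a$charges[3], -1L)
  ## unknown element is an error, not a chemical rejection
  expect_error(assignBondOrders(matrix(0L, 1, 1), atoms = atomTable("He")),
               "valence model")
})

test_that("metal complexes bypass the octet model but obey coordination", {
  hco <- chemState(atomTable(c("Co", "H", "C", "O", "C", "O", "C", "O")),
                   rbind(c(1, 2), c(1, 3), c(3, 4), c(1, 5), c(5, 6),
                         c(1, 7), c(7, 8)))
  a <- assignBondOrders(hco)
  expect_true(a$ok)
  expect_true(screenValenceCharge(a, 1L))
  ## seven bonds at the metal exceed the default coordination cap
  crowded <- chemState(atomTable(c("Co", rep("H", 7))), cbind(1L, 2:8))
  expect_false(assignBondOrders(crowded)$ok)
  ## hypervalent hydride (H with two bonds) stays rejected even at a metal
  hyp <- chemState(atomTable(c("Co", "H", "C", "O")),
                   rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_false(assignBondOrders(hyp)$ok)
})

test_that("valence screen matches a brute-force feasibility oracle", {
  ## exhaustive search over edge orders (1..3) and per-atom charges
  oracleFeasible <- function(ac, symbols, total) {
    tab <- list(H = list(`0` = c(-1L, 1L), `1` = 0L),
                C = list(`3` = c(-1L, 1L), `4` = 0L),
                O = list(`1` = -1L, `2` = 0L, `3` = 1L))
    ed <- which(upper.tri(ac) & ac == 1L, arr.ind = TRUE)
    m <- nrow(ed)
    combos <- if (m) expand.grid(rep(list(1:3), m)) else
      data.frame(row.names = 1)
    comp <- oracleComponents(ac)
    for (r in seq_len(nrow(combos))) {
      sums <- integer(length(symbols))
      if (m) for (k in seq_len(m)) {
        o <- combos[r, k]
        sums[ed[k, 1]] <- sums[ed[k, 1]] + o
        sums[ed[k, 2]] <- sums[ed[k, 2]] + o
      }
      sets <- lapply(seq_along(symbols), function(i)
        tab[[symbols[i]]][[as.character(sums[i])]])
      if (any(vapply(sets, is.null, logical(1)))) next
      grid <- expand.grid(sets)
      for (g in seq_len(nrow(grid))) {
        q <- as.integer(grid[g, ])
        if (sum(q) != total) next
        ## per-molecule net charge within -1..1
        if (all(abs(tapply(q, comp, sum)) <= 1)) return(TRUE)
      }
    }
    FALSE
  }
  set.seed(7)
  syms <- c("C", "O", "H")
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    symbols <- sample(syms, n, replace = TRUE)
    ac <- matrix(0L, n, n)
    on <- sample(which(upper.tri(ac)), sample(1:min(5, n * (n - 1) / 2), 1))
    ac[on] <- 1L
    ac <- ac + t(ac)
    storage.mode(ac) <- "integer"
    total <- sample(-1:1, 1)
    mine <- screenValenceCharge(
      assignBondOrders(ac, totalCharge = total,
                       atoms = atomTable(symbols)), 1L)
    expect_identical(mine, oracleFeasible(ac, symbols, total),
                     info = paste("case", rep))
  }
})

test_that("ring screen applies per molecule with a metal exemption", {
  acyclic <- chemState(atomTable(c("C", "C", "C")), rbind(c(1, 2), c(2, 3)))
  expect_true(screenRingCount(acyclic, 0, 0))
  ring6 <- chemState(atomTable(rep("C", 6)),
                     rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6),
                           c(6, 1)))
  expect_false(screenRingCount(ring6, 0, 0))
  expect_true(screenRingCount(ring6, 0, 1))
  ## bicyclic 4-atom graph: 5 edges - 4 atoms + 1 = 2 rings
  bic <- matrix(1L, 4, 4); diag(bic) <- 0L; bic[1, 4] <- bic[4, 1] <- 0L
  expect_false(screenRingCount(bic, 0, 1))
  expect_true(screenRingCount(bic, 0, 2))
  ## pi-coordinated alkene: ring only at the metal complex
  pi <- chemState(atomTable(c("Co", "C", "C")),
                  rbind(c(1, 2), c(1, 3), c(2, 3)))
  expect_true(screenRingCount(pi, 0, 0, ringMaxMetal = 1))
  expect_false(screenRingCount(pi, 0, 0, ringMaxMetal = 0))
})

test_that("charge localization forbids spurious ion pairs", {
  two <- chemState(atomTable(c("H", "H")))   # two lone H atoms, neutral
  expect_true(assignBondOrders(two)$ok)      # H+ / H- pair allowed by default
  expect_false(assignBondOrders(two, localizedCharges = TRUE)$ok)
  ## the single anion of a charged system is still allowed
  eto <- chemState(atomTable(c("C", "C", "O", rep("H", 5))),
                   rbind(c(1, 2), c(2, 3), c(1, 4), c(1, 5), c(1, 6),
                         c(2, 7), c(2, 8)), charge = -1L)
  expect_true(assignBondOrders(eto, localizedCharges = TRUE)$ok)
})

test_that("energy screen is inclusive at the boundary and monotone in eTol", {
  ev <- bondEnergyEvaluator()
  fx <- fixtureInterhalogen()
  sts <- eqn1States()
  eRef <- ev(fx$reactant)
  ## boundary: the reactant itself survives at eTol = 0
  kept0 <- screenEnergy(sts, eRef, 0, ev)
  expect_true(fx$reactant@key %in% names(kept0))
  ## eTol = Inf keeps everything
  keptInf <- screenEnergy(sts, eRef, Inf, ev)
  expect_identical(length(keptInf), length(sts))
  ## monotonicity
  prev <- character(0)
  for (tol in c(0, 25, 50, 100, 200)) {
    cur <- names(screenEnergy(sts, eRef, tol, ev))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  ## energies recorded on survivors
  expect_true(all(!is.na(vapply(keptInf, stateEnergy, numeric(1)))))
})

test_that("evaluator contract: additivity over components", {
  ev <- bondEnergyEvaluator()
  at <- atomTable(c("H", "H", "Cl", "H"))
  both <- chemState(at, rbind(c(1, 2), c(3, 4)))
  h2 <- chemState(atomTable(c("H", "H")), rbind(c(1, 2)))
  hcl <- chemState(atomTable(c("Cl", "H")), rbind(c(1, 2)))
  expect_equal(ev(both), ev(h2) + ev(hcl))
})
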