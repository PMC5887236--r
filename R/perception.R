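## Chemical plausibility screening: AC matrix -> bond-order matrix with
## formal charges (exact per-molecule search), valence/charge/ring screens,
## and the energy-evaluator contract with a built-in additive
## bond-increment surrogate.

## Octet-deficient (valence, charge) combinations: one electron short of a
## full shell. Used to rank assignments: octet satisfaction outweighs
## charge minimization, so a double bond always beats a diradical; the
## radical penalty is below half the cation penalty so that homolysis
## (two radicals) still beats heterolysis (an ion pair).
.OCTET_DEFICIT_COST <- 16L
.RADICAL_COST <- 4L
.octetDeficit <- function(symbol, s, q) {
  if (symbol == "H" && s == 0L && q == 1L) return(1L)   # bare proton
  if (symbol == "C" && s == 3L && q == 1L) return(1L)   # carbocation
  0L
}

## per valence sum: data.frame(q, cost); cost = |q| + penalty for
## octet-deficient entries (including radical entries when enabled)
.valenceOptions <- function(symbol, allowRadicals = FALSE) {
  tab <- .VALENCE_TABLE[[symbol]]
  if (is.null(tab)) return(NULL)
  out <- lapply(names(tab), function(k) {
    s <- as.integer(k)
    q <- tab[[k]]
    data.frame(q = q, cost = abs(q) + .OCTET_DEFICIT_COST *
                 vapply(q, function(qq) .octetDeficit(symbol, s, qq),
                        integer(1)))
  })
  names(out) <- names(tab)
  if (allowRadicals) {
    ## one unpaired electron: neutral atom with valence one below normal
    neutral <- as.integer(names(tab)[vapply(tab, function(q) 0L %in% q,
                                            logical(1))])
    for (s in neutral - 1L) {
      if (s < 0L) next
      key <- as.character(s)
      cur <- out[[key]]
      if (is.null(cur) || !0L %in% cur$q) {
        out[[key]] <- rbind(cur, data.frame(q = 0L, cost = .RADICAL_COST))
        out[[key]] <- out[[key]][order(out[[key]]$q), , drop = FALSE]
      }
    }
  }
  out
}

## Perceive one molecule (connected component without metal atoms):
## exhaustive search over bond orders; for each achievable net charge q in
## -2..2 record the minimal total |formal charge| and the (lexicographically
## smallest) orders/charges realizing it.
.perceiveOrganic <- function(sub, symbols, allowRadicals = FALSE) {
  n <- length(symbols)
  ed <- which(upper.tri(sub) & sub == 1L, arr.ind = TRUE)
  m <- nrow(ed)
  maxOrd <- if (m) mapply(function(i, j) .maxBondOrder(symbols[i], symbols[j]),
                          ed[, 1], ed[, 2]) else integer(0)
  opts <- lapply(symbols, .valenceOptions, allowRadicals = allowRadicals)
  maxVal <- vapply(opts, function(o) max(as.integer(names(o))), numeric(1))
  deg <- rowSums(sub)
  if (any(deg > maxVal)) return(NULL)

  qRange <- -2:2
  best <- vector("list", length(qRange))   # per net charge
  consider <- function(orders, sums) {
    chSets <- vector("list", n)
    for (i in seq_len(n)) {
      d <- opts[[i]][[as.character(sums[i])]]
      if (is.null(d)) return()
      chSets[[i]] <- d
    }
    ## small systems: enumerate charge combinations per net charge via DP
    for (qi in seq_along(qRange)) {
      r <- .chargeDP(chSets, qRange[qi])
      if (is.null(r)) next
      b <- best[[qi]]
      if (is.null(b) || r$cost < b$cost)
        best[[qi]] <<- list(cost = r$cost, orders = orders,
                            charges = r$charges)
    }
  }
  orders <- rep(1L, m)
  sums <- deg
  multi <- which(maxOrd > 1L)
  recurse <- function(k) {
    if (k > length(multi)) { consider(orders, sums); return() }
    e <- multi[k]
    i <- ed[e, 1]; j <- ed[e, 2]
    for (o in 1:maxOrd[e]) {
      extra <- o - 1L
      if (sums[i] + extra > maxVal[i] || sums[j] + extra > maxVal[j]) break
      orders[e] <<- o
      sums[i] <<- sums[i] + extra; sums[j] <<- sums[j] + extra
      recurse(k + 1L)
      sums[i] <<- sums[i] - extra; sums[j] <<- sums[j] - extra
      orders[e] <<- 1L
    }
  }
  recurse(1L)
  if (all(vapply(best, is.null, logical(1)))) return(NULL)
  names(best) <- as.character(qRange)
  list(best = best, edges = ed)
}

## Perceive a metal-containing molecule: the metal bypasses the octet-based
## valence model (bonds to metals are ill-defined); it only obeys a maximum
## coordination number and absorbs the residual formal charge as a
## bookkeeping value. Ligand atoms must still reach an admissible valence
## (counting their metal bonds as order 1).
.perceiveMetal <- function(sub, symbols, maxCoordination = 6L,
                           allowRadicals = FALSE) {
  n <- length(symbols)
  metal <- .isMetal(symbols)
  deg <- rowSums(sub)
  if (any(metal & deg > maxCoordination)) return(NULL)
  ed <- which(upper.tri(sub) & sub == 1L, arr.ind = TRUE)
  m <- nrow(ed)
  maxOrd <- if (m) mapply(function(i, j) {
    if (metal[i] || metal[j]) 1L else .maxBondOrder(symbols[i], symbols[j])
  }, ed[, 1], ed[, 2]) else integer(0)
  opts <- lapply(seq_len(n), function(i) {
    if (metal[i]) NULL else .valenceOptions(symbols[i], allowRadicals)
  })
  maxVal <- vapply(seq_len(n), function(i) {
    if (metal[i]) as.numeric(maxCoordination)
    else max(as.integer(names(opts[[i]])))
  }, numeric(1))
  if (any(deg > maxVal)) return(NULL)

  best <- NULL
  consider <- function(orders, sums) {
    charges <- integer(n)
    cost <- 0L
    for (i in seq_len(n)) {
      if (metal[i]) next
      d <- opts[[i]][[as.character(sums[i])]]
      if (is.null(d)) return()
      r <- which.min(d$cost)
      charges[i] <- d$q[r]
      cost <- cost + d$cost[r]
    }
    ## metal absorbs the residual so the complex is net neutral
    charges[which(metal)[1]] <- -sum(charges)
    if (is.null(best) || cost < best$cost)
      best <<- list(cost = cost, orders = orders, charges = charges)
  }
  orders <- rep(1L, m)
  sums <- deg
  multi <- which(maxOrd > 1L)
  recurse <- function(k) {
    if (k > length(multi)) { consider(orders, sums); return() }
    e <- multi[k]
    i <- ed[e, 1]; j <- ed[e, 2]
    for (o in 1:maxOrd[e]) {
      extra <- o - 1L
      if (sums[i] + extra > maxVal[i] || sums[j] + extra > maxVal[j]) break
      orders[e] <<- o
      sums[i] <<- sums[i] + extra; sums[j] <<- sums[j] + extra
      recurse(k + 1L)
      sums[i] <<- sums[i] - extra; sums[j] <<- sums[j] - extra
      orders[e] <<- 1L
    }
  }
  recurse(1L)
  if (is.null(best)) return(NULL)
  list(best = best, edges = ed)
}

## minimal-cost charge selection: per-atom (q, cost) options, fixed total.
.chargeDP <- function(options, total) {
  n <- length(options)
  ## window must cover every prefix sum, not only the grand total
  lo <- sum(vapply(options, function(o) min(0, min(o$q)), numeric(1)))
  hi <- sum(vapply(options, function(o) max(0, max(o$q)), numeric(1)))
  if (total < lo || total > hi) return(NULL)
  width <- as.integer(hi - lo + 1L)
  INF <- 1e9
  dp <- rep(INF, width)
  dp[0L - lo + 1L] <- 0
  choice <- matrix(NA_integer_, n, width)
  for (i in seq_len(n)) {
    nd <- rep(INF, width)
    d <- options[[i]]
    for (r in seq_len(nrow(d))) {
      q <- d$q[r]
      idx <- seq_len(width)
      tgt <- idx + q
      okk <- tgt >= 1L & tgt <= width
      cand <- dp[idx[okk]] + d$cost[r]
      better <- cand < nd[tgt[okk]]
      upd <- tgt[okk][better]
      nd[upd] <- cand[better]
      choice[i, upd] <- q
    }
    dp <- nd
  }
  pos <- total - lo + 1L
  if (pos < 1L || pos > width || dp[pos] >= INF) return(NULL)
  charges <- integer(n)
  cur <- as.integer(total)
  for (i in rev(seq_len(n))) {
    q <- choice[i, cur - lo + 1L]
    charges[i] <- q
    cur <- cur - q
  }
  list(charges = charges, cost = dp[pos])
}

## memo cache for per-component perception (molecules recur across states)
.perceptionCache <- new.env(parent = emptyenv())

.componentPerception <- function(sub, symbols, maxCoordination,
                                 allowRadicals) {
  key <- paste0(paste(symbols, collapse = ","), "|",
                paste(sub[upper.tri(sub)], collapse = ""), "|",
                maxCoordination, allowRadicals)
  hit <- .perceptionCache[[key]]
  if (!is.null(hit)) return(if (identical(hit, FALSE)) NULL else hit)
  res <- if (any(.isMetal(symbols)))
    list(metal = TRUE,
         r = .perceiveMetal(sub, symbols, maxCoordination, allowRadicals))
  else
    list(metal = FALSE,
         r = .perceiveOrganic(sub, symbols, allowRadicals))
  if (is.null(res$r)) {
    .perceptionCache[[key]] <- FALSE
    return(NULL)
  }
  .perceptionCache[[key]] <- res
  res
}

#' Assign bond orders and formal charges to a state
#'
#' Exact per-molecule search for a valence-model-feasible bond-order
#' matrix: every bond gets an integer order (1-3); each main-group atom's
#' total bond order must sit at a chemically admissible valence with an
#' admissible formal charge; each molecule's net formal charge is
#' restricted to -1..+1; the molecular net charges must sum to the system
#' charge. Among feasible assignments the one minimizing the total |formal
#' charge| is chosen (octet preference), ties broken by lexicographically
#' smallest bond orders. Molecules containing a transition metal bypass
#' the octet model: the metal obeys a maximum coordination number, absorbs
#' the residual formal charge of its complex (net neutral), and its ligand
#' atoms keep ordinary valence limits.
#'
#' @param state a \code{ChemState} (or an AC matrix with \code{atoms}
#'   supplied).
#' @param totalCharge system charge; defaults to the state's charge.
#' @param atoms atom table when \code{state} is a bare matrix.
#' @param maxCoordination metal coordination cap.
#' @param allowRadicals permit one unpaired electron per atom.
#' @param localizedCharges require the number of net-charged molecules to
#'   equal |system charge| (forbids spurious ion-pair states).
#' @return list with \code{ok}; when feasible also \code{orders} (integer
#'   matrix), \code{charges}, \code{valences} (per-atom bond-order sums),
#'   \code{componentCharges} and \code{metal} (per-atom flag); when
#'   infeasible a \code{reason}.
#' @examples
#' st <- chemState(atomTable(c("O", "C", "O")), rbind(c(1, 2), c(2, 3)))
#' assignBondOrders(st)$orders
#' @export
assignBondOrders <- function(state, totalCharge = NULL, atoms = NULL,
                             maxCoordination = 6L, allowRadicals = FALSE,
                             localizedCharges = FALSE) {
  if (is(state, "ChemState")) {
    ac <- state@ac
    atoms <- state@atoms
    if (is.null(totalCharge)) totalCharge <- state@charge
  } else {
    ac <- state
    if (is.null(atoms)) stop("atoms table required with a bare AC matrix")
    if (is.null(totalCharge)) totalCharge <- 0L
  }
  n <- nrow(ac)
  sym <- atoms$symbol
  unknown <- !.isMetal(sym) & !(sym %in% names(.VALENCE_TABLE))
  if (any(unknown))
    stop("no valence model for element(s): ",
         paste(unique(sym[unknown]), collapse = ", "))

  comp <- componentIds(ac)
  compIdx <- split(seq_len(n), comp)
  percs <- vector("list", length(compIdx))
  for (c0 in seq_along(compIdx)) {
    idx <- compIdx[[c0]]
    percs[c0] <- list(.componentPerception(ac[idx, idx, drop = FALSE],
                                           sym[idx], maxCoordination,
                                           allowRadicals))
    if (is.null(percs[[c0]]))
      return(list(ok = FALSE,
                  reason = "no feasible valence assignment for a molecule"))
  }

  ## choose one net charge per molecule so they sum to the system charge,
  ## minimizing total |formal charge|, then the number of charged molecules
  qcands <- lapply(percs, function(p) {
    if (p$metal) {
      data.frame(q = 0L, cost = p$r$best$cost, charged = 0L)
    } else {
      qs <- as.integer(names(p$r$best))
      keep <- !vapply(p$r$best, is.null, logical(1)) & abs(qs) <= 1L
      data.frame(q = qs[keep],
                 cost = vapply(p$r$best[keep], `[[`, numeric(1), "cost"),
                 charged = as.integer(qs[keep] != 0L))
    }
  })
  if (any(vapply(qcands, nrow, integer(1)) == 0L))
    return(list(ok = FALSE,
                reason = "molecule feasible only at |net charge| > 1"))
  pick <- .assignComponentCharges(qcands, as.integer(totalCharge))
  if (is.null(pick))
    return(list(ok = FALSE,
                reason = "molecular charges cannot sum to the system charge"))
  if (localizedCharges &&
      sum(pick != 0L) != abs(as.integer(totalCharge)))
    return(list(ok = FALSE,
                reason = "delocalized ion-pair state (charge localization)"))

  O <- matrix(0L, n, n)
  charges <- integer(n)
  for (c0 in seq_along(compIdx)) {
    idx <- compIdx[[c0]]
    p <- percs[[c0]]
    b <- if (p$metal) p$r$best else p$r$best[[as.character(pick[c0])]]
    ed <- p$r$edges
    if (nrow(ed)) {
      gi <- idx[ed[, 1]]; gj <- idx[ed[, 2]]
      O[cbind(gi, gj)] <- b$orders
      O[cbind(gj, gi)] <- b$orders
    }
    charges[idx] <- b$charges
  }
  list(ok = TRUE, orders = O, charges = charges,
       valences = as.integer(rowSums(O)),
       componentCharges = pick, metal = .isMetal(sym))
}

## DP over molecules: targets sum to total; minimize (cost, #charged)
.assignComponentCharges <- function(qcands, total) {
  k <- length(qcands)
  lo <- sum(vapply(qcands, function(d) min(0L, min(d$q)), numeric(1)))
  hi <- sum(vapply(qcands, function(d) max(0L, max(d$q)), numeric(1)))
  if (total < lo || total > hi) return(NULL)
  width <- as.integer(hi - lo + 1L)
  INF <- 1e9
  dp <- rep(INF, width); nch <- rep(INF, width)
  dp[0L - lo + 1L] <- 0; nch[0L - lo + 1L] <- 0
  choice <- matrix(NA_integer_, k, width)
  for (i in seq_len(k)) {
    nd <- rep(INF, width); nn <- rep(INF, width)
    d <- qcands[[i]]
    for (r in seq_len(nrow(d))) {
      q <- d$q[r]
      idx <- which(dp < INF)
      tgt <- idx + q
      okk <- tgt >= 1L & tgt <= width
      cand <- dp[idx[okk]] + d$cost[r]
      candN <- nch[idx[okk]] + d$charged[r]
      better <- cand < nd[tgt[okk]] |
        (cand == nd[tgt[okk]] & candN < nn[tgt[okk]])
      upd <- tgt[okk][better]
      nd[upd] <- cand[better]
      nn[upd] <- candN[better]
      choice[i, upd] <- q
    }
    dp <- nd; nch <- nn
  }
  pos <- total - lo + 1L
  if (pos < 1L || pos > width || dp[pos] >= INF) return(NULL)
  picks <- integer(k)
  cur <- as.integer(total)
  for (i in rev(seq_len(k))) {
    q <- choice[i, cur - lo + 1L]
    picks[i] <- q
    cur <- cur - q
  }
  picks
}

#' Valence / formal-charge screen
#'
#' Accepts a state when a feasible bond-order assignment exists and no
#' main-group atom carries a formal charge beyond the bound (metal formal
#' charges are bookkeeping values and are exempt).
#'
#' @param assignment result of \code{\link{assignBondOrders}}.
#' @param chargeBound maximum allowed |formal charge| per atom.
#' @return logical: accept (TRUE) or reject.
#' @export
screenValenceCharge <- function(assignment, chargeBound = 1L) {
  if (!isTRUE(assignment$ok)) return(FALSE)
  nonmetal <- if (is.null(assignment$metal)) TRUE else !assignment$metal
  all(abs(assignment$charges[nonmetal]) <= chargeBound)
}

#' Ring-count screen
#'
#' Per-molecule cyclomatic number (edges - atoms + 1) must lie within the
#' configured bounds. Metal complexes may take a separate upper bound
#' (\code{ringMaxMetal}) since pi-coordination of an alkene shows up as a
#' metallacyclic ring in the connectivity graph.
#'
#' @param state a \code{ChemState} or AC matrix.
#' @param ringMin,ringMax inclusive bounds on rings per molecule.
#' @param ringMaxMetal upper bound for metal-containing molecules
#'   (defaults to \code{ringMax}).
#' @param atoms atom table when \code{state} is a bare matrix.
#' @return logical: accept (TRUE) or reject.
#' @export
screenRingCount <- function(state, ringMin = 0, ringMax = Inf,
                            ringMaxMetal = ringMax, atoms = NULL) {
  if (is(state, "ChemState")) {
    ac <- state@ac
    atoms <- state@atoms
  } else {
    ac <- state
  }
  metal <- if (is.null(atoms)) rep(FALSE, nrow(ac)) else .isMetal(atoms$symbol)
  comp <- componentIds(ac)
  for (idx in split(seq_len(nrow(ac)), comp)) {
    sub <- ac[idx, idx, drop = FALSE]
    cyc <- sum(sub) / 2 - length(idx) + 1
    hi <- if (any(metal[idx])) ringMaxMetal else ringMax
    if (cyc < ringMin || cyc > hi) return(FALSE)
  }
  TRUE
}

#' Default perception screens for an enumeration configuration
#'
#' @param cfg an \code{\link{enumerationConfig}}.
#' @return list of predicate functions \code{function(state) -> logical}.
#' @export
perceptionScreens <- function(cfg = enumerationConfig()) {
  list(
    valence = function(state) {
      a <- assignBondOrders(state, maxCoordination = cfg$maxCoordination,
                            allowRadicals = cfg$allowRadicals,
                            localizedCharges = cfg$localizedCharges)
      screenValenceCharge(a, cfg$chargeBound)
    },
    rings = function(state) screenRingCount(state, cfg$ringMin, cfg$ringMax,
                                            cfg$ringMaxMetal)
  )
}

#' Energy-tolerance screen
#'
#' Keeps the states whose total energy does not exceed the reference energy
#' plus the tolerance (inclusive boundary). Energies are recorded on the
#' surviving states.
#'
#' @param states named list of \code{ChemState}.
#' @param eRef reference (reactant) energy, kcal/mol.
#' @param eTol tolerance, kcal/mol.
#' @param evaluator a function \code{function(state) -> energy (kcal/mol)},
#'   e.g. \code{\link{bondEnergyEvaluator}()}.
#' @param onError "drop" (default) discards states whose evaluation fails,
#'   with a warning; "keep" retains them unscreened.
#' @return named list of surviving \code{ChemState} with energies set.
#' @export
screenEnergy <- function(states, eRef, eTol, evaluator,
                         onError = c("drop", "keep")) {
  onError <- match.arg(onError)
  out <- list()
  for (k in names(states)) {
    st <- states[[k]]
    e <- tryCatch(evaluator(st), error = function(err) {
      warning("energy evaluation failed for state ", substr(k, 1, 40), ": ",
              conditionMessage(err))
      NA_real_
    })
    if (is.na(e)) {
      if (onError == "keep") out[[k]] <- st
      next
    }
    if (e <= eRef + eTol) {
      st@energy <- e
      out[[k]] <- st
    }
  }
  out
}

## mean bond enthalpies, kcal/mol, keyed "El1-El2:order" with El1 <= El2
.BOND_ENERGIES <- c(
  "H-H:1" = 104, "C-H:1" = 99, "H-N:1" = 93, "H-O:1" = 111, "H-S:1" = 82,
  "C-C:1" = 83, "C-C:2" = 147, "C-C:3" = 200,
  "C-N:1" = 73, "C-N:2" = 147, "C-N:3" = 213,
  "C-O:1" = 86, "C-O:2" = 178, "C-O:3" = 258,
  "N-N:1" = 39, "N-N:2" = 100, "N-N:3" = 226,
  "N-O:1" = 48, "N-O:2" = 145,
  "O-O:1" = 35, "O-O:2" = 119,
  "C-S:1" = 65, "C-S:2" = 114, "S-S:1" = 54, "O-S:1" = 87,
  "F-H:1" = 135, "Cl-H:1" = 103, "Br-H:1" = 88, "H-I:1" = 71,
  "C-F:1" = 116, "C-Cl:1" = 81, "Br-C:1" = 68, "C-I:1" = 51,
  "F-F:1" = 37, "Cl-Cl:1" = 58, "Br-Br:1" = 46, "I-I:1" = 36,
  "Cl-I:1" = 50, "Br-Cl:1" = 52, "Br-I:1" = 42,
  "Cl-O:1" = 49, "I-O:1" = 48,
  "Co-H:1" = 54, "C-Co:1" = 41, "Co-O:1" = 40, "Co-Co:1" = 20)

#' Built-in additive bond-increment energy evaluator
#'
#' A deterministic surrogate for external electronic-structure backends: the
#' total energy of a state is minus the sum of mean bond enthalpies over its
#' bonds, using the bond orders from \code{\link{assignBondOrders}}. The
#' energy of a multi-molecule state is the sum over components by
#' construction. Pairs missing from the internal table fall back to
#' \code{fallback} kcal/mol per bond order unit.
#'
#' @param fallback energy per bond-order unit for unknown element pairs.
#' @param maxCoordination,allowRadicals passed to the bond-order perception.
#' @return a function \code{function(state) -> energy} (kcal/mol) usable as
#'   an \code{evaluator} in \code{\link{screenEnergy}} and
#'   \code{\link{kineticFilter}}.
#' @export
bondEnergyEvaluator <- function(fallback = 50, maxCoordination = 6L,
                                allowRadicals = TRUE) {
  force(fallback)
  function(state) {
    a <- assignBondOrders(state, maxCoordination = maxCoordination,
                          allowRadicals = allowRadicals)
    if (!isTRUE(a$ok)) stop("no bond-order assignment: ", a$reason)
    sym <- state@atoms$symbol
    ed <- which(upper.tri(a$orders) & a$orders > 0L, arr.ind = TRUE)
    if (!nrow(ed)) return(0)
    e <- 0
    for (r in seq_len(nrow(ed))) {
      i <- ed[r, 1]; j <- ed[r, 2]
      o <- a$orders[i, j]
      pair <- sort(c(sym[i], sym[j]))
      key <- paste0(pair[1], "-", pair[2], ":", o)
      val <- .BOND_ENERGIES[key]
      if (is.na(val)) val <- fallback * o
      e <- e - val
    }
    unname(e)
  }
}

#' Attach an external energy backend as an evaluator
#'
#' Contract for plugging in an external program (semiempirical, DFTB, DFT):
#' the executable is invoked once per state with the path of an SDF payload
#' as its single argument and must write one line containing the total
#' energy in kcal/mol to standard output.
#'
#' @param command path to the executable.
#' @return an evaluator function \code{function(state) -> energy}.
#' @export
externalEvaluator <- function(command) {
  force(command)
  function(state) {
    payload <- tempfile(fileext = ".sdf")
    on.exit(unlink(payload), add = TRUE)
    writeLines(stateToSDF(state), payload)
    out <- system2(command, payload, stdout = TRUE)
    if (length(out) < 1L) stop("external evaluator produced no output")
    as.numeric(trimws(out[[1L]]))
  }
}
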