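## Combinatorial generation of reaction intermediates: conversion-matrix
## enumeration under the bond-change rules, and breadth-first cycling to a
## fixed point with duplicate elimination and plausibility screening.

#' Enumeration configuration
#'
#' Settings for intermediate generation. The defaults encode the standard
#' constraints: at most two bond formations and two dissociations per
#' elementary step, and only uni- or bimolecular steps.
#'
#' @param maxForm maximum bond formations per step.
#' @param maxBreak maximum bond dissociations per step.
#' @param molecularity maximum number of reacting molecules per step (1 or 2).
#' @param maxCycles cap on enumeration cycles (Inf = run to fixed point).
#' @param activeMode use the active-atom reduced basis when active atoms are
#'   flagged.
#' @param inflightEllipse apply the ellipse (digression) screen during
#'   enumeration, not only afterwards.
#' @param delta digression factor for the ellipse criterion (bond changes).
#' @param ringMin,ringMax allowed per-molecule ring (cyclomatic) counts.
#' @param ringMaxMetal ring bound for metal-containing molecules
#'   (pi-coordination forms metallacyclic rings); defaults to
#'   \code{ringMax}.
#' @param eTol energy tolerance in kcal/mol for the energy screen.
#' @param chargeBound maximum |formal charge| allowed on any atom.
#' @param localizedCharges require the number of net-charged molecules in a
#'   state to equal |system charge| (forbids spurious ion-pair states such
#'   as a lone proton plus a carbanion in a neutral system).
#' @param maxCoordination maximum coordination number for transition-metal
#'   atoms (metals bypass the octet-based valence screen).
#' @param allowRadicals permit atoms carrying an unpaired electron.
#' @return a list of class \code{enumerationConfig}.
#' @examples
#' cfg <- enumerationConfig(ringMax = 0)
#' @export
enumerationConfig <- function(maxForm = 2L, maxBreak = 2L, molecularity = 2L,
                              maxCycles = Inf, activeMode = TRUE,
                              inflightEllipse = FALSE, delta = 6L,
                              ringMin = 0L, ringMax = Inf,
                              ringMaxMetal = ringMax, eTol = Inf,
                              chargeBound = 1L, localizedCharges = FALSE,
                              maxCoordination = 6L,
                              allowRadicals = FALSE) {
  stopifnot(maxForm >= 0, maxBreak >= 0, molecularity %in% 1:2,
            ringMin >= 0, ringMax >= ringMin, chargeBound >= 0)
  structure(list(maxForm = as.integer(maxForm),
                 maxBreak = as.integer(maxBreak),
                 molecularity = as.integer(molecularity),
                 maxCycles = maxCycles, activeMode = isTRUE(activeMode),
                 inflightEllipse = isTRUE(inflightEllipse),
                 delta = delta, ringMin = ringMin, ringMax = ringMax,
                 ringMaxMetal = ringMaxMetal,
                 eTol = eTol, chargeBound = as.integer(chargeBound),
                 localizedCharges = isTRUE(localizedCharges),
                 maxCoordination = as.integer(maxCoordination),
                 allowRadicals = isTRUE(allowRadicals)),
            class = "enumerationConfig")
}

## Candidate changed-bond sets for one state, as index pairs into the basis.
## Returns list of list(form = k x 2 matrix, brk = k x 2 matrix).
## comp: component id per basis atom of the full state (molecularity rule).
.conversionPairSets <- function(I, R, cfg, comp = NULL) {
  n <- nrow(I)
  if (!all(dim(I) == dim(R))) stop("basis mismatch between I and R")
  if (is.null(comp)) comp <- componentIds(I)
  ut <- which(upper.tri(I), arr.ind = TRUE)
  ## eqn-style rules: formable where I==0 & R==0 (re-forming a broken
  ## reactant bond is forbidden); breakable where I==1 & R==1 (a bond formed
  ## during the run is never broken)
  iv <- I[ut]; rv <- R[ut]
  Fp <- ut[iv == 0L & rv == 0L, , drop = FALSE]
  Bp <- ut[iv == 1L & rv == 1L, , drop = FALSE]
  out <- vector("list", 256L); cnt <- 0L
  emit <- function(fm, bk) {
    atomsTouched <- c(fm, bk)
    if (length(unique(comp[atomsTouched])) > cfg$molecularity) return()
    cnt <<- cnt + 1L
    out[[cnt]] <<- list(form = fm, brk = bk)
  }
  chooseRows <- function(M, k) {
    if (k == 0L) return(list(M[0, , drop = FALSE]))
    if (nrow(M) < k) return(list())
    idx <- utils::combn(nrow(M), k)
    lapply(seq_len(ncol(idx)), function(j) M[idx[, j], , drop = FALSE])
  }
  formSets <- lapply(0:cfg$maxForm, function(k) chooseRows(Fp, k))
  breakSets <- lapply(0:cfg$maxBreak, function(k) chooseRows(Bp, k))
  for (f in 0:cfg$maxForm) for (b in 0:cfg$maxBreak) {
    if (f + b == 0L) next
    for (fm in formSets[[f + 1L]]) for (bk in breakSets[[b + 1L]]) emit(fm, bk)
  }
  out[seq_len(cnt)]
}

#' Enumerate conversion matrices for a state
#'
#' Generates every nonzero conversion matrix allowed by the bond-change
#' rules: a bond absent from both the current state and the reactant may
#' form; a bond present in both may break; a reactant bond already broken is
#' never re-formed and a bond formed during the run is never broken. At most
#' \code{maxForm} formations and \code{maxBreak} dissociations are allowed,
#' and the changed bonds may touch at most \code{molecularity} molecules of
#' the current state.
#'
#' @param I AC matrix of the current state.
#' @param R AC matrix of the reactant on the same basis.
#' @param cfg an \code{\link{enumerationConfig}}.
#' @param components optional component id per basis atom (needed when
#'   \code{I} is an active-basis matrix whose molecule membership is defined
#'   by the full state).
#' @return list of conversion matrices (symmetric, \{-1,0,1\}, zero diagonal).
#' @examples
#' H2 <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
#' enumerateConversions(H2, H2, enumerationConfig())
#' @export
enumerateConversions <- function(I, R, cfg = enumerationConfig(),
                                 components = NULL) {
  sets <- .conversionPairSets(I, R, cfg, components)
  n <- nrow(I)
  lapply(sets, function(s) {
    C <- matrix(0L, n, n)
    if (nrow(s$form)) {
      C[s$form] <- 1L
      C[s$form[, 2:1, drop = FALSE]] <- 1L
    }
    if (nrow(s$brk)) {
      C[s$brk] <- -1L
      C[s$brk[, 2:1, drop = FALSE]] <- -1L
    }
    C
  })
}

## cheap exact-bytes key of a small 0/1 matrix (upper triangle)
.bitsKey <- function(A) paste(A[upper.tri(A)], collapse = "")

## combn that never falls into the scalar-x trap; k = 0 gives one empty set
.combnIdx <- function(x, k) {
  if (k == 0L) return(matrix(integer(0), 0, 1))
  if (length(x) < k) return(matrix(integer(0), k, 0))
  if (length(x) == 1L) return(matrix(x, 1, 1))
  as.matrix(utils::combn(x, k))
}

#' Enumerate reaction intermediates from a reactant state
#'
#' Breadth-first application of conversion matrices, cycle by cycle, until
#' no new state appears (or \code{maxCycles} is hit). Permutational isomers
#' are removed via the canonical key (eigenvalue spectrum of the alternative
#' Coulomb matrix, exact isomorphism check on collision); states failing the
#' plausibility screens are discarded and never expanded. When active atoms
#' are flagged and \code{cfg$activeMode} is on, enumeration runs on the
#' reduced active-atom basis and every candidate is expanded back to the
#' all-atom basis for screening and deduplication.
#'
#' @param reactant a \code{ChemState}.
#' @param cfg an \code{\link{enumerationConfig}}.
#' @param screens list of predicate functions \code{function(state) ->
#'   logical}; defaults to the perception screens implied by \code{cfg}
#'   (valence/formal charge feasibility and ring count).
#' @param product optional \code{ChemState}; required when
#'   \code{cfg$inflightEllipse} is on.
#' @param verbose print per-cycle counts.
#' @return named list of \code{ChemState} (names = canonical keys),
#'   including the reactant; each state records its first-reached cycle.
#' @export
enumerateIntermediates <- function(reactant, cfg = enumerationConfig(),
                                   screens = NULL, product = NULL,
                                   verbose = FALSE) {
  atoms <- reactant@atoms
  n <- nrow(atoms)
  activeMode <- cfg$activeMode && any(atoms$active)
  actIdx <- if (activeMode) which(atoms$active) else seq_len(n)
  template <- reactant@ac
  Ract <- template[actIdx, actIdx, drop = FALSE]
  if (is.null(screens)) screens <- perceptionScreens(cfg)
  registry <- newKeyRegistry()

  atomsAct <- atoms[actIdx, , drop = FALSE]
  ellipseBound <- Inf
  if (cfg$inflightEllipse) {
    if (is.null(product)) stop("inflight ellipse screening needs a product state")
    Pact <- product@ac[actIdx, actIdx, drop = FALSE]
    cdRP <- cdMin(Ract, Pact, atomsAct)$cd
    ellipseBound <- cdRP + cfg$delta
  }

  expandFull <- function(Aact) {
    out <- template
    out[actIdx, actIdx] <- Aact
    out
  }
  ## default screens run on the bare matrix (no per-candidate S4 overhead);
  ## user-supplied predicates receive a full ChemState
  if (is.null(screens)) {
    passesAC <- function(fullNew) {
      if (!screenRingCount(fullNew, cfg$ringMin, cfg$ringMax,
                           cfg$ringMaxMetal, atoms = atoms)) return(FALSE)
      a <- assignBondOrders(fullNew, totalCharge = reactant@charge,
                            atoms = atoms,
                            maxCoordination = cfg$maxCoordination,
                            allowRadicals = cfg$allowRadicals,
                            localizedCharges = cfg$localizedCharges)
      screenValenceCharge(a, cfg$chargeBound)
    }
  } else {
    passes <- function(state) all(vapply(screens, function(f) isTRUE(f(state)),
                                         logical(1)))
    passesAC <- NULL
  }

  rKey <- canonicalKey(template, atoms, registry)
  r0 <- reactant
  r0@key <- rKey
  r0@cycle <- 0L
  rOK <- if (is.null(passesAC)) passes(r0) else passesAC(template)
  if (!rOK) return(structure(list(), names = character(0)))

  accepted <- list()
  accepted[[rKey]] <- r0
  seen <- new.env(parent = emptyenv())  # normalized bytes of active matrix
  seenCanon <- new.env(parent = emptyenv()) # canonical key -> TRUE
  assign(rKey, TRUE, envir = seenCanon)

  ## bit-vector engine: states on the enumeration basis are rows of
  ## upper-triangle bits; candidate generation, duplicate elimination and
  ## the molecularity rule are batched per frontier state
  na <- length(actIdx)
  m <- na * (na - 1L) / 2L
  utPairs <- which(upper.tri(matrix(0L, na, na)), arr.ind = TRUE)
  utLin <- which(upper.tri(matrix(0L, na, na)))
  toBits <- function(Aact) Aact[utLin]
  fromBits <- function(bits) {
    A <- matrix(0L, na, na)
    A[utLin] <- bits
    A + t(A)
  }
  rv <- toBits(Ract)
  UI <- matrix(0L, na, na)
  UI[utLin] <- seq_len(m)
  UI <- UI + t(UI)

  ## context-preserving permutations of the active atoms: same element and
  ## identical inactive-neighbor set, so each extends to a full-state
  ## automorphism (identity on inactive atoms). Used to normalize candidate
  ## byte keys so most permutational isomers are merged before any spectral
  ## keying.
  inactIdx <- setdiff(seq_len(n), actIdx)
  ctxSig <- vapply(seq_along(actIdx), function(k) {
    a <- actIdx[k]
    paste(atoms$symbol[a],
          paste(which(template[a, inactIdx] == 1L), collapse = ","),
          sep = "|")
  }, character(1))
  ctxPerms <- .allClassMappings(ctxSig, limit = 720L)
  piMat <- NULL
  if (!is.null(ctxPerms) && length(ctxPerms) > 1L) {
    piMat <- t(vapply(ctxPerms, function(p)
      UI[cbind(p[utPairs[, 1]], p[utPairs[, 2]])], integer(m)))
  }
  normKeys <- function(cand, keys) {
    if (is.null(piMat)) return(keys)
    for (s in seq_len(nrow(piMat))) {
      ks <- do.call(paste0, as.data.frame(cand[, piMat[s, ], drop = FALSE]))
      keys <- pmin(keys, ks)
    }
    keys
  }

  ## permuted bit rows of R and P for the vectorized corridor check
  if (cfg$inflightEllipse) {
    sigmaMaps <- .allClassMappings(atomsAct$symbol, limit = 5000L)
    if (!is.null(sigmaMaps)) {
      permBits <- function(B) t(vapply(sigmaMaps, function(s)
        toBits(B[s, s]), integer(m)))
      RactBits <- permBits(Ract)
      PactBits <- permBits(Pact)
      fastEllipse <- function(bits) {
        ## upper-triangle bits count each differing bond exactly once
        dR <- min(rowSums(abs(sweep(RactBits, 2, bits))))
        if (dR > ellipseBound) return(FALSE)
        dP <- min(rowSums(abs(sweep(PactBits, 2, bits))))
        dR + dP <= ellipseBound
      }
    } else {
      fastEllipse <- function(bits) {
        Anew <- fromBits(bits)
        dR <- .cdUpTo(Anew, Ract, atomsAct, ellipseBound)
        if (dR > ellipseBound) return(FALSE)
        dP <- .cdUpTo(Anew, Pact, atomsAct, ellipseBound - dR)
        dR + dP <= ellipseBound
      }
    }
  }

  assign(normKeys(matrix(rv, nrow = 1L), paste(rv, collapse = ""))[1],
         TRUE, envir = seen)
  frontier <- matrix(rv, nrow = 1L)
  cycle <- 0L
  while (nrow(frontier) && cycle < cfg$maxCycles) {
    cycle <- cycle + 1L
    nextFrontier <- list()
    for (fi in seq_len(nrow(frontier))) {
      iv <- frontier[fi, ]
      full <- expandFull(fromBits(iv))
      compAct <- componentIds(full)[actIdx]
      Fp <- which(iv == 0L & rv == 0L)   # formable (never a broken R bond)
      Bp <- which(iv == 1L & rv == 1L)   # breakable (never a formed bond)
      chunks <- list()
      for (f in 0:cfg$maxForm) for (b in 0:cfg$maxBreak) {
        if (f + b == 0L) next
        if (length(Fp) < f || length(Bp) < b) next
        fm <- .combnIdx(Fp, f)
        bm <- .combnIdx(Bp, b)
        nf <- ncol(fm); nb <- ncol(bm)
        if (nf == 0L || nb == 0L) next
        chg <- if (b == 0L) fm else if (f == 0L) bm else
          rbind(fm[, rep(seq_len(nf), each = nb), drop = FALSE],
                bm[, rep(seq_len(nb), times = nf), drop = FALSE])
        chunks[[length(chunks) + 1L]] <- chg
      }
      for (chg in chunks) {
        nC <- ncol(chg)
        ## molecularity: changed bonds touch at most `molecularity`
        ## molecules of the current state
        okMol <- vapply(seq_len(nC), function(j) {
          a <- as.vector(utPairs[chg[, j], ])
          length(unique(compAct[a])) <= cfg$molecularity
        }, logical(1))
        if (!any(okMol)) next
        chg <- chg[, okMol, drop = FALSE]
        nC <- ncol(chg)
        cand <- matrix(iv, nrow = nC, ncol = m, byrow = TRUE)
        ridx <- rep(seq_len(nC), each = nrow(chg))
        cidx <- as.vector(chg)
        cand[cbind(ridx, cidx)] <- 1L - cand[cbind(ridx, cidx)]
        keys <- normKeys(cand, do.call(paste0, as.data.frame(cand)))
        fresh <- !duplicated(keys)
        for (j in which(fresh)) {
          bk <- keys[j]
          if (exists(bk, envir = seen, inherits = FALSE)) next
          assign(bk, TRUE, envir = seen)
          if (cfg$inflightEllipse && !fastEllipse(cand[j, ])) next
          Anew <- fromBits(cand[j, ])
          fullNew <- expandFull(Anew)
          storage.mode(fullNew) <- "integer"
          ck <- canonicalKey(fullNew, atoms, registry)
          if (exists(ck, envir = seenCanon, inherits = FALSE)) next
          assign(ck, TRUE, envir = seenCanon)
          if (is.null(passesAC)) {
            st <- new("ChemState", atoms = atoms, ac = fullNew,
                      charge = reactant@charge, key = ck, cycle = cycle,
                      energy = NULL, smiles = character(0))
            if (!passes(st)) next
          } else {
            if (!passesAC(fullNew)) next
            st <- new("ChemState", atoms = atoms, ac = fullNew,
                      charge = reactant@charge, key = ck, cycle = cycle,
                      energy = NULL, smiles = character(0))
          }
          accepted[[ck]] <- st
          nextFrontier[[length(nextFrontier) + 1L]] <- cand[j, ]
        }
      }
    }
    if (verbose)
      message(sprintf("cycle %d: %d new state(s), %d total",
                      cycle, length(nextFrontier), length(accepted)))
    frontier <- if (length(nextFrontier))
      do.call(rbind, nextFrontier) else matrix(integer(0), 0, m)
  }
  accepted
}
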