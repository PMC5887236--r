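## Chemical distance (CD): the minimum number of bond changes converting one
## state into another, minimized over element-preserving atom mappings, plus
## the ellipse (digression-factor) screening criterion.

#' Chemical distance under a fixed atom ordering
#'
#' Half the elementwise L1 difference of two AC matrices on the same basis:
#' the number of differing bonds without re-mapping atoms.
#'
#' @param A,B AC matrices on the same basis and ordering.
#' @return integer bond-change count.
#' @examples
#' cdFixed(matrix(0L, 2, 2), matrix(c(0L, 1L, 1L, 0L), 2, 2))  # 1
#' @export
cdFixed <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop("basis mismatch between A and B")
  as.integer(sum(abs(A - B)) / 2)
}

## element classes: list of index vectors, one per element, in atom order
.elementClasses <- function(symbols) split(seq_along(symbols), symbols)

## all permutations of 1..n (n small)
.perms <- function(n) {
  if (n == 1L) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(.perms(n - 1L), function(p) c(i, (seq_len(n)[-i])[p]))
  }))
}

#' Minimum chemical distance over element-preserving mappings
#'
#' Exact minimization of \code{\link{cdFixed}} over all permutations of the
#' second state's atoms that preserve element identity, via a
#' branch-and-bound assignment search. Equals the unpermuted distance when
#' every atom is element-distinct; a fixed-order evaluation can only
#' overestimate.
#'
#' @param A,B AC matrices with identical element multisets.
#' @param atoms atom table shared by both (or of \code{A}; \code{atomsB}
#'   for \code{B} when they differ in ordering).
#' @param atomsB optional atom table of \code{B}.
#' @param nodeBudget cap on branch-and-bound nodes; when exhausted, the
#'   best mapping found so far is returned with status "feasible" (an
#'   upper bound on the true minimum) and a warning.
#' @return list with \code{cd} (integer), \code{mapping} (integer vector:
#'   atom u of A maps to atom \code{mapping[u]} of B) and \code{status}
#'   ("optimal" or "feasible").
#' @examples
#' at <- atomTable(c("H", "H", "H", "H"))
#' A <- chemState(at, rbind(c(1, 2)))@ac
#' B <- chemState(at, rbind(c(3, 4)))@ac
#' cdMin(A, B, at)$cd   # 0: permutationally isomorphic
#' @export
cdMin <- function(A, B, atoms, atomsB = NULL, nodeBudget = 2e5) {
  symA <- atoms$symbol[seq_len(nrow(A))]
  symB <- if (is.null(atomsB)) symA else atomsB$symbol[seq_len(nrow(B))]
  if (nrow(A) != nrow(B) ||
      !identical(sort(symA), sort(symB)))
    stop("element multisets differ: states are not interconvertible")
  n <- nrow(A)
  clA <- .elementClasses(symA)
  clB <- .elementClasses(symB)
  ## high-degree atoms first: their mismatches surface early and pruning
  ## bites sooner
  orderA <- unlist(clA, use.names = FALSE)
  orderA <- orderA[order(-rowSums(abs(A))[orderA])]

  ## identity-within-class upper bound
  sigma0 <- integer(n)
  for (e in names(clA)) sigma0[clA[[e]]] <- clB[[e]]
  bestCost <- .mappingCost(A, B, sigma0)
  bestMap <- sigma0
  status <- "optimal"
  if (bestCost > 0L) {
    env <- new.env(parent = emptyenv())
    env$best <- bestCost; env$map <- bestMap
    env$nodes <- 0; env$budget <- nodeBudget; env$hit <- FALSE
    .cdBBrun(A, B, orderA, clB, symA, env)
    bestCost <- env$best
    bestMap <- env$map
    if (env$hit) {
      status <- "feasible"
      warning("cdMin node budget exhausted; returning best feasible bound")
    }
  }
  list(cd = as.integer(bestCost), mapping = bestMap, status = status)
}

## closure-based branch and bound with a node budget
.cdBBrun <- function(A, B, orderA, clB, symA, env) {
  n <- nrow(A)
  sigma <- integer(n)
  usedB <- logical(n)
  recurse <- function(k, partial) {
    if (env$hit) return()
    env$nodes <- env$nodes + 1
    if (env$nodes > env$budget) { env$hit <- TRUE; return() }
    if (k > length(orderA)) {
      if (partial < env$best) { env$best <- partial; env$map <- sigma }
      return()
    }
    u <- orderA[k]
    prev <- orderA[seq_len(k - 1L)]
    for (v in clB[[symA[u]]]) {
      if (usedB[v]) next
      add <- if (k > 1L) sum(abs(A[u, prev] - B[v, sigma[prev]])) else 0L
      if (partial + add >= env$best) next
      sigma[u] <<- v
      usedB[v] <<- TRUE
      recurse(k + 1L, partial + add)
      usedB[v] <<- FALSE
      if (env$hit) return()
    }
  }
  recurse(1L, 0L)
}

.mappingCost <- function(A, B, sigma) {
  as.integer(sum(abs(A - B[sigma, sigma])) / 2)
}

## bounded variant: exact cd when <= limit, otherwise any value > limit
.cdUpTo <- function(A, B, atoms, limit) {
  ## bond-count difference is a permutation-invariant lower bound
  if (abs(sum(A) - sum(B)) / 2 > limit) return(limit + 1L)
  symA <- atoms$symbol
  n <- nrow(A)
  clA <- .elementClasses(symA)
  clB <- clA
  sigma0 <- integer(n)
  for (e in names(clA)) sigma0[clA[[e]]] <- clB[[e]]
  c0 <- .mappingCost(A, B, sigma0)
  best <- min(c0, limit + 1L)
  if (best == 0L) return(0L)
  orderA <- unlist(clA, use.names = FALSE)
  res <- .cdBB(A, B, orderA, clB, symA, 1L, integer(n), logical(n), 0L,
               best, sigma0)
  res$cost
}

## depth-first branch and bound over within-element assignments
.cdBB <- function(A, B, orderA, clB, symA, k, sigma, usedB, partial,
                  bestCost, bestMap) {
  if (partial >= bestCost)
    return(list(cost = bestCost, map = bestMap))
  if (k > length(orderA)) {
    return(list(cost = partial, map = sigma))
  }
  u <- orderA[k]
  prevA <- orderA[seq_len(k - 1L)]
  for (v in clB[[symA[u]]]) {
    if (usedB[v]) next
    add <- 0L
    if (k > 1L)
      add <- sum(abs(A[u, prevA] - B[v, sigma[prevA]]))
    if (partial + add >= bestCost) next
    sigma[u] <- v
    usedB[v] <- TRUE
    res <- .cdBB(A, B, orderA, clB, symA, k + 1L, sigma, usedB,
                 partial + add, bestCost, bestMap)
    bestCost <- res$cost
    bestMap <- res$map
    usedB[v] <- FALSE
  }
  list(cost = bestCost, map = bestMap)
}

## All element-preserving permutations (list of sigma vectors); NULL when the
## count would exceed `limit`.
.allClassMappings <- function(symbols, limit = 50000L) {
  cl <- .elementClasses(symbols)
  sizes <- vapply(cl, length, integer(1))
  if (prod(factorial(sizes)) > limit) return(NULL)
  maps <- list(integer(length(symbols)))
  for (e in names(cl)) {
    idx <- cl[[e]]
    ps <- .perms(length(idx))
    maps <- do.call(c, lapply(maps, function(m) {
      lapply(ps, function(p) { m[idx] <- idx[p]; m })
    }))
  }
  maps
}

## Scaffold-compatible permutations of the active atoms. Enumerated states
## share every bond outside the active block, so an all-atom mapping that
## fixes the scaffold decomposes into a permutation of active atoms with
## equivalent inactive neighborhoods (same element; inactive neighbors with
## identical refinement colors on the scaffold graph). All-atom chemical
## distances between enumerated states are minimized over these mappings,
## evaluated on the active block alone.
.scaffoldPerms <- function(atoms, template, cap = 40320L) {
  actIdx <- which(atoms$active)
  n <- nrow(atoms)
  G0 <- template
  G0[actIdx, actIdx] <- 0L        # active-active bonds vary per state
  nb <- lapply(seq_len(n), function(i) which(G0[i, ] == 1L))
  col <- match(paste(atoms$Z, atoms$active), unique(paste(atoms$Z,
                                                          atoms$active)))
  repeat {
    sig <- vapply(seq_len(n), function(i)
      paste(col[i], paste(sort.int(col[nb[[i]]]), collapse = ","),
            sep = "|"), character(1))
    newcol <- match(sig, sort(unique(sig)))
    if (length(unique(newcol)) == length(unique(col))) { col <- newcol; break }
    col <- newcol
  }
  inact <- setdiff(seq_len(n), actIdx)
  actSig <- vapply(seq_along(actIdx), function(k) {
    a <- actIdx[k]
    nbrs <- intersect(which(template[a, ] == 1L), inact)
    paste(atoms$symbol[a], paste(sort.int(col[nbrs]), collapse = ","),
          sep = "|")
  }, character(1))
  perms <- .allClassMappings(actSig, limit = cap)
  if (is.null(perms)) perms <- list(seq_along(actIdx))
  perms
}

## Characterize the elementary step between two states on a basis:
## feasibility under formation/dissociation caps, minimal CD, and the
## changed-bond sets under a deterministic cap-feasible optimal mapping.
.edgeInfo <- function(A, B, atomsBasis, maxForm = 2L, maxBreak = 2L,
                      maps = NULL) {
  if (is.null(maps)) maps <- .allClassMappings(atomsBasis$symbol)
  if (is.null(maps)) {
    r <- cdMin(A, B, atomsBasis)
    maps <- list(r$mapping)
  }
  ut <- upper.tri(A)
  info <- lapply(maps, function(sigma) {
    D <- A - B[sigma, sigma]
    c(formed = sum(D[ut] == -1L), broken = sum(D[ut] == 1L))
  })
  cds <- vapply(info, sum, numeric(1))
  bestCd <- min(cds)
  ## the step is judged at a CD-optimal mapping: the edge is admissible iff
  ## some optimal mapping satisfies the formation/dissociation caps
  best <- NULL
  for (i in seq_along(maps)) {
    if (cds[i] != bestCd) next
    if (info[[i]]["formed"] <= maxForm && info[[i]]["broken"] <= maxBreak) {
      sigma <- maps[[i]]
      D <- A - B[sigma, sigma]
      best <- list(cd = as.integer(bestCd),
                   formed = unname(info[[i]]["formed"]),
                   broken = unname(info[[i]]["broken"]),
                   formedPairs = which(D == -1L & ut, arr.ind = TRUE),
                   brokenPairs = which(D == 1L & ut, arr.ind = TRUE),
                   mapping = sigma)
      break
    }
  }
  list(cd = as.integer(bestCd), feasible = !is.null(best), step = best)
}

#' Ellipse screening of intermediates (digression criterion)
#'
#' Keeps the states \code{I} with \code{CD(R,I) + CD(I,P) <= CD(R,P) +
#' delta} (inclusive): geometrically, the states inside an ellipse with
#' focal points at the reactant and product. R and P themselves always
#' satisfy the criterion.
#'
#' @param states named list of \code{ChemState}.
#' @param reactant,product \code{ChemState} of the endpoints.
#' @param delta digression factor (bond changes, >= 0).
#' @param basis "all" (default) computes CDs on the full atom basis;
#'   "active" on the active-atom sub-matrix only (cheaper, but mappings
#'   are not required to respect the inactive scaffold, so distances can
#'   be smaller).
#' @return the surviving subset of \code{states}.
#' @export
ellipseFilter <- function(states, reactant, product, delta,
                          basis = c("all", "active")) {
  basis <- match.arg(basis)
  if (delta < 0) stop("digression factor must be >= 0")
  atoms <- reactant@atoms
  partialActive <- any(atoms$active) && !all(atoms$active)
  if (basis == "all" && partialActive) {
    ## enumerated states share the scaffold: all-atom CD via
    ## scaffold-compatible active permutations on the active block
    idx <- which(atoms$active)
    perms <- .scaffoldPerms(atoms, reactant@ac)
    cdPair <- function(A, B) {
      min(vapply(perms, function(s) sum(abs(A - B[s, s])) / 2, numeric(1)))
    }
  } else {
    useActive <- basis == "active" && any(atoms$active)
    idx <- if (useActive) which(atoms$active) else seq_len(nrow(atoms))
    atomsB <- atoms[idx, , drop = FALSE]
    cdPair <- function(A, B) cdMin(A, B, atomsB)$cd
  }
  Ra <- reactant@ac[idx, idx, drop = FALSE]
  Pa <- product@ac[idx, idx, drop = FALSE]
  cdRP <- cdPair(Ra, Pa)
  keep <- vapply(states, function(st) {
    Ia <- st@ac[idx, idx, drop = FALSE]
    cdPair(Ra, Ia) + cdPair(Ia, Pa) <= cdRP + delta
  }, logical(1))
  states[keep]
}
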