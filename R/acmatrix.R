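## Core operations on atom-connectivity (AC) matrices: validation, bond-change
## application, block decomposition, permutation-invariant keying, and the
## active-atom basis reduction.

#' Validate an AC matrix
#'
#' Checks the structural invariants of an atom-connectivity matrix: square,
#' symmetric, zero diagonal, entries in \{0, 1\}.
#'
#' @param A matrix to check.
#' @return list with \code{valid} (logical) and \code{violations}
#'   (character vector, empty when valid).
#' @examples
#' validateAC(matrix(0, 2, 2))$valid
#' @export
validateAC <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("AC matrix must be a square matrix")
  v <- character(0)
  if (!isTRUE(all.equal(unname(A), unname(t(A)))))
    v <- c(v, "matrix is not symmetric")
  if (any(diag(A) != 0))
    v <- c(v, "diagonal entries must be zero")
  if (!all(A %in% c(0, 1)))
    v <- c(v, "entries must be 0 or 1")
  list(valid = length(v) == 0L, violations = v)
}

#' Apply a conversion matrix to an AC matrix
#'
#' A conversion matrix is a symmetric \{-1, 0, 1\} matrix with zero diagonal
#' encoding one elementary reaction: +1 forms a bond, -1 breaks one. The
#' result \code{I + C} must again be a valid AC matrix.
#'
#' @param I AC matrix of the current state.
#' @param C conversion matrix on the same basis.
#' @return the AC matrix \code{I + C}.
#' @examples
#' H2 <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
#' applyConversion(H2, -H2)   # dissociation to two atoms
#' @export
applyConversion <- function(I, C) {
  if (!all(dim(I) == dim(C))) stop("basis mismatch between I and C")
  if (any(diag(C) != 0) || !all(C %in% c(-1, 0, 1)))
    stop("conversion matrix entries must be -1/0/1 with zero diagonal")
  out <- I + C
  if (any(out < 0 | out > 1))
    stop("illegal conversion: resulting AC entries outside {0,1}")
  storage.mode(out) <- "integer"
  out
}

#' Decompose an AC matrix into molecular components
#'
#' Connected components of the bond graph; each component corresponds to one
#' molecule of a (possibly multi-molecule) state.
#'
#' @param A AC matrix.
#' @return list of components, each a list with \code{atoms} (1-based index
#'   vector) and \code{ac} (induced sub-matrix).
#' @examples
#' length(decomposeComponents(matrix(0L, 3, 3)))  # 3 lone atoms
#' @export
decomposeComponents <- function(A) {
  comp <- componentIds(A)
  lapply(split(seq_len(nrow(A)), comp), function(idx) {
    list(atoms = idx, ac = A[idx, idx, drop = FALSE])
  })
}

#' Connected-component ids of the bond graph
#'
#' @param A AC matrix.
#' @return integer vector: component id per atom (ids follow first-atom
#'   order, starting at 1).
#' @export
componentIds <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    frontier <- s
    comp[s] <- cid
    while (length(frontier)) {
      nb <- which(rowSums(A[, frontier, drop = FALSE]) > 0)
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cid
      frontier <- nb
    }
  }
  comp
}

## alternative Coulomb matrix: permutation-covariant, element-aware
.altCoulomb <- function(A, Z) {
  M <- A * outer(Z, Z)
  diag(M) <- 0.5 * Z^2.4
  M
}

#' Permutation-invariant canonical key of a state
#'
#' Key equal for permutationally isomorphic states (same element-preserving
#' relabeling). Implemented as the sorted eigenvalue spectrum of an
#' element-weighted (alternative Coulomb) matrix, rounded to 1e-6, prefixed
#' with the element multiset. Spectral collisions between non-isomorphic
#' graphs are resolved by an exact colored-isomorphism check when a key
#' registry is supplied (as during enumeration).
#'
#' @param A AC matrix.
#' @param atoms atom table.
#' @param registry optional environment from \code{\link{newKeyRegistry}};
#'   enables the exact isomorphism fallback on spectrum collision.
#' @return character key.
#' @export
canonicalKey <- function(A, atoms, registry = NULL) {
  ev <- sort(eigen(.altCoulomb(A, atoms$Z), symmetric = TRUE,
                   only.values = TRUE)$values)
  elems <- paste(sort(atoms$symbol), collapse = "")
  base <- paste0(elems, "|", paste(sprintf("%.6f", round(ev, 6)),
                                   collapse = ","))
  ## -0.000000 and 0.000000 must collapse
  base <- gsub("-0.000000", "0.000000", base, fixed = TRUE)
  if (is.null(registry)) return(base)
  reps <- registry$reps[[base]]
  if (is.null(reps)) {
    registry$reps[[base]] <- list(A)
    return(base)
  }
  for (i in seq_along(reps)) {
    if (.acIsomorphic(A, reps[[i]], atoms$Z, atoms$Z))
      return(if (i == 1L) base else paste0(base, "#", i))
  }
  registry$reps[[base]] <- c(reps, list(A))
  paste0(base, "#", length(reps) + 1L)
}

## key of the spectrum only (shared helper so enumeration can split the
## cheap spectral part from the registry lookup)
.spectralKey <- function(A, atoms) {
  ev <- sort(eigen(.altCoulomb(A, atoms$Z), symmetric = TRUE,
                   only.values = TRUE)$values)
  base <- paste0(paste(sprintf("%.6f", round(ev, 6)), collapse = ","))
  gsub("-0.000000", "0.000000", base, fixed = TRUE)
}

#' Create a canonical-key registry
#'
#' Holds representative matrices per spectral key so that cospectral but
#' non-isomorphic states receive distinct keys.
#' @return an environment usable as the \code{registry} argument of
#'   \code{\link{canonicalKey}}.
#' @export
newKeyRegistry <- function() {
  e <- new.env(parent = emptyenv())
  e$reps <- new.env(parent = emptyenv())   # hashed: spectral key -> matrices
  e
}

## exact element-colored graph isomorphism: joint 1-WL color refinement to
## prune, then class-respecting backtracking (molecular graphs are small and
## sparse, so this is fast and exact)
.acIsomorphic <- function(A, B, zA, zB) {
  n <- nrow(A)
  if (n != nrow(B)) return(FALSE)
  if (sum(A) != sum(B)) return(FALSE)
  if (identical(zA, zB) && identical(A, B)) return(TRUE)
  nbA <- lapply(seq_len(n), function(i) which(A[i, ] == 1L))
  nbB <- lapply(seq_len(n), function(i) which(B[i, ] == 1L))
  ## joint refinement so color ids are comparable across the two graphs
  col <- match(c(zA, zB), sort(unique(c(zA, zB))))
  nb <- c(nbA, lapply(nbB, function(x) x + n))
  repeat {
    sig <- vapply(seq_len(2L * n), function(i)
      paste(col[i], paste(sort.int(col[nb[[i]]]), collapse = ","), sep = "|"),
      character(1))
    newcol <- match(sig, sort(unique(sig)))
    if (length(unique(newcol)) == length(unique(col))) { col <- newcol; break }
    col <- newcol
  }
  cA <- col[seq_len(n)]; cB <- col[n + seq_len(n)]
  if (!identical(sort.int(cA), sort.int(cB))) return(FALSE)
  ## backtracking over color classes, rarest class first
  ord <- order(table(cA)[as.character(cA)], cA)
  sigma <- integer(n)
  used <- logical(n)
  recurse <- function(k) {
    if (k > n) return(TRUE)
    u <- ord[k]
    prev <- ord[seq_len(k - 1L)]
    for (v in which(cB == cA[u] & !used)) {
      if (k > 1L && !all(A[u, prev] == B[v, sigma[prev]])) next
      sigma[u] <<- v
      used[v] <<- TRUE
      if (recurse(k + 1L)) return(TRUE)
      used[v] <<- FALSE
    }
    FALSE
  }
  recurse(1L)
}

#' Project an AC matrix onto the active-atom basis
#'
#' During enumeration only reaction-center ("active") atoms change bonds;
#' the AC matrix is reduced to the rows/columns of the active atoms.
#'
#' @param A_all AC matrix on the all-atom basis.
#' @param atoms atom table with \code{active} flags.
#' @return AC matrix over the active atoms (in atom order).
#' @export
projectActive <- function(A_all, atoms) {
  idx <- which(atoms$active)
  if (!length(idx)) stop("active-atom set is empty")
  A_all[idx, idx, drop = FALSE]
}

#' Expand an active-basis AC matrix back to the all-atom basis
#'
#' Re-inserts every bond not between two active atoms from the all-atom
#' template, so \code{expandActive(projectActive(A), A)} reproduces
#' \code{A}.
#'
#' @param A_active AC matrix on the active basis.
#' @param template all-atom AC matrix providing the untouched bonds.
#' @param atoms atom table with \code{active} flags.
#' @return all-atom AC matrix.
#' @export
expandActive <- function(A_active, template, atoms) {
  idx <- which(atoms$active)
  if (!length(idx)) stop("active-atom set is empty")
  if (length(idx) != nrow(A_active)) stop("active basis size mismatch")
  out <- template
  out[idx, idx] <- A_active
  storage.mode(out) <- "integer"
  out
}
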