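#' @import methods
NULL

#' Atom table constructor
#'
#' Builds the ordered atom list underlying every connectivity matrix.
#' Indices into this table are stable for the lifetime of a run; active
#' atoms mark the reaction center used for reduced-basis enumeration and
#' catalyst atoms drive the catalyst-involvement edge rule.
#'
#' @param symbols character vector of element symbols in atom order.
#' @param active integer or logical vector flagging active atoms
#'   (reaction-center atoms). Integer input is interpreted as 1-based
#'   indices into \code{symbols}.
#' @param catalyst integer or logical vector flagging catalyst atoms.
#' @return a \code{data.frame} with columns \code{symbol}, \code{Z},
#'   \code{active}, \code{catalyst}.
#' @examples
#' atomTable(c("I", "Cl", "H"), active = c(1, 2))
#' @export
atomTable <- function(symbols, active = integer(0), catalyst = integer(0)) {
  if (length(symbols) == 0L) stop("atom list must be nonempty")
  n <- length(symbols)
  toFlag <- function(x) {
    if (is.logical(x)) {
      if (length(x) != n) stop("flag vector length must equal atom count")
      x
    } else {
      x <- as.integer(x)
      if (length(x) && (min(x) < 1L || max(x) > n))
        stop("atom index out of range")
      seq_len(n) %in% x
    }
  }
  data.frame(symbol = as.character(symbols),
             Z = atomicNumber(symbols),
             active = toFlag(active),
             catalyst = toFlag(catalyst),
             stringsAsFactors = FALSE)
}

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' ChemState: one vertex of the reaction network
#'
#' A full-system chemical state: an ordered atom list plus a symmetric 0/1
#' atom-connectivity (AC) matrix, possibly block-diagonal when the state
#' holds several molecules. Carries the total system charge, the canonical
#' key used for duplicate elimination, the enumeration cycle at which it was
#' first reached, and (after an evaluator ran) a total energy in kcal/mol.
#'
#' @slot atoms atom table (see \code{\link{atomTable}}).
#' @slot ac integer AC matrix (symmetric, zero diagonal, entries 0/1).
#' @slot charge integer total system charge (e).
#' @slot key canonical key string (permutation-invariant).
#' @slot cycle integer enumeration cycle at which the state first appeared
#'   (0 for the reactant).
#' @slot energy numeric total energy in kcal/mol, or NULL before evaluation.
#' @slot smiles character vector of per-component SMILES (may be empty).
#' @export
setClass("ChemState",
         representation(atoms = "data.frame",
                        ac = "matrix",
                        charge = "integer",
                        key = "character",
                        cycle = "integer",
                        energy = "numericOrNULL",
                        smiles = "character"),
         prototype(charge = 0L, key = NA_character_, cycle = 0L,
                   energy = NULL, smiles = character(0)))

setValidity("ChemState", function(object) {
  rep <- validateAC(object@ac)
  if (!rep$valid) return(paste(rep$violations, collapse = "; "))
  if (nrow(object@atoms) != nrow(object@ac))
    return("atom table and AC matrix dimension disagree")
  TRUE
})

#' Construct a ChemState
#'
#' @param atoms atom table from \code{\link{atomTable}}.
#' @param bonds two-column matrix of 1-based atom index pairs, or an AC
#'   matrix directly.
#' @param charge integer total charge.
#' @param cycle generation cycle index (0 = reactant).
#' @return a \code{ChemState}.
#' @examples
#' chemState(atomTable(c("H", "H")), rbind(c(1, 2)))
#' @export
chemState <- function(atoms, bonds = NULL, charge = 0L, cycle = 0L) {
  n <- nrow(atoms)
  if (is.null(bonds)) {
    ac <- matrix(0L, n, n)
  } else if (is.matrix(bonds) && nrow(bonds) == n && ncol(bonds) == n) {
    ac <- bonds
    storage.mode(ac) <- "integer"
  } else {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    ac <- matrix(0L, n, n)
    ac[bonds] <- 1L
    ac[bonds[, 2:1, drop = FALSE]] <- 1L
  }
  st <- new("ChemState", atoms = atoms, ac = ac, charge = as.integer(charge),
            cycle = as.integer(cycle))
  st@key <- canonicalKey(ac, atoms)
  st
}

#' @describeIn ChemState-class accessor for the AC matrix
#' @param x a \code{ChemState}.
#' @export
acMatrix <- function(x) x@ac

#' @describeIn ChemState-class accessor for the atom table
#' @export
atoms <- function(x) x@atoms

#' @describeIn ChemState-class accessor for the canonical key
#' @export
stateKey <- function(x) x@key

#' @describeIn ChemState-class accessor for the total energy (kcal/mol)
#' @export
stateEnergy <- function(x) if (is.null(x@energy)) NA_real_ else x@energy

setMethod("show", "ChemState", function(object) {
  comps <- decomposeComponents(object@ac)
  cat(sprintf("ChemState: %d atoms, %d bonds, %d component(s), charge %+d\n",
              nrow(object@atoms), sum(object@ac) / 2L, length(comps),
              object@charge))
  if (length(object@smiles))
    cat("  SMILES:", paste(object@smiles, collapse = " . "), "\n")
  if (!is.null(object@energy))
    cat(sprintf("  energy: %.2f kcal/mol\n", object@energy))
  cat("  key:", substr(object@key, 1, 60),
      if (nchar(object@key) > 60) "..." else "", "\n")
})

#' ReactionNetwork: states linked by elementary reactions
#'
#' Undirected network whose vertices are \code{ChemState}s and whose edges
#' are admissible elementary reactions weighted by chemical distance (the
#' minimal number of bond changes).
#'
#' @slot states named list of \code{ChemState} (names = canonical keys).
#' @slot edges data.frame with columns \code{from}, \code{to} (keys),
#'   \code{weight}, \code{formed}, \code{broken}, \code{catalyst}.
#' @slot reactant canonical key of the reactant vertex.
#' @slot product canonical key of the product vertex.
#' @export
setClass("ReactionNetwork",
         representation(states = "list", edges = "data.frame",
                        reactant = "character", product = "character"))

setValidity("ReactionNetwork", function(object) {
  keys <- names(object@states)
  if (!(object@reactant %in% keys)) return("reactant vertex missing")
  if (!(object@product %in% keys)) return("product vertex missing")
  if (nrow(object@edges)) {
    if (!all(c(object@edges$from, object@edges$to) %in% keys))
      return("edge endpoint not among vertices")
    if (any(object@edges$from == object@edges$to))
      return("self-loop edge")
    if (any(object@edges$weight < 1)) return("edge weight < 1")
  }
  TRUE
})

#' @describeIn ReactionNetwork-class edge table accessor
#' @param x a \code{ReactionNetwork}.
#' @export
networkEdges <- function(x) x@edges

#' @describeIn ReactionNetwork-class state list accessor
#' @export
networkStates <- function(x) x@states

#' @describeIn ReactionNetwork-class reactant key accessor
#' @export
reactantKey <- function(x) x@reactant

#' @describeIn ReactionNetwork-class product key accessor
#' @export
productKey <- function(x) x@product

setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf("ReactionNetwork: %d vertices, %d edges\n",
              length(object@states), nrow(object@edges)))
  cat("  reactant:", substr(object@reactant, 1, 50), "\n")
  cat("  product: ", substr(object@product, 1, 50), "\n")
})

#' ReactionPathSet: sampled reactant-to-product paths
#'
#' @slot paths list of character vectors (canonical-key sequences R -> P).
#' @slot lengths numeric total chemical-distance length per path.
#' @slot ranks integer 1-based rank by length (NA before ranking).
#' @slot percentiles numeric percentile position by length (NA before
#'   ranking).
#' @export
setClass("ReactionPathSet",
         representation(paths = "list", lengths = "numeric",
                        ranks = "integer", percentiles = "numeric"),
         prototype(paths = list(), lengths = numeric(0),
                   ranks = integer(0), percentiles = numeric(0)))

#' Construct a ReactionPathSet
#' @param paths list of canonical-key sequences.
#' @param lengths numeric path lengths (sums of edge weights).
#' @return a \code{ReactionPathSet}.
#' @export
reactionPathSet <- function(paths, lengths) {
  new("ReactionPathSet", paths = paths, lengths = as.numeric(lengths),
      ranks = rep(NA_integer_, length(paths)),
      percentiles = rep(NA_real_, length(paths)))
}

#' @describeIn ReactionPathSet-class number of paths
#' @param x a \code{ReactionPathSet}.
#' @export
pathCount <- function(x) length(x@paths)

#' @describeIn ReactionPathSet-class path lengths accessor
#' @export
pathLengths <- function(x) x@lengths

setMethod("show", "ReactionPathSet", function(object) {
  cat(sprintf("ReactionPathSet: %d path(s)\n", length(object@paths)))
  if (length(object@paths)) {
    cat(sprintf("  lengths: %s\n",
                paste(object@lengths[seq_len(min(10, length(object@lengths)))],
                      collapse = ", ")))
  }
})
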