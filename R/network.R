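## Reaction-network construction, tie-inclusive shortest-path sampling,
## minimal-subnetwork extraction, path ranking, and graph-level kinetic
## filters.

.asIgraph <- function(net) {
  keys <- names(net@states)
  g <- igraph::graph_from_data_frame(
    d = net@edges[, c("from", "to", "weight")],
    directed = FALSE,
    vertices = data.frame(name = keys, stringsAsFactors = FALSE))
  g
}

#' Locate a state in a state list by isomorphism
#'
#' @param states named list of \code{ChemState}.
#' @param state the \code{ChemState} to find.
#' @return the matching canonical key, or \code{NA_character_}.
#' @export
findState <- function(states, state) {
  if (state@key %in% names(states)) return(state@key)
  for (k in names(states)) {
    if (.acIsomorphic(state@ac, states[[k]]@ac, state@atoms$Z,
                      states[[k]]@atoms$Z))
      return(k)
  }
  NA_character_
}

#' Build the chemical-distance-weighted reaction network
#'
#' Links two states by an edge when the bond difference under a
#' CD-optimal element-preserving mapping needs at most \code{maxForm}
#' formations and \code{maxBreak} dissociations, touches at most
#' \code{molecularity} molecules on at least one side, and (for catalytic
#' systems) involves at least one catalyst atom in a changed bond. Edge
#' weight is the minimal chemical distance.
#'
#' @param states named list of \code{ChemState} including reactant and
#'   product.
#' @param reactant,product \code{ChemState} endpoints (located among
#'   \code{states} by key or isomorphism).
#' @param cfg an \code{\link{enumerationConfig}} providing the caps.
#' @param basis CD basis: "all" (default) or "active".
#' @param requireCatalyst apply the catalyst-involvement rule; defaults to
#'   whether any catalyst atom is flagged.
#' @return a \code{ReactionNetwork}.
#' @export
buildNetwork <- function(states, reactant, product,
                         cfg = enumerationConfig(),
                         basis = c("all", "active"),
                         requireCatalyst = NULL) {
  basis <- match.arg(basis)
  rKey <- findState(states, reactant)
  pKey <- findState(states, product)
  if (is.na(rKey)) stop("reactant state missing from the vertex set")
  if (is.na(pKey)) stop("product state missing from the vertex set")
  atoms <- states[[rKey]]@atoms
  if (is.null(requireCatalyst)) requireCatalyst <- any(atoms$catalyst)
  partialActive <- any(atoms$active) && !all(atoms$active)
  maps <- NULL
  if (basis == "all" && partialActive) {
    ## all-atom CD over scaffold-compatible mappings, on the active block
    idx <- which(atoms$active)
    maps <- .scaffoldPerms(atoms, states[[rKey]]@ac)
  } else {
    useActive <- basis == "active" && any(atoms$active)
    idx <- if (useActive) which(atoms$active) else seq_len(nrow(atoms))
  }
  atomsBasis <- atoms[idx, , drop = FALSE]

  keys <- names(states)
  n <- length(keys)
  acts <- lapply(states, function(s) s@ac[idx, idx, drop = FALSE])
  comps <- lapply(states, function(s) componentIds(s@ac))

  rows <- list()
  for (a in seq_len(n - 1L)) for (b in seq(a + 1L, n)) {
    ei <- .edgeInfo(acts[[a]], acts[[b]], atomsBasis,
                    cfg$maxForm, cfg$maxBreak, maps = maps)
    if (!ei$feasible || ei$cd < 1L) next
    st <- ei$step
    changed <- rbind(st$formedPairs, st$brokenPairs)
    ## basis indices -> full-system atom indices, on each side
    touchedA <- idx[unique(as.vector(changed))]
    sigma <- st$mapping
    changedB <- rbind(
      if (nrow(st$formedPairs)) cbind(sigma[st$formedPairs[, 1]],
                                      sigma[st$formedPairs[, 2]]),
      if (nrow(st$brokenPairs)) cbind(sigma[st$brokenPairs[, 1]],
                                      sigma[st$brokenPairs[, 2]]))
    touchedB <- idx[unique(as.vector(changedB))]
    molA <- length(unique(comps[[a]][touchedA]))
    molB <- length(unique(comps[[b]][touchedB]))
    if (min(molA, molB) > cfg$molecularity) next
    catInvolved <- any(atoms$catalyst[touchedA]) ||
      any(atoms$catalyst[touchedB])
    if (requireCatalyst && !catInvolved) next
    rows[[length(rows) + 1L]] <-
      data.frame(from = keys[a], to = keys[b], weight = ei$cd,
                 formed = st$formed, broken = st$broken,
                 catalyst = catInvolved, stringsAsFactors = FALSE)
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(from = character(0), to = character(0), weight = numeric(0),
               formed = integer(0), broken = integer(0),
               catalyst = logical(0), stringsAsFactors = FALSE)
  new("ReactionNetwork", states = states, edges = edges,
      reactant = rKey, product = pKey)
}

## all shortest u -> v paths as lists of key vectors (tie-inclusive)
.allShortest <- function(g, from, to) {
  if (from == to) return(list(from))
  sp <- suppressWarnings(igraph::all_shortest_paths(g, from = from, to = to,
                                                    weights = NULL))
  lapply(sp$res, function(p) names(p))
}

.pathLength <- function(g, keys) {
  if (length(keys) < 2L) return(0)
  eids <- igraph::get_edge_ids(g, as.vector(rbind(keys[-length(keys)],
                                                  keys[-1L])))
  sum(igraph::E(g)$weight[eids])
}

#' All minimal-length loopless paths through a vertex
#'
#' Returns every loopless reactant-to-product path of minimal total
#' chemical distance that passes through vertex \code{v}, ties enumerated
#' exhaustively. Shortest legs (Dijkstra, all equidistant ones) are
#' composed at \code{v}; when every composition repeats a vertex, loopless
#' paths are enumerated in increasing length (Yen's algorithm) until the
#' minimal through-\code{v} length is covered.
#'
#' @param net a \code{ReactionNetwork}.
#' @param v canonical key of the vertex.
#' @param kmax safety cap on Yen enumeration.
#' @return list of character vectors (key sequences, R to P); empty when
#'   \code{v} is disconnected from either endpoint.
#' @export
shortestPathsThrough <- function(net, v, kmax = 4096L) {
  g <- .asIgraph(net)
  r <- net@reactant; p <- net@product
  if (!(v %in% names(net@states))) stop("vertex not in network: ", v)
  dR <- suppressWarnings(igraph::distances(g, v = r, to = v))[1, 1]
  dP <- suppressWarnings(igraph::distances(g, v = v, to = p))[1, 1]
  if (!is.finite(dR) || !is.finite(dP)) return(list())

  legsR <- .allShortest(g, r, v)
  legsP <- .allShortest(g, v, p)
  out <- list()
  for (lr in legsR) for (lp in legsP) {
    full <- c(lr, lp[-1L])
    if (anyDuplicated(full)) next
    out[[length(out) + 1L]] <- full
  }
  if (length(out)) return(unique(out))

  ## all shortest-leg compositions loop: fall back to loopless enumeration
  ## in increasing length over the whole network, filtered on v
  k <- 32L
  repeat {
    ks <- suppressWarnings(igraph::k_shortest_paths(g, from = r, to = p,
                                                    k = k))
    paths <- lapply(ks$vpaths, names)
    lens <- vapply(paths, function(x) .pathLength(g, x), numeric(1))
    through <- vapply(paths, function(x) v %in% x, logical(1))
    if (any(through)) {
      L <- min(lens[through])
      complete <- length(paths) < k || max(lens) > L
      if (complete)
        return(unique(paths[through & lens == L]))
    } else if (length(paths) < k) {
      return(list())   # exhausted: no loopless path visits v
    }
    if (k >= kmax) {
      warning("Yen enumeration cap reached for vertex ", substr(v, 1, 40))
      L <- if (any(through)) min(lens[through]) else return(list())
      return(unique(paths[through & lens == L]))
    }
    k <- k * 2L
  }
}

#' Sample shortest paths through every vertex
#'
#' Union over all network vertices of
#' \code{\link{shortestPathsThrough}}; duplicates (identical key
#' sequences, including reversed ones) are collapsed. With \code{k > 1}
#' the \code{k} smallest distinct through-lengths per vertex are sampled
#' instead of only the minimal one.
#'
#' @param net a \code{ReactionNetwork}.
#' @param k number of distinct shortest through-lengths per vertex.
#' @return a \code{ReactionPathSet}.
#' @export
sampleNetworkPaths <- function(net, k = 1L) {
  g <- .asIgraph(net)
  seen <- new.env(parent = emptyenv())
  paths <- list(); lens <- numeric(0)
  addPath <- function(keys) {
    if (identical(keys[1], net@product)) keys <- rev(keys)
    id <- paste(keys, collapse = "\r")
    if (exists(id, envir = seen, inherits = FALSE)) return()
    assign(id, TRUE, envir = seen)
    paths[[length(paths) + 1L]] <<- keys
    lens[length(lens) + 1L] <<- .pathLength(g, keys)
  }
  for (v in names(net@states)) {
    ps <- shortestPathsThrough(net, v)
    for (x in ps) addPath(x)
    if (k > 1L && length(ps)) {
      ## extend to next-shortest through-lengths via loopless enumeration
      ks <- suppressWarnings(igraph::k_shortest_paths(g, from = net@reactant,
                                                      to = net@product,
                                                      k = 2048L))
      cand <- lapply(ks$vpaths, names)
      cand <- cand[vapply(cand, function(x) v %in% x, logical(1))]
      cl <- vapply(cand, function(x) .pathLength(g, x), numeric(1))
      keepLens <- sort(unique(cl))[seq_len(min(k, length(unique(cl))))]
      for (x in cand[cl %in% keepLens]) addPath(x)
    }
  }
  reactionPathSet(paths, lens)
}

#' Extract the minimal reaction subnetwork
#'
#' Disconnects every edge not on a sampled path and returns the connected
#' component containing the reactant and product; all other vertices are
#' discarded.
#'
#' @param net a \code{ReactionNetwork}.
#' @param paths a \code{ReactionPathSet} from
#'   \code{\link{sampleNetworkPaths}}.
#' @return the minimal \code{ReactionNetwork}.
#' @export
extractMinimalSubnetwork <- function(net, paths) {
  used <- new.env(parent = emptyenv())
  for (keys in paths@paths) {
    if (length(keys) < 2L) next
    for (i in seq_len(length(keys) - 1L)) {
      a <- sort(c(keys[i], keys[i + 1L]))
      assign(paste(a, collapse = "\r"), TRUE, envir = used)
    }
  }
  e <- net@edges
  keep <- vapply(seq_len(nrow(e)), function(i) {
    exists(paste(sort(c(e$from[i], e$to[i])), collapse = "\r"),
           envir = used, inherits = FALSE)
  }, logical(1))
  e <- e[keep, , drop = FALSE]
  ## connected component containing R (and P)
  sub <- new("ReactionNetwork", states = net@states, edges = e,
             reactant = net@reactant, product = net@product)
  g <- .asIgraph(sub)
  memb <- igraph::components(g)$membership
  if (memb[net@reactant] != memb[net@product])
    stop("reactant and product fall in different components: ",
         "inconsistent sampled path set")
  inComp <- names(memb)[memb == memb[net@reactant]]
  e <- e[e$from %in% inComp & e$to %in% inComp, , drop = FALSE]
  new("ReactionNetwork", states = net@states[inComp], edges = e,
      reactant = net@reactant, product = net@product)
}

#' Rank paths and keep the top fraction by chemical distance
#'
#' Distinct paths are sorted by total CD length (ties: lexicographic key
#' sequence) and the shortest \code{ceiling(q * n)} are kept; paths tied in
#' length with the path at the cutoff are kept too. Ranks are 1-based
#' positions in the sorted order; the percentile of a path is the fraction
#' of sampled paths with length up to its own.
#'
#' @param paths a \code{ReactionPathSet}.
#' @param q fraction in (0, 1].
#' @return a \code{ReactionPathSet} with ranks and percentiles set.
#' @export
rankPathsTopq <- function(paths, q) {
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  n <- length(paths@paths)
  if (n == 0L) return(paths)
  sig <- vapply(paths@paths, function(x) paste(x, collapse = "\r"),
                character(1))
  dup <- duplicated(sig)
  ps <- paths@paths[!dup]; ls <- paths@lengths[!dup]
  sig <- sig[!dup]
  ord <- order(ls, sig)
  ps <- ps[ord]; ls <- ls[ord]
  n <- length(ps)
  m <- ceiling(q * n)
  cutoff <- ls[m]
  keep <- ls <= cutoff
  pct <- vapply(ls, function(L) 100 * sum(ls <= L) / n, numeric(1))
  new("ReactionPathSet", paths = ps[keep], lengths = ls[keep],
      ranks = which(keep), percentiles = pct[keep])
}

#' Edge-frequency prioritization
#'
#' Orders edges by how often they appear across the sampled paths
#' (descending), breaking ties by edge weight (ascending) then
#' lexicographically; the order in which transition-state refinement would
#' visit them.
#'
#' @param paths a \code{ReactionPathSet}.
#' @param net optional \code{ReactionNetwork} supplying edge weights.
#' @return data.frame with \code{from}, \code{to}, \code{count},
#'   \code{weight}.
#' @export
edgeFrequencyRanking <- function(paths, net = NULL) {
  if (!length(paths@paths)) stop("empty path set")
  tab <- new.env(parent = emptyenv())
  for (keys in paths@paths) {
    if (length(keys) < 2L) next
    for (i in seq_len(length(keys) - 1L)) {
      id <- paste(sort(c(keys[i], keys[i + 1L])), collapse = "\r")
      assign(id, (if (exists(id, envir = tab, inherits = FALSE))
        get(id, envir = tab) else 0L) + 1L, envir = tab)
    }
  }
  ids <- ls(tab)
  parts <- strsplit(ids, "\r", fixed = TRUE)
  df <- data.frame(from = vapply(parts, `[`, character(1), 1),
                   to = vapply(parts, `[`, character(1), 2),
                   count = vapply(ids, function(i) get(i, envir = tab),
                                  integer(1)),
                   stringsAsFactors = FALSE)
  df$weight <- NA_real_
  if (!is.null(net) && nrow(net@edges)) {
    eid <- paste(ifelse(net@edges$from < net@edges$to, net@edges$from,
                        net@edges$to),
                 ifelse(net@edges$from < net@edges$to, net@edges$to,
                        net@edges$from), sep = "\r")
    df$weight <- net@edges$weight[match(ids, eid)]
  }
  df <- df[order(-df$count, df$weight, df$from, df$to), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Energy-based pruning of the network (kinetic filter)
#'
#' Drops vertices whose energy exceeds the reactant energy plus
#' \code{eTol}, drops edges whose uphill energy difference (in the
#' direction away from the reactant by unweighted graph distance;
#' equidistant edges take the higher-energy endpoint as uphill target)
#' exceeds \code{endoThreshold}, then drops isolated vertices. Reactant and
#' product are always retained.
#'
#' @param net a \code{ReactionNetwork} whose states carry energies (or an
#'   \code{evaluator} to compute them).
#' @param eTol vertex energy tolerance, kcal/mol.
#' @param endoThreshold endothermicity threshold per edge, kcal/mol.
#' @param evaluator optional energy evaluator for states lacking energies.
#' @return the pruned \code{ReactionNetwork}.
#' @export
kineticFilter <- function(net, eTol = Inf, endoThreshold = Inf,
                          evaluator = NULL) {
  states <- net@states
  en <- vapply(names(states), function(k) {
    e <- states[[k]]@energy
    if (is.null(e) && !is.null(evaluator)) {
      e <- evaluator(states[[k]])
      states[[k]]@energy <<- e
    }
    if (is.null(e)) stop("missing energy for vertex ", substr(k, 1, 40))
    e
  }, numeric(1))
  eRef <- en[net@reactant]
  keepV <- en <= eRef + eTol
  keepV[c(net@reactant, net@product)] <- TRUE
  states <- states[keepV]
  e <- net@edges
  e <- e[e$from %in% names(states) & e$to %in% names(states), , drop = FALSE]

  if (is.finite(endoThreshold) && nrow(e)) {
    sub <- new("ReactionNetwork", states = states, edges = e,
               reactant = net@reactant, product = net@product)
    g <- .asIgraph(sub)
    d <- suppressWarnings(igraph::distances(g, v = net@reactant,
                                            weights = NA))[1, ]
    uphill <- vapply(seq_len(nrow(e)), function(i) {
      df <- d[e$from[i]]; dt <- d[e$to[i]]
      ef <- en[e$from[i]]; et <- en[e$to[i]]
      if (is.na(df) || is.na(dt) || df == dt) abs(et - ef)
      else if (dt > df) et - ef else ef - et
    }, numeric(1))
    e <- e[uphill <= endoThreshold, , drop = FALSE]
  }
  ## isolated vertices out (R and P stay)
  touched <- unique(c(e$from, e$to, net@reactant, net@product))
  states <- states[names(states) %in% touched]
  new("ReactionNetwork", states = states, edges = e,
      reactant = net@reactant, product = net@product)
}

#' Remove an edge and every path using it
#'
#' @param net a \code{ReactionNetwork}.
#' @param paths a \code{ReactionPathSet}.
#' @param edge character vector of the two endpoint keys.
#' @return list with the pruned \code{network} and \code{paths}.
#' @export
removeEdgeAndPaths <- function(net, paths, edge) {
  stopifnot(length(edge) == 2L)
  eid <- paste(sort(edge), collapse = "\r")
  e <- net@edges
  hit <- paste(ifelse(e$from < e$to, e$from, e$to),
               ifelse(e$from < e$to, e$to, e$from), sep = "\r") == eid
  e <- e[!hit, , drop = FALSE]
  usesEdge <- vapply(paths@paths, function(keys) {
    if (length(keys) < 2L) return(FALSE)
    any(vapply(seq_len(length(keys) - 1L), function(i) {
      paste(sort(c(keys[i], keys[i + 1L])), collapse = "\r") == eid
    }, logical(1)))
  }, logical(1))
  list(network = new("ReactionNetwork", states = net@states, edges = e,
                     reactant = net@reactant, product = net@product),
       paths = new("ReactionPathSet", paths = paths@paths[!usesEdge],
                   lengths = paths@lengths[!usesEdge],
                   ranks = paths@ranks[!usesEdge],
                   percentiles = paths@percentiles[!usesEdge]))
}
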