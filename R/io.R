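## Tabular and graph exports; every writer has a matching reader so that
## exported artifacts re-import to equal in-memory objects.

#' Write the state dump
#'
#' One CSV row per state: canonical key, first-reached cycle, energy (if
#' evaluated) and per-component SMILES (if Open Babel is available and the
#' state admits a bond-order assignment; otherwise the SMILES field is the
#' flag \code{"<graph-only>"}).
#'
#' @param states named list of \code{ChemState}.
#' @param path output CSV path.
#' @param smiles emit SMILES (needs ChemmineOB).
#' @return invisibly, the data.frame written.
#' @export
writeStateTable <- function(states, path, smiles = FALSE) {
  df <- data.frame(
    key = names(states),
    cycle = vapply(states, function(s) s@cycle, integer(1)),
    energy = vapply(states, stateEnergy, numeric(1)),
    components = vapply(states, function(s)
      length(unique(componentIds(s@ac))), integer(1)),
    stringsAsFactors = FALSE)
  if (smiles) {
    df$smiles <- vapply(states, function(s) {
      out <- tryCatch(paste(toSmiles(s), collapse = "."),
                      error = function(e) "<graph-only>")
      out
    }, character(1))
  }
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read a state dump written by \code{\link{writeStateTable}}
#' @param path CSV path.
#' @return data.frame.
#' @export
readStateTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write the network edge list
#'
#' @param net a \code{ReactionNetwork}.
#' @param path output CSV path.
#' @return invisibly, the data.frame written.
#' @export
writeEdgeList <- function(net, path) {
  utils::write.csv(net@edges, path, row.names = FALSE)
  invisible(net@edges)
}

#' Read an edge list written by \code{\link{writeEdgeList}}
#' @param path CSV path.
#' @return data.frame with the edge columns.
#' @export
readEdgeList <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write the network as GraphML
#'
#' @param net a \code{ReactionNetwork}.
#' @param path output .graphml path.
#' @export
writeGraphML <- function(net, path) {
  g <- .asIgraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(NULL)
}

#' Write the pairwise chemical-distance matrix
#'
#' @param states named list of \code{ChemState}.
#' @param path output CSV path.
#' @param basis "all" or "active" (see \code{\link{ellipseFilter}}).
#' @return invisibly, the labeled distance matrix.
#' @export
writeDistanceMatrix <- function(states, path, basis = c("all", "active")) {
  basis <- match.arg(basis)
  atoms <- states[[1]]@atoms
  useActive <- basis == "active" && any(atoms$active)
  idx <- if (useActive) which(atoms$active) else seq_len(nrow(atoms))
  atomsB <- atoms[idx, , drop = FALSE]
  keys <- names(states)
  n <- length(keys)
  D <- matrix(0L, n, n, dimnames = list(keys, keys))
  acts <- lapply(states, function(s) s@ac[idx, idx, drop = FALSE])
  for (a in seq_len(n - 1L)) for (b in seq(a + 1L, n)) {
    D[a, b] <- D[b, a] <- cdMin(acts[[a]], acts[[b]], atomsB)$cd
  }
  utils::write.csv(as.data.frame(D), path)
  invisible(D)
}

#' Write the ranked-path report
#'
#' Structured JSON: per path the key sequence, per-vertex SMILES when
#' available, total CD length, rank and percentile.
#'
#' @param paths a \code{ReactionPathSet} (ranked or not).
#' @param net the \code{ReactionNetwork} the paths live in.
#' @param path output .json path.
#' @param smiles include per-vertex SMILES.
#' @return invisibly, the report list.
#' @export
writePathReport <- function(paths, net, path, smiles = FALSE) {
  rep <- lapply(seq_along(paths@paths), function(i) {
    keys <- paths@paths[[i]]
    entry <- list(rank = paths@ranks[i],
                  percentile = paths@percentiles[i],
                  length = paths@lengths[i],
                  vertices = keys)
    if (smiles) {
      entry$smiles <- lapply(keys, function(k) {
        tryCatch(unname(toSmiles(net@states[[k]])),
                 error = function(e) "<graph-only>")
      })
    }
    entry
  })
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(rep)
}

#' Read a path report written by \code{\link{writePathReport}}
#' @param path JSON path.
#' @return a \code{ReactionPathSet}.
#' @export
readPathReport <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = FALSE)
  ps <- lapply(rep, function(e) unlist(e$vertices))
  new("ReactionPathSet",
      paths = ps,
      lengths = vapply(rep, function(e) as.numeric(e$length), numeric(1)),
      ranks = vapply(rep, function(e)
        if (is.null(e$rank) || is.na(e$rank)) NA_integer_
        else as.integer(e$rank), integer(1)),
      percentiles = vapply(rep, function(e)
        if (is.null(e$percentile) || is.na(e$percentile)) NA_real_
        else as.numeric(e$percentile), numeric(1)))
}
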