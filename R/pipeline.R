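## End-to-end driver: enumeration -> screens -> network -> minimal
## subnetwork -> ranked paths, with per-stage counts and optional artifact
## export.

#' Run the full reaction-path prediction pipeline
#'
#' Executes the four stages in order: (1) reactant/product to AC matrices;
#' (2) cycle-wise combinatorial enumeration of intermediates with
#' valence/charge/ring screening and optional energy screening; (3)
#' ellipse (digression) screening, CD-weighted network construction,
#' tie-inclusive shortest-path sampling through every vertex, top-q
#' ranking, minimal-subnetwork extraction; (4) optional graph-level
#' kinetic filters when thresholds are finite.
#'
#' @param reactant,product \code{ChemState} endpoints (e.g. from
#'   \code{\link{loadStructures}} or a fixture).
#' @param cfg an \code{\link{enumerationConfig}}.
#' @param delta digression factor for the ellipse criterion.
#' @param eTol energy tolerance (kcal/mol); the energy screen runs when
#'   finite and an evaluator is given.
#' @param evaluator energy evaluator (\code{\link{bondEnergyEvaluator}} or
#'   \code{\link{externalEvaluator}}).
#' @param topq fraction of paths kept in the ranking.
#' @param k number of shortest through-lengths sampled per vertex.
#' @param endoThreshold endothermicity threshold for the kinetic filter
#'   (kcal/mol; Inf disables).
#' @param states optional precomputed result of
#'   \code{\link{enumerateIntermediates}} for this reactant/config;
#'   enumeration is skipped when supplied.
#' @param outdir optional directory for artifact export (state dump,
#'   distance matrix, edge lists, GraphML, path report).
#' @param smilesOut include SMILES in exports (needs ChemmineOB).
#' @param verbose print per-stage counts.
#' @return list with \code{states}, \code{screened}, \code{ellipse},
#'   \code{network}, \code{sampled}, \code{ranked}, \code{minimal},
#'   \code{counts} (named integer vector of per-stage sizes).
#' @export
runPipeline <- function(reactant, product, cfg = enumerationConfig(),
                        delta = 6L, eTol = Inf, evaluator = NULL,
                        topq = 0.5, k = 1L, endoThreshold = Inf,
                        states = NULL, outdir = NULL, smilesOut = FALSE,
                        verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  counts <- c()

  ## Step 2: combinatorial enumeration + perception screens
  if (is.null(states))
    states <- enumerateIntermediates(reactant, cfg, product = product)
  counts["enumerated"] <- length(states)
  say("enumeration: %d intermediates", length(states))

  rKey <- findState(states, reactant)
  if (is.na(rKey)) stop("stage enumeration: reactant screened out")
  screened <- states
  if (!is.null(evaluator) && is.finite(eTol)) {
    eRef <- evaluator(states[[rKey]])
    screened <- screenEnergy(states, eRef, eTol, evaluator)
    if (!rKey %in% names(screened)) screened[[rKey]] <- states[[rKey]]
    counts["energy_screened"] <- length(screened)
    say("energy screen (E_tol = %g): %d intermediates", eTol,
        length(screened))
  }
  pKey <- findState(screened, product)
  if (is.na(pKey))
    stop("stage screening: product state not among surviving intermediates")

  ## Step 3: ellipse screen, network, path sampling, minimal subnetwork
  ellipse <- ellipseFilter(screened, screened[[rKey]], screened[[pKey]],
                           delta)
  counts["ellipse"] <- length(ellipse)
  say("ellipse criterion (delta = %d): %d intermediates", delta,
      length(ellipse))

  net <- buildNetwork(ellipse, screened[[rKey]], screened[[pKey]], cfg)
  counts["vertices"] <- length(net@states)
  counts["edges"] <- nrow(net@edges)
  say("network: %d vertices, %d edges", counts["vertices"], counts["edges"])

  sampled <- sampleNetworkPaths(net, k = k)
  counts["sampled_paths"] <- length(sampled@paths)
  ranked <- rankPathsTopq(sampled, topq)
  counts["ranked_paths"] <- length(ranked@paths)
  minimal <- extractMinimalSubnetwork(net, ranked)
  counts["min_vertices"] <- length(minimal@states)
  counts["min_edges"] <- nrow(minimal@edges)
  say("minimal subnetwork: %d paths, %d vertices, %d edges",
      counts["ranked_paths"], counts["min_vertices"], counts["min_edges"])

  ## Step 4 (optional): kinetic filters at the graph level
  if (!is.null(evaluator) && is.finite(endoThreshold)) {
    minimal <- kineticFilter(minimal, eTol = eTol,
                             endoThreshold = endoThreshold,
                             evaluator = evaluator)
    counts["kinetic_vertices"] <- length(minimal@states)
    counts["kinetic_edges"] <- nrow(minimal@edges)
    say("kinetic filter: %d vertices, %d edges",
        counts["kinetic_vertices"], counts["kinetic_edges"])
  }

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeStateTable(states, file.path(outdir, "states.csv"),
                    smiles = smilesOut)
    writeDistanceMatrix(ellipse, file.path(outdir, "distances.csv"))
    writeEdgeList(net, file.path(outdir, "network_edges.csv"))
    writeGraphML(net, file.path(outdir, "network.graphml"))
    writeEdgeList(minimal, file.path(outdir, "minimal_edges.csv"))
    writePathReport(ranked, net, file.path(outdir, "paths.json"),
                    smiles = smilesOut)
    jsonlite::write_json(as.list(counts), file.path(outdir, "summary.json"),
                         auto_unbox = TRUE)
  }

  list(states = states, screened = screened, ellipse = ellipse,
       network = net, sampled = sampled, ranked = ranked,
       minimal = minimal, counts = counts,
       reactantKey = rKey, productKey = pKey)
}
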