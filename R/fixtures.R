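## Built-in reference systems. Atom tables and bonds are constructed
## explicitly so that atom indices (and hence active/catalyst flags) are
## pinned independently of any external parser.

#' Interhalogen toy reaction fixture: 2 ICl + H2 -> 2 HCl + I2
#'
#' Six atoms, all active; the product is reached through intermediates such
#' as HI + HCl + ICl. Halogen chemistry is homolytic, so the configuration
#' admits open-shell atoms (radicals) but no spurious ion pairs. Small
#' enough for exhaustive oracles.
#'
#' @return list with \code{name}, \code{reactant}, \code{product},
#'   \code{config} and advisory \code{expected} regression numbers.
#' @examples
#' fx <- fixtureInterhalogen()
#' cdMin(fx$reactant@ac, fx$product@ac, fx$reactant@atoms)$cd  # 6
#' @export
fixtureInterhalogen <- function() {
  at <- atomTable(c("I", "Cl", "I", "Cl", "H", "H"), active = 1:6)
  reactant <- chemState(at, rbind(c(1, 2), c(3, 4), c(5, 6)))
  product <- chemState(at, rbind(c(1, 3), c(2, 5), c(4, 6)))
  list(name = "interhalogen",
       reactant = reactant, product = product,
       smiles = list(reactant = "ICl.ICl.[H][H]",
                     product = "Cl.Cl.II"),
       config = enumerationConfig(ringMax = 0, localizedCharges = TRUE,
                                  allowRadicals = TRUE),
       delta = 6L, eTol = 20, topq = 0.5,
       expected = list(cdRP = 6L))
}

#' Claisen ester condensation fixture
#'
#' Two ethyl acetate molecules plus ethoxide (system charge -1) condensing
#' to ethyl acetoacetate, ethanol and regenerated ethoxide. Active atoms
#' (reaction center): the alpha-carbon and one alpha-hydrogen of the first
#' ester, the carbonyl carbon, carbonyl oxygen and ester oxygen of the
#' second ester, and the ethoxide oxygen. The accepted mechanism is
#' deprotonation (enolate), C-C addition (tetrahedral alkoxide), and
#' ethoxide expulsion.
#'
#' @return fixture list as in \code{\link{fixtureInterhalogen}}.
#' @export
fixtureClaisen <- function() {
  ester <- function() {
    ## 1 C(alpha/methyl) 2 C(carbonyl) 3 O(carbonyl) 4 O(ester) 5 C(OCH2)
    ## 6 C(CH3) 7-9 H(alpha) 10-11 H(C5) 12-14 H(C6)
    list(symbols = c("C", "C", "O", "O", "C", "C", rep("H", 8)),
         bonds = rbind(c(1, 2), c(2, 3), c(2, 4), c(4, 5), c(5, 6),
                       c(1, 7), c(1, 8), c(1, 9), c(5, 10), c(5, 11),
                       c(6, 12), c(6, 13), c(6, 14)))
  }
  e <- ester()
  symbols <- c(e$symbols, e$symbols,
               c("C", "C", "O", rep("H", 5)))   # ethoxide: 29-36
  bonds <- rbind(e$bonds,
                 e$bonds + 14L,
                 matrix(c(29, 30, 29, 31, 29, 32, 29, 33,
                          30, 34, 30, 35, 30, 36), ncol = 2, byrow = TRUE))
  ## active: ester1 alpha C (1) + one alpha H (7); ester2 carbonyl C (16),
  ## carbonyl O (17), ester O (18); ethoxide O (31)
  at <- atomTable(symbols, active = c(1L, 7L, 16L, 17L, 18L, 31L))
  reactant <- chemState(at, bonds, charge = -1L)
  pb <- bonds[!(bonds[, 1] == 1 & bonds[, 2] == 7) &
              !(bonds[, 1] == 16 & bonds[, 2] == 18), , drop = FALSE]
  pb <- rbind(pb, c(1, 16), c(7, 31))
  product <- chemState(at, pb, charge = -1L)
  list(name = "claisen",
       reactant = reactant, product = product,
       smiles = list(reactant = "CC(=O)OCC.CC(=O)OCC.CC[O-]",
                     product = "CCOC(=O)CC(C)=O.CCO.CC[O-]"),
       config = enumerationConfig(ringMax = 0, localizedCharges = TRUE),
       delta = 6L, eTol = 20, topq = 0.5,
       expected = list(preEnergy = 113L, postEnergy = 66L, postEllipse = 32L,
                       edges = 376L, paths = 29L, minVertices = 14L,
                       minEdges = 35L))
}

#' Cobalt-catalyzed hydroformylation fixture
#'
#' HCo(CO)3 + ethylene + CO + H2 -> propanal + HCo(CO)3. Eight active
#' atoms: Co, the hydride H, both ethylene carbons, the free CO carbon and
#' oxygen, and both H2 hydrogens. The cobalt center is the catalyst atom,
#' so network edges must change at least one Co bond. Metallacyclic
#' intermediates (pi-coordination) make one ring admissible.
#'
#' @return fixture list as in \code{\link{fixtureInterhalogen}}; use
#'   \code{\link{heckBreslowLike}} to recognize Heck-Breslow paths in this
#'   system.
#' @export
fixtureHydroformylation <- function() {
  ## 1 Co, 2 H(hydride), 3 C + 4 O / 5 C + 6 O / 7 C + 8 O (CO ligands),
  ## 9 C + 10 C (ethylene), 11-12 H(C9), 13-14 H(C10),
  ## 15 C + 16 O (free CO), 17-18 H (H2)
  symbols <- c("Co", "H", "C", "O", "C", "O", "C", "O",
               "C", "C", "H", "H", "H", "H", "C", "O", "H", "H")
  bonds <- rbind(c(1, 2), c(1, 3), c(3, 4), c(1, 5), c(5, 6), c(1, 7),
                 c(7, 8), c(9, 10), c(9, 11), c(9, 12), c(10, 13),
                 c(10, 14), c(15, 16), c(17, 18))
  at <- atomTable(symbols, active = c(1L, 2L, 9L, 10L, 15L, 16L, 17L, 18L),
                  catalyst = 1L)
  reactant <- chemState(at, bonds)
  pb <- bonds[!(bonds[, 1] == 1 & bonds[, 2] == 2) &
              !(bonds[, 1] == 17 & bonds[, 2] == 18), , drop = FALSE]
  pb <- rbind(pb, c(2, 9), c(10, 15), c(15, 17), c(1, 18))
  product <- chemState(at, pb)
  list(name = "hydroformylation",
       reactant = reactant, product = product,
       smiles = list(
         reactant = "[H][Co]([C-]#[O+])([C-]#[O+])[C-]#[O+].C=C.[C-]#[O+].[H][H]",
         product = "CCC=O.[H][Co]([C-]#[O+])([C-]#[O+])[C-]#[O+]"),
       config = enumerationConfig(ringMax = 0, ringMaxMetal = 1,
                                  maxCoordination = 6L,
                                  localizedCharges = TRUE,
                                  inflightEllipse = TRUE, delta = 6L),
       delta = 6L, eTol = 20, topq = 0.5,
       expected = list(preEnergy = 239L, postEnergy = 224L,
                       vertices = 54L, edges = 403L, paths = 91L,
                       minVertices = 39L, minEdges = 104L,
                       heckBreslowPercentile = 33))
}

#' Heck-Breslow milestone test for hydroformylation paths
#'
#' Checks whether a sequence of states (AC matrices in the
#' \code{\link{fixtureHydroformylation}} atom order) passes the three
#' milestones of the Heck-Breslow catalytic cycle in order: olefin
#' coordination (Co bonded to both ethylene carbons), migratory insertion
#' to the alkyl (Co bonded to one ethylene carbon, the other carrying a
#' transferred hydrogen), and CO insertion to the acyl (the free-CO carbon
#' bonded to cobalt and to an ethylene carbon). Hydrogenolysis is implied
#' by reaching the product.
#'
#' @param acSeq list of all-atom AC matrices along a path (reactant to
#'   product).
#' @return logical: does the path realize the mechanism?
#' @export
heckBreslowLike <- function(acSeq) {
  coord <- function(A) A[1, 9] == 1L && A[1, 10] == 1L && A[9, 10] == 1L
  alkyl <- function(A) {
    onCo <- A[1, 9] + A[1, 10]
    if (onCo != 1L || A[9, 10] != 1L) return(FALSE)
    cf <- if (A[1, 9] == 1L) 10L else 9L
    sum(A[c(2, 17, 18), cf]) >= 1L
  }
  acyl <- function(A) {
    A[1, 15] == 1L && A[15, 16] == 1L && (A[15, 9] + A[15, 10]) >= 1L
  }
  stage <- 0L
  for (A in acSeq) {
    if (stage == 0L && coord(A)) stage <- 1L
    else if (stage == 1L && alkyl(A)) stage <- 2L
    else if (stage == 2L && acyl(A)) stage <- 3L
  }
  stage == 3L
}

#' List the built-in fixtures
#' @return named list of fixture constructor functions.
#' @export
builtinFixtures <- function() {
  list(interhalogen = fixtureInterhalogen,
       claisen = fixtureClaisen,
       hydroformylation = fixtureHydroformylation)
}
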