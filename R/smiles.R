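## SMILES / SDF / XYZ conversion. Structure formats go through Open Babel
## (via ChemmineOB); the SDF V2000 text itself is written and parsed here so
## that bond orders and formal charges survive round trips bit-exactly.

.requireOB <- function() {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("ChemmineOB (Open Babel) is required for SMILES/structure conversion")
}

## SDF (V2000) text for a set of atoms + bond-order matrix + charges
.sdfText <- function(symbols, orders, charges, title = "") {
  n <- length(symbols)
  ed <- which(upper.tri(orders) & orders > 0L, arr.ind = TRUE)
  m <- nrow(ed)
  lines <- c(title, " rxnpath", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, symbols[i]))
  }
  if (m) for (r in seq_len(m)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              ed[r, 1], ed[r, 2], orders[ed[r, 1], ed[r, 2]]))
  }
  chg <- which(charges != 0L)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(grp)),
                               paste0(sprintf("%4d%4d", grp, charges[grp]),
                                      collapse = "")))
    }
  }
  c(lines, "M  END", "$$$$")
}

#' Serialize a state to SDF text
#'
#' Bond orders and formal charges come from
#' \code{\link{assignBondOrders}}; the whole (possibly multi-molecule)
#' state is written as one V2000 record with zero coordinates.
#'
#' @param state a \code{ChemState}.
#' @param assignment optional precomputed bond-order assignment.
#' @return character vector of SDF lines.
#' @export
stateToSDF <- function(state, assignment = NULL) {
  if (is.null(assignment)) assignment <- assignBondOrders(state)
  if (!isTRUE(assignment$ok))
    stop("cannot serialize state without a bond-order assignment: ",
         assignment$reason)
  .sdfText(state@atoms$symbol, assignment$orders, assignment$charges,
           title = substr(state@key, 1, 60))
}

#' Canonical SMILES per component of a state
#'
#' Assigns bond orders and formal charges, then emits one canonical SMILES
#' string per molecule via Open Babel. States whose bonding defies the
#' valence model (no feasible assignment) are flagged with an error rather
#' than silently dropped; callers may keep such states under their
#' graph-only canonical key.
#'
#' @param state a \code{ChemState}.
#' @param assignment optional precomputed assignment.
#' @return character vector of canonical SMILES, one per component (in
#'   first-atom order).
#' @export
toSmiles <- function(state, assignment = NULL) {
  .requireOB()
  if (is.null(assignment)) assignment <- assignBondOrders(state)
  if (!isTRUE(assignment$ok))
    stop("no bond-order assignment for SMILES emission: ", assignment$reason)
  comp <- componentIds(state@ac)
  vapply(split(seq_len(nrow(state@ac)), comp), function(idx) {
    sdf <- paste(.sdfText(state@atoms$symbol[idx],
                          assignment$orders[idx, idx, drop = FALSE],
                          assignment$charges[idx]), collapse = "\n")
    out <- ChemmineOB::convertFormat("SDF", "CAN", sdf)
    strsplit(trimws(out), "[ \t\n]")[[1]][1]
  }, character(1))
}

## parse one or more V2000 records from SDF text lines
.parseSDFText <- function(lines) {
  recs <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ## skip leading blank lines between records
    while (i <= n && !grepl("V2000", lines[i], fixed = TRUE)) i <- i + 1L
    if (i > n) break
    counts <- lines[i]
    na <- as.integer(substr(counts, 1, 3))
    nb <- as.integer(substr(counts, 4, 6))
    atomLines <- lines[(i + 1L):(i + na)]
    symbols <- trimws(substr(atomLines, 32, 34))
    bonds <- matrix(integer(0), 0, 3)
    if (nb > 0) {
      bondLines <- lines[(i + na + 1L):(i + na + nb)]
      bonds <- cbind(as.integer(substr(bondLines, 1, 3)),
                     as.integer(substr(bondLines, 4, 6)),
                     as.integer(substr(bondLines, 7, 9)))
    }
    j <- i + na + nb + 1L
    charges <- integer(na)
    while (j <= n && !grepl("^M  END", lines[j])) {
      if (grepl("^M  CHG", lines[j])) {
        k <- as.integer(substr(lines[j], 7, 9))
        for (q in seq_len(k)) {
          off <- 10 + (q - 1) * 8
          charges[as.integer(substr(lines[j], off, off + 3))] <-
            as.integer(substr(lines[j], off + 4, off + 7))
        }
      }
      j <- j + 1L
    }
    recs[[length(recs) + 1L]] <- list(symbols = symbols, bonds = bonds,
                                      charges = charges)
    while (j <= n && !grepl("^\\$\\$\\$\\$", lines[j])) j <- j + 1L
    i <- j + 1L
  }
  recs
}

#' Parse SMILES into a chemical state
#'
#' Hydrogens are made explicit; dot-separated molecules become one
#' block-diagonal state. The total charge is read off the formal charges.
#'
#' @param smiles SMILES string.
#' @param active,catalyst atom index/flag vectors (0-based indices are
#'   accepted via \code{zeroBased}).
#' @param zeroBased treat integer atom indices as 0-based.
#' @return a \code{ChemState}.
#' @export
parseSmiles <- function(smiles, active = integer(0), catalyst = integer(0),
                        zeroBased = FALSE) {
  .requireOB()
  sdf <- ChemmineOB::convertFormat(
    "SMI", "SDF", paste0(smiles, "\n"),
    options = data.frame(names = "h", args = "", stringsAsFactors = FALSE))
  recs <- .parseSDFText(strsplit(sdf, "\n")[[1]])
  if (!length(recs)) stop("unparsable SMILES: ", smiles)
  .recsToState(recs, active, catalyst, zeroBased)
}

.recsToState <- function(recs, active, catalyst, zeroBased) {
  if (zeroBased) {
    if (is.numeric(active)) active <- as.integer(active) + 1L
    if (is.numeric(catalyst)) catalyst <- as.integer(catalyst) + 1L
  }
  symbols <- unlist(lapply(recs, `[[`, "symbols"))
  offs <- cumsum(c(0L, vapply(recs, function(r) length(r$symbols),
                              integer(1))))
  bonds <- do.call(rbind, lapply(seq_along(recs), function(k) {
    b <- recs[[k]]$bonds
    if (nrow(b)) b[, 1:2, drop = FALSE] + offs[k] else NULL
  }))
  charge <- sum(unlist(lapply(recs, `[[`, "charges")))
  at <- atomTable(symbols, active = active, catalyst = catalyst)
  chemState(at, bonds, charge = charge)
}

#' Read an XYZ file into a chemical state
#'
#' Bonds are perceived from interatomic distances: two atoms are bonded
#' when their distance is at most \code{scale} times the sum of their
#' covalent radii.
#'
#' @param path XYZ file path (single frame).
#' @param scale covalent-radius scaling cutoff.
#' @param charge total system charge.
#' @param active,catalyst atom flags as in \code{\link{parseSmiles}}.
#' @param zeroBased treat integer indices as 0-based.
#' @return a \code{ChemState}.
#' @export
readXYZ <- function(path, scale = 1.2, charge = 0L, active = integer(0),
                    catalyst = integer(0), zeroBased = FALSE) {
  lines <- readLines(path)
  na <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[3:(2 + na)]), "[ \t]+")
  symbols <- vapply(rows, `[`, character(1), 1)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  d <- as.matrix(stats::dist(xyz))
  rc <- .covalentRadius(symbols)
  cut <- scale * outer(rc, rc, `+`)
  ac <- (d <= cut) * 1L
  diag(ac) <- 0L
  storage.mode(ac) <- "integer"
  if (zeroBased) {
    if (is.numeric(active)) active <- as.integer(active) + 1L
    if (is.numeric(catalyst)) catalyst <- as.integer(catalyst) + 1L
  }
  at <- atomTable(symbols, active = active, catalyst = catalyst)
  chemState(at, ac, charge = charge)
}

#' Load reactant/product structures
#'
#' Accepts a SMILES string, an SDF/MOL file (multi-record files are
#' concatenated block-diagonally into one state) or an XYZ file with
#' covalent-radius bond perception. Hydrogens are made explicit.
#'
#' @param input SMILES string or file path.
#' @param active,catalyst atom indices into the concatenated atom order.
#' @param zeroBased treat integer indices as 0-based (the config-file
#'   convention).
#' @param charge system charge override (for XYZ, where it cannot be
#'   perceived).
#' @return a \code{ChemState}.
#' @export
loadStructures <- function(input, active = integer(0),
                           catalyst = integer(0), zeroBased = FALSE,
                           charge = NULL) {
  if (file.exists(input)) {
    ext <- tolower(tools::file_ext(input))
    if (ext == "xyz")
      return(readXYZ(input, charge = if (is.null(charge)) 0L else charge,
                     active = active, catalyst = catalyst,
                     zeroBased = zeroBased))
    if (ext %in% c("sdf", "mol")) {
      recs <- .parseSDFText(readLines(input))
      if (!length(recs)) stop("no parsable record in ", input)
      st <- .recsToState(recs, active, catalyst, zeroBased)
      if (!is.null(charge)) st@charge <- as.integer(charge)
      return(st)
    }
    stop("unsupported structure file type: ", input)
  }
  st <- parseSmiles(input, active = active, catalyst = catalyst,
                    zeroBased = zeroBased)
  if (!is.null(charge)) st@charge <- as.integer(charge)
  st
}
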