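## Independent brute-force oracles used across the suite. These deliberately
## re-derive results from first principles (exhaustive enumeration) so they
## share no code path with the implementation they check.

## All conversion matrices by brute force: enumerate every symmetric 0/1
## target matrix A' over the basis (2^(n(n-1)/2) of them) and keep
## C = A' - I when it satisfies the bond-change rules, the caps, and
## (optionally) the molecularity constraint. Independent of the
## implementation's combination generator.
oracleConversions <- function(I, R, maxForm = 2L, maxBreak = 2L,
                              molecularity = NULL, components = NULL) {
  n <- nrow(I)
  pairs <- which(upper.tri(I), arr.ind = TRUE)
  np <- nrow(pairs)
  iv <- I[upper.tri(I)]
  rv <- R[upper.tri(R)]
  ## all 2^np symmetric 0/1 targets, vectorized rule filtering
  TM <- as.matrix(expand.grid(rep(list(0:1), np)))
  CV <- sweep(TM, 2, iv)
  formBad <- sweep(CV == 1, 2, !(iv == 0L & rv == 0L), `&`)
  breakBad <- sweep(CV == -1, 2, !(iv == 1L & rv == 1L), `&`)
  ok <- rowSums(CV != 0) > 0 &
    rowSums(formBad) == 0 & rowSums(breakBad) == 0 &
    rowSums(CV == 1) <= maxForm & rowSums(CV == -1) <= maxBreak
  keep <- list()
  for (r in which(ok)) {
    cv <- CV[r, ]
    if (!is.null(molecularity)) {
      comp <- if (is.null(components)) oracleComponents(I) else components
      touched <- unique(as.vector(pairs[cv != 0L, , drop = FALSE]))
      if (length(unique(comp[touched])) > molecularity) next
    }
    C <- matrix(0L, n, n)
    C[pairs] <- cv
    C <- C + t(C)
    keep[[length(keep) + 1L]] <- C
  }
  keep
}

## connected components by naive transitive closure
oracleComponents <- function(A) {
  n <- nrow(A)
  reach <- (A > 0) | diag(n) > 0
  for (k in seq_len(n)) reach <- reach | (reach %*% (A > 0)) > 0
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ] | reach[, i]] <- cid
    }
  }
  comp
}

## exhaustive-permutation chemical distance (no branch and bound)
oraclePermCD <- function(A, B, symbols) {
  classes <- split(seq_along(symbols), symbols)
  permute <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(permute(v[-i]), function(p) c(v[i], p))))
  }
  classPerms <- lapply(classes, permute)
  maps <- list(integer(length(symbols)))
  for (e in names(classes)) {
    idx <- classes[[e]]
    maps <- do.call(c, lapply(maps, function(m)
      lapply(classPerms[[e]], function(p) { m[idx] <- p; m })))
  }
  min(vapply(maps, function(s) sum(abs(A - B[s, s])) / 2, numeric(1)))
}

## exhaustive simple-path enumeration on a small weighted graph given as an
## edge data.frame (from/to as vertex names, weight)
oracleSimplePaths <- function(edges, from, to) {
  nbrs <- function(v) {
    i <- which(edges$from == v | edges$to == v)
    data.frame(v = ifelse(edges$from[i] == v, edges$to[i], edges$from[i]),
               w = edges$weight[i], stringsAsFactors = FALSE)
  }
  out <- list()
  recurse <- function(path, len) {
    v <- path[length(path)]
    if (v == to) {
      out[[length(out) + 1L]] <<- list(path = path, length = len)
      return()
    }
    nb <- nbrs(v)
    for (r in seq_len(nrow(nb))) {
      if (nb$v[r] %in% path) next
      recurse(c(path, nb$v[r]), len + nb$w[r])
    }
  }
  recurse(from, 0)
  out
}

## random connected weighted graph as a ReactionNetwork over dummy states
randomTestNetwork <- function(nv, p = 0.4, maxw = 4L) {
  keys <- sprintf("v%02d", seq_len(nv))
  repeat {
    e <- which(upper.tri(matrix(0, nv, nv)), arr.ind = TRUE)
    pick <- runif(nrow(e)) < p
    e <- e[pick, , drop = FALSE]
    if (nrow(e) == 0) next
    edges <- data.frame(from = keys[e[, 1]], to = keys[e[, 2]],
                        weight = sample.int(maxw, nrow(e), replace = TRUE),
                        formed = 1L, broken = 0L, catalyst = FALSE,
                        stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges[, 1:3], directed = FALSE,
                                       vertices = data.frame(name = keys))
    if (igraph::is_connected(g)) break
  }
  at <- atomTable("H")
  states <- lapply(keys, function(k) {
    st <- chemState(at, NULL)
    st@key <- k
    st
  })
  names(states) <- keys
  new("ReactionNetwork", states = states, edges = edges,
      reactant = keys[1], product = keys[nv])
}
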