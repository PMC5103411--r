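## Constructors, accessors and invariant checks for the core domain types.

#' Construct a WeightedNetwork
#'
#' Builds a symmetric weighted graph from a (possibly dense) adjacency
#' matrix. Nodes are put in lexicographic order, the canonical order used by
#' every vector and matrix in the package.
#'
#' @param adjacency square numeric matrix (dense or sparse) of edge weights;
#'   rownames/colnames are used as node identifiers unless `nodes` is given.
#' @param nodes optional character vector of node identifiers.
#' @param check if `TRUE` (default) scientific invariants (symmetry,
#'   non-negativity, empty diagonal) are enforced; with `FALSE` only the
#'   structural shape is checked, which permits building deliberately
#'   malformed objects for diagnostic reporting.
#' @return a [WeightedNetwork-class] object.
#' @examples
#' a <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("g1", "g2"), c("g1", "g2")))
#' weightedNetwork(a)
#' @export
weightedNetwork <- function(adjacency, nodes = NULL, check = TRUE) {
  if (is.null(nodes)) nodes <- rownames(adjacency)
  if (is.null(nodes)) stop("node identifiers are required (rownames or 'nodes')")
  nodes <- as.character(nodes)
  adjacency <- as(as(as(Matrix(adjacency, sparse = TRUE), "dMatrix"),
                     "generalMatrix"), "CsparseMatrix")
  dimnames(adjacency) <- list(nodes, nodes)
  ord <- order(nodes)
  net <- new("WeightedNetwork", nodes = nodes[ord],
             adjacency = adjacency[ord, ord, drop = FALSE])
  if (check) {
    bad <- validateNetwork(net)
    if (length(bad)) stop("invalid network: ", paste(bad, collapse = "; "))
  }
  net
}

#' Construct a WeightedNetwork from an edge table
#'
#' Edges are stored once per unordered pair; if a pair appears more than
#' once with different weights the maximum is kept (with a warning), which
#' tolerates real-world edge lists recorded in both directions. Self-loops
#' are dropped with a warning.
#'
#' @param edges data.frame with columns `from`, `to` and optionally
#'   `weight` (default 1).
#' @param nodes optional node universe; defaults to the identifiers present
#'   in `edges`. Isolated nodes can be included by listing them here.
#' @return a [WeightedNetwork-class] object.
#' @export
networkFromEdges <- function(edges, nodes = NULL) {
  stopifnot(ncol(edges) >= 2)
  from <- as.character(edges[[1]]); to <- as.character(edges[[2]])
  w <- if (ncol(edges) >= 3) as.numeric(edges[[3]]) else rep(1, length(from))
  loop <- from == to
  if (any(loop)) {
    warning(sum(loop), " self-loop(s) dropped")
    from <- from[!loop]; to <- to[!loop]; w <- w[!loop]
  }
  if (is.null(nodes)) nodes <- sort(unique(c(from, to)))
  nodes <- sort(unique(as.character(nodes)))
  i <- match(from, nodes); j <- match(to, nodes)
  if (anyNA(i) || anyNA(j)) stop("edge endpoint outside the node universe")
  key <- paste(pmin(i, j), pmax(i, j))
  if (anyDuplicated(key)) {
    agg <- tapply(w, key, max)
    if (any(abs(tapply(w, key, max) - tapply(w, key, min)) > 0))
      warning("duplicate edges with differing weights symmetrized by max")
    key <- names(agg); w <- as.numeric(agg)
    ij <- do.call(rbind, strsplit(key, " "))
    i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
  }
  n <- length(nodes)
  adj <- sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w), dims = c(n, n),
                      dimnames = list(nodes, nodes))
  weightedNetwork(adj, nodes)
}

#' Check the scientific invariants of a network
#'
#' @param net a [WeightedNetwork-class].
#' @param label prefix used in the violation messages.
#' @return character vector of violations; empty when all invariants hold.
#' @export
validateNetwork <- function(net, label = "network") {
  msg <- character()
  a <- net@adjacency
  if (length(a@x) && min(a@x) < 0) {
    bad <- which(as.matrix(a) < 0, arr.ind = TRUE)
    bad <- bad[bad[, 1] <= bad[, 2], , drop = FALSE]
    for (r in seq_len(min(nrow(bad), 5L)))
      msg <- c(msg, sprintf("%s: negative weight on edge %s--%s", label,
                            net@nodes[bad[r, 1]], net@nodes[bad[r, 2]]))
  }
  if (max(abs(a - Matrix::t(a))) > 1e-12)
    msg <- c(msg, sprintf("%s: adjacency is not symmetric", label))
  d <- Matrix::diag(a)
  if (any(d != 0))
    msg <- c(msg, sprintf("%s: self-loop on node(s) %s", label,
                          paste(net@nodes[d != 0], collapse = ", ")))
  msg
}

#' @describeIn weightedNetwork node identifiers in canonical order
#' @param x a WeightedNetwork
#' @export
setMethod("nodeIds", "WeightedNetwork", function(x) x@nodes)

#' @export
setMethod("adjacency", "WeightedNetwork", function(x) x@adjacency)

#' @export
setMethod("numNodes", "WeightedNetwork", function(x) length(x@nodes))

setMethod("show", "WeightedNetwork", function(object) {
  m <- sum(object@adjacency != 0) / 2
  cat(sprintf("WeightedNetwork: %d nodes, %d edges\n",
              length(object@nodes), m))
})

## ---- hyperparameters --------------------------------------------------

#' Create a HyperParams object
#'
#' Defaults follow the standard settings for this family of propagation
#' methods: `c = 0.85` (as in personalized PageRank), `beta = 0.5` for the
#' cross-disease term, `alpha = 0.3` for the scalar center-auxiliary term,
#' and `gamma = 1` for the l2 penalty of the learned auxiliary weights.
#'
#' @param c smoothness/seed trade-off in (0,1).
#' @param beta cross-disease consistency weight, >= 0.
#' @param alpha center-auxiliary consistency weight (scalar star model), >= 0.
#' @param gamma l2 regularization of learned auxiliary weights, > 0.
#' @param tol,maxIter stopping rule of the fixed-point score solvers.
#' @param outerTol,outerMaxIter stopping rule of the alternating solver.
#' @return a [HyperParams-class] object.
#' @export
hyperParams <- function(c = 0.85, beta = 0.5, alpha = 0.3, gamma = 1,
                        tol = 1e-9, maxIter = 1000L,
                        outerTol = 1e-7, outerMaxIter = 200L) {
  new("HyperParams", c = c, beta = beta, alpha = alpha, gamma = gamma,
      tol = tol, maxIter = as.integer(maxIter), outerTol = outerTol,
      outerMaxIter = as.integer(outerMaxIter))
}

setMethod("show", "HyperParams", function(object) {
  cat(sprintf(
    "HyperParams: c=%g beta=%g alpha=%g gamma=%g tol=%g maxIter=%d\n",
    object@c, object@beta, object@alpha, object@gamma, object@tol,
    object@maxIter))
})

## ---- seed vectors and overlaps ----------------------------------------

#' Build a seed vector over the genes of a network
#'
#' Known disease genes present in the network each receive mass `1/s`,
#' where `s` counts the associated genes present in the network; genes
#' absent from the network are dropped with a warning. With no effective
#' seed genes the vector is identically zero (the convention for diseases
#' without known disease genes).
#'
#' @param genes character vector of associated gene identifiers.
#' @param net the [WeightedNetwork-class] the vector indexes.
#' @return named numeric vector aligned with `nodeIds(net)`, summing to 0
#'   or 1.
#' @export
buildSeedVector <- function(genes, net) {
  nodes <- nodeIds(net)
  genes <- unique(as.character(genes))
  present <- intersect(genes, nodes)
  if (length(present) < length(genes))
    warning(length(genes) - length(present),
            " associated gene(s) absent from the network were dropped")
  e <- stats::setNames(numeric(length(nodes)), nodes)
  if (length(present)) e[present] <- 1 / length(present)
  e
}

#' Gene overlap between two networks
#'
#' Partitions the two node sets into the shared genes and the genes unique
#' to each network; all three components are returned sorted.
#'
#' @param netA,netB [WeightedNetwork-class] objects over a common gene
#'   identifier namespace.
#' @return list with components `common`, `onlyLeft`, `onlyRight`.
#' @export
computeOverlaps <- function(netA, netB) {
  a <- nodeIds(netA); b <- nodeIds(netB)
  list(common = sort(intersect(a, b)),
       onlyLeft = sort(setdiff(a, b)),
       onlyRight = sort(setdiff(b, a)))
}

## ---- NoN / NoSN -------------------------------------------------------

.seedsFromAssoc <- function(associations, networks) {
  if (is.null(associations))
    associations <- data.frame(disease = character(), gene = character())
  lapply(stats::setNames(nm = names(networks)), function(d) {
    g <- associations[[2]][associations[[1]] == d]
    suppressWarnings(buildSeedVector(g, networks[[d]]))
  })
}

#' Construct a network of networks (NoN)
#'
#' @param diseaseNet [WeightedNetwork-class] over disease identifiers
#'   (typically a k-nearest-neighbor similarity graph).
#' @param networks named list of molecular [WeightedNetwork-class], one per
#'   disease.
#' @param associations optional two-column data.frame (disease, gene) of
#'   known disease-gene associations from which seed vectors are built;
#'   omitted associations yield all-zero seeds.
#' @return a [NoN-class] object.
#' @export
NoN <- function(diseaseNet, networks, associations = NULL) {
  networks <- networks[order(names(networks))]
  new("NoN", diseaseNet = diseaseNet, networks = networks,
      seeds = .seedsFromAssoc(associations, networks))
}

#' Construct a network of star networks (NoSN)
#'
#' @param diseaseNet [WeightedNetwork-class] over disease identifiers.
#' @param centers named list of center molecular networks, one per disease.
#' @param auxiliaries named list whose element i is a list (possibly empty)
#'   of auxiliary networks for disease i; missing diseases get no
#'   auxiliaries.
#' @param associations optional two-column data.frame (disease, gene); seed
#'   vectors are built per center and per auxiliary network.
#' @return a [NoSN-class] object.
#' @export
NoSN <- function(diseaseNet, centers, auxiliaries = list(),
                 associations = NULL) {
  centers <- centers[order(names(centers))]
  ids <- names(centers)
  aux <- lapply(stats::setNames(nm = ids), function(d) {
    a <- auxiliaries[[d]]
    if (is.null(a)) list() else a
  })
  centerSeeds <- .seedsFromAssoc(associations, centers)
  auxSeeds <- lapply(stats::setNames(nm = ids), function(d) {
    lapply(aux[[d]], function(net) {
      g <- if (is.null(associations)) character()
           else associations[[2]][associations[[1]] == d]
      suppressWarnings(buildSeedVector(g, net))
    })
  })
  new("NoSN", diseaseNet = diseaseNet, centers = centers, auxiliaries = aux,
      centerSeeds = centerSeeds, auxSeeds = auxSeeds)
}

#' @export
setMethod("diseaseNetwork", "NoN", function(x) x@diseaseNet)
#' @export
setMethod("diseaseNetwork", "NoSN", function(x) x@diseaseNet)

#' @export
setMethod("diseaseDegrees", "WeightedNetwork", function(x)
  stats::setNames(as.numeric(Matrix::rowSums(x@adjacency)), x@nodes))
#' @export
setMethod("diseaseDegrees", "NoN", function(x) diseaseDegrees(x@diseaseNet))
#' @export
setMethod("diseaseDegrees", "NoSN", function(x) diseaseDegrees(x@diseaseNet))

#' @export
setMethod("molecularNetworks", "NoN", function(x) x@networks)
#' @export
setMethod("centerNetworks", "NoSN", function(x) x@centers)
#' @export
setMethod("auxNetworks", "NoSN", function(x, disease) x@auxiliaries[[disease]])
#' @export
setMethod("seedVectors", "NoN", function(x) x@seeds)
#' @export
setMethod("seedVectors", "NoSN", function(x)
  list(center = x@centerSeeds, aux = x@auxSeeds))

#' @export
setMethod("numAuxiliaries", "NoSN", function(x)
  vapply(x@auxiliaries, length, integer(1)))

setMethod("show", "NoN", function(object) {
  cat(sprintf("NoN: %d diseases, %d molecular networks\n",
              numNodes(object@diseaseNet), length(object@networks)))
})

setMethod("show", "NoSN", function(object) {
  cat(sprintf("NoSN: %d diseases, auxiliaries per disease: %s\n",
              numNodes(object@diseaseNet),
              paste(range(numAuxiliaries(object)), collapse = "-")))
})

.validateSeed <- function(e, net, label) {
  msg <- character()
  if (!identical(names(e), nodeIds(net))) {
    msg <- c(msg, sprintf("%s: seed vector misaligned with network nodes", label))
    return(msg)
  }
  s <- sum(e != 0)
  if (s > 0 && (any(e[e != 0] != 1 / s) || abs(sum(e) - 1) > 1e-12))
    msg <- c(msg, sprintf("%s: seed vector is not uniform 1/s mass", label))
  if (any(e < 0))
    msg <- c(msg, sprintf("%s: negative seed weight", label))
  msg
}

#' Diagnostic validation of a NoN or NoSN
#'
#' Checks every scientific invariant of the model (symmetry and
#' non-negativity of all adjacencies, absence of self-loops, seed vectors
#' aligned with their networks and carrying uniform 1/s mass) and reports
#' the violations instead of raising an error.
#'
#' @param x a [NoN-class] or [NoSN-class] object.
#' @return character vector of human-readable violations; empty if and only
#'   if all invariants hold.
#' @export
setMethod("validateNoN", "NoN", function(x) {
  msg <- validateNetwork(x@diseaseNet, "disease network")
  for (d in names(x@networks)) {
    msg <- c(msg, validateNetwork(x@networks[[d]], sprintf("network '%s'", d)))
    msg <- c(msg, .validateSeed(x@seeds[[d]], x@networks[[d]],
                                sprintf("disease '%s'", d)))
  }
  msg
})

#' @rdname validateNoN-NoN-method
#' @export
setMethod("validateNoN", "NoSN", function(x) {
  msg <- validateNetwork(x@diseaseNet, "disease network")
  for (d in names(x@centers)) {
    msg <- c(msg, validateNetwork(x@centers[[d]], sprintf("center '%s'", d)))
    msg <- c(msg, .validateSeed(x@centerSeeds[[d]], x@centers[[d]],
                                sprintf("center '%s'", d)))
    auxs <- x@auxiliaries[[d]]
    for (p in seq_along(auxs)) {
      lab <- sprintf("aux %d of '%s'", p, d)
      msg <- c(msg, validateNetwork(auxs[[p]], lab))
      msg <- c(msg, .validateSeed(x@auxSeeds[[d]][[p]], auxs[[p]], lab))
    }
  }
  msg
})

#' Replace the seed vectors of a bundle from an association table
#'
#' Rebuilds every seed vector from the given associations; used by the
#' evaluation protocols, which repeatedly mask associations.
#'
#' @param x a [NoN-class] or [NoSN-class].
#' @param associations two-column data.frame (disease, gene).
#' @return the updated object.
#' @export
setMethod("setSeeds", "NoN", function(x, associations) {
  x@seeds <- .seedsFromAssoc(associations, x@networks)
  x
})

#' @rdname setSeeds-NoN-method
#' @export
setMethod("setSeeds", "NoSN", function(x, associations) {
  x@centerSeeds <- .seedsFromAssoc(associations, x@centers)
  x@auxSeeds <- lapply(stats::setNames(nm = names(x@centers)), function(d) {
    g <- associations[[2]][associations[[1]] == d]
    lapply(x@auxiliaries[[d]], function(net)
      suppressWarnings(buildSeedVector(g, net)))
  })
  x
})

## ---- ScoreSet ---------------------------------------------------------

.scoreSet <- function(scores, keys) new("ScoreSet", scores = scores, keys = keys)

#' @export
setMethod("scoreVectors", "ScoreSet", function(x) x@scores)

#' @describeIn ScoreSet-class stacked score vector in the canonical
#'   concatenation order (diseases ascending; center before auxiliaries).
#' @param x a ScoreSet
#' @export
setMethod("concatScores", "ScoreSet", function(x)
  unlist(x@scores[x@keys], use.names = FALSE))

setMethod("show", "ScoreSet", function(object) {
  cat(sprintf("ScoreSet: %d networks, %d total scores\n",
              length(object@scores),
              sum(lengths(object@scores))))
})

#' Auxiliary-network score keys
#'
#' Score vectors of auxiliary networks are keyed `"<disease>#aux<p>"`;
#' this helper builds such keys.
#'
#' @param disease disease identifier.
#' @param p auxiliary index (1-based).
#' @export
auxKey <- function(disease, p) sprintf("%s#aux%d", disease, p)
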