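#' @import methods
#' @importFrom Matrix Matrix sparseMatrix rowSums colSums diag t crossprod
NULL

#' WeightedNetwork: a symmetric non-negative weighted graph
#'
#' The basic container for all networks handled by the package: the disease
#' similarity network, per-disease tissue-specific molecular networks, and
#' center/auxiliary networks of a star model. Nodes are string identifiers
#' kept in lexicographic order; the adjacency matrix is sparse, symmetric,
#' non-negative and has an empty diagonal (no self-loops).
#'
#' Structural validity (dimension/name agreement) is enforced on
#' construction; the scientific invariants (symmetry, non-negativity, empty
#' diagonal) are checked by [validateNetwork()] so that diagnostic reports
#' can be produced for malformed inputs.
#'
#' @slot nodes character vector of unique node identifiers, sorted.
#' @slot adjacency sparse numeric matrix of edge weights, nodes x nodes.
#' @export
setClass("WeightedNetwork",
  representation(nodes = "character", adjacency = "Matrix"))

setValidity("WeightedNetwork", function(object) {
  msg <- character()
  n <- length(object@nodes)
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "node identifiers must be unique")
  if (is.unsorted(object@nodes))
    msg <- c(msg, "node identifiers must be sorted (canonical node order)")
  if (!all(dim(object@adjacency) == c(n, n)))
    msg <- c(msg, "adjacency dimensions must match the node count")
  if (length(msg)) msg else TRUE
})

#' Hyperparameters of the ranking objectives
#'
#' @slot c numeric in (0,1); trade-off between within-network smoothness and
#'   seed preference. Default 0.85, the typical restart setting of label
#'   propagation / personalized PageRank methods.
#' @slot beta numeric >= 0; weight of the cross-disease consistency term.
#' @slot alpha numeric >= 0; weight of the center-auxiliary consistency term
#'   (scalar variant of the star model).
#' @slot gamma numeric > 0; l2 regularization on the learned auxiliary
#'   weights of the weighted star model.
#' @slot tol convergence tolerance of the fixed-point score solvers
#'   (relative L-infinity change between iterates).
#' @slot maxIter iteration cap of the fixed-point solvers.
#' @slot outerTol relative objective-change tolerance of the alternating
#'   (weighted star) solver.
#' @slot outerMaxIter outer-iteration cap of the alternating solver.
#' @export
setClass("HyperParams",
  representation(c = "numeric", beta = "numeric", alpha = "numeric",
                 gamma = "numeric", tol = "numeric", maxIter = "integer",
                 outerTol = "numeric", outerMaxIter = "integer"))

setValidity("HyperParams", function(object) {
  msg <- character()
  if (length(object@c) != 1 || object@c <= 0 || object@c >= 1)
    msg <- c(msg, "c must be a single value in (0, 1)")
  if (object@beta < 0) msg <- c(msg, "beta must be >= 0")
  if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
  if (object@gamma <= 0) msg <- c(msg, "gamma must be > 0")
  if (object@tol <= 0) msg <- c(msg, "tol must be > 0")
  if (object@maxIter < 1L) msg <- c(msg, "maxIter must be >= 1")
  if (object@outerTol <= 0) msg <- c(msg, "outerTol must be > 0")
  if (object@outerMaxIter < 1L) msg <- c(msg, "outerMaxIter must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Network of networks (NoN)
#'
#' A disease similarity network in which every disease carries its own
#' tissue-specific molecular network and a seed vector of known disease
#' genes. Gene identifiers live in one global namespace, so gene overlaps
#' between molecular networks are defined by identifier equality.
#'
#' @slot diseaseNet [WeightedNetwork-class] over disease identifiers.
#' @slot networks named list of [WeightedNetwork-class], one per disease.
#' @slot seeds named list of numeric seed vectors, aligned with the node
#'   order of the corresponding molecular network; each is either all zero
#'   (no known disease gene) or puts mass 1/s on each of s seed genes.
#' @export
setClass("NoN",
  representation(diseaseNet = "WeightedNetwork", networks = "list",
                 seeds = "list"))

setValidity("NoN", function(object) {
  msg <- character()
  ids <- object@diseaseNet@nodes
  if (!identical(sort(names(object@networks)), ids))
    msg <- c(msg, "molecular networks must be named by the disease identifiers")
  if (!identical(sort(names(object@seeds)), ids))
    msg <- c(msg, "seed vectors must be named by the disease identifiers")
  for (d in names(object@networks)) {
    net <- object@networks[[d]]
    if (!is(net, "WeightedNetwork")) {
      msg <- c(msg, sprintf("entry '%s' is not a WeightedNetwork", d))
      next
    }
    e <- object@seeds[[d]]
    if (!is.null(e) && length(e) != length(net@nodes))
      msg <- c(msg, sprintf("seed vector of '%s' has wrong length", d))
  }
  if (length(msg)) msg else TRUE
})

#' Network of star networks (NoSN)
#'
#' Extends the NoN model: every disease carries a center molecular network
#' (its most reliable tissue-specific network) plus zero or more auxiliary
#' molecular networks, each with its own seed vector. An NoSN in which every
#' disease has zero auxiliaries is structurally a NoN.
#'
#' @slot diseaseNet [WeightedNetwork-class] over disease identifiers.
#' @slot centers named list of center [WeightedNetwork-class] per disease.
#' @slot auxiliaries named list; element i is a (possibly empty) list of
#'   auxiliary [WeightedNetwork-class] for disease i.
#' @slot centerSeeds named list of numeric seed vectors for the centers.
#' @slot auxSeeds named list of lists of numeric seed vectors, parallel to
#'   `auxiliaries`.
#' @export
setClass("NoSN",
  representation(diseaseNet = "WeightedNetwork", centers = "list",
                 auxiliaries = "list", centerSeeds = "list",
                 auxSeeds = "list"))

setValidity("NoSN", function(object) {
  msg <- character()
  ids <- object@diseaseNet@nodes
  for (nm in c("centers", "auxiliaries", "centerSeeds", "auxSeeds"))
    if (!identical(sort(names(slot(object, nm))), ids))
      msg <- c(msg, sprintf("'%s' must be named by the disease identifiers", nm))
  for (d in ids) {
    k <- length(object@auxiliaries[[d]])
    if (length(object@auxSeeds[[d]]) != k)
      msg <- c(msg, sprintf("auxSeeds of '%s' must have one entry per auxiliary", d))
  }
  if (length(msg)) msg else TRUE
})

#' Per-network ranking score vectors
#'
#' Holds one named numeric score vector per molecular network, keyed by the
#' same identifiers as the networks they score, plus the fixed concatenation
#' order used by the solvers: diseases in ascending identifier order and,
#' for a star model, the center first followed by the auxiliaries in their
#' stored order. Auxiliary keys have the form `"<disease>#aux<p>"`.
#'
#' @slot scores named list of numeric vectors (names = gene identifiers).
#' @slot keys character vector giving the concatenation order of `scores`.
#' @export
setClass("ScoreSet",
  representation(scores = "list", keys = "character"))

setValidity("ScoreSet", function(object) {
  msg <- character()
  if (!identical(sort(object@keys), sort(names(object@scores))))
    msg <- c(msg, "keys must be a permutation of the score names")
  if (length(msg)) msg else TRUE
})
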