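## Construction of the networks consumed by the ranking algorithms:
## symmetric normalization, kNN sparsification, WGCNA-style co-expression
## similarity, and assignment of tissue networks to diseases.

#' Symmetrically normalized adjacency matrix
#'
#' Returns `D^{-1/2} G D^{-1/2}` where `D` is the diagonal matrix of row
#' sums of `G`. Rows and columns of isolated nodes (zero degree) are left
#' all zero (the 0/0 convention), so the result is always symmetric with
#' spectral radius at most 1.
#'
#' @param net a [WeightedNetwork-class] or a symmetric non-negative matrix.
#' @return sparse symmetric matrix of the same dimension.
#' @export
symmetricNormalize <- function(net) {
  a <- if (is(net, "WeightedNetwork")) adjacency(net) else
    as(Matrix(net, sparse = TRUE), "CsparseMatrix")
  d <- Matrix::rowSums(a)
  inv <- ifelse(d > 0, 1 / sqrt(d), 0)
  out <- Matrix::Diagonal(x = inv) %*% a %*% Matrix::Diagonal(x = inv)
  dimnames(out) <- dimnames(a)
  out
}

#' k-nearest-neighbor sparsification of a similarity matrix
#'
#' Keeps the edge (x, y) iff y is among x's k most similar neighbors or x is
#' among y's (union symmetrization); retained edges keep their similarity as
#' weight. A node is never its own neighbor and only strictly positive
#' similarities can become edges. Ties in neighbor selection are broken by
#' ascending node identifier, making the construction deterministic.
#'
#' @param similarity dense symmetric matrix of pairwise similarities with
#'   node identifiers as dimnames (or supplied via `nodes`).
#' @param k number of neighbors per node, >= 1. `k >= n-1` yields the
#'   complete graph on positive similarities.
#' @param nodes optional node identifiers.
#' @return a [WeightedNetwork-class].
#' @export
knnSparsify <- function(similarity, k, nodes = NULL) {
  stopifnot(k >= 1)
  similarity <- as.matrix(similarity)
  if (is.null(nodes)) nodes <- rownames(similarity)
  if (is.null(nodes)) stop("node identifiers required")
  nodes <- as.character(nodes)
  n <- length(nodes)
  ord <- order(nodes)
  similarity <- similarity[ord, ord, drop = FALSE]
  nodes <- nodes[ord]
  if (max(abs(similarity - t(similarity))) > 1e-8)
    stop("similarity matrix must be symmetric")
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    s <- similarity[i, ]
    s[i] <- -Inf
    cand <- order(-s, seq_len(n))        # desc similarity, ties by node order
    cand <- cand[s[cand] > 0]
    top <- utils::head(cand, k)
    keep[i, top] <- TRUE
  }
  keep <- keep | t(keep)                 # union symmetrization
  adj <- similarity * keep
  diag(adj) <- 0
  dimnames(adj) <- list(nodes, nodes)
  weightedNetwork(adj, nodes)
}

#' WGCNA soft-threshold similarity
#'
#' Maps a Pearson correlation to the co-expression similarity
#' `(0.5 + 0.5 * cor)^kappa`, a monotone transform onto \[0, 1\]; the power
#' `kappa` (default 12, the typical soft-thresholding setting) suppresses
#' weak correlations.
#'
#' @param cor correlation value(s) in \[-1, 1\].
#' @param kappa soft-threshold power, >= 1.
#' @return similarity value(s) in \[0, 1\].
#' @examples
#' wgcnaNormalize(0, 12)  # 0.5^12
#' @export
wgcnaNormalize <- function(cor, kappa = 12) {
  stopifnot(kappa >= 1)
  if (any(cor < -1 - 1e-12 | cor > 1 + 1e-12, na.rm = TRUE))
    stop("correlation outside [-1, 1]")
  out <- (0.5 + 0.5 * pmin(1, pmax(-1, cor)))^kappa
  attributes(out) <- attributes(cor)   # keep matrix shape and dimnames
  out
}

#' Co-expression network construction parameters
#'
#' @param kappa soft-threshold power of [wgcnaNormalize()].
#' @param knnK neighbor count of the final kNN sparsification.
#' @param exprThreshold minimum mean expression (in platform units) for a
#'   gene to count as expressed in the tissue; genes below it are removed.
#' @return list of parameters for [buildGCN()].
#' @export
coexpressionParams <- function(kappa = 12, knnK = 5, exprThreshold = -Inf) {
  stopifnot(kappa >= 1, knnK >= 1)
  list(kappa = kappa, knnK = knnK, exprThreshold = exprThreshold)
}

#' Build a tissue-specific gene co-expression network
#'
#' Pipeline: drop genes whose mean expression across the tissue's samples is
#' below `exprThreshold` (lowly expressed genes are not tissue-specific);
#' drop genes with zero expression variance (Pearson correlation undefined);
#' compute all pairwise Pearson correlations; map them to similarities with
#' [wgcnaNormalize()]; sparsify with [knnSparsify()].
#'
#' @param expr numeric matrix, genes x samples, with gene identifiers as
#'   rownames; at least 2 samples.
#' @param params result of [coexpressionParams()].
#' @return a [WeightedNetwork-class].
#' @export
buildGCN <- function(expr, params = coexpressionParams()) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2)
  if (anyDuplicated(rownames(expr))) stop("duplicate gene identifiers")
  keep <- rowMeans(expr) >= params$exprThreshold
  expr <- expr[keep, , drop = FALSE]
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant-expression gene(s) dropped")
    expr <- expr[v > 0, , drop = FALSE]
  }
  if (nrow(expr) < 2)
    stop("fewer than 2 genes survive filtering; cannot build a network")
  cc <- stats::cor(t(expr))
  sim <- wgcnaNormalize(cc, params$kappa)
  diag(sim) <- 0
  knnSparsify(sim, params$knnK, nodes = rownames(expr))
}

#' Assign tissue-specific networks to diseases
#'
#' A disease is assigned the network of its most relevant tissue (the
#' argmax of its disease-tissue association probabilities), but only when
#' that probability exceeds the threshold (default 0.4, so that the retained
#' diseases show strong tissue specificity) and a network exists for the
#' tissue. There is no fallback to the second-most-relevant tissue; diseases
#' failing either condition are left unassigned.
#'
#' @param dtm numeric matrix of disease-tissue association probabilities,
#'   diseases x tissues, with identifiers as dimnames.
#' @param tissueNets named list of [WeightedNetwork-class] keyed by tissue.
#' @param threshold assignment probability cutoff (strictly exceeded).
#' @return named list of networks for the assigned diseases (partial map).
#' @export
assignTissueNetworks <- function(dtm, tissueNets, threshold = 0.4) {
  stopifnot(is.matrix(dtm), !is.null(rownames(dtm)), !is.null(colnames(dtm)))
  if (any(dtm < 0 | dtm > 1)) stop("association probabilities must be in [0, 1]")
  out <- list()
  tissues <- colnames(dtm)
  for (d in rownames(dtm)) {
    p <- dtm[d, ]
    best <- tissues[order(-p, tissues)][1]   # ties: lexicographically first
    if (p[best] > threshold && !is.null(tissueNets[[best]]))
      out[[d]] <- tissueNets[[best]]
  }
  out
}

#' Read a genes-x-samples expression matrix from TSV
#'
#' First column holds gene identifiers; the header row holds sample
#' identifiers.
#'
#' @param path TSV file path.
#' @return numeric matrix with gene rownames.
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers")
  m
}

#' Read a disease-tissue probability matrix from TSV
#'
#' First column holds disease identifiers; the header row holds tissue
#' identifiers; cells hold association probabilities in \[0, 1\].
#'
#' @param path TSV file path.
#' @return numeric matrix, diseases x tissues.
#' @export
readDiseaseTissueMap <- function(path) {
  m <- readExpressionMatrix(path)
  if (any(m < 0 | m > 1)) stop("probabilities must be in [0, 1]")
  m
}
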