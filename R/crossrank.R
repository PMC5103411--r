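## CrossRank: label propagation on a network of networks.
##
## The objective over the concatenated score vector r is the quadratic
##   J(r) = r' M r - 2 (1-c) e' r + (1-c) ||e||^2,
## with M = D - C, where D is a constant block diagonal (1 + 2*beta for
## diseases with neighbors, 1 otherwise) and C >= 0 collects c * Gtilde_i
## within each network plus the cross-disease couplings
## 2*beta*A(i,j)/sqrt(d_A(i) d_A(j)) on shared genes. Since M >= (1-c) I and
## C is symmetric non-negative, the Jacobi update r <- D^{-1} (C r + (1-c) e)
## is a convergent non-negative fixed-point iteration whose limit is the
## unique global minimizer.

.tsparse <- function(m) as(m, "TsparseMatrix")

## Assemble D, C, e and the index bookkeeping for the CrossRank system.
.assembleCR <- function(non, hp) {
  ids <- nodeIds(diseaseNetwork(non))
  nets <- molecularNetworks(non)
  sizes <- vapply(ids, function(d) numNodes(nets[[d]]), integer(1))
  offsets <- c(0L, cumsum(sizes))[seq_along(ids)]
  names(offsets) <- ids
  A <- adjacency(diseaseNetwork(non))
  dA <- Matrix::rowSums(A)
  N <- sum(sizes)
  beta <- hp@beta

  Dvec <- numeric(N)
  ti <- tj <- tx <- vector("list", 0L)
  for (d in ids) {
    o <- offsets[[d]]
    Dvec[o + seq_len(sizes[[d]])] <- 1 + 2 * beta * (dA[[d]] > 0)
    g <- .tsparse(symmetricNormalize(nets[[d]]))
    if (length(g@x)) {
      ti[[length(ti) + 1L]] <- o + g@i + 1L
      tj[[length(tj) + 1L]] <- o + g@j + 1L
      tx[[length(tx) + 1L]] <- hp@c * g@x
    }
  }
  At <- .tsparse(A)
  for (k in seq_along(At@x)) {
    i <- At@i[k] + 1L; j <- At@j[k] + 1L
    if (i >= j || At@x[k] == 0) next
    di <- ids[i]; dj <- ids[j]
    common <- intersect(nodeIds(nets[[di]]), nodeIds(nets[[dj]]))
    if (!length(common)) next
    coef <- 2 * beta * At@x[k] / sqrt(dA[[di]] * dA[[dj]])
    if (coef == 0) next
    ii <- offsets[[di]] + match(common, nodeIds(nets[[di]]))
    jj <- offsets[[dj]] + match(common, nodeIds(nets[[dj]]))
    ti[[length(ti) + 1L]] <- c(ii, jj)
    tj[[length(tj) + 1L]] <- c(jj, ii)
    tx[[length(tx) + 1L]] <- rep(coef, 2L * length(common))
  }
  C <- sparseMatrix(i = as.integer(unlist(ti)), j = as.integer(unlist(tj)),
                    x = as.numeric(unlist(tx)), dims = c(N, N))
  e <- unlist(lapply(ids, function(d) seedVectors(non)[[d]]),
              use.names = FALSE)
  list(keys = ids, sizes = sizes, offsets = offsets, D = Dvec, C = C, e = e,
       nodes = lapply(nets[ids], nodeIds), c = hp@c)
}

.splitScores <- function(r, asm) {
  scores <- lapply(seq_along(asm$keys), function(k) {
    o <- asm$offsets[[k]]
    stats::setNames(r[o + seq_len(asm$sizes[[k]])], asm$nodes[[k]])
  })
  names(scores) <- asm$keys
  .scoreSet(scores, asm$keys)
}

.quadObjective <- function(r, asm) {
  as.numeric(sum(r * (asm$D * r)) - sum(r * (asm$C %*% r)) -
             2 * (1 - asm$c) * sum(asm$e * r) + (1 - asm$c) * sum(asm$e^2))
}

## Shared fixed-point driver for the CR and star systems.
.fixedPoint <- function(asm, hp, init = asm$e) {
  b <- (1 - asm$c) * asm$e
  r <- init
  objs <- numeric(0)
  converged <- FALSE
  iter <- 0L
  relChange <- NA_real_
  while (iter < hp@maxIter) {
    iter <- iter + 1L
    rNew <- as.numeric(asm$C %*% r + b) / asm$D
    scale <- max(abs(rNew), .Machine$double.xmin)
    relChange <- max(abs(rNew - r)) / scale
    r <- rNew
    objs <- c(objs, .quadObjective(r, asm))
    if (relChange <= hp@tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fixed-point solver did not converge within ", hp@maxIter,
            " iterations (relative change ", signif(relChange, 3), ")")
  list(r = r, trace = list(iterations = iter, objective = objs,
                           relChange = relChange, converged = converged))
}

.directSolve <- function(asm, guard = 5000L) {
  N <- length(asm$D)
  if (N > guard)
    stop("direct solve refused: ", N, " variables exceeds the guard of ", guard)
  M <- Matrix::forceSymmetric(Matrix::Diagonal(x = asm$D) - asm$C)
  as.numeric(Matrix::solve(M, (1 - asm$c) * asm$e))
}

#' Construct a ScoreSet from a list of score vectors
#'
#' @param scores named list of named numeric vectors, one per network.
#' @param keys concatenation order; defaults to the list names (ascending
#'   disease order for a plain NoN).
#' @export
scoreSet <- function(scores, keys = names(scores)) .scoreSet(scores, keys)

.scoresAligned <- function(scores, key, nodes) {
  r <- scoreVectors(scores)[[key]]
  if (is.null(r)) stop("missing score vector for '", key, "'")
  if (length(r) != length(nodes))
    stop("score vector for '", key, "' has wrong length")
  if (!is.null(names(r))) r <- r[nodes]
  as.numeric(r)
}

## Theta_cross / Phi_cross between two score vectors over their networks:
## squared difference on shared genes (degree-normalized) plus the squared
## scores of the genes exclusive to either network.
.crossTerm <- function(aij, ri, rj, nodesI, nodesJ, di, dj) {
  common <- intersect(nodesI, nodesJ)
  si <- ri / sqrt(di); sj <- rj / sqrt(dj)
  mi <- match(common, nodesI); mj <- match(common, nodesJ)
  onlyI <- if (length(mi)) si[-mi] else si
  onlyJ <- if (length(mj)) sj[-mj] else sj
  shared <- if (length(mi)) sum((si[mi] - sj[mj])^2) else 0
  aij * (shared + sum(onlyI^2) + sum(onlyJ^2))
}

#' CrossRank objective value with per-term breakdown
#'
#' Evaluates the network-of-networks ranking objective: per-disease
#' within-network terms `c r' (I - Gtilde) r + (1-c) ||r - e||^2` plus the
#' cross-disease consistency terms over all ordered disease pairs (the
#' double sum counts each unordered pair twice, which is the convention all
#' reported `beta` values refer to).
#'
#' @param non a [NoN-class].
#' @param scores a [ScoreSet-class] with one vector per disease.
#' @param hp a [HyperParams-class].
#' @return list with components `within` (named numeric), `cross`
#'   (data.frame `i`, `j`, `value` over ordered pairs with positive disease
#'   similarity), `aux` (empty here), `reg` (0 here) and `total`.
#' @export
objectiveCR <- function(non, scores, hp = hyperParams()) {
  ids <- nodeIds(diseaseNetwork(non))
  nets <- molecularNetworks(non)
  seeds <- seedVectors(non)
  A <- adjacency(diseaseNetwork(non))
  dA <- Matrix::rowSums(A)
  within <- vapply(ids, function(d) {
    r <- .scoresAligned(scores, d, nodeIds(nets[[d]]))
    g <- symmetricNormalize(nets[[d]])
    hp@c * (sum(r^2) - sum(r * as.numeric(g %*% r))) +
      (1 - hp@c) * sum((r - seeds[[d]])^2)
  }, numeric(1))
  cross <- data.frame(i = character(), j = character(), value = numeric())
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i == j || A[i, j] == 0) next
    di <- ids[i]; dj <- ids[j]
    val <- .crossTerm(A[i, j],
                          .scoresAligned(scores, di, nodeIds(nets[[di]])),
                          .scoresAligned(scores, dj, nodeIds(nets[[dj]])),
                          nodeIds(nets[[di]]), nodeIds(nets[[dj]]),
                          dA[[di]], dA[[dj]])
    cross <- rbind(cross, data.frame(i = di, j = dj, value = val))
  }
  total <- sum(within) + hp@beta * sum(cross$value)
  structure(list(within = within, cross = cross,
                 aux = data.frame(disease = character(), p = integer(),
                                  value = numeric()),
                 reg = 0, total = total),
            class = "objectiveBreakdown")
}

#' @export
print.objectiveBreakdown <- function(x, ...) {
  cat(sprintf("objective total: %.6g (within %.6g, cross %.6g, aux %.6g, reg %.6g)\n",
              x$total, sum(x$within), sum(x$cross$value),
              sum(x$aux$value), x$reg))
  invisible(x)
}

#' Analytic gradient of the CrossRank objective
#'
#' Exact gradient of [objectiveCR()] with respect to the concatenated score
#' vector, returned in the same per-network shape as the scores.
#'
#' @inheritParams objectiveCR
#' @return a [ScoreSet-class] holding the per-network gradient vectors.
#' @export
gradientCR <- function(non, scores, hp = hyperParams()) {
  asm <- .assembleCR(non, hp)
  r <- unlist(lapply(asm$keys, function(d)
    .scoresAligned(scores, d, asm$nodes[[d]])), use.names = FALSE)
  g <- 2 * (asm$D * r - as.numeric(asm$C %*% r) - (1 - hp@c) * asm$e)
  .splitScores(g, asm)
}

#' Solve the CrossRank ranking problem
#'
#' Minimizes the network-of-networks objective by the convergent
#' non-negative fixed-point (Jacobi/power-style) iteration derived from its
#' stationarity conditions, starting from the concatenated seed vectors.
#' The objective is jointly convex, so the limit is the unique global
#' minimizer; with non-negative inputs all scores stay non-negative.
#'
#' @param non a [NoN-class].
#' @param hp a [HyperParams-class]; `tol` is the relative L-infinity change
#'   between iterates at which the solver stops.
#' @return list with `scores` (a [ScoreSet-class]) and `trace` (iteration
#'   count, per-iteration objective, final relative change, converged flag).
#' @examples
#' path <- weightedNetwork(matrix(c(0, 1, 1, 0), 2, 2,
#'   dimnames = list(c("g1", "g2"), c("g1", "g2"))))
#' dnet <- weightedNetwork(matrix(0, 1, 1, dimnames = list("d1", "d1")))
#' non <- NoN(dnet, list(d1 = path),
#'            data.frame(disease = "d1", gene = "g1"))
#' solveCR(non, hyperParams(beta = 0))$scores
#' @export
solveCR <- function(non, hp = hyperParams()) {
  asm <- .assembleCR(non, hp)
  fp <- .fixedPoint(asm, hp)
  list(scores = .splitScores(fp$r, asm), trace = fp$trace)
}

#' Direct-solve oracle for CrossRank
#'
#' Assembles the linear stationarity system of the objective and solves it
#' with a sparse Cholesky factorization. Intended as an exact cross-check
#' of [solveCR()] on small problems; refuses systems above `guard`
#' variables.
#'
#' @inheritParams solveCR
#' @param guard maximum total number of genes for the direct solve.
#' @return a [ScoreSet-class].
#' @export
solveCRDirect <- function(non, hp = hyperParams(), guard = 5000L) {
  asm <- .assembleCR(non, hp)
  .splitScores(.directSolve(asm, guard), asm)
}

#' Rank the genes of one network by score
#'
#' Sorts genes by decreasing score, removes excluded genes (typically the
#' training seed genes of the query disease, which are known positives),
#' and breaks score ties by ascending gene identifier so the ranking is
#' deterministic.
#'
#' @param scores named numeric vector of gene scores.
#' @param exclude character vector of gene identifiers to drop.
#' @return character vector of gene identifiers, best first.
#' @export
rankGenes <- function(scores, exclude = character()) {
  scores <- scores[!(names(scores) %in% exclude)]
  names(scores)[order(-scores, names(scores))]
}
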