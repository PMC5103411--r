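## CrossRankStar and its weighted variant: ranking on a network of star
## networks. The score subproblems share the quadratic structure of
## CrossRank, extended by center-auxiliary consistency couplings; the
## auxiliary weights of the weighted variant are learned on the probability
## simplex by a closed-form water-filling update.

## Center-auxiliary consistency of one (center, aux) pair; the center vector
## is scaled by 1/sqrt(k) to keep it comparable to the k auxiliaries.
.phiAux <- function(rC, rA, k, nodesC, nodesA) {
  common <- intersect(nodesC, nodesA)
  sC <- rC / sqrt(k)
  mC <- match(common, nodesC); mA <- match(common, nodesA)
  onlyC <- if (length(mC)) sC[-mC] else sC
  onlyA <- if (length(mA)) rA[-mA] else rA
  shared <- if (length(mC)) sum((sC[mC] - rA[mA])^2) else 0
  shared + sum(onlyC^2) + sum(onlyA^2)
}

## Assemble the star system. auxWeights = NULL gives the scalar-alpha model
## (every auxiliary coupled with weight hp@alpha); otherwise the per-aux
## weights (a named list of simplex vectors) replace the scalar.
.assembleStar <- function(noson, hp, auxWeights = NULL) {
  ids <- nodeIds(diseaseNetwork(noson))
  centers <- centerNetworks(noson)
  seeds <- seedVectors(noson)
  keys <- character(0); netList <- list(); seedList <- list()
  wList <- list(); roles <- list()
  for (d in ids) {
    keys <- c(keys, d)
    netList[[d]] <- centers[[d]]
    seedList[[d]] <- seeds$center[[d]]
    auxs <- auxNetworks(noson, d)
    k <- length(auxs)
    for (p in seq_len(k)) {
      key <- auxKey(d, p)
      keys <- c(keys, key)
      netList[[key]] <- auxs[[p]]
      seedList[[key]] <- seeds$aux[[d]][[p]]
    }
    wList[[d]] <- if (is.null(auxWeights)) rep(hp@alpha, k)
                  else auxWeights[[d]]
    if (length(wList[[d]]) != k)
      stop("auxiliary weight vector of '", d, "' must have length ", k)
  }
  sizes <- vapply(netList, numNodes, integer(1))
  offsets <- c(0L, cumsum(sizes))[seq_along(keys)]
  names(offsets) <- keys
  N <- sum(sizes)
  A <- adjacency(diseaseNetwork(noson))
  dA <- Matrix::rowSums(A)
  beta <- hp@beta

  Dvec <- numeric(N)
  ti <- tj <- tx <- list()
  addBlock <- function(i, j, x) {
    ti[[length(ti) + 1L]] <<- i; tj[[length(tj) + 1L]] <<- j
    tx[[length(tx) + 1L]] <<- x
  }
  for (key in keys) {
    o <- offsets[[key]]
    g <- .tsparse(symmetricNormalize(netList[[key]]))
    if (length(g@x)) addBlock(o + g@i + 1L, o + g@j + 1L, hp@c * g@x)
  }
  for (d in ids) {
    k <- length(wList[[d]])
    oC <- offsets[[d]]
    Dvec[oC + seq_len(sizes[[d]])] <-
      1 + 2 * beta * (dA[[d]] > 0) + (if (k) sum(wList[[d]]) / k else 0)
    nodesC <- nodeIds(netList[[d]])
    for (p in seq_len(k)) {
      key <- auxKey(d, p)
      oA <- offsets[[key]]
      w <- wList[[d]][p]
      Dvec[oA + seq_len(sizes[[key]])] <- 1 + w
      if (w == 0) next
      nodesA <- nodeIds(netList[[key]])
      common <- intersect(nodesC, nodesA)
      if (!length(common)) next
      ii <- oC + match(common, nodesC)
      jj <- oA + match(common, nodesA)
      coef <- w / sqrt(k)
      addBlock(c(ii, jj), c(jj, ii), rep(coef, 2L * length(common)))
    }
  }
  At <- .tsparse(A)
  for (kk in seq_along(At@x)) {
    i <- At@i[kk] + 1L; j <- At@j[kk] + 1L
    if (i >= j || At@x[kk] == 0) next
    di <- ids[i]; dj <- ids[j]
    nodesI <- nodeIds(netList[[di]]); nodesJ <- nodeIds(netList[[dj]])
    common <- intersect(nodesI, nodesJ)
    if (!length(common)) next
    coef <- 2 * beta * At@x[kk] / sqrt(dA[[di]] * dA[[dj]])
    if (coef == 0) next
    ii <- offsets[[di]] + match(common, nodesI)
    jj <- offsets[[dj]] + match(common, nodesJ)
    addBlock(c(ii, jj), c(jj, ii), rep(coef, 2L * length(common)))
  }
  C <- sparseMatrix(i = as.integer(unlist(ti)), j = as.integer(unlist(tj)),
                    x = as.numeric(unlist(tx)), dims = c(N, N))
  e <- unlist(seedList[keys], use.names = FALSE)
  list(keys = keys, ids = ids, sizes = sizes, offsets = offsets, D = Dvec,
       C = C, e = e, nodes = lapply(netList[keys], nodeIds), c = hp@c)
}

.starBreakdown <- function(noson, scores, hp, auxWeights = NULL,
                           gammaTerm = FALSE) {
  ids <- nodeIds(diseaseNetwork(noson))
  centers <- centerNetworks(noson)
  seeds <- seedVectors(noson)
  A <- adjacency(diseaseNetwork(noson))
  dA <- Matrix::rowSums(A)
  withinOne <- function(net, r, e) {
    g <- symmetricNormalize(net)
    hp@c * (sum(r^2) - sum(r * as.numeric(g %*% r))) +
      (1 - hp@c) * sum((r - e)^2)
  }
  within <- numeric(0)
  aux <- data.frame(disease = character(), p = integer(), value = numeric(),
                    weight = numeric())
  for (d in ids) {
    rC <- .scoresAligned(scores, d, nodeIds(centers[[d]]))
    within[d] <- withinOne(centers[[d]], rC, seeds$center[[d]])
    auxs <- auxNetworks(noson, d)
    k <- length(auxs)
    for (p in seq_len(k)) {
      key <- auxKey(d, p)
      rA <- .scoresAligned(scores, key, nodeIds(auxs[[p]]))
      within[key] <- withinOne(auxs[[p]], rA, seeds$aux[[d]][[p]])
      w <- if (is.null(auxWeights)) hp@alpha else auxWeights[[d]][p]
      aux <- rbind(aux, data.frame(
        disease = d, p = p,
        value = .phiAux(rC, rA, k, nodeIds(centers[[d]]), nodeIds(auxs[[p]])),
        weight = w))
    }
  }
  cross <- data.frame(i = character(), j = character(), value = numeric())
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i == j || A[i, j] == 0) next
    di <- ids[i]; dj <- ids[j]
    val <- .crossTerm(A[i, j],
                      .scoresAligned(scores, di, nodeIds(centers[[di]])),
                      .scoresAligned(scores, dj, nodeIds(centers[[dj]])),
                      nodeIds(centers[[di]]), nodeIds(centers[[dj]]),
                      dA[[di]], dA[[dj]])
    cross <- rbind(cross, data.frame(i = di, j = dj, value = val))
  }
  reg <- if (gammaTerm && !is.null(auxWeights))
    hp@gamma * sum(vapply(auxWeights, function(a) sum(a^2), numeric(1)))
  else 0
  total <- sum(within) + sum(aux$value * aux$weight) +
    hp@beta * sum(cross$value) + reg
  structure(list(within = within, cross = cross, aux = aux, reg = reg,
                 total = total),
            class = "objectiveBreakdown")
}

#' CrossRankStar objective value with per-term breakdown
#'
#' Evaluates the star-model ranking objective on an NoSN: within-network
#' terms for every center and auxiliary network, center-auxiliary
#' consistency terms (weighted by the scalar `alpha` of `hp`), and
#' cross-disease consistency between centers (weighted by `beta`). With no
#' auxiliaries the value coincides with [objectiveCR()] on the induced NoN.
#'
#' @param noson a [NoSN-class].
#' @param scores a [ScoreSet-class] covering every center and auxiliary.
#' @param hp a [HyperParams-class].
#' @return list with `within`, `cross`, `aux` (per (disease, auxiliary)
#'   inconsistency and the weight applied to it), `reg` and `total`.
#' @export
objectiveCRStar <- function(noson, scores, hp = hyperParams())
  .starBreakdown(noson, scores, hp)

#' Weighted CrossRankStar objective
#'
#' Like [objectiveCRStar()] but with learned per-auxiliary simplex weights
#' replacing the scalar `alpha`, plus the l2 penalty `gamma * sum ||alpha_i||^2`.
#'
#' @inheritParams objectiveCRStar
#' @param auxWeights named list of per-disease weight vectors on the
#'   probability simplex.
#' @export
objectiveWCRStar <- function(noson, scores, auxWeights, hp = hyperParams())
  .starBreakdown(noson, scores, hp, auxWeights, gammaTerm = TRUE)

#' Analytic gradient of the CrossRankStar objective
#'
#' @inheritParams objectiveCRStar
#' @return a [ScoreSet-class] of per-network gradient vectors.
#' @export
gradientCRStar <- function(noson, scores, hp = hyperParams()) {
  asm <- .assembleStar(noson, hp)
  r <- unlist(lapply(asm$keys, function(k)
    .scoresAligned(scores, k, asm$nodes[[k]])), use.names = FALSE)
  g <- 2 * (asm$D * r - as.numeric(asm$C %*% r) - (1 - hp@c) * asm$e)
  .splitScores(g, asm)
}

#' Solve the CrossRankStar ranking problem
#'
#' Fixed-point minimization of the star objective over the concatenation of
#' all center and auxiliary score vectors (diseases ascending, center before
#' auxiliaries). The objective is jointly convex, so the limit is the
#' global minimizer; with all-zero auxiliaries the result equals
#' [solveCR()] on the induced NoN.
#'
#' @inheritParams objectiveCRStar
#' @return list with `scores` and `trace`, as in [solveCR()].
#' @export
solveCRStar <- function(noson, hp = hyperParams()) {
  asm <- .assembleStar(noson, hp)
  fp <- .fixedPoint(asm, hp)
  list(scores = .splitScores(fp$r, asm), trace = fp$trace)
}

#' Direct-solve oracle for CrossRankStar
#'
#' @inheritParams solveCRStar
#' @param guard maximum number of variables for the direct solve.
#' @return a [ScoreSet-class].
#' @export
solveCRStarDirect <- function(noson, hp = hyperParams(), guard = 5000L) {
  asm <- .assembleStar(noson, hp)
  .splitScores(.directSolve(asm, guard), asm)
}

#' Simplex update of auxiliary-network weights
#'
#' Closed-form minimizer of `sum_p alpha_p d_p + gamma * sum_p alpha_p^2`
#' over the probability simplex, where `d_p >= 0` is the ranking
#' inconsistency of auxiliary p against the center. The KKT conditions give
#' the water-filling solution `alpha_p = max(0, (lambda - d_p) / (2 gamma))`
#' with `lambda` chosen so the weights sum to one: auxiliaries with lower
#' inconsistency receive larger weight, as `gamma -> 0` all mass
#' concentrates on the least inconsistent auxiliary, and as `gamma -> Inf`
#' the weights approach uniform.
#'
#' @param d numeric vector of non-negative inconsistencies.
#' @param gamma l2 regularization strength, > 0.
#' @return simplex weight vector of the same length as `d` (empty input
#'   yields an empty vector).
#' @examples
#' updateAlpha(c(0.2, 0.4), gamma = 0.5)  # (0.6, 0.4)
#' @export
updateAlpha <- function(d, gamma) {
  stopifnot(gamma > 0, all(d >= 0))
  k <- length(d)
  if (k == 0) return(numeric(0))
  ord <- order(d)
  ds <- d[ord]
  lambda <- (2 * gamma + cumsum(ds)) / seq_len(k)
  m <- max(which(lambda > ds))        # largest feasible support size
  lam <- lambda[m]
  pmax(0, (lam - d) / (2 * gamma))
}

#' Solve the weighted CrossRankStar problem
#'
#' Alternating minimization of the weighted star objective: with the
#' auxiliary weights fixed, the score subproblem is convex and solved
#' exactly (direct sparse solve up to `guard` variables, the fixed-point
#' iteration beyond); with the scores fixed, each disease's weight vector
#' is updated in closed form by [updateAlpha()]. Both half-steps decrease
#' the objective, so the recorded objective trace is non-increasing and the
#' procedure converges; the overall problem is biconvex, so the result is
#' reported for the fixed uniform initialization of the weights.
#'
#' @inheritParams objectiveCRStar
#' @param guard size limit for the exact score solve per outer iteration.
#' @return list with `scores` (a [ScoreSet-class]), `auxWeights` (named
#'   list of simplex vectors), `inconsistencies` (named list parallel to
#'   `auxWeights`), and `trace` (objective after each outer iteration,
#'   converged flag).
#' @export
solveWCRStar <- function(noson, hp = hyperParams(), guard = 5000L) {
  ids <- nodeIds(diseaseNetwork(noson))
  kvec <- numAuxiliaries(noson)
  alpha <- lapply(stats::setNames(nm = ids), function(d)
    if (kvec[[d]] > 0) rep(1 / kvec[[d]], kvec[[d]]) else numeric(0))
  objs <- numeric(0)
  converged <- FALSE
  scores <- NULL; incons <- NULL
  for (it in seq_len(hp@outerMaxIter)) {
    asm <- .assembleStar(noson, hp, auxWeights = alpha)
    r <- if (length(asm$D) <= guard) .directSolve(asm, guard)
         else .fixedPoint(asm, hp)$r
    scores <- .splitScores(r, asm)
    bd <- .starBreakdown(noson, scores, hp, alpha, gammaTerm = TRUE)
    incons <- lapply(stats::setNames(nm = ids), function(d)
      bd$aux$value[bd$aux$disease == d])
    alpha <- lapply(stats::setNames(nm = ids), function(d)
      if (kvec[[d]] > 0) updateAlpha(incons[[d]], hp@gamma) else numeric(0))
    obj <- .starBreakdown(noson, scores, hp, alpha, gammaTerm = TRUE)$total
    objs <- c(objs, obj)
    if (it > 1 && abs(objs[it - 1] - obj) <=
          hp@outerTol * max(abs(obj), .Machine$double.xmin)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("alternating solver did not converge within ", hp@outerMaxIter,
            " outer iterations")
  list(scores = scores, auxWeights = alpha, inconsistencies = incons,
       trace = list(objective = objs, iterations = length(objs),
                    converged = converged))
}

#' Export learned auxiliary weights as a table
#'
#' @param fit result of [solveWCRStar()].
#' @return data.frame with columns `disease_id`, `aux_index`, `weight`,
#'   `inconsistency`, suitable for writing as TSV and for
#'   weight-vs-inconsistency plots.
#' @export
auxWeightTable <- function(fit) {
  out <- do.call(rbind, lapply(names(fit$auxWeights), function(d) {
    k <- length(fit$auxWeights[[d]])
    if (k == 0) return(NULL)
    data.frame(disease_id = d, aux_index = seq_len(k),
               weight = fit$auxWeights[[d]],
               inconsistency = fit$inconsistencies[[d]])
  }))
  if (is.null(out))
    out <- data.frame(disease_id = character(), aux_index = integer(),
                      weight = numeric(), inconsistency = numeric())
  rownames(out) <- NULL
  out
}
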