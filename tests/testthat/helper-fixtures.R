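## Fixtures built in code; everything is deterministic given the seed.

denseNet <- function(m, nodes = NULL) {
  if (is.null(nodes)) nodes <- rownames(m)
  weightedNetwork(m, nodes)
}

## A hand-checkable two-disease NoN: 3-gene path for d1, 3-gene triangle
## for d2, sharing genes gb and gc.
toyNoN <- function() {
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("d1", "d2"),
                                                   c("d1", "d2")))
  n1 <- matrix(0, 3, 3, dimnames = list(c("ga", "gb", "gc"),
                                        c("ga", "gb", "gc")))
  n1["ga", "gb"] <- n1["gb", "ga"] <- 1
  n1["gb", "gc"] <- n1["gc", "gb"] <- 1
  n2 <- matrix(1, 3, 3, dimnames = list(c("gb", "gc", "gd"),
                                        c("gb", "gc", "gd")))
  diag(n2) <- 0
  NoN(denseNet(d), list(d1 = denseNet(n1), d2 = denseNet(n2)),
      data.frame(disease = c("d1", "d2"), gene = c("ga", "gd")))
}

## Small random NoN/NoSN instances for oracle-based checks.
smallNoN <- function(seed, h = 3, n = 12) {
  generateNoN(h = h, n = n, overlapFrac = 0.6, moduleSize = 4,
              seedsPerDisease = 2, pIn = 0.5, pOut = 0.1, knnK = 2,
              rngSeed = seed)
}

smallNoSN <- function(seed, h = 3, n = 12, noise = c(0, 0.6)) {
  gen <- smallNoN(seed, h, n)
  star <- generateNoSN(gen$non, gen$associations, noiseLevels = noise,
                       rngSeed = seed + 1000)
  c(star, gen["associations"])
}

## Central finite differences of an objective along selected coordinates of
## the concatenated score vector.
finiteDiffGrad <- function(objFun, scoreList, coords, h = 1e-6) {
  lens <- lengths(scoreList)
  locate <- function(i) {
    k <- 1
    while (i > lens[k]) { i <- i - lens[k]; k <- k + 1 }
    c(k, i)
  }
  vapply(coords, function(i) {
    at <- locate(i)
    plus <- scoreList; plus[[at[1]]][at[2]] <- plus[[at[1]]][at[2]] + h
    minus <- scoreList; minus[[at[1]]][at[2]] <- minus[[at[1]]][at[2]] - h
    (objFun(plus) - objFun(minus)) / (2 * h)
  }, numeric(1))
}

## Exact brute-force minimizer of sum(a*d) + gamma*sum(a^2) on the simplex
## by enumerating every possible support set and solving the
## equality-constrained problem in closed form on it.
bruteForceSimplexMin <- function(d, gamma) {
  k <- length(d)
  best <- NULL
  bestVal <- Inf
  for (mask in seq_len(2^k - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    lam <- (2 * gamma + sum(d[S])) / length(S)
    a <- numeric(k)
    a[S] <- (lam - d[S]) / (2 * gamma)
    if (any(a[S] < -1e-12)) next
    a <- pmax(a, 0)
    val <- sum(a * d) + gamma * sum(a^2)
    if (val < bestVal - 1e-15) {
      bestVal <- val
      best <- a
    }
  }
  best
}

## Random score sets over a bundle's networks, for objective/gradient tests.
randomScores <- function(bundle, seed) {
  set.seed(seed)
  if (is(bundle, "NoSN")) {
    keys <- character(0); nets <- list()
    for (d in nodeIds(diseaseNetwork(bundle))) {
      keys <- c(keys, d); nets[[d]] <- centerNetworks(bundle)[[d]]
      auxs <- auxNetworks(bundle, d)
      for (p in seq_along(auxs)) {
        keys <- c(keys, auxKey(d, p)); nets[[auxKey(d, p)]] <- auxs[[p]]
      }
    }
  } else {
    keys <- nodeIds(diseaseNetwork(bundle))
    nets <- molecularNetworks(bundle)[keys]
  }
  sc <- lapply(keys, function(k)
    stats::setNames(runif(numNodes(nets[[k]])), nodeIds(nets[[k]])))
  names(sc) <- keys
  scoreSet(sc, keys)
}
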