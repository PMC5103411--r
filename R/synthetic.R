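## Synthetic network-of-networks generator: a kNN disease graph from a
## latent embedding, per-disease gene networks with overlapping gene sets
## and planted disease modules (stochastic-block edges), seed associations,
## and noisy auxiliary networks. Everything is reproducible from a single
## integer seed, and the generated objects pass the model validators.

.withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(expr)
}

.geneIds <- function(n) sprintf("g%04d", seq_len(n))
.diseaseIds <- function(h) sprintf("d%02d", seq_len(h))

#' Generate a synthetic network of networks with planted disease modules
#'
#' Emulates the structure of a disease-gene prioritization study without any
#' external data: a disease similarity network built as the k-nearest-
#' neighbor graph of a Gaussian-kernel similarity over a 2-D latent
#' embedding; per-disease molecular networks over a shared global gene
#' namespace (the gene universe has about `n / overlapFrac` genes so any
#' two diseases share about `overlapFrac` of their genes); a planted
#' disease module per disease, drawn from a common pool of
#' `2 * moduleSize` genes so the modules of related diseases overlap;
#' stochastic-block edges (within-module probability `pIn`, background
#' `pOut`, unit weights); and seed associations drawn from each module.
#'
#' The defaults are the canonical benchmark conditions used throughout the
#' package's tests.
#'
#' @param h number of diseases.
#' @param n genes per molecular network.
#' @param overlapFrac expected fraction of genes shared by two diseases.
#' @param moduleSize planted module size (<= n).
#' @param seedsPerDisease known disease genes per disease (<= moduleSize).
#' @param pIn,pOut within-module and background edge probabilities,
#'   0 <= pOut < pIn <= 1.
#' @param knnK neighbor count of the disease similarity graph.
#' @param rngSeed integer seed; regeneration is bit-identical.
#' @return list with `non` (a [NoN-class]), `associations` (disease, gene
#'   data.frame of the seeded associations) and `truth` (planted modules,
#'   seed genes, parameters).
#' @export
generateNoN <- function(h = 20, n = 200, overlapFrac = 0.5, moduleSize = 10,
                        seedsPerDisease = 3, pIn = 0.3, pOut = 0.02,
                        knnK = 5, rngSeed = 17) {
  if (moduleSize > n) stop("moduleSize must be <= n")
  if (seedsPerDisease > moduleSize)
    stop("seedsPerDisease must be <= moduleSize")
  if (!(pOut >= 0 && pOut < pIn && pIn <= 1))
    stop("need 0 <= pOut < pIn <= 1")
  if (overlapFrac <= 0 || overlapFrac > 1)
    stop("overlapFrac must be in (0, 1]")
  if (h < 2) stop("need at least 2 diseases")
  .withSeed(rngSeed, {
    ids <- .diseaseIds(h)
    universe <- .geneIds(max(n + 1, round(n / overlapFrac)))
    poolSize <- min(length(universe), 2L * moduleSize)
    pool <- sort(sample(universe, poolSize))

    latent <- matrix(stats::rnorm(h * 2), h, 2)
    dd <- as.matrix(stats::dist(latent))^2
    band <- stats::median(dd[upper.tri(dd)])
    sim <- exp(-dd / band)
    dimnames(sim) <- list(ids, ids)
    diseaseNet <- knnSparsify(sim, knnK)

    modules <- seeds <- list()
    networks <- list()
    for (d in ids) {
      module <- sort(sample(pool, moduleSize))
      others <- sort(sample(setdiff(universe, module), n - moduleSize))
      genes <- sort(c(module, others))
      idx <- match(module, genes)
      p <- matrix(pOut, n, n)
      p[idx, idx] <- pIn
      u <- matrix(stats::runif(n * n), n, n)
      up <- upper.tri(u)
      adj <- matrix(0, n, n, dimnames = list(genes, genes))
      adj[up][u[up] < p[up]] <- 1
      adj <- adj + t(adj)
      networks[[d]] <- weightedNetwork(adj, genes)
      modules[[d]] <- module
      seeds[[d]] <- sort(sample(module, seedsPerDisease))
    }
    associations <- data.frame(
      disease = rep(ids, each = seedsPerDisease),
      gene = unlist(seeds, use.names = FALSE))
    truth <- list(modules = modules, seeds = seeds,
                  params = list(h = h, n = n, overlapFrac = overlapFrac,
                                moduleSize = moduleSize,
                                seedsPerDisease = seedsPerDisease,
                                pIn = pIn, pOut = pOut, knnK = knnK),
                  rngSeed = rngSeed)
    list(non = NoN(diseaseNet, networks, associations),
         associations = associations, truth = truth)
  })
}

## Degree-preserving double-edge swaps on a 0/1 adjacency matrix; rewires
## about `frac` of the edges (each successful swap rewires two).
.rewireAdj <- function(adj, frac) {
  if (frac <= 0) return(adj)
  edges <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  m <- nrow(edges)
  if (m < 2) return(adj)
  target <- round(frac * m / 2)
  done <- 0L
  attempts <- 0L
  maxAttempts <- max(200L, 100L * target)
  while (done < target && attempts < maxAttempts) {
    attempts <- attempts + 1L
    pick <- sample.int(m, 2)
    a <- edges[pick[1], 1]; b <- edges[pick[1], 2]
    c2 <- edges[pick[2], 1]; d2 <- edges[pick[2], 2]
    if (stats::runif(1) < 0.5) { tmp <- c2; c2 <- d2; d2 <- tmp }
    if (length(unique(c(a, b, c2, d2))) < 4) next
    if (adj[a, d2] > 0 || adj[c2, b] > 0) next
    adj[a, b] <- adj[b, a] <- 0
    adj[c2, d2] <- adj[d2, c2] <- 0
    adj[a, d2] <- adj[d2, a] <- 1
    adj[c2, b] <- adj[b, c2] <- 1
    edges[pick[1], ] <- c(min(a, d2), max(a, d2))
    edges[pick[2], ] <- c(min(c2, b), max(c2, b))
    done <- done + 1L
  }
  adj
}

#' Derive a synthetic network of star networks from an NoN
#'
#' Each disease's molecular network becomes the center network; each
#' auxiliary network is a corrupted copy of the center in which a fraction
#' `noise` of the edges is rewired by degree-preserving double-edge swaps
#' (isolating topological noise from degree effects) and a fraction
#' `geneDropFrac * noise` of the genes is removed (emulating incomplete
#' coverage). `noise = 0` yields an exact copy; `noise = 1` a fully
#' rewired network.
#'
#' @param non a [NoN-class], e.g. from [generateNoN()].
#' @param associations association table used to build all seed vectors.
#' @param noiseLevels numeric vector of per-auxiliary noise levels in
#'   \[0, 1\]; every disease receives one auxiliary per entry.
#' @param rngSeed integer seed.
#' @param geneDropFrac maximum fraction of genes dropped (scaled by the
#'   noise level).
#' @return list with `noson` (a [NoSN-class]) and `truth` (the noise
#'   parameters and seed).
#' @export
generateNoSN <- function(non, associations, noiseLevels, rngSeed = 17,
                         geneDropFrac = 0.1) {
  stopifnot(all(noiseLevels >= 0 & noiseLevels <= 1),
            geneDropFrac >= 0, geneDropFrac <= 1)
  .withSeed(rngSeed, {
    ids <- nodeIds(diseaseNetwork(non))
    centers <- molecularNetworks(non)
    auxiliaries <- lapply(stats::setNames(nm = ids), function(d) {
      lapply(noiseLevels, function(noise) {
        adj <- as.matrix(adjacency(centers[[d]]))
        adj <- .rewireAdj(adj, noise)
        nodes <- nodeIds(centers[[d]])
        drop <- round(geneDropFrac * noise * length(nodes))
        if (drop > 0) {
          keep <- sort(sample(seq_along(nodes), length(nodes) - drop))
          adj <- adj[keep, keep, drop = FALSE]
          nodes <- nodes[keep]
        }
        weightedNetwork(adj, nodes)
      })
    })
    noson <- NoSN(diseaseNetwork(non), centers, auxiliaries, associations)
    truth <- list(noiseLevels = noiseLevels, geneDropFrac = geneDropFrac,
                  rngSeed = rngSeed)
    list(noson = noson, truth = truth)
  })
}

#' Generate a block-structured expression matrix
#'
#' Genes of a block share a latent factor (loading 1) plus independent
#' Gaussian noise of standard deviation `noiseSd`; genes outside any block
#' are independent standard normals. Used to exercise the co-expression
#' network construction with a known correlation structure.
#'
#' @param nGenes,nSamples matrix dimensions (`nSamples >= 2`).
#' @param blockSpec integer vector of block sizes; their sum must not
#'   exceed `nGenes`. Blocks occupy the first genes in order.
#' @param noiseSd within-block noise standard deviation; 0 makes block
#'   profiles identical (pairwise correlation exactly 1).
#' @param rngSeed integer seed.
#' @return numeric matrix, genes x samples, with gene/sample dimnames.
#' @export
generateExpression <- function(nGenes, nSamples, blockSpec = integer(),
                               noiseSd = 0.5, rngSeed = 17) {
  stopifnot(nSamples >= 2, sum(blockSpec) <= nGenes, noiseSd >= 0)
  .withSeed(rngSeed, {
    m <- matrix(stats::rnorm(nGenes * nSamples), nGenes, nSamples,
                dimnames = list(.geneIds(nGenes),
                                sprintf("s%03d", seq_len(nSamples))))
    at <- 0L
    for (size in blockSpec) {
      factor <- stats::rnorm(nSamples)
      rows <- at + seq_len(size)
      m[rows, ] <- matrix(rep(factor, each = size), size, nSamples) +
        noiseSd * matrix(stats::rnorm(size * nSamples), size, nSamples)
      at <- at + size
    }
    m
  })
}
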