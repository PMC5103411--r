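test_that("star objective degenerates to the plain model without auxiliaries", {
  gen <- smallNoN(3)
  noson <- NoSN(diseaseNetwork(gen$non), molecularNetworks(gen$non),
                list(), gen$associations)
  hp <- hyperParams()
  sc <- randomScores(gen$non, 12)
  expect_equal(objectiveCRStar(noson, sc, hp)$total,
               objectiveCR(gen$non, sc, hp)$total)

  # all-zero scores: seed preference only, over centers and auxiliaries
  star <- smallNoSN(3)
  sv <- seedVectors(star$noson)
  allSeeds <- c(sv$center, unlist(sv$aux, recursive = FALSE))
  zero <- randomScores(star$noson, 1)
  zero <- scoreSet(lapply(scoreVectors(zero), function(x) x * 0),
                   zero@keys)
  expect_equal(objectiveCRStar(star$noson, zero, hp)$total,
               (1 - 0.85) * sum(vapply(allSeeds, function(e) sum(e^2),
                                       numeric(1))))
})

test_that("a single auxiliary identical to its center has zero inconsistency", {
  gen <- smallNoN(6, h = 2)
  nets <- molecularNetworks(gen$non)
  noson <- NoSN(diseaseNetwork(gen$non), nets,
                lapply(nets, function(n) list(n)), gen$associations)
  # scores: r_aux = r_center / sqrt(1) -> every aux term vanishes
  rc <- lapply(nets, function(n) stats::setNames(runif(numNodes(n)),
                                                 nodeIds(n)))
  keys <- unlist(lapply(names(nets), function(d) c(d, auxKey(d, 1))))
  sc <- scoreSet(c(rc, stats::setNames(rc, vapply(names(rc), auxKey,
                                                  "", p = 1))), keys)
  bd <- objectiveCRStar(noson, sc, hyperParams())
  expect_equal(sum(bd$aux$value), 0)
})

test_that("star solver matches its direct oracle and the k=0 degeneracy", {
  hp <- hyperParams()
  gen <- smallNoN(9)
  noson0 <- NoSN(diseaseNetwork(gen$non), molecularNetworks(gen$non),
                 list(), gen$associations)
  expect_identical(concatScores(solveCRStar(noson0, hp)$scores),
                   concatScores(solveCR(gen$non, hp)$scores))
  for (s in 1:4) {
    star <- smallNoSN(s)
    r1 <- concatScores(solveCRStar(star$noson, hp)$scores)
    r2 <- concatScores(solveCRStarDirect(star$noson, hp))
    expect_lt(sqrt(sum((r1 - r2)^2) / sum(r2^2)), 1e-6)
  }
})

test_that("star gradient matches finite differences", {
  for (s in 1:3) {
    star <- smallNoSN(s)
    hp <- hyperParams()
    sc <- randomScores(star$noson, s + 70)
    ga <- concatScores(gradientCRStar(star$noson, sc, hp))
    objFun <- function(lst) objectiveCRStar(star$noson,
      scoreSet(lst, names(lst)), hp)$total
    set.seed(s)
    coords <- sample(length(ga), 6)
    fd <- finiteDiffGrad(objFun, scoreVectors(sc)[sc@keys], coords)
    expect_lt(max(abs(fd - ga[coords]) / pmax(abs(fd), 1e-8)), 1e-5)
  }
})

test_that("seed mass reaches the center through an auxiliary only", {
  # seeds exist only in the auxiliary network; the coupling must propagate
  # positive mass to the shared genes of the center
  ids <- c("g1", "g2", "g3")
  a <- matrix(0, 3, 3, dimnames = list(ids, ids))
  a["g1", "g2"] <- a["g2", "g1"] <- 1
  a["g2", "g3"] <- a["g3", "g2"] <- 1
  net <- weightedNetwork(a)
  dn <- weightedNetwork(matrix(0, 1, 1, dimnames = list("d1", "d1")))
  noson <- NoSN(dn, list(d1 = net), list(d1 = list(net)), NULL)
  # plant the seed only in the auxiliary
  noson@auxSeeds$d1[[1]] <- buildSeedVector("g1", net)
  r <- scoreVectors(solveCRStarDirect(noson, hyperParams(alpha = 0.3)))
  expect_true(all(r$d1 > 0))
  expect_equal(sum(seedVectors(noson)$center$d1), 0)
})

test_that("simplex weight update solves the KKT system", {
  expect_equal(updateAlpha(c(0.3, 0.3), 2), c(0.5, 0.5))
  expect_equal(updateAlpha(c(0.2, 0.4), 0.5), c(0.6, 0.4))
  # gamma -> 0: all mass on the least inconsistent auxiliary
  expect_equal(updateAlpha(c(0.5, 0.1, 0.9), 1e-9), c(0, 1, 0))
  # gamma -> Inf: uniform weights
  expect_equal(updateAlpha(c(0.5, 0.1, 0.9), 1e6), rep(1 / 3, 3),
               tolerance = 1e-6)
  expect_identical(updateAlpha(numeric(0), 1), numeric(0))
})

test_that("weight update matches the exhaustive simplex minimizer", {
  set.seed(99)
  for (rep in 1:30) {
    k <- sample(2:5, 1)
    d <- runif(k, 0, 2)
    gamma <- runif(1, 0.05, 2)
    expect_equal(updateAlpha(d, gamma), bruteForceSimplexMin(d, gamma),
                 tolerance = 1e-8)
    # monotone: smaller inconsistency never gets smaller weight
    a <- updateAlpha(d, gamma)
    ord <- order(d)
    expect_true(all(diff(a[ord]) <= 1e-12))
  }
})

test_that("support size of the learned weights grows with gamma", {
  d <- c(0.05, 0.2, 0.5, 0.9, 1.4)
  supp <- vapply(c(0.01, 0.05, 0.2, 0.5, 1, 5),
                 function(g) sum(updateAlpha(d, g) > 0), numeric(1))
  expect_true(all(diff(supp) >= 0))
})

test_that("alternating solver keeps simplex invariants and decreases the objective", {
  for (s in 1:4) {
    star <- smallNoSN(s)
    fit <- solveWCRStar(star$noson, hyperParams())
    expect_true(all(diff(fit$trace$objective) <=
                      1e-12 * max(abs(fit$trace$objective))))
    for (a in fit$auxWeights) {
      if (!length(a)) next
      expect_true(all(a >= 0))
      expect_lt(abs(sum(a) - 1), 1e-12)
    }
  }
})

test_that("identical auxiliaries keep uniform weights by symmetry", {
  gen <- smallNoN(13, h = 2)
  nets <- molecularNetworks(gen$non)
  noson <- NoSN(diseaseNetwork(gen$non), nets,
                lapply(nets, function(n) list(n, n)), gen$associations)
  fit <- solveWCRStar(noson, hyperParams())
  for (a in fit$auxWeights) expect_equal(a, c(0.5, 0.5))
})

test_that("one forced auxiliary reduces to the scalar model at alpha = 1", {
  gen <- smallNoN(17, h = 2)
  nets <- molecularNetworks(gen$non)
  star <- generateNoSN(gen$non, gen$associations, noiseLevels = 0.4,
                       rngSeed = 2)
  fit <- solveWCRStar(star$noson, hyperParams())
  for (a in fit$auxWeights) expect_identical(a, 1)
  ref <- solveCRStarDirect(star$noson, hyperParams(alpha = 1))
  expect_equal(concatScores(fit$scores), concatScores(ref),
               tolerance = 1e-7)
})

test_that("clean auxiliaries earn more weight than rewired ones", {
  gen <- generateNoN(h = 8, n = 60, moduleSize = 8, seedsPerDisease = 3,
                     pIn = 0.4, pOut = 0.03, knnK = 3, rngSeed = 23)
  star <- generateNoSN(gen$non, gen$associations, noiseLevels = c(0, 1),
                       rngSeed = 24)
  fit <- solveWCRStar(star$noson, hyperParams(), guard = 20000L)
  tab <- auxWeightTable(fit)
  clean <- tab$weight[tab$aux_index == 1]
  noisy <- tab$weight[tab$aux_index == 2]
  expect_gt(mean(clean > noisy), 0.7)
  # and the mechanism: lower weight reflects higher inconsistency
  ic <- tab$inconsistency[tab$aux_index == 1]
  io <- tab$inconsistency[tab$aux_index == 2]
  expect_gt(mean(io > ic), 0.7)
})
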