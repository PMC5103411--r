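test_that("objective matches hand-computed values in degenerate settings", {
  non <- toyNoN()
  hp <- hyperParams(c = 0.85, beta = 0.5)

  # all-zero scores: only the seed-preference terms survive, (1-c) * 1/s_i
  zero <- scoreSet(lapply(seedVectors(non), function(e) e * 0))
  bd <- objectiveCR(non, zero, hp)
  expect_equal(bd$total, (1 - 0.85) * (1 + 1))
  expect_true(all(bd$cross$value == 0))

  # single isolated seeded gene, beta = 0, r = e: total = c
  one <- weightedNetwork(matrix(0, 1, 1, dimnames = list("g1", "g1")))
  dn <- weightedNetwork(matrix(0, 1, 1, dimnames = list("dx", "dx")))
  non1 <- NoN(dn, list(dx = one), data.frame(disease = "dx", gene = "g1"))
  bd1 <- objectiveCR(non1, scoreSet(seedVectors(non1)),
                     hyperParams(c = 0.85, beta = 0))
  expect_equal(bd1$total, 0.85)

  # two identical diseases with equal scores: cross terms cancel
  nid <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("g1", "g2"),
                                                     c("g1", "g2")))
  dn2 <- weightedNetwork(matrix(c(0, 1, 1, 0), 2, 2,
                                dimnames = list(c("da", "db"),
                                                c("da", "db"))))
  non2 <- NoN(dn2, list(da = weightedNetwork(nid), db = weightedNetwork(nid)),
              data.frame(disease = c("da", "db"), gene = c("g1", "g1")))
  r <- stats::setNames(c(0.7, 0.3), c("g1", "g2"))
  bd2 <- objectiveCR(non2, scoreSet(list(da = r, db = r)), hp)
  expect_equal(sum(bd2$cross$value), 0)
})

test_that("breakdown total agrees with the assembled quadratic form", {
  for (s in 1:3) {
    gen <- smallNoN(s)
    sc <- randomScores(gen$non, s + 50)
    hp <- hyperParams()
    bd <- objectiveCR(gen$non, sc, hp)
    # independent route: evaluate via gradient identity J(r) - J(0)
    # = r' M r - 2 (1-c) e' r  =>  J(r) = 0.5 r' (grad(r) + grad(0)) + J(0)
    g0 <- concatScores(gradientCR(gen$non,
      scoreSet(lapply(scoreVectors(sc), function(x) x * 0)), hp))
    gr <- concatScores(gradientCR(gen$non, sc, hp))
    r <- concatScores(sc)
    j0 <- objectiveCR(gen$non,
      scoreSet(lapply(scoreVectors(sc), function(x) x * 0)), hp)$total
    expect_equal(bd$total, 0.5 * sum(r * (gr + g0)) + j0, tolerance = 1e-10)
  }
})

test_that("analytic gradient matches central finite differences", {
  for (s in 1:5) {
    gen <- smallNoN(s)
    hp <- hyperParams()
    sc <- randomScores(gen$non, s + 7)
    ga <- concatScores(gradientCR(gen$non, sc, hp))
    objFun <- function(lst) objectiveCR(gen$non, scoreSet(lst), hp)$total
    set.seed(s)
    coords <- sample(length(ga), 6)
    fd <- finiteDiffGrad(objFun, scoreVectors(sc), coords)
    expect_lt(max(abs(fd - ga[coords]) / pmax(abs(fd), 1e-8)), 1e-5)
  }
})

test_that("gradient vanishes at the solution and is 2c(I-G)e off-network", {
  gen <- smallNoN(11)
  hp <- hyperParams()
  fit <- solveCR(gen$non, hp)
  g <- concatScores(gradientCR(gen$non, fit$scores, hp))
  expect_lt(max(abs(g)), 1e-6)

  # beta = 0, no edges, r = e: gradient reduces to 2c * e per network
  iso <- weightedNetwork(matrix(0, 2, 2, dimnames = list(c("g1", "g2"),
                                                         c("g1", "g2"))))
  dn <- weightedNetwork(matrix(0, 1, 1, dimnames = list("d1", "d1")))
  non <- NoN(dn, list(d1 = iso), data.frame(disease = "d1", gene = "g1"))
  hp0 <- hyperParams(beta = 0)
  g0 <- scoreVectors(gradientCR(non, scoreSet(seedVectors(non)), hp0))$d1
  expect_equal(unname(g0), 2 * 0.85 * c(1, 0))
})

test_that("fixed-point solver reproduces the closed-form micro example", {
  path <- weightedNetwork(matrix(c(0, 1, 1, 0), 2, 2,
                                 dimnames = list(c("g1", "g2"),
                                                 c("g1", "g2"))))
  dn <- weightedNetwork(matrix(0, 1, 1, dimnames = list("d1", "d1")))
  non <- NoN(dn, list(d1 = path), data.frame(disease = "d1", gene = "g1"))
  fit <- solveCR(non, hyperParams(c = 0.85, beta = 0))
  expect_true(fit$trace$converged)
  r <- scoreVectors(fit$scores)$d1
  # (1-c) (I - c*Gnorm)^{-1} e = 0.15/(1-0.7225) * (1, 0.85)
  expect_equal(unname(r), c(0.5405405405, 0.4594594595), tolerance = 1e-8)
})

test_that("solver agrees with the direct stationarity solve", {
  for (s in 1:5) {
    gen <- smallNoN(s)
    hp <- hyperParams()
    r1 <- concatScores(solveCR(gen$non, hp)$scores)
    r2 <- concatScores(solveCRDirect(gen$non, hp))
    expect_lt(sqrt(sum((r1 - r2)^2) / sum(r2^2)), 1e-6)
    expect_true(all(r1 >= 0))
    # the optimum beats both natural reference points
    obj <- function(r) objectiveCR(gen$non, r, hp)$total
    opt <- obj(solveCRDirect(gen$non, hp))
    expect_lte(opt, obj(scoreSet(seedVectors(gen$non))))
    expect_lte(opt, obj(scoreSet(lapply(seedVectors(gen$non),
                                        function(e) e * 0))))
  }
})

test_that("beta = 0 decouples into per-network label propagation", {
  gen <- smallNoN(21)
  hp <- hyperParams(beta = 0)
  sol <- scoreVectors(solveCRDirect(gen$non, hp))
  for (d in nodeIds(diseaseNetwork(gen$non))) {
    net <- molecularNetworks(gen$non)[[d]]
    g <- as.matrix(symmetricNormalize(net))
    e <- seedVectors(gen$non)[[d]]
    closed <- (1 - 0.85) * solve(diag(nrow(g)) - 0.85 * g, e)
    expect_lt(max(abs(sol[[d]] - closed)), 1e-8)
  }
})

test_that("all-zero seeds give identically zero scores", {
  gen <- smallNoN(5)
  non <- setSeeds(gen$non, data.frame(disease = character(),
                                      gene = character()))
  fit <- solveCR(non, hyperParams())
  expect_identical(unique(concatScores(fit$scores)), 0)
  expect_true(fit$trace$converged)
})

test_that("objective is jointly convex along random segments", {
  gen <- smallNoN(33)
  hp <- hyperParams()
  obj <- function(sc) objectiveCR(gen$non, sc, hp)$total
  s1 <- randomScores(gen$non, 1)
  s2 <- randomScores(gen$non, 2)
  mix <- function(l) scoreSet(Map(function(a, b) l * a + (1 - l) * b,
                                  scoreVectors(s1), scoreVectors(s2)))
  for (l in c(0.25, 0.5, 0.75))
    expect_lte(obj(mix(l)), l * obj(s1) + (1 - l) * obj(s2) + 1e-10)
})

test_that("solution is invariant under relabeling of diseases and genes", {
  gen <- smallNoN(8)
  hp <- hyperParams()
  base <- scoreVectors(solveCR(gen$non, hp)$scores)

  relabel <- function(x, map) {
    stats::setNames(x, unname(map[x]))
  }
  dIds <- nodeIds(diseaseNetwork(gen$non))
  dMap <- stats::setNames(rev(sprintf("z%02d", seq_along(dIds))), dIds)
  gIds <- sort(unique(unlist(lapply(molecularNetworks(gen$non), nodeIds))))
  gMap <- stats::setNames(sprintf("q%04d", rev(seq_along(gIds))), gIds)

  dn <- adjacency(diseaseNetwork(gen$non))
  dimnames(dn) <- list(unname(dMap[dIds]), unname(dMap[dIds]))
  nets <- lapply(molecularNetworks(gen$non), function(net) {
    a <- adjacency(net)
    ids <- unname(gMap[nodeIds(net)])
    dimnames(a) <- list(ids, ids)
    weightedNetwork(a, ids)
  })
  names(nets) <- unname(dMap[names(nets)])
  assoc <- data.frame(disease = unname(dMap[gen$associations$disease]),
                      gene = unname(gMap[gen$associations$gene]))
  non2 <- NoN(weightedNetwork(dn), nets, assoc)
  perm <- scoreVectors(solveCR(non2, hp)$scores)
  for (d in dIds) {
    orig <- base[[d]]
    mapped <- perm[[dMap[[d]]]][unname(gMap[names(orig)])]
    expect_equal(unname(mapped), unname(orig), tolerance = 1e-7)
  }
})

test_that("gene ranking sorts by score with deterministic tie-breaks", {
  s <- c(a = 0.9, b = 0.1, c = 0.5)
  expect_identical(rankGenes(s), c("a", "c", "b"))
  expect_identical(rankGenes(s, exclude = "a"), c("c", "b"))
  tied <- c(b = 0.5, c = 0.5, a = 0.9)
  expect_identical(rankGenes(tied), c("a", "b", "c"))
})
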