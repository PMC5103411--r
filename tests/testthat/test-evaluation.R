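test_that("truncated ROC area follows the single-positive closed form", {
  expect_equal(aucAtK(0, 50), 1)
  expect_equal(aucAtK(10, 50), 0.8)
  expect_equal(aucAtK(50, 50), 0)
  expect_equal(aucAtK(120, 50), 0)
  # non-increasing in f, non-decreasing in k
  f <- seq(0, 80, by = 5)
  expect_true(all(diff(aucAtK(f, 50)) <= 0))
  ks <- c(50, 100, 300, 500, 700, 1000)
  expect_true(all(diff(aucAtK(25, ks)) >= 0))
})

test_that("holding out an association removes every association of its gene", {
  non <- toyNoN()
  assoc <- data.frame(disease = c("d1", "d2", "d1"),
                      gene = c("gb", "gb", "ga"))
  seen <- list()
  recorder <- function(train) {
    seen[[length(seen) + 1]] <<- train
    lapply(molecularNetworks(non), function(net)
      stats::setNames(rep(1, numNodes(net)), nodeIds(net)))
  }
  loocv(non, assoc, method = recorder, hp = hyperParams(), kList = 50)
  # first run tests (d1, gb): gb must be gone everywhere, (d1, ga) kept
  first <- seen[[1]]
  expect_false("gb" %in% first$gene)
  expect_true(any(first$disease == "d1" & first$gene == "ga"))
})

test_that("a perfect scorer attains AUC 1 at every truncation point", {
  non <- toyNoN()
  assoc <- data.frame(disease = c("d1", "d2"), gene = c("ga", "gd"))
  perfect <- function(train) {
    sc <- lapply(molecularNetworks(non), function(net)
      stats::setNames(numeric(numNodes(net)), nodeIds(net)))
    sc$d1["ga"] <- 1
    sc$d2["gd"] <- 1
    sc
  }
  res <- loocv(non, assoc, method = perfect, kList = c(50, 300))
  expect_true(all(res$perTest$f == 0))
  expect_equal(unname(res$meanAuc), c(1, 1))
})

test_that("LOOCV excludes remaining seeds, skips absent genes, is deterministic", {
  gen <- smallNoN(14)
  res1 <- loocv(gen$non, gen$associations, method = "cr")
  res2 <- loocv(gen$non, gen$associations, method = "cr")
  expect_identical(res1$perTest, res2$perTest)
  expect_true(all(res1$perTest$f >= 0))
  expect_true(all(res1$meanAuc >= 0 & res1$meanAuc <= 1))
  # per-k means are non-decreasing in k
  expect_true(all(diff(unname(res1$meanAuc)) >= 0))
  # candidates exclude the query disease's remaining seeds
  nGenes <- numNodes(molecularNetworks(gen$non)[[1]])
  expect_true(all(res1$perTest$candidates <= nGenes - 1))

  # association to a gene outside the network is skipped, not scored
  assoc2 <- rbind(gen$associations,
                  data.frame(disease = gen$associations$disease[1],
                             gene = "not_in_any_network"))
  res3 <- loocv(gen$non, assoc2, method = "cr")
  expect_equal(nrow(res3$skipped), 1)
  expect_equal(nrow(res3$perTest), nrow(gen$associations))
})

test_that("LOOCV accepts star bundles with the star methods", {
  star <- smallNoSN(4)
  res <- loocv(star$noson, star$associations, method = "crstar",
               kList = c(50, 300))
  expect_true(all(res$meanAuc >= 0 & res$meanAuc <= 1))
  expect_gt(nrow(res$perTest), 0)
  # the cached-factorization path must agree with a fresh full solve
  res2 <- loocv(star$noson, star$associations, method = "wcrstar",
                kList = c(50, 300))
  expect_equal(nrow(res2$perTest), nrow(res$perTest))
})

test_that("paired t-test handles degenerate and textbook cases", {
  same <- c(0.4, 0.5, 0.6)
  expect_equal(pairedTTest(same, same), list(statistic = 0, p.value = 1))
  out <- pairedTTest(same + 0.1, same)
  expect_equal(out$p.value, 0)
  expect_true(is.infinite(out$statistic) && out$statistic > 0)

  a <- c(0.9, 0.8, 0.7); b <- c(0.6, 0.5, 0.7)
  res <- pairedTTest(a, b)
  d <- a - b
  tHand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$statistic, tHand)
  expect_equal(res$p.value, 2 * pt(-abs(tHand), df = 2))
})

test_that("temporal split masks other train associations of the test gene", {
  gen <- smallNoN(19)
  assoc <- gen$associations
  test <- assoc[1, ]
  train <- assoc[-1, ]
  resA <- temporalSplitEval(gen$non, train, test, method = "cr",
                            maskKnown = FALSE, kList = c(50, 300))
  resB <- temporalSplitEval(gen$non, train, test, method = "cr",
                            maskKnown = TRUE, kList = c(50, 300))
  expect_equal(nrow(resA$perTest), 1)
  hasOther <- any(train$gene == test$gene & train$disease != test$disease)
  if (hasOther) {
    # removing supporting seeds can only push the test gene down
    expect_gte(resB$perTest$f, resA$perTest$f)
  } else {
    expect_identical(resA$perTest, resB$perTest)
  }
  # pooled ROC is a valid curve
  expect_true(all(diff(resA$pooledRoc$fpr) >= 0))
  expect_true(all(resA$pooledRoc$tpr >= 0 & resA$pooledRoc$tpr <= 1))

  # a test gene with no train associations is mask-invariant
  testNew <- data.frame(disease = test$disease, gene = test$gene)
  trainWithout <- train[train$gene != test$gene, ]
  rA <- temporalSplitEval(gen$non, trainWithout, testNew, method = "cr",
                          maskKnown = FALSE, kList = 50)
  rB <- temporalSplitEval(gen$non, trainWithout, testNew, method = "cr",
                          maskKnown = TRUE, kList = 50)
  expect_identical(rA$perTest, rB$perTest)

  # empty test table gives an empty result
  empty <- temporalSplitEval(gen$non, train, train[0, ], method = "cr")
  expect_equal(nrow(empty$perTest), 0)
})
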