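## Evaluation protocols: leave-one-out cross validation with truncated ROC
## areas, paired t-tests between methods, and the temporal-split experiment.

#' Truncated ROC area for a single held-out positive
#'
#' With one positive per validation run, the area under the ROC curve
#' truncated at `k` false positives (normalized to \[0, 1\]) is
#' `max(0, (k - f) / k)`, where `f` is the number of false positives ranked
#' above the positive; candidate genes tied with the positive contribute
#' half a false positive each. AUC-at-k is 1 when the test gene is ranked
#' first and 0 when it appears after the k-th false positive.
#'
#' @param f number (possibly fractional, from ties) of false positives
#'   ranked above the held-out gene; >= 0.
#' @param k truncation point(s), >= 1.
#' @return numeric value(s) in \[0, 1\].
#' @examples
#' aucAtK(0, 50)   # 1
#' aucAtK(10, 50)  # 0.8
#' @export
aucAtK <- function(f, k) {
  stopifnot(all(f >= 0), all(k >= 1))
  pmax(0, (k - f) / k)
}

## False positives ranked above the test gene among the candidate scores
## (the test gene itself excluded); ties count one half each.
.falsePositives <- function(scores, gene) {
  sg <- scores[[gene]]
  others <- scores[names(scores) != gene]
  sum(others > sg) + 0.5 * sum(others == sg)
}

#' Degree-ranking baseline scorer
#'
#' Returns a scorer usable as the `method` argument of [loocv()] /
#' [temporalSplitEval()]: every gene is scored by its weighted degree in the
#' query disease's (center) network, ignoring the seed associations. A
#' standard null baseline for propagation methods.
#'
#' @param bundle a [NoN-class] or [NoSN-class].
#' @return function(associations) returning a named list of per-disease
#'   score vectors.
#' @export
degreeScorer <- function(bundle) {
  nets <- if (is(bundle, "NoSN")) centerNetworks(bundle)
          else molecularNetworks(bundle)
  deg <- lapply(nets, function(net)
    stats::setNames(as.numeric(Matrix::rowSums(adjacency(net))),
                    nodeIds(net)))
  function(associations) deg
}

## Build a scorer closure for a bundle + method. For the convex methods the
## system matrix does not depend on the seeds, so it is assembled and
## factorized once and every validation run is a single triangular solve.
.makeScorer <- function(bundle, method, hp) {
  if (is.function(method)) return(method)
  method <- match.arg(method, c("cr", "crstar", "wcrstar"))
  if (method == "cr" && is(bundle, "NoSN")) bundle <- asNoN(bundle)
  if (method %in% c("crstar", "wcrstar") && !is(bundle, "NoSN"))
    stop("method '", method, "' requires an NoSN bundle")
  if (method == "wcrstar") {
    return(function(associations) {
      fit <- solveWCRStar(setSeeds(bundle, associations), hp)
      sv <- scoreVectors(fit$scores)
      sv[nodeIds(diseaseNetwork(bundle))]
    })
  }
  asmFor <- function(b) if (method == "cr") .assembleCR(b, hp)
                        else .assembleStar(b, hp)
  asm <- asmFor(bundle)
  M <- Matrix::forceSymmetric(Matrix::Diagonal(x = asm$D) - asm$C)
  fac <- Matrix::Cholesky(M, LDL = FALSE)
  function(associations) {
    b2 <- setSeeds(bundle, associations)
    e <- if (method == "cr")
      unlist(seedVectors(b2)[asm$keys], use.names = FALSE)
    else {
      sv <- seedVectors(b2)
      unlist(lapply(asm$keys, function(key) {
        if (key %in% nodeIds(diseaseNetwork(bundle))) sv$center[[key]]
        else {
          parts <- strsplit(key, "#aux", fixed = TRUE)[[1]]
          sv$aux[[parts[1]]][[as.integer(parts[2])]]
        }
      }), use.names = FALSE)
    }
    r <- as.numeric(Matrix::solve(fac, (1 - hp@c) * e, system = "A"))
    sv <- scoreVectors(.splitScores(r, asm))
    sv[nodeIds(diseaseNetwork(bundle))]
  }
}

#' Coerce an NoSN to the induced NoN
#'
#' Drops all auxiliary networks, keeping the disease network, the center
#' networks and the center seeds.
#'
#' @param noson a [NoSN-class].
#' @return a [NoN-class].
#' @export
asNoN <- function(noson) {
  non <- new("NoN", diseaseNet = noson@diseaseNet, networks = noson@centers,
             seeds = noson@centerSeeds)
  non
}

.queryNetwork <- function(bundle, d) {
  if (is(bundle, "NoSN")) centerNetworks(bundle)[[d]]
  else molecularNetworks(bundle)[[d]]
}

.evalResult <- function(perTest, kList, skipped, method, hp,
                        pooledRoc = NULL) {
  meanAuc <- if (nrow(perTest))
    colMeans(perTest[, paste0("auc", kList), drop = FALSE])
  else stats::setNames(rep(NA_real_, length(kList)), paste0("auc", kList))
  structure(list(perTest = perTest, meanAuc = meanAuc, kList = kList,
                 skipped = skipped, method = method, hp = hp,
                 pooledRoc = pooledRoc),
            class = "EvalResult")
}

#' @export
print.EvalResult <- function(x, ...) {
  cat(sprintf("EvalResult (%s): %d test associations, %d skipped\n",
              if (is.character(x$method)) x$method else "custom scorer",
              nrow(x$perTest), nrow(x$skipped)))
  print(round(x$meanAuc, 4))
  invisible(x)
}

.emptyPerTest <- function(kList) {
  df <- data.frame(disease = character(), gene = character(),
                   rank = numeric(), f = numeric(),
                   candidates = integer())
  for (k in kList) df[[paste0("auc", k)]] <- numeric(0)
  df
}

.scoreOneQuery <- function(bundle, scores, trainAssoc, d, g, kList) {
  net <- .queryNetwork(bundle, d)
  nodes <- nodeIds(net)
  trainSeedsD <- intersect(trainAssoc[[2]][trainAssoc[[1]] == d], nodes)
  cand <- setdiff(nodes, setdiff(trainSeedsD, g))
  s <- scores[[d]]
  s <- stats::setNames(as.numeric(s[cand]), cand)
  f <- .falsePositives(s, g)
  row <- data.frame(disease = d, gene = g,
                    rank = sum(s[names(s) != g] > s[[g]]) + 1,
                    f = f, candidates = length(cand))
  for (k in kList) row[[paste0("auc", k)]] <- aucAtK(f, k)
  row
}

#' Leave-one-out cross validation of a prioritization method
#'
#' For every known association (d, g): remove it *together with every other
#' association involving gene g*, rebuild all seed vectors from the
#' remaining associations, run the method, and rank the genes of d's
#' network with the remaining training seed genes of d excluded (they are
#' known positives). The number `f` of candidate genes ranked above g
#' yields the truncated ROC areas via [aucAtK()] for each requested
#' truncation point. Associations whose gene is absent from the query
#' disease's network cannot be scored and are reported separately.
#'
#' @param bundle a [NoN-class] or [NoSN-class].
#' @param associations two-column data.frame (disease, gene); duplicates
#'   are removed.
#' @param method `"cr"`, `"crstar"`, `"wcrstar"`, or a scorer function
#'   taking an association table and returning a named list of per-disease
#'   score vectors (see [degreeScorer()]).
#' @param hp a [HyperParams-class].
#' @param kList truncation points of the ROC area.
#' @return an `EvalResult`: per-test table (rank, f, per-k AUC), mean AUC
#'   per truncation point, and the skipped (uncoverable) associations.
#' @export
loocv <- function(bundle, associations, method = "cr", hp = hyperParams(),
                  kList = c(50, 100, 300, 500, 700, 1000)) {
  associations <- unique(associations[, 1:2])
  scorer <- .makeScorer(bundle, method, hp)
  perTest <- .emptyPerTest(kList)
  skipped <- data.frame(disease = character(), gene = character())
  for (t in seq_len(nrow(associations))) {
    d <- as.character(associations[[1]][t])
    g <- as.character(associations[[2]][t])
    net <- .queryNetwork(bundle, d)
    if (is.null(net)) stop("no network for disease '", d, "'")
    if (!(g %in% nodeIds(net))) {
      skipped <- rbind(skipped, data.frame(disease = d, gene = g))
      next
    }
    train <- associations[associations[[2]] != g, , drop = FALSE]
    scores <- scorer(train)
    perTest <- rbind(perTest,
                     .scoreOneQuery(bundle, scores, train, d, g, kList))
  }
  rownames(perTest) <- NULL
  .evalResult(perTest, kList, skipped,
              if (is.function(method)) "custom" else method, hp)
}

#' Paired t-test between two per-test AUC vectors
#'
#' Standard paired two-sided t-test, with deterministic conventions for the
#' degenerate cases: identical vectors (zero-variance, zero-mean
#' differences) give t = 0 and p = 1; constant non-zero differences give
#' p = 0 with an infinite t statistic of the corresponding sign.
#'
#' @param a,b numeric vectors of equal length >= 2, paired by test
#'   association.
#' @return list with `statistic` and `p.value`.
#' @export
pairedTTest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(statistic = 0, p.value = 1))
    return(list(statistic = sign(mean(d)) * Inf, p.value = 0))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

#' Temporal-split evaluation: predicting newly discovered associations
#'
#' Seeds are built from the earlier (training) association table only; each
#' later (test) association (d, g) is scored by ranking g among the
#' candidate genes of d's network, as in [loocv()]. With
#' `maskKnown = TRUE`, the test gene's training associations with *other*
#' diseases are removed before solving, which isolates the harder task of
#' predicting genes with no known associations at training time. A pooled
#' ROC over all test runs is also returned, with the negatives of each run
#' being all non-seed, non-test genes of the query network.
#'
#' @param bundle a [NoN-class] or [NoSN-class].
#' @param trainAssoc,testAssoc two-column association tables (disease,
#'   gene); they must be disjoint as pairs.
#' @param method,hp,kList as in [loocv()].
#' @param maskKnown remove the test gene's other training associations
#'   before solving each query.
#' @return an `EvalResult` with a `pooledRoc` data.frame (`fpr`, `tpr`).
#' @export
temporalSplitEval <- function(bundle, trainAssoc, testAssoc, method = "cr",
                              hp = hyperParams(), maskKnown = FALSE,
                              kList = c(50, 100, 300, 500, 700, 1000)) {
  trainAssoc <- unique(trainAssoc[, 1:2])
  testAssoc <- unique(testAssoc[, 1:2])
  pairKey <- function(x) paste(x[[1]], x[[2]], sep = "\r")
  if (length(intersect(pairKey(trainAssoc), pairKey(testAssoc))))
    stop("train and test association tables must be disjoint")
  scorer <- .makeScorer(bundle, method, hp)
  perTest <- .emptyPerTest(kList)
  skipped <- data.frame(disease = character(), gene = character())
  baseScores <- if (nrow(testAssoc)) scorer(trainAssoc) else NULL
  for (t in seq_len(nrow(testAssoc))) {
    d <- as.character(testAssoc[[1]][t])
    g <- as.character(testAssoc[[2]][t])
    net <- .queryNetwork(bundle, d)
    if (is.null(net) || !(g %in% nodeIds(net))) {
      skipped <- rbind(skipped, data.frame(disease = d, gene = g))
      next
    }
    hasOther <- any(trainAssoc[[2]] == g & trainAssoc[[1]] != d)
    if (maskKnown && hasOther) {
      train <- trainAssoc[!(trainAssoc[[2]] == g & trainAssoc[[1]] != d), ,
                          drop = FALSE]
      scores <- scorer(train)
    } else {
      train <- trainAssoc
      scores <- baseScores
    }
    perTest <- rbind(perTest,
                     .scoreOneQuery(bundle, scores, train, d, g, kList))
  }
  rownames(perTest) <- NULL
  pooled <- NULL
  if (nrow(perTest)) {
    negs <- perTest$candidates - 1L
    xs <- sort(unique(c(0, floor(perTest$f), max(negs))))
    pooled <- data.frame(
      fpr = vapply(xs, function(x) mean(pmin(x, negs) / negs), numeric(1)),
      tpr = vapply(xs, function(x) mean(perTest$f <= x), numeric(1)))
  }
  .evalResult(perTest, kList, skipped,
              if (is.function(method)) "custom" else method, hp, pooled)
}

#' Write an EvalResult to disk
#'
#' Writes the per-test table as TSV (`disease_id`, `gene_id`, `rank`, `f`,
#' one AUC column per truncation point) and a JSON summary with the mean
#' AUC values.
#'
#' @param res an `EvalResult`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
writeEvalResult <- function(res, dir, prefix = "loocv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, paste0(prefix, "_per_test.tsv"))
  utils::write.table(res$perTest, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(list(method = res$method,
                            meanAuc = as.list(res$meanAuc),
                            nTests = nrow(res$perTest),
                            nSkipped = nrow(res$skipped)),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
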