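test_that("an exactly factorizable matrix is recovered at rank 1", {
  set.seed(2)
  w <- runif(20, 0.5, 2); h <- runif(12, 0.5, 2)
  V <- outer(w, h)
  dimnames(V) <- list(sprintf("g%d", 1:20), sprintf("s%d", 1:12))
  fit <- nmfFactorize(V, 1, seed = 4, maxIter = 2000, tol = 1e-12)
  relErr <- norm(V - basisMatrix(fit) %*% coefMatrix(fit), "F") / norm(V, "F")
  expect_lt(relErr, 1e-6)
  expect_equal(unname(sqrt(colSums(basisMatrix(fit)^2))), 1,
               tolerance = 1e-9)
})

test_that("the same seed gives the identical factorization", {
  V <- abs(makeExprs(15, 10, seed = 6))
  f1 <- nmfFactorize(V, 3, seed = 21, maxIter = 200)
  f2 <- nmfFactorize(V, 3, seed = 21, maxIter = 200)
  expect_identical(basisMatrix(f1), basisMatrix(f2))
  expect_identical(coefMatrix(f1), coefMatrix(f2))
})

test_that("the multiplicative-update objective never increases", {
  set.seed(31)
  for (rep in 1:20) {
    V <- matrix(runif(20 * 15, 0, 5), 20, 15)
    fit <- nmfFactorize(V, sample(2:4, 1), seed = rep, maxIter = 100,
                        tol = 0)
    d <- diff(fit@objective)
    expect_true(all(d <= 1e-8 * fit@objective[1]))
  }
})

test_that("negative input is rejected with the shift instruction", {
  V <- makeExprs(6, 4) - 100
  expect_error(nmfFactorize(V, 2), "nonnegativeShift")
  Vs <- nonnegativeShift(V)
  expect_gte(min(Vs), 0)
  expect_equal(attr(Vs, "shift"), min(V))
})

blockMatrix <- function(seed = 1) {
  set.seed(seed)
  V <- matrix(runif(30 * 20, 0, 0.3), 30, 20)
  V[1:15, 1:10] <- V[1:15, 1:10] + 5
  V[16:30, 11:20] <- V[16:30, 11:20] + 5
  dimnames(V) <- list(sprintf("g%d", 1:30), sprintf("s%d", 1:20))
  V
}

test_that("perfect two-block data gives a 0/1 consensus and cophenetic 1", {
  cons <- consensusCluster(blockMatrix(), 2, nRuns = 10, seed = 5,
                           maxIter = 300)
  cm <- consensusMatrix(cons)
  expect_true(all(cm %in% c(0, 1)))
  expect_identical(unname(diag(cm)), rep(1, 20))
  expect_equal(copheneticCoef(cons), 1.0)
  lab <- clusterLabels(cons)
  expect_equal(length(unique(lab[1:10])), 1L)
  expect_equal(length(unique(lab[11:20])), 1L)
  expect_false(lab[1] == lab[20])
})

test_that("pure noise is less stable than block structure at the same rank", {
  worse <- vapply(1:5, function(s) {
    set.seed(s + 50)
    noise <- matrix(runif(30 * 20, 0, 5), 30, 20,
                    dimnames = dimnames(blockMatrix()))
    cN <- consensusCluster(noise, 2, nRuns = 10, seed = s, maxIter = 300)
    cB <- consensusCluster(blockMatrix(s), 2, nRuns = 10, seed = s,
                           maxIter = 300)
    copheneticCoef(cN) < copheneticCoef(cB)
  }, NA)
  expect_gte(mean(worse), 0.8)
})

test_that("consensus structure is stable under sample reordering", {
  V <- blockMatrix(3)
  c1 <- consensusCluster(V, 2, nRuns = 8, seed = 2, maxIter = 300)
  perm <- sample(ncol(V))
  c2 <- consensusCluster(V[, perm], 2, nRuns = 8, seed = 2, maxIter = 300)
  expect_equal(consensusMatrix(c1)[colnames(V)[perm], colnames(V)[perm]],
               consensusMatrix(c2), tolerance = 1e-12)
})

test_that("rank selection returns the grid singleton and audit table", {
  sel <- selectRank(blockMatrix(), rankGrid = 2, nRuns = 4, seed = 1,
                    maxIter = 200)
  expect_equal(sel$rank, 2)
  expect_equal(nrow(sel$table), 1)
  expect_error(selectRank(blockMatrix(), rankGrid = integer()), "empty")
})

test_that("refinement reproduces the exclusion-then-merge worked example", {
  sizes <- c(15, 3, 18, 10, 11)
  lab <- rep(as.character(1:5), sizes)
  names(lab) <- sprintf("s%02d", seq_along(lab))
  set.seed(77)
  base <- matrix(rnorm(20 * 5, 5, 2), 20, 5,
                 dimnames = list(sprintf("g%d", 1:20), as.character(1:5)))
  # clusters 4 and 5 share a near-identical centroid profile
  base[, "5"] <- base[, "4"] + rnorm(20, 0, 0.05)
  ref <- refineClusters(lab, base, minSize = 4, targetK = 3)
  expect_length(excludedSamples(ref), 3)
  expect_equal(refinementLog(ref)$excluded[[1]]$cluster, "2")
  expect_equal(as.integer(sort(table(clusterLabels(ref)))), c(15L, 18L, 21L))
  mg <- refinementLog(ref)$merged[[1]]
  expect_setequal(mg$clusters, c("4", "5"))
  expect_gt(mg$pearson_r, 0.99)
})

test_that("refinement is the identity when nothing needs fixing", {
  lab <- rep(c("1", "2", "3"), c(10, 10, 10))
  names(lab) <- sprintf("s%02d", 1:30)
  cents <- matrix(rnorm(15 * 3), 15, 3,
                  dimnames = list(NULL, c("1", "2", "3")))
  ref <- refineClusters(lab, cents, minSize = 4, targetK = 3)
  expect_length(excludedSamples(ref), 0)
  expect_length(refinementLog(ref)$merged, 0)
  expect_equal(as.integer(table(clusterLabels(ref))), rep(10L, 3))
})

test_that("identical centroids are always the first merge", {
  lab <- rep(as.character(1:4), each = 8)
  names(lab) <- sprintf("s%02d", 1:32)
  set.seed(5)
  cents <- matrix(rnorm(10 * 4), 10, 4,
                  dimnames = list(NULL, as.character(1:4)))
  cents[, "3"] <- cents[, "2"]
  ref <- refineClusters(lab, cents, minSize = 2, targetK = 3)
  expect_setequal(refinementLog(ref)$merged[[1]]$clusters, c("2", "3"))
  # determinism: identical inputs, identical log
  ref2 <- refineClusters(lab, cents, minSize = 2, targetK = 3)
  expect_identical(refinementLog(ref), refinementLog(ref2))
})

test_that("too few clusters to reach the target is an error", {
  lab <- rep(c("1", "2"), c(3, 20)); names(lab) <- sprintf("s%02d", 1:23)
  cents <- matrix(rnorm(10 * 2), 10, 2,
                  dimnames = list(NULL, c("1", "2")))
  expect_error(refineClusters(lab, cents, minSize = 4, targetK = 3),
               "cannot reach")
})

test_that("clusters are renamed ImA/ImB/ImC by descending immune score", {
  lab <- factor(rep(c("C1", "C2", "C3"), each = 4))
  names(lab) <- sprintf("s%02d", 1:12)
  asg <- new("ClusterAssignment", labels = lab, refinementLog = list(),
             excludedSamples = character())
  score <- setNames(rep(c(1, 9, 5), each = 4), names(lab))
  out <- relabelByImmuneScore(asg, score)
  expect_equal(as.character(clusterLabels(out)[1]), "ImC")
  expect_equal(as.character(clusterLabels(out)[5]), "ImA")
  expect_equal(as.character(clusterLabels(out)[9]), "ImB")
})

test_that("cluster characterization summarizes scores, TILs and PLR", {
  co <- simulateCohort(syntheticConfig(seed = 13))
  panel <- scorePanel(co)
  lab <- factor(truthLabels(co))
  tab <- characterizeClusters(lab, panel, clinical = clinicalTable(co),
                              cbc = cbcTable(co))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$cluster[which.max(tab$median_cyt)], "ImA")
  expect_equal(tab$cluster[which.max(tab$median_tis)], "ImA")
  one <- characterizeClusters(factor(setNames(rep("all", 54),
                                              colnames(co))), panel)
  expect_equal(nrow(one), 1)
  bad <- factor(setNames(rep("A", 54), colnames(co)), levels = c("A", "B"))
  expect_error(characterizeClusters(bad, panel), "empty")
})
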