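cfgNoWarn <- signatureConfig()

test_that("CYT is the log2 geometric mean of GZMA and PRF1", {
  m <- matrix(c(8, 6, 8, 6), 2, 2,
              dimnames = list(c("GZMA", "PRF1"), c("a", "b")))
  expect_equal(unname(cytScore(m, cfgNoWarn)), c(7, 7))
  # idempotence: equal inputs pass through
  m2 <- matrix(5.5, 2, 2, dimnames = dimnames(m))
  expect_equal(unname(cytScore(m2, cfgNoWarn)), c(5.5, 5.5))
  # linear-scale input: geometric mean of 4 and 9 is 6
  lin <- ImmunoExperiment(
    matrix(c(4, 9, 4, 9), 2, 2, dimnames = dimnames(m)),
    scaleTag = "linear")
  expect_equal(unname(cytScore(lin, cfgNoWarn)), rep(log2(6), 2),
               tolerance = 1e-12)
  expect_error(cytScore(m[1, , drop = FALSE], cfgNoWarn), "PRF1")
})

test_that("TIS averages log2 expression over present signature genes", {
  tg <- cfgNoWarn$tisGenes
  m <- matrix(8.26, length(tg), 2, dimnames = list(tg, c("a", "b")))
  expect_equal(unname(tisScore(m, cfgNoWarn)), c(8.26, 8.26))
  m2 <- m; m2[1:9, ] <- 6; m2[10:18, ] <- 8
  expect_equal(unname(tisScore(m2, cfgNoWarn)), c(7, 7))
  expect_warning(s <- tisScore(m[1:5, , drop = FALSE], cfgNoWarn), "absent")
  expect_equal(unname(s), c(8.26, 8.26))
  expect_error(
    suppressWarnings(tisScore(makeExprs(4, 2, genes = letters[1:4]),
                              cfgNoWarn)),
    "no TIS genes")
})

test_that("aggressive score applies the printed coefficients", {
  m <- matrix(1, 3, 2, dimnames = list(c("CCL5", "DDIT4", "POLR1C"),
                                       c("a", "b")))
  expect_equal(unname(aggressiveScore(m, cfgNoWarn)), c(0.540, 0.540))
  m2 <- m; m2[] <- 0; m2["CCL5", ] <- 10
  expect_equal(unname(aggressiveScore(m2, cfgNoWarn)), c(-3.93, -3.93))
  expect_error(aggressiveScore(m[1:2, ], cfgNoWarn), "POLR1C")
})

test_that("IMS is exactly cyt * tis - aggressive", {
  expect_equal(imsScore(7.11, 8.26, 2.85), 55.8786)
  expect_equal(round(imsScore(7.11, 8.26, 2.85), 2), 55.88)
  expect_equal(imsScore(0, 5, 3), -3)
  expect_equal(imsScore(1, 1, 0), 1)
  expect_error(imsScore(1:3, 1:2, 1:3), "length")
  set.seed(1)
  cyt <- rnorm(100); tis <- rnorm(100); agg <- rnorm(100)
  expect_identical(imsScore(cyt, tis, agg) - (cyt * tis - agg),
                   rep(0, 100))
})

test_that("purity follows the cosine closed form and its domain", {
  sets <- list(stromal = cfgNoWarn$estimateStromal,
               immune = cfgNoWarn$estimateImmune)
  # direct closed-form check at estimate_score = 0
  expect_equal(cos(0.6049872018), 0.82252, tolerance = 1e-4)
  co <- simulateCohort(syntheticConfig(seed = 4))
  est <- estimateScores(co, cfgNoWarn)
  expect_equal(nrow(est), 54)
  ok <- !is.na(est$purity)
  expect_true(all(est$purity[ok] >= 0 & est$purity[ok] <= 1))
  # monotone decreasing in estimate_score on the valid domain
  if (sum(ok) > 2) {
    o <- order(est$estimate_score[ok])
    expect_true(all(diff(est$purity[ok][o]) <= 1e-12))
  }
})

test_that("immunophenoscore discretization follows the stated rule", {
  co <- simulateCohort(syntheticConfig(seed = 4))
  ips <- immunophenoscore(co, cfgNoWarn)
  expect_true(all(ips$ips >= 0 & ips$ips <= 10))
  expect_identical(unname(ips$ips[ips$raw <= 0]), rep(0L, sum(ips$raw <= 0)))
  # null profile: constant expression gives z = 0 everywhere, IPS 0
  wt <- cfgNoWarn$ipsWeights
  m <- matrix(5, nrow(wt), 3, dimnames = list(wt$gene, c("a", "b", "c")))
  expect_equal(unname(immunophenoscore(m, cfgNoWarn)$ips), c(0L, 0L, 0L))
  # cap at 10 for raw >= 3
  expect_identical(ifelse(3.2 <= 0, 0L, min(10L, as.integer(ceiling(10 * 3.2 / 3)))), 10L)
  mBad <- m[wt$category != "MHC", , drop = FALSE]
  expect_error(immunophenoscore(mBad, cfgNoWarn), "MHC")
})

test_that("median dichotomization sends ties to the low group", {
  expect_equal(as.character(dichotomizeByMedian(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(dichotomizeByMedian(c(1, 2, 2, 3))),
               c("low", "low", "low", "high"))
  set.seed(8)
  plr <- rlnorm(54, log(150), 0.3)
  expect_equal(as.integer(table(dichotomizeByMedian(plr))), c(27L, 27L))
  expect_warning(dichotomizeByMedian(rep(2, 5)), "identical")
})

test_that("TILs-high threshold is inclusive at 20 percent", {
  expect_true(tilsHighFlag(20.0))
  expect_false(tilsHighFlag(19.9))
  expect_error(tilsHighFlag(120), "\\[0, 100\\]")
})

test_that("location shifts move CYT/TIS by the shift and leave ssGSEA fixed", {
  m <- makeExprs(40, 5, seed = 3,
                 genes = c("GZMA", "PRF1", cfgNoWarn$tisGenes,
                           sprintf("F%02d", 1:20)))
  set <- list(S = rownames(m)[5:20])
  c0 <- cytScore(m, cfgNoWarn); t0 <- tisScore(m, cfgNoWarn)
  e0 <- ssgseaScores(m, set, normalize = FALSE)
  mShift <- m + 1.7
  expect_equal(cytScore(mShift, cfgNoWarn), c0 + 1.7, tolerance = 1e-12)
  expect_equal(tisScore(mShift, cfgNoWarn), t0 + 1.7, tolerance = 1e-12)
  expect_equal(ssgseaScores(mShift, set, normalize = FALSE), e0,
               tolerance = 1e-12)
})

test_that("the panel carries every score with the IMS invariant intact", {
  co <- simulateCohort(syntheticConfig(seed = 9))
  panel <- scorePanel(co)
  sc <- as.data.frame(scoreTable(panel))
  expect_equal(nrow(sc), 54)
  expect_true(all(c("cyt", "tis", "aggressive", "ims", "purity", "ips",
                    "ssgsea_CD8_ACTIVATED") %in% colnames(sc)))
  expect_equal(sc$ims, sc$cyt * sc$tis - sc$aggressive, tolerance = 1e-12)
})
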