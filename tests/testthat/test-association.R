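test_that("PLR and NLR are plain count ratios with a zero guard", {
  cbc <- data.frame(sample_id = "TN01", neutrophils = 4.40,
                    lymphocytes = 2.00, platelets = 252)
  r <- computeRatios(cbc)
  expect_equal(r$plr, 126.0)
  expect_equal(r$nlr, 2.20)
  cbc$lymphocytes <- 0
  expect_error(computeRatios(cbc), "nonpositive")
})

test_that("2x2 odds ratios and Wald intervals match the printed tables", {
  cases <- list(
    list(cells = c(16, 11, 11, 16), or = 2.12, lo = 0.71, hi = 6.27),
    list(cells = c(18, 9, 9, 18),  or = 4.00, lo = 1.29, hi = 12.40),
    list(cells = c(14, 14, 13, 13), or = 1.00, lo = 0.34, hi = 2.91),
    list(cells = c(10, 17, 17, 10), or = 0.35, lo = 0.11, hi = 1.04))
  for (cs in cases) {
    r <- oddsRatio2x2(cs$cells[1], cs$cells[2], cs$cells[3], cs$cells[4])
    expect_equal(round(r$estimate, 2), cs$or)
    expect_equal(round(r$ci_low, 2), cs$lo)
    expect_equal(round(r$ci_high, 2), cs$hi)
    expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
  }
})

test_that("symmetric tables give OR exactly 1 and zero cells are guarded", {
  for (k in c(1, 7, 30))
    expect_equal(oddsRatio2x2(k, k, k, k)$estimate, 1.0)
  expect_error(oddsRatio2x2(5, 0, 3, 2), "zero cell")
  r <- oddsRatio2x2(5, 0, 3, 2, haldane = TRUE)
  expect_equal(r$estimate, (5.5 * 2.5) / (0.5 * 3.5))
})

test_that("odds ratios agree with a logistic ML fit on every small table", {
  set.seed(20)
  for (rep in 1:12) {
    cells <- sample(1:30, 4, replace = TRUE)
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    x <- rep(c(1, 1, 0, 0), c(a, b, c, d))
    y <- rep(c(1, 0, 1, 0), c(a, b, c, d))
    or2 <- oddsRatio2x2(a, b, c, d)
    lg <- binomialLogistic(data.frame(x = x), y)
    expect_equal(lg$estimate, or2$estimate, tolerance = 1e-6)
    expect_equal(lg$ci_low, or2$ci_low, tolerance = 1e-5)
    expect_equal(lg$ci_high, or2$ci_high, tolerance = 1e-5)
  }
})

test_that("logistic regression guards degenerate outcomes and separation", {
  expect_error(binomialLogistic(data.frame(x = rnorm(20)), rep(1, 20)),
               "constant")
  x <- c(rep(0, 20), rep(1, 20)); y <- x
  # glm emits its fitted-probabilities warning on the way to our error
  suppressWarnings(
    expect_error(binomialLogistic(data.frame(x = x), y), "separation"))
})

test_that("age adjustment runs and reports its mode", {
  set.seed(4)
  x <- rbinom(80, 1, 0.5); age <- sample(30:80, 80, TRUE)
  y <- rbinom(80, 1, plogis(-0.3 + 0.5 * x))
  crude <- binomialLogistic(data.frame(x = x), y)
  adj <- binomialLogistic(data.frame(x = x), y, age = age)
  expect_equal(crude$adjustment, "crude")
  expect_equal(adj$adjustment, "age-adjusted")
  expect_equal(nrow(adj), 1)
})

test_that("multinomial odds ratios are location-invariant and null-consistent", {
  set.seed(5)
  n <- 3000
  lab <- sample(c("ImA", "ImB", "ImC"), n, TRUE)
  x <- rnorm(n, 150, 40)
  r1 <- multinomialLogistic(x, lab, ref = "ImA", unitScale = 10)
  expect_equal(nrow(r1), 2)
  expect_true(all(r1$estimate > 0.9 & r1$estimate < 1.1))
  r2 <- multinomialLogistic(x + 500, lab, ref = "ImA", unitScale = 10)
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-3)
  expect_error(multinomialLogistic(x, lab, ref = "ImZ"), "empty")
})

test_that("multinomial fits agree with pairwise binomial recoding", {
  set.seed(6)
  n <- 900
  lab <- sample(c("ImA", "ImB", "ImC"), n, TRUE)
  x <- rnorm(n) + 0.4 * (lab == "ImB") - 0.3 * (lab == "ImC")
  mn <- multinomialLogistic(x, lab, ref = "ImA")
  pair <- lab %in% c("ImA", "ImB")
  bg <- binomialLogistic(data.frame(x = x[pair]),
                         as.integer(lab[pair] == "ImB"))
  est <- mn$estimate[mn$contrast == "ImB vs ImA"]
  expect_lt(abs(log(est) - log(bg$estimate)), 0.08)
})

test_that("rank statistics match hand computation and trivial limits", {
  expect_equal(spearmanRho(1:10, (1:10)^3)$rho, 1.0)
  expect_equal(kruskalWallis(list(a = c(5, 6), b = c(5, 6)))$H, 0)
  # three groups holding ranks {1,2},{3,4},{5,6}:
  # H = 12/(n(n+1)) * sum n_i (rbar_i - rbar)^2 = 32/7
  kw <- kruskalWallis(list(g1 = c(10, 11), g2 = c(12, 13), g3 = c(14, 15)))
  expect_equal(kw$H, 32 / 7, tolerance = 1e-12)
  expect_error(kruskalWallis(list(a = 1:3, b = numeric())), "empty group")
  expect_error(fisherExactKx2(rbind(c(0, 0), c(3, 4))), "empty group")
  expect_lt(fisherExactKx2(rbind(c(9, 1), c(1, 9))), 0.05)
})

test_that("Kaplan-Meier DFS handles no-event and identical groups", {
  km0 <- kmDfs(times = c(100, 400, 900), events = c(0, 0, 0))
  expect_equal(unname(km0$surv_at_horizon), 1.0)
  t2 <- rep(c(100, 300, 800, 1500), 2)
  e2 <- rep(c(1, 0, 1, 0), 2)
  g2 <- rep(c("a", "b"), each = 4)
  km2 <- kmDfs(t2, e2, g2)
  expect_gt(km2$logrank_p, 0.95)
})

test_that("exponential arms with hazard ratio 3 show it in KM medians", {
  set.seed(7)
  n <- 500
  tA <- rexp(n, rate = log(2) / 1000)   # median 1000
  tB <- rexp(n, rate = 3 * log(2) / 1000) # median 1000/3
  km <- kmDfs(c(tA, tB), rep(1, 2 * n), rep(c("A", "B"), each = n),
              horizonDays = 1e9)
  med <- summary(km$fit)$table[, "median"]
  ratio <- med[["g=A"]] / med[["g=B"]]
  expect_gt(ratio, 2.2); expect_lt(ratio, 4.0)
  expect_lt(km$logrank_p, 1e-10)
})

test_that("quadrants follow the high/low convention with boundaries low", {
  expect_equal(quadrantClassify(5, 9, 4, 8), "Q2")
  expect_equal(quadrantClassify(5, 7, 4, 8), "Q4")
  expect_equal(quadrantClassify(3, 9, 4, 8), "Q1")
  expect_equal(quadrantClassify(4, 8, 4, 8), "Q3")
  expect_equal(quadrantClassify(c(5, 3), c(9, 9), 4, 8), c("Q2", "Q1"))
})
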