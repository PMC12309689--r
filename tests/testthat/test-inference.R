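test_that("partial Spearman matches a brute-force rank-regression oracle", {
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(12); y <- rnorm(12); cv <- rnorm(12)
    rx <- rank(x); ry <- rank(y); rc <- rank(cv)
    brute <- cor(resid(lm(rx ~ rc)), resid(lm(ry ~ rc)))
    expect_equal(spearmanPartial(x, y, cv), brute)
  }

  # y == x with rank-independent covariate: rho = 1
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearmanPartial(x, x, rev(seq_along(x))), 1)

  # x monotone in cov only, y random: rho approximately 0 in expectation
  set.seed(22)
  rhos <- suppressWarnings(replicate(300, {
    cv <- rnorm(8)
    spearmanPartial(cv + rnorm(8, 0, 0.3), rnorm(8), cv)
  }))
  # draws whose ranks coincide exactly with the covariate are undefined (NA)
  expect_lt(abs(mean(rhos, na.rm = TRUE)), 0.05)

  expect_error(spearmanPartial(1:3, 1:3, 1:3), "at least 4")
  expect_warning(spearmanPartial(1:6, (1:6)^2, 1:6), "undefined")
})

test_that("model fitting selects the generating boundary", {
  models <- fixtureModels()
  ac <- fixtureAcoustic()

  fit <- fitCategoricalModels(models[["5"]], models, ac)
  expect_equal(fit$bestModel, 5L)
  expect_equal(fit$bestRho, max(fit$rhoPerModel))

  # response tracking the covariate: all partial rhos near zero
  set.seed(19)
  nearAc <- new("RSM",
                matrix = rsmFromTriangle(lowerTriangle(ac) + rnorm(78, 0, 1e-4)),
                kind = "one-minus-absdiff", labels = as.character(1:13))
  fit0 <- fitCategoricalModels(nearAc, models, ac)
  expect_lt(max(abs(fit0$rhoPerModel)), 0.3)

  # noisy categorical responses: boundary 5 recovered in >= 95/100 seeded runs
  tri5 <- lowerTriangle(models[["5"]])
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    resp <- new("RSM", matrix = rsmFromTriangle(tri5 + rnorm(78, 0, 0.15)),
                kind = "one-minus-absdiff", labels = as.character(1:13))
    # one-minus-absdiff kind tolerates the perturbed diagonal-free triangle
    f <- fitCategoricalModels(resp, models, ac)
    if (f$bestModel == 5L) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("permutation p values hit the estimator floor for perfect structure", {
  models <- fixtureModels()
  ac <- fixtureAcoustic()
  res <- permutationTestIndividual(models[["5"]], models, ac, nIter = 300,
                                   seed = 5)
  expect_equal(res$p, 1 / 301)
  expect_equal(res$bestModel, 5L)
  expect_length(res$null$values, 300)
})

test_that("permutation p is invariant to order-preserving transforms", {
  models <- fixtureModels()
  ac <- fixtureAcoustic()
  set.seed(31)
  tri <- lowerTriangle(models[["4"]]) * 0.4 + runif(78, 0, 0.2)
  mk <- function(v) new("RSM", matrix = rsmFromTriangle(v),
                        kind = "one-minus-absdiff",
                        labels = as.character(1:13))
  p1 <- permutationTestIndividual(mk(tri), models, ac, nIter = 200, seed = 9)
  p2 <- permutationTestIndividual(mk(exp(2 * tri)), models, ac, nIter = 200,
                                  seed = 9)
  expect_equal(p1$p, p2$p)
  expect_equal(p1$observed, p2$observed)
})

test_that("group statistic is exactly the mean of individual statistics", {
  models <- fixtureModels()
  ac <- fixtureAcoustic()
  set.seed(41)
  resps <- lapply(1:4, function(i) {
    tri <- lowerTriangle(models[["5"]]) + rnorm(78, 0, 0.3)
    new("RSM", matrix = rsmFromTriangle(tri), kind = "one-minus-absdiff",
        labels = as.character(1:13))
  })
  grp <- permutationTestGroup(resps, models, ac, nIter = 100, seed = 3)
  indiv <- vapply(resps, function(r)
    fitCategoricalModels(r, models, ac)$bestRho, numeric(1))
  expect_equal(grp$observed, mean(indiv))
  expect_equal(grp$perParticipant$bestRho, indiv)

  # single participant reduces to the individual statistic
  one <- permutationTestGroup(resps[1], models, ac, nIter = 50, seed = 3)
  expect_equal(one$observed, indiv[1])
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroniCorrect(0.0001, 10), 0.001)
  expect_equal(bonferroniCorrect(0.2, 10), 1)
  expect_equal(bonferroniCorrect(0.03, 1), 0.03)
})

test_that("bootstrap median CIs are degenerate, reproducible and calibrated", {
  allsame <- bootstrapMedianCI(rep(0.56, 6), nBoot = 100, seed = 1)
  expect_equal(c(allsame$ciLow, allsame$ciHigh), c(0.56, 0.56))

  a <- bootstrapMedianCI(1:5, nBoot = 500, seed = 77)
  b <- bootstrapMedianCI(1:5, nBoot = 500, seed = 77)
  expect_equal(a, b)

  # coverage near nominal for 18 draws of a known distribution
  set.seed(55)
  trueMed <- 0.56
  cover <- mean(replicate(200, {
    v <- rnorm(18, trueMed, 0.02)
    ci <- bootstrapMedianCI(v, nBoot = 300, seed = sample.int(1e6, 1))
    ci$ciLow <= trueMed && trueMed <= ci$ciHigh
  }))
  expect_gte(cover, 0.85)
  expect_lte(cover, 0.99)
})

test_that("RSM comparisons recover identity and reject the covariate", {
  ac <- fixtureAcoustic()
  set.seed(61)
  tri <- runif(78)
  mk <- function(v) new("RSM", matrix = rsmFromTriangle(v),
                        kind = "one-minus-absdiff",
                        labels = as.character(1:13))
  a <- mk(tri)
  same <- compareRSMs(a, mk(tri), ac, nIter = 100, seed = 2)
  expect_equal(same$rho, 1)
  expect_equal(same$p, 1 / 101)

  self <- compareRSMs(mk(lowerTriangle(ac) + rnorm(78, 0, 1e-4)), mk(tri),
                      ac, nIter = 50, seed = 2)
  expect_lt(abs(self$rho), 0.3)

  # group variant averages per-participant rhos exactly
  asr <- lapply(1:3, function(i) mk(runif(78)))
  bsr <- lapply(1:3, function(i) mk(runif(78)))
  grp <- compareRSMsGroup(asr, bsr, ac, nIter = 50, seed = 4)
  indiv <- vapply(1:3, function(i)
    spearmanPartial(lowerTriangle(asr[[i]]), lowerTriangle(bsr[[i]]),
                    lowerTriangle(ac)), numeric(1))
  expect_equal(grp$rho, mean(indiv))
})

test_that("independent-noise RSM comparisons have calibrated type-I error", {
  ac <- fixtureAcoustic()
  mk <- function(v) new("RSM", matrix = rsmFromTriangle(v),
                        kind = "one-minus-absdiff",
                        labels = as.character(1:13))
  set.seed(71)
  rej <- mean(replicate(120, {
    compareRSMs(mk(runif(78)), mk(runif(78)), ac, nIter = 150)$p < 0.05
  }))
  expect_gte(rej, 0.01)
  expect_lte(rej, 0.12)
})

test_that("profile similarity uses Fisher transforms with a hand oracle", {
  p1 <- seq(0.1, 0.55, length.out = 10)
  # perfectly (anti)correlated profiles also trigger the clipping warning
  # when the resulting r = +/-1 is Fisher-transformed
  expect_warning(same <- modelProfileSimilarity(p1, p1), "clipped")
  expect_equal(same$r, 1)
  expect_warning(anti <- modelProfileSimilarity(p1, -p1), "clipped")
  expect_equal(anti$r, -1)

  rs <- c(0.9, 0.7, 0.8)
  z <- atanh(rs)
  res <- profileSimilarityGroupTest(rs)
  expect_equal(res$t, mean(z) / (sd(z) / sqrt(3)))
  expect_equal(res$df, 2)
  expect_warning(modelProfileSimilarity(c(1, 0.5, 0.2), c(0.9, 0.4, 0.1)),
                 "clipped")
})

test_that("t tests match stats::t.test and handle degenerate input", {
  a <- c(5.1, 4.9, 5.3, 5.0, 5.2)
  res <- tTests(a)
  ref <- t.test(a)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  expect_equal(res$df, 4)

  b <- a + 0.2
  paired <- tTests(b, a)
  expect_equal(paired$t, Inf)
  expect_equal(paired$p, 0)
  expect_message(same <- tTests(a, a), "convention")
  expect_equal(same$p, 1)
  expect_error(tTests(1), "at least 2")
})
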