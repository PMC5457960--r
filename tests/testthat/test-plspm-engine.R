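# engine: standardization, fitting, paths, quality indices

test_that("standardizeColumns matches the n-1 formula and is idempotent", {
  expect_equal(drop(standardizeColumns(cbind(a = c(1, 2, 3)))),
               c(-1, 0, 1), ignore_attr = TRUE)
  # hand-computed: mean 30, var (400+100+100+400)/3, sd = sqrt(1000/3)
  x <- c(10, 20, 40, 50)
  expect_equal(drop(standardizeColumns(cbind(v = x))),
               (x - 30) / sqrt(1000 / 3), ignore_attr = TRUE)
  z <- standardizeColumns(cbind(v = rnorm(20)))
  expect_lt(max(abs(standardizeColumns(z) - z)), 1e-12)
  expect_error(standardizeColumns(cbind(ok = 1:5, flat = rep(2, 5))),
               "flat")
})

test_that("two identical single-MV blocks give path 1 and R2 1", {
  m <- twoLVModel()
  x <- rnorm(30)
  fit <- plsFit(cbind(x = x, y = x), m$blocks, m$inner)
  expect_equal(unname(pathCoefficients(fit)$Y[["X"]]), 1, tolerance = 1e-10)
  expect_equal(unname(rSquared(fit)[["Y"]]), 1, tolerance = 1e-10)
})

test_that("degenerate two-LV model returns the sample Pearson r, all schemes", {
  set.seed(20240915)
  m <- twoLVModel()
  for (rho in c(0.8, -0.5)) {
    x <- rnorm(500)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(500)
    r <- cor(x, y)
    for (sch in c("centroid", "factorial", "path")) {
      fit <- plsFit(cbind(x = x, y = y), m$blocks, m$inner, scheme = sch)
      expect_equal(unname(pathCoefficients(fit)$Y[["X"]]), r,
                   tolerance = 1e-10)
      expect_equal(unname(rSquared(fit)[["Y"]]), r^2, tolerance = 1e-10)
    }
  }
})

test_that("fitted results satisfy the score and index identities", {
  specs <- list(sfaLatentBenchmark(n = 120, seed = 21),
                sfaLatentBenchmark(n = 80, seed = 22, sinkR2 = NULL))
  for (spec in specs) {
    sim <- simulateLatent(spec)
    for (sch in c("centroid", "factorial", "path")) {
      fit <- plsFit(sim$data, benchmarkBlocks(spec), spec@inner,
                    scheme = sch)
      sc <- lvScores(fit)
      expect_lt(max(abs(colMeans(sc))), 1e-10)
      expect_lt(max(abs(apply(sc, 2, var) - 1)), 1e-10)
      for (lv in names(mvLoadings(fit))) {
        expect_lt(max(abs(communalities(fit)[[lv]] -
                            mvLoadings(fit)[[lv]]^2)), 1e-12)
        own <- if (lv %in% names(rSquared(fit)))
          rSquared(fit)[[lv]] else 0
        expect_lt(max(abs(redundancies(fit)[[lv]] -
                            communalities(fit)[[lv]] * own)), 1e-12)
      }
      expect_equal(diag(lvCorrelations(fit)), rep(1, 4),
                   ignore_attr = TRUE)
      # GoF identity under the selected variant
      multi <- vapply(fit@blocks, function(b) length(b@mvNames) > 1, TRUE)
      expect_equal(gofValue(fit),
                   sqrt(mean(unlist(communalities(fit)[multi])) *
                          mean(rSquared(fit))),
                   tolerance = 1e-12)
    }
  }
})

test_that("the SFA model reports R2 exactly for the two endogenous LVs", {
  d <- simulateSFAData(n = 60, seed = 5)
  fit <- fitSFA(d)
  expect_setequal(names(rSquared(fit)), c("LV_overall", "LV_setback"))
  expect_setequal(names(pathCoefficients(fit)),
                  c("LV_overall", "LV_setback"))
})

test_that("row permutation leaves results unchanged; MV order permutes outputs", {
  spec <- sfaLatentBenchmark(n = 90, seed = 31)
  sim <- simulateLatent(spec)
  blocks <- benchmarkBlocks(spec)
  fit <- plsFit(sim$data, blocks, spec@inner)
  perm <- sample(nrow(sim$data))
  fit2 <- plsFit(sim$data[perm, ], blocks, spec@inner)
  expect_lt(max(abs(unlist(outerWeights(fit2)) -
                      unlist(outerWeights(fit)))), 1e-12)
  expect_lt(max(abs(unlist(pathCoefficients(fit2)) -
                      unlist(pathCoefficients(fit)))), 1e-12)
  expect_lt(max(abs(lvScores(fit2)[order(perm), ] - lvScores(fit))), 1e-12)
  # reorder the MVs of the overall block
  blocks2 <- blocks
  blocks2[[2]] <- blockSpec("LV_overall", rev(blocks[[2]]@mvNames),
                            "formative")
  fit3 <- plsFit(sim$data, blocks2, spec@inner)
  expect_equal(outerWeights(fit3)$LV_overall,
               rev(outerWeights(fit)$LV_overall), tolerance = 1e-12)
  expect_lt(max(abs(unlist(pathCoefficients(fit3)) -
                      unlist(pathCoefficients(fit)))), 1e-12)
})

test_that("negating an MV column only flips its weight/loading signs", {
  spec <- sfaLatentBenchmark(n = 90, seed = 41)
  sim <- simulateLatent(spec)
  blocks <- benchmarkBlocks(spec)
  # the flipped column changes the all-ones starting point, so agreement
  # is limited by the convergence tolerance
  fit <- plsFit(sim$data, blocks, spec@inner, tol = 1e-10)
  d2 <- sim$data
  d2[, "ov_2"] <- -d2[, "ov_2"]
  fit2 <- plsFit(d2, blocks, spec@inner, tol = 1e-10)
  w1 <- outerWeights(fit)$LV_overall
  w2 <- outerWeights(fit2)$LV_overall
  expect_equal(unname(w2[["ov_2"]]), -unname(w1[["ov_2"]]),
               tolerance = 1e-7)
  expect_equal(w2[c("ov_1", "ov_3")], w1[c("ov_1", "ov_3")],
               tolerance = 1e-7)
  expect_lt(max(abs(unlist(pathCoefficients(fit2)) -
                      unlist(pathCoefficients(fit)))), 1e-7)
})

test_that("sign canonicalization points the dominant loading positive", {
  spec <- sfaLatentBenchmark(n = 200, seed = 51)
  sim <- simulateLatent(spec)
  fit <- plsFit(sim$data, benchmarkBlocks(spec), spec@inner)
  for (lv in names(mvLoadings(fit))) {
    l <- mvLoadings(fit)[[lv]]
    expect_gt(l[which.max(abs(l))], 0)
  }
  expect_true(all(orientation(fit) %in% c(-1, 1)))
})

test_that("the three schemes agree on well-separated reflective data", {
  m <- threeLVReflective(n = 1000, seed = 99)
  paths <- sapply(c("centroid", "factorial", "path"), function(sch) {
    fit <- plsFit(m$data, m$blocks, m$inner, scheme = sch)
    unlist(pathCoefficients(fit))
  })
  expect_lt(max(abs(paths[, "centroid"] - paths[, "factorial"])), 0.02)
  expect_lt(max(abs(paths[, "centroid"] - paths[, "path"])), 0.02)
})

test_that("non-convergence is flagged and warned", {
  spec <- sfaLatentBenchmark(n = 60, seed = 61)
  sim <- simulateLatent(spec)
  expect_warning(
    fit <- plsFit(sim$data, benchmarkBlocks(spec), spec@inner,
                  tol = 1e-12, maxIter = 1L),
    "did not converge")
  expect_false(isConverged(fit))
})

test_that("degenerate inputs raise informative errors", {
  m <- twoLVModel()
  # formative block with perfectly collinear MVs
  x <- rnorm(30)
  blocks <- list(blockSpec("F", c("a", "b"), "formative"),
                 blockSpec("Y", "y", "reflective"))
  inner <- innerSpec(c("F", "Y"), list(c("F", "Y")))
  X <- cbind(a = x, b = 2 * x, y = x + rnorm(30))
  expect_error(plsFit(X, blocks, inner), "formative block 'F'")
  # more formative MVs than rows
  blocks5 <- list(blockSpec("F", letters[1:5], "formative"),
                  blockSpec("Y", "y", "reflective"))
  X5 <- cbind(matrix(rnorm(20), 4, 5, dimnames = list(NULL, letters[1:5])),
              y = rnorm(4))
  expect_error(
    plsFit(X5, blocks5, innerSpec(c("F", "Y"), list(c("F", "Y")))),
    "more rows")
  # mismatched LV sets
  expect_error(plsFit(cbind(x = rnorm(10), y = rnorm(10)),
                      m$blocks, innerSpec(c("X", "Z"), list(c("X", "Z")))),
               "coincide")
})

test_that("inner OLS matches an explicit normal-equation solve", {
  set.seed(7)
  n <- 200
  A <- rnorm(n); B <- 0.5 * A + rnorm(n); C <- rnorm(n)
  Y <- 0.4 * A - 0.3 * B + 0.2 * C + rnorm(n)
  sc <- standardizeColumns(cbind(A = A, B = B, C = C, Y = Y))
  inner <- innerSpec(c("A", "B", "C", "Y"),
                     list(c("A", "Y"), c("B", "Y"), c("C", "Y")))
  got <- plsPathCoefficients(sc, inner)
  # independent oracle: solve the normal equations on raw data directly
  Xp <- sc[, c("A", "B", "C")]
  beta <- solve(crossprod(Xp), crossprod(Xp, sc[, "Y"]))
  expect_equal(unname(got$coefficients$Y), unname(drop(beta)),
               tolerance = 1e-12)
  res <- sc[, "Y"] - Xp %*% beta
  expect_equal(unname(got$rSquared[["Y"]]),
               1 - sum(res^2) / sum(sc[, "Y"]^2), tolerance = 1e-12)
})

test_that("orthogonal predictors recover their marginal correlations", {
  set.seed(11)
  n <- 5000
  A <- rnorm(n); B <- rnorm(n)
  Y <- 0.5 * A + 0.3 * B + rnorm(n)
  sc <- standardizeColumns(cbind(A = A, B = B, Y = Y))
  inner <- innerSpec(c("A", "B", "Y"), list(c("A", "Y"), c("B", "Y")))
  got <- plsPathCoefficients(sc, inner)
  C <- cor(sc)
  bAB <- solve(C[c("A", "B"), c("A", "B")], C[c("A", "B"), "Y"])
  expect_equal(unname(got$coefficients$Y), unname(bAB), tolerance = 1e-12)
  # single-predecessor case: coefficient is exactly the correlation
  inner1 <- innerSpec(c("A", "B", "Y"), list(c("A", "Y"), c("A", "B")))
  got1 <- plsPathCoefficients(sc, inner1)
  expect_equal(unname(got1$coefficients$Y[["A"]]), C["A", "Y"],
               tolerance = 1e-12)
  expect_equal(unname(got1$rSquared[["Y"]]), C["A", "Y"]^2,
               tolerance = 1e-12)
})

test_that("collinear predecessor scores raise an error naming the LVs", {
  x <- rnorm(50)
  sc <- cbind(A = x, B = x, Y = rnorm(50))
  sc <- standardizeColumns(sc)
  inner <- innerSpec(c("A", "B", "Y"), list(c("A", "Y"), c("B", "Y")))
  expect_error(plsPathCoefficients(sc, inner), "collinear")
})

test_that("olsFromCorrelation validates inputs and reports conditioning", {
  R <- diag(3)
  dimnames(R) <- list(c("a", "b", "y"), c("a", "b", "y"))
  R["a", "y"] <- R["y", "a"] <- 0.6
  R["b", "y"] <- R["y", "b"] <- 0.3
  got <- olsFromCorrelation(R, "y", c("a", "b"))
  expect_equal(got$coefficients, c(a = 0.6, b = 0.3))
  expect_equal(got$rSquared, 0.45)
  expect_equal(got$conditionNumber, 1)
  Rbad <- R; diag(Rbad)[1] <- 2
  expect_error(olsFromCorrelation(Rbad, "y", c("a", "b")), "diagonal")
  Rs <- R; Rs["a", "b"] <- Rs["b", "a"] <- 1
  expect_error(olsFromCorrelation(Rs, "y", c("a", "b")), "singular")
})

test_that("goodnessOfFit closed forms, variants and errors", {
  expect_equal(goodnessOfFit(rep(1, 5), rep(1, 2)), 1)
  expect_equal(goodnessOfFit(rep(0.25, 4), rep(1, 2)), 0.5)
  comm <- list(A = c(0.9, 0.8), B = 1)
  expect_equal(goodnessOfFit(comm, 0.5, variant = "multi_mv_blocks"),
               sqrt(0.85 * 0.5))
  expect_equal(goodnessOfFit(comm, 0.5, variant = "all_mvs"),
               sqrt(0.9 * 0.5))
  expect_error(goodnessOfFit(numeric(0), 0.5), "non-empty")
  expect_error(goodnessOfFit(c(0.5, 1.2), 0.5), "0, 1")
})

test_that("lvCorrelationMatrix is symmetric, unit-diagonal and labelled", {
  set.seed(3)
  sc <- standardizeColumns(cbind(P = rnorm(10000), Q = rnorm(10000)))
  C <- lvCorrelationMatrix(sc)
  expect_identical(colnames(C), c("P", "Q"))
  expect_equal(diag(C), c(P = 1, Q = 1))
  expect_lt(max(abs(C - t(C))), 1e-12)
  expect_lt(abs(C["P", "Q"]), 0.05)   # independent columns at n = 1e4
})
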