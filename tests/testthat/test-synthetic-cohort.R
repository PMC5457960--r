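# generators: determinism, moment fidelity, recovery, round trips

test_that("simulateLatent is deterministic and leaves the RNG untouched", {
  spec <- sfaLatentBenchmark(n = 50, seed = 7)
  set.seed(123); before <- rnorm(1)
  a <- simulateLatent(spec)
  b <- simulateLatent(spec)
  expect_identical(a$data, b$data)
  expect_identical(a$truth$paths, b$truth$paths)
  set.seed(123)
  expect_identical(rnorm(1), before)
})

test_that("noiseless generation is refit exactly (in-sample oracle)", {
  blocks <- list(
    list(lvName = "A", mvNames = c("a1", "a2"), mode = "reflective",
         lambda = c(1, 1)),
    list(lvName = "B", mvNames = "b1", mode = "reflective", lambda = 1),
    list(lvName = "Y", mvNames = "y1", mode = "reflective", lambda = 1))
  inner <- innerSpec(c("A", "B", "Y"), list(c("A", "Y"), c("B", "Y")))
  spec <- latentSimSpec(blocks, inner,
                        c("A->Y" = 0.6, "B->Y" = 0.3),
                        residualSD = c(Y = 0), n = 400, seed = 3)
  sim <- simulateLatent(spec)
  fit <- plsFit(sim$data,
                list(blockSpec("A", c("a1", "a2"), "reflective"),
                     blockSpec("B", "b1", "reflective"),
                     blockSpec("Y", "y1", "reflective")), inner)
  expect_equal(unname(rSquared(fit)[["Y"]]), 1, tolerance = 1e-6)
  # oracle: regression on the realized (sample-standardized) latents
  sc <- standardizeColumns(sim$truth$lvScores)
  oracle <- plsPathCoefficients(sc, inner)
  expect_equal(pathCoefficients(fit)$Y, oracle$coefficients$Y,
               tolerance = 1e-6)
})

test_that("a strong single path is recovered at n = 2000", {
  # six indicators per block keep composite attenuation at lambda = 0.9
  # well inside the recovery tolerance
  xm <- paste0("x", 1:6); ym <- paste0("y", 1:6)
  blocks <- list(
    list(lvName = "X", mvNames = xm, mode = "reflective",
         lambda = rep(0.9, 6)),
    list(lvName = "Y", mvNames = ym, mode = "reflective",
         lambda = rep(0.9, 6)))
  engBlocks <- list(blockSpec("X", xm, "reflective"),
                    blockSpec("Y", ym, "reflective"))
  inner <- innerSpec(c("X", "Y"), list(c("X", "Y")))
  spec <- latentSimSpec(blocks, inner, c("X->Y" = 0.8), n = 2000, seed = 19)
  fit <- plsFit(simulateLatent(spec)$data, engBlocks, inner)
  expect_lt(abs(pathCoefficients(fit)$Y[["X"]] - 0.8), 0.05)
  # null path: estimate stays near zero
  spec0 <- latentSimSpec(blocks, inner, c("X->Y" = 0), n = 2000, seed = 20)
  fit0 <- plsFit(simulateLatent(spec0)$data, engBlocks, inner)
  expect_lt(abs(pathCoefficients(fit0)$Y[["X"]]), 0.1)
})

test_that("paths implying variance above one are rejected", {
  blocks <- list(
    list(lvName = "X", mvNames = "x1", mode = "reflective", lambda = 1),
    list(lvName = "Y", mvNames = "y1", mode = "reflective", lambda = 1))
  inner <- innerSpec(c("X", "Y"), list(c("X", "Y")))
  spec <- latentSimSpec(blocks, inner, c("X->Y" = 1.2), n = 50, seed = 1)
  expect_error(simulateLatent(spec), "variance")
})

test_that("recoveryExperiment reports near-zero error for noiseless specs", {
  blocks <- list(
    list(lvName = "X", mvNames = "x1", mode = "reflective", lambda = 1),
    list(lvName = "Y", mvNames = "y1", mode = "reflective", lambda = 1))
  inner <- innerSpec(c("X", "Y"), list(c("X", "Y")))
  spec <- latentSimSpec(blocks, inner, c("X->Y" = 0.7),
                        residualSD = c(Y = 0), n = 100, seed = 1)
  res <- recoveryExperiment(spec, reps = 5, seed = 50)
  expect_equal(res$truth, 1)   # deterministic relation standardizes to 1
  expect_lt(max(res$rmse), 1e-6)
  expect_identical(attr(res, "nonConverged"), 0L)
})

test_that("recovery RMSE shrinks as the sample grows", {
  rmse <- sapply(c(250, 1000, 4000), function(n) {
    spec <- sfaLatentBenchmark(n = n, seed = 1)
    res <- recoveryExperiment(spec, reps = 8, seed = 400, scheme = "path")
    max(res$rmse)
  })
  expect_true(all(diff(rmse) < 0))
})

test_that("cohort moments and correlations are calibrated", {
  # zero-SD roster: every patient sits at the mean vector
  sp0 <- cohortSpec(n = 5, seed = 2)
  sp0@roster[, c("sd_T0", "sd_T1", "sd_T2")] <- 0
  co0 <- simulateCohort(sp0)
  expect_equal(co0$B_s_0, rep(66.6, 5))
  expect_equal(co0$VD_2, rep(8.2, 5))
  expect_equal(co0$B_s_20, rep(59.0 - 66.6, 5), tolerance = 1e-12)
  expect_equal(co0$VD_10, rep(9.9 - 11.8, 5), tolerance = 1e-12)

  # large-sample moment fidelity (3-sigma bounds at n = 1e4)
  co <- simulateCohort(cohortSpec(n = 10000, seed = 3))
  expect_lt(abs(mean(co$VD_0) - 11.8), 3 * 3.3 / 100)
  expect_lt(abs(mean(co$Me_f_1) - 94.3), 3 * 6.6 / 100)
  expect_lt(abs(sd(co$B_s_0) - 7.0), 0.25)
  # configured distal-segment collinearity
  expect_lt(abs(cor(co$B_s_0, co$Me_s_0) - 0.9), 0.02)
  # cross-block background correlation
  expect_lt(abs(cor(co$A_s_0, co$Cd_s_0) - 0.3), 0.04)
  # cross-timepoint correlation of one variable
  expect_lt(abs(cor(co$B_s_0, co$B_s_1) - 0.8), 0.02)
  # increments are exact differences
  expect_equal(co$B_s_10, co$B_s_1 - co$B_s_0, tolerance = 1e-12)
  expect_true(all(co[, c("VD_0", "VD_1", "VD_2")] >= 0))
})

test_that("cohort generation is reproducible under its seed", {
  a <- simulateCohort(cohortSpec(n = 25, seed = 11))
  b <- simulateCohort(cohortSpec(n = 25, seed = 11))
  expect_identical(a, b)
  c2 <- simulateCohort(cohortSpec(n = 25, seed = 12))
  expect_false(identical(a$B_s_0, c2$B_s_0))
})

test_that("landmark synthesis inverts measurement derivation", {
  co <- simulateCohort(cohortSpec(n = 3, seed = 21))
  for (i in seq_len(nrow(co))) {
    lms <- synthesizeLandmarks(co[i, , drop = FALSE])
    back <- deriveMeasurements(lms)
    common <- setdiff(intersect(names(co), names(back)), "patient_id")
    expect_gt(length(common), 80L)
    expect_lt(max(abs(unlist(co[i, common]) - unlist(back[1, common]))),
              1e-9)
  }
})

test_that("a zero measurement row collapses landmarks onto Sella", {
  row <- data.frame(patient_id = "z", B_s_0 = 0, B_f_0 = 0,
                    Me_s_0 = 0, Me_f_0 = 0)
  lms <- synthesizeLandmarks(row)
  at0 <- lms[lms$landmark %in% c("B", "Me") & lms$timepoint == "T0", ]
  expect_true(all(abs(at0$x_mm) < 1e-12 & abs(at0$y_mm) < 1e-12))
})

test_that("measurements are invariant to the synthesis frame", {
  co <- simulateCohort(cohortSpec(n = 1, seed = 31))
  th <- pi / 4
  fr <- buildFrame(Po = c(cos(th + pi), sin(th + pi)) * 40,
                   Or = c(cos(th), sin(th)) * 40, S = c(5, -3),
                   inferior = c(5, -3) + c(sin(th), -cos(th)) * 50)
  a <- deriveMeasurements(synthesizeLandmarks(co))
  b <- deriveMeasurements(synthesizeLandmarks(co, frame = fr))
  common <- setdiff(names(a), "patient_id")
  expect_lt(max(abs(unlist(a[common]) - unlist(b[common]))), 1e-9)
})
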