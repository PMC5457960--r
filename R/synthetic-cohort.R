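## Synthetic data: latent-structured datasets with known truth for
## parameter recovery, and moment-calibrated cephalometric cohorts with
## landmark-level round-trip support.

## run code under a seed without disturbing the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

## exchangeable correlation matrix
.exch <- function(p, rho) {
  m <- matrix(rho, p, p); diag(m) <- 1; m
}

## clip eigenvalues to make a correlation matrix positive definite
.nearPDCorr <- function(C, eps = 1e-8) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) > eps) return(list(C = C, repaired = FALSE))
  v <- pmax(e$values, eps)
  M <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  diag(M) <- 1
  dimnames(M) <- dimnames(C)
  list(C = M, repaired = TRUE)
}

## ---------------------------------------------------------------------------
## Latent-structured simulation
## ---------------------------------------------------------------------------

#' Simulate data from a known PLS path model
#'
#' Exogenous LVs are generated first (standard normal for reflective
#' blocks; for formative blocks the MVs are drawn jointly with
#' intra-block correlation `rho` and the LV defined as the
#' population-standardized weighted composite).  Each endogenous LV is
#' the path-weighted sum of its predecessors plus an independent normal
#' residual, rescaled to unit population variance; its reflective MVs
#' are `lambda * LV + sqrt(1 - lambda^2) * noise`, and its formative MVs
#' are drawn from the conditional MV distribution given the composite,
#' so the weighted composite reproduces the LV exactly.
#'
#' The truth record stores both the population standardized paths
#' implied by the generating covariance (the recovery targets) and the
#' realized latent scores, from which in-sample "oracle" paths can be
#' computed for noiseless checks.
#'
#' @param spec a [LatentSimSpec-class].
#' @return List with `data` (n x MVs matrix) and `truth` (list with
#'   `paths`, `lvCov`, `lvScores`, `seed`).
#' @export
simulateLatent <- function(spec) {
  validObject(spec)
  .withSeed(spec@seed, {
    inner <- spec@inner
    lvs <- inner@lvNames
    blocks <- spec@blocks[match(lvs,
                                vapply(spec@blocks, `[[`, "", "lvName"))]
    names(blocks) <- lvs
    n <- spec@n
    topo <- .topoSort(lvs, inner@edges)
    S <- diag(length(lvs)); dimnames(S) <- list(lvs, lvs)
    eta <- matrix(NA_real_, n, length(lvs), dimnames = list(NULL, lvs))
    dat <- list()

    for (lv in topo) {
      b <- blocks[[lv]]
      p <- predecessorsOf(inner, lv)
      if (!length(p)) {                     # exogenous
        if (b$mode == "reflective") {
          y <- rnorm(n)
          for (k in seq_along(b$mvNames)) {
            lam <- b$lambda[k]
            dat[[b$mvNames[k]]] <- lam * y + sqrt(1 - lam^2) * rnorm(n)
          }
        } else {
          R <- .exch(length(b$mvNames), b$rho)
          Xb <- MASS::mvrnorm(n, mu = rep(0, ncol(R)), Sigma = R)
          a <- b$weights
          sa <- sqrt(drop(t(a) %*% R %*% a))
          y <- drop(Xb %*% a) / sa
          for (k in seq_along(b$mvNames)) dat[[b$mvNames[k]]] <- Xb[, k]
        }
        eta[, lv] <- y
        ## independent of everything generated so far: S entries stay 0
      } else {                              # endogenous
        beta <- spec@paths[paste0(p, "->", lv)]
        lin <- drop(eta[, p, drop = FALSE] %*% beta)
        v <- drop(t(beta) %*% S[p, p, drop = FALSE] %*% beta)
        sdres <- if (lv %in% names(spec@residualSD)) {
          spec@residualSD[[lv]]
        } else {
          if (v > 1 + 1e-12)
            stop(sprintf(
              "paths into '%s' imply variance %.3f > 1; give residualSD",
              lv, v))
          sqrt(max(0, 1 - v))
        }
        tot <- v + sdres^2
        if (tot <= 0)
          stop(sprintf("zero total variance for endogenous LV '%s'", lv))
        y <- (lin + sdres * rnorm(n)) / sqrt(tot)
        ## propagate population covariance
        for (k in lvs)
          S[lv, k] <- S[k, lv] <-
            if (k == lv) 1 else
              drop(S[k, p, drop = FALSE] %*% beta) / sqrt(tot)
        eta[, lv] <- y
        if (b$mode == "reflective") {
          for (k in seq_along(b$mvNames)) {
            lam <- b$lambda[k]
            dat[[b$mvNames[k]]] <- lam * y + sqrt(1 - lam^2) * rnorm(n)
          }
        } else {
          R <- .exch(length(b$mvNames), b$rho)
          a <- b$weights
          sa <- sqrt(drop(t(a) %*% R %*% a))
          m <- drop(R %*% a) / sa            # Cov(X, composite)
          Cond <- R - tcrossprod(m)          # PSD, rank p-1
          ec <- eigen(Cond, symmetric = TRUE)
          hl <- ec$vectors %*% (sqrt(pmax(ec$values, 0)) * t(ec$vectors))
          Z <- matrix(rnorm(n * ncol(R)), n) %*% hl
          Xb <- outer(y, m) + Z
          for (k in seq_along(b$mvNames)) dat[[b$mvNames[k]]] <- Xb[, k]
        }
      }
    }

    endo <- endogenousLVs(inner)
    truthPaths <- lapply(endo, function(lv) {
      p <- predecessorsOf(inner, lv)
      setNames(drop(solve(S[p, p, drop = FALSE], S[p, lv])), p)
    })
    names(truthPaths) <- endo
    X <- do.call(cbind, dat)
    colnames(X) <- names(dat)
    rownames(X) <- sprintf("sim%04d", seq_len(n))
    list(data = X,
         truth = list(paths = truthPaths, lvCov = S, lvScores = eta,
                      seed = spec@seed))
  })
}

#' Parameter-recovery experiment
#'
#' Draws `reps` independent datasets from a latent specification (seeds
#' `seed + 1, ..., seed + reps`), refits the engine on each, and reports
#' per-path bias, RMSE and Monte-Carlo standard errors of the estimates
#' against the population standardized paths.  Replicates that fail to
#' converge are excluded and counted.
#'
#' @param spec a [LatentSimSpec-class]; its own seed is ignored.
#' @param reps number of replicates (at least 2).
#' @param seed base RNG seed.
#' @param scheme inner weighting scheme for the refits.
#' @return data.frame with one row per inner path (`path`, `truth`,
#'   `meanEstimate`, `bias`, `rmse`, `mcse`, `nUsed`); attribute
#'   `"nonConverged"` counts excluded replicates.
#' @export
recoveryExperiment <- function(spec, reps, seed = 1L, scheme = "centroid") {
  stopifnot(reps >= 2L)
  engineBlocks <- lapply(spec@blocks, function(b)
    blockSpec(b$lvName, b$mvNames, b$mode))
  truth <- NULL
  ests <- list()
  bad <- 0L
  for (r in seq_len(reps)) {
    s2 <- spec
    s2@seed <- as.integer(seed + r)
    sim <- simulateLatent(s2)
    if (is.null(truth)) truth <- sim$truth$paths
    fit <- tryCatch(
      withCallingHandlers(
        plsFit(sim$data, engineBlocks, spec@inner, scheme = scheme),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(fit) || !isConverged(fit)) { bad <- bad + 1L; next }
    pc <- pathCoefficients(fit)
    est <- unlist(lapply(names(truth), function(lv)
      setNames(pc[[lv]][names(truth[[lv]])],
               paste0(names(truth[[lv]]), "->", lv))))
    ests[[length(ests) + 1L]] <- est
  }
  if (!length(ests)) stop("no replicate converged")
  E <- do.call(rbind, ests)
  tv <- unlist(lapply(names(truth), function(lv)
    setNames(truth[[lv]], paste0(names(truth[[lv]]), "->", lv))))
  tv <- tv[colnames(E)]
  out <- data.frame(
    path = colnames(E),
    truth = unname(tv),
    meanEstimate = colMeans(E),
    bias = colMeans(E) - unname(tv),
    rmse = sqrt(colMeans(sweep(E, 2L, tv)^2)),
    mcse = apply(E, 2L, sd) / sqrt(nrow(E)),
    nUsed = nrow(E), row.names = NULL)
  attr(out, "nonConverged") <- bad
  out
}

## ---------------------------------------------------------------------------
## Setback-model-shaped simulation (shared manifest variables)
## ---------------------------------------------------------------------------

#' Simulate data shaped like the setback path model
#'
#' Generates the six model columns with the study's qualitative sign
#' structure: the five predictor MVs are drawn jointly (B/Me setbacks
#' strongly collinear, the vertical dimension change negatively related
#' to them), the three formative composites are defined from the same
#' draw with the overall composite weighting `VD_10` negatively, the
#' sink LV is a path-weighted sum of the composites (positive
#' overall-to-setback path) plus noise, and `B_s_20` reflects the sink
#' exactly.  Because the overall block reuses the setback MVs, the
#' composite correlations mimic the near-collinearity of the published
#' LV correlation matrix.
#'
#' @param n sample size.
#' @param seed RNG seed.
#' @param betas named paths into the sink from `LV_10`, `LV_overall`,
#'   `LV_1`.
#' @param sigma residual SD of the sink before standardization.
#' @return n x 6 matrix with attribute `"truth"` (composite weights,
#'   latent scores, betas).
#' @export
simulateSFAData <- function(n = 40L, seed = 1L,
                            betas = c(LV_10 = -0.2, LV_overall = 0.9,
                                      LV_1 = 0.25),
                            sigma = 0.45) {
  stopifnot(all(c("LV_10", "LV_overall", "LV_1") %in% names(betas)))
  .withSeed(seed, {
    mvs <- c("B_s_10", "Me_s_10", "A_s_1", "Cp_f_1", "VD_10")
    R <- diag(5); dimnames(R) <- list(mvs, mvs)
    R["B_s_10", "Me_s_10"] <- 0.90
    R["A_s_1", "Cp_f_1"] <- 0.30
    R["B_s_10", "A_s_1"] <- R["B_s_10", "Cp_f_1"] <- 0.20
    R["Me_s_10", "A_s_1"] <- R["Me_s_10", "Cp_f_1"] <- 0.20
    R["VD_10", "B_s_10"] <- R["VD_10", "Me_s_10"] <- -0.30
    R["VD_10", "A_s_1"] <- R["VD_10", "Cp_f_1"] <- 0.10
    R[lower.tri(R)] <- t(R)[lower.tri(R)]
    R <- .nearPDCorr(R)$C
    X <- MASS::mvrnorm(n, mu = rep(0, 5), Sigma = R)
    colnames(X) <- mvs
    comp <- function(cols, a) {
      a <- setNames(a, cols)
      sa <- sqrt(drop(t(a) %*% R[cols, cols] %*% a))
      drop(X[, cols] %*% a) / sa
    }
    lv10 <- comp(c("B_s_10", "Me_s_10"), c(0.64, 0.37))
    lv1 <- comp(c("A_s_1", "Cp_f_1"), c(-0.71, 0.77))
    lvOv <- comp(mvs, c(0.54, 0.43, 0.12, 0.08, -0.20))
    lin <- betas[["LV_10"]] * lv10 + betas[["LV_overall"]] * lvOv +
      betas[["LV_1"]] * lv1
    sink <- lin + sigma * rnorm(n)
    sink <- (sink - mean(sink)) / sd(sink)
    out <- cbind(X, B_s_20 = sink)
    rownames(out) <- sprintf("sim%04d", seq_len(n))
    attr(out, "truth") <- list(
      betas = betas, sigma = sigma,
      lvScores = cbind(LV_10 = lv10, LV_overall = lvOv, LV_1 = lv1,
                       LV_setback = sink))
    out
  })
}

## ---------------------------------------------------------------------------
## Moment-calibrated cephalometric cohort
## ---------------------------------------------------------------------------

## published cohort moments: mean (SD) per variable at T0/T1/T2
.table2Roster <- function() {
  txt <- "variable mean_T0 sd_T0 mean_T1 sd_T1 mean_T2 sd_T2
A_s 62.5 4.4 63.0 4.5 62.6 4.8
PNS_s 20.0 3.1 20.3 3.1 20.8 3.1
B_s 66.6 7.0 58.2 6.7 59.0 7.3
Pog_s 68.3 7.5 61.1 7.4 62.0 7.9
Me_s 62.1 7.4 54.4 7.0 55.2 8.1
Cd_s -12.0 3.3 -11.2 3.4 -12.1 3.3
Cp_s 25.1 3.7 25.7 3.8 25.4 3.7
U1_s 69.3 5.0 69.1 5.2 68.8 5.6
U1r_s 58.3 4.5 58.9 4.8 58.8 5.1
L1_s 70.7 6.6 62.1 5.6 64.5 5.8
L1r_s 63.7 7.2 55.4 6.8 55.4 7.3
U6_s 43.3 4.2 43.5 4.7 42.9 4.9
L6_s 47.1 17.6 38.8 14.4 40.2 15.4
A_f 31.2 3.3 28.2 3.5 27.8 3.4
PNS_f 24.9 2.8 20.2 3.9 20.0 3.8
B_f 77.9 6.5 75.0 5.4 75.2 7.5
Pog_f 91.8 8.0 88.1 6.6 86.0 7.1
Me_f 98.3 8.1 94.3 6.6 92.6 7.3
Cd_f 2.6 2.0 3.4 2.4 2.5 2.5
Cp_f 9.8 4.8 11.3 4.6 8.6 4.7
U1_f 55.2 5.1 53.4 4.7 53.5 4.7
U1r_f 34.3 4.2 31.3 3.8 31.3 3.8
L1_f 55.6 5.2 52.4 4.3 51.1 4.7
L1r_f 74.8 6.1 71.5 5.1 70.3 5.5
U6_f 47.6 4.4 44.1 4.3 43.5 4.5
L6_f 54.0 18.6 50.7 17.3 48.8 16.6
VD 11.8 3.3 9.9 1.9 8.2 1.3"
  utils::read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
}

#' Create a cohort simulation specification
#'
#' Defaults reproduce the published cohort: the printed per-variable
#' means and SDs at the three timepoints, strong exchangeable
#' correlation (0.9) among the distal-segment variables (B, Pog, Me, L1,
#' L6, horizontal and vertical), a weaker background correlation (0.3)
#' between all other variable pairs, and correlation 0.8 between
#' timepoints of the same variable (the between-variable and
#' between-timepoint structures combine as a Kronecker product).
#'
#' @param n cohort size (default 40, the published sample size).
#' @param seed RNG seed.
#' @param roster variable roster (see [CohortSpec-class]); defaults to
#'   the published moments.
#' @param rhoWithin,rhoBetween,rhoTime correlation parameters.
#' @param distalBlock variables in the collinear distal-segment block.
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(n = 40L, seed = 1L, roster = .table2Roster(),
                       rhoWithin = 0.9, rhoBetween = 0.3, rhoTime = 0.8,
                       distalBlock = c("B_s", "B_f", "Pog_s", "Pog_f",
                                       "Me_s", "Me_f", "L1_s", "L1_f",
                                       "L6_s", "L6_f")) {
  new("CohortSpec", roster = roster,
      distalBlock = intersect(distalBlock, roster$variable),
      rhoWithin = rhoWithin, rhoBetween = rhoBetween, rhoTime = rhoTime,
      n = as.integer(n), seed = as.integer(seed))
}

#' Simulate a cephalometric cohort
#'
#' Draws the full variable-by-timepoint vector for each patient from a
#' single multivariate normal whose means/SDs follow the roster and
#' whose correlation is the Kronecker product of the between-variable
#' and between-timepoint structures (repaired by eigenvalue clipping at
#' 1e-8 if numerically non-PD; a message reports any repair).
#' Simulated occlusal vertical dimensions are truncated at 0.
#' Increment columns are exact differences of the drawn values.
#'
#' @param spec a [CohortSpec-class].
#' @return Wide measurement data.frame (one row per patient, column
#'   dialect as in [deriveMeasurements()]), with the specification in
#'   attribute `"spec"`.
#' @export
simulateCohort <- function(spec) {
  validObject(spec)
  ro <- spec@roster
  vars <- ro$variable
  p <- length(vars)
  Cvar <- matrix(spec@rhoBetween, p, p, dimnames = list(vars, vars))
  d <- vars %in% spec@distalBlock
  Cvar[d, d] <- spec@rhoWithin
  diag(Cvar) <- 1
  Ctime <- .exch(3L, spec@rhoTime)
  C <- kronecker(Cvar, Ctime)
  nm <- as.vector(t(outer(vars, c("_0", "_1", "_2"), paste0)))
  dimnames(C) <- list(nm, nm)
  rep <- .nearPDCorr(C)
  if (rep$repaired)
    message("cohort correlation repaired to positive definite (eigenvalue clipping at 1e-8)")
  C <- rep$C
  mu <- as.vector(t(as.matrix(ro[, c("mean_T0", "mean_T1", "mean_T2")])))
  sdv <- as.vector(t(as.matrix(ro[, c("sd_T0", "sd_T1", "sd_T2")])))
  Sigma <- C * tcrossprod(sdv)
  X <- .withSeed(spec@seed,
                 MASS::mvrnorm(spec@n, mu = mu, Sigma = Sigma))
  if (spec@n == 1L) X <- matrix(X, nrow = 1L)
  colnames(X) <- nm
  vd <- grep("^VD_", nm, value = TRUE)
  X[, vd] <- pmax(X[, vd], 0)
  out <- data.frame(patient_id = sprintf("pt%04d", seq_len(spec@n)),
                    X, check.names = FALSE)
  out <- addIncrements(out)
  attr(out, "spec") <- spec
  out
}

#' Reconstruct landmark coordinates from a measurement row
#'
#' Inverse of [deriveMeasurements()] for one patient: every base
#' quantity with both `_s` and `_f` values at a timepoint becomes a
#' landmark at `origin + s * fhAxis + f * sperpAxis`; Sella sits at the
#' frame origin with Porion and Orbitale placed on the frame's FH line;
#' the molar mesial contacts are placed so the occlusal vertical
#' dimension reproduces `VD_<t>` exactly.
#'
#' @param row single-row measurement data.frame.
#' @param frame target [ReferenceFrame-class] (default: axis-aligned at
#'   the origin).
#' @return Long-format landmark data.frame (`patient_id`, `timepoint`,
#'   `landmark`, `x_mm`, `y_mm`).
#' @export
synthesizeLandmarks <- function(row,
                                frame = buildFrame(c(-40, 0), c(40, 0),
                                                   c(0, 0))) {
  stopifnot(nrow(row) == 1L)
  pid <- as.character(row$patient_id)
  place <- function(s, f) frame@origin + s * frame@fhAxis + f * frame@sperpAxis
  recs <- list()
  addPt <- function(tp, lm, xy)
    recs[[length(recs) + 1L]] <<- data.frame(
      patient_id = pid, timepoint = tp, landmark = lm,
      x_mm = xy[1L], y_mm = xy[2L])
  for (tp in .TIMEPOINTS) {
    sfx <- .TP_SUFFIX[[tp]]
    addPt(tp, "S", frame@origin)
    addPt(tp, "Po", place(-40, 0))
    addPt(tp, "Or", place(40, 0))
    sCols <- grep(paste0("_s_", sfx, "$"), names(row), value = TRUE)
    for (sc in sCols) {
      base <- sub(paste0("_s_", sfx, "$"), "", sc)
      fc <- paste0(base, "_f_", sfx)
      if (!fc %in% names(row)) next
      addPt(tp, base, place(row[[sc]], row[[fc]]))
    }
    vc <- paste0("VD_", sfx)
    if (vc %in% names(row)) {
      u6s <- if (paste0("U6_s_", sfx) %in% names(row))
        row[[paste0("U6_s_", sfx)]] else 43
      addPt(tp, "U6mc", place(u6s, 45))
      addPt(tp, "L6mc", place(u6s, 45 + row[[vc]]))
    }
  }
  do.call(rbind, recs)
}
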